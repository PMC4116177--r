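# Seeded synthetic-data generators. Each generator is a pure function of
# its spec (seed included): the caller's RNG state is saved and restored,
# and identical specs give identical output.
#
# The synthetic complexes are geometric, not physical: pocket residues are
# small pseudo-residues planted at controlled minimum distances from the
# ligand, which is all that distance-cutoff pocket extraction depends on.

#' Generate a synthetic protein-ligand complex with known pocket geometry
#'
#' Places a compact ligand near the origin, then plants one pseudo-residue
#' per requested pocket distance such that the residue's nearest heavy atom
#' sits at exactly that distance (to 0.05 Angstrom) from the nearest ligand
#' atom. Far residues are placed beyond `cutoff + 2` Angstrom. The ground
#' truth (planted distance per residue) is returned with the model.
#'
#' @param pocket_distances Numeric vector of planted minimum distances
#'   (Angstrom), one pocket residue each.
#' @param n_far_residues Number of residues planted beyond `cutoff + 2`.
#' @param ligand_atoms Number of ligand heavy atoms (default 12).
#' @param cutoff Reference cutoff used to position far residues (default 6).
#' @param seed Integer seed.
#' @param atoms_per_residue Range of heavy atoms per pseudo-residue (1-5).
#' @return List with `model` (a `StructureModel`), `pdb` (PDB text lines),
#'   `truth` (data frame `chain`, `resno`, `planted_distance`,
#'   `is_pocket` at the given cutoff), and `ligand_code` ("LIG").
#' @export
make_complex <- function(pocket_distances, n_far_residues = 10L,
                         ligand_atoms = 12L, cutoff = 6.0, seed = 1L,
                         atoms_per_residue = c(1L, 5L)) {
  stopifnot(all(pocket_distances > 0), n_far_residues >= 0,
            ligand_atoms >= 1, cutoff > 0)
  n_res <- length(pocket_distances) + n_far_residues
  if (n_res > 400L)
    stop("spec not geometrically satisfiable: too many residues (",
         n_res, ")")
  with_seed(seed, {
    # compact ligand: atoms on a jittered grid within ~2.5 A of origin
    lig <- matrix(stats::runif(3 * ligand_atoms, -2.5, 2.5), ncol = 3)
    far_dist <- stats::runif(n_far_residues, cutoff + 2 + 0.5, cutoff + 2 + 12)
    dists <- c(pocket_distances, far_dist)
    is_pocket_truth <- c(pocket_distances <= cutoff,
                         rep(FALSE, n_far_residues))

    dirs <- random_directions(n_res)
    atoms <- list()
    serial <- 0L
    for (j in seq_len(ligand_atoms)) {
      serial <- serial + 1L
      atoms[[serial]] <- atom_row(serial, paste0("C", j), "LIG", "L", 900L,
                                  lig[j, ], TRUE)
    }
    truth <- data.frame(chain = character(), resno = integer(),
                        planted_distance = numeric(),
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_res)) {
      u <- dirs[i, ]
      anchor <- point_at_distance(lig, u, dists[i])
      n_at <- sample(seq(atoms_per_residue[1], atoms_per_residue[2]), 1L)
      resno <- 100L + i
      for (k in seq_len(n_at)) {
        serial <- serial + 1L
        # extra atoms strictly farther out along the same direction
        pos <- anchor + (k - 1L) * 1.5 * u
        atoms[[serial]] <- atom_row(serial, paste0("C", k), "ALA", "A",
                                    resno, pos, FALSE)
      }
      truth <- rbind(truth, data.frame(chain = "A", resno = resno,
                                       planted_distance = dists[i],
                                       stringsAsFactors = FALSE))
    }
    at <- do.call(rbind, atoms)
    rownames(at) <- NULL
    model <- structure(list(id = sprintf("synthetic_%d", seed),
                            model_index = 1L, atoms = at),
                       class = "StructureModel")
    truth$is_pocket <- truth$planted_distance <= cutoff
    list(model = model, pdb = write_pdb(model), truth = truth,
         ligand_code = "LIG")
  })
}

atom_row <- function(serial, name, resname, chain, resno, xyz, het) {
  data.frame(serial = serial, name = name, altloc = "", resname = resname,
             chain = chain, resno = as.integer(resno), icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
             element = "C", is_hetero = het, is_hydrogen = FALSE,
             stringsAsFactors = FALSE)
}

# n approximately separated random unit vectors (rejection on close pairs
# when few residues; falls back to plain random for large n)
random_directions <- function(n) {
  out <- matrix(0, n, 3)
  i <- 0L; tries <- 0L
  while (i < n) {
    v <- stats::rnorm(3)
    v <- v / vnorm(v)
    tries <- tries + 1L
    ok <- TRUE
    if (i > 0L && tries < 50L * n) {
      cosmax <- max(out[seq_len(i), , drop = FALSE] %*% v)
      ok <- cosmax < cos(pi / 18)  # at least 10 degrees apart when possible
    }
    if (ok) {
      i <- i + 1L
      out[i, ] <- v
    }
  }
  out
}

# Point at exact minimum distance d from the ligand atom set along outward
# direction u: anchor on the atom with maximal projection onto u. For any
# other atom a_j, |a* + d u - a_j|^2 = |a* - a_j|^2 +
# 2 d (a* - a_j).u + d^2 >= d^2 since (a* - a_j).u >= 0, so the minimum
# distance is achieved at a* and equals d exactly.
point_at_distance <- function(lig, u, d) {
  proj <- as.numeric(lig %*% u)
  a_star <- lig[which.max(proj), ]
  a_star + d * u
}

#' Generate an alignment with prescribed per-column residue counts
#'
#' Builds an `n_sequences`-row alignment whose columns at the specified
#' reference positions contain exactly the requested residue counts; all
#' other columns are fully conserved (every row carries the reference
#' residue). Row order of the variant residues is shuffled by the seed.
#' The reference sequence is row 1 and is included in the counts; its
#' residue at a specified column is `reference_residue` (default the modal
#' residue), which must have a positive count there.
#'
#' @param n_sequences Total number of rows, reference included.
#' @param column_specs Named list: names are reference positions, values
#'   are named integer vectors of residue counts summing to `n_sequences`,
#'   e.g. `list("421" = c(M = 170, L = 5, I = 3, F = 22))`.
#' @param reference_start First reference position (default 303, an
#'   ER-alpha LBD-style register).
#' @param length Number of columns (default spans the specified positions
#'   plus 10, minimum 30).
#' @param reference_residues Optional named character vector giving the
#'   reference row's residue at specified positions (default: modal).
#' @param seed Integer seed.
#' @param reference_name Name for row 1 (default "reference").
#' @return An `Alignment`.
#' @export
make_alignment <- function(n_sequences, column_specs = list(),
                           reference_start = 303L, length = NULL,
                           reference_residues = NULL, seed = 1L,
                           reference_name = "reference") {
  stopifnot(n_sequences >= 2L)
  pos <- as.integer(names(column_specs))
  if (length(column_specs) && anyNA(pos))
    stop("column_specs must be named by integer reference positions")
  if (is.null(length)) {
    length <- max(30L, if (base::length(pos)) max(pos) - reference_start + 11L
                  else 30L)
  }
  if (base::length(pos) && any(pos < reference_start |
                                 pos > reference_start + length - 1L))
    stop("specified positions fall outside the alignment")

  with_seed(seed, {
    # conserved background: a deterministic (seeded) residue per column
    background <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                         length, replace = TRUE)
    mat <- matrix(rep(background, each = n_sequences), nrow = n_sequences)
    for (i in seq_along(column_specs)) {
      counts <- column_specs[[i]]
      if (sum(counts) != n_sequences)
        stop("counts at position ", pos[i], " sum to ", sum(counts),
             ", expected n_sequences = ", n_sequences)
      ref_res <- if (!is.null(reference_residues) &&
                     as.character(pos[i]) %in% names(reference_residues))
        reference_residues[[as.character(pos[i])]]
      else names(counts)[which.max(counts)]
      if (!ref_res %in% names(counts) || counts[[ref_res]] < 1L)
        stop("reference residue '", ref_res, "' has no count at position ",
             pos[i])
      pool <- rep(names(counts), counts)
      pool <- pool[-match(ref_res, pool)]           # row 1 takes one copy
      col <- c(ref_res, sample(pool))
      mat[, pos[i] - reference_start + 1L] <- col
    }
    seqs <- apply(mat, 1L, paste, collapse = "")
    names(seqs) <- c(reference_name,
                     sprintf("species_%03d", seq_len(n_sequences - 1L)))
    new_alignment(seqs, reference_name, reference_start)
  })
}

#' Generate one-site competition curves with known parameters
#'
#' Points follow
#' `y = min + (max - min)/(1 + 10^(hill (log10 x - log10 IC50)))` with
#' optional seeded Gaussian noise of standard deviation
#' `noise_sd * (max - min)`.
#'
#' @param true_ic50 IC50 in mol/L.
#' @param min,max Lower/upper polarization asymptotes (default 50, 300,
#'   millipolarization-like units).
#' @param hill Slope (default 1).
#' @param concentrations Concentration grid in mol/L; default 12 log-spaced
#'   points from 1e-11 to 1e-5.
#' @param noise_sd Noise standard deviation as a fraction of the range
#'   (default 0).
#' @param n_replicates Number of curves to generate.
#' @param seed Integer seed.
#' @param ligand,receptor Optional labels.
#' @return A `CompetitionCurve` (or a list of them when
#'   `n_replicates > 1`).
#' @export
make_competition_curve <- function(true_ic50, min = 50, max = 300, hill = 1,
                                   concentrations = 10^seq(-11, -5,
                                                           length.out = 12),
                                   noise_sd = 0, n_replicates = 1L,
                                   seed = 1L, ligand = NA_character_,
                                   receptor = NA_character_) {
  stopifnot(true_ic50 > 0, noise_sd >= 0, all(concentrations > 0))
  with_seed(seed, {
    mu <- competition_model(log10(concentrations), min, max,
                            log10(true_ic50), hill)
    curves <- lapply(seq_len(n_replicates), function(i) {
      y <- mu + stats::rnorm(length(mu), 0, noise_sd * (max - min))
      competition_curve(concentrations, y, ligand = ligand,
                        receptor = receptor)
    })
    if (n_replicates == 1L) curves[[1]] else curves
  })
}

#' Generate Boltzmann melt curves with known Tm
#'
#' @param true_tm Melting temperature in degrees C.
#' @param slope_width Transition width in degrees C (default 2).
#' @param folded,unfolded Baseline signals (defaults -20, -2; CD at 222 nm
#'   is negative for helical protein and rises toward zero on unfolding).
#' @param temperatures Temperature grid, default 25-90 degrees C in 1-degree
#'   steps.
#' @param noise_sd Noise standard deviation as a fraction of the baseline
#'   separation (default 0).
#' @param n_replicates Number of curves.
#' @param seed Integer seed.
#' @param receptor Optional label.
#' @return A `MeltCurve` (or list). If `true_tm` lies outside the grid the
#'   curve carries attribute `tm_outside_grid = TRUE` (a fit cannot be
#'   expected to recover it).
#' @export
make_melt_curve <- function(true_tm, slope_width = 2, folded = -20,
                            unfolded = -2, temperatures = 25:90,
                            noise_sd = 0, n_replicates = 1L, seed = 1L,
                            receptor = NA_character_) {
  stopifnot(slope_width > 0, noise_sd >= 0, all(diff(temperatures) > 0))
  outside <- true_tm < min(temperatures) || true_tm > max(temperatures)
  with_seed(seed, {
    mu <- boltzmann_model(temperatures, folded, unfolded, true_tm,
                          slope_width)
    curves <- lapply(seq_len(n_replicates), function(i) {
      y <- mu + stats::rnorm(length(mu), 0,
                             noise_sd * abs(folded - unfolded))
      cv <- melt_curve(temperatures, y, receptor = receptor)
      attr(cv, "tm_outside_grid") <- outside
      cv
    })
    if (n_replicates == 1L) curves[[1]] else curves
  })
}
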