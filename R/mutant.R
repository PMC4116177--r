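# Rotamer-based point-mutant modeling and steric-clash assessment.

#' Clash-scoring parameters
#'
#' Van der Waals radii (Angstrom), soft tolerance and bonded-pair exclusion
#' used by [clash_score()]. An atom pair counts as overlapping when
#' `rA + rB - d - tolerance > 0`.
#'
#' @param vdw_radii Named vector of radii per element.
#' @param tolerance Soft-sphere allowance in Angstrom (default 0.4).
#' @param bonded_exclusion Pairs separated by at most this many covalent
#'   bonds are never scored (default 3).
#' @return List of class `ClashParameters`.
#' @export
clash_parameters <- function(vdw_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                           S = 1.80),
                             tolerance = 0.4, bonded_exclusion = 3L) {
  stopifnot(all(vdw_radii > 0), tolerance >= 0, bonded_exclusion >= 0)
  structure(list(vdw_radii = vdw_radii, tolerance = tolerance,
                 bonded_exclusion = as.integer(bonded_exclusion)),
            class = "ClashParameters")
}

vdw_radius <- function(element, radii) {
  r <- radii[toupper(element)]
  r[is.na(r)] <- 1.70  # default to carbon-like for unparameterised elements
  unname(r)
}

#' Model a point mutation by rotamer-library side-chain substitution
#'
#' Replaces the side chain of the residue at `position` with the target
#' residue type, rebuilding the side chain from ideal internal geometry
#' onto the existing backbone (N, CA, C; the native CB is reused when
#' present). One placement is produced per rotamer of the target residue in
#' the library. Placements are not yet clash-scored; see [clash_score()]
#' and [best_placement()].
#'
#' @param model A `StructureModel`.
#' @param position Author residue number of the residue to mutate.
#' @param target_residue Target residue, one-letter or three-letter code.
#' @param rotamer_library Data frame from [rotamer_library()]; defaults to
#'   the embedded library.
#' @param chain Chain identifier; default the first protein chain.
#' @return List of `RotamerPlacement` objects, each with `position`,
#'   `chain`, `target`, `chi`, `atoms` (data frame of rebuilt side-chain
#'   atoms incl. CB), `clash_score` (NA until scored).
#' @export
mutate_residue <- function(model, position, target_residue,
                           rotamer_library = NULL, chain = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  target <- normalize_residue_code(target_residue)
  if (!target %in% SUPPORTED_TARGETS)
    stop("unsupported target residue '", target, "'; templates exist for: ",
         paste(SUPPORTED_TARGETS, collapse = " "))
  rk <- residue_keys(model)
  prot <- rk[!rk$is_hetero, , drop = FALSE]
  if (is.null(chain)) chain <- prot$chain[1]
  hit <- prot[prot$chain == chain & prot$resno == position, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("no residue ", position, " in chain ", chain)
  res_at <- residue_atoms(model, hit$key[1])
  bb <- backbone_coords(res_at)

  lib <- rotamer_library %||% rotamer_library()
  chis <- rotamer_chis(lib, target)
  lapply(seq_along(chis), function(i) {
    m <- build_sidechain(target, bb, chis[[i]])
    atoms <- if (nrow(m)) data.frame(
      serial = NA_integer_, name = rownames(m), altloc = "",
      resname = target, chain = chain, resno = as.integer(position),
      icode = hit$icode[1], x = m[, 1], y = m[, 2], z = m[, 3],
      occupancy = 1, element = substr(rownames(m), 1, 1),
      is_hetero = FALSE, is_hydrogen = FALSE, stringsAsFactors = FALSE)
    else model$atoms[0, ]
    rownames(atoms) <- NULL
    structure(list(position = as.integer(position), chain = chain,
                   target = target, rotamer = i, chi = chis[[i]],
                   atoms = atoms,
                   clash_score = if (nrow(atoms)) NA_real_ else 0),
              class = "RotamerPlacement")
  })
}

normalize_residue_code <- function(x) {
  x <- toupper(x)
  if (nchar(x) == 1L) aa_one_to_three(x) else x
}

backbone_coords <- function(res_at) {
  get1 <- function(nm) {
    r <- res_at[res_at$name == nm, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1, c("x", "y", "z")])
  }
  bb <- list(N = get1("N"), CA = get1("CA"), C = get1("C"),
             O = get1("O"), CB = get1("CB"))
  if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C))
    stop("missing backbone atoms (need N, CA, C) in residue ",
         res_at$resno[1])
  bb
}

#' @export
print.RotamerPlacement <- function(x, ...) {
  cat("RotamerPlacement: ", x$target, x$position, " rotamer ", x$rotamer,
      if (length(x$chi)) paste0(" (chi ", paste(round(x$chi), collapse = "/"),
                                ")") else "",
      ", ", nrow(x$atoms), " side-chain atoms",
      if (!is.na(x$clash_score)) sprintf(", clash %.2f", x$clash_score)
      else "", "\n", sep = "")
  invisible(x)
}

#' Score van der Waals clashes of a placed side chain
#'
#' For each placed side-chain atom against every heavy environment atom,
#' overlap is `rA + rB - d - tolerance` when positive. The environment is
#' all protein heavy atoms except the mutated residue's replaced side
#' chain, plus (optionally) hetero groups other than waters. Pairs within
#' `bonded_exclusion` covalent bonds (side chain through its own backbone
#' and the flanking peptide bonds) are excluded.
#'
#' @param model A `StructureModel`.
#' @param placement A `RotamerPlacement` built for `model`.
#' @param params A `ClashParameters` object.
#' @param include_ligand Include hetero (ligand) atoms in the environment?
#'   `FALSE` assesses the unbound receptor, `TRUE` the ligand-bound state.
#' @return Object of class `ClashReport`: `pairs` (data frame `atom_a`,
#'   `atom_b`, `overlap`), `total`, `max_overlap`, `clashing`.
#'   The placement's `clash_score` is also returned in `total`.
#' @export
clash_score <- function(model, placement, params = clash_parameters(),
                        include_ligand = TRUE) {
  stopifnot(inherits(model, "StructureModel"),
            inherits(placement, "RotamerPlacement"),
            inherits(params, "ClashParameters"))
  placed <- placement$atoms
  if (nrow(placed) == 0L)
    return(new_clash_report(placed[0, ], placement))

  a <- model$atoms
  res_sel <- !a$is_hetero & a$chain == placement$chain &
    a$resno == placement$position
  env <- a[!a$is_hydrogen, , drop = FALSE]
  # replaced side chain (and old CB duplicate) leaves the environment;
  # backbone of the mutated residue stays but is bonded-excluded below
  env <- env[!(( !env$is_hetero & env$chain == placement$chain &
                   env$resno == placement$position) &
                 !env$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
  if (!include_ligand) env <- env[!env$is_hetero, , drop = FALSE]
  else env <- env[!(env$is_hetero & env$resname %in% WATER_CODES), ,
                  drop = FALSE]
  if (nrow(env) == 0L) return(new_clash_report(placed[0, ], placement))

  sep <- bond_separation(model, placement)
  d <- cross_dist(as_coord_matrix(placed), as_coord_matrix(env))
  ra <- vdw_radius(placed$element, params$vdw_radii)
  rb <- vdw_radius(env$element, params$vdw_radii)
  overlap <- outer(ra, rb, "+") - d - params$tolerance

  env_key <- paste(env$chain, env$resno, env$icode, env$name, sep = "|")
  excl <- matrix(FALSE, nrow(placed), nrow(env))
  for (i in seq_len(nrow(placed))) {
    s <- sep[[placed$name[i]]]
    if (is.null(s)) next
    known <- intersect(names(s), env_key)
    if (length(known))
      excl[i, match(known, env_key)] <-
        s[known] <= params$bonded_exclusion
  }
  overlap[excl] <- -Inf

  hits <- which(overlap > 0, arr.ind = TRUE)
  pairs <- if (nrow(hits)) data.frame(
    atom_a = paste0(placement$target, placement$position, ":",
                    placed$name[hits[, 1]]),
    atom_b = paste(env$resname[hits[, 2]], env$resno[hits[, 2]],
                   env$name[hits[, 2]], sep = ":"),
    overlap = overlap[hits],
    stringsAsFactors = FALSE)
  else data.frame(atom_a = character(), atom_b = character(),
                  overlap = numeric(), stringsAsFactors = FALSE)
  new_clash_report(pairs, placement)
}

new_clash_report <- function(pairs, placement) {
  total <- sum(pairs$overlap)
  structure(list(pairs = pairs, total = total,
                 max_overlap = if (nrow(pairs)) max(pairs$overlap) else 0,
                 clashing = total > 0,
                 placement = placement),
            class = "ClashReport")
}

# Bond separations from each placed side-chain atom to atoms of the mutated
# residue and the flanking backbone, via BFS over the covalent graph.
# Returns, per placed atom name, a named vector of separations keyed by
# "chain|resno|icode|name".
bond_separation <- function(model, placement) {
  a <- model$atoms
  ch <- placement$chain; resno <- placement$position
  icode <- if (nrow(placement$atoms)) placement$atoms$icode[1] else ""

  node <- function(rn, nm) paste(ch, rn, icode, nm, sep = "|")
  edges <- list(c(node(resno, "N"), node(resno, "CA")),
                c(node(resno, "CA"), node(resno, "C")),
                c(node(resno, "C"), node(resno, "O")),
                c(node(resno, "CA"), node(resno, "CB")))
  sb <- sidechain_bonds(placement$target)
  if (!is.null(sb))
    for (i in seq_len(nrow(sb)))
      edges[[length(edges) + 1L]] <- c(node(resno, sb[i, 1]),
                                       node(resno, sb[i, 2]))
  # peptide bonds to flanking residues (author numbering +/- 1)
  for (nb in c(-1L, 1L)) {
    nb_res <- a[!a$is_hetero & a$chain == ch & a$resno == resno + nb, ,
                drop = FALSE]
    if (nrow(nb_res) == 0L) next
    nb_ic <- nb_res$icode[1]
    nbnode <- function(nm) paste(ch, resno + nb, nb_ic, nm, sep = "|")
    if (nb == -1L) {
      edges[[length(edges) + 1L]] <- c(nbnode("C"), node(resno, "N"))
      edges[[length(edges) + 1L]] <- c(nbnode("CA"), nbnode("C"))
      edges[[length(edges) + 1L]] <- c(nbnode("O"), nbnode("C"))
    } else {
      edges[[length(edges) + 1L]] <- c(node(resno, "C"), nbnode("N"))
      edges[[length(edges) + 1L]] <- c(nbnode("N"), nbnode("CA"))
    }
  }
  em <- do.call(rbind, edges)
  verts <- unique(as.vector(em))
  adj <- split(c(em[, 2], em[, 1]), c(em[, 1], em[, 2]))

  out <- list()
  for (nm in placement$atoms$name) {
    start <- node(resno, nm)
    dist <- stats::setNames(rep(Inf, length(verts)), verts)
    if (!start %in% verts) { out[[nm]] <- dist[0]; next }
    dist[start] <- 0
    frontier <- start
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    out[[nm]] <- dist[is.finite(dist)]
  }
  out
}

#' @export
print.ClashReport <- function(x, ...) {
  cat("ClashReport: total ", sprintf("%.3f", x$total), " A over ",
      nrow(x$pairs), " pair(s), max ", sprintf("%.3f", x$max_overlap),
      " A -> ", if (x$clashing) "CLASHING" else "clash-free", "\n", sep = "")
  invisible(x)
}

#' Pick the best rotamer placement by clash score
#'
#' Minimum total overlap; ties broken by lowest maximum single-pair
#' overlap, then by library order.
#'
#' @param placements List of `RotamerPlacement`.
#' @param reports List of corresponding `ClashReport`s (same order), or
#'   `NULL` to use the `clash_score` stored on the placements.
#' @return The winning `RotamerPlacement`, with its `ClashReport` attached
#'   as attribute `report` when reports were supplied.
#' @export
best_placement <- function(placements, reports = NULL) {
  if (length(placements) == 0L) stop("no placements to choose from")
  if (!is.null(reports)) {
    stopifnot(length(reports) == length(placements))
    totals <- vapply(reports, function(r) r$total, 0)
    maxes <- vapply(reports, function(r) r$max_overlap, 0)
  } else {
    totals <- vapply(placements, function(p) p$clash_score, 0)
    if (anyNA(totals)) stop("placements are unscored; supply clash reports")
    maxes <- totals
  }
  best <- order(totals, maxes, seq_along(placements))[1]
  out <- placements[[best]]
  out$clash_score <- totals[best]
  if (!is.null(reports)) attr(out, "report") <- reports[[best]]
  out
}

#' Score all rotamers of a mutation and keep the best
#'
#' Convenience wrapper: [mutate_residue()], [clash_score()] on every
#' placement, then [best_placement()].
#'
#' @inheritParams mutate_residue
#' @inheritParams clash_score
#' @return The best `RotamerPlacement` with its `ClashReport` attached.
#' @export
model_mutation <- function(model, position, target_residue,
                           rotamer_library = NULL, chain = NULL,
                           params = clash_parameters(),
                           include_ligand = TRUE) {
  placements <- mutate_residue(model, position, target_residue,
                               rotamer_library, chain)
  reports <- lapply(placements, clash_score, model = model, params = params,
                    include_ligand = include_ligand)
  best_placement(placements, reports)
}

#' Apply a placement to a structure model
#'
#' Returns a new `StructureModel` in which the mutated residue's old side
#' chain (beyond CB) is replaced by the placement's atoms and the residue
#' renamed to the target type.
#'
#' @param model A `StructureModel`.
#' @param placement A `RotamerPlacement`.
#' @return Modified `StructureModel`.
#' @export
apply_placement <- function(model, placement) {
  stopifnot(inherits(model, "StructureModel"),
            inherits(placement, "RotamerPlacement"))
  a <- model$atoms
  in_res <- !a$is_hetero & a$chain == placement$chain &
    a$resno == placement$position
  keep_bb <- !in_res | a$name %in% c("N", "CA", "C", "O")
  a <- a[keep_bb, , drop = FALSE]
  a$resname[!a$is_hetero & a$chain == placement$chain &
              a$resno == placement$position] <- placement$target
  new <- placement$atoms
  if (nrow(new)) {
    new$serial <- max(a$serial, na.rm = TRUE) + seq_len(nrow(new))
    a <- rbind(a, new)
  }
  a <- a[order(a$chain, a$resno, a$icode, a$is_hetero), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  structure(list(id = paste0(model$id, "_", placement$target,
                             placement$position),
                 model_index = model$model_index, atoms = a),
            class = "StructureModel")
}

RING_ATOMS <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

#' Aromatic ring proximity between a placed side chain and the ligand
#'
#' Centroid-to-centroid distance between the placed aromatic residue's ring
#' and a ligand ring. With `ligand_ring_atoms = "auto"` the ligand's rings
#' are perceived from interatomic distances (5- and 6-membered cycles) and
#' the minimum centroid distance over all rings is reported.
#'
#' @param placement A `RotamerPlacement` of PHE, TYR or TRP.
#' @param ligand A `LigandSelection`.
#' @param ligand_ring_atoms Character vector of ligand atom names forming
#'   the ring, or `"auto"`.
#' @return Object of class `ProximityReport`: `residue_centroid`,
#'   `ligand_centroid`, `centroid_distance` (Angstrom), `ring_atoms_used`.
#' @export
aromatic_proximity <- function(placement, ligand, ligand_ring_atoms = "auto") {
  stopifnot(inherits(placement, "RotamerPlacement"),
            inherits(ligand, "LigandSelection"))
  ring_names <- RING_ATOMS[[placement$target]]
  if (is.null(ring_names))
    stop("placement residue ", placement$target,
         " is not aromatic (need PHE, TYR or TRP)")
  pa <- placement$atoms
  miss <- setdiff(ring_names, pa$name)
  if (length(miss))
    stop("placement lacks ring atoms: ", paste(miss, collapse = ", "))
  res_ring <- as_coord_matrix(pa[match(ring_names, pa$name), , drop = FALSE])
  res_centroid <- colMeans(res_ring)

  lig <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  if (identical(ligand_ring_atoms, "auto")) {
    rings <- perceive_rings(lig)
    if (length(rings) == 0L)
      stop("no 5- or 6-membered rings found in ligand ", ligand$het_code)
  } else {
    miss <- setdiff(ligand_ring_atoms, lig$name)
    if (length(miss))
      stop("ligand ring atoms not found: ", paste(miss, collapse = ", "))
    rings <- list(ligand_ring_atoms)
  }
  dists <- vapply(rings, function(rn) {
    vnorm(colMeans(as_coord_matrix(lig[match(rn, lig$name), ,
                                       drop = FALSE])) - res_centroid)
  }, 0)
  best <- which.min(dists)
  structure(list(residue_centroid = res_centroid,
                 ligand_centroid = colMeans(
                   as_coord_matrix(lig[match(rings[[best]], lig$name), ,
                                       drop = FALSE])),
                 centroid_distance = dists[best],
                 ring_atoms_used = rings[[best]]),
            class = "ProximityReport")
}

# Minimal ring perception: covalent bonds from heavy-atom distances
# (< 1.8 Angstrom), then unique chordless cycles of size 5-6 via per-edge
# shortest paths.
perceive_rings <- function(atoms) {
  xyz <- as_coord_matrix(atoms)
  n <- nrow(xyz)
  if (n < 5L) return(list())
  d <- cross_dist(xyz, xyz)
  bonded <- which(d > 0.1 & d < 1.8 & upper.tri(d), arr.ind = TRUE)
  if (nrow(bonded) == 0L) return(list())
  g <- igraph::graph_from_edgelist(cbind(bonded[, 1], bonded[, 2]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(bonded))) {
    u <- bonded[k, 1]; v <- bonded[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) %in% c(5L, 6L)) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- atoms$name[path]
      }
    }
  }
  rings
}

#' @export
print.ProximityReport <- function(x, ...) {
  cat("ProximityReport: ring centroid distance ",
      sprintf("%.2f", x$centroid_distance), " A (ligand ring: ",
      paste(x$ring_atoms_used, collapse = " "), ")\n", sep = "")
  invisible(x)
}
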