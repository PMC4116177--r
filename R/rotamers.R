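# Side-chain templates (ideal internal geometry) and the embedded
# backbone-independent rotamer set.
#
# Each template atom is placed by the standard internal-coordinate (NeRF)
# construction from three previously placed atoms: bond length to the third,
# bond angle over the last two, and a dihedral over all three. Dihedrals are
# either fixed numbers or expressions in the chi angles ("chi1",
# "chi2+122.5", ...). The CB atom is placed from the backbone with the
# L-amino-acid improper dihedral C-N-CA-CB of -122.0 degrees.

CB_RULE <- list(name = "CB", refs = c("C", "N", "CA"),
                bond = 1.53, angle = 110.5, dihedral = "-122.0")

# atom = c(name, ref_a, ref_b, ref_c, bond, angle, dihedral)
sidechain_template <- function(resname) {
  t <- list(
    GLY = list(),
    ALA = list(),  # CB only, via CB_RULE
    VAL = list(
      list("CG1", "N", "CA", "CB", 1.52, 110.5, "chi1"),
      list("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1+122.3")),
    LEU = list(
      list("CG",  "N",  "CA", "CB", 1.53, 116.3, "chi1"),
      list("CD1", "CA", "CB", "CG", 1.52, 110.7, "chi2"),
      list("CD2", "CA", "CB", "CG", 1.52, 110.7, "chi2+122.6")),
    ILE = list(
      list("CG1", "N",  "CA", "CB",  1.53, 110.4, "chi1"),
      list("CG2", "N",  "CA", "CB",  1.52, 110.5, "chi1-122.3"),
      list("CD1", "CA", "CB", "CG1", 1.52, 113.9, "chi2")),
    MET = list(
      list("CG", "N",  "CA", "CB", 1.52, 114.1, "chi1"),
      list("SD", "CA", "CB", "CG", 1.80, 112.7, "chi2"),
      list("CE", "CB", "CG", "SD", 1.79, 100.2, "chi3")),
    PHE = list(
      list("CG",  "N",  "CA",  "CB",  1.51, 113.8, "chi1"),
      list("CD1", "CA", "CB",  "CG",  1.39, 120.0, "chi2"),
      list("CD2", "CA", "CB",  "CG",  1.39, 120.0, "chi2+180"),
      list("CE1", "CB", "CG",  "CD1", 1.39, 120.0, "180"),
      list("CE2", "CB", "CG",  "CD2", 1.39, 120.0, "180"),
      list("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, "0")),
    TYR = list(
      list("CG",  "N",   "CA",  "CB",  1.51, 113.8, "chi1"),
      list("CD1", "CA",  "CB",  "CG",  1.39, 120.0, "chi2"),
      list("CD2", "CA",  "CB",  "CG",  1.39, 120.0, "chi2+180"),
      list("CE1", "CB",  "CG",  "CD1", 1.39, 120.0, "180"),
      list("CE2", "CB",  "CG",  "CD2", 1.39, 120.0, "180"),
      list("CZ",  "CG",  "CD1", "CE1", 1.39, 120.0, "0"),
      list("OH",  "CD1", "CE1", "CZ",  1.38, 120.0, "180"))
  )
  resname <- toupper(resname)
  if (!resname %in% names(t))
    stop("no side-chain template for residue '", resname,
         "'; supported: ", paste(names(t), collapse = " "))
  t[[resname]]
}

SUPPORTED_TARGETS <- c("GLY", "ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TYR")

# chi angle counts per supported residue type
N_CHI <- c(GLY = 0L, ALA = 0L, VAL = 1L, LEU = 2L, ILE = 2L, MET = 3L,
           PHE = 2L, TYR = 2L)

# template connectivity (for bonded-pair exclusion in clash scoring)
sidechain_bonds <- function(resname) {
  b <- list(
    GLY = NULL,
    ALA = NULL,
    VAL = rbind(c("CB", "CG1"), c("CB", "CG2")),
    LEU = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
    ILE = rbind(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
    MET = rbind(c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
    PHE = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"),
                c("CE2", "CZ")),
    TYR = rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"),
                c("CE2", "CZ"), c("CZ", "OH"))
  )
  b[[toupper(resname)]]
}

#' The embedded backbone-independent rotamer library
#'
#' A minimal canonical-chi rotamer set shipped as a plain-text table with
#' the package (`inst/extdata/rotamers.tsv`): for each supported residue
#' type, the cross product of canonical chi-angle wells (e.g. for
#' phenylalanine chi1 in \{-65, 180, 62\} by chi2 in \{90, -85\}). Users may
#' supply their own table with the same columns.
#'
#' @param file Optional path to an alternative library table with columns
#'   `resname`, `rotamer`, `chi1` ... `chi4` (blank/NA for unused angles).
#' @return Data frame with columns `resname`, `rotamer`, `chi1`..`chi4`.
#' @export
rotamer_library <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "rotamers.tsv", package = "erdesign")
  lib <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("resname", "rotamer", "chi1", "chi2", "chi3", "chi4")
  if (!all(need %in% names(lib)))
    stop("rotamer library must have columns: ", paste(need, collapse = ", "))
  lib$resname <- toupper(lib$resname)
  lib
}

rotamer_chis <- function(lib, resname) {
  resname <- toupper(resname)
  rows <- lib[lib$resname == resname, , drop = FALSE]
  nchi <- N_CHI[[resname]]
  if (nchi == 0L) return(list(numeric(0)))
  if (nrow(rows) == 0L)
    stop("rotamer library has no entries for residue '", resname, "'")
  lapply(seq_len(nrow(rows)), function(i)
    as.numeric(rows[i, paste0("chi", seq_len(nchi))]))
}

# NeRF atom placement: position d with |d-c| = bond, angle(b,c,d) = angle,
# dihedral(a,b,c,d) = dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d_local <- c(-bond * cos(ang),
               bond * cos(dih) * sin(ang),
               bond * sin(dih) * sin(ang))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}

eval_dihedral_spec <- function(spec, chis) {
  m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9.]+)?$", spec))[[1]]
  if (length(m)) {
    k <- as.integer(m[2])
    off <- if (m[3] == "") 0 else as.numeric(m[3])
    return(chis[k] + off)
  }
  as.numeric(spec)
}

# Build the heavy side-chain atoms (beyond the backbone) of `resname` onto
# backbone coordinates. `backbone` is a named list of 3-vectors with at
# least N, CA, C. Returns a matrix with rownames = atom names (includes CB
# unless glycine).
build_sidechain <- function(resname, backbone, chis) {
  resname <- toupper(resname)
  nchi <- N_CHI[[resname]]
  if (length(chis) != nchi)
    stop(resname, " needs ", nchi, " chi angle(s), got ", length(chis))
  coords <- list(N = backbone$N, CA = backbone$CA, C = backbone$C)
  if (any(vapply(coords, is.null, TRUE)))
    stop("backbone atoms N, CA, C are required to rebuild a side chain")
  out <- list()
  if (resname != "GLY") {
    # reuse the existing CB when the backbone provides one; only side-chain
    # atoms beyond CB are rebuilt in that case
    cb <- backbone$CB %||% place_atom(coords$C, coords$N, coords$CA,
                                      CB_RULE$bond, CB_RULE$angle,
                                      as.numeric(CB_RULE$dihedral))
    coords$CB <- cb
    out$CB <- cb
  }
  for (at in sidechain_template(resname)) {
    nm <- at[[1]]
    pos <- place_atom(coords[[at[[2]]]], coords[[at[[3]]]], coords[[at[[4]]]],
                      at[[5]], at[[6]], eval_dihedral_spec(at[[7]], chis))
    coords[[nm]] <- pos
    out[[nm]] <- pos
  }
  if (length(out) == 0L)
    return(matrix(numeric(0), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("x", "y", "z")
  m
}
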