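# Reading protein-ligand complexes from PDB-format text and basic geometry.
#
# The internal structure model is deliberately plain: a data frame of atoms
# plus a label. Atoms carry author residue numbering verbatim (chain, number,
# insertion code) because pocket positions downstream are reported in author
# (human ER-alpha) numbering.

WATER_CODES <- c("HOH", "WAT", "DOD")
ION_OR_BUFFER_CODES <- c("NA", "CL", "MG", "ZN", "CA", "K", "SO4", "PO4",
                         "GOL", "EDO")

#' Read a PDB-format structure into a structure model
#'
#' Parses `ATOM`/`HETATM` records of the first `MODEL` block (crystal
#' structures normally have a single model; for multi-model files only model
#' one is used). Alternate locations are collapsed to a single atom by
#' keeping the highest-occupancy copy; ties are broken toward the
#' lexicographically smallest altloc character. Hydrogens are parsed and
#' flagged but excluded from pocket distance computations downstream.
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline or more than one element is treated as
#'   literal text).
#' @param id Structure label; defaults to the file base name.
#' @return An object of class `StructureModel`: a list with `id`,
#'   `model_index` and `atoms`, a data frame with one row per atom
#'   (`serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `icode`,
#'   `x`, `y`, `z`, `occupancy`, `element`, `is_hetero`, `is_hydrogen`).
#' @export
read_pdb <- function(file, id = NULL) {
  from_text <- length(file) > 1L || any(grepl("\n", file, fixed = TRUE)) ||
    grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK)", file[1])
  if (from_text) {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(lines, path)
    if (is.null(id)) id <- "structure"
  } else {
    if (!file.exists(file)) stop("PDB file not found: ", file)
    lines <- readLines(file, warn = FALSE)
    path <- file
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(file))
  }

  validate_pdb_coords(lines)

  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  )
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty structure: no ATOM or HETATM records")

  element <- at$elesy
  element[is.na(element) | element == ""] <- NA_character_
  missing_el <- is.na(element)
  if (any(missing_el)) element[missing_el] <- guess_element(at$elety[missing_el])
  occ <- at$o
  occ[is.na(occ)] <- 1

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    element = toupper(element),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure ", id)
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1] in structure ", id)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")

  atoms <- collapse_altlocs(atoms)
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0L) stop("empty structure: no atoms after parsing")

  structure(list(id = id, model_index = 1L, atoms = atoms),
            class = "StructureModel")
}

# Index range of lines after the first ENDMDL (ignored records).
lines_after_first_endmdl <- function(lines) {
  e <- grep("^ENDMDL", lines)
  if (length(e) == 0L) return(integer(0))
  seq.int(e[1] + 1L, length(lines))
}

# Fail early, naming the offending line, if a coordinate field is malformed.
validate_pdb_coords <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  drop <- lines_after_first_endmdl(lines)
  idx <- setdiff(idx, drop)
  if (length(idx) == 0L)
    stop("empty structure: no ATOM or HETATM records before ENDMDL")
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed coordinate record at line ", i,
                             ": record shorter than coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate field at line ", i, ": '",
           substr(ln, 31, 54), "'")
  }
  invisible(TRUE)
}

guess_element <- function(atom_names) {
  nm <- gsub("[0-9'\"]", "", trimws(atom_names))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"), two, one)
}

collapse_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
    if (length(ix) == 1L) return(ix)
    sub <- atoms[ix, ]
    best <- which(sub$occupancy == max(sub$occupancy))
    if (length(best) > 1L) best <- best[order(sub$altloc[best])][1]
    ix[best[1]]
  }), use.names = FALSE)
  atoms[sort(keep), ]
}

#' @export
print.StructureModel <- function(x, ...) {
  rk <- residue_keys(x)
  cat("StructureModel '", x$id, "': ", nrow(x$atoms), " atoms, ",
      nrow(rk), " residues (", sum(!rk$is_hetero), " protein, ",
      sum(rk$is_hetero), " hetero)\n", sep = "")
  invisible(x)
}

#' Residue table of a structure model
#'
#' One row per residue in file order, keyed by (chain, number, insertion
#' code), with the residue name and whether the residue is a hetero group.
#'
#' @param model A `StructureModel`.
#' @return Data frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `is_hetero`, `key`.
#' @export
residue_keys <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resname = a$resname[first],
                    is_hetero = a$is_hetero[first],
                    key = key[first], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

residue_atoms <- function(model, key) {
  a <- model$atoms
  a[paste(a$chain, a$resno, a$icode, sep = "|") == key, , drop = FALSE]
}

#' Write a structure model as minimal PDB text
#'
#' Emits `ATOM`/`HETATM` records (plus `TER`/`END`) sufficient to round-trip
#' the models produced by this package; used mainly to materialise synthetic
#' fixtures and mutant models.
#'
#' @param model A `StructureModel`.
#' @param file Optional path; if omitted the PDB text is returned invisibly
#'   as a character vector.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(model, file = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  name4 <- vapply(a$name, format_atom_name, "")
  lines <- sprintf("%s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, name4,
                   ifelse(a$altloc == "", " ", a$altloc),
                   a$resname, ifelse(a$chain == "", " ", a$chain),
                   a$resno, ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, a$occupancy, 0,
                   substr(a$element, 1, 2))
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# PDB atom-name column convention: single-letter elements start in column 14.
format_atom_name <- function(nm) {
  if (nchar(nm) >= 4L) return(substr(nm, 1, 4))
  el2 <- toupper(substr(nm, 1, 2)) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
  if (el2) sprintf("%-4s", nm) else sprintf(" %-3s", nm)
}

#' Select the ligand group of a complex
#'
#' If `het_code` is given, returns that hetero group; otherwise auto-selects
#' the hetero group with the most atoms after excluding waters
#' (HOH/WAT/DOD) and a fixed list of small ions and buffer components
#' (NA, CL, MG, ZN, CA, K, SO4, PO4, GOL, EDO).
#'
#' @param model A `StructureModel`.
#' @param het_code Optional 3-letter chemical component code.
#' @return An object of class `LigandSelection` with `structure_id`,
#'   `het_code`, `chain`, and `atoms` (data frame as in the model).
#' @export
select_ligand <- function(model, het_code = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  het <- a[a$is_hetero, , drop = FALSE]
  if (nrow(het) == 0L) stop("no hetero groups in structure ", model$id)
  if (!is.null(het_code)) {
    het_code <- toupper(het_code)
    if (het_code %in% c(WATER_CODES, ION_OR_BUFFER_CODES))
      stop("het_code '", het_code, "' is an excluded water/ion/buffer code")
    grp <- het[het$resname == het_code, , drop = FALSE]
    if (nrow(grp) == 0L)
      stop("hetero group '", het_code, "' not found in structure ", model$id)
  } else {
    cand <- het[!het$resname %in% c(WATER_CODES, ION_OR_BUFFER_CODES), ,
                drop = FALSE]
    cand <- cand[!cand$is_hydrogen, , drop = FALSE]
    if (nrow(cand) == 0L)
      stop("no qualifying ligand group in structure ", model$id,
           " (only waters/ions present)")
    sizes <- table(cand$resname)
    # single-atom groups never qualify as ligand
    sizes <- sizes[sizes > 1L]
    if (length(sizes) == 0L)
      stop("no qualifying ligand group in structure ", model$id)
    pick <- names(sizes)[which.max(sizes)]
    grp <- het[het$resname == pick, , drop = FALSE]
  }
  # restrict to a single residue instance (first chain/number seen)
  keys <- paste(grp$chain, grp$resno, grp$icode, sep = "|")
  grp <- grp[keys == keys[1], , drop = FALSE]
  structure(list(structure_id = model$id,
                 het_code = grp$resname[1],
                 chain = grp$chain[1],
                 atoms = grp),
            class = "LigandSelection")
}

#' @export
print.LigandSelection <- function(x, ...) {
  cat("LigandSelection: ", x$het_code, " (chain ", x$chain, ", ",
      nrow(x$atoms), " atoms) in ", x$structure_id, "\n", sep = "")
  invisible(x)
}

#' Minimum interatomic distance between two atom sets
#'
#' The minimum Euclidean centre-to-centre distance over all atom pairs, in
#' Angstrom. This is the primitive behind the distance-cutoff pocket rule.
#'
#' @param atoms_a,atoms_b Data frames with `x`, `y`, `z` columns (or numeric
#'   matrices with 3 columns).
#' @return Minimum distance in Angstrom.
#' @export
min_distance <- function(atoms_a, atoms_b) {
  ca <- as_coord_matrix(atoms_a)
  cb <- as_coord_matrix(atoms_b)
  if (nrow(ca) == 0L || nrow(cb) == 0L)
    stop("min_distance requires non-empty atom sets")
  min(cross_dist(ca, cb))
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(x)
  }
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  stop("expected a data frame with x/y/z columns or an n x 3 matrix")
}
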