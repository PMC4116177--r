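# Ligand binding pocket extraction and cross-structure union.
#
# A residue belongs to the pocket of a complex when any of its heavy atoms
# lies within a distance cutoff (default 6 Angstrom, inclusive) of any ligand
# atom. Pockets from several complexes of the same receptor are unioned in
# reference numbering to obtain a conservative description of the binding
# site.

#' Extract the ligand binding pocket of one complex
#'
#' Returns the protein residues whose minimum heavy-atom distance to the
#' ligand is less than or equal to `cutoff` (closed interval). The ligand's
#' own residue, other hetero groups and hydrogens are excluded.
#'
#' @param model A `StructureModel`.
#' @param ligand A `LigandSelection` belonging to `model`.
#' @param cutoff Distance cutoff in Angstrom; must be > 0. Default 6.0.
#' @return Data frame of pocket residues: `chain`, `resno`, `icode`,
#'   `resname`, `min_dist` (Angstrom), ordered by chain then residue number.
#' @export
extract_pocket <- function(model, ligand, cutoff = 6.0) {
  stopifnot(inherits(model, "StructureModel"),
            inherits(ligand, "LigandSelection"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive distance in Angstrom")
  if (!identical(ligand$structure_id, model$id))
    stop("ligand selection does not belong to this model")
  a <- model$atoms
  lig_serials <- ligand$atoms$serial
  if (!all(lig_serials %in% a$serial))
    stop("ligand atoms not found in model")

  lig_xyz <- as_coord_matrix(ligand$atoms[!ligand$atoms$is_hydrogen, ,
                                          drop = FALSE])
  prot <- a[!a$is_hetero & !a$is_hydrogen, , drop = FALSE]
  if (nrow(prot) == 0L || nrow(lig_xyz) == 0L) {
    return(data.frame(chain = character(), resno = integer(),
                      icode = character(), resname = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE))
  }
  d <- cross_dist(as_coord_matrix(prot), lig_xyz)
  per_atom_min <- apply(d, 1L, min)
  key <- paste(prot$chain, prot$resno, prot$icode, sep = "|")
  per_res_min <- tapply(per_atom_min, key, min)

  hit <- per_res_min <= cutoff
  keys_hit <- names(per_res_min)[hit]
  first <- prot[!duplicated(key), , drop = FALSE]
  first_key <- key[!duplicated(key)]
  sel <- match(keys_hit, first_key)
  out <- data.frame(chain = first$chain[sel], resno = first$resno[sel],
                    icode = first$icode[sel], resname = first$resname[sel],
                    min_dist = as.numeric(per_res_min[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map structure residue numbering to a reference sequence register
#'
#' If the author numbering of the chain already matches the reference
#' register (at least 95 percent identity at shared numbers) the identity
#' map is returned. Otherwise a global pairwise alignment (match +1,
#' mismatch -1, gap open -2, gap extend -1) between the chain sequence and
#' the reference sequence defines the mapping through aligned columns.
#'
#' @param model A `StructureModel`.
#' @param reference_sequence One-letter reference sequence (single string).
#' @param reference_start Reference number of the first reference residue.
#' @param chain Chain to map; default the first protein chain.
#' @return An object of class `NumberingMap`: data frame `pairs` with
#'   `chain`, `resno`, `icode`, `ref_position`, plus attributes `method`
#'   ("identity" or "global_alignment") and `identity` (fraction of mapped
#'   pairs with identical residues).
#' @export
map_to_reference <- function(model, reference_sequence, reference_start = 1L,
                             chain = NULL) {
  stopifnot(inherits(model, "StructureModel"), is_string(reference_sequence))
  rk <- residue_keys(model)
  prot <- rk[!rk$is_hetero, , drop = FALSE]
  if (nrow(prot) == 0L) stop("model has no protein residues to map")
  if (is.null(chain)) chain <- prot$chain[1]
  prot <- prot[prot$chain == chain, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein residues in chain ", chain)

  seq1 <- vapply(prot$resname, aa_three_to_one, "")
  ref <- strsplit(toupper(reference_sequence), "")[[1]]
  ref_positions <- seq.int(reference_start, length.out = length(ref))

  # try the identity register first
  shared <- prot$resno %in% ref_positions
  if (any(shared)) {
    ref_at <- ref[match(prot$resno[shared], ref_positions)]
    ident <- mean(seq1[shared] == ref_at)
    if (ident >= 0.95) {
      pairs <- data.frame(chain = prot$chain[shared],
                          resno = prot$resno[shared],
                          icode = prot$icode[shared],
                          ref_position = prot$resno[shared],
                          stringsAsFactors = FALSE)
      return(new_numbering_map(pairs, "identity", ident))
    }
  }

  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seq1, collapse = "")),
    Biostrings::AAString(paste(ref, collapse = "")),
    type = "global",
    substitutionMatrix = unit_substitution_matrix(),
    gapOpening = 2, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  i <- 0L; j <- 0L
  idx_struct <- integer(0); idx_ref <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") i <- i + 1L
    if (s[k] != "-") j <- j + 1L
    if (p[k] != "-" && s[k] != "-") {
      idx_struct <- c(idx_struct, i)
      idx_ref <- c(idx_ref, j)
    }
  }
  if (length(idx_struct) == 0L) stop("unmappable: alignment has no matched columns")
  ident <- mean(seq1[idx_struct] == ref[idx_ref])
  if (ident < 0.30)
    stop("unmappable: alignment identity ", sprintf("%.2f", ident),
         " below 0.30")
  pairs <- data.frame(chain = prot$chain[idx_struct],
                      resno = prot$resno[idx_struct],
                      icode = prot$icode[idx_struct],
                      ref_position = ref_positions[idx_ref],
                      stringsAsFactors = FALSE)
  new_numbering_map(pairs, "global_alignment", ident)
}

new_numbering_map <- function(pairs, method, identity) {
  structure(list(pairs = pairs, method = method, identity = identity),
            class = "NumberingMap")
}

#' @export
print.NumberingMap <- function(x, ...) {
  cat("NumberingMap: ", nrow(x$pairs), " mapped residues, method = ",
      x$method, ", identity = ", sprintf("%.3f", x$identity), "\n", sep = "")
  invisible(x)
}

unit_substitution_matrix <- function() {
  alpha <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V", "X", "B", "Z")
  m <- matrix(-1, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  m
}

aa_three_to_one <- function(code) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V", MSE = "M")
  out <- tab[toupper(code)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(letter) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[toupper(letter)]
  if (any(is.na(out))) stop("unknown one-letter residue code: ",
                            paste(letter[is.na(out)], collapse = ", "))
  unname(out)
}

#' Translate a per-structure pocket into reference positions
#'
#' @param pocket Data frame from [extract_pocket()].
#' @param map A `NumberingMap` from [map_to_reference()], or `NULL` to take
#'   author numbers as reference positions directly.
#' @return Integer vector of reference positions (sorted, unique), with the
#'   reference residue names as a `refname` attribute.
#' @export
pocket_reference_positions <- function(pocket, map = NULL) {
  if (is.null(map)) {
    pos <- pocket$resno
    nm <- pocket$resname
  } else {
    stopifnot(inherits(map, "NumberingMap"))
    mk <- paste(map$pairs$chain, map$pairs$resno, map$pairs$icode, sep = "|")
    pk <- paste(pocket$chain, pocket$resno, pocket$icode, sep = "|")
    hit <- match(pk, mk)
    if (anyNA(hit)) {
      warning(sum(is.na(hit)), " pocket residue(s) not covered by the ",
              "numbering map were dropped")
    }
    pos <- map$pairs$ref_position[hit[!is.na(hit)]]
    nm <- pocket$resname[!is.na(hit)]
  }
  o <- order(pos)
  pos <- pos[o]; nm <- nm[o]
  keep <- !duplicated(pos)
  structure(as.integer(pos[keep]), refname = nm[keep])
}

#' Union pocket definitions across complexes
#'
#' Set union of per-structure pockets expressed in reference numbering,
#' with provenance recording which source structures contributed each
#' position. All pockets must have been extracted at the same cutoff.
#'
#' @param pockets Named list: one element per source structure, each an
#'   integer vector of reference positions (optionally with a `refname`
#'   attribute as returned by [pocket_reference_positions()]).
#' @param cutoff The common cutoff in Angstrom the pockets were extracted
#'   at, or a vector of per-pocket cutoffs (must all be equal).
#' @return An object of class `PocketDefinition`: list with `cutoff`,
#'   `positions` (data frame `position`, `refname`, `n_sources`), and
#'   `provenance` (data frame `position`, `source`).
#' @export
union_pockets <- function(pockets, cutoff = 6.0) {
  stopifnot(is.list(pockets), length(pockets) >= 1L)
  if (is.null(names(pockets)) || any(names(pockets) == ""))
    names(pockets) <- paste0("structure", seq_along(pockets))
  cutoff <- unique(as.numeric(cutoff))
  if (length(cutoff) != 1L)
    stop("mixed cutoffs: a pocket union is defined at a single cutoff")
  if (cutoff <= 0) stop("cutoff must be positive")

  prov <- do.call(rbind, lapply(names(pockets), function(src) {
    pos <- pockets[[src]]
    if (length(pos) == 0L) return(NULL)
    data.frame(position = as.integer(pos), source = src,
               refname = refnames_or_na(pos), stringsAsFactors = FALSE)
  }))
  if (is.null(prov) || nrow(prov) == 0L) {
    positions <- data.frame(position = integer(), refname = character(),
                            n_sources = integer(), stringsAsFactors = FALSE)
    prov <- data.frame(position = integer(), source = character(),
                       stringsAsFactors = FALSE)
    return(structure(list(cutoff = cutoff, positions = positions,
                          provenance = prov), class = "PocketDefinition"))
  }
  prov <- prov[order(prov$position, prov$source), , drop = FALSE]
  upos <- sort(unique(prov$position))
  refname <- vapply(upos, function(p) {
    nm <- prov$refname[prov$position == p]
    nm <- nm[!is.na(nm)]
    if (length(nm)) nm[1] else NA_character_
  }, "")
  n_sources <- vapply(upos, function(p)
    length(unique(prov$source[prov$position == p])), 1L)
  positions <- data.frame(position = upos, refname = refname,
                          n_sources = n_sources, stringsAsFactors = FALSE)
  rownames(positions) <- NULL
  structure(list(cutoff = cutoff, positions = positions,
                 provenance = prov[, c("position", "source")]),
            class = "PocketDefinition")
}

refnames_or_na <- function(pos) {
  nm <- attr(pos, "refname")
  if (is.null(nm)) rep(NA_character_, length(pos)) else nm
}

#' @export
print.PocketDefinition <- function(x, ...) {
  cat("PocketDefinition: ", nrow(x$positions), " positions at ",
      x$cutoff, " Angstrom cutoff, union of ",
      length(unique(x$provenance$source)), " structure(s)\n", sep = "")
  if (nrow(x$positions))
    cat("  positions: ", paste(x$positions$position, collapse = " "), "\n",
        sep = "")
  invisible(x)
}

#' Write a pocket definition as TSV and JSON reports
#'
#' @param pocket A `PocketDefinition`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @param header_lines Optional comment lines (e.g. a config fingerprint)
#'   prepended to the TSV with a leading `#`.
#' @return Invisibly, the report data frame.
#' @export
write_pocket_report <- function(pocket, tsv = NULL, json = NULL,
                                header_lines = character()) {
  stopifnot(inherits(pocket, "PocketDefinition"))
  df <- pocket$positions
  df$sources <- vapply(df$position, function(p)
    paste(sort(unique(pocket$provenance$source[pocket$provenance$position == p])),
          collapse = ","), "")
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    on.exit(close(con))
    if (length(header_lines))
      writeLines(paste0("# ", header_lines), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(cutoff = pocket$cutoff, positions = df,
           provenance = pocket$provenance),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(df)
}
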