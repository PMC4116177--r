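# Conservation profiling of pocket positions across an ortholog alignment
# and enumeration of natural-variant candidate mutations.
#
# The conservation metric is the modal-residue fraction of a column: the
# fraction of counted sequences carrying the most common residue. Gaps are
# absence of evidence and are never counted; ambiguous letters (X/B/Z) are
# excluded from both counts and the effective number of sequences.

ALIGNMENT_ALPHABET <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                        "X", "B", "Z", "-", ".")

#' Read a multiple sequence alignment
#'
#' @param file Path to an alignment in FASTA or Clustal format.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference_name Name of the sequence carrying reference numbering;
#'   must be present in the alignment.
#' @param reference_start Reference number of the first non-gap reference
#'   column (e.g. 303 for an ER-alpha LBD fragment).
#' @return An object of class `Alignment`: list with `sequences` (named
#'   character vector of equal-length aligned strings), `reference_name`,
#'   `reference_start`.
#' @export
read_alignment <- function(file, format = c("fasta", "clustal"),
                           reference_name, reference_start = 1L) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- read_fasta_alignment(file)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(file, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(aln))
  }
  new_alignment(seqs, reference_name, reference_start)
}

# FASTA rows may be ragged (a format error for an alignment); read them
# leniently so the length check can produce a meaningful message.
read_fasta_alignment <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not FASTA: no '>' headers in ", file)
  id <- cumsum(hdr)
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)
  body <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  seqs <- toupper(gsub("\\s", "", body))
  names(seqs) <- nm
  seqs
}

new_alignment <- function(seqs, reference_name, reference_start = 1L) {
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: row lengths ", paste(sort(unique(w)), collapse = ", "))
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 ALIGNMENT_ALPHABET)
  if (length(bad))
    stop("alignment contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = " "))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all alignment rows must be named")
  if (!reference_name %in% names(seqs))
    stop("reference sequence '", reference_name, "' not in alignment")
  structure(list(sequences = seqs, reference_name = reference_name,
                 reference_start = as.integer(reference_start)),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat("Alignment: ", length(x$sequences), " sequences x ",
      nchar(x$sequences[1]), " columns (reference: ", x$reference_name,
      ", first position ", x$reference_start, ")\n", sep = "")
  invisible(x)
}

alignment_matrix <- function(a) {
  do.call(rbind, strsplit(unname(a$sequences), ""))
}

# Column index for a reference position; errors if the position falls on a
# reference gap or outside the reference.
reference_column <- function(a, reference_position) {
  ref <- strsplit(a$sequences[[a$reference_name]], "")[[1]]
  nongap <- which(!ref %in% c("-", "."))
  pos <- seq.int(a$reference_start, length.out = length(nongap))
  hit <- match(reference_position, pos)
  if (is.na(hit))
    stop("reference position ", reference_position,
         " is outside the reference sequence (",
         pos[1], "-", pos[length(pos)], ")")
  nongap[hit]
}

#' Remove duplicate and incomplete sequences from an alignment
#'
#' Drops exact duplicate sequence strings (keeping the first in row order)
#' and sequences whose non-gap coverage of the reference's non-gap columns
#' falls below `min_coverage`. The reference sequence is never removed.
#' Idempotent.
#'
#' @param a An `Alignment`.
#' @param min_coverage Minimum fraction of reference columns a row must
#'   cover with non-gap residues. Default 0.8.
#' @return A cleaned `Alignment`.
#' @export
clean_alignment <- function(a, min_coverage = 0.8) {
  stopifnot(inherits(a, "Alignment"), min_coverage >= 0, min_coverage <= 1)
  seqs <- a$sequences
  ref <- strsplit(seqs[[a$reference_name]], "")[[1]]
  ref_cols <- which(!ref %in% c("-", "."))

  dup <- duplicated(unname(seqs))
  cov <- vapply(seqs, function(s) {
    r <- strsplit(s, "")[[1]][ref_cols]
    mean(!r %in% c("-", "."))
  }, 0)
  keep <- (!dup & cov >= min_coverage) | names(seqs) == a$reference_name
  out <- seqs[keep]
  if (length(out) < 2L)
    stop("cleaning left fewer than 2 sequences (", length(out), ")")
  new_alignment(out, a$reference_name, a$reference_start)
}

#' Amino-acid frequency profile of one reference column
#'
#' Counts residues over non-gap, non-ambiguous symbols in the alignment
#' column under the given reference position. Conservation is the modal
#' residue fraction, `max(counts)/n_effective`.
#'
#' @param a An `Alignment`.
#' @param reference_position Integer position in reference numbering.
#' @return An object of class `AlignmentColumnProfile`: list with
#'   `reference_position`, `counts` (named integer vector, decreasing),
#'   `n_effective`, `conservation`, `modal_residue`, `wild_type` (the
#'   reference sequence's residue at that position).
#' @export
column_profile <- function(a, reference_position) {
  stopifnot(inherits(a, "Alignment"))
  col <- reference_column(a, reference_position)
  letters_col <- vapply(a$sequences, function(s) substr(s, col, col), "")
  counted <- letters_col[!letters_col %in% c("-", ".", "X", "B", "Z")]
  if (length(counted) == 0L)
    stop("column at reference position ", reference_position,
         " has no countable residues")
  counts <- sort(table(counted), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_eff <- sum(counts)
  structure(list(reference_position = as.integer(reference_position),
                 counts = counts,
                 n_effective = n_eff,
                 conservation = max(counts) / n_eff,
                 modal_residue = names(counts)[1],
                 wild_type = unname(letters_col[a$reference_name])),
            class = "AlignmentColumnProfile")
}

#' @export
print.AlignmentColumnProfile <- function(x, ...) {
  cat("Position ", x$reference_position, ": modal ", x$modal_residue,
      " (", sprintf("%.1f%%", 100 * x$conservation), " of ",
      x$n_effective, "), wild type ", x$wild_type, "\n", sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = ":",
                          collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Conservation profiles for all pocket positions
#'
#' One column profile per pocket position, in ascending position order.
#' Positions that do not map into the reference (or fall on reference gaps)
#' are not silent: they are reported in the `skipped` attribute.
#'
#' @param a An `Alignment`.
#' @param pocket A `PocketDefinition`, or an integer vector of reference
#'   positions.
#' @return List of `AlignmentColumnProfile` (class
#'   `PocketConservationReport`), with attribute `skipped`: data frame of
#'   positions that could not be profiled and the reason.
#' @export
pocket_conservation <- function(a, pocket) {
  positions <- if (inherits(pocket, "PocketDefinition"))
    pocket$positions$position else as.integer(pocket)
  positions <- sort(unique(positions))
  profiles <- list()
  skipped <- data.frame(position = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  for (p in positions) {
    pr <- tryCatch(column_profile(a, p), error = function(e) e)
    if (inherits(pr, "error")) {
      skipped <- rbind(skipped, data.frame(position = p,
                                           reason = conditionMessage(pr),
                                           stringsAsFactors = FALSE))
    } else {
      profiles[[as.character(p)]] <- pr
    }
  }
  structure(profiles, skipped = skipped, class = "PocketConservationReport")
}

#' @export
print.PocketConservationReport <- function(x, ...) {
  cat("Pocket conservation over", length(x), "positions\n")
  for (pr in x)
    cat(sprintf("  %4d %s %.3f\n", pr$reference_position, pr$modal_residue,
                pr$conservation))
  sk <- attr(x, "skipped")
  if (nrow(sk)) cat("  skipped:", paste(sk$position, collapse = " "), "\n")
  invisible(x)
}

#' Enumerate natural-variant candidate mutations
#'
#' For each profiled position, every residue other than the wild type
#' (taken from the reference sequence, not the modal residue) observed in
#' at least `min_support` sequences becomes a candidate mutation. Candidates
#' are ranked by variant fraction (descending), then position (ascending).
#'
#' @param profiles A `PocketConservationReport` or list of
#'   `AlignmentColumnProfile`.
#' @param min_support Minimum number of sequences carrying the variant.
#'   Default 2.
#' @return Data frame of class `CandidateMutations`: `position`,
#'   `wild_type`, `variant`, `support`, `variant_fraction`, `label`
#'   (e.g. "M421F").
#' @export
candidate_mutations <- function(profiles, min_support = 2L) {
  stopifnot(min_support >= 1)
  rows <- list()
  for (pr in profiles) {
    stopifnot(inherits(pr, "AlignmentColumnProfile"))
    wt <- pr$wild_type
    for (res in names(pr$counts)) {
      if (res == wt) next
      sup <- pr$counts[[res]]
      if (sup < min_support) next
      rows[[length(rows) + 1L]] <- data.frame(
        position = pr$reference_position, wild_type = wt, variant = res,
        support = sup, variant_fraction = sup / pr$n_effective,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), wild_type = character(),
               variant = character(), support = integer(),
               variant_fraction = numeric(), stringsAsFactors = FALSE)
  out <- out[order(-out$variant_fraction, out$position), , drop = FALSE]
  out$label <- if (nrow(out))
    paste0(out$wild_type, out$position, out$variant) else character(0)
  rownames(out) <- NULL
  class(out) <- c("CandidateMutations", "data.frame")
  out
}

#' Write a conservation report as TSV/JSON
#'
#' @param profiles A `PocketConservationReport`.
#' @param tsv,json Output paths (`NULL` to skip either).
#' @param header_lines Optional `#`-prefixed comment lines for the TSV.
#' @return Invisibly, the report data frame (position, wild type, modal
#'   residue, conservation, n_effective, variants with supports).
#' @export
write_conservation_report <- function(profiles, tsv = NULL, json = NULL,
                                      header_lines = character()) {
  df <- do.call(rbind, lapply(unclass(profiles), function(pr) {
    variants <- pr$counts[names(pr$counts) != pr$modal_residue]
    data.frame(position = pr$reference_position,
               wild_type = pr$wild_type,
               modal_residue = pr$modal_residue,
               conservation = pr$conservation,
               n_effective = pr$n_effective,
               variants = paste(names(variants), variants, sep = ":",
                                collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame()
  rownames(df) <- NULL
  if (!is.null(tsv)) {
    con <- file(tsv, "w"); on.exit(close(con))
    if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(df)
}
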