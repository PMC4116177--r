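# Workflow orchestration: config-driven runs of the pocket, design, mutate
# and assay stages, writing versioned TSV/JSON reports stamped with a
# fingerprint of the configuration. These functions are the programmatic
# surface behind the `inst/cli/erdesign` wrapper script.

REPORT_SCHEMA_VERSION <- "1"

#' Read a workflow run configuration
#'
#' YAML key-value config. Recognised keys: `structures` (list of entries
#' with `path`, optional `ligand` code, optional `id`), `cutoff`,
#' `alignment` (`path`, `format`, `reference`, `reference_start`),
#' `min_support`, `min_coverage`, `clash` (`tolerance`), `assay`
#' (`affinity_table` and/or `plate_table`, `mode`, `reference_receptor`),
#' `outdir`, `seed`.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return List of class `RunConfig` with a `hash` attribute (FNV-1a over
#'   the canonical JSON form).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$cutoff <- cfg$cutoff %||% 6.0
  if (cfg$cutoff <= 0) stop("config: cutoff must be > 0")
  cfg$min_support <- cfg$min_support %||% 2L
  cfg$min_coverage <- cfg$min_coverage %||% 0.8
  cfg$seed <- cfg$seed %||% 1L
  cfg$outdir <- cfg$outdir %||% "."
  for (s in cfg$structures)
    if (!is.null(s$path) && !file.exists(s$path))
      stop("config: structure file not found: ", s$path)
  if (!is.null(cfg$alignment$path) && !file.exists(cfg$alignment$path))
    stop("config: alignment file not found: ", cfg$alignment$path)
  attr(cfg, "hash") <- fnv1a_hash(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  class(cfg) <- c("RunConfig", class(cfg))
  cfg
}

config_header <- function(cfg) {
  c(paste0("erdesign report v", REPORT_SCHEMA_VERSION),
    paste0("config ", attr(cfg, "hash") %||% "unhashed"))
}

#' Run the pocket stage: union pocket over a structure manifest
#'
#' Reads every structure in the config manifest, selects its ligand,
#' extracts the pocket at the configured cutoff, and unions the per-
#' structure pockets in reference numbering (author numbering is taken as
#' the reference register unless the config supplies a
#' `reference_sequence`/`reference_start` to align against). Writes
#' `pocket.tsv` and `pocket.json` to the output directory.
#'
#' @param config A `RunConfig`, a config list, or a YAML path.
#' @return The union `PocketDefinition`, invisibly.
#' @export
run_pocket <- function(config) {
  cfg <- as_run_config(config)
  if (length(cfg$structures) == 0L)
    stop("usage: config lists no structures")
  pockets <- list()
  for (s in cfg$structures) {
    model <- read_pdb(s$path, id = s$id %||% NULL)
    ligand <- select_ligand(model, het_code = s$ligand %||% NULL)
    pocket <- extract_pocket(model, ligand, cutoff = cfg$cutoff)
    map <- NULL
    if (!is.null(cfg$reference_sequence))
      map <- map_to_reference(model, cfg$reference_sequence,
                              cfg$reference_start %||% 1L)
    pockets[[model$id]] <- pocket_reference_positions(pocket, map)
  }
  un <- union_pockets(pockets, cutoff = cfg$cutoff)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_pocket_report(un,
                      tsv = file.path(cfg$outdir, "pocket.tsv"),
                      json = file.path(cfg$outdir, "pocket.json"),
                      header_lines = config_header(cfg))
  invisible(un)
}

as_run_config <- function(config) {
  if (inherits(config, "RunConfig")) config else read_run_config(config)
}

#' Run the design stage: conservation profiles and candidate mutations
#'
#' Profiles the alignment at the pocket positions (from a prior
#' [run_pocket()] report in `outdir`, or a `positions` vector in the
#' config) and enumerates natural-variant candidate mutations. Writes
#' `conservation.tsv` and `candidates.tsv`.
#'
#' @param config A `RunConfig`, config list, or YAML path.
#' @return The `CandidateMutations` data frame, invisibly.
#' @export
run_design <- function(config) {
  cfg <- as_run_config(config)
  if (is.null(cfg$alignment$path)) stop("usage: config lacks an alignment")
  aln <- read_alignment(cfg$alignment$path,
                        format = cfg$alignment$format %||% "fasta",
                        reference_name = cfg$alignment$reference,
                        reference_start = cfg$alignment$reference_start %||% 1L)
  # duplicate/low-coverage removal is an explicit preprocessing choice
  # (config key `clean: true`): alignments curated upstream, or synthetic
  # alignments whose background columns are deliberately identical across
  # rows, must not be thinned silently
  if (isTRUE(cfg$clean))
    aln <- clean_alignment(aln, min_coverage = cfg$min_coverage)
  positions <- cfg$positions
  if (is.null(positions)) {
    pocket_tsv <- file.path(cfg$outdir, "pocket.tsv")
    if (!file.exists(pocket_tsv))
      stop("usage: no pocket positions in config and no pocket.tsv in ",
           cfg$outdir, "; run run_pocket() first")
    positions <- utils::read.delim(pocket_tsv, comment.char = "#")$position
  }
  profiles <- pocket_conservation(aln, as.integer(positions))
  cands <- candidate_mutations(profiles, min_support = cfg$min_support)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_conservation_report(profiles,
                            tsv = file.path(cfg$outdir, "conservation.tsv"),
                            header_lines = config_header(cfg))
  con <- file(file.path(cfg$outdir, "candidates.tsv"), "w")
  writeLines(paste0("# ", config_header(cfg)), con)
  utils::write.table(as.data.frame(cands), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(cands)
}

#' Run the mutate stage: model one point mutation
#'
#' Parses a mutation spec like `"M421F"` (wild type, position, target)
#' against the first manifest structure, verifies the wild-type residue,
#' scores all rotamers in bound and unbound states, and writes the best
#' mutant model as PDB plus a JSON clash/proximity report.
#'
#' @param config A `RunConfig`, config list, or YAML path.
#' @param mutation Mutation spec string, e.g. `"M421F"`.
#' @return List with `placement`, `report_bound`, `report_unbound`,
#'   `proximity` (NULL for non-aromatic targets), invisibly.
#' @export
run_mutate <- function(config, mutation) {
  cfg <- as_run_config(config)
  if (length(cfg$structures) == 0L) stop("usage: config lists no structures")
  m <- regmatches(mutation,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", mutation))[[1]]
  if (length(m) != 4L)
    stop("malformed mutation spec '", mutation, "'; expected e.g. M421F")
  wt <- toupper(m[2]); pos <- as.integer(m[3]); target <- toupper(m[4])

  s <- cfg$structures[[1]]
  model <- read_pdb(s$path, id = s$id %||% NULL)
  rk <- residue_keys(model)
  prot <- rk[!rk$is_hetero, , drop = FALSE]
  hit <- prot[prot$resno == pos, , drop = FALSE]
  if (nrow(hit) == 0L) stop("no residue ", pos, " in structure ", model$id)
  found <- aa_three_to_one(hit$resname[1])
  if (found != wt)
    stop("wild-type mismatch at position ", pos, ": spec says ", wt,
         " but structure has ", found, " (", hit$resname[1], ")")

  params <- clash_parameters(tolerance = cfg$clash$tolerance %||% 0.4)
  lib <- if (!is.null(cfg$rotamer_library)) rotamer_library(cfg$rotamer_library)
  else rotamer_library()
  placements <- mutate_residue(model, pos, target, rotamer_library = lib,
                               chain = hit$chain[1])
  rep_bound <- lapply(placements, clash_score, model = model,
                      params = params, include_ligand = TRUE)
  rep_unbound <- lapply(placements, clash_score, model = model,
                        params = params, include_ligand = FALSE)
  best <- best_placement(placements, rep_bound)
  best_report <- attr(best, "report")
  unbound_report <- rep_unbound[[best$rotamer]]

  prox <- NULL
  if (best$target %in% names(RING_ATOMS)) {
    ligand <- tryCatch(select_ligand(model, het_code = s$ligand %||% NULL),
                       error = function(e) NULL)
    if (!is.null(ligand))
      prox <- tryCatch(aromatic_proximity(best, ligand),
                       error = function(e) NULL)
  }

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  mutant <- apply_placement(model, best)
  write_pdb(mutant, file.path(cfg$outdir, paste0("mutant_", mutation, ".pdb")))
  jsonlite::write_json(
    list(schema_version = REPORT_SCHEMA_VERSION,
         config = attr(cfg, "hash"),
         mutation = mutation,
         rotamer = best$rotamer,
         chi = best$chi,
         clash_bound = list(total = best_report$total,
                            max_overlap = best_report$max_overlap,
                            clashing = best_report$clashing,
                            pairs = best_report$pairs),
         clash_unbound = list(total = unbound_report$total,
                              max_overlap = unbound_report$max_overlap,
                              clashing = unbound_report$clashing),
         proximity = if (!is.null(prox))
           list(centroid_distance = prox$centroid_distance,
                ring_atoms = prox$ring_atoms_used)),
    file.path(cfg$outdir, paste0("mutant_", mutation, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(placement = best, report_bound = best_report,
                 report_unbound = unbound_report, proximity = prox))
}

#' Run the assay stage: curve fits and fold-change classification
#'
#' If the config names a `plate_table` (columns `receptor`, `ligand`,
#' `concentration`, `unit`, `F_parallel`, `F_perpendicular`, or
#' pre-computed `p`), every receptor x ligand curve is fitted and an
#' affinity table assembled from the fits; zero-concentration control
#' wells are excluded from fits and reported separately. If the config
#' names an `affinity_table` (pre-fitted IC50s), it is read directly.
#' Fold changes of every other receptor against `reference_receptor` are
#' then classified. Writes `fits.tsv` and `fold_change.tsv`.
#'
#' @param config A `RunConfig`, config list, or YAML path.
#' @return List with `fits` (may be NULL), `affinity` (`AffinityTable`),
#'   `fold_changes` (list of `FoldChangeReport` by variant receptor),
#'   invisibly.
#' @export
run_assay <- function(config) {
  cfg <- as_run_config(config)
  fits <- NULL
  if (!is.null(cfg$assay$plate_table)) {
    plate <- utils::read.delim(cfg$assay$plate_table, comment.char = "#",
                               check.names = FALSE)
    fits <- fit_plate_table(plate, mode = cfg$assay$mode %||% "three_param")
    affinity <- fits_to_affinity(fits)
  } else if (!is.null(cfg$assay$affinity_table)) {
    affinity <- read_affinity_table(cfg$assay$affinity_table)
  } else {
    stop("usage: config lacks assay input (plate_table or affinity_table)")
  }
  ref <- cfg$assay$reference_receptor %||% unique(affinity$receptor)[1]
  variants <- setdiff(unique(affinity$receptor), ref)
  fcs <- lapply(variants, function(v) fold_change(affinity, ref, v))
  names(fcs) <- variants

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(cfg$outdir, "fits.tsv"), "w")
  writeLines(paste0("# ", config_header(cfg)), con)
  utils::write.table(as.data.frame(affinity), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  if (length(fcs)) {
    all_fc <- do.call(rbind, lapply(variants, function(v) {
      df <- as.data.frame(fcs[[v]])
      df$receptor <- v
      df$reference <- ref
      df
    }))
    con <- file(file.path(cfg$outdir, "fold_change.tsv"), "w")
    writeLines(paste0("# ", config_header(cfg)), con)
    utils::write.table(all_fc, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(list(fits = fits, affinity = affinity, fold_changes = fcs))
}

# Fit every receptor x ligand group of a long-format plate table.
fit_plate_table <- function(plate, mode = "three_param") {
  need_any <- all(c("receptor", "ligand", "concentration") %in% names(plate))
  if (!need_any)
    stop("plate table needs receptor, ligand and concentration columns; ",
         "found: ", paste(names(plate), collapse = ", "))
  if (!"p" %in% names(plate)) {
    if (!all(c("F_parallel", "F_perpendicular") %in% names(plate)))
      stop("plate table needs either a 'p' column or F_parallel and ",
           "F_perpendicular intensity columns")
    plate$p <- polarization(plate$F_parallel, plate$F_perpendicular)
  }
  if ("unit" %in% names(plate)) {
    fac <- CONC_UNIT_FACTORS[plate$unit]
    if (anyNA(fac)) {
      bad <- which(is.na(fac))
      stop("unresolvable concentration unit at plate row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    plate$concentration <- plate$concentration * fac
  }
  controls <- plate[plate$concentration == 0, , drop = FALSE]
  plate <- plate[plate$concentration > 0, , drop = FALSE]
  groups <- split(plate, list(plate$receptor, plate$ligand), drop = TRUE)
  fits <- lapply(groups, function(g)
    fit_competition(competition_curve(g$concentration, g$p,
                                      ligand = g$ligand[1],
                                      receptor = g$receptor[1]),
                    mode = mode))
  attr(fits, "controls") <- controls
  fits
}

fits_to_affinity <- function(fits) {
  rows <- Filter(function(f) f$converged, fits)
  if (length(rows) == 0L) stop("no competition fit converged")
  affinity_table(
    receptor = vapply(rows, function(f) f$receptor, ""),
    ligand = vapply(rows, function(f) f$ligand, ""),
    ic50 = vapply(rows, function(f)
      1e9 * 10^f$coefficients[["log_ic50"]], 0),
    se = vapply(rows, function(f) {
      s <- summary(f)
      max(1e9 * s$ic50_se, 1e-12)
    }, 0),
    unit = rep("nM", length(rows)))
}

#' Run the simulate stage: write synthetic fixtures
#'
#' Emits, under the config output directory, one synthetic complex
#' (`synthetic_complex.pdb` + ground truth TSV), one alignment
#' (`synthetic_alignment.fasta`), and competition/melt assay tables, all
#' generated from the config `seed`.
#'
#' @param config A `RunConfig`, config list, or YAML path.
#' @return Invisibly, a list of the generated objects.
#' @export
run_simulate <- function(config) {
  cfg <- as_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  cx <- make_complex(pocket_distances = c(3.5, 4.0, 4.5, 5.0, 5.5, 5.9),
                     n_far_residues = 8L, cutoff = cfg$cutoff, seed = seed)
  writeLines(cx$pdb, file.path(cfg$outdir, "synthetic_complex.pdb"))
  utils::write.table(cx$truth,
                     file.path(cfg$outdir, "synthetic_complex_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  aln <- make_alignment(200L,
                        column_specs = list(
                          "421" = c(M = 170, L = 5, I = 3, F = 22)),
                        seed = seed)
  writeLines(paste0(">", names(aln$sequences), "\n", aln$sequences),
             file.path(cfg$outdir, "synthetic_alignment.fasta"))
  curve <- make_competition_curve(1e-8, noise_sd = 0.03, seed = seed)
  utils::write.table(data.frame(concentration = curve$concentration,
                                p = curve$p),
                     file.path(cfg$outdir, "synthetic_competition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  melt <- make_melt_curve(59.5, noise_sd = 0.02, seed = seed)
  utils::write.table(data.frame(temperature = melt$temperature,
                                signal = melt$signal),
                     file.path(cfg$outdir, "synthetic_melt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(complex = cx, alignment = aln, competition = curve,
                 melt = melt))
}
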