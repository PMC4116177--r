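#!/usr/bin/env Rscript
# Fetch the real human ER-alpha LBD complex structures used for the
# 25-residue pocket reproduction, and write the manifest the pocket stage
# consumes. Network access required; the tested core never downloads.
#
# Usage: Rscript scripts/fetch_structures.R [--dest DIR]
# Default destination: inst/extdata/structures (re-install the package
# afterwards so system.file() can see the manifest).

args <- commandArgs(trailingOnly = TRUE)
dest <- "inst/extdata/structures"
if (length(args) >= 2 && args[1] == "--dest") dest <- args[2]
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

# ER-alpha LBD complexes with chemically distinct ligands:
#   1ERE  17beta-estradiol (EST)
#   3UU7  bisphenol-A (BPA)
#   3ERT  4-hydroxytamoxifen (OHT)
manifest <- list(structures = list(
  list(id = "1ERE", file = "1ERE.pdb", ligand = "EST", chain = "A"),
  list(id = "3UU7", file = "3UU7.pdb", ligand = "BPA", chain = "A"),
  list(id = "3ERT", file = "3ERT.pdb", ligand = "OHT", chain = "A")
))

for (s in manifest$structures) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", s$id)
  path <- file.path(dest, s$file)
  message("fetching ", url)
  utils::download.file(url, path, quiet = TRUE, mode = "wb")
}
yaml::write_yaml(manifest, file.path(dest, "manifest.yaml"))
message("manifest written to ", file.path(dest, "manifest.yaml"))
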