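# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

with_seed_local <- erdesign:::with_seed

# A PDB line for one atom.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          het = FALSE, occ = 1, altloc = " ",
                          element = substr(name, 1, 1)) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%s%5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM  ", serial, name4,
          altloc, resname, chain, resno, x, y, z, occ, 0, element)
}

# CA-only chain with the given one-letter sequence and author numbering.
make_chain_pdb <- function(seq_letters, start_resno = 1L, chain = "A") {
  three <- vapply(strsplit(seq_letters, "")[[1]],
                  erdesign:::aa_one_to_three, "")
  lines <- vapply(seq_along(three), function(i) {
    pdb_atom_line(i, "CA", three[i], chain, start_resno + i - 1L,
                  x = 3.8 * i, y = 0, z = 0, element = "C")
  }, "")
  c(lines, "END")
}

# Ideal backbone for one residue at the origin (N, CA, C, O), residue
# name/number configurable, plus optional extra PDB lines.
ideal_backbone_lines <- function(resname = "ALA", chain = "A", resno = 1L,
                                 serial0 = 0L) {
  c(pdb_atom_line(serial0 + 1, "N", resname, chain, resno, -0.525, 1.362, 0,
                  element = "N"),
    pdb_atom_line(serial0 + 2, "CA", resname, chain, resno, 0, 0, 0,
                  element = "C"),
    pdb_atom_line(serial0 + 3, "C", resname, chain, resno, 1.526, 0, 0,
                  element = "C"),
    pdb_atom_line(serial0 + 4, "O", resname, chain, resno, 2.153, 1.047, 0,
                  element = "O"))
}

backbone_model <- function(extra_lines = character(), resname = "ALA",
                           resno = 1L) {
  read_pdb(paste(c(ideal_backbone_lines(resname = resname, resno = resno),
                   extra_lines, "END"), collapse = "\n"))
}

# Model holding a complete idealised residue of the given type built from
# the package's own side-chain templates at the given chi angles.
ideal_residue_model <- function(resname, chis) {
  bb <- list(N = c(-0.525, 1.362, 0), CA = c(0, 0, 0), C = c(1.526, 0, 0))
  sc <- erdesign:::build_sidechain(resname, bb, chis)
  lines <- ideal_backbone_lines(resname = resname)
  s <- 4L
  for (nm in rownames(sc)) {
    s <- s + 1L
    lines <- c(lines, pdb_atom_line(s, nm, resname, "A", 1L,
                                    sc[nm, 1], sc[nm, 2], sc[nm, 3],
                                    element = substr(nm, 1, 1)))
  }
  read_pdb(paste(c(lines, "END"), collapse = "\n"))
}

# Brute-force pocket oracle: per-residue all-pairs minimum distance, plain
# loops, independent of extract_pocket's vectorised path.
brute_force_pocket <- function(model, ligand, cutoff) {
  a <- model$atoms
  lig <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  prot <- a[!a$is_hetero & !a$is_hydrogen, , drop = FALSE]
  keys <- unique(paste(prot$chain, prot$resno, prot$icode, sep = "|"))
  hits <- character(0)
  for (k in keys) {
    res <- prot[paste(prot$chain, prot$resno, prot$icode, sep = "|") == k, ]
    dmin <- Inf
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(lig))) {
      d <- sqrt((res$x[i] - lig$x[j])^2 + (res$y[i] - lig$y[j])^2 +
                  (res$z[i] - lig$z[j])^2)
      if (d < dmin) dmin <- d
    }
    if (dmin <= cutoff) hits <- c(hits, k)
  }
  sort(hits)
}

pocket_keys <- function(pocket_df) {
  sort(paste(pocket_df$chain, pocket_df$resno, pocket_df$icode, sep = "|"))
}
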