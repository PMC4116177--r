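test_that("a minimal hand-written PDB parses with all records", {
  txt <- paste(c(
    pdb_atom_line(1, "N", "ALA", "A", 10, 1, 2, 3, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 10, 2, 2, 3),
    pdb_atom_line(3, "C", "ALA", "A", 10, 3, 2, 3),
    "END"), collapse = "\n")
  m <- read_pdb(txt)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(residue_keys(m)), 1L)
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  expect_equal(m$atoms$resno, rep(10L, 3))
})

test_that("synthetic complexes round-trip through write/read", {
  cx <- make_complex(c(3.5, 4.5, 5.5), n_far_residues = 4, seed = 11)
  m2 <- read_pdb(paste(write_pdb(cx$model), collapse = "\n"))
  k1 <- residue_keys(cx$model)
  k2 <- residue_keys(m2)
  expect_equal(k2$key, k1$key)
  expect_equal(k2$resname, k1$resname)
  expect_equal(m2$atoms$name, cx$model$atoms$name)
  expect_lt(max(abs(m2$atoms$x - cx$model$atoms$x)), 1e-3)
  expect_lt(max(abs(m2$atoms$y - cx$model$atoms$y)), 1e-3)
  expect_lt(max(abs(m2$atoms$z - cx$model$atoms$z)), 1e-3)
  # parsing drops nothing: counts match the record count
  expect_equal(nrow(m2$atoms),
               sum(grepl("^(ATOM  |HETATM)", cx$pdb)))
})

test_that("altloc copies collapse to the highest-occupancy atom", {
  txt <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.6, altloc = "A"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 2, 0, 0, occ = 0.4, altloc = "B"),
    "END"), collapse = "\n")
  m <- read_pdb(txt)
  cb <- m$atoms[m$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 1)  # the occupancy-0.6 A copy

  # occupancy tie breaks toward the lexicographically smaller altloc
  txt2 <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 5, 0, 0, occ = 0.5, altloc = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 6, 0, 0, occ = 0.5, altloc = "A"),
    "END"), collapse = "\n")
  cb2 <- read_pdb(txt2)$atoms
  cb2 <- cb2[cb2$name == "CB", ]
  expect_equal(cb2$x, 6)  # altloc A wins the tie
})

test_that("only the first MODEL of a multi-model file is read", {
  txt <- paste(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 99, 0, 0),
    "ENDMDL", "END"), collapse = "\n")
  m <- read_pdb(txt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 0)
  expect_equal(m$model_index, 1L)
})

test_that("malformed and empty structures raise informative errors", {
  bad <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END")
  bad[1] <- sub("   0.000", "  bogusX", bad[1])
  expect_error(read_pdb(paste(bad, collapse = "\n")),
               "malformed coordinate field at line 1")
  expect_error(read_pdb("REMARK nothing here\nEND"), "empty structure")
})

test_that("hydrogens are parsed and flagged", {
  txt <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "HA", "ALA", "A", 1, 0.5, 0, 0, element = "H"),
    "END"), collapse = "\n")
  m <- read_pdb(txt)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$is_hydrogen, c(FALSE, TRUE))
})

test_that("ligand auto-selection picks the largest non-water hetero group", {
  # one 12-atom ligand among waters -> the ligand
  cx <- make_complex(c(4), n_far_residues = 0, ligand_atoms = 12, seed = 3)
  waters <- vapply(1:5, function(i)
    pdb_atom_line(200 + i, "O", "HOH", "W", 500 + i, 30 + i, 30, 30,
                  het = TRUE, element = "O"), "")
  m <- read_pdb(paste(c(write_pdb(cx$model)[-length(cx$pdb)], waters, "END"),
                      collapse = "\n"))
  lig <- select_ligand(m)
  expect_equal(lig$het_code, "LIG")
  expect_equal(nrow(lig$atoms), 12L)

  # two hetero groups of 20 and 6 atoms -> the 20-atom group
  g20 <- vapply(1:20, function(i)
    pdb_atom_line(i, paste0("C", i), "BIG", "B", 901, i, 0, 0, het = TRUE), "")
  g6 <- vapply(1:6, function(i)
    pdb_atom_line(20 + i, paste0("C", i), "SML", "B", 902, i, 10, 0,
                  het = TRUE), "")
  m2 <- read_pdb(paste(c(g20, g6, "END"), collapse = "\n"))
  expect_equal(select_ligand(m2)$het_code, "BIG")
  # explicit request for a water is rejected
  expect_error(select_ligand(m2, "HOH"), "excluded")
  # absent code is a not-found error
  expect_error(select_ligand(m2, "XYZ"), "not found")
})

test_that("min_distance matches hand values and the all-pairs oracle", {
  a <- matrix(c(0, 0, 0), ncol = 3)
  b <- matrix(c(3, 4, 0), ncol = 3)
  expect_equal(min_distance(a, b), 5)
  expect_equal(min_distance(a, a), 0)
  expect_error(min_distance(a[0, , drop = FALSE], b), "non-empty")

  set.seed(99)
  for (rep in 1:5) {
    A <- matrix(rnorm(30, sd = 5), ncol = 3)
    B <- matrix(rnorm(30, sd = 5), ncol = 3)
    brute <- Inf
    for (i in 1:10) for (j in 1:10)
      brute <- min(brute, sqrt(sum((A[i, ] - B[j, ])^2)))
    expect_equal(min_distance(A, B), brute)
    # symmetry and non-negativity
    expect_equal(min_distance(B, A), min_distance(A, B))
    expect_gte(min_distance(A, B), 0)
  }
})
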