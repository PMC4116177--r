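test_that("internal-coordinate placement achieves the requested geometry", {
  a <- c(1.2, -0.3, 0.8); b <- c(0, 0, 0); c3 <- c(1.5, 0, 0)
  for (dih in c(-120, -65, 0, 60, 90, 180)) {
    d <- erdesign:::place_atom(a, b, c3, bond = 1.52, angle = 111, dihedral = dih)
    expect_equal(erdesign:::vnorm(d - c3), 1.52, tolerance = 1e-9)
    expect_equal(erdesign:::bond_angle(b, c3, d), 111, tolerance = 1e-6)
    got <- erdesign:::dihedral_angle(a, b, c3, d)
    expect_equal(((got - dih + 180) %% 360) - 180, 0, tolerance = 1e-6)
  }
})

test_that("mutating to glycine leaves no side chain and zero clash", {
  m <- backbone_model()
  pl <- mutate_residue(m, 1, "GLY")
  expect_length(pl, 1L)
  expect_equal(nrow(pl[[1]]$atoms), 0L)
  expect_equal(pl[[1]]$clash_score, 0)
  rep <- clash_score(m, pl[[1]])
  expect_false(rep$clashing)
})

test_that("phenylalanine placements match the library and ideal ring geometry", {
  m <- backbone_model()
  lib <- rotamer_library()
  pl <- mutate_residue(m, 1, "PHE", rotamer_library = lib)
  expect_length(pl, sum(lib$resname == "PHE"))
  for (p in pl) {
    expect_equal(sort(p$atoms$name),
                 sort(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")))
    expect_length(p$chi, 2L)  # F has two chi angles
    ring <- as.matrix(p$atoms[p$atoms$name != "CB", c("x", "y", "z")])
    # planarity: smallest principal extent below 0.05 A
    expect_lt(svd(scale(ring, scale = FALSE))$d[3], 0.05)
  }
  # chi counts by residue type
  expect_length(mutate_residue(m, 1, "MET")[[1]]$chi, 3L)
  expect_length(mutate_residue(m, 1, "ILE")[[1]]$chi, 2L)
  expect_length(mutate_residue(m, 1, "LEU")[[1]]$chi, 2L)
})

test_that("backbone atoms are required and unknown targets rejected", {
  txt <- paste(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END"),
               collapse = "\n")
  m <- read_pdb(txt)
  expect_error(mutate_residue(m, 1, "PHE"), "backbone")
  expect_error(mutate_residue(backbone_model(), 1, "TRP"), "unsupported")
  expect_error(mutate_residue(backbone_model(), 99, "PHE"), "no residue")
})

test_that("re-placing the native residue at native chi reproduces its coordinates", {
  for (case in list(list("PHE", c(-65, 90)), list("MET", c(180, 180, 75)),
                    list("LEU", c(62, 175)))) {
    resname <- case[[1]]; chis <- case[[2]]
    m <- ideal_residue_model(resname, chis)
    pl <- mutate_residue(m, 1, resname)
    match_rot <- Filter(function(p) all(abs(p$chi - chis) < 1e-6), pl)
    expect_length(match_rot, 1L)
    new_at <- match_rot[[1]]$atoms
    old_at <- m$atoms[m$atoms$name %in% new_at$name, ]
    new_at <- new_at[match(old_at$name, new_at$name), ]
    dev <- sqrt((new_at$x - old_at$x)^2 + (new_at$y - old_at$y)^2 +
                  (new_at$z - old_at$z)^2)
    expect_lt(max(dev), 0.5)
  }
})

test_that("the overlap arithmetic matches the soft-sphere formula", {
  # environment: a single carbon probe in a second residue, placed at a
  # controlled distance from the rebuilt CB of residue 1
  m0 <- backbone_model()
  pl <- mutate_residue(m0, 1, "ALA")[[1]]
  cb <- as.numeric(pl$atoms[1, c("x", "y", "z")])
  probe_at <- function(d) {
    dir <- erdesign:::unit(cb - c(0, 0, 0))
    pos <- cb + d * dir
    backbone_model(pdb_atom_line(90, "C", "GLY", "B", 50,
                                 pos[1], pos[2], pos[3]))
  }
  # 4.0 A apart: 1.7 + 1.7 - 4.0 - 0.4 < 0 -> no pair
  rep_far <- clash_score(probe_at(4.0), mutate_residue(probe_at(4.0), 1, "ALA")[[1]])
  expect_equal(nrow(rep_far$pairs), 0L)
  expect_false(rep_far$clashing)
  # 1.0 A apart: overlap = 1.7 + 1.7 - 1.0 - 0.4 = 2.0
  m_close <- probe_at(1.0)
  rep_close <- clash_score(m_close, mutate_residue(m_close, 1, "ALA")[[1]])
  expect_equal(nrow(rep_close$pairs), 1L)
  expect_equal(rep_close$pairs$overlap, 2.0, tolerance = 1e-4)
  expect_equal(rep_close$total, 2.0, tolerance = 1e-4)
  expect_true(rep_close$clashing)
})

test_that("clash total is non-increasing as the tolerance grows", {
  cx <- make_complex(c(2.5, 3.0), n_far_residues = 0, seed = 31)
  lines <- c(ideal_backbone_lines(), write_pdb(cx$model)[
    grepl("^HETATM", write_pdb(cx$model))], "END")
  m <- read_pdb(paste(lines, collapse = "\n"))
  pl <- mutate_residue(m, 1, "PHE")
  tols <- c(0, 0.2, 0.4, 0.8, 1.5)
  for (p in pl) {
    totals <- vapply(tols, function(tl)
      clash_score(m, p, clash_parameters(tolerance = tl))$total, 0)
    expect_true(all(diff(totals) <= 1e-12))
  }
})

test_that("a cramped site clashes for every rotamer and a roomy one does not", {
  # cramped: carbon shell at 2.4 A around the CA, inside any side chain
  shell <- list()
  k <- 0
  for (th in seq(0, pi, length.out = 5)) for (ph in seq(0, 2 * pi,
                                                        length.out = 7)[-7]) {
    k <- k + 1
    shell[[k]] <- pdb_atom_line(100 + k, paste0("C", k), "LIG", "L", 900,
                                2.4 * sin(th) * cos(ph),
                                2.4 * sin(th) * sin(ph),
                                2.4 * cos(th), het = TRUE)
  }
  m_cramped <- backbone_model(unlist(shell))
  pl <- mutate_residue(m_cramped, 1, "PHE")
  reps <- lapply(pl, clash_score, model = m_cramped, include_ligand = TRUE)
  expect_true(all(vapply(reps, function(r) r$clashing, TRUE)))
  # the unbound state (ligand omitted) accommodates the same side chain
  reps_unbound <- lapply(pl, clash_score, model = m_cramped,
                         include_ligand = FALSE)
  expect_false(any(vapply(reps_unbound, function(r) r$clashing, TRUE)))

  # roomy: single distant ligand atom
  m_roomy <- backbone_model(pdb_atom_line(100, "C1", "LIG", "L", 900,
                                          20, 20, 20, het = TRUE))
  pl2 <- mutate_residue(m_roomy, 1, "PHE")
  reps2 <- lapply(pl2, clash_score, model = m_roomy, include_ligand = TRUE)
  expect_true(any(!vapply(reps2, function(r) r$clashing, TRUE)))
})

test_that("best_placement is the clash argmin with stable tie-breaks", {
  m <- backbone_model(pdb_atom_line(100, "C1", "LIG", "L", 900, 20, 20, 20,
                                    het = TRUE))
  pl <- mutate_residue(m, 1, "PHE")
  fake <- function(total, maxo) list(total = total, max_overlap = maxo)
  reps <- list(fake(2.1, 1.0), fake(0.0, 0.0), fake(0.7, 0.7),
               fake(0.0, 0.0), fake(1.0, 0.4), fake(0.0, 0.1))
  best <- best_placement(pl, reps)
  expect_equal(best$rotamer, 2L)  # first of the zero-total ties

  set.seed(123)
  for (i in 1:100) {
    totals <- round(runif(6, 0, 3), 2)
    maxes <- round(runif(6, 0, 1), 2)
    reps <- Map(fake, totals, maxes)
    best <- best_placement(pl, reps)
    # exhaustive oracle
    oracle <- 1L
    for (j in 2:6) {
      if (totals[j] < totals[oracle] ||
          (totals[j] == totals[oracle] && maxes[j] < maxes[oracle]))
        oracle <- j
    }
    expect_equal(best$rotamer, oracle)
  }
  expect_error(best_placement(list()), "no placements")
})

test_that("aromatic proximity computes centroid distances and auto-detects rings", {
  hexagon <- function(cx, cy, cz, r = 1.39) t(vapply(0:5, function(k)
    c(cx + r * cos(k * pi / 3), cy + r * sin(k * pi / 3), cz), numeric(3)))

  # two parallel rings 3.8 A apart as residue ring + ligand ring
  m <- backbone_model()
  pl <- mutate_residue(m, 1, "PHE")[[1]]
  ring <- as.matrix(pl$atoms[pl$atoms$name != "CB", c("x", "y", "z")])
  centroid <- colMeans(ring)
  # ligand ring: the residue ring translated by 3.8 A
  shift <- c(0, 0, 3.8)
  lig_lines <- vapply(1:6, function(i)
    pdb_atom_line(100 + i, paste0("C", i), "BPA", "B", 901,
                  ring[i, 1] + shift[1], ring[i, 2] + shift[2],
                  ring[i, 3] + shift[3], het = TRUE), "")
  m2 <- read_pdb(paste(c(ideal_backbone_lines(), lig_lines, "END"),
                       collapse = "\n"))
  prox <- aromatic_proximity(pl, select_ligand(m2), paste0("C", 1:6))
  expect_equal(prox$centroid_distance, 3.8, tolerance = 1e-3)

  # identical ring coordinates -> distance 0
  lig0 <- vapply(1:6, function(i)
    pdb_atom_line(100 + i, paste0("C", i), "BPA", "B", 901,
                  ring[i, 1], ring[i, 2], ring[i, 3], het = TRUE), "")
  m0 <- read_pdb(paste(c(ideal_backbone_lines(), lig0, "END"),
                       collapse = "\n"))
  expect_equal(aromatic_proximity(pl, select_ligand(m0),
                                  paste0("C", 1:6))$centroid_distance,
               0, tolerance = 1e-3)

  # bisphenol-like two-ring ligand: auto selection takes the closer ring
  ring_a <- hexagon(centroid[1], centroid[2], centroid[3] + 4.2)
  ring_b <- hexagon(centroid[1] + 6.0, centroid[2], centroid[3] + 4.2)
  two_ring <- c(
    vapply(1:6, function(i) pdb_atom_line(100 + i, paste0("CA", i), "BPA",
                                          "B", 901, ring_a[i, 1], ring_a[i, 2],
                                          ring_a[i, 3], het = TRUE), ""),
    vapply(1:6, function(i) pdb_atom_line(110 + i, paste0("CB", i), "BPA",
                                          "B", 901, ring_b[i, 1], ring_b[i, 2],
                                          ring_b[i, 3], het = TRUE), ""))
  mb <- read_pdb(paste(c(ideal_backbone_lines(), two_ring, "END"),
                       collapse = "\n"))
  prox_auto <- aromatic_proximity(pl, select_ligand(mb), "auto")
  d_a <- erdesign:::vnorm(colMeans(ring_a) - centroid)
  d_b <- erdesign:::vnorm(colMeans(ring_b) - centroid)
  expect_equal(prox_auto$centroid_distance, min(d_a, d_b), tolerance = 1e-3)

  # non-aromatic placements are rejected
  pl_met <- mutate_residue(m, 1, "MET")[[1]]
  expect_error(aromatic_proximity(pl_met, select_ligand(m2)), "not aromatic")
})
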