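test_that("PDB ensembles roundtrip through write and read", {
  e1 <- make_torsion_ensemble(60.0, -30.0)
  path <- tempfile(fileext = ".pdb")
  write_ensemble(e1, path)
  e2 <- read_ensemble(path)
  expect_equal(length(e2$models), 1L)
  expect_equal(e2$atoms$name, e1$atoms$name)
  expect_lt(max(abs(e2$models[[1]] - e1$models[[1]])), 5e-4)

  phis <- seq(-170, 170, length.out = 20)
  psis <- seq(-80, 80, length.out = 20)
  e20 <- make_torsion_ensemble(phis, psis)
  write_ensemble(e20, path)
  r20 <- read_ensemble(path)
  expect_equal(length(r20$models), 20L)
  for (m in c(1, 10, 20))
    expect_lt(max(abs(r20$models[[m]] - e20$models[[m]])), 5e-4)
})

test_that("roster mismatches between models are rejected with the offender named", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  O5  PYR A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  C1  PYR A   1       1.430   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  O5  PYR A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  C2  PYR A   1       1.430   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END")
  expect_error(read_ensemble(lines), "roster")
})

test_that("glycosidic torsions are recovered exactly from constructed geometry", {
  e <- make_torsion_ensemble(c(60.0, -123.4), c(-30.0, 171.2))
  lk <- glycosidic_linkage(1, 2, ox = "O4", cx = "C4", cprev = "C3")
  tr <- glycosidic_torsions(e, lk)
  expect_lt(max(abs(tr$phi - c(60.0, -123.4))), 1e-6)
  expect_lt(max(abs(tr$psi - c(-30.0, 171.2))), 1e-6)

  ## single-model ensemble: zero spread
  tr1 <- glycosidic_torsions(make_torsion_ensemble(60, -30), lk)
  expect_equal(tr1$phi_sd, 0, tolerance = 1e-9)
  expect_equal(tr1$phi_mean, 60, tolerance = 1e-6)

  ## the proton-based convention is a fixed offset of the same torsion set
  trh <- glycosidic_torsions(e, lk, convention = "h1")
  expect_equal(trh$convention, "h1")
  expect_lt(max(abs(trh$psi - tr$psi)), 1e-9)
  expect_lt(diff(range(wrap_angle(trh$phi - tr$phi))), 1e-6)

  ## missing atoms are reported by name
  e_bad <- e
  e_bad$atoms$name[e_bad$atoms$name == "C3"] <- "CX"
  expect_error(glycosidic_torsions(e_bad, lk), "C3")
})

test_that("circular statistics respect the wrap point", {
  e <- make_torsion_ensemble(c(179, -179), c(10, 20))
  lk <- glycosidic_linkage(1, 2, ox = "O4", cx = "C4", cprev = "C3")
  tr <- glycosidic_torsions(e, lk)
  expect_equal(tr$phi_mean, 180, tolerance = 1e-6)
  expect_equal(tr$phi_sd, 1, tolerance = 0.01)
})

test_that("ensemble RMSD is zero for identical or rigidly moved models", {
  e <- make_torsion_ensemble(c(60, 60, 60), c(-30, -30, -30))
  r <- ensemble_rmsd(e, rep(TRUE, 6))
  expect_equal(r$mean_rmsd, 0, tolerance = 1e-9)

  ## rigid rotation + translation of one model: still zero after fitting
  e$models[[2]] <- random_rigid(e$models[[2]], 4)
  r2 <- ensemble_rmsd(e, rep(TRUE, 6))
  expect_equal(r2$mean_rmsd, 0, tolerance = 1e-9)

  ## invariance of a nonzero RMSD to per-model rigid transforms
  e3 <- make_torsion_ensemble(c(60, 80, 100), c(-30, -10, 20))
  base <- ensemble_rmsd(e3, rep(TRUE, 6))$mean_rmsd
  e3$models <- lapply(seq_along(e3$models), function(m)
    random_rigid(e3$models[[m]], 100 + m))
  expect_equal(ensemble_rmsd(e3, rep(TRUE, 6))$mean_rmsd, base,
               tolerance = 1e-9)

  expect_error(ensemble_rmsd(e3, c(TRUE, TRUE, rep(FALSE, 4))), "3 atoms")
})

test_that("SVD superposition agrees with the quaternion oracle on random point sets", {
  set.seed(57)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- matrix(rnorm(3 * n), n, 3)
    y <- matrix(rnorm(3 * n), n, 3)
    a <- glycotop:::superpose_rmsd(x, y)
    b <- oracle_quaternion_rmsd(x, y)
    expect_lt(abs(a - b), 1e-9)
  }
})

test_that("to-mean RMSD mode is consistent with the pairwise mode ordering", {
  e <- make_torsion_ensemble(c(60, 75, 90, 105), c(-30, -20, -10, 0))
  rp <- ensemble_rmsd(e, rep(TRUE, 6), mode = "pairwise")
  rm <- ensemble_rmsd(e, rep(TRUE, 6), mode = "to_mean")
  expect_gt(rp$mean_rmsd, 0)
  expect_gt(rm$mean_rmsd, 0)
  ## spread to the mean structure is smaller than mean pairwise spread
  expect_lt(rm$mean_rmsd, rp$mean_rmsd + 1e-9)
})

test_that("Cremer-Pople classification spans planar, chair and boat", {
  ## planar hexagon
  j <- 0:5
  hexagon <- cbind(cos(j * pi / 3), sin(j * pi / 3), 0) * 1.45
  rownames(hexagon) <- c("O5", "C1", "C2", "C3", "C4", "C5")
  pk <- ring_pucker(hexagon)
  expect_equal(pk$Q, 0, tolerance = 1e-12)
  expect_equal(pk$class, "planar")

  b <- make_pyranose()
  pc <- ring_pucker(b$conf)
  expect_equal(pc$class, "chair")
  expect_true(pc$theta <= 10 || pc$theta >= 170)
  expect_gt(pc$Q, 0.4)

  pb <- ring_pucker(b$variants$boat)
  expect_equal(pb$theta, 90, tolerance = 1e-6)
  expect_equal(pb$class, "boat")

  ## a twist-boat: m = 2 mode with a 30-degree phase
  twist <- glycotop:::.boat_ring(phi2 = 30)
  rownames(twist) <- c("O5", "C1", "C2", "C3", "C4", "C5")
  pt <- ring_pucker(twist)
  expect_equal(pt$class, "twist-boat")

  ## non-ring input warns but computes
  stretched <- hexagon * 2
  expect_warning(ring_pucker(stretched), "not mutually bonded")
})

test_that("mirror-imaging flips torsion signs and chair handedness together", {
  e <- make_torsion_ensemble(c(60, 70), c(-30, -40))
  lk <- glycosidic_linkage(1, 2, ox = "O4", cx = "C4", cprev = "C3")
  t0 <- glycosidic_torsions(e, lk)
  em <- e
  em$models <- lapply(em$models, function(x) { x[, 1] <- -x[, 1]; x })
  t1 <- glycosidic_torsions(em, lk)
  expect_equal(t1$phi, -t0$phi, tolerance = 1e-9)
  expect_equal(t1$psi, -t0$psi, tolerance = 1e-9)

  b <- make_pyranose()
  th0 <- ring_pucker(b$conf)$theta
  th1 <- ring_pucker(b$variants$mirror)$theta
  expect_equal(th1, 180 - th0, tolerance = 1e-6)
  ## and chirality checking flags every center of the mirror image
  expect_equal(nrow(check_chirality(b$variants$mirror, b$centers)),
               nrow(b$centers))
})

test_that("XPLOR assign statements parse, span lines, and count symmetrically", {
  expect_length(parse_distance_restraints(""), 0L)

  txt <- c(
    "! toy NOE table",
    "assign (resid 166 and name H1) (resid 12 and name HB) 3.5 1.7 0.5",
    "assign (resid 166 and name H8)",
    "       (resid 40 and name HN) 4.0 2.2 1.0",
    "assign (resid 166 and name H1) (resid 166 and name H3) 2.8 1.0 0.5")
  rec <- parse_distance_restraints(txt)
  expect_length(rec, 3L)
  expect_equal(rec[[1]]$d, 3.5)
  expect_equal(rec[[2]]$sel2[[1]]$resid, "40")

  sugar <- list(resid = 166)
  protein <- list(resid = 166, negate = TRUE)
  expect_equal(count_between(rec, sugar, protein), 2L)
  expect_equal(count_between(rec, protein, sugar), 2L)
  expect_equal(count_between(rec, sugar, sugar), 1L)

  ## segid + resname clauses and or-groups
  txt2 <- "assign (segid A and resname A2G and name H1 or segid A and resname A2G and name H8) (resid 5 and name HN) 4.0 2.2 1.0"
  rec2 <- parse_distance_restraints(txt2)
  expect_equal(count_between(rec2, list(resname = "A2G"),
                             list(resname = "A2G", negate = TRUE)), 1L)

  expect_error(parse_distance_restraints("assign (resid 1 and name H1) 3.5 1.7 0.5"),
               "two selections")
  expect_error(parse_distance_restraints("assign (resid 1) (resid 2) 3.5"),
               "three distance values")
})
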