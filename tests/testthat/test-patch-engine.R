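make_ser_topology <- function() {
  t <- new_topology_set(autogenerate_angles = TRUE)
  res <- glycotop:::new_residue_topology("SER")
  res$atoms <- data.frame(name = c("CA", "HA", "CB", "HB1", "HB2", "OG", "HG"),
                          type = c("CT", "HA", "CT", "HA", "HA", "OH", "HO"),
                          charge = 0, mass = NA_real_, stringsAsFactors = FALSE)
  res$bonds <- rbind(c("CA", "HA"), c("CA", "CB"), c("CB", "HB1"),
                     c("CB", "HB2"), c("CB", "OG"), c("OG", "HG"))
  t$residues[["SER"]] <- glycotop:::.check_residue(res, "SER")
  t
}

test_that("build_molecule concatenates residues without inter-residue bonds", {
  b <- make_pyranose()
  mol1 <- build_molecule("PYR", b$topology)
  expect_equal(nrow(mol1$atoms), 24L)
  expect_equal(glycotop:::n_components(mol1), 1L)

  mol2 <- build_molecule(c("PYR", "PYR"), b$topology)
  expect_equal(nrow(mol2$atoms), 48L)
  expect_equal(glycotop:::n_components(mol2), 2L)
  expect_equal(nrow(mol2$bonds), 2L * nrow(mol1$bonds))

  expect_error(build_molecule("XYZ", b$topology), "unknown residue")
})

test_that("instantiated term lists equal a brute-force enumeration", {
  b <- make_pyranose()
  mol <- build_molecule("PYR", b$topology)
  oracle <- oracle_residue_terms(b$topology$residues$PYR)
  norm <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
  expect_equal(norm(unname(mol$bonds)), norm(unname(oracle$bonds)))
  expect_equal(norm(unname(mol$impropers)), norm(unname(oracle$impropers)))
})

test_that("an empty patch leaves the molecule unchanged", {
  b <- make_pyranose()
  mol <- build_molecule("PYR", b$topology)
  p <- glycotop:::new_patch_def("NOP")
  expect_equal(apply_patch(mol, p, 1L), mol)
})

test_that("a glycosidic linkage patch condenses two rings into one molecule", {
  b <- make_pyranose()
  mol <- build_molecule(c("PYR", "PYR"), b$topology)
  n_bonds0 <- nrow(mol$bonds)
  n_atoms0 <- nrow(mol$atoms)

  b14 <- glycotop:::new_patch_def("B14")
  b14$statements <- list(
    list(action = "delete", kind = "atom", refs = "1-O1"),
    list(action = "delete", kind = "atom", refs = "1-HO1"),
    list(action = "delete", kind = "atom", refs = "2-HO4"),
    list(action = "add", kind = "bond", refs = c("1-C1", "2-O4")))
  out <- apply_patch(mol, b14, c(1L, 2L))

  expect_equal(nrow(out$atoms), n_atoms0 - 3L)
  expect_equal(glycotop:::n_components(out), 1L)
  ## bonds touching O1 (2), HO1 (already counted), HO4 (1) vanish; 1 added
  expect_equal(nrow(out$bonds), n_bonds0 - 3L + 1L)
  ## the new bond joins C1 of residue 1 to O4 of residue 2
  i_c1 <- which(out$atoms$res_index == 1 & out$atoms$name == "C1")
  i_o4 <- which(out$atoms$res_index == 2 & out$atoms$name == "O4")
  hit <- apply(out$bonds, 1, function(r) setequal(r, c(i_c1, i_o4)))
  expect_equal(sum(hit), 1L)

  expect_error(apply_patch(mol, local({
    p <- glycotop:::new_patch_def("BAD")
    p$statements <- list(list(action = "delete", kind = "atom", refs = "1-ZZ"))
    p
  }), c(1L, 2L)), "1-ZZ")
})

test_that("the glycosylation catalogue has the sixteen linkage patches", {
  patches <- generate_glycosylation_patches()
  expect_setequal(names(patches),
                  c("A1S", "A1T", "B1S", "B1T", "A1C", "B1C", "B13", "B16",
                    "B13L", "B16L", "A1SL", "B1SL", "A1TL", "B1TL", "A1CL", "B1CL"))
  expect_equal(patches$A1C$link_atom, "SG")
  expect_equal(patches$B1C$link_atom, "SG")
  expect_equal(patches$A1S$link_atom, "OG")
  expect_equal(patches$A1T$link_atom, "OG1")
  ## every patch adds exactly one bond, from the sugar C1
  for (p in patches) {
    adds <- Filter(function(s) s$kind == "bond" && s$action == "add", p$statements)
    expect_length(adds, 1L)
    expect_equal(adds[[1]]$refs[1], "1-C1")
    expect_equal(adds[[1]]$refs[2], paste0("2-", p$link_atom))
    dels <- vapply(Filter(function(s) s$kind == "atom" && s$action == "delete",
                          p$statements), function(s) s$refs, character(1))
    expect_true(all(c("1-O1", "1-HO1") %in% dels))
  }
})

test_that("applying A1S to sugar + serine forms exactly one C1-OG bond", {
  b <- make_pyranose()
  t <- b$topology
  t$residues[["SER"]] <- make_ser_topology()$residues$SER
  mol <- build_molecule(c("PYR", "SER"), t)
  p <- generate_glycosylation_patches()$A1S
  out <- apply_patch(mol, p, c(1L, 2L))
  expect_equal(glycotop:::n_components(out), 1L)
  i_c1 <- which(out$atoms$res_index == 1 & out$atoms$name == "C1")
  i_og <- which(out$atoms$res_index == 2 & out$atoms$name == "OG")
  cross <- apply(out$bonds, 1, function(r)
    length(unique(out$atoms$res_index[r])) == 2)
  expect_equal(sum(cross), 1L)
  expect_true(setequal(out$bonds[cross, ], c(i_c1, i_og)))
  ## the patch installed one four-vertex improper at C1
  expect_equal(nrow(out$impropers), nrow(mol$impropers) - 1L + 1L)
})

test_that("patch c1_sign fields follow the alpha/beta and D/L truth table", {
  ## construct an idealized anomeric center: alpha-D arrangement of
  ## (H1, link oxygen, ring O5, C2) on exact tetrahedral directions,
  ## beta = swap H1 and the link atom, L = mirror image
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  geo <- function(alpha, L) {
    h <- tet[1, ] * 1.09; link <- tet[2, ] * 1.43
    if (!alpha) { tmp <- h; h <- tet[2, ] * 1.09; link <- tet[1, ] * 1.43 }
    o5 <- tet[3, ] * 1.43; c2 <- tet[4, ] * 1.526
    m <- rbind(h, link, o5, c2)
    if (L) m[, 1] <- -m[, 1]
    m
  }
  meas <- function(alpha, L) {
    m <- geo(alpha, L)
    signed_dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
  }
  s_ad <- sign(meas(TRUE, FALSE))
  expect_equal(sign(meas(FALSE, FALSE)), -s_ad)  # beta flips
  expect_equal(sign(meas(TRUE, TRUE)), -s_ad)    # L flips
  expect_equal(sign(meas(FALSE, TRUE)), s_ad)    # beta-L flips twice
  patches <- generate_glycosylation_patches()
  for (p in patches) {
    expected <- s_ad * (if (p$anomeric == "alpha") 1 else -1) *
      (if (p$series == "L") -1 else 1)
    expect_equal(sign(meas(p$anomeric == "alpha", p$series == "L")) ,
                 expected, info = p$name)
    expect_equal(p$c1_sign * s_ad,
                 sign(meas(p$anomeric == "alpha", p$series == "L")),
                 info = p$name)
  }
})

test_that("random delete/add patches never leave dangling term references", {
  b <- make_pyranose()
  set.seed(99)
  for (rep in 1:20) {
    mol <- build_molecule("PYR", b$topology)
    deletable <- c("HO1", "HO2", "HO3", "HO4", "HO6", "O1", "O2")
    del <- sample(deletable, sample(1:3, 1))
    p <- glycotop:::new_patch_def("FUZZ")
    p$statements <- c(
      lapply(del, function(a) list(action = "delete", kind = "atom",
                                   refs = paste0("1-", a))),
      list(list(action = "add", kind = "bond", refs = c("1-H61", "1-H62"))))
    out <- apply_patch(mol, p, 1L)
    n <- nrow(out$atoms)
    idx <- c(out$bonds, out$angles, out$dihedrals, out$impropers)
    expect_true(all(idx >= 1 & idx <= n))
    ## deleted atoms are gone along with every term touching them
    expect_false(any(del %in% out$atoms$name))
  }
})

test_that("patches on disjoint atom sets commute", {
  b <- make_pyranose()
  mol <- build_molecule(c("PYR", "PYR"), b$topology)
  p1 <- glycotop:::new_patch_def("M1")
  p1$statements <- list(list(action = "modify", kind = "atom", refs = "1-C1",
                             charge = 0.42))
  p2 <- glycotop:::new_patch_def("M2")
  p2$statements <- list(list(action = "modify", kind = "atom", refs = "2-C3",
                             type = "CX"))
  a <- apply_patch(apply_patch(mol, p1, c(1L, 2L)), p2, c(1L, 2L))
  bb <- apply_patch(apply_patch(mol, p2, c(1L, 2L)), p1, c(1L, 2L))
  expect_equal(a, bb)
})

test_that("the patch catalogue writes as PRESidue blocks and reparses", {
  t <- new_topology_set()
  for (p in generate_glycosylation_patches()) {
    q <- glycotop:::new_patch_def(p$name)
    q$statements <- p$statements
    t$patches[[p$name]] <- q
  }
  out <- write_topology(t)
  expect_equal(sum(grepl("^PRESIDUE ", out)), 16L)
  t2 <- parse_topology(out)
  expect_setequal(names(t2$patches), names(t$patches))
  expect_equal(t2$patches$B13$statements, t$patches$B13$statements)
})
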