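test_that("minimal topology statements parse to the expected structures", {
  expect_equal(length(parse_topology("")$residues), 0L)
  expect_equal(length(parse_topology("")$patches), 0L)

  t <- parse_topology(c(
    "! a tiny residue",
    "RESIDUE TST",
    "  ATOM C1 TYPE=CC CHARGE=0.1 END",
    "  ATOM O1 TYPE=OH CHARGE=-0.5 END",
    "  BOND C1 O1",
    "END"))
  expect_named(t$residues, "TST")
  res <- t$residues$TST
  expect_equal(res$atoms$name, c("C1", "O1"))
  expect_equal(res$atoms$type, c("CC", "OH"))
  expect_equal(res$atoms$charge, c(0.1, -0.5))
  expect_equal(nrow(res$bonds), 1L)
  expect_equal(unname(res$bonds[1, ]), c("C1", "O1"))
})

test_that("line continuation and case-insensitive 4-char keywords work", {
  t <- parse_topology(c(
    "resi ABC",
    "  atom C1 type=CC charge=0.0 end",
    "  atom C2 type=CC charge=0.0 end",
    "  bond C1 -",
    "    C2",
    "end"))
  expect_equal(unname(t$residues$ABC$bonds[1, ]), c("C1", "C2"))
})

test_that("topology parse errors carry useful context", {
  expect_error(parse_topology(c("RESIDUE A", "ATOM X TYPE=T END")),
               "unterminated")
  expect_error(parse_topology(c("RESIDUE A", "END", "RESIDUE A", "END")),
               "duplicate residue name 'A'")
  expect_error(parse_topology(c("RESIDUE A",
                                "ATOM C1 TYPE=T END",
                                "BOND C1 C9", "END")),
               "undefined atom 'C9'")
})

test_that("parameter statements parse and duplicates resolve to the last entry", {
  p <- parse_parameters("BOND CC OC 1000.0 1.43")
  expect_equal(nrow(p$bonds), 1L)
  expect_equal(p$bonds$k, 1000.0)
  expect_equal(p$bonds$b0, 1.43)

  expect_equal(nrow(parse_parameters("")$bonds), 0L)

  expect_warning(
    pdup <- parse_parameters(c("BOND CC OC 900.0 1.40", "BOND CC OC 1000.0 1.43")),
    "last occurrence wins")
  expect_equal(nrow(pdup$bonds), 1L)
  expect_equal(pdup$bonds$k, 1000.0)
})

test_that("topology and parameter roundtrips hold over 50 randomized sets", {
  for (seed in 1:50) {
    t <- make_random_topology(seed)
    t2 <- parse_topology(write_topology(t))
    expect_equal(t2, t, info = sprintf("topology seed %d", seed))

    p <- make_random_parameters(seed)
    p2 <- parse_parameters(write_parameters(p))
    expect_equal(p2, p, info = sprintf("parameters seed %d", seed))
  }
})

test_that("unknown statements pass through a read/modify/write cycle verbatim", {
  txt <- c("SET ECHO=FALSE END",
           "RESIDUE QQQ",
           "  GROUP",
           "  ATOM C1 TYPE=CC CHARGE=0.0 END",
           "  DONOR C1",
           "END")
  t <- parse_topology(txt)
  expect_equal(t$passthrough, "SET ECHO=FALSE END")
  expect_true(all(c("GROUP", "DONOR C1") %in% t$residues$QQQ$passthrough))
  out <- write_topology(t)
  expect_true(any(grepl("SET ECHO=FALSE END", out, fixed = TRUE)))
  expect_true(any(grepl("DONOR C1", out, fixed = TRUE)))
  expect_equal(parse_topology(out), t)
})

test_that("harmonize_energies sets the annealing constants and nothing else", {
  p <- make_random_parameters(7)
  h <- harmonize_energies(p)
  expect_true(all(h$bonds$k == 1000.0))
  expect_true(all(h$angles$k == 500.0))
  expect_true(all(h$impropers$k == 500.0))
  expect_true(all(h$dihedrals$k == 2.0))
  ## geometry targets untouched
  expect_equal(h$bonds$b0, p$bonds$b0)
  expect_equal(h$angles$theta0, p$angles$theta0)
  expect_equal(h$impropers$phi0, p$impropers$phi0)
  expect_equal(h$dihedrals$n, p$dihedrals$n)
  expect_equal(h$dihedrals$delta, p$dihedrals$delta)
  expect_equal(h$nonbonded, p$nonbonded)
  ## idempotent
  expect_equal(harmonize_energies(h), h)
  ## empty set in, empty set out
  expect_equal(harmonize_energies(new_parameter_set()), new_parameter_set())
  expect_error(harmonize_energies(p, k_bond = -1), "non-negative")
  ## harmonized angle constants dominate typical restraint constants
  expect_true(check_restraint_compatibility(h))
})

test_that("parameter lookup matches a brute-force matcher with wildcard precedence", {
  p <- new_parameter_set()
  p$dihedrals <- data.frame(
    a = c("X", "T1", "T2"), b = c("T2", "T2", "T2"),
    c = c("T3", "T3", "T3"), d = c("X", "T4", "X"),
    k = c(1, 2, 3), n = c(3L, 3L, 3L), delta = 0,
    stringsAsFactors = FALSE)
  ## exact beats wildcard
  hit <- glycotop:::lookup_param(p, "dihedral", c("T1", "T2", "T3", "T4"))
  expect_equal(hit$k, 2)
  ## reversed tuple matches
  hit_rev <- glycotop:::lookup_param(p, "dihedral", c("T4", "T3", "T2", "T1"))
  expect_equal(hit_rev$k, 2)
  ## property: agree with the brute-force oracle over random queries
  set.seed(11)
  pr <- make_random_parameters(11)
  types <- c(paste0("T", 1:5))
  for (kind in c("bond", "angle", "dihedral", "improper")) {
    klen <- switch(kind, bond = 2, angle = 3, 4)
    for (rep in 1:40) {
      q <- sample(types, klen, replace = TRUE)
      a <- glycotop:::lookup_param(pr, kind, q)
      b <- oracle_lookup(pr, kind, q)
      if (is.null(b)) expect_null(a) else expect_equal(a$k, b$k)
    }
  }
})

test_that("coverage checking reports exactly the terms with no parameter", {
  b <- make_pyranose()
  expect_equal(nrow(check_coverage(b$molecule, b$parameters)), 0L)

  ## remove one angle parameter: exactly the matching triples are reported
  p2 <- b$parameters
  drop <- p2$angles$a == "CC" & p2$angles$b == "CC" & p2$angles$c == "OH"
  expect_true(any(drop))
  p2$angles <- p2$angles[!drop, , drop = FALSE]
  gaps <- check_coverage(b$molecule, p2)
  expect_true(all(gaps$kind == "angle"))
  typ <- b$molecule$atoms$type
  inst <- glycotop:::enumerate_term_atoms(b$molecule)
  tri <- matrix(typ[inst$angles], ncol = 3)
  expected_n <- sum(apply(tri, 1, function(r)
    all(sort(c(r[1], r[3])) == c("CC", "OH")) && r[2] == "CC"))
  expect_equal(nrow(gaps), expected_n)
  expect_true(expected_n > 0)

  ## amide fixture stripped of its improper parameters: exactly 3 missing
  am <- make_amide_fixture()
  expect_equal(nrow(check_coverage(am$molecule, am$parameters_full)), 0L)
  gaps <- check_coverage(am$molecule, am$parameters_stripped)
  expect_equal(nrow(gaps), 3L)
  expect_true(all(gaps$kind == "improper"))
})

test_that("coverage is empty iff every term matches under the brute-force matcher", {
  am <- make_amide_fixture()
  for (p in list(am$parameters_full, am$parameters_stripped)) {
    gaps <- check_coverage(am$molecule, p)
    inst <- glycotop:::enumerate_term_atoms(am$molecule)
    typ <- am$molecule$atoms$type
    miss <- 0L
    for (kind in c("bond", "angle", "dihedral", "improper")) {
      m <- inst[[c(bond = "bonds", angle = "angles", dihedral = "dihedrals",
                   improper = "impropers")[[kind]]]]
      for (r in seq_len(nrow(m)))
        if (is.null(oracle_lookup(p, kind, typ[m[r, ]]))) miss <- miss + 1L
    }
    expect_equal(nrow(gaps), miss)
  }
})
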