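## Synthetic inputs: a minimal pyranose residue with ideal chair
## coordinates built so that every bond, angle and improper term sits
## exactly at its equilibrium value; flipped-hydrogen / mirror / boat /
## noisy variants; an amide-bearing residue for parameter-coverage
## checks; randomized topology and parameter sets for roundtrip fuzzing;
## and constructed two-residue ensembles with exact glycosidic torsions.
##
## Ideal geometry constants (internal consistency is what matters, not
## chemical accuracy): C-C 1.526 A, exocyclic C-O 1.420 A, C-H 1.090 A,
## O-H 0.960 A, all heavy/hydrogen angles tetrahedral (109.4712 deg).
## Ring bonds (including the two C-O5 ether bonds) all use 1.526 A so
## that an exact tetrahedral chair closes the ring with zero strain.

GLYCO_GEOM <- list(cc = 1.526, co = 1.420, ch = 1.090, oh = 0.960,
                   tet = 109.47122063449069)

## run code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## exact chair ring: six atoms, equal bond length L, all internal angles
## exactly tetrahedral: radius r = L*sqrt(8)/3, alternating z = +/- L/6
.chair_ring <- function(L = GLYCO_GEOM$cc) {
  r <- L * sqrt(8) / 3
  h <- L / 6
  k <- 0:5
  cbind(r * cos(k * pi / 3), r * sin(k * pi / 3), h * (-1)^k)
}

## boat-family ring: hexagon with out-of-plane displacements taken from
## the m = 2 puckering mode only (q3 = 0 -> theta = 90 exactly)
.boat_ring <- function(L = GLYCO_GEOM$cc, q2 = 0.65, phi2 = 0) {
  r <- L * sqrt(8) / 3
  j <- 0:5
  z <- sqrt(2 / 6) * q2 * cos(deg2rad(phi2) + 4 * pi * j / 6)
  cbind(r * cos(j * pi / 3), r * sin(j * pi / 3), z)
}

## place a hydroxyl hydrogen off oxygen o bonded to carbon c: exact
## tetrahedral C-O-H angle, deterministic azimuth
.place_hydroxyl_h <- function(o, c) {
  u <- unit(c - o)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- unit(cross3(u, ref))
  th <- deg2rad(GLYCO_GEOM$tet)
  o + GLYCO_GEOM$oh * (cos(th) * u + sin(th) * w)
}

.pyranose_topology <- function() {
  t <- new_topology_set(autogenerate_angles = TRUE)
  res <- new_residue_topology("PYR")
  atoms <- rbind(
    data.frame(name = "O5", type = "OE", charge = -0.4),
    data.frame(name = c("C1", "C2", "C3", "C4", "C5"), type = "CC", charge = 0.1),
    data.frame(name = c("H1", "H2", "H3", "H4", "H5"), type = "HA", charge = 0.0),
    data.frame(name = c("O1", "O2", "O3", "O4"), type = "OH", charge = -0.5),
    data.frame(name = c("HO1", "HO2", "HO3", "HO4"), type = "HO", charge = 0.3),
    data.frame(name = "C6", type = "CC", charge = 0.05),
    data.frame(name = c("H61", "H62"), type = "HA", charge = 0.0),
    data.frame(name = "O6", type = "OH", charge = -0.5),
    data.frame(name = "HO6", type = "HO", charge = 0.3))
  atoms$mass <- NA_real_
  res$atoms <- atoms
  ring <- c("O5", "C1", "C2", "C3", "C4", "C5")
  bonds <- rbind(cbind(ring, ring[c(2:6, 1)]),
                 cbind(paste0("C", 1:5), paste0("H", 1:5)),
                 cbind(paste0("C", 1:4), paste0("O", 1:4)),
                 cbind(paste0("O", 1:4), paste0("HO", 1:4)),
                 c("C5", "C6"), c("C6", "H61"), c("C6", "H62"),
                 c("C6", "O6"), c("O6", "HO6"))
  dimnames(bonds) <- NULL
  res$bonds <- bonds
  t$residues[["PYR"]] <- .check_residue(res, "PYR")
  t
}

## coordinates of the full pyranose given a ring-builder; slot_flip is a
## named logical (C1..C5): swap which tetrahedral slot takes the oxygen
.pyranose_coords <- function(ring_xyz, slot_flip) {
  g <- GLYCO_GEOM
  names_ring <- c("O5", "C1", "C2", "C3", "C4", "C5")
  xyz <- matrix(NA_real_, 24, 3,
                dimnames = list(c("O5", "C1", "C2", "C3", "C4", "C5",
                                  "H1", "H2", "H3", "H4", "H5",
                                  "O1", "O2", "O3", "O4",
                                  "HO1", "HO2", "HO3", "HO4",
                                  "C6", "H61", "H62", "O6", "HO6"), NULL))
  xyz[names_ring, ] <- ring_xyz
  for (k in 1:5) {
    cn <- paste0("C", k)
    prev <- names_ring[k]          # ring neighbor before C_k
    nxt <- if (k < 5) names_ring[k + 2] else "O5"
    ci <- xyz[cn, ]
    u1 <- unit(xyz[prev, ] - ci)
    u2 <- unit(xyz[nxt, ] - ci)
    comp <- tetrahedral_complements(u1, u2)
    if (isTRUE(slot_flip[[cn]])) comp <- comp[c(2, 1)]
    if (k < 5) {
      on <- paste0("O", k); hn <- paste0("H", k)
      xyz[on, ] <- ci + g$co * comp[[1]]
      xyz[hn, ] <- ci + g$ch * comp[[2]]
      xyz[paste0("HO", k), ] <- .place_hydroxyl_h(xyz[on, ], ci)
    } else {
      xyz["C6", ] <- ci + g$cc * comp[[1]]
      xyz["H5", ] <- ci + g$ch * comp[[2]]
    }
  }
  ## exocyclic CH2OH at C6: exact tetrahedral fan around the C5-C6 bond
  u <- unit(xyz["C5", ] - xyz["C6", ])
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w1 <- unit(cross3(u, ref))
  w2 <- cross3(u, w1)
  th <- deg2rad(GLYCO_GEOM$tet)
  dirs <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(az)
    cos(th) * u + sin(th) * (cos(az) * w1 + sin(az) * w2))
  xyz["O6", ] <- xyz["C6", ] + g$co * dirs[[1]]
  xyz["H61", ] <- xyz["C6", ] + g$ch * dirs[[2]]
  xyz["H62", ] <- xyz["C6", ] + g$ch * dirs[[3]]
  xyz["HO6", ] <- .place_hydroxyl_h(xyz["O6", ], xyz["C6", ])
  xyz
}

## choose slot_flip per center so that centers sharing an improper type
## tuple measure identical four-vertex targets (one parameter per tuple)
.consistent_slots <- function(build_fun) {
  slot_flip <- stats::setNames(as.list(rep(FALSE, 5)), paste0("C", 1:5))
  tuple_val <- list()
  tuple_of <- c(C1 = "HA:OH:OE:CC", C2 = "HA:OH:CC:CC", C3 = "HA:OH:CC:CC",
                C4 = "HA:OH:CC:CC", C5 = "HA:OE:CC:CC")
  quad_names <- list(C1 = c("H1", "O1", "O5", "C2"),
                     C2 = c("H2", "O2", "C1", "C3"),
                     C3 = c("H3", "O3", "C2", "C4"),
                     C4 = c("H4", "O4", "C3", "C5"),
                     C5 = c("H5", "O5", "C4", "C6"))
  for (cn in paste0("C", 1:5)) {
    vals <- vapply(c(FALSE, TRUE), function(fl) {
      sf <- slot_flip; sf[[cn]] <- fl
      xyz <- build_fun(sf)
      q <- quad_names[[cn]]
      signed_dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    }, numeric(1))
    tup <- tuple_of[[cn]]
    if (is.null(tuple_val[[tup]])) {
      tuple_val[[tup]] <- vals[1]
    } else {
      pick <- which.min(abs(vals - tuple_val[[tup]]))
      slot_flip[[cn]] <- c(FALSE, TRUE)[pick]
    }
  }
  slot_flip
}

#' Generate the pyranose fixture bundle
#'
#' Builds a minimal single-residue pyranose (ring O5, C1-C5, hydroxyls at
#' C1-C4, exocyclic CH2OH at C5) whose reference conformation is an
#' exact tetrahedral chair: every bond, angle and improper term of the
#' accompanying parameter set is at equilibrium, so the reference energy
#' is numerically zero. Chirality impropers are provided in both styles:
#' heavy-atom-only (center atom plus its three heavy substituents) and
#' four-vertex (the four substituents, hydrogen included), selectable
#' via `improper_mode` of [pyranose_terms()].
#'
#' @param seed RNG seed for the `noisy` variant (default 1).
#' @param noise_sd Gaussian displacement of the noisy variant, Å.
#' @return a `fixture_bundle`: `topology` (four-vertex impropers),
#'   `topology_heavy`, `parameters` (covering both improper styles),
#'   `molecule`, `molecule_heavy`, `conf` (reference chair), `variants`
#'   (`flipped_H3`, `mirror`, `boat`, `noisy`), `centers` (chiral-center
#'   table with measured targets).
#' @export
make_pyranose <- function(seed = 1, noise_sd = 0.05) {
  topo <- .pyranose_topology()
  build_chair <- function(sf) .pyranose_coords(.chair_ring(), sf)
  slots <- .consistent_slots(build_chair)
  conf <- build_chair(slots)
  boat <- .pyranose_coords(.boat_ring(), slots)

  mol0 <- build_molecule("PYR", topo)
  cc <- chiral_centers(mol0, conf[mol0$atoms$name, , drop = FALSE])

  ## four-vertex and heavy-only improper name quadruples
  four <- t(vapply(seq_len(nrow(cc)), function(r)
    mol0$atoms$name[c(cc$v1[r], cc$v2[r], cc$v3[r], cc$v4[r])], character(4)))
  heavy <- t(vapply(seq_len(nrow(cc)), function(r) {
    verts <- c(cc$v1[r], cc$v2[r], cc$v3[r], cc$v4[r])
    hv <- verts[element_of(mol0$atoms$name[verts]) != "H"]
    c(mol0$atoms$name[cc$center[r]], mol0$atoms$name[hv])
  }, character(4)))

  topo_four <- topo
  topo_four$residues$PYR$impropers <- four
  topo_heavy <- topo
  topo_heavy$residues$PYR$impropers <- heavy

  mol_four <- build_molecule("PYR", topo_four)
  mol_heavy <- build_molecule("PYR", topo_heavy)

  params <- .pyranose_parameters(mol_four, mol_heavy, conf)

  variants <- list(
    flipped_H3 = flip_through(conf, which(rownames(conf) == "H3"),
                              which(rownames(conf) == "C3")),
    mirror = { m <- conf; m[, 1] <- -m[, 1]; m },
    boat = boat,
    noisy = with_seed(seed, conf + matrix(stats::rnorm(length(conf), 0, noise_sd),
                                          nrow(conf), 3))
  )

  centers <- chiral_centers(mol_four, conf[mol_four$atoms$name, , drop = FALSE])
  structure(list(topology = topo_four, topology_heavy = topo_heavy,
                 parameters = params, molecule = mol_four,
                 molecule_heavy = mol_heavy,
                 conf = conf[mol_four$atoms$name, , drop = FALSE],
                 variants = lapply(variants, function(v)
                   v[mol_four$atoms$name, , drop = FALSE]),
                 centers = centers, seed = seed),
            class = "fixture_bundle")
}

## parameter set with complete coverage for both improper styles; all
## equilibrium values measured from / consistent with the reference
.pyranose_parameters <- function(mol_four, mol_heavy, conf) {
  g <- GLYCO_GEOM
  p <- new_parameter_set()
  p$bonds <- data.frame(
    a = c("CC", "CC", "CC", "CC", "OH"),
    b = c("CC", "OE", "OH", "HA", "HO"),
    k = 1000.0,
    b0 = c(g$cc, g$cc, g$co, g$ch, g$oh),
    stringsAsFactors = FALSE)
  ## every angle triple at the tetrahedral value
  inst <- enumerate_term_atoms(mol_four, autogenerate_angles = TRUE)
  typ <- mol_four$atoms$type
  tri <- unique(t(apply(matrix(typ[inst$angles], ncol = 3), 1, function(r)
    if (r[1] <= r[3]) r else rev(r))))
  p$angles <- data.frame(a = tri[, 1], b = tri[, 2], c = tri[, 3],
                         k = 500.0, theta0 = g$tet, stringsAsFactors = FALSE)
  ## improper targets measured on the reference, one entry per type tuple
  imp <- rbind(mol_four$impropers, mol_heavy$impropers)
  nm4 <- mol_four$atoms$name
  rows <- list()
  seen <- character()
  for (r in seq_len(nrow(imp))) {
    q <- imp[r, ]
    tt <- typ[q]
    key <- paste(tt, collapse = "/")
    if (key %in% seen) next
    seen <- c(seen, key)
    phi0 <- signed_dihedral(conf[nm4[q[1]], ], conf[nm4[q[2]], ],
                            conf[nm4[q[3]], ], conf[nm4[q[4]], ])
    rows[[length(rows) + 1L]] <- data.frame(
      a = tt[1], b = tt[2], c = tt[3], d = tt[4],
      k = 500.0, n = 0L, phi0 = phi0, stringsAsFactors = FALSE)
  }
  p$impropers <- do.call(rbind, rows)
  p$nonbonded <- data.frame(
    type = c("CC", "OE", "OH", "HA", "HO"),
    eps = 0.1, sigma = c(1.5, 1.4, 1.4, 0.9, 0.7),
    eps14 = 0.1, sigma14 = c(1.5, 1.4, 1.4, 0.9, 0.7),
    stringsAsFactors = FALSE)
  p
}

#' Term lists for the pyranose fixture
#'
#' @param bundle a `fixture_bundle` from [make_pyranose()].
#' @param improper_mode `"four_vertex"` or `"heavy_only"`: which
#'   chirality improper style the term list carries.
#' @param ... passed to [enumerate_terms()].
#' @return a `term_list`.
#' @export
pyranose_terms <- function(bundle, improper_mode = c("four_vertex", "heavy_only"),
                           ...) {
  improper_mode <- match.arg(improper_mode)
  mol <- if (improper_mode == "four_vertex") bundle$molecule else bundle$molecule_heavy
  enumerate_terms(mol, bundle$parameters, autogenerate_angles = TRUE, ...)
}

#' Amide-bearing residue fixture for coverage checks
#'
#' A minimal N-acetyl fragment (sugar C2 carrying an N-H amide bonded to
#' a carbonyl carbon with its methyl), whose topology declares the three
#' amide IMPROPER terms: planarity at the amide nitrogen, planarity at
#' the carbonyl carbon, and the trans-amide torsion improper. The
#' `parameters_full` set covers everything; `parameters_stripped` is the
#' same set with the three improper entries removed, so coverage
#' checking against it reports exactly the three missing amide improper
#' parameters.
#'
#' @return list: `topology`, `molecule`, `parameters_full`,
#'   `parameters_stripped`.
#' @export
make_amide_fixture <- function() {
  t <- new_topology_set(autogenerate_angles = TRUE)
  res <- new_residue_topology("NAC")
  res$atoms <- data.frame(
    name = c("C2", "H2", "N2", "HN2", "C7", "O7", "C8", "H81", "H82", "H83"),
    type = c("CC", "HA", "NA", "HN", "CO", "OC", "CC", "HA", "HA", "HA"),
    charge = 0, mass = NA_real_, stringsAsFactors = FALSE)
  res$bonds <- rbind(c("C2", "H2"), c("C2", "N2"), c("N2", "HN2"),
                     c("N2", "C7"), c("C7", "O7"), c("C7", "C8"),
                     c("C8", "H81"), c("C8", "H82"), c("C8", "H83"))
  res$impropers <- rbind(c("N2", "C2", "C7", "HN2"),
                         c("C7", "N2", "O7", "C8"),
                         c("C2", "N2", "C7", "O7"))
  t$residues[["NAC"]] <- .check_residue(res, "NAC")
  mol <- build_molecule("NAC", t)

  p <- new_parameter_set()
  p$bonds <- data.frame(a = c("CC", "CC", "NA", "NA", "CO", "CO"),
                        b = c("HA", "NA", "HN", "CO", "OC", "CC"),
                        k = 1000.0,
                        b0 = c(1.09, 1.45, 1.01, 1.33, 1.23, 1.50),
                        stringsAsFactors = FALSE)
  inst <- enumerate_term_atoms(mol, autogenerate_angles = TRUE)
  typ <- mol$atoms$type
  tri <- unique(t(apply(matrix(typ[inst$angles], ncol = 3), 1, function(r)
    if (r[1] <= r[3]) r else rev(r))))
  p$angles <- data.frame(a = tri[, 1], b = tri[, 2], c = tri[, 3],
                         k = 500.0, theta0 = ifelse(tri[, 2] %in% c("NA", "CO"),
                                                    120.0, 109.47),
                         stringsAsFactors = FALSE)
  p$nonbonded <- data.frame(type = c("CC", "NA", "CO", "OC", "HA", "HN"),
                            eps = 0.1,
                            sigma = c(1.5, 1.4, 1.5, 1.4, 0.9, 0.7),
                            eps14 = 0.1,
                            sigma14 = c(1.5, 1.4, 1.5, 1.4, 0.9, 0.7),
                            stringsAsFactors = FALSE)
  p_full <- p
  p_full$impropers <- data.frame(
    a = c("NA", "CO", "CC"), b = c("CC", "NA", "NA"),
    c = c("CO", "OC", "CO"), d = c("HN", "CC", "OC"),
    k = 500.0, n = 0L, phi0 = c(0, 0, 180), stringsAsFactors = FALSE)
  list(topology = t, molecule = mol,
       parameters_full = p_full, parameters_stripped = p)
}

#' Randomized topology sets for roundtrip fuzzing
#'
#' Valid-by-construction and deterministic per seed: residue/patch names,
#' atom tables, bonds (a random tree plus extra edges) and explicit term
#' tuples are all drawn from a seeded RNG.
#'
#' @param seed integer seed.
#' @param n_residues,n_patches sizes (>= 0).
#' @return a `topology_set`.
#' @export
make_random_topology <- function(seed, n_residues = 3, n_patches = 2) {
  with_seed(seed, {
    t <- new_topology_set(autogenerate_angles = sample(c(TRUE, FALSE), 1))
    types <- paste0("T", 1:5)
    t$masses <- stats::setNames(round(stats::runif(3, 1, 32), 2),
                                paste0("T", 1:3))
    rnames <- character()
    for (i in seq_len(n_residues)) {
      repeat {
        nm <- paste(sample(LETTERS, 3), collapse = "")
        if (!nm %in% rnames) break
      }
      rnames <- c(rnames, nm)
      res <- new_residue_topology(nm)
      na <- sample(4:8, 1)
      anames <- paste0("A", seq_len(na))
      res$atoms <- data.frame(name = anames,
                              type = sample(types, na, replace = TRUE),
                              charge = round(stats::runif(na, -0.5, 0.5), 2),
                              mass = ifelse(stats::runif(na) < 0.3,
                                            round(stats::runif(na, 1, 16), 1),
                                            NA_real_),
                              stringsAsFactors = FALSE)
      ## random tree over the atoms
      bonds <- t(vapply(2:na, function(k)
        c(anames[sample(k - 1, 1)], anames[k]), character(2)))
      res$bonds <- bonds
      if (na >= 4) {
        res$angles <- matrix(anames[sample(na, 3)], 1, 3)
        res$dihedrals <- matrix(anames[sample(na, 4)], 1, 4)
        res$impropers <- matrix(anames[sample(na, 4)], 1, 4)
      }
      t$residues[[nm]] <- .check_residue(res, nm)
    }
    for (i in seq_len(n_patches)) {
      nm <- paste0("P", i, paste(sample(LETTERS, 2), collapse = ""))
      p <- new_patch_def(nm)
      p$statements <- list(
        list(action = "delete", kind = "atom", refs = "1-A1"),
        list(action = "add", kind = "bond", refs = c("1-A2", "2-A1")),
        list(action = "modify", kind = "atom", refs = "2-A2",
             type = sample(types, 1), charge = round(stats::runif(1, -0.5, 0.5), 2)),
        list(action = "add", kind = "improper",
             refs = c("1-A2", "1-A3", "2-A1", "2-A2")))
      t$patches[[nm]] <- p
    }
    t
  })
}

#' Randomized parameter sets for roundtrip fuzzing
#'
#' @param seed integer seed.
#' @return a `parameter_set`, deterministic per seed.
#' @export
make_random_parameters <- function(seed) {
  with_seed(seed, {
    p <- new_parameter_set()
    types <- c(paste0("T", 1:5), "X")
    nb <- sample(2:6, 1)
    p$bonds <- unique(data.frame(
      a = sample(types, nb, replace = TRUE), b = sample(types, nb, replace = TRUE),
      k = round(stats::runif(nb, 100, 1200), 2),
      b0 = round(stats::runif(nb, 0.9, 1.8), 3), stringsAsFactors = FALSE))
    p$bonds <- suppressWarnings(.dedup_last(p$bonds, c("a", "b"), "BOND"))
    na <- sample(2:6, 1)
    p$angles <- suppressWarnings(.dedup_last(unique(data.frame(
      a = sample(types, na, replace = TRUE), b = sample(types, na, replace = TRUE),
      c = sample(types, na, replace = TRUE),
      k = round(stats::runif(na, 50, 600), 2),
      theta0 = round(stats::runif(na, 60, 150), 2), stringsAsFactors = FALSE)),
      c("a", "b", "c"), "ANGLE"))
    nd <- sample(1:4, 1)
    p$dihedrals <- suppressWarnings(.dedup_last(unique(data.frame(
      a = sample(types, nd, replace = TRUE), b = sample(types, nd, replace = TRUE),
      c = sample(types, nd, replace = TRUE), d = sample(types, nd, replace = TRUE),
      k = round(stats::runif(nd, 0.5, 5), 2),
      n = sample(0:3, nd, replace = TRUE),
      delta = sample(c(0, 180), nd, replace = TRUE), stringsAsFactors = FALSE)),
      c("a", "b", "c", "d"), "DIHEDRAL"))
    ni <- sample(1:4, 1)
    p$impropers <- suppressWarnings(.dedup_last(unique(data.frame(
      a = sample(types, ni, replace = TRUE), b = sample(types, ni, replace = TRUE),
      c = sample(types, ni, replace = TRUE), d = sample(types, ni, replace = TRUE),
      k = round(stats::runif(ni, 50, 600), 2), n = 0L,
      phi0 = round(stats::runif(ni, -170, 170), 2), stringsAsFactors = FALSE)),
      c("a", "b", "c", "d"), "IMPROPER"))
    nn <- sample(1:5, 1)
    p$nonbonded <- suppressWarnings(.dedup_last(unique(data.frame(
      type = sample(setdiff(types, "X"), nn), eps = round(stats::runif(nn, 0.01, 0.3), 3),
      sigma = round(stats::runif(nn, 0.8, 2), 3),
      eps14 = round(stats::runif(nn, 0.01, 0.3), 3),
      sigma14 = round(stats::runif(nn, 0.8, 2), 3), stringsAsFactors = FALSE)),
      "type", "NONBONDED"))
    p
  })
}

#' Construct a two-residue ensemble with exact glycosidic torsions
#'
#' One model per (phi, psi) pair: a donor fragment (O5, C1, H1) linked to
#' an acceptor fragment (O4, C4, C3), built by internal-coordinate
#' placement so the heavy-atom convention recovers the requested angles
#' exactly.
#'
#' @param phi_list,psi_list equal-length numeric vectors, degrees.
#' @return an `ensemble` with one model per pair; donor is residue 1,
#'   acceptor residue 2.
#' @export
make_torsion_ensemble <- function(phi_list, psi_list) {
  if (length(phi_list) != length(psi_list))
    stop("phi_list and psi_list must have equal length")
  g <- GLYCO_GEOM
  atoms <- data.frame(
    chain = "A",
    resid = c(1L, 1L, 1L, 2L, 2L, 2L),
    resname = "PYR",
    name = c("O5", "C1", "H1", "O4", "C4", "C3"),
    elem = c("O", "C", "H", "O", "C", "C"),
    het = TRUE, stringsAsFactors = FALSE)
  models <- lapply(seq_along(phi_list), function(m) {
    o5 <- c(0, 0, 0)
    c1 <- c(g$co, 0, 0)
    th <- deg2rad(g$tet)
    o4 <- c1 + g$co * c(-cos(th), sin(th), 0)
    c4 <- place_atom(o5, c1, o4, g$co, g$tet, phi_list[m])
    c3 <- place_atom(c1, o4, c4, g$cc, g$tet, psi_list[m])
    ## H1 is fixed in the O5/C1/O4 frame so that the proton-based phi
    ## convention differs from the heavy-atom one by a constant offset
    h1 <- place_atom(o5, o4, c1, g$ch, g$tet, 120)
    x <- rbind(o5, c1, h1, o4, c4, c3)
    rownames(x) <- atoms$name
    x
  })
  structure(list(atoms = atoms, models = models), class = "ensemble")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("pyranose fixture: %d atoms, %d chiral centers, variants: %s\n",
              nrow(x$conf), nrow(x$centers),
              paste(names(x$variants), collapse = ", ")))
  invisible(x)
}
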