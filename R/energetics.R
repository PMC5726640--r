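## Bonded + repulsive-nonbonded energy model with analytic gradients.
##
## Functional forms (no 1/2 factors, matching the convention implied by
## the printed force constants of the file dialect):
##   E_bond     = k (b - b0)^2                [k: kcal mol^-1 A^-2]
##   E_angle    = k (theta - theta0)^2        [k: kcal mol^-1 rad^-2]
##   E_dihedral = k (1 + cos(n phi - delta))  for periodicity n > 0
##              = k wrap(phi - phi0)^2        for n = 0 (harmonic)
##   E_improper = k wrap(phi - phi0)^2        [minimal-image difference]
##   E_repel    = k_rep (max(0, (s sigma_ij)^2 - r^2))^2
## Angles/torsions are stored in degrees in term tables and converted to
## radians inside the evaluation.

#' Instantiate an evaluated term list for a molecule
#'
#' Resolves every bond/angle/dihedral/improper instance of the molecule
#' against the parameter set (exact-before-wildcard, symmetric lookup)
#' and builds the repulsive nonbonded pair list (all pairs separated by
#' three or more bonds; 1-2 and 1-3 pairs are excluded, 1-4 pairs enter
#' at full weight).
#'
#' @param mol a `molecule_graph`.
#' @param p a `parameter_set`.
#' @param autogenerate_angles logical; angle instances from the bond
#'   graph (TRUE) or the explicit angle list (FALSE).
#' @param k_rep repulsive force constant, kcal mol^-1 A^-4 (default 4.0).
#' @param repel_scale scale factor s applied to sigma_ij (default 0.8).
#' @return an object of class `term_list`.
#' @export
enumerate_terms <- function(mol, p, autogenerate_angles = TRUE,
                            k_rep = 4.0, repel_scale = 0.8) {
  gaps <- check_coverage(mol, p, autogenerate_angles = autogenerate_angles)
  if (nrow(gaps))
    stop("parameter coverage gaps: ",
         paste(sprintf("%s(%s)", gaps$kind, gaps$types), collapse = ", "))
  inst <- enumerate_term_atoms(mol, autogenerate_angles = autogenerate_angles)
  typ <- mol$atoms$type

  grab <- function(kind, m, fields) {
    if (!nrow(m)) {
      df <- as.data.frame(matrix(numeric(), 0, ncol(m) + length(fields)))
      names(df) <- c(paste0("a", seq_len(ncol(m))), fields)
      return(df)
    }
    rows <- t(vapply(seq_len(nrow(m)), function(r) {
      pr <- lookup_param(p, kind, typ[m[r, ]])
      c(as.numeric(m[r, ]), as.numeric(unlist(pr[fields])))
    }, numeric(ncol(m) + length(fields))))
    df <- as.data.frame(rows)
    names(df) <- c(paste0("a", seq_len(ncol(m))), fields)
    df
  }

  bonds <- grab("bond", inst$bonds, c("k", "b0"))
  angles <- grab("angle", inst$angles, c("k", "theta0"))
  dihedrals <- grab("dihedral", inst$dihedrals, c("k", "n", "delta"))
  impropers <- grab("improper", inst$impropers, c("k", "n", "phi0"))

  pairs <- nonbonded_pairs(mol)
  sig <- stats::setNames(p$nonbonded$sigma, p$nonbonded$type)
  repel <- if (nrow(pairs)) {
    s1 <- sig[typ[pairs[, 1]]]
    s2 <- sig[typ[pairs[, 2]]]
    if (anyNA(s1) || anyNA(s2))
      stop("missing NONBONDED sigma for type(s): ",
           paste(unique(c(typ[pairs[, 1]][is.na(s1)],
                          typ[pairs[, 2]][is.na(s2)])), collapse = ", "))
    data.frame(a1 = pairs[, 1], a2 = pairs[, 2],
               rcut = repel_scale * (s1 + s2) / 2, k = k_rep)
  } else data.frame(a1 = integer(), a2 = integer(), rcut = numeric(), k = numeric())
  rownames(repel) <- NULL

  tl <- structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                       impropers = impropers, repel = repel),
                  class = "term_list")
  .cache_terms(tl)
}

## precompute integer index matrices and numeric parameter vectors so the
## energy/gradient inner loops never touch data.frames
.cache_terms <- function(tl) {
  im <- function(df, k) {
    m <- as.matrix(df[, seq_len(k), drop = FALSE])
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  }
  tl$cache <- list(
    bi = im(tl$bonds, 2), bk = tl$bonds$k, bb0 = tl$bonds$b0,
    ai = im(tl$angles, 3), ak = tl$angles$k, ath0 = deg2rad(tl$angles$theta0),
    di = im(tl$dihedrals, 4), dk = tl$dihedrals$k, dn = tl$dihedrals$n,
    dd = deg2rad(tl$dihedrals$delta),
    ii = im(tl$impropers, 4), ik = tl$impropers$k,
    ip0 = deg2rad(tl$impropers$phi0),
    ri = im(tl$repel, 2), rk = tl$repel$k, rc2 = tl$repel$rcut^2
  )
  tl
}

## vectorized geometry over index tuples ------------------------------

.vec_bond_lengths <- function(x, m) {
  d <- x[m[, 1], , drop = FALSE] - x[m[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

.vec_angles_rad <- function(x, m) {
  u <- x[m[, 1], , drop = FALSE] - x[m[, 2], , drop = FALSE]
  v <- x[m[, 3], , drop = FALSE] - x[m[, 2], , drop = FALSE]
  cu <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  acos(pmin(1, pmax(-1, cu)))
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## signed torsions (radians) for an n x 4 index matrix
.vec_dihedrals_rad <- function(x, m) {
  p1 <- x[m[, 1], , drop = FALSE]; p2 <- x[m[, 2], , drop = FALSE]
  p3 <- x[m[, 3], , drop = FALSE]; p4 <- x[m[, 4], , drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .rowcross(b1, b2)
  n2 <- .rowcross(b2, b3)
  b2n <- sqrt(rowSums(b2 * b2))
  if (any(b2n < 1e-12)) stop("overlapping atoms in a dihedral frame")
  m1 <- .rowcross(n1, b2 / b2n)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

.wrap_rad <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Evaluate the energy of a conformation
#'
#' @param conf numeric n x 3 coordinate matrix (Å).
#' @param terms a `term_list` from [enumerate_terms()].
#' @return an `energy_breakdown`: list with `bond`, `angle`, `dihedral`,
#'   `improper`, `repel` and `total` (kcal mol^-1).
#' @export
ff_energy <- function(conf, terms) {
  stopifnot(inherits(terms, "term_list"))
  if (any(!is.finite(conf))) stop("non-finite coordinates")
  if (is.null(terms$cache)) terms <- .cache_terms(terms)
  ch <- terms$cache
  e <- c(bond = 0, angle = 0, dihedral = 0, improper = 0, repel = 0)
  if (nrow(ch$bi)) {
    b <- .vec_bond_lengths(conf, ch$bi)
    e["bond"] <- sum(ch$bk * (b - ch$bb0)^2)
  }
  if (nrow(ch$ai)) {
    th <- .vec_angles_rad(conf, ch$ai)
    e["angle"] <- sum(ch$ak * (th - ch$ath0)^2)
  }
  if (nrow(ch$di)) {
    ph <- .vec_dihedrals_rad(conf, ch$di)
    per <- ch$dn > 0
    if (any(per))
      e["dihedral"] <- e["dihedral"] +
        sum(ch$dk[per] * (1 + cos(ch$dn[per] * ph[per] - ch$dd[per])))
    if (any(!per))
      e["dihedral"] <- e["dihedral"] +
        sum(ch$dk[!per] * .wrap_rad(ph[!per] - ch$dd[!per])^2)
  }
  if (nrow(ch$ii)) {
    ph <- .vec_dihedrals_rad(conf, ch$ii)
    e["improper"] <- sum(ch$ik * .wrap_rad(ph - ch$ip0)^2)
  }
  if (nrow(ch$ri)) {
    d <- conf[ch$ri[, 1], , drop = FALSE] - conf[ch$ri[, 2], , drop = FALSE]
    viol <- pmax(0, ch$rc2 - rowSums(d * d))
    e["repel"] <- sum(ch$rk * viol^2)
  }
  structure(c(as.list(e), list(total = sum(e))), class = "energy_breakdown")
}

## total energy restricted to given term rows (for incremental updates);
## sel is a list with integer vectors b, a, d, i, r (may be missing/NULL)
.subset_energy <- function(conf, ch, sel) {
  e <- 0
  if (length(sel$b)) {
    b <- .vec_bond_lengths(conf, ch$bi[sel$b, , drop = FALSE])
    e <- e + sum(ch$bk[sel$b] * (b - ch$bb0[sel$b])^2)
  }
  if (length(sel$a)) {
    th <- .vec_angles_rad(conf, ch$ai[sel$a, , drop = FALSE])
    e <- e + sum(ch$ak[sel$a] * (th - ch$ath0[sel$a])^2)
  }
  if (length(sel$d)) {
    ph <- .vec_dihedrals_rad(conf, ch$di[sel$d, , drop = FALSE])
    n <- ch$dn[sel$d]; k <- ch$dk[sel$d]; dd <- ch$dd[sel$d]
    per <- n > 0
    if (any(per)) e <- e + sum(k[per] * (1 + cos(n[per] * ph[per] - dd[per])))
    if (any(!per)) e <- e + sum(k[!per] * .wrap_rad(ph[!per] - dd[!per])^2)
  }
  if (length(sel$i)) {
    ph <- .vec_dihedrals_rad(conf, ch$ii[sel$i, , drop = FALSE])
    e <- e + sum(ch$ik[sel$i] * .wrap_rad(ph - ch$ip0[sel$i])^2)
  }
  if (length(sel$r)) {
    ri <- ch$ri[sel$r, , drop = FALSE]
    d <- conf[ri[, 1], , drop = FALSE] - conf[ri[, 2], , drop = FALSE]
    viol <- pmax(0, ch$rc2[sel$r] - rowSums(d * d))
    e <- e + sum(ch$rk[sel$r] * viol^2)
  }
  e
}

## per-atom incidence: which term rows touch each atom
.term_incidence <- function(terms, n_atoms) {
  ch <- if (is.null(terms$cache)) .cache_terms(terms)$cache else terms$cache
  one <- function(m) {
    out <- vector("list", n_atoms)
    if (!nrow(m)) return(out)
    for (col in seq_len(ncol(m))) {
      sp <- split(seq_len(nrow(m)), m[, col])
      for (key in names(sp)) {
        k <- as.integer(key)
        out[[k]] <- c(out[[k]], sp[[key]])
      }
    }
    lapply(out, unique)
  }
  list(b = one(ch$bi), a = one(ch$ai), d = one(ch$di),
       i = one(ch$ii), r = one(ch$ri))
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy (kcal/mol): total %.6g [bond %.4g | angle %.4g | dihedral %.4g | improper %.4g | repel %.4g]\n",
              x$total, x$bond, x$angle, x$dihedral, x$improper, x$repel))
  invisible(x)
}

#' Analytic gradient of the energy
#'
#' @param conf numeric n x 3 coordinate matrix (Å).
#' @param terms a `term_list`.
#' @return n x 3 matrix of dE/dx (kcal mol^-1 Å^-1).
#' @export
ff_gradient <- function(conf, terms) {
  stopifnot(inherits(terms, "term_list"))
  if (is.null(terms$cache)) terms <- .cache_terms(terms)
  ch <- terms$cache
  g <- matrix(0, nrow(conf), 3)
  ## accumulate rows of val into g at (possibly repeated) indices idx
  acc <- function(idx, val) {
    for (c3 in 1:3) {
      s <- rowsum(val[, c3], idx)
      rid <- as.integer(rownames(s))
      g[rid, c3] <<- g[rid, c3] + s[, 1]
    }
    invisible(NULL)
  }
  if (nrow(ch$bi)) {
    m <- ch$bi
    d <- conf[m[, 1], , drop = FALSE] - conf[m[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    coef <- 2 * ch$bk * (r - ch$bb0) / r
    gv <- d * coef
    acc(m[, 1], gv)
    acc(m[, 2], -gv)
  }
  if (nrow(ch$ai)) {
    m <- ch$ai
    u <- conf[m[, 1], , drop = FALSE] - conf[m[, 2], , drop = FALSE]
    v <- conf[m[, 3], , drop = FALSE] - conf[m[, 2], , drop = FALSE]
    ru <- sqrt(rowSums(u * u)); rv <- sqrt(rowSums(v * v))
    uh <- u / ru; vh <- v / rv
    ct <- pmin(1, pmax(-1, rowSums(uh * vh)))
    st <- sqrt(pmax(1e-12, 1 - ct^2))
    th <- acos(ct)
    dEdth <- 2 * ch$ak * (th - ch$ath0)
    ga <- -(vh - ct * uh) / (ru * st) * dEdth
    gc <- -(uh - ct * vh) / (rv * st) * dEdth
    acc(m[, 1], ga)
    acc(m[, 3], gc)
    acc(m[, 2], -(ga + gc))
  }
  tor_grad <- function(m, dEdphi) {
    p1 <- conf[m[, 1], , drop = FALSE]; p2 <- conf[m[, 2], , drop = FALSE]
    p3 <- conf[m[, 3], , drop = FALSE]; p4 <- conf[m[, 4], , drop = FALSE]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- .rowcross(b1, b2); n2 <- .rowcross(b2, b3)
    n1sq <- rowSums(n1 * n1); n2sq <- rowSums(n2 * n2)
    b2n <- sqrt(rowSums(b2 * b2))
    dp1 <- n1 * (b2n / n1sq)
    dp4 <- -n2 * (b2n / n2sq)
    c12 <- rowSums(b1 * b2) / (b2n^2)
    c32 <- rowSums(b3 * b2) / (b2n^2)
    dp2 <- -dp1 * (1 + c12) + dp4 * c32
    dp3 <- -dp4 * (1 + c32) + dp1 * c12
    acc(m[, 1], dp1 * dEdphi)
    acc(m[, 2], dp2 * dEdphi)
    acc(m[, 3], dp3 * dEdphi)
    acc(m[, 4], dp4 * dEdphi)
  }
  if (nrow(ch$di)) {
    m <- ch$di
    ph <- .vec_dihedrals_rad(conf, m)
    per <- ch$dn > 0
    dEdphi <- numeric(nrow(m))
    dEdphi[per] <- -ch$dk[per] * ch$dn[per] * sin(ch$dn[per] * ph[per] - ch$dd[per])
    dEdphi[!per] <- 2 * ch$dk[!per] * .wrap_rad(ph[!per] - ch$dd[!per])
    tor_grad(m, dEdphi)
  }
  if (nrow(ch$ii)) {
    m <- ch$ii
    ph <- .vec_dihedrals_rad(conf, m)
    dEdphi <- 2 * ch$ik * .wrap_rad(ph - ch$ip0)
    tor_grad(m, dEdphi)
  }
  if (nrow(ch$ri)) {
    d <- conf[ch$ri[, 1], , drop = FALSE] - conf[ch$ri[, 2], , drop = FALSE]
    viol <- ch$rc2 - rowSums(d * d)
    act <- viol > 0
    if (any(act)) {
      coef <- -4 * ch$rk[act] * viol[act]
      gv <- d[act, , drop = FALSE] * coef
      acc(ch$ri[act, 1], gv)
      acc(ch$ri[act, 2], -gv)
    }
  }
  g
}

#' Bonded force constants used by the standard annealing protocol
#'
#' The uniform constants applied by [harmonize_energies()] defaults:
#' BOND 1000.0, ANGLE 500.0, IMPROPER 500.0, DIHEDRAL 2.0 (kcal mol^-1
#' per squared Å/radian as appropriate). `check_restraint_compatibility()`
#' verifies that the harmonized ANGLE constant is not smaller than the
#' force constants typically applied to experimental distance/dihedral
#' restraints in the default annealing protocol; an angle constant below
#' that level lets restraint energies distort covalent geometry.
#'
#' @return named numeric vector of the four constants.
#' @export
nmr_energy_constants <- function() {
  c(bond = 1000.0, angle = 500.0, improper = 500.0, dihedral = 2.0)
}

#' @param p a `parameter_set`.
#' @param typical_restraint_k typical experimental-restraint force
#'   constant (kcal mol^-1 Å^-2), default 50 (final NOE scale of the
#'   standard annealing schedule).
#' @return logical: TRUE when every ANGLE constant is >= the restraint
#'   constant.
#' @rdname nmr_energy_constants
#' @export
check_restraint_compatibility <- function(p, typical_restraint_k = 50) {
  stopifnot(inherits(p, "parameter_set"))
  !nrow(p$angles) || all(p$angles$k >= typical_restraint_k)
}
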