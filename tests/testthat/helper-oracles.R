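# Independent oracle implementations used to cross-check the package's
# fast paths. Each oracle deliberately takes a different route than the
# implementation it validates.

# torsion by projection: angle between the components of (p1-p2) and
# (p4-p3) perpendicular to the p2->p3 axis, signed by a triple product
oracle_dihedral <- function(p1, p2, p3, p4) {
  axis <- p3 - p2
  axis <- axis / sqrt(sum(axis^2))
  u <- (p1 - p2) - sum((p1 - p2) * axis) * axis
  v <- (p4 - p3) - sum((p4 - p3) * axis) * axis
  cp <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sqrt(sum(cp^2)), sum(u * v)) * 180 / pi
  ## sign: looking down the p2->p3 axis, clockwise (u rotating onto v
  ## against the axis direction) is positive
  if (sum(cp * axis) > 0) ang <- -ang
  # map to (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

# literal transcription of the energy forms, scalar loops throughout
oracle_energy <- function(conf, terms) {
  d2r <- pi / 180
  wrap <- function(x) {
    y <- (x + pi) %% (2 * pi) - pi
    if (y == -pi) y <- pi
    y
  }
  e <- 0
  for (r in seq_len(nrow(terms$bonds))) {
    tb <- terms$bonds[r, ]
    b <- sqrt(sum((conf[tb$a1, ] - conf[tb$a2, ])^2))
    e <- e + tb$k * (b - tb$b0)^2
  }
  for (r in seq_len(nrow(terms$angles))) {
    ta <- terms$angles[r, ]
    u <- conf[ta$a1, ] - conf[ta$a2, ]
    v <- conf[ta$a3, ] - conf[ta$a2, ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    e <- e + ta$k * (th - ta$theta0 * d2r)^2
  }
  for (r in seq_len(nrow(terms$dihedrals))) {
    td <- terms$dihedrals[r, ]
    ph <- oracle_dihedral(conf[td$a1, ], conf[td$a2, ], conf[td$a3, ], conf[td$a4, ]) * d2r
    e <- e + if (td$n > 0) td$k * (1 + cos(td$n * ph - td$delta * d2r))
    else td$k * wrap(ph - td$delta * d2r)^2
  }
  for (r in seq_len(nrow(terms$impropers))) {
    ti <- terms$impropers[r, ]
    ph <- oracle_dihedral(conf[ti$a1, ], conf[ti$a2, ], conf[ti$a3, ], conf[ti$a4, ]) * d2r
    e <- e + ti$k * wrap(ph - ti$phi0 * d2r)^2
  }
  for (r in seq_len(nrow(terms$repel))) {
    tr <- terms$repel[r, ]
    r2 <- sum((conf[tr$a1, ] - conf[tr$a2, ])^2)
    v <- max(0, tr$rcut^2 - r2)
    e <- e + tr$k * v^2
  }
  e
}

# optimal-superposition RMSD by the quaternion eigenvector method
# (Kearsley/Horn), independent of the SVD route
oracle_quaternion_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  sm <- xc + yc
  df <- yc - xc
  xm <- sm[, 1]; ym <- sm[, 2]; zm <- sm[, 3]
  xp <- df[, 1]; yp <- df[, 2]; zp <- df[, 3]
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xp^2 + yp^2 + zp^2)
  K[2, 2] <- sum(xp^2 + ym^2 + zm^2)
  K[3, 3] <- sum(xm^2 + yp^2 + zm^2)
  K[4, 4] <- sum(xm^2 + ym^2 + zp^2)
  K[1, 2] <- K[2, 1] <- sum(yp * zm - ym * zp)
  K[1, 3] <- K[3, 1] <- sum(xm * zp - xp * zm)
  K[1, 4] <- K[4, 1] <- sum(xp * ym - xm * yp)
  K[2, 3] <- K[3, 2] <- sum(xp * yp - xm * ym)
  K[2, 4] <- K[4, 2] <- sum(xp * zp - xm * zm)
  K[3, 4] <- K[4, 3] <- sum(yp * zp - ym * zm)
  lam <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, lam) / nrow(x))
}

# brute-force parameter matcher: enumerate every entry, score exact
# (non-wildcard) positions in either direction, take the best
oracle_lookup <- function(p, kind, types) {
  df <- switch(kind, bond = p$bonds, angle = p$angles,
               dihedral = p$dihedrals, improper = p$impropers)
  tcols <- switch(kind, bond = c("a", "b"), angle = c("a", "b", "c"),
                  c("a", "b", "c", "d"))
  best <- NULL
  best_score <- -1
  for (i in seq_len(nrow(df))) {
    et <- unlist(df[i, tcols], use.names = FALSE)
    for (qt in list(types, rev(types))) {
      if (all(et == qt | et == "X")) {
        sc <- sum(et != "X")
        if (sc > best_score) { best_score <- sc; best <- df[i, ] }
      }
    }
  }
  if (is.null(best)) NULL else as.list(best)
}

# brute-force term instantiation straight from a residue topology
oracle_residue_terms <- function(res) {
  idx <- stats::setNames(seq_len(nrow(res$atoms)), res$atoms$name)
  list(bonds = matrix(idx[res$bonds], ncol = 2),
       dihedrals = matrix(idx[res$dihedrals], ncol = 4),
       impropers = matrix(idx[res$impropers], ncol = 4))
}

# brute-force angle triples of a bond graph: every ordered pair of
# distinct neighbors j-i-k counted once
oracle_angle_triples <- function(bonds, n_atoms) {
  out <- list()
  for (j in seq_len(n_atoms)) {
    nb <- sort(unique(c(bonds[bonds[, 1] == j, 2], bonds[bonds[, 2] == j, 1])))
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (b <= a) next
      out[[length(out) + 1L]] <- c(nb[a], j, nb[b])
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

# random rigid transform
random_rigid <- function(x, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(x %*% t(R), 2, rnorm(3, 0, 5), `+`)
}
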