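## Chirality enforcement for tetrahedral (sugar) carbons.
##
## An improper torsion defined over the central carbon plus its heavy
## substituents cannot see a hydrogen mirror-flipped through the carbon:
## the flip leaves every heavy-atom improper, bond length and most angle
## terms near a local minimum, so annealing traps the flipped state. The
## fix is to define the chirality improper over the four tetrahedral
## vertex atoms themselves -- hydrogen included, center excluded -- whose
## signed value changes sign under the flip and therefore drives the
## hydrogen back. This module finds chiral centers, rewrites topology
## impropers into the four-vertex form with targets measured from an
## ideal reference conformation, and checks coordinates against targets.

.ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

## Element symbol inferred from an atom name (first alphabetic character;
## standard monosaccharide/protein atom naming).
element_of <- function(name) {
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", toupper(name))
}

## Per-neighbor signature used to decide whether four substituents are
## distinguishable: a breadth-first walk rooted at the substituent with
## the center removed from the graph, recording the sorted element
## multiset at each shell (a Morgan-style environment signature; shells
## around a ring are walked in both directions until they meet).
.substituent_signature <- function(mol, adj, center, nb, max_depth = 6L) {
  el <- element_of(mol$atoms$name)
  seen <- c(center, nb)
  shell <- nb
  sig <- el[nb]
  for (d in seq_len(max_depth)) {
    nxt <- setdiff(unique(unlist(adj[shell])), seen)
    if (!length(nxt)) break
    ## multiset, not set: count repeated elements reached at this depth
    reached <- unlist(lapply(shell, function(v) setdiff(adj[[v]], seen)))
    sig <- paste(sig, paste(sort(el[reached]), collapse = ""), sep = "|")
    seen <- c(seen, nxt)
    shell <- nxt
  }
  sig
}

## TRUE when atom i lies on a cycle of length <= max_len in the bond graph.
.in_ring <- function(adj, i, max_len = 8L) {
  nb <- adj[[i]]
  if (length(nb) < 2) return(FALSE)
  n <- length(adj)
  for (a_i in seq_along(nb)) for (b_i in seq_along(nb)) {
    if (b_i <= a_i) next
    ## BFS from nb[a] to nb[b] avoiding i, depth limit max_len - 2
    start <- nb[a_i]; goal <- nb[b_i]
    dist <- rep(NA_integer_, n)
    dist[start] <- 0L
    queue <- start
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (dist[v] >= max_len - 2L) next
      for (w in adj[[v]]) {
        if (w == i || !is.na(dist[w])) next
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    if (!is.na(dist[goal])) return(TRUE)
  }
  FALSE
}

#' Find tetrahedral stereocenters of a molecule
#'
#' A chiral center is a carbon with exactly four bonded neighbors whose
#' four substituents are pairwise distinguishable by a one-bond
#' environment signature (element plus sorted neighbor elements). With
#' `ring_only = TRUE` only carbons lying on a ring of the bond graph are
#' returned.
#'
#' @param mol a `molecule_graph`.
#' @param ring_only restrict to ring carbons (default FALSE: all
#'   tetrahedral stereocenters).
#' @return data.frame: `center` (atom index), `v1`..`v4` (vertex atom
#'   indices ordered hydrogen first, then by descending atomic number,
#'   then by atom name).
#' @export
find_chiral_centers <- function(mol, ring_only = FALSE) {
  adj <- .adjacency(mol)
  rows <- list()
  for (i in seq_len(nrow(mol$atoms))) {
    if (element_of(mol$atoms$name[i]) != "C") next
    nb <- adj[[i]]
    if (length(nb) != 4) next
    sigs <- vapply(nb, function(j) .substituent_signature(mol, adj, i, j),
                   character(1))
    if (anyDuplicated(sigs)) next
    if (ring_only && !.in_ring(adj, i)) next
    rows[[length(rows) + 1L]] <-
      c(center = i, stats::setNames(order_improper_vertices(mol, nb),
                                    paste0("v", 1:4)))
  }
  if (!length(rows))
    return(data.frame(center = integer(), v1 = integer(), v2 = integer(),
                      v3 = integer(), v4 = integer()))
  as.data.frame(do.call(rbind, rows))
}

## Fixed vertex ordering for a four-vertex improper: hydrogen first, then
## the remaining substituents by descending atomic number, then by name.
order_improper_vertices <- function(mol, vertices) {
  el <- element_of(mol$atoms$name[vertices])
  z <- .ATOMIC_NUMBER[el]
  z[is.na(z)] <- 0
  is_h <- el == "H"
  key <- order(!is_h, -z, mol$atoms$name[vertices])
  vertices[key]
}

#' Measure chiral-center improper targets from a reference conformation
#'
#' @param mol a `molecule_graph`.
#' @param conf reference coordinates (n x 3 matrix, rows = atoms of `mol`).
#' @param ring_only see [find_chiral_centers()].
#' @return data.frame of chiral centers with a `target` column: the
#'   signed four-vertex improper (degrees) measured on `conf`.
#' @export
chiral_centers <- function(mol, conf, ring_only = FALSE) {
  cc <- find_chiral_centers(mol, ring_only = ring_only)
  cc$target <- vapply(seq_len(nrow(cc)), function(r)
    signed_dihedral(conf[cc$v1[r], ], conf[cc$v2[r], ],
                    conf[cc$v3[r], ], conf[cc$v4[r], ]), numeric(1))
  cc
}

#' Check conformation chirality against four-vertex improper targets
#'
#' A center is reported when the sign of its measured four-vertex
#' improper differs from the sign of the target, or when the
#' minimal-image deviation from the target exceeds `tolerance_deg`.
#'
#' @param conf n x 3 coordinate matrix.
#' @param centers data.frame from [chiral_centers()] (columns `center`,
#'   `v1`..`v4`, `target`).
#' @param tolerance_deg deviation tolerance in degrees (default 25; the
#'   sign is the diagnostic, the tolerance only guards near-planar
#'   noise).
#' @return data.frame of violations: `center`, `measured`, `target`
#'   (degrees); zero rows when all centers are consistent.
#' @export
check_chirality <- function(conf, centers, tolerance_deg = 25) {
  out <- list()
  for (r in seq_len(nrow(centers))) {
    meas <- signed_dihedral(conf[centers$v1[r], ], conf[centers$v2[r], ],
                            conf[centers$v3[r], ], conf[centers$v4[r], ])
    tgt <- centers$target[r]
    if (sign(meas) != sign(tgt) || abs(wrap_angle(meas - tgt)) > tolerance_deg)
      out[[length(out) + 1L]] <- data.frame(center = centers$center[r],
                                            measured = meas, target = tgt)
  }
  if (!length(out))
    return(data.frame(center = integer(), measured = numeric(),
                      target = numeric()))
  do.call(rbind, out)
}

#' Rewrite chiral-center impropers into the four-vertex form
#'
#' For every chiral carbon of every residue in the topology (identified
#' on a single-residue molecule built from the residue definition), any
#' improper that lists the center atom among its four members and draws
#' all its members from the center plus its substituents (the
#' heavy-atom-only style) is removed, and one four-vertex improper over
#' the substituent atoms -- hydrogen included, ordered hydrogen first
#' then by descending atomic number then name -- is installed. The
#' target value of each new improper is the signed dihedral measured on
#' the supplied ideal reference conformation, returned in the
#' `improper_targets` element so it can be written into a parameter set.
#'
#' @param t a `topology_set`.
#' @param reference_coords named list: residue name -> n x 3 coordinate
#'   matrix with rownames equal to the residue's atom names.
#' @param ring_only restrict to ring stereocenters (default FALSE).
#' @return the modified `topology_set`, with an `improper_targets`
#'   data.frame element (`residue`, `a1`..`a4` atom names, `t1`..`t4`
#'   type codes, `phi0` degrees).
#' @export
retarget_impropers <- function(t, reference_coords, ring_only = FALSE) {
  stopifnot(inherits(t, "topology_set"))
  targets <- list()
  for (rn in names(t$residues)) {
    if (!rn %in% names(reference_coords)) next
    res <- t$residues[[rn]]
    mol <- build_molecule(rn, t)
    conf <- reference_coords[[rn]]
    if (is.null(rownames(conf)) ||
        !all(res$atoms$name %in% rownames(conf)))
      stop(sprintf("reference conformation for %s lacks named coordinates", rn))
    conf <- conf[res$atoms$name, , drop = FALSE]
    cc <- find_chiral_centers(mol, ring_only = ring_only)
    for (r in seq_len(nrow(cc))) {
      verts <- c(cc$v1[r], cc$v2[r], cc$v3[r], cc$v4[r])
      if (!any(element_of(mol$atoms$name[verts]) == "H"))
        stop(sprintf("chiral carbon %s in residue %s has no bonded hydrogen in the reference",
                     mol$atoms$name[cc$center[r]], rn))
      cname <- mol$atoms$name[cc$center[r]]
      members <- c(cname, mol$atoms$name[verts])
      if (nrow(res$impropers)) {
        heavy_style <- apply(res$impropers, 1, function(q)
          cname %in% q && all(q %in% members))
        res$impropers <- res$impropers[!heavy_style, , drop = FALSE]
      }
      quad <- mol$atoms$name[verts]
      res$impropers <- rbind(res$impropers, matrix(quad, 1, 4))
      phi0 <- signed_dihedral(conf[quad[1], ], conf[quad[2], ],
                              conf[quad[3], ], conf[quad[4], ])
      targets[[length(targets) + 1L]] <- data.frame(
        residue = rn, a1 = quad[1], a2 = quad[2], a3 = quad[3], a4 = quad[4],
        t1 = mol$atoms$type[verts[1]], t2 = mol$atoms$type[verts[2]],
        t3 = mol$atoms$type[verts[3]], t4 = mol$atoms$type[verts[4]],
        phi0 = phi0, stringsAsFactors = FALSE)
    }
    t$residues[[rn]] <- res
  }
  t$improper_targets <- if (length(targets)) do.call(rbind, targets) else
    data.frame(residue = character(), a1 = character(), a2 = character(),
               a3 = character(), a4 = character(), t1 = character(),
               t2 = character(), t3 = character(), t4 = character(),
               phi0 = numeric(), stringsAsFactors = FALSE)
  t
}

## Mirror-flip one atom through a center: returns conf with atoms[i]
## replaced by 2*center - atom (the inverted position on the C-H line).
flip_through <- function(conf, atom_idx, center_idx) {
  conf[atom_idx, ] <- 2 * conf[center_idx, ] - conf[atom_idx, ]
  conf
}
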