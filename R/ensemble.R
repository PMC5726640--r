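## NMR ensemble analyses: multi-model PDB ingestion (via bio3d),
## glycosidic phi/psi torsion statistics with circular means, sugar
## heavy-atom ensemble RMSD after optimal superposition, Cremer-Pople
## ring pucker classification, and XPLOR-style distance-restraint
## parsing/counting.

#' Read a multi-model PDB into an ensemble
#'
#' Wraps `bio3d::read.pdb`. Models must share one atom roster (enforced
#' before parsing); alternate location indicator A is preferred when
#' present; HETATM records (sugars) are retained.
#'
#' @param pdb path to a PDB file, or the file's lines as a character
#'   vector of length > 1.
#' @return an object of class `ensemble`: `atoms` data.frame (chain,
#'   resid, resname, name, elem, het) and `models`, a list of n x 3
#'   coordinate matrices.
#' @export
read_ensemble <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  }
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    mid <- cumsum(model_starts)
    per_model <- table(mid[is_atom & mid > 0])
    if (length(unique(as.integer(per_model))) > 1)
      stop("models have differing atom counts: roster mismatch")
    rosters <- split(substr(lines[is_atom & mid > 0], 13, 27), mid[is_atom & mid > 0])
    ref <- rosters[[1]]
    for (k in seq_along(rosters)) {
      bad <- which(rosters[[k]] != ref)
      if (length(bad))
        stop(sprintf("model %d atom roster differs from model 1 at atom record %d (%s)",
                     k, bad[1], trimws(rosters[[k]][bad[1]])))
    }
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  atoms <- data.frame(chain = at$chain[keep], resid = at$resno[keep],
                      resname = at$resid[keep], name = at$elety[keep],
                      elem = ifelse(is.na(at$elesy[keep]) | at$elesy[keep] == "",
                                    element_of(at$elety[keep]), at$elesy[keep]),
                      het = at$type[keep] == "HETATM",
                      stringsAsFactors = FALSE)
  nm <- nrow(p$xyz)
  cols <- which(keep)
  models <- lapply(seq_len(nm), function(m) {
    xyz <- matrix(p$xyz[m, ], ncol = 3, byrow = TRUE)[cols, , drop = FALSE]
    rownames(xyz) <- atoms$name
    xyz
  })
  structure(list(atoms = atoms, models = models), class = "ensemble")
}

#' Write an ensemble as a multi-model PDB
#'
#' @param e an `ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  stopifnot(inherits(e, "ensemble"))
  out <- character()
  for (m in seq_along(e$models)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    x <- e$models[[m]]
    for (i in seq_len(nrow(e$atoms))) {
      a <- e$atoms[i, ]
      name4 <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else a$name
      out <- c(out, sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                            if (isTRUE(a$het)) "HETATM" else "ATOM", i, name4,
                            a$resname, a$chain, a$resid,
                            x[i, 1], x[i, 2], x[i, 3], 1.0, 0.0, a$elem))
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d model(s), %d atoms, %d residue(s)\n",
              length(x$models), nrow(x$atoms),
              nrow(unique(x$atoms[c("chain", "resid")]))))
  invisible(x)
}

## circular statistics (degrees) -----------------------------------------

circular_mean <- function(deg) {
  s <- mean(sin(deg2rad(deg)))
  c <- mean(cos(deg2rad(deg)))
  wrap_angle(rad2deg(atan2(s, c)))
}

circular_sd <- function(deg) {
  s <- mean(sin(deg2rad(deg)))
  c <- mean(cos(deg2rad(deg)))
  r <- min(1, sqrt(s^2 + c^2))
  rad2deg(sqrt(-2 * log(max(r, .Machine$double.xmin))))
}

## atom lookup in an ensemble: unique atom index for (resid, name)
.atom_idx <- function(e, resid, name, chain = NULL) {
  ok <- e$atoms$resid == resid & e$atoms$name == name
  if (!is.null(chain)) ok <- ok & e$atoms$chain == chain
  hit <- which(ok)
  if (length(hit) != 1)
    stop(sprintf("atom '%s' of residue %s %s", name, resid,
                 if (length(hit)) "is not unique" else "is missing"))
  hit
}

#' Describe a glycosidic linkage for torsion analysis
#'
#' @param donor residue number of the sugar contributing C1.
#' @param acceptor residue number of the acceptor (sugar or amino acid).
#' @param ox,cx,cprev acceptor atom names bracketing the linkage: the
#'   linkage oxygen (e.g. "O3", "O4", Thr "OG1"), the carbon it sits on
#'   (e.g. "C3", "C4", Thr "CB") and the next carbon back (e.g. "C2",
#'   "C3", Thr "CA").
#' @param chain optional chain id restricting both residues.
#' @param label plot/report label.
#' @return a `linkage_spec` list.
#' @export
glycosidic_linkage <- function(donor, acceptor, ox, cx, cprev,
                               chain = NULL, label = NULL) {
  structure(list(donor = donor, acceptor = acceptor, ox = ox, cx = cx,
                 cprev = cprev, chain = chain,
                 label = if (is.null(label))
                   sprintf("%s->%s(%s)", donor, acceptor, ox) else label),
            class = "linkage_spec")
}

#' Glycosidic phi/psi torsions of an ensemble
#'
#' Computes, for every model, phi and psi across a glycosidic or
#' glycoprotein linkage and reports circular means and circular standard
#' deviations. Two phi conventions are supported: the heavy-atom
#' definition `phi = O5-C1-Ox'-Cx'` (default) and the proton-based
#' definition `phi = H1-C1-Ox'-Cx'`; psi is always `C1-Ox'-Cx'-C(x-1)'`.
#'
#' @param e an `ensemble`.
#' @param linkage a `linkage_spec` from [glycosidic_linkage()].
#' @param convention `"heavy"` or `"h1"`.
#' @return a `torsion_result`: per-model `phi`, `psi` (degrees) and
#'   `phi_mean`, `phi_sd`, `psi_mean`, `psi_sd`.
#' @export
glycosidic_torsions <- function(e, linkage, convention = c("heavy", "h1")) {
  stopifnot(inherits(e, "ensemble"), inherits(linkage, "linkage_spec"))
  convention <- match.arg(convention)
  first_atom <- if (convention == "heavy") "O5" else "H1"
  i1 <- .atom_idx(e, linkage$donor, first_atom, linkage$chain)
  i2 <- .atom_idx(e, linkage$donor, "C1", linkage$chain)
  i3 <- .atom_idx(e, linkage$acceptor, linkage$ox, linkage$chain)
  i4 <- .atom_idx(e, linkage$acceptor, linkage$cx, linkage$chain)
  i5 <- .atom_idx(e, linkage$acceptor, linkage$cprev, linkage$chain)
  phi <- vapply(e$models, function(x)
    signed_dihedral(x[i1, ], x[i2, ], x[i3, ], x[i4, ]), numeric(1))
  psi <- vapply(e$models, function(x)
    signed_dihedral(x[i2, ], x[i3, ], x[i4, ], x[i5, ]), numeric(1))
  structure(list(label = linkage$label, convention = convention,
                 phi = phi, psi = psi,
                 phi_mean = circular_mean(phi), phi_sd = circular_sd(phi),
                 psi_mean = circular_mean(psi), psi_sd = circular_sd(psi)),
            class = "torsion_result")
}

#' @export
print.torsion_result <- function(x, ...) {
  cat(sprintf("%s [%s]: phi %.1f +/- %.1f, psi %.1f +/- %.1f (n=%d)\n",
              x$label, x$convention, x$phi_mean, x$phi_sd,
              x$psi_mean, x$psi_sd, length(x$phi)))
  invisible(x)
}

#' Ensemble RMSD over an atom selection
#'
#' Optimal least-squares (Kabsch) superposition on the selection for
#' every model pair (`mode = "pairwise"`, reported as the mean pairwise
#' RMSD) or against an iteratively refined mean structure
#' (`mode = "to_mean"`).
#'
#' @param e an `ensemble`.
#' @param selection integer/logical index into `e$atoms`, or a predicate
#'   `function(atoms)` returning one.
#' @param mode `"pairwise"` or `"to_mean"`.
#' @return an `rmsd_report`: `mean_rmsd` (Å), `per_model` (for
#'   `to_mean`: RMSD of each model to the mean structure; for
#'   `pairwise`: mean RMSD of each model to the others), `n_atoms`.
#' @export
ensemble_rmsd <- function(e, selection, mode = c("pairwise", "to_mean")) {
  stopifnot(inherits(e, "ensemble"))
  mode <- match.arg(mode)
  if (is.function(selection)) selection <- selection(e$atoms)
  if (is.logical(selection)) selection <- which(selection)
  if (length(selection) < 3) stop("selection must cover at least 3 atoms")
  xs <- lapply(e$models, function(x) x[selection, , drop = FALSE])
  nm <- length(xs)
  if (mode == "pairwise") {
    if (nm == 1) return(structure(list(mean_rmsd = 0, per_model = 0,
                                       n_atoms = length(selection), mode = mode),
                                  class = "rmsd_report"))
    rm <- matrix(0, nm, nm)
    for (i in seq_len(nm - 1)) for (j in seq(i + 1, nm)) {
      rm[i, j] <- rm[j, i] <- superpose_rmsd(xs[[i]], xs[[j]])
    }
    structure(list(mean_rmsd = mean(rm[upper.tri(rm)]),
                   per_model = rowSums(rm) / (nm - 1),
                   pair_matrix = rm,
                   n_atoms = length(selection), mode = mode),
              class = "rmsd_report")
  } else {
    fitted <- c(list(xs[[1]]), lapply(xs[-1], function(y) superpose_fit(xs[[1]], y)))
    for (it in 1:5) {
      mref <- Reduce(`+`, fitted) / nm
      fitted <- lapply(xs, function(y) superpose_fit(mref, y))
    }
    mref <- Reduce(`+`, fitted) / nm
    per <- vapply(fitted, function(y) sqrt(sum((y - mref)^2) / nrow(mref)),
                  numeric(1))
    structure(list(mean_rmsd = mean(per), per_model = per,
                   n_atoms = length(selection), mode = mode),
              class = "rmsd_report")
  }
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("ensemble RMSD (%s, %d atoms): %.3f A\n",
              x$mode, x$n_atoms, x$mean_rmsd))
  invisible(x)
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the puckering amplitude Q (Å), polar angle theta (degrees)
#' and phase phi2 (degrees) of a six-membered ring, plus a conformer
#' class: `chair` (theta < 45 or > 135), `boat` / `twist-boat`
#' (80 <= theta <= 100, split by the phi2 phase: boats at multiples of
#' 60 degrees +/- 15), `envelope/half-chair` otherwise, and `planar`
#' when Q < 0.05 Å. Ring atoms are taken in the cyclic order
#' O5, C1, ..., C5 (or any consistent cyclic order).
#'
#' @param conf coordinate matrix with rownames, or an n x 3 matrix.
#' @param ring six atom names (matched against rownames) or row indices,
#'   in cyclic order.
#' @return a `pucker_result`: `Q`, `theta`, `phi2`, `class`, `z`
#'   (out-of-plane displacements).
#' @export
ring_pucker <- function(conf, ring = c("O5", "C1", "C2", "C3", "C4", "C5")) {
  if (is.character(ring)) {
    if (is.null(rownames(conf))) stop("conf needs rownames to select ring atoms by name")
    idx <- match(ring, rownames(conf))
    if (anyNA(idx)) stop("ring atom(s) missing: ",
                         paste(ring[is.na(idx)], collapse = ", "))
  } else idx <- ring
  if (length(idx) != 6) stop("exactly 6 ring atoms are required")
  x <- conf[idx, , drop = FALSE]
  d <- sqrt(rowSums((x - x[c(2:6, 1), , drop = FALSE])^2))
  if (any(d > 2.2))
    warning("ring atoms are not mutually bonded in sequence; computing anyway")
  n <- 6L
  ctr <- colMeans(x)
  r <- sweep(x, 2, ctr)
  j <- 0:(n - 1)
  rp <- colSums(r * sin(2 * pi * j / n))
  rpp <- colSums(r * cos(2 * pi * j / n))
  nrm <- unit(cross3(rp, rpp))
  z <- as.vector(r %*% nrm)
  q2c <- sqrt(2 / n) * sum(z * cos(4 * pi * j / n))
  q2s <- -sqrt(2 / n) * sum(z * sin(4 * pi * j / n))
  q3 <- sqrt(1 / n) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  bigq <- sqrt(q2^2 + q3^2)
  theta <- if (bigq < 1e-12) 0 else rad2deg(acos(pmin(1, pmax(-1, q3 / bigq))))
  phi2 <- if (q2 < 1e-12) 0 else (rad2deg(atan2(q2s, q2c)) %% 360)
  cls <- if (bigq < 0.05) "planar"
  else if (theta < 45 || theta > 135) "chair"
  else if (theta >= 80 && theta <= 100) {
    if (min(abs(wrap_angle(phi2 - seq(0, 300, by = 60)))) <= 15) "boat" else "twist-boat"
  } else "envelope/half-chair"
  structure(list(Q = bigq, theta = theta, phi2 = phi2, class = cls, z = z,
                 ring = if (is.character(ring)) ring else rownames(conf)[idx]),
            class = "pucker_result")
}

#' @export
print.pucker_result <- function(x, ...) {
  cat(sprintf("pucker: Q=%.3f A, theta=%.1f deg, phi2=%.1f deg -> %s\n",
              x$Q, x$theta, x$phi2, x$class))
  invisible(x)
}

## ---------------------------------------------------------------------
## XPLOR-style distance restraints

.parse_selection <- function(s, line) {
  ## flat and/or grammar over segid/resid/residue/resname/name clauses
  or_parts <- strsplit(s, "(?i)\\bor\\b", perl = TRUE)[[1]]
  lapply(or_parts, function(part) {
    clauses <- strsplit(part, "(?i)\\band\\b", perl = TRUE)[[1]]
    out <- list()
    for (cl in clauses) {
      toks <- .tokens(gsub("[()]", " ", cl))
      if (!length(toks)) next
      if (length(toks) < 2)
        stop(sprintf("line %d: cannot parse selection clause '%s'", line, cl))
      key <- .kw(toks[1])
      field <- switch(key, SEGI = "segid", RESI = "resid", RESN = "resname",
                      NAME = "name",
                      stop(sprintf("line %d: unsupported selection keyword '%s'",
                                   line, toks[1])))
      out[[field]] <- toupper(toks[2])
    }
    out
  })
}

#' Parse XPLOR-style distance restraints
#'
#' Reads `assign (selection) (selection) d dminus dplus` statements,
#' which may span physical lines. Selections support `segid`, `resid`
#' (or `residue`), `resname` and `name` clauses joined by `and`/`or`.
#'
#' @param text character vector of lines or one string.
#' @return list of `restraint_record`s, each with `sel1`, `sel2` (lists
#'   of and-clauses), `d`, `dminus`, `dplus`.
#' @export
parse_distance_restraints <- function(text) {
  raw <- paste(unlist(strsplit(paste(text, collapse = "\n"), "\n")), collapse = "\n")
  raw <- gsub("!.*?(\n|$)", "\n", raw)
  ## locate assign statements
  out <- list()
  pos <- gregexpr("(?i)\\bassi[a-z]*\\b", raw, perl = TRUE)[[1]]
  if (pos[1] == -1) return(out)
  line_of <- function(p) 1L + sum(strsplit(substr(raw, 1, p), "")[[1]] == "\n")
  ends <- c(pos[-1], nchar(raw) + 1L)
  for (k in seq_along(pos)) {
    chunk <- substr(raw, pos[k], ends[k] - 1L)
    ln <- line_of(pos[k])
    ## extract two balanced parenthesized groups
    chars <- strsplit(chunk, "")[[1]]
    groups <- character()
    depth <- 0L
    start <- NA_integer_
    for (i in seq_along(chars)) {
      if (chars[i] == "(") {
        if (depth == 0L) start <- i
        depth <- depth + 1L
      } else if (chars[i] == ")") {
        depth <- depth - 1L
        if (depth < 0L) stop(sprintf("line %d: unbalanced parentheses in assign", ln))
        if (depth == 0L) {
          groups <- c(groups, paste(chars[(start + 1):(i - 1)], collapse = ""))
          if (length(groups) == 2L) { rest <- paste(chars[-(1:i)], collapse = ""); break }
        }
      }
    }
    if (length(groups) != 2L)
      stop(sprintf("line %d: assign statement needs two selections", ln))
    nums <- suppressWarnings(as.numeric(.tokens(rest)))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 3)
      stop(sprintf("line %d: assign statement needs three distance values", ln))
    out[[length(out) + 1L]] <- structure(list(
      sel1 = .parse_selection(groups[1], ln),
      sel2 = .parse_selection(groups[2], ln),
      d = nums[1], dminus = nums[2], dplus = nums[3]), class = "restraint_record")
  }
  out
}

## does a parsed restraint selection (list of and-clauses) match a query
## spec list(resid=, resname=, name=, segid=, negate=)?
.sel_matches <- function(sel, query) {
  q <- query[setdiff(names(query), "negate")]
  hit <- any(vapply(sel, function(clause) {
    all(vapply(names(q), function(f) {
      !is.null(clause[[f]]) && toupper(clause[[f]]) %in% toupper(as.character(q[[f]]))
    }, logical(1)))
  }, logical(1)))
  if (isTRUE(query$negate)) !hit else hit
}

#' Count restraints bridging two selections
#'
#' A restraint counts when one of its two members matches `sel_a` and
#' the other matches `sel_b` (symmetric in the arguments). Query
#' selections are lists with any of `resid`, `resname`, `name`, `segid`
#' (values may be vectors) plus optional `negate = TRUE`.
#'
#' @param records list from [parse_distance_restraints()].
#' @param sel_a,sel_b query selection lists.
#' @return integer count.
#' @export
count_between <- function(records, sel_a, sel_b) {
  sum(vapply(records, function(r) {
    (.sel_matches(r$sel1, sel_a) && .sel_matches(r$sel2, sel_b)) ||
      (.sel_matches(r$sel1, sel_b) && .sel_matches(r$sel2, sel_a))
  }, logical(1)))
}
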