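## Molecule assembly: instantiate residue topologies into an indexed atom
## + bond graph, apply PRESidue patches (add/delete/modify), and generate
## the O-/S-glycosylation and glycosidic linkage patch catalogue.

#' Build a molecule graph from a residue sequence
#'
#' Concatenates the named residues' atoms in order and instantiates each
#' residue's intra-residue bonds, angles, dihedrals and impropers as
#' atom-index tuples. No inter-residue bonds are created; linkages are
#' made afterwards with [apply_patch()].
#'
#' @param sequence character vector of residue names, all present in `t`.
#' @param t a `topology_set`.
#' @return an object of class `molecule_graph` with elements `atoms`
#'   (data.frame: res_index, res_name, name, type, charge), `bonds`
#'   (2-column index matrix), `angles`, `dihedrals`, `impropers`
#'   (explicit index tuples carried from the topology).
#' @export
build_molecule <- function(sequence, t) {
  stopifnot(inherits(t, "topology_set"))
  missing <- setdiff(sequence, names(t$residues))
  if (length(missing))
    stop("unknown residue name(s): ", paste(missing, collapse = ", "))
  atoms <- list()
  bonds <- list(); angles <- list(); dihedrals <- list(); impropers <- list()
  offset <- 0L
  for (ri in seq_along(sequence)) {
    res <- t$residues[[sequence[ri]]]
    na <- nrow(res$atoms)
    atoms[[ri]] <- data.frame(res_index = ri, res_name = res$name,
                              name = res$atoms$name, type = res$atoms$type,
                              charge = res$atoms$charge,
                              stringsAsFactors = FALSE)
    idx_of <- stats::setNames(seq_len(na) + offset, res$atoms$name)
    map_tuples <- function(m) {
      if (!nrow(m)) return(matrix(integer(), 0, ncol(m)))
      matrix(idx_of[as.vector(m)], nrow = nrow(m), ncol = ncol(m))
    }
    bonds[[ri]] <- map_tuples(res$bonds)
    angles[[ri]] <- map_tuples(res$angles)
    dihedrals[[ri]] <- map_tuples(res$dihedrals)
    impropers[[ri]] <- map_tuples(res$impropers)
    offset <- offset + na
  }
  mol <- structure(list(
    atoms = do.call(rbind, atoms),
    bonds = do.call(rbind, bonds),
    angles = do.call(rbind, angles),
    dihedrals = do.call(rbind, dihedrals),
    impropers = do.call(rbind, impropers)
  ), class = "molecule_graph")
  rownames(mol$atoms) <- NULL
  validate_molecule(mol)
}

validate_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  idx <- c(mol$bonds, mol$angles, mol$dihedrals, mol$impropers)
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    stop("molecule term references an atom index out of range")
  if (nrow(mol$bonds)) {
    if (any(mol$bonds[, 1] == mol$bonds[, 2]))
      stop("molecule bond graph contains a self-edge")
    key <- paste(pmin(mol$bonds[, 1], mol$bonds[, 2]),
                 pmax(mol$bonds[, 1], mol$bonds[, 2]))
    if (anyDuplicated(key)) stop("molecule bond graph contains a duplicate edge")
  }
  mol
}

## adjacency list of the bond graph
.adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

## number of connected components of the bond graph
n_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0) return(0L)
  adj <- .adjacency(mol)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  comps
}

## Resolve a patch atom reference "1-NAME"/"2-NAME" to an atom index.
.resolve_ref <- function(mol, ref, mapping) {
  m <- regmatches(ref, regexec("^([12])-(.+)$", ref))[[1]]
  if (length(m) != 3)
    stop(sprintf("patch reference '%s' is not of the form 1-NAME or 2-NAME", ref))
  res_idx <- mapping[[as.integer(m[2])]]
  if (is.null(res_idx) || is.na(res_idx))
    stop(sprintf("patch reference '%s' has no residue mapping", ref))
  hit <- which(mol$atoms$res_index == res_idx & mol$atoms$name == m[3])
  if (length(hit) != 1)
    stop(sprintf("patch reference '%s' does not resolve to a unique atom (residue index %d)",
                 ref, res_idx))
  hit
}

#' Apply a patch to a molecule graph
#'
#' Executes the patch statements in order: `delete atom` removes the atom
#' and every bond/angle/dihedral/improper touching it; `add` statements
#' insert atoms, bonds and explicit terms; `modify atom` overwrites type
#' and/or charge. Atom references are `1-NAME`/`2-NAME`, resolved through
#' `mapping` to residue indices of `mol`.
#'
#' @param mol a `molecule_graph`.
#' @param patch a `patch_def`.
#' @param mapping integer vector of length 1 or 2: the residue indices
#'   that `1-` and `2-` select.
#' @return the patched `molecule_graph`.
#' @export
apply_patch <- function(mol, patch, mapping) {
  stopifnot(inherits(mol, "molecule_graph"), inherits(patch, "patch_def"))
  mapping <- as.integer(mapping)
  for (st in patch$statements) {
    if (st$kind == "atom" && st$action == "delete") {
      i <- .resolve_ref(mol, st$refs, mapping)
      mol <- .delete_atom(mol, i)
    } else if (st$kind == "atom" && st$action == "modify") {
      i <- .resolve_ref(mol, st$refs, mapping)
      if (!is.null(st$type)) mol$atoms$type[i] <- st$type
      if (!is.null(st$charge)) mol$atoms$charge[i] <- st$charge
    } else if (st$kind == "atom" && st$action == "add") {
      m <- regmatches(st$refs, regexec("^([12])-(.+)$", st$refs))[[1]]
      if (length(m) != 3)
        stop(sprintf("patch reference '%s' is not of the form 1-NAME or 2-NAME", st$refs))
      ri <- mapping[[as.integer(m[2])]]
      if (is.null(st$type)) stop("added atom needs TYPE=")
      rn <- mol$atoms$res_name[match(ri, mol$atoms$res_index)]
      mol$atoms <- rbind(mol$atoms, data.frame(
        res_index = ri, res_name = rn, name = m[3], type = st$type,
        charge = if (is.null(st$charge)) 0 else st$charge,
        stringsAsFactors = FALSE))
      rownames(mol$atoms) <- NULL
    } else {
      idx <- vapply(st$refs, function(r) .resolve_ref(mol, r, mapping), integer(1))
      if (st$action == "delete") {
        mol <- .delete_term(mol, st$kind, idx)
      } else {
        slot <- c(bond = "bonds", angle = "angles",
                  dihedral = "dihedrals", improper = "impropers")[[st$kind]]
        mol[[slot]] <- rbind(mol[[slot]], matrix(idx, nrow = 1))
      }
    }
  }
  validate_molecule(mol)
}

.delete_atom <- function(mol, i) {
  keep_term <- function(m) {
    if (!nrow(m)) return(m)
    m[!apply(m == i, 1, any), , drop = FALSE]
  }
  mol$bonds <- keep_term(mol$bonds)
  mol$angles <- keep_term(mol$angles)
  mol$dihedrals <- keep_term(mol$dihedrals)
  mol$impropers <- keep_term(mol$impropers)
  shift <- function(m) { m[m > i] <- m[m > i] - 1L; m }
  mol$bonds <- shift(mol$bonds)
  mol$angles <- shift(mol$angles)
  mol$dihedrals <- shift(mol$dihedrals)
  mol$impropers <- shift(mol$impropers)
  mol$atoms <- mol$atoms[-i, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol
}

.delete_term <- function(mol, kind, idx) {
  slot <- c(bond = "bonds", angle = "angles",
            dihedral = "dihedrals", improper = "impropers")[[kind]]
  m <- mol[[slot]]
  if (!nrow(m)) stop("no ", kind, " terms to delete")
  hit <- apply(m, 1, function(r) all(r == idx) || all(r == rev(idx)))
  if (!any(hit)) stop("patch deletes a nonexistent ", kind, " term")
  mol[[slot]] <- m[!hit, , drop = FALSE]
  mol
}

#' Generate the glycosylation and glycosidic-linkage patch catalogue
#'
#' Constructs the sixteen linkage patches: A1S/A1T for alpha linkage of
#' the sugar C1 to Ser OG / Thr OG1, B1S/B1T for the beta equivalents,
#' A1C/B1C for alpha/beta linkage of C1 to Cys SG, B13/B16 for
#' beta(1,3)- and beta(1,6)-glycosidic bonds, and the eight L-sugar
#' variants B13L, B16L, A1SL, B1SL, A1TL, B1TL, A1CL, B1CL. In every
#' patch residue `1-` is the sugar contributing C1 and `2-` is the
#' acceptor. Each patch deletes the sugar anomeric hydroxyl (O1, HO1)
#' and the acceptor hydroxyl/thiol hydrogen, adds the single new
#' C1-acceptor bond, and installs one four-vertex chirality improper at
#' C1 (H1, linked acceptor atom, O5, C2). Alpha vs beta and D vs L
#' variants differ only in the sign of that improper's target, recorded
#' in the patch's `c1_sign` field (+1 for alpha-D; beta and L each flip
#' the sign).
#'
#' @return named list of `patch_def` objects (length 16).
#' @export
generate_glycosylation_patches <- function() {
  spec <- list(
    ## name, acceptor link atom, acceptor H deleted, anomeric alpha?, L?
    A1S  = list(link = "OG",  hdel = "HG",  alpha = TRUE,  L = FALSE),
    B1S  = list(link = "OG",  hdel = "HG",  alpha = FALSE, L = FALSE),
    A1T  = list(link = "OG1", hdel = "HG1", alpha = TRUE,  L = FALSE),
    B1T  = list(link = "OG1", hdel = "HG1", alpha = FALSE, L = FALSE),
    A1C  = list(link = "SG",  hdel = "HG",  alpha = TRUE,  L = FALSE),
    B1C  = list(link = "SG",  hdel = "HG",  alpha = FALSE, L = FALSE),
    B13  = list(link = "O3",  hdel = "HO3", alpha = FALSE, L = FALSE),
    B16  = list(link = "O6",  hdel = "HO6", alpha = FALSE, L = FALSE),
    A1SL = list(link = "OG",  hdel = "HG",  alpha = TRUE,  L = TRUE),
    B1SL = list(link = "OG",  hdel = "HG",  alpha = FALSE, L = TRUE),
    A1TL = list(link = "OG1", hdel = "HG1", alpha = TRUE,  L = TRUE),
    B1TL = list(link = "OG1", hdel = "HG1", alpha = FALSE, L = TRUE),
    A1CL = list(link = "SG",  hdel = "HG",  alpha = TRUE,  L = TRUE),
    B1CL = list(link = "SG",  hdel = "HG",  alpha = FALSE, L = TRUE),
    B13L = list(link = "O3",  hdel = "HO3", alpha = FALSE, L = TRUE),
    B16L = list(link = "O6",  hdel = "HO6", alpha = FALSE, L = TRUE)
  )
  out <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    p <- new_patch_def(nm)
    p$statements <- list(
      list(action = "delete", kind = "atom", refs = "1-O1"),
      list(action = "delete", kind = "atom", refs = "1-HO1"),
      list(action = "delete", kind = "atom", refs = paste0("2-", s$hdel)),
      list(action = "add", kind = "bond",
           refs = c("1-C1", paste0("2-", s$link))),
      list(action = "add", kind = "improper",
           refs = c("1-H1", paste0("2-", s$link), "1-O5", "1-C2"))
    )
    p$link_atom <- s$link
    p$anomeric <- if (s$alpha) "alpha" else "beta"
    p$series <- if (s$L) "L" else "D"
    p$c1_sign <- (if (s$alpha) 1 else -1) * (if (s$L) -1 else 1)
    out[[nm]] <- p
  }
  out
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("molecule_graph: %d atoms, %d bonds, %d components (%d dihedral, %d improper terms)\n",
              nrow(x$atoms), nrow(x$bonds), n_components(x),
              nrow(x$dihedrals), nrow(x$impropers)))
  invisible(x)
}

## Enumerate term instances of a molecule as index tuples. Angles are
## either all bonded triples (autogenerated) or the explicit list;
## dihedrals/impropers are always the explicit lists.
enumerate_term_atoms <- function(mol, autogenerate_angles = TRUE) {
  angles <- if (autogenerate_angles) .autogen_angles(mol) else mol$angles
  list(bonds = mol$bonds, angles = angles,
       dihedrals = mol$dihedrals, impropers = mol$impropers)
}

.autogen_angles <- function(mol) {
  adj <- .adjacency(mol)
  out <- list()
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (k in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- c(cmb[1, k], j, cmb[2, k])
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

## Graph distance >= 3 pair list (for the repulsive nonbonded term):
## returns 2-column matrix of atom index pairs excluding 1-2 and 1-3.
nonbonded_pairs <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    excl[[i]] <- unique(c(i, one, two))
  }
  out <- list()
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), excl[[i]])
    js <- js[js > i]
    if (length(js)) out[[length(out) + 1L]] <- cbind(i, js)
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}
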