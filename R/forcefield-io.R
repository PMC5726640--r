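## Reader/writer for the CNS/XPLOR-style topology (.top) and parameter
## (.param) dialect subset used by carbohydrate force-field files:
## RESIdue/PRESidue blocks, ATOM/BOND/ANGLe/DIHEdral/IMPRoper statements,
## MASS, AUTOgenerate, "!" comments, case-insensitive keywords matched on
## their first four characters, and a verbatim passthrough store for
## everything else so foreign content survives a read/modify/write cycle.

KEYWORD_MIN <- 4L

.kw <- function(token) toupper(substr(token, 1L, KEYWORD_MIN))

.is_kw <- function(token, keyword) {
  !is.na(token) && nzchar(token) && .kw(token) == toupper(substr(keyword, 1L, KEYWORD_MIN))
}

## Split a physical text into logical statements: "!" comments stripped
## (kept separately), a line whose last token is a lone "-" continues on
## the next line. Returns data.frame(line = first physical line, text).
.logical_lines <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  out_text <- character()
  out_line <- integer()
  buf <- ""
  buf_line <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln) && !nzchar(buf)) next
    if (is.na(buf_line)) buf_line <- i
    cont <- grepl("(^|[[:space:]])-$", ln)
    if (cont) ln <- trimws(sub("-$", "", ln))
    buf <- trimws(paste(buf, ln))
    if (!cont) {
      if (nzchar(buf)) {
        out_text <- c(out_text, buf)
        out_line <- c(out_line, buf_line)
      }
      buf <- ""
      buf_line <- NA_integer_
    }
  }
  if (nzchar(buf)) {
    out_text <- c(out_text, buf)
    out_line <- c(out_line, buf_line)
  }
  data.frame(line = out_line, text = out_text, stringsAsFactors = FALSE)
}

.tokens <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]

## Parse "KEY=value" fields out of a token vector; returns a named list
## plus the tokens that were not KEY=value pairs.
.kv_fields <- function(toks) {
  kv <- list()
  plain <- character()
  for (t in toks) {
    if (grepl("=", t, fixed = TRUE)) {
      parts <- strsplit(t, "=", fixed = TRUE)[[1]]
      kv[[.kw(parts[1])]] <- paste(parts[-1], collapse = "=")
    } else plain <- c(plain, t)
  }
  list(kv = kv, plain = plain)
}

.parse_bool <- function(x) toupper(substr(x, 1, 4)) %in% c("TRUE", "T", "ON", "YES", "1")

new_residue_topology <- function(name) {
  structure(list(
    name = name,
    atoms = data.frame(name = character(), type = character(),
                       charge = numeric(), mass = numeric(),
                       stringsAsFactors = FALSE),
    bonds = matrix(character(), 0, 2),
    angles = matrix(character(), 0, 3),
    dihedrals = matrix(character(), 0, 4),
    impropers = matrix(character(), 0, 4),
    passthrough = character()
  ), class = "residue_topology")
}

new_patch_def <- function(name) {
  structure(list(name = name, statements = list(), passthrough = character()),
            class = "patch_def")
}

#' Construct an empty topology set
#'
#' A topology set holds residue definitions, patch (PRESidue) definitions,
#' per-type masses, the autogenerate flags, and a verbatim passthrough
#' store of unrecognized statements.
#'
#' @param autogenerate_angles,autogenerate_dihedrals logical; whether
#'   angle/dihedral terms are to be generated from the bond graph rather
#'   than taken from explicit statements.
#' @return an object of class `topology_set`.
#' @export
new_topology_set <- function(autogenerate_angles = FALSE,
                             autogenerate_dihedrals = FALSE) {
  structure(list(
    residues = list(),
    patches = list(),
    masses = numeric(),
    autogenerate_angles = autogenerate_angles,
    autogenerate_dihedrals = autogenerate_dihedrals,
    passthrough = character()
  ), class = "topology_set")
}

.check_residue <- function(res, where) {
  nm <- res$atoms$name
  if (anyDuplicated(nm))
    stop(sprintf("duplicate atom name '%s' in residue %s",
                 nm[duplicated(nm)][1], where))
  refs <- c(res$bonds, res$angles, res$dihedrals, res$impropers)
  bad <- setdiff(refs, nm)
  if (length(bad))
    stop(sprintf("residue %s references undefined atom '%s'", where, bad[1]))
  if (nrow(res$bonds)) {
    key <- apply(res$bonds, 1, function(r) paste(sort(r), collapse = "~"))
    if (anyDuplicated(key))
      stop(sprintf("duplicate bond %s in residue %s",
                   key[duplicated(key)][1], where))
  }
  invisible(res)
}

#' Parse topology (.top) dialect text
#'
#' Supports RESIdue and PRESidue blocks, ATOM (with TYPE= and CHARge=,
#' optionally MASS=), BOND, ANGLe, DIHEdral, IMPRoper, DELETE/ADD/MODIfy
#' patch statements, GROUp (preserved verbatim), MASS, AUTOgenerate and
#' "!" comments. Keywords are case-insensitive and matched on their first
#' four characters. Unrecognized statements are preserved in a
#' passthrough store and re-emitted by [write_topology()].
#'
#' Patch statements reference atoms as `1-NAME` / `2-NAME`, selecting the
#' first or second residue the patch is applied to.
#'
#' @param text character vector (lines, or one string with newlines).
#' @return a `topology_set`.
#' @export
parse_topology <- function(text) {
  ts <- new_topology_set()
  ll <- .logical_lines(text)
  i <- 1L
  n <- nrow(ll)
  while (i <= n) {
    toks <- .tokens(ll$text[i])
    head_kw <- .kw(toks[1])
    if (head_kw == "MASS" && length(toks) >= 3) {
      ts$masses[toks[2]] <- as.numeric(toks[3])
      i <- i + 1L
    } else if (head_kw == "AUTO") {
      f <- .kv_fields(toks[-1])
      if (!is.null(f$kv$ANGL)) ts$autogenerate_angles <- .parse_bool(f$kv$ANGL)
      if (!is.null(f$kv$DIHE)) ts$autogenerate_dihedrals <- .parse_bool(f$kv$DIHE)
      i <- i + 1L
    } else if (head_kw %in% c("RESI", "PRES")) {
      if (length(toks) < 2)
        stop(sprintf("line %d: %s block without a name", ll$line[i], toks[1]))
      block_name <- toks[2]
      j <- i + 1L
      depth_end <- NA_integer_
      while (j <= n) {
        jt <- .tokens(ll$text[j])
        if (.kw(jt[1]) %in% c("RESI", "PRES"))
          stop(sprintf("line %d: unterminated block '%s' (missing END)",
                       ll$line[i], block_name))
        if (.kw(jt[1]) == "END" && length(jt) == 1L) { depth_end <- j; break }
        j <- j + 1L
      }
      if (is.na(depth_end))
        stop(sprintf("line %d: unterminated block '%s' (missing END)",
                     ll$line[i], block_name))
      body <- ll[seq(i + 1L, length.out = depth_end - i - 1L), , drop = FALSE]
      if (head_kw == "RESI") {
        if (block_name %in% names(ts$residues))
          stop(sprintf("duplicate residue name '%s'", block_name))
        ts$residues[[block_name]] <- .parse_residue_body(block_name, body)
      } else {
        if (block_name %in% names(ts$patches))
          stop(sprintf("duplicate patch name '%s'", block_name))
        ts$patches[[block_name]] <- .parse_patch_body(block_name, body)
      }
      i <- depth_end + 1L
    } else {
      ts$passthrough <- c(ts$passthrough, ll$text[i])
      i <- i + 1L
    }
  }
  ts
}

.parse_atom_stmt <- function(toks, line) {
  f <- .kv_fields(toks)
  plain <- f$plain
  plain <- plain[.kw(plain) != "END"]
  if (length(plain) < 1)
    stop(sprintf("line %d: ATOM statement without an atom name", line))
  name <- plain[1]
  type <- f$kv$TYPE
  if (is.null(type) || !nzchar(type))
    stop(sprintf("line %d: ATOM %s has no TYPE=", line, name))
  charge <- if (!is.null(f$kv$CHAR)) as.numeric(f$kv$CHAR) else 0
  mass <- if (!is.null(f$kv$MASS)) as.numeric(f$kv$MASS) else NA_real_
  list(name = name, type = type, charge = charge, mass = mass)
}

.take_tuples <- function(toks, k, what, line) {
  if (length(toks) %% k != 0L || length(toks) == 0L)
    stop(sprintf("line %d: %s statement needs atom names in groups of %d",
                 line, what, k))
  matrix(toks, ncol = k, byrow = TRUE)
}

.parse_residue_body <- function(name, body) {
  res <- new_residue_topology(name)
  for (r in seq_len(nrow(body))) {
    toks <- .tokens(body$text[r])
    kw <- .kw(toks[1])
    line <- body$line[r]
    if (kw == "ATOM") {
      a <- .parse_atom_stmt(toks[-1], line)
      res$atoms <- rbind(res$atoms,
                         data.frame(name = a$name, type = a$type,
                                    charge = a$charge, mass = a$mass,
                                    stringsAsFactors = FALSE))
    } else if (kw == "BOND") {
      res$bonds <- rbind(res$bonds, .take_tuples(toks[-1], 2L, "BOND", line))
    } else if (kw == "ANGL") {
      res$angles <- rbind(res$angles, .take_tuples(toks[-1], 3L, "ANGLE", line))
    } else if (kw == "DIHE") {
      res$dihedrals <- rbind(res$dihedrals, .take_tuples(toks[-1], 4L, "DIHEDRAL", line))
    } else if (kw == "IMPR") {
      res$impropers <- rbind(res$impropers, .take_tuples(toks[-1], 4L, "IMPROPER", line))
    } else if (kw == "GROU") {
      res$passthrough <- c(res$passthrough, body$text[r])
    } else {
      res$passthrough <- c(res$passthrough, body$text[r])
    }
  }
  .check_residue(res, name)
}

.KIND_BY_KW <- c(ATOM = "atom", BOND = "bond", ANGL = "angle",
                 DIHE = "dihedral", IMPR = "improper")

.parse_patch_stmt <- function(toks, line) {
  action <- "add"
  kw <- .kw(toks[1])
  if (kw %in% c("DELE", "ADD", "MODI")) {
    action <- c(DELE = "delete", ADD = "add", MODI = "modify")[[kw]]
    toks <- toks[-1]
    kw <- .kw(toks[1])
  }
  if (!kw %in% names(.KIND_BY_KW))
    stop(sprintf("line %d: unsupported patch statement '%s'", line, toks[1]))
  kind <- .KIND_BY_KW[[kw]]
  rest <- toks[-1]
  if (kind == "atom") {
    f <- .kv_fields(rest)
    plain <- f$plain[.kw(f$plain) != "END"]
    if (!length(plain))
      stop(sprintf("line %d: patch ATOM statement without an atom reference", line))
    st <- list(action = action, kind = "atom", refs = plain[1])
    if (!is.null(f$kv$TYPE)) st$type <- f$kv$TYPE
    if (!is.null(f$kv$CHAR)) st$charge <- as.numeric(f$kv$CHAR)
    st
  } else {
    k <- c(bond = 2L, angle = 3L, dihedral = 4L, improper = 4L)[[kind]]
    if (length(rest) != k)
      stop(sprintf("line %d: patch %s statement needs %d atom references",
                   line, toupper(kind), k))
    list(action = action, kind = kind, refs = rest)
  }
}

.parse_patch_body <- function(name, body) {
  p <- new_patch_def(name)
  for (r in seq_len(nrow(body))) {
    toks <- .tokens(body$text[r])
    kw <- .kw(toks[1])
    if (kw %in% c("DELE", "ADD", "MODI", names(.KIND_BY_KW))) {
      p$statements[[length(p$statements) + 1L]] <-
        .parse_patch_stmt(toks, body$line[r])
    } else {
      p$passthrough <- c(p$passthrough, body$text[r])
    }
  }
  p
}

.fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.1f", x),
                vapply(x, function(v) format(v, digits = 10, trim = TRUE,
                                             scientific = FALSE),
                       character(1))))
}

#' Write a topology set back to .top dialect text
#'
#' The emitted text re-parses with [parse_topology()] to a structurally
#' equal topology set; passthrough statements are re-emitted in place.
#'
#' @param t a `topology_set`.
#' @return character vector of lines.
#' @export
write_topology <- function(t) {
  stopifnot(inherits(t, "topology_set"))
  out <- c("! topology written by glycotop",
           sprintf("AUTOGENERATE ANGLES=%s DIHEDRALS=%s END",
                   if (t$autogenerate_angles) "TRUE" else "FALSE",
                   if (t$autogenerate_dihedrals) "TRUE" else "FALSE"))
  if (length(t$masses))
    out <- c(out, sprintf("MASS %s %s", names(t$masses), .fmt_num(unname(t$masses))))
  out <- c(out, t$passthrough)
  for (res in t$residues) {
    out <- c(out, "", sprintf("RESIDUE %s", res$name), res$passthrough)
    for (r in seq_len(nrow(res$atoms))) {
      a <- res$atoms[r, ]
      ln <- sprintf("  ATOM %s TYPE=%s CHARGE=%s", a$name, a$type, .fmt_num(a$charge))
      if (!is.na(a$mass)) ln <- paste0(ln, sprintf(" MASS=%s", .fmt_num(a$mass)))
      out <- c(out, paste0(ln, " END"))
    }
    emit_tuples <- function(m, kw)
      if (nrow(m)) sprintf("  %s %s", kw, apply(m, 1, paste, collapse = " ")) else character()
    out <- c(out,
             emit_tuples(res$bonds, "BOND"),
             emit_tuples(res$angles, "ANGLE"),
             emit_tuples(res$dihedrals, "DIHEDRAL"),
             emit_tuples(res$impropers, "IMPROPER"),
             "END")
  }
  for (p in t$patches) {
    out <- c(out, "", sprintf("PRESIDUE %s", p$name), p$passthrough)
    for (st in p$statements) {
      verb <- toupper(st$action)
      if (verb == "ADD") verb <- "ADD"
      if (st$kind == "atom") {
        ln <- sprintf("  %s ATOM %s", verb, st$refs)
        if (!is.null(st$type)) ln <- paste0(ln, sprintf(" TYPE=%s", st$type))
        if (!is.null(st$charge)) ln <- paste0(ln, sprintf(" CHARGE=%s", .fmt_num(st$charge)))
        out <- c(out, paste0(ln, " END"))
      } else {
        out <- c(out, sprintf("  %s %s %s", verb, toupper(st$kind),
                              paste(st$refs, collapse = " ")))
      }
    }
    out <- c(out, "END")
  }
  out
}

## ---------------------------------------------------------------------
## Parameter files

#' Construct an empty parameter set
#'
#' @return an object of class `parameter_set` with empty BOND, ANGLE,
#'   DIHEDRAL, IMPROPER and NONBONDED tables.
#' @export
new_parameter_set <- function() {
  structure(list(
    bonds = data.frame(a = character(), b = character(),
                       k = numeric(), b0 = numeric(), stringsAsFactors = FALSE),
    angles = data.frame(a = character(), b = character(), c = character(),
                        k = numeric(), theta0 = numeric(), stringsAsFactors = FALSE),
    dihedrals = data.frame(a = character(), b = character(), c = character(),
                           d = character(), k = numeric(), n = integer(),
                           delta = numeric(), stringsAsFactors = FALSE),
    impropers = data.frame(a = character(), b = character(), c = character(),
                           d = character(), k = numeric(), n = integer(),
                           phi0 = numeric(), stringsAsFactors = FALSE),
    nonbonded = data.frame(type = character(), eps = numeric(), sigma = numeric(),
                           eps14 = numeric(), sigma14 = numeric(),
                           stringsAsFactors = FALSE),
    passthrough = character()
  ), class = "parameter_set")
}

.dedup_last <- function(df, keycols, what) {
  if (!nrow(df)) return(df)
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  if (anyDuplicated(key)) {
    warning(sprintf("duplicate %s parameter entries: last occurrence wins", what),
            call. = FALSE)
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Parse parameter (.param) dialect text
#'
#' Recognizes BOND, ANGLe, DIHEdral, IMPRoper and NONBonded statements
#' ("X" is the wildcard type); anything else is preserved verbatim.
#' Duplicate entries with identical type tuples: the last occurrence wins,
#' with a warning.
#'
#' @param text character vector of lines or a single string.
#' @return a `parameter_set`.
#' @export
parse_parameters <- function(text) {
  p <- new_parameter_set()
  ll <- .logical_lines(text)
  for (i in seq_len(nrow(ll))) {
    toks <- .tokens(ll$text[i])
    kw <- .kw(toks[1])
    rest <- toks[-1]
    line <- ll$line[i]
    bad <- function(what, need)
      stop(sprintf("line %d: %s statement needs %s", line, what, need))
    if (kw == "BOND") {
      if (length(rest) != 4) bad("BOND", "2 types and 2 numbers")
      p$bonds <- rbind(p$bonds, data.frame(
        a = rest[1], b = rest[2],
        k = as.numeric(rest[3]), b0 = as.numeric(rest[4]),
        stringsAsFactors = FALSE))
    } else if (kw == "ANGL") {
      if (length(rest) != 5) bad("ANGLE", "3 types and 2 numbers")
      p$angles <- rbind(p$angles, data.frame(
        a = rest[1], b = rest[2], c = rest[3],
        k = as.numeric(rest[4]), theta0 = as.numeric(rest[5]),
        stringsAsFactors = FALSE))
    } else if (kw == "DIHE") {
      if (length(rest) != 7) bad("DIHEDRAL", "4 types and 3 numbers")
      p$dihedrals <- rbind(p$dihedrals, data.frame(
        a = rest[1], b = rest[2], c = rest[3], d = rest[4],
        k = as.numeric(rest[5]), n = as.integer(rest[6]),
        delta = as.numeric(rest[7]), stringsAsFactors = FALSE))
    } else if (kw == "IMPR") {
      if (length(rest) != 7) bad("IMPROPER", "4 types and 3 numbers")
      p$impropers <- rbind(p$impropers, data.frame(
        a = rest[1], b = rest[2], c = rest[3], d = rest[4],
        k = as.numeric(rest[5]), n = as.integer(rest[6]),
        phi0 = as.numeric(rest[7]), stringsAsFactors = FALSE))
    } else if (kw == "NONB") {
      if (!length(rest) %in% c(3, 5)) bad("NONBONDED", "1 type and 2 or 4 numbers")
      v <- as.numeric(rest[-1])
      if (length(v) == 2) v <- c(v, v)
      p$nonbonded <- rbind(p$nonbonded, data.frame(
        type = rest[1], eps = v[1], sigma = v[2], eps14 = v[3], sigma14 = v[4],
        stringsAsFactors = FALSE))
    } else {
      p$passthrough <- c(p$passthrough, ll$text[i])
    }
  }
  p$bonds <- .dedup_last(p$bonds, c("a", "b"), "BOND")
  p$angles <- .dedup_last(p$angles, c("a", "b", "c"), "ANGLE")
  p$dihedrals <- .dedup_last(p$dihedrals, c("a", "b", "c", "d"), "DIHEDRAL")
  p$impropers <- .dedup_last(p$impropers, c("a", "b", "c", "d"), "IMPROPER")
  p$nonbonded <- .dedup_last(p$nonbonded, "type", "NONBONDED")
  p
}

#' Write a parameter set to .param dialect text
#'
#' @param p a `parameter_set`.
#' @return character vector of lines; re-parses to an equal set.
#' @export
write_parameters <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  out <- "! parameters written by glycotop"
  out <- c(out, p$passthrough)
  if (nrow(p$bonds))
    out <- c(out, sprintf("BOND %s %s %s %s", p$bonds$a, p$bonds$b,
                          .fmt_num(p$bonds$k), .fmt_num(p$bonds$b0)))
  if (nrow(p$angles))
    out <- c(out, sprintf("ANGLE %s %s %s %s %s", p$angles$a, p$angles$b,
                          p$angles$c, .fmt_num(p$angles$k), .fmt_num(p$angles$theta0)))
  if (nrow(p$dihedrals))
    out <- c(out, sprintf("DIHEDRAL %s %s %s %s %s %d %s",
                          p$dihedrals$a, p$dihedrals$b, p$dihedrals$c, p$dihedrals$d,
                          .fmt_num(p$dihedrals$k), p$dihedrals$n, .fmt_num(p$dihedrals$delta)))
  if (nrow(p$impropers))
    out <- c(out, sprintf("IMPROPER %s %s %s %s %s %d %s",
                          p$impropers$a, p$impropers$b, p$impropers$c, p$impropers$d,
                          .fmt_num(p$impropers$k), p$impropers$n, .fmt_num(p$impropers$phi0)))
  if (nrow(p$nonbonded))
    out <- c(out, sprintf("NONBONDED %s %s %s %s %s", p$nonbonded$type,
                          .fmt_num(p$nonbonded$eps), .fmt_num(p$nonbonded$sigma),
                          .fmt_num(p$nonbonded$eps14), .fmt_num(p$nonbonded$sigma14)))
  out
}

#' Set all bonded force constants to the NMR annealing values
#'
#' Rewrites every BOND, ANGLE, IMPROPER and DIHEDRAL force constant to a
#' single value per term kind, leaving all geometry targets (b0, theta0,
#' phi0, periodicity, delta) and the NONBONDED table untouched. The
#' defaults are the constants used by the standard protein/nucleic-acid
#' parameter files for simulated annealing, so a parameter file
#' harmonized with the defaults can be dropped into the standard
#' protocol without its bonded terms being overpowered by experimental
#' restraint energies.
#'
#' @param p a `parameter_set`.
#' @param k_bond bond force constant, kcal mol^-1 A^-2 (default 1000.0).
#' @param k_angle angle force constant, kcal mol^-1 rad^-2 (default 500.0).
#' @param k_improper improper force constant, kcal mol^-1 rad^-2 (default 500.0).
#' @param k_dihedral dihedral force constant, kcal mol^-1 (default 2.0).
#' @return the harmonized `parameter_set`.
#' @export
harmonize_energies <- function(p, k_bond = 1000.0, k_angle = 500.0,
                               k_improper = 500.0, k_dihedral = 2.0) {
  stopifnot(inherits(p, "parameter_set"))
  ks <- c(k_bond, k_angle, k_improper, k_dihedral)
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("force constants must be finite and non-negative")
  if (nrow(p$bonds)) p$bonds$k <- k_bond
  if (nrow(p$angles)) p$angles$k <- k_angle
  if (nrow(p$impropers)) p$impropers$k <- k_improper
  if (nrow(p$dihedrals)) p$dihedrals$k <- k_dihedral
  p
}

## ---------------------------------------------------------------------
## Parameter lookup (symmetry + wildcard precedence)

.match_tuple <- function(entry_types, query_types) {
  ## returns match score: -1 no match, else number of exact (non-wildcard)
  ## positions; symmetric under full reversal
  score_dir <- function(et, qt) {
    ok <- et == qt | et == "X"
    if (!all(ok)) return(-1L)
    sum(et != "X")
  }
  max(score_dir(entry_types, query_types),
      score_dir(entry_types, rev(query_types)))
}

## Find the best parameter entry of the given kind for a type tuple.
## Exact positions beat wildcards; among equal scores the first entry
## wins. Returns the row (list) or NULL.
lookup_param <- function(p, kind, types) {
  df <- switch(kind,
               bond = p$bonds, angle = p$angles,
               dihedral = p$dihedrals, improper = p$impropers,
               stop("unknown parameter kind: ", kind))
  if (!nrow(df)) return(NULL)
  tcols <- switch(kind, bond = c("a", "b"), angle = c("a", "b", "c"),
                  c("a", "b", "c", "d"))
  best <- NULL
  best_score <- -1L
  for (i in seq_len(nrow(df))) {
    sc <- .match_tuple(unlist(df[i, tcols], use.names = FALSE), types)
    if (sc > best_score) {
      best_score <- sc
      best <- df[i, ]
    }
  }
  if (best_score < 0L) NULL else as.list(best)
}

#' Report molecule terms with no matching parameter
#'
#' Enumerates every bond, angle, dihedral and improper term instance of a
#' molecule and returns those for which the parameter set has no entry,
#' exact or wildcard. An empty result means an energy evaluation over the
#' molecule cannot fail on parameter lookup. A carbohydrate distribution
#' missing, for example, the three IMPROPER parameters of an
#' N-acetyl amide group shows up here as exactly those improper type
#' tuples.
#'
#' @param mol a `molecule_graph` (see [build_molecule()]).
#' @param p a `parameter_set`.
#' @param autogenerate_angles logical; if TRUE angle instances are all
#'   bonded triples, otherwise the explicit angle list is used.
#' @return data.frame with columns `kind`, `types` (slash-separated type
#'   tuple), `atoms` (slash-separated atom names); zero rows when
#'   coverage is complete.
#' @export
check_coverage <- function(mol, p, autogenerate_angles = TRUE) {
  stopifnot(inherits(mol, "molecule_graph"), inherits(p, "parameter_set"))
  terms <- enumerate_term_atoms(mol, autogenerate_angles = autogenerate_angles)
  out <- list()
  typ <- mol$atoms$type
  nm <- mol$atoms$name
  add_missing <- function(kind, idx_mat) {
    for (r in seq_len(nrow(idx_mat))) {
      tt <- typ[idx_mat[r, ]]
      if (is.null(lookup_param(p, kind, tt)))
        out[[length(out) + 1L]] <<- data.frame(
          kind = kind,
          types = paste(tt, collapse = "/"),
          atoms = paste(nm[idx_mat[r, ]], collapse = "/"),
          stringsAsFactors = FALSE)
    }
  }
  add_missing("bond", terms$bonds)
  add_missing("angle", terms$angles)
  add_missing("dihedral", terms$dihedrals)
  add_missing("improper", terms$impropers)
  if (!length(out))
    return(data.frame(kind = character(), types = character(),
                      atoms = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' @export
print.topology_set <- function(x, ...) {
  cat(sprintf("topology_set: %d residue(s), %d patch(es)%s\n",
              length(x$residues), length(x$patches),
              if (x$autogenerate_angles) ", autogenerate angles" else ""))
  if (length(x$residues))
    cat("  residues:", paste(names(x$residues), collapse = " "), "\n")
  if (length(x$patches))
    cat("  patches: ", paste(names(x$patches), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("parameter_set: %d bond, %d angle, %d dihedral, %d improper, %d nonbonded\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$impropers), nrow(x$nonbonded)))
  invisible(x)
}
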