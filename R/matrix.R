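#' Discrete morphological character matrices
#'
#' A `char_matrix` holds a taxa x characters grid of unordered discrete
#' states coded as single digits 0-9, with `NA` as the missing marker
#' (written `?` in all file dialects).  Characters are numbered 1..k in
#' input order; taxa are addressed by label throughout the package, never
#' by index.
#'
#' @param states integer matrix (taxa in rows, characters in columns);
#'   values in 0-9 or `NA`.  Row names supply taxon labels unless `taxa`
#'   is given.
#' @param taxa character vector of taxon labels.
#' @param char_names optional character descriptions, one per column.
#' @param weights per-character positive weights (default 1; the shipped
#'   analysis is equal-weights).
#' @param outgroup optional taxon label used for rooting.
#' @return an object of class `char_matrix`.
#' @examples
#' m <- char_matrix(rbind(A = c(0, 1), B = c(0, 1), C = c(1, 0)))
#' summary(m)
#' @export
char_matrix <- function(states, taxa = rownames(states), char_names = NULL,
                        weights = 1, outgroup = NULL) {
  states <- as.matrix(states)
  if (is.null(taxa)) stop("taxon labels are required (row names or `taxa`)")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(states)) stop("`taxa` must match the number of rows")
  storage.mode(states) <- "integer"
  rownames(states) <- taxa
  colnames(states) <- as.character(seq_len(ncol(states)))
  weights <- rep_len(as.numeric(weights), ncol(states))
  x <- structure(list(
    states = states,
    taxa = taxa,
    char_ids = seq_len(ncol(states)),
    char_names = char_names,
    char_type = rep("unordered", ncol(states)),
    weights = weights,
    outgroup = outgroup
  ), class = "char_matrix")
  validate_char_matrix(x)
  x
}

validate_char_matrix <- function(x) {
  s <- x$states
  if (nrow(s) < 3L) stop("a character matrix needs at least 3 taxa")
  if (ncol(s) < 1L) stop("a character matrix needs at least 1 character")
  if (anyDuplicated(x$taxa)) {
    stop("duplicate taxon label: ",
         paste(unique(x$taxa[duplicated(x$taxa)]), collapse = ", "))
  }
  bad <- !is.na(s) & (s < 0L | s > 9L | s != trunc(s))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid state %s at taxon '%s', character %d (states must be 0-9 or ?)",
                 s[bad][1], x$taxa[i[1]], i[2]))
  }
  if (!is.null(x$char_names) && length(x$char_names) != ncol(s))
    stop("`char_names` must have one entry per character")
  if (any(x$weights <= 0)) stop("character weights must be positive")
  if (!is.null(x$outgroup) && !x$outgroup %in% x$taxa)
    stop("outgroup '", x$outgroup, "' is not among the taxa")
  invisible(x)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (unordered, states 0-9)\n",
              nrow(x$states), ncol(x$states)))
  if (!is.null(x$outgroup)) cat("outgroup:", x$outgroup, "\n")
  n_missing <- sum(is.na(x$states))
  if (n_missing > 0) cat("missing cells:", n_missing, "\n")
  mat <- apply(x$states, 1, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))
  lab <- format(names(mat))
  for (i in seq_along(mat)) cat(" ", lab[i], " ", mat[i], "\n", sep = "")
  invisible(x)
}

#' Tabulate character behaviour
#'
#' Classifies every character as constant, autapomorphic (variable but
#' parsimony-uninformative: only one non-singleton state) or
#' parsimony-informative (at least two states each present in two or more
#' taxa), counting non-missing cells only.
#'
#' @param object a [char_matrix].
#' @param ... unused.
#' @return a `summary.char_matrix` with counts and per-character flags.
#' @export
summary.char_matrix <- function(object, ...) {
  s <- object$states
  flags <- apply(s, 2, function(col) {
    tab <- table(col[!is.na(col)])
    if (length(tab) <= 1L) "constant"
    else if (sum(tab >= 2L) >= 2L) "informative"
    else "autapomorphic"
  })
  out <- structure(list(
    n_taxa = nrow(s),
    n_characters = ncol(s),
    n_ingroup = nrow(s) - !is.null(object$outgroup),
    flags = flags,
    state_counts = apply(s, 2, function(col) table(col[!is.na(col)]),
                         simplify = FALSE),
    n_constant = sum(flags == "constant"),
    n_autapomorphic = sum(flags == "autapomorphic"),
    n_informative = sum(flags == "informative")
  ), class = "summary.char_matrix")
  out
}

#' @export
print.summary.char_matrix <- function(x, ...) {
  cat(sprintf("%d taxa (%d ingroup), %d characters\n",
              x$n_taxa, x$n_ingroup, x$n_characters))
  cat(sprintf("  constant: %d   autapomorphic: %d   parsimony-informative: %d\n",
              x$n_constant, x$n_autapomorphic, x$n_informative))
  invisible(x)
}

## ------------------------------------------------------------------------
## parsing
## ------------------------------------------------------------------------

#' Parse a character matrix
#'
#' Reads a discrete character matrix from text in one of three dialects:
#' `"csv"` (first field the taxon label, then one state per field; an
#' optional header row is recognised by a leading `#taxon` sentinel),
#' `"tnt"` (an `xread 'title' nchar ntax` block of `label statestring`
#' rows terminated by `;`) or `"nexus"` (a minimal `#NEXUS` CHARACTERS
#' block).  `?` is the missing marker in every dialect; `-` is rejected
#' (no gap semantics for morphology).  Polymorphic cells such as `{01}`
#' are not supported.
#'
#' @param text the matrix source as a single string or character vector of
#'   lines.
#' @param dialect one of `"csv"`, `"tnt"`, `"nexus"`; never sniffed.
#' @param ... passed to [char_matrix] (e.g. `outgroup`).
#' @return a [char_matrix]; taxon and character order follow the source.
#' @seealso [read_char_matrix] for file input, [write_char_matrix].
#' @export
parse_char_matrix <- function(text, dialect = c("csv", "tnt", "nexus"), ...) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (all(!nzchar(trimws(text)))) stop("empty matrix source")
  rows <- switch(dialect,
    csv = parse_rows_csv(text),
    tnt = parse_rows_tnt(text),
    nexus = parse_rows_nexus(text))
  build_from_rows(rows, ...)
}

#' @rdname parse_char_matrix
#' @param file path to a matrix file.
#' @export
read_char_matrix <- function(file, dialect = c("csv", "tnt", "nexus"), ...) {
  parse_char_matrix(readLines(file, warn = FALSE), dialect, ...)
}

# rows: named list label -> character vector of state symbols
build_from_rows <- function(rows, ...) {
  labs <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(labs))
    stop("duplicate taxon label: ", labs[duplicated(labs)][1])
  widths <- lengths(rows) - 1L
  if (length(unique(widths)) != 1L) {
    ref <- widths[1]
    off <- labs[which(widths != ref)[1]]
    stop(sprintf("ragged matrix: taxon '%s' has %d states where %d were expected",
                 off, widths[widths != ref][1], ref))
  }
  if (widths[1] < 1L) stop("a character matrix needs at least 1 character")
  states <- matrix(NA_integer_, length(rows), widths[1],
                   dimnames = list(labs, NULL))
  for (i in seq_along(rows)) {
    sym <- rows[[i]][-1L]
    bad <- !(sym %in% c(as.character(0:9), "?"))
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf("unknown state symbol '%s' at taxon '%s', character %d",
                   sym[j], labs[i], j))
    }
    states[i, ] <- suppressWarnings(as.integer(ifelse(sym == "?", NA, sym)))
  }
  char_matrix(states, ...)
}

parse_rows_csv <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "#taxon")) lines <- lines[-1L]
  if (!length(lines)) stop("empty matrix source")
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  lapply(lines, function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1]]))
}

parse_rows_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  if (!grepl("xread", txt)) stop("tnt dialect: no 'xread' block found")
  body <- sub(".*?xread", "", txt)
  body <- sub(";.*$", "", body)
  body <- gsub("'[^']*'", "", body)             # drop quoted title
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  if (length(toks) < 2L) stop("tnt dialect: missing nchar/ntax header")
  nchar_decl <- suppressWarnings(as.integer(toks[1]))
  ntax_decl <- suppressWarnings(as.integer(toks[2]))
  if (is.na(nchar_decl) || is.na(ntax_decl))
    stop("tnt dialect: nchar and ntax must follow xread")
  toks <- toks[-(1:2)]
  if (length(toks) != 2L * ntax_decl)
    stop("tnt dialect: expected ", ntax_decl, " 'label statestring' rows")
  rows <- vector("list", ntax_decl)
  for (i in seq_len(ntax_decl)) {
    lab <- toks[2L * i - 1L]
    sym <- strsplit(toks[2L * i], "")[[1]]
    if (length(sym) != nchar_decl)
      stop(sprintf("ragged matrix: taxon '%s' has %d states where %d were expected",
                   lab, length(sym), nchar_decl))
    rows[[i]] <- c(lab, sym)
  }
  rows
}

parse_rows_nexus <- function(lines) {
  if (!grepl("#NEXUS", lines[1], ignore.case = TRUE))
    stop("nexus dialect: file must start with #NEXUS")
  txt <- paste(lines, collapse = "\n")
  mat <- regmatches(txt, regexpr("(?is)MATRIX.*?;", txt, perl = TRUE))
  if (!length(mat)) stop("nexus dialect: no MATRIX block found")
  body <- sub("(?i)^MATRIX", "", mat, perl = TRUE)
  body <- sub(";$", "", body)
  rls <- trimws(strsplit(body, "\n")[[1]])
  rls <- rls[nzchar(rls)]
  lapply(rls, function(l) {
    toks <- strsplit(l, "\\s+")[[1]]
    lab <- gsub("^'|'$", "", toks[1])
    c(lab, strsplit(paste(toks[-1], collapse = ""), "")[[1]])
  })
}

## ------------------------------------------------------------------------
## writing
## ------------------------------------------------------------------------

#' Write a character matrix
#'
#' Serialises a [char_matrix] in any of the dialects understood by
#' [parse_char_matrix]; parse/write round-trips reproduce the matrix.
#'
#' @param x a [char_matrix].
#' @param file optional path; if `NULL` the text is returned.
#' @inheritParams parse_char_matrix
#' @return the serialised lines, invisibly when written to a file.
#' @export
write_char_matrix <- function(x, file = NULL, dialect = c("csv", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  sym <- apply(x$states, 1, function(r)
    ifelse(is.na(r), "?", as.character(r)))
  sym <- matrix(sym, ncol = nrow(x$states))       # chars x taxa
  strings <- apply(sym, 2, paste, collapse = "")
  lines <- switch(dialect,
    csv = c(paste(c("#taxon", x$char_ids), collapse = ","),
            vapply(seq_along(x$taxa), function(i)
              paste(c(x$taxa[i], sym[, i]), collapse = ","), "")),
    tnt = c(sprintf("xread 'character matrix' %d %d",
                    ncol(x$states), nrow(x$states)),
            paste(x$taxa, strings),
            ";"),
    nexus = c("#NEXUS",
              "BEGIN CHARACTERS;",
              sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                      nrow(x$states), ncol(x$states)),
              "  FORMAT SYMBOLS=\"0123456789\" MISSING=?;",
              "  MATRIX",
              paste("   ", x$taxa, strings),
              "  ;",
              "END;"))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

## ------------------------------------------------------------------------
## bundled data
## ------------------------------------------------------------------------

#' The Drosophila saltans group terminalia matrix
#'
#' Returns the bundled 11-taxon x 19-character matrix of male terminalia
#' and aedeagus structures scored across ten species of the *Drosophila
#' saltans* group plus the outgroup *D. willistoni* (all-absent row).
#' States: 0 = absent, 1 = present, 2 = present with modifications
#' (characters 5 and 13 only).  The outgroup is preset to `willistoni`.
#'
#' @return a [char_matrix] with 11 taxa, 19 characters and character
#'   descriptions in `$char_names`.
#' @examples
#' m <- saltans_matrix()
#' summary(m)
#' @export
saltans_matrix <- function() {
  path <- system.file("extdata", "saltans_table2.csv",
                      package = "mpsaltans", mustWork = TRUE)
  m <- read_char_matrix(path, "csv", outgroup = "willistoni")
  m$char_names <- c(
    "Fused ventral parameres",
    "Middle ventral process",
    "Scales in the middle ventral process",
    "Punctiform projection in the aedeagus apex",
    "Ventral parameres of epandrium",
    "Concaved surstylus",
    "Apical crest of aedeagus",
    "Apical crest with punctiform projection",
    "Groove in the apical crest",
    "Bristles in the aedeagus apical crest",
    "Scales in the aedeagus apical crest",
    "Aedeagus cape",
    "Serrated edge of aedeagus cape",
    "Dorsal cleft of aedeagus",
    "Frontal processes of aedeagus",
    "Bipartite aedeagus apex",
    "Surstylus processes",
    "Sickle-shaped processes of aedeagus",
    "Long apodeme")
  m
}
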