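#' Map character changes onto a tree
#'
#' Attaches every inferred change ([unambiguous_changes]) to its branch
#' and classifies it in the style of a cladogram figure legend:
#'
#' * `autapomorphy` -- terminal branch, derived state present in exactly
#'   one taxon;
#' * `homoplasy` -- any change of a character whose observed steps exceed
#'   its minimum (`s > m` on this tree: the character cannot fit without
#'   extra steps, so its changes are homoplastic);
#' * `synapomorphy` -- an unambiguous change on a branch subtending two
#'   or more taxa of a character with `s = m`.
#'
#' Ambiguous changes are retained in the table but excluded from the
#' figure-style annotation (unambiguous optimization).
#'
#' @inheritParams unambiguous_changes
#' @return an `mp_annotated`: the rooted presentation tree (rooted at the
#'   matrix outgroup when set) and a `changes` data frame adding a
#'   `classification` column to the change records.
#' @examples
#' m <- saltans_matrix()
#' ann <- annotate_tree(parse_newick(saltans_certificate_newick()), m)
#' subset(ann$changes, classification == "synapomorphy")
#' @export
annotate_tree <- function(tree, matrix, max_mprs = 1e6) {
  ch <- unambiguous_changes(tree, matrix, max_mprs = max_mprs)
  b <- char_bounds(matrix)
  s <- tree_length(tree, matrix)$per_character
  cls <- character(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    j <- match(ch$char[i], b$char)
    derived_count <- sum(matrix$states[, j] == ch$to[i], na.rm = TRUE)
    cls[i] <-
      if (s[j] > b$m[j]) "homoplasy"
      else if (ch$clade_size[i] == 1L && derived_count == 1L) "autapomorphy"
      else if (ch$clade_size[i] >= 2L) "synapomorphy"
      else "autapomorphy"
  }
  ch$classification <- cls
  rooted <- if (!is.null(matrix$outgroup))
    root_at_outgroup(tree, matrix$outgroup) else tree
  structure(list(tree = rooted, changes = ch,
                 outgroup = matrix$outgroup), class = "mp_annotated")
}

#' @export
print.mp_annotated <- function(x, ...) {
  cat("annotated tree with", nrow(x$changes), "change record(s)\n")
  tab <- table(x$changes$classification[x$changes$ambiguity == "unambiguous"])
  if (length(tab)) {
    cat("unambiguous: ")
    cat(paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  n_amb <- sum(x$changes$ambiguity == "ambiguous")
  if (n_amb) cat("ambiguous (excluded from annotation):", n_amb, "\n")
  invisible(x)
}

#' @export
plot.mp_annotated <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}

#' Export an annotated tree as newick with change comments
#'
#' Writes the rooted presentation tree with a `[&changes=...]` comment on
#' every branch that carries unambiguous changes, e.g.
#' `[&changes=12:0>1]`, alongside (optionally) the change table as TSV.
#'
#' @param x an `mp_annotated` from [annotate_tree].
#' @param file optional path for the newick line.
#' @param tsv optional path for the change table.
#' @return the newick string, invisibly when written.
#' @export
write_annotated_newick <- function(x, file = NULL, tsv = NULL) {
  stopifnot(inherits(x, "mp_annotated"))
  tr <- x$tree
  n <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  below <- function(v) {
    if (v <= n) return(tr$tip.label[v])
    sort(unlist(lapply(kids[[as.character(v)]], below)))
  }
  un <- x$changes[x$changes$ambiguity == "unambiguous", , drop = FALSE]
  comment_for <- function(v) {
    lab <- paste(below(v), collapse = "|")
    hit <- un[un$clade == lab, , drop = FALSE]
    if (!nrow(hit)) return("")
    paste0("[&changes=",
           paste(sprintf("%d:%d>%d", hit$char, hit$from, hit$to),
                 collapse = ","), "]")
  }
  render <- function(v) {
    base <- if (v <= n) tr$tip.label[v]
      else paste0("(", paste(vapply(kids[[as.character(v)]], render, ""),
                             collapse = ","), ")")
    paste0(base, comment_for(v))
  }
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  nw <- paste0(render(root), ";")
  if (!is.null(tsv)) {
    lines <- c(paste(names(un), collapse = "\t"),
               apply(un, 1, function(r) paste(trimws(r), collapse = "\t")))
    writeLines(lines, tsv)
  }
  if (is.null(file)) return(nw)
  writeLines(nw, file)
  invisible(nw)
}

## ------------------------------------------------------------------------
## verbal topology claims
## ------------------------------------------------------------------------

#' Construct a topology statement
#'
#' Machine-checkable renderings of the verbal claims made about a rooted
#' cladogram:
#'
#' * `most_basal(x)`: the taxa `x` are the sister of all remaining
#'   ingroup taxa;
#' * `sister_taxa(x, y)`: the two leaves form a clade;
#' * `sister_clades(x, y)`: each set is a clade (or single leaf) and
#'   their union is a clade;
#' * `closer_than(x, y, z)`: the smallest clade containing `x` and `y`
#'   excludes `z`.
#'
#' @param kind one of `"most_basal"`, `"sister_taxa"`, `"sister_clades"`,
#'   `"closer_than"`.
#' @param x,y taxon labels or label vectors (per kind above).
#' @param z excluded taxon for `closer_than`.
#' @return a `topology_statement`.
#' @export
topology_statement <- function(kind = c("most_basal", "sister_taxa",
                                        "sister_clades", "closer_than"),
                               x, y = NULL, z = NULL) {
  kind <- match.arg(kind)
  if (kind == "closer_than") {
    if (is.null(z)) stop("closer_than needs x, y and z")
    if (z %in% c(x, y)) stop("closer_than operands overlap: '", z,
                             "' appears on both sides")
  }
  structure(list(kind = kind, x = x, y = y, z = z),
            class = "topology_statement")
}

#' The four verbal claims about the saltans-group cladogram
#'
#' The claims reported for the bundled analysis: the cordata subgroup
#' (neocordata) is the most basal lineage; dacunhai and milleri are
#' sister taxa; parasaltans is sister to the saltans subgroup clade; and
#' prosaltans and austrosaltans are closer to each other than either is
#' to saltans.
#'
#' @return a list of [topology_statement]s.
#' @export
saltans_statements <- function() {
  list(
    cordata_most_basal = topology_statement("most_basal", "neocordata"),
    dacunhai_milleri_sisters =
      topology_statement("sister_taxa", "dacunhai", "milleri"),
    parasaltans_sister_to_saltans_subgroup =
      topology_statement("sister_clades", "parasaltans",
                         c("saltans", "prosaltans", "austrosaltans",
                           "lusaltans")),
    prosaltans_austrosaltans_closer =
      topology_statement("closer_than", "prosaltans", "austrosaltans",
                         "saltans"))
}

#' Check verbal topology statements against a tree
#'
#' Evaluates each [topology_statement] on the tree rooted at the
#' outgroup.  Results are invariant to child order and to how the tree
#' was stored (rooted or unrooted).
#'
#' @param tree a `phylo` containing all statement operands and the
#'   outgroup.
#' @param statements a [topology_statement] or list of them.
#' @param outgroup the rooting taxon (excluded from the ingroup).
#' @return a named logical vector, one entry per statement.
#' @examples
#' tr <- parse_newick(saltans_certificate_newick())
#' check_topology_statements(tr, saltans_statements(), "willistoni")
#' @export
check_topology_statements <- function(tree, statements, outgroup) {
  if (inherits(statements, "topology_statement")) statements <- list(statements)
  rooted <- root_at_outgroup(tree, outgroup)
  n <- length(rooted$tip.label)
  kids <- split(rooted$edge[, 2], rooted$edge[, 1])
  below <- vector("list", n + rooted$Nnode)
  fill <- function(v) {
    below[[v]] <<- if (v <= n) rooted$tip.label[v]
      else sort(unlist(lapply(kids[[as.character(v)]], fill)))
    below[[v]]
  }
  root <- setdiff(rooted$edge[, 1], rooted$edge[, 2])[1]
  fill(root)
  clades <- below[(n + 1):(n + rooted$Nnode)]
  is_clade <- function(set) {
    set <- sort(set)
    if (length(set) == 1L) return(set %in% rooted$tip.label)
    any(vapply(clades, identical, TRUE, y = set))
  }
  ingroup <- setdiff(rooted$tip.label, outgroup)
  check_one <- function(st) {
    for (lab in c(st$x, st$y, st$z))
      if (!lab %in% rooted$tip.label) stop("unknown taxon label: ", lab)
    switch(st$kind,
      most_basal = {
        mrca_set <- sort(ingroup)
        node <- which(vapply(below, identical, TRUE, y = mrca_set))[1]
        if (is.na(node)) return(FALSE)
        ks <- kids[[as.character(node)]]
        length(ks) == 2L &&
          any(vapply(ks, function(k) identical(sort(below[[k]]),
                                               sort(st$x)), TRUE))
      },
      sister_taxa = is_clade(c(st$x, st$y)),
      sister_clades = is_clade(st$x) && is_clade(st$y) &&
        is_clade(c(st$x, st$y)),
      closer_than = {
        sets <- c(below[seq_len(n)], clades)
        containing <- sets[vapply(sets, function(s)
          all(c(st$x, st$y) %in% s), TRUE)]
        smallest <- containing[[which.min(lengths(containing))]]
        !(st$z %in% smallest)
      })
  }
  out <- vapply(statements, check_one, TRUE)
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- vapply(statements, function(s)
      paste(c(s$kind, s$x, s$y, s$z), collapse = "_"), "")
  out
}
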