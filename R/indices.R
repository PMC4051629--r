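#' Consistency and retention index report
#'
#' Per-character and ensemble fit statistics for a tree on a matrix.
#' With per-character minimum steps `m` ([char_bounds]), maximum steps
#' `g` (star-tree convention) and observed steps `s` ([tree_length]):
#' `ci = m/s` (undefined at `s = 0`), `ri = (g - s)/(g - m)` (undefined
#' at `g = m`); ensemble `CI = sum(m)/L`, `RI = (sum(g) - L)/(sum(g) -
#' sum(m))`, `HI = 1 - CI`, `RC = CI * RI`.  Uninformative characters
#' are included in the ensemble sums by default (the convention of the
#' common parsimony programs); `include_uninformative = FALSE` drops
#' them.  `printed_CI`/`printed_RI` are the percent renderings truncated
#' toward zero (never rounded), e.g. 0.875 prints as 87 and 0.90625 as
#' 90.
#'
#' @param matrix a [char_matrix] with at least one variable character.
#' @param tree a `phylo` on the matrix taxa.
#' @param include_uninformative include constant/autapomorphic characters
#'   in the ensemble sums (default `TRUE`).
#' @return an `index_report`: per-character data frame plus the ensemble
#'   list `L`, `M`, `G`, `CI`, `RI`, `HI`, `RC`, `printed_CI`,
#'   `printed_RI`.
#' @examples
#' m <- saltans_matrix()
#' index_report(m, parse_newick(saltans_certificate_newick()))
#' @export
index_report <- function(matrix, tree, include_uninformative = TRUE) {
  b <- char_bounds(matrix)
  len <- tree_length(tree, matrix)
  s <- as.integer(len$per_character)
  if (all(b$m == 0L)) stop("all characters constant: CI undefined")
  per <- data.frame(char = b$char, m = b$m, g = b$g, s = s,
                    ci = ifelse(s > 0, b$m / s, NA_real_),
                    ri = ifelse(b$g > b$m, (b$g - s) / (b$g - b$m), NA_real_))
  keep <- if (include_uninformative) rep(TRUE, nrow(per))
          else summary(matrix)$flags == "informative"
  w <- matrix$weights[keep]
  L <- sum(w * s[keep]); M <- sum(w * b$m[keep]); G <- sum(w * b$g[keep])
  if (M == 0) stop("no variable characters in the ensemble sums: CI undefined")
  CI <- M / L
  RI <- if (G > M) (G - L) / (G - M) else NA_real_
  structure(list(
    per_character = per,
    L = L, M = M, G = G,
    CI = CI, RI = RI, HI = 1 - CI,
    RC = if (is.na(RI)) NA_real_ else CI * RI,
    printed_CI = trunc(100 * CI),
    printed_RI = if (is.na(RI)) NA_real_ else trunc(100 * RI),
    include_uninformative = include_uninformative
  ), class = "index_report")
}

#' @export
print.index_report <- function(x, digits = 4, ...) {
  cat(sprintf("L = %g  (sum m = %g, sum g = %g)\n", x$L, x$M, x$G))
  cat(sprintf("CI = %.*g  RI = %.*g  HI = %.*g  RC = %.*g\n",
              digits, x$CI, digits, x$RI, digits, x$HI, digits, x$RC))
  cat(sprintf("printed (floor percent): CI = %d, RI = %d\n",
              x$printed_CI, x$printed_RI))
  invisible(x)
}

#' @rdname index_report
#' @param x an `index_report`.
#' @param file optional path for the per-character TSV.
#' @export
write_index_tsv <- function(x, file = NULL) {
  stopifnot(inherits(x, "index_report"))
  lines <- c(paste(names(x$per_character), collapse = "\t"),
             apply(x$per_character, 1, function(r)
               paste(trimws(format(r, digits = 6)), collapse = "\t")))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
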