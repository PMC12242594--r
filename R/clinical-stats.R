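#' Exact two-tailed Fisher test of a 2x2 contingency table
#'
#' Exact two-sided p-value for independence in a 2x2 table with counts
#' a (group-1 affected), b (group-1 unaffected), c (group-2 affected),
#' d (group-2 unaffected). The two-sided p is the sum of hypergeometric
#' point probabilities, at the observed margins, of all tables no more
#' probable than the observed one (with a 1e-7 relative tolerance on the
#' comparison) — the convention of [stats::fisher.test()], which performs
#' the computation.
#'
#' @param a,b,c,d nonnegative integer counts; alternatively \code{a} may be
#'   a 2x2 matrix \code{rbind(c(a, b), c(c, d))}.
#' @return The exact two-sided p-value in \eqn{(0, 1]}.
#' @examples
#' fisher_two_tailed(27, 9, 0, 8)   # 0.0001 at 4 decimals
#' @export
fisher_two_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (!all(tab >= 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (sum(tab) == 0)
    stop("degenerate table: all counts are zero")
  stats::fisher.test(tab)$p.value
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise significance level in (0, 1); default 0.05.
#' @param m number of comparisons (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_alpha(0.05, 18)  # 0.0028 at 4 decimals
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
    stop("invalid comparison count: m must be an integer >= 1")
  alpha / m
}

#' Fisher-test a table of clinical phenotype frequencies
#'
#' Applies the exact two-tailed Fisher test to every row of a phenotype
#' count table (one clinical feature per row, affected/total counts per
#' group) and flags rows significant at the Bonferroni-corrected level
#' \code{alpha / m}.
#'
#' @param counts data frame (or path to a CSV file) with columns
#'   \code{feature}, \code{affected_1}, \code{total_1}, \code{affected_2},
#'   \code{total_2}.
#' @param m number of comparisons for the Bonferroni correction; defaults
#'   to the number of rows.
#' @param alpha family-wise level (default 0.05).
#' @return Data frame of class \code{phenotype_comparison}: the input
#'   columns plus \code{p_value} and \code{significant}.
#' @examples
#' tab <- mn1_phenotypes()
#' res <- compare_phenotypes(tab, m = 18)
#' subset(res, significant)
#' @export
compare_phenotypes <- function(counts, m = NULL, alpha = 0.05) {
  if (is.character(counts) && length(counts) == 1L)
    counts <- utils::read.csv(counts, stringsAsFactors = FALSE)
  need <- c("feature", "affected_1", "total_1", "affected_2", "total_2")
  if (!all(need %in% names(counts)))
    stop("counts must contain columns ", paste(need, collapse = ", "))
  for (col in need[-1L]) {
    v <- counts[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stop(sprintf("parse error in column '%s': row(s) %s are not nonnegative integer counts",
                   col, paste(which(!is.finite(v) | v < 0 | v != round(v)),
                              collapse = ", ")))
  }
  bad <- counts$affected_1 > counts$total_1 | counts$affected_2 > counts$total_2
  if (any(bad))
    stop("parse error: affected exceeds total in row(s) ",
         paste(counts$feature[bad], collapse = ", "))
  if (is.null(m)) m <- nrow(counts)
  thr <- bonferroni_alpha(alpha, m)
  p <- mapply(function(a1, t1, a2, t2)
    fisher_two_tailed(a1, t1 - a1, a2, t2 - a2),
    counts$affected_1, counts$total_1, counts$affected_2, counts$total_2)
  out <- cbind(counts, p_value = as.numeric(p), significant = p < thr)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("phenotype_comparison", class(out))
  out
}

#' @export
print.phenotype_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Phenotype comparison: %d features, Bonferroni alpha = %.4f (%.2f/%d)\n\n",
              nrow(x), bonferroni_alpha(attr(x, "alpha"), attr(x, "m")),
              attr(x, "alpha"), attr(x, "m")))
  y <- as.data.frame(x)
  y$p_value <- signif(y$p_value, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Clinical feature counts for the MN1 truncating-variant cohorts
#'
#' Published affected/total counts of clinical features in 56 individuals
#' with MN1 truncating variants, split into the C-terminal (CTT, group 1)
#' and N-terminal (NTT, group 2) truncation cohorts. Columns
#' \code{printed_p} and \code{verifiable} carry the p-value as printed in
#' the source table and whether it is reproducible under the standard
#' two-sided Fisher convention (the high-arched-palate row is not, and one
#' row is descriptive only).
#'
#' @return Data frame with one row per clinical feature.
#' @export
mn1_phenotypes <- function() {
  path <- system.file("extdata", "mn1_table1_counts.csv",
                      package = "lumpsplit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
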