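#' Positive predictive value from sensitivity, specificity and pre-test
#' probability
#'
#' Bayes' rule for the probability that two cohorts flagged as distinct are
#' truly distinct:
#' \deqn{PPV = \frac{se \cdot p}{se \cdot p + (1 - sp)(1 - p)}}
#' with sensitivity \eqn{se}, specificity \eqn{sp} and pre-test probability
#' \eqn{p}. The default \eqn{p = 0.5} encodes no prior information: the
#' same prior probability of the cohorts being one syndrome or two.
#'
#' @param sensitivity,specificity,pretest probabilities in \eqn{[0, 1]}.
#' @return The PPV, a value in \eqn{[0, 1]}; monotone increasing in both
#'   sensitivity and specificity.
#' @examples
#' estimate_ppv(0.9, 0.9)            # 0.9
#' estimate_ppv(0.911, 0.885)        # ~0.888
#' @export
estimate_ppv <- function(sensitivity, specificity, pretest = 0.5) {
  for (v in c(sensitivity, specificity, pretest))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("sensitivity, specificity and pretest must lie in [0, 1]")
  denom <- sensitivity * pretest + (1 - specificity) * (1 - pretest)
  if (denom == 0)
    stop("undefined PPV: zero denominator (sensitivity 0 and specificity 1)")
  sensitivity * pretest / denom
}

#' Range-based sensitivity and specificity from pooled control
#' distributions
#'
#' For a distance range \eqn{[lo, hi]} observed among resampled subgroup
#' comparisons, estimates the probability that a different-syndrome
#' comparison falls inside the range (sensitivity) and that a same-syndrome
#' comparison falls outside it (specificity), from the pooled empirical
#' control distributions. Both estimates are clipped away from 0 and 1 by
#' \eqn{1/(n+1)} (n = size of the respective distribution) to avoid
#' degenerate probabilities from finite samples. A degenerate range
#' (\eqn{lo = hi}) is treated as a point query under the same rule.
#'
#' @param range numeric length-2 vector \code{c(lo, hi)}.
#' @param controls list with numeric components \code{same} and
#'   \code{different} (pooled control distance distributions).
#' @return List with \code{sensitivity} and \code{specificity}.
#' @export
range_probabilities <- function(range, controls) {
  if (length(controls$same) == 0L || length(controls$different) == 0L)
    stop("empty distribution: pooled controls must be nonempty")
  lo <- min(range); hi <- max(range)
  clip <- function(p, n) pmin(pmax(p, 1 / (n + 1)), n / (n + 1))
  nd <- length(controls$different)
  ns <- length(controls$same)
  sens <- clip(mean(controls$different >= lo & controls$different <= hi), nd)
  spec <- clip(mean(controls$same < lo | controls$same > hi), ns)
  list(sensitivity = sens, specificity = spec)
}

#' Decide lump versus split for two candidate cohorts
#'
#' The core decision of the package. Computes the mean pairwise cosine
#' distance \eqn{d(C_1, C_2)} between the two cohorts and quantifies its
#' uncertainty by drawing \code{n_subgroups} random subgroup pairs: from
#' each cohort a subgroup of independent uniform size (1 to the cohort
#' size) is sampled without replacement, and the subgroup-pair distance is
#' recorded. If more than 50\% of those distances exceed the calibrated
#' threshold, the verdict is "split" (evidence for two distinct syndromes);
#' otherwise "lump". The positive predictive value of the decision is
#' estimated from the probability of the observed subgroup-distance range
#' under the pooled same-/different-syndrome control distributions of the
#' calibration, at a pre-test probability of 50\%.
#'
#' @param calib a \code{lumpsplit_calib} object (see
#'   [calibrate_lumpsplit()]).
#' @param coll the [fpd_collection()] holding both cohorts.
#' @param c1,c2 disjoint nonempty character vectors of image ids.
#' @param n_subgroups number of subgroup pairs to draw (default 100).
#' @param seed optional integer seed.
#' @param pretest pre-test probability of the cohorts being distinct
#'   (default 0.5).
#' @return An object of class \code{split_decision}: list with
#'   \code{cohort_distance}, \code{threshold}, \code{subgroup_distances},
#'   \code{proportion_above}, \code{verdict} ("split" or "lump"),
#'   \code{ppv}, \code{distance_range} and the range-based
#'   \code{sensitivity}/\code{specificity} behind the PPV.
#' @examples
#' coll <- simulate_cfps(12, 2, 2, within_syndrome_spread = 0.1, seed = 3)
#' fit <- calibrate_lumpsplit(coll, seed = 3)
#' a <- coll$meta$image_id[coll$meta$syndrome_id == "S01"]
#' b <- coll$meta$image_id[coll$meta$syndrome_id == "S02"]
#' compare_cohorts(fit, coll, a, b, seed = 3)
#' @export
compare_cohorts <- function(calib, coll, c1, c2, n_subgroups = 100L,
                            seed = NULL, pretest = 0.5) {
  stopifnot(inherits(calib, "lumpsplit_calib"), inherits(coll, "fpd_collection"))
  if (length(c1) == 0L || length(c2) == 0L)
    stop("empty cohort: both cohorts must contain at least one image")
  if (length(intersect(c1, c2)))
    stop("overlapping cohorts: image(s) ",
         paste(intersect(c1, c2), collapse = ", "),
         " appear in both cohorts")
  check_images(coll, c(c1, c2))
  local_seed(seed)

  d_full <- cohort_distance(coll, c1, c2)
  sub <- numeric(n_subgroups)
  for (i in seq_len(n_subgroups)) {
    g1 <- sample(c1, sample.int(length(c1), 1L))
    g2 <- sample(c2, sample.int(length(c2), 1L))
    sub[i] <- cohort_distance(coll, g1, g2)
  }
  prop <- mean(sub > calib$threshold)
  rng <- range(sub)
  pr <- range_probabilities(rng, calib$pooled_controls)
  structure(list(
    cohort_distance = d_full,
    threshold = calib$threshold,
    subgroup_distances = sub,
    proportion_above = prop,
    verdict = if (prop > 0.5) "split" else "lump",
    ppv = estimate_ppv(pr$sensitivity, pr$specificity, pretest),
    sensitivity = pr$sensitivity,
    specificity = pr$specificity,
    distance_range = rng,
    n1 = length(c1), n2 = length(c2)
  ), class = "split_decision")
}

#' @rdname compare_cohorts
#' @param object a \code{lumpsplit_calib} object.
#' @param ... passed on to \code{compare_cohorts}.
#' @export
predict.lumpsplit_calib <- function(object, coll, c1, c2, ...) {
  compare_cohorts(object, coll, c1, c2, ...)
}

#' @export
print.split_decision <- function(x, ...) {
  cat("Lump/split decision\n")
  cat(sprintf("  cohorts: %d vs %d images\n", x$n1, x$n2))
  cat(sprintf("  d(C1,C2) = %.4f  (threshold c = %.4f)\n",
              x$cohort_distance, x$threshold))
  cat(sprintf("  subgroup resampling: %d draws, %.1f%% above threshold, range [%.4f, %.4f]\n",
              length(x$subgroup_distances), 100 * x$proportion_above,
              x$distance_range[1], x$distance_range[2]))
  cat(sprintf("  verdict: %s (PPV %.1f%%)\n", toupper(x$verdict), 100 * x$ppv))
  if (min(x$n1, x$n2) == 1L)
    cat("  note: a cohort of size 1 gives a low-confidence decision\n")
  invisible(x)
}

#' Downsampling stability of the cohort distance
#'
#' Measures how stable the cohort distance is as the cohorts shrink. For
#' each sample size \eqn{n} from 1 to the smaller cohort's size, \code{draws}
#' random subsets of n sampling units are drawn (without replacement within
#' a draw) from each cohort and their mean pairwise cosine distance is
#' recorded. When every patient contributes a single image the sampling
#' unit is the image; with multi-image patients, whole patients are sampled
#' and all their images enter the distance.
#'
#' @param calib a \code{lumpsplit_calib} object (supplies the threshold for
#'   the summary; the draws themselves do not depend on it).
#' @param coll the [fpd_collection()].
#' @param c1,c2 nonempty character vectors of image ids.
#' @param draws draws per sample size (default 100).
#' @param seed optional integer seed.
#' @return An object of class \code{downsample_result}: list with
#'   \code{distances} (matrix, one row per n, \code{draws} columns),
#'   \code{threshold} and \code{unit} ("patient" or "image").
#' @export
downsample_cohorts <- function(calib, coll, c1, c2, draws = 100L, seed = NULL) {
  stopifnot(inherits(calib, "lumpsplit_calib"), inherits(coll, "fpd_collection"))
  if (length(c1) == 0L || length(c2) == 0L)
    stop("empty cohort: both cohorts must contain at least one image")
  check_images(coll, c(c1, c2))
  local_seed(seed)

  m <- coll$meta
  units_of <- function(ids) split(ids, m[ids, "patient_id"])
  u1 <- units_of(c1); u2 <- units_of(c2)
  unit_kind <- if (all(lengths(u1) == 1L) && all(lengths(u2) == 1L))
    "image" else "patient"
  n_max <- min(length(u1), length(u2))
  out <- matrix(NA_real_, n_max, draws,
                dimnames = list(n = seq_len(n_max), NULL))
  for (n in seq_len(n_max)) {
    for (b in seq_len(draws)) {
      g1 <- unlist(u1[sample.int(length(u1), n)], use.names = FALSE)
      g2 <- unlist(u2[sample.int(length(u2), n)], use.names = FALSE)
      out[n, b] <- cohort_distance(coll, g1, g2)
    }
  }
  structure(list(distances = out, threshold = calib$threshold,
                 unit = unit_kind, draws = draws),
            class = "downsample_result")
}

#' @export
summary.downsample_result <- function(object, ...) {
  d <- object$distances
  data.frame(
    n = as.integer(rownames(d)),
    median = apply(d, 1, stats::median),
    iqr = apply(d, 1, stats::IQR),
    sd = apply(d, 1, stats::sd),
    prop_above = rowMeans(d > object$threshold)
  )
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf("Downsampling stability (%s-level, %d draws per size)\n",
              x$unit, x$draws))
  print(summary(x), digits = 4, row.names = FALSE)
  if (nrow(x$distances) >= 1L)
    cat("note: size-1 rows are single-unit comparisons; treat their verdicts as low-confidence\n")
  invisible(x)
}

#' Plot downsampling stability
#'
#' Boxplots of subgroup distances per sample size, with the calibrated
#' threshold as a horizontal line.
#'
#' @param x a \code{downsample_result}.
#' @param ... passed to [graphics::boxplot()].
#' @return \code{x}, invisibly.
#' @export
plot.downsample_result <- function(x, ...) {
  graphics::boxplot(t(x$distances), names = rownames(x$distances),
                    xlab = sprintf("%ss sampled per cohort", x$unit),
                    ylab = "mean pairwise cosine distance", ...)
  graphics::abline(h = x$threshold, lwd = 2, col = "tomato")
  invisible(x)
}
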