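#' Keep only syndromes with at least two distinct patients
#'
#' Same-syndrome control sampling needs within-syndrome replication, so the
#' calibration dataset retains only syndromes represented by two or more
#' distinct patients; all images of retained syndromes are kept.
#'
#' @param coll an [fpd_collection()].
#' @return The filtered \code{fpd_collection}.
#' @export
filter_collection <- function(coll) {
  stopifnot(inherits(coll, "fpd_collection"))
  m <- coll$meta
  npat <- tapply(m$patient_id, m$syndrome_id,
                 function(p) length(unique(p)))
  keep_syn <- names(npat)[npat >= 2]
  if (length(keep_syn) == 0L)
    stop("empty dataset: no syndrome has at least two distinct patients")
  subset_images(coll, m$image_id[m$syndrome_id %in% keep_syn])
}

#' Partition syndromes into cross-validation folds
#'
#' Randomly splits syndrome ids into \code{k} folds of as-equal-as-possible
#' size. Because the split is by syndrome, all images of a patient (and all
#' patients of a syndrome) fall into the same fold, so training and
#' validation sets are truly distinct.
#'
#' @param coll an [fpd_collection()].
#' @param k number of folds (default 5).
#' @param seed optional integer seed.
#' @return Named integer vector: fold index (1..k) per syndrome id.
#' @export
make_syndrome_folds <- function(coll, k = 5L, seed = NULL) {
  stopifnot(inherits(coll, "fpd_collection"))
  syn <- sort(unique(coll$meta$syndrome_id))
  if (length(syn) < k)
    stop(sprintf("insufficient syndromes: %d syndromes for %d folds",
                 length(syn), k))
  local_seed(seed)
  # fold labels 1..k assigned cyclically along a shuffled syndrome order
  shuffled <- sample(syn)
  folds <- stats::setNames(rep_len(seq_len(k), length(syn)), shuffled)
  folds[syn]
}

# images of each syndrome, as a named list
syndrome_images <- function(coll, syndromes = unique(coll$meta$syndrome_id)) {
  m <- coll$meta
  lapply(stats::setNames(syndromes, syndromes),
         function(s) m$image_id[m$syndrome_id == s])
}

# dedup key for one sampled comparison: unordered pair of frozen id sets
pair_key <- function(g1, g2) {
  a <- paste(sort(g1), collapse = ",")
  b <- paste(sort(g2), collapse = ",")
  paste(sort(c(a, b)), collapse = " || ")
}

#' Sample the same-syndrome control distance distribution
#'
#' For each syndrome, its images are randomly divided into two nonempty
#' groups (each image to either side with probability 1/2, redrawing when a
#' side is empty) and the mean pairwise cosine distance between the groups
#' is recorded. This is repeated \code{reps} times per syndrome; duplicated
#' group-pair comparisons are removed. Syndromes with a single image cannot
#' be partitioned and are skipped with a warning.
#'
#' @param coll an [fpd_collection()].
#' @param syndromes syndrome ids to sample from (default: all).
#' @param reps partitions attempted per syndrome (default 10).
#' @param seed optional integer seed.
#' @return Numeric vector of distances, with attribute \code{"syndrome"}
#'   giving the source syndrome of each entry.
#' @export
sample_same_syndrome <- function(coll, syndromes = unique(coll$meta$syndrome_id),
                                 reps = 10L, seed = NULL) {
  stopifnot(inherits(coll, "fpd_collection"))
  local_seed(seed)
  dist_out <- numeric(0)
  syn_out <- character(0)
  keys <- character(0)
  for (s in syndromes) {
    imgs <- coll$meta$image_id[coll$meta$syndrome_id == s]
    n <- length(imgs)
    if (n < 2L) {
      warning(sprintf("syndrome '%s' has a single image; skipped", s))
      next
    }
    for (r in seq_len(reps)) {
      repeat {
        side <- stats::runif(n) < 0.5
        if (any(side) && any(!side)) break
      }
      g1 <- imgs[side]
      g2 <- imgs[!side]
      key <- pair_key(g1, g2)
      if (key %in% keys) next
      keys <- c(keys, key)
      dist_out <- c(dist_out, cohort_distance(coll, g1, g2))
      syn_out <- c(syn_out, s)
    }
  }
  structure(dist_out, syndrome = syn_out)
}

#' Sample the different-syndrome control distance distribution
#'
#' For every unordered pair of distinct syndromes, one group of uniformly
#' random size (between 1 and the syndrome's image count) is sampled
#' without replacement from each syndrome's images, and the mean pairwise
#' cosine distance between the two groups is recorded. This is repeated
#' \code{reps} times per pair; duplicated group-pair comparisons are
#' removed.
#'
#' @param coll an [fpd_collection()].
#' @param syndromes syndrome ids to sample from (default: all; at least 2).
#' @param reps comparisons attempted per syndrome pair (default 5).
#' @param seed optional integer seed.
#' @return Numeric vector of distances with attribute \code{"pair"} naming
#'   the syndrome pair of each entry.
#' @export
sample_different_syndromes <- function(coll,
                                       syndromes = unique(coll$meta$syndrome_id),
                                       reps = 5L, seed = NULL) {
  stopifnot(inherits(coll, "fpd_collection"))
  if (length(syndromes) < 2L)
    stop("need at least two syndromes to sample different-syndrome pairs")
  local_seed(seed)
  imgs_by_syn <- syndrome_images(coll, syndromes)
  dist_out <- numeric(0)
  pair_out <- character(0)
  keys <- character(0)
  combs <- utils::combn(sort(syndromes), 2L)
  for (j in seq_len(ncol(combs))) {
    s1 <- combs[1L, j]; s2 <- combs[2L, j]
    i1 <- imgs_by_syn[[s1]]; i2 <- imgs_by_syn[[s2]]
    for (r in seq_len(reps)) {
      g1 <- sample(i1, sample.int(length(i1), 1L))
      g2 <- sample(i2, sample.int(length(i2), 1L))
      key <- pair_key(g1, g2)
      if (key %in% keys) next
      keys <- c(keys, key)
      dist_out <- c(dist_out, cohort_distance(coll, g1, g2))
      pair_out <- c(pair_out, paste(s1, s2, sep = "|"))
    }
  }
  structure(dist_out, pair = pair_out)
}

#' ROC threshold by maximising the Youden index
#'
#' Given control distances (same-syndrome comparisons, expected below the
#' threshold) and case distances (different-syndrome comparisons, expected
#' above), scans candidate thresholds and returns the one maximising
#' Youden's J = sensitivity + specificity - 1. Sensitivity is the fraction
#' of cases strictly above the threshold; specificity the fraction of
#' controls at or below it (a distance exactly at the threshold counts as
#' "lump"). Candidates are the midpoints between consecutive values of the
#' pooled sorted distances, plus sentinels below and above all data; ties
#' in J are broken toward the smallest threshold. AUC is computed from the
#' Wilcoxon rank statistic.
#'
#' @param controls numeric vector of same-syndrome distances.
#' @param cases numeric vector of different-syndrome distances.
#' @return List with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{youden} and \code{auc}.
#' @export
youden_threshold <- function(controls, cases) {
  if (length(controls) == 0L || length(cases) == 0L)
    stop("empty distribution: both controls and cases must be nonempty")
  pooled <- sort(unique(c(controls, cases)))
  cand <- if (length(pooled) > 1L)
    (pooled[-1L] + pooled[-length(pooled)]) / 2 else numeric(0)
  cand <- c(pooled[1L] - 1, cand, pooled[length(pooled)] + 1)
  sens <- vapply(cand, function(c0) mean(cases > c0), numeric(1))
  spec <- vapply(cand, function(c0) mean(controls <= c0), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # first maximum = smallest threshold
  n1 <- length(cases); n0 <- length(controls)
  r <- rank(c(cases, controls))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best], auc = auc)
}

#' Calibrate the lump/split distance threshold by cross-validation
#'
#' Fits the split-decision threshold on a descriptor collection. Syndromes
#' (after filtering to those with at least two patients) are split into
#' \code{k} random folds. For each fold, the same-syndrome and
#' different-syndrome control distributions are sampled on the other
#' \eqn{k-1} folds' syndromes, the threshold maximising the Youden index is
#' derived from the resulting ROC, and the same sampling schemes are
#' applied to the held-out syndromes to measure validation sensitivity and
#' specificity at that threshold. The fold with the highest validation
#' Youden index supplies the final threshold. The validation control
#' distributions of all folds are pooled; they are the empirical basis for
#' the positive-predictive-value estimate in [compare_cohorts()].
#'
#' @param coll an [fpd_collection()]; syndromes with fewer than two
#'   patients are dropped before calibration.
#' @param k number of folds (default 5).
#' @param reps_same same-syndrome partitions per syndrome (default 10).
#' @param reps_diff comparisons per different-syndrome pair (default 5).
#' @param seed optional integer seed controlling folds and sampling.
#' @return An object of class \code{lumpsplit_calib}: list with
#'   \code{threshold}, \code{selected_fold}, \code{folds} (syndrome to fold
#'   map), per-fold table \code{fold_stats}, training and validation
#'   sensitivity/specificity of the selected fold, \code{train_auc}, and
#'   \code{pooled_controls} (list \code{same}, \code{different}).
#' @seealso [compare_cohorts()], [validate_lump_split()]
#' @examples
#' coll <- simulate_cfps(12, 2, 2, within_syndrome_spread = 0.1, seed = 7)
#' fit <- calibrate_lumpsplit(coll, seed = 7)
#' fit
#' @export
calibrate_lumpsplit <- function(coll, k = 5L, reps_same = 10L, reps_diff = 5L,
                                seed = NULL) {
  coll <- filter_collection(coll)
  local_seed(seed)
  folds <- make_syndrome_folds(coll, k)
  syn_all <- names(folds)

  fold_stats <- data.frame(fold = seq_len(k), threshold = NA_real_,
                           train_sensitivity = NA_real_,
                           train_specificity = NA_real_,
                           train_auc = NA_real_,
                           validation_sensitivity = NA_real_,
                           validation_specificity = NA_real_,
                           validation_youden = NA_real_)
  pooled_same <- numeric(0)
  pooled_diff <- numeric(0)
  for (f in seq_len(k)) {
    train_syn <- syn_all[folds != f]
    val_syn <- syn_all[folds == f]
    ctrl_tr <- suppressWarnings(sample_same_syndrome(coll, train_syn, reps_same))
    case_tr <- sample_different_syndromes(coll, train_syn, reps_diff)
    roc <- youden_threshold(ctrl_tr, case_tr)
    ctrl_v <- suppressWarnings(sample_same_syndrome(coll, val_syn, reps_same))
    case_v <- if (length(val_syn) >= 2L)
      sample_different_syndromes(coll, val_syn, reps_diff) else numeric(0)
    v_sens <- if (length(case_v)) mean(case_v > roc$threshold) else NA_real_
    v_spec <- if (length(ctrl_v)) mean(ctrl_v <= roc$threshold) else NA_real_
    fold_stats[f, -1L] <- c(roc$threshold, roc$sensitivity, roc$specificity,
                            roc$auc, v_sens, v_spec,
                            v_sens + v_spec - 1)
    pooled_same <- c(pooled_same, as.numeric(ctrl_v))
    pooled_diff <- c(pooled_diff, as.numeric(case_v))
  }
  best <- which.max(fold_stats$validation_youden)
  structure(list(
    threshold = fold_stats$threshold[best],
    selected_fold = best,
    folds = folds,
    fold_stats = fold_stats,
    train_sensitivity = fold_stats$train_sensitivity[best],
    train_specificity = fold_stats$train_specificity[best],
    train_auc = fold_stats$train_auc[best],
    validation_sensitivity = fold_stats$validation_sensitivity[best],
    validation_specificity = fold_stats$validation_specificity[best],
    pooled_controls = list(same = pooled_same, different = pooled_diff),
    k = k, reps_same = reps_same, reps_diff = reps_diff
  ), class = "lumpsplit_calib")
}

#' @export
print.lumpsplit_calib <- function(x, ...) {
  cat("Lump/split threshold calibration (syndrome-based cross-validation)\n")
  cat(sprintf("  threshold c = %.4f (fold %d of %d)\n",
              x$threshold, x$selected_fold, x$k))
  cat(sprintf("  training:   sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              x$train_sensitivity, x$train_specificity, x$train_auc))
  cat(sprintf("  validation: sensitivity %.3f, specificity %.3f\n",
              x$validation_sensitivity, x$validation_specificity))
  cat(sprintf("  pooled validation controls: %d same-syndrome, %d different-syndrome distances\n",
              length(x$pooled_controls$same), length(x$pooled_controls$different)))
  invisible(x)
}

#' @export
summary.lumpsplit_calib <- function(object, ...) {
  print(object)
  cat("\nPer-fold statistics:\n")
  print(object$fold_stats, digits = 4, row.names = FALSE)
  invisible(object$fold_stats)
}

#' @export
coef.lumpsplit_calib <- function(object, ...) {
  c(threshold = object$threshold)
}

#' Plot the calibrated control distributions and threshold
#'
#' Overlaid histograms of the pooled same-syndrome and different-syndrome
#' validation distance distributions, with the calibrated threshold as a
#' vertical line.
#'
#' @param x a \code{lumpsplit_calib} object.
#' @param ... passed to [graphics::hist()].
#' @return \code{x}, invisibly.
#' @export
plot.lumpsplit_calib <- function(x, ...) {
  same <- x$pooled_controls$same
  diff <- x$pooled_controls$different
  brk <- pretty(c(same, diff), 30)
  h1 <- graphics::hist(same, breaks = brk, plot = FALSE)
  h2 <- graphics::hist(diff, breaks = brk, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, xlab = "mean pairwise cosine distance",
                 main = "Control distance distributions", ...)
  graphics::plot(h2, col = grDevices::adjustcolor("tomato", 0.5), add = TRUE)
  graphics::abline(v = x$threshold, lwd = 2)
  graphics::legend("topright",
                   legend = c("same syndrome", "different syndromes",
                              sprintf("threshold c = %.3f", x$threshold)),
                   fill = c("steelblue", "tomato", NA), border = NA,
                   lty = c(NA, NA, 1), lwd = c(NA, NA, 2), bty = "n")
  invisible(x)
}

#' Validate the calibrated decision rule on held-out syndromes
#'
#' Two analyses on the selected fold's validation syndromes: (1) every
#' unordered pair of distinct syndromes is run through the full split
#' decision ([compare_cohorts()]); the fraction decided "split" is the
#' validation sensitivity. (2) every syndrome with at least two images is
#' randomly split into two groups and run through the same decision; the
#' fraction decided "lump" is the validation specificity.
#'
#' @param calib a \code{lumpsplit_calib} object.
#' @param coll the [fpd_collection()] the calibration refers to.
#' @param n_subgroups subgroup draws per decision (default 100).
#' @param seed optional integer seed.
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{n_pairs} and \code{n_syndromes}.
#' @export
validate_lump_split <- function(calib, coll, n_subgroups = 100L, seed = NULL) {
  stopifnot(inherits(calib, "lumpsplit_calib"))
  coll <- filter_collection(coll)
  local_seed(seed)
  val_syn <- names(calib$folds)[calib$folds == calib$selected_fold]
  imgs <- syndrome_images(coll, val_syn)

  combs <- utils::combn(val_syn, 2L)
  split_hits <- logical(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    dec <- compare_cohorts(calib, coll, imgs[[combs[1L, j]]],
                           imgs[[combs[2L, j]]], n_subgroups)
    split_hits[j] <- dec$verdict == "split"
  }

  lump_hits <- logical(0)
  for (s in val_syn) {
    ii <- imgs[[s]]
    if (length(ii) < 2L) next
    repeat {
      side <- stats::runif(length(ii)) < 0.5
      if (any(side) && any(!side)) break
    }
    dec <- compare_cohorts(calib, coll, ii[side], ii[!side], n_subgroups)
    lump_hits <- c(lump_hits, dec$verdict == "lump")
  }
  list(sensitivity = mean(split_hits), specificity = mean(lump_hits),
       n_pairs = length(split_hits), n_syndromes = length(lump_hits))
}
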