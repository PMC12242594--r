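#' Read a beta-value matrix from tab-separated text
#'
#' Expects a TSV whose first column is \code{probe_id} and whose remaining
#' columns are one per sample, holding methylation beta values in
#' \eqn{[0, 1]} (0 = unmethylated, 1 = fully methylated). Missing values
#' are imputed per probe with the probe's row mean at load time; probes
#' with no observed value are rejected.
#'
#' @param path path to a TSV file.
#' @return Numeric probes x samples matrix with probe-id rownames.
#' @export
read_beta_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "probe_id")
    stop("beta matrix must have probe_id as its first column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$probe_id
  if (anyNA(m)) {
    all_na <- rowSums(!is.na(m)) == 0L
    if (any(all_na))
      stop("probe(s) with no observed value: ",
           paste(rownames(m)[all_na], collapse = ", "))
    rm_ <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm_[idx[, 1L]]
  }
  validate_beta(m)
  m
}

validate_beta <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("beta matrix must be a numeric probes x samples matrix")
  if (anyNA(m) || any(m < 0) || any(m > 1))
    stop("beta values must lie in [0, 1] with no missing values")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("beta matrix needs probe rownames and sample colnames")
  invisible(m)
}

#' Read a sample sheet
#'
#' CSV with columns \code{sample_id}, \code{group} ("case"/"control") and
#' \code{role} ("discovery"/"validation"/"test"); optional \code{age},
#' \code{sex}.
#'
#' @param path path to a CSV file.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sheet(sheet)
  sheet
}

validate_sheet <- function(sheet) {
  need <- c("sample_id", "group", "role")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must contain columns ", paste(need, collapse = ", "))
  if (!all(sheet$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  if (!all(sheet$role %in% c("discovery", "validation", "test")))
    stop("role must be 'discovery', 'validation' or 'test'")
  disc <- sheet[sheet$role == "discovery", ]
  if (!all(c("case", "control") %in% disc$group))
    stop("discovery set must contain both cases and controls")
  invisible(sheet)
}

#' Leading principal components of the sample space
#'
#' Returns per-sample scores on the first two principal components of the
#' column-centred beta matrix restricted to the given samples. These are
#' used as covariates in the differential-methylation model to absorb
#' broad structure (age, sex, blood-cell composition, technical noise)
#' without modelling each factor explicitly. PC1 explains at least as much
#' variance as PC2; the sign of each component is fixed so that its
#' largest-magnitude probe loading is positive.
#'
#' @param beta numeric probes x samples matrix of values in \eqn{[0, 1]}.
#' @param samples sample ids (columns) to use; default all. At least 3.
#' @param n_pcs number of components (default 2).
#' @return Samples x n_pcs matrix of scores (columns \code{PC1},
#'   \code{PC2}, ...).
#' @export
compute_covariate_pcs <- function(beta, samples = colnames(beta), n_pcs = 2L) {
  validate_beta(beta)
  if (length(samples) < 3L)
    stop("insufficient samples: need at least 3 for principal components")
  leading_pcs(t(beta[, samples, drop = FALSE]), n_pcs)
}

# PC scores of a samples x probes matrix with a fixed sign convention:
# the largest-magnitude probe loading of each component is positive
leading_pcs <- function(x, n_pcs) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2L,
                  flip[seq_len(n_pcs)], `*`)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(x)
  scores
}

#' Differential methylation with empirical-Bayes moderated t-statistics
#'
#' Per probe, fits the linear model
#' \code{beta ~ intercept + group + PC1 + PC2} on the discovery samples
#' and tests the case-vs-control coefficient with the moderated
#' t-statistic: probe-wise residual variances are shrunk toward a pooled
#' prior (estimated degrees of freedom \eqn{d_0} and scale \eqn{s_0^2}),
#' stabilising inference at small sample sizes. Two-sided p-values are
#' adjusted by the Benjamini-Hochberg step-up procedure across all probes.
#' The fit is delegated to \pkg{limma}.
#'
#' The effect size \code{delta_beta} is the raw difference of group means
#' (case minus control), reported alongside the covariate-adjusted test.
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet; only rows with \code{role == "discovery"}
#'   enter the fit.
#' @param covariates optional samples x p numeric matrix (rownames =
#'   sample ids). Default: the first two principal components of the
#'   within-group-centred discovery matrix. Group-centring before the
#'   decomposition keeps the covariates orthogonal to the case-control
#'   contrast, so they absorb background structure (age, sex, cell
#'   composition, batch) without also absorbing the effect under test.
#' @return Data frame with columns \code{probe_id}, \code{delta_beta},
#'   \code{moderated_t}, \code{p}, \code{q}, and attributes
#'   \code{df_prior} (\eqn{d_0}) and \code{s2_prior} (\eqn{s_0^2}).
#' @export
differential_methylation <- function(beta, sheet, covariates = NULL) {
  validate_beta(beta)
  validate_sheet(sheet)
  disc <- sheet[sheet$role == "discovery", ]
  if (!all(disc$sample_id %in% colnames(beta)))
    stop("discovery sample(s) missing from the beta matrix")
  if (min(table(disc$group)) < 2L)
    stop("degenerate design: each discovery group needs at least 2 samples")
  b <- beta[, disc$sample_id, drop = FALSE]
  grp <- as.integer(disc$group == "case")
  if (is.null(covariates)) {
    centred <- b
    centred[, grp == 1L] <- b[, grp == 1L] - rowMeans(b[, grp == 1L, drop = FALSE])
    centred[, grp == 0L] <- b[, grp == 0L] - rowMeans(b[, grp == 0L, drop = FALSE])
    covariates <- leading_pcs(t(centred), 2L)
  }
  covariates <- covariates[disc$sample_id, , drop = FALSE]
  design <- cbind(Intercept = 1, group = grp, covariates)
  fit <- limma::eBayes(limma::lmFit(b, design))
  t_mod <- fit$t[, "group"]
  p <- fit$p.value[, "group"]
  # constant probes: zero coefficient and zero residual variance; report 0/1
  const <- apply(b, 1L, function(r) all(r == r[1L]))
  t_mod[const] <- 0
  p[const] <- 1
  dbeta <- rowMeans(b[, grp == 1L, drop = FALSE]) -
    rowMeans(b[, grp == 0L, drop = FALSE])
  out <- data.frame(probe_id = rownames(b), delta_beta = as.numeric(dbeta),
                    moderated_t = as.numeric(t_mod), p = as.numeric(p),
                    q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- unname(fit$df.prior[1L])
  attr(out, "s2_prior") <- unname(fit$s2.prior[1L])
  out
}

#' Select an episignature from per-probe statistics
#'
#' Keeps probes with \code{q <= q_max} and \code{|delta_beta| >=
#' min_abs_delta}, ordered by ascending q and then descending
#' \code{|delta_beta|}. An empty result is allowed (reported with a
#' message): not every case-control contrast carries a methylation
#' signature.
#'
#' @param stats output of [differential_methylation()].
#' @param q_max FDR ceiling (default 0.05).
#' @param min_abs_delta minimum absolute group-mean beta difference
#'   (default 0.05, i.e. 5 percentage points of methylation).
#' @return Character vector of signature probe ids.
#' @export
select_signature <- function(stats, q_max = 0.05, min_abs_delta = 0.05) {
  if (nrow(stats) == 0L) stop("empty probe statistics")
  keep <- stats$q <= q_max & abs(stats$delta_beta) >= min_abs_delta
  sel <- stats[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    message("no probe passes q <= ", q_max, " and |delta beta| >= ", min_abs_delta)
    return(character(0))
  }
  sel <- sel[order(sel$q, -abs(sel$delta_beta), sel$probe_id), ]
  sel$probe_id
}

#' Train a margin-based episignature classifier
#'
#' Fits a maximum-margin linear separator (support vector machine, linear
#' kernel) on the signature-site beta values of the discovery cases and
#' controls, then calibrates a monotone sigmoid mapping decision margins to
#' scores in \eqn{[0, 1]} (Platt scaling with regularised targets, fitted
#' on the training margins). Higher scores mean a more case-like
#' methylation profile. The model stores explicit weights and bias, so
#' scoring does not depend on the fitting library.
#'
#' @param beta probes x samples beta matrix containing the discovery
#'   samples.
#' @param sheet sample sheet; rows with \code{role == "discovery"} are the
#'   training set.
#' @param signature nonempty character vector of signature probe ids.
#' @return Object of class \code{episignature_model}: list with
#'   \code{signature}, \code{weights}, \code{bias}, calibration
#'   coefficients \code{platt_a}, \code{platt_b}, and the training scores.
#' @export
train_classifier <- function(beta, sheet, signature) {
  validate_beta(beta)
  validate_sheet(sheet)
  if (length(signature) == 0L) stop("empty signature")
  missing_probes <- setdiff(signature, rownames(beta))
  if (length(missing_probes))
    stop("missing signature probe(s): ", paste(missing_probes, collapse = ", "))
  disc <- sheet[sheet$role == "discovery", ]
  if (length(unique(disc$group)) < 2L)
    stop("degenerate training set: both classes required")
  x <- t(beta[signature, disc$sample_id, drop = FALSE])  # samples x probes
  y <- factor(disc$group, levels = c("control", "case"))
  sv <- e1071::svm(x, y, kernel = "linear", scale = FALSE, cost = 10)
  w <- drop(t(sv$coefs) %*% sv$SV)
  b0 <- -sv$rho
  margins <- drop(x %*% w) + b0
  # orient so cases sit on the positive side
  if (mean(margins[y == "case"]) < mean(margins[y == "control"])) {
    w <- -w; b0 <- -b0; margins <- -margins
  }
  cal <- platt_calibrate(margins, y == "case")
  model <- structure(list(
    signature = signature,
    weights = stats::setNames(w, signature),
    bias = b0,
    platt_a = cal[["a"]],
    platt_b = cal[["b"]],
    training_scores = stats::setNames(
      plogis_ab(margins, cal[["a"]], cal[["b"]]), disc$sample_id),
    n_case = sum(y == "case"), n_control = sum(y == "control")
  ), class = "episignature_model")
  model
}

# Platt scaling: fit P(case | margin) = 1 / (1 + exp(-(a*m + b))) by
# minimising cross-entropy against regularised targets
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2); keeps a >= 0 so the map is
# monotone even on degenerate margins.
platt_calibrate <- function(margins, is_case) {
  np <- sum(is_case); nn <- sum(!is_case)
  targ <- ifelse(is_case, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    eta <- pmin(pmax(exp(par[1L]) * margins + par[2L], -30), 30)
    p <- 1 / (1 + exp(-eta))
    -sum(targ * log(p) + (1 - targ) * log(1 - p))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS")
  c(a = exp(fit$par[1L]), b = fit$par[2L])
}

plogis_ab <- function(margin, a, b) 1 / (1 + exp(-pmin(pmax(a * margin + b, -30), 30)))

#' @export
print.episignature_model <- function(x, ...) {
  cat(sprintf("Episignature classifier: %d signature probes, linear margin + sigmoid score\n",
              length(x$signature)))
  cat(sprintf("  trained on %d cases vs %d controls\n", x$n_case, x$n_control))
  cat(sprintf("  training score range %.3f-%.3f, calibration a=%.3g b=%.3g\n",
              min(x$training_scores), max(x$training_scores),
              x$platt_a, x$platt_b))
  invisible(x)
}

#' Score samples against an episignature model
#'
#' Computes the 0-1 methylation score of each sample at the signature
#' sites and classifies it as \code{"case-like"} (score > 0.5),
#' \code{"not-case"} (score < 0.5) or \code{"indeterminate"} (score
#' exactly 0.5).
#'
#' @param model an \code{episignature_model}.
#' @param beta probes x samples beta matrix containing all signature
#'   probes.
#' @param samples sample ids to score (default: all columns).
#' @return Data frame with columns \code{sample_id}, \code{score},
#'   \code{label}.
#' @export
score_samples <- function(model, beta, samples = colnames(beta)) {
  stopifnot(inherits(model, "episignature_model"))
  validate_beta(beta)
  missing_probes <- setdiff(model$signature, rownames(beta))
  if (length(missing_probes))
    stop("missing signature probe(s): ", paste(missing_probes, collapse = ", "))
  x <- t(beta[model$signature, samples, drop = FALSE])
  margins <- drop(x %*% model$weights) + model$bias
  score <- plogis_ab(margins, model$platt_a, model$platt_b)
  label <- ifelse(score > 0.5, "case-like",
                  ifelse(score < 0.5, "not-case", "indeterminate"))
  data.frame(sample_id = samples, score = as.numeric(score), label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname score_samples
#' @param object an \code{episignature_model}.
#' @param ... ignored.
#' @export
predict.episignature_model <- function(object, beta,
                                       samples = colnames(beta), ...) {
  score_samples(object, beta, samples)
}

#' Discover and fit an episignature in one step
#'
#' Convenience wrapper: covariate PCs, moderated-t differential
#' methylation, q/delta-beta signature selection, and classifier training,
#' on the discovery samples of the sheet.
#'
#' @inheritParams differential_methylation
#' @inheritParams select_signature
#' @return An \code{episignature_model} with the per-probe statistics
#'   attached as element \code{stats}.
#' @export
fit_episignature <- function(beta, sheet, q_max = 0.05, min_abs_delta = 0.05,
                             covariates = NULL) {
  stats_ <- differential_methylation(beta, sheet, covariates)
  sig <- select_signature(stats_, q_max, min_abs_delta)
  if (length(sig) == 0L)
    stop("no episignature found at q <= ", q_max,
         ", |delta beta| >= ", min_abs_delta)
  model <- train_classifier(beta, sheet, sig)
  model$stats <- stats_
  model
}

#' Export the signature-site beta submatrix
#'
#' Returns the beta values restricted to the signature sites, the input
#' for heatmap or clustering displays.
#'
#' @param model an \code{episignature_model}.
#' @param beta probes x samples beta matrix.
#' @return Numeric matrix (signature probes x samples).
#' @export
signature_matrix <- function(model, beta) {
  stopifnot(inherits(model, "episignature_model"))
  validate_beta(beta)
  missing_probes <- setdiff(model$signature, rownames(beta))
  if (length(missing_probes))
    stop("missing signature probe(s): ", paste(missing_probes, collapse = ", "))
  beta[model$signature, , drop = FALSE]
}

#' Simulate a beta matrix with a planted episignature
#'
#' Generates a probes x samples matrix of methylation beta values:
#' background probes fluctuate around probe-specific baselines (uniform in
#' \eqn{[0.1, 0.9]}) with Gaussian noise of scale \code{noise_sd}, clipped
#' to \eqn{[0, 1]}; a planted set of signature probes is shifted by
#' \code{+delta_beta} in case samples. Discovery cases/controls,
#' validation cases/controls and signature-free "test" case samples (an
#' other-subgroup analogue that does not carry the signature) are laid out
#' in the returned sample sheet.
#'
#' @param n_probes total probes.
#' @param n_signature planted differential probes (<= n_probes).
#' @param delta_beta mean case-control shift at planted probes.
#' @param noise_sd Gaussian noise scale.
#' @param n_cases,n_controls discovery group sizes.
#' @param n_validation_cases,n_validation_controls held-out samples
#'   carrying (cases) or lacking (controls) the planted signature.
#' @param n_test signature-free case-like samples with role "test".
#' @param seed optional integer seed.
#' @return List with \code{beta} (matrix), \code{sheet} (data frame) and
#'   \code{planted} (character vector of planted probe ids).
#' @export
simulate_beta <- function(n_probes = 2000L, n_signature = 30L,
                          delta_beta = 0.10, noise_sd = 0.03,
                          n_cases = 9L, n_controls = 41L,
                          n_validation_cases = 0L,
                          n_validation_controls = 0L,
                          n_test = 0L, seed = NULL) {
  if (n_signature > n_probes)
    stop("config error: n_signature must not exceed n_probes")
  if (delta_beta < 0 || noise_sd < 0)
    stop("config error: delta_beta and noise_sd must be >= 0")
  if (n_cases < 1L || n_controls < 1L)
    stop("config error: need at least one case and one control")
  local_seed(seed)

  sheet <- data.frame(
    sample_id = character(0), group = character(0), role = character(0),
    stringsAsFactors = FALSE)
  add <- function(sheet, n, group, role, prefix) {
    if (n == 0L) return(sheet)
    rbind(sheet, data.frame(
      sample_id = sprintf("%s%02d", prefix, seq_len(n)),
      group = group, role = role, stringsAsFactors = FALSE))
  }
  sheet <- add(sheet, n_cases, "case", "discovery", "DC")
  sheet <- add(sheet, n_controls, "control", "discovery", "DN")
  sheet <- add(sheet, n_validation_cases, "case", "validation", "VC")
  sheet <- add(sheet, n_validation_controls, "control", "validation", "VN")
  sheet <- add(sheet, n_test, "case", "test", "TT")

  probes <- sprintf("cg%07d", seq_len(n_probes))
  planted <- probes[seq_len(n_signature)]
  baseline <- stats::runif(n_probes, 0.1, 0.9)
  # keep headroom so the planted shift does not saturate at 1
  baseline[seq_len(n_signature)] <-
    stats::runif(n_signature, 0.1, 0.9 - delta_beta)
  n_s <- nrow(sheet)
  b <- baseline + matrix(stats::rnorm(n_probes * n_s, sd = noise_sd),
                         n_probes, n_s)
  # signature carriers: discovery and validation cases (test cases are the
  # signature-free other-subgroup analogue)
  carrier <- sheet$group == "case" & sheet$role != "test"
  b[seq_len(n_signature), carrier] <-
    b[seq_len(n_signature), carrier] + delta_beta
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(probes, sheet$sample_id)
  list(beta = b, sheet = sheet, planted = planted)
}

#' Write a beta matrix as tab-separated text
#'
#' @param beta probes x samples matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta(beta)
  out <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
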