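# small planted-signature dataset reused across blocks
sim_small <- function(seed, ...) {
  simulate_beta(n_probes = 600, n_signature = 20, delta_beta = 0.10,
                noise_sd = 0.03, n_cases = 6, n_controls = 12, seed = seed,
                ...)
}

test_that("covariate PC scores are orthogonal, zero-mean and variance-ordered", {
  sim <- sim_small(61)
  pcs <- compute_covariate_pcs(sim$beta)
  expect_equal(colnames(pcs), c("PC1", "PC2"))
  expect_equal(colMeans(pcs), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])), 1e-8)
  expect_gte(var(pcs[, 1]), var(pcs[, 2]))
  expect_error(compute_covariate_pcs(sim$beta, colnames(sim$beta)[1:2]),
               "insufficient samples")
})

test_that("planted orthogonal factors are recovered by the leading PCs", {
  set.seed(62)
  n <- 24
  f1 <- rep(c(-1, 1), each = n / 2)        # strong factor
  f2 <- rep(c(-1, 1), times = n / 2) * 0.5 # weaker orthogonal factor
  # loadings on disjoint probe sets, so the factors are the principal axes
  l1 <- c(runif(150, 0.02, 0.05), rep(0, 150))
  l2 <- c(rep(0, 150), runif(150, 0.02, 0.05))
  m <- 0.5 + outer(l1, f1) + outer(l2, f2) +
    matrix(rnorm(300 * n, sd = 1e-4), 300, n)
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(paste0("p", 1:300), paste0("s", 1:n))
  pcs <- compute_covariate_pcs(m)
  expect_gt(abs(cor(pcs[, 1], f1)), 0.99)
  expect_gt(abs(cor(pcs[, 2], f2)), 0.99)
  # duplicating every sample leaves the leading subspace unchanged
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("s", 1:(2 * n))
  pcs2 <- compute_covariate_pcs(m2)
  expect_gt(abs(cor(pcs2[1:n, 1], pcs[, 1])), 0.999)
})

test_that("moderated t reduces to ordinary t when residual variances are equal", {
  set.seed(63)
  n1 <- 5; n2 <- 5
  base <- matrix(rnorm(40 * (n1 + n2), sd = 0.02), 40, n1 + n2)
  # rescale every probe's residuals to identical variance
  grp <- rep(c(1, 0), c(n1, n2))
  for (i in 1:40) {
    r <- base[i, ]
    r[grp == 1] <- r[grp == 1] - mean(r[grp == 1])
    r[grp == 0] <- r[grp == 0] - mean(r[grp == 0])
    base[i, ] <- 0.5 + r / sd(r) * 0.01 + grp * runif(1, 0, 0.05)
  }
  b <- pmin(pmax(base, 0), 1)
  dimnames(b) <- list(paste0("p", 1:40), paste0("s", 1:(n1 + n2)))
  sheet <- data.frame(sample_id = colnames(b),
                      group = ifelse(grp == 1, "case", "control"),
                      role = "discovery")
  # covariates set to zero columns would be singular; use none by passing
  # an explicit empty matrix
  covar <- matrix(numeric(0), nrow = n1 + n2, ncol = 0,
                  dimnames = list(colnames(b), NULL))
  st <- differential_methylation(b, sheet, covariates = covar)
  tt <- apply(b, 1, function(r) unname(t.test(r[grp == 1], r[grp == 0],
                                              var.equal = TRUE)$statistic))
  expect_equal(st$moderated_t, unname(tt), tolerance = 1e-6)
})

test_that("probe statistics carry the shrinkage contract and BH adjustment", {
  sim <- sim_small(64)
  st <- differential_methylation(sim$beta, sim$sheet)
  expect_true(all(st$q >= st$p - 1e-12))
  expect_true(all(abs(st$delta_beta) <= 1))
  expect_gt(attr(st, "df_prior"), 0)
  expect_gt(attr(st, "s2_prior"), 0)
  expect_equal(st$q, oracle_bh(st$p), tolerance = 1e-12)

  # constant probe reports delta 0, t 0, p 1
  b <- sim$beta
  b["cg0000600", ] <- 0.5
  st2 <- differential_methylation(b, sim$sheet)
  row <- st2[st2$probe_id == "cg0000600", ]
  expect_equal(row$delta_beta, 0)
  expect_equal(row$moderated_t, 0)
  expect_equal(row$p, 1)

  sheet_bad <- sim$sheet
  sheet_bad$group[sheet_bad$role == "discovery" & sheet_bad$group == "case"][-1] <- "control"
  expect_error(differential_methylation(sim$beta, sheet_bad),
               "degenerate design")
})

test_that("BH matches the textbook step-up on many random p-vectors", {
  set.seed(65)
  for (i in 1:1000) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("few discoveries arise under the complete null", {
  frac <- vapply(1:5, function(seed) {
    sim <- simulate_beta(n_probes = 1000, n_signature = 1, delta_beta = 0,
                         noise_sd = 0.03, n_cases = 6, n_controls = 12,
                         seed = 700 + seed)
    st <- differential_methylation(sim$beta, sim$sheet)
    mean(st$q <= 0.05)
  }, numeric(1))
  expect_lt(mean(frac), 0.01)
})

test_that("signature selection applies the q and delta-beta rules in order", {
  st <- data.frame(
    probe_id = c("keep", "small_delta", "big_q", "better"),
    delta_beta = c(0.06, 0.04, 0.20, 0.10),
    moderated_t = 1, p = c(0.01, 0.01, 0.02, 0.001),
    q = c(0.04, 0.04, 0.06, 0.01))
  sig <- select_signature(st, q_max = 0.05, min_abs_delta = 0.05)
  expect_equal(sig, c("better", "keep"))  # ascending q
  expect_message(
    out <- select_signature(data.frame(probe_id = "x", delta_beta = 0.01,
                                       moderated_t = 0, p = 0.9, q = 0.9)),
    "no probe")
  expect_length(out, 0)
})

test_that("a planted signature is recovered with few false positives", {
  res <- vapply(1:5, function(seed) {
    sim <- sim_small(800 + seed)
    st <- differential_methylation(sim$beta, sim$sheet)
    sig <- select_signature(st)
    c(hits = length(intersect(sig, sim$planted)),
      fp = length(setdiff(sig, sim$planted)))
  }, numeric(2))
  expect_gte(median(res["hits", ]), 18)  # >= 18 of 20 planted
  expect_lte(median(res["fp", ]), 2)
})

test_that("classifier separates training groups and keeps scores in [0, 1]", {
  sim <- sim_small(66, n_validation_cases = 2, n_validation_controls = 6,
                   n_test = 3)
  model <- fit_episignature(sim$beta, sim$sheet)
  disc <- sim$sheet[sim$sheet$role == "discovery", ]
  tr <- model$training_scores
  expect_true(all(tr[disc$group == "case"] > 0.5))
  expect_true(all(tr[disc$group == "control"] < 0.5))
  sc <- score_samples(model, sim$beta)
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  # order invariance: permuting probes consistently leaves scores unchanged
  perm <- sample(nrow(sim$beta))
  sc2 <- score_samples(model, sim$beta[perm, ])
  expect_equal(sc$score, sc2$score, tolerance = 1e-12)

  # missing probe is named in the error
  b_missing <- sim$beta[setdiff(rownames(sim$beta), model$signature[1]), ]
  expect_error(score_samples(model, b_missing), model$signature[1])
  expect_error(train_classifier(sim$beta, sim$sheet, character(0)),
               "empty signature")
})

test_that("held-out carriers score case-like and signature-free samples do not", {
  ok <- vapply(1:5, function(seed) {
    sim <- sim_small(900 + seed, n_validation_cases = 1,
                     n_validation_controls = 10, n_test = 3)
    model <- fit_episignature(sim$beta, sim$sheet)
    sc <- score_samples(model, sim$beta)
    sc <- merge(sc, sim$sheet, by = "sample_id")
    val_case <- sc$score[sc$role == "validation" & sc$group == "case"]
    val_ctrl <- sc$score[sc$role == "validation" & sc$group == "control"]
    tst <- sc$score[sc$role == "test"]
    all(val_case > 0.5) && all(val_ctrl < 0.5) && all(tst < 0.5)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("score labels follow the 0.5 rule with an explicit boundary state", {
  model <- structure(list(signature = c("p1", "p2"),
                          weights = c(p1 = 1, p2 = -1), bias = 0,
                          platt_a = 1, platt_b = 0),
                     class = "episignature_model")
  b <- matrix(c(0.9, 0.1, 0.1, 0.9, 0.5, 0.5), nrow = 2,
              dimnames = list(c("p1", "p2"), c("hi", "lo", "mid")))
  sc <- score_samples(model, b)
  expect_equal(sc$label, c("case-like", "not-case", "indeterminate"))
  expect_gt(sc$score[1], 0.5)
  expect_lt(sc$score[2], 0.5)
  expect_equal(sc$score[3], 0.5)
})

test_that("beta simulation is seed-stable and hits the planted effect size", {
  s1 <- sim_small(67)
  s2 <- sim_small(67)
  expect_identical(s1$beta, s2$beta)
  # planted probes show the requested mean case-control shift
  disc <- s1$sheet[s1$sheet$role == "discovery", ]
  cs <- disc$sample_id[disc$group == "case"]
  ct <- disc$sample_id[disc$group == "control"]
  shift <- rowMeans(s1$beta[s1$planted, cs]) - rowMeans(s1$beta[s1$planted, ct])
  expect_lt(abs(mean(shift) - 0.10), 0.02)
  expect_true(all(s1$beta >= 0 & s1$beta <= 1))
  expect_error(simulate_beta(n_probes = 10, n_signature = 20), "config error")
})

test_that("beta matrices and sample sheets round-trip through text files", {
  sim <- sim_small(68)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(sim$beta, f)
  back <- read_beta_matrix(f)
  expect_equal(dim(back), dim(sim$beta))
  expect_equal(back, sim$beta, tolerance = 1e-6)

  fs <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim$sheet, fs, row.names = FALSE)
  sheet <- read_sample_sheet(fs)
  expect_equal(sheet$sample_id, sim$sheet$sample_id)

  # per-probe mean imputation at load time
  b2 <- sim$beta
  b2[1, 1] <- NA
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(probe_id = rownames(b2), b2, check.names = FALSE),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  b3 <- read_beta_matrix(f2)
  expect_equal(b3[1, 1], mean(sim$beta[1, -1]), tolerance = 1e-6)
})
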