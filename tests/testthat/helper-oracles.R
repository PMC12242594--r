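# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: double loops instead of matrix algebra, explicit
# enumeration instead of library calls.

# mean pairwise distance by explicit double loop
oracle_cohort_distance <- function(coll, c1, c2) {
  acc <- 0
  for (i in c1) for (j in c2) acc <- acc + image_distance(coll, i, j)
  acc / (length(c1) * length(c2))
}

# exhaustive Youden scan over midpoint candidates plus sentinels
oracle_youden <- function(controls, cases) {
  pooled <- sort(unique(c(controls, cases)))
  cand <- c(pooled[1] - 1,
            if (length(pooled) > 1) (pooled[-1] + pooled[-length(pooled)]) / 2,
            pooled[length(pooled)] + 1)
  best <- NULL
  for (c0 in cand) {
    sens <- sum(cases > c0) / length(cases)
    spec <- sum(controls <= c0) / length(controls)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-15)
      best <- list(threshold = c0, sensitivity = sens, specificity = spec,
                   youden = j)
  }
  best
}

# exact two-sided Fisher p by full enumeration of tables at fixed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# direct closed-form PPV
oracle_ppv <- function(se, sp, p) se * p / (se * p + (1 - sp) * (1 - p))

# random valid 12 x 512 descriptor ensemble
rand_descriptor <- function() {
  matrix(rnorm(12 * 512), 12, 512)
}

# a hand-built collection of n random, unrelated images
rand_collection <- function(n, syndrome = rep("S1", n),
                            patient = paste0("P", seq_len(n))) {
  ids <- paste0("img", seq_len(n))
  descriptors <- lapply(ids, function(i) rand_descriptor())
  names(descriptors) <- ids
  fpd_collection(
    data.frame(image_id = ids, patient_id = patient, syndrome_id = syndrome,
               stringsAsFactors = FALSE),
    descriptors)
}

# descriptor whose 12 slots are standard basis vectors e_{off+1..off+12}
basis_descriptor <- function(offset = 0L) {
  d <- matrix(0, 12, 512)
  for (k in 1:12) d[k, offset + k] <- 1
  d
}
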