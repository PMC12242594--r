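#' Simulate a syndrome-structured descriptor collection
#'
#' Generates facial-phenotype-descriptor collections with a controllable
#' syndrome / patient / image hierarchy on the 512-dimensional unit
#' hypersphere, so that every distance-based operation in the package can
#' be exercised with known geometry.
#'
#' Syndrome mean directions are drawn independently and uniformly on the
#' sphere (normalised standard Gaussians). Patient means are the
#' unit-normalised sum of their syndrome mean and an isotropic Gaussian
#' perturbation whose expected Euclidean norm is
#' \code{within_syndrome_spread} (per-component standard deviation
#' \code{spread / sqrt(512)}); against the unit-length mean this makes the
#' spread an angular dispersion in radians, to first order. Each image
#' draws one shared perturbation of norm-scale \code{within_patient_spread},
#' and each of its 12 descriptor slots adds an independent perturbation of
#' norm-scale \code{slot_jitter}; every slot is unit-normalised. With all
#' spreads zero, all images of a syndrome coincide and same-syndrome
#' distances are exactly zero; unrelated syndrome means are near-orthogonal
#' in 512 dimensions, so different-syndrome distances concentrate near 1.
#'
#' This is a tangent-space Gaussian construction rather than an exact
#' directional distribution: only relative separations matter for the
#' statistics built on cosine distance, and unit normalisation makes the
#' distances depend on direction alone.
#'
#' @param n_syndromes number of syndromes (>= 1).
#' @param patients_per_syndrome integer, or integer vector of length
#'   \code{n_syndromes}.
#' @param images_per_patient integer, or integer vector recycled over
#'   patients.
#' @param within_syndrome_spread nonnegative; angular dispersion of patient
#'   means around their syndrome mean.
#' @param within_patient_spread nonnegative; dispersion of image centres
#'   around the patient mean.
#' @param slot_jitter nonnegative; independent per-slot perturbation across
#'   the 12 descriptors of an image.
#' @param seed optional integer seed; the same seed reproduces the
#'   collection exactly.
#' @return An [fpd_collection()] with labels
#'   \code{S<i>} / \code{S<i>P<j>} / \code{S<i>P<j>I<k>}.
#' @examples
#' coll <- simulate_cfps(4, 2, 2, within_syndrome_spread = 0.1, seed = 1)
#' coll
#' @export
simulate_cfps <- function(n_syndromes,
                          patients_per_syndrome = 3L,
                          images_per_patient = 2L,
                          within_syndrome_spread = 0.15,
                          within_patient_spread = 0.05,
                          slot_jitter = 0.02,
                          seed = NULL) {
  if (n_syndromes < 1) stop("config error: n_syndromes must be >= 1")
  if (any(patients_per_syndrome < 1) || any(images_per_patient < 1))
    stop("config error: counts must be >= 1")
  if (within_syndrome_spread < 0 || within_patient_spread < 0 || slot_jitter < 0)
    stop("config error: spreads must be >= 0")
  npat <- rep_len(as.integer(patients_per_syndrome), n_syndromes)
  # spreads are expected perturbation norms; convert to per-component sd
  ws <- within_syndrome_spread / sqrt(N_DIMS)
  wp <- within_patient_spread / sqrt(N_DIMS)
  sj <- slot_jitter / sqrt(N_DIMS)

  local_seed(seed)
  meta <- list()
  descriptors <- list()
  for (s in seq_len(n_syndromes)) {
    syn <- sprintf("S%02d", s)
    s_mean <- unit(stats::rnorm(N_DIMS))
    for (p in seq_len(npat[s])) {
      pat <- sprintf("%sP%02d", syn, p)
      p_mean <- unit(s_mean + ws * stats::rnorm(N_DIMS))
      nimg <- rep_len(as.integer(images_per_patient), npat[s])[p]
      for (i in seq_len(nimg)) {
        img <- sprintf("%sI%02d", pat, i)
        centre <- p_mean + wp * stats::rnorm(N_DIMS)
        slots <- matrix(NA_real_, N_SLOTS, N_DIMS)
        for (k in seq_len(N_SLOTS))
          slots[k, ] <- unit(centre + sj * stats::rnorm(N_DIMS))
        meta[[img]] <- data.frame(image_id = img, patient_id = pat,
                                  syndrome_id = syn, stringsAsFactors = FALSE)
        descriptors[[img]] <- slots
      }
    }
  }
  fpd_collection(do.call(rbind, meta), descriptors)
}

unit <- function(x) x / sqrt(sum(x^2))

# Set the RNG seed for the calling function only, restoring the caller's
# RNG state on exit (the convention of simulate() methods). seed = NULL
# leaves the global stream untouched.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  restore <- if (is.null(old))
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  else bquote(assign(".Random.seed", .(old), globalenv()))
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}
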