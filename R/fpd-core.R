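#' @keywords internal
"_PACKAGE"

# Each image is an ensemble of 12 descriptor vectors of 512 components.
N_SLOTS <- 12L
N_DIMS <- 512L

#' Construct a facial phenotype descriptor collection
#'
#' A descriptor collection holds, per image, an ensemble of twelve
#' 512-dimensional facial phenotype descriptors together with image,
#' patient and syndrome identity. The distance between two images is the
#' average of the twelve per-slot cosine distances, so only vector
#' directions matter; descriptors are unit-normalised per slot at
#' construction.
#'
#' @param meta data frame with columns \code{image_id}, \code{patient_id},
#'   \code{syndrome_id}; one row per image, image ids unique.
#' @param descriptors named list (by \code{image_id}) of numeric
#'   12 x 512 matrices, row \code{k} being the k-th descriptor slot.
#' @return An object of class \code{fpd_collection}.
#' @details All images of one patient must carry the same syndrome label;
#'   descriptors must be finite with strictly positive per-slot norms.
#' @seealso [read_fpd()], [simulate_cfps()], [image_distance()]
#' @export
fpd_collection <- function(meta, descriptors) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("image_id", "patient_id", "syndrome_id")
  if (!all(need %in% names(meta)))
    stop("meta must contain columns image_id, patient_id, syndrome_id")
  meta$image_id <- as.character(meta$image_id)
  meta$patient_id <- as.character(meta$patient_id)
  meta$syndrome_id <- as.character(meta$syndrome_id)
  if (anyDuplicated(meta$image_id))
    stop("duplicate image_id in collection")
  psyn <- unique(meta[, c("patient_id", "syndrome_id")])
  if (anyDuplicated(psyn$patient_id))
    stop("images of one patient carry different syndrome labels")
  if (!all(meta$image_id %in% names(descriptors)))
    stop("missing descriptors for some image_ids")

  emb <- matrix(NA_real_, nrow(meta), N_SLOTS * N_DIMS,
                dimnames = list(meta$image_id, NULL))
  for (id in meta$image_id) {
    emb[id, ] <- as.vector(t(normalize_slots(descriptors[[id]], id)))
  }
  # Rows of emb/sqrt(12) have unit norm overall, so the dot product of two
  # rows equals the mean per-slot cosine similarity.
  emb <- emb / sqrt(N_SLOTS)
  rownames(meta) <- meta$image_id
  structure(list(meta = meta, emb = emb), class = "fpd_collection")
}

# validate one image's 12 x 512 descriptor ensemble and unit-normalise rows
normalize_slots <- function(d, id) {
  d <- as.matrix(d)
  if (nrow(d) != N_SLOTS || ncol(d) != N_DIMS)
    stop(sprintf("descriptor shape error for image '%s': expected %d x %d, got %d x %d",
                 id, N_SLOTS, N_DIMS, nrow(d), ncol(d)))
  if (!all(is.finite(d)))
    stop(sprintf("invalid descriptor for image '%s': non-finite components", id))
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm <= 0))
    stop(sprintf("invalid descriptor for image '%s': zero-norm vector in slot(s) %s",
                 id, paste(which(nrm <= 0), collapse = ",")))
  d / nrm
}

#' @export
print.fpd_collection <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Facial phenotype descriptor collection: %d images, %d patients, %d syndromes\n",
              nrow(m), length(unique(m$patient_id)), length(unique(m$syndrome_id))))
  cat(sprintf("Each image: %d descriptor slots x %d dimensions (unit-normalised)\n",
              N_SLOTS, N_DIMS))
  invisible(x)
}

#' @export
length.fpd_collection <- function(x) nrow(x$meta)

#' Subset a descriptor collection by image ids
#'
#' @param x an \code{fpd_collection}.
#' @param ids character vector of image ids to keep.
#' @return The reduced \code{fpd_collection}.
#' @export
subset_images <- function(x, ids) {
  stopifnot(inherits(x, "fpd_collection"))
  missing_ids <- setdiff(ids, x$meta$image_id)
  if (length(missing_ids))
    stop("missing image(s) in collection: ", paste(missing_ids, collapse = ", "))
  keep <- x$meta$image_id %in% ids
  structure(list(meta = x$meta[keep, , drop = FALSE],
                 emb = x$emb[x$meta$image_id[keep], , drop = FALSE]),
            class = "fpd_collection")
}

check_images <- function(coll, ids, what = "image") {
  missing_ids <- setdiff(ids, coll$meta$image_id)
  if (length(missing_ids))
    stop(sprintf("missing %s(s) in collection: %s", what,
                 paste(missing_ids, collapse = ", ")))
  invisible(TRUE)
}

#' Ensemble cosine distance between two images
#'
#' The distance between images i and j is the average of the twelve cosine
#' distances between their corresponding descriptor slots,
#' \eqn{d(i,j) = \frac{1}{12}\sum_{k=1}^{12}(1 - \cos(x_{i,k}, x_{j,k}))}.
#' It lies in \eqn{[0, 2]}, is symmetric, and is zero for identical images.
#'
#' @param coll an \code{fpd_collection}.
#' @param a,b image ids present in \code{coll}.
#' @return A single numeric distance.
#' @export
image_distance <- function(coll, a, b) {
  stopifnot(inherits(coll, "fpd_collection"))
  check_images(coll, c(a, b))
  clamp02(1 - sum(coll$emb[a, ] * coll$emb[b, ]))
}

# guard against sub-eps float excursions outside the cosine range
clamp02 <- function(x) pmin(pmax(x, 0), 2)

#' Ensemble cosine distance between two raw descriptor matrices
#'
#' Works directly on two 12 x 512 descriptor matrices without a
#' collection; useful for standalone pairs.
#'
#' @param a,b numeric 12 x 512 matrices.
#' @return A single numeric distance in \eqn{[0, 2]}.
#' @export
descriptor_distance <- function(a, b) {
  ua <- normalize_slots(a, "a")
  ub <- normalize_slots(b, "b")
  mean(1 - rowSums(ua * ub))
}

#' Mean pairwise cosine distance between two cohorts
#'
#' For cohorts C1 and C2 of images, computes
#' \eqn{d(C_1, C_2) = \frac{1}{|C_1||C_2|}\sum_{i \in C_1}\sum_{j \in C_2} d(i, j)},
#' the mean of the ensemble cosine distance over all cross pairs. Images
#' shared by both cohorts still contribute their (zero) self-pairs; callers
#' needing disjoint cohorts must enforce disjointness upstream.
#'
#' @param coll an \code{fpd_collection}.
#' @param c1,c2 nonempty character vectors of image ids.
#' @return A single numeric distance in \eqn{[0, 2]}.
#' @export
cohort_distance <- function(coll, c1, c2) {
  stopifnot(inherits(coll, "fpd_collection"))
  if (length(c1) == 0L || length(c2) == 0L)
    stop("empty cohort: both cohorts must contain at least one image")
  check_images(coll, c(c1, c2))
  m1 <- colMeans(coll$emb[c1, , drop = FALSE])
  m2 <- colMeans(coll$emb[c2, , drop = FALSE])
  # mean over pairs of (1 - <x_i, x_j>) = 1 - <mean_i x_i, mean_j x_j>
  clamp02(1 - sum(m1 * m2))
}

# Full pairwise distance matrix; used to make heavy resampling cheap.
pairwise_distances <- function(coll, ids = coll$meta$image_id) {
  e <- coll$emb[ids, , drop = FALSE]
  d <- 1 - tcrossprod(e)
  d[d < 0] <- 0
  d
}

#' Rank a gallery of images by distance to a probe image
#'
#' Orders the gallery by ascending ensemble cosine distance to the probe.
#' Ranks start at 1; exact ties are broken lexicographically by image id so
#' that the ranking is deterministic.
#'
#' @param coll an \code{fpd_collection}.
#' @param probe image id of the probe.
#' @param gallery nonempty character vector of gallery image ids.
#' @return Data frame with columns \code{image_id}, \code{distance},
#'   \code{rank}, sorted by rank.
#' @export
rank_gallery <- function(coll, probe, gallery) {
  stopifnot(inherits(coll, "fpd_collection"))
  if (length(gallery) == 0L) stop("empty gallery")
  check_images(coll, probe, "probe image")
  check_images(coll, gallery, "gallery image")
  d <- 1 - as.vector(coll$emb[gallery, , drop = FALSE] %*% coll$emb[probe, ])
  ord <- order(d, gallery)
  data.frame(image_id = gallery[ord], distance = d[ord],
             rank = seq_along(gallery), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a descriptor table from tab-separated text
#'
#' Two layouts are accepted. \code{"long"}: one row per (image, slot) with
#' columns \code{image_id}, \code{patient_id}, \code{syndrome_id},
#' \code{slot} (1-12) and 512 value columns; exactly 12 slots per image are
#' required. \code{"wide"}: one row per image with the three id columns
#' followed by 6144 values, slot-major.
#'
#' The file may contain images the current analysis never references; all
#' rows are kept.
#'
#' @param path path to a TSV file.
#' @param layout \code{"long"} (default) or \code{"wide"}.
#' @return An \code{fpd_collection}.
#' @export
read_fpd <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("image_id", "patient_id", "syndrome_id", "slot")
    if (!all(need %in% names(tab)))
      stop("long layout requires columns image_id, patient_id, syndrome_id, slot")
    vals <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
    if (ncol(vals) != N_DIMS)
      stop(sprintf("expected %d value columns, found %d", N_DIMS, ncol(vals)))
    ids <- unique(tab$image_id)
    descriptors <- vector("list", length(ids))
    names(descriptors) <- ids
    for (id in ids) {
      idx <- which(tab$image_id == id)
      if (length(idx) != N_SLOTS || !setequal(tab$slot[idx], seq_len(N_SLOTS)))
        stop(sprintf("image '%s' does not have exactly %d slots 1..%d",
                     id, N_SLOTS, N_SLOTS))
      descriptors[[id]] <- unname(vals[idx[order(tab$slot[idx])], , drop = FALSE])
    }
    meta <- unique(tab[, c("image_id", "patient_id", "syndrome_id")])
  } else {
    need <- c("image_id", "patient_id", "syndrome_id")
    if (!all(need %in% names(tab)))
      stop("wide layout requires columns image_id, patient_id, syndrome_id")
    vals <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
    if (ncol(vals) != N_SLOTS * N_DIMS)
      stop(sprintf("expected %d value columns, found %d",
                   N_SLOTS * N_DIMS, ncol(vals)))
    descriptors <- lapply(seq_len(nrow(tab)), function(i)
      matrix(vals[i, ], nrow = N_SLOTS, ncol = N_DIMS, byrow = TRUE))
    names(descriptors) <- tab$image_id
    meta <- tab[, need]
  }
  fpd_collection(meta, descriptors)
}

#' Write a descriptor collection as tab-separated text
#'
#' Writes the unit-normalised descriptors in the long or wide layout
#' accepted by [read_fpd()].
#'
#' @param coll an \code{fpd_collection}.
#' @param path output file path.
#' @param layout \code{"long"} or \code{"wide"}.
#' @return \code{path}, invisibly.
#' @export
write_fpd <- function(coll, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(coll, "fpd_collection"))
  m <- coll$meta
  emb <- coll$emb * sqrt(N_SLOTS)  # undo ensemble scaling: unit slot rows
  if (layout == "long") {
    out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
      slots <- matrix(emb[i, ], nrow = N_SLOTS, ncol = N_DIMS, byrow = TRUE)
      cbind(data.frame(image_id = m$image_id[i], patient_id = m$patient_id[i],
                       syndrome_id = m$syndrome_id[i], slot = seq_len(N_SLOTS),
                       stringsAsFactors = FALSE),
            as.data.frame(slots))
    }))
    names(out)[-(1:4)] <- sprintf("v%03d", seq_len(N_DIMS))
  } else {
    out <- cbind(m[, c("image_id", "patient_id", "syndrome_id")],
                 as.data.frame(emb, row.names = FALSE))
    names(out)[-(1:3)] <- sprintf("v%04d", seq_len(N_SLOTS * N_DIMS))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
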