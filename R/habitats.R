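#' Normalize a CBV map to relative CBV (rCBV)
#'
#' Divides the cerebral-blood-volume map by its mean over normal-appearing
#' white matter (NAWM), so the NAWM mean of the output is exactly 1.
#'
#' @param cbv_map 3-D numeric array.
#' @param nawm_mask logical array of the same shape.
#' @return 3-D rCBV array.
#' @export
normalize_rcbv <- function(cbv_map, nawm_mask) {
  if (!identical(dim(cbv_map), dim(nawm_mask)))
    stopf("CBV map and NAWM mask shapes differ")
  if (!any(nawm_mask)) stopf("NAWM mask is empty")
  m <- mean(cbv_map[nawm_mask])
  if (!is.finite(m) || m <= 0) stopf("NAWM mean CBV must be > 0 (got %g)", m)
  cbv_map / m
}

#' One-dimensional k-means clustering of map intensities
#'
#' Lloyd iterations on sorted values (assignment by center midpoints,
#' prefix-sum updates) from k-means++ starts, best of `n_init` restarts by
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param values numeric vector (e.g. within-tumor voxel intensities).
#' @param k number of clusters (>= 2).
#' @param n_init restarts (default 10).
#' @param seed integer seed.
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `cluster_result`: `labels` (1..k, indexing
#'   `centers`), `centers` (ascending), `inertia`.
#' @export
kmeans_scalar <- function(values, k, n_init = 10, seed = 1,
                          tol = 1e-6, max_iter = 300) {
  if (k < 2) stopf("k must be >= 2")
  if (any(!is.finite(values))) stopf("values must be finite")
  ux <- unique(values)
  if (length(ux) < k)
    stopf("fewer distinct values (%d) than clusters (%d)", length(ux), k)
  vs <- sort(values)
  cs1 <- cumsum(vs); cs2 <- cumsum(vs^2)
  n <- length(vs)
  seg_cost <- function(lo, hi) { # SSE of vs[lo..hi]
    s1 <- cs1[hi] - if (lo > 1) cs1[lo - 1] else 0
    s2 <- cs2[hi] - if (lo > 1) cs2[lo - 1] else 0
    s2 - s1^2 / (hi - lo + 1)
  }
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- kmeanspp_init(vs, k)
      for (it in seq_len(max_iter)) {
        centers <- sort(centers)
        cut <- (centers[-k] + centers[-1]) / 2
        pos <- findInterval(cut, vs) # last sorted index in each cluster
        lo <- c(1L, pos + 1L); hi <- c(pos, n)
        newc <- centers
        for (j in seq_len(k)) {
          if (hi[j] >= lo[j]) {
            s1 <- cs1[hi[j]] - if (lo[j] > 1) cs1[lo[j] - 1] else 0
            newc[j] <- s1 / (hi[j] - lo[j] + 1)
          } else { # empty cluster: restart it at a random data point
            newc[j] <- vs[sample.int(n, 1)]
          }
        }
        shift <- max(abs(newc - centers))
        centers <- newc
        if (shift < tol) break
      }
      centers <- sort(centers)
      cut <- (centers[-k] + centers[-1]) / 2
      pos <- findInterval(cut, vs)
      lo <- c(1L, pos + 1L); hi <- c(pos, n)
      inertia <- sum(vapply(seq_len(k), function(j)
        if (hi[j] >= lo[j]) seg_cost(lo[j], hi[j]) else 0, numeric(1)))
      if (is.null(best) || inertia < best$inertia)
        best <- list(centers = centers, cut = cut, inertia = inertia)
    }
  })
  labels <- findInterval(values, best$cut) + 1L
  structure(list(labels = labels, centers = best$centers,
                 inertia = max(best$inertia, 0)),
            class = "cluster_result")
}

# k-means++ seeding on a sorted value vector.
kmeanspp_init <- function(vs, k) {
  n <- length(vs)
  centers <- numeric(k)
  centers[1] <- vs[sample.int(n, 1)]
  d2 <- (vs - centers[1])^2
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j] <- vs[sample.int(n, 1)]
    } else {
      centers[j] <- vs[sample.int(n, 1, prob = d2)]
    }
    d2 <- pmin(d2, (vs - centers[j])^2)
  }
  centers
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k=%d, inertia %.6g>\ncenters: %s\n",
              length(x$centers), x$inertia,
              paste(signif(x$centers, 5), collapse = ", ")))
  invisible(x)
}

#' Segment one tumor map into named intensity clusters
#'
#' Runs [kmeans_scalar()] on the within-tumor voxels (pooled 3-D by default,
#' or per axial slice with label harmonization by center ordering) and names
#' the clusters by ascending cluster center, e.g. post-contrast T1:
#' necrotic < non-enhanced < enhancing; MD: LMD < HMD; rCBV: LrCBV < HrCBV.
#'
#' @param map 3-D numeric array.
#' @param tumor_mask logical array, same shape.
#' @param k number of clusters; must equal `length(ordering)`.
#' @param ordering cluster names from lowest to highest center.
#' @param seed integer seed.
#' @param slicewise if `TRUE`, cluster each axial slice separately and
#'   harmonize labels by center ordering (thin-slice fallback: slices with
#'   fewer than `k` distinct values inherit pooled 3-D boundaries).
#' @param ... passed to [kmeans_scalar()].
#' @return Named list of logical masks partitioning the tumor mask.
#' @export
segment_map <- function(map, tumor_mask, k, ordering, seed = 1,
                        slicewise = FALSE, ...) {
  if (!identical(dim(map), dim(tumor_mask))) stopf("map/mask shapes differ")
  if (length(ordering) != k) stopf("ordering must have length k")
  vals <- map[tumor_mask]
  masks <- lapply(seq_len(k), function(j) array(FALSE, dim(map)))
  names(masks) <- ordering
  if (slicewise) {
    pooled <- kmeans_scalar(vals, k, seed = seed, ...)
    labels <- array(0L, dim(map))
    for (z in seq_len(dim(map)[3])) {
      sl <- tumor_mask[, , z]
      if (!any(sl)) next
      v <- map[, , z][sl]
      lab <- if (length(unique(v)) >= k) {
        kmeans_scalar(v, k, seed = derive_seed(seed, z), ...)$labels
      } else { # degenerate slice: use pooled cut points
        cut <- (pooled$centers[-k] + pooled$centers[-1]) / 2
        findInterval(v, cut) + 1L
      }
      lz <- labels[, , z]; lz[sl] <- lab; labels[, , z] <- lz
    }
    for (j in seq_len(k)) masks[[j]][labels == j & tumor_mask] <- TRUE
  } else {
    cl <- kmeans_scalar(vals, k, seed = seed, ...)
    tidx <- which(tumor_mask)
    for (j in seq_len(k)) masks[[j]][tidx[cl$labels == j]] <- TRUE
  }
  masks
}

#' Derive the ten-ROI habitat catalog by mask intersection
#'
#' Combines the per-map cluster masks into the named habitat ROIs:
#' the three post-contrast T1 compartments (`CE`, `non_en`, `necrotic`),
#' the MD clusters (`LMD`, `HMD`), the low-perfusion cluster (`LrCBV`), and
#' the intersection habitats `LMD_LrCBV_CE`, `LMD_LrCBV_nec`,
#' `HMD_LrCBV_nec` and `En_HrCBV` (enhancing voxels outside the
#' low-perfusion cluster). Empty intersections are permitted and flagged
#' with a warning, not an error.
#'
#' @param t1c_masks named masks from [segment_map()] on post-contrast T1
#'   (`necrotic`, `non_en`, `CE`).
#' @param md_masks named masks (`LMD`, `HMD`).
#' @param rcbv_masks named masks (`LrCBV`, `HrCBV`).
#' @param tumor_mask logical array.
#' @param voxel_size voxel edge lengths (mm).
#' @return Object of class `roi_catalog` with `masks` (the ten ROIs) and
#'   `voxel_size`.
#' @export
build_roi_catalog <- function(t1c_masks, md_masks, rcbv_masks, tumor_mask,
                              voxel_size) {
  all_masks <- c(t1c_masks, md_masks, rcbv_masks)
  for (m in all_masks)
    if (!identical(dim(m), dim(tumor_mask))) stopf("mask shapes differ")
  ce <- t1c_masks$CE; nec <- t1c_masks$necrotic
  lmd <- md_masks$LMD; hmd <- md_masks$HMD; lr <- rcbv_masks$LrCBV
  masks <- list(
    CE = ce, non_en = t1c_masks$non_en, necrotic = nec,
    LMD = lmd, HMD = hmd, LrCBV = lr,
    LMD_LrCBV_CE = lmd & lr & ce,
    LMD_LrCBV_nec = lmd & lr & nec,
    HMD_LrCBV_nec = hmd & lr & nec,
    En_HrCBV = ce & !lr & tumor_mask)
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty))
    warnf("empty habitat ROI(s): %s", paste(empty, collapse = ", "))
  structure(list(masks = masks, voxel_size = voxel_size),
            class = "roi_catalog")
}

#' @export
print.roi_catalog <- function(x, ...) {
  counts <- vapply(x$masks, sum, numeric(1))
  cat("<roi_catalog>\n")
  print(counts)
  invisible(x)
}

#' Segment one subject end to end
#'
#' Convenience wrapper: rCBV normalization, the three per-map k-means
#' segmentations and the ROI catalog.
#'
#' @param subject a `subject_volumes` object (see [generate_subject()]).
#' @param seed integer seed.
#' @param slicewise see [segment_map()].
#' @param ... passed to [kmeans_scalar()].
#' @return A `roi_catalog`.
#' @export
segment_subject <- function(subject, seed = 1, slicewise = FALSE, ...) {
  stopifnot(inherits(subject, "subject_volumes"))
  rcbv <- normalize_rcbv(subject$maps$CBV, subject$nawm_mask)
  tm <- subject$tumor_mask
  t1c <- segment_map(subject$maps$T1c, tm, 3,
                     c("necrotic", "non_en", "CE"),
                     seed = derive_seed(seed, 1), slicewise = slicewise, ...)
  md <- segment_map(subject$maps$MD, tm, 2, c("LMD", "HMD"),
                    seed = derive_seed(seed, 2), slicewise = slicewise, ...)
  rc <- segment_map(rcbv, tm, 2, c("LrCBV", "HrCBV"),
                    seed = derive_seed(seed, 3), slicewise = slicewise, ...)
  build_roi_catalog(t1c, md, rc, tm, subject$voxel_size)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
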