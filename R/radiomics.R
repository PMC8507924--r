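#' Histogram statistics of ROI intensities
#'
#' Mean, sample standard deviation (n-1), moment skewness
#' `g1 = m3 / m2^1.5` and excess kurtosis `g2 = m4 / m2^2 - 3`, with central
#' moments `mk`. With fewer than 3 voxels or zero variance, skewness and
#' kurtosis are `NA` (imputed downstream); an empty input gives all `NA`.
#'
#' @param values numeric vector.
#' @return Named numeric: `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
histogram_stats <- function(values) {
  n <- length(values)
  if (n == 0)
    return(c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
             kurtosis = NA_real_))
  mu <- mean(values)
  if (n == 1)
    return(c(mean = mu, sd = NA_real_, skewness = NA_real_,
             kurtosis = NA_real_))
  d <- values - mu
  m2 <- mean(d^2)
  out <- c(mean = mu, sd = sd(values), skewness = NA_real_,
           kurtosis = NA_real_)
  if (n >= 3 && m2 > 0) {
    out["skewness"] <- mean(d^3) / m2^1.5
    out["kurtosis"] <- mean(d^4) / m2^2 - 3
  }
  out
}

#' Quantize ROI intensities to gray levels
#'
#' Equal-width bins over the ROI's own `[min, max]` range; a degenerate
#' range maps every voxel to level 1.
#'
#' @param values numeric vector (must be non-empty).
#' @param n_levels number of gray levels (>= 2).
#' @return Integer levels in `1..n_levels`.
#' @export
quantize_roi <- function(values, n_levels = 32) {
  if (length(values) == 0) stopf("cannot quantize an empty ROI")
  if (n_levels < 2) stopf("n_levels must be >= 2")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  lev <- floor((values - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L
  pmin.int(lev, n_levels)
}

#' Gray-level co-occurrence (GLCM) texture features
#'
#' Accumulates co-occurrence counts of in-ROI level pairs over all axial
#' slices and all offsets, symmetrically (each pair counted in both
#' directions), pools them into one matrix normalized to sum 1, and returns
#' contrast `sum p(i,j) (i-j)^2`, correlation
#' `sum p(i,j)(i-mu_i)(j-mu_j)/(sigma_i sigma_j)` (defined as 0 when a
#' marginal SD is 0), energy `sum p^2` and homogeneity
#' `sum p / (1 + |i-j|)`. With zero valid pairs all features are `NA`.
#'
#' @param level_image 2-D or 3-D integer array of gray levels with `NA`
#'   outside the ROI.
#' @param offsets list of in-plane displacement vectors `c(dr, dc)`
#'   (default: the four distance-1 directions).
#' @param n_levels number of gray levels spanned by `level_image`.
#' @return Named numeric: `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
glcm_features <- function(level_image,
                          offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                         c(1L, -1L)),
                          n_levels = 32) {
  d <- dim(level_image)
  if (length(d) == 2) { dim(level_image) <- c(d, 1L); d <- dim(level_image) }
  L <- n_levels
  counts <- numeric(L * L)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(d[1], d[1] - dr)
    c1 <- max(1, 1 - dc):min(d[2], d[2] - dc)
    if (!length(r1) || !length(c1)) next
    a <- level_image[r1, c1, , drop = FALSE]
    b <- level_image[r1 + dr, c1 + dc, , drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ai <- a[ok]; bi <- b[ok]
    counts <- counts + tabulate((ai - 1L) * L + bi, nbins = L * L) +
      tabulate((bi - 1L) * L + ai, nbins = L * L)
  }
  tot <- sum(counts)
  if (tot == 0)
    return(c(contrast = NA_real_, correlation = NA_real_, energy = NA_real_,
             homogeneity = NA_real_))
  p <- matrix(counts / tot, L, L)
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu_i <- sum(seq_len(L) * pi_)
  sd_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_))
  # symmetric matrix: marginals coincide
  corr <- if (sd_i > 0) sum(p * (i - mu_i) * (j - mu_i)) / sd_i^2 else 0
  c(contrast = sum(p * (i - j)^2),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))))
}

#' Per-ROI absolute and relative volumes
#'
#' Absolute volume is voxel count x voxel volume / 1000 (cm^3); relative
#' volume divides by the whole-tumor absolute volume. Besides the ten
#' catalog ROIs, the tumor-wide low-diffusivity/low-perfusion intersection
#' `LMD_LrCBV` (the habitat whose volume the group tables report) and the
#' whole tumor are included.
#'
#' @param catalog a `roi_catalog`.
#' @param tumor_mask logical array.
#' @param voxel_size voxel edge lengths (mm).
#' @return Data frame (class `volume_report`) with columns `roi`,
#'   `absolute_cm3`, `relative`.
#' @export
roi_volumes <- function(catalog, tumor_mask, voxel_size) {
  stopifnot(inherits(catalog, "roi_catalog"))
  if (!any(tumor_mask)) stopf("tumor mask is empty")
  vx <- prod(voxel_size) / 1000
  masks <- c(catalog$masks,
             list(LMD_LrCBV = catalog$masks$LMD & catalog$masks$LrCBV,
                  tumor = tumor_mask))
  tumor_abs <- sum(tumor_mask) * vx
  out <- data.frame(
    roi = names(masks),
    absolute_cm3 = vapply(masks, function(m) sum(m) * vx, numeric(1)),
    relative = vapply(masks, function(m) sum(m) * vx / tumor_abs,
                      numeric(1)))
  rownames(out) <- NULL
  class(out) <- c("volume_report", "data.frame")
  out
}

map_names <- function() c("T1c", "T2", "MD", "FA", "CBV", "CBF")
roi_names <- function() c("CE", "non_en", "necrotic", "LMD", "HMD", "LrCBV",
                          "LMD_LrCBV_CE", "LMD_LrCBV_nec", "HMD_LrCBV_nec",
                          "En_HrCBV")
#' Extract the fused per-subject radiomic feature vector
#'
#' For each of the 10 habitat ROIs and each of the 6 maps: 4 histogram
#' statistics plus 4 GLCM texture features, i.e. exactly 480 named values
#' `"{roi}__{map}__{feature}"`. The CBV map is normalized to rCBV before
#' extraction. An empty ROI yields `NA` for its 48 features (imputed at
#' table assembly).
#'
#' @param subject a `subject_volumes` object.
#' @param catalog a `roi_catalog`.
#' @param config list: `n_levels` (gray levels, default 32) and `offsets`
#'   (GLCM displacement vectors).
#' @return Named numeric vector of length 480.
#' @export
extract_subject_features <- function(subject, catalog,
                                     config = list()) {
  stopifnot(inherits(subject, "subject_volumes"),
            inherits(catalog, "roi_catalog"))
  n_levels <- config$n_levels %||% 32
  offsets <- config$offsets %||% list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                      c(1L, -1L))
  missing_maps <- setdiff(map_names(), names(subject$maps))
  if (length(missing_maps))
    stopf("missing map(s): %s", paste(missing_maps, collapse = ", "))
  missing_rois <- setdiff(roi_names(), names(catalog$masks))
  if (length(missing_rois))
    stopf("missing ROI(s): %s", paste(missing_rois, collapse = ", "))

  maps <- subject$maps
  maps$CBV <- normalize_rcbv(maps$CBV, subject$nawm_mask)
  out <- numeric(0)
  for (roi in roi_names()) {
    mask <- catalog$masks[[roi]]
    nvox <- sum(mask)
    for (mp in map_names()) {
      vals <- maps[[mp]][mask]
      hs <- histogram_stats(vals)
      gl <- if (nvox > 0) {
        lev <- array(NA_integer_, dim(mask))
        lev[mask] <- quantize_roi(vals, n_levels)
        glcm_features(lev, offsets, n_levels)
      } else {
        c(contrast = NA_real_, correlation = NA_real_, energy = NA_real_,
          homogeneity = NA_real_)
      }
      v <- c(hs, gl)
      names(v) <- paste(roi, mp, names(v), sep = "__")
      out <- c(out, v)
    }
  }
  out
}

#' Assemble the cohort feature table
#'
#' Binds per-subject feature vectors, imputes missing entries by the
#' per-column cohort median, drops all-missing columns with a warning, and
#' stores both the imputed raw matrix and a per-column z-scored copy.
#' Cross-validation refits the standardization on each training fold; the
#' stored z-scored matrix is for whole-cohort summaries.
#'
#' @param vectors list of equally named feature vectors
#'   (see [extract_subject_features()]).
#' @param labels survival classes, one per subject (two levels; `"short"`
#'   is the positive class).
#' @param imputation `"median"` (only policy implemented).
#' @return Object of class `feature_table`: `x` (z-scored), `x_raw`
#'   (imputed, unscaled), `labels` (factor), `subject_ids`, `dropped`.
#' @export
assemble_feature_table <- function(vectors, labels, imputation = "median") {
  imputation <- match.arg(imputation, "median")
  if (length(vectors) != length(labels))
    stopf("need one label per subject (%d vectors, %d labels)",
          length(vectors), length(labels))
  if (anyNA(labels)) stopf("missing survival label")
  nm <- names(vectors[[1]])
  for (v in vectors)
    if (!identical(names(v), nm)) stopf("feature vectors differ in names")
  x <- do.call(rbind, vectors)
  colnames(x) <- nm
  rownames(x) <- names(vectors) %||% sprintf("sub-%03d", seq_len(nrow(x)))
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warnf("dropping %d all-missing feature column(s)", sum(all_na))
    x <- x[, !all_na, drop = FALSE]
  }
  x_raw <- apply(x, 2, function(col) {
    col[is.na(col)] <- median(col, na.rm = TRUE)
    col
  })
  z <- standardize_cols(x_raw)
  labels <- factor(as.character(labels))
  if (nlevels(labels) > 2) stopf("labels must be binary")
  if (all(c("short", "long") %in% levels(labels)))
    labels <- factor(labels, levels = c("long", "short")) # short = positive
  structure(list(x = z$x, x_raw = x_raw, labels = labels,
                 subject_ids = rownames(x),
                 dropped = nm[all_na]),
            class = "feature_table")
}

# z-score columns; zero-variance columns become all-zero.
standardize_cols <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d subjects x %d features (%s)>\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", levels(x$labels),
                            tabulate(x$labels, nlevels(x$labels))),
                    collapse = ", ")))
  invisible(x)
}

#' Extract the full cohort feature table from generated subjects
#'
#' Segmentation ([segment_subject()]) plus feature extraction and fusion for
#' every subject of a generated cohort.
#'
#' @param cohort result of [generate_cohort()].
#' @param seed integer seed (per-subject segmentation seeds derive from it).
#' @param config radiomics options, see [extract_subject_features()].
#' @param slicewise see [segment_map()].
#' @return A [assemble_feature_table()] result.
#' @export
cohort_feature_table <- function(cohort, seed = 1, config = list(),
                                 slicewise = FALSE) {
  vecs <- list(); labs <- character(0)
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    cat_i <- suppressWarnings(
      segment_subject(sub$volumes, seed = derive_seed(seed, i),
                      slicewise = slicewise))
    vecs[[cohort$manifest$subject_id[i]]] <-
      extract_subject_features(sub$volumes, cat_i, config)
    labs <- c(labs, sub$truth$survival_class)
  }
  assemble_feature_table(vecs, labs)
}
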