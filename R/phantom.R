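#' Per-group generative model for synthetic tumor phantoms
#'
#' Describes one survival group of the synthetic cohort: the distribution of
#' habitat volumes, the per-compartment map intensities, the voxel noise, and
#' the survival cutoff. Defaults reproduce the published group statistics of
#' the study cohort this generator emulates: five sub-ROI volumes
#' (enhancing `En`, necrotic `Nec`, tumor-wide low-diffusivity/low-perfusion
#' `LMD_LrCBV`, high-diffusivity/low-perfusion-in-necrosis `HMD_LrCBV`,
#' enhancing/high-perfusion `En_HrCBV`) are drawn with the reported group
#' means and SDs, and the whole-tumor volume is derived as the sum of
#' compartments plus a non-enhancing filler whose mean calibrates the
#' whole-tumor mean to its reported value (the whole-tumor SD is emergent;
#' see the methods vignette for why the reported compartment SDs and a
#' whole-tumor SD of ~5 cm^3 cannot jointly hold under per-subject volume
#' accounting).
#'
#' Sub-habitats that must fit inside a parent compartment (`HMD_LrCBV`
#' inside `Nec`, `En_HrCBV` inside `En`) are drawn as
#' `parent * cap * Beta(a, b)` with the Beta moment-matched so the child's
#' marginal mean and SD equal the requested values while the child never
#' exceeds `cap = 0.9` of its parent; this avoids reject/redraw bias.
#'
#' @param group `"short"` or `"long"` survival group.
#' @param volume_params data frame with columns `roi`, `mean`, `sd` (cm^3)
#'   for rois `En`, `Nec`, `LMD_LrCBV`, `HMD_LrCBV`, `En_HrCBV`, `tumor`.
#'   Defaults to the published group values.
#' @param lmd_lrcbv_nec_mean,lmd_lrcbv_nec_sd mean/SD (cm^3) of the
#'   low-diffusivity/low-perfusion sub-habitat inside necrosis (not reported
#'   in the published group tables; small positive default).
#' @param intensity_params per-map intensity model, see
#'   [default_intensity_params()].
#' @param noise_sd named numeric, additive voxel noise SD per map.
#' @param survival_cutoff_months dichotomization cutoff (months).
#' @return An object of class `group_model`.
#' @export
group_model <- function(group = c("short", "long"),
                        volume_params = NULL,
                        lmd_lrcbv_nec_mean = 0.30,
                        lmd_lrcbv_nec_sd = 0.10,
                        intensity_params = NULL,
                        noise_sd = NULL,
                        survival_cutoff_months = 15) {
  group <- match.arg(group)
  if (is.null(volume_params)) volume_params <- default_volume_params(group)
  if (is.null(intensity_params))
    intensity_params <- default_intensity_params(group)
  if (is.null(noise_sd)) noise_sd <- default_noise_sd()

  need <- c("En", "Nec", "LMD_LrCBV", "HMD_LrCBV", "En_HrCBV", "tumor")
  if (!all(need %in% volume_params$roi))
    stopf("volume_params must contain rois: %s", paste(need, collapse = ", "))
  vp <- volume_params[match(need, volume_params$roi), ]
  if (any(vp$sd < 0)) stopf("volume SDs must be >= 0")
  if (any(vp$mean <= 0)) stopf("volume means must be > 0")
  if (survival_cutoff_months <= 0) stopf("survival cutoff must be > 0")
  vm <- setNames(vp$mean, vp$roi); vs <- setNames(vp$sd, vp$roi)
  if (vm["HMD_LrCBV"] > vm["Nec"])
    stopf("HMD_LrCBV mean volume exceeds its parent compartment (Nec)")
  if (vm["En_HrCBV"] > vm["En"])
    stopf("En_HrCBV mean volume exceeds its parent compartment (En)")
  if (vm["LMD_LrCBV"] > vm["tumor"])
    stopf("LMD_LrCBV mean volume exceeds the tumor volume")
  if (any(noise_sd < 0)) stopf("noise_sd must be >= 0")

  cap <- 0.9
  model <- structure(list(
    group_name = group,
    volume_params = vp,
    lmd_lrcbv_nec = c(mean = lmd_lrcbv_nec_mean, sd = lmd_lrcbv_nec_sd),
    beta_hl = beta_product_params(vm["HMD_LrCBV"], vs["HMD_LrCBV"],
                                  vm["Nec"], vs["Nec"], cap),
    beta_eh = beta_product_params(vm["En_HrCBV"], vs["En_HrCBV"],
                                  vm["En"], vs["En"], cap),
    cap = cap,
    intensity_params = intensity_params,
    noise_sd = noise_sd,
    survival_cutoff_months = survival_cutoff_months
  ), class = "group_model")
  model$slack_mean <- slack_mean_for(model)
  model
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model: %s-term survival group (cutoff %g months)>\n",
              x$group_name, x$survival_cutoff_months))
  print(x$volume_params, row.names = FALSE)
  invisible(x)
}

# Published group volume statistics (cm^3). `LMD_LrCBV` is tumor-wide
# LMD intersect LrCBV; `HMD_LrCBV` is the within-necrosis ROI.
default_volume_params <- function(group) {
  if (group == "short") {
    data.frame(roi = c("En", "Nec", "LMD_LrCBV", "HMD_LrCBV", "En_HrCBV",
                       "tumor"),
               mean = c(1.51, 2.07, 3.20, 1.01, 0.65, 6.02),
               sd = c(0.45, 0.59, 0.73, 0.49, 0.37, 5.1))
  } else {
    data.frame(roi = c("En", "Nec", "LMD_LrCBV", "HMD_LrCBV", "En_HrCBV",
                       "tumor"),
               mean = c(1.26, 2.64, 2.47, 1.95, 0.42, 6.07),
               sd = c(0.41, 0.65, 0.88, 0.77, 0.23, 5.4))
  }
}

#' Default per-map intensity model for the phantom generator
#'
#' Intensities are in arbitrary map units (MD in um^2/ms, CBV normalized so
#' NAWM has unit mean). Each map is keyed by one voxel classification:
#' `compartment` (necrotic / non-enhanced / contrast-enhanced),
#' `md_class` (LMD / HMD) or `cbv_class` (LrCBV / HrCBV). Per subject, each
#' class mean is perturbed by a between-subject SD; voxels then receive
#' additive noise (`noise_sd` of the [group_model()]). Group contrasts follow
#' the reported effect directions: the short-term group has lower MD and
#' higher rCBV/CBF in the low-perfusion classes and higher T2 in necrosis.
#' Magnitudes (about 1.5 between-subject SDs for the MD and rCBV contrasts)
#' are a design choice documented in the methods vignette.
#'
#' @param group `"short"` or `"long"`.
#' @return Named list, one entry per map, with fields `key`, `mean`
#'   (named per-class vector) and `between_sd`.
#' @export
default_intensity_params <- function(group = c("short", "long")) {
  group <- match.arg(group)
  s <- group == "short"
  list(
    T1c = list(key = "compartment",
               mean = c(necrotic = 40, non_en = 100, CE = 180),
               between_sd = c(necrotic = 8, non_en = 8, CE = 8)),
    T2 = list(key = "compartment",
              mean = c(necrotic = if (s) 165 else 157, non_en = 125,
                       CE = if (s) 112 else 108),
              between_sd = c(necrotic = 8, non_en = 8, CE = 8)),
    MD = list(key = "md_class",
              mean = c(LMD = if (s) 0.70 else 0.78, HMD = 1.30),
              between_sd = c(LMD = 0.055, HMD = 0.08)),
    FA = list(key = "compartment",
              mean = c(necrotic = 0.10, non_en = 0.22, CE = 0.30),
              between_sd = c(necrotic = 0.03, non_en = 0.03, CE = 0.03)),
    CBV = list(key = "cbv_class",
               mean = c(LrCBV = if (s) 1.05 else 0.72, HrCBV = 3.0),
               between_sd = c(LrCBV = 0.22, HrCBV = 0.40)),
    CBF = list(key = "cbv_class",
               mean = c(LrCBV = if (s) 35 else 28, HrCBV = 90),
               between_sd = c(LrCBV = 6, HrCBV = 12))
  )
}

default_noise_sd <- function() {
  c(T1c = 10, T2 = 9, MD = 0.12, FA = 0.04, CBV = 0.25, CBF = 10)
}

# Reference values painted outside the tumor.
nawm_means <- function() {
  c(T1c = 80, T2 = 100, MD = 0.78, FA = 0.45, CBV = 1.0, CBF = 25)
}
background_means <- function() {
  c(T1c = 70, T2 = 90, MD = 0.85, FA = 0.30, CBV = 1.2, CBF = 30)
}

# Moment-match Beta(a, b) so that child = cap * parent * B has the requested
# marginal mean/SD given the parent's mean/SD, with B independent of parent.
beta_product_params <- function(child_mean, child_sd, parent_mean, parent_sd,
                                cap = 0.9) {
  child_mean <- unname(child_mean); child_sd <- unname(child_sd)
  parent_mean <- unname(parent_mean); parent_sd <- unname(parent_sd)
  m <- child_mean / (cap * parent_mean)
  if (m <= 0 || m >= 1)
    stopf("child volume mean must lie in (0, %g x parent mean)", cap)
  e2 <- (child_sd^2 + child_mean^2) / (cap^2 * (parent_sd^2 + parent_mean^2))
  v <- e2 - m^2
  if (v < 1e-12) return(c(a = Inf, b = Inf, m = m))
  if (v >= m * (1 - m))
    stopf("child volume SD too large for a Beta product inside the parent")
  nu <- m * (1 - m) / v - 1
  c(a = m * nu, b = (1 - m) * nu, m = m)
}

rbeta_pp <- function(n, par) {
  if (!is.finite(par[["a"]])) return(rep(par[["m"]], n))
  rbeta(n, par[["a"]], par[["b"]])
}

# Expected non-enhancing filler mean that calibrates the whole-tumor mean,
# evaluated by plugging group means into the allocation rule (the min() terms
# make this an approximation; the residual bias is well under the whole-tumor
# sampling error).
slack_mean_for <- function(model) {
  vm <- setNames(model$volume_params$mean, model$volume_params$roi)
  x2 <- min(model$lmd_lrcbv_nec[["mean"]],
            0.5 * (vm["Nec"] - vm["HMD_LrCBV"]), 0.3 * vm["LMD_LrCBV"])
  x1 <- min(0.2 * vm["LMD_LrCBV"], 0.8 * (vm["En"] - vm["En_HrCBV"]),
            vm["LMD_LrCBV"] - x2)
  x3 <- vm["LMD_LrCBV"] - x1 - x2
  base <- vm["En"] + vm["Nec"] + x3
  unname(max(vm["tumor"] - base, 0.2))
}

#' Draw ground-truth habitat volumes for one group
#'
#' Samples the per-subject volume decomposition (cm^3) that
#' [generate_subject()] voxelizes, without building any image. Useful for
#' fast calibration checks of the volume distributions.
#'
#' @param model a [group_model()].
#' @param n number of subjects.
#' @return Data frame with one row per subject: compartment volumes (`En`,
#'   `Nec`, `non_en`, `tumor`), Table-style ROI volumes (`LMD_LrCBV`,
#'   `HMD_LrCBV`, `En_HrCBV`) and the internal allocation
#'   (`LMD_LrCBV_CE`, `LMD_LrCBV_nec`, `LMD_LrCBV_non`, fillers).
#' @export
draw_group_volumes <- function(model, n = 1) {
  stopifnot(inherits(model, "group_model"))
  vm <- setNames(model$volume_params$mean, model$volume_params$roi)
  vs <- setNames(model$volume_params$sd, model$volume_params$roi)
  vEn <- rtnorm_lower(n, vm["En"], vs["En"], 0.05)
  vNec <- rtnorm_lower(n, vm["Nec"], vs["Nec"], 0.05)
  vLL <- rtnorm_lower(n, vm["LMD_LrCBV"], vs["LMD_LrCBV"], 0.05)
  ll_nec_t <- rtnorm_lower(n, model$lmd_lrcbv_nec[["mean"]],
                           model$lmd_lrcbv_nec[["sd"]], 0.01)
  vHL <- model$cap * vNec * rbeta_pp(n, model$beta_hl)
  vEH <- model$cap * vEn * rbeta_pp(n, model$beta_eh)

  x2 <- pmin(ll_nec_t, 0.5 * (vNec - vHL), 0.3 * vLL)
  x1 <- pmin(0.2 * vLL, 0.8 * (vEn - vEH), vLL - x2)
  x3 <- vLL - x1 - x2
  rem_nec <- vNec - vHL - x2  # HMD/HrCBV filler inside necrosis
  rem_ce <- vEn - vEH - x1    # LMD/HrCBV filler inside enhancing rim
  slack <- rgamma(n, shape = 2, scale = model$slack_mean / 2)
  non_en <- x3 + slack
  tumor <- vEn + vNec + non_en
  data.frame(En = vEn, Nec = vNec, non_en = non_en, tumor = tumor,
             LMD_LrCBV = vLL, HMD_LrCBV = vHL, En_HrCBV = vEH,
             LMD_LrCBV_CE = x1, LMD_LrCBV_nec = x2, LMD_LrCBV_non = x3,
             nec_filler = rem_nec, ce_filler = rem_ce, non_filler = slack)
}

#' Cohort-level phantom specification
#'
#' @param grid_shape integer voxel grid per axis (default 64^3).
#' @param voxel_size voxel edge lengths in mm (default 1 mm isotropic).
#' @param n_short,n_long subjects per survival group (defaults 16 / 13, the
#'   emulated cohort split).
#' @param seed integer; all per-subject seeds derive from it.
#' @param group_models named list with `short` and `long` [group_model()]s.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = c(1, 1, 1),
                         n_short = 16L, n_long = 13L, seed = 1L,
                         group_models = list(short = group_model("short"),
                                             long = group_model("long"))) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("grid_shape must be three axis lengths >= 8")
  if (any(voxel_size <= 0)) stopf("voxel_size must be strictly positive")
  if (n_short + n_long < 1) stopf("cohort must contain at least one subject")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 n_short = as.integer(n_short), n_long = as.integer(n_long),
                 seed = as.integer(seed), group_models = group_models),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec: %d short + %d long subjects, grid %s @ %s mm, seed %d>\n",
    x$n_short, x$n_long, paste(x$grid_shape, collapse = "x"),
    paste(x$voxel_size, collapse = "x"), x$seed))
  invisible(x)
}

# Seeded stochastic region growing: pick `n_target` voxels from
# `parent` (linear indices into a dims grid), connected 6-neighbourhood
# waves from a random interior seed; jumps to a fresh seed if the available
# region disconnects. Exact target size by partial sampling of the last wave.
region_grow <- function(parent, n_target, dims) {
  n_target <- as.integer(n_target)
  if (n_target <= 0) return(integer(0))
  if (n_target > length(parent))
    stopf("region growing target (%d voxels) exceeds its parent compartment (%d voxels)",
          n_target, length(parent))
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  offs <- c(-1L, 1L, -nx, nx, -nxy, nxy)
  avail <- logical(prod(dims)); avail[parent] <- TRUE
  sel <- integer(0)
  frontier <- parent[sample.int(length(parent), 1L)]
  avail[frontier] <- FALSE
  while (length(sel) < n_target) {
    if (length(frontier) == 0L) { # disconnected remainder: jump
      rest <- which(avail)
      frontier <- rest[sample.int(length(rest), 1L)]
      avail[frontier] <- FALSE
    }
    need <- n_target - length(sel)
    if (length(frontier) > need)
      frontier <- frontier[sample.int(length(frontier), need)]
    sel <- c(sel, frontier)
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[nb >= 1L & nb <= length(avail)]
    nb <- nb[avail[nb]]
    avail[nb] <- FALSE
    frontier <- nb
  }
  sel
}

# Smallest-ellipsoidal-radius ordering of all voxels around a center.
ellipsoid_order <- function(dims, center, axes) {
  cx <- (seq_len(dims[1]) - center[1]) / axes[1]
  cy <- (seq_len(dims[2]) - center[2]) / axes[2]
  cz <- (seq_len(dims[3]) - center[3]) / axes[3]
  rho2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  order(rho2)
}

#' Generate one synthetic multimodal tumor subject
#'
#' Builds the six co-registered maps (T1c, T2, MD, FA, CBV, CBF), the tumor
#' and NAWM masks, and the voxel-level ground truth for one subject of a
#' survival group. The tumor is an ellipsoid with a necrotic core, an
#' enhancing shell and a non-enhancing margin; sub-habitats are placed by
#' seeded region growing inside their parent compartment until the drawn
#' target voxel count is reached; intensities are painted per class and
#' perturbed by voxel noise. Identical `(spec, model, subject_seed)` give
#' bitwise-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param model the subject's [group_model()].
#' @param subject_seed integer seed for this subject.
#' @return List with elements `volumes` (class `subject_volumes`: `maps`,
#'   `tumor_mask`, `nawm_mask`, `voxel_size`) and `truth` (class
#'   `ground_truth`: `compartment_labels` (0 background / 1 necrotic /
#'   2 non-enhanced / 3 enhancing), `subhabitat_masks`, `md_class`,
#'   `cbv_class`, `true_volumes`, `target_volumes`, `survival_class`).
#' @export
generate_subject <- function(spec, model, subject_seed) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "group_model"))
  with_seed(subject_seed, {
    dims <- spec$grid_shape
    vx_cm3 <- prod(spec$voxel_size) / 1000
    vols <- draw_group_volumes(model, 1)
    cnt <- function(v) max(0L, as.integer(round(v / vx_cm3)))

    n_hl <- cnt(vols$HMD_LrCBV); n_x2 <- cnt(vols$LMD_LrCBV_nec)
    n_necf <- cnt(vols$nec_filler)
    n_eh <- cnt(vols$En_HrCBV); n_x1 <- cnt(vols$LMD_LrCBV_CE)
    n_cef <- cnt(vols$ce_filler)
    n_x3 <- cnt(vols$LMD_LrCBV_non); n_nonf <- cnt(vols$non_filler)
    n_nec <- n_hl + n_x2 + n_necf
    n_en <- n_eh + n_x1 + n_cef
    n_non <- n_x3 + n_nonf
    n_t <- n_nec + n_en + n_non
    if (min(n_nec, n_en, n_non) < 1L)
      stopf("drawn volumes give an empty compartment; enlarge the volume means or shrink voxels")

    center <- round(dims * c(0.32, 0.5, 0.5))
    ord <- ellipsoid_order(dims, center, c(1, 0.9, 0.8))
    if (n_t > length(ord)) stopf("grid too small for the drawn tumor volume")
    tum_idx <- ord[seq_len(n_t)]
    ijk <- arrayInd(tum_idx, dims)
    if (any(ijk == 1L) || any(sweep(ijk, 2, dims) == 0L))
      stopf("grid too small: tumor touches the grid boundary")

    nec_idx <- tum_idx[seq_len(n_nec)]
    en_idx <- tum_idx[n_nec + seq_len(n_en)]
    non_idx <- tum_idx[n_nec + n_en + seq_len(n_non)]

    hl_idx <- region_grow(nec_idx, n_hl, dims)
    x2_idx <- region_grow(setdiff(nec_idx, hl_idx), n_x2, dims)
    eh_idx <- region_grow(en_idx, n_eh, dims)
    x1_idx <- region_grow(setdiff(en_idx, eh_idx), n_x1, dims)
    x3_idx <- region_grow(non_idx, n_x3, dims)

    nv <- prod(dims)
    comp <- integer(nv)
    comp[nec_idx] <- 1L; comp[non_idx] <- 2L; comp[en_idx] <- 3L

    # voxel classes driving the MD and CBV maps. Fillers are HMD/LrCBV in
    # the enhancing rim and HMD/HrCBV elsewhere, so each named ground-truth
    # sub-habitat coincides exactly with its class-intersection definition
    # (e.g. CE minus LrCBV equals the grown En_HrCBV blob).
    lmd <- logical(nv); lrcbv <- logical(nv)
    ll_idx <- c(x1_idx, x2_idx, x3_idx)
    cef_idx <- setdiff(en_idx, c(eh_idx, x1_idx))
    lmd[ll_idx] <- TRUE
    lrcbv[c(ll_idx, hl_idx, cef_idx)] <- TRUE

    # NAWM: contralateral ellipsoid, clear of the tumor
    nawm_center <- round(dims * c(0.78, 0.5, 0.5))
    nawm_idx <- ellipsoid_order(dims, nawm_center, c(1, 1, 1))[seq_len(
      max(200L, as.integer(round(1 / vx_cm3))))]
    nawm_idx <- setdiff(nawm_idx, tum_idx)

    tumor_mask <- array(FALSE, dims); tumor_mask[tum_idx] <- TRUE
    nawm_mask <- array(FALSE, dims); nawm_mask[nawm_idx] <- TRUE

    in_tum <- logical(nv); in_tum[tum_idx] <- TRUE
    class_of <- function(key) {
      cls <- integer(nv)
      if (key == "compartment") cls <- comp
      else if (key == "md_class") cls[in_tum] <- ifelse(lmd[in_tum], 1L, 2L)
      else cls[in_tum] <- ifelse(lrcbv[in_tum], 1L, 2L)
      cls
    }
    key_levels <- list(compartment = c("necrotic", "non_en", "CE"),
                       md_class = c("LMD", "HMD"),
                       cbv_class = c("LrCBV", "HrCBV"))

    nw_mu <- nawm_means(); bg_mu <- background_means()
    maps <- lapply(names(model$intensity_params), function(mp) {
      ip <- model$intensity_params[[mp]]
      lev <- key_levels[[ip$key]]
      subj_mu <- rnorm(length(lev), ip$mean[lev], ip$between_sd[lev])
      nz <- model$noise_sd[[mp]]
      vals <- rnorm(nv, bg_mu[[mp]], nz)
      cls <- class_of(ip$key)
      for (k in seq_along(lev)) {
        vk <- which(cls == k)
        vals[vk] <- subj_mu[k] + (if (nz > 0) rnorm(length(vk), 0, nz) else 0)
      }
      vals[nawm_idx] <- nw_mu[[mp]] +
        (if (nz > 0) rnorm(length(nawm_idx), 0, nz) else 0)
      if (mp == "MD") vals <- pmax(vals, 1e-4)
      array(vals, dims)
    })
    names(maps) <- names(model$intensity_params)

    mk <- function(idx) { m <- array(FALSE, dims); m[idx] <- TRUE; m }
    true_vol <- c(
      En = n_en, Nec = n_nec, non_en = n_non, tumor = n_t,
      LMD_LrCBV = length(ll_idx), LMD_LrCBV_CE = n_x1, LMD_LrCBV_nec = n_x2,
      HMD_LrCBV = n_hl, En_HrCBV = n_eh) * vx_cm3
    target_vol <- c(
      En = vols$En, Nec = vols$Nec, non_en = vols$non_en, tumor = vols$tumor,
      LMD_LrCBV = vols$LMD_LrCBV, LMD_LrCBV_CE = vols$LMD_LrCBV_CE,
      LMD_LrCBV_nec = vols$LMD_LrCBV_nec, HMD_LrCBV = vols$HMD_LrCBV,
      En_HrCBV = vols$En_HrCBV)

    volumes <- structure(list(maps = maps, tumor_mask = tumor_mask,
                              nawm_mask = nawm_mask,
                              voxel_size = spec$voxel_size),
                         class = "subject_volumes")
    truth <- structure(list(
      compartment_labels = array(comp, dims),
      subhabitat_masks = list(LMD_LrCBV_CE = mk(x1_idx),
                              LMD_LrCBV_nec = mk(x2_idx),
                              HMD_LrCBV_nec = mk(hl_idx),
                              En_HrCBV = mk(eh_idx)),
      md_class = mk(which(lmd)),     # TRUE = LMD
      cbv_class = mk(which(lrcbv)),  # TRUE = LrCBV
      true_volumes = true_vol,
      target_volumes = target_vol,
      survival_class = model$group_name,
      voxel_size = spec$voxel_size), class = "ground_truth")
    list(volumes = volumes, truth = truth)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws `n_short + n_long` subjects with per-subject seeds derived
#' deterministically from `spec$seed`, and a manifest of ids, groups and
#' ground-truth volumes.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir optional directory; if given, per-subject NIfTI maps and
#'   masks, ground-truth JSON and the manifest CSV are written there via
#'   [write_subject()].
#' @return List with `subjects` (list of [generate_subject()] results) and
#'   `manifest` (data frame).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  groups <- c(rep("short", spec$n_short), rep("long", spec$n_long))
  subjects <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sid <- sprintf("sub-%03d", i)
    res <- tryCatch(
      generate_subject(spec, spec$group_models[[groups[i]]],
                       derive_seed(spec$seed, i)),
      error = function(e) stopf("subject %s: %s", sid, conditionMessage(e)))
    subjects[[i]] <- res
    rows[[i]] <- data.frame(subject_id = sid, group = groups[i],
                            as.list(res$truth$true_volumes),
                            check.names = TRUE)
    if (!is.null(out_dir)) write_subject(res, sid, out_dir)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(subjects = subjects, manifest = manifest)
}

#' Write one generated subject to disk
#'
#' Gzipped NIfTI per map and mask plus a ground-truth JSON, under
#' `dir/subject_id/`.
#'
#' @param subject result of [generate_subject()].
#' @param subject_id directory-safe id.
#' @param dir output root.
#' @return The subject directory, invisibly.
#' @export
write_subject <- function(subject, subject_id, dir) {
  sdir <- file.path(dir, subject_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  vx <- subject$volumes$voxel_size
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr * 1, pixdim = vx)
    RNifti::writeNifti(img, file.path(sdir, paste0(name, ".nii.gz")))
  }
  for (mp in names(subject$volumes$maps)) wr(subject$volumes$maps[[mp]], mp)
  wr(subject$volumes$tumor_mask, "tumor_mask")
  wr(subject$volumes$nawm_mask, "nawm_mask")
  truth <- subject$truth
  jsonlite::write_json(
    list(survival_class = truth$survival_class,
         true_volumes = as.list(truth$true_volumes),
         target_volumes = as.list(truth$target_volumes)),
    file.path(sdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sdir)
}
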