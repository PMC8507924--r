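test_that("rCBV normalization divides by the NAWM mean", {
  arr <- array(4, c(4, 4, 2))
  nawm <- array(FALSE, c(4, 4, 2)); nawm[1:2, 1, 1] <- TRUE
  expect_equal(normalize_rcbv(arr, nawm), array(1, c(4, 4, 2)))

  arr2 <- array(2, c(4, 4, 2)); arr2[3, 3, 1] <- 6
  r <- normalize_rcbv(arr2, nawm)
  expect_equal(r[3, 3, 1], 3)
  expect_equal(mean(r[nawm]), 1)

  expect_error(normalize_rcbv(arr, array(FALSE, c(4, 4, 2))), "empty")
  expect_error(normalize_rcbv(-arr, nawm), "> 0")
  expect_error(normalize_rcbv(arr, nawm[, , 1, drop = FALSE]), "shape")
})

test_that("scalar k-means resolves separable clusters exactly", {
  cl <- kmeans_scalar(c(0, 0, 0, 10, 10), k = 2, seed = 1)
  expect_equal(cl$centers, c(0, 10))
  expect_equal(cl$inertia, 0)
  expect_equal(cl$labels, c(1, 1, 1, 2, 2))

  x <- c(1, 4, 9, 9, 4, 1)
  cl3 <- kmeans_scalar(x, k = 3, seed = 2)  # k = number of distinct values
  expect_equal(cl3$inertia, 0)
  expect_equal(cl3$centers, c(1, 4, 9))

  expect_error(kmeans_scalar(rep(5, 10), k = 2), "distinct")
  expect_error(kmeans_scalar(c(1, 2, 3), k = 4), "distinct")
})

test_that("restarted Lloyd matches the exact 1-D dynamic-programming optimum", {
  n_match <- 0
  n_trials <- 100
  for (s in seq_len(n_trials)) {
    set.seed(s)
    x <- c(rnorm(20, 0), rnorm(20, 3.5), rnorm(20, 8))
    cl <- kmeans_scalar(x, k = 3, n_init = 50, seed = s)
    opt <- dp_kmeans_1d(x, 3)
    expect_gte(cl$inertia, opt - 1e-8)
    if (cl$inertia <= opt + 1e-6 * (1 + opt)) n_match <- n_match + 1
  }
  expect_gte(n_match, 99)
})

test_that("cluster names bind to sorted centers, not input order", {
  vals <- c(rep(10, 50), rep(100, 60), rep(180, 40))
  tm <- array(FALSE, c(10, 15, 1)); tm[seq_along(vals)] <- TRUE
  mp <- array(0, c(10, 15, 1)); mp[tm] <- vals
  seg <- segment_map(mp, tm, 3, c("necrotic", "non_en", "CE"), seed = 1)
  expect_equal(sum(seg$necrotic), 50)
  expect_equal(sum(seg$non_en), 60)
  expect_equal(sum(seg$CE), 40)
  # shuffling the voxel order must not change the named masks
  set.seed(3)
  perm <- sample(which(tm))
  mp2 <- mp; mp2[perm] <- mp[which(tm)]
  seg2 <- segment_map(mp2, tm, 3, c("necrotic", "non_en", "CE"), seed = 9)
  expect_equal(sum(seg2$necrotic), 50)
  expect_equal(sum(seg2$CE), 40)
})

test_that("per-map cluster masks always partition the tumor", {
  sub <- small_subject(21)
  for (cfg in list(list(m = "T1c", k = 3, o = c("necrotic", "non_en", "CE")),
                   list(m = "MD", k = 2, o = c("LMD", "HMD")))) {
    seg <- segment_map(sub$volumes$maps[[cfg$m]], sub$volumes$tumor_mask,
                       cfg$k, cfg$o, seed = 4)
    total <- Reduce(`+`, lapply(seg, sum))
    expect_equal(total, sum(sub$volumes$tumor_mask))
    overlap <- Reduce(`+`, lapply(seg, function(m) m * 1))
    expect_true(all(overlap[sub$volumes$tumor_mask] == 1))
  }
  expect_error(segment_map(sub$volumes$maps$T1c * 0,
                           sub$volumes$tumor_mask, 2, c("a", "b")),
               "distinct")
})

test_that("noise-free phantom segmentation recovers ground truth exactly", {
  sub <- small_subject(31, noise_sd = zero_noise())
  cat0 <- suppressWarnings(segment_subject(sub$volumes, seed = 2))
  lab <- sub$truth$compartment_labels
  expect_equal(dice(cat0$masks$necrotic, lab == 1), 1.0)
  expect_equal(dice(cat0$masks$non_en, lab == 2), 1.0)
  expect_equal(dice(cat0$masks$CE, lab == 3), 1.0)
  expect_equal(dice(cat0$masks$LMD, sub$truth$md_class), 1.0)
  expect_equal(dice(cat0$masks$LrCBV, sub$truth$cbv_class), 1.0)
  for (nm in names(sub$truth$subhabitat_masks))
    expect_equal(dice(cat0$masks[[nm]], sub$truth$subhabitat_masks[[nm]]),
                 1.0)
})

test_that("default-noise segmentation stays close to ground truth", {
  sub <- small_subject(32)
  cat1 <- suppressWarnings(segment_subject(sub$volumes, seed = 2))
  lmd_true <- sub$truth$md_class
  expect_gte(dice(cat1$masks$LMD, lmd_true), 0.9)
  expect_gte(dice(cat1$masks$LrCBV, sub$truth$cbv_class), 0.9)
})

test_that("segmentation quality degrades monotonically with voxel noise", {
  base <- default_noise <- c(T1c = 10, T2 = 9, MD = 0.12, FA = 0.04,
                             CBV = 0.25, CBF = 10)
  scales <- c(0, 1, 3, 6)
  dices <- vapply(seq_along(scales), function(i) {
    sub <- generate_subject(small_spec(noise_sd = base * scales[i]),
                            small_group_model("short", base * scales[i]),
                            55)
    seg <- segment_map(sub$volumes$maps$MD, sub$volumes$tumor_mask, 2,
                       c("LMD", "HMD"), seed = 5)
    dice(seg$LMD, sub$truth$md_class)
  }, numeric(1))
  expect_true(all(diff(dices) <= 0.002))
  expect_lt(dices[length(dices)], dices[1])
})

test_that("ROI catalog obeys its intersection identities", {
  sub <- small_subject(33)
  cat1 <- suppressWarnings(segment_subject(sub$volumes, seed = 6))
  m <- cat1$masks
  tm <- sub$volumes$tumor_mask
  expect_equal(sum(m$CE) + sum(m$non_en) + sum(m$necrotic), sum(tm))
  expect_equal(sum(m$LMD) + sum(m$HMD), sum(tm))
  expect_identical(m$LMD_LrCBV_CE, m$LMD & m$LrCBV & m$CE)
  expect_identical(m$LMD_LrCBV_nec, m$LMD & m$LrCBV & m$necrotic)
  expect_identical(m$HMD_LrCBV_nec, m$HMD & m$LrCBV & m$necrotic)
  expect_identical(m$En_HrCBV, m$CE & !m$LrCBV & tm)
  for (nm in names(m)) expect_true(all(tm[m[[nm]]]))
})

test_that("catalog intersections with full sets collapse as expected", {
  sub <- small_subject(34)
  tm <- sub$volumes$tumor_mask
  none <- array(FALSE, dim(tm))
  t1c <- suppressWarnings(segment_map(sub$volumes$maps$T1c, tm, 3,
                                      c("necrotic", "non_en", "CE"),
                                      seed = 1))
  full_md <- list(LMD = tm, HMD = none)
  full_rc <- list(LrCBV = tm, HrCBV = none)
  cat1 <- suppressWarnings(
    build_roi_catalog(t1c, full_md, full_rc, tm, c(1, 1, 1)))
  expect_identical(cat1$masks$LMD_LrCBV_CE, t1c$CE)
  expect_equal(sum(cat1$masks$En_HrCBV), 0)
  expect_warning(build_roi_catalog(t1c, full_md, full_rc, tm, c(1, 1, 1)),
                 "empty")
  expect_error(build_roi_catalog(t1c, full_md, full_rc, tm[, , 1,
                                                           drop = FALSE],
                                 c(1, 1, 1)), "shape")
})

test_that("slicewise segmentation matches pooled on plateau maps", {
  sub <- small_subject(36, noise_sd = zero_noise())
  pooled <- segment_map(sub$volumes$maps$MD, sub$volumes$tumor_mask, 2,
                        c("LMD", "HMD"), seed = 3)
  sliced <- segment_map(sub$volumes$maps$MD, sub$volumes$tumor_mask, 2,
                        c("LMD", "HMD"), seed = 3, slicewise = TRUE)
  expect_gte(dice(pooled$LMD, sliced$LMD), 0.999)
})

test_that("dice overlap follows its definition", {
  a <- array(FALSE, c(3, 3, 1)); b <- a
  a[1:4] <- TRUE; b[1:4] <- TRUE
  expect_equal(dice(a, b), 1.0)
  b[] <- FALSE; b[5:6] <- TRUE
  expect_equal(dice(a, b), 0.0)
  b[] <- FALSE; b[3:8] <- TRUE  # |a|=4, |b|=6, overlap {3,4} = 2 -> 0.4
  expect_equal(dice(a, b), 2 * 2 / (4 + 6))
  a2 <- array(FALSE, c(3, 3, 1)); a2[c(1, 2, 3, 4)] <- TRUE
  b2 <- array(FALSE, c(3, 3, 1)); b2[c(2, 3, 4, 5, 6, 7)] <- TRUE
  expect_equal(dice(a2, b2), 0.6)  # intersection 3 of sizes 4 and 6
  expect_equal(dice(array(FALSE, c(2, 2)), array(FALSE, c(2, 2))), 1)
  expect_error(dice(a, array(FALSE, c(2, 2))), "shape")
})
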