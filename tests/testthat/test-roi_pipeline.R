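test_that("ROI averaging is the echo-wise mean and reports voxel count", {
  spec <- box_phantom(mono_params(100, 10), dims = c(4, 4, 1), noise = "none")
  syn <- synthesize_echo_series(spec, TE12)
  roi <- syn$truth$label_map > 0
  avg <- roi_average_decay(syn$series, roi)
  expect_equal(avg$n_voxels, 16)
  expect_equal(avg$signal, eval_mono(mono_params(100, 10), as.numeric(TE12)))
  # linearity: averaging s and (2*c - s) gives the constant c
  d <- array(0, c(2, 1, 1, 12))
  s <- eval_mono(mono_params(50, 5), as.numeric(TE12))
  d[1, 1, 1, ] <- s; d[2, 1, 1, ] <- 2 * 3 - s
  avg <- roi_average_decay(echo_series(d, TE12), array(TRUE, c(2, 1, 1)))
  expect_equal(avg$signal, rep(3, 12))
  expect_error(roi_average_decay(syn$series, array(FALSE, c(4, 4, 1))),
               "empty")
})

test_that("averaging n voxels cuts the noise SD by about sqrt(n)", {
  # 100-voxel slice at voxel SNR 35 -> residual SD around the true curve
  # should shrink ~10-fold
  spec <- box_phantom(mono_params(100, 10), dims = c(10, 10, 8), snr = 35,
                      seed = 55)
  syn <- synthesize_echo_series(spec, TE12)
  clean <- eval_mono(mono_params(100, 10), as.numeric(TE12))
  resid <- sapply(1:8, function(k) {
    roi <- array(FALSE, c(10, 10, 8)); roi[, , k] <- TRUE
    roi_average_decay(syn$series, roi)$signal - clean
  })
  emp_sd <- sd(as.numeric(resid))
  expect_equal(emp_sd, syn$truth$noise_sd / 10, tolerance = 0.2)
})

test_that("slice-wise ROI selection saturates on noise-free truth", {
  mask_all <- function(d) array(TRUE, d)
  spec_m <- box_phantom(mono_params(100, 10), dims = c(3, 3, 4), noise = "none")
  syn <- synthesize_echo_series(spec_m, TE12)
  res <- roi_fit_and_select(syn$series, roi = mask_all(c(3, 3, 4)))
  expect_equal(res$summary$pct_bi_aicc, 0)
  expect_equal(res$summary$pct_bi_ftest, 0)
  expect_equal(res$summary$n_slices, 4)
  expect_equal(res$summary$t2m_mean, 10, tolerance = 1e-6)

  spec_b <- box_phantom(bi_params(50, 50, 1.5, 15), dims = c(3, 3, 4),
                        noise = "none")
  syn <- synthesize_echo_series(spec_b, TE12)
  res <- roi_fit_and_select(syn$series, roi = mask_all(c(3, 3, 4)))
  expect_equal(res$summary$pct_bi_aicc, 100)
  expect_equal(res$summary$pct_bi_ftest, 100)
  expect_equal(res$summary$t2s_mean, 1.5, tolerance = 1e-3)
  expect_equal(res$summary$fs_mean, 50, tolerance = 1e-3)
  # homogeneous noise-free ROI: averaged-decay fit equals a member voxel fit
  one <- fit_bi(syn$series$data[1, 1, 1, ], TE12)
  expect_equal(res$per_slice$t2s_ms[1], one$params$t2s_ms, tolerance = 1e-6)
  expect_error(roi_fit_and_select(syn$series, roi = array(FALSE, c(3, 3, 4))),
               "empty|no slices")
})

test_that("ROI-level detection beats voxel-level detection on the same bi phantom", {
  spec <- box_phantom(table2_roi1_0(), dims = c(10, 10, 6), snr = 35, seed = 77)
  syn <- synthesize_echo_series(spec, TE12)
  mask <- array(TRUE, c(10, 10, 6))
  mm <- fit_volume(syn$series, mask = mask, model = "mono")
  mb <- fit_volume(syn$series, mask = mask, model = "bi")
  vox <- biexp_percentage(select_voxels(mm, mb), "ftest")
  roi <- roi_fit_and_select(syn$series, roi = mask)
  expect_gte(roi$summary$pct_bi_ftest, vox)
})

test_that("weighted grand means follow the voxel counts", {
  expect_equal(grand_mean_weighted(c(2, 4), c(1, 3)), 3.5)
  expect_equal(grand_mean_weighted(c(2, 4, 6), c(5, 5, 5)), 4)
  expect_equal(grand_mean_weighted(7.7, 12), 7.7)
  set.seed(9)
  m <- runif(10, 0, 30); n <- sample(10:200, 10)
  g <- grand_mean_weighted(m, n)
  expect_gte(g, min(m)); expect_lte(g, max(m))
  expect_error(grand_mean_weighted(numeric(0), numeric(0)), "empty")
  expect_error(grand_mean_weighted(c(1, 2), c(1, 0)), "> 0")
  expect_error(grand_mean_weighted(c(1, 2), 1), "lengths differ")
})

test_that("Bartlett's screen separates homo- from heteroscedastic groups", {
  set.seed(13)
  hom <- bartlett_test(list(rnorm(200), rnorm(200)))
  expect_gt(hom$p_value, 0.05)
  expect_true(hom$homoscedastic)
  het <- bartlett_test(list(rnorm(50, sd = 1), rnorm(50, sd = sqrt(10))))
  expect_lt(het$p_value, 0.01)
  expect_false(het$homoscedastic)
  expect_error(bartlett_test(list(rnorm(5))), "at least 2 groups")
  expect_error(bartlett_test(list(rep(1, 5), rnorm(5))), "zero-variance")
})

test_that("ANOVA dispatch: identity, null behavior, and injected angle effect", {
  # two-level single factor: F equals the squared pooled t statistic
  set.seed(19)
  df <- data.frame(y = rnorm(40), g = rep(c("a", "b"), each = 20))
  out <- anova_dispatch(df, "y", "g", homoscedastic = TRUE)
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(out$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  # and the Welch branch matches the Welch t-test
  outw <- anova_dispatch(df, "y", "g", homoscedastic = FALSE)
  tw <- t.test(y ~ g, data = df)
  expect_equal(outw$statistic, unname(tw$statistic)^2, tolerance = 1e-9)
  expect_equal(outw$method, "welch")

  # null simulation: nonsignificant in the vast majority of runs
  set.seed(29)
  hits <- replicate(100, {
    d <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
    anova_dispatch(d, "y", "g", homoscedastic = TRUE)$significant
  })
  expect_gte(mean(!hits), 0.9)

  # angle effect injected through the phantom's anisotropy is detected
  te <- as.numeric(TE12)
  C <- calibrate_anisotropy(12.19, 3.3)
  reg <- region_spec(1, list(type = "band", x_mm = c(0, 1), y_mm = c(0, 1)),
                     mono_params(100, 12.19), anisotropy_rate_coeff = C)
  set.seed(37)
  samp <- do.call(rbind, lapply(c(0, 55, 90), function(a) {
    p <- angle_modulated_params(reg, a)
    t2 <- replicate(12, {
      y <- eval_mono(p, te) + rnorm(12, 0, 100 * exp(-0.82 / 12.19) / 35)
      fit_mono(y, TE12)$params$t2star_ms
    })
    data.frame(angle = factor(a), t2 = t2)
  }))
  out <- anova_dispatch(samp, "t2", "angle", homoscedastic = FALSE)
  expect_true(out$significant)
  expect_error(anova_dispatch(samp, "t2", "nope", TRUE))
})
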