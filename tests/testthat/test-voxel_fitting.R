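test_that("noise-free monoexponential signals are recovered essentially exactly", {
  truth <- mono_params(100, 10, 0)
  y <- eval_mono(truth, as.numeric(TE12))
  fit <- fit_mono(y, TE12)
  expect_equal(fit$params$a1, 100, tolerance = 1e-6)
  expect_equal(fit$params$t2star_ms, 10, tolerance = 1e-6)
  expect_equal(fit$params$epsilon, 0, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$dof, 9)
})

test_that("a constant signal is absorbed by the offset", {
  y <- rep(7.3, 12)
  fit <- fit_mono(y, TE12)
  expect_lt(fit$sse, 1e-12)
  expect_equal(eval_mono(fit$params, as.numeric(TE12)), y, tolerance = 1e-7)
})

test_that("noise-free biexponential signals are recovered", {
  truth <- bi_params(60, 40, 1.5, 12, 0)
  y <- eval_bi(truth, as.numeric(TE12))
  fit <- fit_bi(y, TE12)
  expect_equal(fit$params$b1, 60, tolerance = 1e-4)
  expect_equal(fit$params$b2, 40, tolerance = 1e-4)
  expect_equal(fit$params$t2s_ms, 1.5, tolerance = 1e-4)
  expect_equal(fit$params$t2l_ms, 12, tolerance = 1e-4)
  expect_lte(fit$params$t2s_ms, fit$params$t2l_ms)
  expect_equal(fit$dof, 7)
})

test_that("the biexponential fit never does worse than the monoexponential", {
  # noise-free mono input and random noisy decays
  set.seed(11)
  te <- as.numeric(TE12)
  for (i in 1:25) {
    y <- if (i == 1) eval_mono(mono_params(100, 10), te)
         else eval_mono(mono_params(runif(1, 20, 150), runif(1, 1, 30)),
                        te) + rnorm(12, 0, runif(1, 0.5, 5))
    fm <- fit_mono(y, TE12)
    fb <- fit_bi(y, TE12, fm)
    expect_lte(fb$sse, fm$sse * (1 + 1e-9) + 1e-12)
    # bound compliance
    expect_lte(fb$params$t2s_ms, 20)
    expect_lte(fb$params$t2l_ms, 200)
    expect_gte(min(fb$params$b1, fb$params$b2), 0)
    expect_lte(fm$params$t2star_ms, 200)
  }
})

test_that("LM solutions match a grid + polish brute-force oracle", {
  set.seed(17)
  te <- as.numeric(TE12)
  for (i in 1:5) {
    truth <- mono_params(100, runif(1, 2, 25))
    y <- eval_mono(truth, te) + rnorm(12, 0, 2)
    fm <- fit_mono(y, TE12)
    om <- oracle_fit_mono(y, te)
    expect_lte(fm$sse, om$sse * 1.01)
    fb <- fit_bi(y, TE12, fm)
    ob <- oracle_fit_bi(y, te)
    expect_lte(fb$sse, ob$sse * 1.01)
  }
})

test_that("noisy monoexponential T2* recovery at SNR 35 is as good as the brute-force optimum", {
  # With the free baseline offset in the 3-parameter model, the attainable
  # median |T2* error| at SNR 35 on the 12-echo design is ~6% (measured
  # with the grid+polish oracle); the LM fit must match that optimum.
  set.seed(23)
  te <- as.numeric(TE12)
  sdn <- 100 * exp(-0.82 / 10) / 35
  ys <- replicate(300, eval_mono(mono_params(100, 10), te) + rnorm(12, 0, sdn))
  err_lm <- apply(ys, 2, function(y)
    abs(fit_mono(y, TE12)$params$t2star_ms - 10) / 10)
  expect_lt(median(err_lm), 0.08)
  # paired against the oracle on the same replicates: LM finds the same optima
  err_lm40 <- err_lm[1:40]
  err_oracle <- apply(ys[, 1:40], 2, function(y)
    abs(oracle_fit_mono(y, te)$par[2] - 10) / 10)
  expect_lte(median(err_lm40), median(err_oracle) * 1.05 + 0.002)
})

test_that("recovery error grows as SNR falls", {
  te <- as.numeric(TE12)
  med_err <- sapply(c(350, 35, 10), function(snr) {
    set.seed(31)
    sdn <- 100 * exp(-0.82 / 10) / snr
    median(replicate(120, {
      y <- eval_mono(mono_params(100, 10), te) + rnorm(12, 0, sdn)
      abs(fit_mono(y, TE12)$params$t2star_ms - 10) / 10
    }))
  })
  expect_true(all(diff(med_err) > 0))
})

test_that("short-component recovery at ROI-level SNR on the closely spaced two-pool decay", {
  # t2s = 1.34 vs t2l = 4.50 ms is the stress case: the pools are close
  set.seed(41)
  te <- as.numeric(TE12)
  truth <- table2_roi1_0()
  sdn <- eval_bi(truth, te[1]) / 350
  err <- replicate(150, {
    y <- eval_bi(truth, te) + rnorm(12, 0, sdn)
    abs(fit_bi(y, TE12)$params$t2s_ms - 1.34) / 1.34
  })
  expect_lt(median(err), 0.25)
})

test_that("fit_volume writes sentinel NA outside the mask and is deterministic", {
  spec <- box_phantom(mono_params(100, 10), dims = c(4, 4, 2), seed = 6)
  syn <- synthesize_echo_series(spec, TE12)
  mask <- array(FALSE, c(4, 4, 2)); mask[1:2, 1:2, 1] <- TRUE
  m1 <- fit_volume(syn$series, mask = mask, model = "mono")
  m2 <- fit_volume(syn$series, mask = mask, model = "mono")
  expect_identical(m1$t2star_ms, m2$t2star_ms)
  expect_true(all(is.na(m1$t2star_ms[!mask])))
  expect_true(all(!is.na(m1$t2star_ms[mask])))
  empty <- fit_volume(syn$series, mask = array(FALSE, c(4, 4, 2)), model = "bi")
  expect_true(all(is.na(empty$t2s_ms)))
  expect_error(fit_volume(syn$series, schedule = echo_schedule(1:5),
                          mask = mask), "does not match")
})

test_that("noise-free phantom round-trips through volume fitting", {
  spec <- box_phantom(bi_params(60, 40, 1.5, 12), dims = c(3, 3, 2),
                      noise = "none")
  syn <- synthesize_echo_series(spec, TE12)
  mask <- syn$truth$label_map > 0
  maps <- fit_volume(syn$series, mask = mask, model = "bi")
  expect_equal(maps$t2s_ms[mask], syn$truth$params$t2s_ms[mask],
               tolerance = 1e-4)
  expect_equal(maps$t2l_ms[mask], syn$truth$params$t2l_ms[mask],
               tolerance = 1e-4)
  expect_equal(maps$fs_percent[mask], syn$truth$params$fs_percent[mask],
               tolerance = 1e-4)
})

test_that("foreground masking keeps tissue and drops background", {
  # noise-free: mask equals the nonzero-signal support
  spec0 <- meniscus_demo_spec(seed = 3, noise_model = "none")
  syn0 <- synthesize_echo_series(spec0, TE12)
  m0 <- mask_foreground(syn0$series, 5)
  expect_identical(m0, syn0$truth$label_map > 0)
  # all-background volume: empty mask with a warning
  z <- echo_series(array(0, c(4, 4, 2, 12)), TE12)
  expect_warning(mz <- mask_foreground(z, 5), "empty")
  expect_false(any(mz))
  # at SNR 35 at least 99% of tissue voxels survive a 5-sigma threshold
  spec <- meniscus_demo_spec(seed = 3)
  syn <- synthesize_echo_series(spec, TE12)
  m <- mask_foreground(syn$series, 5, noise_sd = syn$truth$noise_sd)
  tissue <- syn$truth$label_map > 0
  expect_gte(sum(m & tissue) / sum(tissue), 0.99)
})
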