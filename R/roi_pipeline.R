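#' ROI-averaged decay vector
#'
#' Averages the voxel decay curves of a region of interest echo-by-echo.
#' Averaging n voxels raises the SNR by about sqrt(n), which is the lever
#' that makes biexponential components detectable at ROI level when they
#' are invisible voxel-wise. Note that averaging voxels with heterogeneous
#' T2* produces a genuine multi-exponential mixture; the average of
#' monoexponential decays with different T2* is itself not monoexponential.
#'
#' @param series An [echo_series()].
#' @param roi Logical 3D array (or integer index vector into the spatial
#'   grid) selecting the ROI voxels.
#' @return A list: `signal` (mean decay vector, one value per echo) and
#'   `n_voxels`.
#' @export
roi_average_decay <- function(series, roi) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  sigmat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(idx) == 0L) stop("ROI is empty")
  list(signal = colMeans(sigmat[idx, , drop = FALSE]), n_voxels = length(idx))
}

#' ROI-averaged fit and model selection, slice by slice
#'
#' For each slice intersecting the ROI, averages the decay over the ROI
#' voxels of that slice, fits both decay models, and applies AICc and the
#' nested F-test. Returns the per-slice results and a one-row summary in the
#' style of an orientational ROI table: mean +/- SD of the mono T2* and of
#' the biexponential short and long T2* across slices, the mean short
#' fraction, and the percentage of slices preferring the biexponential
#' model under each criterion. Slices whose fits did not converge are
#' excluded from the percentages. With fewer than 2 contributing slices the
#' SDs are reported as `NA`.
#'
#' @param series An [echo_series()].
#' @param schedule Echo schedule; defaults to the one stored in `series`.
#' @param roi Logical 3D array selecting the ROI.
#' @param alpha F-test significance level. Default 0.05.
#' @return A list: `summary` (one-row data frame with `n_slices`,
#'   `mean_n_voxels`, `t2m_mean`, `t2m_sd`, `t2s_mean`, `t2s_sd`,
#'   `t2l_mean`, `t2l_sd`, `fs_mean`, `pct_bi_aicc`, `pct_bi_ftest`) and
#'   `per_slice` (data frame with the slice-level fits and decisions).
#' @export
roi_fit_and_select <- function(series, schedule = NULL, roi, alpha = 0.05) {
  stopifnot(inherits(series, "echo_series"))
  schedule <- schedule %||% series$schedule
  if (!inherits(schedule, "echo_schedule")) schedule <- echo_schedule(schedule)
  d <- dim(series$data)
  if (!identical(dim(roi), d[1:3])) stop("ROI shape does not match series")
  n <- d[4]

  rows <- list()
  for (k in seq_len(d[3])) {
    sl <- array(FALSE, d[1:3]); sl[, , k] <- roi[, , k]
    nv <- sum(sl)
    if (nv == 0L) next
    avg <- roi_average_decay(series, sl)
    fm <- fit_mono(avg$signal, schedule)
    fb <- fit_bi(avg$signal, schedule, mono_fit = fm)
    am <- aicc(fm$sse, n, 3L)
    ab <- aicc(fb$sse, n, 5L)
    ft <- f_test(fm$sse, fb$sse, n)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = k, n_voxels = nv,
      t2m_ms = fm$params$t2star_ms,
      t2s_ms = fb$params$t2s_ms, t2l_ms = fb$params$t2l_ms,
      fs_percent = short_fraction(fb$params),
      sse_mono = fm$sse, sse_bi = fb$sse,
      aicc_mono = as.numeric(am), aicc_bi = as.numeric(ab),
      f_stat = ft$f_stat, p_value = ft$p_value,
      prefer_bi_aicc = as.numeric(ab) < as.numeric(am),
      prefer_bi_ftest = ft$p_value < alpha,
      converged = fm$converged && fb$converged)
  }
  if (length(rows) == 0L) stop("ROI intersects no slices")
  per_slice <- do.call(rbind, rows)
  rownames(per_slice) <- NULL

  ok <- per_slice$converged
  msd <- function(x) if (sum(ok) >= 2) sd(x[ok]) else NA_real_
  summary <- data.frame(
    n_slices = nrow(per_slice),
    mean_n_voxels = mean(per_slice$n_voxels),
    t2m_mean = mean(per_slice$t2m_ms[ok]), t2m_sd = msd(per_slice$t2m_ms),
    t2s_mean = mean(per_slice$t2s_ms[ok]), t2s_sd = msd(per_slice$t2s_ms),
    t2l_mean = mean(per_slice$t2l_ms[ok]), t2l_sd = msd(per_slice$t2l_ms),
    fs_mean = mean(per_slice$fs_percent[ok]),
    pct_bi_aicc = 100 * sum(per_slice$prefer_bi_aicc[ok]) / sum(ok),
    pct_bi_ftest = 100 * sum(per_slice$prefer_bi_ftest[ok]) / sum(ok))
  list(summary = summary, per_slice = per_slice)
}

#' Voxel-count-weighted grand mean
#'
#' Grand mean across slices, each slice mean weighted by its voxel count:
#' sum(m_i * n_i) / sum(n_i). Used for whole-segment mean T2*.
#'
#' @param slice_means Numeric vector of per-slice means.
#' @param voxel_counts Positive voxel counts, same length.
#' @return The weighted grand mean (scalar).
#' @examples
#' grand_mean_weighted(c(2, 4), c(1, 3))  # 3.5
#' @export
grand_mean_weighted <- function(slice_means, voxel_counts) {
  if (length(slice_means) == 0L) stop("empty input")
  if (length(slice_means) != length(voxel_counts))
    stop("slice_means and voxel_counts lengths differ")
  if (any(voxel_counts <= 0)) stop("voxel counts must be > 0")
  weighted.mean(slice_means, voxel_counts)
}

#' Bartlett's test for homogeneity of variances
#'
#' Screens grouped T2* samples for heteroscedasticity before choosing
#' between classical and Welch ANOVA. Following the conventional rule, the
#' data are called homoscedastic when p > 0.05.
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2 and nonzero
#'   variance.
#' @return A list: `statistic` (Bartlett's K-squared), `p_value`, and the
#'   logical `homoscedastic` flag.
#' @export
bartlett_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  if (any(vapply(groups, function(g) sd(g) == 0, logical(1))))
    stop("zero-variance group: Bartlett's statistic is undefined")
  bt <- bartlett.test(groups)
  list(statistic = unname(bt$statistic), p_value = bt$p.value,
       homoscedastic = bt$p.value > 0.05)
}

#' Factorial or Welch ANOVA over region/angle groups
#'
#' Dispatches on the homoscedasticity screen: with homogeneous variances a
#' classical factorial ANOVA (main effects of the listed factors) is run;
#' otherwise Welch's ANOVA is applied factor-wise, since no standard
#' multi-way Welch procedure exists. Significance is declared at
#' p <= 0.05 per factor.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the response column (e.g. fitted T2*).
#' @param factors Character vector of factor column names (e.g.
#'   `c("region", "angle")`).
#' @param homoscedastic Logical, typically from [bartlett_test()].
#' @return A data frame with one row per factor: `factor`, `method`,
#'   `statistic` (F), `df1`, `df2`, `p_value`, `significant`.
#' @export
anova_dispatch <- function(data, response, factors, homoscedastic) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)), is.logical(homoscedastic))
  for (f in factors) {
    tab <- table(data[[f]])
    if (any(tab == 0) || length(tab) < 2L)
      stop("factor '", f, "' has empty or single cell(s): ",
           paste(names(tab)[tab == 0], collapse = ", "))
    data[[f]] <- factor(data[[f]])
  }
  if (homoscedastic) {
    fit <- aov(stats::reformulate(factors, response), data = data)
    at <- anova(fit)
    resid_df <- at["Residuals", "Df"]
    rows <- lapply(factors, function(f) data.frame(
      factor = f, method = "anova",
      statistic = at[f, "F value"], df1 = at[f, "Df"], df2 = resid_df,
      p_value = at[f, "Pr(>F)"]))
  } else {
    rows <- lapply(factors, function(f) {
      w <- oneway.test(stats::reformulate(f, response), data = data,
                       var.equal = FALSE)
      data.frame(factor = f, method = "welch",
                 statistic = unname(w$statistic),
                 df1 = unname(w$parameter[1]), df2 = unname(w$parameter[2]),
                 p_value = w$p.value)
    })
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value <= 0.05
  rownames(out) <- NULL
  out
}
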