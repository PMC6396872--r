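#' Small-sample corrected Akaike information criterion
#'
#' For a least-squares fit with Gaussian residuals of constant variance,
#' AICc = 2k + n * log(SSE / n) + 2k(k + 1) / (n - k - 1), with the natural
#' logarithm. The second-order correction term matters here because the
#' number of echoes (n, typically 9-12) is small relative to the parameter
#' counts (k = 3 mono, k = 5 bi). The model with the lower AICc is
#' preferred.
#'
#' @param sse Residual sum of squares (> 0; a perfect fit of `sse = 0`
#'   returns `-Inf` with attribute `perfect_fit = TRUE`).
#' @param n Number of data points.
#' @param k Number of fitted parameters; requires `n - k - 1 >= 1`.
#' @return The AICc value (scalar).
#' @examples
#' aicc(sse = 12, n = 12, k = 3)  # penalty only: 2k + 2k(k+1)/(n-k-1) = 9
#' @export
aicc <- function(sse, n, k) {
  stopifnot(length(sse) == 1, length(n) == 1, length(k) == 1)
  if (n - k - 1 < 1) stop("AICc requires n - k - 1 >= 1 (n = ", n, ", k = ", k, ")")
  if (sse < 0) stop("sse must be >= 0")
  if (sse == 0) return(structure(-Inf, perfect_fit = TRUE))
  2 * k + n * log(sse / n) + 2 * k * (k + 1) / (n - k - 1)
}

#' Nested F-test between the mono- and biexponential fits
#'
#' Tests whether the two extra parameters of the biexponential model reduce
#' the residual error beyond chance:
#' F = ((SSE_mono - SSE_bi) / SSE_bi) * (v_bi / (v_mono - v_bi)) with
#' v = n - k degrees of freedom (v_mono = n - 3, v_bi = n - 5), so the
#' numerator df is 2 and the denominator df is n - 5. The p-value is the
#' upper tail of the F(2, n - 5) distribution. When a local-minimum artifact
#' yields `sse_mono < sse_bi`, F is clamped to 0 (the fitting layer's
#' nesting guarantee normally prevents this).
#'
#' @param sse_mono,sse_bi Residual sums of squares of the two fits
#'   (`sse_bi > 0`; `sse_bi = 0` with `sse_mono > 0` gives the limit
#'   F = Inf, p = 0).
#' @param n Number of data points (>= 7, so the denominator df is >= 2).
#' @return A list: `f_stat`, `p_value`, `df1`, `df2`.
#' @export
f_test <- function(sse_mono, sse_bi, n) {
  stopifnot(length(n) == 1)
  df1 <- 2L
  df2 <- as.integer(n) - 5L
  if (df2 < 2L) stop("F-test requires n >= 7 echoes")
  if (sse_bi < 0 || sse_mono < 0) stop("sse must be >= 0")
  if (sse_bi == 0) {
    if (sse_mono == 0) return(list(f_stat = 0, p_value = 1, df1 = df1, df2 = df2))
    return(list(f_stat = Inf, p_value = 0, df1 = df1, df2 = df2))
  }
  f <- max(0, (sse_mono - sse_bi) / sse_bi * (df2 / df1))
  list(f_stat = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Per-voxel decay-type selection
#'
#' Compares the mono and bi parameter maps voxel-by-voxel with AICc and the
#' nested F-test and emits binary decay-type maps (0 = mono, 1 = bi, one map
#' per criterion), the short/long component-fraction maps, and the
#' underlying statistic volumes. Only voxels where both fits converged take
#' part; others are marked invalid and excluded from downstream
#' percentages. An AICc tie resolves to mono (parsimony).
#'
#' @param maps_mono,maps_bi `parameter_maps` from [fit_volume()] with models
#'   `"mono"` and `"bi"` on the same series and mask.
#' @param alpha Significance level for the F-test. Default 0.05.
#' @return A `decay_type_map` object: binary arrays `bi_aicc` and
#'   `bi_ftest`, fraction maps `fs_percent` and `fl_percent` (summing to 100
#'   on valid bi-fit voxels; `NA` where B1 + B2 = 0), statistic arrays
#'   `aicc_mono`, `aicc_bi`, `f_stat`, `p_value`, the logical `valid` map,
#'   and `alpha`.
#' @export
select_voxels <- function(maps_mono, maps_bi, alpha = 0.05) {
  stopifnot(inherits(maps_mono, "parameter_maps"),
            inherits(maps_bi, "parameter_maps"),
            identical(maps_mono$model, "mono"), identical(maps_bi$model, "bi"))
  if (!identical(dim(maps_mono$sse), dim(maps_bi$sse)))
    stop("mono and bi maps are not aligned")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  dims <- dim(maps_mono$sse)
  n <- maps_mono$n_points

  valid <- !is.na(maps_mono$sse) & !is.na(maps_bi$sse) &
    maps_mono$converged & maps_bi$converged
  valid[is.na(valid)] <- FALSE

  out <- list(bi_aicc = array(NA_real_, dims), bi_ftest = array(NA_real_, dims),
              aicc_mono = array(NA_real_, dims), aicc_bi = array(NA_real_, dims),
              f_stat = array(NA_real_, dims), p_value = array(NA_real_, dims),
              fs_percent = array(NA_real_, dims), fl_percent = array(NA_real_, dims))
  for (i in which(valid)) {
    am <- aicc(maps_mono$sse[i], n, 3L)
    ab <- aicc(maps_bi$sse[i], n, 5L)
    ft <- f_test(maps_mono$sse[i], maps_bi$sse[i], n)
    out$aicc_mono[i] <- am
    out$aicc_bi[i] <- ab
    out$f_stat[i] <- ft$f_stat
    out$p_value[i] <- ft$p_value
    out$bi_aicc[i] <- as.numeric(ab < am)          # tie -> mono
    out$bi_ftest[i] <- as.numeric(ft$p_value < alpha)
    fs <- maps_bi$fs_percent[i]
    out$fs_percent[i] <- fs
    out$fl_percent[i] <- if (is.na(fs)) NA_real_ else 100 - fs
  }
  structure(c(out, list(valid = valid, alpha = alpha)),
            class = "decay_type_map")
}

#' Percentage of voxels preferring the biexponential model
#'
#' 100 x flagged / (masked, converged) voxels under the chosen criterion.
#' Voxels where either fit failed are excluded from both numerator and
#' denominator.
#'
#' @param selection A `decay_type_map` from [select_voxels()].
#' @param criterion `"aicc"` or `"ftest"`.
#' @param mask Optional logical array restricting the count (e.g. one ROI).
#' @return Percentage in \[0, 100\].
#' @export
biexp_percentage <- function(selection, criterion = c("aicc", "ftest"),
                             mask = NULL) {
  stopifnot(inherits(selection, "decay_type_map"))
  criterion <- match.arg(criterion)
  flags <- if (criterion == "aicc") selection$bi_aicc else selection$bi_ftest
  keep <- selection$valid
  if (!is.null(mask)) keep <- keep & mask
  denom <- sum(keep)
  if (denom == 0) stop("no valid voxels under the mask")
  100 * sum(flags[keep], na.rm = TRUE) / denom
}

#' Per-slice decay-type summary
#'
#' Tabulates, slice by slice, the number of valid voxels and the percentage
#' flagged biexponential under each criterion.
#'
#' @param selection A `decay_type_map` from [select_voxels()].
#' @return A data frame with columns `slice`, `n_voxels`, `pct_bi_aicc`,
#'   `pct_bi_ftest`.
#' @export
slice_summary <- function(selection) {
  stopifnot(inherits(selection, "decay_type_map"))
  nz <- dim(selection$valid)[3]
  rows <- lapply(seq_len(nz), function(k) {
    v <- selection$valid[, , k]
    nvox <- sum(v)
    data.frame(
      slice = k, n_voxels = nvox,
      pct_bi_aicc = if (nvox) 100 * sum(selection$bi_aicc[, , k][v]) / nvox else NA_real_,
      pct_bi_ftest = if (nvox) 100 * sum(selection$bi_ftest[, , k][v]) / nvox else NA_real_)
  })
  do.call(rbind, rows)
}
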