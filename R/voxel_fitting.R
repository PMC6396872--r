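# Bounded Levenberg-Marquardt fitting of the decay models, per decay vector
# and per volume. Time-constant lower bounds of 0 are floored at 1e-6 ms
# inside the solver to keep exp(-te/T2) defined.

.T2_FLOOR <- 1e-6

# Below this fraction of the total signal energy an SSE is floating-point
# residue of a perfect fit; it is reported as exactly 0 so that downstream
# AICc/F-test comparisons see "no residual" rather than rounding noise.
.SSE_ZERO_REL <- 1e-14

.clean_sse <- function(sse, signal) {
  if (sse < .SSE_ZERO_REL * (sum(signal^2) + 1)) 0 else sse
}

.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 200)
}

# one nls.lm run; returns list(par, sse, converged) or NULL on failure
.lm_run <- function(start, resid_fn, lower, upper) {
  lower[is.finite(lower) & lower == 0 & grepl("t2", names(lower))] <- .T2_FLOOR
  start <- pmin(pmax(start, lower), upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn, control = .lm_control()),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = coef(fit), sse = fit$deviance,
       converged = fit$info %in% 1:4, hessian = fit$hessian)
}

# parameter standard errors from the Gauss-Newton Hessian approximation
.lm_se <- function(run, dof) {
  if (dof < 1 || is.null(run$hessian)) return(rep(NA_real_, length(run$par)))
  tryCatch(sqrt(diag(solve(run$hessian)) * run$sse / dof),
           error = function(e) rep(NA_real_, length(run$par)))
}

.fit_result <- function(params, sse, n, k, converged, se) {
  structure(list(params = params, sse = sse, n_points = n, k_params = k,
                 dof = n - k, converged = converged, se = se),
            class = "fit_result")
}

#' Fit the monoexponential model to one decay vector
#'
#' Constrained Levenberg-Marquardt least squares of
#' S(TE) = A1 * exp(-TE/T2*) + epsilon against the sampled decay. Two starts
#' are tried — the literature initialization (T2* = 10 ms, amplitude from the
#' first echo, offset 0) and an offset-aware variant seeded with the minimum
#' signal as baseline — and the lower-SSE solution is kept. Parameter
#' standard errors are derived from the Jacobian at the solution.
#'
#' @param signal Numeric vector of magnitude signals, one per echo.
#' @param schedule An [echo_schedule()] of matching length (>= 4 echoes).
#' @return A `fit_result`: `params` ([mono_params()]), `sse` (residual sum
#'   of squares), `n_points`, `k_params` (3), `dof`, `converged`, `se`.
#' @export
fit_mono <- function(signal, schedule) {
  if (!inherits(schedule, "echo_schedule")) schedule <- echo_schedule(schedule)
  te <- as.numeric(schedule)
  n <- length(signal)
  if (n != length(te)) stop("signal and schedule lengths differ")
  if (n < 4L) stop("monoexponential fit needs at least 4 echoes")
  b <- parameter_bounds("mono")
  resid_fn <- function(p) p[1] * exp(-te / p[2]) + p[3] - signal
  s1 <- signal[1]
  starts <- list(c(a1 = max(s1, 0), t2star_ms = 10, epsilon = 0),
                 c(a1 = max(s1 - min(signal), 0), t2star_ms = 10,
                   epsilon = min(signal)))
  best <- NULL
  for (st in starts) {
    run <- .lm_run(st, resid_fn, b$lower, b$upper)
    if (!is.null(run) && (is.null(best) || run$sse < best$sse)) best <- run
  }
  if (is.null(best)) stop("monoexponential fit failed to evaluate")
  p <- unname(best$par)
  .fit_result(mono_params(p[1], max(p[2], .T2_FLOOR), p[3]),
              .clean_sse(best$sse, signal), n, 3L, best$converged,
              .lm_se(best, n - 3L))
}

#' Fit the biexponential model to one decay vector
#'
#' Constrained Levenberg-Marquardt least squares of
#' S(TE) = B1 * exp(-TE/T2*s) + B2 * exp(-TE/T2*l) + epsilon with bounds
#' T2*s in \[0, 20\] ms and T2*l in \[0, 200\] ms. To tame local minima the
#' fit is multi-start: (1) the literature initialization (2 ms / 15 ms,
#' amplitude split 50/50); (2) a start seeded from the monoexponential
#' solution (B1 = B2 = A1/2, T2*l = T2*m, T2*s = 0.2 * T2*m). If neither
#' polished solution beats the monoexponential SSE, the exact embedding of
#' the mono solution in the biexponential family is substituted, so
#' `sse_bi <= sse_mono` always holds (the models are nested). Components are
#' returned in canonical order `t2s_ms <= t2l_ms`.
#'
#' @param signal Numeric vector of magnitude signals, one per echo.
#' @param schedule An [echo_schedule()] of matching length (>= 6 echoes).
#' @param mono_fit Optional `fit_result` from [fit_mono()] on the same
#'   signal; computed internally when absent.
#' @return A `fit_result` with `params` a [bi_params()], `k_params` 5.
#' @export
fit_bi <- function(signal, schedule, mono_fit = NULL) {
  if (!inherits(schedule, "echo_schedule")) schedule <- echo_schedule(schedule)
  te <- as.numeric(schedule)
  n <- length(signal)
  if (n != length(te)) stop("signal and schedule lengths differ")
  if (n < 6L) stop("biexponential fit needs at least 6 echoes")
  if (is.null(mono_fit)) mono_fit <- fit_mono(signal, schedule)
  b <- parameter_bounds("bi")
  resid_fn <- function(p)
    p[1] * exp(-te / p[3]) + p[2] * exp(-te / p[4]) + p[5] - signal

  mp <- mono_fit$params
  starts <- list(
    c(b1 = max(signal[1], 0) / 2, b2 = max(signal[1], 0) / 2,
      t2s_ms = 2, t2l_ms = 15, epsilon = 0),
    c(b1 = mp$a1 / 2, b2 = mp$a1 / 2,
      t2s_ms = min(0.2 * mp$t2star_ms, 20),
      t2l_ms = min(mp$t2star_ms, 200), epsilon = mp$epsilon))
  best <- NULL
  for (st in starts) {
    run <- .lm_run(st, resid_fn, b$lower, b$upper)
    if (!is.null(run) && (is.null(best) || run$sse < best$sse)) best <- run
  }

  # nesting guarantee: embed the mono solution exactly if LM did worse
  if (is.null(best) || best$sse > mono_fit$sse) {
    embed <- if (mp$t2star_ms <= 20)
      c(mp$a1, 0, mp$t2star_ms, max(mp$t2star_ms, 15), mp$epsilon)
    else
      c(0, mp$a1, 2, mp$t2star_ms, mp$epsilon)
    names(embed) <- names(b$lower)
    run <- .lm_run(embed, resid_fn, b$lower, b$upper)
    if (!is.null(run) && (is.null(best) || run$sse < best$sse)) best <- run
    if (is.null(best) || best$sse > mono_fit$sse) {
      if (is.null(best)) best <- list(par = embed)
      best$par <- embed
      best$sse <- mono_fit$sse
      best$converged <- mono_fit$converged
      best$hessian <- NULL
    }
  }
  p <- unname(best$par)
  se <- unname(.lm_se(best, n - 5L))
  if (p[3] > p[4]) se <- se[c(2, 1, 4, 3, 5)]   # track canonical swap
  .fit_result(bi_params(p[1], p[2], max(p[3], .T2_FLOOR),
                        max(p[4], .T2_FLOOR), p[5]),
              .clean_sse(best$sse, signal), n, 5L, best$converged, se)
}

#' Estimate background noise SD from corner patches
#'
#' Samples cubic patches at the 8 corners of the first-echo volume — in a
#' specimen acquisition these contain signal-free background — and returns
#' the standard deviation of those voxels.
#'
#' @param series An [echo_series()].
#' @param patch Patch edge length in voxels (default 4, clipped to the grid).
#' @return Estimated noise standard deviation.
#' @export
estimate_noise_sd <- function(series, patch = 4L) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)[1:3]
  first <- series$data[, , , 1, drop = FALSE]
  p <- pmin(patch, d)
  vals <- c()
  for (ix in list(seq_len(p[1]), d[1] - seq_len(p[1]) + 1L))
    for (iy in list(seq_len(p[2]), d[2] - seq_len(p[2]) + 1L))
      for (iz in list(seq_len(p[3]), d[3] - seq_len(p[3]) + 1L))
        vals <- c(vals, first[ix, iy, iz, 1])
  sd(vals)
}

#' Foreground mask from the first echo
#'
#' A voxel is foreground when its first-echo signal exceeds
#' `threshold_factor` times the background noise SD (estimated from corner
#' patches unless supplied). With noise-free data the mask reduces to the
#' nonzero-signal support.
#'
#' @param series An [echo_series()].
#' @param threshold_factor Multiple of the noise SD. Default 5.
#' @param noise_sd Optional known noise SD; overrides the corner estimate.
#' @return Logical 3D array.
#' @export
mask_foreground <- function(series, threshold_factor = 5, noise_sd = NULL) {
  stopifnot(inherits(series, "echo_series"))
  first <- series$data[, , , 1]
  if (all(first == 0)) {
    warning("all-zero first echo: empty mask")
    return(array(FALSE, dim(series$data)[1:3]))
  }
  sdv <- noise_sd %||% estimate_noise_sd(series)
  mask <- first > threshold_factor * sdv
  if (!any(mask)) warning("foreground mask is empty")
  mask
}

#' Fit a decay model over a masked volume
#'
#' Applies [fit_mono()] or [fit_bi()] voxel-by-voxel over the mask and
#' collects parameter maps. Unmasked voxels hold `NA`. Deterministic given
#' its inputs (the fit has no random component).
#'
#' @param series An [echo_series()].
#' @param schedule Echo schedule; defaults to the one stored in `series`.
#' @param mask Logical 3D array matching the series' spatial shape.
#' @param model `"mono"` or `"bi"`.
#' @return A `parameter_maps` object: a list of 3D arrays — for mono `a1`,
#'   `t2star_ms`, `epsilon`; for bi `b1`, `b2`, `t2s_ms`, `t2l_ms`,
#'   `epsilon`, `fs_percent` — plus `sse`, `converged`, and the `mask`.
#' @export
fit_volume <- function(series, schedule = NULL, mask, model = c("mono", "bi")) {
  stopifnot(inherits(series, "echo_series"))
  model <- match.arg(model)
  schedule <- schedule %||% series$schedule
  if (!inherits(schedule, "echo_schedule")) schedule <- echo_schedule(schedule)
  d <- dim(series$data)
  if (d[4] != length(schedule))
    stop("echo count of series (", d[4], ") does not match schedule (",
         length(schedule), ")")
  if (!identical(dim(mask), d[1:3])) stop("mask shape does not match series")

  dims <- d[1:3]
  blank <- function() array(NA_real_, dims)
  maps <- if (model == "mono") {
    list(a1 = blank(), t2star_ms = blank(), epsilon = blank())
  } else {
    list(b1 = blank(), b2 = blank(), t2s_ms = blank(), t2l_ms = blank(),
         epsilon = blank(), fs_percent = blank())
  }
  maps$sse <- blank()
  maps$converged <- array(NA, dims)

  idx <- which(mask)
  sigmat <- matrix(series$data, nrow = prod(dims), ncol = d[4])
  for (i in idx) {
    fit <- if (model == "mono") fit_mono(sigmat[i, ], schedule)
           else fit_bi(sigmat[i, ], schedule)
    p <- fit$params
    if (model == "mono") {
      maps$a1[i] <- p$a1; maps$t2star_ms[i] <- p$t2star_ms
    } else {
      maps$b1[i] <- p$b1; maps$b2[i] <- p$b2
      maps$t2s_ms[i] <- p$t2s_ms; maps$t2l_ms[i] <- p$t2l_ms
      maps$fs_percent[i] <- short_fraction(p)
    }
    maps$epsilon[i] <- p$epsilon
    maps$sse[i] <- fit$sse
    maps$converged[i] <- fit$converged
  }
  structure(c(maps, list(mask = mask, model = model,
                         n_points = d[4], k_params = if (model == "mono") 3L else 5L)),
            class = "parameter_maps")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: sse = %.6g, n = %d, k = %d, dof = %d, converged = %s\n",
              if (x$k_params == 3L) "monoexponential" else "biexponential",
              x$sse, x$n_points, x$k_params, x$dof, x$converged))
  print(x$params)
  invisible(x)
}
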