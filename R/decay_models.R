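#' Echo-time schedule
#'
#' Validates and wraps a vector of echo times (TEs). The decay curve is
#' sampled at these TEs; they must be strictly increasing and positive.
#'
#' @param te_ms Numeric vector of echo times in milliseconds.
#' @return An object of class `echo_schedule` (a numeric vector).
#' @examples
#' echo_schedule(c(0.82, 1.82, 2.82, 7.23, 9.23, 11.23,
#'                 13.39, 15.39, 17.39, 19.55, 21.55, 23.55))
#' @export
echo_schedule <- function(te_ms) {
  te_ms <- as.numeric(te_ms)
  if (length(te_ms) == 0L) stop("echo schedule must be nonempty")
  if (anyNA(te_ms) || any(!is.finite(te_ms))) stop("echo times must be finite")
  if (any(te_ms <= 0)) stop("all echo times must be > 0")
  if (any(diff(te_ms) <= 0)) stop("echo times must be strictly increasing")
  structure(te_ms, class = "echo_schedule")
}

#' Monoexponential decay parameters
#'
#' The 3-parameter model S(TE) = A1 * exp(-TE / T2*) + epsilon, where A1 is
#' the signal at TE = 0 and epsilon a baseline offset accounting for signal
#' that has not converged toward zero.
#'
#' @param a1 Signal amplitude at TE = 0 (arbitrary units, >= 0).
#' @param t2star_ms Effective transverse relaxation time T2* in ms (> 0).
#' @param epsilon Baseline offset (arbitrary units). Default 0.
#' @return An object of class `mono_params`.
#' @export
mono_params <- function(a1, t2star_ms, epsilon = 0) {
  stopifnot(is.numeric(a1), is.numeric(t2star_ms), is.numeric(epsilon))
  if (!is.finite(t2star_ms) || t2star_ms <= 0) stop("t2star_ms must be > 0")
  if (!is.finite(a1) || a1 < 0) stop("a1 must be >= 0")
  structure(list(a1 = a1, t2star_ms = t2star_ms, epsilon = epsilon),
            class = c("mono_params", "decay_params"))
}

#' Biexponential decay parameters
#'
#' The 5-parameter model
#' S(TE) = B1 * exp(-TE / T2*s) + B2 * exp(-TE / T2*l) + epsilon,
#' where the short component (T2*s) is commonly attributed to collagen-bound
#' water and the long component (T2*l) to free water. The stored
#' representation is canonical: components are sorted so that
#' `t2s_ms <= t2l_ms` (the model is invariant under swapping the two
#' components, so without the ordering the representation is not unique).
#'
#' @param b1 Short-component amplitude (>= 0).
#' @param b2 Long-component amplitude (>= 0).
#' @param t2s_ms Short T2* in ms (> 0, <= 20 ms).
#' @param t2l_ms Long T2* in ms (> 0, <= 200 ms).
#' @param epsilon Baseline offset. Default 0.
#' @return An object of class `bi_params`, with components ordered
#'   `t2s_ms <= t2l_ms`.
#' @export
bi_params <- function(b1, b2, t2s_ms, t2l_ms, epsilon = 0) {
  stopifnot(is.numeric(b1), is.numeric(b2),
            is.numeric(t2s_ms), is.numeric(t2l_ms), is.numeric(epsilon))
  if (!is.finite(t2s_ms) || t2s_ms <= 0) stop("t2s_ms must be > 0")
  if (!is.finite(t2l_ms) || t2l_ms <= 0) stop("t2l_ms must be > 0")
  if (b1 < 0 || b2 < 0) stop("amplitudes must be >= 0")
  if (t2s_ms > t2l_ms) {          # canonical ordering: swap components
    tmp <- b1; b1 <- b2; b2 <- tmp
    tmp <- t2s_ms; t2s_ms <- t2l_ms; t2l_ms <- tmp
  }
  if (t2s_ms > 20) stop("t2s_ms exceeds the 20 ms short-component cap")
  if (t2l_ms > 200) stop("t2l_ms exceeds the 200 ms long-component cap")
  structure(list(b1 = b1, b2 = b2, t2s_ms = t2s_ms, t2l_ms = t2l_ms,
                 epsilon = epsilon),
            class = c("bi_params", "decay_params"))
}

#' Evaluate the monoexponential decay model
#'
#' @param params A [mono_params()] object.
#' @param te Echo time(s) in ms (>= 0); vectorized.
#' @return Signal value(s), same length as `te`.
#' @examples
#' eval_mono(mono_params(100, 10), te = 10)  # 100/e
#' @export
eval_mono <- function(params, te) {
  stopifnot(inherits(params, "mono_params"))
  if (any(te < 0)) stop("te must be >= 0")
  params$a1 * exp(-te / params$t2star_ms) + params$epsilon
}

#' Evaluate the biexponential decay model
#'
#' @param params A [bi_params()] object.
#' @param te Echo time(s) in ms (>= 0); vectorized.
#' @return Signal value(s), same length as `te`.
#' @export
eval_bi <- function(params, te) {
  stopifnot(inherits(params, "bi_params"))
  if (any(te < 0)) stop("te must be >= 0")
  params$b1 * exp(-te / params$t2s_ms) +
    params$b2 * exp(-te / params$t2l_ms) + params$epsilon
}

#' Default fit initializations
#'
#' Literature-informed starting values for the nonlinear fit: mono T2* starts
#' at 10 ms; the biexponential components start at T2*s = 2 ms and
#' T2*l = 15 ms. Amplitudes are initialized from the first-echo signal (the
#' total amplitude, split 50/50 between the two components for the
#' biexponential model); the offset starts at 0.
#'
#' @param model `"mono"` or `"bi"`.
#' @param first_echo_signal Signal at the first echo used to seed amplitudes.
#'   Default 1.
#' @return A [mono_params()] or [bi_params()] object.
#' @export
default_inits <- function(model, first_echo_signal = 1) {
  model <- match.arg(model, c("mono", "bi"))
  s0 <- max(first_echo_signal, 0)
  if (model == "mono") {
    mono_params(a1 = s0, t2star_ms = 10, epsilon = 0)
  } else {
    bi_params(b1 = s0 / 2, b2 = s0 / 2, t2s_ms = 2, t2l_ms = 15, epsilon = 0)
  }
}

#' Parameter bounds for constrained fitting
#'
#' Box constraints used by the Levenberg-Marquardt fit: time constants are
#' bounded to \[0, 20\] ms for the short component and \[0, 200\] ms for the
#' long component (the mono T2* inherits the long-component cap); amplitudes
#' are nonnegative and the offset is unbounded.
#'
#' @param model `"mono"` or `"bi"`.
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
parameter_bounds <- function(model) {
  model <- match.arg(model, c("mono", "bi"))
  if (model == "mono") {
    list(lower = c(a1 = 0, t2star_ms = 0, epsilon = -Inf),
         upper = c(a1 = Inf, t2star_ms = 200, epsilon = Inf))
  } else {
    list(lower = c(b1 = 0, b2 = 0, t2s_ms = 0, t2l_ms = 0, epsilon = -Inf),
         upper = c(b1 = Inf, b2 = Inf, t2s_ms = 20, t2l_ms = 200,
                   epsilon = Inf))
  }
}

#' Short-component signal fraction
#'
#' Fs = 100 * B1 / (B1 + B2), the percentage of the total decaying amplitude
#' carried by the short T2* component.
#'
#' @param params A [bi_params()] object.
#' @return Fraction in percent, or `NA` when B1 + B2 = 0.
#' @export
short_fraction <- function(params) {
  stopifnot(inherits(params, "bi_params"))
  tot <- params$b1 + params$b2
  if (tot == 0) return(NA_real_)
  100 * params$b1 / tot
}

#' Serialize decay parameters to JSON
#'
#' @param params A `mono_params` or `bi_params` object.
#' @return A JSON string tagging the model kind alongside the parameters.
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "decay_params"))
  kind <- if (inherits(params, "mono_params")) "mono" else "bi"
  jsonlite::toJSON(c(list(model = kind), unclass(params)),
                   auto_unbox = TRUE, digits = NA)
}

#' Deserialize decay parameters from JSON
#'
#' @param json A JSON string produced by [params_to_json()].
#' @return A `mono_params` or `bi_params` object.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (identical(x$model, "mono")) {
    mono_params(x$a1, x$t2star_ms, x$epsilon)
  } else if (identical(x$model, "bi")) {
    bi_params(x$b1, x$b2, x$t2s_ms, x$t2l_ms, x$epsilon)
  } else {
    stop("unknown model kind in JSON: ", x$model)
  }
}

#' @export
print.mono_params <- function(x, ...) {
  cat(sprintf("monoexponential decay: A1 = %.4g, T2* = %.4g ms, offset = %.4g\n",
              x$a1, x$t2star_ms, x$epsilon))
  invisible(x)
}

#' @export
print.bi_params <- function(x, ...) {
  cat(sprintf(
    "biexponential decay: B1 = %.4g (T2*s = %.4g ms), B2 = %.4g (T2*l = %.4g ms), offset = %.4g, Fs = %.4g%%\n",
    x$b1, x$t2s_ms, x$b2, x$t2l_ms, x$epsilon, short_fraction(x)))
  invisible(x)
}
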