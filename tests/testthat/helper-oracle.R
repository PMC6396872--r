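# Brute-force reference fits, independent of the package's LM path:
# coarse grid over the nonlinear time constants, linear least squares for
# amplitudes and offset at each grid node, then an optim() L-BFGS-B polish.

oracle_sse <- function(pred, y) sum((pred - y)^2)

oracle_fit_mono <- function(y, te) {
  t2_grid <- exp(seq(log(0.2), log(200), length.out = 120))
  best <- list(sse = Inf)
  for (t2 in t2_grid) {
    X <- cbind(exp(-te / t2), 1)
    cf <- qr.coef(qr(X), y)
    if (cf[1] < 0) cf[1] <- 0
    sse <- oracle_sse(X %*% cf, y)
    if (sse < best$sse) best <- list(sse = sse, par = c(cf[1], t2, cf[2]))
  }
  obj <- function(p) oracle_sse(p[1] * exp(-te / p[2]) + p[3], y)
  pol <- optim(best$par, obj, method = "L-BFGS-B",
               lower = c(0, 1e-6, -Inf), upper = c(Inf, 200, Inf),
               control = list(maxit = 500))
  list(par = pol$par, sse = pol$value)
}

oracle_fit_bi <- function(y, te) {
  t2s_grid <- exp(seq(log(0.2), log(20), length.out = 35))
  t2l_grid <- exp(seq(log(0.5), log(200), length.out = 35))
  best <- list(sse = Inf)
  for (t2s in t2s_grid) for (t2l in t2l_grid) {
    if (t2s >= t2l) next
    X <- cbind(exp(-te / t2s), exp(-te / t2l), 1)
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    cf[1:2] <- pmax(cf[1:2], 0)
    sse <- oracle_sse(X %*% cf, y)
    if (sse < best$sse)
      best <- list(sse = sse, par = c(cf[1], cf[2], t2s, t2l, cf[3]))
  }
  obj <- function(p)
    oracle_sse(p[1] * exp(-te / p[3]) + p[2] * exp(-te / p[4]) + p[5], y)
  pol <- optim(best$par, obj, method = "L-BFGS-B",
               lower = c(0, 0, 1e-6, 1e-6, -Inf),
               upper = c(Inf, Inf, 20, 200, Inf),
               control = list(maxit = 1000))
  list(par = pol$par, sse = pol$value)
}
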