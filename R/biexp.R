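#' Fit a biexponential decay
#'
#' Least-squares fit of `y(t) = a1*exp(-t/tau1) + a2*exp(-t/tau2)` to the
#' descending phase of a postsynaptic current, the standard description of
#' IPSC decay kinetics. The fit is initialized from a log-spaced grid of
#' `(tau1, tau2)` pairs (amplitudes solved linearly for each pair) and the
#' best starts are refined by Levenberg-Marquardt under the constraints
#' `a1, a2 >= 0` and `tau1 < tau2`. If the second component does not improve
#' on a single exponential (degenerate data) the single-exponential solution
#' is returned with `a2 = 0` and `tau2 = NA`.
#'
#' @param y decay segment starting at the trough/peak (first sample is the
#'   extremum). May be negative-going (raw inward current) or positive; the
#'   magnitude is fitted.
#' @param dt sampling interval (ms). Alternatively supply `t`.
#' @param t optional explicit time axis (ms, starting at 0).
#' @param normalize if `TRUE` (default) the segment is normalized to its
#'   trough magnitude before fitting, so `a1 + a2 ~ 1`.
#' @param n_starts number of grid starts refined by nonlinear LS (>= 5).
#' @param start_frac the fit starts where the decay has fallen to this
#'   fraction of the trough magnitude (default 0.85), skipping the first
#'   samples where the waveform is still shaped by the rising phase; the
#'   amplitudes are back-extrapolated to the trough so `a1 + a2` stays on the
#'   trough scale. Set to 1 to fit from the trough sample.
#' @return object of class `"biexp_fit"` with components `a1`, `tau1`, `a2`,
#'   `tau2`, `rse` (residual standard error), `sse`, `converged`, `model`
#'   (`"biexp"` or `"single"`), and the fitted data.
#' @examples
#' t <- seq(0, 30, 0.1)
#' y <- 0.7 * exp(-t / 1.5) + 0.3 * exp(-t / 10)
#' coef(fit_biexp_decay(y, dt = 0.1))
#' @export
fit_biexp_decay <- function(y, dt = NULL, t = NULL, normalize = TRUE,
                            n_starts = 6, start_frac = 0.85) {
  y <- as.numeric(y)
  if (is.null(t)) {
    if (is.null(dt)) stop("supply dt or t", call. = FALSE)
    t <- (seq_along(y) - 1) * dt
  }
  if (length(y) != length(t)) stop("y and t lengths differ", call. = FALSE)
  if (t[length(t)] - t[1] < 5)
    stop("decay segment must span at least 5 ms", call. = FALSE)
  # canonical polarity: decaying positive transient
  if (y[1] < 0) y <- -y
  scale0 <- abs(y[1])
  if (scale0 <= 0) stop("trough value must be nonzero", call. = FALSE)
  if (normalize) y <- y / scale0
  # skip the rise-contaminated shoulder just after the trough
  t_skip <- 0
  if (start_frac < 1) {
    i0 <- which(y <= start_frac * y[1])[1]
    if (!is.na(i0) && i0 > 1L && t[length(t)] - t[i0] >= 4) {
      t_skip <- t[i0] - t[1]
      y <- y[i0:length(y)]
      t <- t[i0:length(t)] - t[i0] + 0  # refit clock starts at the new origin
    }
  }
  n <- length(y)

  sse_of <- function(pred) sum((y - pred)^2)

  # single-exponential reference fit
  single <- fit_single_exp(t, y)

  # grid of (tau1, tau2) with linearly solved nonnegative amplitudes
  span <- t[n] - t[1]
  taus <- exp(seq(log(max(2 * mean(diff(t)), span / 500)),
                  log(span * 2), length.out = 12))
  grid <- expand.grid(tau1 = taus, tau2 = taus)
  grid <- grid[grid$tau2 > 2 * grid$tau1, ]
  grid_fit <- function(t1, t2) {
    X <- cbind(exp(-t / t1), exp(-t / t2))
    cf <- tryCatch(stats::.lm.fit(X, y)$coefficients,
                   error = function(e) c(NA, NA))
    if (anyNA(cf)) return(NULL)
    cf <- pmax(cf, 0)
    list(a1 = cf[1], a2 = cf[2], tau1 = t1, tau2 = t2,
         sse = sse_of(X %*% cf))
  }
  cand <- Map(grid_fit, grid$tau1, grid$tau2)
  cand <- cand[!vapply(cand, is.null, TRUE)]
  ord <- order(vapply(cand, `[[`, 0, "sse"))
  starts <- cand[ord[seq_len(min(max(5, n_starts), length(cand)))]]

  best <- NULL
  df <- data.frame(t = t, y = y)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2), data = df,
        start = list(a1 = max(s$a1, 1e-6), a2 = max(s$a2, 1e-6),
                     tau1 = s$tau1, tau2 = s$tau2),
        lower = c(0, 0, mean(diff(t)) / 20, mean(diff(t)) / 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(a1 = cf[["a1"]], a2 = cf[["a2"]], tau1 = cf[["tau1"]],
                   tau2 = cf[["tau2"]], sse = sse)
    }
  }
  converged <- !is.null(best)
  if (!converged) best <- starts[[1]]
  # order components: tau1 fast, tau2 slow
  if (best$tau1 > best$tau2) {
    best <- list(a1 = best$a2, a2 = best$a1, tau1 = best$tau2,
                 tau2 = best$tau1, sse = best$sse)
  }
  model <- "biexp"
  # degenerate data: biexp no better than single exponential
  tiny <- 1e-10 * sum(y^2)
  if (!converged || single$sse <= best$sse * (1 + 1e-6) || single$sse < tiny) {
    if (single$sse <= best$sse * (1 + 1e-6)) {
      best <- list(a1 = single$a, a2 = 0, tau1 = single$tau, tau2 = NA_real_,
                   sse = single$sse)
      model <- "single"
      converged <- single$converged
    }
  }
  pred <- best$a1 * exp(-t / best$tau1) +
    (if (is.na(best$tau2)) 0 else best$a2 * exp(-t / best$tau2))
  # report amplitudes on the trough scale (back-extrapolated over the skip)
  a1_rep <- unname(best$a1) * exp(t_skip / best$tau1)
  a2_rep <- if (is.na(best$tau2)) unname(best$a2)
  else unname(best$a2) * exp(t_skip / best$tau2)
  out <- list(a1 = a1_rep, tau1 = unname(best$tau1),
              a2 = a2_rep, tau2 = unname(best$tau2),
              sse = unname(best$sse),
              rse = sqrt(best$sse / max(1, n - 4)),
              converged = converged, model = model,
              normalized = normalize, scale = scale0,
              data = data.frame(t = t + t_skip, y = y), fitted = pred)
  class(out) <- "biexp_fit"
  out
}

fit_single_exp <- function(t, y) {
  pos <- y > 0
  if (sum(pos) >= 3) {
    cf <- unname(stats::lm.fit(cbind(1, t[pos]), log(y[pos]))$coefficients)
    a0 <- exp(cf[1]); tau0 <- if (cf[2] < 0) -1 / cf[2] else (t[length(t)] - t[1])
  } else {
    a0 <- max(abs(y)); tau0 <- (t[length(t)] - t[1]) / 3
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau), data = df,
                      start = list(a = a0, tau = tau0),
                      lower = c(0, mean(diff(t)) / 20)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(a = a0, tau = tau0,
                sse = sum((y - a0 * exp(-t / tau0))^2), converged = FALSE))
  cf <- stats::coef(fit)
  list(a = unname(cf[["a"]]), tau = unname(cf[["tau"]]),
       sse = sum(stats::residuals(fit)^2), converged = TRUE)
}

#' @export
coef.biexp_fit <- function(object, ...) {
  c(a1 = object$a1, tau1 = object$tau1, a2 = object$a2, tau2 = object$tau2)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("biexponential decay fit\n")
  if (x$model == "single" || x$a2 == 0) {
    cat(sprintf("  y = %.3g * exp(-t/%.4g)   [single-exponential solution]\n",
                x$a1, x$tau1))
  } else {
    cat(sprintf("  y = %.3g * exp(-t/%.4g) + %.3g * exp(-t/%.4g)\n",
                x$a1, x$tau1, x$a2, x$tau2))
  }
  cat(sprintf("  residual SE %.3g on %d points%s\n", x$rse, nrow(x$data),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.biexp_fit <- function(object, ...) {
  print(object)
  tot <- object$a1 + object$a2
  if (tot > 0 && object$a2 > 0)
    cat(sprintf("  fast fraction a1/(a1+a2) = %.2f; weighted tau = %.3g ms\n",
                object$a1 / tot,
                (object$a1 * object$tau1 + object$a2 * object$tau2) / tot))
  invisible(object)
}

#' @export
predict.biexp_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) return(object$fitted)
  object$a1 * exp(-t / object$tau1) +
    (if (is.na(object$tau2) || object$a2 == 0) 0
     else object$a2 * exp(-t / object$tau2))
}

#' @export
residuals.biexp_fit <- function(object, ...) object$data$y - object$fitted

#' @export
plot.biexp_fit <- function(x, ...) {
  plot(x$data$t, x$data$y, pch = 16, cex = 0.4, col = "grey50",
       xlab = "time from trough (ms)",
       ylab = if (x$normalized) "normalized current" else "current", ...)
  graphics::lines(x$data$t, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}
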