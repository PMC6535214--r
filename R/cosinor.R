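#' Cosinor regression for a single feature
#'
#' Ordinary least squares fit of
#' \deqn{y = \beta_0 + a \cos(2\pi t/\tau) + b \sin(2\pi t/\tau) + \epsilon}
#' at a fixed candidate period \eqn{\tau}. Rhythmicity is assessed by the
#' F-test comparing this model against the intercept-only model. The fitted
#' amplitude and phase come from the trigonometric identity
#' \eqn{a\cos\theta + b\sin\theta = c\sin(\theta + \phi)} with
#' \eqn{c = \sqrt{a^2 + b^2}} and \eqn{\phi = \pi/2 - \mathrm{atan2}(b, a)};
#' the phase is reported in hours in \eqn{[0, \tau)} and matches the
#' simulator's convention, where the phase is \emph{added} to \eqn{t} inside
#' the waveform argument (so a fitted phase of 6 h means the sine peaks at
#' \eqn{\tau/4 - 6} h).
#'
#' @param times Sampling times in hours.
#' @param values Measured abundances (same length). Count data should be
#'   variance-stabilized first, e.g. with [log_transform_counts()].
#' @param period Candidate period \eqn{\tau} in hours (default 24).
#'
#' @return An object of class \code{"cosinor"} with components
#'   \code{coefficients} (intercept, cos, sin), \code{amplitude},
#'   \code{phase} (hours in \eqn{[0, \tau)}), \code{period}, \code{p_value},
#'   \code{fitted.values}, \code{residuals}, \code{times}, \code{values},
#'   \code{df.residual}.
#' @examples
#' t = 0:47
#' y = 2 * sin(2 * pi * t / 24) + rnorm(48, sd = 0.5)
#' fit = cosinor_fit(t, y)
#' coef(fit); fit$amplitude; fit$phase; fit$p_value
#' @export
cosinor_fit = function(times, values, period = 24) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 4L)
    stop("cosinor regression needs at least 4 samples")
  if (length(unique(times)) < 2L)
    stop("all samples share one time; the rhythmic terms are not estimable")
  fit = cosinor_fit_matrix(times, matrix(values, nrow = 1L), period)
  structure(
    list(coefficients = c(intercept = unname(fit$intercept[1L]),
                          cos = unname(fit$coef_cos[1L]),
                          sin = unname(fit$coef_sin[1L])),
         amplitude = unname(fit$amplitude[1L]),
         phase = unname(fit$phase[1L]),
         period = period, p_value = unname(fit$p_value[1L]),
         fitted.values = fit$fitted[1L, ], residuals = fit$resid[1L, ],
         times = times, values = values,
         df.residual = length(times) - 3L),
    class = "cosinor")
}

# Vectorized cosinor: one QR factorization shared by all features.
# `values` is a features x samples matrix; returns per-feature coefficients,
# amplitude/phase and intercept-only F-test p-values.
cosinor_fit_matrix = function(times, values, period = 24) {
  stopifnot(is.matrix(values), ncol(values) == length(times))
  theta = 2 * pi * times / period
  X = cbind(1, cos(theta), sin(theta))
  qr_x = qr(X)
  if (qr_x$rank < 3L)
    stop("rank-deficient cosinor design; times do not span the period")
  n = length(times)
  Yt = t(values)                                   # samples x features
  coefs = qr.coef(qr_x, Yt)                        # 3 x features
  fitted = X %*% coefs
  resid = Yt - fitted
  sse = colSums(resid^2)
  sst = colSums(sweep(Yt, 2L, colMeans(Yt))^2)
  df2 = n - 3L
  # guard exact fits (sse ~ 0): F explodes, p underflows to the minimum double
  msr = pmax(sse, 0) / df2
  fstat = ((sst - sse) / 2) / msr
  p = stats::pf(fstat, 2, df2, lower.tail = FALSE)
  p[!is.finite(fstat) & sst > sse] = 0
  p[sst <= .Machine$double.eps * n] = 1            # constant input: no signal
  p = pmin(pmax(p, .Machine$double.xmin), 1)
  ap = amp_phase_from_coefs(coefs[2L, ], coefs[3L, ], period)
  list(intercept = unname(coefs[1L, ]), coef_cos = unname(coefs[2L, ]),
       coef_sin = unname(coefs[3L, ]), amplitude = ap[, "amplitude"],
       phase = ap[, "phase"], p_value = unname(p),
       fitted = t(fitted), resid = t(resid))
}

#' Amplitude and phase from cosinor coefficients
#'
#' Converts fitted cosine/sine coefficients to a sine-referenced amplitude
#' and phase via \eqn{c = \sqrt{a^2 + b^2}},
#' \eqn{\phi = (\pi/2 - \mathrm{atan2}(b, a)) \bmod 2\pi}, reported in hours
#' on \eqn{[0, \tau)}. The degenerate case \eqn{a = b = 0} returns amplitude
#' 0 with phase 0 by convention.
#'
#' @param coef_cos Coefficient(s) of \eqn{\cos(2\pi t/\tau)}.
#' @param coef_sin Coefficient(s) of \eqn{\sin(2\pi t/\tau)}.
#' @param period Period \eqn{\tau} in hours.
#' @return A matrix with columns \code{amplitude} and \code{phase}.
#' @examples
#' amp_phase_from_coefs(0, 1)   # pure sine: amplitude 1, phase 0 h
#' amp_phase_from_coefs(1, 0)   # pure cosine: amplitude 1, phase 6 h
#' @export
amp_phase_from_coefs = function(coef_cos, coef_sin, period = 24) {
  amp = sqrt(coef_cos^2 + coef_sin^2)
  phi = (pi / 2 - atan2(coef_sin, coef_cos)) %% (2 * pi)
  phase = phi * period / (2 * pi)
  phase[amp == 0] = 0
  cbind(amplitude = amp, phase = phase %% period)
}

#' log2(counts + 1) transform
#'
#' The variance-stabilizing transform applied to negative binomial counts
#' before cosinor fitting.
#'
#' @param counts Non-negative counts.
#' @return \code{log2(counts + 1)}, elementwise.
#' @export
log_transform_counts = function(counts) {
  if (any(counts < 0)) stop("'counts' must be non-negative")
  log2(counts + 1)
}

#' @export
print.cosinor = function(x, ...) {
  cat(sprintf("Cosinor fit (period %g h, n = %d)\n", x$period,
              length(x$values)))
  cat(sprintf("  amplitude %.4g, phase %.4g h, p = %.3g\n",
              x$amplitude, x$phase, x$p_value))
  invisible(x)
}

#' @export
summary.cosinor = function(object, ...) {
  n = length(object$values)
  sse = sum(object$residuals^2)
  sst = sum((object$values - mean(object$values))^2)
  out = list(coefficients = object$coefficients,
             amplitude = object$amplitude, phase = object$phase,
             period = object$period, p_value = object$p_value,
             r.squared = if (sst > 0) 1 - sse / sst else NA_real_,
             sigma = sqrt(sse / object$df.residual), n = n)
  class(out) = "summary.cosinor"
  out
}

#' @export
print.summary.cosinor = function(x, ...) {
  cat(sprintf("Cosinor regression, period %g h, n = %d\n", x$period, x$n))
  print(x$coefficients)
  cat(sprintf("amplitude %.4g, phase %.4g h (sine convention, phase added to t)\n",
              x$amplitude, x$phase))
  cat(sprintf("residual sd %.4g, R-squared %.4g, rhythmicity p = %.3g\n",
              x$sigma, x$r.squared, x$p_value))
  invisible(x)
}

#' @export
coef.cosinor = function(object, ...) object$coefficients

#' @export
fitted.cosinor = function(object, ...) object$fitted.values

#' @export
residuals.cosinor = function(object, ...) object$residuals

#' Predicted abundance from a cosinor fit
#'
#' @param object A \code{"cosinor"} fit.
#' @param newtimes Times in hours at which to predict; defaults to the
#'   fitted times.
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.cosinor = function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$fitted.values)
  theta = 2 * pi * newtimes / object$period
  b = object$coefficients
  unname(b[1L] + b[2L] * cos(theta) + b[3L] * sin(theta))
}

#' Plot a cosinor fit
#'
#' @param x A \code{"cosinor"} fit.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.cosinor = function(x, ...) {
  plot(x$times, x$values, xlab = "time (h)", ylab = "abundance", ...)
  tt = seq(min(x$times), max(x$times), length.out = 400L)
  graphics::lines(tt, predict(x, tt), lwd = 2)
  invisible(x)
}
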