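#' Default mean-dispersion curve for negative binomial sampling
#'
#' Maps expected counts \eqn{\mu} to the negative binomial dispersion
#' \eqn{\alpha} (parameterization \eqn{Var(Y) = \mu + \alpha\mu^2}) via the
#' parametric form
#' \deqn{\alpha(\mu) = \alpha_0 + \alpha_1 / \mu,}
#' which reproduces the empirical tendency of RNA-seq dispersion to fall as
#' expression rises: lowly expressed genes are strongly overdispersed while
#' highly expressed genes approach the asymptotic dispersion \eqn{\alpha_0}.
#' Any user-supplied function of \eqn{\mu} can be used in its place.
#'
#' @param mu Expected counts; must be positive.
#' @param alpha0 Asymptotic dispersion at high expression (default 0.01).
#' @param alpha1 Coefficient of the \eqn{1/\mu} term (default 2.0).
#' @return Dispersion value(s), strictly positive and non-increasing in
#'   \code{mu}.
#' @examples
#' default_dispersion(1)      # 2.01
#' default_dispersion(1e6)    # ~0.01
#' @export
default_dispersion = function(mu, alpha0 = 0.01, alpha1 = 2) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  alpha0 + alpha1 / mu
}

#' Draw Gaussian measurements around expected abundances
#'
#' \eqn{Y \sim N(m, \sigma^2)}. Uses R's global random number generator;
#' call \code{set.seed} (or use the \code{seed} argument of
#' [simulate_rhythms()]) for reproducibility.
#'
#' @param m Expected abundance(s).
#' @param sd Standard deviation, positive (default 1, i.e., unit variance).
#' @return Numeric vector of draws, one per element of \code{m}.
#' @export
sample_gaussian = function(m, sd = 1) {
  if (any(sd <= 0)) stop("'sd' must be positive")
  stats::rnorm(length(m), mean = m, sd = sd)
}

# largest admissible expected abundance on the log2-counts scale; beyond this
# mu = 2^m approaches double overflow in the NB machinery
.max_log2_mean = 62

#' Draw negative binomial counts around expected log2 abundances
#'
#' Counts are drawn as \eqn{Y \sim NB(\mu = 2^m, \alpha = g(\mu))} with
#' \eqn{Var(Y) = \mu + \alpha\mu^2}; a dispersion of exactly zero degenerates
#' to Poisson(\eqn{\mu}). Internally the (\eqn{\mu}, \eqn{\alpha}) contract is
#' converted to R's size/mu parameterization, \code{size} = \eqn{1/\alpha}.
#'
#' @param m Expected abundance(s) on the log2-counts scale; capped at 62
#'   (errors above, to keep \eqn{2^m} finite in double precision).
#' @param dispersion Function mapping expected counts to dispersion;
#'   default [default_dispersion()].
#' @return Integer-valued vector of non-negative counts.
#' @export
sample_negbinom = function(m, dispersion = default_dispersion) {
  if (any(!is.finite(m))) stop("'m' must be finite")
  if (any(m > .max_log2_mean))
    stop("log2 expected abundance above ", .max_log2_mean,
         " would overflow expected counts")
  mu = 2^m
  alpha = rep_len(dispersion(mu), length(mu))
  if (any(alpha < 0)) stop("dispersion function returned a negative value")
  out = numeric(length(mu))
  pois = alpha == 0
  if (any(pois)) out[pois] = stats::rpois(sum(pois), mu[pois])
  if (any(!pois))
    out[!pois] = stats::rnbinom(sum(!pois), size = 1 / alpha[!pois],
                                mu = mu[!pois])
  out
}

#' Prediction interval for a simulated measurement
#'
#' Central interval expected to contain a fraction \code{level} of sampled
#' measurements at a given expected abundance. For the Gaussian family this is
#' \eqn{m \pm z_{(1+level)/2}\,\sigma}. For the negative binomial family the
#' endpoints are the integer \eqn{(1-level)/2} and \eqn{(1+level)/2} quantiles
#' of \eqn{NB(\mu = 2^m, \alpha = g(\mu))}, so realized coverage is at least
#' \code{level} (discrete distributions are conservatively covered).
#'
#' @param m Expected abundance(s) on the model scale (log2 counts for the
#'   negative binomial family).
#' @param level Coverage level in (0, 1); default 0.90.
#' @param family \code{"gaussian"} or \code{"negbinom"}.
#' @param sd Gaussian standard deviation.
#' @param dispersion Mean-dispersion function (negative binomial family).
#' @return A two-column matrix with columns \code{lo} and \code{hi}, one row
#'   per element of \code{m}.
#' @examples
#' prediction_interval(0, level = 0.9)                     # +/- 1.6449
#' prediction_interval(8, family = "negbinom")             # integer endpoints
#' @export
prediction_interval = function(m, level = 0.90,
                               family = c("gaussian", "negbinom"),
                               sd = 1, dispersion = default_dispersion) {
  family = match.arg(family)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)")
  p_lo = (1 - level) / 2
  p_hi = (1 + level) / 2
  if (family == "gaussian") {
    z = stats::qnorm(p_hi)
    out = cbind(lo = m - z * sd, hi = m + z * sd)
  } else {
    mu = 2^m
    alpha = rep_len(dispersion(mu), length(mu))
    if (any(alpha < 0)) stop("dispersion function returned a negative value")
    lo = hi = numeric(length(mu))
    pois = alpha == 0
    if (any(pois)) {
      lo[pois] = stats::qpois(p_lo, mu[pois])
      hi[pois] = stats::qpois(p_hi, mu[pois])
    }
    if (any(!pois)) {
      sz = 1 / alpha[!pois]
      lo[!pois] = stats::qnbinom(p_lo, size = sz, mu = mu[!pois])
      hi[!pois] = stats::qnbinom(p_hi, size = sz, mu = mu[!pois])
    }
    out = cbind(lo = lo, hi = hi)
  }
  out
}

#' Simulate a rhythmic abundance experiment
#'
#' The top-level simulator: builds (or accepts) an experimental design,
#' realizes per-feature ground-truth parameters from the group
#' specifications, evaluates expected abundances, and draws measurements from
#' each group's sampling family. Identical inputs and seed give identical
#' output.
#'
#' @param design A \code{"rhythm_design"} (from [build_design()]) or a
#'   \code{"design_spec"}; defaults to the standard design (0-48 h every 3 h,
#'   2 samples per time point, 1 condition).
#' @param groups Feature group specification(s); see [build_feature_table()]
#'   for the accepted shapes, including per-condition parameter variation.
#' @param seed Optional integer seed; when supplied the result is fully
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return An object of class \code{"rhythm_sim"}: a list with
#'   \describe{
#'     \item{\code{abundance}}{long-format data frame, one row per
#'       feature x sample: \code{feature}, \code{sample}, \code{cond},
#'       \code{time}, \code{mu} (expected abundance on the model scale) and
#'       \code{abund} (sampled measurement; non-negative integer for the
#'       negative binomial family).}
#'     \item{\code{features}}{the ground-truth \code{"feature_table"}.}
#'     \item{\code{design}}{the expanded design.}
#'     \item{\code{seed}}{the seed used (or NULL).}
#'   }
#' @examples
#' sim = simulate_rhythms(groups = feature_group(3, amp = 1), seed = 1)
#' head(sim$abundance)
#' @export
simulate_rhythms = function(design = NULL, groups = feature_group(),
                            seed = NULL) {
  if (!is.null(seed)) {
    old = get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  if (is.null(design)) design = design_spec()
  if (inherits(design, "design_spec")) design = build_design(design)
  stopifnot(inherits(design, "rhythm_design"))
  n_conditions = attr(design, "spec")$n_conditions

  features = build_feature_table(groups, n_conditions)
  mmat = evaluate_trajectories(features, design)

  n_feat = nrow(mmat)
  n_samp = nrow(design)
  abund = data.frame(
    feature = rep(rownames(mmat), times = n_samp),
    sample = rep(design$sample, each = n_feat),
    cond = rep(design$cond, each = n_feat),
    time = rep(design$time, each = n_feat),
    mu = as.vector(mmat),
    stringsAsFactors = FALSE)

  # look up each row's (feature, condition) ground-truth record
  row_rec = match(paste(abund$feature, abund$cond),
                  paste(features$feature, features$cond))
  fam = features$family[row_rec]
  vals = numeric(nrow(abund))
  gau = fam == "gaussian"
  if (any(gau))
    vals[gau] = sample_gaussian(abund$mu[gau], sd = features$sd[row_rec][gau])
  if (any(!gau)) {
    # dispersion functions are shared within a (condition, group); draw
    # group-wise so each batch is one vectorized call
    gkey = paste(features$cond, features$group)[row_rec]
    for (gk in unique(gkey[!gau])) {
      ii = which(!gau & gkey == gk)
      vals[ii] = sample_negbinom(
        abund$mu[ii], dispersion = features$dispersion[[row_rec[ii][1L]]])
    }
  }
  abund$abund = vals

  structure(list(abundance = abund, features = features, design = design,
                 seed = seed),
            class = "rhythm_sim")
}

#' @export
print.rhythm_sim = function(x, ...) {
  fams = unique(x$features$family)
  cat(sprintf(
    "Simulated rhythmic experiment: %d feature(s) x %d sample(s), %d condition(s), family: %s\n",
    length(unique(x$features$feature)), nrow(x$design),
    attr(x$design, "spec")$n_conditions, paste(fams, collapse = "+")))
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.rhythm_sim = function(object, ...) {
  ab = object$abundance
  per_feat = tapply(ab$abund, ab$feature, mean)
  out = list(
    n_features = length(unique(object$features$feature)),
    n_samples = nrow(object$design),
    n_conditions = attr(object$design, "spec")$n_conditions,
    families = table(object$features$family[
      !duplicated(object$features$feature)]),
    abund_range = range(ab$abund),
    mean_abund = mean(per_feat))
  class(out) = "summary.rhythm_sim"
  out
}

#' @export
print.summary.rhythm_sim = function(x, ...) {
  cat(sprintf("%d feature(s) x %d sample(s) in %d condition(s)\n",
              x$n_features, x$n_samples, x$n_conditions))
  cat("families: ",
      paste(names(x$families), x$families, sep = "=", collapse = ", "), "\n")
  cat(sprintf("measured abundance range: [%.4g, %.4g]; grand mean %.4g\n",
              x$abund_range[1L], x$abund_range[2L], x$mean_abund))
  invisible(x)
}

#' Plot one simulated feature's trajectory
#'
#' Sampled measurements, the noise-free expected trajectory, and the central
#' prediction interval ribbon, in the style of published example figures.
#'
#' @param x A \code{"rhythm_sim"}.
#' @param feature Feature id to plot (default: the first).
#' @param cond Condition to plot (default 1).
#' @param level Prediction-interval level (default 0.90).
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the data frame of plotted points.
#' @export
plot.rhythm_sim = function(x, feature = NULL, cond = 1L, level = 0.90, ...) {
  if (is.null(feature)) feature = x$features$feature[1L]
  rec = x$features[x$features$feature == feature & x$features$cond == cond, ]
  if (nrow(rec) != 1L) stop("no unique record for that feature/condition")
  ab = x$abundance[x$abundance$feature == feature & x$abundance$cond == cond, ]
  tt = seq(min(ab$time), max(ab$time), length.out = 400L)
  mm = expected_abundance(tt, amp = rec$amp[[1L]], phase = rec$phase,
                          period = rec$period, base = rec$base[[1L]],
                          waveform = rec$waveform[[1L]])
  pi_args = list(m = mm, level = level, family = rec$family)
  if (rec$family == "gaussian") pi_args$sd = rec$sd
  else pi_args$dispersion = rec$dispersion[[1L]]
  band = do.call(prediction_interval, pi_args)
  yy = if (rec$family == "negbinom") 2^mm else mm
  ylim = range(band, ab$abund, yy)
  plot(ab$time, ab$abund, xlab = "time (h)", ylab = "abundance",
       ylim = ylim, main = feature, ...)
  graphics::polygon(c(tt, rev(tt)), c(band[, "lo"], rev(band[, "hi"])),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(tt, yy, lwd = 2)
  graphics::points(ab$time, ab$abund)
  invisible(ab)
}
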