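#' Define a group of features sharing rhythmic and noise parameters
#'
#' A feature group is a set of \code{n_features} simulated features (genes)
#' that share a parameter specification within one condition. The expected
#' abundance of each feature follows
#' \deqn{m(t) = a(t) \cdot f\left(\frac{2\pi}{\tau}(t + \phi)\right) + b(t),}
#' where \eqn{a} is the amplitude, \eqn{f} a periodic waveform with period
#' \eqn{2\pi} (default \code{sin}), \eqn{\tau} the period in hours (default
#' 24), \eqn{\phi} the phase in hours and \eqn{b} the baseline. Amplitude and
#' baseline may be functions of time, giving damped rhythms or drifting
#' baselines; \code{amp = 0} defines a non-rhythmic feature. Amplitude, phase,
#' period and baseline may also be vectors of length \code{n_features}
#' (scalars recycle), so each feature in a group can have its own parameters.
#'
#' Note the phase sign convention: \eqn{\phi} is added to \eqn{t} inside the
#' waveform argument, so a positive phase shifts the waveform \emph{earlier} —
#' with \code{f = sin} the peak sits at \eqn{t = \tau/4 - \phi \pmod\tau}.
#' Many rhythm tools use the opposite convention.
#'
#' For the \code{"negbinom"} family, \code{m} is interpreted on the log2
#' counts scale: counts are drawn with mean \eqn{\mu = 2^m} and dispersion
#' \eqn{\alpha = g(\mu)}, where \eqn{g} is the mean-dispersion function
#' (default [default_dispersion()]) and \eqn{Var(Y) = \mu + \alpha\mu^2}.
#'
#' @param n_features Number of features in the group.
#' @param amp Amplitude: scalar, vector of length \code{n_features}, or a
#'   (vectorizable) function of time.
#' @param phase Phase in hours (scalar or per-feature vector).
#' @param period Period \eqn{\tau} in hours; must be positive. Default 24.
#' @param base Baseline abundance: scalar, per-feature vector, or function of
#'   time. For the negative binomial family this is baseline log2 counts.
#' @param waveform Periodic function of angle with period \eqn{2\pi};
#'   default \code{sin}.
#' @param family Sampling family, \code{"gaussian"} or \code{"negbinom"}.
#' @param sd Gaussian standard deviation (so variance \code{sd^2}; default 1).
#' @param dispersion Mean-dispersion function \eqn{g(\mu)} for the negative
#'   binomial family; default [default_dispersion()].
#'
#' @return An object of class \code{"feature_group"}.
#' @examples
#' feature_group(10, amp = 1, phase = 6)                  # rhythmic, gaussian
#' feature_group(5, amp = 0, base = 8, family = "negbinom") # flat counts
#' feature_group(1, amp = function(t) exp(-t / 24))       # damped rhythm
#' @export
feature_group = function(n_features = 1L, amp = 0, phase = 0, period = 24,
                         base = 0, waveform = sin,
                         family = c("gaussian", "negbinom"),
                         sd = 1, dispersion = default_dispersion) {
  family = match.arg(family)
  stopifnot(is.numeric(n_features), length(n_features) == 1L,
            n_features >= 1, n_features == round(n_features))
  n_features = as.integer(n_features)

  check_par = function(x, nm, fn_ok = TRUE) {
    if (is.function(x)) {
      if (!fn_ok) stop("'", nm, "' cannot be a function")
      return(x)
    }
    if (!is.numeric(x) || any(!is.finite(x)))
      stop("'", nm, "' must be finite numeric or a function")
    if (!length(x) %in% c(1L, n_features))
      stop("'", nm, "' must have length 1 or n_features")
    x
  }
  amp = check_par(amp, "amp")
  base = check_par(base, "base")
  phase = check_par(phase, "phase", fn_ok = FALSE)
  period = check_par(period, "period", fn_ok = FALSE)
  if (any(period <= 0)) stop("'period' must be positive")
  if (!is.function(waveform)) stop("'waveform' must be a function")
  check_periodic(waveform)
  if (family == "gaussian") {
    if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
      stop("'sd' must be a positive number")
  } else {
    if (!is.function(dispersion)) stop("'dispersion' must be a function")
  }

  structure(
    list(n_features = n_features, amp = amp, phase = phase, period = period,
         base = base, waveform = waveform, family = family, sd = sd,
         dispersion = dispersion),
    class = "feature_group")
}

# waveform must satisfy f(theta + 2*pi) = f(theta) on a probe grid
check_periodic = function(f, tol = 1e-6) {
  theta = seq(0, 2 * pi, length.out = 17L)
  d = f(theta + 2 * pi) - f(theta)
  if (any(!is.finite(d)) || max(abs(d)) > tol)
    stop("'waveform' must be periodic with period 2*pi")
  invisible(TRUE)
}

#' Default waveform: sine
#'
#' The default periodic shape of the rhythmic component, \eqn{f(\theta) =
#' \sin(\theta)}.
#'
#' @param theta Angle in radians.
#' @return \code{sin(theta)}.
#' @export
default_waveform = function(theta) sin(theta)

#' Expected abundance under the rhythmic model
#'
#' Evaluates \eqn{m(t) = a(t) f((2\pi/\tau)(t+\phi)) + b(t)} at the given
#' times. Scalar \code{amp}/\code{base} are treated as constant functions.
#'
#' @param t Time(s) in hours.
#' @param amp Amplitude (scalar or function of time).
#' @param phase Phase in hours.
#' @param period Period in hours.
#' @param base Baseline (scalar or function of time).
#' @param waveform Periodic function of angle; default \code{sin}.
#' @return Numeric vector of expected abundances, one per time.
#' @examples
#' expected_abundance(6, amp = 1)                      # sin(pi/2) = 1
#' expected_abundance(0:47, amp = 2, phase = 6)
#' @export
expected_abundance = function(t, amp = 0, phase = 0, period = 24, base = 0,
                              waveform = sin) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  a = if (is.function(amp)) amp(t) else amp
  b = if (is.function(base)) base(t) else base
  m = a * waveform((2 * pi / period) * (t + phase)) + b
  if (any(!is.finite(m)))
    stop("expected abundance is non-finite; check amp/base/waveform")
  m
}

#' Build the ground-truth feature table
#'
#' Realizes per-feature, per-condition parameters from group specifications.
#' Each simulated feature gets one record per condition carrying everything
#' needed to recompute its expected abundance exactly — the ground-truth
#' ledger used by the detection-evaluation functions.
#'
#' @param groups A \code{"feature_group"}, a list of groups (applied to every
#'   condition), or a list with one list of groups per condition. Per-condition
#'   lists must be parallel: the same number of groups with the same
#'   \code{n_features} and \code{family} in each position, so that a feature's
#'   amplitude/phase/period may differ across conditions but its identity and
#'   family may not.
#' @param n_conditions Number of conditions.
#'
#' @return A data frame of class \code{"feature_table"} with one row per
#'   (feature, condition): columns \code{feature}, \code{cond}, \code{group},
#'   \code{amp}, \code{phase}, \code{period}, \code{base}, \code{family},
#'   \code{sd}; \code{amp} and \code{base} are list columns (scalar or
#'   function per element). Waveform and dispersion functions are kept in
#'   list columns \code{waveform} and \code{dispersion}.
#' @export
build_feature_table = function(groups, n_conditions = 1L) {
  per_cond = normalize_groups(groups, n_conditions)
  g1 = per_cond[[1L]]
  n_per_group = vapply(g1, function(g) g$n_features, integer(1L))
  fam_per_group = vapply(g1, function(g) g$family, character(1L))

  for (k in seq_along(per_cond)) {
    gk = per_cond[[k]]
    if (length(gk) != length(g1))
      stop("all conditions must have the same number of feature groups")
    nk = vapply(gk, function(g) g$n_features, integer(1L))
    fk = vapply(gk, function(g) g$family, character(1L))
    if (!identical(nk, n_per_group))
      stop("group sizes must match across conditions")
    if (!identical(fk, fam_per_group))
      stop("a feature's sampling family cannot differ across conditions")
  }

  feature_id = sprintf("feature_%d", seq_len(sum(n_per_group)))
  group_of = rep(seq_along(n_per_group), times = n_per_group)

  recs = list()
  for (k in seq_along(per_cond)) {
    off = 0L
    for (gi in seq_along(per_cond[[k]])) {
      g = per_cond[[k]][[gi]]
      n = g$n_features
      idx = off + seq_len(n)
      expand = function(x) {
        if (is.function(x)) rep(list(x), n) else as.list(rep_len(x, n))
      }
      recs[[length(recs) + 1L]] = data.frame(
        feature = feature_id[idx], cond = k, group = gi,
        phase = rep_len(g$phase, n), period = rep_len(g$period, n),
        family = g$family, sd = g$sd, stringsAsFactors = FALSE)
      recs[[length(recs)]]$amp = expand(g$amp)
      recs[[length(recs)]]$base = expand(g$base)
      recs[[length(recs)]]$waveform = rep(list(g$waveform), n)
      recs[[length(recs)]]$dispersion = rep(list(g$dispersion), n)
      off = off + n
    }
  }
  out = do.call(rbind, recs)
  rownames(out) = NULL
  class(out) = c("feature_table", "data.frame")
  out
}

# groups -> list (one element per condition) of lists of feature_group
normalize_groups = function(groups, n_conditions) {
  n_conditions = as.integer(n_conditions)
  if (inherits(groups, "feature_group"))
    return(rep(list(list(groups)), n_conditions))
  if (!is.list(groups) || length(groups) == 0L)
    stop("'groups' must be a feature_group or a non-empty list")
  if (all(vapply(groups, inherits, logical(1L), "feature_group")))
    return(rep(list(groups), n_conditions))
  # list of per-condition lists
  ok = vapply(groups, function(gk) {
    is.list(gk) && all(vapply(gk, inherits, logical(1L), "feature_group"))
  }, logical(1L))
  if (!all(ok))
    stop("'groups' must be feature_group objects or per-condition lists of them")
  if (length(groups) != n_conditions)
    stop("per-condition group list must have length n_conditions")
  groups
}

#' Expected-abundance matrix for a design
#'
#' Applies the rhythmic model to every (feature, sample) pair: entry
#' \code{[i, j]} is the expected abundance of feature \code{i}, under its
#' parameters in sample \code{j}'s condition, at sample \code{j}'s time.
#'
#' @param features A \code{"feature_table"} from [build_feature_table()].
#' @param design A \code{"rhythm_design"} from [build_design()].
#' @return Numeric matrix, features x samples, dimnames set to feature and
#'   sample ids.
#' @export
evaluate_trajectories = function(features, design) {
  stopifnot(inherits(features, "feature_table"))
  fids = unique(features$feature)
  m = matrix(NA_real_, nrow = length(fids), ncol = nrow(design),
             dimnames = list(fids, design$sample))
  key = paste(features$feature, features$cond, sep = "\r")
  rec_idx = stats::setNames(seq_len(nrow(features)), key)
  for (k in unique(design$cond)) {
    jj = which(design$cond == k)
    tt = design$time[jj]
    ii = rec_idx[paste(fids, k, sep = "\r")]
    if (any(is.na(ii)))
      stop("missing feature-table record for condition ", k)
    for (r in seq_along(fids)) {
      rec = features[ii[r], ]
      m[r, jj] = expected_abundance(
        tt, amp = rec$amp[[1L]], phase = rec$phase, period = rec$period,
        base = rec$base[[1L]], waveform = rec$waveform[[1L]])
    }
  }
  m
}

#' Write a feature table as tab-delimited text
#'
#' Functional amplitude/baseline columns are summarized by their value at
#' t = 0 (columns \code{amp0}, \code{base0}).
#'
#' @param features A \code{"feature_table"}.
#' @param path File path.
#' @return \code{read_feature_table} returns a plain data frame with columns
#'   \code{feature}, \code{cond}, \code{group}, \code{amp0}, \code{phase},
#'   \code{period}, \code{base0}, \code{family}.
#' @export
write_feature_table = function(features, path) {
  at0 = function(x) if (is.function(x)) x(0) else x
  flat = data.frame(
    feature = features$feature, cond = features$cond, group = features$group,
    amp0 = vapply(features$amp, at0, numeric(1L)),
    phase = features$phase, period = features$period,
    base0 = vapply(features$base, at0, numeric(1L)),
    family = features$family, stringsAsFactors = FALSE)
  utils::write.table(format_num_df(flat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table = function(path) {
  out = utils::read.delim(path, stringsAsFactors = FALSE)
  need = c("feature", "cond", "group", "amp0", "phase", "period", "base0",
           "family")
  miss = setdiff(need, names(out))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  out
}

# format numeric columns with 6 significant digits for compact text output
format_num_df = function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] = signif(df[[nm]], 6L)
  }
  df
}
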