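#' Area under the ROC curve from two score groups
#'
#' The probability that a randomly chosen positive (rhythmic) feature's score
#' exceeds a randomly chosen negative (non-rhythmic) feature's score, with
#' ties counting one half — the normalized Mann-Whitney rank-sum statistic.
#' Higher scores must indicate stronger evidence of rhythmicity (e.g.,
#' \code{-log(p)}); a p-value column can be negated to serve as a score.
#'
#' @param scores_pos Scores of the labeled-positive group.
#' @param scores_neg Scores of the labeled-negative group.
#' @return AUROC in [0, 1]: 0.5 is random detection, 1 perfect detection.
#' @examples
#' auroc(c(10, 9, 8), c(3, 2, 1))  # perfectly separated: 1
#' auroc(c(3, 1), 2)               # one win, one loss: 0.5
#' @export
auroc = function(scores_pos, scores_neg) {
  n_pos = length(scores_pos)
  n_neg = length(scores_neg)
  if (n_pos == 0L || n_neg == 0L)
    stop("both score groups must be non-empty")
  r = rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score rhythm-detection accuracy against simulation ground truth
#'
#' Fits a cosinor regression to every feature of a simulated experiment,
#' scores each feature by its rhythmicity p-value, and computes one AUROC per
#' (amplitude, baseline) group of rhythmic features versus the pooled
#' amplitude-0 (non-rhythmic) features. Counts from the negative binomial
#' family are log2(counts + 1)-transformed before fitting; Gaussian data are
#' used untransformed. Evaluation runs on one condition of one simulated
#' experiment.
#'
#' An external detector can be evaluated instead of the built-in cosinor
#' F-test by supplying \code{scores}: a named numeric vector (names =
#' feature ids) in which larger values mean stronger evidence of rhythmicity.
#'
#' @param sim A \code{"rhythm_sim"} from [simulate_rhythms()], or a long
#'   abundance data frame with columns \code{feature}, \code{cond},
#'   \code{time}, \code{abund} (then \code{features} is required).
#' @param features Ground-truth feature table (data frame with columns
#'   \code{feature}, \code{cond}, plus amplitude and baseline); defaults to
#'   \code{sim$features}. Functional amplitudes/baselines are summarized by
#'   their value at t = 0 for grouping.
#' @param cond Condition to evaluate (default 1).
#' @param period Candidate period for the cosinor fit (default 24 h).
#' @param scores Optional external per-feature scores (larger = more
#'   rhythmic) replacing the built-in cosinor p-values.
#' @return Data frame with one row per rhythmic (amplitude, baseline) group:
#'   columns \code{amp}, \code{base}, \code{n_pos}, \code{n_neg},
#'   \code{auroc}.
#' @export
evaluate_detection = function(sim, features = NULL, cond = 1L, period = 24,
                              scores = NULL) {
  if (inherits(sim, "rhythm_sim")) {
    ab = sim$abundance
    if (is.null(features)) features = sim$features
  } else {
    ab = sim
    if (is.null(features)) stop("'features' is required with a plain table")
  }
  need = c("feature", "cond", "time", "abund")
  miss = setdiff(need, names(ab))
  if (length(miss))
    stop("abundance table is missing column(s): ", paste(miss, collapse = ", "))
  ab = ab[ab$cond == cond, ]
  if (nrow(ab) == 0L) stop("no samples in condition ", cond)

  truth = truth_amp_base(features, cond)
  if (!any(truth$amp == 0))
    stop("ground truth contains no amplitude-0 (non-rhythmic) features")

  if (is.null(scores)) {
    wide = long_to_matrix(ab)
    fam = truth$family[match(rownames(wide), truth$feature)]
    if (any(is.na(fam))) stop("abundance features missing from ground truth")
    nb = !is.na(fam) & fam == "negbinom"
    if (any(nb)) wide[nb, ] = log_transform_counts(wide[nb, ])
    times = as.numeric(colnames(wide))
    fit = cosinor_fit_matrix(times, wide, period)
    scores = stats::setNames(-fit$p_value, rownames(wide))
  }
  sc = scores[truth$feature]
  if (any(is.na(sc))) stop("scores missing for some ground-truth features")

  neg = truth$amp == 0
  pos_groups = unique(truth[!neg, c("amp", "base")])
  pos_groups = pos_groups[order(pos_groups$amp, pos_groups$base), ]
  res = lapply(seq_len(nrow(pos_groups)), function(i) {
    sel = !neg & truth$amp == pos_groups$amp[i] &
      truth$base == pos_groups$base[i]
    data.frame(amp = pos_groups$amp[i], base = pos_groups$base[i],
               n_pos = sum(sel), n_neg = sum(neg),
               auroc = auroc(sc[sel], sc[neg]))
  })
  out = do.call(rbind, res)
  rownames(out) = NULL
  out
}

# numeric amplitude/baseline per feature for one condition (functions
# summarized at t = 0), tolerant of both feature_table and flat TSV schemas
truth_amp_base = function(features, cond) {
  tr = features[features$cond == cond, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no ground-truth records for condition ", cond)
  at0 = function(x) {
    vapply(x, function(e) if (is.function(e)) e(0) else as.numeric(e),
           numeric(1L))
  }
  amp = if (!is.null(tr$amp)) at0(tr$amp) else tr$amp0
  base = if (!is.null(tr$base)) at0(tr$base) else tr$base0
  if (is.null(amp) || is.null(base))
    stop("ground truth must carry amplitude (amp/amp0) and baseline (base/base0)")
  fam = if (!is.null(tr$family)) tr$family else rep(NA_character_, nrow(tr))
  data.frame(feature = tr$feature, amp = amp, base = base, family = fam,
             stringsAsFactors = FALSE)
}

# long abundance records -> features x samples matrix, columns named by time
long_to_matrix = function(ab) {
  feats = unique(ab$feature)
  samps = unique(ab$sample)
  m = matrix(NA_real_, nrow = length(feats), ncol = length(samps),
             dimnames = list(feats, samps))
  m[cbind(match(ab$feature, feats), match(ab$sample, samps))] = ab$abund
  if (anyNA(m)) stop("abundance table is not one record per feature x sample")
  colnames(m) = ab$time[match(samps, ab$sample)]
  m
}

#' Sweep detection accuracy over design and rhythm parameters
#'
#' Runs one simulated experiment per sampling interval — negative binomial
#' counts, one replicate per time point over 0-48 h, one feature group per
#' (amplitude, baseline) combination including amplitude 0 — then scores
#' detection with [evaluate_detection()]. This reproduces, at configurable
#' scale, the standard benchmark in which detection accuracy is mapped
#' against rhythm amplitude, baseline expression and sampling interval.
#'
#' @param intervals Sampling intervals in hours, one simulation each.
#' @param amps Rhythm amplitudes in log2 counts; must include 0 (the
#'   non-rhythmic negative class).
#' @param bases Baseline log2 counts.
#' @param n_per_group Features per (amplitude, baseline) group.
#' @param first,last Design window in hours (default 0-48).
#' @param period Rhythm and detection period (default 24 h).
#' @param dispersion Mean-dispersion function (default
#'   [default_dispersion()]).
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{interval}, \code{amp}, \code{base},
#'   \code{n_pos}, \code{n_neg}, \code{auroc}.
#' @export
detection_sweep = function(intervals = c(2, 4, 6),
                           amps = c(0, 0.25, 0.5, 1, 2),
                           bases = c(2, 8), n_per_group = 200L,
                           first = 0, last = 48, period = 24,
                           dispersion = default_dispersion, seed = NULL) {
  if (!any(amps == 0))
    stop("'amps' must include 0 so a non-rhythmic negative class exists")
  if (!is.null(seed)) {
    old = get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  combos = expand.grid(amp = amps, base = bases)
  groups = lapply(seq_len(nrow(combos)), function(i) {
    feature_group(n_per_group, amp = combos$amp[i], base = combos$base[i],
                  period = period, family = "negbinom",
                  dispersion = dispersion)
  })
  res = lapply(intervals, function(iv) {
    sim = simulate_rhythms(
      design_spec(mode = "interval", first = first, last = last,
                  interval = iv, n_per_timepoint = 1L),
      groups = groups)
    ev = evaluate_detection(sim, period = period)
    cbind(interval = iv, ev)
  })
  out = do.call(rbind, res)
  rownames(out) = NULL
  out
}
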