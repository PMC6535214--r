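#' Specify an experimental design
#'
#' A design specification describes when samples are collected in a simulated
#' time-course experiment. Three modes are supported:
#' \describe{
#'   \item{\code{"interval"}}{evenly spaced time points from \code{first} to
#'     (at most) \code{last} in steps of \code{interval}, each with
#'     \code{n_per_timepoint} samples per condition. This is the default
#'     scheme: 0 h to 48 h every 3 h with 2 samples per time point.}
#'   \item{\code{"explicit"}}{exactly the supplied \code{times}, each with its
#'     own replicate count (\code{n_per_timepoint} may be a scalar, recycled,
#'     or a vector matching \code{times}).}
#'   \item{\code{"uniform"}}{\code{n_total} sampling times per condition drawn
#'     independently from the continuous uniform distribution on
#'     \code{[first, last]}.}
#' }
#'
#' @param mode One of \code{"interval"}, \code{"explicit"}, \code{"uniform"}.
#' @param first,last First and last (possible) time points, in hours.
#' @param interval Spacing between time points in hours (interval mode);
#'   must be positive.
#' @param times Numeric vector of exact time points (explicit mode). Negative
#'   times are allowed here only.
#' @param n_per_timepoint Samples per time point per condition; in explicit
#'   mode may be a vector of the same length as \code{times}.
#' @param n_total Total samples per condition (uniform mode).
#' @param n_conditions Number of experimental conditions.
#' @param seed Optional integer seed making uniform-mode draws reproducible.
#'
#' @return An object of class \code{"design_spec"}.
#' @seealso [build_design()]
#' @export
design_spec = function(mode = c("interval", "explicit", "uniform"),
                       first = 0, last = 48, interval = 3,
                       times = NULL, n_per_timepoint = 2,
                       n_total = NULL, n_conditions = 1L, seed = NULL) {
  mode = match.arg(mode)
  stopifnot(is.numeric(n_conditions), length(n_conditions) == 1L,
            n_conditions >= 1, n_conditions == round(n_conditions))

  if (mode == "interval") {
    stopifnot(is.numeric(first), is.numeric(last), length(first) == 1L,
              length(last) == 1L, is.finite(first), is.finite(last))
    if (last < first) stop("'last' must be >= 'first'")
    if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
      stop("'interval' must be a positive number")
    if (!is.numeric(n_per_timepoint) || length(n_per_timepoint) != 1L ||
        n_per_timepoint < 1 || n_per_timepoint != round(n_per_timepoint))
      stop("'n_per_timepoint' must be a positive integer in interval mode")
  } else if (mode == "explicit") {
    if (is.null(times) || length(times) == 0L)
      stop("explicit mode requires a non-empty 'times' vector")
    if (!is.numeric(times) || any(!is.finite(times)))
      stop("'times' must be finite numbers")
    if (!is.numeric(n_per_timepoint) || any(n_per_timepoint < 1) ||
        any(n_per_timepoint != round(n_per_timepoint)))
      stop("'n_per_timepoint' must be positive integers")
    if (!length(n_per_timepoint) %in% c(1L, length(times)))
      stop("'n_per_timepoint' must be scalar or match length(times)")
  } else { # uniform
    stopifnot(is.numeric(first), is.numeric(last), is.finite(first),
              is.finite(last))
    if (last < first) stop("'last' must be >= 'first'")
    if (is.null(n_total) || !is.numeric(n_total) || length(n_total) != 1L ||
        n_total < 1 || n_total != round(n_total))
      stop("uniform mode requires integer 'n_total' >= 1")
  }

  structure(
    list(mode = mode, first = first, last = last, interval = interval,
         times = times, n_per_timepoint = n_per_timepoint, n_total = n_total,
         n_conditions = as.integer(n_conditions), seed = seed),
    class = "design_spec")
}

#' Build the sample table for an experimental design
#'
#' Expands a [design_spec()] into one row per sample, with a unique sample id,
#' a 1-based integer condition id, and a sampling time in hours. The result is
#' deterministic given the spec (including its \code{seed} in uniform mode).
#'
#' @param spec A \code{"design_spec"} object (or arguments forwarded to
#'   [design_spec()] when \code{spec} is missing).
#' @param ... Forwarded to [design_spec()] when \code{spec} is not supplied.
#'
#' @return A data frame of class \code{"rhythm_design"} with columns
#'   \code{sample} (character, \code{"sample_<cond>_<k>"}), \code{cond}
#'   (integer) and \code{time} (hours). The spec is kept in attribute
#'   \code{"spec"}.
#' @examples
#' d = build_design(design_spec())          # default: 0-48 h by 3 h, 2 reps
#' nrow(d)                                  # 17 time points x 2 = 34 samples
#' @export
build_design = function(spec, ...) {
  if (missing(spec)) spec = design_spec(...)
  stopifnot(inherits(spec, "design_spec"))

  times_one_cond = switch(
    spec$mode,
    interval = {
      n_steps = floor((spec$last - spec$first) / spec$interval + 1e-9)
      tp = spec$first + spec$interval * seq.int(0L, n_steps)
      rep(tp, each = spec$n_per_timepoint)
    },
    explicit = {
      reps = rep_len(spec$n_per_timepoint, length(spec$times))
      rep(spec$times, times = reps)
    },
    uniform = NULL)

  draw_uniform = function() {
    stats::runif(spec$n_total, spec$first, spec$last)
  }

  if (spec$mode == "uniform" && !is.null(spec$seed)) {
    old = get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(spec$seed)
  }

  rows = lapply(seq_len(spec$n_conditions), function(k) {
    tms = if (spec$mode == "uniform") draw_uniform() else times_one_cond
    data.frame(sample = sprintf("sample_%d_%d", k, seq_along(tms)),
               cond = k, time = tms, stringsAsFactors = FALSE)
  })
  out = do.call(rbind, rows)
  rownames(out) = NULL
  structure(out, spec = spec, class = c("rhythm_design", "data.frame"))
}

# restore (or clear) the global RNG state saved before a seeded section
restore_rng = function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.rhythm_design = function(x, ...) {
  spec = attr(x, "spec")
  cat(sprintf("Experimental design (%s mode): %d samples, %d condition(s), %d distinct time(s)\n",
              spec$mode, nrow(x), spec$n_conditions,
              length(unique(x$time))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Write or read a design's sample-metadata table
#'
#' Tab-delimited with columns \code{sample}, \code{cond}, \code{time}.
#'
#' @param design A \code{"rhythm_design"} data frame.
#' @param path File path.
#' @return \code{read_design} returns a data frame with the three columns.
#' @export
write_design = function(design, path) {
  utils::write.table(as.data.frame(design)[, c("sample", "cond", "time")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design = function(path) {
  out = utils::read.delim(path, stringsAsFactors = FALSE)
  need = c("sample", "cond", "time")
  miss = setdiff(need, names(out))
  if (length(miss))
    stop("design table is missing column(s): ", paste(miss, collapse = ", "))
  out
}
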