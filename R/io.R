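# Registered named built-ins usable in config files, where arbitrary R code
# is deliberately not allowed. Each entry maps (numeric args) -> function.

.waveform_registry = list(
  sin = function() sin,
  cos = function() cos,
  square = function() function(theta) sign(sin(theta)),
  triangle = function() function(theta) (2 / pi) * asin(sin(theta)))

.trend_registry = list(
  constant = function(value = 0) function(t) rep_len(value, length(t)),
  # damped rhythm / decaying baseline: value * exp(-rate * t)
  exp_decay = function(value = 1, rate = 1 / 24)
    function(t) value * exp(-rate * t),
  # linear drift: value + slope * t
  linear_drift = function(value = 0, slope = 0)
    function(t) value + slope * t)

resolve_registered = function(x, registry, what) {
  if (is.numeric(x)) return(x)
  if (is.character(x)) x = list(name = x)
  if (!is.list(x) || is.null(x$name))
    stop("'", what, "' must be numeric or a registered name with arguments")
  maker = registry[[x$name]]
  if (is.null(maker))
    stop("unknown ", what, " '", x$name, "'; available: ",
         paste(names(registry), collapse = ", "))
  args = x[setdiff(names(x), "name")]
  do.call(maker, args)
}

#' Default simulation configuration
#'
#' A fully populated configuration: one condition, the default design
#' (0-48 h every 3 h, 2 samples per time point), and a single Gaussian
#' feature group with amplitude 0, baseline 0, period 24 h, sine waveform
#' and unit standard deviation.
#'
#' @return A named list of class \code{"sim_config"}.
#' @export
default_config = function() {
  structure(list(
    seed = NULL,
    design = list(mode = "interval", first = 0, last = 48, interval = 3,
                  n_per_timepoint = 2, n_conditions = 1),
    groups = list(list(n_features = 1, amp = 0, phase = 0, period = 24,
                       base = 0, waveform = "sin", family = "gaussian",
                       sd = 1))),
    class = "sim_config")
}

.design_keys = c("mode", "first", "last", "interval", "times",
                 "n_per_timepoint", "n_total", "n_conditions", "seed")
.group_keys = c("n_features", "amp", "phase", "period", "base", "waveform",
                "family", "sd", "dispersion")

#' Load and validate a simulation configuration
#'
#' Configurations are YAML with three top-level sections — \code{seed},
#' \code{design} and \code{groups} — all optional; omitted values take the
#' defaults of [default_config()]. Functional parameters are expressed as
#' registered built-ins: waveforms \code{sin}, \code{cos}, \code{square},
#' \code{triangle}; amplitude/baseline trends \code{constant},
#' \code{exp_decay} (\code{value}, \code{rate}) and \code{linear_drift}
#' (\code{value}, \code{slope}), written as \code{{name: exp_decay, value: 2,
#' rate: 0.05}}. The dispersion curve accepts \code{{alpha0: ..., alpha1:
#' ...}} overriding [default_dispersion()]'s parameters. Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated \code{"sim_config"} list with all defaults filled.
#' @seealso [save_config()], [config_inputs()], [run_simulate()]
#' @export
load_config = function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw = yaml::read_yaml(path)
  if (is.null(raw)) raw = list()
  as_sim_config(raw)
}

#' @rdname load_config
#' @param config A configuration list (possibly partial).
#' @export
as_sim_config = function(config) {
  stopifnot(is.list(config))
  base = unclass(default_config())
  unknown = setdiff(names(config), c(names(base), "seed"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) base$seed = as.integer(config$seed)
  if (!is.null(config$design)) {
    unknown = setdiff(names(config$design), .design_keys)
    if (length(unknown))
      stop("unknown design key(s): ", paste(unknown, collapse = ", "))
    base$design = utils::modifyList(base$design, config$design)
  }
  if (!is.null(config$groups)) {
    if (!is.list(config$groups) || length(config$groups) == 0L)
      stop("'groups' must be a non-empty list")
    for (g in config$groups) {
      unknown = setdiff(names(g), .group_keys)
      if (length(unknown))
        stop("unknown group key(s): ", paste(unknown, collapse = ", "))
    }
    base$groups = config$groups
  }
  cfg = structure(base, class = "sim_config")
  config_inputs(cfg)  # full validation: every field must build
  cfg
}

#' Save a configuration as YAML
#'
#' @param config A \code{"sim_config"} list.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
save_config = function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Translate a configuration into simulator inputs
#'
#' @param config A \code{"sim_config"} list.
#' @return A list with elements \code{design} (a \code{"design_spec"}),
#'   \code{groups} (list of [feature_group()] objects) and \code{seed}.
#' @export
config_inputs = function(config) {
  d = config$design
  spec_args = d[!vapply(d, is.null, logical(1L))]
  spec = do.call(design_spec, spec_args)
  groups = lapply(config$groups, function(g) {
    args = list(
      n_features = g$n_features %||% 1,
      amp = resolve_registered(g$amp %||% 0, .trend_registry, "amp"),
      phase = g$phase %||% 0,
      period = g$period %||% 24,
      base = resolve_registered(g$base %||% 0, .trend_registry, "base"),
      waveform = resolve_registered(g$waveform %||% "sin",
                                    .waveform_registry, "waveform"),
      family = g$family %||% "gaussian",
      sd = g$sd %||% 1)
    if (!is.null(g$dispersion)) {
      dp = g$dispersion
      if (!is.list(dp) ||
          length(setdiff(names(dp), c("alpha0", "alpha1"))) > 0L)
        stop("'dispersion' must be a list with keys alpha0 and/or alpha1")
      a0 = dp$alpha0 %||% 0.01
      a1 = dp$alpha1 %||% 2
      args$dispersion = function(mu) default_dispersion(mu, a0, a1)
    }
    do.call(feature_group, args)
  })
  list(design = spec, groups = groups, seed = config$seed)
}

`%||%` = function(a, b) if (is.null(a)) b else a

#' Run a configured simulation and write its outputs
#'
#' Writes four files to \code{out_dir}: \code{abundance.tsv} (long-format
#' measurements), \code{features.tsv} (ground truth), \code{samples.tsv}
#' (design metadata) and \code{manifest.yaml} (seed, package version and a
#' full echo of the configuration).
#'
#' @param config A \code{"sim_config"}, a path to a YAML config, or a partial
#'   list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
run_simulate = function(config = default_config(), out_dir, seed = NULL,
                        quiet = FALSE) {
  if (is.character(config)) config = load_config(config)
  if (!inherits(config, "sim_config")) config = as_sim_config(config)
  if (!is.null(seed)) config$seed = as.integer(seed)
  inputs = config_inputs(config)
  say = function(...) if (!quiet) message(...)
  say("seed: ", if (is.null(inputs$seed)) "none (non-reproducible)"
      else inputs$seed)

  say("building design (", inputs$design$mode, " mode)")
  say("simulating ",
      sum(vapply(inputs$groups, function(g) g$n_features, integer(1L))),
      " feature(s) per condition")
  sim = simulate_rhythms(inputs$design, inputs$groups, seed = inputs$seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths = c(abundance = file.path(out_dir, "abundance.tsv"),
            features = file.path(out_dir, "features.tsv"),
            samples = file.path(out_dir, "samples.tsv"),
            manifest = file.path(out_dir, "manifest.yaml"))
  say("writing tables to ", out_dir)
  write_abundance(sim$abundance, paths[["abundance"]])
  write_feature_table(sim$features, paths[["features"]])
  write_design(sim$design, paths[["samples"]])
  manifest = list(
    package = "rhythmsim",
    version = as.character(utils::packageVersion("rhythmsim")),
    seed = inputs$seed,
    config = unclass(config))
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

#' Evaluate rhythm detection from files
#'
#' Reads a written abundance table and ground-truth feature table, runs the
#' cosinor detector, scores AUROC per (amplitude, baseline) group against the
#' pooled amplitude-0 features, and writes a tab-delimited result with
#' columns \code{amp}, \code{base}, \code{interval}, \code{auroc} (interval
#' is the median spacing of the distinct sample times).
#'
#' @param abund_path Path to an abundance table (from [run_simulate()]).
#' @param truth_path Path to the matching feature table.
#' @param out_path Output TSV path.
#' @param cond Condition to evaluate (default 1).
#' @param period Candidate period in hours (default 24).
#' @return Invisibly, the evaluation data frame.
#' @export
run_evaluate = function(abund_path, truth_path, out_path, cond = 1L,
                        period = 24) {
  ab = read_abundance(abund_path)
  truth = read_feature_table(truth_path)
  ev = evaluate_detection(ab, features = truth, cond = cond, period = period)
  tms = sort(unique(ab$time[ab$cond == cond]))
  interval = if (length(tms) > 1L) stats::median(diff(tms)) else NA_real_
  out = data.frame(amp = ev$amp, base = ev$base, interval = interval,
                   auroc = ev$auroc)
  utils::write.table(format_num_df(out), out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Write or read a long-format abundance table
#'
#' Tab-delimited columns: \code{feature}, \code{sample}, \code{cond},
#' \code{time}, \code{mu} (expected abundance on the model scale, 6
#' significant digits) and \code{abund} (sampled measurement; integer counts
#' for the negative binomial family).
#'
#' @param abundance Long-format abundance data frame.
#' @param path File path.
#' @return \code{read_abundance} returns the data frame.
#' @export
write_abundance = function(abundance, path) {
  if (all(abundance$abund == round(abundance$abund)) &&
      max(abs(abundance$abund)) < .Machine$integer.max)
    abundance$abund = as.integer(round(abundance$abund))  # counts stay exact
  utils::write.table(format_num_df(abundance), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance = function(path) {
  out = utils::read.delim(path, stringsAsFactors = FALSE)
  need = c("feature", "sample", "cond", "time", "mu", "abund")
  miss = setdiff(need, names(out))
  if (length(miss))
    stop("abundance table is missing column(s): ",
         paste(miss, collapse = ", "))
  out
}
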