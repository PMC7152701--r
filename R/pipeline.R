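# Config documents are YAML with top-level fields:
#   fixture: <name>                 (or a full `experiment:` block)
#   experiment: {label, cues, weights?, conditions: {baseline, interference}}
#     each condition: {chunks: [{id, features, creation_time?}], fan?}
#   target: {mean_ms, sd_ms? , cri_low_ms?, cri_high_ms?}
#   prior: {shape_a, shape_b}
#   preset: default | simulation
#   params: {F?, f?, tau?, d?, ANS?, MAS?, MP?, beta?}   (overrides)
#   n_accept, k, n_mc, seed
config_fields <- c("fixture", "experiment", "target", "prior", "preset",
                   "params", "n_accept", "k", "n_mc", "seed")

#' Serialise an experiment to a config list
#'
#' Produces the plain-list representation used in YAML config documents;
#' [experiment_from_config()] inverts it exactly (fan counts and weights
#' are written out explicitly, so the round trip is lossless).
#'
#' @param experiment an [experiment_spec()].
#' @return A named list suitable for `yaml::write_yaml()`.
#' @export
experiment_to_config <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_spec"))
  cond_cfg <- function(cond) {
    list(
      chunks = lapply(cond$chunks, function(ch) {
        out <- list(id = ch$id, features = ch$features)
        if (!is.null(ch$creation_time)) out$creation_time <- ch$creation_time
        out
      }),
      fan = as.list(cond$cues$fan)
    )
  }
  base <- experiment$baseline
  list(
    label = experiment$label,
    cues = base$cues$cues,
    weights = as.list(base$cues$weights),
    conditions = list(
      baseline = cond_cfg(experiment$baseline),
      interference = cond_cfg(experiment$interference)
    )
  )
}

#' Build an experiment from a config list
#'
#' @param cfg a list with fields `cues`, `conditions$baseline`,
#'   `conditions$interference` and optionally `weights`, `label` (the
#'   shape written by [experiment_to_config()]).
#' @return An [experiment_spec()].
#' @export
experiment_from_config <- function(cfg) {
  for (fld in c("cues", "conditions")) {
    if (is.null(cfg[[fld]])) {
      stop("config error: experiment is missing field '", fld, "'",
           call. = FALSE)
    }
  }
  for (cn in c("baseline", "interference")) {
    if (is.null(cfg$conditions[[cn]])) {
      stop("config error: experiment is missing condition '", cn, "'",
           call. = FALSE)
    }
  }
  parse_cond <- function(ccfg, name) {
    if (is.null(ccfg$chunks) || length(ccfg$chunks) == 0L) {
      stop("config error: condition '", name, "' has no chunks",
           call. = FALSE)
    }
    chunks <- lapply(ccfg$chunks, function(ch) {
      if (is.null(ch$id) || is.null(ch$features)) {
        stop("config error: every chunk needs 'id' and 'features'",
             call. = FALSE)
      }
      chunk(ch$id, ch$features, creation_time = ch$creation_time)
    })
    cues <- cue_set(cfg$cues, weights = cfg$weights, fan = ccfg$fan)
    condition_spec(chunks, cues, name = name)
  }
  experiment_spec(
    baseline = parse_cond(cfg$conditions$baseline, "baseline"),
    interference = parse_cond(cfg$conditions$interference, "interference"),
    label = cfg$label
  )
}

resolve_config <- function(config) {
  if (inherits(config, "fixture")) {
    return(list(fixture = config$name))
  }
  if (is.character(config) && length(config) == 1L) {
    if (file.exists(config)) {
      config <- yaml::read_yaml(config)
    } else if (config %in% list_fixtures()) {
      config <- list(fixture = config)
    } else {
      stop("config error: '", config, "' is neither a config file nor a ",
           "fixture name", call. = FALSE)
    }
  }
  if (!is.list(config)) {
    stop("config error: expected a list, a YAML path or a fixture name",
         call. = FALSE)
  }
  unknown <- setdiff(names(config), config_fields)
  if (length(unknown)) {
    stop("config error: unknown field '", unknown[1], "'", call. = FALSE)
  }
  if (is.null(config$fixture) && is.null(config$experiment)) {
    stop("config error: need either 'fixture' or 'experiment'",
         call. = FALSE)
  }
  config
}

# Assemble experiment/target/prior/params from a resolved config,
# letting explicit config entries override fixture contents.
build_run_inputs <- function(cfg) {
  if (!is.null(cfg$fixture)) {
    fx <- load_fixture(cfg$fixture)
    experiment <- fx$experiment
    target <- fx$target
    prior <- fx$prior
    params <- fx$params
  } else {
    experiment <- experiment_from_config(cfg$experiment)
    target <- NULL
    prior <- prior_spec(2, 6)
    params <- model_params(preset = "simulation")
  }
  if (!is.null(cfg$target)) {
    t <- cfg$target
    if (is.null(t$mean_ms)) {
      stop("config error: target needs 'mean_ms'", call. = FALSE)
    }
    target <- observed_target(t$mean_ms, sd_ms = t$sd_ms,
                              cri_low_ms = t$cri_low_ms,
                              cri_high_ms = t$cri_high_ms)
  }
  if (is.null(target)) {
    stop("config error: need a 'target' (mean_ms with sd_ms or CrI)",
         call. = FALSE)
  }
  if (!is.null(cfg$prior)) {
    if (is.null(cfg$prior$shape_a) || is.null(cfg$prior$shape_b)) {
      stop("config error: prior needs 'shape_a' and 'shape_b'",
           call. = FALSE)
    }
    prior <- prior_spec(cfg$prior$shape_a, cfg$prior$shape_b)
  }
  if (!is.null(cfg$preset)) {
    params <- model_params(preset = cfg$preset)
  }
  if (!is.null(cfg$params)) {
    params <- do.call(model_params,
                      c(cfg$params,
                        list(preset = if (!is.null(cfg$preset)) cfg$preset
                             else "simulation")))
  }
  list(experiment = experiment, target = target, prior = prior,
       params = params, fixture = cfg$fixture)
}

#' Run the full ABC pipeline
#'
#' Prior definition, ABC rejection sampling of the latency factor, and
#' the posterior predictive distribution of the interference effect, with
#' all artifacts written to an output directory: `samples.csv` (accepted
#' draws), `predictive.csv` (posterior predictive draws), and
#' `metadata.json` (seed, proposal counts, acceptance rate, band, and the
#' full parameter set, for provenance). Re-running with the same seed
#' reproduces the outputs byte for byte.
#'
#' @param config a fixture name, a path to a YAML config document, or a
#'   config list (see the package vignette for the schema).
#' @param out_dir output directory (created if needed); `NULL` writes no
#'   files.
#' @param n_accept,k,n_mc,seed override the corresponding config entries;
#'   defaults (used when neither argument nor config supplies a value) are
#'   2000, 1, 5000 and 1.
#' @param n_predictive posterior predictive draws (default 2000).
#' @param resimulate regenerate predictive effects with fresh noise
#'   (default) or reuse accepted effects.
#' @param plots also write density PNGs (posterior and predictive).
#' @param quiet suppress progress logging.
#' @return (invisibly) a list with `posterior`, `predictive`, `band`,
#'   `inputs` and `paths`.
#' @examples
#' \donttest{
#' res <- run_pipeline("jaeger_agreement", out_dir = tempfile(),
#'                     n_accept = 100, n_mc = 1000, seed = 1)
#' res$posterior
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, n_accept = NULL, k = NULL,
                         n_mc = NULL, seed = NULL, n_predictive = 2000L,
                         resimulate = TRUE, plots = FALSE, quiet = TRUE) {
  cfg <- resolve_config(config)
  inputs <- build_run_inputs(cfg)
  pick <- function(arg, cfg_val, default) {
    if (!is.null(arg)) arg else if (!is.null(cfg_val)) cfg_val else default
  }
  n_accept <- pick(n_accept, cfg$n_accept, 2000L)
  k <- pick(k, cfg$k, 1)
  n_mc <- pick(n_mc, cfg$n_mc, 5000L)
  seed <- pick(seed, cfg$seed, 1L)

  simulator <- make_simulator(inputs$experiment, inputs$params,
                              n_mc = n_mc,
                              master_seed = substream_seed(seed, 1))
  posterior <- abc_reject(inputs$prior, simulator, inputs$target,
                          n_accept = n_accept, k = k,
                          seed = substream_seed(seed, 2),
                          progress_every = if (quiet) Inf else 1e4)
  predictive <- posterior_predictive(posterior, simulator,
                                     n_draws = n_predictive,
                                     resimulate = resimulate,
                                     seed = substream_seed(seed, 3))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      samples = file.path(out_dir, "samples.csv"),
      predictive = file.path(out_dir, "predictive.csv"),
      metadata = file.path(out_dir, "metadata.json")
    )
    utils::write.csv(
      data.frame(draw_index = seq_along(posterior$theta),
                 theta = posterior$theta,
                 effect_ms = posterior$effect_ms),
      paths$samples, row.names = FALSE)
    utils::write.csv(
      data.frame(draw_index = seq_along(predictive$effects_ms),
                 theta = predictive$theta,
                 effect_ms = predictive$effects_ms),
      paths$predictive, row.names = FALSE)
    meta <- list(
      fixture = inputs$fixture,
      seed = seed,
      n_accept = n_accept,
      k = k,
      n_mc = n_mc,
      n_predictive = n_predictive,
      resimulate = resimulate,
      n_proposed = posterior$n_proposed,
      acceptance_rate = posterior$acceptance_rate,
      band_ms = as.list(posterior$band),
      prior = list(shape_a = inputs$prior$shape_a,
                   shape_b = inputs$prior$shape_b),
      target = list(mean_ms = inputs$target$mean_ms,
                    sd_ms = inputs$target$sd_ms),
      params = unclass(inputs$params)
    )
    jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    if (plots) {
      grDevices::png(file.path(out_dir, "posterior.png"), 640, 480)
      plot(posterior)
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, "predictive.png"), 640, 480)
      plot(predictive)
      grDevices::dev.off()
      paths$plots <- file.path(out_dir, c("posterior.png",
                                          "predictive.png"))
    }
  }
  invisible(list(posterior = posterior, predictive = predictive,
                 band = posterior$band, inputs = inputs, paths = paths))
}
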