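#' Specify a two-condition interference experiment
#'
#' Pairs a baseline retrieval condition with an interference condition.
#' The interference effect is the contrast
#' `mean latency(interference) - mean latency(baseline)` in milliseconds,
#' so facilitatory interference is negative.
#'
#' @param baseline,interference [condition_spec()] objects sharing the
#'   same cue names.
#' @param label optional experiment label.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(baseline, interference, label = NULL) {
  stopifnot(inherits(baseline, "condition_spec"),
            inherits(interference, "condition_spec"))
  if (!identical(sort(names(baseline$cues$cues)),
                 sort(names(interference$cues$cues)))) {
    stop("invalid spec: cue names must be identical across conditions",
         call. = FALSE)
  }
  structure(list(baseline = baseline, interference = interference,
                 label = label),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("Interference experiment",
      if (!is.null(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  baseline    :", paste(x$baseline$ids, collapse = ", "), "\n")
  cat("  interference:", paste(x$interference$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the mean interference effect for one parameter setting
#'
#' Runs `n_mc` Monte-Carlo retrievals per condition, averages the
#' latencies (failed retrievals contribute their time-to-threshold
#' latency; dropping them would bias the contrast), converts to
#' milliseconds, and returns the contrast
#' `interference - baseline`.
#'
#' @param experiment an [experiment_spec()].
#' @param params a [model_params()].
#' @param n_mc Monte-Carlo retrievals per condition (>= 1).
#' @param crn use common random numbers: one logistic noise stream shared
#'   across the two conditions (variance reduction; makes the effect
#'   exactly 0 for identical conditions and exactly linear in `F`).
#' @param keep_draws also return the per-run latencies (ms) per condition.
#' @return An object of class `effect_prediction` with fields
#'   `effect_ms`, `mean_baseline_ms`, `mean_interference_ms`, `n_mc`,
#'   `failure_rate` (named, per condition) and optionally `draws_ms`.
#' @examples
#' fx <- load_fixture("jaeger_agreement")
#' set.seed(1)
#' predict_effect(fx$experiment, model_params(preset = "simulation"),
#'                n_mc = 1000)
#' @export
predict_effect <- function(experiment, params = model_params(),
                           n_mc = 5000L, crn = FALSE,
                           keep_draws = FALSE) {
  stopifnot(inherits(experiment, "experiment_spec"))
  params <- validate_model_params(params)
  if (!is.numeric(n_mc) || length(n_mc) != 1L || n_mc < 1) {
    stop("`n_mc` must be a single count >= 1", call. = FALSE)
  }
  n_mc <- as.integer(n_mc)

  a0 <- condition_activations(experiment, params)
  effect_core(a0, params, n_mc, crn, keep_draws)
}

condition_activations <- function(experiment, params) {
  lapply(list(baseline = experiment$baseline,
              interference = experiment$interference),
         function(cond) {
           vapply(cond$chunks, noiseless_activation, numeric(1),
                  cues = cond$cues, params = params)
         })
}

# Shared Monte-Carlo core working from precomputed noiseless activations;
# make_simulator() calls this directly so the condition structure is not
# re-traversed on every ABC proposal.
effect_core <- function(a0, params, n_mc, crn = FALSE,
                        keep_draws = FALSE) {
  shared_eps <- if (crn) noise_matrix(n_mc, max(lengths(a0)), params$ANS)
  means <- fails <- numeric(2)
  draws <- list()
  for (i in 1:2) {
    eps <- if (crn) shared_eps else
      noise_matrix(n_mc, length(a0[[i]]), params$ANS)
    res <- simulate_latencies(a0[[i]], params, n_mc, eps)
    means[i] <- mean(res$latency_s) * 1000
    fails[i] <- mean(res$fail)
    if (keep_draws) draws[[names(a0)[i]]] <- res$latency_s * 1000
  }
  out <- list(
    effect_ms = means[2] - means[1],
    mean_baseline_ms = means[1],
    mean_interference_ms = means[2],
    n_mc = n_mc,
    failure_rate = stats::setNames(fails, names(a0))
  )
  if (keep_draws) out$draws_ms <- draws
  structure(out, class = "effect_prediction")
}

#' @export
print.effect_prediction <- function(x, ...) {
  cat(sprintf(
    "Predicted interference effect: %.2f ms (baseline %.1f ms, interference %.1f ms; n_mc = %d)\n",
    x$effect_ms, x$mean_baseline_ms, x$mean_interference_ms, x$n_mc))
  invisible(x)
}

# Deterministic sub-seed for call `i` under a master seed; kept below 2^31.
substream_seed <- function(master_seed, i) {
  x <- ((as.double(master_seed) %% 2147483647) * 48271 +
          1103 * as.double(i)) %% 2147483647
  as.integer(x)
}

#' Build an effect simulator over the latency factor
#'
#' Returns a function `theta -> effect_ms` that substitutes `theta` for
#' the latency factor `F` in `params` and calls [predict_effect()]. This
#' is the simulator the ABC rejection loop and the predictive
#' distributions call.
#'
#' With a `master_seed`, every call runs on its own deterministic
#' sub-stream (indexed by an internal call counter, or by an explicit
#' `call_index` argument for exact replay); the caller's random-number
#' state is left untouched. Without one, the global RNG stream is used.
#'
#' @inheritParams predict_effect
#' @param master_seed optional integer master seed.
#' @return A function `function(theta, call_index = NULL)` returning the
#'   predicted effect in ms. `theta` must be a single value in `[0, Inf)`.
#' @examples
#' fx <- load_fixture("jaeger_agreement")
#' sim <- make_simulator(fx$experiment,
#'                       model_params(preset = "simulation"),
#'                       n_mc = 1000, master_seed = 7)
#' sim(0.1)
#' sim(0.1, call_index = 1) # replays call 1 exactly
#' @export
make_simulator <- function(experiment, params = model_params(),
                           n_mc = 5000L, master_seed = NULL,
                           crn = FALSE) {
  stopifnot(inherits(experiment, "experiment_spec"))
  params <- validate_model_params(params)
  n_mc <- as.integer(n_mc)
  a0 <- condition_activations(experiment, params) # F-independent
  counter <- 0L
  function(theta, call_index = NULL) {
    if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
        theta < 0) {
      stop("`theta` (latency factor) must be a single number in [0, Inf)",
           call. = FALSE)
    }
    p <- params
    p$F <- theta
    if (is.null(master_seed)) {
      return(effect_core(a0, p, n_mc, crn)$effect_ms)
    }
    if (is.null(call_index)) {
      counter <<- counter + 1L
      call_index <- counter
    }
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(substream_seed(master_seed, call_index))
    effect_core(a0, p, n_mc, crn)$effect_ms
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
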