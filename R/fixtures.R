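# Canonical two-chunk ungrammatical-interference design. The retrieval
# target matches one of the two cues; the distractor matches both cues in
# the interference condition and neither in the baseline, so with noise
# switched off the interference condition is retrieved strictly faster
# (facilitatory, negative effect) for any positive latency factor. Cue
# names are cosmetic (agreement vs reflexive flavour); the structure is an
# illustrative stand-in for the condition files of the original studies,
# not a replica.
interference_experiment <- function(cue_names = c("number", "person"),
                                    match_val = c("sg", "3"),
                                    target_val = c("pl", "3"),
                                    base_distractor_val = c("pl", "1"),
                                    label = NULL) {
  cues <- stats::setNames(as.list(match_val), cue_names)
  target <- chunk("target", stats::setNames(as.list(target_val), cue_names))
  dist_int <- chunk("distractor",
                    stats::setNames(as.list(match_val), cue_names))
  dist_base <- chunk("distractor",
                     stats::setNames(as.list(base_distractor_val),
                                     cue_names))
  experiment_spec(
    baseline = condition_spec(list(target, dist_base), cues,
                              name = "baseline"),
    interference = condition_spec(list(target, dist_int), cues,
                                  name = "interference"),
    label = label
  )
}

fixture_registry <- function() {
  list(
    dillon_agreement = list(
      target = observed_target(-60, 33, cri_low_ms = -112, cri_high_ms = -5),
      cue_names = c("number", "person"),
      notes = paste("Agreement interference in ungrammatical conditions,",
                    "smaller-sample eye-tracking estimate:",
                    "Normal(-60, 33^2), CrI [-112, -5] ms.")
    ),
    dillon_reflexive = list(
      target = observed_target(-18, 27, cri_low_ms = -72, cri_high_ms = 36),
      cue_names = c("gender", "animacy"),
      notes = paste("Reflexive interference in ungrammatical conditions,",
                    "smaller-sample estimate: Normal(-18, 27^2),",
                    "CrI [-72, 36] ms.")
    ),
    jaeger_agreement = list(
      target = observed_target(-22, 13, cri_low_ms = -46, cri_high_ms = 3),
      cue_names = c("number", "person"),
      notes = paste("Agreement interference, large-sample replication",
                    "estimate: Normal(-22, 13^2), CrI [-46, 3] ms.")
    ),
    jaeger_reflexive = list(
      target = observed_target(-23, 13, cri_low_ms = -48, cri_high_ms = 2),
      cue_names = c("gender", "animacy"),
      notes = paste("Reflexive interference, large-sample replication",
                    "estimate: Normal(-23, 13^2), CrI [-48, 2] ms.")
    )
  )
}

#' List the packaged interference fixtures
#'
#' @return Character vector of fixture names usable with
#'   [load_fixture()].
#' @export
list_fixtures <- function() {
  names(fixture_registry())
}

#' Load a packaged interference fixture
#'
#' Each fixture bundles a two-condition interference experiment, the
#' observed-effect target (mean and SD of its normal approximation, plus
#' the 95% credible interval it came from), the `Beta(2, 6)` prior and
#' the `"simulation"` parameter preset. The chunk/cue structure is an
#' illustrative canonical design (see the package vignette), not a replica
#' of the original studies' condition files; the targets are the published
#' effect estimates.
#'
#' @param name one of [list_fixtures()].
#' @return An object of class `fixture`: `name`, `experiment`, `target`,
#'   `prior`, `params`, `notes`.
#' @examples
#' fx <- load_fixture("jaeger_agreement")
#' fx$target$mean_ms
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available fixtures: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  entry <- reg[[name]]
  is_gender <- identical(entry$cue_names[1], "gender")
  exp <- if (is_gender) {
    interference_experiment(cue_names = entry$cue_names,
                            match_val = c("masc", "animate"),
                            target_val = c("fem", "animate"),
                            base_distractor_val = c("fem", "inanimate"),
                            label = name)
  } else {
    interference_experiment(cue_names = entry$cue_names, label = name)
  }
  structure(list(
    name = name,
    experiment = exp,
    target = entry$target,
    prior = prior_spec(2, 6),
    params = model_params(preset = "simulation"),
    notes = entry$notes
  ), class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat("Fixture '", x$name, "': target ", x$target$mean_ms, " ms (SD ",
      x$target$sd_ms, " ms), Beta(", x$prior$shape_a, ", ",
      x$prior$shape_b, ") prior\n", sep = "")
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' Deterministic toy simulator
#'
#' The linear map `delta(theta) = slope * theta`, used as an analytic
#' oracle for the rejection sampler: with a deterministic monotone
#' simulator the ABC posterior must equal the prior truncated to the
#' preimage of the acceptance band.
#'
#' @param slope nonzero slope (ms per unit latency factor).
#' @return A function `theta -> effect_ms`.
#' @examples
#' toy_simulator(100)(0.2) # 20
#' @export
toy_simulator <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope == 0) {
    stop("`slope` must be a single nonzero number", call. = FALSE)
  }
  function(theta, call_index = NULL) slope * theta
}
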