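#' Model parameters for the cue-based retrieval model
#'
#' Constructs the set of eight parameters governing activation, noise and
#' latency in the simplified cue-based retrieval model. Defaults follow the
#' standard defaults of the ACT-R declarative-memory framework; the
#' `"simulation"` preset carries the values used in large-scale evaluations
#' of the model against published reading experiments (MAS = 1.5,
#' MP = 0.25).
#'
#' @param F latency factor (seconds); scales retrieval latency
#'   `T = F * exp(-f * A)` onto the reading-time scale. Millisecond
#'   conversion happens once, in [predict_effect()].
#' @param f latency exponent (unitless).
#' @param tau retrieval threshold (activation units); a retrieval fails
#'   when no candidate's sampled activation reaches `tau`.
#' @param d base-level decay rate (unitless, in \[0, 1\]).
#' @param ANS activation noise scale of the logistic noise added to each
#'   chunk's activation per retrieval attempt (activation units).
#' @param MAS maximum associative strength (activation units).
#' @param MP mismatch penalty per mismatching retrieval cue
#'   (activation units).
#' @param beta base-level activation constant (activation units).
#' @param preset either `"default"` or `"simulation"`; selects a named set
#'   of values which individual arguments may then override.
#'
#' @return An object of class `model_params`: a named list of the eight
#'   parameters.
#' @examples
#' model_params()
#' model_params(preset = "simulation")
#' model_params(F = 0.15, ANS = 0)
#' @export
model_params <- function(F = NULL, f = NULL, tau = NULL, d = NULL,
                         ANS = NULL, MAS = NULL, MP = NULL, beta = NULL,
                         preset = c("default", "simulation")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    default    = list(F = 0.2, f = 1, tau = -1.5, d = 0.5,
                      ANS = 0.2, MAS = 1,   MP = 1,    beta = 0),
    simulation = list(F = 0.2, f = 1, tau = -1.5, d = 0.5,
                      ANS = 0.2, MAS = 1.5, MP = 0.25, beta = 0)
  )
  override <- list(F = F, f = f, tau = tau, d = d, ANS = ANS,
                   MAS = MAS, MP = MP, beta = beta)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) p[[nm]] <- override[[nm]]
  }
  validate_model_params(structure(p, class = "model_params"))
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("F", "f", "tau", "d", "ANS", "MAS", "MP", "beta")) {
    if (!num1(p[[nm]])) {
      stop("model parameter `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$F < 0)   stop("latency factor `F` must be >= 0", call. = FALSE)
  if (p$f < 0)   stop("latency exponent `f` must be >= 0", call. = FALSE)
  if (p$ANS < 0) stop("activation noise `ANS` must be >= 0", call. = FALSE)
  if (p$MP < 0)  stop("mismatch penalty `MP` must be >= 0", call. = FALSE)
  if (p$d < 0 || p$d > 1) {
    stop("decay rate `d` must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cue-based retrieval model parameters:\n")
  vals <- unlist(x[c("F", "f", "tau", "d", "ANS", "MAS", "MP", "beta")])
  print(vals)
  invisible(x)
}
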