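#' Base-level activation of a chunk
#'
#' Returns the constant base level `beta` when the chunk has no encoding
#' time, or the single-presentation decayed level
#' `beta - d * log(creation_time)` when it does. The simplified model
#' abstracts away from incremental parsing, so no multi-presentation
#' history exists.
#'
#' @param chunk a [chunk()].
#' @param params a [model_params()].
#' @return Base-level activation (activation units).
#' @examples
#' base_level(chunk("x", c(a = "1")), model_params())            # beta = 0
#' base_level(chunk("x", c(a = "1"), creation_time = 4),
#'            model_params())                                    # -0.5*log(4)
#' @export
base_level <- function(chunk, params = model_params()) {
  stopifnot(inherits(chunk, "chunk"))
  params <- validate_model_params(params)
  if (is.null(chunk$creation_time)) {
    return(params$beta)
  }
  params$beta - params$d * log(chunk$creation_time)
}

#' Spreading activation received by a chunk from the retrieval cues
#'
#' Each cue `j` the chunk matches contributes
#' `weights[j] * (MAS - log(fan[j]))`; cues the chunk does not match
#' contribute nothing here (their cost is the mismatch penalty).
#'
#' @inheritParams base_level
#' @param cues a [cue_set()] with fan counts filled in.
#' @return Spreading activation (activation units).
#' @export
spreading_activation <- function(chunk, cues, params = model_params()) {
  stopifnot(inherits(chunk, "chunk"), inherits(cues, "cue_set"))
  params <- validate_model_params(params)
  if (is.null(cues$fan)) {
    stop("invalid spec: cue set has no fan counts; build the cue set ",
         "through condition_spec() or supply `fan`", call. = FALSE)
  }
  if (any(cues$fan < 1)) {
    stop("invalid spec: fan counts must be >= 1", call. = FALSE)
  }
  s <- 0
  for (j in names(cues$cues)) {
    if (identical(chunk$features[[j]], cues$cues[[j]])) {
      s <- s + cues$weights[[j]] * (params$MAS - log(cues$fan[[j]]))
    }
  }
  s
}

#' Mismatch penalty incurred by a chunk
#'
#' `-MP` per retrieval cue whose required value the chunk does not carry
#' (missing features count as mismatches). Always non-positive.
#'
#' @inheritParams spreading_activation
#' @return Penalty (activation units, <= 0).
#' @export
mismatch_penalty <- function(chunk, cues, params = model_params()) {
  stopifnot(inherits(chunk, "chunk"), inherits(cues, "cue_set"))
  params <- validate_model_params(params)
  n_miss <- sum(vapply(names(cues$cues), function(j) {
    !identical(chunk$features[[j]], cues$cues[[j]])
  }, logical(1)))
  -params$MP * n_miss
}

noiseless_activation <- function(chunk, cues, params) {
  base_level(chunk, params) +
    spreading_activation(chunk, cues, params) +
    mismatch_penalty(chunk, cues, params)
}

#' Sample a chunk's total activation
#'
#' Total activation is base level + spreading activation + mismatch
#' penalty + logistic noise with scale `ANS` (location 0). With `ANS = 0`
#' the result is deterministic and no random numbers are consumed.
#'
#' @inheritParams spreading_activation
#' @return One sampled activation value.
#' @export
sample_activation <- function(chunk, cues, params = model_params()) {
  a <- noiseless_activation(chunk, cues, params)
  if (params$ANS > 0) {
    a <- a + stats::rlogis(1L, location = 0, scale = params$ANS)
  }
  a
}

#' Retrieval latency from activation
#'
#' The core latency equation `T = F * exp(-f * A)` (seconds): strictly
#' decreasing in activation, linear in the latency factor `F`.
#'
#' @param A activation value(s).
#' @param params a [model_params()].
#' @return Latency in seconds, vectorised over `A`.
#' @examples
#' latency_from_activation(0)            # = F = 0.2 s
#' latency_from_activation(1.5)          # 0.2 * exp(-1.5)
#' @export
latency_from_activation <- function(A, params = model_params()) {
  params <- validate_model_params(params)
  params$F * exp(-params$f * A)
}
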