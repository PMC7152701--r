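# Vectorised Monte-Carlo core shared by retrieve(), retrieval
# probabilities and the effect simulator. Given the noiseless activation
# vector a0 (one entry per chunk) and an n x K noise matrix (or NULL for
# ANS = 0), returns per-replicate winner index (NA = failure) and latency.
simulate_latencies <- function(a0, params, n, eps = NULL) {
  K <- length(a0)
  if (is.null(eps)) {
    A <- matrix(a0, nrow = n, ncol = K, byrow = TRUE)
  } else {
    A <- eps[, seq_len(K), drop = FALSE]
    for (kk in seq_len(K)) A[, kk] <- A[, kk] + a0[kk]
  }
  # overall argmax; ties broken by declaration order (first column)
  j <- max.col(A, ties.method = "first")
  Aw <- A[cbind(seq_len(n), j)]
  fail <- Aw < params$tau
  lat <- params$F * exp(-params$f * Aw)
  if (any(fail)) {
    lat[fail] <- params$F * exp(-params$f * params$tau)
    j[fail] <- NA_integer_
  }
  list(winner = j, latency_s = lat, fail = fail)
}

noise_matrix <- function(n, K, ANS) {
  if (ANS <= 0) return(NULL)
  matrix(stats::rlogis(n * K, location = 0, scale = ANS), nrow = n)
}

#' Simulate one retrieval attempt
#'
#' Samples one activation per candidate chunk, picks the highest-activation
#' chunk at or above the retrieval threshold `tau`, and converts its
#' activation to a latency. If no chunk reaches `tau` the retrieval fails
#' and the latency is the time to threshold, `F * exp(-f * tau)`.
#'
#' @param condition a [condition_spec()].
#' @param params a [model_params()].
#' @return A list of class `retrieval_outcome`: `winner` (chunk id, or
#'   `"FAILURE"`), `latency_s`, and `activations` (named vector of the
#'   sampled activations).
#' @examples
#' cond <- condition_spec(list(chunk("t", c(num = "sg"))), c(num = "sg"))
#' retrieve(cond, model_params(ANS = 0))
#' @export
retrieve <- function(condition, params = model_params()) {
  stopifnot(inherits(condition, "condition_spec"))
  params <- validate_model_params(params)
  a0 <- vapply(condition$chunks, noiseless_activation, numeric(1),
               cues = condition$cues, params = params)
  A <- a0
  if (params$ANS > 0) {
    A <- A + stats::rlogis(length(A), location = 0, scale = params$ANS)
  }
  j <- which.max(A) # ties broken by declaration order
  if (A[j] >= params$tau) {
    winner <- condition$ids[j]
    lat <- params$F * exp(-params$f * A[j])
  } else {
    winner <- "FAILURE"
    lat <- params$F * exp(-params$f * params$tau)
  }
  structure(list(
    winner = winner,
    latency_s = lat,
    activations = stats::setNames(A, condition$ids)
  ), class = "retrieval_outcome")
}

#' @export
print.retrieval_outcome <- function(x, ...) {
  cat("Retrieval outcome: winner =", x$winner,
      sprintf("(latency %.1f ms)\n", 1000 * x$latency_s))
  invisible(x)
}

#' Monte-Carlo retrieval probabilities
#'
#' Frequencies with which each chunk (or failure) wins the retrieval over
#' `n_mc` simulated attempts. Counts-based, so the probabilities sum to 1
#' exactly.
#'
#' @inheritParams retrieve
#' @param n_mc number of Monte-Carlo retrieval attempts (>= 1).
#' @return Named numeric vector of probabilities over the chunk ids plus
#'   `"FAILURE"`.
#' @export
retrieval_probabilities <- function(condition, params = model_params(),
                                    n_mc = 10000L) {
  stopifnot(inherits(condition, "condition_spec"))
  params <- validate_model_params(params)
  if (!is.numeric(n_mc) || n_mc < 1) stop("`n_mc` must be >= 1")
  n_mc <- as.integer(n_mc)
  a0 <- vapply(condition$chunks, noiseless_activation, numeric(1),
               cues = condition$cues, params = params)
  res <- simulate_latencies(a0, params, n = n_mc,
                            eps = noise_matrix(n_mc, length(a0), params$ANS))
  lev <- c(condition$ids, "FAILURE")
  win <- ifelse(is.na(res$winner), "FAILURE", condition$ids[res$winner])
  counts <- table(factor(win, levels = lev))
  stats::setNames(as.numeric(counts) / n_mc, lev)
}
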