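#' Prior predictive distribution of the interference effect
#'
#' Draws `theta` from the Beta prior and pushes each draw through the
#' simulator, giving the distribution of predicted effects implied by the
#' prior alone, before any data are taken into account.
#'
#' @param prior a [prior_spec()].
#' @param simulator a function `theta -> effect_ms`.
#' @param n_draws number of predictive draws (>= 1).
#' @param seed optional integer seed for the global RNG.
#' @return An object of class `predictive_distribution` with fields
#'   `kind` (`"prior"`), `effects_ms`, `theta`, `theta_source`, `n_draws`.
#' @export
prior_predictive <- function(prior, simulator, n_draws = 2000L,
                             seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"), is.function(simulator))
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("`n_draws` must be >= 1", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rbeta(n_draws, prior$shape_a, prior$shape_b)
  effects <- vapply(theta, function(th) simulator(th), numeric(1))
  structure(list(
    kind = "prior",
    effects_ms = effects,
    theta = theta,
    theta_source = sprintf("Beta(%g, %g) prior draws",
                           prior$shape_a, prior$shape_b),
    n_draws = n_draws
  ), class = "predictive_distribution")
}

#' Posterior predictive distribution of the interference effect
#'
#' Approximates the posterior predictive integral by Monte Carlo:
#' `theta` is resampled uniformly with replacement from the accepted ABC
#' draws (integrating the parameter out rather than conditioning on a
#' point estimate). By default each resampled `theta` is pushed through
#' the simulator with fresh noise (`resimulate = TRUE`); with
#' `resimulate = FALSE` the effect stored at acceptance time is reused,
#' which is faster and keeps every draw inside the acceptance band by
#' construction.
#'
#' @param posterior a `posterior_samples` object from [abc_reject()].
#' @param simulator the simulator to re-run when `resimulate = TRUE`;
#'   ignored otherwise.
#' @param n_draws number of predictive draws (>= 1).
#' @param resimulate regenerate each predicted effect with fresh
#'   simulation noise (default) or reuse the stored accepted effects.
#' @param seed optional integer seed for the global RNG.
#' @return An object of class `predictive_distribution` (`kind =
#'   "posterior"`).
#' @export
posterior_predictive <- function(posterior, simulator = NULL,
                                 n_draws = 2000L, resimulate = TRUE,
                                 seed = NULL) {
  stopifnot(inherits(posterior, "posterior_samples"))
  if (length(posterior$theta) == 0L) {
    stop("invalid input: empty posterior", call. = FALSE)
  }
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("`n_draws` must be >= 1", call. = FALSE)
  }
  if (resimulate && !is.function(simulator)) {
    stop("`simulator` is required when resimulate = TRUE", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(posterior$theta), n_draws, replace = TRUE)
  theta <- posterior$theta[idx]
  effects <- if (resimulate) {
    vapply(theta, function(th) simulator(th), numeric(1))
  } else {
    posterior$effect_ms[idx]
  }
  structure(list(
    kind = "posterior",
    effects_ms = effects,
    theta = theta,
    theta_source = sprintf(
      "resampled from %d ABC-accepted draws (%s)",
      length(posterior$theta),
      if (resimulate) "resimulated" else "stored effects"),
    n_draws = n_draws
  ), class = "predictive_distribution")
}

#' Summarise a predictive distribution
#'
#' Mean, SD and central 95% interval of the predicted effects.
#'
#' @param object a `predictive_distribution`.
#' @param ... unused.
#' @return A list with `kind`, `n_draws`, `mean_ms`, `sd_ms`, `q2.5_ms`,
#'   `q97.5_ms`.
#' @export
summary.predictive_distribution <- function(object, ...) {
  x <- object$effects_ms
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  out <- list(
    kind = object$kind,
    n_draws = object$n_draws,
    mean_ms = mean(x),
    sd_ms = if (length(x) >= 2L) stats::sd(x) else NA_real_,
    q2.5_ms = q[1],
    q97.5_ms = q[2]
  )
  class(out) <- "summary.predictive_distribution"
  out
}

#' @export
print.summary.predictive_distribution <- function(x, ...) {
  cat(sprintf(
    "%s predictive distribution of the effect (%d draws):\n",
    x$kind, x$n_draws))
  cat(sprintf("  mean %.2f ms, SD %.2f ms, 95%% interval [%.2f, %.2f] ms\n",
              x$mean_ms, x$sd_ms, x$q2.5_ms, x$q97.5_ms))
  invisible(x)
}

#' @export
print.predictive_distribution <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Density plot of a predictive distribution or an ABC posterior
#'
#' Simple base-graphics density plot, mirroring the usual prior /
#' posterior / posterior-predictive panels.
#'
#' @param x a `predictive_distribution` or `posterior_samples` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.predictive_distribution <- function(x, ...) {
  plot(stats::density(x$effects_ms),
       main = paste(x$kind, "predictive distribution"),
       xlab = "predicted interference effect (ms)", ...)
  invisible(x)
}

#' @rdname plot.predictive_distribution
#' @export
plot.posterior_samples <- function(x, ...) {
  plot(stats::density(x$theta, from = 0, to = 1),
       main = "ABC posterior of the latency factor",
       xlab = "latency factor", ...)
  invisible(x)
}
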