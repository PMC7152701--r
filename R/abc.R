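#' Beta prior on the latency factor
#'
#' The latency factor lives in (0, 1); a Beta(2, 6) prior downweights very
#' small and very large values while remaining relatively uninformative.
#'
#' @param shape_a,shape_b Beta shape parameters (> 0); default `Beta(2, 6)`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(shape_a = 2, shape_b = 6) {
  if (!is.numeric(shape_a) || length(shape_a) != 1L || !is.finite(shape_a) ||
      shape_a <= 0 ||
      !is.numeric(shape_b) || length(shape_b) != 1L || !is.finite(shape_b) ||
      shape_b <= 0) {
    stop("invalid prior: Beta shape parameters must be positive numbers",
         call. = FALSE)
  }
  structure(list(shape_a = shape_a, shape_b = shape_b),
            class = "prior_spec")
}

#' Observed interference-effect target
#'
#' The observed effect enters the ABC algorithm as a normal approximation:
#' a mean and SD in milliseconds. If `sd_ms` is supplied it is used as-is
#' (published SDs are authoritative even where CrI arithmetic disagrees
#' slightly); otherwise it is derived from a 95% credible interval via
#' [normal_approx_from_cri()].
#'
#' @param mean_ms observed mean interference effect (ms).
#' @param sd_ms SD of the normal approximation (ms, > 0); optional when a
#'   CrI is given.
#' @param cri_low_ms,cri_high_ms optional 95% credible-interval bounds.
#' @return An object of class `observed_target`.
#' @examples
#' observed_target(-22, 13)
#' observed_target(-60, cri_low_ms = -112, cri_high_ms = -5)
#' @export
observed_target <- function(mean_ms, sd_ms = NULL,
                            cri_low_ms = NULL, cri_high_ms = NULL) {
  if (!is.numeric(mean_ms) || length(mean_ms) != 1L || !is.finite(mean_ms)) {
    stop("invalid target: `mean_ms` must be a single number", call. = FALSE)
  }
  has_cri <- !is.null(cri_low_ms) && !is.null(cri_high_ms)
  if (has_cri) {
    if (!(cri_low_ms < mean_ms && mean_ms < cri_high_ms)) {
      stop("invalid target: mean must lie strictly inside the CrI",
           call. = FALSE)
    }
  }
  if (is.null(sd_ms)) {
    if (!has_cri) {
      stop("invalid target: supply `sd_ms` or both CrI bounds",
           call. = FALSE)
    }
    sd_ms <- (cri_high_ms - cri_low_ms) / (2 * stats::qnorm(0.975))
  }
  if (!is.numeric(sd_ms) || length(sd_ms) != 1L || !is.finite(sd_ms) ||
      sd_ms <= 0) {
    stop("invalid target: `sd_ms` must be > 0", call. = FALSE)
  }
  structure(list(mean_ms = mean_ms, sd_ms = sd_ms,
                 cri_low_ms = cri_low_ms, cri_high_ms = cri_high_ms),
            class = "observed_target")
}

#' Normal approximation of an effect from its 95% credible interval
#'
#' `sd_ms = (cri_high - cri_low) / (2 * 1.959964)`, i.e. the interval is
#' treated as mean +/- 1.96 SD of a normal sampling distribution.
#'
#' @inheritParams observed_target
#' @return An [observed_target()].
#' @examples
#' normal_approx_from_cri(-22, -46, 3)   # sd ~ 12.5, reported as 13
#' @export
normal_approx_from_cri <- function(mean_ms, cri_low_ms, cri_high_ms) {
  if (!is.numeric(cri_low_ms) || !is.numeric(cri_high_ms) ||
      !(cri_low_ms < cri_high_ms)) {
    stop("invalid target: need cri_low_ms < cri_high_ms", call. = FALSE)
  }
  observed_target(mean_ms, sd_ms = NULL,
                  cri_low_ms = cri_low_ms, cri_high_ms = cri_high_ms)
}

#' ABC acceptance band around the observed mean
#'
#' The closed interval `[mean - k*sd, mean + k*sd]`. The default `k = 1`
#' (accept simulations within one SD of the observed mean) reasonably
#' constrains the accepted values; larger `k` yields a more broadly
#' distributed posterior, smaller `k` a more narrowly distributed one.
#'
#' @param target an [observed_target()].
#' @param k band half-width in SD units (> 0).
#' @return Numeric length-2 vector `c(lower, upper)` in ms.
#' @examples
#' acceptance_band(observed_target(-22, 13))        # [-35, -9]
#' @export
acceptance_band <- function(target, k = 1) {
  stopifnot(inherits(target, "observed_target"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("invalid band: `k` must be a positive number", call. = FALSE)
  }
  c(lower = target$mean_ms - k * target$sd_ms,
    upper = target$mean_ms + k * target$sd_ms)
}

#' ABC rejection sampling for the latency factor
#'
#' Repeats: draw `theta ~ Beta(shape_a, shape_b)`; simulate the predicted
#' mean effect `delta = simulator(theta)`; accept `theta` iff `delta`
#' falls inside the acceptance band (boundary hits accept). Stops once
#' `n_accept` draws are accepted. The accepted draws approximate the
#' posterior of the latency factor given the observed effect.
#'
#' @param prior a [prior_spec()].
#' @param simulator a function `theta -> effect_ms`, e.g. from
#'   [make_simulator()] or [toy_simulator()].
#' @param target an [observed_target()].
#' @param n_accept number of accepted draws to collect (>= 1).
#' @param k acceptance-band half-width in SD units (see
#'   [acceptance_band()]).
#' @param max_proposals proposal budget; if exhausted before `n_accept`
#'   acceptances an error of class `cueabc_no_acceptance` is thrown
#'   reporting the running acceptance rate (a symptom of a band/model
#'   mismatch).
#' @param seed optional integer; seeds the global RNG for the proposal
#'   stream.
#' @param progress_every emit a running acceptance rate to stderr every
#'   this many proposals; `Inf` disables logging.
#' @return An object of class `posterior_samples`: `theta` (accepted
#'   draws), `effect_ms` (their simulated effects), `n_proposed`,
#'   `acceptance_rate`, `band`, `k`, `prior`, `target`, `seed`.
#' @examples
#' post <- abc_reject(prior_spec(2, 6), toy_simulator(100),
#'                    observed_target(20, 5), n_accept = 200, seed = 1)
#' post$acceptance_rate
#' @export
abc_reject <- function(prior, simulator, target, n_accept = 2000L,
                       k = 1, max_proposals = 2e6, seed = NULL,
                       progress_every = 1e4) {
  stopifnot(inherits(prior, "prior_spec"), is.function(simulator),
            inherits(target, "observed_target"))
  if (!is.numeric(n_accept) || n_accept < 1) {
    stop("`n_accept` must be >= 1", call. = FALSE)
  }
  n_accept <- as.integer(n_accept)
  if (max_proposals < n_accept) {
    stop("`max_proposals` must be >= `n_accept`", call. = FALSE)
  }
  band <- acceptance_band(target, k)
  if (!is.null(seed)) set.seed(seed)

  theta_acc <- numeric(n_accept)
  eff_acc <- numeric(n_accept)
  n_acc <- 0L
  n_prop <- 0
  next_report <- progress_every
  while (n_acc < n_accept && n_prop < max_proposals) {
    th <- stats::rbeta(1L, prior$shape_a, prior$shape_b)
    delta <- simulator(th)
    n_prop <- n_prop + 1
    if (delta >= band[["lower"]] && delta <= band[["upper"]]) {
      n_acc <- n_acc + 1L
      theta_acc[n_acc] <- th
      eff_acc[n_acc] <- delta
    }
    if (n_prop >= next_report) {
      message(sprintf("abc_reject: %d proposals, %d accepted (rate %.4f)",
                      as.integer(n_prop), n_acc, n_acc / n_prop))
      next_report <- next_report + progress_every
    }
  }
  if (n_acc < n_accept) {
    stop(structure(class = c("cueabc_no_acceptance", "error", "condition"),
      list(message = sprintf(
        paste0("no-acceptance: only %d of %d draws accepted after %d ",
               "proposals (rate %.2e); the acceptance band [%g, %g] ms ",
               "may be unreachable by the simulator"),
        n_acc, n_accept, as.integer(n_prop), n_acc / n_prop,
        band[["lower"]], band[["upper"]]),
        call = sys.call())))
  }
  structure(list(
    theta = theta_acc,
    effect_ms = eff_acc,
    n_proposed = as.integer(n_prop),
    acceptance_rate = n_accept / n_prop,
    band = band,
    k = k,
    prior = prior,
    target = target,
    seed = seed
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  q <- stats::quantile(x$theta, c(0.025, 0.5, 0.975))
  cat(sprintf(
    paste0("ABC posterior of the latency factor: %d draws ",
           "(%d proposals, acceptance rate %.3f)\n"),
    length(x$theta), x$n_proposed, x$acceptance_rate))
  cat(sprintf("  median %.3f, 95%% interval [%.3f, %.3f]\n",
              q[2], q[1], q[3]))
  cat(sprintf("  acceptance band: [%g, %g] ms (k = %g)\n",
              x$band[["lower"]], x$band[["upper"]], x$k))
  invisible(x)
}
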