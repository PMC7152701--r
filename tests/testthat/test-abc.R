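trunc_beta_cdf <- function(a, b, lo, hi) {
  plo <- stats::pbeta(lo, a, b)
  phi <- stats::pbeta(hi, a, b)
  function(q) {
    pmin(1, pmax(0, (stats::pbeta(q, a, b) - plo) / (phi - plo)))
  }
}

test_that("the normal approximation of a credible interval recovers the implied SD", {
  t1 <- normal_approx_from_cri(-22, -46, 3)
  expect_equal(t1$mean_ms, -22)
  expect_equal(t1$sd_ms, 12.5, tolerance = 1e-4)
  t2 <- normal_approx_from_cri(0, -1.959964, 1.959964)
  expect_equal(t2$sd_ms, 1.0, tolerance = 1e-6)
  t3 <- normal_approx_from_cri(-60, -112, -5)
  expect_equal(t3$sd_ms, 27.3, tolerance = 1e-2)
  expect_error(normal_approx_from_cri(0, 2, 2), "invalid target")
  # a directly supplied SD takes precedence over the CrI arithmetic
  t4 <- observed_target(-60, sd_ms = 33, cri_low_ms = -112, cri_high_ms = -5)
  expect_identical(t4$sd_ms, 33)
  expect_error(observed_target(-10, 5, cri_low_ms = 0, cri_high_ms = 10),
               "inside the CrI")
})

test_that("the acceptance band is mean +/- k SD, closed, and requires k > 0", {
  expect_equal(unname(acceptance_band(observed_target(-22, 13))),
               c(-35, -9))
  expect_equal(unname(acceptance_band(observed_target(0, 1), k = 2)),
               c(-2, 2))
  expect_equal(unname(acceptance_band(observed_target(-60, 33))),
               c(-93, -27))
  expect_equal(unname(acceptance_band(observed_target(-22, 13), k = 0.5)),
               c(-28.5, -15.5))
  expect_error(acceptance_band(observed_target(0, 1), k = 0),
               "invalid band")
})

test_that("a deterministic monotone simulator yields the truncated-prior posterior", {
  post <- abc_reject(prior_spec(2, 6), toy_simulator(100),
                     observed_target(20, 5), n_accept = 2000, seed = 8)
  expect_true(all(post$theta >= 0.15 & post$theta <= 0.25))
  expect_true(all(post$effect_ms >= 15 & post$effect_ms <= 25))
  ks <- suppressWarnings(
    stats::ks.test(post$theta, trunc_beta_cdf(2, 6, 0.15, 0.25)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a vacuous acceptance band returns the prior", {
  post <- abc_reject(prior_spec(2, 6), function(theta, ...) -22,
                     observed_target(-22, 13), n_accept = 2000, seed = 9)
  expect_identical(post$acceptance_rate, 1)
  expect_identical(post$n_proposed, 2000L)
  set.seed(10)
  fresh <- stats::rbeta(2000, 2, 6)
  ks <- suppressWarnings(stats::ks.test(post$theta, fresh))
  expect_gt(ks$p.value, 0.01)
})

test_that("an unreachable band raises a diagnostic no-acceptance error", {
  expect_error(
    abc_reject(prior_spec(2, 6), toy_simulator(100),
               observed_target(1e6, 1), n_accept = 10,
               max_proposals = 500, seed = 11),
    class = "cueabc_no_acceptance")
  err <- tryCatch(
    abc_reject(prior_spec(2, 6), toy_simulator(100),
               observed_target(1e6, 1), n_accept = 10,
               max_proposals = 500, seed = 11),
    error = function(e) e)
  expect_match(conditionMessage(err), "no-acceptance")
  expect_match(conditionMessage(err), "500 proposals")
})

test_that("accepted draws stay in the Beta support and their effects in the band", {
  fx <- load_fixture("jaeger_agreement")
  sim <- make_simulator(fx$experiment, fx$params, n_mc = 1000,
                        master_seed = 21)
  post <- abc_reject(fx$prior, sim, fx$target, n_accept = 200, seed = 22)
  expect_true(all(post$theta > 0 & post$theta < 1))
  band <- acceptance_band(fx$target)
  expect_true(all(post$effect_ms >= band[["lower"]] &
                    post$effect_ms <= band[["upper"]]))
  expect_identical(post$acceptance_rate, 200 / post$n_proposed)
})

test_that("widening the band moves the posterior toward the prior", {
  ks_to_prior <- function(k) {
    post <- abc_reject(prior_spec(2, 6), toy_simulator(100),
                       observed_target(20, 5), n_accept = 1500,
                       k = k, seed = 30 + k)
    suppressWarnings(
      stats::ks.test(post$theta,
                     function(q) stats::pbeta(q, 2, 6)))$statistic
  }
  expect_lt(ks_to_prior(4), ks_to_prior(1))
  expect_lt(ks_to_prior(1), ks_to_prior(0.25))
})

test_that("prior validation rejects non-positive shapes", {
  expect_error(prior_spec(0, 6), "invalid prior")
  expect_error(prior_spec(2, -1), "invalid prior")
})
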