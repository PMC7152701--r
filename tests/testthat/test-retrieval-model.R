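test_that("base-level activation follows single-presentation decay", {
  p <- model_params()
  ch <- chunk("x", c(a = "1"))
  expect_identical(base_level(ch, p), 0)
  expect_identical(base_level(chunk("x", c(a = "1"), creation_time = 1), p), 0)
  expect_equal(base_level(chunk("x", c(a = "1"), creation_time = 4), p),
               -0.5 * log(4))
  expect_equal(base_level(chunk("x", c(a = "1"), creation_time = 4),
                          model_params(beta = 0.3, d = 0.4)),
               0.3 - 0.4 * log(4))
  expect_error(chunk("x", c(a = "1"), creation_time = 0),
               "invalid schedule")
  expect_error(chunk("x", c(a = "1"), creation_time = -2),
               "invalid schedule")
})

test_that("spreading activation sums weighted fan-discounted strengths", {
  cond <- one_chunk_condition()
  ch <- cond$chunks[[1]]
  expect_equal(spreading_activation(ch, cond$cues, model_params(MAS = 1)), 1)
  # fan 2 dilutes the associative strength
  cues2 <- cue_set(c(cue = "v"), weights = c(cue = 1), fan = c(cue = 2))
  expect_equal(spreading_activation(ch, cues2,
                                    model_params(MAS = 1.5, preset = "simulation")),
               1.5 - log(2))
  # non-matching chunk receives nothing
  miss <- chunk("m", c(cue = "other"))
  expect_identical(spreading_activation(miss, cond$cues, model_params()), 0)
  expect_error(cue_set(c(cue = "v"), fan = c(cue = 0)), "invalid spec")
})

test_that("mismatch penalty counts unmatched cues", {
  cues <- cue_set(c(a = "1", b = "2"))
  full <- chunk("full", c(a = "1", b = "2"))
  one <- chunk("one", c(a = "1", b = "x"))
  none <- chunk("none", c(a = "0", b = "x"))
  expect_identical(mismatch_penalty(full, cues, model_params()), 0)
  expect_equal(mismatch_penalty(one, cues, model_params(MP = 1)), -1)
  expect_equal(mismatch_penalty(none, cues, model_params(MP = 0.25)), -0.5)
  # missing feature counts as a mismatch
  missing <- chunk("missing", c(a = "1"))
  expect_equal(mismatch_penalty(missing, cues, model_params(MP = 1)), -1)
})

test_that("sampled activation is the sum of parts plus zero-mean logistic noise", {
  cond <- one_chunk_condition()
  ch <- cond$chunks[[1]]
  expect_identical(sample_activation(ch, cond$cues, model_params(ANS = 0)), 1)
  set.seed(101)
  draws <- replicate(2e4, sample_activation(ch, cond$cues,
                                            model_params(ANS = 0.2)))
  expect_lt(abs(mean(draws) - 1), 0.01) # 3 SE ~ 0.008
  set.seed(5)
  d1 <- sample_activation(ch, cond$cues, model_params())
  set.seed(5)
  d2 <- sample_activation(ch, cond$cues, model_params())
  expect_identical(d1, d2)
})

test_that("latency equation is exact, monotone in A and linear in F", {
  p <- model_params()
  expect_equal(latency_from_activation(0, p), 0.2)
  expect_equal(latency_from_activation(1.5, p), 0.2 * exp(-1.5))
  expect_equal(latency_from_activation(1.5, p), 0.044626, tolerance = 1e-4)
  expect_identical(latency_from_activation(3, model_params(F = 0)), 0)
  A <- seq(-3, 3, by = 0.25)
  lat <- latency_from_activation(A, p)
  expect_true(all(diff(lat) < 0))
  expect_equal(latency_from_activation(A, model_params(F = 0.4)), 2 * lat)
})

test_that("retrieve picks the argmax above threshold and fails below it", {
  p0 <- params_with_activation(1, ANS = 0)
  out <- retrieve(one_chunk_condition(), p0)
  expect_identical(out$winner, "only")
  expect_equal(out$latency_s, 0.2 * exp(-1))
  expect_equal(out$latency_s, 0.07358, tolerance = 1e-4)

  pfail <- params_with_activation(-2, ANS = 0)
  out <- retrieve(one_chunk_condition(), pfail)
  expect_identical(out$winner, "FAILURE")
  expect_equal(out$latency_s, 0.2 * exp(1.5))
  expect_equal(out$latency_s, 0.89634, tolerance = 1e-4)

  # two chunks: higher activation wins; exact tie broken by order
  cues <- cue_set(c(a = "1", b = "2"))
  both <- condition_spec(list(chunk("c1", c(a = "1", b = "2")),
                              chunk("c2", c(a = "1", b = "x"))), cues)
  out <- retrieve(both, model_params(ANS = 0))
  expect_identical(out$winner, "c1")
  tie <- condition_spec(list(chunk("first", c(a = "1", b = "x")),
                             chunk("second", c(a = "x", b = "2"))), cues)
  out <- retrieve(tie, model_params(ANS = 0))
  expect_identical(out$winner, "first")

  expect_error(condition_spec(list(), cue_set(c(a = "1"))), "invalid spec")
})

test_that("retrieval probabilities are count frequencies matching the logistic law", {
  # deterministic: single chunk above threshold always retrieved
  probs <- retrieval_probabilities(one_chunk_condition(),
                                   params_with_activation(1, ANS = 0),
                                   n_mc = 100)
  expect_identical(unname(probs["only"]), 1)
  expect_identical(sum(probs), 1)

  # A = tau: symmetric noise gives P ~ 0.5
  set.seed(2)
  probs <- retrieval_probabilities(one_chunk_condition(),
                                   params_with_activation(-1.5), n_mc = 2e4)
  expect_lt(abs(probs[["only"]] - 0.5), 3 * sqrt(0.25 / 2e4))

  # closed form P(A + eps > tau) = plogis((A - tau)/ANS) at one offset
  p <- params_with_activation(-1.5 + 0.2) # (A - tau)/ANS = 1
  set.seed(3)
  probs <- retrieval_probabilities(one_chunk_condition(), p, n_mc = 2e4)
  ptrue <- 1 / (1 + exp(-1))
  expect_lt(abs(probs[["only"]] - ptrue),
            3 * sqrt(ptrue * (1 - ptrue) / 2e4))
  expect_identical(sum(probs), 1)
})

test_that("parameter presets and validation enforce the documented ranges", {
  d <- model_params()
  expect_equal(unlist(d[c("F", "f", "tau", "d", "ANS", "MAS", "MP", "beta")]),
               c(F = 0.2, f = 1, tau = -1.5, d = 0.5, ANS = 0.2,
                 MAS = 1, MP = 1, beta = 0))
  s <- model_params(preset = "simulation")
  expect_equal(s$MAS, 1.5)
  expect_equal(s$MP, 0.25)
  expect_error(model_params(F = -1), "F")
  expect_error(model_params(ANS = -0.1), "ANS")
  expect_error(model_params(d = 1.5), "decay")
})
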