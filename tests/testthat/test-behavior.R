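test_that("outing decisions are Bernoulli with the state's probability", {
  set.seed(1)
  n <- 10000
  rates <- c(healthy = 0.7, weak = 0.5, disabled = 0.3)
  for (st in names(rates)) {
    hit <- mean(decide_outing(rep(st, n)))
    se <- sqrt(rates[[st]] * (1 - rates[[st]]) / n)
    expect_lt(abs(hit - rates[[st]]), 3 * se)
  }
  p0 <- behavior_params(p_out = c(healthy = 0, weak = 0, disabled = 0))
  expect_false(any(decide_outing(rep("healthy", 100), p0)))
  p1 <- behavior_params(p_out = c(healthy = 1, weak = 1, disabled = 1))
  expect_true(all(decide_outing(rep("disabled", 100), p1)))
})

test_that("facility-type choice follows the per-state preference weights", {
  set.seed(2)
  n <- 10000
  w <- default_type_weights()
  for (st in rownames(w)) {
    draws <- choose_type(rep(st, n))
    obs <- table(factor(draws, levels = colnames(w)))
    expect_gt(stats::chisq.test(obs, p = w[st, ])$p.value, 0.01)
  }
  only_prev <- behavior_params(type_weights = matrix(c(1, 0, 0), 3, 3, byrow = TRUE,
                                                    dimnames = dimnames(w)))
  expect_true(all(choose_type(rep("weak", 200), only_prev) == "prevention"))
})

test_that("facility choice searches in radius, then falls back to the nearest", {
  ag <- toy_agent(H = 0.9)  # healthy, radius 5 km
  one <- toy_facilities(2, 0, "prevention")
  set.seed(3)
  ch <- choose_facility(ag, "prevention", one, eu)
  expect_equal(ch$facility_id, 1L)
  expect_equal(ch$distance_km, 2)
  expect_false(ch$fallback_used)

  # nothing in radius: fallback goes to the nearest matching facility
  far <- toy_facilities(c(9, 6), c(0, 0), c("prevention", "prevention"))
  always <- behavior_params(fallback_p = 1)
  ch2 <- choose_facility(ag, "prevention", far, eu, always)
  expect_equal(ch2$facility_id, 2L)   # the 6 km site
  expect_true(ch2$fallback_used)
  never <- behavior_params(fallback_p = 0)
  expect_null(choose_facility(ag, "prevention", far, eu, never))

  # equidistant tie beyond radius: lowest facility id wins
  tie <- toy_facilities(c(7, -7), c(0, 0), c("care", "care"))
  ch3 <- choose_facility(toy_agent(H = 0.9), "care", tie, eu, always)
  expect_equal(ch3$facility_id, 1L)

  # fallback is taken in about half of the attempts
  set.seed(4)
  taken <- vapply(1:2000, function(i) {
    !is.null(choose_facility(ag, "prevention", far, eu))
  }, logical(1))
  expect_lt(abs(mean(taken) - 0.5), 3 * sqrt(0.25 / 2000))

  # a demanded type absent everywhere cancels the outing
  expect_null(choose_facility(ag, "treatment", far, eu))
})

test_that("comprehensive hubs satisfy every demanded type", {
  hub <- toy_facilities(1, 0, "comprehensive", education_host = TRUE)
  hub$gain <- 0.05
  for (ty in c("prevention", "treatment", "care")) {
    ch <- choose_facility(toy_agent(H = 0.5), ty, hub, eu)
    expect_equal(ch$facility_id, 1L)
  }
})

test_that("zero live_adjust makes education flags irrelevant", {
  ag <- toy_agent(H = 0.9)
  fac_a <- toy_facilities(c(1, 2, 3), c(0, 0, 0), rep("prevention", 3),
                          education_host = c(TRUE, FALSE, TRUE))
  fac_b <- fac_a
  fac_b$education_host <- FALSE
  p0 <- behavior_params(live_adjust = 0)
  picks_a <- {
    set.seed(7)
    vapply(1:500, function(i) choose_facility(ag, "prevention", fac_a, eu, p0)$facility_id,
           integer(1))
  }
  picks_b <- {
    set.seed(7)
    vapply(1:500, function(i) choose_facility(ag, "prevention", fac_b, eu, p0)$facility_id,
           integer(1))
  }
  expect_identical(picks_a, picks_b)
})

test_that("an agent-day composes the chain and yields at most one visit", {
  fac <- toy_facilities(c(1, 2, 3), c(0, 0, 0), c("prevention", "treatment", "care"))
  stay <- behavior_params(p_out = c(healthy = 0, weak = 0, disabled = 0))
  expect_null(simulate_agent_day(toy_agent(), fac, eu, stay))
  go <- behavior_params(p_out = c(healthy = 1, weak = 1, disabled = 1))
  set.seed(8)
  ev <- simulate_agent_day(toy_agent(H = 0.9), fac, eu, go, day = 5L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$day, 5L)
  expect_lte(ev$distance_km, behavior_params()$radius[["healthy"]])
  expect_false(ev$fallback_used)
})

test_that("behavioural parameter validation rejects malformed inputs", {
  expect_error(behavior_params(p_out = c(healthy = 1.2, weak = 0.5, disabled = 0.3)), "\\[0, 1\\]")
  expect_error(behavior_params(radius = c(healthy = 5, weak = -3, disabled = 1)), "positive")
  w <- default_type_weights(); w[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(behavior_params(type_weights = w), "sum to 1")
})
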