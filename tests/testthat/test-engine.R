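test_that("run configuration validates its invariants", {
  cfg <- sim_config()
  expect_equal(cfg$n_agents, 200L)
  expect_equal(cfg$n_days, 500L)
  expect_equal(cfg$burn_in, 60L)
  expect_error(sim_config(n_days = 50, burn_in = 60), "exceed")
  expect_error(sim_config(burn_in = -1), "exceed|>= 0")
  expect_error(sim_config(distance = list(mode = "teleport")), "euclidean")
  expect_error(run_simulation(sim_config(scenario = "S9")), "unknown scenario")
})

test_that("simulations are reproducible given (config, seed)", {
  cfg <- fast_config()
  a <- run_simulation(cfg, 5)
  b <- run_simulation(cfg, 5)
  expect_identical(a$panel, b$panel)
  expect_identical(a$visits, b$visits)
  expect_false(identical(a$panel, run_simulation(cfg, 6)$panel))
  expect_equal(dim(a$panel), c(40L, 80L))
  expect_true(all(a$mean_h >= 0 & a$mean_h <= 1))
})

test_that("with no facilities every trajectory is pure piecewise decay", {
  cfg <- fast_config(n_agents = 20L, n_days = 300L, burn_in = 10L,
                     facility_counts = c(prevention = 0L, treatment = 0L, care = 0L))
  res <- run_simulation(cfg, 3)
  expect_equal(nrow(res$visits), 0L)
  hp <- cfg$health
  for (i in 1:20) {
    ref <- reference_trajectory(res$population$H[i], res$population$living[i],
                                res$population$econ[i], hp, 300L)
    expect_equal(res$panel[i, ], ref, tolerance = 1e-12)
  }
  # within the first band the trajectory also matches the geometric closed form
  i <- which(res$population$initial_state == "healthy")[1]
  h0 <- res$population$H[i]
  pen <- hp$alone_decay * (res$population$living[i] == "alone") +
    hp$low_econ_decay * (res$population$econ[i] == "low")
  r <- hp$decay[["healthy"]] + pen
  t_in_band <- sum(decay_closed_form(h0, r, 1:300) >= 0.7)
  expect_equal(res$panel[i, seq_len(t_in_band)],
               decay_closed_form(h0, r, seq_len(t_in_band)), tolerance = 1e-12)
})

test_that("the same seed yields the same world for every scenario", {
  cfg <- fast_config()
  runs <- lapply(c("S0", "S1", "S2"), function(s) {
    cfg$scenario <- s
    run_simulation(cfg, 11)
  })
  expect_identical(runs[[1]]$population, runs[[2]]$population)
  expect_identical(runs[[1]]$population, runs[[3]]$population)
  expect_identical(runs[[1]]$base_facilities, runs[[2]]$base_facilities)
  # S1 adds exactly its hub count on top of the shared base
  expect_equal(nrow(runs[[2]]$facilities), nrow(runs[[1]]$facilities) + 10L)
  expect_true(all(utils::tail(runs[[2]]$facilities$type, 10) == "comprehensive"))
  expect_equal(utils::tail(runs[[2]]$facilities$gain, 10), rep(0.05, 10))
})

test_that("subgroup means aggregate back to the population mean", {
  res <- run_simulation(fast_config(), 2)
  pop <- res$population
  for (col in c("initial_state", "living", "econ")) {
    groups <- split(seq_len(nrow(pop)), pop[[col]])
    agg <- Reduce(`+`, lapply(groups, function(rows) {
      length(rows) * colMeans(res$panel[rows, , drop = FALSE])
    })) / nrow(pop)
    expect_equal(agg, res$mean_h, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("paired experiments contrast scenarios within replicates", {
  # 100 agents so every living-status subgroup is populated (alone gets 1)
  cfg <- fast_config(n_agents = 100L, record_visits = FALSE)
  ex <- run_experiment(cfg, scenarios = c("S0", "S2"), replicates = 2, base_seed = 3)
  # S0 against itself is identically zero
  s0 <- ex$delta[ex$delta$scenario == "S0", ]
  expect_true(all(s0$delta_h == 0))
  # contract: one post-burn-in row per scenario, replicate and day
  expect_equal(nrow(ex$delta), 2 * 2 * (80 - 10))
  expect_equal(sort(unique(ex$delta$day)), 11:80)
  expect_equal(nrow(ex$gini), 2 * 3 * 2 * (80 - 10))
  expect_setequal(ex$final$scenario, c("S0", "S2"))
  expect_error(run_experiment(cfg, scenarios = "S7"), "unknown scenario")
})

test_that("sensitivity sweeps are paired, tabular, and monotone in decay", {
  cfg <- fast_config(n_agents = 30L, n_days = 60L, burn_in = 10L)
  expect_error(univariate_sensitivity(cfg, "volumeOfBeer"), "valid names")
  tab <- univariate_sensitivity(cfg, c("healthyDecayRate", "weakDecayRate"),
                                rel_grid = c(-0.5, 0, 0.5), trials = 4,
                                base_seed = 2)
  expect_equal(nrow(tab), 2L * 3L)
  expect_equal(unique(tab$n_trials), 4L)
  # the baseline grid point reproduces the unperturbed runs exactly
  seeds <- (2L * 1000L + 1:4) %% 536870912L
  cfg0 <- cfg; cfg0$record_visits <- FALSE
  base_fin <- mean(vapply(seeds, function(s) run_simulation(cfg0, s)$mean_h[60],
                          numeric(1)))
  expect_equal(tab$mean_final_h[tab$parameter == "healthyDecayRate" & tab$rel_change == 0],
               base_fin, tolerance = 1e-12)
  # faster decay lowers mean final health (small slack for the behavioural
  # re-alignment noise that paired seeds cannot remove)
  for (p in unique(tab$parameter)) {
    resp <- tab$mean_final_h[tab$parameter == p][order(tab$rel_change[tab$parameter == p])]
    expect_true(all(diff(resp) < 0.005))
    expect_lt(resp[3], resp[1])
  }
})

test_that("run configurations round-trip through YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_agents: 25",
    "n_days: 40",
    "burn_in: 5",
    "behavior:",
    "  fallback_p: 0.4",
    "health:",
    "  alone_decay: 0.002"
  ), yml)
  cfg <- read_run_config(yml)
  expect_equal(cfg$n_agents, 25L)
  expect_equal(cfg$behavior$fallback_p, 0.4)
  expect_equal(cfg$health$alone_decay, 0.002)
  expect_equal(cfg$health$decay[["weak"]], 0.009)  # untouched defaults remain

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_agents": 12, "n_days": 30, "burn_in": 3, "scenario": "S2"}', js)
  cfg2 <- read_run_config(js)
  expect_equal(cfg2$n_agents, 12L)
  expect_equal(cfg2$scenario, "S2")

  man <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(cfg, 9L, man)
  back <- jsonlite::fromJSON(man)
  expect_equal(back$seed, 9L)
  expect_equal(back$behavior$fallback_p, 0.4)
})
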