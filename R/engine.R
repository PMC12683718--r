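#' Build a simulation run configuration
#'
#' Bundles every parameter block of the model. Defaults reproduce the study
#' conditions: 200 agents, 100 facilities (40 prevention / 40 treatment /
#' 20 long-term care), 500 daily time steps with a 60-day burn-in, baseline
#' behavioural and health parameters.
#'
#' @param n_agents Number of older-adult agents (default 200).
#' @param n_days Simulation length in days (default 500).
#' @param burn_in Days excluded from all summaries (default 60; must be
#'   smaller than `n_days`).
#' @param scenario Scenario name (see [builtin_scenarios()]) or a
#'   `scenario_spec`.
#' @param region Region parameter list, see [generate_region()].
#' @param facility_counts Named per-type facility counts.
#' @param distance List with `mode` (`"euclidean"` or `"network"`) and, for
#'   network mode, `grid_spacing` and `jitter`.
#' @param behavior A `behavior_params`.
#' @param health A `health_params`.
#' @param proportions Attribute proportions, see [default_proportions()].
#' @param home_placement `"density"` or `"uniform"` agent home placement.
#' @param education_fraction Fraction of prevention facilities hosting
#'   education sessions.
#' @param record_visits Keep the per-event visit log (default `TRUE`; turn
#'   off for large replicate experiments).
#' @param facilities Optional facility tibble to use instead of generating
#'   one (e.g. read from CSV/GeoJSON).
#' @param network Optional road network (list with `graph`, `nodes`) used in
#'   network mode instead of the synthetic grid.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents = 200L, n_days = 500L, burn_in = 60L,
                       scenario = "S0",
                       region = list(),
                       facility_counts = c(prevention = 40L, treatment = 40L, care = 20L),
                       distance = list(mode = "euclidean", grid_spacing = 0.5, jitter = 0.2),
                       behavior = behavior_params(),
                       health = health_params(),
                       proportions = default_proportions(),
                       home_placement = c("density", "uniform"),
                       education_fraction = 1,
                       record_visits = TRUE,
                       facilities = NULL,
                       network = NULL) {
  home_placement <- match.arg(home_placement)
  n_agents <- as.integer(n_agents); n_days <- as.integer(n_days); burn_in <- as.integer(burn_in)
  if (n_agents < 0L) stop("`n_agents` must be non-negative", call. = FALSE)
  if (burn_in < 0L || n_days <= burn_in) {
    stop("`n_days` must exceed `burn_in` and `burn_in` must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(behavior, "behavior_params"), inherits(health, "health_params"))
  distance <- utils::modifyList(list(mode = "euclidean", grid_spacing = 0.5, jitter = 0.2),
                                as.list(distance))
  if (!distance$mode %in% c("euclidean", "network")) {
    stop("`distance$mode` must be 'euclidean' or 'network'", call. = FALSE)
  }
  structure(list(n_agents = n_agents, n_days = n_days, burn_in = burn_in,
                 scenario = scenario, region = region,
                 facility_counts = facility_counts, distance = distance,
                 behavior = behavior, health = health,
                 proportions = proportions, home_placement = home_placement,
                 education_fraction = education_fraction,
                 record_visits = record_visits,
                 facilities = facilities, network = network),
            class = "sim_config")
}

.resolve_scenario <- function(scenario) {
  if (inherits(scenario, "scenario_spec")) return(scenario)
  sc <- builtin_scenarios()
  if (!scenario %in% names(sc)) {
    stop("unknown scenario '", scenario, "'; built-ins: ",
         paste(names(sc), collapse = ", "), call. = FALSE)
  }
  sc[[scenario]]
}

# Generate the world shared by every scenario at a given seed: region,
# base facilities, population, distance model. Deterministic given `seed`.
.build_world <- function(config, seed) {
  seed <- as.integer(seed)
  region <- generate_region(config$region, seed = seed)
  fac <- config$facilities %||%
    generate_facilities(region, config$facility_counts, seed = seed + 1L,
                        gains = config$health$gain,
                        education_fraction = config$education_fraction)
  pop <- initialize_population(config$n_agents, config$proportions,
                               region = region, seed = seed + 2L,
                               home_placement = config$home_placement,
                               thresholds = config$health$thresholds)
  dm <- if (config$distance$mode == "network") {
    if (!is.null(config$network)) {
      distance_model("network", graph = config$network$graph,
                     nodes = config$network$nodes)
    } else {
      distance_model("network", region = region,
                     grid_spacing = config$distance$grid_spacing,
                     jitter = config$distance$jitter, seed = seed + 3L)
    }
  } else {
    distance_model("euclidean")
  }
  list(region = region, facilities = fac, population = pop, dist = dm)
}

#' Run one seeded simulation
#'
#' Generates the synthetic world (region, facilities, population, distance
#' model) from the seed, applies the scenario overlay (behavioural overrides
#' and coverage-gap facility additions), then iterates the daily cycle: each
#' agent decides whether to go out, picks a facility type by its
#' current-state preference weights, searches within its activity radius
#' (with the out-of-radius fallback), and its health value is updated with
#' the day's decay and any visit gain. Behaviour and decay key on the state
#' at the start of the day; the visit gain applies the same day.
#'
#' The world depends only on `(config, seed)` and not on the scenario, so
#' runs of different scenarios at the same seed are paired: identical
#' region, facilities, population and distance model.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (< 2^30).
#' @return An object of class `sim_result`: list with `config`, `seed`,
#'   `scenario`, `region`, `population`, `facilities` (after scenario
#'   additions), `base_facilities`, `panel` (n_agents x n_days matrix of H
#'   after each day's update), `mean_h` (per-day population mean), and
#'   `visits` (event tibble, when recorded).
#' @export
run_simulation <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  spec <- .resolve_scenario(config$scenario)
  world <- .build_world(config, seed)
  pop <- world$population
  fac <- world$facilities
  if (spec$add_count > 0L) {
    cand <- if (spec$siting == "grid") {
      g <- expand.grid(x = seq(0, world$region$width, length.out = 25),
                       y = seq(0, world$region$height, length.out = 25))
      tibble::tibble(id = seq_len(nrow(g)), x = g$x, y = g$y)
    } else {
      pop[, c("id", "x", "y")]
    }
    new_sites <- site_new_facilities(spec$add_count, cand, fac, world$dist)
    new_sites$type <- spec$add_type
    new_sites$gain <- spec$add_gain
    fac <- dplyr::bind_rows(fac, new_sites)
  }
  beh <- apply_scenario(config$behavior, spec)
  hp <- config$health
  n <- config$n_agents
  n_days <- config$n_days

  D <- distance_matrix(world$dist, cbind(pop$x, pop$y), cbind(fac$x, fac$y))
  type_idx <- lapply(.ftypes[1:3], .candidates_of_type, facilities = fac)
  type_w <- lapply(type_idx, function(ix) 1 + beh$live_adjust * fac$education_host[ix])
  cw <- t(apply(beh$type_weights, 1L, cumsum))
  pen <- hp$alone_decay * (pop$living == "alone") +
    hp$low_econ_decay * (pop$econ == "low")

  # independent behavioural stream, identical across scenarios of a replicate
  set.seed(as.integer(seed) + 499979L)
  H <- pop$H
  panel <- matrix(NA_real_, nrow = n, ncol = n_days)
  cap <- max(1L, n * n_days)
  v_day <- integer(cap); v_agent <- integer(cap); v_fac <- integer(cap)
  v_type <- character(cap); v_dist <- numeric(cap); v_fb <- logical(cap)
  nv <- 0L

  for (day in seq_len(n_days)) {
    st <- .state_code(H, hp$thresholds)
    visit_gain <- numeric(n)
    if (n > 0L) {
      out <- runif(n) < beh$p_out[st]
      idx <- which(out)
      if (length(idx)) {
        u <- runif(length(idx))
        ty <- 1L + (u > cw[st[idx], 1L]) + (u > cw[st[idx], 2L])
        for (k in seq_along(idx)) {
          i <- idx[k]
          cand <- type_idx[[ty[k]]]
          if (!length(cand)) next
          d <- D[i, cand]
          res <- .facility_draw(d, fac$id[cand], type_w[[ty[k]]],
                                beh$radius[st[i]], beh$fallback_p)
          if (is.na(res$pick)) next
          j <- cand[res$pick]
          visit_gain[i] <- fac$gain[j]
          nv <- nv + 1L
          v_day[nv] <- day; v_agent[nv] <- pop$id[i]; v_fac[nv] <- fac$id[j]
          v_type[nv] <- fac$type[j]; v_dist[nv] <- d[res$pick]; v_fb[nv] <- res$fallback
        }
      }
      fdecay <- 1 - unname(hp$decay[st]) - pen
      H <- if (hp$gain_mode == "multiplicative") {
        H * fdecay * (1 + visit_gain)
      } else {
        H * (fdecay + visit_gain)
      }
      H <- pmin(1, pmax(0, H))
    }
    panel[, day] <- H
  }

  visits <- NULL
  if (isTRUE(config$record_visits)) {
    sel <- seq_len(nv)
    visits <- tibble::tibble(day = v_day[sel], agent_id = v_agent[sel],
                             facility_id = v_fac[sel], ftype = v_type[sel],
                             distance_km = v_dist[sel], fallback_used = v_fb[sel])
  }
  structure(list(config = config, seed = as.integer(seed), scenario = spec$name,
                 region = world$region, population = pop,
                 facilities = fac, base_facilities = world$facilities,
                 panel = panel, mean_h = colMeans(panel), visits = visits),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> scenario %s, seed %d: %d agents x %d days, final mean H = %.4f\n",
              x$scenario, x$seed, nrow(x$panel), ncol(x$panel),
              x$mean_h[length(x$mean_h)]))
  invisible(x)
}

#' Run a paired-seed multi-scenario experiment
#'
#' For every replicate, the same seed (hence the same synthetic city and
#' population) is used for every scenario, so scenario contrasts are
#' within-replicate. The baseline `S0` is always included as the reference
#' for the per-day health change.
#'
#' @param config A `sim_config` (its `scenario` field is ignored).
#' @param scenarios Character vector of scenario names (or list of
#'   `scenario_spec`s).
#' @param replicates Number of replicates (default 30).
#' @param base_seed Integer base seed; replicate r runs at seed
#'   `base_seed * 1000 + r`.
#' @return A list of tibbles:
#'   \describe{
#'     \item{mean_h}{`scenario`, `replicate`, `day`, `mean_h` (all days).}
#'     \item{delta}{`scenario`, `replicate`, `day`, `delta_h` — scenario
#'       minus `S0`, same replicate and day, post-burn-in days only.}
#'     \item{gini}{`scenario`, `dimension`, `replicate`, `day`, `gini`,
#'       post-burn-in days only.}
#'     \item{final}{replicate-mean `mean_h` and `delta_h` at the final day,
#'       one row per scenario.}
#'   }
#' @export
run_experiment <- function(config, scenarios = c("S0", "S1", "S2", "S3", "S4"),
                           replicates = 30L, base_seed = 1L) {
  stopifnot(replicates >= 1L)
  specs <- lapply(scenarios, .resolve_scenario)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (!"S0" %in% names(specs)) specs <- c(list(S0 = .resolve_scenario("S0")), specs)
  config$record_visits <- FALSE
  dims <- c("initial_health", "economic", "living")
  mean_rows <- list(); gini_rows <- list()
  for (r in seq_len(replicates)) {
    seed_r <- (as.integer(base_seed) * 1000L + r) %% 536870912L
    for (s in names(specs)) {
      cfg <- config
      cfg$scenario <- specs[[s]]
      res <- run_simulation(cfg, seed_r)
      mean_rows[[length(mean_rows) + 1L]] <- tibble::tibble(
        scenario = s, replicate = r, day = seq_len(config$n_days),
        mean_h = res$mean_h)
      for (dm in dims) {
        g <- gini_timeseries(res, dm)
        gini_rows[[length(gini_rows) + 1L]] <- tibble::tibble(
          scenario = s, dimension = dm, replicate = r, day = g$day, gini = g$gini)
      }
    }
  }
  mean_h <- dplyr::bind_rows(mean_rows)
  gini <- dplyr::bind_rows(gini_rows)
  base <- dplyr::select(dplyr::filter(mean_h, .data$scenario == "S0"),
                        "replicate", "day", base_h = "mean_h")
  delta <- dplyr::mutate(dplyr::inner_join(mean_h, base, by = c("replicate", "day")),
                         delta_h = .data$mean_h - .data$base_h)
  delta <- dplyr::select(dplyr::filter(delta, .data$day > config$burn_in),
                         "scenario", "replicate", "day", "delta_h")
  final <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(delta, .data$day == config$n_days), .data$scenario),
    delta_h = mean(.data$delta_h), .groups = "drop")
  fin_h <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(mean_h, .data$day == config$n_days), .data$scenario),
    mean_h = mean(.data$mean_h), .groups = "drop")
  final <- dplyr::inner_join(fin_h, final, by = "scenario")
  list(mean_h = mean_h, delta = delta, gini = gini, final = final,
       scenarios = names(specs), replicates = replicates, base_seed = base_seed)
}

# Map public parameter names (the model's tunables) onto config slots.
.sensitivity_params <- function() {
  list(
    healthyDecayRate = function(cfg, v) { cfg$health$decay["healthy"] <- v; cfg },
    weakDecayRate = function(cfg, v) { cfg$health$decay["weak"] <- v; cfg },
    disabledDecayRate = function(cfg, v) { cfg$health$decay["disabled"] <- v; cfg },
    aloneDecayRate = function(cfg, v) { cfg$health$alone_decay <- v; cfg },
    lowEconomicDecay = function(cfg, v) { cfg$health$low_econ_decay <- v; cfg },
    preHealthIncreaseRatio = function(cfg, v) { cfg$health$gain["prevention"] <- v; cfg },
    treHealthIncreaseRatio = function(cfg, v) { cfg$health$gain["treatment"] <- v; cfg },
    rehHealthIncreaseRatio = function(cfg, v) { cfg$health$gain["care"] <- v; cfg }
  )
}

.sensitivity_base <- function(cfg, name) {
  switch(name,
         healthyDecayRate = cfg$health$decay[["healthy"]],
         weakDecayRate = cfg$health$decay[["weak"]],
         disabledDecayRate = cfg$health$decay[["disabled"]],
         aloneDecayRate = cfg$health$alone_decay,
         lowEconomicDecay = cfg$health$low_econ_decay,
         preHealthIncreaseRatio = cfg$health$gain[["prevention"]],
         treHealthIncreaseRatio = cfg$health$gain[["treatment"]],
         rehHealthIncreaseRatio = cfg$health$gain[["care"]])
}

#' Univariate sensitivity protocol
#'
#' Perturbs one parameter at a time over a relative grid, runs a set of
#' seeded trials at each grid point (the same seed set at every point, so
#' responses are paired), and aggregates mean final-day health and mean
#' post-burn-in health.
#'
#' @param config Base `sim_config`.
#' @param params Character vector of parameter names; see
#'   `names(eldersim:::.sensitivity_params())` for the valid set.
#' @param rel_grid Relative perturbations (e.g. `c(-0.2, -0.1, 0, 0.1, 0.2)`).
#' @param trials Seeded simulation trials per grid point (default 100).
#' @param base_seed Integer base seed.
#' @return A tibble with one row per parameter x grid point: `parameter`,
#'   `rel_change`, `value`, `n_trials`, `mean_final_h`, `sd_final_h`,
#'   `mean_postburn_h`.
#' @export
univariate_sensitivity <- function(config, params,
                                   rel_grid = c(-0.2, -0.1, 0, 0.1, 0.2),
                                   trials = 100L, base_seed = 1L) {
  setters <- .sensitivity_params()
  bad <- setdiff(params, names(setters))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(setters), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.finite(rel_grid), trials >= 1L)
  config$record_visits <- FALSE
  seeds <- (as.integer(base_seed) * 1000L + seq_len(trials)) %% 536870912L
  rows <- list()
  for (p in params) {
    base_val <- .sensitivity_base(config, p)
    for (g in rel_grid) {
      val <- base_val * (1 + g)
      cfg <- setters[[p]](config, val)
      fin <- numeric(trials); post <- numeric(trials)
      for (t in seq_len(trials)) {
        res <- run_simulation(cfg, seeds[t])
        fin[t] <- res$mean_h[config$n_days]
        post[t] <- mean(res$mean_h[(config$burn_in + 1L):config$n_days])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = p, rel_change = g, value = val, n_trials = trials,
        mean_final_h = mean(fin), sd_final_h = stats::sd(fin),
        mean_postburn_h = mean(post))
    }
  }
  dplyr::bind_rows(rows)
}
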