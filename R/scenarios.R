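#' Define an intervention scenario
#'
#' A scenario is a declarative bundle of overrides on the baseline
#' behavioural parameters plus an optional batch of new facilities sited by
#' the coverage-gap rule. Applying a scenario never mutates the baseline.
#'
#' @param name Scenario name.
#' @param p_out Optional named outing-probability overrides per state.
#' @param radius Optional named activity-radius overrides per state (km).
#' @param live_adjust Optional education-host weight bonus override.
#' @param add_count Number of facilities to add (>= 0).
#' @param add_gain Per-visit gain of the added facilities.
#' @param add_type Type of the added facilities (default `"comprehensive"`).
#' @param siting `"coverage_gap"` (greedy max-min over agent homes) or
#'   `"grid"` (greedy max-min over a dense grid of candidate sites).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, p_out = NULL, radius = NULL, live_adjust = NULL,
                          add_count = 0L, add_gain = 0.05,
                          add_type = "comprehensive",
                          siting = c("coverage_gap", "grid")) {
  siting <- match.arg(siting)
  if (!is.null(p_out) && any(p_out < 0 | p_out > 1)) {
    stop("overridden outing probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(radius) && any(radius <= 0)) {
    stop("overridden radii must be positive", call. = FALSE)
  }
  if (add_count < 0) stop("`add_count` must be non-negative", call. = FALSE)
  structure(list(name = name, p_out = p_out, radius = radius,
                 live_adjust = live_adjust,
                 add_count = as.integer(add_count), add_gain = add_gain,
                 add_type = add_type, siting = siting),
            class = "scenario_spec")
}

#' Built-in intervention scenarios
#'
#' * `S0` — baseline: no overrides.
#' * `S1` — multi-functional community centres: 10 comprehensive hubs sited
#'   at the largest service-coverage gaps, per-visit gain 0.05.
#' * `S2` — senior-friendly transport: outing probabilities raised to
#'   0.8/0.7/0.4 and activity radii to 10/8/3 km.
#' * `S3` — community health education: outing probabilities 0.75/0.6/0.35
#'   and education-host weight bonus raised to 0.2; no new facilities, radii
#'   unchanged.
#' * `S4` — comprehensive package: [combine_scenarios()] of S1–S3 (maxima of
#'   shared scalars; facility additions accumulated).
#'
#' @return A named list of `scenario_spec` objects.
#' @export
builtin_scenarios <- function() {
  s1 <- scenario_spec("S1", add_count = 10L, add_gain = 0.05)
  s2 <- scenario_spec("S2",
                      p_out = c(healthy = 0.8, weak = 0.7, disabled = 0.4),
                      radius = c(healthy = 10, weak = 8, disabled = 3))
  s3 <- scenario_spec("S3",
                      p_out = c(healthy = 0.75, weak = 0.6, disabled = 0.35),
                      live_adjust = 0.2)
  s4 <- combine_scenarios(list(s1, s2, s3), name = "S4")
  list(S0 = scenario_spec("S0"), S1 = s1, S2 = s2, S3 = s3, S4 = s4)
}

#' Combine scenarios into a single package
#'
#' For each shared scalar parameter (per-state outing probability, per-state
#' radius, education-weight bonus) the maximum over the scenarios that set it
#' is taken; facility additions are accumulated.
#'
#' @param specs A non-empty list of `scenario_spec` objects.
#' @param name Name of the combined scenario.
#' @return A `scenario_spec`.
#' @export
combine_scenarios <- function(specs, name = "combined") {
  stopifnot(length(specs) >= 1L)
  max_field <- function(field, states = TRUE) {
    vals <- Filter(Negate(is.null), lapply(specs, `[[`, field))
    if (!length(vals)) return(NULL)
    if (states) {
      out <- setNames(rep(-Inf, 3L), .states)
      for (v in vals) out[names(v)] <- pmax(out[names(v)], v)
      out[is.infinite(out)] <- NA_real_
      out <- out[!is.na(out)]
      out
    } else {
      max(unlist(vals))
    }
  }
  adds <- vapply(specs, `[[`, integer(1), "add_count")
  gain <- if (any(adds > 0)) max(vapply(specs[adds > 0], `[[`, numeric(1), "add_gain")) else 0.05
  scenario_spec(name,
                p_out = max_field("p_out"),
                radius = max_field("radius"),
                live_adjust = max_field("live_adjust", states = FALSE),
                add_count = sum(adds),
                add_gain = gain)
}

#' Apply a scenario's overrides to behavioural parameters
#'
#' @param params Baseline `behavior_params`.
#' @param spec A `scenario_spec`.
#' @return A new `behavior_params`; the input is not modified.
#' @export
apply_scenario <- function(params, spec) {
  p_out <- params$p_out
  radius <- params$radius
  if (!is.null(spec$p_out)) p_out[names(spec$p_out)] <- spec$p_out
  if (!is.null(spec$radius)) radius[names(spec$radius)] <- spec$radius
  behavior_params(p_out = p_out, radius = radius,
                  fallback_p = params$fallback_p,
                  live_adjust = spec$live_adjust %||% params$live_adjust,
                  type_weights = params$type_weights)
}

#' Site new facilities at the largest coverage gaps
#'
#' Greedy max-min siting: repeatedly place the next facility at the
#' candidate location whose distance to its nearest existing-or-new facility
#' is largest (ties broken by lowest candidate id). By default candidates
#' are the agent home locations, so hubs land where agents are worst served.
#' Deterministic given its inputs.
#'
#' @param k Number of facilities to site (>= 0).
#' @param homes Tibble of candidate locations with columns `id`, `x`, `y`
#'   (non-empty).
#' @param facilities Existing facility tibble (may have zero rows).
#' @param dist A `distance_model`.
#' @return A tibble of new sites (`id`, `x`, `y`, `type = "comprehensive"`,
#'   `gain`, `education_host`); ids continue after the existing maximum.
#' @export
site_new_facilities <- function(k, homes, facilities, dist) {
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be non-negative", call. = FALSE)
  empty <- tibble::tibble(id = integer(0), x = numeric(0), y = numeric(0),
                          type = character(0), gain = numeric(0),
                          education_host = logical(0))
  if (k == 0L) return(empty)
  if (nrow(homes) == 0L) stop("`homes` must be non-empty", call. = FALSE)
  hxy <- cbind(homes$x, homes$y)
  nearest <- if (nrow(facilities)) {
    apply(distance_matrix(dist, hxy, cbind(facilities$x, facilities$y)), 1L, min)
  } else {
    rep(Inf, nrow(homes))
  }
  hid <- if ("id" %in% names(homes)) homes$id else seq_len(nrow(homes))
  picks <- integer(k)
  for (i in seq_len(k)) {
    best <- order(-nearest, hid)[1L]
    picks[i] <- best
    d_new <- distance_matrix(dist, hxy, hxy[best, , drop = FALSE])[, 1L]
    nearest <- pmin(nearest, d_new)
  }
  next_id <- if (nrow(facilities)) max(facilities$id) else 0L
  tibble::tibble(id = next_id + seq_len(k),
                 x = homes$x[picks], y = homes$y[picks],
                 type = "comprehensive", gain = NA_real_,
                 education_host = TRUE)
}
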