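#' Behavioural parameters for daily travel and facility choice
#'
#' Baseline values encode the state gradient in mobility: healthy agents go
#' out with probability 0.7 within a 5 km activity radius, weak agents 0.5
#' within 3 km, disabled agents 0.3 within 1 km. When no facility of the
#' demanded type lies within the radius, the agent travels to the nearest
#' matching facility beyond it with probability `fallback_p`, otherwise the
#' outing is cancelled. `type_weights` are the per-state facility-type
#' preference shares (rows: healthy/weak/disabled; columns:
#' prevention/treatment/care). `live_adjust` is the extra multiplicative
#' selection weight `1 + live_adjust` given to facilities hosting community
#' health-education sessions.
#'
#' @param p_out Named outing probabilities per state.
#' @param radius Named activity radii per state (km, > 0).
#' @param fallback_p Probability of travelling beyond the radius when the
#'   in-radius pool is empty.
#' @param live_adjust Education-host selection-weight bonus (>= 0).
#' @param type_weights 3x3 matrix of type preference shares; each row must
#'   sum to 1 within 1e-9.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_out = c(healthy = 0.7, weak = 0.5, disabled = 0.3),
                            radius = c(healthy = 5, weak = 3, disabled = 1),
                            fallback_p = 0.5,
                            live_adjust = 0.1,
                            type_weights = default_type_weights()) {
  p_out <- p_out[.states]; radius <- radius[.states]
  type_weights <- as.matrix(type_weights)
  dimnames(type_weights) <- list(.states, .ftypes[1:3])
  if (any(is.na(p_out)) || any(p_out < 0 | p_out > 1)) {
    stop("`p_out` must give probabilities in [0, 1] for all three states", call. = FALSE)
  }
  if (any(is.na(radius)) || any(radius <= 0)) {
    stop("`radius` must be positive for all three states", call. = FALSE)
  }
  if (fallback_p < 0 || fallback_p > 1) stop("`fallback_p` must be in [0, 1]", call. = FALSE)
  if (live_adjust < 0) stop("`live_adjust` must be non-negative", call. = FALSE)
  if (any(abs(rowSums(type_weights) - 1) > 1e-9) || any(type_weights < 0)) {
    stop("each row of `type_weights` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(p_out = p_out, radius = radius, fallback_p = fallback_p,
                 live_adjust = live_adjust, type_weights = type_weights),
            class = "behavior_params")
}

#' Baseline facility preference weights by current health state
#'
#' Healthy agents favour prevention (0.6/0.2/0.2), weak agents favour
#' treatment (0.3/0.5/0.2), disabled agents favour long-term care
#' (0.1/0.3/0.6).
#'
#' @return A 3x3 matrix, rows = states, columns = prevention/treatment/care.
#' @export
default_type_weights <- function() {
  matrix(c(0.6, 0.2, 0.2,
           0.3, 0.5, 0.2,
           0.1, 0.3, 0.6),
         nrow = 3, byrow = TRUE,
         dimnames = list(.states, .ftypes[1:3]))
}

#' Daily outing decision
#'
#' Bernoulli draw with the state's outing probability. Vectorized over
#' `state`; draws come from R's global RNG stream.
#'
#' @param state Character vector of current health states.
#' @param params A `behavior_params`.
#' @return Logical vector.
#' @export
decide_outing <- function(state, params = behavior_params()) {
  runif(length(state)) < params$p_out[state]
}

#' Facility-type choice
#'
#' Categorical draw from the current state's type preference weights.
#' Vectorized over `state`.
#'
#' @inheritParams decide_outing
#' @return Character vector over `"prevention"`, `"treatment"`, `"care"`.
#' @export
choose_type <- function(state, params = behavior_params()) {
  cw <- t(apply(params$type_weights, 1L, cumsum))
  u <- runif(length(state))
  si <- match(state, .states)
  .ftypes[1L + (u > cw[si, 1L]) + (u > cw[si, 2L])]
}

# Core facility draw shared by choose_facility() and the engine day loop.
# `d` distances to the candidate facilities, `ids` their ids, `w` their
# selection weights. Returns list(pick = index into candidates or NA,
# fallback = logical). Consumes at most one RNG draw.
.facility_draw <- function(d, ids, w, radius, fallback_p) {
  if (length(d) == 0L) return(list(pick = NA_integer_, fallback = FALSE))
  inr <- which(d <= radius)
  if (length(inr)) {
    pick <- if (length(inr) == 1L) inr else inr[sample.int(length(inr), 1L, prob = w[inr])]
    return(list(pick = pick, fallback = FALSE))
  }
  if (runif(1L) < fallback_p) {
    return(list(pick = order(d, ids)[1L], fallback = TRUE))
  }
  list(pick = NA_integer_, fallback = FALSE)
}

# Candidate facility row indices for a demanded type; comprehensive hubs
# match every demanded type.
.candidates_of_type <- function(facilities, type) {
  which(facilities$type == type | facilities$type == "comprehensive")
}

#' Choose a facility of a demanded type
#'
#' Builds the candidate pool of facilities matching `chosen_type`
#' (comprehensive hubs match every type) within the agent's state-dependent
#' activity radius and samples one, with education-host facilities weighted
#' by `1 + live_adjust`. If the pool is empty, with probability `fallback_p`
#' the agent travels to the nearest matching facility beyond the radius
#' (ties broken by lowest facility id); otherwise the outing is cancelled.
#'
#' @param agent A one-row population tibble (or list with `x`, `y`, `H`).
#' @param chosen_type `"prevention"`, `"treatment"` or `"care"`.
#' @param facilities Facility tibble.
#' @param dist A `distance_model`.
#' @param params A `behavior_params`.
#' @return A one-row tibble (`facility_id`, `ftype`, `distance_km`,
#'   `fallback_used`) or `NULL` when the outing is cancelled or no matching
#'   facility exists anywhere.
#' @export
choose_facility <- function(agent, chosen_type, facilities, dist,
                            params = behavior_params()) {
  state <- classify_state(agent$H)
  cand <- .candidates_of_type(facilities, chosen_type)
  if (!length(cand)) return(NULL)
  d <- distance_matrix(dist, cbind(agent$x, agent$y),
                       cbind(facilities$x[cand], facilities$y[cand]))[1L, ]
  w <- 1 + params$live_adjust * facilities$education_host[cand]
  res <- .facility_draw(d, facilities$id[cand], w, params$radius[state], params$fallback_p)
  if (is.na(res$pick)) return(NULL)
  j <- cand[res$pick]
  tibble::tibble(facility_id = facilities$id[j], ftype = facilities$type[j],
                 distance_km = d[res$pick], fallback_used = res$fallback)
}

#' Simulate one agent-day of the travel decision process
#'
#' Composes the daily decision chain: outing decision, facility-type choice
#' by current-state preference weights, in-radius facility search with the
#' fallback rule. The agent returns home the same day; an agent-day yields
#' at most one visit.
#'
#' @inheritParams choose_facility
#' @param day Integer day stamp for the visit event (>= 1).
#' @return A one-row visit-event tibble (`day`, `agent_id`, `facility_id`,
#'   `ftype`, `distance_km`, `fallback_used`) or `NULL` when the agent stays
#'   home or cancels.
#' @export
simulate_agent_day <- function(agent, facilities, dist,
                               params = behavior_params(), day = 1L) {
  state <- classify_state(agent$H)
  if (!decide_outing(state, params)) return(NULL)
  type <- choose_type(state, params)
  ch <- choose_facility(agent, type, facilities, dist, params)
  if (is.null(ch)) return(NULL)
  tibble::tibble(day = as.integer(day), agent_id = as.integer(agent$id), ch)
}

#' Write a visit log to CSV
#'
#' @param visits A visit-event tibble.
#' @param path File path.
#' @export
write_visits_csv <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE)
  invisible(path)
}
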