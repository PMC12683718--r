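#' Health-dynamics parameters
#'
#' Daily natural decay is stratified by the agent's current state (healthy
#' 0.006, weak 0.009, disabled 0.012 per day), with additional decay for
#' living alone and for low economic status (0.001 each). A facility visit
#' multiplies the day's outcome by `1 + gain[type]`. Health is clipped to
#' \[0, 1\] after every update.
#'
#' With the baseline coefficients every per-day net factor
#' `(1 - decay - penalties) * (1 + gain)` is below 1 (the largest base gain,
#' 0.003, is smaller than the smallest decay, 0.006), so an unaided
#' population declines; only the comprehensive-hub gain (0.05) can produce a
#' net factor above 1 for non-disabled agents.
#'
#' @param decay Named per-state daily decay rates.
#' @param alone_decay Additional daily decay for agents living alone.
#' @param low_econ_decay Additional daily decay for low economic status.
#' @param gain Named per-visit gain coefficients by facility type.
#' @param thresholds Health band boundaries (strictly increasing, in (0,1)).
#' @param gain_mode `"multiplicative"` (default) applies the visit gain as a
#'   factor on the decayed value, `H' = H(1-a-b-g)(1+d)`; `"additive"` adds
#'   the gain term to the decay factor, `H' = H(1-a-b-g+d)`. The two differ
#'   only at second order.
#' @return An object of class `health_params`.
#' @export
health_params <- function(decay = c(healthy = 0.006, weak = 0.009, disabled = 0.012),
                          alone_decay = 0.001,
                          low_econ_decay = 0.001,
                          gain = default_facility_gains(),
                          thresholds = c(0.3, 0.7),
                          gain_mode = c("multiplicative", "additive")) {
  gain_mode <- match.arg(gain_mode)
  decay <- decay[.states]
  if (any(is.na(decay)) || any(decay < 0)) {
    stop("`decay` must give non-negative rates for all three states", call. = FALSE)
  }
  if (!(decay["disabled"] >= decay["weak"] && decay["weak"] >= decay["healthy"])) {
    stop("decay rates must not decrease with worse health state", call. = FALSE)
  }
  if (alone_decay < 0 || low_econ_decay < 0 || any(gain < 0)) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2] ||
      thresholds[1] <= 0 || thresholds[2] >= 1) {
    stop("`thresholds` must be strictly increasing within (0, 1)", call. = FALSE)
  }
  structure(list(decay = decay, alone_decay = alone_decay,
                 low_econ_decay = low_econ_decay, gain = gain,
                 thresholds = thresholds, gain_mode = gain_mode),
            class = "health_params")
}

#' Daily health update
#'
#' Applies one day of health dynamics: natural decay at the current state's
#' rate, extra decay for living alone and low economic status, and the visit
#' gain when a facility was visited that day, then clips to \[0, 1\]:
#' `H' = clip(H * (1 - decay - alone - low_econ) * (1 + gain[visit]), 0, 1)`.
#'
#' Vectorized over agents; `visit` is `NA` for agents without a visit.
#'
#' @param H Numeric health values in \[0, 1\].
#' @param living Character vector of living status.
#' @param econ Character vector of economic status.
#' @param visit Character vector of visited facility types, `NA` = no visit.
#' @param params A `health_params`.
#' @param state Optional current states; derived from `H` when `NULL`.
#' @return Updated health values in \[0, 1\].
#' @export
#' @examples
#' update_health(1, "with_spouse", "mid", NA)            # 0.994
#' update_health(0.5, "alone", "low", "treatment")       # ~0.49598
update_health <- function(H, living, econ, visit = NA_character_,
                          params = health_params(), state = NULL) {
  if (any(!is.finite(H)) || any(H < 0 | H > 1)) {
    stop("health values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(state)) state <- classify_state(H, params$thresholds)
  fdecay <- 1 - unname(params$decay[state]) -
    params$alone_decay * (living == "alone") -
    params$low_econ_decay * (econ == "low")
  delta <- ifelse(is.na(visit), 0, unname(params$gain[visit]))
  out <- if (params$gain_mode == "multiplicative") {
    H * fdecay * (1 + delta)
  } else {
    H * (fdecay + delta)
  }
  pmin(1, pmax(0, out))
}

#' Closed-form trajectory under constant decay
#'
#' Geometric decay `H0 * (1 - r)^t`; matches iterated [update_health()] with
#' no visits and no attribute penalties for as long as the trajectory stays
#' within one state band (so the decay rate is constant).
#'
#' @param H0 Initial health value.
#' @param r Constant daily decay rate in \[0, 1).
#' @param t Days (>= 0).
#' @return Health value after `t` days (not clipped; H0 in \[0,1\] keeps it there).
#' @export
#' @examples
#' decay_closed_form(1, 0.006, 100)  # ~0.5478
decay_closed_form <- function(H0, r, t) {
  stopifnot(r >= 0, r < 1, t >= 0)
  H0 * (1 - r)^t
}
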