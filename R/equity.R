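#' Weighted multi-group Gini coefficient
#'
#' Inequality across subgroup mean outcomes, weighting each pairwise absolute
#' difference by the product of the subgroups' population shares and
#' normalizing by twice the weighted mean:
#' `G = sum_{i<j} w_i w_j |x_i - x_j| / (2 sum_i w_i x_i)`.
#' 0 indicates perfect equity. Equivalently, G is the sum of absolute
#' differences over unordered pairs of an expanded pseudo-population (group i
#' replicated in proportion `w_i`) divided by `2 N^2 mu`.
#'
#' @param x Non-negative subgroup means (at least one strictly positive).
#' @param w Positive subgroup weights summing to 1 within 1e-6.
#' @return The Gini value in \[0, 1\].
#' @export
#' @examples
#' weighted_gini(c(0.5, 0.5, 0.5), c(0.8, 0.16, 0.04))  # 0
#' weighted_gini(c(1, 0, 0), rep(1 / 3, 3))             # 1/3
weighted_gini <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) >= 2L)
  if (any(x < 0)) stop("subgroup means must be non-negative", call. = FALSE)
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-6) {
    stop("weights must be positive and sum to 1", call. = FALSE)
  }
  mu <- sum(w * x)
  if (mu == 0) stop("all subgroup means are zero; Gini is undefined", call. = FALSE)
  num <- 0
  for (i in seq_len(length(x) - 1L)) {
    j <- (i + 1L):length(x)
    num <- num + sum(w[i] * w[j] * abs(x[i] - x[j]))
  }
  num / (2 * mu)
}

#' Subgroup definitions for the three equity stratifications
#'
#' Maps each equity dimension to the population column holding the (initial)
#' attribute, the fixed subgroup order, and the default census-share weights.
#' Orders follow the convention healthy/weak/disabled, high/mid/low,
#' with_spouse/with_children/alone.
#'
#' @param dimension One of `"initial_health"`, `"economic"`, `"living"`.
#' @param proportions Attribute proportions as in [default_proportions()],
#'   used for the weights.
#' @return A list with `column`, `groups`, `weights`.
#' @export
strata_spec <- function(dimension = c("initial_health", "economic", "living"),
                        proportions = default_proportions()) {
  dimension <- match.arg(dimension)
  switch(dimension,
    initial_health = list(column = "initial_state",
                          groups = c("healthy", "weak", "disabled"),
                          weights = unname(proportions$health[c("healthy", "weak", "disabled")])),
    economic = list(column = "econ",
                    groups = c("high", "mid", "low"),
                    weights = unname(proportions$econ[c("high", "mid", "low")])),
    living = list(column = "living",
                  groups = c("with_spouse", "with_children", "alone"),
                  weights = unname(proportions$living[c("with_spouse", "with_children", "alone")]))
  )
}

#' Daily weighted-Gini time series from a simulation result
#'
#' For each retained day, computes the mean health value of each subgroup
#' (grouped by the agents' INITIAL attributes, so membership is fixed over
#' the run) and evaluates the weighted Gini with the stratification's census
#' weights. Days up to and including the burn-in are excluded.
#'
#' With the default population (n = 200) the `alone` subgroup holds only two
#' agents, so the living-status series is noisy; average it across replicates
#' (see [run_experiment()]) before interpreting it.
#'
#' @param result A `sim_result` from [run_simulation()], or a list with
#'   elements `panel` (agents x days health matrix) and `population`.
#' @param dimension Stratification, see [strata_spec()].
#' @param burn_in Days to drop from the start (default: the result's
#'   configured burn-in).
#' @param weights Optional length-3 weight override.
#' @return A tibble with columns `dimension`, `day`, `gini`.
#' @export
gini_timeseries <- function(result, dimension = c("initial_health", "economic", "living"),
                            burn_in = NULL, weights = NULL) {
  dimension <- match.arg(dimension)
  if (is.null(burn_in)) burn_in <- result$config$burn_in %||% 0L
  panel <- result$panel
  n_days <- ncol(panel)
  if (burn_in >= n_days) stop("`burn_in` must be smaller than the run length", call. = FALSE)
  spec <- strata_spec(dimension,
                      proportions = result$config$proportions %||% default_proportions())
  if (!is.null(weights)) spec$weights <- weights
  member <- result$population[[spec$column]]
  means <- matrix(NA_real_, nrow = length(spec$groups), ncol = n_days)
  for (gi in seq_along(spec$groups)) {
    rows <- which(member == spec$groups[gi])
    if (!length(rows)) {
      stop(sprintf("subgroup '%s' is empty; cannot compute its mean health",
                   spec$groups[gi]), call. = FALSE)
    }
    means[gi, ] <- colMeans(panel[rows, , drop = FALSE])
  }
  days <- (burn_in + 1L):n_days
  g <- vapply(days, function(d) weighted_gini(means[, d], spec$weights), numeric(1))
  tibble::tibble(dimension = dimension, day = as.integer(days), gini = g)
}

#' Write Gini series to CSV
#'
#' Writes a long table with columns `scenario`, `dimension`, `day`, `gini`,
#' `replicate`, and (optionally) a companion file of replicate means.
#'
#' @param gini A tibble as produced by [run_experiment()]`$gini`.
#' @param path File path.
#' @param mean_path Optional path for the replicate-mean file.
#' @export
write_gini_csv <- function(gini, path, mean_path = NULL) {
  utils::write.csv(gini, path, row.names = FALSE)
  if (!is.null(mean_path)) {
    m <- dplyr::summarise(
      dplyr::group_by(gini, dplyr::across(dplyr::any_of(c("scenario", "dimension", "day")))),
      gini = mean(.data$gini), .groups = "drop")
    utils::write.csv(m, mean_path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
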