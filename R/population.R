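#' Default initialization proportions for agent attributes
#'
#' Marginal proportions of the three categorical attribute dimensions in the
#' simulated older-adult population: health status (healthy / weak /
#' disabled), living status (with spouse / with children / alone) and
#' economic status (low / mid / high, proxied by household vehicle value).
#'
#' @return A list of three named numeric vectors, each summing to 1.
#' @export
default_proportions <- function() {
  list(
    health = c(healthy = 0.80, weak = 0.16, disabled = 0.04),
    living = c(with_spouse = 0.70, with_children = 0.29, alone = 0.01),
    econ   = c(low = 0.69, mid = 0.26, high = 0.05)
  )
}

#' Classify a continuous health value into a categorical state
#'
#' Health is a continuous index H in \[0, 1\] (0 = complete unhealthiness,
#' 1 = optimal health). Bands map H to the three census-style states:
#' healthy for H >= 0.7, weak for 0.3 <= H < 0.7, disabled for H < 0.3.
#' Band boundaries are assigned to the upper band so classification is a
#' total function.
#'
#' @param H Numeric vector in \[0, 1\].
#' @param thresholds Increasing length-2 vector of band boundaries
#'   (default `c(0.3, 0.7)`).
#' @return Character vector over `"healthy"`, `"weak"`, `"disabled"`.
#' @export
#' @examples
#' classify_state(c(0.85, 0.3, 0))
classify_state <- function(H, thresholds = c(0.3, 0.7)) {
  if (any(!is.finite(H)) || any(H < 0 | H > 1)) {
    stop("health values must lie in [0, 1]", call. = FALSE)
  }
  .states[3L - findInterval(H, thresholds)]
}

# Integer state codes 1 = healthy, 2 = weak, 3 = disabled; used by the engine.
.state_code <- function(H, thresholds = c(0.3, 0.7)) {
  3L - findInterval(H, thresholds)
}

#' Largest-remainder allocation of n units to proportions
#'
#' @param n Total count.
#' @param p Named proportions summing to 1.
#' @return Named integer counts summing to `n`. Ties in the remainders are
#'   broken in favour of earlier categories.
#' @export
#' @examples
#' largest_remainder(25, c(a = 0.8, b = 0.16, c = 0.04))  # 20 4 1
largest_remainder <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1", call. = FALSE)
  quota <- n * p
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  extra <- integer(length(p))
  if (left > 0L) extra[order(-(quota - base))[seq_len(left)]] <- 1L
  setNames(as.integer(base + extra), names(p))
}

#' Initialize the older-adult agent population
#'
#' Creates `n` agents whose categorical attributes follow the configured
#' marginal proportions exactly (largest-remainder stratified allocation,
#' then an independent seeded shuffle per dimension), whose initial health
#' value H is drawn uniformly within the band of the assigned initial state,
#' and whose home locations are sampled from the region's density surface
#' (or uniformly).
#'
#' The three attribute dimensions are assigned independently of one another;
#' only the marginal proportions are controlled, not the joint distribution.
#'
#' @param n Number of agents.
#' @param proportions List as in [default_proportions()]; each vector must
#'   sum to 1 within 1e-9.
#' @param region A `study_region` (used when `homes` is not supplied).
#' @param seed Integer seed.
#' @param homes Optional tibble of home coordinates (`x`, `y`), `n` rows.
#' @param home_placement `"density"` (default) or `"uniform"`.
#' @param thresholds Health band boundaries, see [classify_state()].
#' @return A tibble with columns `id`, `x`, `y`, `H`, `initial_state`,
#'   `living`, `econ`.
#' @export
initialize_population <- function(n, proportions = default_proportions(),
                                  region = NULL, seed = 1L, homes = NULL,
                                  home_placement = c("density", "uniform"),
                                  thresholds = c(0.3, 0.7)) {
  n <- as.integer(n)
  home_placement <- match.arg(home_placement)
  for (nm in c("health", "living", "econ")) {
    if (abs(sum(proportions[[nm]]) - 1) > 1e-9) {
      stop(sprintf("`proportions$%s` must sum to 1", nm), call. = FALSE)
    }
  }
  if (n == 0L) {
    return(tibble::tibble(id = integer(0), x = numeric(0), y = numeric(0),
                          H = numeric(0), initial_state = character(0),
                          living = character(0), econ = character(0)))
  }
  set.seed(as.integer(seed))
  draw_dim <- function(p) {
    counts <- largest_remainder(n, p)
    sample(rep(names(p), times = counts))
  }
  st <- draw_dim(proportions$health)
  lv <- draw_dim(proportions$living)
  ec <- draw_dim(proportions$econ)
  # uniform H within each state's band; upper band closed at 1
  lo <- c(healthy = thresholds[2], weak = thresholds[1], disabled = 0)
  hi <- c(healthy = 1, weak = thresholds[2], disabled = thresholds[1])
  H <- runif(n, lo[st], hi[st])
  if (is.null(homes)) {
    if (is.null(region)) stop("either `region` or `homes` must be supplied", call. = FALSE)
    homes <- sample_points(region, n, uniform = home_placement == "uniform")
  }
  stopifnot(nrow(homes) == n)
  tibble::tibble(id = seq_len(n), x = homes$x, y = homes$y, H = H,
                 initial_state = st, living = lv, econ = ec)
}

#' Read / write a population snapshot
#'
#' CSV with columns `id`, `x`, `y`, `H`, `initial_state`, `living`, `econ`.
#'
#' @param population A population tibble.
#' @param path File path.
#' @return `read_population_csv()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_population_csv <- function(population, path) {
  utils::write.csv(population, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x", "y", "H", "initial_state", "living", "econ") %in% names(df)))
  tibble::as_tibble(df)
}
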