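#' Read a run configuration from YAML or JSON
#'
#' The file holds plain scalar blocks mirroring the arguments of
#' [sim_config()]; parameter blocks (`behavior`, `health`) are given as
#' named lists of their constructor arguments. Unspecified values fall back
#' to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw),
                        c("n_agents", "n_days", "burn_in", "scenario", "region",
                          "facility_counts", "distance", "proportions",
                          "home_placement", "education_fraction", "record_visits"))]
  if (!is.null(raw$behavior)) {
    b <- raw$behavior
    if (!is.null(b$type_weights)) b$type_weights <- matrix(unlist(b$type_weights), nrow = 3, byrow = TRUE)
    for (nm in c("p_out", "radius")) if (!is.null(b[[nm]])) b[[nm]] <- unlist(b[[nm]])
    args$behavior <- do.call(behavior_params, b)
  }
  if (!is.null(raw$health)) {
    h <- raw$health
    for (nm in c("decay", "gain", "thresholds")) if (!is.null(h[[nm]])) h[[nm]] <- unlist(h[[nm]])
    args$health <- do.call(health_params, h)
  }
  if (!is.null(args$facility_counts)) args$facility_counts <- unlist(args$facility_counts)
  if (!is.null(args$proportions)) args$proportions <- lapply(args$proportions, unlist)
  do.call(sim_config, args)
}

#' Write a run manifest
#'
#' Records the resolved configuration and seed of a run as JSON, for
#' reproducibility audits.
#'
#' @param config A `sim_config`.
#' @param seed The seed used.
#' @param path Output path.
#' @export
write_run_manifest <- function(config, seed, path) {
  man <- list(
    seed = as.integer(seed),
    n_agents = config$n_agents, n_days = config$n_days, burn_in = config$burn_in,
    scenario = if (inherits(config$scenario, "scenario_spec")) config$scenario$name else config$scenario,
    facility_counts = as.list(config$facility_counts),
    distance = config$distance,
    home_placement = config$home_placement,
    education_fraction = config$education_fraction,
    behavior = list(p_out = as.list(config$behavior$p_out),
                    radius = as.list(config$behavior$radius),
                    fallback_p = config$behavior$fallback_p,
                    live_adjust = config$behavior$live_adjust,
                    type_weights = apply(config$behavior$type_weights, 1, as.list, simplify = FALSE)),
    health = list(decay = as.list(config$health$decay),
                  alone_decay = config$health$alone_decay,
                  low_econ_decay = config$health$low_econ_decay,
                  gain = as.list(config$health$gain),
                  thresholds = config$health$thresholds,
                  gain_mode = config$health$gain_mode),
    proportions = lapply(config$proportions, as.list)
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
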