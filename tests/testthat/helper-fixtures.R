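# Small in-code fixtures shared across the suite.

# A 10 x 10 km region with one central density kernel.
tiny_region <- function(spread = 1.5) {
  generate_region(list(width = 10, height = 10,
                       kernels = data.frame(x = 5, y = 5, weight = 1,
                                            spread = spread)))
}

# A compact configuration for engine tests: same rules, smaller world.
fast_config <- function(...) {
  args <- list(n_agents = 40L, n_days = 80L, burn_in = 10L,
               facility_counts = c(prevention = 8L, treatment = 8L, care = 4L),
               region = list(width = 8, height = 6, n_kernels = 2L))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# A one-row agent for behaviour-level tests.
toy_agent <- function(x = 0, y = 0, H = 0.9, id = 1L) {
  tibble::tibble(id = id, x = x, y = y, H = H,
                 initial_state = classify_state(H),
                 living = "with_spouse", econ = "mid")
}

# Hand-built facility table: locations and types fully controlled.
toy_facilities <- function(x, y, type, education_host = FALSE,
                           gains = default_facility_gains()) {
  tibble::tibble(id = seq_along(x), x = x, y = y, type = type,
                 gain = unname(gains[type]),
                 education_host = rep_len(education_host, length(x)))
}

eu <- distance_model("euclidean")

# Direct expansion of the grouped Gini definition: replicate group i in
# proportion w_i, sum |x_a - x_b| over unordered individual pairs, and
# normalize by 2 N^2 mu. Independent of the package's closed-form path.
pseudo_population_gini <- function(x, counts) {
  v <- rep(x, times = counts)
  N <- length(v)
  s <- 0
  for (a in seq_len(N - 1L)) {
    for (b in (a + 1L):N) s <- s + abs(v[a] - v[b])
  }
  s / (2 * N^2 * mean(v))
}

# Piecewise geometric closed form for a no-visit trajectory: within a band
# the trajectory is H_seg * (1 - r)^(t - t_seg); at a band crossing a new
# segment starts with the new state's decay rate.
piecewise_closed_form <- function(H0, living, econ, params, n_days) {
  pen <- params$alone_decay * (living == "alone") +
    params$low_econ_decay * (econ == "low")
  rate_of <- function(h) unname(params$decay[classify_state(h, params$thresholds)]) + pen
  out <- numeric(n_days)
  h_seg <- H0; day0 <- 0; r_seg <- rate_of(H0)
  for (d in seq_len(n_days)) {
    h <- decay_closed_form(h_seg, r_seg, d - day0)
    out[d] <- h
    r_new <- rate_of(h)
    if (r_new != r_seg) {
      h_seg <- h; day0 <- d; r_seg <- r_new
    }
  }
  out
}

# Scalar reference trajectory for a single agent under the daily update,
# written independently of the engine's vectorized loop.
reference_trajectory <- function(H0, living, econ, params, n_days) {
  h <- H0
  out <- numeric(n_days)
  pen <- params$alone_decay * (living == "alone") +
    params$low_econ_decay * (econ == "low")
  for (d in seq_len(n_days)) {
    st <- classify_state(h, params$thresholds)
    h <- h * (1 - unname(params$decay[st]) - pen)
    h <- min(1, max(0, h))
    out[d] <- h
  }
  out
}
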