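# Shared fixtures: deterministic test signals and tiny cohorts.

tone <- function(freq, rate, n, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / rate + phase)
}

# Small, fast cohort builders used across test files. Short recordings keep
# unit tests quick; the acceptance tests use full-length cohorts.
small_cohort_spec <- function(seed, n_per_class = 10, duration = 10,
                              tremor_amp_pd = 1.5) {
  cohort_spec(n_healthy = n_per_class, n_pd = n_per_class,
              duration = duration, sampling_rate = 100,
              pd = class_params(tremor_amp = tremor_amp_pd), seed = seed)
}

# Brute-force scan oracle for extrema / zero-crossing counts (no plateaus in
# the inputs it is used with).
scan_counts <- function(x) {
  n <- length(x)
  mx <- mn <- 0L
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- mx + 1L
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- mn + 1L
  }
  s <- sign(x)
  s <- s[s != 0]
  zc <- if (length(s) < 2) 0L else sum(diff(s) != 0)
  c(maxima = mx, minima = mn, zero_crossings = as.integer(zc))
}

# Brute-force Dempster combination: enumerate all focal-set products for a
# list of masses on {Healthy, PD, Theta}; independent of dempster_combine().
brute_dempster <- function(masses) {
  sets <- list(Healthy = "H", PD = "P", Theta = c("H", "P"))
  acc <- c(Healthy = 0, PD = 0, Theta = 0, conflict = 0)
  combos <- expand.grid(rep(list(names(sets)), length(masses)),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    focal <- as.character(combos[r, ])
    w <- prod(vapply(seq_along(masses),
                     function(j) masses[[j]][[focal[j]]], numeric(1)))
    inter <- Reduce(intersect, sets[focal])
    key <- if (length(inter) == 0) "conflict"
           else if (length(inter) == 2) "Theta"
           else if (inter == "H") "Healthy" else "PD"
    acc[key] <- acc[key] + w
  }
  if (1 - acc[["conflict"]] <= 1e-12) return(NULL)
  out <- acc[c("Healthy", "PD", "Theta")] / (1 - acc[["conflict"]])
  out
}
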