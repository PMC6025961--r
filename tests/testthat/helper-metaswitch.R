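# shared fixtures: small parameter sets and configs built in code

quick_params <- function(...) switch_params(...)

# deterministic growth: no noise, no switching, division every 60 min
deterministic_params <- function(...) {
  switch_params(r_cv = 0, div_cv = 0, length_noise_cv = 0,
                k_on_sucC = 0, k0_alsS = 0, kmax_alsS = 0,
                r_base = log(2) / 60, K_tox = Inf, ...)
}

# brute-force per-frame state machine, written independently of the
# rle-based detector: scans one frame at a time
brute_force_events <- function(trace, threshold, frame_interval) {
  n <- length(trace)
  events <- list()
  open <- FALSE
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (!open && trace[i] >= threshold) {
      open <- TRUE; start <- i
    } else if (open && trace[i] < threshold) {
      events[[length(events) + 1L]] <- c(start, i - 1L)
      open <- FALSE
    }
  }
  if (open) events[[length(events) + 1L]] <- c(start, n)
  if (!length(events))
    return(data.frame(start = integer(0), end = integer(0),
                      censored = logical(0)))
  m <- do.call(rbind, events)
  data.frame(start = m[, 1], end = m[, 2],
             censored = m[, 1] == 1L | m[, 2] == n)
}

random_trace <- function(len = 200) {
  # random walk with occasional high plateaus, crossing 0 threshold often
  cumsum(stats::rnorm(len)) + stats::rbinom(len, 1, 0.1) * 5
}
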