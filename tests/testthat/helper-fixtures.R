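# shared miniature fixtures, built in code at test time

# plain matrix view of a raster (drops class and step-size attributes)
rv <- function(x) {
  x <- unclass(x)
  attr(x, "Ts") <- NULL
  x
}

default_cfg <- function(...) {
  args <- utils::modifyList(list(tau_s = 5, tau_r = 5, alpha_r = 2,
                                 theta_u = 10, Ts = 1), list(...))
  do.call(srm_config, args)
}

random_raster <- function(n_steps, n_units, p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spike_raster(matrix(as.numeric(stats::runif(n_steps * n_units) < p),
                      n_steps, n_units))
}

# independent scalar-time-loop SRM oracle: naive triple loop, no shared code
# with srm_forward
srm_oracle <- function(x, W, b, cfg) {
  Tn <- nrow(x); n_out <- ncol(W)
  eps <- function(t) if (t <= 0) 0 else (t / cfg$tau_s) * exp(1 - t / cfg$tau_s)
  nu <- function(t) if (t <= 0) 0 else
    -cfg$alpha_r * cfg$theta_u * (t / cfg$tau_r) * exp(1 - t / cfg$tau_r)
  u <- matrix(0, Tn, n_out); s <- matrix(0, Tn, n_out)
  for (t in seq_len(Tn)) {
    for (i in seq_len(n_out)) {
      acc <- b[i]
      for (j in seq_len(ncol(x))) for (m in seq_len(t)) {
        lag <- (t - m) * cfg$Ts
        if (x[m, j] > 0 && lag < cfg$kernel_window * cfg$Ts)
          acc <- acc + W[j, i] * x[m, j] * eps(lag)
      }
      for (m in seq_len(t)) {
        lag <- (t - m) * cfg$Ts
        if (s[m, i] > 0 && lag < cfg$kernel_window * cfg$Ts)
          acc <- acc + s[m, i] * nu(lag)
      }
      u[t, i] <- acc
      s[t, i] <- as.numeric(acc >= cfg$theta_u)
    }
  }
  list(membrane = u, spikes = s)
}

# tiny event set spanning three classes, used by the io round-trip tests
tiny_event_samples <- function(n_channels = 6L) {
  list(
    event_sample(c(1.0, 2.5, 10.0), c(0L, 3L, 5L), label = 0L,
                 n_channels = n_channels),
    event_sample(c(0.0, 4.0, 4.2, 30.5), c(1L, 2L, 2L, 4L), label = 2L,
                 n_channels = n_channels),
    event_sample(numeric(0), integer(0), label = 1L, n_channels = n_channels)
  )
}
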