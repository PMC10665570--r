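#' Synthetic coincidence-coding task configuration
#'
#' The generator emulates the structure of event-based spoken-digit data at
#' miniature scale: sparse binary rasters over a few tens of channels and a
#' fixed horizon, in which class identity is carried purely by inter-channel
#' timing. Each sample is background Bernoulli noise plus a small number of
#' planted pattern occurrences: at every anchor time, channel \code{j} fires
#' at \code{anchor + offset_table[class, j]} (plus rounded Gaussian jitter).
#' Absolute anchor positions are random, so per-channel firing rates carry no
#' class information — only the relative lags do, which is exactly the
#' structure a coincidence detector behind learnable axonal delays can
#' exploit.
#'
#' @param n_classes number of classes.
#' @param n_channels number of input channels.
#' @param n_steps raster horizon in steps.
#' @param base_rate background spike probability per step and channel.
#' @param offset_table integer matrix \code{n_classes x n_channels} of
#'   per-class per-channel lags (steps). Defaults to
#'   \code{(c * j) \%\% (max_offset + 1)} for class \code{c} (1-based) and
#'   channel \code{j}, which gives every class pair a distinct relative-lag
#'   structure and no class a fully synchronous (delay-free) pattern.
#' @param max_offset largest default lag (ignored when \code{offset_table}
#'   is supplied).
#' @param jitter_sd standard deviation of the Gaussian timing jitter
#'   (steps; applied to every pattern event and rounded).
#' @param pattern_width duration of each pattern event in steps: a channel
#'   responds with \code{pattern_width} consecutive spikes starting at its
#'   offset, emulating the short spike trains a cochlear channel emits when
#'   energy enters its band (1 = single spikes).
#' @param n_repeats planted pattern occurrences per sample.
#' @param n_train,n_test split sizes (classes balanced by round-robin).
#' @param seed RNG seed; the same seed reproduces the datasets exactly.
#' @return An object of class \code{synthetic_task_config}.
#' @export
synthetic_task_config <- function(n_classes = 3, n_channels = 8, n_steps = 120,
                                  base_rate = 0.02, offset_table = NULL,
                                  max_offset = 10, jitter_sd = 0.5,
                                  pattern_width = 1, n_repeats = 3,
                                  n_train = 60, n_test = 30, seed = 1L) {
  if (base_rate < 0 || base_rate > 1)
    stop("base_rate must be a probability", call. = FALSE)
  if (is.null(offset_table)) {
    offset_table <- outer(seq_len(n_classes), seq_len(n_channels),
                          function(c, j) (c * j) %% (max_offset + 1L))
  }
  offset_table <- matrix(as.integer(offset_table), n_classes, n_channels)
  if (any(offset_table < 0L) || any(offset_table >= n_steps))
    stop("offsets must lie in [0, n_steps)", call. = FALSE)
  structure(
    list(n_classes = as.integer(n_classes), n_channels = as.integer(n_channels),
         n_steps = as.integer(n_steps), base_rate = base_rate,
         offset_table = offset_table, jitter_sd = jitter_sd,
         pattern_width = as.integer(pattern_width),
         n_repeats = as.integer(n_repeats), n_train = as.integer(n_train),
         n_test = as.integer(n_test), seed = as.integer(seed)),
    class = "synthetic_task_config"
  )
}

synth_sample <- function(cfg, label) {
  x <- matrix(as.numeric(stats::runif(cfg$n_steps * cfg$n_channels) <
                           cfg$base_rate),
              cfg$n_steps, cfg$n_channels)
  offs <- cfg$offset_table[label + 1L, ]
  span <- max(offs) + cfg$pattern_width - 1L
  hi <- cfg$n_steps - span
  for (r in seq_len(cfg$n_repeats)) {
    anchor <- sample.int(max(hi, 1L), 1L)
    t <- anchor + offs
    if (cfg$jitter_sd > 0)
      t <- t + round(stats::rnorm(cfg$n_channels, 0, cfg$jitter_sd))
    for (w in seq_len(cfg$pattern_width) - 1L) {
      tw <- t + w
      ok <- tw >= 1L & tw <= cfg$n_steps
      x[cbind(tw[ok], which(ok))] <- 1
    }
  }
  list(raster = spike_raster(x), label = as.integer(label))
}

#' Generate a synthetic coincidence-coding dataset
#'
#' Draws balanced train and test splits under
#' [synthetic_task_config()]. Reproducible: the same config (including its
#' seed) always yields identical datasets, and the generator restores the
#' caller's RNG state.
#'
#' @param cfg a [synthetic_task_config()].
#' @return List with \code{train} and \code{test}, each a list of samples
#'   (\code{raster}, 0-based \code{label}).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_task_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  make_split <- function(n) {
    labels <- rep_len(seq_len(cfg$n_classes) - 1L, n)
    lapply(labels, function(lb) synth_sample(cfg, lb))
  }
  list(train = make_split(cfg$n_train), test = make_split(cfg$n_test))
}

#' Delay-and-coincidence oracle classifier
#'
#' Brute-force reference classifier for the synthetic task: for each
#' candidate class, channels are delayed by the complement of that class's
#' lag pattern (so a matching sample becomes synchronous) and the score is
#' the number of time steps at which every channel fires simultaneously. The
#' predicted class is the argmax. On a jitter-free, noise-free instance this
#' classifier is exact by construction, which makes it an independent
#' separability oracle for the learning pipeline.
#'
#' @param raster input spike raster.
#' @param cfg the [synthetic_task_config()] that generated the data.
#' @return 0-based predicted class.
#' @export
oracle_classify <- function(raster, cfg) {
  x <- raster_values(raster)
  scores <- vapply(seq_len(cfg$n_classes), function(c) {
    offs <- cfg$offset_table[c, ]
    d <- max(offs) - offs   # complement: aligns a class-c pattern
    aligned <- shift_forward(x, as.integer(d))
    sum(rowSums(aligned) == cfg$n_channels)
  }, numeric(1))
  as.integer(which.max(scores)) - 1L
}
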