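dataset_profiles <- list(
  ntidigits = list(n_in = 64L, n_classes = 11L, tau_s = 5, tau_r = 5,
                   theta_d = 128L, bin_ms = 1, n_steps = 300L),
  shd = list(n_in = 700L, n_classes = 20L, tau_s = 1, tau_r = 1,
             theta_d = 64L, bin_ms = 4, n_steps = 250L),
  synthetic = list(n_in = 8L, n_classes = 3L, tau_s = 3, tau_r = 3,
                   theta_d = 16L, bin_ms = 1, n_steps = 120L)
)

experiment_table <- list(
  # name = list(hidden sizes, vad, local, dloss, l2)
  "FF128-SNN" = list(hidden = c(128L, 128L), vad = FALSE, local = FALSE,
                     dloss = FALSE, l2 = FALSE),
  "L128-SNN" = list(hidden = c(128L, 128L), vad = FALSE, local = TRUE,
                    dloss = FALSE, l2 = FALSE),
  "D128-SNN" = list(hidden = c(128L, 128L), vad = TRUE, local = FALSE,
                    dloss = FALSE, l2 = FALSE),
  "DL128-SNN" = list(hidden = c(128L, 128L), vad = TRUE, local = TRUE,
                     dloss = FALSE, l2 = FALSE),
  "DL128-SNN-Dloss" = list(hidden = c(128L, 128L), vad = TRUE, local = TRUE,
                           dloss = TRUE, l2 = FALSE),
  "DL256-SNN-Dloss" = list(hidden = c(128L, 256L), vad = TRUE, local = TRUE,
                           dloss = TRUE, l2 = FALSE),
  "DL128-SNN-Dloss-L2" = list(hidden = c(128L, 128L), vad = TRUE, local = TRUE,
                              dloss = TRUE, l2 = TRUE)
)

# the two ablation baselines are also reachable under their structural names
experiment_aliases <- c(
  "Input-128FC-128FC-Output" = "FF128-SNN",
  "Input-128FC-Local-128FC-Local-Output" = "L128-SNN"
)

#' Resolve a named experiment to its configurations
#'
#' Maps the published architecture names (\code{D128-SNN}, \code{DL128-SNN},
#' \code{DL128-SNN-Dloss}, \code{DL256-SNN-Dloss}, \code{DL128-SNN-Dloss-L2},
#' plus the plain and local-only baselines \code{FF128-SNN} / \code{L128-SNN})
#' to a fully specified network, loss and training configuration for a given
#' dataset. Dataset profiles fix the input width, class count, time constants
#' and delay cap: the silicon-cochlea digits use
#' \eqn{\tau_s=\tau_r=5, \theta_d=128} over 64 channels and 11 classes; SHD
#' uses \eqn{\tau_s=\tau_r=1, \theta_d=64} over 700 channels and 20 classes;
#' \code{synthetic} is the miniature in-package task.
#'
#' @param name experiment name (see above). Unknown names raise an error
#'   listing the options.
#' @param dataset one of \code{"ntidigits"}, \code{"shd"},
#'   \code{"synthetic"}.
#' @param l2_delay coefficient used when the name enables the delay
#'   regularizer.
#' @return List with \code{network} (a [network_spec()]), \code{loss} (a
#'   [loss_config()]), \code{train} (a [train_config()]) and \code{profile}.
#' @export
resolve_experiment <- function(name, dataset = c("ntidigits", "shd", "synthetic"),
                               l2_delay = 1e-3) {
  dataset <- match.arg(dataset)
  if (name %in% names(experiment_aliases)) name <- experiment_aliases[[name]]
  if (!name %in% names(experiment_table))
    stop("unknown experiment '", name, "'; options: ",
         paste(sort(unique(c(names(experiment_table),
                             names(experiment_aliases)))), collapse = ", "),
         call. = FALSE)
  ex <- experiment_table[[name]]
  pr <- dataset_profiles[[dataset]]
  srm <- srm_config(tau_s = pr$tau_s, tau_r = pr$tau_r, alpha_r = 2,
                    theta_u = 10, Ts = 1)
  sizes <- c(pr$n_in, ex$hidden, pr$n_classes)
  layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
    hidden <- i < length(sizes) - 1L
    layer_spec(sizes[i], sizes[i + 1L],
               vad = hidden && ex$vad, local = hidden && ex$local,
               theta_d = pr$theta_d)
  })
  list(
    network = network_spec(layers, pr$n_classes, srm),
    loss = loss_config(use_dloss = ex$dloss,
                       l2_delay = if (ex$l2) l2_delay else 0),
    train = train_config(lr = 0.1, batch_size = 128, epochs = 40,
                         pretrain_epochs = 20),
    profile = pr
  )
}

#' Per-layer histogram of effective axonal delays
#'
#' Counts neurons at each integer delay value \code{0..theta_d} for every
#' VAD layer. A freshly built model has all mass at 0; after training the
#' histogram shows how the layer spreads its temporal alignment.
#'
#' @param model an [build_network()] model.
#' @return Named list of integer count vectors (names \code{layer<k>}, one
#'   per VAD layer; each sums to the layer width).
#' @export
delay_histogram <- function(model) {
  stopifnot(inherits(model, "axodelay_net"))
  out <- list()
  for (li in seq_along(model$layers)) {
    d <- model$layers[[li]]$delay
    if (is.null(d)) next
    counts <- tabulate(d$effective + 1L, nbins = d$theta_d + 1L)
    names(counts) <- 0:d$theta_d
    out[[paste0("layer", li)]] <- counts
  }
  out
}

#' Cumulative spike curves for one labeled sample
#'
#' Returns the running total of input spikes and of the true-class readout
#' neuron's spikes over the horizon — the curves used to visualize how
#' delay-equipped models defer their decision and then commit steeply.
#'
#' @param model an [build_network()] model.
#' @param sample a list with \code{raster} and 0-based \code{label}.
#' @return Data frame with \code{step}, \code{input_cum},
#'   \code{true_neuron_cum}; both curves are monotone non-decreasing.
#' @export
cumulative_spike_curves <- function(model, sample) {
  x <- raster_values(sample$raster)
  out <- network_forward(model, sample$raster)
  s <- raster_values(out$spikes)
  data.frame(
    step = seq_len(nrow(x)),
    input_cum = cumsum(rowSums(x)),
    true_neuron_cum = cumsum(s[, sample$label + 1L])
  )
}

synthetic_variant_spec <- function(variant, cfg, srm, theta_d) {
  vad <- variant %in% c("vad", "vad_local")
  local <- variant == "vad_local"
  n_hidden <- 2L * cfg$n_channels
  network_spec(
    list(layer_spec(cfg$n_channels, n_hidden, vad = vad, local = local,
                    theta_d = theta_d),
         layer_spec(n_hidden, cfg$n_classes)),
    cfg$n_classes, srm)
}

#' Order-coded coincidence task
#'
#' The study conditions of the packaged miniature experiments: three classes
#' over six channels that share one multiset of pairwise lags (a rising ramp,
#' the reversed ramp, and a zigzag of the same values, spaced 3 steps apart)
#' so that no class is separable by lag *magnitudes* alone — only by which
#' channel leads which, exactly the information per-neuron axonal delays can
#' re-align. Each pattern event is a 3-step burst, the short spike train a
#' cochlear channel emits when energy enters its band, which also gives the
#' one-step finite-difference delay gradient a usable basin.
#'
#' @param seed RNG seed of the generated datasets.
#' @return A [synthetic_task_config()].
#' @export
coincidence_task <- function(seed = 1L) {
  ramp <- seq(0L, 15L, by = 3L)
  synthetic_task_config(
    n_classes = 3, n_channels = 6, n_steps = 120, base_rate = 0.02,
    offset_table = rbind(ramp, rev(ramp), c(0L, 9L, 3L, 12L, 6L, 15L)),
    jitter_sd = 0.5, pattern_width = 3, n_repeats = 3,
    n_train = 60, n_test = 30, seed = seed)
}

#' Ablation study on the synthetic coincidence task
#'
#' Trains one-hidden-layer variants (\code{"plain"}: no delays, no local
#' connections; \code{"vad"}: learnable axonal delays; \code{"vad_local"}:
#' delays plus local skip-connections) over several seeds and reports
#' per-seed test accuracies — the miniature analogue of the published
#' ablation grid, asserting direction rather than external-data magnitudes.
#'
#' @param variants subset of \code{c("plain", "vad", "vad_local")}.
#' @param n_seeds independent trials per variant (seeds are
#'   \code{base_seed + 0:(n_seeds-1)}).
#' @param base_seed first seed.
#' @param task a [synthetic_task_config()]; its seed is offset per trial so
#'   every trial sees fresh data.
#' @param epochs,alpha_r,theta_d,target_true,target_false training and model
#'   settings shared by all variants.
#' @param use_dloss enable the suppressed loss for the second half of
#'   training.
#' @return Data frame with \code{variant}, \code{seed}, \code{accuracy}.
#' @export
ablation_experiment <- function(variants = c("plain", "vad", "vad_local"),
                                n_seeds = 5, base_seed = 1L,
                                task = coincidence_task(),
                                epochs = 30, alpha_r = 2, theta_d = 24L,
                                target_true = 12, target_false = 2,
                                use_dloss = FALSE) {
  variants <- match.arg(variants, c("plain", "vad", "vad_local"),
                        several.ok = TRUE)
  srm <- srm_config(tau_s = 2, tau_r = 2, alpha_r = alpha_r, theta_u = 10)
  res <- expand.grid(variant = variants,
                     seed = base_seed + seq_len(n_seeds) - 1L,
                     stringsAsFactors = FALSE)
  res$accuracy <- NA_real_
  for (i in seq_len(nrow(res))) {
    seed <- res$seed[i]
    task_i <- task
    task_i$seed <- task$seed + 1000L * (seed - base_seed)
    data <- generate_synthetic(task_i)
    spec <- synthetic_variant_spec(res$variant[i], task_i, srm, theta_d)
    model <- build_network(spec, seed = seed)
    loss <- loss_config(target_true = target_true,
                        target_false = target_false,
                        use_dloss = use_dloss)
    tr <- train_config(lr = 0.1, batch_size = 10, epochs = epochs,
                       pretrain_epochs = if (use_dloss) epochs %/% 2 else epochs,
                       seed = seed)
    fit <- train_network(model, data$train, tr, loss)
    res$accuracy[i] <- evaluate_network(fit$model, data$test)
  }
  res
}

#' Accuracy under a sweep of refractory scales
#'
#' Re-runs the miniature synthetic experiment for each refractory scale
#' \eqn{\alpha_r}, comparing the delay-only variant ("VAD") with delays plus
#' local skip-connections ("VAD+Local"). Reports per-cell mean and standard
#' deviation over trials — the in-package analogue of the published
#' refractory-robustness analysis (local connections are expected to hold up
#' better at large \eqn{\alpha_r}, where deep resets discard information).
#'
#' @param alpha_values refractory scales to test.
#' @param n_seeds trials per cell.
#' @param base_seed first seed.
#' @param task a [synthetic_task_config()].
#' @param epochs training epochs per run.
#' @return Data frame with one row per (alpha_r, variant):
#'   \code{alpha_r}, \code{variant}, \code{mean_acc}, \code{sd_acc},
#'   \code{n}.
#' @export
refractory_sweep <- function(alpha_values, n_seeds = 5, base_seed = 1L,
                             task = synthetic_task_config(), epochs = 30) {
  rows <- list()
  for (a in alpha_values) {
    res <- ablation_experiment(c("vad", "vad_local"), n_seeds = n_seeds,
                               base_seed = base_seed, task = task,
                               epochs = epochs, alpha_r = a)
    agg <- stats::aggregate(accuracy ~ variant, res,
                            function(x) c(mean = mean(x), sd = stats::sd(x)))
    for (j in seq_len(nrow(agg))) {
      rows[[length(rows) + 1L]] <- data.frame(
        alpha_r = a,
        variant = ifelse(agg$variant[j] == "vad", "VAD", "VAD+Local"),
        mean_acc = agg$accuracy[j, "mean"],
        sd_acc = agg$accuracy[j, "sd"],
        n = n_seeds)
    }
  }
  do.call(rbind, rows)
}

#' Planted-lag delay recovery experiment
#'
#' Two input channels fire at shared random anchor times, channel B lagging
#' channel A by a planted \code{k} steps. A two-unit first layer with frozen
#' identity-like weights mirrors the channels (with the refractory term off
#' it answers each input spike with a short burst, which keeps the
#' coincidence signal graded over several steps of misalignment); its axonal
#' delays are the only trained parameters. The readout neuron's frozen
#' weights are too weak for one channel's burst alone to reach threshold,
#' so its spike count grows with the temporal overlap of the two delayed
#' bursts — the rate target therefore rewards re-aligning the channels,
#' and the loss is minimized when \code{d_A - d_B = k}.
#'
#' Because the delay gradient is a one-step finite difference, its per-sample
#' sign fluctuates far from alignment; the burst coding widens the basin so
#' that batch-averaged descent recovers lags of up to about ten steps.
#'
#' @param k planted lag in steps.
#' @param seed RNG seed for data and training.
#' @param n_steps horizon.
#' @param n_samples training samples.
#' @param n_anchors pattern occurrences per sample.
#' @param epochs training epochs (delays only).
#' @param theta_d delay cap.
#' @return List with \code{d_A}, \code{d_B}, \code{recovered_lag}
#'   (\code{d_A - d_B}), \code{k}, and the trained \code{model}.
#' @export
delay_recovery_experiment <- function(k, seed = 1L, n_steps = 100L,
                                      n_samples = 24L, n_anchors = 3L,
                                      epochs = 80, theta_d = 16L) {
  stopifnot(k >= 0, k < n_steps - 17L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  data <- lapply(seq_len(n_samples), function(i) {
    x <- matrix(0, n_steps, 2L)
    repeat {  # anchors spaced out so same-channel bursts never stack
      anchors <- sort(sample.int(n_steps - k - 16L, n_anchors))
      if (n_anchors == 1L || min(diff(anchors)) >= 18L) break
    }
    x[cbind(anchors, 1L)] <- 1
    x[cbind(anchors + k, 2L)] <- 1
    list(raster = spike_raster(x), label = 0L)
  })
  srm <- srm_config(tau_s = 3, tau_r = 3, alpha_r = 0, theta_u = 10)
  spec <- network_spec(
    list(layer_spec(2L, 2L, vad = TRUE, theta_d = theta_d),
         layer_spec(2L, 1L)),
    n_classes = 1L, srm = srm)
  model <- build_network(spec, seed = seed)
  model$layers[[1L]]$W <- diag(2) * 14
  model$layers[[1L]]$b <- c(0, 0)
  model$layers[[2L]]$W <- matrix(c(1.35, 1.35), 2L, 1L)
  model$layers[[2L]]$b <- 0
  # target above the best attainable count so the pull toward alignment
  # never switches off as the count approaches it
  loss <- loss_config(target_true = 4 * n_anchors + 2, target_false = 0)
  tr <- train_config(lr = 0.1, batch_size = 8, epochs = epochs,
                     pretrain_epochs = 0, seed = seed, update = "delays")
  fit <- train_network(model, data, tr, loss)
  d <- fit$model$layers[[1L]]$delay$effective
  list(d_A = d[1L], d_B = d[2L], recovered_lag = d[1L] - d[2L], k = k,
       model = fit$model)
}
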