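#' Surrogate-gradient configuration
#'
#' The backward pass replaces the derivative of the Heaviside spike function
#' with \eqn{f'_s = \tau_{scale} \exp(-|u - \vartheta| / \tau_\vartheta)}
#' (the SLayer-style exponential proxy), where \eqn{\vartheta} is the firing
#' threshold. Neither parameter is part of the published hyper-parameter
#' table; the defaults (\code{tau_scale = 1}, \code{tau_theta = 1} mV,
#' adopted from the cited surrogate formulation) are implementation choices
#' exposed here. The narrow width also keeps backpropagation through the
#' refractory feedback loop stable: immediately after a spike the membrane
#' sits far below threshold, so a narrow surrogate damps the recurrent
#' backward gain that a wide one would amplify exponentially.
#'
#' @param tau_scale peak amplitude of the surrogate at the threshold.
#' @param tau_theta decay width in mV.
#' @return An object of class \code{surrogate_config}.
#' @export
surrogate_config <- function(tau_scale = 1, tau_theta = 1) {
  if (tau_scale <= 0 || tau_theta <= 0)
    stop("tau_scale and tau_theta must be positive", call. = FALSE)
  structure(list(tau_scale = tau_scale, tau_theta = tau_theta),
            class = "surrogate_config")
}

#' Surrogate derivative of the spike function
#'
#' Evaluates \eqn{\tau_{scale} \exp(-|u - \vartheta| / \tau_\vartheta)}
#' elementwise; equals \code{tau_scale} at the threshold and is symmetric
#' around it. Used only in the backward pass.
#'
#' @param u membrane trace (matrix or vector, mV).
#' @param cfg a [surrogate_config()].
#' @param theta_u the firing threshold \eqn{\vartheta}.
#' @return Object of the same shape as \code{u}.
#' @export
surrogate_grad <- function(u, cfg = surrogate_config(), theta_u = 10) {
  cfg$tau_scale * exp(-abs(u - theta_u) / cfg$tau_theta)
}

# smooth spike function whose derivative is exactly half the surrogate;
# used by the soft forward mode for gradient verification
soft_spike <- function(u, cfg, theta_u) {
  z <- (u - theta_u) / cfg$tau_theta
  a <- cfg$tau_scale * cfg$tau_theta
  ifelse(z >= 0, a * (1 - 0.5 * exp(-z)), a * 0.5 * exp(z))
}

soft_spike_grad <- function(u, cfg, theta_u) {
  0.5 * surrogate_grad(u, cfg, theta_u)
}

# backward pass through one SRM layer.
# ds_ext: dL/ds arriving from outside (later layers / the loss);
# du_ext: direct dL/du (suppressed loss), or NULL.
# refr_grad = "full" unrolls the refractory feedback (spike at t changes u
# at t+k through nu) backward in time before the surrogate is applied; it is
# exact in the smooth regime but the loop gain |nu|*surrogate makes
# hard-threshold training unstable, so "detached" (treat the reset drive as
# a constant, the convention of the SLAYER lineage) is the training default.
srm_backward <- function(cache, ds_ext, du_ext, weights, cfg, surrogate,
                         soft = FALSE, refr_grad = "detached") {
  u <- cache$membrane
  psp <- cache$psp
  Tn <- nrow(u); n_out <- ncol(u)
  sg <- if (soft) soft_spike_grad(u, surrogate, cfg$theta_u)
        else surrogate_grad(u, surrogate, cfg$theta_u)
  du <- matrix(0, Tn, n_out)
  use_refr <- cfg$alpha_r > 0 && identical(refr_grad, "full")
  if (use_refr) {
    nu <- refractory_kernel(cfg)
    K <- length(nu)
    racc <- matrix(0, Tn, n_out)  # dL/ds accumulated through the nu kernel
    for (t in rev(seq_len(Tn))) {
      dut <- (ds_ext[t, ] + racc[t, ]) * sg[t, ]
      if (!is.null(du_ext)) dut <- dut + du_ext[t, ]
      du[t, ] <- dut
      kmax <- min(K - 1L, t - 1L)
      if (kmax >= 1L && any(dut != 0)) {
        idx <- t - seq_len(kmax)
        racc[idx, ] <- racc[idx, ] + outer(nu[1L + seq_len(kmax)], dut)
      }
    }
  } else {
    du <- ds_ext * sg
    if (!is.null(du_ext)) du <- du + du_ext
  }
  list(
    dW = crossprod(psp, du),
    db = colSums(du),
    dx = corr_causal(du %*% t(weights), response_kernel(cfg))
  )
}

# full backward pass; returns per-layer gradients
# ds_out: dL/ds at the readout raster; du_out: direct dL/du at the readout
# membrane (suppressed loss) or NULL.
network_backward <- function(model, caches, ds_out, du_out = NULL,
                             surrogate = surrogate_config(), soft = FALSE,
                             refr_grad = "detached") {
  cfg <- model$cfg
  n_layers <- length(model$layers)
  grads <- vector("list", n_layers)
  upstream <- ds_out
  duext <- du_out
  for (li in rev(seq_len(n_layers))) {
    L <- model$layers[[li]]
    cc <- caches[[li]]
    if (!is.null(L$V)) {
      lb <- srm_backward(list(membrane = cc$lf$membrane, psp = cc$lf$psp),
                         ds_ext = upstream, du_ext = NULL, weights = L$V,
                         cfg = cfg, surrogate = surrogate, soft = soft,
                         refr_grad = refr_grad)
      dV <- lb$dW; dlocal_b <- lb$db
      ds_d <- upstream + lb$dx   # s_out = s_d + s_hat: both paths
    } else {
      dV <- NULL; dlocal_b <- NULL
      ds_d <- upstream
    }
    if (!is.null(L$delay)) {
      ddelay <- delay_gradient(ds_d, cc$s_d, Ts = cfg$Ts)
      ds <- shift_back(ds_d, L$delay$effective)
    } else {
      ddelay <- NULL
      ds <- ds_d
    }
    mb <- srm_backward(list(membrane = cc$fw$membrane, psp = cc$fw$psp),
                       ds_ext = ds, du_ext = duext, weights = L$W,
                       cfg = cfg, surrogate = surrogate, soft = soft,
                       refr_grad = refr_grad)
    grads[[li]] <- list(dW = mb$dW, db = mb$db, dV = dV,
                        dlocal_b = dlocal_b, ddelay = ddelay)
    upstream <- mb$dx
    duext <- NULL  # the suppressed loss touches the readout membrane only
  }
  grads
}

# loss + gradients for one labeled sample
sample_grads <- function(model, x, label, loss_cfg, surrogate,
                         use_dloss = FALSE, soft = FALSE,
                         refr_grad = "detached") {
  fwd <- network_forward(model, x, soft = soft, surrogate = surrogate,
                         keep_cache = TRUE)
  s <- raster_values(fwd$spikes)
  C <- ncol(s)
  targets <- rate_targets(label, C, loss_cfg)
  counts <- colSums(s)
  rl <- sum(0.5 * (targets - counts)^2)
  ds_out <- matrix(rep(counts - targets, each = nrow(s)), nrow(s), C)
  dl <- 0
  du_out <- NULL
  if (use_dloss) {
    mask <- class_mask(label, C)
    dl <- suppressed_loss(fwd$spikes, fwd$membrane, mask, loss_cfg)
    du_out <- suppressed_loss_membrane_grad(fwd$spikes, fwd$membrane, mask,
                                            loss_cfg)
  }
  grads <- network_backward(model, fwd$caches, ds_out, du_out,
                            surrogate = surrogate, soft = soft,
                            refr_grad = refr_grad)
  list(rate_loss = rl, dloss = dl, grads = grads,
       correct = predict_class(fwd$spikes) == label)
}

#' Training configuration
#'
#' @param lr Adam learning rate shared by all parameter groups, including the
#'   delay shadows.
#' @param batch_size samples per optimizer step.
#' @param epochs total training epochs.
#' @param pretrain_epochs epochs trained with the rate loss alone before the
#'   suppressed loss (if enabled in the [loss_config()]) is switched on.
#' @param seed RNG seed controlling shuffling (and anything the caller
#'   derives from it).
#' @param update which parameter groups to update: any subset of
#'   \code{"weights"} (weights, biases, local weights) and \code{"delays"}.
#' @param lr_delay optional separate Adam learning rate for the delay
#'   shadows; \code{NULL} (the default) keeps the single global group.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(lr = 0.1, batch_size = 128, epochs = 40,
                         pretrain_epochs = 20, seed = 1L,
                         update = c("weights", "delays"), lr_delay = NULL) {
  if (lr < 0) stop("lr must be >= 0", call. = FALSE)
  if (!is.null(lr_delay) && lr_delay < 0)
    stop("lr_delay must be >= 0", call. = FALSE)
  if (pretrain_epochs > epochs)
    stop("pretrain_epochs must be <= epochs", call. = FALSE)
  update <- match.arg(update, several.ok = TRUE)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = as.integer(seed), update = update,
                 lr_delay = lr_delay),
            class = "train_config")
}

# Adam state helpers: state is a list parallel to the gradient tensors
adam_init <- function(param) list(m = param * 0, v = param * 0)

adam_update <- function(param, grad, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a network with surrogate-gradient BPTT
#'
#' Runs Adam over mini-batches of labeled spike rasters. Per batch, gradients
#' of the rate loss (plus, after \code{pretrain_epochs} and when enabled, the
#' suppressed-membrane loss, plus the delay regularizer) are averaged over
#' samples and applied to weights, biases, local weights and delay shadows;
#' the integer effective delays are re-projected after every optimizer step.
#' Training is fully reproducible per seed. Diverging losses (NaN/Inf) abort
#' with a diagnostic.
#'
#' @param model an [build_network()] model.
#' @param data list of samples, each a list with \code{raster} and 0-based
#'   \code{label} (as produced by [generate_synthetic()]).
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param surrogate a [surrogate_config()].
#' @param test_data optional held-out samples evaluated each epoch.
#' @param verbose print per-epoch progress.
#' @return A list with the trained \code{model} and a per-epoch
#'   \code{history} data frame (epoch, rate_loss, dloss, l2, train_acc,
#'   test_acc).
#' @export
train_network <- function(model, data, cfg = train_config(),
                          loss_cfg = loss_config(),
                          surrogate = surrogate_config(),
                          test_data = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "axodelay_net"), length(data) >= 1L)
  set.seed(cfg$seed)
  n <- length(data)
  opt <- list()   # adam state per parameter tensor, keyed by layer/name
  step <- 0L
  upd_w <- "weights" %in% cfg$update
  upd_d <- "delays" %in% cfg$update
  hist <- data.frame(epoch = integer(), rate_loss = double(),
                     dloss = double(), l2 = double(),
                     train_acc = double(), test_acc = double())
  for (epoch in seq_len(cfg$epochs)) {
    use_dloss <- loss_cfg$use_dloss && epoch > cfg$pretrain_epochs
    order <- sample.int(n)
    ep_rl <- 0; ep_dl <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1L, n)]
      bsz <- length(idx)
      acc <- NULL
      for (j in idx) {
        sg <- sample_grads(model, data[[j]]$raster, data[[j]]$label,
                           loss_cfg, surrogate, use_dloss = use_dloss)
        ep_rl <- ep_rl + sg$rate_loss
        ep_dl <- ep_dl + sg$dloss
        ep_correct <- ep_correct + sg$correct
        acc <- if (is.null(acc)) sg$grads else accumulate_grads(acc, sg$grads)
      }
      if (!is.finite(ep_rl + ep_dl))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      step <- step + 1L
      model <- apply_batch_update(model, acc, bsz, cfg$lr, step, opt,
                                  loss_cfg, upd_w, upd_d,
                                  lr_delay = if (is.null(cfg$lr_delay)) cfg$lr
                                             else cfg$lr_delay)
      opt <- attr(model, "opt"); attr(model, "opt") <- NULL
    }
    l2 <- delay_l2(model, loss_cfg$l2_delay, loss_cfg$l2_mode)
    test_acc <- if (!is.null(test_data)) evaluate_network(model, test_data)
                else NA_real_
    hist <- rbind(hist, data.frame(
      epoch = epoch, rate_loss = ep_rl / n, dloss = ep_dl / n, l2 = l2,
      train_acc = ep_correct / n, test_acc = test_acc))
    if (verbose)
      message(sprintf("epoch %3d  rate %.3f  dloss %.3f  acc %.3f%s",
                      epoch, ep_rl / n, ep_dl / n, ep_correct / n,
                      if (is.na(test_acc)) "" else sprintf("  test %.3f", test_acc)))
  }
  list(model = model, history = hist)
}

accumulate_grads <- function(a, b) {
  for (li in seq_along(a)) {
    for (nm in names(b[[li]])) {
      if (!is.null(b[[li]][[nm]]))
        a[[li]][[nm]] <- a[[li]][[nm]] + b[[li]][[nm]]
    }
  }
  a
}

apply_batch_update <- function(model, acc, bsz, lr, step, opt, loss_cfg,
                               upd_w, upd_d, lr_delay = lr) {
  for (li in seq_along(model$layers)) {
    L <- model$layers[[li]]
    g <- acc[[li]]
    if (upd_w) {
      for (nm in c("W", "b", "V", "local_b")) {
        gn <- switch(nm, W = g$dW, b = g$db, V = g$dV, local_b = g$dlocal_b)
        if (is.null(gn) || is.null(L[[nm]])) next
        key <- paste0(li, ".", nm)
        if (is.null(opt[[key]])) opt[[key]] <- adam_init(L[[nm]])
        res <- adam_update(L[[nm]], gn / bsz, opt[[key]], lr, step)
        L[[nm]] <- res$param
        opt[[key]] <- res$state
      }
    }
    if (upd_d && !is.null(L$delay) && !is.null(g$ddelay)) {
      gd <- g$ddelay / bsz
      if (loss_cfg$l2_delay > 0) {
        gd <- gd + if (loss_cfg$l2_mode == "squared")
          2 * loss_cfg$l2_delay * L$delay$shadow
        else loss_cfg$l2_delay
      }
      key <- paste0(li, ".delay")
      if (is.null(opt[[key]])) opt[[key]] <- adam_init(L$delay$shadow)
      res <- adam_update(L$delay$shadow, gd, opt[[key]], lr_delay, step)
      L$delay$shadow <- res$param
      opt[[key]] <- res$state
      L$delay <- project_delays(L$delay)
    }
    model$layers[[li]] <- L
  }
  attr(model, "opt") <- opt
  model
}

#' Classification accuracy on a labeled dataset
#'
#' Fraction of samples whose [predict_class()] (argmax of readout spike
#' counts) equals the stored label.
#'
#' @param model an [build_network()] model.
#' @param data list of samples with \code{raster} and \code{label}.
#' @return Accuracy in \eqn{[0, 1]}.
#' @export
evaluate_network <- function(model, data) {
  if (length(data) < 1L) stop("empty dataset", call. = FALSE)
  correct <- vapply(data, function(smp) {
    out <- network_forward(model, smp$raster)
    predict_class(out$spikes) == smp$label
  }, logical(1))
  mean(correct)
}
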