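#' Loss configuration
#'
#' Bundles the spike-count targets of the rate loss, the suppressed-membrane
#' penalty settings, and the delay regularizer.
#'
#' @param target_true desired output spike count of the correct-class neuron
#'   over the observation window.
#' @param target_false desired count for every incorrect-class neuron; must
#'   be strictly smaller than \code{target_true}.
#' @param lambda_u suppression factor in \eqn{(0, 1]}; the suppression
#'   threshold is \code{u_theta = lambda_u * theta_u}.
#' @param theta_u firing threshold in mV (used to derive \code{u_theta}).
#' @param l2_delay non-negative coefficient of the delay regularizer.
#' @param l2_mode \code{"squared"} penalizes \code{coeff * sum(shadow^2)};
#'   \code{"sum"} penalizes \code{coeff * sum(shadow)} (delays are
#'   non-negative after projection). Both readings of an "L2 regularizer on
#'   the summed delays" are exposed; \code{"squared"} is the default.
#' @param use_dloss enable the suppressed-membrane loss (typically switched
#'   on after a rate-loss-only pretraining phase).
#' @return An object of class \code{loss_config}.
#' @export
loss_config <- function(target_true = 30, target_false = 5, lambda_u = 0.995,
                        theta_u = 10, l2_delay = 0,
                        l2_mode = c("squared", "sum"), use_dloss = FALSE) {
  l2_mode <- match.arg(l2_mode)
  if (!(target_true > target_false) || target_false < 0)
    stop("require target_true > target_false >= 0", call. = FALSE)
  if (!(lambda_u > 0 && lambda_u <= 1))
    stop("lambda_u must be in (0, 1]", call. = FALSE)
  if (l2_delay < 0) stop("l2_delay must be >= 0", call. = FALSE)
  structure(
    list(target_true = target_true, target_false = target_false,
         lambda_u = lambda_u, theta_u = theta_u,
         u_theta = lambda_u * theta_u,
         l2_delay = l2_delay, l2_mode = l2_mode, use_dloss = isTRUE(use_dloss)),
    class = "loss_config"
  )
}

#' Class mask for the suppressed loss
#'
#' Zero at the true class, one at every false class, so that the
#' suppressed-membrane penalty acts on wrong-class neurons only.
#'
#' @param label 0-based class index (the convention of the event-data files).
#' @param C number of classes.
#' @return Binary numeric vector of length \code{C} summing to \code{C - 1}.
#' @export
class_mask <- function(label, C) {
  label <- as.integer(label); C <- as.integer(C)
  if (C < 1L) stop("C must be >= 1", call. = FALSE)
  if (is.na(label) || label < 0L || label >= C)
    stop(sprintf("label %d out of range [0, %d)", label, C), call. = FALSE)
  m <- rep(1, C)
  m[label + 1L] <- 0
  m
}

# per-neuron target spike counts for a given label
rate_targets <- function(label, C, cfg) {
  tg <- rep(cfg$target_false, C)
  tg[label + 1L] <- cfg$target_true
  tg
}

#' Spike-rate loss
#'
#' Compares the integrated output spike count of every readout neuron with
#' its class-dependent target: \code{target_true} for the labeled class,
#' \code{target_false} for the others;
#' \eqn{L = \sum_i \frac12 (target_i - count_i)^2}.
#'
#' @param output readout spike raster, \code{n_steps x C}.
#' @param label 0-based class index.
#' @param cfg a [loss_config()].
#' @return Non-negative scalar.
#' @export
rate_loss <- function(output, label, cfg = loss_config()) {
  x <- raster_values(output)
  C <- ncol(x)
  if (label < 0 || label >= C)
    stop(sprintf("label %d out of range for %d output neurons", label, C),
         call. = FALSE)
  counts <- colSums(x)
  sum(0.5 * (rate_targets(label, C, cfg) - counts)^2)
}

#' Suppressed-membrane loss
#'
#' Penalizes the pre-spike membrane of wrong-class readout neurons at the
#' instants they fire:
#' \eqn{L_{Mem} = \sum_{t,i} \frac12 (s[t,i] \cdot mask_i \cdot
#' (u[t-1,i] - u_\theta))^2} with \eqn{u_\theta = \lambda_u \theta_u} and
#' \eqn{u[0] := 0}. True-class neurons and silent steps contribute nothing,
#' so the loss acts as a soft winner-takes-all regularizer.
#'
#' @param output readout spike raster.
#' @param membrane readout membrane trace of the same shape (mV).
#' @param mask a [class_mask()].
#' @param cfg a [loss_config()] providing \code{u_theta}.
#' @return Non-negative scalar.
#' @export
suppressed_loss <- function(output, membrane, mask, cfg = loss_config()) {
  s <- raster_values(output)
  u <- as.matrix(membrane)
  if (!all(dim(s) == dim(u)))
    stop("raster and membrane shapes disagree", call. = FALSE)
  if (length(mask) != ncol(s))
    stop("mask length does not match the number of output neurons", call. = FALSE)
  u_pre <- rbind(0, u[-nrow(u), , drop = FALSE])  # u(t - Ts), u before t=0 is 0
  z <- sweep(s * (u_pre - cfg$u_theta), 2L, mask, "*")
  sum(0.5 * z^2)
}

# gradient of the suppressed loss w.r.t. the membrane trace (the membrane
# path of the product only; s and mask are binary so squares collapse)
suppressed_loss_membrane_grad <- function(output, membrane, mask, cfg) {
  s <- raster_values(output)
  u <- as.matrix(membrane)
  Tn <- nrow(u)
  u_pre <- rbind(0, u[-Tn, , drop = FALSE])
  g_pre <- sweep(s * (u_pre - cfg$u_theta), 2L, mask, "*")
  # g_pre[t, ] is dL/du[t-1, ]; shift up one step, nothing flows to u[Tn, ]
  rbind(g_pre[-1L, , drop = FALSE], 0)
}

#' Delay regularizer
#'
#' Penalty on the continuous delay shadows of every VAD layer (the shadow is
#' the differentiable optimizer state; projection to integers still runs
#' after each update). Zero when all delays are zero or the coefficient is 0.
#'
#' @param model an [build_network()] model.
#' @param coeff non-negative coefficient.
#' @param mode \code{"squared"} (\code{coeff * sum(shadow^2)}) or
#'   \code{"sum"} (\code{coeff * sum(shadow)}).
#' @return Non-negative scalar.
#' @export
delay_l2 <- function(model, coeff, mode = c("squared", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "axodelay_net"))
  if (coeff < 0) stop("coeff must be >= 0", call. = FALSE)
  if (coeff == 0) return(0)
  total <- 0
  for (L in model$layers) {
    if (!is.null(L$delay)) {
      sh <- L$delay$shadow
      total <- total + if (mode == "squared") sum(sh^2) else sum(sh)
    }
  }
  coeff * total
}

#' Predict the class of a readout raster
#'
#' Argmax of the per-neuron total spike count over the observation window;
#' ties (including the all-silent raster) break to the lowest class index.
#'
#' @param output readout spike raster.
#' @return 0-based class index.
#' @export
predict_class <- function(output) {
  counts <- colSums(raster_values(output))
  if (length(counts) < 1L) stop("empty raster", call. = FALSE)
  as.integer(which.max(counts)) - 1L
}
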