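#' Per-neuron axonal delay vector
#'
#' Holds the learnable axonal delays of one layer. The optimizer works on the
#' continuous \code{shadow} values (in ms); the forward pass uses the
#' \code{effective} integer delays (in steps) obtained by projecting the
#' shadow after every update: clip to \code{[0, theta_d]} and round down
#' (or to nearest, see \code{rounding}). Delays initialize at zero.
#'
#' @param n_units number of neurons in the layer.
#' @param theta_d maximum delay in steps (upper clip).
#' @param shadow initial continuous delays in ms (recycled to
#'   \code{n_units}); default 0.
#' @param Ts simulation step in ms.
#' @param rounding \code{"floor"} (delays are rounded down after each
#'   backpropagation; the default) or \code{"nearest"}.
#' @return An object of class \code{delay_vector} with fields \code{shadow},
#'   \code{effective}, \code{theta_d}, \code{Ts}, \code{rounding}.
#' @export
delay_vector <- function(n_units, theta_d, shadow = 0, Ts = 1,
                         rounding = c("floor", "nearest")) {
  rounding <- match.arg(rounding)
  n_units <- as.integer(n_units)
  theta_d <- as.integer(theta_d)
  if (n_units < 1L) stop("n_units must be >= 1", call. = FALSE)
  if (theta_d < 0L) stop("theta_d must be >= 0", call. = FALSE)
  shadow <- rep_len(as.numeric(shadow), n_units)
  if (anyNA(shadow) || any(!is.finite(shadow)))
    stop("shadow delays must be finite", call. = FALSE)
  d <- structure(
    list(shadow = shadow, effective = integer(n_units), theta_d = theta_d,
         Ts = as.numeric(Ts), rounding = rounding),
    class = "delay_vector"
  )
  project_delays(d)
}

#' @export
print.delay_vector <- function(x, ...) {
  cat(sprintf("<delay_vector> %d units, theta_d=%d steps, effective in [%d, %d]\n",
              length(x$effective), x$theta_d,
              min(x$effective), max(x$effective)))
  invisible(x)
}

#' Project continuous delays onto the admissible integer range
#'
#' Applies \code{effective = min(max(0, round_down(shadow / Ts)), theta_d)}
#' to every unit; the continuous shadow itself is left untouched so the
#' optimizer keeps full-precision state. Run after every optimizer step.
#'
#' @param delays a [delay_vector()].
#' @return The delay vector with its \code{effective} field refreshed.
#' @export
project_delays <- function(delays) {
  stopifnot(inherits(delays, "delay_vector"))
  steps <- delays$shadow / delays$Ts
  r <- if (delays$rounding == "floor") floor(steps) else round(steps)
  delays$effective <- as.integer(pmin(pmax(0, r), delays$theta_d))
  delays
}

# shift columns of a plain matrix down by integer delays, dropping spikes
# pushed past the horizon
shift_forward <- function(x, effective) {
  Tn <- nrow(x)
  out <- matrix(0, Tn, ncol(x))
  for (i in seq_len(ncol(x))) {
    di <- effective[i]
    if (di == 0L) {
      out[, i] <- x[, i]
    } else if (di < Tn) {
      out[(di + 1L):Tn, i] <- x[seq_len(Tn - di), i]
    }
  }
  out
}

# adjoint of shift_forward: pull upstream gradients back to pre-delay times
shift_back <- function(x, effective) {
  Tn <- nrow(x)
  out <- matrix(0, Tn, ncol(x))
  for (i in seq_len(ncol(x))) {
    di <- effective[i]
    if (di == 0L) {
      out[, i] <- x[, i]
    } else if (di < Tn) {
      out[seq_len(Tn - di), i] <- x[(di + 1L):Tn, i]
    }
  }
  out
}

#' Apply axonal delays to a spike raster
#'
#' Every spike of unit \code{i} at step \code{m} moves to step
#' \code{m + effective[i]}. Spikes shifted beyond the fixed observation
#' horizon are dropped (the raster is never extended), so the total spike
#' count can only stay equal or decrease. No spikes are created.
#'
#' @param spikes a [spike_raster()] or matrix.
#' @param delays a [delay_vector()] whose length matches the raster width.
#' @return A raster of the same shape and type as the input.
#' @export
apply_delay <- function(spikes, delays) {
  stopifnot(inherits(delays, "delay_vector"))
  x <- raster_values(spikes)
  if (ncol(x) != length(delays$effective))
    stop("delay vector length does not match raster width", call. = FALSE)
  if (any(delays$effective < 0L))
    stop("negative effective delay", call. = FALSE)
  out <- shift_forward(x, delays$effective)
  if (inherits(spikes, "spike_raster"))
    spike_raster(out, Ts = raster_Ts(spikes)) else out
}

#' Finite-difference gradient of the loss with respect to axonal delays
#'
#' Estimates \eqn{\partial L / \partial d_i} for each unit of a delayed spike
#' train by the backward finite difference of the train: since
#' \eqn{s_d(t) = s(t - d)}, \eqn{\partial s_d[m] / \partial d \approx
#' -(s_d[m] - s_d[m-1]) / T_s} (with \eqn{s_d[-1] = 0}), so
#' \deqn{grad_i = \sum_m (s_d[m-1, i] - s_d[m, i]) \cdot upstream[m, i]}
#' where \code{upstream} is \eqn{\partial L / \partial s_d} accumulated over
#' all later time steps by backpropagation through time (the \code{Ts}
#' factors of the time integral and of the difference quotient cancel).
#' For a constant upstream the differences telescope to the final-step value,
#' so a train with no spike at the last step gets zero gradient.
#'
#' @param upstream real matrix \code{n_steps x n_units}:
#'   \eqn{\partial L / \partial s_d}.
#' @param delayed_spikes the delayed raster \eqn{s_d} the upstream refers to.
#' @param Ts simulation step (kept for the signature; it cancels).
#' @return Numeric vector of per-unit delay gradients.
#' @export
delay_gradient <- function(upstream, delayed_spikes, Ts = 1) {
  x <- raster_values(delayed_spikes)
  upstream <- as.matrix(upstream)
  if (!all(dim(upstream) == dim(x)))
    stop("upstream and delayed raster shapes disagree", call. = FALSE)
  lagged <- rbind(0, x[-nrow(x), , drop = FALSE])  # s_d[m-1], s_d[-1] = 0
  colSums((lagged - x) * upstream)
}
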