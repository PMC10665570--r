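#' SRM neuron configuration
#'
#' Parameters of the discrete-time Spike Response Model (SRM). A neuron's
#' membrane potential is the weighted sum of input spike trains convolved with
#' the response kernel \eqn{\epsilon(t) = (t/\tau_s) \exp(1 - t/\tau_s)}, plus
#' the neuron's own output spikes convolved with the refractory kernel
#' \eqn{\nu(t) = -\alpha_r \theta_u (t/\tau_r) \exp(1 - t/\tau_r)}. A spike is
#' emitted whenever the membrane reaches the threshold \code{theta_u}
#' (ties fire: the Heaviside is evaluated as \code{u >= theta_u}).
#'
#' @param tau_s response-kernel time constant, in units of \code{Ts}. Must be
#'   positive. The kernel peaks at \code{t = tau_s} with value 1.
#' @param tau_r refractory time constant, in units of \code{Ts}.
#' @param alpha_r dimensionless refractory scale; 0 disables the reset term,
#'   large values deepen it (the kernel minimum is \code{-alpha_r * theta_u}).
#' @param theta_u firing threshold in mV.
#' @param Ts simulation step in ms.
#' @param kernel_window truncation length of the discretized kernels, in
#'   steps. Defaults to \code{8 * max(tau_s, tau_r) / Ts}, at which the
#'   remaining tail is below 1e-3 of the kernel peak.
#' @return An object of class \code{srm_config}.
#' @export
srm_config <- function(tau_s = 5, tau_r = 5, alpha_r = 2, theta_u = 10,
                       Ts = 1, kernel_window = NULL) {
  if (!is.numeric(tau_s) || length(tau_s) != 1L || !is.finite(tau_s) || tau_s <= 0)
    stop("tau_s must be a single positive number", call. = FALSE)
  if (!is.numeric(tau_r) || length(tau_r) != 1L || !is.finite(tau_r) || tau_r <= 0)
    stop("tau_r must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha_r) || length(alpha_r) != 1L || !is.finite(alpha_r) || alpha_r < 0)
    stop("alpha_r must be a single non-negative number", call. = FALSE)
  if (!is.numeric(theta_u) || length(theta_u) != 1L || !is.finite(theta_u) || theta_u <= 0)
    stop("theta_u must be a single positive number", call. = FALSE)
  if (!is.numeric(Ts) || length(Ts) != 1L || !is.finite(Ts) || Ts <= 0)
    stop("Ts must be a single positive number", call. = FALSE)
  if (is.null(kernel_window))
    kernel_window <- as.integer(ceiling(8 * max(tau_s, tau_r) / Ts))
  kernel_window <- as.integer(kernel_window)
  if (is.na(kernel_window) || kernel_window < 1L)
    stop("kernel_window must be >= 1", call. = FALSE)
  structure(
    list(tau_s = as.numeric(tau_s), tau_r = as.numeric(tau_r),
         alpha_r = as.numeric(alpha_r), theta_u = as.numeric(theta_u),
         Ts = as.numeric(Ts), kernel_window = kernel_window),
    class = "srm_config"
  )
}

#' @export
print.srm_config <- function(x, ...) {
  cat(sprintf(
    "<srm_config> tau_s=%g tau_r=%g alpha_r=%g theta_u=%g mV Ts=%g ms window=%d steps\n",
    x$tau_s, x$tau_r, x$alpha_r, x$theta_u, x$Ts, x$kernel_window))
  invisible(x)
}

is_srm_config <- function(x) inherits(x, "srm_config")

#' Spike raster
#'
#' A dense time-by-unit spike train at a fixed simulation step. Entries are
#' non-negative integer spike counts per step; rasters produced by
#' [srm_forward()] are strictly binary, while the combined train emitted by a
#' local skip-connection ([local_skip_forward()]) may contain a 2 where the
#' delayed and the locally generated spike coincide.
#'
#' @param values numeric matrix, rows = time steps, columns = units.
#' @param Ts step size in ms.
#' @return A matrix of class \code{spike_raster} with a \code{Ts} attribute.
#' @export
spike_raster <- function(values, Ts = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop("spike raster values must be numeric and non-missing", call. = FALSE)
  if (any(values < 0) || any(values != round(values)))
    stop("spike raster entries must be non-negative integers", call. = FALSE)
  structure(values, Ts = Ts, class = c("spike_raster", class(values)))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d steps x %d units, Ts=%g ms, %d spikes\n",
              nrow(x), ncol(x), attr(x, "Ts"), sum(x)))
  invisible(x)
}

# strip class/attributes down to a plain numeric matrix
raster_values <- function(x) {
  if (inherits(x, "spike_raster")) {
    attr(x, "Ts") <- NULL
    class(x) <- "matrix"
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

raster_Ts <- function(x, default = 1) {
  ts <- attr(x, "Ts")
  if (is.null(ts)) default else ts
}

#' Discretized response kernel
#'
#' Samples \eqn{\epsilon(t) = (t/\tau_s)\exp(1 - t/\tau_s)\Theta(t)} at
#' \code{t = k * Ts} for \code{k = 0, ..., kernel_window - 1}. The first entry
#' is 0 (the kernel is causal and vanishes at the spike instant) and the peak
#' value 1 is attained at \code{t = tau_s}.
#'
#' @param cfg an [srm_config()].
#' @return Numeric vector of length \code{cfg$kernel_window}.
#' @export
response_kernel <- function(cfg) {
  stopifnot(is_srm_config(cfg))
  t <- (seq_len(cfg$kernel_window) - 1) * cfg$Ts
  (t / cfg$tau_s) * exp(1 - t / cfg$tau_s)
}

#' Discretized refractory kernel
#'
#' Samples \eqn{\nu(t) = -\alpha_r \theta_u (t/\tau_r)\exp(1 - t/\tau_r)\Theta(t)}
#' at \code{t = k * Ts}. All entries are non-positive; the minimum
#' \code{-alpha_r * theta_u} is attained at \code{t = tau_r}.
#'
#' @param cfg an [srm_config()].
#' @return Numeric vector of length \code{cfg$kernel_window}.
#' @export
refractory_kernel <- function(cfg) {
  stopifnot(is_srm_config(cfg))
  t <- (seq_len(cfg$kernel_window) - 1) * cfg$Ts
  -cfg$alpha_r * cfg$theta_u * (t / cfg$tau_r) * exp(1 - t / cfg$tau_r)
}

# causal convolution: y[t, ] = sum_k kern[k + 1] * x[t - k, ]
conv_causal <- function(x, kern) {
  Tn <- nrow(x)
  y <- matrix(0, Tn, ncol(x))
  K <- min(length(kern), Tn)
  for (k in seq_len(K)) {
    if (kern[k] != 0)
      y[k:Tn, ] <- y[k:Tn, ] + kern[k] * x[seq_len(Tn - k + 1L), , drop = FALSE]
  }
  y
}

# adjoint of conv_causal: y[t, ] = sum_k kern[k + 1] * x[t + k, ]
corr_causal <- function(x, kern) {
  Tn <- nrow(x)
  y <- matrix(0, Tn, ncol(x))
  K <- min(length(kern), Tn)
  for (k in seq_len(K)) {
    if (kern[k] != 0)
      y[seq_len(Tn - k + 1L), ] <- y[seq_len(Tn - k + 1L), ] +
        kern[k] * x[k:Tn, , drop = FALSE]
  }
  y
}

#' Run one SRM layer forward
#'
#' Time-causal simulation of a fully-connected SRM layer. At every step the
#' membrane is the weighted \eqn{\epsilon}-filtered input drive plus a bias
#' plus the \eqn{\nu}-filtered history of the unit's own already-emitted
#' spikes (self-reset only); an output spike is emitted iff the membrane
#' reaches \code{cfg$theta_u} at that step. Because the discretized kernels
#' vanish at lag 0, a spike affects the membrane only from the next step on.
#'
#' @param input a [spike_raster()] or plain matrix, \code{n_steps x n_in}.
#'   Entries may exceed 1 (coincident spikes from a local skip-connection add
#'   linearly through the \eqn{\epsilon} convolution).
#' @param weights numeric matrix \code{n_in x n_out}; must be finite.
#' @param bias numeric vector of length \code{n_out}.
#' @param cfg an [srm_config()].
#' @param soft if \code{TRUE}, replace the hard threshold by the smooth spike
#'   function whose derivative is half the surrogate (see
#'   [surrogate_grad()]); used for gradient verification, not for inference.
#' @param surrogate a [surrogate_config()], only consulted when
#'   \code{soft = TRUE}.
#' @return A list with \code{membrane} (\code{n_steps x n_out} matrix, mV),
#'   \code{spikes} (a [spike_raster()] in hard mode; real matrix in soft
#'   mode), and \code{psp} (the \eqn{\epsilon}-filtered input, used by the
#'   backward pass).
#' @export
srm_forward <- function(input, weights, bias = NULL, cfg = srm_config(),
                        soft = FALSE, surrogate = surrogate_config()) {
  x <- raster_values(input)
  weights <- as.matrix(weights)
  if (ncol(x) != nrow(weights))
    stop(sprintf("shape mismatch: raster has %d units but weights expect %d inputs",
                 ncol(x), nrow(weights)), call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("weights contain NaN/Inf", call. = FALSE)
  n_out <- ncol(weights)
  if (is.null(bias)) bias <- numeric(n_out)
  if (length(bias) != n_out)
    stop("bias length does not match the number of output units", call. = FALSE)

  eps <- response_kernel(cfg)
  nu <- refractory_kernel(cfg)
  psp <- conv_causal(x, eps)
  drive <- sweep(psp %*% weights, 2L, bias, "+")

  Tn <- nrow(x)
  u <- matrix(0, Tn, n_out)
  s <- matrix(0, Tn, n_out)
  refr <- matrix(0, Tn, n_out)
  K <- length(nu)
  use_refr <- cfg$alpha_r > 0
  for (t in seq_len(Tn)) {
    u[t, ] <- drive[t, ] + refr[t, ]
    st <- if (soft) soft_spike(u[t, ], surrogate, cfg$theta_u)
          else as.numeric(u[t, ] >= cfg$theta_u)
    s[t, ] <- st
    if (use_refr && t < Tn && any(st != 0)) {
      kmax <- min(K - 1L, Tn - t)
      if (kmax >= 1L) {
        idx <- t + seq_len(kmax)
        refr[idx, ] <- refr[idx, ] + outer(nu[1L + seq_len(kmax)], st)
      }
    }
  }
  spikes <- if (soft) s else spike_raster(s, Ts = cfg$Ts)
  list(membrane = u, spikes = spikes, psp = psp)
}
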