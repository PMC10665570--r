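#' Specification of one fully-connected SRM layer
#'
#' @param n_in number of input units.
#' @param n_out number of neurons in the layer.
#' @param vad if \code{TRUE}, a per-neuron learnable axonal delay (VAD) is
#'   attached to the layer output (adds \code{n_out} parameters).
#' @param local if \code{TRUE}, a local skip-connection (a square same-layer
#'   synaptic map re-processing the delayed output spikes) is attached
#'   (adds \code{n_out^2 + n_out} parameters).
#' @param theta_d maximum delay in steps when \code{vad} is set.
#' @return An object of class \code{layer_spec}.
#' @export
layer_spec <- function(n_in, n_out, vad = FALSE, local = FALSE, theta_d = 64L) {
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  if (n_in < 1L || n_out < 1L) stop("layer sizes must be >= 1", call. = FALSE)
  structure(list(n_in = n_in, n_out = n_out, vad = isTRUE(vad),
                 local = isTRUE(local), theta_d = as.integer(theta_d)),
            class = "layer_spec")
}

#' Network specification
#'
#' Ordered stack of [layer_spec()]s ending in the readout layer. Consecutive
#' layer sizes must chain, the last layer's width must equal
#' \code{n_classes}, and the readout layer carries neither a delay module nor
#' a local skip-connection.
#'
#' @param layers list of [layer_spec()].
#' @param n_classes number of output classes.
#' @param srm the shared [srm_config()].
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(layers, n_classes, srm = srm_config()) {
  stopifnot(is.list(layers), length(layers) >= 1L, is_srm_config(srm))
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "layer_spec"))
      stop("layers must be layer_spec objects", call. = FALSE)
    if (i > 1L && layers[[i]]$n_in != layers[[i - 1L]]$n_out)
      stop(sprintf("layer %d expects %d inputs but layer %d emits %d units",
                   i, layers[[i]]$n_in, i - 1L, layers[[i - 1L]]$n_out),
           call. = FALSE)
  }
  last <- layers[[length(layers)]]
  if (last$n_out != n_classes)
    stop("final layer width must equal n_classes", call. = FALSE)
  if (last$vad || last$local)
    stop("the readout layer carries no VAD and no local skip-connection",
         call. = FALSE)
  structure(list(layers = layers, n_classes = as.integer(n_classes), srm = srm),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  parts <- vapply(x$layers, function(l) {
    paste0(l$n_out, "FC",
           if (l$vad) "-VAD" else "",
           if (l$local) "-Local" else "")
  }, character(1))
  cat(sprintf("<network_spec> Input(%d)-%s | %d classes | %s parameters\n",
              x$layers[[1L]]$n_in, paste(parts, collapse = "-"),
              x$n_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a network
#'
#' Every fully-connected layer contributes \code{n_in * n_out} weights plus
#' \code{n_out} biases; a VAD module adds one delay per neuron
#' (\code{n_out}); a local skip-connection adds a square weight matrix plus
#' its biases (\code{n_out^2 + n_out}).
#'
#' @param spec a [network_spec()] or a model built by [build_network()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  if (inherits(spec, "axodelay_net")) spec <- spec$spec
  stopifnot(inherits(spec, "network_spec"))
  total <- 0
  for (l in spec$layers) {
    total <- total + l$n_in * l$n_out + l$n_out
    if (l$vad) total <- total + l$n_out
    if (l$local) total <- total + l$n_out^2 + l$n_out
  }
  as.integer(total)
}

#' Build a network with seed-controlled initialization
#'
#' Weights are drawn from a scaled uniform fan-in distribution
#' \code{U(-a, a)} with \code{a = init_gain * theta_u / sqrt(n_in)}
#' (\code{init_gain = 3} by default, chosen so that sparse spiking input
#' drives initial membranes into the threshold's neighbourhood); biases start
#' at zero, local weights use the same scheme with fan-in \code{n_out}, and
#' all axonal delays start at zero. The same seed always yields identical
#' parameters.
#'
#' @param spec a [network_spec()].
#' @param seed integer RNG seed.
#' @param init_gain scale of the uniform weight initialization.
#' @param rounding delay rounding convention, see [delay_vector()].
#' @return An object of class \code{axodelay_net}: a list with the spec and a
#'   per-layer parameter list (\code{W}, \code{b}, optional \code{delay},
#'   \code{V}, \code{local_b}).
#' @export
build_network <- function(spec, seed = 1L, init_gain = 3, rounding = "floor") {
  stopifnot(inherits(spec, "network_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cfg <- spec$srm
  layers <- lapply(spec$layers, function(l) {
    a <- init_gain * cfg$theta_u / sqrt(l$n_in)
    layer <- list(
      W = matrix(stats::runif(l$n_in * l$n_out, -a, a), l$n_in, l$n_out),
      b = numeric(l$n_out)
    )
    if (l$vad)
      layer$delay <- delay_vector(l$n_out, theta_d = l$theta_d, Ts = cfg$Ts,
                                  rounding = rounding)
    if (l$local) {
      al <- init_gain * cfg$theta_u / sqrt(l$n_out)
      layer$V <- matrix(stats::runif(l$n_out * l$n_out, -al, al),
                        l$n_out, l$n_out)
      layer$local_b <- numeric(l$n_out)
    }
    layer
  })
  structure(list(spec = spec, cfg = cfg, layers = layers, seed = as.integer(seed)),
            class = "axodelay_net")
}

#' @export
print.axodelay_net <- function(x, ...) {
  print(x$spec)
  invisible(x)
}

#' Local skip-connection forward pass
#'
#' Runs a second SRM pass with the square local weight matrix \code{V} over
#' the delayed spike train \eqn{s_d} to generate compensation spikes
#' \eqn{\hat{s}}, and returns the combined train \eqn{s_d + \hat{s}} that is
#' fed to the next layer's shared weights. Where a delayed spike and a local
#' spike coincide the combined entry is 2: the \eqn{\epsilon} convolution is
#' linear, so this simply counts two coincident spikes. Local spikes are not
#' re-delayed; the local neuron keeps its own refractory state.
#'
#' @param s_d delayed spike raster of the layer, \code{n_steps x n}.
#' @param V square local weight matrix \code{n x n}.
#' @param local_bias bias of the local pass (length \code{n}).
#' @param cfg an [srm_config()].
#' @return A [spike_raster()] with the combined (possibly non-binary) train.
#' @export
local_skip_forward <- function(s_d, V, local_bias = NULL, cfg = srm_config()) {
  V <- as.matrix(V)
  if (nrow(V) != ncol(V))
    stop("local weight matrix must be square", call. = FALSE)
  fw <- srm_forward(s_d, V, local_bias, cfg)
  out <- raster_values(s_d) + raster_values(fw$spikes)
  spike_raster(out, Ts = cfg$Ts)
}

#' Network forward pass
#'
#' Maps an input spike raster through every layer: SRM dynamics, then the
#' per-neuron axonal delay (if present), then the local skip-connection (if
#' present). Returns the readout layer's spike raster and membrane trace (the
#' membrane is needed by the suppressed loss).
#'
#' @param model an [build_network()] model.
#' @param input spike raster \code{n_steps x n_in}.
#' @param soft smooth-threshold mode, see [srm_forward()].
#' @param surrogate a [surrogate_config()] (soft mode only).
#' @param keep_cache keep per-layer intermediates for backpropagation.
#' @return A list with \code{spikes} (readout raster), \code{membrane}
#'   (readout trace) and, when requested, \code{caches}.
#' @export
network_forward <- function(model, input, soft = FALSE,
                            surrogate = surrogate_config(),
                            keep_cache = FALSE) {
  stopifnot(inherits(model, "axodelay_net"))
  cfg <- model$cfg
  x <- raster_values(input)
  if (ncol(x) != model$spec$layers[[1L]]$n_in)
    stop("input width does not match the first layer", call. = FALSE)
  caches <- vector("list", length(model$layers))
  fw <- NULL
  for (li in seq_along(model$layers)) {
    L <- model$layers[[li]]
    fw <- srm_forward(x, L$W, L$b, cfg, soft = soft, surrogate = surrogate)
    s <- raster_values(fw$spikes)
    s_d <- if (!is.null(L$delay)) shift_forward(s, L$delay$effective) else s
    if (!is.null(L$V)) {
      lf <- srm_forward(s_d, L$V, L$local_b, cfg, soft = soft,
                        surrogate = surrogate)
      s_out <- s_d + raster_values(lf$spikes)
    } else {
      lf <- NULL
      s_out <- s_d
    }
    if (keep_cache)
      caches[[li]] <- list(x = x, fw = fw, s_d = s_d, lf = lf, s_out = s_out)
    x <- s_out
  }
  out <- list(
    spikes = if (soft) x else spike_raster(x, Ts = cfg$Ts),
    membrane = fw$membrane
  )
  if (keep_cache) out$caches <- caches
  out
}
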