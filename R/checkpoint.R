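#' Save a model checkpoint
#'
#' Serializes the network specification, SRM configuration and every
#' per-layer parameter array (\code{W}, \code{b}, \code{V}, \code{local_b},
#' delay shadow and effective values) to a structured JSON text file. Doubles
#' are written with 17 significant digits, so a load followed by a save
#' round-trips bit-exactly.
#'
#' @param model an [build_network()] model.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "axodelay_net"))
  spec <- model$spec
  obj <- list(
    format = "axodelay-checkpoint-1",
    srm = unclass(spec$srm),
    n_classes = spec$n_classes,
    seed = model$seed,
    layers = lapply(seq_along(model$layers), function(li) {
      ls <- spec$layers[[li]]
      L <- model$layers[[li]]
      out <- list(n_in = ls$n_in, n_out = ls$n_out, vad = ls$vad,
                  local = ls$local, theta_d = ls$theta_d,
                  W = as.vector(L$W), b = as.vector(L$b))
      if (!is.null(L$delay)) {
        out$delay_shadow <- L$delay$shadow
        out$delay_effective <- L$delay$effective
        out$delay_rounding <- L$delay$rounding
      }
      if (!is.null(L$V)) {
        out$V <- as.vector(L$V)
        out$local_b <- as.vector(L$local_b)
      }
      out
    })
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Reads a file written by [save_checkpoint()] and rebuilds the model
#' bit-exactly (parameters, delay shadows and effective integer delays).
#'
#' @param path checkpoint file path.
#' @return An \code{axodelay_net} model.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "axodelay-checkpoint-1"))
    stop("not an axodelay checkpoint: ", path, call. = FALSE)
  srm <- do.call(srm_config, obj$srm)
  specs <- lapply(obj$layers, function(l)
    layer_spec(l$n_in, l$n_out, vad = l$vad, local = l$local,
               theta_d = l$theta_d))
  spec <- network_spec(specs, obj$n_classes, srm)
  layers <- lapply(obj$layers, function(l) {
    out <- list(W = matrix(l$W, l$n_in, l$n_out), b = as.numeric(l$b))
    if (isTRUE(l$vad)) {
      d <- delay_vector(l$n_out, theta_d = l$theta_d, Ts = srm$Ts,
                        rounding = l$delay_rounding)
      d$shadow <- as.numeric(l$delay_shadow)
      d$effective <- as.integer(l$delay_effective)
      out$delay <- d
    }
    if (isTRUE(l$local)) {
      out$V <- matrix(l$V, l$n_out, l$n_out)
      out$local_b <- as.numeric(l$local_b)
    }
    out
  })
  structure(list(spec = spec, cfg = srm, layers = layers,
                 seed = as.integer(obj$seed)),
            class = "axodelay_net")
}

#' Read a training configuration file
#'
#' YAML file whose keys mirror the published hyper-parameter table:
#' \code{batch_size}, \code{learning_rate}, \code{tau_s}, \code{tau_r},
#' \code{theta_u}, \code{alpha_r}, \code{theta_d}, \code{lambda_u}, plus
#' optional \code{epochs}, \code{pretrain_epochs}, \code{target_true},
#' \code{target_false}, \code{l2_delay}. Missing keys fall back to the
#' defaults of the respective constructors.
#'
#' @param path YAML file path.
#' @return List with \code{srm} ([srm_config()]), \code{train}
#'   ([train_config()]), \code{loss} ([loss_config()]) and \code{theta_d}.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  srm <- srm_config(tau_s = pick("tau_s", 5), tau_r = pick("tau_r", 5),
                    alpha_r = pick("alpha_r", 2),
                    theta_u = pick("theta_u", 10), Ts = pick("Ts", 1))
  train <- train_config(lr = pick("learning_rate", 0.1),
                        batch_size = pick("batch_size", 128),
                        epochs = pick("epochs", 40),
                        pretrain_epochs = pick("pretrain_epochs", 20))
  loss <- loss_config(target_true = pick("target_true", 30),
                      target_false = pick("target_false", 5),
                      lambda_u = pick("lambda_u", 0.995),
                      theta_u = pick("theta_u", 10),
                      l2_delay = pick("l2_delay", 0),
                      use_dloss = pick("use_dloss", FALSE))
  list(srm = srm, train = train, loss = loss,
       theta_d = as.integer(pick("theta_d", 64)))
}

#' Write a run manifest
#'
#' Records everything needed to re-run a result bit-identically: the resolved
#' configuration, the seed and the package version.
#'
#' @param path output JSON path.
#' @param config any serializable configuration list.
#' @param seed the seed used.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  obj <- list(
    package = "axodelay",
    version = as.character(utils::packageVersion("axodelay")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              force = TRUE), path)
  invisible(path)
}
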