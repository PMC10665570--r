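#' Event sample
#'
#' A raw event-based recording before binning: spike times in ms, 0-based
#' channel ids, and a 0-based class label. Times are sorted on construction.
#'
#' @param times numeric vector of spike times (ms), non-negative.
#' @param channels integer vector of channel ids, same length as
#'   \code{times}.
#' @param label 0-based class index.
#' @param n_channels declared channel count; every channel id must be in
#'   \code{[0, n_channels)}.
#' @return An object of class \code{event_sample}.
#' @export
event_sample <- function(times, channels, label, n_channels) {
  times <- as.numeric(times)
  channels <- as.integer(channels)
  if (length(times) != length(channels))
    stop("times and channels must have equal length", call. = FALSE)
  if (anyNA(times) || any(times < 0))
    stop("event times must be non-negative", call. = FALSE)
  if (length(channels) && (min(channels) < 0L || max(channels) >= n_channels))
    stop(sprintf("channel id out of range [0, %d)", n_channels), call. = FALSE)
  ord <- order(times)
  structure(list(times = times[ord], channels = channels[ord],
                 label = as.integer(label),
                 n_channels = as.integer(n_channels)),
            class = "event_sample")
}

#' @export
print.event_sample <- function(x, ...) {
  cat(sprintf("<event_sample> %d events over %d channels, label %d\n",
              length(x$times), x$n_channels, x$label))
  invisible(x)
}

#' Bin an event sample into a fixed-horizon spike raster
#'
#' An event at time \code{t} lands in step \code{floor(t / bin_ms)} (an event
#' exactly on a bin boundary goes to the later bin). Multiple events of one
#' channel in the same bin clamp to a single spike, mirroring the benchmark
#' preprocessing in which each channel carries at most one spike per bin.
#' Recordings shorter than the horizon are zero-padded; longer ones are
#' truncated.
#'
#' @param sample an [event_sample()].
#' @param bin_ms bin width in ms (positive).
#' @param n_channels raster width; defaults to the sample's declared count.
#' @param n_steps fixed raster length in steps.
#' @return A binary [spike_raster()] of \code{n_steps x n_channels} with
#'   \code{Ts = bin_ms}.
#' @export
bin_events <- function(sample, bin_ms, n_channels = sample$n_channels,
                       n_steps) {
  stopifnot(inherits(sample, "event_sample"))
  if (bin_ms <= 0) stop("bin_ms must be positive", call. = FALSE)
  x <- matrix(0, n_steps, n_channels)
  if (length(sample$times)) {
    step <- floor(sample$times / bin_ms) + 1L
    keep <- step <= n_steps & sample$channels < n_channels
    if (any(keep))
      x[cbind(step[keep], sample$channels[keep] + 1L)] <- 1
  }
  spike_raster(x, Ts = bin_ms)
}

#' Recover events from a binary raster
#'
#' Inverse of [bin_events()] up to within-bin timing: each spike at step
#' \code{k} (1-based) becomes an event at \code{(k - 1) * Ts} ms. Per-channel
#' spike counts round-trip exactly whenever the bin width does not exceed the
#' minimum inter-event gap.
#'
#' @param raster a binary [spike_raster()].
#' @param label 0-based label to attach.
#' @return An [event_sample()].
#' @export
unbin_raster <- function(raster, label = 0L) {
  x <- raster_values(raster)
  ts <- raster_Ts(raster)
  idx <- which(x > 0, arr.ind = TRUE)
  event_sample(times = (idx[, 1L] - 1) * ts, channels = idx[, 2L] - 1L,
               label = label, n_channels = ncol(x))
}

# run one of the bundled h5py bridge scripts; the SHD releases store spikes
# as ragged (variable-length) HDF5 datasets, which the available R HDF5
# bindings do not handle, so HDF5 traffic goes through the system python
pybridge <- function(script, args) {
  py <- Sys.which(c("python3", "python"))
  py <- py[nzchar(py)][1]
  if (is.na(py) || !nzchar(py))
    stop("no python interpreter found on PATH (needed for HDF5 spike files)",
         call. = FALSE)
  helper <- system.file("pybridge", script, package = "axodelay")
  if (!nzchar(helper))
    stop("bundled bridge script not found: ", script, call. = FALSE)
  res <- suppressWarnings(
    system2(py, c(shQuote(helper), shQuote(args)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 bridge failed: ", paste(res, collapse = "; "), call. = FALSE)
  invisible(res)
}

#' Load an SHD-schema HDF5 spike file
#'
#' Expects the layout of the Spiking Heidelberg Digits releases: ragged
#' datasets \code{spikes/times} (per-sample spike times in seconds) and
#' \code{spikes/units} (channel indices), plus a \code{labels} vector.
#' Times are converted to ms on load. A file missing one of the required
#' datasets raises a format error naming the offending path.
#'
#' @param path HDF5 file path.
#' @param n_channels declared channel count (700 for SHD).
#' @return List of [event_sample()].
#' @export
load_shd <- function(path, n_channels = 700L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  pybridge("shd_dump.py", c(path.expand(path), tmp))
  lines <- readLines(tmp)
  n <- as.integer(lines[1L])
  if (is.na(n)) stop("empty or corrupt SHD dump for ", path, call. = FALSE)
  lapply(seq_len(n), function(i) {
    base <- 2L + (i - 1L) * 3L
    head <- as.integer(strsplit(lines[base], " ", fixed = TRUE)[[1L]])
    k <- head[2L]
    times <- if (k > 0L)
      as.numeric(strsplit(lines[base + 1L], " ", fixed = TRUE)[[1L]])
    else numeric(0)
    units <- if (k > 0L)
      as.integer(strsplit(lines[base + 2L], " ", fixed = TRUE)[[1L]])
    else integer(0)
    event_sample(times = times * 1000,  # s -> ms
                 channels = units, label = head[1L], n_channels = n_channels)
  })
}

#' Write a miniature SHD-schema HDF5 fixture
#'
#' Emits the same layout the [load_shd()] reader expects (ragged
#' \code{spikes/times} in seconds, \code{spikes/units}, \code{labels}), so
#' synthetic miniature datasets can stand in for the real benchmark files in
#' offline tests.
#'
#' @param samples list of [event_sample()] (times in ms; written as
#'   seconds).
#' @param path output file path (overwritten).
#' @return \code{path}, invisibly.
#' @export
write_shd <- function(samples, path) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  writeLines(as.character(length(samples)), con)
  for (s in samples) {
    stopifnot(inherits(s, "event_sample"))
    writeLines(sprintf("%d %d", s$label, length(s$times)), con)
    writeLines(paste(sprintf("%.17g", s$times / 1000), collapse = " "), con)
    writeLines(paste(s$channels, collapse = " "), con)
  }
  close(con)
  if (file.exists(path)) unlink(path)
  pybridge("shd_pack.py", c(tmp, path.expand(path)))
  invisible(path)
}

#' Load an event-list directory
#'
#' Plain-text fallback for cochlea event data (the NTIDIDIGITS-style format):
#' a directory of files named \code{<anything>_label<k>.txt}, one
#' \code{time_ms channel} pair per line. Events need not be sorted on disk.
#'
#' @param path directory path.
#' @param n_channels declared channel count (64 for the silicon-cochlea
#'   digits data).
#' @return List of [event_sample()], in lexicographic file order.
#' @export
load_event_dir <- function(path, n_channels = 64L) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "_label\\d+\\.txt$",
                           full.names = TRUE))
  if (!length(files))
    stop("no event-list files (*_label<k>.txt) in ", path, call. = FALSE)
  lapply(files, function(f) {
    label <- as.integer(sub(".*_label(\\d+)\\.txt$", "\\1", basename(f)))
    m <- tryCatch(
      as.matrix(utils::read.table(f, col.names = c("time_ms", "channel"))),
      error = function(e) stop("malformed event list ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(m) && (any(m[, 2L] < 0) || any(m[, 2L] >= n_channels)))
      stop(sprintf("channel id out of range [0, %d) in %s", n_channels, f),
           call. = FALSE)
    event_sample(times = m[, 1L], channels = m[, 2L], label = label,
                 n_channels = n_channels)
  })
}

#' Write an event-list directory
#'
#' Inverse of [load_event_dir()]: one \code{%04d_label<k>.txt} file per
#' sample, one \code{time_ms channel} pair per line.
#'
#' @param samples list of [event_sample()].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_event_dir <- function(samples, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    f <- file.path(path, sprintf("%04d_label%d.txt", i, s$label))
    utils::write.table(data.frame(time_ms = s$times, channel = s$channels),
                       f, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load silicon-cochlea digit events
#'
#' Reads single-digit cochlea event data from an event-list directory (see
#' [load_event_dir()]). Labels follow the 11-class convention of the spoken
#' digits task ("oh" plus "0"-"9").
#'
#' @param path directory of event-list files.
#' @param n_channels cochlea channel count (64).
#' @return List of [event_sample()].
#' @export
load_ntidigits <- function(path, n_channels = 64L) {
  load_event_dir(path, n_channels = n_channels)
}

#' Export a raster as plain text
#'
#' Dense 0/1 matrix, one time step per row, space-separated; a debugging aid
#' and a text-only interchange format.
#'
#' @param raster a [spike_raster()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_raster_text <- function(raster, path) {
  utils::write.table(raster_values(raster), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
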