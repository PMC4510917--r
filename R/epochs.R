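#' Epoched ERP data container
#'
#' An `epochs_set` holds single-trial epoched potentials as a 3-D numeric array
#' with dimensions channels x time points x trials (microvolts), together with
#' the sampling metadata needed to place the time axis: the sampling rate in Hz
#' and the epoch start in ms relative to stimulus onset.  Trials are kept on
#' the last axis so that every resampling scheme is a single-axis gather.
#'
#' @param data numeric 3-D array, channels x timepoints x trials, in microvolts.
#'   No missing values are allowed.
#' @param sampling_rate sampling rate in Hz (default 250).
#' @param epoch_start epoch start relative to stimulus onset, in ms
#'   (default -300).
#' @param channel_ids character vector of channel labels, one per channel; by
#'   default `"Ch001"`, `"Ch002"`, ...  Channel order is the authoritative
#'   index: adjacency graphs refer to channels by position in this vector.
#'
#' @return An object of class `epochs_set`.
#' @seealso [read_epochs()], [write_epochs()], [epochs_subset()]
#' @export
#' @examples
#' e <- epochs_set(array(rnorm(4 * 10 * 6), c(4, 10, 6)))
#' dim(e$data)
#' times_ms(e)[1:3]
epochs_set <- function(data, sampling_rate = 250, epoch_start = -300,
                       channel_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data))
    stop_validation("`data` must be a 3-D numeric array (channels x time x trials)")
  if (any(dim(data) < 1L))
    stop_validation("all three dimensions of `data` must be >= 1")
  if (anyNA(data))
    stop_validation("`data` must not contain missing values")
  check_scalar_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_scalar_number(epoch_start, "epoch_start")
  nc <- dim(data)[1]
  if (is.null(channel_ids)) channel_ids <- sprintf("Ch%03d", seq_len(nc))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nc)
    stop_validation("`channel_ids` has length %d but the array has %d channels",
                    length(channel_ids), nc)
  if (anyDuplicated(channel_ids))
    stop_validation("`channel_ids` must be unique")
  structure(
    list(data = data, sampling_rate = sampling_rate,
         epoch_start = epoch_start, channel_ids = channel_ids),
    class = "epochs_set")
}

#' Time axis of an epochs set, in milliseconds
#' @param x an `epochs_set`.
#' @return numeric vector of length `n_timepoints`.
#' @export
times_ms <- function(x) {
  stopifnot(inherits(x, "epochs_set"))
  x$epoch_start + (seq_len(dim(x$data)[2]) - 1) * 1000 / x$sampling_rate
}

#' Select a subset of trials
#' @param x an `epochs_set`.
#' @param trials integer vector of trial indices (may repeat, as when
#'   resampling with replacement).
#' @return An `epochs_set` with the selected trials, metadata unchanged.
#' @export
epochs_subset <- function(x, trials) {
  stopifnot(inherits(x, "epochs_set"))
  n <- dim(x$data)[3]
  trials <- as.integer(trials)
  if (any(trials < 1L) || any(trials > n))
    stop_validation("trial index out of range 1..%d", n)
  epochs_set(x$data[, , trials, drop = FALSE], x$sampling_rate, x$epoch_start,
             x$channel_ids)
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs_set> %d channels x %d timepoints x %d trials @ %g Hz, epoch %g..%g ms\n",
    d[1], d[2], d[3], x$sampling_rate, x$epoch_start, max(times_ms(x))))
  invisible(x)
}

#' @export
dim.epochs_set <- function(x) dim(x$data)

# channels x time x trials array flattened to points x trials
flatten_epochs <- function(x) {
  d <- dim(x$data)
  matrix(x$data, d[1] * d[2], d[3])
}

#' Write an epochs set to a plain-text container
#'
#' The container is a pair of files: `path` holds one whitespace-separated
#' channels x timepoints matrix per trial, trials separated by blank lines, and
#' `<path>.json` is a sidecar with the metadata fields `sampling_rate`,
#' `epoch_start_ms`, `channel_ids` and the array dimensions.  Reading the pair
#' back reproduces the object (values go through full-precision decimal
#' formatting, exact for round-trip at 17 significant digits).
#'
#' @param x an `epochs_set`.
#' @param path data file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epochs_set"))
  d <- dim(x$data)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (k in seq_len(d[3])) {
    mat <- x$data[, , k, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, d[1], d[2])
    writeLines(apply(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                     1L, paste, collapse = " "), con)
    if (k < d[3]) writeLines("", con)
  }
  meta <- list(sampling_rate = x$sampling_rate, epoch_start_ms = x$epoch_start,
               channel_ids = x$channel_ids, n_channels = d[1],
               n_timepoints = d[2], n_trials = d[3])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epochs set from a plain-text container
#'
#' @param path data file written by [write_epochs()]; the metadata sidecar
#'   `<path>.json` must sit next to it.
#' @return An [epochs_set()].
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop_format("epochs container not found: %s", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_format("missing metadata sidecar: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("sampling_rate", "epoch_start_ms", "channel_ids",
                  "n_channels", "n_timepoints", "n_trials")) {
    if (is.null(meta[[field]]))
      stop_format("malformed epochs container: missing field `%s`", field)
  }
  lines <- readLines(path)
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  if (length(blocks) != meta$n_trials)
    stop_validation("container has %d trial blocks but sidecar declares %d",
                    length(blocks), meta$n_trials)
  arr <- array(NA_real_, c(meta$n_channels, meta$n_timepoints, meta$n_trials))
  for (k in seq_along(blocks)) {
    rows <- blocks[[k]]
    if (length(rows) != meta$n_channels)
      stop_validation("trial %d has %d rows, expected %d channels",
                      k, length(rows), meta$n_channels)
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "[[:space:]]+"), as.numeric))
    if (ncol(m) != meta$n_timepoints)
      stop_validation("trial %d has %d columns, expected %d timepoints",
                      k, ncol(m), meta$n_timepoints)
    arr[, , k] <- m
  }
  epochs_set(arr, meta$sampling_rate, meta$epoch_start_ms,
             as.character(meta$channel_ids))
}
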