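# Containers for epoched / averaged multichannel datasets, validation,
# trial averaging, and the on-disk container (binary array + YAML sidecar).

.CHANNEL_TYPES <- c("EEG", "MEG", "MEGPLANAR", "LFP", "Other")

#' 2D channel layout on the normalized head disc
#'
#' Positions live in a flattened head frame: the unit disc, with the head
#' apex at the origin and the nose towards +y.
#'
#' @param positions2d n x 2 numeric matrix of channel positions.
#' @return An object of class `channel_layout`.
#' @export
channel_layout <- function(positions2d) {
  positions2d <- as.matrix(positions2d)
  if (ncol(positions2d) != 2L) stop("positions2d must be an n x 2 matrix")
  if (nrow(positions2d) >= 2L) {
    d <- stats::dist(positions2d)
    if (min(d) <= 1e-9) stop("layout contains coincident channel positions")
  }
  colnames(positions2d) <- c("x", "y")
  structure(list(positions2d = positions2d), class = "channel_layout")
}

#' Epoched multichannel dataset
#'
#' The core container: a trials x channels x time array with peristimulus
#' time in ms (0 = stimulus onset), channel metadata, a 2D sensor layout,
#' and bad-channel / rejected-trial flags.
#'
#' @param data numeric array `[n_trials, n_channels, n_time]`.
#' @param time_axis strictly increasing, uniformly sampled time in ms.
#' @param channel_names unique channel identifiers.
#' @param channel_types one of EEG, MEG, MEGPLANAR, LFP, Other per channel.
#' @param condition_labels one label per trial (exact, case-sensitive
#'   strings).
#' @param layout a [channel_layout] with one position per channel.
#' @param bad_channels logical flag per channel.
#' @param rejected_trials logical flag per trial.
#' @return An object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(data, time_axis, channel_names,
                            channel_types = rep("EEG", length(channel_names)),
                            condition_labels, layout,
                            bad_channels = rep(FALSE, length(channel_names)),
                            rejected_trials = rep(FALSE, dim(data)[1])) {
  ds <- structure(
    list(data = data, time_axis = as.numeric(time_axis),
         channel_names = as.character(channel_names),
         channel_types = as.character(channel_types),
         condition_labels = as.character(condition_labels),
         layout = layout,
         bad_channels = as.logical(bad_channels),
         rejected_trials = as.logical(rejected_trials)),
    class = "epoched_dataset")
  rep <- validate_dataset(ds)
  if (!rep$pass)
    stop("invalid dataset: ", paste(rep$violations, collapse = "; "))
  ds
}

#' Condition-averaged dataset
#'
#' Same metadata as [epoched_dataset] but the first array dimension indexes
#' conditions rather than trials.
#'
#' @param data numeric array `[n_conditions, n_channels, n_time]`.
#' @param conditions condition labels, one per slice of `data`.
#' @param time_axis,channel_names,channel_types,layout,bad_channels as in
#'   [epoched_dataset].
#' @param n_trials optional count of trials that entered each average.
#' @return An object of class `averaged_dataset`.
#' @export
averaged_dataset <- function(data, conditions, time_axis, channel_names,
                             channel_types = rep("EEG", length(channel_names)),
                             layout,
                             bad_channels = rep(FALSE, length(channel_names)),
                             n_trials = rep(NA_integer_, length(conditions))) {
  if (dim(data)[1] != length(conditions))
    stop("data first dimension must match the number of conditions")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  structure(
    list(data = data, conditions = as.character(conditions),
         time_axis = as.numeric(time_axis),
         channel_names = as.character(channel_names),
         channel_types = as.character(channel_types),
         layout = layout, bad_channels = as.logical(bad_channels),
         n_trials = as.integer(n_trials)),
    class = "averaged_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_dataset> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples; dt = ", format(diff(x$time_axis[1:2]), digits = 4),
      " ms; conditions: ",
      paste(unique(x$condition_labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.averaged_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<averaged_dataset> ", d[1], " conditions x ", d[2], " channels x ",
      d[3], " samples\n", sep = "")
  invisible(x)
}

#' Validate an epoched dataset against its structural invariants
#'
#' Reports (never errors, never mutates): array shape versus metadata
#' lengths, unique channel names, recognized channel types, strictly
#' increasing uniform time axis, layout size and coincidence, flag lengths.
#'
#' @param ds an [epoched_dataset] (or a bare list with the same fields).
#' @return list with `pass` (logical) and `violations` (character vector).
#' @export
validate_dataset <- function(ds) {
  v <- character(0)
  d <- dim(ds$data)
  if (length(d) != 3L) {
    v <- c(v, "data must be a 3D trials x channels x time array")
    return(list(pass = FALSE, violations = v))
  }
  if (length(ds$channel_names) != d[2])
    v <- c(v, "channel name count does not match data")
  if (anyDuplicated(ds$channel_names)) v <- c(v, "duplicate channel names")
  if (length(ds$channel_types) != d[2])
    v <- c(v, "channel type count does not match data")
  if (!all(ds$channel_types %in% .CHANNEL_TYPES))
    v <- c(v, "unrecognized channel type")
  if (length(ds$condition_labels) != d[1])
    v <- c(v, "condition label count does not match number of trials")
  if (length(ds$time_axis) != d[3])
    v <- c(v, "time axis length does not match data")
  if (length(ds$time_axis) >= 2L) {
    dt <- diff(ds$time_axis)
    if (any(dt <= 0)) v <- c(v, "time axis not strictly increasing")
    else if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
      v <- c(v, "time axis not uniformly sampled")
  }
  if (!inherits(ds$layout, "channel_layout"))
    v <- c(v, "layout missing or not a channel_layout")
  else if (nrow(ds$layout$positions2d) != d[2])
    v <- c(v, "layout size mismatch")
  if (length(ds$bad_channels) != d[2])
    v <- c(v, "bad channel flag count does not match data")
  if (length(ds$rejected_trials) != d[1])
    v <- c(v, "rejected trial flag count does not match data")
  list(pass = length(v) == 0L, violations = v)
}

#' Average epochs into per-condition evoked responses
#'
#' Arithmetic mean over the non-rejected trials of each condition; rejected
#' trials never contribute. Metadata (layout, channel flags, time axis) is
#' carried over unchanged.
#'
#' @param ds an [epoched_dataset].
#' @param conditions conditions to retain; default all distinct labels of
#'   non-rejected trials, in order of first appearance.
#' @return An [averaged_dataset] with one slice per condition.
#' @export
average_epochs <- function(ds, conditions = NULL) {
  keep <- !ds$rejected_trials
  if (is.null(conditions))
    conditions <- unique(ds$condition_labels[keep])
  d <- dim(ds$data)
  out <- array(NA_real_, c(length(conditions), d[2], d[3]))
  n_used <- integer(length(conditions))
  for (i in seq_along(conditions)) {
    idx <- which(keep & ds$condition_labels == conditions[i])
    if (length(idx) == 0L)
      stop("condition '", conditions[i], "' has no retained trials")
    n_used[i] <- length(idx)
    sl <- ds$data[idx, , , drop = FALSE]
    out[i, , ] <- colMeans(sl, dims = 1)
  }
  averaged_dataset(out, conditions, ds$time_axis, ds$channel_names,
                   ds$channel_types, ds$layout, ds$bad_channels,
                   n_trials = n_used)
}

#' Hanning taper over an epoch
#'
#' Pointwise multiplication by the Hanning window
#' `0.5 * (1 - cos(2*pi*k/(N-1)))`, `k = 0..N-1`, which is exactly zero at
#' both epoch ends. Down-weights baseline noise at the edges of the trial.
#'
#' @param x numeric vector, matrix or array; the **last** dimension is time.
#' @return Tapered object of the same shape.
#' @export
hanning_taper <- function(x) {
  n <- if (is.null(dim(x))) length(x) else dim(x)[length(dim(x))]
  if (n < 3L) stop("hanning taper requires at least 3 time samples")
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  if (is.null(dim(x))) return(x * w)
  dm <- dim(x)
  nrest <- prod(dm[-length(dm)])
  y <- matrix(x, nrow = nrest) * rep(w, each = nrest)
  array(y, dm)
}

# ---- on-disk container: flat float64 array + YAML sidecar -------------------

#' Write a dataset to its on-disk container
#'
#' One directory per dataset: `data.bin` (little-endian float64, column
#' order trials/conditions x channels x time) plus `meta.yaml` holding
#' sampling rate, onset, channel names and types, 2D layout, condition
#' labels and bad/rejected flags. The round trip is lossless.
#'
#' @param ds an [epoched_dataset] or [averaged_dataset].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dt <- diff(ds$time_axis[1:2])
  # floats stored as %.17g strings: YAML float emission drops the last ulp
  num <- function(x) sprintf("%.17g", x)
  meta <- list(
    kind = if (inherits(ds, "averaged_dataset")) "averaged" else "epoched",
    dims = as.integer(dim(ds$data)),
    sampling_rate_hz = num(1000 / dt),
    time_onset_ms = num(ds$time_axis[1]),
    channel_names = as.list(ds$channel_names),
    channel_types = as.list(ds$channel_types),
    layout = lapply(seq_len(nrow(ds$layout$positions2d)),
                    function(i) num(ds$layout$positions2d[i, ])),
    bad_channels = as.list(ds$bad_channels))
  if (inherits(ds, "averaged_dataset")) {
    meta$conditions <- as.list(ds$conditions)
    meta$n_trials <- as.list(ds$n_trials)
  } else {
    meta$conditions <- as.list(ds$condition_labels)
    meta$rejected_trials <- as.list(ds$rejected_trials)
  }
  writeLines(yaml::as.yaml(meta), file.path(path, "meta.yaml"))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(ds$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a dataset container written by [write_dataset]
#'
#' @param path dataset directory.
#' @return An [epoched_dataset] or [averaged_dataset].
#' @export
read_dataset <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  dims <- as.integer(unlist(meta$dims))
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = prod(dims), size = 8L,
               endian = "little")
  data <- array(x, dims)
  lay <- channel_layout(do.call(rbind, lapply(meta$layout, as.numeric)))
  rownames(lay$positions2d) <- unlist(meta$channel_names)
  dt <- 1000 / as.numeric(meta$sampling_rate_hz)
  time_axis <- as.numeric(meta$time_onset_ms) + (seq_len(dims[3]) - 1) * dt
  if (identical(meta$kind, "averaged")) {
    averaged_dataset(data, unlist(meta$conditions), time_axis,
                     unlist(meta$channel_names), unlist(meta$channel_types),
                     lay, unlist(meta$bad_channels),
                     n_trials = unlist(meta$n_trials))
  } else {
    epoched_dataset(data, time_axis, unlist(meta$channel_names),
                    unlist(meta$channel_types), unlist(meta$conditions),
                    lay, unlist(meta$bad_channels),
                    unlist(meta$rejected_trials))
  }
}
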