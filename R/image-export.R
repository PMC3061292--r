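# Sensor data -> NIfTI summary-statistic images: scalp-map interpolation,
# space x space x time volumes, time-window averages, planar RMS
# combination, and masked Gaussian smoothing in physical units.

# layout units are normalized (unit disc); images carry a nominal
# mm-equivalent scale so smoothing kernels specified in mm are meaningful
.LAYOUT_MM_SCALE <- 100   # unit disc radius == 100 mm

#' Define the interpolation grid for scalp-map images
#'
#' @param layout a [channel_layout].
#' @param n_pixels pixels per spatial dimension (default 64).
#' @param margin fractional margin added around the good-channel bounding
#'   box (default 5%).
#' @param good logical vector of channels to bound; default all.
#' @return list of class `image_grid` with pixel center coordinates `xo`,
#'   `yo` (layout units) and `pixel_mm` sizes on the nominal mm scale.
#' @export
image_grid <- function(layout, n_pixels = 64, margin = 0.05, good = NULL) {
  if (n_pixels < 8) stop("n_pixels must be at least 8")
  pos <- layout$positions2d
  if (!is.null(good)) pos <- pos[good, , drop = FALSE]
  rx <- range(pos[, 1]); ry <- range(pos[, 2])
  ex <- diff(rx) * margin; ey <- diff(ry) * margin
  xo <- seq(rx[1] - ex, rx[2] + ex, length.out = n_pixels)
  yo <- seq(ry[1] - ey, ry[2] + ey, length.out = n_pixels)
  structure(list(xo = xo, yo = yo, n_pixels = as.integer(n_pixels),
                 pixel_mm = c(diff(xo[1:2]), diff(yo[1:2])) *
                   .LAYOUT_MM_SCALE),
            class = "image_grid")
}

#' A 2D/3D statistical image with physical axis metadata
#'
#' @param data numeric array (<= 3 dimensions; `NA` marks missing voxels).
#' @param pixdim physical size of a voxel along each dimension.
#' @param units character vector of axis units (e.g. `c("mm","mm","ms")`).
#' @param origin physical coordinate of voxel (1, 1[, 1]).
#' @param field optional list `(type, dof)` for statistical maps, where
#'   `type` is one of "Gaussian", "t", "F".
#' @param provenance optional free-form list (dataset, condition, trial).
#' @return object of class `stat_image`.
#' @export
stat_image <- function(data, pixdim, units, origin = rep(0, length(dim(data))),
                       field = NULL, provenance = list()) {
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L) stop("stat_image is limited to 2 or 3 dimensions")
  if (length(pixdim) != nd || length(units) != nd)
    stop("axis metadata must cover every dimension")
  structure(list(data = data, pixdim = as.numeric(pixdim),
                 units = as.character(units), origin = as.numeric(origin),
                 field = field, provenance = provenance),
            class = "stat_image")
}

#' @export
print.stat_image <- function(x, ...) {
  cat("<stat_image> ", paste(dim(x$data), collapse = " x "),
      " voxels; pixdim ", paste(format(x$pixdim, digits = 4), x$units,
                                collapse = ", "), sep = "")
  if (!is.null(x$field))
    cat("; ", x$field$type, " field, dof ",
        paste(x$field$dof, collapse = ","), sep = "")
  cat("\n")
  invisible(x)
}

# barycentric linear interpolation weight matrix: rows = pixels (x fastest),
# cols = good channels; NA rows outside the convex hull are all-zero and
# tracked via the `inside` attribute
.interp_weights <- function(positions, grid) {
  n <- nrow(positions)
  if (n < 3L) stop("at least 3 good channels are required for interpolation")
  d <- svd(sweep(positions, 2, colMeans(positions)))$d
  if (d[2] <= 1e-9 * max(d[1], 1e-300))
    stop("good channels are collinear; scalp map is not defined")
  np <- length(grid$xo) * length(grid$yo)
  w <- matrix(0, np, n)
  inside <- rep(TRUE, np)
  for (c in seq_len(n)) {
    e <- numeric(n); e[c] <- 1
    g <- interp::interp(positions[, 1], positions[, 2], e,
                        xo = grid$xo, yo = grid$yo, method = "linear",
                        output = "grid")$z
    miss <- is.na(g)
    inside <- inside & !as.vector(miss)
    g[miss] <- 0
    w[, c] <- as.vector(g)
  }
  attr(w, "inside") <- inside
  w
}

#' Interpolate channel values into a 2D scalp map
#'
#' Delaunay triangulation of the good-channel layout positions with
#' barycentric linear interpolation inside the convex hull; pixels outside
#' the hull are `NA`. With `bad_channel_mode = "interpolate"` bad channels
#' are simply omitted from the triangulation; with `"remove"`, pixels whose
#' nearest channel is bad are additionally set to `NA`, leaving holes that
#' propagate through all later analysis stages (distance ties favour the
#' good channel).
#'
#' @param values numeric vector, one value per channel of the layout.
#' @param layout a [channel_layout].
#' @param grid an [image_grid]; default `image_grid(layout, 64)` over the
#'   good channels.
#' @param bad_channels logical flag per channel.
#' @param bad_channel_mode `"interpolate"` (default) or `"remove"`.
#' @return A 2D [stat_image] in nominal mm units.
#' @export
interpolate_scalp_map <- function(values, layout, grid = NULL,
                                  bad_channels = NULL,
                                  bad_channel_mode = c("interpolate",
                                                       "remove")) {
  bad_channel_mode <- match.arg(bad_channel_mode)
  pos <- layout$positions2d
  if (length(values) != nrow(pos))
    stop("one value per layout channel is required")
  if (is.null(bad_channels)) bad_channels <- rep(FALSE, nrow(pos))
  good <- !bad_channels
  if (is.null(grid)) grid <- image_grid(layout, good = good)
  w <- .interp_weights(pos[good, , drop = FALSE], grid)
  img <- w %*% values[good]
  img[!attr(w, "inside")] <- NA_real_
  img <- matrix(img, length(grid$xo), length(grid$yo))
  if (bad_channel_mode == "remove" && any(bad_channels))
    img[.bad_nearest_mask(pos, bad_channels, grid)] <- NA_real_
  stat_image(img, pixdim = grid$pixel_mm, units = c("mm", "mm"),
             origin = c(grid$xo[1], grid$yo[1]) * .LAYOUT_MM_SCALE)
}

# pixels whose nearest channel (over all channels) is bad; ties go to good
.bad_nearest_mask <- function(positions, bad, grid) {
  px <- rep(grid$xo, times = length(grid$yo))
  py <- rep(grid$yo, each = length(grid$xo))
  d2g <- rep(Inf, length(px)); d2b <- rep(Inf, length(px))
  for (c in seq_len(nrow(positions))) {
    d2 <- (px - positions[c, 1])^2 + (py - positions[c, 2])^2
    if (bad[c]) d2b <- pmin(d2b, d2) else d2g <- pmin(d2g, d2)
  }
  matrix(d2b < d2g, length(grid$xo), length(grid$yo))
}

# channels entering image export: one modality among EEG/MEG/MEGPLANAR;
# LFP/Other are carried in datasets but never imaged
.select_modality <- function(ds, modality = NULL) {
  imageable <- ds$channel_types %in% c("EEG", "MEG", "MEGPLANAR")
  present <- unique(ds$channel_types[imageable])
  if (is.null(modality)) {
    if (length(present) > 1L)
      stop("dataset mixes modalities (", paste(present, collapse = ", "),
           "); select one explicitly")
    if (length(present) == 0L) stop("no imageable channels in dataset")
    modality <- present
  }
  which(ds$channel_types == modality)
}

#' Convert a dataset to space x space x time NIfTI volumes
#'
#' Scalp maps are generated for every time frame and stacked over
#' peristimulus time (z axis = time, voxel thickness = dt in ms). A
#' directory named after the dataset is created with one subdirectory per
#' condition; averaged input yields a single 3D image per condition,
#' epoched input one image per retained (non-rejected) trial.
#'
#' @param ds an [epoched_dataset] or [averaged_dataset].
#' @param out_dir output parent directory.
#' @param name dataset name (directory stem).
#' @param grid an [image_grid]; defaults to 64 pixels over good channels.
#' @param bad_channel_mode passed to [interpolate_scalp_map].
#' @param modality which channel modality to image when several exist.
#' @return data.frame manifest with columns `file`, `condition`, `trial`.
#' @export
dataset_to_volumes <- function(ds, out_dir, name = "dataset", grid = NULL,
                               bad_channel_mode = c("interpolate", "remove"),
                               modality = NULL) {
  bad_channel_mode <- match.arg(bad_channel_mode)
  chans <- .select_modality(ds, modality)
  lay <- channel_layout(ds$layout$positions2d[chans, , drop = FALSE])
  bad <- ds$bad_channels[chans]
  good <- !bad
  if (is.null(grid)) grid <- image_grid(lay, good = good)
  w <- .interp_weights(lay$positions2d[good, , drop = FALSE], grid)
  outside <- !attr(w, "inside")
  hole <- if (bad_channel_mode == "remove" && any(bad))
    as.vector(.bad_nearest_mask(lay$positions2d, bad, grid)) else
      rep(FALSE, length(outside))
  dt <- diff(ds$time_axis[1:2])
  averaged <- inherits(ds, "averaged_dataset")
  conds <- if (averaged) ds$conditions else
    unique(ds$condition_labels[!ds$rejected_trials])
  root <- file.path(out_dir, name)
  manifest <- NULL
  for (ci in seq_along(conds)) {
    cdir <- file.path(root, conds[ci])
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    slices <- if (averaged) ci else
      which(!ds$rejected_trials & ds$condition_labels == conds[ci])
    for (k in seq_along(slices)) {
      frames <- ds$data[slices[k], chans, , drop = TRUE][good, , drop = FALSE]
      vol <- w %*% frames                       # pixels x time
      vol[outside | hole, ] <- NA_real_
      vol <- array(vol, c(length(grid$xo), length(grid$yo), ncol(frames)))
      img <- stat_image(vol, pixdim = c(grid$pixel_mm, dt),
                        units = c("mm", "mm", "ms"),
                        origin = c(grid$xo[1] * .LAYOUT_MM_SCALE,
                                   grid$yo[1] * .LAYOUT_MM_SCALE,
                                   ds$time_axis[1]),
                        provenance = list(dataset = name,
                                          condition = conds[ci],
                                          trial = if (averaged) NA_integer_
                                          else slices[k]))
      file <- file.path(cdir, if (averaged) "average.nii" else
        sprintf("trial%04d.nii", slices[k]))
      write_stat_image(img, file)
      manifest <- rbind(manifest,
                        data.frame(file = file, condition = conds[ci],
                                   trial = if (averaged) NA_integer_ else
                                     slices[k]))
    }
  }
  manifest
}

#' Average a time window, then interpolate once
#'
#' Channel data are averaged over all samples falling inside
#' `[window_ms[1], window_ms[2]]` (inclusive) and the resulting per-channel
#' values interpolated into a single 2D scalp map.
#'
#' @param ds an [epoched_dataset] or [averaged_dataset].
#' @param window_ms `c(t1, t2)` in peristimulus ms.
#' @param condition which condition (label) to summarize; defaults to the
#'   first. For epoched input, retained trials of that condition are
#'   averaged first.
#' @param grid,bad_channel_mode,modality as in [dataset_to_volumes].
#' @return A 2D [stat_image].
#' @export
average_time_window_image <- function(ds, window_ms, condition = NULL,
                                      grid = NULL,
                                      bad_channel_mode = c("interpolate",
                                                           "remove"),
                                      modality = NULL) {
  bad_channel_mode <- match.arg(bad_channel_mode)
  sel <- which(ds$time_axis >= window_ms[1] & ds$time_axis <= window_ms[2])
  if (length(sel) == 0L) stop("time window does not intersect the epoch")
  if (inherits(ds, "epoched_dataset")) ds <- average_epochs(ds)
  conds <- ds$conditions
  if (is.null(condition)) condition <- conds[1]
  ci <- match(condition, conds)
  if (is.na(ci)) stop("condition '", condition, "' not present")
  chans <- .select_modality(ds, modality)
  lay <- channel_layout(ds$layout$positions2d[chans, , drop = FALSE])
  vals <- rowMeans(array(ds$data[ci, chans, sel], c(length(chans),
                                                    length(sel))))
  interpolate_scalp_map(vals, lay, grid = grid,
                        bad_channels = ds$bad_channels[chans],
                        bad_channel_mode = bad_channel_mode)
}

#' Combine planar gradiometer pairs by root-mean-square
#'
#' MEG planar gradiometers come in orthogonal pairs at each sensor
#' location; their amplitudes are combined as
#' `sqrt((g1^2 + g2^2) / 2)` per location.
#'
#' @param g1,g2 numeric vectors/arrays of the two gradiometer channels
#'   (matched shapes), or `g1` a 2-row matrix when `g2` is missing.
#' @return combined values, same shape as `g1`.
#' @export
combine_planar_rms <- function(g1, g2 = NULL) {
  if (is.null(g2)) {
    if (is.matrix(g1) && nrow(g1) == 2L) {
      g2 <- g1[2, ]; g1 <- g1[1, ]
    } else stop("planar channels must come in pairs")
  }
  if (length(g1) != length(g2))
    stop("planar channels must come in pairs of equal length")
  sqrt((g1^2 + g2^2) / 2)
}

#' Pair and combine the planar gradiometers of a dataset
#'
#' @param ds an [epoched_dataset] whose MEGPLANAR channels pair up by name
#'   as `<loc>_1`, `<loc>_2` (any other channels cause an error).
#' @return A new [epoched_dataset] of MEG channels, one per location.
#' @export
combine_planar_dataset <- function(ds) {
  pl <- which(ds$channel_types == "MEGPLANAR")
  if (length(pl) == 0L) stop("dataset has no planar gradiometer channels")
  loc <- sub("_[12]$", "", ds$channel_names[pl])
  suff <- sub("^.*_([12])$", "\\1", ds$channel_names[pl])
  if (any(suff == ds$channel_names[pl]))
    stop("unpaired planar channel: ",
         ds$channel_names[pl][suff == ds$channel_names[pl]][1])
  locs <- unique(loc)
  i1 <- match(paste0(locs, "_1"), ds$channel_names)
  i2 <- match(paste0(locs, "_2"), ds$channel_names)
  if (anyNA(i1) || anyNA(i2))
    stop("unpaired planar channel: ",
         locs[which(is.na(i1) | is.na(i2))][1])
  d <- dim(ds$data)
  out <- array(NA_real_, c(d[1], length(locs), d[3]))
  for (k in seq_along(locs))
    out[, k, ] <- combine_planar_rms(ds$data[, i1[k], ], ds$data[, i2[k], ])
  pos <- (ds$layout$positions2d[i1, , drop = FALSE] +
            ds$layout$positions2d[i2, , drop = FALSE]) / 2
  epoched_dataset(out, ds$time_axis, locs, rep("MEG", length(locs)),
                  ds$condition_labels, channel_layout(pos),
                  ds$bad_channels[i1] | ds$bad_channels[i2],
                  ds$rejected_trials)
}

#' Gaussian smoothing of a statistical image in physical units
#'
#' Separable Gaussian convolution with per-dimension FWHM given in the
#' image's own physical units (mm / ms / Hz), kernel truncated at 4 sigma.
#' Border voxels are handled by renormalizing the kernel mass that falls
#' inside the image. Missing-value voxels stay missing and are excluded
#' from their neighbours' kernel mass (masked, renormalized convolution),
#' so holes persist through smoothing.
#'
#' @param img a [stat_image].
#' @param fwhm numeric vector, FWHM per image dimension in physical units;
#'   0 skips a dimension.
#' @return smoothed [stat_image].
#' @export
gaussian_smooth_image <- function(img, fwhm) {
  nd <- length(dim(img$data))
  if (length(fwhm) != nd)
    stop("fwhm must give one value per image dimension (", nd, ")")
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  sig_vox <- .fwhm_to_sigma(fwhm) / img$pixdim
  kerns <- lapply(sig_vox, .gauss_kernel)
  x <- img$data
  miss <- is.na(x)
  x0 <- x; x0[miss] <- 0
  m <- array(as.numeric(!miss), dim(x))
  num <- .sep_convolve(x0, kerns)
  den <- .sep_convolve(m, kerns)
  out <- num / den
  out[miss | den == 0] <- NA_real_
  img$data <- out
  img
}

#' Write a [stat_image] as NIfTI-1
#'
#' float32 voxels, `NA` encoded as NaN, pixdim carrying the physical axis
#' sizes, and field type/dof recorded in the description header field.
#'
#' @param img a [stat_image].
#' @param file output path (`.nii`).
#' @return `file`, invisibly.
#' @export
write_stat_image <- function(img, file) {
  nd <- length(dim(img$data))
  pd <- c(-1, img$pixdim, rep(1, 7 - nd))
  desc <- paste0("topostat;units=", paste(img$units, collapse = ","),
                 ";origin=", paste(format(img$origin, digits = 10),
                                   collapse = ","),
                 if (!is.null(img$field))
                   paste0(";field=", img$field$type, ";dof=",
                          paste(img$field$dof, collapse = ",")))
  nif <- RNifti::asNifti(img$data,
                         reference = list(pixdim = pd, descrip = desc,
                                          datatype = 16L))
  RNifti::writeNifti(nif, file)
  invisible(file)
}

#' Read a NIfTI written by [write_stat_image] back into a [stat_image]
#'
#' @param file NIfTI path.
#' @return A [stat_image]; axis metadata recovered from the header.
#' @export
read_stat_image <- function(file) {
  nif <- RNifti::readNifti(file)
  hdr <- RNifti::niftiHeader(nif)
  nd <- hdr$dim[1]
  data <- array(as.numeric(nif), dim(nif))
  units <- rep("unknown", nd)
  origin <- rep(0, nd)
  field <- NULL
  desc <- hdr$descrip
  if (grepl("^topostat;", desc)) {
    kv <- strsplit(sub("^topostat;", "", desc), ";")[[1]]
    kv <- strsplit(kv, "=")
    vals <- stats::setNames(vapply(kv, `[`, "", 2),
                            vapply(kv, `[`, "", 1))
    if (!is.na(vals["units"]))
      units <- strsplit(vals[["units"]], ",")[[1]]
    if (!is.na(vals["origin"]))
      origin <- as.numeric(strsplit(vals[["origin"]], ",")[[1]])
    if ("field" %in% names(vals))
      field <- list(type = vals[["field"]],
                    dof = as.numeric(strsplit(vals[["dof"]], ",")[[1]]))
  }
  stat_image(data, pixdim = hdr$pixdim[2:(nd + 1)], units = units,
             origin = origin, field = field)
}
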