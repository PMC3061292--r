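# Random field theory inference: residual smoothness (FWHM / resel)
# estimation, Euler characteristic densities for Gaussian, t and F fields,
# peak- and cluster-level FWER-corrected p-values, and the topological
# results report with optional window-restricted (small-volume) search.

#' Estimate residual field smoothness and resel counts
#'
#' Residual images are standardized to unit variance at every voxel; the
#' per-dimension roughness `lambda_j` is the mean squared first difference
#' of the standardized residuals along dimension j (over images and
#' in-mask voxel pairs), giving `FWHM_j = sqrt(4*log(2) / lambda_j)` in
#' voxels. Resel counts follow the cuboid formulas applied to the mask's
#' bounding box, with the top dimension count taken as
#' `#mask voxels / prod(FWHM)`.
#'
#' @param residuals n x V matrix of residual images (e.g.
#'   `model$residuals`), or a `glm_model` from [fit_glm].
#' @param dims voxel dimensions of each image (ignored for a `glm_model`).
#' @param mask logical vector of analysis voxels (default: complete voxels).
#' @return object of class `smoothness_estimate`: `fwhm` (voxels, per
#'   dimension), `resels` (length D+1, orders 0..D), `lambda`, `n_mask`,
#'   `dims`.
#' @export
estimate_smoothness <- function(residuals, dims = NULL, mask = NULL) {
  if (inherits(residuals, "glm_model")) {
    if (is.null(dims)) dims <- residuals$dims
    if (is.null(mask)) mask <- residuals$mask
    residuals <- residuals$residuals
  }
  if (is.null(dims)) stop("dims must be supplied for a residual matrix")
  n <- nrow(residuals)
  if (is.null(n) || n < 2) stop("at least 2 residual images are required")
  if (is.null(mask)) mask <- colSums(is.na(residuals)) == 0L
  if (!any(mask)) stop("empty analysis mask")
  # standardize to unit variance at each in-mask voxel
  vv <- colMeans(residuals^2)
  ok <- mask & is.finite(vv) & vv > 0
  if (!any(ok)) stop("residuals have zero variance everywhere in the mask")
  Z <- residuals[, ok, drop = FALSE] /
    rep(sqrt(vv[ok]), each = n)
  D <- length(dims)
  full <- matrix(NA_real_, n, length(mask))
  full[, ok] <- Z
  maskar <- array(ok, dims)
  lambda <- numeric(D)
  for (j in seq_len(D)) {
    # voxel pairs (v, v + e_j) with both members in the mask
    idx_lo <- .slab_indices(dims, j, seq_len(dims[j] - 1L))
    idx_hi <- .slab_indices(dims, j, seq_len(dims[j] - 1L) + 1L)
    pair_ok <- maskar[idx_lo] & maskar[idx_hi]
    if (!any(pair_ok))
      stop("mask has no interior voxel pairs along dimension ", j)
    dif <- full[, idx_hi[pair_ok], drop = FALSE] -
      full[, idx_lo[pair_ok], drop = FALSE]
    lambda[j] <- mean(dif^2)
  }
  if (any(lambda <= 0)) stop("degenerate roughness estimate")
  fwhm <- sqrt(4 * log(2) / lambda)
  structure(list(fwhm = fwhm, lambda = lambda,
                 resels = resel_counts(dims, fwhm, n_mask = sum(ok)),
                 n_mask = sum(ok), dims = dims),
            class = "smoothness_estimate")
}

# linear indices of the hyperplane(s) at positions `pos` along dim j
.slab_indices <- function(dims, j, pos) {
  idx <- lapply(seq_along(dims), function(k)
    if (k == j) pos else seq_len(dims[k]))
  grid <- as.matrix(do.call(expand.grid, idx))
  as.vector(1L + (grid - 1L) %*% cumprod(c(1L, dims[-length(dims)])))
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("<smoothness_estimate> FWHM [voxels]: ",
      paste(format(x$fwhm, digits = 4), collapse = " x "),
      "; resels R0..R", length(x$resels) - 1L, ": ",
      paste(format(x$resels, digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Resel counts of a cuboid search region
#'
#' Edge lengths in FWHM units `L_j = n_j / FWHM_j` give
#' `R_0 = 1, R_1 = sum L_j, R_2 = sum_{j<k} L_j L_k, R_3 = prod L_j`.
#' When `n_mask` is given (irregular masks), the top-order count is
#' replaced by `n_mask / prod(FWHM)` and lower orders keep the
#' bounding-box values.
#'
#' @param dims voxel extents of the search region (bounding box).
#' @param fwhm smoothness per dimension, voxels.
#' @param n_mask optional number of in-mask voxels.
#' @return numeric vector `R_0 .. R_D`.
#' @export
resel_counts <- function(dims, fwhm, n_mask = NULL) {
  fwhm <- rep_len(fwhm, length(dims))
  if (any(fwhm <= 0)) stop("FWHM must be positive")
  L <- dims / fwhm
  D <- length(dims)
  R <- numeric(D + 1)
  R[1] <- 1
  for (d in seq_len(D)) {
    cmb <- utils::combn(D, d, function(ix) prod(L[ix]))
    R[d + 1] <- sum(cmb)
  }
  if (!is.null(n_mask)) R[D + 1] <- n_mask / prod(fwhm)
  R
}

#' Euler characteristic densities
#'
#' Per-resel EC densities `rho_d(u)` for Gaussian, t and F random fields
#' (unified-field-theory forms), dimensions d = 0..3. These drive the
#' expected Euler characteristic `E[EC] = sum_d R_d * rho_d(u)`, which for
#' high thresholds approximates the FWER of threshold `u`.
#'
#' @param u threshold (vectorized).
#' @param d EC density order (0, 1, 2 or 3).
#' @param type `"Gaussian"`, `"t"` or `"F"`.
#' @param dof degrees of freedom: ignored for Gaussian, `nu` (or `c(1,nu)`)
#'   for t, `c(k, nu)` for F.
#' @return numeric vector of densities.
#' @export
ec_density <- function(u, d, type = c("Gaussian", "t", "F"), dof = NULL) {
  type <- match.arg(type)
  a <- 4 * log(2)
  tp <- 2 * pi
  switch(type,
    Gaussian = switch(d + 1L,
      stats::pnorm(u, lower.tail = FALSE),
      sqrt(a) / tp * exp(-u^2 / 2),
      a / tp^1.5 * u * exp(-u^2 / 2),
      a^1.5 / tp^2 * (u^2 - 1) * exp(-u^2 / 2)),
    t = {
      v <- dof[length(dof)]
      if (is.null(v) || v < 1) stop("t field needs degrees of freedom")
      cfac <- (1 + u^2 / v)^((1 - v) / 2)
      b <- exp(lgamma((v + 1) / 2) - lgamma(v / 2))
      switch(d + 1L,
        stats::pt(u, v, lower.tail = FALSE),
        sqrt(a) / tp * cfac,
        a / tp^1.5 * cfac * u * b / sqrt(v / 2),
        a^1.5 / tp^2 * cfac * ((v - 1) * u^2 / v - 1))
    },
    F = {
      if (length(dof) != 2) stop("F field needs dof = c(k, nu)")
      k <- dof[1]; v <- dof[2]
      lb <- lgamma(v / 2) + lgamma(k / 2)
      z <- k * u / v
      switch(d + 1L,
        stats::pf(u, k, v, lower.tail = FALSE),
        sqrt(a / tp) * exp(lgamma((v + k - 1) / 2) - lb) * sqrt(2) *
          z^((k - 1) / 2) * (1 + z)^(-(v + k - 2) / 2),
        a / tp * exp(lgamma((v + k - 2) / 2) - lb) *
          z^((k - 2) / 2) * (1 + z)^(-(v + k - 2) / 2) *
          ((v - 1) * z - (k - 1)),
        (a / tp)^1.5 * exp(lgamma((v + k - 3) / 2) - lb) / sqrt(2) *
          z^((k - 3) / 2) * (1 + z)^(-(v + k - 2) / 2) *
          ((v - 1) * (v - 2) * z^2 - (2 * v * k - v - k - 1) * z +
             (k - 1) * (k - 2)))
    })
}

#' Peak-level FWER-corrected p-value by random field theory
#'
#' `p = min(1, sum_d R_d * rho_d(u))`, floored by the Bonferroni bound over
#' the mask voxels when `n_vox` is given: the reported value is
#' `min(p_RFT, p_Bonferroni)`, preserving validity at low smoothness.
#'
#' @param u observed peak height.
#' @param type,dof field type and degrees of freedom (see [ec_density]).
#' @param resels resel counts `R_0..R_D` (e.g. from [estimate_smoothness]).
#' @param n_vox optional number of voxels searched, enabling the
#'   Bonferroni floor.
#' @return corrected p-value in `[0, 1]`.
#' @export
rft_peak_p <- function(u, type = "Gaussian", dof = NULL, resels,
                       n_vox = NULL) {
  if (any(resels < 0)) stop("resel counts must be non-negative")
  if (!all(is.finite(u))) stop("threshold must be finite")
  ec_sum <- function(v) {
    s <- 0
    for (d in seq_along(resels) - 1L)
      s <- s + resels[d + 1L] * ec_density(v, d, type, dof)
    s
  }
  # the expected-EC approximation is only meaningful on its decreasing
  # branch (high thresholds); below the branch the p-value saturates,
  # keeping p monotone nonincreasing in u
  ustar <- stats::optimize(ec_sum, c(0, 10), maximum = TRUE)$maximum
  p <- ec_sum(pmax(u, ustar))
  p <- pmin(1, pmax(p, 0))
  if (!is.null(n_vox)) {
    punc <- ec_density(u, 0L, type, dof)
    p <- pmin(p, pmin(1, n_vox * punc))
  }
  p
}

#' Critical threshold at a target corrected level
#'
#' Inverts [rft_peak_p] in `u` by bisection.
#'
#' @param alpha corrected significance level (default 0.05).
#' @param type,dof,resels,n_vox as in [rft_peak_p].
#' @return threshold `u` with corrected p equal to `alpha`.
#' @export
rft_threshold <- function(alpha = 0.05, type = "Gaussian", dof = NULL,
                          resels, n_vox = NULL) {
  f <- function(u) rft_peak_p(u, type, dof, resels, n_vox) - alpha
  # the EC sum is only monotone on its decreasing branch (high u): start
  # at the uncorrected quantile and walk up until the sum drops below alpha
  lo <- switch(type,
               Gaussian = stats::qnorm(alpha, lower.tail = FALSE),
               t = stats::qt(alpha, dof[length(dof)], lower.tail = FALSE),
               F = stats::qf(alpha, dof[1], dof[2], lower.tail = FALSE))
  lo <- max(lo, 1e-3)
  hi <- lo
  step <- max(0.5, 0.1 * lo)
  while (f(hi) > 0 && hi < 1e6) { lo <- hi; hi <- hi + step }
  if (f(hi) > 0) stop("no finite threshold at this level")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Gaussianize a threshold of a t/F field through its upper-tail p-value
.gaussianize <- function(u, type, dof) {
  if (type == "Gaussian") return(u)
  p <- ec_density(u, 0L, type, dof)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Cluster-level FWER-corrected p-value
#'
#' Gaussian-field approximation for the probability of observing a cluster
#' of `k` or more voxels above the cluster-forming threshold `u_c`
#' anywhere in the search region: with expected cluster count
#' `E[m] = sum_d R_d rho_d` and expected suprathreshold volume
#' `E[n] = n_vox * (1 - Phi(u_c))`, extents follow
#' `P(extent >= k) = exp(-beta * k_resel^(2/D))`,
#' `beta = (gamma(D/2 + 1) * E[m] / E[n_resel])^(2/D)`, and
#' `p = 1 - exp(-E[m] * P(extent >= k))`. t and F fields are probit
#' Gaussianized before applying these forms.
#'
#' @param k cluster extent in voxels.
#' @param u_c cluster-forming threshold (positive-tail, > 0).
#' @param type,dof field type and degrees of freedom.
#' @param resels resel counts of the search region.
#' @param fwhm per-dimension FWHM in voxels (converts `k` to resels).
#' @param n_vox voxels in the search region.
#' @return cluster-level corrected p-value.
#' @export
rft_cluster_p <- function(k, u_c, type = "Gaussian", dof = NULL, resels,
                          fwhm, n_vox) {
  if (u_c <= 0) stop("cluster-forming threshold must be positive")
  if (any(k < 0)) stop("cluster extent must be non-negative")
  D <- length(fwhm)
  ug <- .gaussianize(u_c, type, dof)
  Em <- 0  # expected cluster count: unclamped EC sum on the Gaussian scale
  for (d in seq_along(resels) - 1L)
    Em <- Em + resels[d + 1L] * ec_density(ug, d, "Gaussian")
  Em <- max(Em, .Machine$double.xmin)
  En_resel <- n_vox * stats::pnorm(ug, lower.tail = FALSE) / prod(fwhm)
  k_resel <- k / prod(fwhm)
  if (En_resel <= 0) return(rep(1, length(k)) * 0 + 1 - exp(-Em * (k == 0)))
  beta <- (gamma(D / 2 + 1) * Em / En_resel)^(2 / D)
  p_ext <- exp(-beta * k_resel^(2 / D))
  1 - exp(-Em * p_ext)
}

# ---- topological report -----------------------------------------------------

# neighbour offsets: 8-connectivity in 2D, 18-connectivity in 3D
.neighbour_offsets <- function(D) {
  if (D == 2) {
    g <- as.matrix(expand.grid(-1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0 & rowSums(abs(g)) <= 2, , drop = FALSE]
  }
}

# connected component labels of a logical array under the package
# connectivity convention; returns integer array (0 = background)
.label_components <- function(bin) {
  dims <- dim(bin)
  D <- length(dims)
  offs <- .neighbour_offsets(D)
  lab <- array(0L, dims)
  idx_all <- which(bin)
  if (length(idx_all) == 0L) return(lab)
  coords <- arrayInd(idx_all, dims)
  rownames(coords) <- NULL
  pos_of <- array(0L, dims)
  pos_of[idx_all] <- seq_along(idx_all)
  cur <- 0L
  for (start in seq_along(idx_all)) {
    if (lab[idx_all[start]] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[idx_all[start]] <- cur
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cc <- coords[p, ]
      for (o in seq_len(nrow(offs))) {
        q <- cc + offs[o, ]
        if (any(q < 1L) || any(q > dims)) next
        qi <- 1L + sum((q - 1L) * cumprod(c(1L, dims[-D])))
        if (bin[qi] && lab[qi] == 0L) {
          lab[qi] <- cur
          stack <- c(stack, pos_of[qi])
        }
      }
    }
  }
  lab
}

# local maxima under the connectivity convention; ties resolved by
# first-index order (a voxel equal to a neighbour counts as a maximum only
# if it precedes it in linear order)
.local_maxima <- function(x, mask) {
  dims <- dim(x)
  D <- length(dims)
  offs <- .neighbour_offsets(D)
  xm <- x
  xm[!mask] <- -Inf
  ismax <- mask
  n <- prod(dims)
  lin <- array(seq_len(n), dims)
  for (o in seq_len(nrow(offs))) {
    shifted <- .shift_array(xm, offs[o, ], fill = -Inf)
    shlin <- .shift_array(lin, offs[o, ], fill = 0L)
    ismax <- ismax & (xm > shifted |
                        (xm == shifted & lin < shlin & shlin > 0L))
  }
  which(ismax & is.finite(xm))
}

.shift_array <- function(x, by, fill) {
  dims <- dim(x)
  idx <- lapply(seq_along(dims), function(j) {
    i <- seq_len(dims[j]) - by[j]
    i
  })
  ok <- lapply(seq_along(dims), function(j)
    idx[[j]] >= 1L & idx[[j]] <= dims[j])
  out <- array(fill, dims)
  dst <- lapply(seq_along(dims), function(j) which(ok[[j]]))
  src <- lapply(seq_along(dims), function(j) idx[[j]][ok[[j]]])
  out_idx <- do.call(`[<-`, c(list(out), dst,
                              list(do.call(`[`, c(list(x), src,
                                                  list(drop = FALSE))))))
  out_idx
}

#' Topological inference report for a statistical map
#'
#' Thresholds the map at the cluster-forming level, finds suprathreshold
#' clusters (8-connectivity in 2D, 18-connectivity in 3D) and their local
#' maxima, and reports peak- and cluster-level FWER-corrected p-values
#' from random field theory, with the Bonferroni floor on peaks. The
#' search may be restricted to a window (small-volume correction): resels
#' are then recomputed on the restricted mask.
#'
#' @param img a [stat_image] with field metadata (from
#'   [compute_contrast]), or a bare array with `type`/`dof` supplied.
#' @param smoothness a `smoothness_estimate` from [estimate_smoothness].
#' @param alpha corrected significance level (default 0.05).
#' @param cluster_p uncorrected height p defining the cluster-forming
#'   threshold (default 0.001).
#' @param window optional logical array (same shape) restricting the
#'   search.
#' @param type,dof field metadata overrides.
#' @return data.frame of class `stat_results_table`, one row per local
#'   maximum: peak coordinates (voxel and physical), statistic value,
#'   `p_fwe_peak`, cluster extent `k`, `p_fwe_cluster`, uncorrected
#'   `p_unc`, and `significant` at `alpha`; sorted by `p_fwe_peak`.
#' @export
topological_report <- function(img, smoothness, alpha = 0.05,
                               cluster_p = 0.001, window = NULL,
                               type = NULL, dof = NULL) {
  if (inherits(img, "stat_image")) {
    x <- img$data
    if (is.null(type)) type <- img$field$type
    if (is.null(dof)) dof <- img$field$dof
    pixdim <- img$pixdim; origin <- img$origin
  } else {
    x <- img
    pixdim <- rep(1, length(dim(x))); origin <- rep(0, length(dim(x)))
  }
  if (is.null(type)) stop("field type metadata is required")
  dims <- dim(x)
  mask <- !is.na(x)
  if (!is.null(window)) {
    if (!identical(dim(window), dims))
      stop("window mask shape does not match the image")
    if (!any(window & mask))
      stop("window mask is disjoint from the analysis mask")
    mask <- mask & window
  }
  # resels on the (possibly restricted) mask: bounding box of the mask
  bb <- apply(arrayInd(which(mask), dims), 2, range)
  bdims <- bb[2, ] - bb[1, ] + 1L
  resels <- resel_counts(bdims, smoothness$fwhm, n_mask = sum(mask))
  n_vox <- sum(mask)
  # cluster-forming threshold at the uncorrected height p
  u_c <- switch(type,
    Gaussian = stats::qnorm(cluster_p, lower.tail = FALSE),
    t = stats::qt(cluster_p, dof[length(dof)], lower.tail = FALSE),
    F = stats::qf(cluster_p, dof[1], dof[2], lower.tail = FALSE))
  bin <- mask & !is.na(x) & x > u_c
  lab <- .label_components(array(bin, dims))
  peaks <- .local_maxima(array(ifelse(mask, x, NA), dims), array(bin, dims))
  if (length(peaks) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      statistic = numeric(0), p_fwe_peak = numeric(0),
                      k = integer(0), p_fwe_cluster = numeric(0),
                      p_unc = numeric(0), significant = logical(0))
    class(out) <- c("stat_results_table", class(out))
    attr(out, "threshold") <- u_c
    return(out)
  }
  ksize <- tabulate(lab)
  rows <- lapply(peaks, function(pk) {
    u <- x[pk]
    ci <- lab[pk]
    k <- ksize[ci]
    coord <- arrayInd(pk, dims)[1, ]
    phys <- origin + (coord - 1) * pixdim
    data.frame(x = phys[1], y = phys[2],
               z = if (length(dims) > 2) phys[3] else NA_real_,
               statistic = u,
               p_fwe_peak = rft_peak_p(u, type, dof, resels, n_vox),
               k = k,
               p_fwe_cluster = rft_cluster_p(k, u_c, type, dof, resels,
                                             smoothness$fwhm, n_vox),
               p_unc = ec_density(u, 0L, type, dof))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_fwe_peak < alpha
  out <- out[order(out$p_fwe_peak), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stat_results_table", class(out))
  attr(out, "threshold") <- u_c
  attr(out, "resels") <- resels
  out
}
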