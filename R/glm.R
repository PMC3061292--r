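# Mass-univariate general linear model over image voxels: standard designs,
# voxelwise least squares, and t / F contrast maps.

#' Build a standard design matrix
#'
#' @param kind one of `"one-sample"`, `"two-sample"`, `"paired"`.
#' @param n number of images (one-sample) or subjects (paired).
#' @param groups group sizes `c(n1, n2)` for the two-sample design.
#' @return list of class `design_matrix` with `X`, column `labels`, `kind`,
#'   rank, and residual degrees of freedom `df`.
#' @export
build_design <- function(kind = c("one-sample", "two-sample", "paired"),
                         n = NULL, groups = NULL) {
  kind <- match.arg(kind)
  X <- switch(kind,
    "one-sample" = {
      if (is.null(n) || n < 1) stop("one-sample design needs n >= 1")
      matrix(1, n, 1, dimnames = list(NULL, "mean"))
    },
    "two-sample" = {
      if (is.null(groups) || length(groups) != 2 || any(groups < 1))
        stop("two-sample design needs groups = c(n1, n2)")
      X <- matrix(0, sum(groups), 2,
                  dimnames = list(NULL, c("group1", "group2")))
      X[seq_len(groups[1]), 1] <- 1
      X[groups[1] + seq_len(groups[2]), 2] <- 1
      X
    },
    "paired" = {
      if (is.null(n) || n < 2) stop("paired design needs n >= 2 subjects")
      cond <- kronecker(diag(2), rep(1, n))
      subj <- rbind(diag(n), diag(n))
      colnames(cond) <- c("cond1", "cond2")
      colnames(subj) <- sprintf("subj%02d", seq_len(n))
      cbind(cond, subj)
    })
  r <- qr(X)$rank
  if (nrow(X) <= r)
    stop("design has no residual degrees of freedom (n <= rank)")
  structure(list(X = X, labels = colnames(X), kind = kind, rank = r,
                 df = nrow(X) - r),
            class = "design_matrix")
}

# images argument -> list(Y = n x V matrix, dims, pixdim, units, origin)
.images_to_matrix <- function(images) {
  if (is.character(images)) images <- lapply(images, read_stat_image)
  if (is.list(images)) {
    arrs <- lapply(images, function(im)
      if (inherits(im, "stat_image")) im$data else im)
    dims <- dim(arrs[[1]])
    if (!all(vapply(arrs, function(a) identical(dim(a), dims), logical(1))))
      stop("images differ in shape")
    meta <- if (inherits(images[[1]], "stat_image")) images[[1]] else NULL
    Y <- do.call(rbind, lapply(arrs, as.vector))
    list(Y = Y, dims = dims,
         pixdim = if (!is.null(meta)) meta$pixdim else rep(1, length(dims)),
         units = if (!is.null(meta)) meta$units else
           rep("voxel", length(dims)),
         origin = if (!is.null(meta)) meta$origin else rep(0, length(dims)))
  } else if (is.array(images) && length(dim(images)) >= 3) {
    # first dimension indexes images
    dm <- dim(images)
    Y <- matrix(images, nrow = dm[1])
    list(Y = Y, dims = dm[-1], pixdim = rep(1, length(dm) - 1),
         units = rep("voxel", length(dm) - 1), origin = rep(0, length(dm) - 1))
  } else stop("images must be a list of arrays/stat_images, paths, or an array")
}

#' Fit the GLM at every voxel
#'
#' Least-squares coefficients via the pseudoinverse (rank-deficient designs
#' allowed), residual variance `RSS / df`. Voxels missing (`NA`) in any
#' image are masked out of the analysis, so holes propagate.
#'
#' @param images one image per row of the design: a list of
#'   [stat_image]s/arrays, a character vector of NIfTI paths, or an array
#'   whose first dimension indexes images.
#' @param design a [build_design] result or a bare design matrix.
#' @return object of class `glm_model`: `beta` (p x V), `sigma2`, `df`,
#'   `mask`, standardized-ready `residuals` (n x V), design and image
#'   geometry metadata.
#' @export
fit_glm <- function(images, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  im <- .images_to_matrix(images)
  Y <- im$Y
  if (nrow(Y) != nrow(X))
    stop("number of images (", nrow(Y), ") does not match design rows (",
         nrow(X), ")")
  if (any(colSums(abs(X)) == 0)) stop("design contains an all-zero column")
  r <- qr(X)$rank
  df <- nrow(X) - r
  if (df < 1) stop("no residual degrees of freedom")
  mask <- colSums(is.na(Y)) == 0L
  Xp <- .pinv(X)
  beta <- matrix(NA_real_, ncol(X), ncol(Y))
  sigma2 <- rep(NA_real_, ncol(Y))
  res <- matrix(NA_real_, nrow(Y), ncol(Y))
  Ym <- Y[, mask, drop = FALSE]
  B <- Xp %*% Ym
  R <- Ym - X %*% B
  beta[, mask] <- B
  res[, mask] <- R
  sigma2[mask] <- colSums(R^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df, mask = mask,
                 residuals = res, X = X, rank = r, dims = im$dims,
                 pixdim = im$pixdim, units = im$units, origin = im$origin),
            class = "glm_model")
}

#' @export
print.glm_model <- function(x, ...) {
  cat("<glm_model> ", nrow(x$X), " images, ", ncol(x$X),
      " columns (rank ", x$rank, "), df ", x$df, "; ",
      sum(x$mask), "/", length(x$mask), " voxels in mask\n", sep = "")
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD
.pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Compute a t or F contrast map
#'
#' For a weight vector `c`, `t = c'b / sqrt(s2 * c' (X'X)^- c)` with the
#' generalized inverse. For a weight matrix (or to test a vector with an
#' F test), F is the extra sum of squares between the full model and the
#' model reduced by the contrast, on `(rank_full - rank_reduced, df)`
#' degrees of freedom. Contrasts must be estimable (lie in the row space
#' of the design).
#'
#' @param model a `glm_model` from [fit_glm].
#' @param contrast numeric vector (t) or matrix with one contrast per row
#'   (F) over design columns.
#' @param type `"t"` or `"F"`; defaults to `"t"` for vectors, `"F"` for
#'   matrices.
#' @return A [stat_image] with field metadata (type and degrees of
#'   freedom); masked voxels are `NA`.
#' @export
compute_contrast <- function(model, contrast, type = NULL) {
  C <- if (is.matrix(contrast)) contrast else matrix(contrast, nrow = 1)
  if (ncol(C) != ncol(model$X))
    stop("contrast length does not match design columns")
  if (all(C == 0)) stop("contrast must be non-zero")
  if (is.null(type)) type <- if (nrow(C) == 1) "t" else "F"
  type <- match.arg(type, c("t", "F"))
  X <- model$X
  # estimability: rows of C must lie in the row space of X
  Pr <- .pinv(X) %*% X
  if (max(abs(C - C %*% Pr)) > 1e-8 * max(1, max(abs(C))))
    stop("contrast is not estimable under this design")
  mask <- model$mask
  stat <- rep(NA_real_, length(mask))
  if (type == "t") {
    if (nrow(C) != 1) stop("t contrasts must be a single weight vector")
    cv <- as.vector(C)
    xtxinv <- .pinv(crossprod(X))
    se2 <- as.numeric(t(cv) %*% xtxinv %*% cv)
    cb <- as.vector(C %*% model$beta[, mask, drop = FALSE])
    stat[mask] <- cb / sqrt(model$sigma2[mask] * se2)
    dof <- c(1, model$df)
  } else {
    # reduced design: columns of X restricted to the null space of C
    N <- .null_basis(C)
    X0 <- if (ncol(N) > 0) X %*% N else matrix(0, nrow(X), 0)
    r0 <- if (ncol(X0) > 0) qr(X0)$rank else 0L
    df1 <- model$rank - r0
    if (df1 < 1) stop("contrast spans no testable dimension")
    Ym <- model$residuals[, mask, drop = FALSE] +
      X %*% model$beta[, mask, drop = FALSE]
    rss_full <- model$sigma2[mask] * model$df
    if (ncol(X0) > 0) {
      B0 <- .pinv(X0) %*% Ym
      R0 <- Ym - X0 %*% B0
    } else R0 <- Ym
    rss_red <- colSums(R0^2)
    stat[mask] <- (pmax(rss_red - rss_full, 0) / df1) /
      (rss_full / model$df)
    dof <- c(df1, model$df)
  }
  stat_image(array(stat, model$dims), pixdim = model$pixdim,
             units = model$units, origin = model$origin,
             field = list(type = type, dof = dof))
}

# orthonormal basis of the null space of C (rows = contrasts)
.null_basis <- function(C) {
  s <- svd(C, nv = ncol(C))
  tol <- max(dim(C)) * max(s$d, 0) * .Machine$double.eps
  rank <- sum(s$d > tol)
  if (rank >= ncol(C)) matrix(0, ncol(C), 0) else
    s$v[, (rank + 1):ncol(C), drop = FALSE]
}
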