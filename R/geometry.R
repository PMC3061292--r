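# Canonical surfaces, sensor layout projection, and rigid coregistration.

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z), in meters.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param closed logical; if `TRUE` the mesh is checked to be a closed
#'   genus-0 surface (Euler characteristic V - E + F = 2).
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, closed = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (!all(seq_len(nrow(vertices)) %in% faces))
    stop("mesh contains unreferenced vertices")
  if (closed) {
    e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    chi <- nrow(vertices) - nrow(e) + nrow(faces)
    if (chi != 2L)
      stop("mesh is not a closed genus-0 surface (Euler characteristic ",
           chi, ")")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Unit sphere by recursive icosahedral subdivision
#'
#' Starts from a regular icosahedron and subdivides each triangle into four,
#' deduplicating edge midpoints and projecting them back to the unit sphere.
#' Level 4 yields the 2562-vertex tessellation used for canonical
#' inner-skull, outer-skull and scalp surfaces.
#'
#' @param level non-negative integer subdivision depth; the result has
#'   `10 * 4^level + 2` vertices.
#' @return A closed [surface_mesh] with unit-radius vertices.
#' @export
#' @examples
#' m <- icosphere(2)
#' nrow(m$vertices)  # 162
icosphere <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0 ||
      level != round(level))
    stop("level must be a single non-negative integer")
  level <- as.integer(level)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    # midpoint index for each undirected edge, deduplicated via a keyed cache
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    ukey <- unique(key)
    mididx <- nv + match(key, ukey)
    ue <- edges[match(ukey, key), , drop = FALSE]
    mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  surface_mesh(v, f)
}

#' Project 3D sensor positions to a 2D layout disc
#'
#' Azimuthal-equidistant projection about the vertical apex of the head:
#' planar radius is proportional to the polar angle from the apex, azimuth
#' is preserved, and the result is scaled so the outermost sensor lies on
#' the unit circle (apex maps to the origin).
#'
#' @param positions numeric n x 3 matrix of sensor positions (meters).
#' @param center head center, default the origin.
#' @param channel_names optional names carried into the layout.
#' @return A [channel_layout] with one 2D position per sensor.
#' @export
project_to_layout <- function(positions, center = c(0, 0, 0),
                              channel_names = NULL) {
  positions <- as.matrix(positions)
  v <- sweep(positions, 2, center)
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-12)) stop("sensor coincident with head center")
  theta <- acos(pmin(1, pmax(-1, v[, 3] / r)))
  azim <- atan2(v[, 2], v[, 1])
  tmax <- max(theta)
  rho <- if (tmax > 0) theta / tmax else theta
  xy <- cbind(x = rho * cos(azim), y = rho * sin(azim))
  rownames(xy) <- channel_names
  channel_layout(xy)
}

# Kabsch/Procrustes core: least-squares rigid fit src -> dst (no scaling),
# reflection guarded so det(R) = +1 always.
.rigid_fit <- function(src, dst, check_collinear = TRUE) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  ps <- sweep(src, 2, cs)
  pd <- sweep(dst, 2, cd)
  if (check_collinear) {
    d <- svd(ps)$d
    if (d[2] <= 1e-10 * max(d[1], 1e-300))
      stop("points are collinear; rigid fit is not determined")
  }
  h <- crossprod(ps, pd)
  s <- svd(h)
  dsign <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  tr <- cd - as.vector(r %*% cs)
  res <- sweep(src %*% t(r), 2, tr, "+") - dst
  rigid_transform(r, tr, rms = sqrt(mean(rowSums(res^2))))
}

#' Construct a rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (meters).
#' @param rms optional residual RMS recorded by the fitting routine.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rms = NA_real_) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix must have determinant +1 (no reflections)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rms = rms),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> angle ", format(rotation_angle(x) * 180 / pi,
                                         digits = 4),
      " deg, |t| ", format(sqrt(sum(x$translation^2)), digits = 4), " m\n",
      sep = "")
  invisible(x)
}

#' Apply a rigid transform to a point set
#'
#' @param transform a [rigid_transform].
#' @param points n x 3 matrix.
#' @return Transformed n x 3 matrix `points %*% t(R) + t`.
#' @export
apply_transform <- function(transform, points) {
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Rotation angle of a rigid transform
#'
#' @param transform a [rigid_transform].
#' @return angle in radians.
#' @export
rotation_angle <- function(transform) {
  acos(pmin(1, pmax(-1, (sum(diag(transform$rotation)) - 1) / 2)))
}

#' Rigid landmark (fiducial) fit
#'
#' Least-squares rigid registration of matched named landmarks (e.g. nasion
#' and the two preauricular points) by the closed-form orthogonal Procrustes
#' solution, with the reflection branch excluded. At least three
#' non-collinear pairs are required.
#'
#' @param src,dst n x 3 matrices with matching rownames (landmark names), in
#'   the same row order or reorderable by name.
#' @return A [rigid_transform] mapping `src` onto `dst`; its `rms` element
#'   is the residual root-mean-square distance.
#' @export
landmark_fit <- function(src, dst) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  if (nrow(src) < 3L) stop("at least three landmark pairs are required")
  if (!is.null(rownames(src)) && !is.null(rownames(dst))) {
    if (!setequal(rownames(src), rownames(dst)))
      stop("landmark names do not match between src and dst")
    dst <- dst[rownames(src), , drop = FALSE]
  } else if (nrow(src) != nrow(dst)) {
    stop("landmark sets differ in size and carry no names to match by")
  }
  .rigid_fit(src, dst)
}

# brute-force nearest neighbour; fine for icosphere-scale targets
.nearest_index <- function(query, target) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(target))) -
    2 * query %*% t(target)
  d2 <- sweep(d2, 2, rowSums(target^2), "+")
  max.col(-d2, ties.method = "first")
}

#' Iterative closest point rigid alignment
#'
#' Aligns a point cloud (e.g. digitized head-shape points) to a target
#' surface or point set by alternating three phases: establish
#' point-to-nearest-vertex correspondence, estimate the rigid transform that
#' best maps the points onto their correspondents, and apply it. The
#' residual RMS is non-increasing across iterations; convergence is declared
#' when it changes by less than `tol`.
#'
#' @param points n x 3 matrix of points to align (meters).
#' @param target a [surface_mesh] or an m x 3 matrix of target points.
#' @param init initial [rigid_transform], typically from [landmark_fit].
#' @param tol convergence tolerance on the RMS change, meters.
#' @param max_iter iteration cap.
#' @return list with `transform` (cumulative [rigid_transform]), `rms`,
#'   `iterations`, `converged`, and the per-iteration `rms_trace`.
#' @export
icp_align <- function(points, target, init = rigid_transform(),
                      tol = 1e-6, max_iter = 50) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (nrow(points) < 3L) stop("at least three points are required")
  tv <- if (inherits(target, "surface_mesh")) target$vertices else
    as.matrix(target)
  cur <- init
  rms_trace <- numeric(0)
  rms_prev <- Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    moved <- apply_transform(cur, points)
    nn <- .nearest_index(moved, tv)
    cur <- .rigid_fit(points, tv[nn, , drop = FALSE])
    rms_trace <- c(rms_trace, cur$rms)
    if (is.finite(rms_prev) && abs(rms_prev - cur$rms) < tol) {
      converged <- TRUE
      break
    }
    rms_prev <- cur$rms
  }
  list(transform = cur, rms = cur$rms, iterations = iterations,
       converged = converged, rms_trace = rms_trace)
}
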