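#' Projected (x-y) area of a particle
#'
#' Area of the particle's projection onto the x-y plane: the union of its
#' voxel columns over z, times the pixel area `dx * dy`. Overlapping voxels
#' at different depths count once (union, not sum), matching what a 2D
#' transmitted-light measurement of the same particle would see.
#'
#' @param labels a `label_volume`.
#' @param particle_id particle label.
#' @return Area in square micrometres.
#' @export
projected_area <- function(labels, particle_id) {
  pc <- particle_index_ranges(labels, particle_id)
  sp <- labels$spacing
  d <- dim(labels$voxels)
  n_cells <- length(unique(pc$y + as.double(d[2L]) * pc$x))
  n_cells * sp[["dx"]] * sp[["dy"]]
}

# logical (y, x) projection matrix of one particle, cropped to its bbox
particle_projection <- function(labels, particle_id) {
  pc <- particle_index_ranges(labels, particle_id)
  y <- pc$y - min(pc$y)
  x <- pc$x - min(pc$x)
  m <- matrix(FALSE, max(y) + 1L, max(x) + 1L)
  m[cbind(y + 1L, x + 1L)] <- TRUE
  m
}

#' Axis-aligned bounding-box extents of a particle
#'
#' Extents in micrometres along the screen axes (index span + 1 voxel,
#' times spacing): this mirrors on-screen manual measurement, so the box
#' is axis-aligned, not oriented, and in-plane rotation of an elongated
#' particle changes (L, W). L and W are the in-plane extents sorted so
#' L >= W; D is the axial (z) extent.
#'
#' @param labels a `label_volume`.
#' @param particle_id particle label.
#' @return Named numeric vector `c(L, W, D)` in micrometres.
#' @export
bounding_box_extents <- function(labels, particle_id) {
  pc <- particle_index_ranges(labels, particle_id)
  sp <- labels$spacing
  ex <- (max(pc$x) - min(pc$x) + 1L) * sp[["dx"]]
  ey <- (max(pc$y) - min(pc$y) + 1L) * sp[["dy"]]
  ez <- (max(pc$z) - min(pc$z) + 1L) * sp[["dz"]]
  c(L = max(ex, ey), W = min(ex, ey), D = ez)
}

#' Manual length x width x depth volume estimate
#'
#' The crude manual estimate used at the microscope: length and width read
#' off the image, depth from focusing through the axial planes, multiplied
#' together. It treats the particle as a filled box, so it always
#' overestimates the rendered volume (by a factor of roughly 2.4-3.9 for
#' real charcoal fragments).
#'
#' @param L,W,D extents in micrometres, all positive.
#' @return Volume in cubic micrometres.
#' @export
manual_volume_estimate <- function(L, W, D) {
  if (any(c(L, W, D) <= 0)) stop("extents must be positive", call. = FALSE)
  L * W * D
}

#' Ellipsoid-equivalent principal semi-axes
#'
#' Eigen-decomposition of the covariance of the particle's voxel-centre
#' coordinates (physical micrometres, uniform weights). Semi-axes are
#' `sqrt(5 * eigenvalue)`, descending: a uniform solid ellipsoid with
#' these semi-axes has the same second moments as the particle. Degenerate
#' (coplanar or collinear) particles are reported with the affected axes
#' clamped to half the corresponding spacing and flagged via the
#' `degenerate` attribute.
#'
#' @param labels a `label_volume`.
#' @param particle_id particle label.
#' @return Named numeric vector `c(a, b, c)` in micrometres, `a >= b >= c`.
#' @export
principal_semi_axes <- function(labels, particle_id) {
  pc <- particle_index_ranges(labels, particle_id)
  sp <- labels$spacing
  P <- cbind(pc$x * sp[["dx"]], pc$y * sp[["dy"]], pc$z * sp[["dz"]])
  n <- nrow(P)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  S <- crossprod(Pc) / n  # population second moments
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ax <- sqrt(5 * pmax(ev, 0))
  floor_c <- min(unclass(sp)) / 2
  degenerate <- n < 4L || any(ax <= floor_c * 1e-8)
  ax <- pmax(ax, c(sp[["dx"]], sp[["dy"]], sp[["dz"]])[order(-ev)] / 2)
  ax <- sort(ax, decreasing = TRUE)
  structure(c(a = ax[1L], b = ax[2L], c = ax[3L]), degenerate = degenerate)
}

#' Classify particle shape from its semi-axes
#'
#' Relative differences of consecutive semi-axes against a tolerance
#' `tol`: `sphere` if both (a-b)/a and (b-c)/b are below `tol`; `oblate`
#' (flattened: a ~ b >> c) if only the first is; `prolate` (elongated:
#' a >> b ~ c) if only the second is; otherwise `triaxial`.
#'
#' @param a,b,c semi-axes in micrometres, `a >= b >= c > 0`.
#' @param tol relative tolerance in (0, 1); default 0.2.
#' @return One of `"sphere"`, `"oblate"`, `"prolate"`, `"triaxial"`.
#' @export
shape_class <- function(a, b, c, tol = 0.2) {
  if (!(a >= b && b >= c && c > 0)) {
    stop("semi-axes must satisfy a >= b >= c > 0", call. = FALSE)
  }
  if (!(tol > 0 && tol < 1)) stop("tol must be in (0, 1)", call. = FALSE)
  flat_ab <- (a - b) / a < tol
  flat_bc <- (b - c) / b < tol
  if (flat_ab && flat_bc) "sphere"
  else if (flat_ab) "oblate"
  else if (flat_bc) "prolate"
  else "triaxial"
}

#' Circularity of a particle's x-y projection
#'
#' `4 * pi * A / P^2` with A the projected area and P the length of the
#' projection outline, measured by linear-interpolated marching squares on
#' a lightly smoothed copy of the projection (a raw binary contour carries
#' staircase facets that inflate P by several percent). 1 for a circle,
#' much smaller for elongated outlines; discretisation can push values
#' marginally above 1 for large near-circular projections.
#'
#' @param labels a `label_volume`.
#' @param particle_id particle label.
#' @param smooth_sigma Gaussian sigma (pixels) for the contour field.
#' @return Dimensionless circularity.
#' @export
circularity <- function(labels, particle_id, smooth_sigma = 0.85) {
  sp <- labels$spacing
  A <- projected_area(labels, particle_id)
  m <- particle_projection(labels, particle_id)
  P <- projection_perimeter(m, sp[["dx"]], sp[["dy"]], smooth_sigma)
  4 * pi * A / P^2
}

# Marching-squares contour length of a binary (y, x) matrix, in um.
projection_perimeter <- function(m, dx, dy, smooth_sigma = 0.85) {
  pad <- 1L + if (smooth_sigma > 0) max(1L, ceiling(2.5 * smooth_sigma)) else 0L
  f <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  f[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- as.numeric(m)
  if (smooth_sigma > 0) {
    a <- array(f, dim = c(1L, dim(f)))
    a <- gaussian_smooth3(a, c(0, smooth_sigma, smooth_sigma))
    sm <- a[1L, , ]
    # one-pixel-wide outlines nearly vanish under smoothing; keep the raw
    # binary contour for those
    if (max(sm[f > 0.5]) >= 0.75) f <- sm
  }
  level <- 0.5
  ny <- nrow(f); nx <- ncol(f)
  # cell corners: tl = f[i, j], tr = f[i, j+1], bl = f[i+1, j], br = f[i+1, j+1]
  tl <- f[-ny, -nx]; tr <- f[-ny, -1L]; bl <- f[-1L, -nx]; br <- f[-1L, -1L]
  inl <- (tl >= level) + 2L * (tr >= level) + 4L * (bl >= level) +
    8L * (br >= level)
  mixed <- which(inl != 0L & inl != 15L)
  if (!length(mixed)) return(0)
  total <- 0
  for (ci in mixed) {
    i <- (ci - 1L) %% (ny - 1L) + 1L
    j <- (ci - 1L) %/% (ny - 1L) + 1L
    v <- c(f[i, j], f[i, j + 1L], f[i + 1L, j + 1L], f[i + 1L, j])  # cw
    # corner coords (x, y) in um; x along columns, y along rows (0-based)
    px <- c(j - 1L, j, j, j - 1L) * dx
    py <- c(i - 1L, i - 1L, i, i) * dy
    pts <- NULL
    for (e in 1:4) {
      a <- e
      b <- if (e == 4L) 1L else e + 1L
      if ((v[a] >= level) != (v[b] >= level)) {
        t <- (level - v[a]) / (v[b] - v[a])
        pts <- rbind(pts, c(px[a] + t * (px[b] - px[a]),
                            py[a] + t * (py[b] - py[a]), e))
      }
    }
    if (is.null(pts)) next
    if (nrow(pts) == 2L) {
      total <- total + sqrt(sum((pts[1L, 1:2] - pts[2L, 1:2])^2))
    } else if (nrow(pts) == 4L) {
      # saddle: resolve by the cell-centre value
      centre_in <- mean(v) >= level
      corner1_in <- v[1L] >= level
      # edges ordered 1..4 (top, right, bottom, left)
      if (centre_in == corner1_in) {
        pairs <- list(c(4L, 1L), c(2L, 3L))
      } else {
        pairs <- list(c(1L, 2L), c(3L, 4L))
      }
      for (pr in pairs) {
        p1 <- pts[pts[, 3L] == pr[1L], 1:2]
        p2 <- pts[pts[, 3L] == pr[2L], 1:2]
        total <- total + sqrt(sum((p1 - p2)^2))
      }
    }
  }
  total
}

#' Length-width aspect ratio
#'
#' @param L,W in-plane extents in micrometres, `L >= W > 0`.
#' @return `L / W` (>= 1).
#' @export
aspect_ratio <- function(L, W) {
  if (!(L >= W && W > 0)) stop("require L >= W > 0", call. = FALSE)
  L / W
}

#' Full morphometric record for one particle
#'
#' Combines the mesh surface statistics with projected area, bounding-box
#' extents, the manual L x W x D estimate, ellipsoid-equivalent semi-axes,
#' shape class, circularity and aspect ratio into one row.
#'
#' @param labels a `label_volume`.
#' @param particle_id particle label.
#' @param mesh_stats optional precomputed [mesh_statistics()] list; when
#'   `NULL` the surface is extracted here.
#' @param shape_tol tolerance for [shape_class()].
#' @param smooth_sigma isosurface smoothing, see [extract_surface()].
#' @return A one-row data.frame (see [write_morphometrics_table()] for the
#'   column contract).
#' @export
measure_particle <- function(labels, particle_id, mesh_stats = NULL,
                             shape_tol = 0.2, smooth_sigma = 0.85) {
  if (is.null(mesh_stats)) {
    mesh_stats <- mesh_statistics(
      extract_surface(labels, particle_id, smooth_sigma = smooth_sigma))
  }
  ext <- bounding_box_extents(labels, particle_id)
  ax <- principal_semi_axes(labels, particle_id)
  nvox <- length(particle_index_ranges(labels, particle_id)$z)
  data.frame(
    particle_id = particle_id,
    volume_um3 = mesh_stats$enclosed_volume,
    surface_area_um2 = mesh_stats$surface_area,
    projected_area_um2 = projected_area(labels, particle_id),
    bbox_length_um = ext[["L"]],
    bbox_width_um = ext[["W"]],
    bbox_depth_um = ext[["D"]],
    semi_a_um = ax[["a"]],
    semi_b_um = ax[["b"]],
    semi_c_um = ax[["c"]],
    shape_class = shape_class(ax[["a"]], ax[["b"]], ax[["c"]],
                              tol = shape_tol),
    circularity = circularity(labels, particle_id),
    aspect_ratio = aspect_ratio(ext[["L"]], ext[["W"]]),
    manual_volume_um3 = manual_volume_estimate(ext[["L"]], ext[["W"]],
                                               ext[["D"]]),
    voxel_volume_um3 = nvox * voxel_volume_um3(labels$spacing),
    n_voxels = nvox,
    n_triangles = mesh_stats$n_triangles,
    border_flag = labels$border_flags[particle_id],
    degenerate_axes = isTRUE(attr(ax, "degenerate")),
    stringsAsFactors = FALSE
  )
}

#' Measure every particle in a label volume
#'
#' @param labels a `label_volume`.
#' @param shape_tol,smooth_sigma see [measure_particle()].
#' @return A data.frame with one row per particle.
#' @export
measure_all_particles <- function(labels, shape_tol = 0.2,
                                  smooth_sigma = 0.85) {
  if (labels$n_particles == 0L) {
    return(read_morphometrics_table(write_morphometrics_table(
      NULL, tempfile(fileext = ".csv"))))
  }
  do.call(rbind, lapply(seq_len(labels$n_particles), function(id) {
    measure_particle(labels, id, shape_tol = shape_tol,
                     smooth_sigma = smooth_sigma)
  }))
}
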