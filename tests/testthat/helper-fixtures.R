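# Shared in-code fixtures: small digitized solids and assemblages.

mask_from_array <- function(arr, spacing = voxel_spacing(1, 1, 1)) {
  structure(list(voxels = arr, spacing = spacing), class = "binary_mask")
}

labels_from_array <- function(arr, spacing = voxel_spacing(1, 1, 1),
                              connectivity = 26L) {
  label_particles(mask_from_array(arr, spacing), connectivity)
}

# solid axis-aligned block of given voxel extents inside a padded stack
block_array <- function(nz, ny, nx, pad = 2L) {
  arr <- array(FALSE, c(nz + 2L * pad, ny + 2L * pad, nx + 2L * pad))
  arr[pad + seq_len(nz), pad + seq_len(ny), pad + seq_len(nx)] <- TRUE
  arr
}

# digitized ball of radius r_um, voxel centres inside the sphere
sphere_labels <- function(r_um, spacing = voxel_spacing(1, 1, 1),
                          pad = 3L) {
  step <- c(spacing[["dx"]], spacing[["dy"]], spacing[["dz"]])
  nd <- ceiling(r_um / step) + pad
  nx <- 2L * nd[1L] + 1L
  ny <- 2L * nd[2L] + 1L
  nz <- 2L * nd[3L] + 1L
  x <- (0:(nx - 1L)) * step[1L]
  y <- (0:(ny - 1L)) * step[2L]
  z <- (0:(nz - 1L)) * step[3L]
  ctr <- c(x[nd[1L] + 1L], y[nd[2L] + 1L], z[nd[3L] + 1L])
  arr <- array(FALSE, c(nz, ny, nx))
  for (ix in seq_len(nx)) {
    dx2 <- (x[ix] - ctr[1L])^2
    for (iy in seq_len(ny)) {
      d2 <- dx2 + (y[iy] - ctr[2L])^2
      arr[, iy, ix] <- d2 + (z - ctr[3L])^2 <= r_um^2
    }
  }
  labels_from_array(arr, spacing)
}

# digitized solid ellipsoid (axis-aligned or rotated about z)
ellipsoid_labels <- function(axes_um, spacing = voxel_spacing(1, 1, 1),
                             angle_z = 0, pad = 3L) {
  rot <- matrix(c(cos(angle_z), sin(angle_z), 0,
                  -sin(angle_z), cos(angle_z), 0,
                  0, 0, 1), 3L, 3L)
  h <- sqrt(diag(rot %*% diag(axes_um^2) %*% t(rot)))
  step <- c(spacing[["dx"]], spacing[["dy"]], spacing[["dz"]])
  nd <- ceiling(h / step) + pad
  dims <- c(2L * nd[3L] + 1L, 2L * nd[2L] + 1L, 2L * nd[1L] + 1L)
  stk <- intensity_stack(array(0, dims), spacing, bit_depth = 8L)
  ctr <- c(nd[1L] * step[1L], nd[2L] * step[2L], nd[3L] * step[3L])
  stk <- render_ellipsoid(stk, ctr, axes_um, rot, intensity = 200)
  label_particles(binarize(stk, 100))
}

# small fast assemblage at coarse spacing (keeps stacks tiny); any
# generator_params() argument can be overridden through ...
small_assemblage_params <- function(n = 10L, seed = 11L, ...) {
  args <- list(n_particles = n, spacing = voxel_spacing(10, 10, 10),
               volume_median_um3 = 1e6, depth_um = 300, seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(generator_params, args)
}

# unit cube as a hand-built 12-triangle mesh (edge length s, corner at org)
unit_cube_mesh <- function(s = 1, org = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
  v <- sweep(v, 2L, org, `+`)
  # triangles with outward orientation, vertex ids per expand.grid order
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = s face (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = s (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = s (+x)
  triangle_mesh(v, tr, particle_id = 1L)
}

# geodesic sphere of radius r: subdivided octahedron projected to the
# sphere, triangles oriented outward
geodesic_sphere_mesh <- function(r = 10, subdiv = 4L) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (it in seq_len(subdiv)) {
    mid <- new.env()
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c_ <- f[k, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      f2[4L * k - 3:0, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                  c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  f <- orient_outward(v, f, c(0, 0, 0))
  triangle_mesh(r * v, f, particle_id = 1L)
}

# flip triangles whose normal points toward `centre` (valid for shapes
# star-shaped about that point)
orient_outward <- function(v, f, centre) {
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1L], ]; b <- v[f[k, 2L], ]; c_ <- v[f[k, 3L], ]
    n <- c((b - a)[2L] * (c_ - a)[3L] - (b - a)[3L] * (c_ - a)[2L],
           (b - a)[3L] * (c_ - a)[1L] - (b - a)[1L] * (c_ - a)[3L],
           (b - a)[1L] * (c_ - a)[2L] - (b - a)[2L] * (c_ - a)[1L])
    if (sum(n * ((a + b + c_) / 3 - centre)) < 0) {
      f[k, ] <- f[k, c(1L, 3L, 2L)]
    }
  }
  f
}

# tie-corrected Kruskal-Wallis H computed directly from rank sums:
# the brute-force oracle for compare_groups()
kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  rk <- rank(x)
  Rj <- vapply(split(rk, rep(seq_along(groups), n)), sum, numeric(1L))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}
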