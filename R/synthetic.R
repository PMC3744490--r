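#' Parameters for the synthetic assemblage generator
#'
#' Defaults emulate a mesofossil charcoal slide imaged in reflectance
#' mode with the 10x preset: anisotropic voxels of
#' 2.768 x 2.768 x 5 um, a 150 um deep stack (slide preparations run
#' roughly 40-215 um), 100 sparse non-touching particles, lognormal
#' volumes with median 1227426 um^3 and sigma_log 0.8 (a Cretaceous
#' mesofossil-like distribution: its mean/median ratio ~1.35 implies
#' sigma ~0.78), and predominantly oblate shapes - flattened spheres with
#' near-circular plan (b/a in \[0.85, 1\]) and thickness ratio c/b in
#' \[0.15, 0.5\]. Particles settle flat by default (`orientation =
#' "flat"`: random in-plane rotation about z), as slide-mounted platy
#' particles do; `"random"` draws full 3D rotations, `"axis-aligned"`
#' none. Foreground/background intensities 200/10 on an 8-bit range with
#' Gaussian noise SD 5 mimic the bright-particle/dark-background contrast
#' of reflectance imaging. `shape = NULL` auto-sizes the x-y field so
#' that particle bounding boxes occupy at most `max_footprint_frac` of
#' the stack area. Volume draws whose particle would be thicker than the
#' stack depth are redrawn: the lognormal is truncated to particles that
#' physically fit the preparation.
#'
#' @param n_particles number of particles.
#' @param spacing a [voxel_spacing()].
#' @param volume_median_um3,volume_sigma_log lognormal volume distribution.
#' @param axis_ratio_b_a,axis_ratio_c_b uniform ranges for the semi-axis
#'   ratios b/a and c/b.
#' @param orientation `"flat"`, `"random"` or `"axis-aligned"`.
#' @param foreground,background mean intensities.
#' @param noise_sd Gaussian noise SD (0 disables).
#' @param bit_depth intensity bit depth.
#' @param bottom_reflection add a bright artifact sheet on the deepest
#'   slice.
#' @param shape `c(slices, height, width)` or `NULL` to auto-size.
#' @param depth_um stack depth when auto-sizing.
#' @param max_footprint_frac packing feasibility bound: total particle
#'   bounding-box footprint must stay below this fraction of stack area.
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_particles = 100L,
                             spacing = spacing_mesofossil(),
                             volume_median_um3 = 1227426,
                             volume_sigma_log = 0.8,
                             axis_ratio_b_a = c(0.85, 1),
                             axis_ratio_c_b = c(0.15, 0.5),
                             orientation = c("flat", "random",
                                             "axis-aligned"),
                             foreground = 200, background = 10,
                             noise_sd = 5, bit_depth = 8L,
                             bottom_reflection = FALSE,
                             shape = NULL, depth_um = 150,
                             max_footprint_frac = 0.3, seed = 1L) {
  orientation <- match.arg(orientation)
  structure(list(n_particles = as.integer(n_particles),
                 spacing = as_spacing(spacing),
                 volume_median_um3 = volume_median_um3,
                 volume_sigma_log = volume_sigma_log,
                 axis_ratio_b_a = axis_ratio_b_a,
                 axis_ratio_c_b = axis_ratio_c_b,
                 orientation = orientation,
                 foreground = foreground, background = background,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 bottom_reflection = isTRUE(bottom_reflection),
                 shape = shape, depth_um = depth_um,
                 max_footprint_frac = max_footprint_frac,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# rotation matrix: columns are the ellipsoid axes in lab frame
rotation_for <- function(orientation) {
  if (orientation == "axis-aligned") return(diag(3))
  if (orientation == "flat") {
    th <- runif(1, 0, 2 * pi)
    return(matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                  3, 3))
  }
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# half-extents of a rotated ellipsoid along the lab axes (support function)
ellipsoid_half_extents <- function(axes, R) {
  M <- R %*% diag(axes^2) %*% t(R)
  sqrt(pmax(diag(M), 0))
}

# Thomsen's approximation to the ellipsoid surface area (max error ~1.06%)
ellipsoid_surface_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Render a solid ellipsoid into an intensity stack
#'
#' Sets every voxel whose centre falls inside the rotated ellipsoid
#' (physical coordinates, anisotropic spacing respected) to `intensity`.
#' An ellipsoid thinner than half a z step (`c < dz/2`) could miss every
#' voxel-centre plane; such degenerate particles are rendered one voxel
#' thick on the nearest slice over their footprint and flagged via the
#' `degenerate` attribute.
#'
#' @param stack an [intensity_stack()].
#' @param center_um ellipsoid centre `(x, y, z)` in micrometres.
#' @param semi_axes `(a, b, c)` in micrometres.
#' @param rotation 3x3 rotation matrix (columns = ellipsoid axes in lab
#'   frame), or `NULL` for axis-aligned.
#' @param intensity voxel value to write.
#' @return The modified stack (attribute `degenerate` set when the
#'   one-voxel floor was applied).
#' @export
render_ellipsoid <- function(stack, center_um, semi_axes, rotation = NULL,
                             intensity = 200) {
  stopifnot(inherits(stack, "intensity_stack"))
  sel <- ellipsoid_voxel_sel(dim(stack$voxels), stack$spacing, center_um,
                             semi_axes, rotation)
  stack$voxels[sel] <- intensity
  if (isTRUE(attr(sel, "degenerate"))) attr(stack, "degenerate") <- TRUE
  stack
}

# (z, y, x) 1-based index matrix of the voxels inside a rotated ellipsoid
ellipsoid_voxel_sel <- function(d, sp, center_um, semi_axes,
                                rotation = NULL) {
  if (is.null(rotation)) rotation <- diag(3)
  h <- ellipsoid_half_extents(semi_axes, rotation)
  lo <- center_um - h
  hi <- center_um + h
  step <- c(sp[["dx"]], sp[["dy"]], sp[["dz"]])
  lims <- c((d[3L] - 1L) * step[1L], (d[2L] - 1L) * step[2L],
            (d[1L] - 1L) * step[3L])
  if (any(lo < -step / 2 + 1e-9) || any(hi > lims + step / 2 - 1e-9)) {
    stop("ellipsoid does not fit inside the stack", call. = FALSE)
  }
  i_lo <- pmax(0, floor(lo / step))
  i_hi <- pmin(c(d[3L], d[2L], d[1L]) - 1, ceiling(hi / step))
  ix <- i_lo[1L]:i_hi[1L]
  iy <- i_lo[2L]:i_hi[2L]
  iz <- i_lo[3L]:i_hi[3L]
  if (semi_axes[3L] < step[3L] / 2) {
    # degenerate thin particle: one-voxel-thick floor on the nearest slice
    z_near <- round(center_um[3L] / step[3L])
    g <- expand.grid(x = ix, y = iy)
    q <- t(rotation) %*% rbind(g$x * step[1L] - center_um[1L],
                               g$y * step[2L] - center_um[2L], 0)
    inside <- (q[1L, ] / semi_axes[1L])^2 +
      (q[2L, ] / semi_axes[2L])^2 <= 1
    sel <- cbind(z_near + 1L, g$y[inside] + 1L, g$x[inside] + 1L)
    attr(sel, "degenerate") <- TRUE
    return(sel)
  }
  g <- expand.grid(x = ix, y = iy, z = iz)
  p <- rbind(g$x * step[1L] - center_um[1L],
             g$y * step[2L] - center_um[2L],
             g$z * step[3L] - center_um[3L])
  q <- t(rotation) %*% p
  inside <- (q[1L, ] / semi_axes[1L])^2 + (q[2L, ] / semi_axes[2L])^2 +
    (q[3L, ] / semi_axes[3L])^2 <= 1
  cbind(g$z[inside] + 1L, g$y[inside] + 1L, g$x[inside] + 1L)
}

#' Add clipped Gaussian noise to a stack
#'
#' Additive, i.i.d., rounded to integers and clipped to the bit-depth
#' range; deterministic per seed. `sd = 0` is the identity.
#'
#' @param stack an [intensity_stack()].
#' @param sd noise standard deviation.
#' @param seed integer seed.
#' @return The noisy stack.
#' @export
add_noise <- function(stack, sd, seed = 1L) {
  stopifnot(inherits(stack, "intensity_stack"), sd >= 0)
  if (sd == 0) return(stack)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  vmax <- 2^stack$bit_depth - 1
  v <- stack$voxels + rnorm(length(stack$voxels), 0, sd)
  stack$voxels <- array(pmin(pmax(round(v), 0), vmax), dim(stack$voxels))
  stack
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a ground-truthed synthetic assemblage
#'
#' Draws per-particle volumes and axis ratios, converts them to ellipsoid
#' semi-axes, places the particles without contact (their one-voxel-padded
#' bounding boxes are kept disjoint, so rendered particles cannot touch
#' even under 26-connectivity), renders them into a reflectance-like
#' stack, and adds noise. Placement proceeds largest-first by bounded
#' rejection sampling; if a particle cannot be placed the generation
#' aborts, reporting the achieved count. Fully deterministic per seed.
#'
#' @param params a [generator_params()].
#' @return A list: `stack` (an [intensity_stack()]) and `truth`, a
#'   data.frame with one row per particle: id, centre (um), semi-axes
#'   (um), orientation angle/matrix hash, analytic volume `4/3 pi a b c`
#'   (um^3) and analytic surface area (Thomsen approximation, p = 1.6075,
#'   um^2).
#' @export
generate_assemblage <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(params$seed)
  sp <- params$spacing
  n <- params$n_particles
  step <- c(sp[["dx"]], sp[["dy"]], sp[["dz"]])

  # depth available for particle thickness when the stack is auto-sized
  depth_avail <- if (is.null(params$shape)) {
    params$depth_um
  } else {
    (params$shape[1L] - 1L) * sp[["dz"]]
  }
  # particle thickness is truncated to what physically fits the slide
  # depth: particles thicker than the preparation cannot occur, so draws
  # that do not fit are redrawn
  a <- b <- cc <- hx <- hy <- hz <- numeric(n)
  rots <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      vol <- rlnorm(1, log(params$volume_median_um3),
                    params$volume_sigma_log)
      r1 <- runif(1, params$axis_ratio_b_a[1L], params$axis_ratio_b_a[2L])
      r2 <- runif(1, params$axis_ratio_c_b[1L], params$axis_ratio_c_b[2L])
      ai <- (3 * vol / (4 * pi * r1^2 * r2))^(1 / 3)
      rot <- rotation_for(params$orientation)
      h <- ellipsoid_half_extents(c(ai, r1 * ai, r2 * r1 * ai), rot)
      if (2 * h[3L] + 4 * sp[["dz"]] <= depth_avail) {
        a[i] <- ai
        b[i] <- r1 * ai
        cc[i] <- r2 * r1 * ai
        rots[[i]] <- rot
        hx[i] <- h[1L]; hy[i] <- h[2L]; hz[i] <- h[3L]
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not draw a particle fitting the stack depth (",
           depth_avail, " um); placed ", i - 1L, " of ", n, call. = FALSE)
    }
  }
  vols <- 4 / 3 * pi * a * b * cc

  if (is.null(params$shape)) {
    nz <- max(3L, ceiling(params$depth_um / sp[["dz"]]))
    need <- sum(4 * (hx + step[1L]) * (hy + step[2L])) /
      params$max_footprint_frac
    side_um <- max(sqrt(max(need, 1)), 2 * max(hx, 0) + 4 * step[1L],
                   2 * max(hy, 0) + 4 * step[2L], 20 * step[1L])
    shape <- c(nz, ceiling(side_um / sp[["dy"]]) + 1L,
               ceiling(side_um / sp[["dx"]]) + 1L)
  } else {
    shape <- params$shape
    footprint <- sum(4 * (hx + step[1L]) * (hy + step[2L]))
    area <- (shape[2L] * sp[["dy"]]) * (shape[3L] * sp[["dx"]])
    if (n > 0 && footprint > params$max_footprint_frac * area) {
      stop("infeasible packing: particle footprint ",
           round(footprint), " um^2 exceeds ",
           params$max_footprint_frac * 100, "% of stack area", call. = FALSE)
    }
  }
  lims <- c((shape[3L] - 1L) * step[1L], (shape[2L] - 1L) * step[2L],
            (shape[1L] - 1L) * step[3L])
  if (n > 0 && any(2 * hz + 3 * step[3L] > lims[3L])) {
    stop("stack too shallow for the thickest particle", call. = FALSE)
  }

  # place largest-footprint first; keep padded bounding boxes disjoint
  ord <- if (n > 0) order(-(hx * hy)) else integer(0)
  centers <- matrix(NA_real_, n, 3L)
  placed <- matrix(numeric(0), 0L, 6L)  # xlo xhi ylo yhi zlo zhi (padded)
  margin <- 1.5 * step
  for (i in ord) {
    h <- c(hx[i], hy[i], hz[i])
    ok <- FALSE
    for (try in seq_len(500L)) {
      ctr <- runif(3, h + margin, lims - h - margin)
      box <- c(ctr[1L] - h[1L] - margin[1L], ctr[1L] + h[1L] + margin[1L],
               ctr[2L] - h[2L] - margin[2L], ctr[2L] + h[2L] + margin[2L],
               ctr[3L] - h[3L] - margin[3L], ctr[3L] + h[3L] + margin[3L])
      if (nrow(placed) == 0L ||
          !any(box[1L] < placed[, 2L] & box[2L] > placed[, 1L] &
               box[3L] < placed[, 4L] & box[4L] > placed[, 3L] &
               box[5L] < placed[, 6L] & box[6L] > placed[, 5L])) {
        centers[i, ] <- ctr
        placed <- rbind(placed, box)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place particle after 500 attempts; placed ",
           nrow(placed), " of ", n, " - enlarge the stack or reduce n",
           call. = FALSE)
    }
  }

  vox <- array(as.numeric(params$background), dim = shape)
  for (i in seq_len(n)) {
    sel <- ellipsoid_voxel_sel(shape, sp, centers[i, ],
                               c(a[i], b[i], cc[i]), rots[[i]])
    vox[sel] <- params$foreground
  }
  if (params$bottom_reflection) {
    vox[shape[1L], , ] <- params$foreground
  }
  if (params$noise_sd > 0) {
    set.seed(params$seed + 1000003L)
    vmax <- 2^params$bit_depth - 1
    # slice-wise to bound peak memory on large stacks
    for (iz in seq_len(shape[1L])) {
      pl <- vox[iz, , ] + rnorm(shape[2L] * shape[3L], 0, params$noise_sd)
      vox[iz, , ] <- pmin(pmax(round(pl), 0), vmax)
    }
  }
  stack <- intensity_stack(vox, sp, bit_depth = params$bit_depth)
  truth <- data.frame(
    particle_id = seq_len(n),
    center_x_um = centers[, 1L], center_y_um = centers[, 2L],
    center_z_um = centers[, 3L],
    semi_a_um = a, semi_b_um = b, semi_c_um = cc,
    volume_um3 = 4 / 3 * pi * a * b * cc,
    surface_area_um2 = ellipsoid_surface_area(a, b, cc),
    oblateness_b_c = ifelse(b > 0, (b - cc) / b, NA_real_)
  )
  if (n > 0) {
    truth$rotation <- I(rots)
  }
  list(stack = stack, truth = truth)
}
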