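#' Threshold a reflectance stack into a binary particle mask
#'
#' Charcoal is opaque and highly reflective, so particles are bright on a
#' dark background. A voxel is foreground iff its intensity is greater than
#' or equal to the threshold. `threshold = "auto"` computes a two-class
#' threshold on the intensity histogram by maximising the between-class
#' variance (Otsu's criterion) and records the value used in the
#' `threshold_used` attribute of the result.
#'
#' @param stack an [intensity_stack()].
#' @param threshold `"auto"` or a fixed numeric intensity.
#' @return A `binary_mask` object (logical array + spacing), with
#'   attribute `threshold_used`.
#' @export
binarize <- function(stack, threshold = "auto") {
  stopifnot(inherits(stack, "intensity_stack"))
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(stack$voxels, stack$bit_depth,
                          stack_name = deparse(substitute(stack)))
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    thr <- threshold
  }
  m <- stack$voxels >= thr
  structure(list(voxels = m, spacing = stack$spacing),
            class = "binary_mask", threshold_used = thr)
}

# Two-class inter-class-variance histogram split on integer intensities.
# Returns the lowest foreground intensity: voxels >= value are foreground.
otsu_threshold <- function(voxels, bit_depth, stack_name = "stack") {
  v <- as.integer(round(voxels))
  h <- as.numeric(tabulate(v + 1L, nbins = 2^bit_depth))
  if (sum(h > 0L) < 2L) {
    stop("automatic threshold failed: '", stack_name,
         "' has constant intensity (no two-class histogram split exists)",
         call. = FALSE)
  }
  n <- sum(h)
  lev <- seq_along(h) - 1  # intensity levels 0 .. 2^bit - 1
  w0 <- cumsum(h)                     # class 0: levels <= t
  mu0 <- cumsum(h * lev)
  muT <- mu0[length(mu0)]
  w1 <- n - w0
  between <- (muT * w0 - mu0 * n)^2 / (w0 * w1)  # prop. to between-class var
  between[w0 == 0 | w1 == 0] <- -Inf
  t_star <- which.max(between) - 1L   # background is <= t_star
  t_star + 1L                         # foreground is >= t_star + 1
}

#' Delete the deepest z slices of a mask
#'
#' Thick particles can reflect off the slide and paint a spurious bright
#' sheet on the final (deepest) focal plane; deleting that layer removes
#' the artifact. All other voxels are unchanged. `n_slices = 0` is the
#' identity.
#'
#' @param mask a `binary_mask` from [binarize()].
#' @param n_slices number of deepest slices to clear; must be smaller than
#'   the stack depth.
#' @return The modified `binary_mask`.
#' @export
suppress_bottom_reflection <- function(mask, n_slices) {
  stopifnot(inherits(mask, "binary_mask"))
  nz <- dim(mask$voxels)[1L]
  n_slices <- as.integer(n_slices)
  if (n_slices < 0L) stop("n_slices must be >= 0", call. = FALSE)
  if (n_slices >= nz) {
    stop("n_slices (", n_slices, ") must be smaller than the stack depth (",
         nz, ")", call. = FALSE)
  }
  if (n_slices > 0L) {
    mask$voxels[(nz - n_slices + 1L):nz, , ] <- FALSE
  }
  mask
}

#' Label connected particles in a binary mask
#'
#' Connected components under the configured 3D connectivity become
#' particles labeled `1..n` in deterministic raster-scan discovery order
#' (row-major across the x-y field of view, depth last), so particle 1 is
#' the component whose first voxel is encountered first on a top-left,
#' row-major transect. Components touching any stack face are marked in
#' `border_flags`.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default).
#' @return A `label_volume`: integer array (0 = background), spacing,
#'   `n_particles`, per-label `border_flags`.
#' @export
label_particles <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  d <- dim(mask$voxels)
  lab <- cpp_label3d(as.logical(mask$voxels), as.integer(d), connectivity)
  n <- attr(lab, "n_components")
  dim(lab) <- d
  new_label_volume(lab, mask$spacing, n,
                   border_flags = face_touching_labels(lab, n),
                   connectivity = connectivity)
}

new_label_volume <- function(voxels, spacing, n_particles, border_flags,
                             connectivity = 26L) {
  structure(list(voxels = voxels, spacing = as_spacing(spacing),
                 n_particles = as.integer(n_particles),
                 border_flags = as.logical(border_flags),
                 connectivity = as.integer(connectivity),
                 # per-particle voxel coordinates, filled lazily (one pass
                 # over the volume instead of one scan per particle)
                 cache = new.env(parent = emptyenv())),
            class = "label_volume")
}

# 0-based (z, y, x) voxel coordinates of every particle, computed once
particle_coords_all <- function(labels) {
  cache <- labels$cache
  if (is.null(cache$coords)) {
    v <- labels$voxels
    d <- dim(v)
    idx <- which(v > 0L)
    lab <- v[idx]
    i0 <- idx - 1
    z <- as.integer(i0 %% d[1L])
    r <- i0 %/% d[1L]
    y <- as.integer(r %% d[2L])
    x <- as.integer(r %/% d[2L])
    f <- factor(lab, levels = seq_len(labels$n_particles))
    cache$coords <- Map(function(z, y, x) list(z = z, y = y, x = x),
                        split(z, f), split(y, f), split(x, f))
  }
  cache$coords
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %d particles in a %s voxel grid (%d flagged at border)\n",
              x$n_particles, paste(dim(x$voxels), collapse = " x "),
              sum(x$border_flags)))
  invisible(x)
}

face_touching_labels <- function(lab, n) {
  if (n == 0L) return(logical(0))
  d <- dim(lab)
  faces <- c(lab[1L, , ], lab[d[1L], , ], lab[, 1L, ], lab[, d[2L], ],
             lab[, , 1L], lab[, , d[3L]])
  flags <- logical(n)
  ids <- unique(faces[faces > 0L])
  flags[ids] <- TRUE
  flags
}

# per-label voxel counts
label_counts <- function(labels) {
  v <- labels$voxels
  tabulate(v[v > 0L], nbins = labels$n_particles)
}

# per-label projected (x-y) area in um^2
label_projected_areas <- function(labels) {
  v <- labels$voxels
  d <- dim(v)
  idx <- which(v > 0L)
  lab <- v[idx]
  i0 <- idx - 1L
  yx <- (i0 %/% d[1L])  # y + ny * x, i.e. the projected pixel id
  cells <- unique(lab * (as.double(d[2L]) * d[3L] + 1) + yx)
  per <- tabulate(floor(cells / (as.double(d[2L]) * d[3L] + 1)),
                  nbins = labels$n_particles)
  sp <- labels$spacing
  per * sp[["dx"]] * sp[["dy"]]
}

relabel_keep <- function(labels, keep_ids, border_flags = NULL) {
  map <- integer(labels$n_particles)
  map[keep_ids] <- seq_along(keep_ids)
  v <- labels$voxels
  pos <- v > 0L
  v[pos] <- map[v[pos]]
  flags <- if (is.null(border_flags)) labels$border_flags[keep_ids] else
    border_flags
  new_label_volume(v, labels$spacing, length(keep_ids), flags,
                   labels$connectivity)
}

#' Remove noise objects and handle border particles
#'
#' Small-object removal is the "smoothing" step of the workflow: components
#' with fewer than `min_voxels` voxels or with x-y projected area below
#' `min_projected_area_um2` are treated as noise or artifacts and removed.
#' No upper size limit is applied. Survivors are renumbered consecutively
#' in their original order. Components touching the stack border are kept
#' (`"keep"`), kept and flagged (`"flag"`, default), or removed (`"drop"`).
#' The operation is idempotent.
#'
#' @param labels a `label_volume`.
#' @param min_voxels minimum voxel count (0 disables).
#' @param min_projected_area_um2 minimum projected area in square
#'   micrometres (0 disables).
#' @param border_policy `"keep"`, `"drop"` or `"flag"`.
#' @return A filtered `label_volume`.
#' @export
filter_particles <- function(labels, min_voxels = 0L,
                             min_projected_area_um2 = 0,
                             border_policy = c("flag", "keep", "drop")) {
  stopifnot(inherits(labels, "label_volume"))
  border_policy <- match.arg(border_policy)
  if (labels$n_particles == 0L) return(labels)
  counts <- label_counts(labels)
  keep <- counts >= min_voxels
  if (min_projected_area_um2 > 0) {
    keep <- keep & (label_projected_areas(labels) >= min_projected_area_um2)
  }
  if (border_policy == "drop") keep <- keep & !labels$border_flags
  keep_ids <- which(keep)
  flags <- labels$border_flags[keep_ids]
  if (border_policy == "keep") flags[] <- FALSE
  relabel_keep(labels, keep_ids, border_flags = flags)
}

#' Retain the first n particles in transect order
#'
#' Emulates the acquisition protocol of imaging every particle encountered
#' along a raster transect until a fixed count is reached: labels are
#' already in raster discovery order, so the first `n` are retained and
#' renumbered `1..n`. If fewer than `n` exist, all are kept and the
#' shortfall is recorded in the `shortfall` attribute. Deterministic for a
#' given volume.
#'
#' @param labels a `label_volume`.
#' @param n number of particles to retain (>= 1).
#' @return A `label_volume` with at most `n` particles.
#' @export
select_n_particles <- function(labels, n) {
  stopifnot(inherits(labels, "label_volume"), n >= 1)
  n_keep <- min(as.integer(n), labels$n_particles)
  out <- relabel_keep(labels, seq_len(n_keep))
  attr(out, "shortfall") <- as.integer(n) - n_keep
  out
}
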