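#' Intensity stack container
#'
#' A reflectance confocal z-stack: a 3D grid of grayscale intensities with
#' physical voxel spacing. Voxels are stored in `(z, y, x)` order; the voxel
#' with 0-based index `(iz, iy, ix)` is centred at physical coordinate
#' `(ix * dx, iy * dy, iz * dz)` micrometres.
#'
#' @param voxels numeric or integer 3D array, dim `(slices, height, width)`.
#'   A matrix is accepted as a single-slice stack.
#' @param spacing a [voxel_spacing()].
#' @param bit_depth integer bit depth; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return An `intensity_stack` object.
#' @export
intensity_stack <- function(voxels, spacing, bit_depth = 16L) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3D array with dim (slices, height, width)",
         call. = FALSE)
  }
  if (dim(voxels)[1L] < 1L) stop("stack needs at least one slice",
                                 call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  vmax <- 2^bit_depth - 1
  rng <- range(voxels)
  if (rng[1L] < 0 || rng[2L] > vmax) {
    stop("intensities outside [0, ", vmax, "] for bit depth ", bit_depth,
         call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = as_spacing(spacing),
                 bit_depth = bit_depth),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "intensity_stack: %d slices of %d x %d (%d-bit), dx=%g dy=%g dz=%g um\n",
    d[1L], d[2L], d[3L], x$bit_depth,
    x$spacing[["dx"]], x$spacing[["dy"]], x$spacing[["dz"]]))
  invisible(x)
}

#' Read a multi-page grayscale TIFF as an intensity stack
#'
#' Pages become z slices in file order. Spacing is supplied by the caller
#' (typically from the acquisition settings, e.g. [spacing_mesofossil()]);
#' vendor metadata tags are deliberately not parsed. Intensities are read
#' as stored, without rescaling.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing a [voxel_spacing()]; never defaulted silently.
#' @param channel for RGB/multi-channel pages, the 1-based channel to keep;
#'   `NULL` (default) rejects multi-channel input.
#' @return An [intensity_stack()].
#' @export
read_stack <- function(path, spacing, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  pages <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (is.null(channel)) {
        stop("page ", i, " has ", dim(p)[3L],
             " channels; pass 'channel' to select one", call. = FALSE)
      }
      p <- p[, , channel]
    }
    p
  })
  hw <- vapply(pages, dim, integer(2L))
  if (any(hw[1L, ] != hw[1L, 1L]) || any(hw[2L, ] != hw[2L, 1L])) {
    stop("inconsistent page dimensions across the stack", call. = FALSE)
  }
  vox <- array(0, dim = c(length(pages), hw[1L, 1L], hw[2L, 1L]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  intensity_stack(vox, spacing, bit_depth = bits)
}

#' Write an intensity stack as a multi-page grayscale TIFF
#'
#' Integer intensities round-trip exactly through [read_stack()].
#'
#' @param stack an [intensity_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "intensity_stack"))
  vmax <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$voxels)[1L]), function(i) {
    stack$voxels[i, , ] / vmax
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

config_defaults <- function() {
  list(
    spacing = spacing_mesofossil(),
    threshold = "auto",
    min_voxels = 10L,
    min_projected_area_um2 = 0,
    connectivity = 26L,
    border_policy = "flag",
    bottom_reflection_slices = 0L,
    conversion_factor = 13,
    shape_tolerance = 0.2,
    select_n = NULL,
    smooth_sigma = 0.85
  )
}

#' Load an analysis configuration from YAML
#'
#' Absent keys take the documented defaults; unknown keys raise a warning;
#' invalid values are rejected with the offending field name. An empty (or
#' missing `path = NULL`) document yields the full default configuration:
#' spacing from the mesofossil preset, automatic threshold, `min_voxels`
#' 10, no projected-area filter, connectivity 26, `border_policy` "flag",
#' no bottom-slice deletion, conversion factor 13.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of class `analysis_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.list(cfg$spacing) || is.numeric(cfg$spacing)) {
    sp <- cfg$spacing
    if (is.list(sp)) {
      for (f in c("dx", "dy", "dz")) {
        v <- sp[[f]]
        if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
          stop("invalid config value for spacing.", f, call. = FALSE)
        }
      }
    }
    cfg$spacing <- as_spacing(sp)
  }
  if (!identical(cfg$threshold, "auto") &&
      !(is.numeric(cfg$threshold) && length(cfg$threshold) == 1L)) {
    stop("invalid config value for threshold", call. = FALSE)
  }
  if (!is.numeric(cfg$min_voxels) || cfg$min_voxels < 0) {
    stop("invalid config value for min_voxels", call. = FALSE)
  }
  if (!is.numeric(cfg$min_projected_area_um2) ||
      cfg$min_projected_area_um2 < 0) {
    stop("invalid config value for min_projected_area_um2", call. = FALSE)
  }
  if (!cfg$connectivity %in% c(6L, 18L, 26L)) {
    stop("invalid config value for connectivity (must be 6, 18 or 26)",
         call. = FALSE)
  }
  if (!cfg$border_policy %in% c("keep", "drop", "flag")) {
    stop("invalid config value for border_policy", call. = FALSE)
  }
  if (!is.numeric(cfg$bottom_reflection_slices) ||
      cfg$bottom_reflection_slices < 0) {
    stop("invalid config value for bottom_reflection_slices", call. = FALSE)
  }
  if (!is.numeric(cfg$conversion_factor) || cfg$conversion_factor <= 0) {
    stop("invalid config value for conversion_factor", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

# Stable column order of the per-particle morphometrics table; names carry
# the units so the CSV header is self-documenting.
morphometrics_columns <- function() {
  c("particle_id", "volume_um3", "surface_area_um2", "projected_area_um2",
    "bbox_length_um", "bbox_width_um", "bbox_depth_um",
    "semi_a_um", "semi_b_um", "semi_c_um", "shape_class",
    "circularity", "aspect_ratio", "manual_volume_um3", "voxel_volume_um3",
    "n_voxels", "n_triangles", "border_flag", "degenerate_axes")
}

#' Write / read the per-particle morphometrics table
#'
#' One row per particle, fixed column order; column names carry the units
#' (`_um3` = cubic micrometres, `_um2` = square micrometres, `_um` =
#' micrometres). An empty record set writes a header-only file. Numeric
#' values round-trip at full precision.
#'
#' @param records data.frame of particle morphometrics
#'   (see [measure_particle()]).
#' @param path output CSV path.
#' @return `path` invisibly; `read_morphometrics_table()` returns the
#'   data.frame.
#' @export
write_morphometrics_table <- function(records, path) {
  cols <- morphometrics_columns()
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                      cols))
  } else {
    records <- as.data.frame(records)
    missing <- setdiff(cols, names(records))
    for (m in missing) records[[m]] <- NA
    records <- records[, cols]
  }
  write.csv(format(records, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphometrics_table
#' @export
read_morphometrics_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (lg in c("border_flag", "degenerate_axes")) {
    if (lg %in% names(df)) df[[lg]] <- as.logical(df[[lg]])
  }
  df
}
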