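#' Physical voxel spacing
#'
#' Edge lengths of one voxel in micrometres. Confocal stacks are routinely
#' anisotropic (the z step is set by the focus drive, not the detector), so
#' `dz` usually differs from `dx`/`dy`; the anisotropy is preserved through
#' every downstream computation.
#'
#' @param dx,dy µm per voxel in x and y.
#' @param dz µm per z step (slice separation).
#' @return A `voxel_spacing` object (named numeric vector `dx`, `dy`, `dz`).
#' @examples
#' voxel_spacing(2.768, 2.768, 5)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  for (f in names(s)) {
    if (!is.finite(s[[f]]) || s[[f]] <= 0) {
      stop("spacing.", f, " must be a strictly positive number", call. = FALSE)
    }
  }
  structure(s, class = "voxel_spacing")
}

#' Acquisition presets for the two charcoal size fractions
#'
#' Voxel spacings for the two standard imaging modes: the 10x objective used
#' for mesofossil-fraction (and large bonfire) particles, and the 20x
#' objective used for the microfossil fraction.
#'
#' @return A [voxel_spacing()] object.
#' @export
spacing_mesofossil <- function() voxel_spacing(2.768, 2.768, 5.00)

#' @rdname spacing_mesofossil
#' @export
spacing_microfossil <- function() voxel_spacing(0.526, 0.526, 1.060)

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx = %g, dy = %g, dz = %g um\n",
              x[["dx"]], x[["dy"]], x[["dz"]]))
  invisible(x)
}

as_spacing <- function(x) {
  if (inherits(x, "voxel_spacing")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(voxel_spacing(x[[1L]], x[[2L]], x[[3L]]))
  }
  if (is.list(x) && all(c("dx", "dy", "dz") %in% names(x))) {
    return(voxel_spacing(x$dx, x$dy, x$dz))
  }
  stop("cannot interpret 'spacing'; supply voxel_spacing(dx, dy, dz)",
       call. = FALSE)
}

voxel_volume_um3 <- function(spacing) {
  prod(unclass(as_spacing(spacing)))
}
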