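#' Descriptive statistics of an assemblage
#'
#' Sample-level size distribution summary: n, mean, median (average of the
#' two central order statistics for even n), standard error (sample SD /
#' sqrt(n)), minimum and maximum, for particle volume and surface area.
#' The area column defaults to total mesh surface area
#' (`surface_area_um2`); set `area_metric = "projected"` to summarise x-y
#' projected areas instead, for comparability with 2D light-microscope
#' workflows.
#'
#' @param records data.frame of particle morphometrics.
#' @param sample_id label for the sample.
#' @param area_metric `"mesh"` or `"projected"`.
#' @return A list of class `assemblage_summary`.
#' @export
summarize_assemblage <- function(records, sample_id = "sample",
                                 area_metric = c("mesh", "projected")) {
  area_metric <- match.arg(area_metric)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no particle records", call. = FALSE)
  vol <- records$volume_um3
  area <- if (area_metric == "mesh") records$surface_area_um2 else
    records$projected_area_um2
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  structure(list(
    sample_id = sample_id, n = nrow(records), area_metric = area_metric,
    mean_volume_um3 = mean(vol), median_volume_um3 = median(vol),
    se_volume_um3 = se(vol),
    min_volume_um3 = min(vol), max_volume_um3 = max(vol),
    mean_area_um2 = mean(area), median_area_um2 = median(area),
    se_area_um2 = se(area),
    min_area_um2 = min(area), max_area_um2 = max(area)
  ), class = "assemblage_summary")
}

#' @export
print.assemblage_summary <- function(x, ...) {
  cat(sprintf(
    "assemblage '%s': n = %d\n  volume (um^3): mean %.0f, median %.0f, se %.0f, range [%.0f, %.0f]\n  area   (um^2): mean %.0f, median %.0f, se %.0f, range [%.0f, %.0f]\n",
    x$sample_id, x$n, x$mean_volume_um3, x$median_volume_um3,
    x$se_volume_um3, x$min_volume_um3, x$max_volume_um3, x$mean_area_um2,
    x$median_area_um2, x$se_area_um2, x$min_area_um2, x$max_area_um2))
  invisible(x)
}

#' Estimate the total charcoal volume in a sample
#'
#' Total volume = particle count x median particle volume, the abundance
#' proxy that replaces raw particle counts. The product is carried at full
#' floating precision and converted to cubic millimetres
#' (1 mm^3 = 1e9 um^3); rounding to 4 decimals happens only at display.
#' Feeding a display-rounded median back in loses the final digits of the
#' total, so keep medians in um^3.
#'
#' @param particle_count total number of particles in the sample (>= 0).
#' @param median_particle_volume_um3 median particle volume in um^3 (> 0).
#' @return A list of class `total_volume_estimate` with
#'   `particle_count`, `median_particle_volume_mm3`, `estimated_total_mm3`.
#' @export
estimate_total_volume <- function(particle_count,
                                  median_particle_volume_um3) {
  if (particle_count < 0) stop("particle_count must be >= 0", call. = FALSE)
  if (median_particle_volume_um3 <= 0) {
    stop("median particle volume must be positive", call. = FALSE)
  }
  med_mm3 <- median_particle_volume_um3 / 1e9
  structure(list(particle_count = as.integer(particle_count),
                 median_particle_volume_mm3 = med_mm3,
                 estimated_total_mm3 = particle_count * med_mm3),
            class = "total_volume_estimate")
}

#' @export
print.total_volume_estimate <- function(x, ...) {
  cat(sprintf("total volume: %d particles x median %.4f mm^3 = %.4f mm^3\n",
              x$particle_count, x$median_particle_volume_mm3,
              x$estimated_total_mm3))
  invisible(x)
}

#' Manual-vs-rendered overestimate factor
#'
#' How much a manual L x W x D box estimate exceeds the rendered
#' (mesh-enclosed) volume. Returned at full precision; conventionally
#' displayed with 2 decimals.
#'
#' @param manual,rendered volumes in the same unit (both > 0).
#' @return `manual / rendered`.
#' @export
overestimate_factor <- function(manual, rendered) {
  if (any(c(manual, rendered) <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  manual / rendered
}

#' Linear area-volume calibration
#'
#' Ordinary least squares of particle volume (um^3) on surface area (um^2)
#' across an assemblage. Both the free-intercept fit and the
#' through-origin fit are computed; for the through-origin fit r^2 is
#' defined about the origin-constrained model, `1 - RSS / sum(y^2)`. The
#' slope of the through-origin fit is the area-to-volume conversion
#' factor (um): thin oblate particles give a factor near half their
#' typical thickness.
#'
#' @param records data.frame with `volume_um3` and an area column.
#' @param through_origin if `TRUE` the returned primary fit is the
#'   origin-constrained one (the other is still reported).
#' @param area_metric `"mesh"` or `"projected"`.
#' @return A list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `through_origin`, `n`, plus `alternative` (the other
#'   fit's slope/intercept/r_squared).
#' @export
area_volume_regression <- function(records, through_origin = FALSE,
                                   area_metric = c("mesh", "projected")) {
  area_metric <- match.arg(area_metric)
  records <- as.data.frame(records)
  y <- records$volume_um3
  x <- if (area_metric == "mesh") records$surface_area_um2 else
    records$projected_area_um2
  if (length(x) < 3L) stop("need at least 3 particles", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("areas and volumes must be positive", call. = FALSE)
  }
  if (sd(x) == 0) stop("degenerate input: constant area", call. = FALSE)
  free <- lm(y ~ x)
  origin <- lm(y ~ 0 + x)
  r2_free <- 1 - sum(residuals_of(free)) / sum((y - mean(y))^2)
  r2_origin <- 1 - sum(residuals_of(origin)) / sum(y^2)
  fit_free <- list(slope = unname(coef(free)[2L]),
                   intercept = unname(coef(free)[1L]),
                   r_squared = r2_free)
  fit_origin <- list(slope = unname(coef(origin)[1L]), intercept = 0,
                     r_squared = r2_origin)
  primary <- if (through_origin) fit_origin else fit_free
  alt <- if (through_origin) fit_free else fit_origin
  structure(c(primary,
              list(through_origin = through_origin, n = length(x),
                   area_metric = area_metric, alternative = alt)),
            class = "regression_fit")
}

residuals_of <- function(fit) stats::residuals(fit)^2

#' Convert a 2D area measurement to an estimated volume
#'
#' `volume = k * area` with the dimensionless-looking conversion factor k
#' carrying implicit units of um (um^3 per um^2). The default k = 13
#' converts mesh surface area of thin oblate charcoal to volume. `k = 1`
#' is an identity in mixed units and is flagged in the result's
#' `unit_caveat` attribute.
#'
#' @param area_um2 area in square micrometres (> 0).
#' @param k conversion factor in micrometres (> 0), default 13.
#' @return Estimated volume in cubic micrometres.
#' @export
predict_volume_from_area <- function(area_um2, k = 13) {
  if (any(area_um2 <= 0)) stop("area must be positive", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  out <- k * area_um2
  if (k == 1) attr(out, "unit_caveat") <-
    "k = 1: result equals the area value; units are mixed"
  out
}

#' Kruskal-Wallis comparison of particle-size groups
#'
#' Tie-corrected Kruskal-Wallis rank test across two or more samples of
#' particle volumes (or areas), with the p-value from the chi-square
#' approximation on groups - 1 degrees of freedom. When every value in
#' every group is identical there is no rank information: H = 0, p = 1.
#' `log10_p` reports the p-value on the log10 scale, which stays finite
#' when p underflows.
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @return A list of class `group_comparison`: `H`, `df`, `p_value`,
#'   `log10_p`, `group_ns`.
#' @export
compare_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]])) groups <- groups[[1L]]
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 1L) || sum(ns) < 3L) {
    stop("each group needs n >= 1 and total N >= 3", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L) {
    return(structure(list(H = 0, df = df, p_value = 1, log10_p = 0,
                          group_ns = as.integer(ns)),
                     class = "group_comparison"))
  }
  kt <- kruskal.test(x, g)
  H <- unname(kt$statistic)
  log10_p <- pchisq(H, df, lower.tail = FALSE, log.p = TRUE) / log(10)
  structure(list(H = H, df = df, p_value = unname(kt$p.value),
                 log10_p = log10_p, group_ns = as.integer(ns)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4g, df = %d, p = %.3g (log10 p = %.2f), n = %s\n",
    x$H, x$df, x$p_value, x$log10_p, paste(x$group_ns, collapse = "/")))
  invisible(x)
}

#' Size sorting of an assemblage
#'
#' Two standard, scale-invariant dispersion metrics of particle volume:
#' the coefficient of variation (SD / mean) and the quartile coefficient
#' of dispersion ((Q3 - Q1) / (Q3 + Q1)). Lower values mean better
#' sorting (a narrower size distribution), interpreted as a
#' transport-history signal.
#'
#' @param records data.frame with `volume_um3`, or a numeric vector of
#'   volumes; n >= 2.
#' @return Named numeric vector `c(cv, quartile_coefficient)`.
#' @export
size_sorting <- function(records) {
  v <- if (is.numeric(records)) records else
    as.data.frame(records)$volume_um3
  if (length(v) < 2L) stop("need at least 2 particles", call. = FALSE)
  q <- unname(quantile(v, c(0.25, 0.75)))
  c(cv = sd(v) / mean(v),
    quartile_coefficient = if (q[2L] + q[1L] == 0) 0 else
      (q[2L] - q[1L]) / (q[2L] + q[1L]))
}

#' Ranked size distribution
#'
#' Values sorted ascending with their rank, plus the median and the rank
#' position it sits at (the average of the two central ranks for even n) -
#' the form in which per-sample size spectra are plotted with the median
#' marked.
#'
#' @param records data.frame with the metric column, or a numeric vector.
#' @param metric column to rank when `records` is a data.frame.
#' @return A list: `ranks` data.frame (`rank`, `value`), `median`,
#'   `median_rank`.
#' @export
ranked_distribution <- function(records, metric = "volume_um3") {
  v <- if (is.numeric(records)) records else
    as.data.frame(records)[[metric]]
  if (!length(v)) stop("no values to rank", call. = FALSE)
  s <- sort(v)  # stable; duplicates preserved
  list(ranks = data.frame(rank = seq_along(s), value = s),
       median = median(s), median_rank = (length(s) + 1) / 2)
}
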