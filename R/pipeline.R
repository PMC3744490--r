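#' Run the full stack-to-summary pipeline
#'
#' For each input stack: read, threshold, optionally delete the deepest
#' reflection-artifact slices, label 3D connected components, filter small
#' objects and border particles, optionally keep only the first
#' `select_n` particles in transect order, mesh and measure every
#' particle, and summarise the assemblage. Writes one morphometrics CSV
#' per sample, a `summary.json` mirroring the per-sample statistics and
#' total-volume estimates (plus a cross-sample comparison block when
#' there are two or more samples), optional per-particle meshes, and a
#' run manifest recording the tool version, configuration (with its
#' hash), input checksums, per-stage particle counts, thresholds actually
#' used, and timestamps. Outputs other than the manifest's timestamps are
#' byte-identical across reruns with the same inputs and configuration.
#'
#' @param stack_paths character vector of TIFF paths; names become sample
#'   ids (basenames otherwise).
#' @param config an `analysis_config` from [load_config()].
#' @param out_dir output directory (created if needed).
#' @param write_meshes write per-particle OBJ meshes under
#'   `out_dir/meshes/`.
#' @return Invisibly, a list with `records` (per-sample data.frames),
#'   `summaries`, `totals`, `comparison` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(stack_paths, config = load_config(),
                         out_dir = ".", write_meshes = FALSE) {
  stopifnot(length(stack_paths) >= 1L)
  if (!inherits(config, "analysis_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(stack_paths)
  if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(stack_paths))
  ids[ids == ""] <- tools::file_path_sans_ext(
    basename(stack_paths[ids == ""]))

  records <- list()
  summaries <- list()
  totals <- list()
  stages <- list()
  thresholds <- numeric(0)

  for (s in seq_along(stack_paths)) {
    id <- ids[s]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", what, "' failed for sample '", id, "': ",
             conditionMessage(e), call. = FALSE)
      })
    }
    stk <- stage("read", read_stack(stack_paths[s], config$spacing))
    mask <- stage("binarize", binarize(stk, config$threshold))
    thresholds[id] <- attr(mask, "threshold_used")
    if (config$bottom_reflection_slices > 0L) {
      mask <- stage("suppress_bottom_reflection",
                    suppress_bottom_reflection(
                      mask, config$bottom_reflection_slices))
    }
    lab <- stage("label", label_particles(mask, config$connectivity))
    n_labeled <- lab$n_particles
    lab <- stage("filter", filter_particles(
      lab, config$min_voxels, config$min_projected_area_um2,
      config$border_policy))
    n_filtered <- lab$n_particles
    shortfall <- 0L
    if (!is.null(config$select_n)) {
      lab <- stage("select", select_n_particles(lab, config$select_n))
      shortfall <- attr(lab, "shortfall")
    }
    stages[[id]] <- list(labeled = n_labeled, after_filter = n_filtered,
                         measured = lab$n_particles, shortfall = shortfall)
    recs <- stage("measure", measure_all_particles(
      lab, shape_tol = config$shape_tolerance,
      smooth_sigma = config$smooth_sigma))
    if (isTRUE(write_meshes)) {
      mesh_dir <- file.path(out_dir, "meshes", id)
      dir.create(mesh_dir, showWarnings = FALSE, recursive = TRUE)
      for (pid in seq_len(lab$n_particles)) {
        write_mesh(extract_surface(lab, pid,
                                   smooth_sigma = config$smooth_sigma),
                   file.path(mesh_dir, sprintf("particle_%04d.obj", pid)))
      }
    }
    write_morphometrics_table(recs,
                              file.path(out_dir, paste0(id,
                                                        "_particles.csv")))
    records[[id]] <- recs
    if (nrow(recs) > 0L) {
      summaries[[id]] <- summarize_assemblage(recs, id)
      totals[[id]] <- estimate_total_volume(
        nrow(recs), summaries[[id]]$median_volume_um3)
    }
  }

  comparison <- if (length(summaries) >= 2L) {
    compare_samples(summaries,
                    counts = vapply(records, nrow, integer(1L)))
  } else NULL

  summary_out <- list(
    samples = lapply(names(summaries), function(id) {
      su <- summaries[[id]]
      to <- totals[[id]]
      c(unclass(su),
        list(total_volume_mm3 = to$estimated_total_mm3,
             median_particle_volume_mm3 = to$median_particle_volume_mm3,
             mean_based_total_mm3 = su$n * su$mean_volume_um3 / 1e9))
    }),
    comparison = if (is.null(comparison)) NULL else unclass(comparison)
  )
  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  manifest <- list(
    tool = "charstack3d",
    version = as.character(packageVersion("charstack3d")),
    config = config_for_json(config),
    config_hash = config_hash(config),
    inputs = lapply(seq_along(stack_paths), function(s) {
      list(sample = ids[s], path = as.character(stack_paths[s]),
           md5 = unname(tools::md5sum(stack_paths[s])))
    }),
    stage_counts = stages,
    thresholds_used = as.list(thresholds),
    seed = NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(records = records, summaries = summaries, totals = totals,
                 comparison = comparison, manifest = manifest))
}

config_for_json <- function(config) {
  cfg <- unclass(config)
  cfg$spacing <- as.list(unclass(cfg$spacing))
  cfg
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config_for_json(config), tf)
  unname(tools::md5sum(tf))
}

#' Compare charcoal abundance across samples
#'
#' Given per-sample summaries (and the particle counts), reports the
#' count ordering, the estimated-total-volume ordering, all pairwise
#' total-volume ratios, and raises an explicit flag when the two
#' orderings disagree - the situation in which counting particles and
#' measuring their volume tell opposite stories about relative fire
#' activity.
#'
#' @param summaries list of `assemblage_summary` objects (>= 2), or a
#'   numeric vector of median particle volumes in um^3.
#' @param counts total particle counts per sample (defaults to each
#'   summary's n).
#' @return A list of class `sample_comparison`: `table` (sample, count,
#'   median volume, total mm^3), `count_order`, `volume_order`,
#'   `orderings_disagree`, `pairwise_ratios` (data.frame with the
#'   total-volume ratio of each sample pair, larger/smaller).
#' @export
compare_samples <- function(summaries, counts = NULL) {
  if (is.numeric(summaries)) {
    medians <- summaries
    ids <- names(medians)
    if (is.null(ids)) ids <- paste0("sample", seq_along(medians))
  } else {
    medians <- vapply(summaries, function(s) s$median_volume_um3,
                      numeric(1L))
    ids <- vapply(summaries, function(s) s$sample_id, character(1L))
    if (is.null(counts)) counts <- vapply(summaries, function(s) s$n,
                                          numeric(1L))
  }
  if (length(medians) < 2L) stop("need at least two samples", call. = FALSE)
  if (is.null(counts)) stop("supply particle counts", call. = FALSE)
  totals <- vapply(seq_along(medians), function(i) {
    estimate_total_volume(counts[i], medians[i])$estimated_total_mm3
  }, numeric(1L))
  tab <- data.frame(sample = ids, particle_count = as.integer(counts),
                    median_volume_um3 = medians, total_volume_mm3 = totals,
                    stringsAsFactors = FALSE)
  count_order <- ids[order(-counts)]
  volume_order <- ids[order(-totals)]
  pairs <- utils::combn(seq_along(ids), 2L)
  ratios <- data.frame(
    sample_a = ids[pairs[1L, ]], sample_b = ids[pairs[2L, ]],
    ratio_a_over_b = totals[pairs[1L, ]] / totals[pairs[2L, ]],
    stringsAsFactors = FALSE)
  structure(list(table = tab, count_order = count_order,
                 volume_order = volume_order,
                 orderings_disagree = !identical(count_order, volume_order),
                 pairwise_ratios = ratios),
            class = "sample_comparison")
}

#' @export
print.sample_comparison <- function(x, ...) {
  print(x$table)
  cat("count ordering: ", paste(x$count_order, collapse = " > "), "\n")
  cat("volume ordering:", paste(x$volume_order, collapse = " > "), "\n")
  if (x$orderings_disagree) {
    cat("FLAG: particle-count and total-volume orderings disagree\n")
  }
  invisible(x)
}

#' Write an assemblage summary (and totals) to JSON
#'
#' @param summary an `assemblage_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
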