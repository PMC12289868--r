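## canonical stage order; a run must be a prefix-closed subsequence, i.e.
## each requested stage finds its inputs either in the same run or on disk
.PIPELINE_STAGES <- c("simulate", "segment", "porosity", "profile", "stats")

#' Run the analysis pipeline
#'
#' Orchestrates the stage sequence simulate -> segment -> porosity ->
#' profile -> stats in `out_dir`, writing a manifest with the configuration
#' snapshot, seed, and an MD5 checksum for every output so that runs are
#' auditable and reruns comparable. Later stages may be run alone if the
#' outputs they depend on already exist in `out_dir`. With identical config
#' and seed all stage outputs are byte-identical.
#'
#' @param config A [run_config()]; its `seed` drives the simulate stage.
#' @param stages Character vector of stages to run, in canonical order.
#' @param out_dir Output directory (created if missing).
#' @param input_nc Optional path to a scanned tomogram NetCDF; used by
#'   `segment` instead of the simulated phantom.
#' @param truth_args Named list of overrides for [synthetic_truth()] in the
#'   simulate stage.
#' @param dims Phantom dimensions for the simulate stage.
#' @param dry_run Validate the request and write a manifest without
#'   computing.
#' @return The manifest, invisibly (also written to
#'   `out_dir/run_manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), stages = .PIPELINE_STAGES,
                         out_dir, input_nc = NULL, truth_args = list(),
                         dims = c(120L, 120L, 300L), dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  if (!length(stages)) stop("no stages requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    phantom = file.path(out_dir, "phantom.nc"),
    truth = file.path(out_dir, "truth.json"),
    truth_labels = file.path(out_dir, "truth_labels.nc"),
    labels = file.path(out_dir, "labels.nc"),
    map = file.path(out_dir, "porosity_map.csv"),
    profile = file.path(out_dir, "profile.csv"),
    transformed = file.path(out_dir, "profile_transformed.csv"),
    loess = file.path(out_dir, "loess_curves.csv"),
    extrema = file.path(out_dir, "extrema.csv"),
    stats = file.path(out_dir, "stats.csv"))
  ## dependency check: each stage needs its input from this run or on disk
  needs <- list(segment = if (is.null(input_nc)) "phantom" else NULL,
                porosity = "labels", profile = "map",
                stats = c("profile", "extrema"))
  produced <- character(0)
  for (st in stages) {
    for (dep in needs[[st]]) {
      producer <- switch(dep, phantom = "simulate", labels = "segment",
                         map = "porosity", profile = "profile",
                         extrema = "profile")
      if (!(producer %in% stages && producer %in% c(produced, stages[seq_len(which(stages == st) - 1L)])) &&
          !file.exists(paths[[dep]]))
        stop(sprintf(
          "stage '%s' requires '%s' from stage '%s', which is neither requested before it nor present in '%s'",
          st, basename(paths[[dep]]), producer, out_dir))
    }
    produced <- c(produced, st)
  }
  outputs <- character(0)
  if (!dry_run) {
    for (st in stages) outputs <- c(outputs, switch(st,
      simulate = stage_simulate(config, truth_args, dims, paths),
      segment = stage_segment(config, input_nc, paths),
      porosity = stage_porosity(config, paths),
      profile = stage_profile(config, paths),
      stats = stage_stats(config, paths)))
  }
  manifest <- list(
    package = "coralpore",
    version = as.character(utils::packageVersion("coralpore")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, stages = stages, dry_run = dry_run,
    config = unclass(config),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, truth_args, dims, paths) {
  args <- modifyList(list(seed = config$seed), truth_args)
  truth <- do.call(synthetic_truth, args)
  ph <- generate_phantom(truth, dims = dims,
                         voxel_size_um = config$voxel_size_um %||% 24.3)
  write_tomogram(ph$tomogram, paths$phantom)
  write_phase_volume(ph$labels, paths$truth_labels)
  jsonlite::write_json(unclass(ph$truth), paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  cp_log("simulate", ph$tomogram$fragment_id, "written")
  c(paths$phantom, paths$truth_labels, paths$truth)
}

stage_segment <- function(config, input_nc, paths) {
  src <- if (is.null(input_nc)) paths$phantom else input_nc
  tom <- read_tomogram(src, var = config$nc_var,
                       voxel_size_um = config$voxel_size_um,
                       flip_z = config$flip_z)
  seg <- segment_tomogram(tom, config)
  write_phase_volume(seg, paths$labels)
  cp_log("segment", tom$fragment_id,
         sprintf("thresholds %.4g/%.4g", seg$thresholds[1],
                 seg$thresholds[2]))
  paths$labels
}

stage_porosity <- function(config, paths) {
  seg <- read_phase_volume(paths$labels)
  pm <- compute_porosity_map(seg, config$window_size_mm,
                             config$min_colony_fraction)
  write_porosity_map(pm, paths$map)
  cp_log("porosity", seg$fragment_id,
         sprintf("%d windows (%d valid)", nrow(pm), sum(pm$valid)))
  paths$map
}

stage_profile <- function(config, paths) {
  pm <- read_porosity_map(paths$map)
  vp <- extract_vertical_profile(pm)
  vp <- normalize_coordinates(vp, conversion_mm = config$conversion_mm,
                              correction_mm = config$correction_mm)
  write.csv(as.data.frame(vp), paths$profile, row.names = FALSE)
  ## range-normalized variables for pooled intra-colonial analysis
  tr <- data.frame(z = vp$z, z_mm = vp$z_mm)
  for (v in c("mip", "map", "tp", "svf")) {
    tv <- tryCatch(transform_variable(vp[[paste0(v, "_mean")]]),
                   error = function(e) NULL)
    tr[[paste0(v, "_norm")]] <- if (is.null(tv)) NA_real_ else tv$v_norm
  }
  write.csv(tr, paths$transformed, row.names = FALSE)
  ex <- find_band_extrema(vp, span = config$loess_span)
  write.csv(ex, paths$extrema, row.names = FALSE)
  curves <- lapply(c("mip", "map"), function(v) {
    K <- nrow(vp)
    cv <- suppressWarnings(fit_loess(
      vp$z_mm_window, vp[[paste0(v, "_mean")]],
      span = max(config$loess_span, min(1, 3.2 / K)), variable = v))
    data.frame(variable = v, z_mm = cv$grid, fitted = cv$fitted)
  })
  write.csv(do.call(rbind, curves), paths$loess, row.names = FALSE)
  cp_log("profile", attr(pm, "fragment_id"),
         sprintf("%d Z levels", nrow(vp)))
  c(paths$profile, paths$transformed, paths$extrema, paths$loess)
}

stage_stats <- function(config, paths) {
  vp <- read.csv(paths$profile)
  ex <- read.csv(paths$extrema)
  rows <- list()
  ## degenerate profiles (constant macroporosity on tiny phantoms) still
  ## produce a stats table, with NA for the undefined correlation
  rho <- tryCatch(correlate_profiles(vp$mip_mean, vp$map_mean),
                  error = function(e) NULL)
  rows[[1]] <- data.frame(
    test = "spearman_profile", variable = "mip~map",
    grouping = "intra-colonial",
    statistic = if (is.null(rho)) NA_real_ else rho$estimate,
    p_value = if (is.null(rho)) NA_real_ else rho$p_value,
    n = nrow(vp))
  ## zone comparison against the phantom's own band interval when available
  if (file.exists(paths$truth)) {
    truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
    band <- truth$band_interval_mm
    zones <- assign_zones(vp$z_mm_window, band)
    if (nlevels(droplevels(zones)) == 3L &&
        all(table(droplevels(zones)) >= 2L)) {
      tv <- transform_variable(vp$mip_mean)
      zs <- zone_anova(tv$v_norm, zones)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "zone_anova", variable = "mip_norm", grouping = "zones",
        statistic = zs$anova$f, p_value = zs$anova$p_value,
        n = sum(zs$zone_summary$n))
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    test = "extremum", variable = ex$variable, grouping = ex$kind,
    statistic = ex$location_mm, p_value = NA_real_, n = nrow(vp))
  write.csv(do.call(rbind, rows), paths$stats, row.names = FALSE)
  paths$stats
}

`%||%` <- function(a, b) if (is.null(a)) b else a
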