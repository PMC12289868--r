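#' Load fragment metadata from a YAML file
#'
#' Fragment metadata carries what the porosity pipeline cannot compute from a
#' scan: species, sampling location and depth, and the green-band interval
#' measured on the cut face with a stereoscope (in mm on the vertical
#' profile, apical end = 0). The file holds a top-level `fragments:` list;
#' each entry requires `id`, `species`, `location`, `depth_m` and
#' `green_band_mm` (a `[low, high]` interval). Optional: `selected`
#' (fragment used for intra-colonial profile analysis). Unknown fields are
#' preserved in the `"annotations"` attribute.
#'
#' A ready-made file for the twelve profiled *Porites* fragments ships with
#' the package: `system.file("extdata", "porites_fragments.yaml",
#' package = "coralpore")`.
#'
#' @param path YAML file path.
#' @return A data.frame with columns `fragment_id`, `species`, `location`,
#'   `depth_m`, `gb_low_mm`, `gb_high_mm`, `selected`, plus an
#'   `"annotations"` attribute (list of per-fragment extra fields).
#' @export
load_fragment_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  doc <- yaml::read_yaml(path)
  frs <- doc$fragments
  if (is.null(frs) || !length(frs))
    stop(sprintf("'%s' has no 'fragments' entries", path))
  required <- c("id", "species", "location", "depth_m", "green_band_mm")
  known <- c(required, "selected")
  rows <- vector("list", length(frs))
  annotations <- vector("list", length(frs))
  for (i in seq_along(frs)) {
    fr <- frs[[i]]
    lab <- if (!is.null(fr$id)) fr$id else sprintf("entry %d", i)
    miss <- setdiff(required, names(fr))
    if (length(miss))
      stop(sprintf("fragment '%s': missing required field(s): %s",
                   lab, paste(miss, collapse = ", ")))
    gb <- as.numeric(fr$green_band_mm)
    if (length(gb) != 2L || anyNA(gb))
      stop(sprintf("fragment '%s': green_band_mm must be [low, high]", lab))
    if (!(gb[1] >= 0 && gb[1] < gb[2]))
      stop(sprintf(
        "fragment '%s': invalid green-band interval [%s, %s] (need 0 <= low < high)",
        lab, format(gb[1]), format(gb[2])))
    depth <- as.numeric(fr$depth_m)
    if (!is.finite(depth) || depth < 0)
      stop(sprintf("fragment '%s': depth_m must be >= 0", lab))
    rows[[i]] <- data.frame(
      fragment_id = as.character(fr$id),
      species = as.character(fr$species),
      location = as.character(fr$location),
      depth_m = depth, gb_low_mm = gb[1], gb_high_mm = gb[2],
      selected = isTRUE(fr$selected),
      stringsAsFactors = FALSE)
    annotations[[i]] <- fr[setdiff(names(fr), known)]
  }
  out <- do.call(rbind, rows)
  names(annotations) <- out$fragment_id
  attr(out, "annotations") <- annotations
  out
}

#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the pipeline with its default. The
#' conversion factor (8 mm) is the vertical length of the largest porosity
#' map among the profiled fragments and the correction factor (0.45 mm)
#' shifts each profile point to the middle of its 0.9 mm sampling interval;
#' both enter the coordinate normalization (see
#' [normalize_coordinates()]).
#'
#' @param window_size_mm Edge of the cubic porosity windows (mm).
#' @param min_colony_fraction Smallest fraction of non-mask voxels for a
#'   window to be counted as valid.
#' @param loess_span LOESS span for profile smoothing, in (0, 1].
#' @param conversion_mm Conversion factor of the coordinate normalization.
#' @param correction_mm Correction factor of the coordinate normalization.
#' @param vertical_scale_max_mm Display cap of the vertical scale (mm);
#'   presentation only, computations use the full normalized scale.
#' @param segmentation_mode `"auto"` (multi-level Otsu) or `"fixed"`.
#' @param t_low,t_high Fixed thresholds, required when
#'   `segmentation_mode = "fixed"`.
#' @param n_bins Histogram bins for automatic threshold selection.
#' @param connectivity Voxel connectivity of the boundary flood (6 or 26).
#' @param air_threshold Optional fixed air/mask threshold (else automatic).
#' @param container_policy `"components"` to mask non-colony structures
#'   (container tube, separators) or `"none"`.
#' @param flip_z Reverse Z on read (volumes scanned basal-side-up).
#' @param voxel_size_um Fallback voxel size for files lacking the attribute.
#' @param nc_var Optional NetCDF variable name override.
#' @param seed Base random seed of a pipeline run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(window_size_mm = 0.9, min_colony_fraction = 0.05,
                       loess_span = 0.3, conversion_mm = 8,
                       correction_mm = 0.45, vertical_scale_max_mm = 10,
                       segmentation_mode = c("auto", "fixed"),
                       t_low = NULL, t_high = NULL, n_bins = 256L,
                       connectivity = 6L, air_threshold = NULL,
                       container_policy = c("components", "none"),
                       flip_z = FALSE, voxel_size_um = NULL, nc_var = NULL,
                       seed = NULL) {
  segmentation_mode <- match.arg(segmentation_mode)
  container_policy <- match.arg(container_policy)
  if (!is.numeric(window_size_mm) || window_size_mm <= 0)
    stop("window_size_mm must be > 0")
  if (!(loess_span > 0 && loess_span <= 1))
    stop("loess_span must be in (0, 1]")
  if (conversion_mm <= 0 || correction_mm <= 0)
    stop("conversion and correction factors must be > 0")
  if (min_colony_fraction < 0 || min_colony_fraction > 1)
    stop("min_colony_fraction must be in [0, 1]")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(
    window_size_mm = window_size_mm,
    min_colony_fraction = min_colony_fraction,
    loess_span = loess_span, conversion_mm = conversion_mm,
    correction_mm = correction_mm,
    vertical_scale_max_mm = vertical_scale_max_mm,
    segmentation_mode = segmentation_mode, t_low = t_low, t_high = t_high,
    n_bins = as.integer(n_bins), connectivity = as.integer(connectivity),
    air_threshold = air_threshold, container_policy = container_policy,
    flip_z = flip_z, voxel_size_um = voxel_size_um, nc_var = nc_var,
    seed = seed), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys in the file override the defaults of [run_config()]; unknown keys
#' are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop(sprintf("unknown config key(s) in '%s': %s", path,
                 paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}
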