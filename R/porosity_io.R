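## porosity-map CSV schema: '#'-prefixed header lines carry the map
## attributes, then one data row per window. Doubles are written with
## "%.17g" so write -> read is bit-exact.

.pm_double_cols <- c("cx_mm", "cy_mm", "cz_mm", "mip", "map", "tp", "svf",
                     "colony_fraction")
.pm_int_cols <- c("i", "j", "k", "cx_vox", "cy_vox", "cz_vox",
                  "n_solid", "n_micropore", "n_air", "n_mask", "n_total")

#' Write a porosity map to CSV
#'
#' One row per window with window indices, center coordinates (voxel and
#' mm), phase voxel counts, the four response variables (MiP, MaP, TP, SVF),
#' the colony fraction and the validity flag. Map-level attributes (window
#' size, voxel size, fragment id, grid shape, colony bounding-box origin)
#' are stored in `#`-prefixed header lines. Floating-point columns are
#' written with 17 significant digits so that [read_porosity_map()]
#' reproduces them bit-exactly.
#'
#' @param map A porosity map from [compute_porosity_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_porosity_map <- function(map, path) {
  stopifnot(inherits(map, "porosity_map"))
  if (!nrow(map)) stop("empty porosity map")
  at <- attributes(map)
  hdr <- c(
    sprintf("# coralpore porosity map v1"),
    sprintf("# fragment_id: %s", at$fragment_id),
    sprintf("# voxel_size_um: %.17g", at$voxel_size_um),
    sprintf("# window_size_mm: %.17g", at$window_size_mm),
    sprintf("# window_vox: %d", at$window_vox),
    sprintf("# grid: %d %d %d", at$grid[1], at$grid[2], at$grid[3]),
    sprintf("# bbox_origin_vox: %d %d %d",
            at$bbox_origin_vox[1], at$bbox_origin_vox[2],
            at$bbox_origin_vox[3]))
  df <- as.data.frame(map)
  out <- df
  for (cc in .pm_double_cols) out[[cc]] <- sprintf("%.17g", df[[cc]])
  out$valid <- ifelse(df$valid, "TRUE", "FALSE")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a porosity map written by [write_porosity_map()]
#'
#' @param path CSV path.
#' @return A `"porosity_map"` data.frame; numeric content is identical to
#'   what was written.
#' @export
read_porosity_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get1 <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) stop(sprintf("'%s': missing header '# %s:'", path, key))
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  for (cc in .pm_double_cols) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in .pm_int_cols) df[[cc]] <- as.integer(df[[cc]])
  df$valid <- as.logical(df$valid)
  structure(df,
            class = c("porosity_map", "data.frame"),
            fragment_id = get1("fragment_id"),
            voxel_size_um = as.numeric(get1("voxel_size_um")),
            window_size_mm = as.numeric(get1("window_size_mm")),
            window_vox = as.integer(get1("window_vox")),
            grid = as.integer(strsplit(get1("grid"), " +")[[1]]),
            bbox_origin_vox = as.integer(
              strsplit(get1("bbox_origin_vox"), " +")[[1]]))
}
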