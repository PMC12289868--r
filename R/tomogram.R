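#' Construct a tomogram object
#'
#' A tomogram is a 3D grid of X-ray attenuation values with a physical voxel
#' size. Axes follow the package-wide convention `(X, Y, Z)` with Z the
#' vertical axis of the fragment: Z index 1 is the apical end (living tissue)
#' and the last index the basal skeleton. Volumes scanned the other way up
#' should be read with `flip_z = TRUE` (see [read_tomogram()]).
#'
#' @param intensities Numeric 3D array of attenuation values (arbitrary
#'   units); all values must be finite.
#' @param voxel_size_um Edge length of one (cubic) voxel in micrometers.
#'   The scans this package targets have a minimum resolution of 24.3 um.
#' @param fragment_id Identifier of the skeletal fragment.
#' @return An object of class `"tomogram"`.
#' @export
#' @examples
#' tom <- tomogram(array(runif(8), c(2, 2, 2)), voxel_size_um = 24.3, "demo")
#' dim(tom$intensities)
tomogram <- function(intensities, voxel_size_um, fragment_id = "unknown") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array")
  if (any(dim(intensities) < 1L))
    stop("all three dimensions must be >= 1")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("'voxel_size_um' must be a single positive number")
  structure(
    list(intensities = intensities,
         voxel_size_um = as.numeric(voxel_size_um),
         fragment_id = as.character(fragment_id)),
    class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$intensities)
  mm <- d * x$voxel_size_um / 1000
  cat(sprintf("<tomogram '%s'> %d x %d x %d voxels @ %.4g um (%.3g x %.3g x %.3g mm)\n",
              x$fragment_id, d[1], d[2], d[3], x$voxel_size_um,
              mm[1], mm[2], mm[3]))
  invisible(x)
}

#' Physical Z extent of a tomogram in millimeters
#'
#' @param tom A [tomogram()].
#' @return Length of the vertical (Z) axis in mm.
#' @export
z_extent_mm <- function(tom) {
  stopifnot(inherits(tom, "tomogram"))
  dim(tom$intensities)[3] * tom$voxel_size_um / 1000
}

## pick the first variable with 3 dimensions, or a named one
find_3d_var <- function(nc, path, var = NULL) {
  vars <- nc$var
  if (!is.null(var)) {
    if (!var %in% names(vars))
      stop(sprintf("variable '%s' not found in '%s'", var, path))
    if (length(vars[[var]]$dim) != 3L)
      stop(sprintf("variable '%s' in '%s' is not 3D", var, path))
    return(var)
  }
  for (v in names(vars)) if (length(vars[[v]]$dim) == 3L) return(v)
  stop(sprintf("no 3D volume found in '%s'", path))
}

#' Read a tomogram from a NetCDF file
#'
#' Reads the first 3D variable (or a named one) from a `.nc` file. The voxel
#' size is taken from the variable attribute `voxel_size_um`, then from the
#' global attribute of the same name, and finally from the `voxel_size_um`
#' argument; it is never silently defaulted, because every millimeter-scale
#' output depends on it.
#'
#' @param path Path to a NetCDF (.nc) file.
#' @param fragment_id Fragment identifier; defaults to the file's global
#'   `fragment_id` attribute or the file name.
#' @param var Optional NetCDF variable name; by default the first 3D
#'   variable is used.
#' @param voxel_size_um Voxel size to use when the file carries none.
#' @param flip_z Reverse the Z axis on read, for volumes scanned
#'   basal-side-up. The package convention is Z index 1 = apical end.
#' @return A [tomogram()].
#' @export
read_tomogram <- function(path, fragment_id = NULL, var = NULL,
                          voxel_size_um = NULL, flip_z = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  v <- find_3d_var(nc, path, var)
  vox <- ncdf4::ncatt_get(nc, v, "voxel_size_um")
  if (!vox$hasatt) vox <- ncdf4::ncatt_get(nc, 0, "voxel_size_um")
  if (!vox$hasatt) {
    if (is.null(voxel_size_um))
      stop(sprintf(
        "no 'voxel_size_um' attribute on variable '%s' in '%s' and none supplied",
        v, path))
    vs <- voxel_size_um
  } else vs <- as.numeric(vox$value)
  if (!is.finite(vs) || vs <= 0)
    stop(sprintf("invalid voxel size (%s) for variable '%s' in '%s'",
                 format(vs), v, path))
  if (is.null(fragment_id)) {
    fid <- ncdf4::ncatt_get(nc, 0, "fragment_id")
    fragment_id <- if (fid$hasatt) fid$value else
      sub("\\.nc$", "", basename(path))
  }
  arr <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
  if (flip_z) arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
  tomogram(arr, vs, fragment_id)
}

#' Write a tomogram to a NetCDF file
#'
#' The intensity volume is stored as a double variable `intensity` with a
#' `voxel_size_um` attribute; [read_tomogram()] inverts the operation
#' exactly.
#'
#' @param tom A [tomogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tom, path) {
  stopifnot(inherits(tom, "tomogram"))
  d <- dim(tom$intensities)
  dims <- list(ncdf4::ncdim_def("x", "voxel", seq_len(d[1])),
               ncdf4::ncdim_def("y", "voxel", seq_len(d[2])),
               ncdf4::ncdim_def("z", "voxel", seq_len(d[3])))
  v <- ncdf4::ncvar_def("intensity", "attenuation", dims, prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v, tom$intensities)
  ncdf4::ncatt_put(nc, v, "voxel_size_um", tom$voxel_size_um, prec = "double")
  ncdf4::ncatt_put(nc, 0, "fragment_id", tom$fragment_id)
  ncdf4::ncatt_put(nc, 0, "z_orientation", "index 1 = apical (living tissue)")
  invisible(path)
}

#' Construct a phase label volume
#'
#' Per-voxel phase labels on the same lattice as the source tomogram, using
#' the fixed codes of [phase_codes()]: 0 mask, 1 air (macropore),
#' 2 micropore, 3 solid.
#'
#' @param labels Integer 3D array of codes in 0..3.
#' @param voxel_size_um Voxel edge length in micrometers.
#' @param fragment_id Source fragment identifier.
#' @param thresholds Optional numeric `c(t_low, t_high)` used to produce the
#'   labels (provenance).
#' @param provenance Optional list of masking/segmentation parameters.
#' @return An object of class `"phase_volume"`.
#' @export
phase_volume <- function(labels, voxel_size_um, fragment_id = "unknown",
                         thresholds = NULL, provenance = list()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 3L))
    stop("labels must be integer codes 0 (mask), 1 (air), 2 (micropore), 3 (solid)")
  structure(
    list(labels = labels, voxel_size_um = as.numeric(voxel_size_um),
         fragment_id = as.character(fragment_id),
         thresholds = thresholds, provenance = provenance),
    class = "phase_volume")
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(x$labels + 1L, 4L)
  cat(sprintf("<phase_volume '%s'> %d x %d x %d voxels @ %.4g um\n",
              x$fragment_id, d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  mask %d | air %d | micropore %d | solid %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Write or read a labelled phase volume (NetCDF)
#'
#' Stores the integer phase codes as variable `phase` with the code table in
#' attributes, plus `voxel_size_um`.
#'
#' @param phases A [phase_volume()].
#' @param path File path.
#' @return `write_phase_volume` returns `path` invisibly;
#'   `read_phase_volume` returns a [phase_volume()].
#' @export
write_phase_volume <- function(phases, path) {
  stopifnot(inherits(phases, "phase_volume"))
  d <- dim(phases$labels)
  dims <- list(ncdf4::ncdim_def("x", "voxel", seq_len(d[1])),
               ncdf4::ncdim_def("y", "voxel", seq_len(d[2])),
               ncdf4::ncdim_def("z", "voxel", seq_len(d[3])))
  v <- ncdf4::ncvar_def("phase", "code", dims, prec = "integer")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v, phases$labels)
  ncdf4::ncatt_put(nc, v, "voxel_size_um", phases$voxel_size_um,
                   prec = "double")
  ncdf4::ncatt_put(nc, v, "codes", "0=mask 1=air 2=micropore 3=solid")
  if (!is.null(phases$thresholds))
    ncdf4::ncatt_put(nc, v, "thresholds", as.numeric(phases$thresholds),
                     prec = "double")
  ncdf4::ncatt_put(nc, 0, "fragment_id", phases$fragment_id)
  invisible(path)
}

#' @rdname write_phase_volume
#' @export
read_phase_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  v <- find_3d_var(nc, path, "phase")
  vox <- ncdf4::ncatt_get(nc, v, "voxel_size_um")
  if (!vox$hasatt) stop(sprintf("no 'voxel_size_um' attribute in '%s'", path))
  fid <- ncdf4::ncatt_get(nc, 0, "fragment_id")
  thr <- ncdf4::ncatt_get(nc, v, "thresholds")
  phase_volume(ncdf4::ncvar_get(nc, v, collapse_degen = FALSE),
               as.numeric(vox$value),
               if (fid$hasatt) fid$value else "unknown",
               thresholds = if (thr$hasatt) as.numeric(thr$value) else NULL)
}
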