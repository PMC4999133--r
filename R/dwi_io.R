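# Study I/O: minimal NIfTI-1 codec, FSL gradient tables, study bundles and
# ROI extraction.
#
# No NIfTI-capable R package is available in the supported environment, so
# a deliberately small NIfTI-1 reader/writer lives here: single-file
# uncompressed .nii, identity rotation (the phantom frame is the scanner
# frame), voxel sizes in the header, little- or big-endian input, output
# always little-endian.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "integer"),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "integer"),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r = "integer"),  # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "double"),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "double"))   # float64

#' Write an array as a NIfTI-1 volume
#'
#' @param x Numeric array (3D or 4D).
#' @param path Output path ending in `.nii`.
#' @param voxel_mm Voxel dimensions in mm (length 3).
#' @param datatype One of "float32", "int32", "int16", "float64".
#' @return `path`, invisibly.
#' @export
nifti_write <- function(x, path, voxel_mm = c(1, 1, 1),
                        datatype = c("float32", "int32", "int16", "float64")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, float32 = 16L, int32 = 8L, int16 = 4L, float64 = 64L)
  bitpix <- switch(datatype, float32 = 32L, int32 = 32L, int16 = 16L, float64 = 64L)
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  if (length(dims) > 7L) stopf("arrays beyond 7 dimensions are not supported")
  ndim <- length(dims)
  dim8 <- as.integer(c(ndim, dims, rep(1L, 7L - ndim)))
  pixdim8 <- c(1, voxel_mm, rep(1, 4))[1:8]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                     # sizeof_hdr
  wc(35)                          # data_type[10] + db_name[18] + extents(4) + session_error(2) + regular(1)
  wi(0L, 1)                       # dim_info
  wi(c(ndim, dim8[-1]), 2)        # dim[8]
  wf(c(0, 0, 0))                  # intent_p1..p3
  wi(0L, 2)                       # intent_code
  wi(code, 2)                     # datatype
  wi(bitpix, 2)                   # bitpix
  wi(0L, 2)                       # slice_start
  wf(pixdim8)                     # pixdim[8]
  wf(352)                         # vox_offset
  wf(c(1, 0))                     # scl_slope, scl_inter
  wi(0L, 2)                       # slice_end
  wi(0L, 1)                       # slice_code
  wi(2L, 1)                       # xyzt_units: mm
  wf(c(0, 0, 0, 0))               # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                # glmax, glmin
  wc(80 + 24)                     # descrip, aux_file
  wi(0L, 2)                       # qform_code
  wi(1L, 2)                       # sform_code
  wf(rep(0, 6))                   # quatern_b..d, qoffset_x..z
  wf(c(voxel_mm[1], 0, 0, 0))     # srow_x
  wf(c(0, voxel_mm[2], 0, 0))     # srow_y
  wf(c(0, 0, voxel_mm[3], 0))     # srow_z
  wc(16)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wc(4)                           # extension flag
  if (code %in% c(4L, 8L)) {
    writeBin(as.integer(round(x)), con, size = bitpix %/% 8L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to an uncompressed single-file `.nii`.
#' @return List with `data` (array), `voxel_mm`, `datatype`.
#' @export
nifti_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (hdr_size != 348L) {
    hdr_swapped <- readBin(writeBin(as.integer(hdr_size), raw()), "integer",
                           1L, size = 4L, endian = "swap")
    if (hdr_swapped == 348L) endian <- "big"
    else stopf("%s is not a NIfTI-1 file (sizeof_hdr = %d)", path, hdr_size)
  }
  ri <- function(n, size) readBin(con, "integer", n, size = size, endian = endian)
  rf <- function(n, size = 4L) readBin(con, "double", n, size = size, endian = endian)
  invisible(readBin(con, "raw", 35L))
  invisible(ri(1L, 1))                   # dim_info
  dim8 <- ri(8L, 2)
  invisible(rf(3L)); invisible(ri(1L, 2))  # intent
  datatype <- ri(1L, 2)
  bitpix <- ri(1L, 2)
  invisible(ri(1L, 2))                   # slice_start
  pixdim <- rf(8L)
  vox_offset <- rf(1L)
  scl_slope <- rf(1L)
  scl_inter <- rf(1L)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", datatype)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + ndim)]
  n <- prod(dims)
  seek(con, where = vox_offset, origin = "start")
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stopf("truncated NIfTI data in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims),
       voxel_mm = pixdim[2:4],
       datatype = datatype)
}

#' Construct a DWI study
#'
#' @param data 4D magnitude array `(x, y, slice, volume)`, all values >= 0.
#' @param voxel_mm Voxel dimensions in mm, strictly positive.
#' @param scheme A [gradient_scheme()] whose length equals the number of
#'   volumes.
#' @param meta Metadata list (subject_id, group, timepoint, protocol, ...).
#' @return An object of class `dwi_study`.
#' @export
dwi_study <- function(data, voxel_mm, scheme, meta = list()) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(dim(data)) != 4L) stopf("data must be a 4D array")
  if (dim(data)[4] != scheme_length(scheme))
    stopf("volume-count mismatch: %d data volumes vs %d scheme entries",
          dim(data)[4], scheme_length(scheme))
  if (min(data) < 0) stopf("magnitude data must be non-negative")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stopf("voxel_mm must be 3 strictly positive sizes")
  structure(list(data = data, voxel_mm = voxel_mm, scheme = scheme,
                 meta = meta),
            class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_study> %dx%dx%d voxels, %d volumes (%d b0), subject=%s protocol=%s\n",
              d[1], d[2], d[3], d[4], scheme_n_b0(x$scheme),
              x$meta$subject_id %||% "?", x$meta$protocol %||% "?"))
  invisible(x)
}

#' Save a study bundle (NIfTI + bval/bvec + JSON sidecar)
#'
#' Data are written as float32; `load_study(save_study(s))` reproduces the
#' data bit-exactly at float32 precision and the scheme within `%.6f`
#' formatting. b-values on disk are in s/mm^2.
#'
#' @param study A `dwi_study`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix, default "dwi".
#' @return Named character vector of the four paths, invisibly.
#' @export
save_study <- function(study, out_dir, prefix = "dwi") {
  stopifnot(inherits(study, "dwi_study"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  paths <- c(image = file.path(out_dir, paste0(prefix, ".nii")),
             bval = file.path(out_dir, paste0(prefix, ".bval")),
             bvec = file.path(out_dir, paste0(prefix, ".bvec")),
             meta = file.path(out_dir, paste0(prefix, ".json")))
  nifti_write(study$data, paths[["image"]], voxel_mm = study$voxel_mm,
              datatype = "float32")
  write_fsl_gradients(study$scheme, paths[["bval"]], paths[["bvec"]])
  jsonlite::write_json(study$meta[setdiff(names(study$meta), "voxel_mm")],
                       paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a study bundle
#'
#' @param image_path Path to the 4D NIfTI volume.
#' @param bval_path,bvec_path FSL gradient-table paths.
#' @param meta_path Optional JSON sidecar path.
#' @return A `dwi_study`. Volumes with b < 50 s/mm^2 are classified as b0.
#' @export
load_study <- function(image_path, bval_path, bvec_path, meta_path = NULL) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  nii <- nifti_read(image_path)
  data <- nii$data
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  scheme <- read_fsl_gradients(bval_path, bvec_path)
  if (dim(data)[4] != scheme_length(scheme))
    stopf("volume-count mismatch: image has %d volumes, gradient table %d",
          dim(data)[4], scheme_length(scheme))
  meta <- if (!is.null(meta_path) && file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  meta$voxel_mm <- nii$voxel_mm
  dwi_study(data, nii$voxel_mm, scheme, meta)
}

#' ROI label set
#'
#' Wraps an integer label map with the fixed label table
#' (background=0, vWM=1, dWM=2, vlWM=3, dlWM=4, vGM=5, dGM=6) plus the
#' composite labels `wholeWM` (union of the four WM sectors) and `wholeGM`
#' (union of the two GM sectors).
#'
#' @param label_map Integer 3D array.
#' @param label_names Named integer vector mapping names to label values;
#'   defaults to the package table.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(label_map, label_names = ROI_LABELS) {
  stopifnot(is.array(label_map), length(dim(label_map)) == 3L)
  structure(list(label_map = label_map, label_names = label_names),
            class = "roi_set")
}

#' Available ROI labels of a set (including composites)
#'
#' @param rois A `roi_set`.
#' @return Character vector of label names.
#' @export
roi_labels <- function(rois) c(names(rois$label_names), "wholeWM", "wholeGM")

roi_mask <- function(rois, label) {
  ln <- rois$label_names
  if (label == "wholeWM") {
    values <- ln[WM_ROIS]
  } else if (label == "wholeGM") {
    values <- ln[GM_ROIS]
  } else if (label %in% names(ln)) {
    values <- ln[[label]]
  } else {
    stopf("unknown ROI label '%s'; available: %s", label,
          paste(roi_labels(rois), collapse = ", "))
  }
  rois$label_map %in% values
}

#' Extract voxel values inside an ROI
#'
#' Values are returned in raster (array storage) order, which is stable
#' across calls; every ROI statistic in the package is computed from this
#' extraction.
#'
#' @param values Scalar volume (3D array) aligned to the label map.
#' @param rois A `roi_set`.
#' @param label ROI name (one of [roi_labels()]).
#' @return Numeric vector of the voxel values inside the label.
#' @export
extract_roi <- function(values, rois, label) {
  stopifnot(inherits(rois, "roi_set"))
  if (!identical(dim(values)[1:3], dim(rois$label_map)))
    stopf("values and label map have different grids")
  m <- roi_mask(rois, label)
  out <- values[m]
  if (length(out) == 0L)
    stopf("ROI '%s' is empty on this grid", label)
  out
}
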