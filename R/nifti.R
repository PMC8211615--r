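# Minimal self-contained NIfTI-1 (.nii / .nii.gz) reader and writer.
# Single-file NIfTI-1 only, sform written on output (qform honoured on
# input), little-endian on disk, no scaling slope other than identity.
# The R imaging stacks were deliberately not added as dependencies so the
# package runs on a bare scientific R installation.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,   size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,   size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L,  size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L,  size = 8L, what = "double",  signed = TRUE),
  uint16  = list(code = 512L, size = 2L, what = "integer", signed = FALSE)
)

nifti_open_read <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  gzfile(path, "rb")   # reads plain files transparently as well
}

nifti_open_write <- function(path) {
  ok <- tryCatch({
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    con
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ok)) stop("unwritable path: ", path)
  ok
}

pad_chars <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) >= n) r <- r[seq_len(n - 1)]
  c(r, raw(n - length(r)))
}

# Low-level writer: arbitrary-dimensional array (used to build malformed
# fixtures in tests); the public API goes through write_volume/write_labels.
nifti_write <- function(data, path, spacing, affine, datatype = "float32",
                        descrip = "") {
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  dims <- dim(data)
  ndim <- length(dims)
  con <- nifti_open_write(path)
  on.exit(close(con))
  en <- "little"
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = en)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = en)
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = en)
  w_raw <- function(r) writeBin(r, con)

  w_i32(348L)                          # sizeof_hdr
  w_raw(raw(10 + 18))                  # data_type, db_name (unused)
  w_i32(0L); w_i16(0L)                 # extents, session_error
  w_raw(as.raw(c(114L, 0L)))           # regular = 'r', dim_info
  dimv <- rep(1L, 8); dimv[1] <- ndim; dimv[1 + seq_len(ndim)] <- dims
  w_i16(dimv)                          # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)         # intent_p1..3, intent_code
  w_i16(dt$code); w_i16(dt$size * 8L)  # datatype, bitpix
  w_i16(0L)                            # slice_start
  pd <- rep(1, 8); pd[1] <- 1
  pd[1 + seq_len(min(ndim, 3))] <- spacing[seq_len(min(ndim, 3))]
  w_f32(pd)                            # pixdim[8] (pixdim[0] = qfac)
  w_f32(352); w_f32(1); w_f32(0)       # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(raw(1))             # slice_end, slice_code
  w_raw(as.raw(2L))                    # xyzt_units = mm
  w_f32(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                     # glmax, glmin
  w_raw(pad_chars(descrip, 80))        # descrip
  w_raw(raw(24))                       # aux_file
  w_i16(0L); w_i16(1L)                 # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0)); w_f32(c(0, 0, 0)) # quaternions, qoffsets (unused)
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(raw(16))                       # intent_name
  w_raw(c(charToRaw("n+1"), raw(1)))   # magic
  w_raw(raw(4))                        # extension indicator

  if (dt$what == "integer") {
    writeBin(as.integer(data), con, size = dt$size, endian = en)
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = en)
  }
  invisible(path)
}

nifti_read <- function(path) {
  con <- nifti_open_read(path)
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header")
  rd <- function(what, off, n, size, endian, signed = TRUE)
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  en <- "little"
  if (rd("integer", 0, 1, 4, en) != 348L) {
    en <- "big"
    if (rd("integer", 0, 1, 4, en) != 348L) stop("not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  dimv <- rd("integer", 40, 8, 2, en)
  ndim <- dimv[1]
  if (ndim != 3L) stop("non-3-D: volume has ", ndim, " dimensions")
  dims <- dimv[2:4]
  datatype <- rd("integer", 70, 1, 2, en)
  pixdim <- rd("double", 76, 8, 4, en)
  vox_offset <- rd("double", 108, 1, 4, en)
  scl_slope <- rd("double", 112, 1, 4, en)
  scl_inter <- rd("double", 116, 1, 4, en)
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  qform_code <- rd("integer", 252, 1, 2, en)
  sform_code <- rd("integer", 254, 1, 2, en)

  affine <- NULL
  if (sform_code > 0L) {
    affine <- rbind(rd("double", 280, 4, 4, en),
                    rd("double", 296, 4, 4, en),
                    rd("double", 312, 4, 4, en),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- rd("double", 256, 3, 4, en)   # quatern b, c, d
    qo <- rd("double", 268, 3, 4, en)
    b <- q[1]; c_ <- q[2]; d <- q[3]
    a <- sqrt(max(0, 1 - b^2 - c_^2 - d^2))
    R <- matrix(c(a^2 + b^2 - c_^2 - d^2, 2*(b*c_ - a*d),  2*(b*d + a*c_),
                  2*(b*c_ + a*d),  a^2 + c_^2 - b^2 - d^2, 2*(c_*d - a*b),
                  2*(b*d - a*c_),  2*(c_*d + a*b),  a^2 + d^2 - b^2 - c_^2),
                3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    affine <- rbind(cbind(R %*% S, qo), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine in header")

  dtname <- names(Filter(function(d) d$code == datatype, NIFTI_DTYPES))
  if (length(dtname) == 0L) stop("unsupported NIfTI datatype code ", datatype)
  dt <- NIFTI_DTYPES[[dtname]]

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = en,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dims), spacing = abs(pixdim[2:4]),
       affine = affine, descrip = descrip, datatype = dtname)
}

#' Read a 3-D volume from a NIfTI-1 file
#'
#' Spacing and affine are taken from the header (sform preferred, qform as
#' fallback); intensities are returned unmodified apart from the header's
#' scaling slope/intercept.  The modality tag round-trips through the
#' header description field when the file was written by [write_volume()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality to assume when the file carries no tag.
#' @return An [nvc_volume()].
#' @export
read_volume <- function(path, modality = "CISS") {
  r <- nifti_read(path)
  m <- regmatches(r$descrip, regexpr("modality=[A-Z]+", r$descrip))
  if (length(m) == 1L) modality <- sub("modality=", "", m)
  nvc_volume(r$data, spacing = r$spacing, affine = r$affine,
             modality = modality)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v an [nvc_volume()].
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param datatype on-disk type, `"float32"` (default) or `"float64"`.
#'   `float64` gives bit-exact round trips; `float32` is the conventional
#'   imaging choice.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float64") {
  stopifnot(inherits(v, "nvc_volume"))
  nifti_write(v$data, path, v$spacing, v$affine, datatype = datatype,
              descrip = paste0("nvcfuse modality=", v$modality))
  invisible(path)
}

legend_sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}

#' Read / write label volumes
#'
#' Labels are stored as `int32` NIfTI-1 with the legend in a JSON sidecar
#' (`<stem>.labels.json`) next to the image; integer identity is preserved
#' exactly.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return [read_labels()] returns an [nvc_label_volume()].
#' @export
read_labels <- function(path) {
  r <- nifti_read(path)
  if (!r$datatype %in% c("uint8", "int16", "int32", "uint16"))
    stop("labels must be integral (found ", r$datatype, ")")
  sp <- legend_sidecar_path(path)
  legend <- if (file.exists(sp)) {
    l <- jsonlite::read_json(sp)
    setNames(as.integer(unlist(l)), names(l))
  } else nvc_legend()
  nvc_label_volume(r$data, legend = legend, spacing = r$spacing,
                   affine = r$affine)
}

#' @rdname read_labels
#' @param lv an [nvc_label_volume()].
#' @export
write_labels <- function(lv, path) {
  stopifnot(inherits(lv, "nvc_label_volume"))
  if (is.double(lv$labels) && any(lv$labels != round(lv$labels)))
    stop("labels must be integral")
  nifti_write(lv$labels, path, lv$spacing, lv$affine, datatype = "int32",
              descrip = "nvcfuse labels")
  jsonlite::write_json(as.list(lv$legend), legend_sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}
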