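#' Read an MRC2014 volume
#'
#' Minimal little-endian MRC2014 reader sufficient for segmentation label
#' volumes: modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are
#' supported. The voxel size is taken from the cell dimensions divided by the
#' grid size (MRC headers are in Angstrom; values are returned in Angstrom
#' and converted to nm by callers). Anisotropic voxels are rejected.
#'
#' @param path path to an MRC file.
#' @return list with `data` (3D array, x fastest), `voxel_size_ang`
#'   (scalar, NA when the header carries no usable cell size), `mode`,
#'   `origin_ang`.
#' @seealso [write_mrc()], [read_label_volume()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) .stopf("MRC file not found: %s", path,
                                 class = "fibrilstats_format_error")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_int <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  hdr_num <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")

  nxyz <- hdr_int(3)
  mode <- hdr_int(1)
  hdr_int(3)                      # nxstart/nystart/nzstart
  mxyz <- hdr_int(3)
  cella <- hdr_num(3)
  hdr_num(3)                      # cellb
  hdr_int(3)                      # mapc/mapr/maps
  hdr_num(3)                      # dmin/dmax/dmean
  hdr_int(1)                      # ispg
  nsymbt <- hdr_int(1)
  hdr_int(25)                     # extra
  origin <- hdr_num(3)
  readBin(con, "raw", n = 1024 - 208)  # map id, machst, rms, labels

  if (length(nxyz) != 3 || any(is.na(nxyz)) || any(nxyz <= 0))
    .stopf("not a readable MRC file (bad dimensions): %s", path,
           class = "fibrilstats_format_error")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)

  n <- prod(as.numeric(nxyz))
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    .stopf("unsupported MRC mode %d in %s", mode, path,
           class = "fibrilstats_format_error"))
  if (length(data) < n)
    .stopf("truncated MRC data in %s", path, class = "fibrilstats_format_error")

  vs <- rep(NA_real_, 3)
  ok <- mxyz > 0 & cella > 0
  vs[ok] <- cella[ok] / mxyz[ok]
  voxel <- NA_real_
  if (all(ok)) {
    if (diff(range(vs)) > 1e-3 * mean(vs))
      .stopf("anisotropic voxels (%s Angstrom) are not supported",
             paste(signif(vs, 6), collapse = " x "),
             class = "fibrilstats_unit_error")
    voxel <- mean(vs)
  }
  list(data = array(data, dim = nxyz), voxel_size_ang = voxel,
       mode = mode, origin_ang = origin)
}

#' Write an MRC2014 volume
#'
#' Writes mode 1 (int16) for integer data and mode 2 (float32) otherwise,
#' little-endian, with the voxel size recorded in the cell dimensions in
#' Angstrom.
#'
#' @param vol 3D array.
#' @param path output path.
#' @param voxel_size_ang voxel edge in Angstrom (isotropic).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path, voxel_size_ang) {
  stopifnot(length(dim(vol)) == 3, voxel_size_ang > 0)
  is_int <- all(vol == round(vol)) && max(abs(vol)) < 32767
  mode <- if (is_int) 1L else 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wn <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- dim(vol)
  wi(d); wi(mode); wi(c(0L, 0L, 0L)); wi(d)
  wn(d * voxel_size_ang); wn(c(90, 90, 90)); wi(1:3)
  wn(c(min(vol), max(vol), mean(vol)))
  wi(1L); wi(0L); wi(integer(25)); wn(c(0, 0, 0))
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  wn(stats::sd(as.numeric(vol))); wi(0L)
  writeBin(raw(800), con)
  if (mode == 1L) writeBin(as.integer(vol), con, size = 2, endian = "little")
  else writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}
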