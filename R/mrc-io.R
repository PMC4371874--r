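#' Read and write MRC2014 density files
#'
#' Mode-2 (32-bit float) MRC files, little-endian, with the voxel size
#' recorded in the cell dimensions.  The slowest axis is z (the helix axis
#' for filament volumes), matching the MRC2014 convention for the default
#' axis mapping (mapc, mapr, maps) = (1, 2, 3).  `write_mrc` accepts a
#' [volume_grid()], an [image_grid()] or a 3-D stack of square images
#' carrying an `apix` attribute; `read_mrc` restores the matching kind.
#'
#' @param x grid or stack to write.
#' @param path file path.
#' @param apix sampling override (defaults to `apix(x)`).
#' @return `read_mrc` returns a `volume_grid` (cubic data), an `image_grid`
#'   (nz = 1) or a 3-D array of class `image_stack` with an `apix`
#'   attribute.
#' @export
write_mrc <- function(x, path, apix = NULL) {
  if (is.null(apix)) apix <- attr(x, "apix")
  if (is.null(apix)) stop("no apix given and none attached to the object")
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L) stop("write_mrc handles 2-D and 3-D arrays only")
  vol <- length(unique(d)) == 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L,
                             endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L,
                             endian = "little")
  dat <- as.numeric(x)
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * apix)               # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(dat), max(dat), mean(dat)))
  wi(if (vol) 1L else 0L)    # ispg: 1 volume, 0 image/stack
  wi(0L)                     # nsymbt
  wi(rep(0L, 25L))           # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(dat))                # rms
  wi(1L)                     # nlabl
  lab <- sprintf("%-80s", "written by helixamb")
  writeChar(substr(lab, 1, 80), con, nchars = 80L, eos = NULL)
  writeChar(paste(rep(" ", 9 * 80), collapse = ""), con, nchars = 720L,
            eos = NULL)
  writeBin(dat, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4L,
                            endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4L,
                            endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                               # nstart
  m <- ri(3)
  cella <- rf(3)
  rf(3)                               # cellb
  maps <- ri(3)
  if (length(d) != 3 || any(!is.finite(d)) || any(d <= 0))
    stop("malformed MRC header: bad dimensions in ", path)
  if (!identical(mode, 2L))
    stop("malformed or unsupported MRC: only mode 2 (float32) is read, got mode ",
         mode)
  if (!identical(maps, 1:3))
    stop("malformed MRC header: unsupported axis mapping ",
         paste(maps, collapse = ","))
  if (any(m <= 0) || any(!is.finite(cella)) || cella[1] <= 0)
    stop("malformed MRC header: bad cell in ", path)
  seek(con, 1024L)
  dat <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  if (length(dat) != prod(d))
    stop("truncated MRC data block in ", path)
  apx <- cella[1] / m[1]
  if (d[3] == 1L) {
    image_grid(matrix(dat, d[1], d[2]), apx)
  } else if (d[1] == d[2] && d[2] == d[3]) {
    volume_grid(array(dat, d), apx)
  } else {
    structure(array(dat, d), apix = apx, class = "image_stack")
  }
}
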