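#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG or an uncompressed grayscale TIFF (8- or
#' 16-bit) into an integer matrix (rows = image rows). RGB PNG input is
#' rejected: the pipeline operates on single-channel nuclear-marker images,
#' and any colour preprocessing is a user-side concern.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff)
#' @return integer matrix of pixel values
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] >= 3 &&
          (max(abs(a[, , 1] - a[, , 2])) > 1e-9 ||
           max(abs(a[, , 1] - a[, , 3])) > 1e-9)) {
        stop("RGB PNG input is not supported; convert to grayscale first")
      }
      a <- a[, , 1]
    }
    return(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
  }
  if (ext %in% c("tif", "tiff")) return(read_tiff_gray(path))
  stop("unsupported image format: ", ext)
}

#' Write a grayscale image
#'
#' 8-bit matrices can go to PNG or TIFF; 16-bit data (e.g. instance label
#' masks) is written as uncompressed grayscale TIFF.
#'
#' @param img integer matrix
#' @param path output path (.png, .tif/.tiff)
#' @param bits 8 or 16
#' @export
write_image <- function(img, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) stop("PNG output is 8-bit only; use TIFF for 16-bit")
    png::writePNG(matrix(pmin(pmax(img, 0L), 255L) / 255, nrow(img)), path)
    return(invisible(path))
  }
  if (ext %in% c("tif", "tiff")) {
    write_tiff_gray(img, path, bits = bits)
    return(invisible(path))
  }
  stop("unsupported image format: ", ext)
}

# Minimal baseline TIFF: little-endian, single strip, no compression,
# grayscale (PhotometricInterpretation = BlackIsZero). Enough for the
# fixtures and instance masks this package writes; not a general TIFF codec.

write_tiff_gray <- function(img, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  h <- nrow(img); w <- ncol(img)
  vals <- as.integer(t(img))  # row-major pixel order
  if (any(vals < 0) || any(vals > 2^bits - 1)) stop("pixel values out of range")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_off <- 8L
  nbytes <- h * w * (bits %/% 8L)
  ifd_off <- data_off + nbytes
  writeBin(ifd_off, con, size = 4, endian = "little")
  if (bits == 8L) writeBin(as.raw(vals), con)
  else writeBin(vals, con, size = 2, endian = "little")
  tags <- list(  # tag, type (3 = SHORT, 4 = LONG), count, value
    c(256L, 4L, 1L, w), c(257L, 4L, 1L, h), c(258L, 3L, 1L, bits),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, data_off),
    c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, h), c(279L, 4L, 1L, nbytes))
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    if (tg[2] == 3L) {
      writeBin(tg[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(tg[4], con, size = 4, endian = "little")
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(raw[1:2]), "II")) stop("only little-endian TIFF supported")
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  ifd <- u32(4L)
  ntags <- u16(ifd)
  fields <- list()
  for (i in seq_len(ntags)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(off); typ <- u16(off + 2L)
    val <- if (typ == 3L) u16(off + 8L) else u32(off + 8L)
    fields[[as.character(tag)]] <- val
  }
  w <- fields[["256"]]; h <- fields[["257"]]
  bits <- if (is.null(fields[["258"]])) 8L else fields[["258"]]
  if (!is.null(fields[["259"]]) && fields[["259"]] != 1L)
    stop("compressed TIFF not supported")
  off <- fields[["273"]]
  n <- h * w
  vals <- if (bits == 8L) {
    as.integer(raw[off + seq_len(n)])
  } else {
    b <- as.integer(raw[off + seq_len(2L * n)])
    b[seq(1L, 2L * n, 2L)] + 256L * b[seq(2L, 2L * n, 2L)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
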