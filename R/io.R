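#' Read a grayscale image
#'
#' Supports PNG and TIFF (first channel of multi-channel files) and NPY
#' arrays. PNG/TIFF intensities are returned in `[0, 1]`; NPY arrays are
#' returned as stored.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, `.npy`).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    npy = read_npy(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  as.matrix(img)
}

#' Write a grayscale image
#'
#' PNG is written 8-bit, TIFF 16-bit (both from `[0, 1]` floats, clipped),
#' NPY as float64.
#'
#' @param img numeric matrix.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pmin(pmax(img, 0), 1), path),
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(img, 0), 1), path,
                           bits.per.sample = 16L),
    npy = write_npy(img, path),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

# ---- minimal NPY v1.0 reader/writer (float arrays, no installed package
# provides the format) ---------------------------------------------------

#' Write a numeric array as NPY (v1.0, float64, Fortran order)
#'
#' @param x numeric vector, matrix or array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  shape <- if (length(d) == 1L) sprintf("(%d,)", d) else
    paste0("(", paste(d, collapse = ", "), ")")
  hdr <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                 shape)
  total <- 10L + nchar(hdr) + 1L
  padlen <- (64L - total %% 64L) %% 64L
  hdr <- paste0(hdr, strrep(" ", padlen), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 1L, 0L)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2L, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NPY array (v1.0/2.0, float32/float64/int)
#'
#' @param path file path.
#' @return numeric array with the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stop("not an NPY file", call. = FALSE)
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little") else
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  hdr <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- prod(shape)
  x <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4L,
                               endian = "little")),
    stop("unsupported NPY dtype: ", descr, call. = FALSE))
  if (length(shape) <= 1L) return(x)
  if (fortran) {
    array(x, shape)
  } else {
    aperm(array(x, rev(shape)), rev(seq_along(shape)))
  }
}

# ---- dataset manifest -------------------------------------------------------

#' Write a dataset to disk with a plain-text manifest
#'
#' Writes each pair as `hr_%03d.<fmt>` / `lr_%03d.<fmt>` plus a
#' tab-separated `manifest.tsv` listing index, split, generator seed and
#' relative paths.
#'
#' @param data an `sr_dataset`.
#' @param dir output directory (created if missing).
#' @param format `"png"`, `"tiff"` or `"npy"`.
#' @return path to the manifest, invisibly.
#' @export
write_dataset <- function(data, dir, format = "png") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(data$pairs), function(i) {
    hrp <- sprintf("hr_%03d.%s", i, format)
    lrp <- sprintf("lr_%03d.%s", i, format)
    write_image(data$pairs[[i]]$hr, file.path(dir, hrp))
    write_image(data$pairs[[i]]$lr, file.path(dir, lrp))
    data.frame(index = i, split = data$split[i], seed = data$pairs[[i]]$seed,
               lr = lrp, hr = hrp)
  })
  manifest <- do.call(rbind, rows)
  attr_line <- sprintf("# scale=%d", data$scale)
  mf <- file.path(dir, "manifest.tsv")
  writeLines(attr_line, mf)
  suppressWarnings(utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(mf)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return an `sr_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  first <- readLines(mf, n = 1L)
  scale <- as.integer(sub("# scale=", "", first))
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE, skip = 1L)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    list(hr = read_image(file.path(dir, manifest$hr[i])),
         lr = read_image(file.path(dir, manifest$lr[i])),
         seed = manifest$seed[i])
  })
  structure(list(pairs = pairs, split = as.character(manifest$split),
                 scale = scale), class = "sr_dataset")
}
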