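# Raster file I/O for en face angiograms and masks.
#
# PNG goes through the `png` package. TIFF support is a minimal baseline
# implementation (single-channel, uncompressed, 8- or 16-bit greyscale) —
# no TIFF reader is available among the installed packages. PGM (plain P2
# and raw P5) is supported as a plain-text-friendly interchange format for
# fixtures.

#' Read a greyscale raster image
#'
#' Reads a single-channel 8- or 16-bit greyscale raster (PNG, baseline
#' uncompressed TIFF, or PGM) and maps integer intensities linearly to
#' `[0, 1]` by dividing by the dtype maximum (255 or 65535).
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.pgm` file.
#' @return A list with `pixels` (numeric matrix in `[0, 1]`, rows = image
#'   rows) and `bit_depth` (8 or 16).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read raster: file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = read_png_gray(path),
    tif  = ,
    tiff = read_tiff_gray(path),
    pgm  = read_pgm(path),
    stop("unsupported raster format '", ext, "' for ", path)
  )
}

#' Write a greyscale raster image
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, `.pgm`).
#' @param bit_depth 8 or 16. PNG output is always 8-bit (writer
#'   limitation); TIFF and PGM honour the request.
#' @return `path`, invisibly.
#' @export
write_raster <- function(pixels, path, bit_depth = 8) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  pixels <- pmin(pmax(pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(pixels, path),
    tif  = ,
    tiff = write_tiff_gray(pixels, path, bit_depth),
    pgm  = write_pgm(pixels, path, bit_depth),
    stop("unsupported raster format '", ext, "' for ", path)
  )
  invisible(path)
}

read_png_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L) {
      stop("multi-channel image rejected (", dim(px)[3], " channels): ", path)
    }
    px <- px[, , 1L]
  }
  # readPNG already divides by the dtype maximum
  list(pixels = px, bit_depth = if (is_png_16bit(path)) 16L else 8L)
}

is_png_16bit <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 25L)
  # IHDR bit depth is byte 25 of the file (8 sig + 8 len/type + 8 w/h + 1)
  length(hdr) >= 25L && as.integer(hdr[25]) == 16L
}

# ---- PGM ------------------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  width  <- as.integer(read_pnm_token(con))
  height <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  n <- width * height
  if (magic == "P2") {
    vals <- integer(0)
    while (length(vals) < n) {
      tok <- read_pnm_token(con)
      if (!length(tok)) break
      vals <- c(vals, as.integer(tok))
    }
  } else if (maxval > 255L) {
    vals <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                    endian = "big")
  } else {
    vals <- as.integer(readBin(con, "raw", n = n))
  }
  if (length(vals) != n) stop("truncated PGM file: ", path)
  list(pixels = matrix(vals / maxval, nrow = height, ncol = width,
                       byrow = TRUE),
       bit_depth = if (maxval > 255L) 16L else 8L)
}

read_pnm_token <- function(con) {
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || !nzchar(ch)) return(character(0))
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
    } else if (!grepl("[[:space:]]", ch)) {
      break
    }
  }
  tok <- ch
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || grepl("[[:space:]]", ch)) break
    tok <- paste0(tok, ch)
  }
  tok
}

write_pgm <- function(pixels, path, bit_depth = 8) {
  maxval <- if (bit_depth == 16L) 65535L else 255L
  vals <- matrix(as.integer(round(pixels * maxval)), nrow = nrow(pixels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval)),
             con)
  # one image row per line, plain text
  apply(vals, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

# ---- minimal baseline TIFF ------------------------------------------------

TIFF_TAG <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
              photometric = 262L, strip_offsets = 273L, samples = 277L,
              rows_per_strip = 278L, strip_bytes = 279L)

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2L,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4L,
                               endian = endian)
  if (u16(2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(4L)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
    read_val <- function(at, k) {
      if (type == 3L) vapply(seq_len(k) - 1L, function(j) u16(at + 2L * j),
                             integer(1))
      else vapply(seq_len(k) - 1L, function(j) u32(at + 4L * j), integer(1))
    }
    size <- if (type == 3L) 2L else 4L
    vals <- if (count * size <= 4L) read_val(off + 8L, count)
            else read_val(u32(off + 8L), count)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, ": ", path)
      default
    } else v
  }
  width  <- need(TIFF_TAG[["width"]])
  height <- need(TIFF_TAG[["height"]])
  bits   <- need(TIFF_TAG[["bits"]], 1L)
  if (need(TIFF_TAG[["compression"]], 1L) != 1L) {
    stop("only uncompressed TIFF supported: ", path)
  }
  samples <- need(TIFF_TAG[["samples"]], 1L)
  if (samples != 1L || length(bits) != 1L) {
    stop("multi-channel image rejected (", samples, " samples/pixel): ", path)
  }
  if (!bits %in% c(8L, 16L)) stop("unsupported TIFF bit depth ", bits)
  photometric <- need(TIFF_TAG[["photometric"]], 1L)
  offs  <- need(TIFF_TAG[["strip_offsets"]])
  cnts  <- need(TIFF_TAG[["strip_bytes"]], width * height * bits / 8L)
  data <- unlist(lapply(seq_along(offs), function(i) {
    raw[(offs[i] + 1L):(offs[i] + cnts[i])]
  }))
  vals <- if (bits == 8L) as.integer(data)
          else readBin(data, "integer", n = width * height, size = 2L,
                       signed = FALSE, endian = endian)
  maxval <- if (bits == 8L) 255 else 65535
  px <- matrix(vals / maxval, nrow = height, ncol = width, byrow = TRUE)
  if (photometric == 0L) px <- 1 - px  # WhiteIsZero
  list(pixels = px, bit_depth = bits)
}

write_tiff_gray <- function(pixels, path, bit_depth = 8) {
  height <- nrow(pixels); width <- ncol(pixels)
  maxval <- if (bit_depth == 16L) 65535 else 255
  vals <- as.integer(round(t(pixels) * maxval))  # row-major order
  data <- if (bit_depth == 8L) as.raw(vals)
          else writeBin(vals, raw(), size = 2L, endian = "little")
  data_off <- 8L
  ifd_off <- data_off + length(data)
  entries <- list(
    c(TIFF_TAG[["width"]],          4L, 1L, width),
    c(TIFF_TAG[["height"]],         4L, 1L, height),
    c(TIFF_TAG[["bits"]],           3L, 1L, bit_depth),
    c(TIFF_TAG[["compression"]],    3L, 1L, 1L),
    c(TIFF_TAG[["photometric"]],    3L, 1L, 1L),
    c(TIFF_TAG[["strip_offsets"]],  4L, 1L, data_off),
    c(TIFF_TAG[["samples"]],        3L, 1L, 1L),
    c(TIFF_TAG[["rows_per_strip"]], 4L, 1L, height),
    c(TIFF_TAG[["strip_bytes"]],    4L, 1L, length(data))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_off, con, size = 4L, endian = "little")
  writeBin(data, con)
  writeBin(length(entries), con, size = 2L, endian = "little")
  for (e in entries) {
    e <- as.integer(e)
    writeBin(e[1], con, size = 2L, endian = "little")
    writeBin(e[2], con, size = 2L, endian = "little")
    writeBin(e[3], con, size = 4L, endian = "little")
    if (e[2] == 3L) {  # SHORT: value left-justified in 4-byte slot
      writeBin(e[4], con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(e[4], con, size = 4L, endian = "little")
    }
  }
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}

#' Export a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
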