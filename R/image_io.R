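# Image input/output and grid resampling.
#
# PNG and TIFF go through the png/tiff packages; pixel values are restored
# to their stored integer representation (the readers rescale to [0,1] by
# the bit depth). DICOM support is a purpose-built reader for single-frame
# uncompressed monochrome slices — the only DICOM flavor the registration
# consumes — parsing just the elements needed: Rows, Columns, PixelSpacing,
# BitsAllocated, PixelRepresentation, RescaleSlope/Intercept and PixelData.

#' Load a 2D grayscale image
#'
#' Reads a DICOM, PNG, TIFF, or CSV image into an \linkS4class{Image2D}.
#' Pixel spacing is taken from DICOM metadata when present; other formats
#' get spacing (1, 1). PNG/TIFF values are returned on their stored
#' integer scale (e.g. 0..255 for 8-bit); no further rescaling is applied.
#'
#' @param path path to the image file.
#' @param format_hint one of "auto" (default; by extension and magic
#'   bytes), "dicom", "png", "tiff", "csv".
#' @return an \linkS4class{Image2D}.
#' @export
loadImage <- function(path, format_hint = c("auto", "dicom", "png", "tiff",
                                            "csv")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (format_hint != "auto") format_hint else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("dcm", "dicom", "ima")) "dicom"
    else if (ext == "png") "png"
    else if (ext %in% c("tif", "tiff")) "tiff"
    else if (ext %in% c("csv", "txt")) "csv"
    else {
      magic <- readBin(path, "raw", n = 132L)
      if (length(magic) >= 132L &&
          rawToChar(magic[129:132]) == "DICM") "dicom"
      else if (length(magic) >= 4L &&
               identical(magic[1:4],
                         as.raw(c(0x89, 0x50, 0x4e, 0x47)))) "png"
      else stop("cannot determine format of ", path,
                "; pass format_hint")
    }
  }
  switch(fmt,
    png  = .load_raster(png::readPNG(path)),
    tiff = .load_raster(tiff::readTIFF(path)),
    dicom = .load_dicom(path),
    csv  = Image2D(as.matrix(utils::read.csv(path, header = FALSE)))
  )
}

.load_raster <- function(arr) {
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L &&
        !all(arr[, , 1] == arr[, , 2]))
      stop("color images are not supported; supply a grayscale image")
    arr <- arr[, , 1]
  }
  # readPNG/readTIFF scale to [0,1]; restore the stored integer scale
  # (8-bit values are exact multiples of 1/255, else assume 16-bit)
  v8 <- arr * 255
  px <- if (max(abs(v8 - round(v8))) < 1e-9) round(v8)
        else round(arr * 65535)
  Image2D(px)
}

#' Write an image as PNG (8-bit), TIFF (16-bit) or CSV
#'
#' Integer-valued images round-trip bit-exactly through the raster
#' formats within each format's stored range (0..255 for PNG, 0..65535
#' for TIFF); CSV dumps the raw matrix for plain-text fixtures.
#'
#' @param img an \linkS4class{Image2D} or matrix.
#' @param path output path; format chosen by extension (.png, .tif/.tiff,
#'   .csv).
#' @return the path, invisibly.
#' @export
writeImage <- function(img, path) {
  px <- .as_pixel_matrix(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(px, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "png") {
    if (min(px) < 0 || max(px) > 255)
      stop("pixel values must lie in 0..255 for 8-bit PNG output; ",
           "use TIFF for 16-bit data")
    png::writePNG(px / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (min(px) < 0 || max(px) > 65535)
      stop("pixel values must lie in 0..65535 for 16-bit TIFF output")
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else stop("unsupported output extension: ", ext)
  invisible(path)
}

# --- minimal DICOM reader (explicit/implicit VR little endian,
#     single-frame monochrome, uncompressed) ---------------------------

.dcm_u16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
.dcm_u32 <- function(raw, at) {
  v <- as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
       65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
  v
}

.load_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 200L) stop("not a DICOM file: ", path)
  pos <- if (rawToChar(raw[129:132]) == "DICM") 133L else 1L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  meta <- list(rows = NA, cols = NA, spacing = c(NA, NA), bits = 16L,
               signed = FALSE, slope = 1, intercept = 0, frames = 1L,
               photometric = "MONOCHROME2", pixel_data = NULL)
  explicit <- TRUE
  n <- length(raw)
  first <- TRUE
  while (pos + 8L <= n) {
    group <- .dcm_u16(raw, pos); elem <- .dcm_u16(raw, pos + 2L)
    if (first && group != 2L) {
      # detect implicit VR: bytes 5-6 not a plausible VR
      vr_try <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (!grepl("^[A-Z][A-Z]$", vr_try)) explicit <- FALSE
      first <- FALSE
    }
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- .dcm_u32(raw, pos + 8L); data_at <- pos + 12L
      } else {
        len <- .dcm_u16(raw, pos + 6L); data_at <- pos + 8L
      }
    } else {
      vr <- ""; len <- .dcm_u32(raw, pos + 4L); data_at <- pos + 8L
    }
    if (len == 4294967295) stop("encapsulated/undefined-length DICOM not supported")
    val_raw <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw[0]
    tag <- sprintf("%04x,%04x", group, elem)
    str_val <- function() trimws(rawToChar(val_raw))
    if (tag == "0028,0010") meta$rows <- .dcm_u16(val_raw, 1L)
    else if (tag == "0028,0011") meta$cols <- .dcm_u16(val_raw, 1L)
    else if (tag == "0028,0100") meta$bits <- .dcm_u16(val_raw, 1L)
    else if (tag == "0028,0103") meta$signed <- .dcm_u16(val_raw, 1L) == 1L
    else if (tag == "0028,0002" && .dcm_u16(val_raw, 1L) != 1L)
      stop("only single-sample (monochrome) DICOM is supported")
    else if (tag == "0028,0008") meta$frames <- as.integer(str_val())
    else if (tag == "0028,0030")
      meta$spacing <- as.numeric(strsplit(str_val(), "\\\\")[[1]])
    else if (tag == "0028,1052") meta$intercept <- as.numeric(str_val())
    else if (tag == "0028,1053") meta$slope <- as.numeric(str_val())
    else if (tag == "0002,0010") {
      ts <- str_val()
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax: ", ts)
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      first <- FALSE
    }
    else if (tag == "7fe0,0010") { meta$pixel_data <- val_raw; break }
    pos <- data_at + len
  }
  if (is.na(meta$frames)) meta$frames <- 1L
  if (meta$frames > 1L) stop("multi-frame DICOM is not supported")
  if (is.na(meta$rows) || is.null(meta$pixel_data))
    stop("DICOM file lacks image dimensions or pixel data")
  bytes <- if (meta$bits > 8L) 2L else 1L
  npx <- meta$rows * meta$cols
  if (length(meta$pixel_data) < npx * bytes)
    stop("DICOM pixel data truncated")
  vals <- readBin(meta$pixel_data, what = "integer", n = npx,
                  size = bytes, signed = if (bytes == 1L) FALSE else meta$signed,
                  endian = "little")
  if (bytes == 2L && !meta$signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  px <- matrix(as.numeric(vals), nrow = meta$rows, ncol = meta$cols,
               byrow = TRUE)
  px <- px * meta$slope + meta$intercept
  sp <- if (anyNA(meta$spacing)) c(1, 1) else meta$spacing
  Image2D(px, spacing = sp)
}

# --- resampling -------------------------------------------------------

#' Resample an image onto a target grid
#'
#' Maps the image onto a grid with the given pixel spacing and shape while
#' preserving the physical field of view: both grids are aligned at their
#' physical centers, so changing spacing magnifies or shrinks the content
#' by the spacing ratio (e.g. a 384x384 CBCT slice at 1.27 mm upsampled to
#' the 512x512, 1.17 mm CT grid is magnified by 1.27/1.17). Positions
#' falling outside the input are padded with the input minimum.
#'
#' @param img an \linkS4class{Image2D}.
#' @param target_spacing numeric(2), (row_mm, col_mm) > 0.
#' @param target_shape integer(2), output (rows, cols); defaults to the
#'   input shape.
#' @param interpolation "bilinear" (default) or "nearest".
#' @return an \linkS4class{Image2D} with exactly \code{target_shape}.
#' @examples
#' cb <- makePhantom(phantomSpec(shape = c(96, 96), seed = 2))
#' cb@spacing <- c(1.27, 1.27)
#' up <- resampleToGrid(cb, c(1.17, 1.17), c(128, 128))
#' dim(up)
#' @export
resampleToGrid <- function(img, target_spacing, target_shape = NULL,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(img, "Image2D"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 2L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target_spacing must be two strictly positive numbers")
  px <- img@pixels
  if (is.null(target_shape)) target_shape <- dim(px)
  target_shape <- as.integer(target_shape)
  if (identical(target_shape, dim(px)) &&
      isTRUE(all.equal(target_spacing, img@spacing)))
    return(img)
  M <- nrow(px); N <- ncol(px)
  Mo <- target_shape[1]; No <- target_shape[2]
  # align physical centers; source position of output pixel (r, c):
  src_r <- ((seq_len(Mo) - 1) - (Mo - 1) / 2) * target_spacing[1] /
           img@spacing[1] + (M - 1) / 2
  src_c <- ((seq_len(No) - 1) - (No - 1) / 2) * target_spacing[2] /
           img@spacing[2] + (N - 1) / 2
  pad <- min(px)
  if (interpolation == "nearest") {
    ri <- round(src_r) + 1; ci <- round(src_c) + 1
    rok <- ri >= 1 & ri <= M; cok <- ci >= 1 & ci <= N
    out <- matrix(pad, Mo, No)
    out[rok, cok] <- px[ri[rok], ci[cok], drop = FALSE]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    # clamp exact upper-border hits into the last cell
    hit <- r0 == M - 1 & fr == 0; r0[hit] <- M - 2; fr[hit] <- 1
    hit <- c0 == N - 1 & fc == 0; c0[hit] <- N - 2; fc[hit] <- 1
    rok <- r0 >= 0 & r0 <= M - 2; cok <- c0 >= 0 & c0 <= N - 2
    out <- matrix(pad, Mo, No)
    if (any(rok) && any(cok)) {
      r0i <- r0[rok] + 1; c0i <- c0[cok] + 1
      frv <- fr[rok]; fcv <- fc[cok]
      A <- px[r0i, c0i, drop = FALSE]; B <- px[r0i, c0i + 1, drop = FALSE]
      C <- px[r0i + 1, c0i, drop = FALSE]; D <- px[r0i + 1, c0i + 1, drop = FALSE]
      W1 <- outer(1 - frv, 1 - fcv); W2 <- outer(1 - frv, fcv)
      W3 <- outer(frv, 1 - fcv); W4 <- outer(frv, fcv)
      out[rok, cok] <- W1 * A + W2 * B + W3 * C + W4 * D
    }
  }
  Image2D(out, spacing = target_spacing, origin = img@origin)
}
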