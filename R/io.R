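# Image and point-table I/O. PNG via the png package, TIFF via the tiff
# package; both return intensities already scaled by the format maximum,
# which matches the pipeline's [0, 1] convention.

#' Read a grayscale image as a ThermalImage
#'
#' Intensities are scaled to \code{[0, 1]} by the format maximum
#' (255 for 8-bit, 65535 for 16-bit). Multi-channel files are an error
#' unless a collapse rule is given.
#'
#' @param path PNG or TIFF file.
#' @param channels how to handle multi-channel input: \code{"error"}
#'   (default), \code{"mean"} (average channels) or \code{"first"}.
#' @return A \linkS4class{ThermalImage}.
#' @export
readThermalImage <- function(path, channels = c("error", "mean", "first")) {
  channels <- match.arg(channels)
  if (!file.exists(path)) stop("image file not found: ", path)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  is_tif <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (!is_png && !is_tif) stop("unsupported image format: ", path)
  if (is_png) {
    arr <- png::readPNG(path)
    # png::readPNG divides by 2^depth - 1; recover depth from the raw IHDR
    depth <- .png_bit_depth(path)
  } else {
    arr <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(arr, "bits.per.sample")
    depth <- if (isTRUE(bps == 16L)) 16L else 8L
  }
  if (length(dim(arr)) == 3L) {
    if (channels == "error")
      stop("multi-channel image; pass channels = 'mean' or 'first'")
    arr <- if (channels == "mean") apply(arr, c(1, 2), mean) else arr[, , 1]
  }
  if (length(arr) == 0L) stop("zero-size image: ", path)
  arr <- array(as.numeric(arr), dim(arr))  # drop reader metadata attrs
  ThermalImage(arr, bitDepth = depth)
}

.png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 33L)
  # IHDR bit depth is byte 25 (8 signature + 4 length + 4 "IHDR" + 8 dims)
  as.integer(hdr[25])
}

#' Write a ThermalImage to PNG or TIFF
#'
#' Quantizes the \code{[0, 1]} intensities at the requested bit depth;
#' values already on the k/(2^depth - 1) grid round-trip bit-identically.
#' PNG output is 8-bit (the png writer's native depth); use TIFF for
#' 16-bit output.
#'
#' @param img a \linkS4class{ThermalImage}.
#' @param path destination (\code{.png} or \code{.tif}/\code{.tiff}).
#' @param bitDepth 8 or 16; defaults to the image's metadata depth.
#' @return \code{path}, invisibly.
#' @export
writeThermalImage <- function(img, path, bitDepth = NULL) {
  stopifnot(is(img, "ThermalImage"))
  if (is.null(bitDepth)) bitDepth <- img@bitDepth
  stopifnot(bitDepth %in% c(8L, 16L))
  p <- pmin(pmax(pixels(img), 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (bitDepth == 16L)
      stop("16-bit output requires TIFF; PNG output is 8-bit")
    png::writePNG(p, target = path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(p, path, bits.per.sample = as.integer(bitDepth))
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Read control-point pairs from CSV
#'
#' Expects the header
#' \code{id,x_source,y_source,x_target,y_target,cost,provenance}.
#'
#' @param path CSV file.
#' @return A \linkS4class{MatchSet}.
#' @export
readControlPoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_source", "y_source", "x_target", "y_target")
  if (!all(need %in% names(df)))
    stop("control-point CSV must contain columns ",
         paste(need, collapse = ", "))
  if (is.null(df$cost)) df$cost <- 0
  if (is.null(df$provenance)) df$provenance <- "strict"
  MatchSet(df$x_source, df$y_source, df$x_target, df$y_target,
           df$cost, df$provenance)
}

#' Write control-point pairs to CSV
#'
#' @param matches a \linkS4class{MatchSet}.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
writeControlPoints <- function(matches, path) {
  utils::write.csv(as.data.frame(matches), path, row.names = FALSE)
  invisible(path)
}

#' Write detected feature points to CSV
#'
#' Emits columns \code{x,y,response,kind,suppression_radius}.
#'
#' @param points a \linkS4class{FeaturePointSet}.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
writeFeaturePoints <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

# run a block with a private, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
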