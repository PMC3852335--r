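# Image and sidecar I/O.
#
# Images are read from PNG or TIFF (8-bit grayscale or RGB; RGB is converted
# by luminance). Contours and ground truth are written as JSON sidecars with
# boundaries as coordinate arrays in 0-based pixel coordinates, x rightward,
# y downward.

#' Read a biopsy image from PNG or TIFF
#'
#' @param path image file (\code{.png}, \code{.tif}/\code{.tiff}).
#' @param grade optional grade label to attach.
#' @return A \linkS4class{BiopsyImage} on the 0--255 intensity scale.
#' @export
readBiopsyImage <- function(path, grade = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = {
                if (!requireNamespace("tiff", quietly = TRUE))
                  stop("reading TIFF requires the 'tiff' package")
                tiff::readTIFF(path)
              },
              stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3L) {
    if (dim(a)[3L] >= 3L)
      a <- 0.2126 * a[, , 1L] + 0.7152 * a[, , 2L] + 0.0722 * a[, , 3L]
    else a <- a[, , 1L]
  }
  BiopsyImage(a * 255, grade = grade, sourceId = basename(path))
}

#' Write a biopsy image as 8-bit grayscale PNG
#'
#' @param image a \linkS4class{BiopsyImage}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBiopsyImage <- function(image, path) {
  stopifnot(is(image, "BiopsyImage"))
  png::writePNG(pmin(pmax(pixels(image) / 255, 0), 1), path)
  invisible(path)
}

boundaryToList <- function(b) {
  list(closed = b@closed,
       x = as.numeric(vertices(b)[, 1L]),
       y = as.numeric(vertices(b)[, 2L]))
}

listToBoundary <- function(l)
  Boundary(cbind(as.numeric(l$x), as.numeric(l$y)), closed = isTRUE(l$closed))

#' Write ground truth as a JSON sidecar
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  doc <- list(grade = truth@grade,
              crypt_count = length(truth@boundaries),
              crypt_boundaries = lapply(truth@boundaries, boundaryToList),
              crypt_centroids = list(x = as.numeric(truth@centroids[, 1L]),
                                     y = as.numeric(truth@centroids[, 2L])),
              muscularis_polyline = list(x = as.numeric(truth@muscularis[, 1L]),
                                         y = as.numeric(truth@muscularis[, 2L])))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path file written by \code{\link{writeGroundTruth}}.
#' @return A \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bnds <- lapply(seq_len(doc$crypt_count), function(i)
    listToBoundary(list(closed = doc$crypt_boundaries$closed[i],
                        x = doc$crypt_boundaries$x[[i]],
                        y = doc$crypt_boundaries$y[[i]])))
  new("GroundTruth", boundaries = bnds,
      centroids = cbind(doc$crypt_centroids$x, doc$crypt_centroids$y),
      muscularis = cbind(x = doc$muscularis_polyline$x,
                         y = doc$muscularis_polyline$y),
      grade = doc$grade)
}

#' Write a contour set as a JSON sidecar
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContourSet <- function(contours, path) {
  stopifnot(is(contours, "ContourSet"))
  doc <- list(crypts = lapply(crypts(contours), boundaryToList),
              muscularis = if (is.null(muscularis(contours))) NULL
                           else boundaryToList(muscularis(contours)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a contour-set JSON sidecar
#'
#' @param path file written by \code{\link{writeContourSet}}.
#' @return A \linkS4class{ContourSet}.
#' @export
readContourSet <- function(path) {
  doc <- jsonlite::read_json(path)
  ContourSet(crypts = lapply(doc$crypts, listToBoundary),
             muscularis = if (is.null(doc$muscularis)) NULL
                          else listToBoundary(doc$muscularis))
}
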