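## TIFF / YAML / CSV interfaces.
## Fields travel as multi-page 16-bit TIFF (fixed channel order DAPI, NPM1,
## NCL, mHTT) plus a channel-map YAML carrying channel names and the pixel
## size; intensities are rounded to 16-bit at write time only.

#' Write an ImageField as a multi-page 16-bit TIFF
#'
#' @param field an [ImageField-class].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
writeImageField <- function(field, path) {
  d <- dim(field@imageData)
  pages <- lapply(seq_len(d[3]), function(k)
    round(pmin(pmax(field@imageData[, , k], 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an ImageField
#'
#' @param path TIFF path.
#' @param channels channel names, one per page (e.g. from [readChannelMap()]).
#' @param pixelSize micrometres per pixel.
#' @param fieldId,sampleId identifiers (default: file name).
#' @return An [ImageField-class] with intensities on the \[0, 65535\] scale.
#' @export
readImageField <- function(path, channels, pixelSize,
                           fieldId = sub("\\.tiff?$", "", basename(path)),
                           sampleId = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channels))
    stop("TIFF has ", length(pages), " pages but ", length(channels),
         " channel names were given")
  d <- dim(pages[[1]])
  img <- array(0, dim = c(d[1], d[2], length(pages)),
               dimnames = list(NULL, NULL, channels))
  for (k in seq_along(pages)) img[, , k] <- pages[[k]] * 65535
  ImageField(img, channels, pixelSize, fieldId, sampleId)
}

#' Read a channel-map YAML
#'
#' Expected keys: `channels` (list of names in page order) and `pixelSize`
#' (um/pixel).
#'
#' @param path YAML file path.
#' @return List with `channels` and `pixelSize`.
#' @export
readChannelMap <- function(path) {
  cm <- yaml::read_yaml(path)
  if (is.null(cm$channels) || is.null(cm$pixelSize))
    stop("channel map must define 'channels' and 'pixelSize'")
  list(channels = unlist(cm$channels), pixelSize = as.numeric(cm$pixelSize))
}
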