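#' Construct an ImageField
#'
#' @param imageData numeric array (rows, cols, channels) in \[0, 65535\].
#' @param channelNames character vector naming the channels.
#' @param pixelSize micrometres per pixel.
#' @param fieldId,sampleId identifiers.
#' @return An [ImageField-class] object.
#' @export
ImageField <- function(imageData, channelNames, pixelSize,
                       fieldId = "field", sampleId = NA_character_) {
  new("ImageField", imageData = imageData, channelNames = channelNames,
      pixelSize = pixelSize, fieldId = fieldId, sampleId = sampleId)
}

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageField", function(x) x@pixelSize)

#' @rdname channelNames
#' @export
setMethod("channelNames", "ImageField", function(x) x@channelNames)

#' @rdname fieldId
#' @export
setMethod("fieldId", "ImageField", function(x) x@fieldId)

#' @rdname getChannel
#' @export
setMethod("getChannel", "ImageField", function(x, channel) {
  i <- match(channel, x@channelNames)
  if (is.na(i))
    stop("channel '", channel, "' not present; available: ",
         paste(x@channelNames, collapse = ", "))
  x@imageData[, , i]
})

setMethod("dim", "ImageField", function(x) dim(x@imageData))

setMethod("show", "ImageField", function(object) {
  d <- dim(object@imageData)
  cat("ImageField '", object@fieldId, "': ", d[1], " x ", d[2], " px, ",
      d[3], " channels (", paste(object@channelNames, collapse = ", "),
      ") at ", object@pixelSize, " um/px\n", sep = "")
})
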