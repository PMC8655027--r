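#' @include AllClasses.R
NULL

#' Physical pixel size of an object
#'
#' @param x an object carrying a pixel size (an [ImageField] or [NucleusSet]).
#' @return Pixel edge length in micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Channel names of an image field
#'
#' @param x an [ImageField].
#' @return Character vector of channel names in storage order.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel as an intensity matrix
#'
#' @param x an [ImageField].
#' @param channel channel name (e.g. `"DAPI"`, `"NPM1"`, `"NCL"`, `"mHTT"`).
#' @return Numeric matrix of intensities (rows x cols).
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' Field identifier
#'
#' @param x an [ImageField] or [NucleusSet].
#' @return Character scalar field id.
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' Label raster of a segmentation
#'
#' @param x a [NucleusSet].
#' @return Integer matrix; 0 is background, positive integers are nucleus ids.
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' Per-nucleus feature table of a segmentation
#'
#' @param x a [NucleusSet].
#' @return `data.frame` with one row per nucleus (id, centroid, area, mean
#'   DAPI intensity).
#' @export
setGeneric("nucleusTable", function(x) standardGeneric("nucleusTable"))

#' P-value of a statistical comparison
#'
#' @param x a [ComparisonResult].
#' @return Numeric scalar: the (omnibus) p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Pairwise post hoc table of a comparison
#'
#' @param x a [ComparisonResult].
#' @return `data.frame` of pairwise contrasts (empty for two-group tests).
#' @export
setGeneric("pairwiseTable", function(x) standardGeneric("pairwiseTable"))

#' Relative difference of group means
#'
#' For two groups A (first) and B (second), `100 * (1 - mean_B / mean_A)`.
#'
#' @param x a [ComparisonResult].
#' @return Numeric scalar in percent (NA when not a two-group comparison).
#' @export
setGeneric("relativeDifference", function(x) standardGeneric("relativeDifference"))

#' Per-sample values entering a comparison
#'
#' @param x a [ComparisonResult].
#' @return Named list of numeric vectors, one per group.
#' @export
setGeneric("groupValues", function(x) standardGeneric("groupValues"))
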