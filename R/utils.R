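## shared helpers: background estimation and field -> sample aggregation

## modal intensity of a channel, used as the field background estimate
## (background pixels dominate the raster, so the density mode sits on them)
.modalIntensity <- function(img) {
  v <- as.numeric(img)
  if (length(v) > 2e5) v <- v[seq(1L, length(v), length.out = 2e5)]
  d <- stats::density(v, n = 512)
  d$x[which.max(d$y)]
}

#' Aggregate per-nucleus measurements to per-sample values
#'
#' Implements the two-level aggregation used throughout: per-field mean of a
#' per-nucleus column, then per-sample mean over the sample's fields. Rows
#' flagged `skipped` are dropped. Fields without nuclei contribute no
#' estimate; a sample whose fields are all empty gets `NA` (undefined, not
#' zero).
#'
#' @param measurements `data.frame` with a `fieldId` column and the value
#'   column (per-nucleus rows).
#' @param value name of the column to aggregate (logical columns are
#'   averaged as 0/1 fractions).
#' @param manifest cohort manifest mapping `fieldId` to `sampleId` and
#'   `group` (see [cohortManifest()]); `NULL` returns per-field values only.
#' @param na.rm drop `NA` values within a field before averaging.
#' @return With a manifest: `data.frame(group, sampleId, value, nFields,
#'   nNuclei)`, one row per sample. Without: `data.frame(fieldId, value, n)`.
#' @export
summarizeBySample <- function(measurements, value, manifest = NULL,
                              na.rm = TRUE) {
  if (!value %in% names(measurements))
    stop("no column '", value, "' in measurements")
  df <- measurements
  if ("skipped" %in% names(df)) df <- df[!(df$skipped %in% TRUE), ]
  v <- as.numeric(df[[value]])
  perField <- if (nrow(df) == 0L) data.frame(
    fieldId = character(), value = numeric(), n = integer(),
    stringsAsFactors = FALSE) else data.frame(
    fieldId = names(tapply(v, df$fieldId, function(x) 1)),
    value = as.numeric(tapply(v, df$fieldId, mean, na.rm = na.rm)),
    n = as.integer(tapply(v, df$fieldId, function(x) sum(!is.na(x)))),
    stringsAsFactors = FALSE)
  if (is.null(manifest)) return(perField)
  man <- unique(manifest[, c("group", "sampleId", "fieldId")])
  merged <- merge(man, perField, by = "fieldId", all.x = TRUE)
  agg <- lapply(split(merged, merged$sampleId), function(s) {
    data.frame(group = s$group[1], sampleId = s$sampleId[1],
               value = if (all(is.na(s$value))) NA_real_ else
                 mean(s$value, na.rm = TRUE),
               nFields = sum(!is.na(s$value)),
               nNuclei = sum(s$n, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$group, out$sampleId), ]
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))
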