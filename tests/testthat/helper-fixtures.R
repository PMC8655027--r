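# constructed fixtures and independent oracles used across the suite

# logical disk mask (pixel centers inside the circle)
diskMask <- function(shape, cr, cc, r) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# ImageField from a named list of intensity matrices
makeField <- function(channels, pixelSize = 0.1, fieldId = "fix") {
  d <- dim(channels[[1]])
  img <- array(0, dim = c(d[1], d[2], length(channels)),
               dimnames = list(NULL, NULL, names(channels)))
  for (k in seq_along(channels)) img[, , k] <- channels[[k]]
  ImageField(img, names(channels), pixelSize, fieldId = fieldId)
}

# NucleusSet from a list of logical masks (hand-built segmentation)
makeNucleusSet <- function(masks, pixelSize = 0.1, fieldId = "fix",
                           dapi = NULL) {
  sh <- dim(masks[[1]])
  lab <- matrix(0L, sh[1], sh[2])
  rows <- lapply(seq_along(masks), function(i) {
    lab[masks[[i]]] <<- i
    ij <- which(masks[[i]], arr.ind = TRUE)
    data.frame(nucleusId = i, centroidRow = mean(ij[, 1]),
               centroidCol = mean(ij[, 2]), areaPx = nrow(ij),
               areaUm2 = nrow(ij) * pixelSize^2,
               meanDapi = if (is.null(dapi)) NA_real_ else
                 mean(dapi[masks[[i]]]))
  })
  new("NucleusSet", labels = lab, nuclei = do.call(rbind, rows),
      pixelSize = pixelSize, fieldId = fieldId)
}

# brute-force two-sided Mann-Whitney p by full enumeration of group
# assignments, computed from rank sums (independent of the package path)
mwuOracle <- function(x, y) {
  n1 <- length(x)
  all <- c(x, y)
  rk <- rank(all)
  wObs <- sum(rk[seq_len(n1)])
  sets <- utils::combn(length(all), n1)
  w <- apply(sets, 2, function(s) sum(rk[s]))
  min(1, 2 * min(mean(w <= wObs + 1e-9), mean(w >= wObs - 1e-9)))
}

# tie-corrected Kruskal-Wallis H from the textbook rank formula
kwOracle <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  rk <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  rSum <- tapply(rk, idx, sum)
  n <- lengths(groups)
  h <- 12 / (N * (N + 1)) * sum(rSum^2 / n) - 3 * (N + 1)
  ties <- table(rk)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# reconstruct a nucleus ellipse mask from one ground-truth row
truthNucleusMask <- function(row, shape, pixelSize) {
  a <- row$radiusUm / pixelSize * sqrt(row$aspect)
  b <- row$radiusUm / pixelSize / sqrt(row$aspect)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rows - row$centerRow
  dc <- cols - row$centerCol
  u <- dr * cos(row$theta) + dc * sin(row$theta)
  v <- -dr * sin(row$theta) + dc * cos(row$theta)
  (u / a)^2 + (v / b)^2 <= 1
}
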