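# Image I/O helpers.  The TIFF writer stores data normalised to [0, 1]
# (the tiff package's storage contract) and records the affine scale in a
# JSON sidecar so arbitrary-valued images round-trip to 32-bit float
# precision.

.write_scaled_tiff <- function(imgs, path) {
  if (!is.list(imgs)) imgs <- list(imgs)
  lo <- min(vapply(imgs, min, numeric(1)))
  hi <- max(vapply(imgs, max, numeric(1)))
  span <- if (hi > lo) hi - lo else 1
  scaled <- lapply(imgs, function(m) (m - lo) / span)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = TRUE)
  jsonlite::write_json(list(min = lo, max = hi),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_scaled_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  span <- if (meta$max > meta$min) meta$max - meta$min else 1
  lapply(imgs, function(m) m * span + meta$min)
}
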