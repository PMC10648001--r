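# SPLASH spectral hash (mass-spectrum flavour, "splash10-").
#
# Four dash-separated blocks:
#   1. "splash" + spectrum type (1 = MS) + protocol version (0)
#   2. prefilter histogram: intensities summed into 10 wrapped 5-Da bins,
#      scaled to base-3 digits, the base-3 number re-encoded in base 36 and
#      left-padded to 4 characters
#   3. similarity histogram: 10 wrapped 100-Da bins scaled to base-10 digits
#   4. first 20 hex characters of the SHA256 of the peak list, peaks sorted
#      by m/z (ties: intensity descending), each encoded as
#      round(mz * 1e6):round(999 * intensity / max intensity) joined by " "
# Intensities only ever enter after normalisation, so the hash is invariant
# under intensity scaling. Constants are pinned here; the bundled Python
# script inst/splash/splash_oracle.py re-implements the same protocol
# independently for cross-checking.

.splash_eps <- 1e-7
.base36 <- c(0:9, letters)

splash_histogram <- function(mz, intensity, base, nbins, bin_size) {
  bins <- (floor(mz / bin_size) %% nbins) + 1
  h <- vapply(seq_len(nbins), function(b) sum(intensity[bins == b]), numeric(1))
  m <- max(h)
  if (m <= 0) return(rep(0L, nbins))
  as.integer(floor(.splash_eps + (base - 1) * h / m))
}

base36_encode <- function(digits, base, width) {
  # digits: most-significant first, in `base`
  val <- 0
  for (d in digits) val <- val * base + d
  out <- character()
  while (val > 0) {
    out <- c(.base36[(val %% 36) + 1], out)
    val <- val %/% 36
  }
  paste0(strrep("0", max(0, width - length(out))), paste(out, collapse = ""))
}

#' Compute the SPLASH of a peak list
#'
#' @param peaks Two-column matrix or data frame with m/z and intensity
#'   (>= 1 peak).
#' @return SPLASH string with prefix `"splash10-"`.
#' @examples
#' compute_splash(cbind(mz = c(100.0212, 145.1015), intensity = c(500, 1000)))
#' @export
compute_splash <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (!nrow(peaks)) abort("empty peak list", class = "mixlib_splash_error")
  mz <- as.numeric(peaks[, 1]); intensity <- as.numeric(peaks[, 2])
  block2 <- base36_encode(splash_histogram(mz, intensity, 3, 10, 5),
                          base = 3, width = 4)
  block3 <- paste(splash_histogram(mz, intensity, 10, 10, 100), collapse = "")
  ord <- order(mz, -intensity)
  rel <- round(999 * intensity / max(intensity))
  payload <- paste(sprintf("%.0f:%.0f", round(mz[ord] * 1e6), rel[ord]),
                   collapse = " ")
  block4 <- substr(digest::digest(payload, algo = "sha256", serialize = FALSE), 1, 20)
  paste("splash10", block2, block3, block4, sep = "-")
}
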