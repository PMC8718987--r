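# Independent oracles and small fixture builders shared across tests.

# brute-force integrated density: explicit double loop over every pixel
brute_force_disk_sum <- function(pixels, row0, col0, radius, background = 0) {
  total <- 0
  area <- 0L
  for (r in seq_len(nrow(pixels))) {
    for (cc in seq_len(ncol(pixels))) {
      if ((r - row0)^2 + (cc - col0)^2 <= radius^2) {
        total <- total + pixels[r, cc]
        area <- area + 1L
      }
    }
  }
  list(integrated = total - background * area, area = area)
}

# brute-force exact two-sided Wilcoxon rank-sum p by enumerating every
# assignment of the pooled values to the two groups
brute_force_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  all_u <- apply(utils::combn(N, m), 2, u_of)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# hard-edged disk image: intensity `value` where dist <= radius, else `bg`
disk_image <- function(height, width, row0, col0, radius, value, bg = 0) {
  d2 <- outer((seq_len(height) - row0)^2, (seq_len(width) - col0)^2, `+`)
  px <- matrix(bg, height, width)
  px[d2 <= radius^2] <- value
  membrane_image(px, is_reductive_scale = TRUE, scale_note = "test disk")
}

# join phantom spot measurements with nominal concentrations for calibration
phantom_series <- function(phantom, background = "annulus_median") {
  meas <- measure_spots(phantom$image, phantom$rois, background = background)
  calibration_series(meas)
}
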