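#' Extract a lane intensity profile
#'
#' Gel-Analyzer-style quantification collapses a rectangular lane to a 1D
#' profile: the mean reductive intensity of each slice perpendicular to the
#' lane axis. Axis `"row"` produces one value per image row inside the
#' rectangle (a dorsoventral profile); `"col"` one value per column.
#'
#' @param img Reductive-scale `membrane_image`.
#' @param lane Rectangle `list(row0, col0, height, width)` — top-left corner
#'   (1-based, inclusive) plus extents in px.
#' @param axis `"row"` or `"col"`: the direction the profile runs along.
#' @return A tibble with columns `position` (pixel index along the axis),
#'   `value` (mean intensity) and `baseline` (zeros until
#'   [subtract_profile_baseline()] is applied).
#' @export
extract_lane_profile <- function(img, lane, axis = c("row", "col")) {
  assert_reductive(img, "extract_lane_profile()")
  axis <- match.arg(axis)
  need <- c("row0", "col0", "height", "width")
  if (!all(need %in% names(lane))) {
    stop("lane spec needs row0, col0, height, width", call. = FALSE)
  }
  if (lane$height < 1 || lane$width < 1) {
    stop("degenerate lane rectangle (zero extent)", call. = FALSE)
  }
  rs <- lane$row0:(lane$row0 + lane$height - 1)
  cs <- lane$col0:(lane$col0 + lane$width - 1)
  if (min(rs) < 1 || max(rs) > img$height_px ||
      min(cs) < 1 || max(cs) > img$width_px) {
    stop("lane rectangle leaves image bounds", call. = FALSE)
  }
  block <- img$pixels[rs, cs, drop = FALSE]
  if (axis == "row") {
    tibble::tibble(position = rs, value = rowMeans(block),
                   baseline = 0)
  } else {
    tibble::tibble(position = cs, value = colMeans(block),
                   baseline = 0)
  }
}

# local maxima with simple prominence: height above the higher of the two
# flanking minima
find_profile_peaks <- function(v, min_prominence) {
  n <- length(v)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1L  # plateau
      if (j == n || v[j + 1] < v[i]) peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks)) return(integer(0))
  keep <- vapply(peaks, function(p) {
    lmin <- min(v[1:p]); rmin <- min(v[p:n])
    v[p] - max(lmin, rmin) >= min_prominence
  }, logical(1))
  peaks[keep]
}

# trough (local minimum) flanking a peak on one side
flanking_min <- function(v, p, dir) {
  n <- length(v)
  i <- p
  repeat {
    nxt <- i + dir
    if (nxt < 1L || nxt > n) break
    if (v[nxt] > v[i]) break
    i <- nxt
  }
  i
}

#' Subtract a local-minima baseline from a lane profile
#'
#' Emulates the manual baseline-drawing step of densitometric lane analysis:
#' peaks with prominence of at least `prominence_frac` of the profile range
#' are detected, the local minima flanking each peak become baseline anchor
#' points, and the baseline is the piecewise-linear interpolation through
#' those anchors (flat beyond the outermost anchors). The corrected profile
#' is `max(value - baseline, 0)`. A flat profile yields a baseline equal to
#' the profile and an all-zero output.
#'
#' @param profile Tibble from [extract_lane_profile()] (>= 3 positions).
#' @param prominence_frac Minimum peak prominence, as a fraction of the
#'   profile range. Default 0.05.
#' @return The profile tibble with `baseline` filled in and `value` replaced
#'   by the baseline-subtracted, floored-at-zero values.
#' @export
subtract_profile_baseline <- function(profile, prominence_frac = 0.05) {
  v <- profile$value
  n <- length(v)
  if (n < 3L) stop("profile too short: need at least 3 positions", call. = FALSE)
  rng <- diff(range(v))
  if (rng <= .Machine$double.eps) {
    profile$baseline <- v
    profile$value <- rep(0, n)
    return(profile)
  }
  peaks <- find_profile_peaks(v, prominence_frac * rng)
  if (!length(peaks)) {
    profile$baseline <- v
    profile$value <- rep(0, n)
    return(profile)
  }
  anchors <- sort(unique(c(
    vapply(peaks, flanking_min, integer(1), v = v, dir = -1L),
    vapply(peaks, flanking_min, integer(1), v = v, dir = 1L)
  )))
  if (length(anchors) == 1L) {
    base <- rep(v[anchors], n)
  } else {
    base <- stats::approx(x = anchors, y = v[anchors], xout = seq_len(n),
                          rule = 2)$y
  }
  profile$baseline <- base
  profile$value <- pmax(v - base, 0)
  profile
}

#' Integrate peak areas of a baseline-subtracted profile
#'
#' Contiguous runs of strictly positive corrected values are peaks; each
#' peak's area is the sum of its values (intensity x px) and its position the
#' location of its maximum. This is the peak-area readout of lane
#' densitometry.
#'
#' @param profile Baseline-subtracted profile tibble.
#' @return Tibble with columns `position` (peak apex, ascending) and `area`;
#'   zero rows when there are no peaks.
#' @export
integrate_profile_peaks <- function(profile) {
  v <- profile$value
  pos <- profile$position
  above <- v > 0
  if (!any(above)) return(tibble::tibble(position = numeric(0), area = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- purrr::map_dfr(runs, function(k) {
    idx <- starts[k]:ends[k]
    tibble::tibble(position = pos[idx][which.max(v[idx])],
                   area = sum(v[idx]))
  })
  dplyr::arrange(out, .data$position)
}
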