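#' Spot ROI tables
#'
#' Dot-blot quantification works from a tibble of circular regions of
#' interest, one per applied 1-ul sample spot:
#' \describe{
#'   \item{label}{sample identifier}
#'   \item{row, col}{center, 1-based pixel coordinates}
#'   \item{radius}{disk radius in pixels}
#'   \item{nominal}{optional nominal concentration (mol/L) for calibration
#'     samples, `NA` otherwise}
#' }
#'
#' @param label Character vector of sample identifiers.
#' @param row,col Numeric center coordinates.
#' @param radius Positive disk radius in px (recycled).
#' @param nominal Optional nominal concentrations (mol/L).
#' @return A tibble with class-checked columns as above.
#' @export
spot_rois <- function(label, row, col, radius, nominal = NA_real_) {
  out <- tibble::tibble(
    label = as.character(label),
    row = as.numeric(row),
    col = as.numeric(col),
    radius = as.numeric(radius),
    nominal = as.numeric(nominal)
  )
  if (any(out$radius <= 0)) stop("`radius` must be positive", call. = FALSE)
  out
}

check_roi_bounds <- function(img, rois) {
  bad <- rois$row - rois$radius < 1 | rois$row + rois$radius > img$height_px |
    rois$col - rois$radius < 1 | rois$col + rois$radius > img$width_px
  if (any(bad)) {
    stop("ROI disk leaves image bounds: ",
         paste(rois$label[bad], collapse = ", "), call. = FALSE)
  }
  invisible(rois)
}

#' Locate dot-blot spots
#'
#' With a `grid` layout the expected spot centers are known up to pipetting
#' jitter: each grid node is refined to the intensity-weighted centroid of the
#' surrounding window (half a grid spacing), iterated to convergence. Without
#' a grid, blob detection runs a scale-normalized Laplacian-of-Gaussian over
#' the stated radius range and returns local maxima above `threshold`, sorted
#' row-major. Both paths are deterministic for a fixed image.
#'
#' @param img Reductive-scale `membrane_image`.
#' @param grid Optional list describing the layout:
#'   `list(rows, cols, row0, col0, row_spacing, col_spacing, radius)` where
#'   `(row0, col0)` is the center of the top-left spot.
#' @param radius_range Numeric length-2, candidate blob radii in px (blob
#'   mode only).
#' @param threshold Minimum scale-normalized LoG response for a detection
#'   (blob mode only).
#' @return A [spot_rois()] tibble; labels are `"r<i>c<j>"` for grid mode and
#'   `"blob<k>"` in detection order otherwise. An empty tibble (with a
#'   `no_detections` attribute set) when nothing is found in blob mode.
#' @export
detect_spots <- function(img, grid = NULL, radius_range = c(3, 12),
                         threshold = 0.02) {
  assert_reductive(img, "detect_spots()")
  if (!is.null(grid)) {
    return(detect_spots_grid(img, grid))
  }
  detect_spots_log(img, radius_range, threshold)
}

detect_spots_grid <- function(img, grid) {
  need <- c("rows", "cols", "row0", "col0", "row_spacing", "col_spacing", "radius")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("grid spec missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  rows_idx <- seq_len(grid$rows)
  cols_idx <- seq_len(grid$cols)
  centers <- expand.grid(gr = rows_idx, gc = cols_idx)
  centers <- centers[order(centers$gr, centers$gc), ]
  r0 <- grid$row0 + (centers$gr - 1) * grid$row_spacing
  c0 <- grid$col0 + (centers$gc - 1) * grid$col_spacing
  half_r <- grid$row_spacing / 2
  half_c <- grid$col_spacing / 2
  if (any(r0 - half_r < 0.5) || any(r0 + half_r > img$height_px + 0.5) ||
      any(c0 - half_c < 0.5) || any(c0 + half_c > img$width_px + 0.5)) {
    stop("grid exceeds image bounds", call. = FALSE)
  }
  px <- img$pixels
  refine <- function(r, c) {
    for (it in 1:3) {
      rs <- max(1L, floor(r - half_r)):min(img$height_px, ceiling(r + half_r))
      cs <- max(1L, floor(c - half_c)):min(img$width_px, ceiling(c + half_c))
      w <- px[rs, cs, drop = FALSE]
      w <- w - min(w)   # local background removal before centroiding
      tw <- sum(w)
      if (tw <= .Machine$double.eps) break
      rn <- sum(rowSums(w) * rs) / tw
      cn <- sum(colSums(w) * cs) / tw
      if (abs(rn - r) < 0.05 && abs(cn - c) < 0.05) { r <- rn; c <- cn; break }
      r <- rn; c <- cn
    }
    c(r, c)
  }
  ref <- mapply(refine, r0, c0)
  spot_rois(
    label = sprintf("r%dc%d", centers$gr, centers$gc),
    row = ref[1, ], col = ref[2, ], radius = grid$radius
  )
}

# scale-normalized LoG blob detection over a small set of candidate scales
detect_spots_log <- function(img, radius_range, threshold) {
  sigmas <- unique(pmax(0.8, seq(radius_range[1], radius_range[2],
                                 length.out = 5) / sqrt(2)))
  px <- img$pixels
  best <- matrix(-Inf, nrow(px), ncol(px))
  best_sigma <- matrix(sigmas[1], nrow(px), ncol(px))
  for (s in sigmas) {
    sm <- gaussian_smooth(px, s)
    lap <- discrete_laplacian(sm)
    resp <- -s^2 * lap     # bright blobs give negative LoG; flip sign
    upd <- resp > best
    best[upd] <- resp[upd]
    best_sigma[upd] <- s
  }
  pk <- local_maxima_2d(best, threshold)
  if (nrow(pk) == 0L) {
    out <- spot_rois(character(0), numeric(0), numeric(0), numeric(0))
    attr(out, "no_detections") <- TRUE
    warning("no spots detected; returning empty ROI table", call. = FALSE)
    return(out)
  }
  pk <- pk[order(pk$row, pk$col), , drop = FALSE]
  spot_rois(
    label = sprintf("blob%d", seq_len(nrow(pk))),
    row = pk$row, col = pk$col,
    radius = best_sigma[cbind(pk$row, pk$col)] * sqrt(2)
  )
}

# separable Gaussian smoothing with replicate-edge padding
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + length(v))]
  }
  m2 <- apply(m, 2, conv1)          # along rows
  t(apply(m2, 1, conv1))            # along columns
}

discrete_laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), ]
  dn <- m[c(seq_len(nr - 1) + 1, nr), ]
  lf <- m[, c(1, seq_len(nc - 1))]
  rt <- m[, c(seq_len(nc - 1) + 1, nc)]
  up + dn + lf + rt - 4 * m
}

local_maxima_2d <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  keep <- m >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- m[pmin(pmax(seq_len(nr) + dr, 1), nr),
                 pmin(pmax(seq_len(nc) + dc, 1), nc)]
    keep <- keep & (m >= shifted)
  }
  idx <- which(keep, arr.ind = TRUE)
  # suppress plateau duplicates: keep one per 8-connected cluster
  if (nrow(idx) > 1L) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    taken <- rep(TRUE, nrow(idx))
    for (i in seq_len(nrow(idx))) {
      if (!taken[i]) next
      for (j in seq_len(nrow(idx))[-seq_len(i)]) {
        if (taken[j] && abs(idx[j, 1] - idx[i, 1]) <= 1 &&
            abs(idx[j, 2] - idx[i, 2]) <= 1) taken[j] <- FALSE
      }
    }
    idx <- idx[taken, , drop = FALSE]
  }
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
}

#' Measure background-corrected integrated density of spots
#'
#' For each ROI, sums reductive intensity over the disk of pixel centers at
#' distance `<= radius` from the ROI center (boundary ties included, so
#' `area_px` is deterministic) after subtracting a per-pixel background
#' estimate: the median intensity over an annulus of inner radius
#' `1.2 * radius` and outer radius `1.8 * radius` (`"annulus_median"`), or 0
#' (`"none"`). The median, rather than the mean, resists bleed from
#' neighboring spots. This is the digital analogue of integrated-intensity
#' readout of dots on the developed membrane.
#'
#' @param img Reductive-scale `membrane_image`.
#' @param rois A [spot_rois()] tibble (or any tibble with `label`, `row`,
#'   `col`, `radius` and optionally `nominal`).
#' @param background `"annulus_median"` (default) or `"none"`.
#' @return A tibble with one row per ROI: `label`, `integrated_density`
#'   (intensity x px), `background_level` (intensity/px), `area_px`,
#'   `nominal` (carried through) and `flags` (comma-joined quality notes:
#'   `below_background`, `partial_annulus`).
#' @export
measure_spots <- function(img, rois, background = c("annulus_median", "none")) {
  assert_reductive(img, "measure_spots()")
  background <- match.arg(background)
  check_roi_bounds(img, rois)
  res <- purrr::pmap(
    list(rois$label, rois$row, rois$col, rois$radius),
    function(label, row, col, radius) {
      measure_one_spot(img, row, col, radius, background, label)
    }
  )
  out <- dplyr::bind_rows(res)
  out$nominal <- if ("nominal" %in% names(rois)) rois$nominal else NA_real_
  out
}

measure_one_spot <- function(img, row, col, radius, background, label) {
  px <- img$pixels
  outer_r <- if (background == "annulus_median") 1.8 * radius else radius
  rs <- floor(row - outer_r):ceiling(row + outer_r)
  cs <- floor(col - outer_r):ceiling(col + outer_r)
  rs_in <- rs[rs >= 1 & rs <= img$height_px]
  cs_in <- cs[cs >= 1 & cs <= img$width_px]
  d <- sqrt(outer(rs_in - row, cs_in - col, function(a, b) a^2 + b^2))
  win <- px[rs_in, cs_in, drop = FALSE]
  disk <- d <= radius
  flags <- character(0)
  if (background == "annulus_median") {
    ann <- d >= 1.2 * radius & d <= 1.8 * radius
    clipped <- length(rs_in) < length(rs) || length(cs_in) < length(cs)
    if (clipped) flags <- c(flags, "partial_annulus")
    if (!any(ann)) stop("empty background annulus for ROI ", label, call. = FALSE)
    b <- stats::median(win[ann])
  } else {
    b <- 0
  }
  area <- sum(disk)
  id <- sum(win[disk]) - b * area
  if (id < 0) flags <- c(flags, "below_background")
  tibble::tibble(
    label = label,
    integrated_density = id,
    background_level = b,
    area_px = area,
    flags = paste(flags, collapse = ",")
  )
}
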