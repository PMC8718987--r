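#' Estimate the medial line of a bilateral tissue print
#'
#' Brain-slice prints are near mirror-symmetric about the medial line. The
#' estimator scans candidate columns (by default the central third of the
#' image) and returns the column maximizing the Pearson correlation between
#' the left block and the column-mirrored right block over their overlap.
#' Ties break toward the smaller index; the result is deterministic. A
#' manually drawn midline always takes precedence downstream — pass it
#' directly to [mirror_pair()] instead of calling this.
#'
#' @param img Reductive-scale `membrane_image`, width >= 9.
#' @param search Optional integer vector of candidate columns.
#' @return The estimated midline column (1-based).
#' @export
estimate_midline <- function(img, search = NULL) {
  assert_reductive(img, "estimate_midline()")
  wpx <- img$width_px
  if (wpx < 9) stop("image too narrow for midline estimation (width < 9)",
                    call. = FALSE)
  if (is.null(search)) {
    search <- seq.int(floor(wpx / 3) + 1L, ceiling(2 * wpx / 3))
  }
  search <- sort(unique(as.integer(search)))
  search <- search[search >= 2 & search <= wpx - 1]
  if (!length(search)) stop("empty midline search range", call. = FALSE)
  px <- img$pixels
  scores <- vapply(search, function(m) {
    w <- min(m - 1L, wpx - m)
    if (w < 1L) return(NA_real_)
    left <- as.vector(px[, m - seq_len(w), drop = FALSE])
    right <- as.vector(px[, m + seq_len(w), drop = FALSE])
    if (stats::sd(left) <= .Machine$double.eps ||
        stats::sd(right) <= .Machine$double.eps) return(NA_real_)
    stats::cor(left, right)
  }, numeric(1))
  if (all(is.na(scores))) {
    stop("flat correlation surface (uniform image?): supply the midline manually",
         call. = FALSE)
  }
  search[which.max(scores)]   # which.max takes the first (smallest) maximizer
}

#' Split an image at the midline into ipsilateral and mirrored contralateral fields
#'
#' The mirror axis passes through the center of column `midline_col`
#' (`col' = 2 * midline_col - col`), and the midline column itself belongs to
#' neither side — this convention makes mirroring an exact involution on the
#' integer pixel grid. Both returned fields are `height x overlap` matrices
#' indexed by the offset `d = 1..overlap` from the midline: column `d` of
#' `ipsi` is the pixel `d` columns into the lesioned side, and column `d` of
#' `contra` is its mirror-matched pixel on the intact side, so homologous
#' positions share indices.
#'
#' @param img Reductive-scale `membrane_image`.
#' @param midline_col Midline column (1-based); from [estimate_midline()] or
#'   drawn manually (the manual value is authoritative).
#' @param ipsilateral_side `"right"` or `"left"`: which side carries the
#'   lesion.
#' @return A `bilateral_pair`: list with `ipsi`, `contra` (matrices),
#'   `midline_col`, `ipsilateral_side`, `overlap_width_px`.
#' @export
mirror_pair <- function(img, midline_col, ipsilateral_side = c("right", "left")) {
  assert_reductive(img, "mirror_pair()")
  ipsilateral_side <- match.arg(ipsilateral_side)
  m <- as.integer(midline_col)
  if (m < 1L || m > img$width_px) stop("midline column out of range", call. = FALSE)
  w <- min(m - 1L, img$width_px - m)
  if (w < 1L) stop("midline leaves no overlap between the two sides", call. = FALSE)
  d <- seq_len(w)
  px <- img$pixels
  if (ipsilateral_side == "right") {
    ipsi <- px[, m + d, drop = FALSE]
    contra <- px[, m - d, drop = FALSE]
  } else {
    ipsi <- px[, m - d, drop = FALSE]
    contra <- px[, m + d, drop = FALSE]
  }
  structure(
    list(ipsi = ipsi, contra = contra, midline_col = m,
         ipsilateral_side = ipsilateral_side, overlap_width_px = w,
         height_px = img$height_px, width_px = img$width_px),
    class = "bilateral_pair"
  )
}

#' Pixel-wise sum and difference maps of a bilateral pair
#'
#' The summation map (`ipsi + contra`) shows the shared anatomy; the
#' difference map (`ipsi - contra`) isolates lateralized signal — a lesion
#' that destroyed reductive capacity appears as a negative well in
#' `diff_map`. A perfectly mirror-symmetric slice yields `diff_map == 0`
#' everywhere.
#'
#' @param pair A `bilateral_pair` from [mirror_pair()], or a matrix (the
#'   ipsilateral field), in which case `contra` must be supplied.
#' @param contra Contralateral field matrix when `pair` is a matrix.
#' @return A `bilateral_map`: the pair fields plus `sum_map` and `diff_map`.
#' @export
bilateral_maps <- function(pair, contra = NULL) {
  if (is.matrix(pair)) {
    if (is.null(contra)) stop("supply `contra` when `pair` is a matrix", call. = FALSE)
    pair <- structure(
      list(ipsi = pair, contra = contra, midline_col = NA_integer_,
           ipsilateral_side = "right", overlap_width_px = ncol(pair),
           height_px = nrow(pair), width_px = NA_integer_),
      class = "bilateral_pair"
    )
  }
  if (!identical(dim(pair$ipsi), dim(pair$contra))) {
    stop("ipsilateral and contralateral fields differ in shape", call. = FALSE)
  }
  out <- pair
  out$sum_map <- pair$ipsi + pair$contra
  out$diff_map <- pair$ipsi - pair$contra
  class(out) <- c("bilateral_map", "bilateral_pair")
  out
}

#' @export
print.bilateral_pair <- function(x, ...) {
  cat(sprintf(
    "<%s> midline col %s, ipsilateral = %s, overlap %d px x %d rows\n",
    class(x)[1], as.character(x$midline_col), x$ipsilateral_side,
    x$overlap_width_px, nrow(x$ipsi)
  ))
  invisible(x)
}

#' Paired dorsoventral line profiles
#'
#' Extracts the ipsilateral and contralateral intensity along one
#' parasagittal line of interest: the column at offset `d` from the midline,
#' read in dorsoventral orientation (increasing row index).
#'
#' @param pair A `bilateral_pair` or `bilateral_map`.
#' @param d Column offset from the midline, `1 <= d <= overlap_width_px`.
#' @return Tibble with columns `row`, `ipsi`, `contra`.
#' @export
line_profile <- function(pair, d) {
  d <- as.integer(d)
  if (d < 1L || d > pair$overlap_width_px) {
    stop("offset `d` out of range [1, ", pair$overlap_width_px, "]", call. = FALSE)
  }
  tibble::tibble(
    row = seq_len(nrow(pair$ipsi)),
    ipsi = pair$ipsi[, d],
    contra = pair$contra[, d]
  )
}

#' Define a region of interest
#'
#' Regions are drawn once, on the ipsilateral side, in source-image
#' coordinates; the mirror map samples the homologous contralateral pixels
#' automatically. Either a circle (`center`, `radius`) or a simple polygon
#' (`vertices`, a 2-column row/col matrix) can be given.
#'
#' @param name Region name (e.g. an anatomical abbreviation).
#' @param center Length-2 `(row, col)` circle center.
#' @param radius Circle radius in px.
#' @param vertices 2-column matrix of polygon vertices `(row, col)`.
#' @return A `region_roi` list.
#' @export
region_roi <- function(name, center = NULL, radius = NULL, vertices = NULL) {
  if (is.null(vertices) && (is.null(center) || is.null(radius))) {
    stop("supply either `center` + `radius` or `vertices`", call. = FALSE)
  }
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
      stop("polygon needs a 2-column matrix with >= 3 vertices", call. = FALSE)
    }
  }
  structure(list(name = as.character(name), center = center, radius = radius,
                 vertices = vertices),
            class = "region_roi")
}

# (row, col) pixel centers inside the region, as a 2-column matrix
roi_pixels <- function(roi, height_px, width_px) {
  if (!is.null(roi$vertices)) {
    vr <- roi$vertices[, 1]; vc <- roi$vertices[, 2]
    rs <- max(1L, floor(min(vr))):min(height_px, ceiling(max(vr)))
    cs <- max(1L, floor(min(vc))):min(width_px, ceiling(max(vc)))
    g <- expand.grid(row = rs, col = cs)
    inside <- point_in_polygon(g$row, g$col, vr, vc)
    cbind(row = g$row[inside], col = g$col[inside])
  } else {
    r0 <- roi$center[1]; c0 <- roi$center[2]; rad <- roi$radius
    rs <- max(1L, floor(r0 - rad)):min(height_px, ceiling(r0 + rad))
    cs <- max(1L, floor(c0 - rad)):min(width_px, ceiling(c0 + rad))
    g <- expand.grid(row = rs, col = cs)
    inside <- (g$row - r0)^2 + (g$col - c0)^2 <= rad^2
    cbind(row = g$row[inside], col = g$col[inside])
  }
}

# even-odd ray casting; rows play y, cols play x
point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Compare a region's ipsilateral and contralateral intensity distributions
#'
#' Samples the region's pixels on the ipsilateral field and the
#' mirror-matched pixels on the contralateral field, summarizes both
#' distributions (means, Gaussian kernel densities with Silverman bandwidth
#' on a shared 256-point grid) and records the Euclidean distance from the
#' region centroid to the trauma site in source-image pixels. The *oxidative
#' increment*, `contra_mean - ipsi_mean`, is positive where the lesioned side
#' lost reductive capacity.
#'
#' @param bmap A `bilateral_map` built from a full image (midline known).
#' @param roi A [region_roi()] drawn on the ipsilateral side.
#' @param trauma Length-2 `(row, col)` trauma-site coordinates.
#' @return One-row tibble: `name`, `n_px`, `distance_px`, `ipsi_mean`,
#'   `contra_mean`, `oxidative_increment`, `flags`, plus list-columns
#'   `ipsi_values`, `contra_values` and `density` (tibble `value`,
#'   `ipsi_density`, `contra_density`; each density trapezoid-integrates
#'   to 1 on its grid).
#' @export
compare_region <- function(bmap, roi, trauma) {
  if (!inherits(bmap, "bilateral_map")) stop("`bmap` must be a bilateral_map",
                                             call. = FALSE)
  m <- bmap$midline_col
  if (is.na(m)) stop("bilateral_map lacks a midline: build it via mirror_pair()",
                     call. = FALSE)
  pixels <- roi_pixels(roi, bmap$height_px, bmap$width_px)
  if (nrow(pixels) == 0L) stop("empty region: ", roi$name, call. = FALSE)
  d_off <- if (bmap$ipsilateral_side == "right") pixels[, "col"] - m
           else m - pixels[, "col"]
  if (any(d_off < 1L)) {
    stop("region '", roi$name, "' straddles or crosses the midline", call. = FALSE)
  }
  if (any(d_off > bmap$overlap_width_px)) {
    stop("region '", roi$name, "' leaves the bilateral overlap", call. = FALSE)
  }
  idx <- cbind(pixels[, "row"], d_off)
  ipsi_values <- bmap$ipsi[idx]
  contra_values <- bmap$contra[idx]
  centroid <- c(mean(pixels[, "row"]), mean(pixels[, "col"]))
  dist_px <- sqrt(sum((centroid - trauma)^2))
  flags <- if (nrow(pixels) < 10L) "small_roi" else ""
  dens <- paired_density(ipsi_values, contra_values)
  tibble::tibble(
    name = roi$name,
    n_px = nrow(pixels),
    distance_px = dist_px,
    ipsi_mean = mean(ipsi_values),
    contra_mean = mean(contra_values),
    oxidative_increment = mean(contra_values) - mean(ipsi_values),
    flags = flags,
    ipsi_values = list(ipsi_values),
    contra_values = list(contra_values),
    density = list(dens)
  )
}

# shared-grid Gaussian KDEs; grid spans the pooled range padded by 6
# bandwidths and each curve is trapezoid-renormalized to integrate to 1
paired_density <- function(a, b, n_grid = 256L) {
  pooled <- c(a, b)
  bw <- tryCatch(stats::bw.nrd0(pooled), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-6, 1e-3 * max(abs(pooled), 1))
  lo <- min(pooled) - 6 * bw
  hi <- max(pooled) + 6 * bw
  grid <- seq(lo, hi, length.out = n_grid)
  kde <- function(x) {
    d <- stats::density(x, bw = bw, from = lo, to = hi, n = n_grid)$y
    d / trapezoid(grid, d)
  }
  tibble::tibble(value = grid, ipsi_density = kde(a), contra_density = kde(b))
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Compare several regions at once
#'
#' @param bmap A `bilateral_map`.
#' @param rois List of [region_roi()] objects.
#' @param trauma `(row, col)` trauma site.
#' @return Row-bound tibble of [compare_region()] results.
#' @export
compare_regions <- function(bmap, rois, trauma) {
  dplyr::bind_rows(lapply(rois, function(r) compare_region(bmap, r, trauma)))
}

#' Rank region comparisons by distance to the trauma site
#'
#' Orders regions by ascending distance (alphabetical tie-break) and reports
#' the Spearman rank correlation between distance and oxidative increment —
#' strongly negative when the regions closest to the trauma site are the ones
#' with the greatest loss of reductive capacity.
#'
#' @param comparisons Tibble from [compare_regions()].
#' @return The tibble, sorted, with a `rank` column; attribute
#'   `spearman_rho` carries the distance-vs-increment rank correlation
#'   (`NA` with fewer than 3 regions).
#' @export
rank_regions <- function(comparisons) {
  if (nrow(comparisons) == 0L) stop("no region comparisons to rank", call. = FALSE)
  if (any(!is.finite(comparisons$distance_px))) {
    stop("non-finite region distances", call. = FALSE)
  }
  out <- dplyr::arrange(comparisons, .data$distance_px, .data$name)
  out$rank <- seq_len(nrow(out))
  attr(out, "spearman_rho") <-
    if (nrow(out) >= 3) {
      suppressWarnings(
        stats::cor(out$distance_px, out$oxidative_increment,
                   method = "spearman"))  # NA when all distances tie
    } else NA_real_
  out
}

#' Export a pixel field as a long-format surface table
#'
#' Flattens an image or map to `(row, col, value)` rows — the tabular
#' counterpart of an intensity surface plot. Re-shaping the table back into
#' a matrix reproduces the field exactly.
#'
#' @param x A `membrane_image`, `bilateral_map` (uses `sum_map`), or matrix.
#' @param which For a `bilateral_map`: `"sum"` or `"diff"`.
#' @return Tibble `row`, `col`, `value` in row-major order.
#' @export
export_surface <- function(x, which = c("sum", "diff")) {
  which <- match.arg(which)
  m <- if (is_membrane_image(x)) x$pixels
       else if (inherits(x, "bilateral_map")) {
         if (which == "sum") x$sum_map else x$diff_map
       } else if (is.matrix(x)) x
       else stop("cannot export surface of a ", class(x)[1], call. = FALSE)
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  ) |> dplyr::arrange(.data$row, .data$col)
}
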