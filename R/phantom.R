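# Synthetic membrane phantoms with exact ground truth. The generators emulate
# the two experimental designs the quantification pipeline targets: graded
# dot-blot series on a membrane, and bilaterally near-symmetric brain-slice
# prints carrying a radially decaying unilateral lesion.

with_fixed_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# dose-response of spot amplitude on concentration
response_amplitude <- function(conc, response) {
  switch(response$type,
    linear = response$slope * conc,
    saturating = response$a_max * (1 - exp(-response$k * conc)),
    stop("unknown response type: ", response$type, call. = FALSE)
  )
}

# soft-edged disk profile: flat plateau with a ~2 px Gaussian-smoothed rim
spot_profile <- function(dist, radius, rim_sigma = 1) {
  stats::pnorm((radius - dist) / rim_sigma)
}

#' Generate a synthetic dot-blot membrane with ground truth
#'
#' Emulates the graded-concentration validation design: a grid of spots, one
#' row per nominal level and one column per replicate, on a gently tilted
#' background plane. Spot amplitude follows the chosen dose-response (linear
#' by default, matching the assay's validated range; a saturating option
#' exists to exercise validation-failure reporting), multiplied by a
#' per-replicate lognormal factor with the requested CV. Pixel noise is
#' additive Gaussian, and the image is clipped to `[0, 1]` (clipping is
#' flagged). Spots are rendered as flat disks with a 2 px Gaussian-smoothed
#' rim so pixel areas are stable against aliasing.
#'
#' The truth table records, per spot, the exact noiseless integrated density
#' over the *measurement disk* of radius `spot_radius + 3` px (which covers
#' the rim), so zero-noise pipeline measurements with background `"none"` can
#' be checked against it to floating tolerance.
#'
#' @param levels Nominal concentrations (mol/L), strictly increasing.
#' @param replicates Spots per level.
#' @param spot_radius Plateau radius in px.
#' @param spacing Grid spacing in px (default `4 * spot_radius + 4`).
#' @param response `list(type = "linear", slope = )` (intensity per mol/L) or
#'   `list(type = "saturating", a_max = , k = )`.
#' @param replicate_cv Multiplicative lognormal replicate CV (fraction).
#' @param pixel_noise_sd Additive Gaussian pixel noise SD.
#' @param background Length-3 plane coefficients `c(b0, b_row, b_col)`:
#'   intensity at the origin plus per-pixel gradients.
#' @param loading Optional per-spot loading factors (length
#'   `levels x replicates`, row-major) emulating unequal sample loading
#'   (e.g. protein content differences); they multiply spot amplitudes and
#'   are recorded in the truth table.
#' @param seed Integer; fixes the whole phantom byte-for-byte.
#' @return List: `image` (reductive-scale `membrane_image`), `truth`
#'   (tibble: `label`, `level`, `rep`, `nominal`, `rep_factor`, `amplitude`,
#'   `row`, `col`, `true_integrated_density`), `rois` ([spot_rois()] with the
#'   measurement radius), `grid` (spec for [detect_spots()]), `clipped`
#'   (logical), and `true_density_slope` (noiseless integrated density per
#'   mol/L, linear response only).
#' @export
make_dotblot <- function(levels = seq(0.01, 0.1, length.out = 10),
                         replicates = 6,
                         spot_radius = 5,
                         spacing = NULL,
                         response = list(type = "linear", slope = 8),
                         replicate_cv = 0.05,
                         pixel_noise_sd = 0.01,
                         background = c(0.05, 1e-4, 1e-4),
                         loading = NULL,
                         seed = 1L) {
  if (any(diff(levels) <= 0) || any(levels <= 0)) {
    stop("`levels` must be positive and strictly increasing", call. = FALSE)
  }
  meas_radius <- spot_radius + 3
  if (is.null(spacing)) spacing <- 4 * spot_radius + 4
  if (spacing < 2 * meas_radius + 2) {
    stop("grid too dense for the spot radius: increase `spacing`", call. = FALSE)
  }
  n_lev <- length(levels)
  margin <- meas_radius + ceiling(0.8 * meas_radius) + 2
  height <- 2 * margin + (n_lev - 1) * spacing
  width <- 2 * margin + (replicates - 1) * spacing

  design <- tidyr::expand_grid(level = seq_len(n_lev), rep = seq_len(replicates))
  design$nominal <- levels[design$level]
  design$row <- margin + (design$level - 1) * spacing
  design$col <- margin + (design$rep - 1) * spacing
  design$label <- sprintf("r%dc%d", design$level, design$rep)

  sdlog <- sqrt(log(1 + replicate_cv^2))
  out <- with_fixed_seed(seed, {
    rep_factor <- if (replicate_cv > 0) {
      stats::rlnorm(nrow(design), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(design))
    noise <- if (pixel_noise_sd > 0) {
      matrix(stats::rnorm(height * width, sd = pixel_noise_sd), height, width)
    } else matrix(0, height, width)
    list(rep_factor = rep_factor, noise = noise)
  })
  design$rep_factor <- out$rep_factor
  if (is.null(loading)) loading <- rep(1, nrow(design))
  if (length(loading) != nrow(design)) {
    stop("`loading` must have one factor per spot (", nrow(design), ")",
         call. = FALSE)
  }
  design$loading <- loading
  design$amplitude <- response_amplitude(design$nominal, response) *
    design$rep_factor * design$loading

  canvas <- outer(seq_len(height) - 1, rep(background[2], width)) +
    outer(rep(1, height), (seq_len(width) - 1) * background[3]) + background[1]
  truth_id <- numeric(nrow(design))
  half <- ceiling(meas_radius) + 3L
  for (i in seq_len(nrow(design))) {
    r0 <- design$row[i]; c0 <- design$col[i]
    rs <- (r0 - half):(r0 + half)
    cs <- (c0 - half):(c0 + half)
    d <- sqrt(outer((rs - r0)^2, (cs - c0)^2, `+`))
    prof <- spot_profile(d, spot_radius)
    canvas[rs, cs] <- canvas[rs, cs] + design$amplitude[i] * prof
    truth_id[i] <- design$amplitude[i] * sum(prof[d <= meas_radius])
  }
  design$true_integrated_density <- truth_id
  raw <- canvas + out$noise
  clipped <- any(raw < 0) || any(raw > 1)
  img <- membrane_image(pmin(pmax(raw, 0), 1), is_reductive_scale = TRUE,
                        scale_note = sprintf("dot-blot phantom (seed %d)", seed))
  unit_disk_sum <- {
    rs <- -half:half
    d <- sqrt(outer(rs^2, rs^2, `+`))
    prof <- spot_profile(d, spot_radius)
    sum(prof[d <= meas_radius])
  }
  list(
    image = img,
    truth = tibble::as_tibble(design[c("label", "level", "rep", "nominal",
                                       "rep_factor", "loading", "amplitude",
                                       "row", "col",
                                       "true_integrated_density")]),
    rois = spot_rois(design$label, design$row, design$col, meas_radius,
                     nominal = design$nominal),
    grid = list(rows = n_lev, cols = replicates, row0 = margin, col0 = margin,
                row_spacing = spacing, col_spacing = spacing,
                radius = meas_radius),
    clipped = clipped,
    true_density_slope = if (identical(response$type, "linear")) {
      response$slope * unit_disk_sum
    } else NA_real_
  )
}

#' Generate paired untreated/oxidized membranes
#'
#' Emulates the isoconcentrated-oxidation design: several independently
#' prepared aliquot pairs of one reducing-agent concentration, one arm left
#' untreated and the other physically oxidized so that a fraction `f` of its
#' reductive capacity is lost. Each arm is rendered as a one-row dot blot;
#' labels pair across arms.
#'
#' @param base_conc Nominal concentration of every aliquot (mol/L).
#' @param oxidized_fraction Fraction `f` of reductive capacity destroyed in
#'   the treated arm (`0 <= f <= 1`).
#' @param n_pairs Number of aliquot pairs.
#' @param seed Integer seed.
#' @param ... Passed to [make_dotblot()] (`spot_radius`, `response`,
#'   `replicate_cv`, `pixel_noise_sd`, `background`).
#' @return List with elements `untreated` and `treated` (each a
#'   [make_dotblot()]-style list) and `truth`, a pair-level tibble
#'   (`pair`, `label`, `arm`, `effective_conc`).
#' @export
make_oxidation_pair <- function(base_conc = 0.05, oxidized_fraction = 0.4,
                                n_pairs = 6, seed = 1L, ...) {
  if (oxidized_fraction < 0 || oxidized_fraction > 1) {
    stop("`oxidized_fraction` must lie in [0, 1]", call. = FALSE)
  }
  one_arm <- function(conc, arm_seed) {
    args <- list(...)
    args$levels <- conc
    args$replicates <- n_pairs
    args$seed <- arm_seed
    do.call(make_dotblot_single_level, args)
  }
  untreated <- one_arm(base_conc, seed)
  treated <- one_arm(base_conc * (1 - oxidized_fraction), seed + 1000L)
  truth <- tibble::tibble(
    pair = rep(seq_len(n_pairs), 2),
    label = c(untreated$truth$label, treated$truth$label),
    arm = rep(c("untreated", "oxidized"), each = n_pairs),
    effective_conc = rep(c(base_conc, base_conc * (1 - oxidized_fraction)),
                         each = n_pairs)
  )
  list(untreated = untreated, treated = treated, truth = truth)
}

# single-level dot blot; tolerant of conc -> 0 (blank arm)
make_dotblot_single_level <- function(levels, ...) {
  if (levels <= 0) {
    # a fully oxidized arm is a blank membrane: render at an epsilon level
    # with zero response so only background and noise remain
    args <- list(...)
    args$levels <- 1e-12
    args$response <- list(type = "linear", slope = 0)
    return(do.call(make_dotblot, args))
  }
  make_dotblot(levels = levels, ...)
}

#' Generate a bilateral brain-print phantom with a unilateral lesion
#'
#' Builds a mirror-symmetric "slice print": a large elliptical tissue region
#' with mirrored internal structures on a dim background, then applies a
#' radial multiplicative suppression
#' \eqn{w(p) = 1 - \delta \exp(-\|p - c\|^2 / 2\sigma_l^2)} to one side only,
#' emulating trauma that destroyed reductive capacity near a probe track.
#' Pixel noise is additive Gaussian. Circular regions of interest are placed
#' at graded distances from the trauma site, all on the lesioned side and
#' all within tissue of uniform base intensity, so the expected oxidative
#' increment decreases strictly with distance.
#'
#' @param height,width Canvas size in px (width odd keeps the midline
#'   column centered).
#' @param midline_col Mirror-axis column.
#' @param lesion_depth Suppression depth `delta` in `[0, 1]` (0 disables the
#'   lesion).
#' @param lesion_sigma Radial scale `sigma_l` in px.
#' @param trauma `(row, col)` lesion center; default sits on the right side.
#' @param ipsilateral_side Side carrying the lesion.
#' @param pixel_noise_sd Additive Gaussian noise SD.
#' @param n_rois Number of graded-distance circular ROIs (>= 2).
#' @param roi_radius ROI radius in px.
#' @param roi_step Distance between consecutive ROI centers in px.
#' @param seed Integer seed.
#' @return List: `image` (lesioned, noisy, reductive scale), `pre_lesion`
#'   (noiseless symmetric field, matrix), `lesion_weight` (matrix of
#'   `w(p)` actually applied, 1 where untouched), `rois` (list of
#'   [region_roi()]), `trauma`, `midline_col`, `ipsilateral_side`.
#' @export
make_brain_phantom <- function(height = 220, width = 241, midline_col = 121,
                               lesion_depth = 0.3, lesion_sigma = 30,
                               trauma = c(95, midline_col + 45),
                               ipsilateral_side = "right",
                               pixel_noise_sd = 0.01,
                               n_rois = 5, roi_radius = 8, roi_step = 20,
                               seed = 1L) {
  if (lesion_depth < 0 || lesion_depth > 1) stop("`lesion_depth` in [0, 1]",
                                                 call. = FALSE)
  m <- as.integer(midline_col)
  rows <- seq_len(height); cols <- seq_len(width)
  rg <- matrix(rows, height, width)
  cg <- matrix(cols, height, width, byrow = TRUE)

  ellipse <- function(r0, c0, ar, ac) ((rg - r0) / ar)^2 + ((cg - c0) / ac)^2 <= 1
  base <- matrix(0.05, height, width)
  base[ellipse(height / 2, m, 0.42 * height, 0.45 * width)] <- 0.55
  # mirrored internal structures, placed clear of the ROI chain
  for (dc in c(-60, 60)) base[ellipse(55, m + dc, 12, 18)] <-
    base[ellipse(55, m + dc, 12, 18)] + 0.18
  for (dc in c(-72, 72)) base[ellipse(170, m + dc, 11, 13)] <-
    base[ellipse(170, m + dc, 11, 13)] + 0.14
  base <- pmin(base, 0.9)

  dist2 <- (rg - trauma[1])^2 + (cg - trauma[2])^2
  w <- 1 - lesion_depth * exp(-dist2 / (2 * lesion_sigma^2))
  side_mask <- if (ipsilateral_side == "right") cg > m else cg < m
  weight <- matrix(1, height, width)
  weight[side_mask] <- w[side_mask]

  lesioned <- base * weight
  noisy <- with_fixed_seed(seed, {
    if (pixel_noise_sd > 0) {
      lesioned + matrix(stats::rnorm(height * width, sd = pixel_noise_sd),
                        height, width)
    } else lesioned
  })
  img <- membrane_image(pmin(pmax(noisy, 0), 1), is_reductive_scale = TRUE,
                        scale_note = sprintf("brain phantom (seed %d)", seed))

  # ROI chain runs dorsoventrally from the trauma site at graded distances
  dists <- (seq_len(n_rois) - 1) * roi_step
  rois <- lapply(seq_len(n_rois), function(i) {
    region_roi(sprintf("roi_d%03d", dists[i]),
               center = c(trauma[1] + dists[i], trauma[2]),
               radius = roi_radius)
  })
  list(image = img, pre_lesion = base, lesion_weight = weight, rois = rois,
       trauma = trauma, midline_col = m, ipsilateral_side = ipsilateral_side)
}
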