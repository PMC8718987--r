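test_that("integrated density of constant disks has the closed form", {
  img <- disk_image(60, 60, 30, 30, 5.5, value = 0.8, bg = 0)
  roi <- spot_rois("s", 30, 30, 5.5)
  m <- measure_spots(img, roi, background = "annulus_median")
  expect_equal(m$background_level, 0)
  expect_equal(m$integrated_density, 0.8 * m$area_px)
  # same disk on a uniform background: background fully cancelled
  img2 <- disk_image(60, 60, 30, 30, 5.5, value = 0.8, bg = 0.1)
  m2 <- measure_spots(img2, roi, background = "annulus_median")
  expect_equal(m2$background_level, 0.1)
  expect_equal(m2$integrated_density, (0.8 - 0.1) * m2$area_px)
})

test_that("disk measurement equals a brute-force per-pixel oracle", {
  set.seed(42)
  h <- 50; w <- 70
  grad <- outer(seq_len(h), seq_len(w), function(r, cc) 0.1 + 0.002 * r + 0.001 * cc)
  d2 <- outer((seq_len(h) - 24)^2, (seq_len(w) - 40)^2, `+`)
  px <- pmin(grad + 0.6 * exp(-d2 / (2 * 4^2)), 1)
  img <- membrane_image(px, is_reductive_scale = TRUE)
  roi <- spot_rois("g", 24, 40, 9)
  m_none <- measure_spots(img, roi, background = "none")
  oracle <- brute_force_disk_sum(px, 24, 40, 9)
  expect_equal(m_none$integrated_density, oracle$integrated, tolerance = 1e-12)
  expect_identical(m_none$area_px, oracle$area)
  # annulus-corrected value matches the oracle given the same background
  m_ann <- measure_spots(img, roi, background = "annulus_median")
  oracle_ann <- brute_force_disk_sum(px, 24, 40, 9,
                                     background = m_ann$background_level)
  expect_equal(m_ann$integrated_density, oracle_ann$integrated, tolerance = 1e-9)
})

test_that("measurement is linear, translation-equivariant and offset-invariant", {
  set.seed(7)
  base <- matrix(runif(40 * 40, 0, 0.3), 40, 40)
  img <- membrane_image(base, is_reductive_scale = TRUE)
  roi <- spot_rois("a", 18, 21, 6)
  m <- measure_spots(img, roi, background = "none")
  # linearity under intensity scaling
  m_k <- measure_spots(membrane_image(base * 0.5, is_reductive_scale = TRUE),
                       roi, background = "none")
  expect_equal(m_k$integrated_density, 0.5 * m$integrated_density)
  # translation equivariance: shift image and ROI together
  shifted <- base[c(4:40, 1:3), c(6:40, 1:5)]
  m_sh <- measure_spots(membrane_image(shifted, is_reductive_scale = TRUE),
                        spot_rois("a", 15, 16, 6), background = "none")
  expect_equal(m_sh$integrated_density, m$integrated_density)
  # adding a global constant leaves the annulus-corrected value unchanged
  m_ann <- measure_spots(img, roi)
  m_ann_c <- measure_spots(membrane_image(base + 0.2, is_reductive_scale = TRUE),
                           roi)
  expect_equal(m_ann_c$integrated_density, m_ann$integrated_density,
               tolerance = 1e-9)
})

test_that("out-of-bounds ROIs and edge annuli are handled", {
  img <- disk_image(40, 40, 20, 20, 5, 0.5)
  expect_error(measure_spots(img, spot_rois("x", 3, 20, 5)), "bounds")
  edge <- measure_spots(img, spot_rois("e", 20, 7, 6))
  expect_match(edge$flags, "partial_annulus")
  dim_spot <- measure_spots(disk_image(40, 40, 20, 20, 5, 0.05, bg = 0.2),
                            spot_rois("d", 20, 20, 5))
  expect_match(dim_spot$flags, "below_background")
  expect_lt(dim_spot$integrated_density, 0)
})

test_that("grid-guided detection refines centers to within 1 px of truth", {
  ph <- make_dotblot(levels = c(0.04, 0.08), replicates = 3, spot_radius = 5,
                     replicate_cv = 0, pixel_noise_sd = 0, seed = 3)
  rois <- detect_spots(ph$image, grid = ph$grid)
  expect_equal(nrow(rois), 6)
  expect_lt(max(abs(rois$row - ph$truth$row)), 1)
  expect_lt(max(abs(rois$col - ph$truth$col)), 1)
  # grid leaving the image is refused
  bad <- ph$grid; bad$col0 <- ph$image$width_px
  expect_error(detect_spots(ph$image, grid = bad), "bounds")
})

test_that("blob detection finds isolated spots and nothing on a blank membrane", {
  img <- disk_image(61, 61, 31, 31, 6, 0.8)
  rois <- detect_spots(img)
  expect_equal(nrow(rois), 1)
  expect_lte(abs(rois$row - 31), 1)
  expect_lte(abs(rois$col - 31), 1)
  blank <- membrane_image(matrix(0, 40, 40), is_reductive_scale = TRUE)
  expect_warning(none <- detect_spots(blank), "no spots")
  expect_equal(nrow(none), 0)
})

test_that("lane profiles average slices along the chosen axis", {
  img <- membrane_image(matrix(0.3, 30, 20), is_reductive_scale = TRUE)
  p <- extract_lane_profile(img, list(row0 = 5, col0 = 3, height = 20, width = 10))
  expect_true(all(p$value == 0.3))
  expect_identical(p$position, 5:24)
  # step band
  px <- matrix(0.1, 40, 20); px[15:20, ] <- 0.9
  step <- extract_lane_profile(membrane_image(px, is_reductive_scale = TRUE),
                               list(row0 = 1, col0 = 1, height = 40, width = 20))
  expect_equal(unique(step$value), c(0.1, 0.9))
  expect_true(all(step$value[15:20] == 0.9))
  expect_error(
    extract_lane_profile(img, list(row0 = 1, col0 = 1, height = 0, width = 5)),
    "degenerate")
})

test_that("a lane across phantom spots peaks at the spot positions", {
  ph <- make_dotblot(levels = c(0.05, 0.1), replicates = 1, spot_radius = 5,
                     replicate_cv = 0, pixel_noise_sd = 0,
                     background = c(0, 0, 0), seed = 1)
  lane <- list(row0 = 1, col0 = ph$truth$col[1] - 8, height = ph$image$height_px,
               width = 17)
  prof <- subtract_profile_baseline(extract_lane_profile(ph$image, lane))
  pk <- integrate_profile_peaks(prof)
  expect_equal(nrow(pk), 2)
  expect_lte(max(abs(pk$position - ph$truth$row)), 1)
})

test_that("baseline subtraction preserves peak areas on flat and tilted baselines", {
  tri <- c(rep(0, 10), seq(0, 1, length.out = 11), seq(1, 0, length.out = 11)[-1],
           rep(0, 10))
  prof <- tibble::tibble(position = seq_along(tri), value = tri, baseline = 0)
  sub <- subtract_profile_baseline(prof)
  expect_equal(sum(sub$value), sum(tri), tolerance = 1e-12)
  # same peak riding a tilted line: area recovered within 2%
  tilt <- 0.2 + 0.002 * seq_along(tri)
  sub_t <- subtract_profile_baseline(
    tibble::tibble(position = seq_along(tri), value = tri + tilt, baseline = 0))
  expect_equal(sum(sub_t$value), sum(tri), tolerance = 0.02)
  # flat profile comes back all zero
  flat <- subtract_profile_baseline(
    tibble::tibble(position = 1:10, value = rep(0.4, 10), baseline = 0))
  expect_true(all(flat$value == 0))
  expect_equal(flat$baseline, rep(0.4, 10))
})

test_that("peak integration sums contiguous positive runs in order", {
  v <- c(0, 0, 2, 2, 2, 0, 0, 1, 1, 0)
  prof <- tibble::tibble(position = 1:10, value = v, baseline = 0)
  pk <- integrate_profile_peaks(prof)
  expect_equal(pk$area, c(6, 2))          # w x h for rectangular peaks
  expect_true(all(diff(pk$position) > 0))
  empty <- integrate_profile_peaks(tibble::tibble(position = 1:5,
                                                  value = rep(0, 5),
                                                  baseline = 0))
  expect_equal(nrow(empty), 0)
})

test_that("disk/annulus and lane-profile quantification agree on clean phantoms", {
  ph <- make_dotblot(levels = c(0.03, 0.06, 0.09), replicates = 1,
                     spot_radius = 5, replicate_cv = 0, pixel_noise_sd = 0,
                     background = c(0.05, 0, 0), seed = 2)
  disk <- measure_spots(ph$image, ph$rois)
  lane_width <- 2 * ph$grid$radius + 1
  lane <- list(row0 = 1, col0 = ph$truth$col[1] - ph$grid$radius,
               height = ph$image$height_px, width = lane_width)
  prof <- subtract_profile_baseline(extract_lane_profile(ph$image, lane))
  pk <- integrate_profile_peaks(prof)
  expect_equal(nrow(pk), 3)
  lane_id <- pk$area * lane_width       # mean-per-slice area back to pixel sum
  expect_equal(lane_id, disk$integrated_density, tolerance = 0.05)
})
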