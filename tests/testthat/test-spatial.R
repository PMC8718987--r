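sym_phantom <- function(noise = 0, seed = 1) {
  make_brain_phantom(lesion_depth = 0, pixel_noise_sd = noise, seed = seed)
}

test_that("midline estimation recovers the constructed symmetry axis", {
  ph <- sym_phantom()
  expect_identical(estimate_midline(ph$image), ph$midline_col)
  # robust to mild pixel noise
  phn <- sym_phantom(noise = 0.02, seed = 4)
  expect_lte(abs(estimate_midline(phn$image) - phn$midline_col), 1)
  flat <- membrane_image(matrix(0.4, 50, 51), is_reductive_scale = TRUE)
  expect_error(estimate_midline(flat), "flat correlation")
  narrow <- membrane_image(matrix(runif(8 * 8), 8, 8), is_reductive_scale = TRUE)
  expect_error(estimate_midline(narrow), "narrow")
})

test_that("mirror pairing keeps homologous pixels aligned", {
  ph <- sym_phantom()
  pair <- mirror_pair(ph$image, ph$midline_col, "right")
  expect_equal(pair$ipsi, pair$contra)   # constructed symmetry
  expect_identical(pair$overlap_width_px,
                   min(ph$midline_col - 1L, ph$image$width_px - ph$midline_col))
  # delta spot at (r, m+5) appears in ipsi at offset 5, not in contra
  px <- matrix(0.2, 31, 41); m <- 21L
  px[16, m + 5] <- 0.9
  img <- membrane_image(px, is_reductive_scale = TRUE)
  p <- mirror_pair(img, m, "right")
  expect_equal(p$ipsi[16, 5], 0.9)
  expect_equal(p$contra[16, 5], 0.2)
  # swapping the side label swaps the fields
  q <- mirror_pair(img, m, "left")
  expect_identical(q$ipsi, p$contra)
  expect_identical(q$contra, p$ipsi)
  expect_error(mirror_pair(img, 1, "right"), "overlap")
})

test_that("mirroring about the same column twice is the identity", {
  set.seed(9)
  px <- matrix(runif(25 * 33), 25, 33)
  img <- membrane_image(px, is_reductive_scale = TRUE)
  m <- 17L
  p1 <- mirror_pair(img, m, "right")
  # rebuild the image with the right side replaced by its mirror, twice
  reflect <- function(mat) {
    w <- min(m - 1L, ncol(mat) - m)
    out <- mat
    out[, m + seq_len(w)] <- mat[, m - seq_len(w)]
    out[, m - seq_len(w)] <- mat[, m + seq_len(w)]
    out
  }
  expect_identical(reflect(reflect(px)), px)
  # and the pair's contra is exactly the mirrored ipsi of the reflected image
  p2 <- mirror_pair(membrane_image(reflect(px), is_reductive_scale = TRUE),
                    m, "right")
  expect_identical(p2$ipsi, p1$contra)
})

test_that("sum/diff maps are element-wise and vanish for symmetric input", {
  ph <- sym_phantom()
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  expect_true(all(bm$diff_map == 0))
  expect_equal(bm$sum_map, 2 * bm$ipsi)
  # adding a constant to ipsi shifts diff everywhere by that constant
  bm2 <- bilateral_maps(bm$ipsi + 0.05, bm$contra)
  expect_equal(bm2$diff_map, bm$diff_map + 0.05)
  expect_error(bilateral_maps(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("the difference map localizes the lesion", {
  ph <- make_brain_phantom(lesion_depth = 0.3, lesion_sigma = 30,
                           pixel_noise_sd = 0, seed = 2)
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  idx <- which(bm$diff_map == min(bm$diff_map), arr.ind = TRUE)[1, ]
  trauma_offset <- ph$trauma[2] - ph$midline_col
  expect_lte(abs(idx[1] - ph$trauma[1]), 3)
  expect_lte(abs(idx[2] - trauma_offset), 3)
  # side symmetry: relabeling the sides negates the difference map
  bm_l <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "left"))
  expect_equal(bm_l$diff_map, -bm$diff_map)
})

test_that("line profiles read dorsoventrally and split at the lesion", {
  ph <- make_brain_phantom(pixel_noise_sd = 0, seed = 1)
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  d_lesion <- ph$trauma[2] - ph$midline_col
  prof <- line_profile(bm, d_lesion)
  expect_identical(prof$row, seq_len(ph$image$height_px))
  lesion_rows <- abs(prof$row - ph$trauma[1]) < 15
  expect_true(all(prof$ipsi[lesion_rows] < prof$contra[lesion_rows]))
  # symmetric phantom: profiles coincide at every offset
  ps <- sym_phantom()
  bms <- bilateral_maps(mirror_pair(ps$image, ps$midline_col, "right"))
  p5 <- line_profile(bms, 5)
  expect_equal(p5$ipsi, p5$contra)
  expect_error(line_profile(bms, 0), "out of range")
  expect_error(line_profile(bms, bms$overlap_width_px + 1), "out of range")
})

test_that("region comparison is null on symmetric input and matches a loop oracle", {
  ph <- sym_phantom()
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  cmp <- compare_regions(bm, ph$rois, ph$trauma)
  expect_lt(max(abs(cmp$oxidative_increment)), 1e-9)
  for (i in seq_len(nrow(cmp))) {
    expect_equal(cmp$density[[i]]$ipsi_density, cmp$density[[i]]$contra_density)
  }
  # masked means equal an explicit per-pixel loop over the source image
  roi <- ph$rois[[2]]
  one <- compare_region(bm, roi, ph$trauma)
  px <- ph$image$pixels; m <- ph$midline_col
  acc_i <- acc_c <- 0; n <- 0L
  for (r in seq_len(nrow(px))) for (cc in seq_len(ncol(px))) {
    if ((r - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2) {
      acc_i <- acc_i + px[r, cc]
      acc_c <- acc_c + px[r, 2 * m - cc]
      n <- n + 1L
    }
  }
  expect_identical(one$n_px, n)
  expect_equal(one$ipsi_mean, acc_i / n, tolerance = 1e-12)
  expect_equal(one$contra_mean, acc_c / n, tolerance = 1e-12)
})

test_that("region densities integrate to one on their grid", {
  ph <- make_brain_phantom(seed = 6)
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  cmp <- compare_region(bm, ph$rois[[1]], ph$trauma)
  dens <- cmp$density[[1]]
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(dens$value, dens$ipsi_density), 1, tolerance = 1e-6)
  expect_equal(trap(dens$value, dens$contra_density), 1, tolerance = 1e-6)
  expect_equal(nrow(dens), 256)
})

test_that("geometry violations and tiny regions are caught", {
  ph <- sym_phantom()
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  straddle <- region_roi("straddle", center = c(100, ph$midline_col), radius = 6)
  expect_error(compare_region(bm, straddle, ph$trauma), "straddles")
  tiny <- region_roi("tiny", center = c(100, ph$midline_col + 30), radius = 1)
  expect_match(compare_region(bm, tiny, ph$trauma)$flags, "small_roi")
})

test_that("regions rank by distance with alphabetical tie-break and Spearman rho", {
  cmp <- tibble::tibble(
    name = c("b", "a", "c"), n_px = 50, distance_px = c(50, 10, 90),
    ipsi_mean = 0.4, contra_mean = c(0.5, 0.6, 0.45),
    oxidative_increment = c(0.1, 0.2, 0.05), flags = "",
    ipsi_values = list(0), contra_values = list(0), density = list(NULL)
  )
  r <- rank_regions(cmp)
  expect_identical(r$name, c("a", "b", "c"))
  expect_equal(attr(r, "spearman_rho"), -1)
  tie <- dplyr::mutate(cmp, distance_px = 10)
  expect_identical(rank_regions(tie)$name, c("a", "b", "c"))
  # monotone lesion phantom: rho is exactly -1 without noise
  ph <- make_brain_phantom(pixel_noise_sd = 0, seed = 3)
  bm <- bilateral_maps(mirror_pair(ph$image, ph$midline_col, "right"))
  ranked <- rank_regions(compare_regions(bm, ph$rois, ph$trauma))
  expect_equal(attr(ranked, "spearman_rho"), -1)
})

test_that("surface export is a faithful long-format round trip", {
  px <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  tab <- export_surface(px)
  expect_equal(nrow(tab), 4)
  back <- matrix(NA_real_, 2, 2)
  back[cbind(tab$row, tab$col)] <- tab$value
  expect_identical(back, px)
  img <- membrane_image(px, is_reductive_scale = TRUE)
  expect_identical(export_surface(img), tab)
})
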