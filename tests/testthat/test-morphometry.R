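test_that("segmentation counts disjoint particles and merges touching ones", {
  im <- draw_pellet_image(n = 5, width = 300, height = 300, scale = 0.05,
                          diameter_mean = 2, diameter_sd = 0.3, seed = 42)
  expect_equal(max(segment(im$image)), 5)

  # two overlapping disks form one 8-connected blob
  m <- disk_mask(15, 50, 50, 120) | disk_mask(15, 70, 60, 120)
  expect_equal(max(segment(mask_to_image(m))), 1)

  # diagonal contact is enough: foreground labeling is 8-connected
  m2 <- matrix(FALSE, 20, 20)
  m2[5, 5] <- TRUE; m2[6, 6] <- TRUE
  expect_equal(max(segment(mask_to_image(m2), threshold = 0.5)), 1)

  # constant image: zero particles with a warning, not an error
  expect_warning(labs <- segment(matrix(0.9, 50, 50)), "constant")
  expect_equal(max(labs), 0)
})

test_that("a fixed threshold respects polarity", {
  img <- matrix(0.9, 30, 30); img[10:15, 10:15] <- 0.1
  expect_equal(max(segment(img, threshold = 0.5, polarity = "dark")), 1)
  expect_equal(max(segment(1 - img, threshold = 0.5, polarity = "light")), 1)
})

test_that("hole filling closes enclosed background", {
  m <- disk_mask(12, 25, 25, 50) & !disk_mask(4, 25, 25, 50)
  ps_fill <- measure_particles(segment(mask_to_image(m)))
  ps_open <- measure_particles(segment(mask_to_image(m), fill_holes = FALSE))
  expect_gt(ps_fill$area_px, ps_open$area_px)
})

test_that("digitized disks measure as nearly circular with accurate Feret", {
  set.seed(5)
  for (r in c(10, 25, 50)) {
    n <- 2 * r + 20
    m <- disk_mask(r, n / 2 + runif(1), n / 2 + runif(1), n)
    ps <- measure_particles(segment(mask_to_image(m)))
    if (r >= 50) {
      expect_gte(ps$circularity, 0.90)
      expect_lte(ps$circularity, 1.00)
    }
    # maximal caliper within 2% of the true diameter for r >= 10 px
    expect_lt(abs(ps$feret - 2 * r) / (2 * r), 0.02)
  }
})

test_that("circularity has its closed-form values and is clamped", {
  expect_equal(circularity(1, 4), pi / 4) # ideal square, polygonal perimeter
  expect_equal(circularity(pi * 4, 2 * pi * 2), 1) # ideal circle
  expect_equal(circularity(100, 1), 1) # clamp
  expect_error(circularity(0, 4), class = "pelletr_domain_error")
})

test_that("digitized disks are rounder than digitized squares of equal area", {
  r <- 20
  m_disk <- disk_mask(r, 40, 40, 80)
  s <- round(sqrt(sum(m_disk))) # square of (almost) equal pixel area
  m_sq <- matrix(FALSE, 80, 80); m_sq[20:(19 + s), 20:(19 + s)] <- TRUE
  c_disk <- measure_particles(segment(mask_to_image(m_disk)))$circularity
  c_sq <- measure_particles(segment(mask_to_image(m_sq)))$circularity
  expect_gt(c_disk, c_sq)
  expect_gt(c_sq, 0) # still a valid circularity
  expect_lte(c_disk, 1)
})

test_that("degenerate single-pixel particles follow the documented convention", {
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  ps <- measure_particles(segment(mask_to_image(m), threshold = 0.5,
                                  fill_holes = FALSE), scale = 0.1)
  expect_equal(ps$area, 0.1^2) # one pixel at scale^2
  expect_equal(ps$feret, 0.1) # floored at one pixel side
  expect_equal(ps$circularity, pi / 4) # 4 pi / (4 px)^2
})

test_that("measurements are invariant to translation and 90-degree rotation", {
  m <- disk_mask(15, 30, 28, 90) | disk_mask(8, 65, 70, 90)
  shifted <- matrix(FALSE, 90, 90)
  shifted[11:90, 6:90] <- m[1:80, 1:85]
  ps1 <- measure_particles(segment(mask_to_image(m)))
  ps2 <- measure_particles(segment(mask_to_image(shifted)))
  expect_equal(ps1$area, ps2$area)
  expect_equal(ps1$perimeter, ps2$perimeter)
  expect_equal(ps1$feret, ps2$feret)

  rot <- t(m)[ncol(m):1, ] # 90-degree rotation
  ps3 <- measure_particles(segment(mask_to_image(rot)))
  expect_equal(sort(ps1$area), sort(ps3$area))
  expect_true(all(abs(sort(ps1$feret) - sort(ps3$feret)) /
                    sort(ps1$feret) < 0.01))
})

test_that("the size/roundness filter keeps inclusive bounds", {
  im <- draw_pellet_image(n = 4, width = 256, height = 256, scale = 0.05,
                          diameters = c(2, 1.5, 1, 0.08), seed = 9)
  ps <- measure_particles(segment(im$image), scale = 0.05)
  # the 0.08 mm speck digitizes to ~0.005 mm^2, below the 0.01 mm^2 default
  kept <- filter_particles(ps)
  expect_equal(nrow(kept), 3)
  expect_equal(nrow(filter_particles(ps, min_size = 0, roundness = c(0, 1))),
               nrow(ps)) # identity settings
  expect_equal(nrow(filter_particles(ps, min_size = 1e6)), 0)
  expect_error(filter_particles(ps, roundness = c(1, 0.1)),
               class = "pelletr_validation_error")
})

test_that("the uniformity coefficient matches hand computation and is scale-free", {
  expect_equal(uniformity_cu(c(3, 3, 3)), 1)
  expect_equal(round(uniformity_cu(c(2, 4)), 4), 0.6667)
  x <- c(1.2, 2.5, 2.8, 3.1)
  expect_equal(uniformity_cu(x * 7), uniformity_cu(x))
  expect_lte(uniformity_cu(x), 1)
  expect_error(uniformity_cu(numeric()), class = "pelletr_validation_error")
  expect_error(uniformity_cu(c(1, -1)), class = "pelletr_domain_error")
})

test_that("population summaries produce the five-number summary and outliers", {
  s1 <- morph_summary(5)
  expect_equal(unname(s1$fivenum), rep(5, 5))
  expect_length(s1$outliers, 0)

  s2 <- morph_summary(c(1, 2, 3, 4, 100))
  expect_equal(s2$outliers, 100) # beyond Q3 + 1.5 IQR with type-7 quartiles
  expect_equal(unname(s2$fivenum[c("q1", "q3")]), c(2, 4))
  expect_true(all(diff(s2$fivenum) >= 0))
  expect_error(morph_summary(numeric()), class = "pelletr_validation_error")

  g <- glance(s2)
  expect_equal(g$count, 5L)
  expect_equal(g$n_outliers, 1L)
  expect_s3_class(autoplot(s2), "ggplot")
})

test_that("measured diameters track generator ground truth on a busy image", {
  im <- draw_pellet_image(n = 120, width = 900, height = 900, scale = 0.05,
                          diameter_mean = 2.1, diameter_sd = 0.4, seed = 31)
  ps <- measure_particles(segment(im$image), scale = 0.05)
  expect_equal(nrow(ps), 120)
  truth <- sort(im$truth$diameter_mm)
  meas <- sort(ps$feret)
  expect_lt(max(abs(meas - truth) / truth), 0.03)
  expect_lt(abs(uniformity_cu(meas) - uniformity_cu(truth)), 0.02)
})

test_that("image round-trip through PNG preserves the segmentation", {
  im <- draw_pellet_image(n = 3, width = 200, height = 200, scale = 0.05,
                          diameter_mean = 2, diameter_sd = 0.2, seed = 4)
  path <- withr::local_tempfile(fileext = ".png")
  write_pellet_image(im$image, path)
  back <- read_pellet_image(path)
  expect_equal(dim(back), dim(im$image))
  expect_equal(max(segment(back)), 3)
  expect_error(read_pellet_image(file.path(tempdir(), "nope.png")),
               class = "pelletr_config_error")
})
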