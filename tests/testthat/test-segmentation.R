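test_that("blank and malformed images are handled as specified", {
  blank <- matrix(0, 40, 40)
  lab <- detect_nuclei(blank, segmentation_params())
  expect_equal(max(lab), 0)
  expect_error(detect_nuclei(array(0, c(4, 4, 2))), "2-D")
})

test_that("well-separated bright discs are each found exactly once", {
  centers <- cbind(x = c(10, 30, 50, 15, 45), y = c(12, 10, 14, 40, 42))
  img <- disc_image(c(60, 70), centers, radii = rep(5, 5), value = 0.8)
  lab <- detect_nuclei(img, segmentation_params(smoothing_sigma = 1,
                                                min_diameter = 4,
                                                max_diameter = 20))
  expect_equal(max(lab), 5)
  hit <- lab[cbind(centers[, "y"] + 1, centers[, "x"] + 1)]
  expect_equal(sort(hit), 1:5)   # one disc per label
})

test_that("declumping splits overlapping discs and can be disabled", {
  # two radius-6 discs with centers 9 px apart: overlap < one radius
  centers <- cbind(x = c(20, 29), y = c(20, 20))
  img <- disc_image(c(40, 56), centers, radii = c(6, 6), value = 0.9)
  on <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0,
                                               declump = TRUE,
                                               min_diameter = 5,
                                               max_diameter = 30))
  off <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0,
                                                declump = FALSE,
                                                min_diameter = 5,
                                                max_diameter = 30))
  expect_equal(max(on), 2)
  expect_equal(max(off), 1)
  expect_false(on[21, 21] == on[21, 30])   # the two centers get split
})

test_that("threshold is otsu x correction clipped to the bounds", {
  img <- disc_image(c(40, 40), cbind(20, 20), 6, value = 0.8)
  lab <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0,
                                                lower = 0.9, upper = 1))
  expect_equal(max(lab), 0)  # lower bound pushed above the disc intensity
  lab2 <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0,
                                                 correction_factor = 10,
                                                 lower = 0, upper = 0.5,
                                                 min_diameter = 4,
                                                 max_diameter = 20))
  expect_equal(max(lab2), 1)  # upper bound clips the inflated threshold
})

test_that("raising the correction factor never increases foreground area", {
  cfg <- noiseless_config(n_cells = 80)
  sim <- generate_tissue(cfg, seed = 12)
  img <- sim$image$images$nuclear
  areas <- sapply(c(0.5, 0.8, 1, 1.2, 2), function(f) {
    lab <- detect_nuclei(img, segmentation_params(correction_factor = f,
                                                  min_diameter = 1,
                                                  max_diameter = 1000))
    sum(lab > 0)
  })
  expect_true(all(diff(areas) <= 0))
})

test_that("soma expansion matches a brute-force nearest-nucleus scan", {
  set.seed(3)
  nuc <- matrix(0L, 35, 45)
  nuc[5:9, 6:10] <- 1L
  nuc[20:26, 28:33] <- 2L
  nuc[28, 8] <- 3L
  for (d in c(0, 3, 6)) {
    expect_equal(unclass(expand_to_soma(nuc, d))[, ],
                 unclass(oracle_expand(nuc, d))[, ], ignore_attr = TRUE)
  }
})

test_that("soma expansion geometry: disc growth and equidistant ties", {
  # single disc radius 5, expansion 3 -> radius-8 disc
  nuc <- matrix(0L, 41, 41)
  for (rr in 1:41) for (cc in 1:41)
    if ((rr - 21)^2 + (cc - 21)^2 <= 25) nuc[rr, cc] <- 1L
  soma <- expand_to_soma(nuc, 3)
  want <- matrix(0L, 41, 41)
  for (rr in 1:41) for (cc in 1:41) {
    d <- sqrt((rr - 21)^2 + (cc - 21)^2)
    if (d <= 5 || (sqrt(sum((c(rr, cc) - 21)^2)) - 5) <= 3) want[rr, cc] <- 1L
  }
  expect_equal(unclass(soma)[, ], want, ignore_attr = TRUE)
  # two single-pixel nuclei 10 px apart, generous expansion: boundary on
  # the equidistant line, tie pixels to the lower label
  nuc2 <- matrix(0L, 21, 31)
  nuc2[11, 9] <- 1L; nuc2[11, 19] <- 2L
  soma2 <- expand_to_soma(nuc2, 10)
  expect_equal(unclass(soma2)[, ], unclass(oracle_expand(nuc2, 10))[, ],
               ignore_attr = TRUE)
  expect_equal(soma2[11, 14], 1L)  # equidistant column goes to label 1
  expect_equal(soma2[5, 14], 1L)
})

test_that("expansion preserves nuclei and distance 0 is the identity", {
  cfg <- noiseless_config(n_cells = 40)
  sim <- generate_tissue(cfg, seed = 21, render = FALSE)
  nuc <- sim$truth$nuclei
  expect_equal(unclass(expand_to_soma(nuc, 0))[, ], unclass(nuc)[, ],
               ignore_attr = TRUE)
  soma <- expand_to_soma(nuc, 4)
  keep <- nuc > 0
  expect_equal(soma[keep], nuc[keep])      # each soma contains its nucleus
  labs <- sort(unique(soma[soma > 0]))
  expect_equal(labs, seq_along(labs))      # contiguous labels
})

test_that("object filtering removes small, large and border objects", {
  lab <- matrix(0L, 20, 20)
  lab[2:4, 2:4] <- 1L          # 9 px
  lab[10:15, 10:15] <- 2L      # 36 px
  lab[1, 18:20] <- 3L          # touches border
  expect_equal(max(filter_objects(lab, 0, Inf, "keep")), 3)
  f <- filter_objects(lab, min_area = 10, max_area = Inf, border_policy = "keep")
  expect_equal(sort(unique(f[f > 0])), 1L)  # only the 36-px object, relabelled
  expect_equal(sum(f == 1), 36)
  f2 <- filter_objects(lab, border_policy = "exclude")
  expect_equal(max(f2), 2)
  expect_equal(sum(f2 > 0), 45)
  expect_error(filter_objects(lab, min_area = 10, max_area = 5), "min_area")
})

test_that("nuclei recall and precision are perfect on clean simulations", {
  pops <- list(population_spec("p", 1, expr_prob = c(A = 0.5), dot_mean = 5,
                               dot_dispersion = 0.1,
                               lamina_weights = c(II = 0.4, III = 0.3, IV = 0.3)))
  cfg <- simulation_config(populations = pops, n_cells = 120, noise_sd = 0,
                           background_dot_rate = 0, nucleus_min_gap = 6,
                           seed = 1)
  sim <- generate_tissue(cfg, seed = 14)
  lab <- detect_nuclei(sim$image$images$nuclear,
                       segmentation_params(min_diameter = 3, max_diameter = 25))
  expect_equal(max(lab), 120)   # precision: no extra objects
  hits <- lab[cbind(round(sim$truth$cells$y) + 1,
                    round(sim$truth$cells$x) + 1)]
  expect_equal(sort(hits), 1:120)  # recall: every nucleus found once
})
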