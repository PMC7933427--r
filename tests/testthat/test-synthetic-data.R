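test_that("ground truth has exactly the requested number of cells", {
  cfg <- noiseless_config(n_cells = 100)
  sim <- generate_tissue(cfg, seed = 2, render = FALSE)
  expect_equal(nrow(sim$truth$cells), 100)
  expect_equal(max(sim$truth$nuclei), 100)
})

test_that("degenerate expression probabilities are honoured exactly", {
  pops <- list(population_spec("only", 1, expr_prob = c(A = 1, B = 0),
                               dot_mean = 5, dot_dispersion = 0.1,
                               lamina_weights = c(II = 1)))
  cfg <- simulation_config(populations = pops, n_cells = 60,
                           background_dot_rate = 0, noise_sd = 0, seed = 1)
  sim <- generate_tissue(cfg, seed = 8, render = FALSE)
  expect_true(all(sim$truth$cells$expr_A))
  expect_false(any(sim$truth$cells$expr_B))
  expect_true(all(sim$truth$cells$dots_B == 0))
})

test_that("per-cell true dot counts equal the number of ground-truth spots", {
  cfg <- noiseless_config(n_cells = 120)
  sim <- generate_tissue(cfg, seed = 5, render = FALSE)
  for (g in cfg$genes) {
    sp <- sim$truth$spots[sim$truth$spots$gene == g & sim$truth$spots$cell > 0, ]
    counted <- tabulate(sp$cell, nbins = 120)
    expect_equal(counted, sim$truth$cells[[paste0("dots_", g)]])
  }
  # every non-background spot's parent exists
  expect_true(all(sim$truth$spots$cell %in% c(0L, sim$truth$cells$cell)))
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- noiseless_config(n_cells = 50)
  a <- generate_tissue(cfg, seed = 33)
  b <- generate_tissue(cfg, seed = 33)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$spots, b$truth$spots)
  expect_identical(a$image$images, b$image$images)
  nc1 <- generate_negative_control(cfg, seed = 34)
  nc2 <- generate_negative_control(cfg, seed = 34)
  expect_identical(nc1$image$images, nc2$image$images)
})

test_that("mixture sampling matches closed-form marginals at large n", {
  # two disjoint populations: P(expressing A) = 1/2, co-expression 0
  pops <- list(
    population_spec("a", 0.5, expr_prob = c(A = 1, B = 0), dot_mean = 30,
                    dot_dispersion = 0.1, lamina_weights = c(II = 0.5, III = 0.5)),
    population_spec("b", 0.5, expr_prob = c(A = 0, B = 1), dot_mean = 30,
                    dot_dispersion = 0.1, lamina_weights = c(IV = 0.5, V = 0.5)))
  cfg <- simulation_config(populations = pops, n_cells = 2000,
                           nucleus_radius_mean = 2, nucleus_radius_sd = 0.2,
                           background_dot_rate = 0, seed = 1)
  sim <- simulate_cell_table(cfg, seed = 17)
  both <- sum(sim$truth$expr_A & sim$truth$expr_B)
  expect_equal(both, 0)
  fa <- mean(sim$truth$expr_A)
  expect_lt(abs(fa - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("negative controls carry only background at the configured rate", {
  cfg0 <- noiseless_config(n_cells = 60)
  nc0 <- generate_negative_control(cfg0, seed = 3, render = FALSE)
  expect_equal(nrow(nc0$truth$spots), 0)      # zero rate: no spots at all
  expect_true(all(nc0$truth$cells$dots_A == 0))

  pops <- mixture_populations()
  cfg <- simulation_config(populations = pops, n_cells = 260,
                           nucleus_radius_mean = 3, nucleus_radius_sd = 0.5,
                           background_dot_rate = 0.5, seed = 1)
  sim <- simulate_cell_table(cfg, seed = 9, negative_control = TRUE)
  expect_true(all(sim$truth[paste0("dots_", cfg$genes)] == 0))
  # measured dots/cell ~ Poisson with mean r * soma_area / unit area
  mean_area <- mean(sim$cells$area)
  expected <- 0.5 * mean_area / dorsalcode:::cell_equivalent_area(cfg)
  n <- nrow(sim$cells) * length(cfg$genes)
  observed <- mean(unlist(sim$cells[paste0("dots_", cfg$genes)]))
  expect_lt(abs(observed - expected), 3 * sqrt(expected / n))
})

test_that("background dots fall both inside and outside somata", {
  pops <- mixture_populations()
  cfg <- simulation_config(populations = pops, n_cells = 200,
                           background_dot_rate = 1, noise_sd = 0, seed = 1)
  nc <- generate_negative_control(cfg, seed = 41, render = FALSE)
  lab <- nc$truth$somata[cbind(round(nc$truth$spots$y) + 1,
                               round(nc$truth$spots$x) + 1)]
  expect_gt(sum(lab > 0), 0)
  expect_gt(sum(lab == 0), 0)
})

test_that("count-matrix generator plants what it claims", {
  # null configuration
  g0 <- generate_count_matrix(50, rep(c("x", "y"), each = 3), seed = 2)
  expect_equal(length(unlist(g0$truth)), 0)
  expect_true(all(g0$folds == 1))
  # deterministic limit: fold-4 gene has exactly 4x the group mean
  g1 <- generate_count_matrix(10, rep(c("x", "y"), each = 3),
                              enriched_sets = list(x = 1:3),
                              fold_changes = 4, dispersion = 0,
                              base = rep(25, 10), seed = 2)
  cm <- g1$cm
  mx <- rowMeans(cm$norm[, cm$groups == "x"])
  my <- rowMeans(cm$norm[, cm$groups == "y"])
  expect_equal(unname(mx[1:3] / my[1:3]), rep(4, 3))
  expect_equal(unname(mx[4:10] / my[4:10]), rep(1, 7))
  # invalid inputs
  expect_error(generate_count_matrix(10, rep(c("x", "y"), each = 3),
                                     dispersion = -1), "dispersion")
  expect_error(generate_count_matrix(10, c("x", "x", "y")), "replicates")
  expect_error(generate_count_matrix(10, rep(c("x", "y"), each = 2),
                                     enriched_sets = list(x = 1:2),
                                     fold_changes = 0.5), ">= 1")
})

test_that("config validation rejects inconsistent mixtures", {
  pops <- mixture_populations()
  bad <- pops
  bad[[1]]$weight <- 0.6
  expect_error(simulation_config(populations = bad), "sum to 1")
  expect_error(population_spec("p", 1, expr_prob = c(A = 1.2), dot_mean = 5,
                               lamina_weights = c(I = 1)))
  expect_error(population_spec("p", 1, expr_prob = c(A = 0.5), dot_mean = -2,
                               lamina_weights = c(I = 1)))
})

test_that("overfull templates fail with a clear placement error", {
  pops <- list(population_spec("p", 1, expr_prob = c(A = 0.5), dot_mean = 5,
                               lamina_weights = c(I = 1)))
  tpl <- default_template(width = 60, height = 60)
  expect_error(
    generate_tissue(simulation_config(template = tpl, populations = pops,
                                      n_cells = 500, seed = 1),
                    seed = 1, render = FALSE),
    "could not place")
})
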