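test_that("background threshold is the nearest-rank percentile", {
  nc <- data.frame(dots_A = c(0, 0, 0, 1, 1, 1, 2, 2, 3, 5))
  expect_equal(background_threshold(nc, 90)$threshold, 3)
  expect_equal(background_threshold(nc, 100)$threshold, 5)   # max
  expect_equal(background_threshold(data.frame(dots_A = rep(0, 8)))$threshold, 0)
  expect_error(background_threshold(data.frame(dots_A = numeric(0))), "empty")
})

test_that("positivity and high-expression boundaries are strict", {
  thr <- background_threshold(data.frame(dots_A = rep(3, 10)), 90)
  cells <- data.frame(cell = 1:4, dots_A = c(3, 4, 20, 21))
  calls <- call_positive(cells, thr)
  expect_equal(as.character(calls$call_A),
               c("negative", "positive", "positive", "high"))
  # high implies positive: a high count below the background threshold
  # of a noisy channel stays negative
  thr30 <- structure(data.frame(gene = "A", threshold = 30, percentile = 90,
                                n_cells = 10),
                     class = c("threshold_set", "data.frame"))
  calls2 <- call_positive(data.frame(cell = 1, dots_A = 25), thr30)
  expect_equal(as.character(calls2$call_A), "negative")
  expect_error(call_positive(data.frame(cell = 1, dots_B = 5), thr),
               "no background threshold")
})

test_that("triple-probe Venn counts match a brute-force enumeration", {
  thr <- structure(data.frame(gene = c("A", "B", "C"), threshold = 0,
                              percentile = 90, n_cells = 10),
                   class = c("threshold_set", "data.frame"))
  # 5 cells A-only, 3 cells A&B, 2 cells A&B&C, 4 triple-negative
  cells <- data.frame(cell = 1:14, animal = 1,
                      dots_A = c(rep(5, 10), rep(0, 4)),
                      dots_B = c(rep(0, 5), rep(5, 5), rep(0, 4)),
                      dots_C = c(rep(0, 8), rep(5, 2), rep(0, 4)))
  calls <- call_positive(cells, thr)
  vc <- venn_counts(calls, c("A", "B", "C"), level = "any")
  got <- setNames(vc$count, vc$region)
  expect_equal(got[["A"]], 5)
  expect_equal(got[["A&B"]], 3)
  expect_equal(got[["A&B&C"]], 2)
  expect_equal(got[["none"]], 4)
  expect_equal(unname(got[c("B", "C", "A&C", "B&C")]), rep(0L, 4))
  expect_equal(sum(vc$count), nrow(cells))   # regions partition the cells
  oracle <- oracle_venn(cells, c("A", "B", "C"), thr, level = "any")
  expect_equal(got[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
  expect_error(venn_counts(calls, c("A", "B", "D")), "absent")
})

test_that("pairwise fractions follow the direct count definition", {
  thr <- structure(data.frame(gene = c("A", "B"), threshold = 0,
                              percentile = 90, n_cells = 10),
                   class = c("threshold_set", "data.frame"))
  # one animal: N_A = 4, N_B = 2, N_AB = 2
  cells <- data.frame(cell = 1:6, animal = 1,
                      dots_A = c(5, 5, 5, 5, 0, 0),
                      dots_B = c(5, 5, 0, 0, 0, 0))
  calls <- call_positive(cells, thr)
  m <- pairwise_matrix(list(calls), level = "any")
  expect_equal(m$fraction["A", "B"], 50)
  expect_equal(m$fraction["B", "A"], 100)
  expect_equal(m$fraction["A", "A"], 100)
  expect_equal(m$fraction["B", "B"], 100)
  # reciprocity on unrounded counts
  expect_equal(m$fraction["A", "B"] * m$n_g["A", "B"],
               m$fraction["B", "A"] * m$n_g["B", "A"])
})

test_that("never co-hybridised pairs are missing, not zero", {
  thr1 <- structure(data.frame(gene = c("A", "B"), threshold = 0,
                               percentile = 90, n_cells = 5),
                    class = c("threshold_set", "data.frame"))
  thr2 <- structure(data.frame(gene = c("C", "D"), threshold = 0,
                               percentile = 90, n_cells = 5),
                    class = c("threshold_set", "data.frame"))
  c1 <- call_positive(data.frame(cell = 1:3, animal = 1,
                                 dots_A = c(5, 5, 0), dots_B = c(5, 0, 0)), thr1)
  c2 <- call_positive(data.frame(cell = 1:3, animal = 1,
                                 dots_C = c(5, 0, 0), dots_D = c(5, 5, 0)), thr2)
  expect_warning(m <- pairwise_matrix(list(c1, c2), level = "any"),
                 "never co-hybridised")
  expect_true(is.na(m$fraction["A", "C"]))
  expect_false(is.na(m$fraction["A", "B"]))
  expect_true(all(c("A", "C") %in% c(m$missing_pairs$gene, m$missing_pairs$other)))
})

test_that("high stringency requires both genes by default, row gene on request", {
  thr <- structure(data.frame(gene = c("A", "B"), threshold = 1,
                              percentile = 90, n_cells = 5),
                   class = c("threshold_set", "data.frame"))
  # A high in 2 cells; B high in 1 of them, merely positive in the other
  cells <- data.frame(cell = 1:3, animal = 1,
                      dots_A = c(30, 30, 0), dots_B = c(30, 10, 0))
  calls <- call_positive(cells, thr)
  both <- pairwise_matrix(list(calls), level = "high", high_rule = "both")
  rowr <- pairwise_matrix(list(calls), level = "high", high_rule = "row")
  expect_equal(both$fraction["A", "B"], 50)
  expect_equal(rowr$fraction["A", "B"], 100)
})

test_that("per-animal averaging is unweighted with sane edge cases", {
  expect_equal(per_animal_average(c(40, 60))$mean, 50)
  one <- per_animal_average(42)
  expect_equal(one$mean, 42)
  expect_true(is.na(one$sd))
  expect_equal(one$n, 1)
  eq <- per_animal_average(c(30, 30, 30))
  expect_equal(eq$sd, 0)
  expect_equal(per_animal_average(c(10, NA, 30))$n, 2)
})

test_that("stringency and threshold monotonicity hold on simulated tissue", {
  pops <- mixture_populations()
  cfg <- simulation_config(populations = pops, n_cells = 260,
                           nucleus_radius_mean = 3, nucleus_radius_sd = 0.5,
                           n_animals = 2, hemisections_per_animal = 1, seed = 1)
  comb <- simulate_combination(cfg, seed = 400)
  genes <- cfg$genes
  # raising the percentile never increases any N_g
  prev <- rep(Inf, length(genes))
  for (p in c(50, 90, 100)) {
    thr <- background_threshold(comb$negctrl, percentile = p)
    calls <- call_positive(comb$cells, thr)
    ng <- sapply(genes, function(g) sum(calls[[paste0("call_", g)]] != "negative"))
    expect_true(all(ng <= prev))
    prev <- ng
  }
  thr <- background_threshold(comb$negctrl)
  calls <- call_positive(comb$cells, thr)
  # high-level counts never exceed any-level counts, per Venn region
  va <- venn_counts(calls, genes, level = "any")
  vh <- venn_counts(calls, genes, level = "high")
  pos_any <- sapply(genes, function(g) calls[[paste0("call_", g)]] != "negative")
  pos_high <- sapply(genes, function(g) calls[[paste0("call_", g)]] == "high")
  for (g in genes) expect_lte(sum(pos_high[, g]), sum(pos_any[, g]))
  strictly <- function(v) v$count[v$region != "none"]
  # each multi-positive region at high level is a subset of cells that
  # are at least as positive at any level: totals cannot grow
  expect_lte(sum(strictly(vh)), sum(strictly(va)))
  expect_equal(sum(va$count), nrow(comb$cells))
  expect_equal(sum(vh$count), nrow(comb$cells))
})
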