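test_that("a gene maximal in every measure is alone on frontier 1", {
  # gene A has both the largest |mean diff| and the largest |median diff|
  ctrl <- rbind(A = c(0, 0, 0), B = c(1, 1, 1), C = c(2, 2, 2), D = c(3, 3, 3))
  case <- rbind(A = c(9, 9, 9), B = c(4, 4, 4), C = c(4, 4, 4), D = c(3.5, 3.5, 3.5))
  ds <- dataset_from_groups(list(Control = ctrl, Case = case))
  fit <- run_single(ds, c("mean", "median"), n_frontiers = 1)
  expect_identical(fit$assignment$gene[fit$assignment$frontier == 1L &
                                         !is.na(fit$assignment$frontier)], "A")
  # A maps to the origin after the max - x transformation
  expect_equal(unlist(fit$criteria[fit$criteria$gene == "A", -1]),
               c(mean = 0, median = 0))
})

test_that("duplicated measures collapse to the argmax set of one criterion", {
  sim <- simulate_dataset(n_genes = 60, n_per_group = 4, seed = 31)
  fit <- run_single(sim$dataset, c("mean", "mean"), n_frontiers = 1)
  pm <- compute_pm(sim$dataset, "mean", comparison = c("Control", "Case"))
  f1 <- fit$assignment$gene[!is.na(fit$assignment$frontier) & fit$assignment$frontier == 1L]
  expect_setequal(f1, pm$gene[pm$value == max(pm$value)])
})

test_that("analysis arity contracts are enforced before computation", {
  sim <- simulate_dataset(n_genes = 10, n_per_group = 2, n_condition_genes = 2, n_sex_genes = 2, seed = 1)
  expect_error(run_single(sim$dataset, "mean"), "2 or 3 performance measures")
  expect_error(run_single(sim$dataset, c("mean", "median", "q3", "mode")),
               "2 or 3 performance measures")
  expect_error(run_meta(list(sim$dataset)), "at least 2 datasets")
})

test_that("meta-analysis joins genes by strict intersection across datasets", {
  mk <- function(genes, id, seed) {
    simulate_dataset(n_genes = length(genes), n_per_group = 3,
                     n_condition_genes = 0, n_sex_genes = 0,
                     dataset_id = id, seed = seed, gene_ids = genes)$dataset
  }
  d1 <- mk(c("g1", "g2", "g3"), "d1", 1)
  d2 <- mk(c("g1", "g2", "g9"), "d2", 2)
  fit <- run_meta(list(d1, d2), "median", n_frontiers = 1)
  expect_identical(sort(fit$criteria$gene), c("g1", "g2"))

  d3 <- mk(c("x1", "x2", "x3"), "d3", 3)
  expect_error(run_meta(list(d1, d3)), "no genes shared")
  expect_match(tryCatch(run_meta(list(d1, d3)), error = conditionMessage),
               "d1 = 3.*d3 = 3")
})

test_that("meta-analysis of identical dataset copies reduces to the shared measure", {
  sim <- simulate_dataset(n_genes = 40, n_per_group = 4, seed = 13)
  copies <- list(sim$dataset, sim$dataset, sim$dataset)
  fit <- run_meta(copies, "median", n_frontiers = 1)
  expect_equal(ncol(fit$criteria) - 1L, 3L)
  pm <- compute_pm(sim$dataset, "median", comparison = c("Control", "Case"))
  f1 <- fit$assignment$gene[!is.na(fit$assignment$frontier)]
  expect_setequal(f1, pm$gene[pm$value == max(pm$value)])
})

test_that("genes-of-interest set algebra follows (1 & 2) minus (3 | 4)", {
  goi <- genes_of_interest(c("a", "b", "c"), c("b", "c", "d"), "c", character())
  expect_identical(attr(goi, "result"), "b")
  expect_identical(goi$gene, c("a", "b", "c", "d"))
  expect_identical(goi$selected, c(FALSE, TRUE, FALSE, FALSE))

  # annihilation: MCO3 = MCO1 empties the result
  same <- genes_of_interest(c("a", "b"), c("a", "b"), c("a", "b"), character())
  expect_length(attr(same, "result"), 0)

  # result never contains a gene absent from MCO1 or MCO2
  g <- withr::with_seed(4, replicate(4, sample(letters, 8), simplify = FALSE))
  goi <- genes_of_interest(g[[1]], g[[2]], g[[3]], g[[4]])
  res <- attr(goi, "result")
  expect_true(all(res %in% g[[1]]) && all(res %in% g[[2]]))
  expect_length(intersect(res, union(g[[3]], g[[4]])), 0)
})

test_that("four-way scheme recovers planted condition genes and excludes sex genes", {
  # 2-PM analysis at a scale where the first 10 frontiers stay a small
  # fraction of the gene universe, so the MCO3/MCO4 subtraction removes
  # sex-dimorphic signal without swallowing the condition genes.
  recovered <- integer(0); leaked <- integer(0)
  for (seed in 1:3) {
    sim <- simulate_dataset(n_genes = 3000, n_per_group = 10, effect_size = 8,
                            seed = seed)
    fw <- suppressWarnings(run_four_way(sim$dataset, "single", n_frontiers = 10))
    cond <- sim$truth$gene[sim$truth$class == "condition"]
    sex <- sim$truth$gene[sim$truth$class == "sex"]
    recovered <- c(recovered, sum(cond %in% fw$result))
    leaked <- c(leaked, sum(sex %in% fw$result))
    expect_true(all(fw$result %in% intersect(fw$members$MCO1, fw$members$MCO2)))
  }
  expect_gte(mean(recovered), 9)
  expect_identical(sum(leaked), 0L)
})

test_that("four-way propagates group errors with comparison context", {
  sim <- simulate_dataset(n_genes = 10, n_per_group = 2, n_condition_genes = 2, n_sex_genes = 2, seed = 1)
  ds <- sim$dataset
  nosex <- expression_dataset(ds$values, ds$annotations[c("sample", "condition")],
                              dataset_id = "nosex")
  expect_error(run_four_way(nosex, "single"), "MaleControl vs MaleCase.*sex")
})

test_that("reruns from identical inputs are identical (repeatability)", {
  sim1 <- simulate_dataset(n_genes = 120, seed = 99)
  sim2 <- simulate_dataset(n_genes = 120, seed = 99)
  expect_identical(sim1$dataset$values, sim2$dataset$values)
  f1 <- run_four_way(sim1$dataset, "single", n_frontiers = 3)
  f2 <- run_four_way(sim2$dataset, "single", n_frontiers = 3)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$result, f2$result)
})

test_that("tidy and glance expose the fit as tables", {
  sim <- simulate_dataset(n_genes = 50, seed = 6)
  fit <- run_single(sim$dataset, c("mean", "median"), n_frontiers = 2)
  td <- tidy(fit)
  expect_true(all(c("gene", "frontier", "mean", "median", "raw_mean", "raw_median")
                  %in% names(td)))
  expect_equal(nrow(td), nrow(fit$criteria))
  # transformed = max(raw) - raw, per criterion
  expect_equal(td$mean, max(td$raw_mean) - td$raw_mean)
  gl <- glance(fit)
  expect_equal(gl$n_genes, 50L)
  expect_equal(gl$n_criteria, 2L)
  expect_equal(gl$frontier1_size, sum(td$frontier == 1L, na.rm = TRUE))

  fw <- run_four_way(sim$dataset, "single", n_frontiers = 2)
  expect_identical(attr(tidy(fw), "result"), fw$result)
  expect_equal(glance(fw)$n_MCO1, length(fw$members$MCO1))
})
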