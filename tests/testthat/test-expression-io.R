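test_that("write-then-read round-trips values bit-exactly", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(n_genes = 40, n_per_group = 3, seed = 17)
  m <- file.path(dir, "m.tsv"); s <- file.path(dir, "s.tsv")
  write_expression(sim$dataset, m, s)
  back <- read_expression(m, s, dataset_id = "sim")
  expect_identical(back$values, sim$dataset$values)
  expect_identical(back$annotations, sim$dataset$annotations)

  # and for a dataset without sex annotations
  toy <- toy_dataset(sex = FALSE)
  write_expression(toy, m, s)
  back <- read_expression(m, s)
  expect_identical(back$values, toy$values)
  expect_false("sex" %in% names(back$annotations))
})

test_that("matrix/sheet disagreements and malformed cells are validation errors", {
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.tsv"); s <- file.path(dir, "s.tsv")
  writeLines(c("feature\ts1\ts2\ts3", "gA\t1\t2\t3", "gB\t4\t5\t6"), m)

  writeLines(c("sample\tcondition", "s1\tcontrol", "s2\tcase"), s)
  expect_error(read_expression(m, s), "in the matrix but not in the sheet: s3")

  writeLines(c("sample\tcondition", "s1\tcontrol", "s2\tcase", "s3\tcase",
               "s9\tcase"), s)
  expect_error(read_expression(m, s), "in the sheet but not in the matrix: s9")

  writeLines(c("sample\tcondition", "s1\tcontrol", "s2\tcase", "s3\tcase"), s)
  writeLines(c("feature\ts1\ts1\ts3", "gA\t1\t2\t3"), m)
  expect_error(read_expression(m, s), "duplicate sample id")

  writeLines(c("feature\ts1\ts2\ts3", "gA\t1\toops\t3"), m)
  expect_error(read_expression(m, s), "'oops' for feature 'gA', sample 's2'")
})

test_that("literal NA cells are kept as missing values and reported", {
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.tsv"); s <- file.path(dir, "s.tsv")
  writeLines(c("feature\ts1\ts2", "gA\tNA\t2", "gB\t3\t4"), m)
  writeLines(c("sample\tcondition", "s1\tcontrol", "s2\tcase"), s)
  expect_message(ds <- read_expression(m, s), "1 missing value")
  expect_true(is.na(ds$values["gA", "s1"]))
  expect_equal(ds$values["gB", ], c(s1 = 3, s2 = 4))
})

test_that("condition labels map only through an explicit user-supplied map", {
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.tsv"); s <- file.path(dir, "s.tsv")
  writeLines(c("feature\ts1\ts2", "gA\t1\t2"), m)
  writeLines(c("sample\tcondition", "s1\thealthy", "s2\tPD"), s)
  expect_error(read_expression(m, s), "condition labels")
  ds <- read_expression(m, s, condition_map = c(pd = "case", HEALTHY = "control"))
  expect_identical(ds$annotations$condition, c("control", "case"))
})

test_that("probe collapsing summarizes per gene symbol", {
  values <- matrix(c(1, 3,
                     3, 5,
                     10, 20,
                     7, 8),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("p1", "p2", "p3", "p4"), c("s1", "s2")))
  ann <- tibble::tibble(sample = c("s1", "s2"), condition = c("control", "case"))
  ds <- expression_dataset(values, ann)
  mapping <- tibble::tibble(probe = c("p1", "p2", "p3"),
                            symbol = c("G", "G", "H"))

  med <- collapse_probes(ds, mapping) # default median
  expect_equal(med$values["G", ], c(s1 = 2, s2 = 4)) # medians of (1,3) and (3,5)
  expect_equal(med$values["H", ], c(s1 = 10, s2 = 20))
  expect_identical(sort(rownames(med$values)), c("G", "H")) # p4 unmapped, dropped

  avg <- collapse_probes(ds, mapping, method = "mean")
  expect_equal(avg$values["G", ], c(s1 = 2, s2 = 4))

  mv <- collapse_probes(ds, tibble::tibble(probe = c("p3", "p4", "p1"),
                                           symbol = c("H", "H", "G")),
                        method = "max_variance")
  expect_equal(mv$values["H", ], values["p3", ]) # var(10,20) > var(7,8)
  expect_equal(mv$values["G", ], values["p1", ])

  one2one <- collapse_probes(ds, tibble::tibble(probe = c("p1", "p4"),
                                                symbol = c("X", "Y")))
  expect_equal(one2one$values["X", ], values["p1", ])
  expect_equal(one2one$values["Y", ], values["p4", ])

  expect_error(collapse_probes(ds, tibble::tibble(probe = "zz", symbol = "Z")),
               "covers none")
  expect_error(collapse_probes(ds, mapping, method = "sum"), "arg")
})

test_that("collapse output has one row per distinct mapped symbol", {
  sim <- simulate_dataset(n_genes = 30, n_per_group = 2, seed = 5)
  probes <- rownames(sim$dataset$values)
  mapping <- tibble::tibble(probe = probes,
                            symbol = rep(sprintf("sym%02d", 1:10), each = 3))
  out <- collapse_probes(sim$dataset, mapping)
  expect_equal(nrow(out$values), 10L)
  expect_identical(sort(rownames(out$values)), sort(unique(mapping$symbol)))
})

test_that("groups partition exactly the annotated samples", {
  sim <- simulate_dataset(n_genes = 5, n_per_group = 2, n_condition_genes = 1, n_sex_genes = 1, seed = 2)
  g4 <- build_groups(sim$dataset, stratify_by_sex = TRUE)
  expect_setequal(unique(g4$group),
                  c("MaleControl", "MaleCase", "FemaleControl", "FemaleCase"))
  expect_equal(unname(table(g4$group)[unique(g4$group)]),
               rep(2L, 4), ignore_attr = TRUE)
  expect_setequal(g4$sample, sim$dataset$annotations$sample)
  expect_false(anyDuplicated(g4$sample) > 0)

  g2 <- build_groups(sim$dataset)
  expect_equal(sum(g2$group == "Control"), 4L)
  expect_equal(sum(g2$group == "Case"), 4L)
})

test_that("group construction fails loudly on impossible stratifications", {
  values <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ann <- tibble::tibble(sample = c("s1", "s2"),
                        condition = c("control", "case"), sex = c("M", "M"))
  ds <- expression_dataset(values, ann)
  expect_error(build_groups(ds, stratify_by_sex = TRUE), "FemaleControl")
  nosex <- expression_dataset(values, ann[1:2])
  expect_error(build_groups(nosex, stratify_by_sex = TRUE), "sex")
  expect_error(
    expression_dataset(values, tibble::tibble(sample = c("s1", "s2"),
                                              condition = c("control", "case"),
                                              sex = c("M", NA))),
    "every sample or for none")
})
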