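# Shared fixtures, built in code.

# Random criteria table: n genes, C criteria, values uniform on [0, 1].
# `ties` rounds values to 1 decimal so duplicated coordinates (and whole
# duplicated rows) occur frequently.
random_cm <- function(n, C, seed, ties = FALSE) {
  withr::with_seed(seed, {
    M <- matrix(runif(n * C), n, C)
    if (ties) M <- round(M, 1)
    tibble::as_tibble(as.data.frame(M)) |>
      stats::setNames(paste0("c", seq_len(C))) |>
      dplyr::mutate(gene = sprintf("g%04d", seq_len(n)), .before = 1)
  })
}

frontier_genes <- function(x) sort(x$gene)

# Hand-built 3-gene x 4-sample dataset used across the I/O tests.
toy_dataset <- function(sex = TRUE) {
  values <- matrix(c(1.25, 2.5, 3.75, 5.125,
                     10, 20, 30, 40,
                     0.1, 0.2, 0.3, 0.4),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("s1", "s2", "s3", "s4")))
  ann <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                        condition = c("control", "control", "case", "case"))
  if (sex) ann$sex <- c("M", "F", "M", "F")
  expression_dataset(values, ann, dataset_id = "toy")
}

# Dataset from explicit per-group value lists: groups is a named list of
# numeric matrices (genes x samples), all with identical rownames.
dataset_from_groups <- function(groups, dataset_id = "manual") {
  mats <- lapply(groups, as.matrix)
  values <- do.call(cbind, mats)
  n <- vapply(mats, ncol, integer(1))
  grp <- rep(names(groups), times = n)
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  ann <- tibble::tibble(
    sample = colnames(values),
    condition = ifelse(grepl("Case", grp), "case", "control"))
  if (any(grepl("Male|Female", grp))) {
    ann$sex <- ifelse(grepl("Male", grp), "M", "F")
  }
  expression_dataset(values, ann, dataset_id = dataset_id)
}

# Does any row of `front` (matrix) dominate vector v? (independent of the
# package's dominates(), used to verify layer structure)
dominated_by_any <- function(front, v) {
  any(apply(front, 1L, function(u) all(u <= v) && any(u < v)))
}
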