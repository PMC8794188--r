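# Synthetic expression data with known ground truth: planted
# condition-responsive genes (shifted in the case groups of both sexes),
# planted sex-dimorphic genes (shifted in both female groups), and null
# genes. Emulates the case/control x sex layout of sex-annotated microarray
# studies at toy scale; it does not attempt realistic microarray artifacts
# (probe cross-hybridization, batch effects, platform-specific intensity
# distributions).

#' Simulate one expression dataset with planted effects
#'
#' Generates a genes-by-samples matrix over the four sex-by-condition groups.
#' Every observation is an independent Gaussian around a gene-specific
#' baseline (drawn uniformly on `baseline_range`) with standard deviation
#' `noise_sd`. Condition genes receive an additive `+effect_size` shift in
#' both case groups (MaleCase and FemaleCase); sex genes receive the shift in
#' both female groups (control and case); the remaining genes are null. An
#' additive location shift moves mean and median identically, so both default
#' performance measures respond to it.
#'
#' @param n_genes Total number of genes.
#' @param n_per_group Samples per group; a single count or a vector of four
#'   (MaleControl, MaleCase, FemaleControl, FemaleCase).
#' @param n_condition_genes,n_sex_genes Numbers of planted genes; must sum to
#'   at most `n_genes`.
#' @param effect_size Mean shift, in units of the noise scale.
#' @param noise_sd Noise standard deviation (the unit of `effect_size`).
#' @param baseline_range Range of the per-gene baseline level, on a
#'   log-intensity-like scale.
#' @param dataset_id Label for the dataset.
#' @param seed Integer seed; the same spec and seed reproduce the dataset
#'   exactly. `NULL` uses the current RNG state.
#' @param gene_ids Optional character vector of gene ids (length `n_genes`);
#'   the planted condition genes are the first `n_condition_genes`, the sex
#'   genes the next `n_sex_genes`. Supplied by [simulate_meta_collection()]
#'   to keep planted genes consistent across datasets.
#' @return A list: `dataset` (an [expression_dataset()]) and `truth` (tibble
#'   `gene`, `class` with class in condition/sex/null).
#' @examples
#' sim <- simulate_dataset(n_genes = 50, n_condition_genes = 5, seed = 1)
#' sim$dataset
#' table(sim$truth$class)
#' @export
simulate_dataset <- function(n_genes = 1000, n_per_group = 10,
                             n_condition_genes = 10, n_sex_genes = 10,
                             effect_size = 5, noise_sd = 1,
                             baseline_range = c(4, 12),
                             dataset_id = "sim", seed = NULL,
                             gene_ids = NULL) {
  if (n_genes < 1 || any(n_per_group < 1) ||
      n_condition_genes < 0 || n_sex_genes < 0) {
    abort("all counts must be positive (planted counts may be zero).")
  }
  if (n_condition_genes + n_sex_genes > n_genes) {
    abort("n_condition_genes + n_sex_genes must not exceed n_genes.")
  }
  n_per_group <- rep(as.integer(n_per_group), length.out = 4L)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  } else if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    abort("`gene_ids` must be `n_genes` unique identifiers.")
  }
  draw <- function() {
    groups <- c("MaleControl", "MaleCase", "FemaleControl", "FemaleCase")
    sample_group <- rep(groups, times = n_per_group)
    n_samples <- length(sample_group)
    sample_ids <- sprintf("%s_s%03d", dataset_id, seq_len(n_samples))
    baseline <- runif(n_genes, baseline_range[1L], baseline_range[2L])
    values <- baseline +
      matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples)
    cls <- rep("null", n_genes)
    cls[seq_len(n_condition_genes)] <- "condition"
    cls[n_condition_genes + seq_len(n_sex_genes)] <- "sex"
    case_cols <- sample_group %in% c("MaleCase", "FemaleCase")
    female_cols <- sample_group %in% c("FemaleControl", "FemaleCase")
    values[cls == "condition", case_cols] <-
      values[cls == "condition", case_cols] + effect_size
    values[cls == "sex", female_cols] <-
      values[cls == "sex", female_cols] + effect_size
    dimnames(values) <- list(gene_ids, sample_ids)
    ann <- tibble(sample = sample_ids,
                  condition = ifelse(case_cols, "case", "control"),
                  sex = ifelse(female_cols, "F", "M"))
    list(dataset = expression_dataset(values, ann, dataset_id = dataset_id),
         truth = tibble(gene = gene_ids, class = cls))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Simulate a collection of datasets for meta-analysis
#'
#' Generates 2-5 datasets that share a configurable fraction of their null
#' gene identifiers, while all planted condition and sex genes are present
#' and shifted consistently in every dataset (emulating multi-platform
#' studies harmonized to shared gene symbols). Non-shared null genes get
#' dataset-specific identifiers and therefore drop out of the strict
#' meta-analysis intersection.
#'
#' @param n_datasets Number of datasets, 2-5.
#' @param shared_fraction Fraction of null genes whose identifiers are common
#'   to all datasets (planted genes are always shared).
#' @inheritParams simulate_dataset
#' @param seed Integer seed; per-dataset seeds are derived from it.
#' @return A list: `datasets` (list of [expression_dataset()]) and `truth`
#'   (tibble for the shared planted/null universe).
#' @examples
#' sim <- simulate_meta_collection(3, n_genes = 100, seed = 2)
#' length(sim$datasets)
#' @export
simulate_meta_collection <- function(n_datasets = 3, n_genes = 1000,
                                     shared_fraction = 1,
                                     n_per_group = 10,
                                     n_condition_genes = 10, n_sex_genes = 10,
                                     effect_size = 5, noise_sd = 1,
                                     baseline_range = c(4, 12),
                                     seed = NULL) {
  if (n_datasets < 2 || n_datasets > 5) {
    abort("`n_datasets` must be between 2 and 5.")
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1].")
  }
  n_planted <- n_condition_genes + n_sex_genes
  n_null <- n_genes - n_planted
  n_shared_null <- round(shared_fraction * n_null)
  shared_ids <- c(sprintf("cond%03d", seq_len(n_condition_genes)),
                  sprintf("sexg%03d", seq_len(n_sex_genes)),
                  sprintf("null%05d", seq_len(n_shared_null)))
  datasets <- vector("list", n_datasets)
  for (k in seq_len(n_datasets)) {
    own_ids <- if (n_null > n_shared_null) {
      sprintf("ds%d_null%05d", k, seq_len(n_null - n_shared_null))
    } else character()
    sim <- simulate_dataset(n_genes = n_genes, n_per_group = n_per_group,
                            n_condition_genes = n_condition_genes,
                            n_sex_genes = n_sex_genes,
                            effect_size = effect_size, noise_sd = noise_sd,
                            baseline_range = baseline_range,
                            dataset_id = sprintf("sim%d", k),
                            seed = if (is.null(seed)) NULL else as.integer(seed) + 1009L * k,
                            gene_ids = c(shared_ids, own_ids))
    datasets[[k]] <- sim$dataset
  }
  truth <- tibble(gene = shared_ids,
                  class = c(rep("condition", n_condition_genes),
                            rep("sex", n_sex_genes),
                            rep("null", n_shared_null)))
  list(datasets = datasets, truth = truth)
}

#' Write a simulated dataset to TSV files
#'
#' Writes the matrix/sheet pair in the formats [read_expression()] reads,
#' plus the ground-truth gene classes.
#'
#' @param sim A list as returned by [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             sheet = file.path(dir, paste0(prefix, "_samples.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_expression(sim$dataset, paths[["matrix"]], paths[["sheet"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
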