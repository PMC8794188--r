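# Expression datasets: a genes x samples numeric matrix plus per-sample
# annotations (condition, optional sex). Values are taken as-is, on whatever
# scale the input provides; no normalization, background correction or log
# transformation is applied here.

GROUP_NAMES <- c("Control", "Case",
                 "MaleControl", "MaleCase", "FemaleControl", "FemaleCase")

#' Construct an expression dataset
#'
#' Bundles a features-by-samples numeric matrix with a per-sample annotation
#' table and validates their agreement. This is the unit one performance
#' measure comparison is computed on.
#'
#' @param values Numeric matrix, rows = features (probes or genes), columns =
#'   samples; `rownames`/`colnames` carry the identifiers.
#' @param annotations Data frame with columns `sample`, `condition`
#'   (`"case"`/`"control"`) and optionally `sex` (`"M"`/`"F"`). Sex may be
#'   absent dataset-wide but not partially.
#' @param dataset_id Short label used in messages and provenance.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, annotations, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs rownames (feature ids) and colnames (sample ids).")
  }
  if (anyDuplicated(colnames(values))) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(colnames(values)[duplicated(colnames(values))]),
                        collapse = ", ")))
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("duplicate feature id(s): %s",
                  paste(head(unique(rownames(values)[duplicated(rownames(values))]), 5L),
                        collapse = ", ")))
  }
  if (!is.data.frame(annotations) || !all(c("sample", "condition") %in% names(annotations))) {
    abort("`annotations` must be a data frame with columns `sample` and `condition`.")
  }
  annotations <- as_tibble(annotations)
  annotations$sample <- as.character(annotations$sample)
  if (anyDuplicated(annotations$sample)) {
    abort("duplicate sample id(s) in the annotation sheet.")
  }
  missing_ann <- setdiff(colnames(values), annotations$sample)
  if (length(missing_ann) > 0L) {
    abort(sprintf("sample(s) in the matrix but not in the sheet: %s",
                  paste(missing_ann, collapse = ", ")))
  }
  extra_ann <- setdiff(annotations$sample, colnames(values))
  if (length(extra_ann) > 0L) {
    abort(sprintf("sample(s) in the sheet but not in the matrix: %s",
                  paste(extra_ann, collapse = ", ")))
  }
  annotations <- annotations[match(colnames(values), annotations$sample), , drop = FALSE]
  cond <- tolower(as.character(annotations$condition))
  if (anyNA(cond) || !all(cond %in% c("case", "control"))) {
    bad <- unique(annotations$condition[is.na(cond) | !cond %in% c("case", "control")])
    abort(sprintf("condition labels must be 'case'/'control' (map others explicitly via `condition_map`); found: %s",
                  paste(bad, collapse = ", ")))
  }
  annotations$condition <- cond
  if ("sex" %in% names(annotations)) {
    sex <- toupper(as.character(annotations$sex))
    if (all(is.na(sex))) {
      annotations$sex <- NULL
    } else {
      if (anyNA(sex)) {
        abort("`sex` must be annotated for every sample or for none (partial annotation is ambiguous).")
      }
      if (!all(sex %in% c("M", "F"))) {
        abort(sprintf("sex labels must be 'M'/'F'; found: %s",
                      paste(unique(sex[!sex %in% c("M", "F")]), collapse = ", ")))
      }
      annotations$sex <- sex
    }
  }
  structure(list(dataset_id = as.character(dataset_id),
                 values = values,
                 annotations = annotations),
            class = "expression_dataset")
}

assert_expression_dataset <- function(ds) {
  if (!inherits(ds, "expression_dataset")) {
    abort("expected an `expression_dataset` (see read_expression()/simulate_dataset()).")
  }
  invisible(ds)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d features x %d samples (%d case / %d control%s)\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              sum(x$annotations$condition == "case"),
              sum(x$annotations$condition == "control"),
              if ("sex" %in% names(x$annotations)) ", sex-annotated" else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix and sample sheet from TSV
#'
#' The matrix is a tab-separated file whose header row holds sample ids and
#' whose first column holds feature ids; the sheet is a TSV with columns
#' `sample`, `condition` and optionally `sex`. Literal `NA` cells are kept as
#' missing values and handled downstream (genes with missing values are
#' excluded per comparison); any other non-numeric cell is an error naming
#' the feature and sample. Samples present in one file but not the other are
#' an error in either direction.
#'
#' @param matrix_path,sheet_path Paths to the two TSV files.
#' @param dataset_id Label for the dataset; defaults to the matrix file name.
#' @param condition_map Optional named character vector explicitly mapping
#'   the sheet's condition labels (matched case-insensitively) to `"case"` or
#'   `"control"`, e.g. `c(PD = "case", healthy = "control")`. Labels are never
#'   guessed.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, sheet_path,
                            dataset_id = NULL, condition_map = NULL) {
  if (!file.exists(matrix_path)) abort(sprintf("matrix file not found: %s", matrix_path))
  if (!file.exists(sheet_path)) abort(sprintf("sample sheet not found: %s", sheet_path))
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(matrix_path))

  header <- strsplit(readLines(matrix_path, n = 1L), "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(header)) {
    abort(sprintf("duplicate sample id(s) in '%s' header: %s", matrix_path,
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  }

  mat_tbl <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE, na = character())
  probs <- readr::problems(mat_tbl)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed TSV '%s': line %d (%s).", matrix_path,
                  probs$row[[1L]] + 1L, probs$expected[[1L]]))
  }
  if (ncol(mat_tbl) < 2L) abort(sprintf("'%s' has no sample columns.", matrix_path))
  feature_ids <- as.character(mat_tbl[[1L]])
  sample_ids <- names(mat_tbl)[-1L]
  values <- matrix(NA_real_, nrow = length(feature_ids), ncol = length(sample_ids),
                   dimnames = list(feature_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- mat_tbl[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(col %in% c("NA", "NaN", "") | is.na(col)))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value '%s' for feature '%s', sample '%s' in %s.",
                    col[bad[1L]], feature_ids[bad[1L]], sample_ids[j], matrix_path))
    }
    values[, j] <- num
  }
  n_missing <- sum(is.na(values))
  if (n_missing > 0L) {
    message(sprintf("[%s] %d missing value(s) read; affected genes are excluded per comparison downstream.",
                    dataset_id, n_missing))
  }

  sheet <- readr::read_tsv(sheet_path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  sprobs <- readr::problems(sheet)
  if (nrow(sprobs) > 0L) {
    abort(sprintf("malformed TSV '%s': line %d.", sheet_path, sprobs$row[[1L]] + 1L))
  }
  if (!all(c("sample", "condition") %in% names(sheet))) {
    abort(sprintf("'%s' must have columns `sample` and `condition` (optional `sex`).", sheet_path))
  }
  if (!is.null(condition_map)) {
    if (is.null(names(condition_map)) || !all(condition_map %in% c("case", "control"))) {
      abort("`condition_map` must be a named vector with values 'case'/'control'.")
    }
    key <- match(tolower(sheet$condition), tolower(names(condition_map)))
    mapped <- unname(condition_map[key])
    sheet$condition <- ifelse(is.na(key), sheet$condition, mapped)
  }
  expression_dataset(values, sheet, dataset_id = dataset_id)
}

#' Write an expression dataset back to TSV
#'
#' Inverse of [read_expression()]: values are written with shortest
#' round-trip decimal representation, so write-then-read reproduces finite
#' values bit-exactly.
#'
#' @param ds An [expression_dataset()].
#' @param matrix_path,sheet_path Output TSV paths.
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, sheet_path) {
  assert_expression_dataset(ds)
  tbl <- bind_cols(tibble(feature = rownames(ds$values)),
                   as_tibble(as.data.frame(ds$values)))
  readr::write_tsv(tbl, matrix_path, progress = FALSE)
  readr::write_tsv(ds$annotations, sheet_path, progress = FALSE)
  invisible(ds)
}

#' Collapse probe-level rows to gene level
#'
#' Maps probe identifiers to gene symbols and summarizes each gene's probe
#' rows per sample. Unmapped probes are dropped. The default summary is the
#' per-sample median across a gene's probes (robust and deterministic);
#' `"mean"` averages them and `"max_variance"` keeps the single most variable
#' probe row per gene. Missing values propagate (no `na.rm`), so genes with
#' missing probes remain flagged for per-comparison exclusion.
#'
#' @param ds An [expression_dataset()] with probe-level rows.
#' @param mapping Data frame with columns `probe` and `symbol` (extra columns
#'   ignored), or a named character vector `probe -> symbol`.
#' @param method `"median"` (default), `"mean"` or `"max_variance"`.
#' @return An [expression_dataset()] with one row per gene symbol.
#' @export
collapse_probes <- function(ds, mapping, method = c("median", "mean", "max_variance")) {
  assert_expression_dataset(ds)
  method <- match.arg(method)
  if (is.character(mapping) && !is.null(names(mapping))) {
    mapping <- tibble(probe = names(mapping), symbol = unname(mapping))
  }
  if (!is.data.frame(mapping) || !all(c("probe", "symbol") %in% names(mapping))) {
    abort("`mapping` must have columns `probe` and `symbol`.")
  }
  mapping <- distinct(tibble(probe = as.character(mapping$probe),
                             symbol = as.character(mapping$symbol)))
  mapping <- mapping[mapping$probe %in% rownames(ds$values), , drop = FALSE]
  if (nrow(mapping) == 0L) {
    abort("`mapping` covers none of the dataset's features.")
  }
  if (anyDuplicated(mapping$probe)) {
    abort("`mapping` assigns some probe to more than one symbol.")
  }
  rows <- split(mapping$probe, mapping$symbol)
  symbols <- names(rows)
  out <- matrix(NA_real_, nrow = length(symbols), ncol = ncol(ds$values),
                dimnames = list(symbols, colnames(ds$values)))
  for (i in seq_along(rows)) {
    block <- ds$values[rows[[i]], , drop = FALSE]
    out[i, ] <- switch(method,
                       median = apply(block, 2L, median),
                       mean = colMeans(block),
                       max_variance = {
                         v <- apply(block, 1L, var)
                         v[is.na(v)] <- -Inf
                         block[which.max(v), ]
                       })
  }
  expression_dataset(out, ds$annotations, dataset_id = ds$dataset_id)
}

#' Partition samples into comparison groups
#'
#' Without sex stratification the samples split into `Control` and `Case`;
#' with it, into the four groups arising from the intersection of sex and
#' condition: `MaleControl`, `MaleCase`, `FemaleControl`, `FemaleCase`.
#' Every referenced group must be non-empty.
#'
#' @param ds An [expression_dataset()].
#' @param stratify_by_sex If `TRUE`, require sex annotations and return the
#'   four sex-by-condition groups.
#' @return A tibble with columns `group` and `sample`; together the rows
#'   partition the dataset's samples.
#' @export
build_groups <- function(ds, stratify_by_sex = FALSE) {
  assert_expression_dataset(ds)
  ann <- ds$annotations
  if (stratify_by_sex) {
    if (!"sex" %in% names(ann)) {
      abort(sprintf("[%s] sex-stratified groups need a `sex` annotation for every sample.",
                    ds$dataset_id))
    }
    grp <- paste0(ifelse(ann$sex == "M", "Male", "Female"),
                  ifelse(ann$condition == "case", "Case", "Control"))
    required <- c("MaleControl", "MaleCase", "FemaleControl", "FemaleCase")
  } else {
    grp <- ifelse(ann$condition == "case", "Case", "Control")
    required <- c("Control", "Case")
  }
  empty <- setdiff(required, unique(grp))
  if (length(empty) > 0L) {
    abort(sprintf("[%s] empty group(s): %s", ds$dataset_id,
                  paste(empty, collapse = ", ")))
  }
  tibble(group = grp, sample = ann$sample)
}

# Sample ids of one named group; accepts MalePD/FemalePD as aliases for the
# Case groups.
resolve_group <- function(ds, name) {
  name <- sub("PD$", "Case", name)
  if (!name %in% GROUP_NAMES) {
    abort(sprintf("unknown group '%s'; expected one of %s.", name,
                  paste(GROUP_NAMES, collapse = ", ")))
  }
  groups <- build_groups(ds, stratify_by_sex = name %in% GROUP_NAMES[-(1:2)])
  ids <- groups$sample[groups$group == name]
  if (length(ids) == 0L) abort(sprintf("[%s] group '%s' is empty.", ds$dataset_id, name))
  ids
}
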