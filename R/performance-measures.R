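# Performance measures: per-gene location-statistic differences between two
# sample groups, and the linear transformation that turns "largest change"
# into a minimization criterion.

PM_STATISTICS <- c("mean", "median", "mode", "q3", "quantile")

#' Describe one performance measure
#'
#' A performance measure (PM) scores each gene by the absolute difference of a
#' location statistic between two sample groups:
#' `|stat(group_a) - stat(group_b)|`. The menu is location statistics only:
#' mean, median, mode, third quartile, or any quantile of interest.
#'
#' @param statistic One of `"mean"`, `"median"`, `"mode"`, `"q3"`,
#'   `"quantile"`. `"q3"` is the quantile at 0.75.
#' @param quantile_q Quantile level in (0, 1); required exactly when
#'   `statistic = "quantile"`. Quantiles use linear interpolation between
#'   order statistics (R's default type 7), fixed so results are reproducible
#'   across implementations.
#' @param group_a,group_b Names of the sample groups to compare (see
#'   [build_groups()]); may be left `NULL` when an analysis flow supplies the
#'   comparison.
#' @return An object of class `pm_spec`.
#' @examples
#' pm_spec("mean")
#' pm_spec("quantile", quantile_q = 0.9)
#' @export
pm_spec <- function(statistic = c("mean", "median", "mode", "q3", "quantile"),
                    quantile_q = NULL, group_a = NULL, group_b = NULL) {
  if (length(statistic) != 1L && !identical(statistic, PM_STATISTICS)) {
    abort("`statistic` must be a single statistic name.")
  }
  statistic <- match.arg(statistic)
  if (statistic == "quantile") {
    if (is.null(quantile_q) || !is.numeric(quantile_q) || length(quantile_q) != 1L ||
        is.na(quantile_q) || quantile_q <= 0 || quantile_q >= 1) {
      abort("`quantile_q` must be a single number in (0, 1) when statistic = \"quantile\".")
    }
  } else if (!is.null(quantile_q)) {
    abort("`quantile_q` is only meaningful for statistic = \"quantile\".")
  }
  structure(list(statistic = statistic,
                 quantile_q = if (statistic == "q3") 0.75 else quantile_q,
                 group_a = group_a, group_b = group_b),
            class = "pm_spec")
}

#' @export
print.pm_spec <- function(x, ...) {
  cat(sprintf("<pm_spec> %s%s%s\n", x$statistic,
              if (!is.null(x$quantile_q) && x$statistic == "quantile")
                sprintf("(q = %g)", x$quantile_q) else "",
              if (!is.null(x$group_a))
                sprintf(" : %s vs %s", x$group_a, x$group_b) else ""))
  invisible(x)
}

pm_label <- function(spec) {
  if (spec$statistic == "quantile") sprintf("quantile%g", spec$quantile_q)
  else spec$statistic
}

# Coerce "mean"/"median"/... shorthands (or pm_spec) into pm_spec objects.
as_pm_spec <- function(x) {
  if (inherits(x, "pm_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(pm_spec(x))
  abort("performance measures must be pm_spec objects or statistic names.")
}

#' Mode of a numeric vector by rounded frequency
#'
#' Estimates the mode of (continuous) expression values as the most frequent
#' value after rounding to `digits` decimals. Ties between equally frequent
#' rounded values are broken by their arithmetic mean; in particular a vector
#' of all-distinct values (all tied at frequency one) returns the mean of the
#' rounded values. Deterministic and parameter-light by design: a
#' density-based estimator would introduce a bandwidth parameter.
#'
#' @param values Non-empty numeric vector.
#' @param digits Decimals to round to before counting (default 4).
#' @return The estimated mode, a single number.
#' @examples
#' estimate_mode(c(1, 1, 2, 3))    # 1
#' estimate_mode(c(1, 1, 2, 2, 5)) # 1.5: mean of tied modes 1 and 2
#' @export
estimate_mode <- function(values, digits = 4) {
  if (!is.numeric(values) || length(values) == 0L) {
    abort("`values` must be a non-empty numeric vector.")
  }
  if (anyNA(values)) return(NA_real_)
  r <- round(values, digits)
  u <- unique(r)
  counts <- tabulate(match(r, u))
  mean(u[counts == max(counts)])
}

# Evaluate the location statistic of a pm_spec on a numeric vector.
location_stat <- function(x, spec) {
  switch(spec$statistic,
         mean = mean(x),
         median = median(x),
         mode = estimate_mode(x),
         q3 = ,
         quantile = unname(quantile(x, probs = spec$quantile_q, type = 7)),
         abort(sprintf("unknown statistic '%s'.", spec$statistic)))
}

#' Compute one performance measure for every gene
#'
#' For each gene, computes the absolute difference of the spec's location
#' statistic between the two sample groups:
#' `|stat(values in group_a) - stat(values in group_b)|`. Genes with any
#' missing value inside either group are excluded from the comparison (no
#' imputation is attempted); the exclusion is reported via a message and the
#' `"excluded_genes"` attribute.
#'
#' @param ds An [expression_dataset()].
#' @param spec A [pm_spec()] with `group_a`/`group_b` set, or a statistic
#'   name combined with `comparison`.
#' @param comparison Length-2 character vector naming `(group_a, group_b)`;
#'   used when `spec` does not carry groups.
#' @return A tibble with columns `gene` and `value` (the raw non-negative
#'   magnitude), carrying the producing `pm_spec` and source dataset id as
#'   attributes `"pm_spec"` and `"source_dataset"`.
#' @examples
#' ds <- simulate_dataset(n_genes = 20, seed = 1)$dataset
#' pm <- compute_pm(ds, "mean", comparison = c("Control", "Case"))
#' head(pm)
#' @export
compute_pm <- function(ds, spec, comparison = NULL) {
  assert_expression_dataset(ds)
  spec <- as_pm_spec(spec)
  if (!is.null(comparison)) {
    if (length(comparison) != 2L) abort("`comparison` must name two groups.")
    spec$group_a <- comparison[[1L]]
    spec$group_b <- comparison[[2L]]
  }
  if (is.null(spec$group_a) || is.null(spec$group_b)) {
    abort("the performance measure needs `group_a` and `group_b` (or `comparison`).")
  }
  a_cols <- resolve_group(ds, spec$group_a)
  b_cols <- resolve_group(ds, spec$group_b)
  A <- ds$values[, a_cols, drop = FALSE]
  B <- ds$values[, b_cols, drop = FALSE]
  ok <- !(rowSums(is.na(A)) > 0L | rowSums(is.na(B)) > 0L)
  excluded <- rownames(ds$values)[!ok]
  if (length(excluded) > 0L) {
    message(sprintf("[%s] excluding %d gene(s) with missing values in %s/%s: %s%s",
                    ds$dataset_id, length(excluded), spec$group_a, spec$group_b,
                    paste(head(excluded, 5L), collapse = ", "),
                    if (length(excluded) > 5L) ", ..." else ""))
  }
  A <- A[ok, , drop = FALSE]
  B <- B[ok, , drop = FALSE]
  value <- if (spec$statistic == "mean") {
    abs(rowMeans(A) - rowMeans(B))
  } else {
    abs(apply(A, 1L, location_stat, spec = spec) -
        apply(B, 1L, location_stat, spec = spec))
  }
  structure(tibble(gene = rownames(ds$values)[ok], value = unname(value)),
            pm_spec = spec,
            source_dataset = ds$dataset_id,
            excluded_genes = excluded)
}

#' Transform a performance measure to a minimization criterion
#'
#' Applies the linear map `max - x` over the genes entering the analysis, so
#' the gene(s) with the largest raw expression change sit exactly at 0 and
#' solutions toward the origin are the most significant. The map reverses the
#' within-vector ordering and nothing else, so Pareto membership is driven by
#' the raw magnitudes.
#'
#' @param pm A tibble as returned by [compute_pm()] (columns `gene`, `value`).
#' @return A tibble with columns `gene`, `raw` (the input magnitude) and
#'   `value` (the transformed, minimized criterion), preserving the
#'   `"pm_spec"` and `"source_dataset"` attributes.
#' @examples
#' pm <- tibble::tibble(gene = c("a", "b", "c"), value = c(5, 0, 3))
#' to_minimization(pm)$value # 0 5 2
#' @export
to_minimization <- function(pm) {
  if (!is.data.frame(pm) || !all(c("gene", "value") %in% names(pm))) {
    abort("`pm` must be a data frame with columns `gene` and `value`.")
  }
  if (nrow(pm) == 0L) abort("cannot transform an empty performance-measure vector.")
  if (anyNA(pm$value)) abort("`pm$value` contains missing values.")
  structure(tibble(gene = as.character(pm$gene),
                   raw = pm$value,
                   value = max(pm$value) - pm$value),
            pm_spec = attr(pm, "pm_spec"),
            source_dataset = attr(pm, "source_dataset"))
}
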