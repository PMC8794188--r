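# Analysis flows: single-dataset MCO (2-3 performance measures), cross-dataset
# meta-analysis (one measure per dataset), and the four-comparison
# sex-stratified scheme with its genes-of-interest set algebra.

FOURWAY_COMPARISONS <- list(
  MCO1 = c("MaleControl", "MaleCase"),
  MCO2 = c("FemaleControl", "FemaleCase"),
  MCO3 = c("MaleControl", "FemaleControl"),
  MCO4 = c("MaleCase", "FemaleCase")
)

# Assemble a criteria table from a list of raw PM tibbles: inner-join on
# gene, then transform each column with max - x over the joined gene set
# (the genes entering the analysis), so criteria are minimized and the
# largest change sits at 0.
build_criteria <- function(pms, labels) {
  counts <- map_int(pms, nrow)
  joined <- purrr::reduce(imap(pms, function(pm, i) {
    setNames(pm[c("gene", "value")], c("gene", labels[[i]]))
  }), inner_join, by = "gene")
  if (nrow(joined) == 0L) {
    abort(sprintf("no genes shared by all criteria after exclusions (per-source gene counts: %s).",
                  paste(sprintf("%s = %d", labels, counts), collapse = ", ")))
  }
  joined <- arrange(joined, .data$gene)
  raw <- joined
  for (lab in labels) joined[[lab]] <- max(joined[[lab]]) - joined[[lab]]
  list(criteria = joined, raw = raw)
}

new_mco_fit <- function(assignment, criteria, raw, pm_specs, mode, comparison,
                        n_frontiers, n_splits, dataset_ids) {
  structure(list(assignment = assignment,
                 criteria = criteria,
                 raw = raw,
                 pm_specs = pm_specs,
                 mode = mode,
                 comparison = comparison,
                 n_frontiers = n_frontiers,
                 n_splits = n_splits,
                 dataset_ids = dataset_ids),
            class = "mco_fit")
}

#' Single-dataset MCO analysis
#'
#' Scores every gene with two or three performance measures on one
#' case/control comparison, transforms each measure to a minimization
#' criterion, and peels the first `n_frontiers` Pareto-efficient frontiers.
#'
#' @param ds An [expression_dataset()].
#' @param pm_specs Two or three performance measures: statistic names (e.g.
#'   `c("mean", "median")`) or a list of [pm_spec()] objects.
#' @param comparison The two group names to compare, e.g.
#'   `c("Control", "Case")` or `c("MaleControl", "MaleCase")`.
#' @param n_frontiers Number of frontiers to extract (`F`).
#' @param n_splits Number of blocks for the split/local/global frontier
#'   scheme (`S`); the result is invariant to it.
#' @return An `mco_fit` object; see [tidy.mco_fit()], [glance.mco_fit()],
#'   [autoplot.mco_fit()].
#' @examples
#' sim <- simulate_dataset(n_genes = 100, seed = 7)
#' fit <- run_single(sim$dataset, c("mean", "median"),
#'                   comparison = c("Control", "Case"), n_frontiers = 3)
#' glance(fit)
#' @export
run_single <- function(ds, pm_specs = c("mean", "median"),
                       comparison = c("Control", "Case"),
                       n_frontiers = 1L, n_splits = 1L) {
  assert_expression_dataset(ds)
  specs <- if (is.character(pm_specs)) map(as.list(pm_specs), as_pm_spec)
           else map(pm_specs, as_pm_spec)
  if (length(specs) < 2L || length(specs) > 3L) {
    abort(sprintf("single-dataset analysis takes 2 or 3 performance measures, got %d.",
                  length(specs)))
  }
  labels <- make.unique(map_chr(specs, pm_label), sep = "_")
  pms <- map(specs, compute_pm, ds = ds, comparison = comparison)
  parts <- build_criteria(pms, labels)
  assignment <- peel_frontiers(parts$criteria, n_frontiers = n_frontiers, s = n_splits)
  new_mco_fit(assignment, parts$criteria, parts$raw, specs, "single",
              comparison, n_frontiers, n_splits, ds$dataset_id)
}

#' Meta-analysis MCO across several datasets
#'
#' Takes one performance measure from each of `K >= 2` datasets as one
#' criterion each, joins on gene identifiers keeping only genes present in
#' all datasets (strict intersection: a Pareto point needs a value in every
#' criterion, and no cross-platform imputation is attempted), and peels
#' frontiers in the resulting K-dimensional criteria space. Because each
#' dataset contributes its own criterion, Pareto efficiency spans datasets
#' without unit harmonization.
#'
#' @param datasets A list of 2 or more [expression_dataset()] objects.
#' @param pm_specs One statistic name / [pm_spec()] applied to every dataset
#'   (default `"median"`), or a list with one entry per dataset.
#' @inheritParams run_single
#' @return An `mco_fit` object.
#' @export
run_meta <- function(datasets, pm_specs = "median",
                     comparison = c("Control", "Case"),
                     n_frontiers = 1L, n_splits = 1L) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    abort("meta-analysis needs a list of at least 2 datasets.")
  }
  purrr::walk(datasets, assert_expression_dataset)
  ids <- map_chr(datasets, "dataset_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  specs <- if (inherits(pm_specs, "pm_spec") ||
               (is.character(pm_specs) && length(pm_specs) == 1L)) {
    rep(list(as_pm_spec(pm_specs)), length(datasets))
  } else {
    map(pm_specs, as_pm_spec)
  }
  if (length(specs) != length(datasets)) {
    abort("supply one performance measure per dataset (or a single shared one).")
  }
  labels <- make.unique(paste0(map_chr(specs, pm_label), "|", ids), sep = "_")
  pms <- map2(datasets, specs, function(d, s) compute_pm(d, s, comparison = comparison))
  parts <- build_criteria(pms, labels)
  assignment <- peel_frontiers(parts$criteria, n_frontiers = n_frontiers, s = n_splits)
  new_mco_fit(assignment, parts$criteria, parts$raw, specs, "meta",
              comparison, n_frontiers, n_splits, ids)
}

#' Genes-of-interest set algebra over the four comparisons
#'
#' Given the gene sets selected by the four sex-stratified comparisons,
#' returns `(MCO1 \eqn{\cap} MCO2) \\ (MCO3 \eqn{\cup} MCO4)`: genes selected
#' in both within-sex disease comparisons but in neither sex-vs-sex
#' comparison, i.e. condition-specific rather than sex-dimorphic signal.
#'
#' @param mco1,mco2,mco3,mco4 Character vectors of gene ids.
#' @return A tibble over the union of all four sets with logical provenance
#'   columns `in_MCO1`..`in_MCO4` and `selected`; attribute `"result"` holds
#'   the sorted selected gene ids.
#' @examples
#' goi <- genes_of_interest(c("a", "b", "c"), c("b", "c", "d"), "c", character())
#' attr(goi, "result") # "b"
#' @export
genes_of_interest <- function(mco1, mco2, mco3, mco4) {
  sets <- list(MCO1 = unique(as.character(mco1)), MCO2 = unique(as.character(mco2)),
               MCO3 = unique(as.character(mco3)), MCO4 = unique(as.character(mco4)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  out <- tibble(gene = universe,
                in_MCO1 = universe %in% sets$MCO1,
                in_MCO2 = universe %in% sets$MCO2,
                in_MCO3 = universe %in% sets$MCO3,
                in_MCO4 = universe %in% sets$MCO4)
  out$selected <- out$in_MCO1 & out$in_MCO2 & !out$in_MCO3 & !out$in_MCO4
  structure(out, result = out$gene[out$selected])
}

#' Four-comparison sex-stratified MCO scheme
#'
#' Runs the configured analysis once per comparison with identical
#' `n_frontiers` and `n_splits`: MCO 1 compares MaleControl vs MaleCase,
#' MCO 2 FemaleControl vs FemaleCase, MCO 3 MaleControl vs FemaleControl, and
#' MCO 4 MaleCase vs FemaleCase. Each comparison contributes the union of its
#' extracted frontiers 1..F; the genes of interest — condition-specific, not
#' sex-dimorphic — are `(MCO1` \eqn{\cap} `MCO2) \\ (MCO3` \eqn{\cup}
#' `MCO4)`.
#'
#' @param x One [expression_dataset()] (`mode = "single"`) or a list of them
#'   (`mode = "meta"`).
#' @param mode `"single"` (2-3 PMs on one dataset) or `"meta"` (one PM per
#'   dataset).
#' @param pm_specs Passed to [run_single()] or [run_meta()].
#' @inheritParams run_single
#' @return An object of class `mco_fourway`: the four `mco_fit`s, the
#'   per-comparison member sets, and the genes-of-interest table.
#' @export
run_four_way <- function(x, mode = c("single", "meta"),
                         pm_specs = NULL, n_frontiers = 1L, n_splits = 1L) {
  mode <- match.arg(mode)
  runner <- switch(mode,
    single = function(cmp) {
      run_single(x, pm_specs %||% c("mean", "median"), comparison = cmp,
                 n_frontiers = n_frontiers, n_splits = n_splits)
    },
    meta = function(cmp) {
      run_meta(x, pm_specs %||% "median", comparison = cmp,
               n_frontiers = n_frontiers, n_splits = n_splits)
    })
  fits <- map(FOURWAY_COMPARISONS, function(cmp) {
    withCallingHandlers(
      runner(cmp),
      error = function(e) {
        abort(sprintf("comparison %s vs %s failed: %s",
                      cmp[[1L]], cmp[[2L]], conditionMessage(e)))
      })
  })
  members <- map(fits, function(f) {
    sort(f$assignment$gene[!is.na(f$assignment$frontier)])
  })
  goi <- genes_of_interest(members$MCO1, members$MCO2, members$MCO3, members$MCO4)
  frontier_of <- function(fit, genes) {
    fit$assignment$frontier[match(genes, fit$assignment$gene)]
  }
  goi$frontier_MCO1 <- frontier_of(fits$MCO1, goi$gene)
  goi$frontier_MCO2 <- frontier_of(fits$MCO2, goi$gene)
  goi$frontier_MCO3 <- frontier_of(fits$MCO3, goi$gene)
  goi$frontier_MCO4 <- frontier_of(fits$MCO4, goi$gene)
  structure(list(fits = fits,
                 members = members,
                 genes_of_interest = goi,
                 result = attr(goi, "result"),
                 mode = mode,
                 n_frontiers = as.integer(n_frontiers),
                 n_splits = as.integer(n_splits)),
            class = "mco_fourway")
}

#' @export
print.mco_fit <- function(x, ...) {
  cat(sprintf("<mco_fit> %s analysis: %d genes x %d criteria [%s], F = %d, S = %d\n",
              x$mode, nrow(x$criteria), ncol(x$criteria) - 1L,
              paste(names(x$criteria)[-1L], collapse = ", "),
              x$n_frontiers, x$n_splits))
  cat(sprintf("  comparison: %s vs %s; frontier 1 holds %d gene(s)\n",
              x$comparison[[1L]], x$comparison[[2L]],
              sum(x$assignment$frontier == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.mco_fourway <- function(x, ...) {
  cat(sprintf("<mco_fourway> %s mode, F = %d\n", x$mode, x$n_frontiers))
  for (nm in names(x$members)) {
    cat(sprintf("  %s (%s vs %s): %d gene(s)\n", nm,
                FOURWAY_COMPARISONS[[nm]][1L], FOURWAY_COMPARISONS[[nm]][2L],
                length(x$members[[nm]])))
  }
  cat(sprintf("  genes of interest (MCO1 & MCO2, not MCO3 | MCO4): %d\n",
              length(x$result)))
  invisible(x)
}

#' Tidy a fitted MCO analysis into a per-gene tibble
#'
#' @param x An `mco_fit`.
#' @param ... Unused.
#' @return A tibble with `gene`, `frontier` (NA for unranked genes), one
#'   transformed-criterion column per performance measure, and matching
#'   `raw_*` columns with the untransformed `|difference|` magnitudes.
#' @export
tidy.mco_fit <- function(x, ...) {
  raw <- x$raw
  names(raw)[-1L] <- paste0("raw_", names(raw)[-1L])
  out <- left_join(as_tibble(x$assignment), raw, by = "gene")
  class(out) <- setdiff(class(out), "mco_frontiers")
  out
}

#' One-row summary of a fitted MCO analysis
#'
#' @param x An `mco_fit`.
#' @param ... Unused.
#' @return A tibble with one row: mode, criteria count, gene counts, the
#'   number of frontiers requested and found, and frontier-1 size.
#' @export
glance.mco_fit <- function(x, ...) {
  tibble(mode = x$mode,
         n_genes = nrow(x$criteria),
         n_criteria = ncol(x$criteria) - 1L,
         n_frontiers_requested = attr(x$assignment, "n_frontiers_requested"),
         n_frontiers_found = attr(x$assignment, "n_frontiers_found"),
         n_ranked = sum(!is.na(x$assignment$frontier)),
         frontier1_size = sum(x$assignment$frontier == 1L, na.rm = TRUE))
}

#' Tidy the four-way scheme into its provenance table
#'
#' @param x An `mco_fourway`.
#' @param ... Unused.
#' @return The genes-of-interest tibble: one row per gene appearing in any
#'   comparison, logical `in_MCO1..4`, frontier indices, and `selected`.
#' @export
tidy.mco_fourway <- function(x, ...) as_tibble(x$genes_of_interest)

#' One-row summary of the four-way scheme
#'
#' @param x An `mco_fourway`.
#' @param ... Unused.
#' @return A tibble with per-comparison set sizes and the size of the final
#'   genes-of-interest set.
#' @export
glance.mco_fourway <- function(x, ...) {
  tibble(mode = x$mode,
         n_frontiers = x$n_frontiers,
         n_MCO1 = length(x$members$MCO1),
         n_MCO2 = length(x$members$MCO2),
         n_MCO3 = length(x$members$MCO3),
         n_MCO4 = length(x$members$MCO4),
         n_selected = length(x$result))
}
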