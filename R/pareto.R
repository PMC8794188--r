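# Pareto-efficient frontier machinery on criteria tables.
#
# A criteria table is a data frame whose first column holds unique gene
# identifiers and whose remaining columns are numeric criteria, all oriented
# to minimization (smaller is better; 0 is the best attainable value after
# the max-minus-x transformation). Comparisons are exact: no floating-point
# tolerance is applied, so results are bit-reproducible for identical input.

# Validate a criteria table and split it into ids + numeric matrix.
criteria_parts <- function(cm, arg = "cm") {
  if (!is.data.frame(cm)) {
    abort(sprintf("`%s` must be a data frame (gene column + criteria columns).", arg))
  }
  if (ncol(cm) < 2L) {
    abort(sprintf("`%s` needs a gene column and at least one criterion column.", arg))
  }
  if (nrow(cm) < 1L) {
    abort(sprintf("`%s` has no genes.", arg))
  }
  genes <- as.character(cm[[1L]])
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(sprintf("duplicated gene ids in `%s`: %s", arg,
                  paste(head(dup, 5L), collapse = ", ")))
  }
  M <- as.matrix(cm[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    abort(sprintf("criteria columns of `%s` must all be numeric.", arg))
  }
  storage.mode(M) <- "double"
  if (!all(is.finite(M))) {
    abort(sprintf("criteria in `%s` must be finite (no NA/NaN/Inf).", arg))
  }
  if (any(M < 0)) {
    abort(sprintf("criteria in `%s` must be non-negative (minimization scale).", arg))
  }
  list(genes = genes, M = M)
}

#' Pareto dominance between two criteria rows (minimization)
#'
#' `u` dominates `v` when `u` is no worse in every criterion and strictly
#' better in at least one. Identical rows do not dominate each other.
#'
#' @param u,v Numeric vectors of equal length (one row of criteria each).
#' @return `TRUE` if `u` dominates `v`, else `FALSE`.
#' @examples
#' dominates(c(1, 2), c(2, 3)) # TRUE
#' dominates(c(1, 3), c(3, 1)) # FALSE: a trade-off, incomparable
#' dominates(c(2, 2), c(2, 2)) # FALSE: no strict improvement
#' @export
dominates <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v)) abort("`u` and `v` must be numeric.")
  if (length(u) != length(v)) {
    abort(sprintf("criteria length mismatch: %d vs %d.", length(u), length(v)))
  }
  if (length(u) < 1L) abort("criteria rows must have length >= 1.")
  all(u <= v) && any(u < v)
}

# Logical index of non-dominated rows of numeric matrix M.
# Production path: lexicographic presort guarantees every dominator of a row
# precedes it, so each row needs checking only against the running frontier
# (transitivity makes earlier dominated rows irrelevant). C = 2 uses a
# linear sweep over the sorted rows instead.
frontier_flags <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(TRUE)
  ord <- do.call(order, c(unname(as.data.frame(M)), list(method = "radix")))
  if (ncol(M) == 2L) {
    return(frontier_flags_2d(M, ord))
  }
  C <- ncol(M)
  keep <- logical(n)
  front <- matrix(0, nrow = C, ncol = n) # transposed frontier, grown in place
  k <- 0L
  for (i in ord) {
    v <- M[i, ]
    if (k > 0L) {
      Fk <- front[, seq_len(k), drop = FALSE]
      le <- Fk <= v
      dominated <- any(.colSums(le, C, k) == C & .colSums(Fk < v, C, k) > 0)
      if (dominated) next
    }
    k <- k + 1L
    front[, k] <- v
    keep[i] <- TRUE
  }
  keep
}

# 2-D sweep: after sorting by (c1, c2), a row survives iff its c2 is strictly
# below every previous c2, or it duplicates the current minimum point.
frontier_flags_2d <- function(M, ord) {
  n <- nrow(M)
  keep <- logical(n)
  best2 <- Inf
  best1 <- Inf # c1 of the row that set best2
  for (i in ord) {
    y <- M[i, 2L]
    if (y < best2) {
      keep[i] <- TRUE
      best2 <- y
      best1 <- M[i, 1L]
    } else if (y == best2 && M[i, 1L] == best1) {
      keep[i] <- TRUE # exact duplicate of the current minimum: co-efficient
    }
  }
  keep
}

#' Extract the Pareto-efficient frontier of a criteria table
#'
#' Returns the rows whose criteria are dominated by no other row: the genes
#' offering the best possible compromises among all criteria simultaneously.
#' Duplicated criteria rows on the frontier are all retained (neither
#' dominates the other).
#'
#' @param cm A criteria table: data frame with a gene-id first column and one
#'   or more numeric criterion columns, all oriented to minimization.
#' @return A tibble: the subset of `cm` rows on the frontier, in input order.
#' @examples
#' cm <- tibble::tibble(gene = c("a", "b", "c", "d"),
#'                      c1 = c(1, 2, 2, 3), c2 = c(2, 1, 2, 3))
#' pareto_frontier(cm) # a and b
#' @seealso [peel_frontiers()], [pareto_frontier_split()], [brute_force_frontier()]
#' @export
pareto_frontier <- function(cm) {
  p <- criteria_parts(cm)
  as_tibble(cm[frontier_flags(p$M), , drop = FALSE])
}

#' Pareto frontier via split, local frontiers, and merge
#'
#' Partitions the genes into `s` contiguous blocks (after a deterministic
#' ordering by gene id), finds each block's local frontier, pools the local
#' frontiers and returns the frontier of the pool. The result is identical to
#' [pareto_frontier()] for every valid `s`; the split exists so very large
#' tables can be processed within modest memory.
#'
#' @inheritParams pareto_frontier
#' @param s Number of blocks, between 1 and the number of genes.
#' @return A tibble: the global frontier rows of `cm`, in input order.
#' @export
pareto_frontier_split <- function(cm, s = 1L) {
  p <- criteria_parts(cm)
  n <- nrow(p$M)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 1L || s > n) {
    abort(sprintf("`s` must be an integer between 1 and the gene count (%d).", n))
  }
  s <- as.integer(s)
  ord <- order(p$genes, method = "radix")
  sizes <- rep(n %/% s, s) + c(rep(1L, n %% s), rep(0L, s - n %% s))
  block_of <- rep(seq_len(s), times = sizes)
  survivors <- logical(n)
  for (b in seq_len(s)) {
    idx <- ord[block_of == b]
    survivors[idx[frontier_flags(p$M[idx, , drop = FALSE])]] <- TRUE
  }
  pool <- which(survivors)
  global <- pool[frontier_flags(p$M[pool, , drop = FALSE])]
  flags <- logical(n)
  flags[global] <- TRUE
  as_tibble(cm[flags, , drop = FALSE])
}

#' Peel successive Pareto-efficient frontiers
#'
#' Applies frontier extraction `n_frontiers` times, each time removing the
#' previous frontier, yielding a hierarchy of gene sets with decreasing
#' significance: frontier 1 is the Pareto-efficient set of the full table,
#' frontier f+1 the frontier of what remains after frontiers 1..f are removed.
#' Peeling stops early, with a warning, if the genes are exhausted first.
#'
#' @inheritParams pareto_frontier
#' @param n_frontiers Number of frontiers to extract (`F >= 1`).
#' @param s Split count handed to the frontier extraction at each peel (the
#'   result is invariant to it); blocks larger than the remaining gene count
#'   are clamped.
#' @return A tibble of class `mco_frontiers`: columns `gene`,
#'   `frontier` (integer rank 1..F, `NA` for genes beyond frontier
#'   `n_frontiers`) and the criterion columns, ordered by frontier then gene
#'   id. Attributes `n_frontiers_requested` and `n_frontiers_found` record
#'   the peeling outcome.
#' @examples
#' cm <- tibble::tibble(gene = c("a", "b", "c"), c1 = 1:3, c2 = 1:3)
#' peel_frontiers(cm, n_frontiers = 3) # one gene per frontier
#' @export
peel_frontiers <- function(cm, n_frontiers = 1L, s = 1L) {
  p <- criteria_parts(cm)
  if (!is.numeric(n_frontiers) || length(n_frontiers) != 1L ||
      is.na(n_frontiers) || n_frontiers < 1L) {
    abort("`n_frontiers` must be a single integer >= 1.")
  }
  n_frontiers <- as.integer(n_frontiers)
  n <- nrow(p$M)
  frontier <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  found <- 0L
  for (f in seq_len(n_frontiers)) {
    if (length(remaining) == 0L) break
    s_eff <- min(as.integer(s), length(remaining))
    hit <- remaining[pareto_membership(p$M[remaining, , drop = FALSE], s_eff)]
    frontier[hit] <- f
    remaining <- setdiff(remaining, hit)
    found <- f
  }
  if (found < n_frontiers && length(remaining) == 0L) {
    warn(sprintf("genes exhausted after %d of %d requested frontiers.",
                 found, n_frontiers))
  }
  out <- bind_cols(tibble(gene = p$genes, frontier = frontier),
                   as_tibble(as.data.frame(p$M)))
  names(out)[-(1:2)] <- names(cm)[-1L]
  out <- arrange(out, .data$frontier, .data$gene)
  structure(out,
            class = c("mco_frontiers", class(out)),
            n_frontiers_requested = n_frontiers,
            n_frontiers_found = found)
}

# Frontier membership flags for a matrix, through the split path when s > 1.
pareto_membership <- function(M, s) {
  if (s <= 1L) return(frontier_flags(M))
  n <- nrow(M)
  sizes <- rep(n %/% s, s) + c(rep(1L, n %% s), rep(0L, s - n %% s))
  block_of <- rep(seq_len(s), times = sizes)
  survivors <- logical(n)
  for (b in seq_len(s)) {
    idx <- which(block_of == b)
    survivors[idx[frontier_flags(M[idx, , drop = FALSE])]] <- TRUE
  }
  pool <- which(survivors)
  flags <- logical(n)
  flags[pool[frontier_flags(M[pool, , drop = FALSE])]] <- TRUE
  flags
}

#' Brute-force Pareto frontier (testing oracle)
#'
#' Exhaustive pairwise dominance check, kept deliberately naive and separate
#' from the production path: every gene is compared against every other gene.
#' Intended as an independent reference for testing on small tables
#' (O(n^2 C) work).
#'
#' @inheritParams pareto_frontier
#' @return A tibble: the frontier rows of `cm`, in input order.
#' @export
brute_force_frontier <- function(cm) {
  p <- criteria_parts(cm)
  M <- p$M
  n <- nrow(M)
  C <- ncol(M)
  Mt <- t(M)
  keep <- logical(n)
  for (i in seq_len(n)) {
    v <- Mt[, i]
    le <- Mt <= v
    dominated <- .colSums(le, C, n) == C & .colSums(Mt < v, C, n) > 0
    keep[i] <- !any(dominated)
  }
  as_tibble(cm[keep, , drop = FALSE])
}

#' @export
print.mco_frontiers <- function(x, ...) {
  req <- attr(x, "n_frontiers_requested")
  found <- attr(x, "n_frontiers_found")
  ranked <- sum(!is.na(x$frontier))
  cat(sprintf("Frontier assignment: %d genes, %d criteria; %d ranked over %d frontier(s) (requested %d)\n",
              nrow(x), ncol(x) - 2L, ranked, found, req))
  NextMethod()
}
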