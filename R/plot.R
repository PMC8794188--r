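# Frontier visualisations: scatter of all genes in transformed criteria
# space with frontier genes highlighted by frontier index. Solutions toward
# the origin are the most significant; plotting is a pure consumer and never
# alters analysis outputs.

#' Plot Pareto frontiers in criteria space
#'
#' Scatters every gene on two (ggplot2) or three (lattice cloud) of the
#' criteria axes, colouring genes by frontier index with unranked genes in
#' grey. The origin — the best attainable corner after the max-minus-x
#' transformation — sits at the lower left (front-lower-left in 3D).
#'
#' @param fit An `mco_fit` (from [run_single()]/[run_meta()]), or a
#'   frontier-assignment tibble from [peel_frontiers()].
#' @param axes Two or three criterion columns to display, as indices into
#'   the criteria columns or their names.
#' @param highlight Frontier indices to colour; others are drawn as
#'   unranked. `NULL` colours every extracted frontier.
#' @param label_frontier1 Annotate frontier-1 genes with their identifiers
#'   (2D only).
#' @param raw_scale Plot the raw `|difference|` magnitudes instead of the
#'   transformed minimization values (2D `mco_fit` only); the geometry flips
#'   so the most significant genes sit away from the origin.
#' @param file Optional output path; the format follows the extension
#'   (`.png`, `.pdf`, `.svg`).
#' @param width,height,dpi Device size in inches and raster resolution.
#' @return The plot object (a ggplot for two axes, a lattice trellis for
#'   three), invisibly when written to file.
#' @export
plot_frontiers <- function(fit, axes = c(1, 2), highlight = NULL,
                           label_frontier1 = FALSE, raw_scale = FALSE,
                           file = NULL, width = 6, height = 5, dpi = 150) {
  if (inherits(fit, "mco_fit")) {
    tbl <- as_tibble(fit$assignment)
    if (raw_scale) {
      raw <- fit$raw
      tbl <- left_join(tbl[c("gene", "frontier")], raw, by = "gene")
    }
  } else if (is.data.frame(fit) && all(c("gene", "frontier") %in% names(fit))) {
    tbl <- as_tibble(fit)
    if (raw_scale) abort("`raw_scale` needs an mco_fit (raw magnitudes are not in the assignment table).")
  } else {
    abort("`fit` must be an mco_fit or a frontier-assignment table.")
  }
  crit_cols <- setdiff(names(tbl), c("gene", "frontier"))
  if (is.numeric(axes)) {
    if (any(axes < 1 | axes > length(crit_cols))) {
      abort(sprintf("`axes` out of range: the table has %d criteria.", length(crit_cols)))
    }
    axes <- crit_cols[axes]
  }
  if (!all(axes %in% crit_cols)) {
    abort(sprintf("unknown axis column(s): %s", paste(setdiff(axes, crit_cols), collapse = ", ")))
  }
  if (!length(axes) %in% c(2L, 3L)) abort("`axes` must select 2 or 3 criteria.")
  shown <- tbl$frontier
  if (!is.null(highlight)) shown[!shown %in% highlight] <- NA_integer_
  tbl$.frontier <- factor(shown)

  if (length(axes) == 2L) {
    p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[axes[1L]]], y = .data[[axes[2L]]])) +
      ggplot2::geom_point(data = tbl[is.na(tbl$.frontier), ],
                          colour = "grey70", size = 1, alpha = 0.6) +
      ggplot2::geom_point(data = tbl[!is.na(tbl$.frontier), ],
                          ggplot2::aes(colour = .data$.frontier), size = 1.8) +
      ggplot2::labs(colour = "frontier",
                    title = if (raw_scale) "Expression change magnitudes" else
                      "Criteria space (solutions toward the origin are more significant)") +
      ggplot2::theme_bw()
    if (label_frontier1 && any(tbl$frontier == 1L, na.rm = TRUE)) {
      f1 <- tbl[!is.na(tbl$frontier) & tbl$frontier == 1L, ]
      p <- p + ggplot2::geom_text(data = f1, ggplot2::aes(label = .data$gene),
                                  vjust = -0.7, size = 2.7)
    }
    if (!is.null(file)) {
      ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
      return(invisible(p))
    }
    return(p)
  }

  form <- stats::as.formula(sprintf("`%s` ~ `%s` * `%s`", axes[3L], axes[1L], axes[2L]))
  grp <- factor(ifelse(is.na(shown), "unranked", paste0("frontier ", shown)))
  cols <- c(grDevices::hcl.colors(max(1L, nlevels(grp) - any(is.na(shown))), "Dark 3"),
            "grey70")[seq_len(nlevels(grp))]
  p <- lattice::cloud(form, data = tbl, groups = grp,
                      pch = 16, cex = 0.6,
                      auto.key = list(space = "right", points = TRUE),
                      par.settings = list(superpose.symbol = list(col = cols, pch = 16)),
                      main = "Criteria space (solutions toward the origin are more significant)")
  if (!is.null(file)) {
    open_device(file, width, height, dpi)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
    return(invisible(p))
  }
  p
}

open_device <- function(file, width, height, dpi) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height, units = "in", res = dpi),
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height),
         abort(sprintf("unsupported plot format '.%s' (use png, pdf or svg).", ext)))
}

#' @rdname plot_frontiers
#' @param object An `mco_fit`.
#' @param ... Passed to [plot_frontiers()].
#' @export
autoplot.mco_fit <- function(object, axes = c(1, 2), ...) {
  plot_frontiers(object, axes = axes, ...)
}

#' @export
plot.mco_fit <- function(x, ...) {
  p <- plot_frontiers(x, ...)
  if (inherits(p, "ggplot")) print(p) else print(p)
  invisible(x)
}
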