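#' Arrange test results as a BCT-by-MoA p-value matrix
#'
#' Rows are BCT codes, columns MoA categories; each tested link fills its
#' cell with the (optionally transformed) p-value and untested cells carry
#' the sentinel `NA` — "never described" is thereby distinguished from
#' "described but weak". Under the `"neglog10"` transform values are
#' \eqn{-\log_{10} p} with p clamped below at 1e-16 (so the transform is
#' bounded at 16).
#'
#' @param results A `moa_link_test` or its [tidy()] tibble (columns
#'   `bct_code`, `moa_id`, `p`).
#' @param transform `"raw"` (default) or `"neglog10"`.
#' @return An object of class `moa_p_matrix`: a list with `values` (a
#'   numeric matrix with BCT codes as rownames and MoA categories as
#'   colnames) and `transform`.
#' @export
build_p_matrix <- function(results, transform = c("raw", "neglog10")) {
  transform <- match.arg(transform)
  if (inherits(results, "moa_link_test")) results <- results$results
  results <- tibble::as_tibble(results)
  stopifnot(all(c("bct_code", "moa_id", "p") %in% names(results)))
  if (anyDuplicated(results[, c("bct_code", "moa_id")])) {
    abort("Duplicate (bct_code, moa_id) pairs in results.",
          class = "moalink_validation_error")
  }
  rows <- sort(unique(results$bct_code))
  cols <- unique(results$moa_id)
  cols <- cols[order(suppressWarnings(as.numeric(cols)), cols)]
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                   dimnames = list(rows, cols))
  p <- results$p
  if (transform == "neglog10") p <- -log10(pmax(p, 1e-16))
  values[cbind(match(results$bct_code, rows),
               match(results$moa_id, cols))] <- p
  structure(list(values = values, transform = transform),
            class = "moa_p_matrix")
}

#' @export
print.moa_p_matrix <- function(x, ...) {
  cat(sprintf("<moa_p_matrix> %d x %d (%s), %d tested cells\n",
              nrow(x$values), ncol(x$values), x$transform,
              sum(!is.na(x$values))))
  invisible(x)
}

# Matrix on the clustering scale: sentinel cells imputed as p = 1, values
# mapped to -log10(p) so strong links dominate the distances.
clustering_values <- function(x) {
  v <- x$values
  if (x$transform == "raw") {
    v[is.na(v)] <- 1
    v <- -log10(pmax(v, 1e-16))
  } else {
    v[is.na(v)] <- 0
  }
  v
}

#' Hierarchical clustering orders for a p-value matrix
#'
#' Rows (BCTs) and columns (MoAs) are clustered independently by
#' agglomerative hierarchical clustering so that techniques linked to
#' similar mechanisms — and mechanisms linked by similar techniques — end
#' up adjacent. Distances are Euclidean on \eqn{-\log_{10} p} (untested
#' cells imputed as p = 1) and linkage is average by default; both are
#' configurable. Output is deterministic.
#'
#' @param x A `moa_p_matrix`.
#' @param method Agglomeration method passed to [stats::hclust()].
#' @param metric Distance metric passed to [stats::dist()].
#' @return An object of class `moa_cluster_order`: list with integer
#'   permutations `row_order` and `col_order` and the two `hclust` trees
#'   (`NULL` for axes of length 1).
#' @export
cluster_orders <- function(x, method = "average", metric = "euclidean") {
  stopifnot(inherits(x, "moa_p_matrix"))
  v <- clustering_values(x)
  if (nrow(v) < 1 || ncol(v) < 1) {
    abort("Matrix must have at least one row and column.",
          class = "moalink_validation_error")
  }
  if (all(is.na(x$values))) {
    abort("All cells are untested; nothing to cluster.",
          class = "moalink_validation_error")
  }
  axis_order <- function(m) {
    if (nrow(m) == 1) return(list(order = 1L, tree = NULL))
    tree <- hclust(dist(m, method = metric), method = method)
    list(order = tree$order, tree = tree)
  }
  r <- axis_order(v)
  c_ <- axis_order(t(v))
  structure(list(row_order = r$order, col_order = c_$order,
                 row_tree = r$tree, col_tree = c_$tree),
            class = "moa_cluster_order")
}

ordered_matrix <- function(x, orders = NULL) {
  v <- x$values
  if (is.null(orders)) return(v)
  stopifnot(inherits(orders, "moa_cluster_order"))
  if (length(orders$row_order) != nrow(v) ||
      length(orders$col_order) != ncol(v)) {
    abort("Cluster orders do not match the matrix dimensions.",
          class = "moalink_validation_error")
  }
  v[orders$row_order, orders$col_order, drop = FALSE]
}

#' Heat map of link enrichment p-values
#'
#' Tile plot of the (optionally clustered) p-value matrix: darker cells
#' mark links described more often than the marginal-product null
#' predicts (smaller p); untested cells — links never described — are
#' drawn in a distinct sentinel colour and labelled as such in the
#' legend. Rows are labelled with BCT code and label, columns with MoA
#' labels.
#'
#' @param x A `moa_p_matrix`.
#' @param orders Optional `moa_cluster_order`; by default computed with
#'   [cluster_orders()].
#' @param bct,moa Registries used for axis labels; pass `NULL` to label
#'   with bare codes/ids (necessary when the matrix covers entities
#'   outside the shipped registries).
#' @return A ggplot object.
#' @export
plot_link_heatmap <- function(x, orders = cluster_orders(x),
                              bct = bct_registry(), moa = moa_registry()) {
  stopifnot(inherits(x, "moa_p_matrix"))
  v <- ordered_matrix(x, orders)
  # plot on the raw-p scale regardless of the stored transform
  p_raw <- if (x$transform == "neglog10") 10^(-v) else v
  df <- tidyr::expand_grid(row = rownames(v), col = colnames(v))
  df <- dplyr::mutate(df,
    row = factor(.data$row, levels = rev(rownames(v))),
    col = factor(.data$col, levels = colnames(v)),
    p = as.vector(t(p_raw)))
  row_labs <- rownames(v)
  if (!is.null(bct)) {
    hit <- match(row_labs, bct$code)
    row_labs <- ifelse(is.na(hit), row_labs,
                       paste0(bct$label[hit], " (", row_labs, ")"))
  }
  col_labs <- colnames(v)
  if (!is.null(moa)) {
    hit <- match(suppressWarnings(as.integer(col_labs)), moa$id)
    col_labs <- ifelse(is.na(hit), col_labs, moa$label[hit])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$p)) +
    ggplot2::geom_tile(color = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_gradient(
      low = "#08306B", high = "#DEEBF7", limits = c(0, 1),
      na.value = "white", name = "p value",
      guide = ggplot2::guide_colorbar(reverse = FALSE)) +
    ggplot2::scale_x_discrete(labels = setNames(col_labs, colnames(v)),
                              position = "top") +
    ggplot2::scale_y_discrete(labels = setNames(row_labs, rownames(v))) +
    ggplot2::labs(x = "Mechanism of action", y = "Behavior change technique",
                  caption = "White cells: link never described (untested)") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 0))
}

#' @rdname test_links
#' @export
autoplot.moa_link_test <- function(object, ...) {
  pm <- build_p_matrix(object)
  plot_link_heatmap(pm, cluster_orders(pm), ...)
}

#' Render the clustered heat map and its data artifacts
#'
#' Writes the figure as PNG and SVG, the clustered matrix (raw p-values in
#' the emitted row/column order) as CSV, and the orders plus merge trees as
#' JSON. The CSV and JSON artifacts are byte-deterministic; raster bytes
#' may vary with the platform's font stack.
#'
#' @param x A `moa_p_matrix`.
#' @param path_prefix Output path prefix; files are
#'   `<prefix>.png`, `<prefix>.svg`, `<prefix>.csv`,
#'   `<prefix>_orders.json`.
#' @param orders Optional `moa_cluster_order` (computed by default).
#' @param formats Subset of `c("png", "svg", "csv", "json")`.
#' @param width,height Figure size in inches.
#' @param bct,moa Registries for labels (see [plot_link_heatmap()]).
#' @return Invisibly, a named character vector of the files written.
#' @export
render_heatmap <- function(x, path_prefix, orders = cluster_orders(x),
                           formats = c("png", "svg", "csv", "json"),
                           width = 10, height = 8,
                           bct = bct_registry(), moa = moa_registry()) {
  stopifnot(inherits(x, "moa_p_matrix"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dirname(path_prefix), showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if (any(c("png", "svg") %in% formats)) {
    plt <- plot_link_heatmap(x, orders, bct = bct, moa = moa)
    if ("png" %in% formats) {
      f <- paste0(path_prefix, ".png")
      ggplot2::ggsave(f, plt, width = width, height = height, dpi = 150,
                      device = grDevices::png, bg = "white")
      out["png"] <- f
    }
    if ("svg" %in% formats) {
      f <- paste0(path_prefix, ".svg")
      ggplot2::ggsave(f, plt, width = width, height = height,
                      device = grDevices::svg, bg = "white")
      out["svg"] <- f
    }
  }
  if ("csv" %in% formats) {
    f <- paste0(path_prefix, ".csv")
    v <- ordered_matrix(x, orders)
    if (x$transform == "neglog10") v <- 10^(-v)
    df <- tibble::as_tibble(v, rownames = "bct_code")
    readr::write_csv(df, f)
    out["csv"] <- f
  }
  if ("json" %in% formats) {
    f <- paste0(path_prefix, "_orders.json")
    tree_repr <- function(tree) {
      if (is.null(tree)) return(NULL)
      list(merge = apply(tree$merge, 1, identity, simplify = FALSE),
           height = tree$height, labels = tree$labels)
    }
    jsonlite::write_json(list(
      row_labels = rownames(x$values), col_labels = colnames(x$values),
      row_order = orders$row_order, col_order = orders$col_order,
      row_tree = tree_repr(orders$row_tree),
      col_tree = tree_repr(orders$col_tree)),
      f, auto_unbox = TRUE, digits = NA, null = "null")
    out["json"] <- f
  }
  invisible(out)
}
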