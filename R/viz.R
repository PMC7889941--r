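## Four visualization modes, each emitting a rendered figure (PNG + SVG)
## plus the exact underlying table, so figures are reproducible from text.

compartment_colors <- function() {
  c(stroma = "#4daf4a", innate = "#ff7f00", adaptive = "#377eb8",
    epithelium = "#f781bf", central = "#999999", other = "#bdbdbd")
}

open_devices <- function(out_path, width = 7, height = 7) {
  # renders both PNG and SVG next to each other; returns closer
  base <- sub("\\.(png|svg)$", "", out_path)
  png_path <- paste0(base, ".png"); svg_path <- paste0(base, ".svg")
  grDevices::png(png_path, width = width * 100, height = height * 100,
                 res = 100)
  list(finish = function(draw) {
    draw()
    grDevices::dev.off()
    grDevices::svg(svg_path, width = width, height = height)
    draw()
    grDevices::dev.off()
    c(png = png_path, svg = svg_path)
  })
}

#' Directed communication network plot
#'
#' One central node per condition-agnostic view: the central cell connects
#' to every partner with an edge whose width is proportional to the
#' rescaled [1, 10] score; optional integer score labels are printed on the
#' edges. Node colors follow the cell-compartment convention (stroma green,
#' innate orange, adaptive blue, epithelium pink, central gray).
#'
#' @param sm a \code{score_matrix} with the rescaled view computed.
#' @param condition which condition (row) to draw.
#' @param node_categories named character vector partner -> compartment
#'   (\code{stroma}, \code{innate}, \code{adaptive}, \code{epithelium});
#'   missing partners default to "other" with a warning.
#' @param out_path output path; ".png" and ".svg" are both written.
#' @param central_label node label of the central cell.
#' @param w_min,w_max edge widths (in lines) mapped linearly from scores 1
#'   and 10: width = w_min + (score - 1) / 9 * (w_max - w_min).
#' @param print_scores print integer-rounded rescaled scores on edges.
#' @param seed layout seed (deterministic figure).
#' @return Invisible list: \code{table} (edge table data.frame),
#'   \code{table_path}, \code{figure_paths}.
#' @export
export_network <- function(sm, condition, node_categories, out_path,
                           central_label = "central", w_min = 0.5,
                           w_max = 10, print_scores = TRUE, seed = 42) {
  stopifnot(inherits(sm, "score_matrix"))
  if (is.null(sm$rescaled))
    stop("rescaled view missing; call rescale_scores() first")
  if (!condition %in% rownames(sm$raw))
    stop("unknown condition: ", condition)
  partners <- colnames(sm$raw)
  missing_cat <- setdiff(partners, names(node_categories))
  if (length(missing_cat) > 0) {
    warning("partner(s) without compartment category default to 'other': ",
            paste(missing_cat, collapse = ", "))
    node_categories <- c(node_categories,
                         stats::setNames(rep("other", length(missing_cat)),
                                         missing_cat))
  }
  resc <- sm$rescaled[condition, ]
  edges <- data.frame(
    source = if (sm$direction == "out") central_label else partners,
    target = if (sm$direction == "out") partners else central_label,
    raw_score = sm$raw[condition, ],
    rescaled_score = resc,
    width = w_min + (resc - 1) / 9 * (w_max - w_min),
    stringsAsFactors = FALSE
  )
  table_path <- paste0(sub("\\.(png|svg)$", "", out_path), "_edges.tsv")
  write.table(edges, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(
      name = c(central_label, partners),
      category = c("central", unname(node_categories[partners]))))
  cols <- compartment_colors()
  vcat <- igraph::V(g)$category
  vcol <- unname(cols[ifelse(vcat %in% names(cols), vcat, "other")])
  dev <- open_devices(out_path)
  figure_paths <- dev$finish(function() {
    set.seed(seed)
    lay <- igraph::layout_in_circle(g, order = seq_along(igraph::V(g)))
    lay[1, ] <- c(0, 0)  # central node in the middle
    graphics::par(mar = c(1, 1, 2, 1))
    igraph::plot.igraph(
      g, layout = lay, vertex.color = vcol, vertex.size = 28,
      vertex.label.color = "black", vertex.label.cex = 0.8,
      edge.width = edges$width, edge.arrow.size = 0.6,
      edge.label = if (print_scores) round(edges$rescaled_score) else NULL,
      edge.label.color = "black",
      main = sprintf("communication network (%sward), condition %s",
                     sm$direction, condition))
  })
  invisible(list(table = edges, table_path = table_path,
                 figure_paths = figure_paths))
}

#' Stacked barplot of family contributions to communication scores
#'
#' One stacked bar per (condition, partner) column; segments are molecular
#' families (or cytokine subfamilies) and sum exactly to the global score.
#' Significance marks from a \code{score_comparison} are drawn at the
#' display threshold.
#'
#' @param contributions named list: column label -> named numeric vector of
#'   per-family sums (see \code{\link{family_contributions}}).
#' @param out_path output path (PNG + SVG written).
#' @param comparisons optional \code{score_comparison}; bars belonging to a
#'   pair with adjusted p <= threshold are starred.
#' @return Invisible list: \code{table}, \code{table_path},
#'   \code{figure_paths}.
#' @export
export_barplot <- function(contributions, out_path, comparisons = NULL) {
  stopifnot(is.list(contributions), length(contributions) > 0)
  fams <- unique(unlist(lapply(contributions, names)))
  mat <- vapply(contributions, function(v) {
    out <- stats::setNames(numeric(length(fams)), fams)
    out[names(v)] <- v
    out
  }, numeric(length(fams)))
  mat <- matrix(mat, nrow = length(fams),
                dimnames = list(fams, names(contributions)))
  tab <- data.frame(family = rownames(mat), mat, check.names = FALSE)
  table_path <- paste0(sub("\\.(png|svg)$", "", out_path), "_table.tsv")
  write.table(tab, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  starred <- character(0)
  if (!is.null(comparisons)) {
    stopifnot(inherits(comparisons, "score_comparison"))
    sig <- comparisons$table[comparisons$table$significant, , drop = FALSE]
    starred <- unique(c(sig$group1, sig$group2))
  }
  dev <- open_devices(out_path)
  figure_paths <- dev$finish(function() {
    graphics::par(mar = c(7, 4, 2, 8), xpd = TRUE)
    cols <- grDevices::hcl.colors(max(3, nrow(mat)), "Dark 3")[seq_len(nrow(mat))]
    bp <- graphics::barplot(mat, col = cols, las = 2,
                            ylab = "communication score",
                            main = "family contributions")
    idx <- match(starred, colnames(mat))
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0)
      graphics::text(bp[idx], colSums(mat)[idx], labels = "*", pos = 3,
                     cex = 1.6)
    graphics::legend("topright", inset = c(-0.28, 0), legend = rownames(mat),
                     fill = cols, cex = 0.7, bty = "n")
  })
  invisible(list(table = tab, table_path = table_path,
                 figure_paths = figure_paths))
}

#' Balloon plot of the top-contributing individual interactions
#'
#' Rows are interactions, columns are (condition, partner) channels,
#' balloon area encodes the per-interaction score. An interaction is shown
#' if its score reaches \code{cutoff} in at least one column; other columns
#' then display their actual value.
#'
#' @param breakdowns named list: column label -> \code{score_result}.
#' @param out_path output path (PNG + SVG written).
#' @param cutoff minimum contribution for display (default 10).
#' @param percent encode percent contribution to S instead of raw score.
#' @return Invisible list: \code{table} (filtered long-format data.frame),
#'   \code{table_path}, \code{figure_paths}.
#' @export
export_balloon <- function(breakdowns, out_path, cutoff = 10,
                           percent = FALSE) {
  stopifnot(is.list(breakdowns), length(breakdowns) > 0,
            all(vapply(breakdowns, inherits, logical(1), "score_result")))
  long <- do.call(rbind, lapply(names(breakdowns), function(lb) {
    b <- breakdowns[[lb]]$breakdown
    val <- if (percent) 100 * b$score / sum(b$score) else b$score
    data.frame(column = lb, interaction_id = b$interaction_id,
               family = b$family, value = val, stringsAsFactors = FALSE)
  }))
  shown_ids <- unique(long$interaction_id[long$value >= cutoff])
  tab <- long[long$interaction_id %in% shown_ids & long$value > 0, ,
              drop = FALSE]
  table_path <- paste0(sub("\\.(png|svg)$", "", out_path), "_table.tsv")
  write.table(tab, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dev <- open_devices(out_path, width = 6,
                      height = max(4, 0.25 * length(shown_ids) + 2))
  figure_paths <- dev$finish(function() {
    graphics::par(mar = c(8, 12, 2, 2))
    cols <- names(breakdowns)
    graphics::plot(NA, xlim = c(0.5, length(cols) + 0.5),
                   ylim = c(0.5, max(1, length(shown_ids)) + 0.5),
                   xaxt = "n", yaxt = "n", xlab = "", ylab = "",
                   main = sprintf("interactions with contribution >= %g",
                                  cutoff))
    graphics::axis(1, at = seq_along(cols), labels = cols, las = 2,
                   cex.axis = 0.8)
    if (length(shown_ids) > 0) {
      graphics::axis(2, at = seq_along(shown_ids), labels = shown_ids,
                     las = 2, cex.axis = 0.7)
      vmax <- max(tab$value)
      for (r in seq_len(nrow(tab))) {
        graphics::points(match(tab$column[r], cols),
                         match(tab$interaction_id[r], shown_ids),
                         cex = 0.5 + 3 * sqrt(tab$value[r] / vmax),
                         pch = 19, col = "#3182bd88")
      }
    }
  })
  invisible(list(table = tab, table_path = table_path,
                 figure_paths = figure_paths))
}

#' Heatmap of adjusted p-values from score comparisons
#'
#' @param comparison a \code{score_comparison} (from
#'   \code{\link{compare_distributions}}).
#' @param out_path output path (PNG + SVG written).
#' @return Invisible list: \code{table} (adjusted p matrix as data.frame),
#'   \code{table_path}, \code{figure_paths}.
#' @export
export_pvalue_heatmap <- function(comparison, out_path) {
  stopifnot(inherits(comparison, "score_comparison"))
  pm <- comparison$p_adj_matrix
  if (nrow(pm) < 2) stop("nothing to compare: a single group")
  tab <- data.frame(group = rownames(pm), pm, check.names = FALSE)
  table_path <- paste0(sub("\\.(png|svg)$", "", out_path), "_table.tsv")
  write.table(tab, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dev <- open_devices(out_path, width = 6, height = 6)
  figure_paths <- dev$finish(function() {
    n <- nrow(pm)
    z <- t(pm)[, rev(seq_len(n)), drop = FALSE]
    graphics::par(mar = c(6, 6, 3, 2))
    pal <- grDevices::hcl.colors(50, "Blues 3")
    graphics::image(seq_len(n), seq_len(n), z, zlim = c(0, 1), col = pal,
                    xaxt = "n", yaxt = "n", xlab = "", ylab = "",
                    main = "BH-adjusted Wilcoxon p-values")
    graphics::axis(1, at = seq_len(n), labels = colnames(pm), las = 2)
    graphics::axis(2, at = seq_len(n), labels = rev(rownames(pm)), las = 2)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      v <- pm[i, j]
      if (!is.na(v))
        graphics::text(j, n - i + 1, sprintf("%.3f", v), cex = 0.8,
                       col = if (v <= comparison$alpha_display) "red" else "black")
    }
  })
  invisible(list(table = tab, table_path = table_path,
                 figure_paths = figure_paths))
}
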