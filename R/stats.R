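## Replicate-wise score distributions, Wilcoxon comparison with BH
## adjustment, and single-cell subsampling robustness.
##
## Two comparison modes mirror the two questions one asks of a score:
##  - partner comparison: does the central cell communicate more with
##    partner type A than B? Average the central replicates (ligand side),
##    score against each partner replicate separately -> one distribution
##    of n scores per partner type (n = partner replicate count).
##  - condition comparison: does condition j communicate more than j'?
##    Score each central replicate separately against the partner mean.

#' Score distributions for comparing partner cell types
#'
#' @param central scaled gene-by-replicate matrix of the central cell; the
#'   ligand (outward) side is averaged over these columns.
#' @param partners scaled gene-by-replicate matrix of partner cells.
#' @param partner_types named character vector mapping each column of
#'   \code{partners} to its cell type.
#' @param db an \code{lr_database}.
#' @inheritParams global_score
#' @return Named list (one element per partner type) of numeric score
#'   vectors; class \code{score_distributions}, attribute \code{mode}.
#' @export
partner_comparison_scores <- function(central, partners, partner_types, db,
                                      direction = c("out", "in"), w = 1,
                                      missing = c("exclude", "zero")) {
  direction <- match.arg(direction)
  missing <- match.arg(missing)
  if (is.null(names(partner_types)))
    stop("partner_types must be named by partner column")
  if (!all(colnames(partners) %in% names(partner_types)))
    stop("every partner column needs a type in partner_types")
  central_mean <- rowMeans(central)
  names(central_mean) <- rownames(central)
  types <- unique(unname(partner_types[colnames(partners)]))
  out <- lapply(types, function(tp) {
    cols <- colnames(partners)[partner_types[colnames(partners)] == tp]
    vapply(cols, function(cc)
      global_score(central_mean, partners[, cc], db, direction, w,
                   missing)$S, numeric(1))
  })
  names(out) <- types
  structure(out, class = "score_distributions", mode = "partner_comparison")
}

#' Score distributions for comparing central-cell conditions
#'
#' @param central scaled gene-by-replicate matrix of the central cell.
#' @param conditions named character vector mapping each central column to
#'   its biological condition.
#' @param partner_mean named numeric vector: replicate-averaged scaled
#'   profile of one partner cell type.
#' @inheritParams partner_comparison_scores
#' @return Named list (one element per condition) of score vectors; class
#'   \code{score_distributions}, attribute \code{mode}.
#' @export
condition_comparison_scores <- function(central, conditions, partner_mean,
                                        db, direction = c("out", "in"),
                                        w = 1,
                                        missing = c("exclude", "zero")) {
  direction <- match.arg(direction)
  missing <- match.arg(missing)
  if (is.null(names(conditions)))
    stop("conditions must be named by central column")
  if (!all(colnames(central) %in% names(conditions)))
    stop("every central column needs a condition label")
  conds <- unique(unname(conditions[colnames(central)]))
  out <- lapply(conds, function(cd) {
    cols <- colnames(central)[conditions[colnames(central)] == cd]
    vapply(cols, function(cc)
      global_score(central[, cc], partner_mean, db, direction, w,
                   missing)$S, numeric(1))
  })
  names(out) <- conds
  structure(out, class = "score_distributions", mode = "condition_comparison")
}

#' Pairwise Wilcoxon comparison of score distributions
#'
#' All pairwise two-sided Wilcoxon rank-sum tests between the groups, exact
#' null when both groups have n <= 25 and no ties are present, normal
#' approximation with tie correction otherwise. P-values are adjusted with
#' Benjamini-Hochberg over the full pairwise family of one call.
#'
#' @param groups named list of numeric score vectors (each length >= 2), as
#'   returned by the *_comparison_scores functions.
#' @param alpha_display adjusted-p threshold used to flag significance for
#'   display (default 0.1).
#' @return Object of class \code{score_comparison}: list with \code{table}
#'   (data.frame: group1, group2, p, p_adj, significant), \code{p_matrix}
#'   and \code{p_adj_matrix} (symmetric, NA diagonal), \code{alpha_display}.
#' @export
compare_distributions <- function(groups, alpha_display = 0.1) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups of scores to compare")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must have unique names")
  nrep <- vapply(groups, length, integer(1))
  if (any(nrep < 2))
    stop("group(s) with fewer than 2 replicates cannot be tested: ",
         paste(names(groups)[nrep < 2], collapse = ", "))
  gn <- names(groups)
  pairs <- utils::combn(gn, 2)
  pv <- apply(pairs, 2, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (length(unique(c(x, y))) == 1) {
      warning("constant and identical groups '", pr[1], "' and '", pr[2],
              "': p set to 1 by convention")
      return(1)
    }
    exact <- length(x) <= 25 && length(y) <= 25 &&
      !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
  })
  padj <- stats::p.adjust(pv, method = "BH")
  tab <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = pv, p_adj = padj,
                    significant = padj <= alpha_display,
                    stringsAsFactors = FALSE)
  pm <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  pam <- pm
  for (idx in seq_len(ncol(pairs))) {
    a <- pairs[1, idx]; b <- pairs[2, idx]
    pm[a, b] <- pm[b, a] <- pv[idx]
    pam[a, b] <- pam[b, a] <- padj[idx]
  }
  structure(list(table = tab, p_matrix = pm, p_adj_matrix = pam,
                 alpha_display = alpha_display),
            class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf("pairwise two-sided Wilcoxon, BH-adjusted (significant at p_adj <= %g):\n",
              x$alpha_display))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Subsampling robustness of a single-cell communication score
#'
#' Randomly subsamples a cluster's cells at each requested fraction,
#' recomputes the cluster mean, re-scales it through the pipeline, scores
#' it against a fixed partner profile, and reports the standard deviation
#' of the scores over \code{n_rep} draws per fraction. Low fractions are
#' expected to give larger SDs (score variability is anti-correlated with
#' the percentage of cells used).
#'
#' Scaling a single subsampled mean in isolation is degenerate (its own
#' maximum would always map to 10), so with \code{scaling =
#' "per_subsample"} the subsample mean is scaled jointly with
#' \code{context}, a raw-unit matrix of the other cluster means -- exactly
#' how the full-data pipeline scales all cluster averages together. With
#' \code{scaling = "fixed"} the full-data denominators of \code{context}
#' plus the complete cluster are reused for every subsample.
#'
#' @param cluster_cells raw gene-by-cell matrix of the focal cluster.
#' @param partner_profile named numeric scaled profile of the fixed partner.
#' @param db an \code{lr_database}.
#' @inheritParams global_score
#' @param fractions fractions of cells to draw, each in (0, 1].
#' @param n_rep random draws per fraction (default 20).
#' @param seed integer seed; recorded in the report.
#' @param context raw gene-by-cluster matrix of the other cluster means,
#'   same genes as \code{cluster_cells}; required for per-subsample scaling.
#' @param scaling "per_subsample" (default) or "fixed".
#' @param top_fraction passed to \code{\link{scale_expression}}.
#' @return Object of class \code{subsampling_report}: list with
#'   \code{fractions}, \code{scores} (n_rep x length(fractions) matrix),
#'   \code{sd} (named per-fraction SD), \code{n_rep}, \code{seed},
#'   \code{scaling}.
#' @export
subsample_robustness <- function(cluster_cells, partner_profile, db,
                                 direction = c("out", "in"),
                                 fractions = c(0.1, 0.25, 0.5, 0.75, 0.9, 1),
                                 n_rep = 20, seed = 1, context = NULL,
                                 scaling = c("per_subsample", "fixed"),
                                 top_fraction = 0.05, w = 1,
                                 missing = c("exclude", "zero")) {
  direction <- match.arg(direction)
  scaling <- match.arg(scaling)
  missing <- match.arg(missing)
  check_expression_matrix(cluster_cells)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.null(context))
    stop("context cluster means are required (see ?subsample_robustness)")
  stopifnot(identical(rownames(context), rownames(cluster_cells)))
  n_cells <- ncol(cluster_cells)
  fixed_denom <- NULL
  if (scaling == "fixed") {
    full <- cbind(focal = rowMeans(cluster_cells), context)
    fixed_denom <- attr(scale_expression(full, top_fraction), "denominators")
  }
  set.seed(seed)
  scores <- matrix(NA_real_, n_rep, length(fractions),
                   dimnames = list(NULL, paste0("f", fractions)))
  for (fi in seq_along(fractions)) {
    size <- as.integer(ceiling(fractions[fi] * n_cells))
    if (size < 1) stop("subsample size rounds to zero cells")
    for (rep_i in seq_len(n_rep)) {
      cells <- sample.int(n_cells, size, replace = FALSE)
      mu <- rowMeans(cluster_cells[, cells, drop = FALSE])
      if (scaling == "per_subsample") {
        joint <- cbind(focal = mu, context)
        scaled <- scale_expression(joint, top_fraction)
        profile <- scaled[, "focal"]
      } else {
        profile <- pmin(10, ifelse(fixed_denom > 0,
                                   10 * mu / fixed_denom, 0))
        names(profile) <- names(mu)
      }
      scores[rep_i, fi] <- global_score(profile, partner_profile, db,
                                        direction, w, missing)$S
    }
  }
  sds <- apply(scores, 2, stats::sd)
  names(sds) <- paste0("f", fractions)
  structure(list(fractions = fractions, scores = scores, sd = sds,
                 n_rep = n_rep, seed = seed, scaling = scaling),
            class = "subsampling_report")
}

#' @export
print.subsampling_report <- function(x, ...) {
  cat(sprintf("subsampling robustness (n_rep = %d, seed = %d, %s scaling):\n",
              x$n_rep, x$seed, x$scaling))
  print(round(rbind(fraction = x$fractions, sd = unname(x$sd)), 3))
  invisible(x)
}

#' Export a subsampling report as a delimited table
#' @param report a \code{subsampling_report}.
#' @param path output TSV path.
#' @export
export_subsampling_report <- function(report, path) {
  stopifnot(inherits(report, "subsampling_report"))
  df <- data.frame(fraction = rep(report$fractions,
                                  each = report$n_rep),
                   rep = rep(seq_len(report$n_rep),
                             times = length(report$fractions)),
                   score = as.vector(report$scores))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
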