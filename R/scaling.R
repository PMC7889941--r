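## Per-gene max-scaling of expression to [0, 10].
##
## Raw expression spans orders of magnitude across communication genes:
## highly bioactive cytokines (IL-12, IL-4) are transcribed at low levels
## while many chemokines are abundant without higher bioactivity. Scoring
## raw values would let a few abundant genes dominate, so each gene is
## scaled to its own ceiling before any score is computed.

#' Max-scale a gene-by-sample expression matrix to [0, 10]
#'
#' For each gene, the ceiling (value 10) is the mean of the
#' \code{top_fraction} highest expression values across the provided
#' samples; every value is divided by that ceiling and multiplied by 10, and
#' outliers above the ceiling are capped at 10. With n samples the ceiling
#' uses the k = max(1, ceiling(top_fraction * n)) largest values, so small
#' datasets (n < 1/top_fraction) still define one. All-zero genes stay zero.
#'
#' Scaling is computed per dataset: a central-cell dataset and a partner
#' reference dataset are scaled independently, since any cross-platform
#' technical effect acts as a constant weight on the global score and does
#' not change relative differences.
#'
#' @param m numeric gene-by-sample matrix, non-negative.
#' @param top_fraction fraction of highest values averaged into the ceiling,
#'   in (0, 1]; default 0.05.
#' @param samples optional character/integer subset of columns used to
#'   compute the ceilings (all columns are still returned scaled); for
#'   sensitivity analysis.
#' @return Matrix of the same shape with values in [0, 10]; class
#'   \code{"scaled_matrix"} marker attribute, and attribute
#'   \code{"denominators"} with the per-gene ceilings (exportable for
#'   audit via \code{\link{export_denominators}}).
#' @examples
#' m <- matrix(1:20, nrow = 1, dimnames = list("G1", paste0("s", 1:20)))
#' scale_expression(m)[1, c(10, 20)]  # 5 and 10
#' @export
scale_expression <- function(m, top_fraction = 0.05, samples = NULL) {
  check_expression_matrix(m)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1 ||
      top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  ref <- if (is.null(samples)) m else m[, samples, drop = FALSE]
  n <- ncol(ref)
  if (n < 1) stop("no sample available to compute scaling ceilings")
  k <- max(1L, as.integer(ceiling(top_fraction * n)))
  denom <- apply(ref, 1, function(x) mean(sort(x, decreasing = TRUE)[seq_len(k)]))
  scaled <- m
  nz <- denom > 0
  scaled[nz, ] <- pmin(10, 10 * m[nz, , drop = FALSE] / denom[nz])
  scaled[!nz, ] <- 0
  attr(scaled, "denominators") <- stats::setNames(denom, rownames(m))
  attr(scaled, "top_fraction") <- top_fraction
  class(scaled) <- c("scaled_matrix", class(scaled))
  scaled
}

#' Export per-gene scaling ceilings as a two-column table
#' @param scaled a matrix from \code{\link{scale_expression}}.
#' @param path output path (TSV).
#' @export
export_denominators <- function(scaled, path) {
  denom <- attr(scaled, "denominators")
  if (is.null(denom)) stop("not a scaled matrix: no denominators attribute")
  write.table(data.frame(gene = names(denom), ceiling = unname(denom)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_scaled <- function(m) inherits(m, "scaled_matrix") ||
  (is.numeric(m) && all(m >= 0) && all(m <= 10))
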