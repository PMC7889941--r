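## Communication scoring.
##
## For interaction i between a central cell in condition j and partner cell
## type k, the score is s_ijk = l_ij * r_ik, where l and r are max-scaled
## expression values in [0, 10]. Multimeric ligands or multi-chain receptors
## combine their subunits by geometric mean (l * sqrt(r1 * r2)), which also
## enforces the co-expression AND-rule: one silent subunit zeroes the side.
## The global score S_jk = w * sum_i s_ijk aggregates all scoreable
## interactions; w is a technical-effect weight that only changes the range,
## never relative differences.

#' Combine subunit expression values by geometric mean
#'
#' Single subunit: identity. Multiple subunits: geometric mean, which is 0
#' as soon as any required subunit is not expressed (co-expression rule).
#'
#' @param values numeric vector of scaled values in [0, 10]; length >= 1.
#' @return A single value in [0, 10].
#' @examples
#' combine_subunits(c(9, 4))  # sqrt(36) = 6
#' @export
combine_subunits <- function(values) {
  if (length(values) == 0) stop("no subunit value to combine")
  if (anyNA(values)) return(NA_real_)
  if (any(values < 0)) stop("subunit values must be non-negative")
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

side_value <- function(genes, profile) {
  # NA when any subunit gene is absent from the platform (score undefined)
  if (!all(genes %in% names(profile))) return(NA_real_)
  combine_subunits(unname(profile[genes]))
}

#' Score one ligand-receptor interaction between two profiles
#'
#' Outward direction: ligand subunits read from the central profile,
#' receptor subunits from the partner profile; inward swaps the roles.
#' When any required subunit gene is missing from its matrix the score is
#' undefined (NA) and the interaction is excluded from global sums, unless
#' \code{missing = "zero"} imputes absent genes as not expressed.
#'
#' @param db an \code{lr_database}.
#' @param i row index of the interaction in \code{db}.
#' @param central,partner named numeric vectors (one column of a scaled
#'   matrix).
#' @param direction "out" (default) or "in".
#' @param missing "exclude" (default) or "zero".
#' @return A list with \code{s}, \code{ligand_value}, \code{receptor_value}.
#' @export
interaction_score <- function(db, i, central, partner,
                              direction = c("out", "in"),
                              missing = c("exclude", "zero")) {
  direction <- match.arg(direction)
  missing <- match.arg(missing)
  lig <- ligand_subunits(db, i)
  rec <- receptor_subunits(db, i)
  lig_profile <- if (direction == "out") central else partner
  rec_profile <- if (direction == "out") partner else central
  if (missing == "zero") {
    lig_profile <- impute_zero(lig_profile, lig)
    rec_profile <- impute_zero(rec_profile, rec)
  }
  l <- side_value(lig, lig_profile)
  r <- side_value(rec, rec_profile)
  list(s = l * r, ligand_value = l, receptor_value = r)
}

# vectorized side values over all records at once: lookup both subunit
# columns by match(), geometric mean where a second subunit exists; a gene
# absent from the profile yields NA (excluded) unless zero-imputed
side_values_vec <- function(sub1, sub2, profile, zero_impute = FALSE) {
  v1 <- unname(profile[match(sub1, names(profile))])
  v2 <- unname(profile[match(sub2, names(profile))])
  has2 <- !is.na(sub2) & nzchar(sub2)
  if (zero_impute) {
    v1[is.na(v1)] <- 0
    v2[has2 & is.na(v2)] <- 0
  }
  out <- v1
  out[has2] <- sqrt(v1[has2] * v2[has2])
  out
}

impute_zero <- function(profile, genes) {
  absent <- setdiff(genes, names(profile))
  if (length(absent) > 0)
    profile <- c(profile, stats::setNames(rep(0, length(absent)), absent))
  profile
}

#' Global communication score between a central and a partner profile
#'
#' Sums per-interaction scores over the whole database (optionally weighted)
#' and keeps the per-interaction breakdown for family decomposition and
#' balloon plots. Interactions whose subunit genes are missing from a
#' platform are excluded and listed, not silently zeroed.
#'
#' @inheritParams interaction_score
#' @param w positive weight for cross-dataset technical effects (default 1).
#' @return An object of class \code{score_result}: list with \code{S},
#'   \code{w}, \code{direction}, \code{breakdown} (data.frame with
#'   interaction_id, family, subfamily, ligand_value, receptor_value,
#'   score), and \code{excluded} (character vector of interaction ids).
#' @export
global_score <- function(central, partner, db,
                         direction = c("out", "in"), w = 1,
                         missing = c("exclude", "zero")) {
  direction <- match.arg(direction)
  missing <- match.arg(missing)
  stopifnot(inherits(db, "lr_database"))
  if (!is.numeric(w) || length(w) != 1 || w <= 0)
    stop("w must be a single positive number")
  lig_profile <- if (direction == "out") central else partner
  rec_profile <- if (direction == "out") partner else central
  l <- side_values_vec(db$ligand_1, db$ligand_2, lig_profile,
                       zero_impute = missing == "zero")
  r <- side_values_vec(db$receptor_1, db$receptor_2, rec_profile,
                       zero_impute = missing == "zero")
  s <- l * r
  keep <- !is.na(s)
  if (!any(keep))
    stop("no scoreable interaction: every required gene is missing from the input")
  breakdown <- data.frame(
    interaction_id = db$interaction_id[keep],
    family = db$family[keep],
    subfamily = db$subfamily[keep],
    ligand_value = l[keep],
    receptor_value = r[keep],
    score = s[keep],
    stringsAsFactors = FALSE
  )
  structure(list(S = w * sum(s[keep]), w = w, direction = direction,
                 breakdown = breakdown,
                 excluded = db$interaction_id[!keep]),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("global communication score (%sward): S = %.4g over %d interactions (%d excluded, w = %g)\n",
              x$direction, x$S, nrow(x$breakdown), length(x$excluded), x$w))
  invisible(x)
}

#' Communication scores over a conditions-by-partners grid
#'
#' Computes \code{\link{global_score}} for every (central condition, partner
#' type) pair. Columns of \code{central} are conditions; columns of
#' \code{partners} are partner cell types (replicate-averaged profiles).
#'
#' @param central,partners scaled gene-by-column matrices.
#' @inheritParams global_score
#' @param keep_breakdown keep per-interaction breakdowns (default TRUE).
#' @return Object of class \code{score_matrix}: list with \code{raw}
#'   (conditions x partners numeric matrix), \code{normalized} and
#'   \code{rescaled} (NULL until computed), \code{direction}, \code{w},
#'   and \code{breakdowns} (condition -> partner -> score_result).
#' @export
score_matrix <- function(central, partners, db,
                         direction = c("out", "in"), w = 1,
                         missing = c("exclude", "zero"),
                         keep_breakdown = TRUE) {
  direction <- match.arg(direction)
  missing <- match.arg(missing)
  conds <- colnames(central); parts <- colnames(partners)
  raw <- matrix(NA_real_, length(conds), length(parts),
                dimnames = list(conds, parts))
  breakdowns <- if (keep_breakdown) list() else NULL
  for (j in conds) {
    for (k in parts) {
      res <- global_score(central[, j], partners[, k], db, direction, w,
                          missing)
      raw[j, k] <- res$S
      if (keep_breakdown) breakdowns[[j]][[k]] <- res
    }
  }
  structure(list(raw = raw, normalized = NULL, rescaled = NULL,
                 direction = direction, w = w, breakdowns = breakdowns),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("communication score matrix (%sward): %d condition(s) x %d partner(s)\n",
              x$direction, nrow(x$raw), ncol(x$raw)))
  print(round(x$raw, 2))
  if (!is.null(x$normalized)) {
    cat("normalized (reference condition = 1):\n"); print(round(x$normalized, 3))
  }
  if (!is.null(x$rescaled)) {
    cat("rescaled to [1, 10]:\n"); print(round(x$rescaled, 2))
  }
  invisible(x)
}

#' Decompose a global score into family or subfamily contributions
#'
#' Groups the per-interaction breakdown by molecular family (or by cytokine
#' subfamily) and sums. Groups partition the breakdown, so contributions sum
#' exactly to S / w.
#'
#' @param result a \code{score_result}.
#' @param by "family" or "subfamily".
#' @return Named numeric vector of per-group sums.
#' @export
family_contributions <- function(result, by = c("family", "subfamily")) {
  by <- match.arg(by)
  stopifnot(inherits(result, "score_result"))
  b <- result$breakdown
  g <- if (by == "family") b$family else {
    ifelse(is.na(b$subfamily), "unclassified", b$subfamily)
  }
  tapply_sum <- tapply(b$score, g, sum)
  out <- as.numeric(tapply_sum)
  names(out) <- names(tapply_sum)
  out
}

#' Normalize a score matrix to a reference condition
#'
#' For every partner k, Sbar_jk = S_jk / S_ref,k: the reference condition
#' row becomes 1 and other conditions are fold changes relative to it.
#'
#' @param sm a \code{score_matrix}.
#' @param reference condition name (row of \code{sm$raw}).
#' @return The \code{score_matrix} with \code{$normalized} filled in.
#' @export
normalize_scores <- function(sm, reference) {
  stopifnot(inherits(sm, "score_matrix"))
  if (!reference %in% rownames(sm$raw))
    stop("reference condition '", reference, "' not found")
  ref <- sm$raw[reference, ]
  zero <- names(ref)[ref == 0]
  if (length(zero) > 0)
    stop("zero reference score for partner(s): ",
         paste(zero, collapse = ", "), "; cannot normalize")
  sm$normalized <- sweep(sm$raw, 2, ref, "/")
  attr(sm$normalized, "reference") <- reference
  sm
}

#' Rescale scores linearly onto [1, 10] for network display
#'
#' Considers all the scores of the chosen view jointly and maps them with
#' x -> 1 + 9 (x - min) / (max - min), so the smallest score displays as 1
#' and the largest as 10; a constant matrix maps to all 10 (degenerate
#' case). The map is affine, hence rank-preserving.
#'
#' @param sm a \code{score_matrix}.
#' @param from which view to rescale: "raw" (default) or "normalized".
#' @return The \code{score_matrix} with \code{$rescaled} filled in.
#' @export
rescale_scores <- function(sm, from = c("raw", "normalized")) {
  stopifnot(inherits(sm, "score_matrix"))
  from <- match.arg(from)
  x <- if (from == "raw") sm$raw else {
    if (is.null(sm$normalized))
      stop("normalized view not computed; call normalize_scores() first")
    sm$normalized
  }
  rng <- range(x)
  sm$rescaled <- if (rng[1] == rng[2]) {
    array(10, dim = dim(x), dimnames = dimnames(x))
  } else {
    1 + 9 * (x - rng[1]) / (rng[2] - rng[1])
  }
  attr(sm$rescaled, "from") <- from
  sm
}

#' Export the views of a score matrix as delimited tables
#' @param sm a \code{score_matrix}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
export_score_matrix <- function(sm, dir, prefix = "scores") {
  stopifnot(inherits(sm, "score_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(mat, tag) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, tag))
    write.table(data.frame(condition = rownames(mat), mat,
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(sm$raw, "raw")
  if (!is.null(sm$normalized)) wr(sm$normalized, "normalized")
  if (!is.null(sm$rescaled)) wr(sm$rescaled, "rescaled")
  invisible(paths)
}
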