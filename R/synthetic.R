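## Seeded synthetic databases and expression datasets with analytically
## known scores, so every pipeline stage is testable offline.
##
## The generator's defaults mirror the conditions of the datasets the
## scoring model was designed for: bulk designs with ~6 and ~3 biological
## replicates per condition, two central-cell conditions with a planted
## fold change, multiplicative lognormal expression noise, and single-cell
## clusters of a few hundred cells. Expected scores in noiseless mode are
## computed by a deliberately plain closed-form routine (explicit loops
## over records) that is independent of the vectorized production path.

#' Configuration for the synthetic data generator
#'
#' @param n_genes genes in the expression universe (>= database needs).
#' @param n_interactions database records to plant.
#' @param frac_multi_ligand,frac_multi_receptor fraction of records with a
#'   second ligand / receptor subunit.
#' @param n_partner_types partner cell types.
#' @param n_replicates replicates per partner type and per condition
#'   (default 6, a typical bulk design).
#' @param n_conditions central-cell conditions (default 2).
#' @param n_cells_per_cluster cells per cluster in single-cell mode.
#' @param n_clusters clusters in single-cell mode.
#' @param expression_level mean planted expression of active ligand and
#'   receptor genes (arbitrary platform units).
#' @param noise_sigma lognormal sigma of multiplicative expression noise
#'   (0 = noiseless).
#' @param effect_size fold change of ligand expression between the two
#'   central conditions (default 2).
#' @param seed integer seed recorded in every generated object.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 200, n_interactions = 40,
                             frac_multi_ligand = 0.15,
                             frac_multi_receptor = 0.35,
                             n_partner_types = 4, n_replicates = 6,
                             n_conditions = 2, n_cells_per_cluster = 100,
                             n_clusters = 4, expression_level = 100,
                             noise_sigma = 0.3, effect_size = 2,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_interactions >= 1, n_partner_types >= 1,
            n_replicates >= 1, n_conditions >= 1, n_cells_per_cluster >= 1,
            n_clusters >= 1, noise_sigma >= 0, effect_size > 0,
            frac_multi_ligand >= 0, frac_multi_ligand <= 1,
            frac_multi_receptor >= 0, frac_multi_receptor <= 1)
  structure(cfg, class = "synthetic_config")
}

#' Generate a seeded toy ligand-receptor database
#'
#' Records are spread round-robin over the six named families (cytokines
#' additionally over the seven subfamilies); requested fractions of records
#' get a second ligand or receptor subunit. Gene symbols are synthetic
#' (SLG*/SRC* prefixes) and unique, so the gene universe never collides
#' with real symbols.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return A validated \code{lr_database}; deterministic per seed.
#' @export
generate_toy_database <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_interactions
  fam_pool <- setdiff(lr_families(), "other")
  fams <- rep_len(fam_pool, n)
  subfam_pool <- setdiff(cytokine_subfamilies(), "unclassified")
  lig2 <- stats::runif(n) < cfg$frac_multi_ligand
  rec2 <- stats::runif(n) < cfg$frac_multi_receptor
  id3 <- function(i) sprintf("%03d", i)
  sub <- ifelse(fams == "Cytokine",
                rep_len(subfam_pool, n), NA_character_)
  db <- lr_database(
    ligand_1 = paste0("SLG", id3(seq_len(n)), "A"),
    ligand_2 = ifelse(lig2, paste0("SLG", id3(seq_len(n)), "B"),
                      NA_character_),
    receptor_1 = paste0("SRC", id3(seq_len(n)), "A"),
    receptor_2 = ifelse(rec2, paste0("SRC", id3(seq_len(n)), "B"),
                        NA_character_),
    family = fams, subfamily = sub,
    pmid = as.character(10000000 + seq_len(n))
  )
  attr(db, "seed") <- cfg$seed
  db
}

# planted mean expression for every gene of the universe, per "column role":
# ligand genes active in the central cell, receptor genes in partners,
# plus background genes. Levels are drawn once per gene (uniform in
# [0.2, 1] x expression_level) so scores differ across interactions.
plant_levels <- function(cfg, db) {
  genes <- gene_universe(db)
  extra <- max(0, cfg$n_genes - length(genes))
  all_genes <- c(genes, if (extra > 0) sprintf("SBG%03d", seq_len(extra)))
  lvl <- cfg$expression_level * stats::runif(length(all_genes), 0.2, 1)
  stats::setNames(lvl, all_genes)
}

noisy <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  mu * stats::rlnorm(length(mu), meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Generate a bulk dataset with analytically known scores
#'
#' Central matrix: \code{n_conditions x n_replicates} columns; condition 2
#' multiplies every ligand gene by \code{effect_size}. Partner matrix:
#' \code{n_partner_types x n_replicates} columns; each partner type
#' expresses a type-specific random subset (about half) of receptor genes.
#' In noiseless mode (\code{noise_sigma = 0}) replicates are identical and
#' the element \code{expected} carries the closed-form expected raw score
#' matrix computed by \code{\link{closed_form_scores}}.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param db an \code{lr_database} (defaults to a generated toy database).
#' @return List with \code{central}, \code{partner} (raw matrices),
#'   \code{conditions}, \code{partner_types} (annotation vectors),
#'   \code{central_means}, \code{partner_means} (noiseless per-column-group
#'   means), \code{expected} (closed-form score matrix in noiseless mode,
#'   else NULL), \code{db}, \code{cfg}.
#' @export
generate_bulk_dataset <- function(cfg, db = generate_toy_database(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  force(db)
  set.seed(cfg$seed + 1L)
  base <- plant_levels(cfg, db)
  genes <- names(base)
  lig_genes <- unique(c(db$ligand_1, db$ligand_2))
  lig_genes <- lig_genes[!is.na(lig_genes)]
  rec_genes <- unique(c(db$receptor_1, db$receptor_2))
  rec_genes <- rec_genes[!is.na(rec_genes)]

  conds <- paste0("cond", seq_len(cfg$n_conditions))
  effect <- cfg$effect_size ^ (seq_len(cfg$n_conditions) - 1)
  central_means <- vapply(seq_along(conds), function(ci) {
    mu <- base
    mu[lig_genes] <- mu[lig_genes] * effect[ci]
    mu[rec_genes] <- mu[rec_genes] * 0.5  # central expresses receptors weakly
    mu
  }, numeric(length(base)))
  dimnames(central_means) <- list(genes, conds)

  types <- paste0("partner", seq_len(cfg$n_partner_types))
  partner_means <- vapply(seq_along(types), function(ti) {
    mu <- base
    # type-specific receptor program: random on/off subset with a
    # type-specific expression multiplier, so scaled values spread (0, 10]
    on <- stats::runif(length(rec_genes)) < 0.5
    mu[rec_genes] <- mu[rec_genes] * stats::runif(length(rec_genes), 0.3, 1)
    mu[rec_genes[!on]] <- 0
    mu[lig_genes] <- mu[lig_genes] * 0.25  # partners express few ligands
    mu
  }, numeric(length(base)))
  dimnames(partner_means) <- list(genes, types)

  rep_cols <- function(means, labels) {
    cols <- lapply(colnames(means), function(cc)
      vapply(seq_len(cfg$n_replicates), function(r)
        noisy(means[, cc], cfg$noise_sigma), numeric(nrow(means))))
    m <- do.call(cbind, cols)
    colnames(m) <- as.vector(t(outer(colnames(means),
                                     seq_len(cfg$n_replicates),
                                     paste, sep = "_rep")))
    rownames(m) <- rownames(means)
    m
  }
  central <- rep_cols(central_means, conds)
  partner <- rep_cols(partner_means, types)
  conditions <- stats::setNames(rep(conds, each = cfg$n_replicates),
                                colnames(central))
  partner_types <- stats::setNames(rep(types, each = cfg$n_replicates),
                                   colnames(partner))
  expected <- if (cfg$noise_sigma == 0)
    closed_form_scores(central_means, partner_means, db,
                       top_fraction = 0.05) else NULL
  list(central = central, partner = partner,
       conditions = conditions, partner_types = partner_types,
       central_means = central_means, partner_means = partner_means,
       expected = expected, db = db, cfg = cfg)
}

#' Closed-form expected raw scores for planted mean profiles
#'
#' Independent oracle for the scoring pipeline: computes the per-gene
#' scaling ceilings, scaled values, geometric-mean subunit combination and
#' score sums with plain explicit loops over records and samples, sharing
#' no code with the vectorized production path.
#'
#' @param central_means,partner_means raw gene-by-column matrices of
#'   planted means.
#' @param db an \code{lr_database}.
#' @param top_fraction scaling parameter (see
#'   \code{\link{scale_expression}}).
#' @param direction "out" or "in".
#' @return Numeric conditions-by-partners matrix of expected raw scores.
#' @export
closed_form_scores <- function(central_means, partner_means, db,
                               top_fraction = 0.05,
                               direction = c("out", "in")) {
  direction <- match.arg(direction)
  scale_one <- function(m) {
    out <- m
    for (g in seq_len(nrow(m))) {
      x <- m[g, ]
      k <- max(1, ceiling(top_fraction * length(x)))
      denom <- mean(sort(x, decreasing = TRUE)[1:k])
      out[g, ] <- if (denom > 0) pmin(10, 10 * x / denom) else 0
    }
    out
  }
  cs <- scale_one(central_means)
  ps <- scale_one(partner_means)
  geo <- function(v) if (any(v == 0)) 0 else exp(mean(log(v)))
  res <- matrix(0, ncol(cs), ncol(ps),
                dimnames = list(colnames(cs), colnames(ps)))
  for (j in seq_len(ncol(cs))) {
    for (k in seq_len(ncol(ps))) {
      total <- 0
      for (i in seq_len(nrow(db))) {
        lig <- ligand_subunits(db, i)
        rec <- receptor_subunits(db, i)
        lp <- if (direction == "out") cs[, j] else ps[, k]
        rp <- if (direction == "out") ps[, k] else cs[, j]
        if (!all(lig %in% names(lp)) || !all(rec %in% names(rp)))
          next  # excluded, matching the pipeline's default
        total <- total + geo(lp[lig]) * geo(rp[rec])
      }
      res[j, k] <- total
    }
  }
  res
}

#' Generate a single-cell dataset with known cluster means
#'
#' Cells are drawn around planted per-cluster mean profiles with lognormal
#' multiplicative noise. Every cluster expresses every gene at a
#' cluster-specific level (uniform multiplier on a shared base) with a
#' random ~30\% of genes silenced per cluster, so no cluster is the top
#' expresser of all genes -- as in real multi-cluster data, where joint
#' max-scaling of cluster averages leaves most scaled values strictly
#' below the ceiling. \code{\link{cluster_average}} recovers the means as
#' sample averages.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param db an \code{lr_database}.
#' @return List with \code{counts} (dense gene-by-cell matrix),
#'   \code{assignment} (cell -> cluster), \code{cluster_means} (planted
#'   means), \code{db}, \code{cfg}.
#' @export
generate_sc_dataset <- function(cfg, db = generate_toy_database(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  force(db)
  set.seed(cfg$seed + 2L)
  base <- plant_levels(cfg, db)
  genes <- names(base)
  lig_genes <- unique(c(db$ligand_1, db$ligand_2)); lig_genes <- lig_genes[!is.na(lig_genes)]
  rec_genes <- unique(c(db$receptor_1, db$receptor_2)); rec_genes <- rec_genes[!is.na(rec_genes)]
  clusters <- paste0("cluster", seq_len(cfg$n_clusters))
  means <- vapply(seq_along(clusters), function(ci) {
    mu <- base * stats::runif(length(base), 0.2, 1)
    mu[stats::runif(length(base)) < 0.3] <- 0
    mu
  }, numeric(length(base)))
  dimnames(means) <- list(genes, clusters)
  cells <- list(); labels <- character(0)
  for (ci in seq_along(clusters)) {
    cc <- vapply(seq_len(cfg$n_cells_per_cluster), function(r)
      noisy(means[, ci], cfg$noise_sigma), numeric(length(base)))
    cells[[ci]] <- cc
    labels <- c(labels, rep(clusters[ci], cfg$n_cells_per_cluster))
  }
  counts <- do.call(cbind, cells)
  colnames(counts) <- sprintf("cell%04d", seq_len(ncol(counts)))
  rownames(counts) <- genes
  assignment <- stats::setNames(labels, colnames(counts))
  list(counts = counts, assignment = assignment, cluster_means = means,
       db = db, cfg = cfg)
}

#' Write a synthetic bulk dataset to the formats the readers consume
#' @param ds result of \code{\link{generate_bulk_dataset}}.
#' @param dir output directory.
#' @return Named list of written paths.
#' @export
write_bulk_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    db = file.path(dir, "database.tsv"),
    central = file.path(dir, "central.tsv"),
    partner = file.path(dir, "partner.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    partner_types = file.path(dir, "partner_types.tsv"))
  write_lr_database(ds$db, paths$db)
  write_expression_table(ds$central, paths$central)
  write_expression_table(ds$partner, paths$partner)
  write.table(data.frame(sample_id = names(ds$conditions),
                         label = unname(ds$conditions)),
              paths$conditions, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(ds$partner_types),
                         label = unname(ds$partner_types)),
              paths$partner_types, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
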