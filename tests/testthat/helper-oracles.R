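# Shared fixtures and independent oracles. The oracles are deliberately
# plain (explicit loops, enumeration) and share no code with the package's
# vectorized paths.

# 3-record hand fixture: a 2+2-subunit cytokine, a checkpoint, a chemokine
toy_db <- function() {
  lr_database(
    ligand_1   = c("IL12A", "CD86", "CCL22"),
    ligand_2   = c("IL12B", NA, NA),
    receptor_1 = c("IL12RB1", "CD28", "CCR4"),
    receptor_2 = c("IL12RB2", NA, NA),
    family     = c("Cytokine", "Checkpoint", "Chemokine"),
    subfamily  = c("type 1", NA, NA),
    pmid       = c("8605867", "8617933", "9169459")
  )
}

toy_db_file <- function(path = tempfile(fileext = ".tsv")) {
  write_lr_database(toy_db(), path)
  path
}

# named profile helper
prof <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

# explicit per-interaction loop oracle for the global score
oracle_global_score <- function(central, partner, db, direction = "out",
                                w = 1) {
  total <- 0
  for (i in seq_len(nrow(db))) {
    lig <- c(db$ligand_1[i], db$ligand_2[i])
    lig <- lig[!is.na(lig) & nzchar(lig)]
    rec <- c(db$receptor_1[i], db$receptor_2[i])
    rec <- rec[!is.na(rec) & nzchar(rec)]
    lp <- if (direction == "out") central else partner
    rp <- if (direction == "out") partner else central
    if (!all(lig %in% names(lp)) || !all(rec %in% names(rp))) next
    geo <- function(v) prod(v)^(1 / length(v))
    total <- total + geo(lp[lig]) * geo(rp[rec])
  }
  unname(w * total)
}

# random scaled profiles over a toy database's gene universe
random_instance <- function(seed) {
  set.seed(seed)
  cfg <- synthetic_config(n_interactions = sample(2:6, 1),
                          frac_multi_ligand = 0.3,
                          frac_multi_receptor = 0.5, seed = seed)
  db <- generate_toy_database(cfg)
  genes <- gene_universe(db)
  central <- stats::setNames(round(runif(length(genes), 0, 10), 3), genes)
  partner <- stats::setNames(round(runif(length(genes), 0, 10), 3), genes)
  # sprinkle exact zeros and the occasional missing gene
  central[runif(length(genes)) < 0.2] <- 0
  partner[runif(length(genes)) < 0.2] <- 0
  if (runif(1) < 0.3) central <- central[-sample(seq_along(central), 1)]
  list(db = db, central = central, partner = partner)
}

# brute-force exact two-sided Wilcoxon rank-sum p-value (no ties)
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  ws <- apply(sets, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# row-subset of a database, class preserved
new_db_subset <- function(db, idx) {
  out <- db[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# tiny scaled matrices used across scoring tests
toy_scaled_pair <- function() {
  genes <- gene_universe(toy_db())
  central <- matrix(0, length(genes), 2,
                    dimnames = list(genes, c("condA", "condB")))
  central[c("IL12A", "IL12B", "CD86", "CCL22"), "condA"] <- c(4, 9, 4, 5)
  central[c("IL12A", "IL12B", "CD86", "CCL22"), "condB"] <- c(2, 3, 8, 1)
  partner <- matrix(0, length(genes), 3,
                    dimnames = list(genes, c("pX", "pY", "pZ")))
  partner[c("IL12RB1", "IL12RB2", "CD28", "CCR4"), "pX"] <- c(9, 4, 3, 4)
  partner[c("IL12RB1", "IL12RB2", "CD28", "CCR4"), "pY"] <- c(1, 0, 6, 2)
  partner[c("IL12RB1", "IL12RB2", "CD28", "CCR4"), "pZ"] <- c(5, 5, 0, 10)
  list(central = central, partner = partner)
}
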