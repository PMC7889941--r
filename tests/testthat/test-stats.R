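single_interaction_db <- function() {
  lr_database(ligand_1 = "LGX", receptor_1 = "RCX", family = "Cytokine",
              subfamily = "type 1")
}

test_that("partner comparison scores one replicate at a time", {
  db <- single_interaction_db()
  central <- matrix(5, 2, 3, dimnames = list(c("LGX", "RCX"),
                                             paste0("c", 1:3)))
  central["RCX", ] <- 0
  partners <- matrix(0, 2, 6,
                     dimnames = list(c("LGX", "RCX"), paste0("p", 1:6)))
  partners["RCX", ] <- c(1, 2, 3, 4, 4, 4)
  types <- setNames(rep(c("A", "B"), each = 3), colnames(partners))
  d <- partner_comparison_scores(central, partners, types, db)
  expect_equal(d$A, c(p1 = 5, p2 = 10, p3 = 15))   # l = 5 times r
  expect_equal(unname(d$B), rep(20, 3))            # identical replicates
  expect_equal(attr(d, "mode"), "partner_comparison")
  # linearity: mean of the distribution equals the score on the
  # replicate-averaged partner (single-subunit receptors only)
  pm <- rowMeans(partners[, 1:3]); names(pm) <- rownames(partners)
  expect_equal(mean(d$A), global_score(rowMeans(central), pm, db)$S)
})

test_that("condition comparison mirrors partner comparison with roles swapped", {
  db <- single_interaction_db()
  central <- matrix(0, 2, 6,
                    dimnames = list(c("LGX", "RCX"), paste0("s", 1:6)))
  central["LGX", ] <- c(1, 2, 3, 7, 7, 7)
  conds <- setNames(rep(c("c1", "c2"), each = 3), colnames(central))
  partner_mean <- c(LGX = 0, RCX = 4)
  d <- condition_comparison_scores(central, conds, partner_mean, db)
  expect_equal(unname(d$c1), c(4, 8, 12))
  expect_equal(unname(d$c2), rep(28, 3))
  # duality with partner_comparison on transposed roles (inward direction:
  # ligand side comes from "partners" = the old central replicates)
  dd <- partner_comparison_scores(
    central = matrix(partner_mean, 2, 1,
                     dimnames = list(names(partner_mean), "m")),
    partners = central, partner_types = conds, db = db, direction = "in")
  expect_equal(unname(dd$c1), unname(d$c1))
  expect_equal(unname(dd$c2), unname(d$c2))
})

test_that("pairwise Wilcoxon + BH behaves on canonical cases", {
  # identical score vectors -> raw p = 1
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  cmp <- compare_distributions(g)
  expect_equal(cmp$table$p, 1)
  # complete separation at n = m = 6: exact two-sided p = 2/924
  sep <- list(lo = 1:6 + 0.5, hi = 101:106 + 0.5)
  cmp2 <- compare_distributions(sep)
  expect_equal(cmp2$table$p, 2 / 924, tolerance = 1e-12)
  expect_true(cmp2$table$significant)
  # constant equal groups -> p = 1 with a warning
  expect_warning(cmp3 <- compare_distributions(list(x = c(2, 2), y = c(2, 2))),
                 "convention")
  expect_equal(cmp3$table$p, 1)
  # group of 1 refused
  expect_error(compare_distributions(list(a = 1, b = c(1, 2))),
               "fewer than 2")
})

test_that("Wilcoxon p equals brute-force enumeration for n + m <= 10", {
  set.seed(42)
  for (rep_i in 1:60) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- round(runif(n, 0, 100), 4)
    y <- round(runif(m, 0, 100) + sample(c(0, 30), 1), 4)
    cmp <- compare_distributions(list(a = x, b = y))
    expect_equal(cmp$table$p, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the textbook step-up", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(9)
  for (rep_i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # adjusted p are monotone non-decreasing in raw-p order, through the API
  g <- list(a = c(1, 2, 3, 9), b = c(4, 5, 6, 7), c = c(10, 12, 14, 16))
  cmp <- compare_distributions(g)
  o <- order(cmp$table$p)
  expect_true(all(diff(cmp$table$p_adj[o]) >= -1e-12))
  expect_true(all(cmp$table$p_adj >= cmp$table$p - 1e-12))
})

test_that("subsampling is deterministic per seed with SD 0 at fraction 1", {
  cfg <- synthetic_config(n_genes = 30, n_interactions = 6,
                          n_cells_per_cluster = 40, n_clusters = 3,
                          noise_sigma = 0.4, seed = 5)
  sc <- generate_sc_dataset(cfg)
  cl <- names(attr(cluster_average(sc$counts, sc$assignment), "n_cells"))
  cells <- sc$counts[, sc$assignment == "cluster1", drop = FALSE]
  means <- cluster_average(sc$counts, sc$assignment)
  context <- means[, -1, drop = FALSE]
  partner_scaled <- scale_expression(means)[, "cluster2"]
  r1 <- subsample_robustness(cells, partner_scaled, sc$db,
                             fractions = c(0.2, 1), n_rep = 8, seed = 7,
                             context = context)
  r2 <- subsample_robustness(cells, partner_scaled, sc$db,
                             fractions = c(0.2, 1), n_rep = 8, seed = 7,
                             context = context)
  expect_identical(r1$scores, r2$scores)           # bit-reproducible
  expect_equal(unname(r1$sd["f1"]), 0)             # full cluster every rep
  expect_gt(unname(r1$sd["f0.2"]), 0)
  # fixed-denominator mode runs and is deterministic too
  r3 <- subsample_robustness(cells, partner_scaled, sc$db,
                             fractions = c(0.5), n_rep = 4, seed = 3,
                             context = context, scaling = "fixed")
  expect_length(r3$sd, 1)
  expect_error(subsample_robustness(cells, partner_scaled, sc$db,
                                    fractions = c(0, 0.5), n_rep = 2,
                                    seed = 1, context = context),
               "fractions")
})

test_that("type-I error is controlled at the display threshold (null sims)", {
  # identical generating distributions: effect_size = 1 between conditions
  set.seed(123)
  n_sim <- 120  # light version; the 500-sim run lives in test-acceptance.R
  rej <- logical(n_sim)
  cfg0 <- synthetic_config(n_genes = 20, n_interactions = 5,
                           n_partner_types = 1, n_replicates = 4,
                           noise_sigma = 0.3, effect_size = 1, seed = 1)
  for (s in seq_len(n_sim)) {
    cfg <- cfg0; cfg$seed <- s
    ds <- generate_bulk_dataset(cfg)
    cs <- scale_expression(ds$central)
    pm <- rowMeans(scale_expression(ds$partner))
    names(pm) <- rownames(ds$partner)
    d <- condition_comparison_scores(cs, ds$conditions, pm, ds$db)
    cmp <- suppressWarnings(compare_distributions(d, alpha_display = 0.1))
    rej[s] <- cmp$table$significant[1]
  }
  se <- sqrt(0.1 * 0.9 / n_sim)
  expect_lte(mean(rej), 0.1 + 3 * se)
})
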