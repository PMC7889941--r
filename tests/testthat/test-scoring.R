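test_that("subunit combination is a geometric mean with an AND-rule", {
  expect_equal(combine_subunits(6), 6)
  expect_equal(combine_subunits(c(9, 4)), 6)
  expect_equal(combine_subunits(c(5, 0)), 0)
  expect_equal(combine_subunits(c(2, 2, 2)), 2)
  expect_error(combine_subunits(numeric(0)), "no subunit")
})

test_that("interaction scores follow l * r with direction and exclusion", {
  db <- toy_db()
  central <- prof(CD86 = 4, IL12A = 4, IL12B = 9, CCL22 = 5,
                  IL12RB1 = 0, IL12RB2 = 0, CD28 = 0, CCR4 = 0)
  partner <- prof(CD28 = 3, IL12RB1 = 9, IL12RB2 = 4, CCR4 = 4,
                  IL12A = 0, IL12B = 0, CD86 = 0, CCL22 = 0)
  expect_equal(interaction_score(db, 2, central, partner, "out")$s, 12)
  # two geometric means then product: sqrt(4*9) * sqrt(9*4) = 36
  expect_equal(interaction_score(db, 1, central, partner, "out")$s, 36)
  # zero ligand subunit kills the interaction
  central0 <- central; central0["IL12B"] <- 0
  expect_equal(interaction_score(db, 1, central0, partner, "out")$s, 0)
  # inward swaps roles: ligand read from partner
  expect_equal(interaction_score(db, 2, partner, central, "in")$s, 12)
  # missing gene -> undefined unless zero-imputed
  expect_true(is.na(interaction_score(db, 2, central[-1], partner)$s))
  expect_equal(interaction_score(db, 2, central[-1], partner,
                                 missing = "zero")$s, 0)
})

test_that("global score sums scoreable interactions and applies w", {
  db <- toy_db()
  central <- prof(CD86 = 4, CCL22 = 5, IL12A = 4, IL12B = 0,
                  IL12RB1 = 0, IL12RB2 = 0, CD28 = 0, CCR4 = 0)
  partner <- prof(CD28 = 3, CCR4 = 4, IL12RB1 = 2, IL12RB2 = 2,
                  IL12A = 0, IL12B = 0, CD86 = 0, CCL22 = 0)
  res <- global_score(central, partner, db)
  expect_equal(res$S, 12 + 20 + 0)
  expect_equal(sum(res$breakdown$score), res$S)

  res2 <- global_score(central, partner, db, w = 2)
  expect_equal(res2$S, 2 * res$S)
  expect_equal(res2$breakdown$score / sum(res2$breakdown$score),
               res$breakdown$score / sum(res$breakdown$score))

  # no scoreable interaction at all -> error
  few <- prof(X = 1)
  expect_error(global_score(few, few, db), "no scoreable")
})

test_that("score_matrix equals independent global_score calls", {
  db <- toy_db()
  tp <- toy_scaled_pair()
  sm <- score_matrix(tp$central, tp$partner, db)
  expect_equal(dim(sm$raw), c(2, 3))
  for (j in colnames(tp$central)) for (k in colnames(tp$partner))
    expect_equal(sm$raw[j, k],
                 global_score(tp$central[, j], tp$partner[, k], db)$S)
  # permutation equivariance over partners
  perm <- c("pZ", "pX", "pY")
  sm2 <- score_matrix(tp$central, tp$partner[, perm], db)
  expect_equal(sm2$raw, sm$raw[, perm])
})

test_that("family contributions partition the score and match filtering", {
  db <- toy_db()
  tp <- toy_scaled_pair()
  res <- global_score(tp$central[, "condA"], tp$partner[, "pX"], db, w = 1)
  contrib <- family_contributions(res)
  expect_equal(sum(contrib), res$S / res$w)
  # equivalence oracle: contribution of family F == score on filtered db
  for (f in names(contrib))
    expect_equal(unname(contrib[f]),
                 global_score(tp$central[, "condA"], tp$partner[, "pX"],
                              filter_lr_database(db, families = f))$S)
  sub <- family_contributions(res, by = "subfamily")
  expect_equal(sum(sub), res$S)
  expect_true("type 1" %in% names(sub))
})

test_that("normalization divides by the reference condition row", {
  raw <- matrix(c(10, 30, 20, 10), 2, 2,
                dimnames = list(c("c0", "c1"), c("p1", "p2")))
  sm <- structure(list(raw = raw, normalized = NULL, rescaled = NULL,
                       direction = "out", w = 1, breakdowns = NULL),
                  class = "score_matrix")
  nm <- normalize_scores(sm, "c0")
  expect_equal(unname(nm$normalized["c0", ]), c(1, 1))
  expect_equal(unname(nm$normalized["c1", ]), c(3, 0.5))
  # scale invariance: multiplying all raw scores leaves Sbar unchanged
  sm2 <- sm; sm2$raw <- raw * 7.3
  expect_equal(normalize_scores(sm2, "c0")$normalized, nm$normalized)
  # zero reference score names the partner
  sm3 <- sm; sm3$raw["c0", "p2"] <- 0
  expect_error(normalize_scores(sm3, "c0"), "p2")
  expect_error(normalize_scores(sm, "nope"), "not found")
})

test_that("rescaling maps scores onto [1, 10] preserving rank", {
  mk <- function(x) structure(list(raw = x, normalized = NULL,
                                   rescaled = NULL, direction = "out",
                                   w = 1, breakdowns = NULL),
                              class = "score_matrix")
  two <- mk(matrix(c(3, 7), 1, 2,
                   dimnames = list("c", c("p1", "p2"))))
  expect_equal(unname(rescale_scores(two)$rescaled[1, ]), c(1, 10))
  three <- mk(matrix(c(0, 5, 10), 1, 3,
                     dimnames = list("c", paste0("p", 1:3))))
  expect_equal(unname(rescale_scores(three)$rescaled[1, ]), c(1, 5.5, 10))
  const <- mk(matrix(4, 1, 2, dimnames = list("c", c("p1", "p2"))))
  expect_equal(unname(rescale_scores(const)$rescaled[1, ]), c(10, 10))
  # rank preservation on random matrices
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rlnorm(12, 5, 1), 3, 4,
                dimnames = list(paste0("c", 1:3), paste0("p", 1:4)))
    r <- rescale_scores(mk(x))$rescaled
    expect_true(all(r >= 1 & r <= 10))
    expect_equal(order(r), order(x))
  }
})

test_that("scoring is additive over disjoint databases and monotone", {
  set.seed(21)
  cfg <- synthetic_config(n_interactions = 10, seed = 21)
  db <- generate_toy_database(cfg)
  genes <- gene_universe(db)
  central <- setNames(runif(length(genes), 0, 10), genes)
  partner <- setNames(runif(length(genes), 0, 10), genes)
  half <- nrow(db) %/% 2
  d1 <- new_db_subset(db, seq_len(half))
  d2 <- new_db_subset(db, (half + 1):nrow(db))
  expect_equal(global_score(central, partner, d1)$S +
                 global_score(central, partner, d2)$S,
               global_score(central, partner, db)$S)
  # zero propagation: silencing one required subunit zeroes exactly that
  # interaction's contribution (toy db genes are record-unique)
  res <- global_score(central, partner, db)
  i <- sample(nrow(db), 1)
  central2 <- central; central2[db$ligand_1[i]] <- 0
  res2 <- global_score(central2, partner, db)
  id <- db$interaction_id[i]
  expect_equal(res2$breakdown$score[res2$breakdown$interaction_id == id], 0)
  keep <- res$breakdown$interaction_id != id
  expect_equal(res2$breakdown$score[keep], res$breakdown$score[keep])
  # monotonicity: raising a ligand value never decreases the outward score
  central3 <- central; central3[db$ligand_1[i]] <- min(10, central[db$ligand_1[i]] + 1)
  expect_gte(global_score(central3, partner, db)$S, res$S)
})

test_that("direction duality: outward A->B equals inward with roles swapped", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 100)
    ok <- all(gene_universe(inst$db) %in% names(inst$central))
    s_out <- tryCatch(global_score(inst$central, inst$partner, inst$db,
                                   "out")$S, error = function(e) NA)
    s_in <- tryCatch(global_score(inst$partner, inst$central, inst$db,
                                  "in")$S, error = function(e) NA)
    expect_equal(s_out, s_in)
  }
})

test_that("vectorized scoring equals the explicit loop oracle", {
  for (seed in 1:200) {
    inst <- random_instance(seed)
    expected <- oracle_global_score(inst$central, inst$partner, inst$db)
    got <- tryCatch(global_score(inst$central, inst$partner, inst$db)$S,
                    error = function(e) 0)
    expect_equal(got, expected, tolerance = 1e-12)
  }
})
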