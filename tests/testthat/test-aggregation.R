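# The five aggregation tests, BH adjustment and scenario sweeps.

test_that("binomial family test gives exact tail probabilities and contracts", {
  fc <- data.frame(family_id = c("A", "Z", "N"),
                   n_phenotyped = c(7L, 5L, 6L),
                   k_affected = c(5L, 0L, 2L))
  res <- binomial_family_test(fc, 46 / 468)
  expect_equal(signif(res$p[1], 5), 1.6242e-4)  # two healthy parents, 5/5 sibs
  expect_equal(res$p[2], 1)                     # no cases: certain event
  expect_equal(res$n_sims, rep(0L, 3))

  expect_equal(
    signif(binomial_family_test(
      data.frame(family_id = "A", n_phenotyped = 7L, k_affected = 5L),
      44 / 468)$p, 5),
    1.3106e-4)

  expect_error(binomial_family_test(
    data.frame(family_id = "X", n_phenotyped = 3L, k_affected = 4L), 0.1),
    "k_affected")
  expect_error(binomial_family_test(fc, 0), "prevalence")
})

test_that("binomial tail is monotone in case count and prevalence", {
  for (n in c(5L, 9L)) {
    p_by_k <- vapply(1:n, function(k) {
      binomial_family_test(
        data.frame(family_id = "F", n_phenotyped = n, k_affected = k), 0.1)$p
    }, 0)
    expect_true(all(diff(p_by_k) < 0))
  }
  p_by_pi <- vapply(c(0.02, 0.05, 0.1, 0.3), function(pi) {
    binomial_family_test(
      data.frame(family_id = "F", n_phenotyped = 7L, k_affected = 3L), pi)$p
  }, 0)
  expect_true(all(diff(p_by_pi) > 0))
})

test_that("kinship sum statistics follow the kinship structure", {
  # an affected individual with 4 affected full sibs scores 4 * 0.25 = 1
  rows <- rbind(nuclear_family_rows("F1", 5, k = 5),
                nuclear_family_rows("F2", 6, k = 0))
  coh <- cohort(rows)
  phi <- kinship_matrix(coh)
  mask <- phenotype_mask(coh, "combined")
  res <- kinship_sum_test(phi, mask, B = 100, seed = 1)
  expect_equal(res$statistic, rep(1, 5))

  # mutually unrelated affected: all statistics 0 and all p = 1
  rows <- do.call(rbind, lapply(1:4, function(i) {
    nuclear_family_rows(paste0("G", i), 2, k = if (i <= 2) 1L else 0L)
  }))
  coh <- cohort(rows)
  res <- kinship_sum_test(kinship_matrix(coh), phenotype_mask(coh, "combined"),
                          B = 50, seed = 1)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p, c(1, 1))

  expect_error(kinship_sum_test(phi, mask, B = 0), "B must be")
})

test_that("kinship sum Monte-Carlo p matches the exhaustive pooled null", {
  # 6 phenotyped: one couple with 2 children plus 2 unrelated founders;
  # the affected pair are the sibs
  rows <- rbind(nuclear_family_rows("F1", 2, k = 2),
                ind_row("L1", "F2"), ind_row("L2", "F3"))
  coh <- cohort(rows)
  phi <- kinship_matrix(coh)
  mask <- phenotype_mask(coh, "combined")
  phen <- names(mask)[mask != "unphenotyped"]

  q <- oracle_kinship_sum_tail(phi, phen, 2L, 0.25)
  expect_equal(q, 10 / 30)  # 5 of the 15 pairs are phi = 0.25 pairs

  B <- 3e4
  res <- kinship_sum_test(phi, mask, B = B, seed = 99)
  for (p_hat in res$p) expect_lt(abs(p_hat - q), mc_ci(q, B))
})

test_that("genealogical index statistic and Monte-Carlo p behave as enumerated", {
  # five affected full sibs: all pairs 0.25, GIF = 25,000
  rows <- rbind(nuclear_family_rows("F1", 5, k = 5),
                nuclear_family_rows("F2", 5))
  coh <- cohort(rows)
  res <- genealogical_index_test(kinship_matrix(coh),
                                 phenotype_mask(coh, "combined"),
                                 B = 200, seed = 3)
  expect_equal(res$statistic, 25000)

  # unrelated affected: GIF 0, p 1
  rows <- do.call(rbind, lapply(1:3, function(i) {
    nuclear_family_rows(paste0("G", i), 1, k = if (i <= 2) 1L else 0L)
  }))
  coh <- cohort(rows)
  res <- genealogical_index_test(kinship_matrix(coh),
                                 phenotype_mask(coh, "combined"),
                                 B = 100, seed = 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # 8-member toy cohort, 2 affected: exhaustive null over C(8,2) pairs
  rows <- rbind(nuclear_family_rows("F1", 4, k = 2),
                ind_row("L1", "F2"), ind_row("L2", "F3"))
  coh <- cohort(rows)
  phi <- kinship_matrix(coh)
  mask <- phenotype_mask(coh, "combined")
  phen <- names(mask)[mask != "unphenotyped"]
  expect_identical(length(phen), 8L)
  q <- oracle_gif_tail(phi, phen, 2L, 25000)
  B <- 2e4
  res <- genealogical_index_test(phi, mask, B = B, seed = 21)
  expect_lt(abs(res$p - q), mc_ci(q, B))
})

test_that("family genealogical index restricts the null to the family", {
  # 4 sibs + 2 parents, 2 affected sibs: oracle over C(6,2) = 15 subsets
  coh <- cohort(nuclear_family_rows("F1", 4, k = 2))
  phi <- kinship_matrix(coh)
  mask <- phenotype_mask(coh, "combined")
  fam <- setNames(coh$individuals$family_id, coh$individuals$id)
  q <- oracle_gif_tail(phi, names(mask), 2L, 25000)
  expect_equal(q, 14 / 15)  # only the parent couple scores below 25,000
  B <- 1e4
  res <- family_genealogical_index_test(phi, mask, fam, "F1", B = B, seed = 5)
  expect_false(res$degenerate)
  expect_lt(abs(res$p - q), mc_ci(q, B))

  # all phenotyped members affected: point-mass null, degenerate
  rows <- nuclear_family_rows("F1", 3, k = 3)
  rows$alive[rows$id %in% c("F1_P0", "F1_P1")] <- FALSE
  rows$phenotype[rows$id %in% c("F1_P0", "F1_P1")] <- "unknown"
  coh <- cohort(rows)
  res <- family_genealogical_index_test(
    kinship_matrix(coh), phenotype_mask(coh, "combined"),
    setNames(coh$individuals$family_id, coh$individuals$id), "F1",
    B = 500, seed = 5)
  expect_true(res$degenerate)
  expect_true(is.na(res$p))

  # affected = the two (unrelated) parents: statistic 0, p = 1
  rows <- nuclear_family_rows("F1", 2)
  rows$phenotype[rows$id %in% c("F1_P0", "F1_P1")] <- "myxedematous_severe"
  coh <- cohort(rows)
  res <- family_genealogical_index_test(
    kinship_matrix(coh), phenotype_mask(coh, "combined"),
    setNames(coh$individuals$family_id, coh$individuals$id), "F1",
    B = 500, seed = 5)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("familial clustering p matches full enumeration and is monotone", {
  # two families of 2 phenotyped each, 2 cases in one family
  fc <- data.frame(family_id = c("X", "Y"), n_phenotyped = c(2L, 2L),
                   k_affected = c(2L, 0L))
  q <- oracle_clustering_p(c(2L, 2L), c(2L, 0L))
  B <- 2e4
  res <- familial_clustering_test(fc, B = B, seed = 31)
  expect_lt(abs(res$p - q), mc_ci(q, B))

  # a larger enumerable configuration
  q2 <- oracle_clustering_p(c(4L, 3L, 3L), c(3L, 0L, 1L))
  fc2 <- data.frame(family_id = c("X", "Y", "Z"), n_phenotyped = c(4L, 3L, 3L),
                    k_affected = c(3L, 0L, 1L))
  res2 <- familial_clustering_test(fc2, B = B, seed = 32)
  expect_lt(abs(res2$p - q2), mc_ci(q2, B))

  # concentrating the same number of cases cannot raise the p-value
  spread <- data.frame(family_id = letters[1:4], n_phenotyped = rep(4L, 4),
                       k_affected = c(1L, 1L, 1L, 0L))
  conc <- transform(spread, k_affected = c(3L, 0L, 0L, 0L))
  p_spread <- familial_clustering_test(spread, B = B, seed = 33)$p
  p_conc <- familial_clustering_test(conc, B = B, seed = 33)$p
  expect_lte(p_conc, p_spread)

  # a single family holding everyone: only one configuration exists
  one <- data.frame(family_id = "X", n_phenotyped = 6L, k_affected = 2L)
  expect_equal(familial_clustering_test(one, B = 100, seed = 3)$p, 1)

  expect_error(familial_clustering_test(
    data.frame(family_id = "X", n_phenotyped = 2L, k_affected = 3L)),
    "more affected")
})

test_that("bh_adjust matches a literal step-up reference and never shrinks p", {
  # the published two-tied-smallest-of-62 configuration
  p <- c(rep(1.6242e-4, 2), rep(0.5, 60))
  adj <- bh_adjust(p)
  expect_equal(signif(adj[1], 3), 5.04e-3)
  expect_equal(adj[1], adj[2])

  expect_equal(bh_adjust(0.037), 0.037)          # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))  # ties adjust to themselves

  set.seed(202)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_reference(p))
    expect_true(all(adj >= p))
  }

  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("prevalence scenario counts are monotone and track the binomial test", {
  specs <- cbind(c(5, 5, 4, 3, 2), c(4, 0, 1, 0, 2))
  coh <- build_unit_cohort(specs)
  sc <- prevalence_scenarios(coh, "combined", c(0.02, 0.05, 0.1, 0.3))
  expect_true(all(diff(sc$n_significant) <= 0))

  # near-certain affection: nothing is surprising
  sc_hi <- prevalence_scenarios(coh, "combined", 0.999)
  expect_identical(sc_hi$n_significant, 0L)

  expect_error(prevalence_scenarios(coh, "combined", numeric(0)), "empty")
})

test_that("identical seeds and inputs give identical Monte-Carlo results", {
  rows <- rbind(nuclear_family_rows("F1", 4, k = 3), nuclear_family_rows("F2", 5))
  coh <- cohort(rows)
  phi <- kinship_matrix(coh)
  mask <- phenotype_mask(coh, "combined")
  fc <- family_counts(coh, "combined")
  fam <- setNames(coh$individuals$family_id, coh$individuals$id)

  expect_identical(kinship_sum_test(phi, mask, B = 500, seed = 7),
                   kinship_sum_test(phi, mask, B = 500, seed = 7))
  expect_identical(genealogical_index_test(phi, mask, B = 500, seed = 7),
                   genealogical_index_test(phi, mask, B = 500, seed = 7))
  expect_identical(familial_clustering_test(fc, B = 500, seed = 7),
                   familial_clustering_test(fc, B = 500, seed = 7))
  expect_identical(
    family_genealogical_index_test(phi, mask, fam, "F1", B = 500, seed = 7),
    family_genealogical_index_test(phi, mask, fam, "F1", B = 500, seed = 7))
})
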