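test_that("dissonance score is the mean absolute pairwise difference", {
  # the two NIN paralog pairs from the curated pathway table
  expect_equal(dissonance_score(c(5.48, 6.47), c(8.30, 7.56)), 1.955)
  expect_equal(dissonance_score(1.7, 1.7), 0)
  expect_equal(dissonance_score(0, 3), 3)
  expect_error(dissonance_score(numeric(0), 1), "empty")
})

test_that("dissonance is symmetric, translation-invariant, and scales linearly", {
  set.seed(8)
  for (i in 1:5) {
    A <- rnorm(sample(1:4, 1), sd = 3)
    B <- rnorm(sample(1:4, 1), sd = 3)
    d <- dissonance_score(A, B)
    expect_equal(dissonance_score(B, A), d)
    expect_equal(dissonance_score(A + 1.3, B + 1.3), d)
    expect_equal(dissonance_score(2.5 * A, 2.5 * B), 2.5 * d)
    expect_gte(d, 0)
  }
})

test_that("overall dissonance is additive and matches a direct-sum oracle", {
  A <- list(g1 = 0, g2 = 0)
  B <- list(g1 = 1, g2 = 2.5)
  expect_equal(overall_dissonance(A, B), 3.5)
  expect_equal(overall_dissonance(A["g1"], B["g1"]), 1)

  set.seed(13)
  a <- rnorm(50)
  b <- rnorm(50)
  An <- as.list(a)
  Bn <- as.list(b)
  names(An) <- names(Bn) <- sprintf("g%02d", 1:50)
  expect_equal(overall_dissonance(An, Bn), sum(abs(a - b)))

  expect_error(overall_dissonance(An, Bn[-1]), "missing a species")
})

test_that("permutation test handles degenerate and concordant cases", {
  # constant fold changes: every permutation equals the observed score
  A <- as.list(rep(2, 20))
  B <- as.list(rep(2, 20))
  names(A) <- names(B) <- paste0("g", 1:20)
  res <- permutation_test(A, B, n_perm = 50, seed = 1)
  expect_equal(res$p_value, 1)

  # perfect concordance: no shuffle can beat B identical to A
  set.seed(2)
  x <- rnorm(500, sd = 2)
  A <- as.list(x)
  B <- as.list(x)
  names(A) <- names(B) <- paste0("g", seq_along(x))
  res <- permutation_test(A, B, n_perm = 300, seed = 7)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 0)
  expect_equal(res$p_plus_one, 1 / 301)
})

test_that("permutation results are reproducible and respect mode/unit options", {
  set.seed(3)
  A <- as.list(rnorm(40))
  B <- as.list(rnorm(40))
  names(A) <- names(B) <- paste0("g", 1:40)
  r1 <- permutation_test(A, B, n_perm = 100, seed = 5)
  r2 <- permutation_test(A, B, n_perm = 100, seed = 5)
  expect_identical(r1$perm_scores, r2$perm_scores)
  r3 <- permutation_test(A, B, n_perm = 100, seed = 6)
  expect_false(identical(r1$perm_scores, r3$perm_scores))

  one <- permutation_test(A, B, n_perm = 100, seed = 5, mode = "one")
  grp <- permutation_test(A, B, n_perm = 100, seed = 5, unit = "groups")
  expect_true(all(is.finite(one$perm_scores)))
  expect_true(all(is.finite(grp$perm_scores)))
  # group-label permutation preserves multisets of values exactly
  expect_equal(grp$observed, r1$observed)
})

test_that("permutation null is near-normal for many groups", {
  set.seed(9)
  rec <- sim_expression(1500, species = c("Ct", "Dg"), rho = 0.3, sd = 2,
                        seed = 31)
  groups <- attr(rec, "groups")
  A <- fc_vectors(groups, rec, "Ct")
  B <- fc_vectors(groups, rec, "Dg")
  res <- permutation_test(A, B, n_perm = 400, seed = 11)
  s <- res$perm_scores
  g1 <- mean((s - mean(s))^3) / sd(s)^3
  expect_lt(abs(g1), 0.2)
})

test_that("representative pairs pick the closest fold changes deterministically", {
  A <- list(g = c(1.0, 4.0))
  B <- list(g = 3.8)
  expect_equal(representative_fc_pairs(A, B)$fc_a, 4.0)
  expect_equal(representative_fc_pairs(A, B)$fc_b, 3.8)

  # singleton x singleton: that pair
  p <- representative_fc_pairs(list(g = 2), list(g = -1))
  expect_equal(c(p$fc_a, p$fc_b), c(2, -1))

  # tie |1-2| = |3-2|: lexicographically smallest pair wins
  p <- representative_fc_pairs(list(g = c(1, 3)), list(g = 2))
  expect_equal(c(p$fc_a, p$fc_b), c(1, 2))
})

test_that("pearson correlation matches exact and simulated expectations", {
  x <- seq(-3, 3, length.out = 20)
  r <- pearson_correlation(data.frame(fc_a = x, fc_b = 2 * x))
  expect_equal(r$r, 1)
  r <- pearson_correlation(data.frame(fc_a = x, fc_b = -x))
  expect_equal(r$r, -1)

  flat <- pearson_correlation(data.frame(fc_a = x, fc_b = rep(1, 20)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))
  expect_error(pearson_correlation(data.frame(fc_a = 1:2, fc_b = 2:1)),
               "at least 3")

  for (seed in c(101, 202, 303)) {
    rec <- sim_expression(1000, species = c("Ct", "Dg"), rho = 0.5, sd = 1,
                          seed = seed)
    groups <- attr(rec, "groups")
    pairs <- representative_fc_pairs(fc_vectors(groups, rec, "Ct"),
                                     fc_vectors(groups, rec, "Dg"))
    r <- pearson_correlation(pairs)
    expect_gt(r$r, 0.45)
    expect_lt(r$r, 0.55)
  }
})
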