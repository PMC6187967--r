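random_freq <- function() {
  p <- rexp(61)
  p / sum(p)
}

test_that("rate matrix has zero row sums, detailed balance, unit mean rate", {
  set.seed(21)
  for (i in 1:5) {
    pi <- random_freq()
    kappa <- runif(1, 0.5, 8)
    omega <- runif(1, 0.05, 3)
    Q <- codon_rate_matrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-14)       # pi_i q_ij = pi_j q_ji
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  }
})

test_that("neutral symmetric model gives equal single-change rates", {
  pi <- rep(1 / 61, 61)
  Q <- codon_rate_matrix(1, 1, pi, scale = FALSE)
  off <- Q[upper.tri(Q)]
  rates <- unique(round(off[off > 0], 12))
  expect_length(rates, 1L)
  expect_error(codon_rate_matrix(2, 0.5, rep(0.5, 61)), "sum to 1")
})

test_that("transition matrices are stochastic over a range of times", {
  set.seed(22)
  pi <- random_freq()
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- codon_transition_matrix(2.2, 0.35, pi, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_gte(min(P), 0)
  }
  # long-time limit approaches the stationary frequencies
  P <- codon_transition_matrix(2.2, 0.35, pi, 200)
  expect_lt(max(abs(sweep(P, 2, pi))), 1e-8)
})

test_that("F3x4 frequencies match the positional closed form", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- sim_codon_alignment(tr, 400, kappa = 2, seed = 5)
  pi <- f3x4_frequencies(aln)
  tab <- nodevol:::codon_table()
  st <- aln$states[!is.na(aln$states)]
  f <- sapply(1:3, function(p) tabulate(tab$pos[st, p], 4) / length(st))
  expected <- f[tab$pos[, 1], 1] * f[tab$pos[, 2], 2] * f[tab$pos[, 3], 3]
  expected <- expected / sum(expected)
  expect_equal(pi, expected, tolerance = 1e-12)
  expect_equal(sum(pi), 1)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.4,D:0.1);")
  set.seed(31)
  for (i in 1:3) {
    pi <- random_freq()
    kappa <- runif(1, 1, 5)
    om <- c(background = runif(1, 0.1, 1.5))
    aln <- sim_codon_alignment(tr, 3, omega_by_class = om, kappa = kappa,
                               pi = pi, seed = 100 + i)
    got <- prune_loglik(aln, tr, kappa, om, pi = pi)
    want <- enum_site_loglik(aln, tr, kappa, om, pi)
    expect_equal(got$site_lnL, want, tolerance = 1e-8)
    expect_equal(got$lnL, sum(want), tolerance = 1e-8)
  }
})

test_that("pruning handles branch classes and missing data like the oracle", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.4,D:0.1);")
  classes <- c("background", "a", "background", "background", "background")
  classes <- classes[seq_len(nrow(tr$edge))]
  pi <- rep(1 / 61, 61)
  om <- c(background = 0.2, a = 1.5)
  aln <- sim_codon_alignment(tr, 4, omega_by_class = om, kappa = 2,
                             pi = pi, edge_classes = classes, seed = 41)
  # blank out one codon entirely and one per-taxon codon
  seqs <- aln$sequences
  substr(seqs["A"], 4, 6) <- "NNN"
  substr(seqs["C"], 7, 9) <- "---"
  aln2 <- codon_alignment(seqs)
  got <- prune_loglik(aln2, tr, 2, om, pi = pi, edge_classes = classes)
  want <- enum_site_loglik(aln2, tr, 2, om, pi, edge_classes = classes)
  expect_equal(got$site_lnL, want, tolerance = 1e-8)
})

test_that("zero-length star tree reduces to the root frequencies", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  pi <- random_freq()
  tab <- nodevol:::codon_table()
  aln <- codon_alignment(setNames(rep(tab$codons[17], 3), c("A", "B", "C")))
  r <- prune_loglik(aln, tr, 2, c(background = 0.5), pi = pi)
  expect_equal(r$lnL, log(pi[17]), tolerance = 1e-10)
})

test_that("site log-likelihoods are additive over sites", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.4,D:0.1);")
  aln <- sim_codon_alignment(tr, 30, kappa = 2, seed = 6)
  doubled <- codon_alignment(setNames(paste0(aln$sequences, aln$sequences),
                                      names(aln$sequences)))
  pi <- f3x4_frequencies(aln)
  r1 <- prune_loglik(aln, tr, 2, c(background = 0.2), pi = pi)
  r2 <- prune_loglik(doubled, tr, 2, c(background = 0.2), pi = pi)
  expect_equal(r2$lnL, 2 * r1$lnL, tolerance = 1e-8)
})

test_that("likelihood is invariant under re-rooting (time reversibility)", {
  set.seed(71)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length * 0.3
  aln <- sim_codon_alignment(tr, 50, kappa = 2.5, seed = 72)
  pi <- f3x4_frequencies(aln)
  r1 <- prune_loglik(aln, tr, 2.5, c(background = 0.4), pi = pi)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "t3", resolve.root = TRUE)
  r2 <- prune_loglik(aln, rerooted, 2.5, c(background = 0.4), pi = pi)
  expect_equal(r1$lnL, r2$lnL, tolerance = 1e-6)
})

test_that("ML fit recovers parameters and behaves as a fixed point", {
  set.seed(81)
  tr <- ape::rtree(8)
  tr$edge.length <- tr$edge.length * 0.25
  aln <- sim_codon_alignment(tr, 400, omega_by_class = c(background = 0.2),
                             kappa = 2, seed = 82)
  fit <- fit_codon_model(aln, tr)
  expect_true(fit$converged)
  expect_gt(fit$omega[["background"]], 0.12)
  expect_lt(fit$omega[["background"]], 0.3)
  expect_gt(fit$kappa, 1.4)
  expect_lt(fit$kappa, 2.8)
  expect_equal(fit$lnL, sum(fit$site_lnL), tolerance = 1e-8)

  # refitting from the optimum does not move the likelihood
  refit <- fit_codon_model(aln, tr, starts = list(
    list(kappa = fit$kappa, omega = unname(fit$omega[1]))))
  expect_lt(abs(refit$lnL - fit$lnL), 1e-6)
})

test_that("freeing branch classes never lowers the maximized likelihood", {
  tr <- nfc_species_tree()
  lab <- label_branches(tr, nfc_clades())
  om <- c(background = 0.2, a = 0.8, b = 0.2, c = 0.2, d = 0.2)
  aln <- sim_codon_alignment(tr, 150, omega_by_class = om, kappa = 2,
                             edge_classes = lab, seed = 83)
  f0 <- fit_codon_model(aln, tr, edge_classes = lab)
  warm <- list(list(kappa = f0$kappa, omega = unname(f0$omega[1])))
  f1 <- fit_codon_model(aln, tr, edge_classes = lab, free_classes = "a",
                        starts = warm)
  f3 <- fit_codon_model(aln, tr, edge_classes = lab,
                        free_classes = c("a", "b", "c", "d"), starts = warm)
  expect_gte(f1$lnL, f0$lnL - 1e-6)
  expect_gte(f3$lnL, f1$lnL - 1e-6)
})

test_that("branch lengths can be re-estimated jointly", {
  tr <- ape::read.tree(text = "((A:0.15,B:0.2):0.1,(C:0.3,D:0.1):0.05);")
  aln <- sim_codon_alignment(tr, 200, kappa = 2, seed = 91)
  perturbed <- tr
  perturbed$edge.length <- rep(0.5, nrow(tr$edge))
  fixed <- fit_codon_model(aln, perturbed)
  free <- fit_codon_model(aln, perturbed, fit_branch_lengths = TRUE)
  expect_gt(free$lnL, fixed$lnL)
  # recovered lengths should be closer to the generating ones than the start
  po <- ape::reorder.phylo(tr, "postorder", index.only = TRUE)
  truth <- tr$edge.length[po]
  expect_lt(mean(abs(free$branch_lengths - truth)),
            mean(abs(0.5 - truth)))
})
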