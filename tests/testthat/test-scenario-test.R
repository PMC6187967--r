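test_that("branch labeling finds one branch per class on the species tree", {
  tr <- nfc_species_tree()
  lab <- label_branches(tr, nfc_clades())
  expect_equal(sum(lab == "a"), 1L)
  expect_equal(sum(lab == "b"), 1L)
  expect_equal(sum(lab == "c"), 1L)
  expect_equal(sum(lab == "d"), 1L)
  expect_true(all(attr(lab, "available")))
  # class b/c sit on the terminal branches of the two actinorhizal hosts
  tips <- tr$tip.label[tr$edge[lab == "b", 2]]
  expect_equal(tips, "Ceanothus_thyrsiflorus")
})

test_that("missing or non-monophyletic clades make classes unavailable", {
  cl <- nfc_clades()
  # unrooted 3-taxon star: no stem branches exist
  toy <- ape::read.tree(text = "(Ceanothus_thyrsiflorus:1,Datisca_glomerata:1,Vitis_vinifera:1);")
  lab <- label_branches(toy, cl)
  av <- attr(lab, "available")
  expect_true(av[["b"]] && av[["c"]])
  expect_false(av[["a"]] || av[["d"]])

  # NFC broken up: its stem branch does not exist
  broken <- ape::read.tree(text = paste0(
    "((Ceanothus_thyrsiflorus:1,Vitis_vinifera:1):1,",
    "(Datisca_glomerata:1,(Medicago_truncatula:1,Lotus_japonicus:1):0.5):1);"))
  lab2 <- label_branches(broken, list(
    nfc = c("Ceanothus_thyrsiflorus", "Datisca_glomerata",
            "Medicago_truncatula", "Lotus_japonicus"),
    legumes = c("Medicago_truncatula", "Lotus_japonicus"),
    ct = "Ceanothus_thyrsiflorus", dg = "Datisca_glomerata"))
  av2 <- attr(lab2, "available")
  expect_false(av2[["a"]])
  expect_true(av2[["d"]])

  expect_error(label_branches(ape::read.tree(text = "(A:1,B:1);"), cl),
               "C. thyrsiflorus")
})

test_that("KH test is calibrated on identical fits and detects dominance", {
  f1 <- list(site_lnL = rnorm(500, -5))
  expect_equal(kh_test(f1, f1, n_rell = 200, seed = 1)$p_value, 1)

  f2 <- list(site_lnL = f1$site_lnL - 0.1)  # uniformly worse at every site
  kh <- kh_test(f1, f2, n_rell = 1000, seed = 2)
  expect_lt(kh$p_value, 0.05)
  expect_equal(kh$delta, 0.1 * 500, tolerance = 1e-9)
  # symmetric in its arguments
  expect_equal(kh_test(f2, f1, n_rell = 1000, seed = 2)$p_value, kh$p_value)
  expect_error(kh_test(f1, list(site_lnL = rnorm(10))), "length")
})

test_that("SH test rejects dominated candidates and never the best", {
  base <- rnorm(300, -6)
  same <- list(s1 = list(site_lnL = base), s2 = list(site_lnL = base),
               s3 = list(site_lnL = base))
  res <- sh_test(same, n_rell = 300, seed = 3)
  expect_length(res$rejected, 0L)

  fits <- list(good = list(site_lnL = base),
               bad = list(site_lnL = base - 50 / 300),
               ok = list(site_lnL = base + rnorm(300, 0, 0.01)))
  res <- sh_test(fits, n_rell = 1000, seed = 4)
  expect_true("bad" %in% res$rejected)
  expect_false(res$best %in% res$rejected)

  # input order does not change the outcome for a fixed seed
  res2 <- sh_test(fits[c(3, 1, 2)], n_rell = 1000, seed = 4)
  expect_equal(res2$p_values[names(res$p_values)], res$p_values)
  expect_setequal(res2$rejected, res$rejected)

  single <- sh_test(fits["good"], n_rell = 100, seed = 5)
  expect_length(single$rejected, 0L)
})

test_that("scenario bookkeeping marks unavailable scenarios and tabulates", {
  # tree without a legume clade: MULTI and TWOSTEP cannot be tested
  cl <- nfc_clades()
  tr <- ape::read.tree(text = paste0(
    "(Vitis_vinifera:0.3,((Ceanothus_thyrsiflorus:0.25,",
    "Prunus_persica:0.2):0.1,(Datisca_glomerata:0.25,",
    "Cucumis_sativus:0.15):0.1):0.15);"))
  lab <- label_branches(tr, cl)
  aln <- sim_codon_alignment(tr, 150, omega_by_class = c(background = 0.3),
                             kappa = 2, seed = 55)
  res <- run_group(aln, tr, cl, test_config(), group_id = "toy")
  expect_setequal(names(res$fits), c("NULL", "SINGLE"))
  expect_true("MULTI" %in% names(res$skipped))
  expect_true("TWOSTEP" %in% names(res$skipped))
  expect_equal(res$branch_bcd_category, "n.a.")

  # hand-built results drive the tabulation
  fake <- function(a, bcd, null_rej = TRUE) {
    structure(list(branch_a_category = a, branch_bcd_category = bcd,
                   null_rejected = null_rej), class = "scenario_result")
  }
  results <- c(replicate(3, fake("reject_SINGLE", "reject_neither"),
                         simplify = FALSE),
               replicate(2, fake("reject_neither", "reject_TWOSTEP"),
                         simplify = FALSE),
               list(fake("n.a.", "reject_MULTI"),
                    fake("n.a.", "n.a.", null_rej = FALSE)))
  tab <- tabulate_scenarios(results)
  expect_equal(tab$branch_a$count, c(0L, 2L, 3L))
  expect_equal(tab$branch_bcd$count, c(2L, 3L, 1L))
  expect_equal(sum(tab$branch_a$percentage), 100, tolerance = 0.2)
  expect_equal(tab$n_null_rejected, 6L)

  empty <- tabulate_scenarios(list())
  expect_true(all(empty$branch_a$count == 0))
})

test_that("tree choice keeps the constrained tree unless clearly beaten", {
  tr <- nfc_species_tree()
  cl <- nfc_clades()
  aln <- sim_codon_alignment(tr, 120, omega_by_class = c(background = 0.3),
                             kappa = 2, seed = 66)
  res <- run_group(aln, list(constrained = tr, unconstrained = tr), cl,
                   test_config(), group_id = "same-tree")
  expect_equal(res$tree_choice$chosen, "constrained")
  expect_equal(res$tree_choice$kh_p, 1)
})
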