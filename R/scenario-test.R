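# Four-scenario branch-model hypothesis test: branch-class labeling on the
# species/gene tree, tree choice by the Kishino-Hasegawa test, scenario
# rejection by the Shimodaira-Hasegawa procedure, and result tabulation.

#' Evolutionary scenarios and their free branch classes
#'
#' `NULL` assumes one dN/dS for the whole tree; `SINGLE` frees the stem
#' branch of the nitrogen-fixing clade (class `a`); `MULTI` frees the
#' branches leading to each host lineage (classes `b`, `c`, `d`, one dN/dS
#' each); `TWOSTEP` frees all four.
#'
#' @return named list mapping scenario name to its free branch classes.
#' @export
scenario_classes <- function() {
  list("NULL" = character(0),
       SINGLE = "a",
       MULTI = c("b", "c", "d"),
       TWOSTEP = c("a", "b", "c", "d"))
}

# descendant tip-label sets per edge (edge order = tree$edge rows)
edge_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edge <- tree$edge[po, , drop = FALSE]
  below <- vector("list", max(edge))
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    ch <- edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  sets <- lapply(tree$edge[, 2], function(n) sort(below[[n]]))
  sets
}

#' Label tree branches with the scenario classes
#'
#' Assigns class `a` to the stem branch of the nitrogen-fixing clade (NFC),
#' `b` and `c` to the terminal branches of *C. thyrsiflorus* and
#' *D. glomerata*, `d` to the stem branch of the legumes, and
#' `"background"` everywhere else. A clade that is absent or
#' non-monophyletic on the tree leaves its class unavailable (recorded in
#' the `available` attribute); a missing `ct`/`dg` tip is an error.
#'
#' @param tree an `ape::phylo` tree.
#' @param clades list with elements `nfc` (taxa of the NFC), `legumes`
#'   (taxa of the legume clade), `ct` and `dg` (tip labels); see
#'   [nfc_clades()].
#' @return character vector of class labels aligned with `tree$edge` rows,
#'   with attribute `available` (named logical over `a`..`d`).
#' @export
label_branches <- function(tree, clades) {
  stopifnot(all(c("nfc", "legumes", "ct", "dg") %in% names(clades)))
  tips <- tree$tip.label
  if (!clades$ct %in% tips) stop("tip for C. thyrsiflorus (", clades$ct, ") absent")
  if (!clades$dg %in% tips) stop("tip for D. glomerata (", clades$dg, ") absent")
  sets <- edge_tipsets(tree)
  labels <- rep("background", nrow(tree$edge))
  available <- c(a = FALSE, b = TRUE, c = TRUE, d = FALSE)

  stem_of <- function(members) {
    members <- sort(intersect(members, tips))
    if (length(members) == 0 || length(members) == length(tips)) return(NA_integer_)
    hit <- which(vapply(sets, function(s) identical(s, members), logical(1)))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }

  ea <- stem_of(clades$nfc)
  if (!is.na(ea)) {
    labels[ea] <- "a"
    available["a"] <- TRUE
  }
  ed <- stem_of(clades$legumes)
  if (!is.na(ed)) {
    if (labels[ed] != "background") {
      available["d"] <- FALSE
    } else {
      labels[ed] <- "d"
      available["d"] <- TRUE
    }
  }
  eb <- which(tree$edge[, 2] == match(clades$ct, tips))
  ec <- which(tree$edge[, 2] == match(clades$dg, tips))
  labels[eb] <- "b"
  labels[ec] <- "c"
  attr(labels, "available") <- available
  labels
}

# ---------------------------------------------------------------------------

rell_weights <- function(n_sites, n_rell) {
  stats::rmultinom(n_rell, n_sites, rep(1 / n_sites, n_sites))
}

#' Kishino-Hasegawa test of two fits
#'
#' RELL bootstrap of the total log-likelihood difference between two fits of
#' the same sites: sites are resampled with replacement, the replicate
#' differences are centered at zero, and the two-sided p-value is the
#' fraction of centered replicates at least as extreme as the observed
#' difference.
#'
#' @param fit1,fit2 `codon_fit` objects (or lists with `site_lnL`) over the
#'   same sites.
#' @param n_rell number of RELL replicates.
#' @param seed integer seed.
#' @return list with `p_value`, `delta` (lnL of `fit1` minus `fit2`),
#'   `n_rell`, `seed`.
#' @export
kh_test <- function(fit1, fit2, n_rell = 1000L, seed = 1L) {
  s1 <- fit1$site_lnL
  s2 <- fit2$site_lnL
  if (length(s1) != length(s2)) stop("site log-likelihood vectors differ in length")
  d <- s1 - s2
  delta <- sum(d)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  W <- rell_weights(length(d), n_rell)
  reps <- as.vector(crossprod(d, W))
  centered <- reps - delta
  list(p_value = mean(abs(centered) >= abs(delta)), delta = delta,
       n_rell = as.integer(n_rell), seed = as.integer(seed))
}

#' Shimodaira-Hasegawa test over a candidate set
#'
#' Joint SH procedure over all fitted candidates: RELL replicates of each
#' candidate's total log-likelihood are centered per candidate, the
#' replicate max-statistic `max_j R_j - R_i` is compared to the observed
#' deficit from the best candidate, and candidates with `p < alpha` are
#' rejected. The best candidate is never rejected.
#'
#' @param fits named list of `codon_fit` objects over the same sites
#'   (at least one; a single candidate yields an empty rejection set).
#' @param n_rell number of RELL replicates.
#' @param alpha rejection level.
#' @param seed integer seed.
#' @return list with `p_values` (named), `rejected` (character vector),
#'   `best` (name of the best candidate).
#' @export
sh_test <- function(fits, n_rell = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  fits <- fits[sort(names(fits))]  # order-invariant given the seed
  S <- vapply(fits, `[[`, numeric(length(fits[[1]]$site_lnL)), "site_lnL")
  if (length(fits) == 1L) {
    return(list(p_values = stats::setNames(1, names(fits)),
                rejected = character(0), best = names(fits)))
  }
  totals <- colSums(S)
  best <- names(which.max(totals))
  delta <- max(totals) - totals
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  W <- rell_weights(nrow(S), n_rell)
  R <- crossprod(S, W)              # candidates x replicates
  R <- R - rowMeans(R)
  mx <- apply(R, 2, max)
  p <- vapply(seq_along(fits), function(i) mean(mx - R[i, ] >= delta[i]),
              numeric(1))
  names(p) <- names(fits)
  list(p_values = p, rejected = names(p)[p < alpha], best = best)
}

# ---------------------------------------------------------------------------

#' Full scenario analysis of one ortholog group
#'
#' Chooses between the constrained and unconstrained candidate tree with a
#' Kishino-Hasegawa test (the constrained tree is kept unless the
#' unconstrained one is significantly better), labels the branches, fits
#' every scenario whose branch classes are available, runs the joint
#' Shimodaira-Hasegawa test (NULL always among the candidates), and derives
#' the per-branch-class categories.
#'
#' Scenario fits share the branch lengths carried by the chosen tree and are
#' warm-started from the NULL fit (TWOSTEP additionally from the SINGLE and
#' MULTI optima), which enforces the nesting inequality
#' `lnL(TWOSTEP) >= lnL(SINGLE), lnL(MULTI) >= lnL(NULL)` numerically.
#'
#' @param aln a [codon_alignment()].
#' @param trees either a single `phylo` tree or a list with elements
#'   `constrained` and `unconstrained`.
#' @param clades clade definitions (see [label_branches()]).
#' @param config an [rns_config()].
#' @param group_id identifier recorded in the result.
#' @param fit_branch_lengths re-estimate branch lengths in the NULL fit and
#'   share them across scenarios (default: use the lengths on the tree).
#' @return object of class `scenario_result` with elements `group_id`,
#'   `tree_choice`, `fits`, `skipped`, `sh` (p-values/rejections),
#'   `null_rejected`, `branch_a_category`, `branch_bcd_category`.
#' @export
run_group <- function(aln, trees, clades, config = rns_config(),
                      group_id = "group", fit_branch_lengths = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(constrained = trees)
  tree <- trees$constrained
  tree_choice <- list(chosen = "constrained", kh_p = NA_real_)
  null_starts <- NULL

  if (!is.null(trees$unconstrained)) {
    fit_c <- fit_codon_model(aln, trees$constrained, config = config,
                             fit_branch_lengths = fit_branch_lengths)
    fit_u <- fit_codon_model(aln, trees$unconstrained, config = config,
                             fit_branch_lengths = fit_branch_lengths)
    kh <- kh_test(fit_c, fit_u, n_rell = config$n_rell, seed = config$seed)
    if (kh$p_value < 0.05 && fit_u$lnL > fit_c$lnL) {
      tree <- trees$unconstrained
      tree_choice$chosen <- "unconstrained"
    }
    tree_choice$kh_p <- kh$p_value
    tree_choice$constrained_lnL <- fit_c$lnL
    tree_choice$unconstrained_lnL <- fit_u$lnL
    chosen_fit <- if (tree_choice$chosen == "constrained") fit_c else fit_u
    null_starts <- list(list(kappa = chosen_fit$kappa,
                             omega = unname(chosen_fit$omega[1])))
  }

  labels <- label_branches(tree, clades)
  available <- attr(labels, "available")
  specs <- scenario_classes()
  fits <- list()
  skipped <- list()

  pi <- f3x4_frequencies(aln)
  fits[["NULL"]] <- fit_codon_model(aln, tree, edge_classes = labels,
                                    free_classes = character(),
                                    config = config, pi = pi,
                                    starts = null_starts,
                                    fit_branch_lengths = fit_branch_lengths)
  if (fit_branch_lengths) {
    # share the NULL-estimated branch lengths across the other scenarios
    po_idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
    tree$edge.length[po_idx] <- fits[["NULL"]]$branch_lengths
  }
  warm <- function(fit, free) {
    bg <- unname(fit$omega["background"])
    if (is.na(bg)) bg <- unname(fit$omega[1])
    om <- rep(bg, length(free) + 1L)
    names(om) <- c("background", sort(free))
    present <- intersect(names(fit$omega), names(om))
    om[present] <- fit$omega[present]
    list(kappa = fit$kappa, omega = om)
  }
  for (sc in c("SINGLE", "MULTI", "TWOSTEP")) {
    free <- specs[[sc]]
    if (!all(available[free])) {
      skipped[[sc]] <- paste("class unavailable:",
                             paste(free[!available[free]], collapse = ", "))
      next
    }
    starts <- list(warm(fits[["NULL"]], free))
    if (sc == "TWOSTEP") {
      # warm-start from the better of the fitted sub-scenarios so the
      # nesting inequality holds numerically
      sub <- fits[intersect(c("SINGLE", "MULTI"), names(fits))]
      if (length(sub) > 0) {
        best_sub <- sub[[which.max(vapply(sub, `[[`, numeric(1), "lnL"))]]
        starts <- c(list(warm(best_sub, free)), starts)
      }
    }
    fits[[sc]] <- fit_codon_model(aln, tree, edge_classes = labels,
                                  free_classes = free, config = config,
                                  pi = pi, starts = starts)
  }

  sh <- sh_test(fits, n_rell = config$n_rell, alpha = config$sh_alpha,
                seed = config$seed)
  null_rejected <- "NULL" %in% sh$rejected

  category <- function(s1, s2, lab1, lab2) {
    if (!null_rejected || !all(c(s1, s2) %in% names(fits))) return("n.a.")
    r1 <- s1 %in% sh$rejected
    r2 <- s2 %in% sh$rejected
    if (r1 && r2) "n.a." else if (r1) lab1 else if (r2) lab2 else "reject_neither"
  }
  res <- list(group_id = group_id, tree_choice = tree_choice,
              fits = fits, skipped = skipped, sh = sh,
              null_rejected = null_rejected,
              branch_a_category = category("SINGLE", "TWOSTEP",
                                           "reject_SINGLE", "reject_TWOSTEP"),
              branch_bcd_category = category("MULTI", "TWOSTEP",
                                             "reject_MULTI", "reject_TWOSTEP"))
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario test for", x$group_id, "\n")
  cat("  tree:", x$tree_choice$chosen, "\n")
  for (sc in names(x$fits)) {
    cat(sprintf("  %-8s lnL = %.3f  SH p = %.3f%s\n", sc, x$fits[[sc]]$lnL,
                x$sh$p_values[sc],
                if (sc %in% x$sh$rejected) "  [rejected]" else ""))
  }
  cat("  NULL rejected:", x$null_rejected,
      "| branch a:", x$branch_a_category,
      "| branches b,c,d:", x$branch_bcd_category, "\n")
  invisible(x)
}

#' Tabulate scenario-test results by branch class
#'
#' Counts groups by their rejection pattern: for the NFC stem branch (class
#' `a`), groups retaining a selection-pressure change there (not rejecting
#' both SINGLE and TWOSTEP) are split into reject-TWOSTEP / reject-neither /
#' reject-SINGLE; analogously for the host-lineage branches (`b`, `c`, `d`)
#' with MULTI in place of SINGLE.
#'
#' @param results list of `scenario_result` objects.
#' @return list of two data.frames (`branch_a`, `branch_bcd`) with counts
#'   and percentages, plus `n_total` and `n_null_rejected`.
#' @export
tabulate_scenarios <- function(results) {
  cats_a <- vapply(results, `[[`, character(1), "branch_a_category")
  cats_b <- vapply(results, `[[`, character(1), "branch_bcd_category")
  tab <- function(cats, labels) {
    cats <- cats[cats != "n.a."]
    cnt <- vapply(labels, function(l) sum(cats == l), integer(1))
    total <- sum(cnt)
    data.frame(category = labels, count = unname(cnt),
               percentage = if (total > 0) round(100 * unname(cnt) / total, 1)
                            else rep(0, length(labels)),
               stringsAsFactors = FALSE)
  }
  list(branch_a = tab(cats_a, c("reject_TWOSTEP", "reject_neither", "reject_SINGLE")),
       branch_bcd = tab(cats_b, c("reject_TWOSTEP", "reject_neither", "reject_MULTI")),
       n_total = length(results),
       n_null_rejected = sum(vapply(results, `[[`, logical(1), "null_rejected")))
}
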