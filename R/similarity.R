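# Cross-species expression concordance: the dissonance statistic with its
# permutation null, representative fold-change pairs, and Pearson subsets.

#' Dissonance score between two species for one ortholog group
#'
#' The average absolute difference in nodule-over-root log2 fold change over
#' all member pairs: `D = sum_ij |A_i - B_j| / (m n)` for `m` members in
#' species A and `n` in species B. Symmetric, non-negative, and zero only
#' when every pair agrees exactly.
#'
#' @param A,B non-empty numeric vectors of member fold changes.
#' @return the dissonance score (scalar).
#' @export
dissonance_score <- function(A, B) {
  if (length(A) == 0 || length(B) == 0) stop("empty fold-change vector")
  if (anyNA(A) || anyNA(B) || any(!is.finite(c(A, B)))) {
    stop("fold changes must be finite")
  }
  mean(abs(outer(A, B, "-")))
}

#' Per-group fold-change vectors for one species
#'
#' @param groups named list of member gene-id vectors.
#' @param records expression records.
#' @param species species tag to extract.
#' @return named list of numeric fold-change vectors (groups with no member
#'   record in `species` are dropped).
#' @export
fc_vectors <- function(groups, records, species) {
  rec <- records[records$species_id == species, , drop = FALSE]
  fc <- stats::setNames(rec$log2fc, rec$gene_id)
  out <- lapply(groups, function(members) unname(fc[intersect(members, names(fc))]))
  out[lengths(out) > 0]
}

align_pair <- function(A, B) {
  if (is.null(names(A)) || is.null(names(B))) stop("group lists must be named")
  common <- intersect(names(A), names(B))
  missing_a <- setdiff(names(B), names(A))
  missing_b <- setdiff(names(A), names(B))
  if (length(missing_a) > 0 || length(missing_b) > 0) {
    stop("group missing a species: ",
         c(missing_a, missing_b)[1])
  }
  list(A = A[common], B = B[common])
}

#' Overall dissonance between two species
#'
#' Sum of [dissonance_score()] over all representative groups. `A` and `B`
#' are parallel named lists of per-group fold-change vectors (see
#' [fc_vectors()]); a group present in one list but not the other is an
#' error.
#'
#' @param A,B named lists of numeric vectors, keyed by group id.
#' @return the summed dissonance score.
#' @export
overall_dissonance <- function(A, B) {
  al <- align_pair(A, B)
  sum(mapply(dissonance_score, al$A, al$B))
}

#' Permutation test of the overall dissonance score
#'
#' Shuffles individual fold-change values across transcripts within each
#' species (group sizes preserved), recomputes the overall dissonance for
#' each replicate, and reports the inclusive permutation p-value: the
#' fraction of replicates with dissonance at or below the observed value.
#' The `(k+1)/(N+1)` estimator is reported alongside since the inclusive
#' fraction degenerates to 0 when no replicate reaches the observed score.
#'
#' @param A,B named lists of per-group fold-change vectors.
#' @param n_perm number of permutation replicates.
#' @param seed integer seed (recorded in the result).
#' @param mode shuffle `"both"` species per replicate, or only the first
#'   (`"one"`).
#' @param unit `"values"` (shuffle fold-change values within species) or
#'   `"groups"` (permute group labels of the second species).
#' @return object of class `dissonance_result`: `observed`, `perm_scores`,
#'   `p_value` (inclusive), `p_plus_one`, `n_perm`, `seed`.
#' @export
permutation_test <- function(A, B, n_perm = 10000L, seed = 1L,
                             mode = c("both", "one"),
                             unit = c("values", "groups")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  stopifnot(n_perm >= 1)
  al <- align_pair(A, B)
  A <- al$A
  B <- al$B
  observed <- overall_dissonance(A, B)

  pool_a <- unlist(A, use.names = FALSE)
  pool_b <- unlist(B, use.names = FALSE)
  ia <- rep(seq_along(A), lengths(A))   # group index of each pooled value
  ib <- rep(seq_along(B), lengths(B))
  single <- lengths(A) == 1L & lengths(B) == 1L
  sa <- match(which(single), ia)        # pool position of singleton groups
  sb <- match(which(single), ib)
  multi <- which(!single)
  ma <- lapply(multi, function(g) which(ia == g))
  mb <- lapply(multi, function(g) which(ib == g))

  total_d <- function(va, vb) {
    d <- sum(abs(va[sa] - vb[sb]))
    for (k in seq_along(multi)) {
      d <- d + mean(abs(outer(va[ma[[k]]], vb[mb[[k]]], "-")))
    }
    d
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  scores <- numeric(n_perm)
  if (unit == "values") {
    for (r in seq_len(n_perm)) {
      va <- pool_a[sample.int(length(pool_a))]
      vb <- if (mode == "both") pool_b[sample.int(length(pool_b))] else pool_b
      scores[r] <- total_d(va, vb)
    }
  } else {
    for (r in seq_len(n_perm)) {
      perm <- sample.int(length(B))
      scores[r] <- sum(mapply(dissonance_score, A, B[perm]))
    }
  }
  k <- sum(scores <= observed)
  structure(list(observed = observed, perm_scores = scores,
                 p_value = k / n_perm,
                 p_plus_one = (k + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 mode = mode, unit = unit),
            class = "dissonance_result")
}

#' @export
print.dissonance_result <- function(x, ...) {
  cat(sprintf(paste0("Dissonance permutation test: observed = %.4f, ",
                     "p = %.4g (inclusive), %.4g ((k+1)/(N+1)), %d replicates\n"),
              x$observed, x$p_value, x$p_plus_one, x$n_perm))
  invisible(x)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Representative fold-change pair per group
#'
#' For groups where a species carries more than one paralog, the pair of
#' fold changes minimizing `|fc_a - fc_b|` represents the group; ties are
#' broken toward the lexicographically smallest `(fc_a, fc_b)` pair so the
#' choice is deterministic.
#'
#' @param A,B named lists of per-group fold-change vectors.
#' @return data.frame with columns `group_id`, `fc_a`, `fc_b`.
#' @export
representative_fc_pairs <- function(A, B) {
  al <- align_pair(A, B)
  rows <- mapply(function(a, b) {
    d <- abs(outer(a, b, "-"))
    hits <- which(d == min(d), arr.ind = TRUE)
    cand <- cbind(a[hits[, 1]], b[hits[, 2]])
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    cand[1, ]
  }, al$A, al$B)
  data.frame(group_id = names(al$A),
             fc_a = rows[1, ], fc_b = rows[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation of paired fold changes
#'
#' Sample Pearson correlation with a two-sided t-test p-value
#' (via [stats::cor.test()]); a margin with zero variance yields a flagged
#' result with `r = NA`.
#'
#' @param pairs data.frame with columns `fc_a`, `fc_b`
#'   (see [representative_fc_pairs()]); at least 3 pairs.
#' @param subset label recorded in the result (`"all"`,
#'   `"nodule_co_enhanced"`, `"root_co_enhanced"`, ...).
#' @return list of class `correlation_result`: `subset`, `r`, `p_value`,
#'   `n_groups`, `degenerate`.
#' @export
pearson_correlation <- function(pairs, subset = "all") {
  if (nrow(pairs) < 3) stop("need at least 3 pairs for a correlation")
  degenerate <- stats::sd(pairs$fc_a) == 0 || stats::sd(pairs$fc_b) == 0
  if (degenerate) {
    res <- list(subset = subset, r = NA_real_, p_value = NA_real_,
                n_groups = nrow(pairs), degenerate = TRUE)
  } else {
    ct <- stats::cor.test(pairs$fc_a, pairs$fc_b, method = "pearson")
    res <- list(subset = subset, r = unname(ct$estimate),
                p_value = ct$p.value, n_groups = nrow(pairs),
                degenerate = FALSE)
  }
  class(res) <- "correlation_result"
  res
}

#' Pairwise expression-similarity analysis between two species
#'
#' Convenience wrapper running the full pairwise comparison: representative
#' fold-change pairs, Pearson correlations for all groups and for the
#' nodule-/root-co-enhanced subsets, and the dissonance permutation test.
#'
#' @param groups named list of representative group member vectors.
#' @param records expression records for both species.
#' @param species_a,species_b species tags.
#' @param calls optional output of [classify_groups()] used to form the
#'   co-enhanced subsets; computed from `records` when `NULL`.
#' @param config an [rns_config()].
#' @return list with `pair`, `correlations` (list of `correlation_result`),
#'   and `dissonance` (a `dissonance_result`).
#' @export
compare_species_pair <- function(groups, records, species_a, species_b,
                                 calls = NULL, config = rns_config()) {
  A <- fc_vectors(groups, records, species_a)
  B <- fc_vectors(groups, records, species_b)
  common <- intersect(names(A), names(B))
  A <- A[common]
  B <- B[common]
  if (length(common) == 0) stop("no groups shared between ",
                                species_a, " and ", species_b)
  if (is.null(calls)) calls <- classify_groups(groups[common], records, config)
  pairs <- representative_fc_pairs(A, B)

  call_of <- function(sp) {
    cc <- calls[calls$species_id == sp, , drop = FALSE]
    stats::setNames(cc$call, cc$group_id)
  }
  ca <- call_of(species_a)[pairs$group_id]
  cb <- call_of(species_b)[pairs$group_id]
  nod <- !is.na(ca) & !is.na(cb) & ca %in% c("nodule", "both") & cb %in% c("nodule", "both")
  rt <- !is.na(ca) & !is.na(cb) & ca %in% c("root", "both") & cb %in% c("root", "both")

  correlations <- list(all = pearson_correlation(pairs, "all"))
  if (sum(nod) >= 3) {
    correlations$nodule_co_enhanced <-
      pearson_correlation(pairs[nod, , drop = FALSE], "nodule_co_enhanced")
  }
  if (sum(rt) >= 3) {
    correlations$root_co_enhanced <-
      pearson_correlation(pairs[rt, , drop = FALSE], "root_co_enhanced")
  }
  dres <- permutation_test(A, B, n_perm = config$n_perm, seed = config$seed,
                           mode = config$permute_mode, unit = config$permute_unit)
  list(pair = c(species_a, species_b), correlations = correlations,
       dissonance = dres)
}
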