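# Independent oracles used by the unit and acceptance tests. These must stay
# independent of the implementation paths they check: merging is re-done by
# naive pairwise closure, and the pruning likelihood is re-computed by
# exhaustive enumeration of internal-node states with Matrix::expm().

# Brute-force transitive closure of overlapping sets: repeatedly merge any
# two sets sharing a member until a fixed point. O(n^2) per pass.
brute_merge <- function(sets) {
  sets <- lapply(sets, function(s) sort(unique(s)))
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0) {
          sets[[i]] <- sort(unique(c(sets[[i]], sets[[j]])))
          sets[[j]] <- NULL
          merged_any <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  unname(sets[order(vapply(sets, `[`, character(1), 1L))])
}

# Exhaustive-site likelihood: sum over all assignments of internal-node
# codon states, with transition matrices from Matrix::expm (not the
# package's spectral path). Only feasible for trees with <= 3 internal nodes.
enum_site_loglik <- function(aln, tree, kappa, omega_by_class, pi,
                             edge_classes = NULL) {
  if (is.null(edge_classes)) edge_classes <- rep("background", nrow(tree$edge))
  po_idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edge <- tree$edge[po_idx, , drop = FALSE]
  len <- tree$edge.length[po_idx]
  cls <- edge_classes[po_idx]
  P <- lapply(seq_len(nrow(edge)), function(e) {
    Q <- codon_rate_matrix(kappa, unname(omega_by_class[cls[e]]), pi)
    as.matrix(Matrix::expm(Matrix::Matrix(Q * len[e])))
  })
  ntip <- length(tree$tip.label)
  internals <- sort(unique(as.vector(edge[edge > ntip])))
  stopifnot(length(internals) <= 3)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:61), length(internals))))
  colnames(grid) <- NULL
  root <- edge[nrow(edge), 1]
  tipstates <- aln$states[tree$tip.label, , drop = FALSE]

  vapply(seq_len(ncol(tipstates)), function(s) {
    state_of <- function(node) {
      if (node <= ntip) {
        st <- tipstates[node, s]
        if (is.na(st)) NA_integer_ else rep(st, nrow(grid))
      } else {
        grid[, match(node, internals)]
      }
    }
    lik <- pi[grid[, match(root, internals)]]
    for (e in seq_len(nrow(edge))) {
      sp <- state_of(edge[e, 1])
      sc <- state_of(edge[e, 2])
      if (length(sc) == 1 && is.na(sc[1])) next  # missing tip: sums to 1
      lik <- lik * P[[e]][cbind(sp, sc)]
    }
    log(sum(lik))
  }, numeric(1))
}

# quick config for tests: small resampling counts, fixed seed
test_config <- function(...) {
  rns_config(n_perm = 200L, n_rell = 300L, seed = 42L, ...)
}

# random prediction sets over a gene universe, for merge property tests
random_predictions <- function(n_sets, n_genes, max_size = 6L,
                               species = c("Ct", "Dg", "Mt")) {
  universe <- paste0(sample(species, n_genes, replace = TRUE), "_g",
                     sprintf("%04d", seq_len(n_genes)))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, sample.int(max_size, 1))
  })
  names(sets) <- vapply(sets, `[`, character(1), 1L)
  sets[!duplicated(names(sets))]
}
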