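# Goldman-Yang codon substitution model with per-branch-class dN/dS:
# rate matrix, spectral decomposition, pruning likelihood, and ML fitting.

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of the Goldman-Yang codon
#' model. Off-diagonal rates are zero for multi-nucleotide changes and
#' proportional to the target codon frequency otherwise, multiplied by
#' `kappa` for transitions and `omega` for non-synonymous changes.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (> 0).
#' @param pi codon frequencies: numeric vector of length 61 summing to 1.
#' @param scale if `TRUE` (default) the matrix is rescaled so that the
#'   expected number of substitutions per codon per unit time is 1 at
#'   stationarity, so branch lengths are expected substitutions per codon.
#' @return 61 x 61 rate matrix with zero row sums, satisfying detailed
#'   balance `pi[i] Q[i,j] == pi[j] Q[j,i]`.
#' @export
codon_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(omega), length(omega) == 1L, omega > 0)
  pi <- validate_codon_freq(pi)
  tab <- codon_table()
  mult <- c(0, 1, kappa, omega, omega * kappa)
  Q <- matrix(mult[tab$type + 1L], 61L, 61L) * rep(pi, each = 61L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu <= 0) stop("degenerate rate matrix: zero expected rate")
    Q <- Q / mu
  }
  Q
}

validate_codon_freq <- function(pi) {
  if (!is.numeric(pi) || length(pi) != 61L || anyNA(pi) || any(pi < 0)) {
    stop("`pi` must be 61 non-negative codon frequencies")
  }
  s <- sum(pi)
  if (abs(s - 1) > 1e-6) stop("codon frequencies must sum to 1 (got ", signif(s, 6), ")")
  # floor to keep the similarity transform well conditioned
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

# Spectral decomposition of the (reversible) GY rate matrix via the symmetric
# similarity transform B = D^{1/2} Q D^{-1/2}: Q = V diag(lambda) Vinv.
codon_eigen <- function(kappa, omega, pi, scale = TRUE) {
  pi <- validate_codon_freq(pi)
  Q <- codon_rate_matrix(kappa, omega, pi, scale = scale)
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = 61L))  # B[i,j] = Q[i,j] * sq[i]/sq[j]
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       V = e$vectors / sq,                # rows scaled by 1/sqrt(pi_i)
       Vinv = t(e$vectors * sq))          # cols of U scaled by sqrt(pi_j), transposed
}

#' Codon transition probability matrix
#'
#' `expm(Q t)` for the Goldman-Yang model, computed from the spectral
#' decomposition of the reversible rate matrix.
#'
#' @inheritParams codon_rate_matrix
#' @param t branch length (expected substitutions per codon when `scale = TRUE`).
#' @return 61 x 61 stochastic matrix.
#' @export
codon_transition_matrix <- function(kappa, omega, pi, t, scale = TRUE) {
  stopifnot(t >= 0)
  eg <- codon_eigen(kappa, omega, pi, scale = scale)
  P <- eg$V %*% (exp(eg$values * t) * eg$Vinv)
  P[P < 0] <- 0
  P
}

#' Empirical F3x4 codon frequencies
#'
#' Estimates codon frequencies from the position-specific nucleotide
#' frequencies of an alignment (the common default of codon-model software),
#' renormalized over the 61 sense codons. Ambiguous/missing codons are
#' ignored in the counts.
#'
#' @param aln a [codon_alignment()].
#' @return numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  aln <- as_codon_alignment(aln)
  tab <- codon_table()
  st <- aln$states[!is.na(aln$states)]
  if (length(st) == 0L) stop("alignment has no resolved codons")
  f <- vapply(1:3, function(p) {
    cnt <- tabulate(tab$pos[st, p], nbins = 4L)
    cnt / sum(cnt)
  }, numeric(4L))
  pi <- f[tab$pos[, 1], 1] * f[tab$pos[, 2], 2] * f[tab$pos[, 3], 3]
  pi / sum(pi)
}

# ---------------------------------------------------------------------------

# reorder a tree postorder together with any per-edge annotation vectors
postorder_edges <- function(tree, ...) {
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  ann <- lapply(list(...), function(v) {
    if (is.null(v)) NULL else v[idx]
  })
  list(edge = tree$edge[idx, , drop = FALSE],
       edge.length = tree$edge.length[idx],
       ann = ann)
}

# resolve class labels -> eigen-system index per edge, with one eigen system
# per distinct omega value (classes tied to the background share a system)
class_systems <- function(edge_classes, omega_by_class) {
  cls <- unique(edge_classes)
  missing <- setdiff(cls, names(omega_by_class))
  if (length(missing) > 0) {
    stop("no omega supplied for branch class(es): ", paste(missing, collapse = ", "))
  }
  om <- omega_by_class[cls]
  uom <- unique(unname(om))
  sys_of_class <- match(om, uom)
  names(sys_of_class) <- cls
  list(omegas = uom, edge_sys = unname(sys_of_class[edge_classes]))
}

#' Per-site pruning log-likelihood of a codon alignment
#'
#' Computes the log-likelihood of an in-frame codon alignment on a rooted,
#' branch-labeled tree under the Goldman-Yang model with one dN/dS value per
#' branch class, by Felsenstein pruning. Gap/ambiguous codons integrate over
#' all 61 states.
#'
#' @param aln a [codon_alignment()]; its taxa must cover the tree's tips.
#' @param tree an `ape::phylo` tree with branch lengths (substitutions/codon).
#' @param kappa transition/transversion ratio.
#' @param omega_by_class named numeric vector of dN/dS per branch class; must
#'   cover every label in `edge_classes`.
#' @param pi codon frequencies (default: F3x4 from the alignment).
#' @param edge_classes character vector of branch-class labels aligned with
#'   the rows of `tree$edge`; default all `"background"`.
#' @return list with `lnL` (total) and `site_lnL` (per codon site).
#' @export
prune_loglik <- function(aln, tree, kappa, omega_by_class,
                         pi = NULL, edge_classes = NULL) {
  aln <- as_codon_alignment(aln)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(edge_classes)) edge_classes <- rep("background", nrow(tree$edge))
  if (length(edge_classes) != nrow(tree$edge)) {
    stop("`edge_classes` must have one label per edge")
  }
  if (anyNA(edge_classes)) stop("unlabeled branch: every edge needs a class")
  miss <- setdiff(tree$tip.label, rownames(aln$states))
  if (length(miss) > 0) stop("taxa missing from alignment: ", paste(miss, collapse = ", "))
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- validate_codon_freq(pi)

  po <- postorder_edges(tree, edge_classes)
  sys <- class_systems(po$ann[[1]], omega_by_class)
  eg <- lapply(sys$omegas, function(om) codon_eigen(kappa, om, pi))

  states <- aln$states[tree$tip.label, , drop = FALSE]
  # compress to site patterns
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat_of_site <- match(key, key[first])
  pat <- states[, first, drop = FALSE]

  site <- cpp_codon_site_loglik(
    po$edge, length(tree$tip.label), max(po$edge),
    as.integer(sys$edge_sys), po$edge.length,
    lapply(eg, `[[`, "V"), lapply(eg, `[[`, "Vinv"), lapply(eg, `[[`, "values"),
    pat, pi)
  site_lnL <- site[pat_of_site]
  list(lnL = sum(site_lnL), site_lnL = site_lnL)
}

# ---------------------------------------------------------------------------

#' Maximum-likelihood fit of a branch-class codon model
#'
#' Fits kappa and one dN/dS per free branch class (all other classes share
#' the background dN/dS) by bounded quasi-Newton optimization on
#' log-transformed parameters, optionally together with the branch lengths.
#' Multiple starting points guard against local optima.
#'
#' @inheritParams prune_loglik
#' @param free_classes character vector of branch-class labels receiving
#'   their own dN/dS; classes absent from the tree are an error.
#' @param config a [rns_config()]; supplies parameter bounds, optimizer
#'   tolerance, and the default starting points.
#' @param starts optional list of starting points, each a list with elements
#'   `kappa` and `omega` (scalar, recycled over classes, or a full named
#'   vector). Defaults to the two points in `config$fit_starts`.
#' @param fit_branch_lengths also estimate branch lengths (slower; default
#'   uses the lengths carried by `tree`, e.g. from the tree-search step).
#' @return object of class `codon_fit`: total and per-site log-likelihood,
#'   `kappa`, `omega` (named per class), `pi`, branch lengths, convergence
#'   flag and iteration count.
#' @export
fit_codon_model <- function(aln, tree, edge_classes = NULL,
                            free_classes = character(), config = rns_config(),
                            pi = NULL, starts = NULL,
                            fit_branch_lengths = FALSE) {
  aln <- as_codon_alignment(aln)
  if (is.null(edge_classes)) edge_classes <- rep("background", nrow(tree$edge))
  present <- unique(edge_classes)
  bad <- setdiff(free_classes, present)
  if (length(bad) > 0) {
    stop("free class(es) not present on the tree: ", paste(bad, collapse = ", "))
  }
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- validate_codon_freq(pi)

  tied <- setdiff(present, free_classes)
  omega_names <- c("background", setdiff(sort(free_classes), "background"))
  n_om <- length(omega_names)

  po <- postorder_edges(tree, edge_classes)
  ecls <- po$ann[[1]]
  # omega parameter index per edge
  om_idx <- ifelse(ecls %in% tied, 1L, match(ecls, omega_names))
  ntip <- length(tree$tip.label)
  states <- aln$states[tree$tip.label, , drop = FALSE]
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat_of_site <- match(key, key[first])
  pat <- states[, first, drop = FALSE]

  nedge <- nrow(po$edge)
  blen0 <- po$edge.length
  eig_cache <- new.env(parent = emptyenv())

  negloglik <- function(par, per_site = FALSE) {
    kappa <- exp(par[1L])
    omegas <- exp(par[2:(1 + n_om)])
    blen <- if (fit_branch_lengths) exp(par[(2 + n_om):(1 + n_om + nedge)]) else blen0
    eg <- lapply(omegas, function(om) {
      k <- sprintf("%.14g|%.14g", kappa, om)
      got <- eig_cache[[k]]
      if (is.null(got)) {
        got <- codon_eigen(kappa, om, pi)
        eig_cache[[k]] <- got
      }
      got
    })
    site <- cpp_codon_site_loglik(po$edge, ntip, max(po$edge),
                                  as.integer(om_idx), blen,
                                  lapply(eg, `[[`, "V"),
                                  lapply(eg, `[[`, "Vinv"),
                                  lapply(eg, `[[`, "values"),
                                  pat, pi)
    if (per_site) return(site[pat_of_site])
    v <- -sum(site[pat_of_site])
    if (!is.finite(v)) v <- .Machine$double.xmax / 1e6
    v
  }

  if (is.null(starts)) starts <- config$fit_starts
  lb <- c(log(config$kappa_bounds[1]), rep(log(config$omega_bounds[1]), n_om))
  ub <- c(log(config$kappa_bounds[2]), rep(log(config$omega_bounds[2]), n_om))
  if (fit_branch_lengths) {
    lb <- c(lb, rep(log(1e-7), nedge))
    ub <- c(ub, rep(log(10), nedge))
  }

  # forward-difference gradient reusing the objective value at the current
  # point (optim evaluates fn and gr at the same par in sequence)
  grad_cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    v <- negloglik(par)
    grad_cache$par <- par
    grad_cache$val <- v
    v
  }
  gr <- function(par) {
    f0 <- if (!is.null(grad_cache$par) && identical(grad_cache$par, par)) {
      grad_cache$val
    } else negloglik(par)
    h <- 1e-5
    vapply(seq_along(par), function(i) {
      ph <- par
      ph[i] <- ph[i] + h
      (negloglik(ph) - f0) / h
    }, numeric(1))
  }

  best <- NULL
  n_iter <- 0L
  for (s in starts) {
    om0 <- s$omega
    om0 <- if (length(om0) == n_om) unname(om0) else rep(om0[1L], n_om)
    par0 <- c(log(s$kappa), log(om0))
    if (fit_branch_lengths) par0 <- c(par0, log(pmax(blen0, 1e-6)))
    par0 <- pmin(pmax(par0, lb), ub)
    opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        lower = lb, upper = ub,
                        control = list(maxit = config$max_iter,
                                       factr = config$optim_factr))
    n_iter <- n_iter + opt$counts[1L]
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  kappa <- exp(best$par[1L])
  om_fit <- exp(best$par[2:(1 + n_om)])
  names(om_fit) <- omega_names
  omega <- om_fit[ifelse(present %in% tied, 1L, match(present, omega_names))]
  names(omega) <- present
  blen <- if (fit_branch_lengths) exp(best$par[(2 + n_om):(1 + n_om + nedge)]) else blen0
  site_lnL <- negloglik(best$par, per_site = TRUE)

  fit <- list(lnL = sum(site_lnL), site_lnL = site_lnL,
              kappa = kappa, omega = omega, pi = pi,
              branch_lengths = blen, edge = po$edge, edge_classes = ecls,
              converged = best$convergence == 0L, n_iter = unname(n_iter),
              free_classes = setdiff(omega_names, "background"))
  class(fit) <- "codon_fit"
  fit
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit (Goldman-Yang, branch classes)\n")
  cat(sprintf("  lnL: %.4f over %d sites%s\n", x$lnL, length(x$site_lnL),
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  kappa: %.4f\n", x$kappa))
  om <- x$omega[!duplicated(names(x$omega))]
  cat("  omega:", paste(sprintf("%s=%.4f", names(om), om), collapse = ", "), "\n")
  invisible(x)
}
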