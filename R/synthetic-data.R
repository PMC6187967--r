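# Simulators for every pipeline input: ortholog predictions with paralogs
# and noise, paired cross-species fold changes with controllable
# correlation, and codon alignments evolved along a branch-labeled tree.

#' Default species tree for the selection-pressure analysis
#'
#' A 15-taxon family-level species tree covering the nitrogen-fixing clade
#' (legumes, Rosales including *C. thyrsiflorus*, Cucurbitales including
#' *D. glomerata*) and close outgroups, rooted on *V. vinifera*. Branch
#' lengths are in expected substitutions per codon and were chosen to give
#' a plausible depth (~3 substitutions/codon total) for rosid divergence;
#' this is a synthetic stand-in topology/branch-length set for simulation
#' and examples, not an estimate from data.
#'
#' @return an `ape::phylo` tree.
#' @export
nfc_species_tree <- function() {
  txt <- paste0(
    "(Vitis_vinifera:0.30,(Arabidopsis_thaliana:0.45,",
    "((Manihot_esculenta:0.25,Populus_trichocarpa:0.25):0.08,",
    "((Medicago_truncatula:0.15,(Lotus_japonicus:0.12,",
    "(Glycine_max:0.08,Phaseolus_vulgaris:0.08):0.04):0.03):0.12,",
    "((Ceanothus_thyrsiflorus:0.20,((Prunus_persica:0.08,",
    "Fragaria_vesca:0.10):0.03,Malus_domestica:0.10):0.08):0.06,",
    "((Cucumis_sativus:0.08,Citrullus_lanatus:0.08):0.10,",
    "Datisca_glomerata:0.22):0.06):0.04):0.12):0.05):0.08);")
  ape::read.tree(text = txt)
}

#' Clade definitions matching [nfc_species_tree()]
#'
#' @return list with `nfc`, `legumes`, `ct`, `dg`, `outgroup` suitable for
#'   [label_branches()].
#' @export
nfc_clades <- function() {
  legumes <- c("Medicago_truncatula", "Lotus_japonicus",
               "Glycine_max", "Phaseolus_vulgaris")
  rosales <- c("Ceanothus_thyrsiflorus", "Prunus_persica",
               "Fragaria_vesca", "Malus_domestica")
  cucurbitales <- c("Cucumis_sativus", "Citrullus_lanatus", "Datisca_glomerata")
  list(nfc = c(legumes, rosales, cucurbitales),
       legumes = legumes,
       ct = "Ceanothus_thyrsiflorus",
       dg = "Datisca_glomerata",
       outgroup = "Vitis_vinifera")
}

#' Simulate per-gene ortholog predictions
#'
#' Generates ground-truth ortholog families (one gene per species, plus
#' extra paralogs at `dup_rate`) and per-gene predictions equal to the
#' family member set; with probability `noise` a prediction additionally
#' absorbs the members of one other random family, creating the overlaps
#' that transitive merging must resolve.
#'
#' @param n_families number of ortholog families.
#' @param species character vector of species tags.
#' @param dup_rate expected number of extra paralogs per (family, species)
#'   (Poisson).
#' @param noise probability that a gene's prediction spills into another
#'   family.
#' @param seed integer seed.
#' @return list with `predictions` (named list per gene) and `families`
#'   (named list of ground-truth member vectors).
#' @export
sim_ortholog_predictions <- function(n_families, species = c("Ct", "Dg", "Mt"),
                                     dup_rate = 0.2, noise = 0, seed = 1L) {
  stopifnot(n_families >= 1, dup_rate >= 0, noise >= 0, noise <= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  families <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    members <- unlist(lapply(species, function(sp) {
      k <- 1L + stats::rpois(1L, dup_rate)
      sprintf("%s_F%04dP%02d", sp, f, seq_len(k))
    }))
    families[[f]] <- sort(members)
  }
  names(families) <- sprintf("Fam%04d", seq_len(n_families))
  predictions <- list()
  fam_of_gene <- rep(seq_len(n_families), lengths(families))
  for (f in seq_len(n_families)) {
    for (g in families[[f]]) {
      pred <- families[[f]]
      if (n_families > 1L && stats::runif(1) < noise) {
        other <- sample(setdiff(seq_len(n_families), f), 1L)
        pred <- sort(unique(c(pred, families[[other]])))
      }
      predictions[[g]] <- pred
    }
  }
  list(predictions = predictions, families = families,
       fam_of_gene = stats::setNames(fam_of_gene, unlist(families)))
}

#' Simulate paired cross-species expression tables
#'
#' Draws per-group nodule-over-root log2 fold changes with a given
#' cross-species correlation: non-enhanced groups follow a (multivariate)
#' normal with standard deviation `sd` and equicorrelation `rho` across
#' species (via a shared group-level factor); enhanced groups add a shared
#' tissue-signed shift of mean `effect_mean`. Adjusted p-values follow a
#' simple two-component model: enhanced genes draw `Uniform(0, 5e-4)`,
#' others `Uniform(0.05, 1)`, so threshold logic is exercised without a
#' differential-expression model.
#'
#' @param n_groups number of ortholog groups.
#' @param species species tags (>= 2).
#' @param rho cross-species fold-change correlation; negative values are
#'   only meaningful for exactly two species.
#' @param sd standard deviation of the non-enhanced component (log2 units).
#' @param frac_nodule,frac_root fractions of groups nodule-/root-enhanced.
#' @param effect_mean mean |shift| of enhanced groups (log2 units).
#' @param paralog_prob probability that a (group, species) carries one extra
#'   paralog (which inherits the group fold change plus unit noise).
#' @param seed integer seed.
#' @return data.frame of expression records (`gene_id`, `species_id`,
#'   `log2fc`, `adj_p`, `group_id`) with attributes `truth` (per-group
#'   labels) and `groups` (named member list).
#' @export
sim_expression <- function(n_groups, species = c("Ct", "Dg"), rho = 0.4,
                           sd = 1.5, frac_nodule = 0, frac_root = 0,
                           effect_mean = 3, paralog_prob = 0, seed = 1L) {
  stopifnot(n_groups >= 1, length(species) >= 2, rho >= -1, rho <= 1,
            sd > 0, frac_nodule >= 0, frac_root >= 0,
            frac_nodule + frac_root <= 1)
  if (rho < 0 && length(species) > 2) {
    stop("negative cross-species correlation requires exactly two species")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  k <- length(species)
  status <- sample(c("nodule", "root", "none"), n_groups, replace = TRUE,
                   prob = c(frac_nodule, frac_root, 1 - frac_nodule - frac_root))
  # equicorrelated null component
  if (rho >= 0) {
    z <- stats::rnorm(n_groups)
    eps <- matrix(stats::rnorm(n_groups * k), n_groups, k)
    fc <- sd * (sqrt(rho) * z + sqrt(1 - rho) * eps)
  } else {
    z1 <- stats::rnorm(n_groups)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_groups)
    fc <- sd * cbind(z1, z2)
  }
  shift <- ifelse(status == "nodule", 1, ifelse(status == "root", -1, 0)) *
    abs(stats::rnorm(n_groups, effect_mean, 1))
  fc <- fc + shift

  gid <- sprintf("G%05d", seq_len(n_groups))
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    extra <- stats::runif(n_groups) < paralog_prob
    gene1 <- sprintf("%s_%sP01", species[j], gid)
    df <- data.frame(gene_id = gene1, species_id = species[j],
                     log2fc = fc[, j],
                     adj_p = ifelse(status == "none",
                                    stats::runif(n_groups, 0.05, 1),
                                    stats::runif(n_groups, 0, 5e-4)),
                     group_id = gid, stringsAsFactors = FALSE)
    if (any(extra)) {
      df2 <- df[extra, , drop = FALSE]
      df2$gene_id <- sprintf("%s_%sP02", species[j], gid[extra])
      df2$log2fc <- df2$log2fc + stats::rnorm(sum(extra))
      df <- rbind(df, df2)
    }
    rows[[j]] <- df
  }
  records <- do.call(rbind, rows)
  groups <- split(records$gene_id, records$group_id)
  attr(records, "truth") <- data.frame(group_id = gid, status = status,
                                       stringsAsFactors = FALSE)
  attr(records, "groups") <- groups
  records
}

#' Simulate a codon alignment along a branch-labeled tree
#'
#' Draws the root codon of each site from `pi` and evolves it down the tree
#' with the Goldman-Yang transition matrices of each branch's class, so the
#' generating process matches the likelihood model exactly.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param n_codons number of codon sites.
#' @param omega_by_class named dN/dS per branch class (must cover every
#'   label used); scalar for an unlabeled tree.
#' @param kappa transition/transversion ratio.
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @param edge_classes per-edge class labels (default all background).
#' @param seed integer seed.
#' @return a [codon_alignment()] of the tip sequences, with the true
#'   parameters in attribute `truth`.
#' @export
sim_codon_alignment <- function(tree, n_codons, omega_by_class = c(background = 0.2),
                                kappa = 2, pi = NULL, edge_classes = NULL,
                                seed = 1L) {
  stopifnot(n_codons >= 1)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (is.null(edge_classes)) edge_classes <- rep("background", nrow(tree$edge))
  if (anyNA(edge_classes)) stop("branch missing a class label")
  if (is.null(names(omega_by_class)) && length(omega_by_class) == 1L) {
    names(omega_by_class) <- "background"
  }
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  pi <- validate_codon_freq(pi)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  po <- postorder_edges(tree, edge_classes)
  sys <- class_systems(po$ann[[1]], omega_by_class)
  eg <- lapply(sys$omegas, function(om) codon_eigen(kappa, om, pi))
  root_state <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  unif <- stats::runif(nrow(po$edge) * n_codons)
  states <- cpp_sim_codon_states(po$edge, length(tree$tip.label), max(po$edge),
                                 as.integer(sys$edge_sys), po$edge.length,
                                 lapply(eg, `[[`, "V"),
                                 lapply(eg, `[[`, "Vinv"),
                                 lapply(eg, `[[`, "values"),
                                 root_state, unif)
  tab <- codon_table()
  seqs <- vapply(seq_along(tree$tip.label), function(i) {
    paste(tab$codons[states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- tree$tip.label
  aln <- codon_alignment(seqs)
  attr(aln, "truth") <- list(kappa = kappa, omega_by_class = omega_by_class,
                             pi = pi, seed = seed)
  aln
}
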