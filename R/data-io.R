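# Readers/writers for the external formats consumed by the pipeline, the
# codon-alignment container, and the run configuration.

#' Analysis configuration
#'
#' Central collection of thresholds and tuning parameters. Defaults follow
#' the study design this package implements: per-species adjusted-p cutoffs
#' (0.005 for *C. thyrsiflorus*, whose fewer biological replicates give limma
#' less power; 0.001 for *D. glomerata* and *M. truncatula*), a log2
#' fold-change cutoff of 1, 10,000 permutation replicates, 1,000 RELL
#' bootstrap replicates, and a 0.05 rejection level for the
#' Shimodaira-Hasegawa test.
#'
#' @param p_cutoffs named numeric vector of per-species adjusted-p cutoffs.
#' @param fc_cutoff absolute log2 fold-change cutoff (strict inequality).
#' @param n_perm permutation replicates for the dissonance test.
#' @param n_rell RELL bootstrap replicates for KH/SH tests.
#' @param sh_alpha rejection level for the SH scenario test.
#' @param seed integer seed used by stochastic stages.
#' @param kappa_bounds,omega_bounds box constraints for the codon-model fit.
#' @param optim_factr `factr` passed to `optim(method = "L-BFGS-B")`.
#' @param max_iter optimizer iteration cap.
#' @param fit_starts list of starting points for [fit_codon_model()].
#' @param tissue_specific_significant treat tissue-specific genes whose
#'   adjusted p was imputed as 1 as significant anyway (the literal rule
#'   keeps them non-significant; see the methods vignette).
#' @param both_counts_both_cores a group scored "both" in a species counts
#'   toward the nodule core and the root core (literal reading of the
#'   paralog rule); set `FALSE` to exclude "both" calls from cores.
#' @param permute_mode shuffle fold changes in `"both"` species per replicate
#'   or in `"one"`.
#' @param permute_unit `"values"` shuffles individual fold-change values
#'   within species (group sizes preserved); `"groups"` permutes group labels.
#' @return a list of class `rns_config`.
#' @export
rns_config <- function(p_cutoffs = c(Ct = 0.005, Dg = 0.001, Mt = 0.001),
                       fc_cutoff = 1,
                       n_perm = 10000L,
                       n_rell = 1000L,
                       sh_alpha = 0.05,
                       seed = 1L,
                       kappa_bounds = c(0.1, 20),
                       omega_bounds = c(1e-4, 20),
                       optim_factr = 1e7,
                       max_iter = 200L,
                       fit_starts = list(list(kappa = 2, omega = 0.5),
                                         list(kappa = 4, omega = 1.5)),
                       tissue_specific_significant = FALSE,
                       both_counts_both_cores = TRUE,
                       permute_mode = c("both", "one"),
                       permute_unit = c("values", "groups")) {
  permute_mode <- match.arg(permute_mode)
  permute_unit <- match.arg(permute_unit)
  stopifnot(all(p_cutoffs > 0), fc_cutoff > 0, n_perm >= 1,
            n_rell >= 1, sh_alpha > 0, sh_alpha < 1,
            kappa_bounds[1] > 0, diff(kappa_bounds) > 0,
            omega_bounds[1] > 0, diff(omega_bounds) > 0)
  cfg <- list(p_cutoffs = p_cutoffs, fc_cutoff = fc_cutoff,
              n_perm = as.integer(n_perm), n_rell = as.integer(n_rell),
              sh_alpha = sh_alpha, seed = as.integer(seed),
              kappa_bounds = kappa_bounds, omega_bounds = omega_bounds,
              optim_factr = optim_factr, max_iter = as.integer(max_iter),
              fit_starts = fit_starts,
              tissue_specific_significant = tissue_specific_significant,
              both_counts_both_cores = both_counts_both_cores,
              permute_mode = permute_mode, permute_unit = permute_unit)
  class(cfg) <- "rns_config"
  cfg
}

# ---------------------------------------------------------------------------

#' Read a per-species expression table
#'
#' Reads a tab-separated table of nodule-over-root log2 fold changes and
#' adjusted p-values. The file must have header columns `gene_id`, `log2fc`
#' and `adj_p`. Rows with unparseable numeric fields are reported and
#' dropped; duplicate gene ids and out-of-range p-values are fatal.
#'
#' @param path path to a TSV file.
#' @param species_id species tag attached to every record.
#' @return data.frame with columns `gene_id`, `species_id`, `log2fc`, `adj_p`.
#' @export
read_expression_table <- function(path, species_id) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "log2fc", "adj_p")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) stop("missing column(s) in ", path, ": ",
                             paste(miss, collapse = ", "))
  fc <- suppressWarnings(as.numeric(raw$log2fc))
  p <- suppressWarnings(as.numeric(raw$adj_p))
  bad <- (is.na(fc) | is.na(p)) & !(is.na(raw$log2fc) & is.na(raw$adj_p))
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable numerics skipped in ", path,
            " (first: gene_id=", raw$gene_id[which(bad)[1]], ")")
  }
  keep <- !bad
  rec <- expression_records(raw$gene_id[keep], species_id, fc[keep], p[keep])
  dup <- rec$gene_id[duplicated(rec$gene_id)]
  if (length(dup) > 0) stop("duplicate gene_id in ", path, ": ", dup[1])
  rec
}

#' Construct expression records
#'
#' @param gene_id,species_id,log2fc,adj_p vectors (recycled `species_id`).
#' @return validated data.frame of expression records.
#' @export
expression_records <- function(gene_id, species_id, log2fc, adj_p) {
  rec <- data.frame(gene_id = as.character(gene_id),
                    species_id = rep_len(as.character(species_id), length(gene_id)),
                    log2fc = as.numeric(log2fc), adj_p = as.numeric(adj_p),
                    stringsAsFactors = FALSE)
  bad_p <- which(!is.na(rec$adj_p) & (rec$adj_p < 0 | rec$adj_p > 1))
  if (length(bad_p) > 0) {
    stop("adjusted p-value outside [0,1] for gene ", rec$gene_id[bad_p[1]],
         " (", rec$adj_p[bad_p[1]], ")")
  }
  inf <- which(!is.na(rec$log2fc) & !is.finite(rec$log2fc))
  if (length(inf) > 0) stop("non-finite log2fc for gene ", rec$gene_id[inf[1]])
  rec
}

#' Impute fold changes for unexpressed and tissue-specific genes
#'
#' Applies the genome-wide preprocessing convention used for the
#' *M. truncatula* data: genes expressed in neither tissue get
#' `log2fc = 0, adj_p = 1`; nodule-specific genes get `log2fc = +15` and
#' root-specific genes `log2fc = -15`, with `adj_p = 1` wherever no p-value
#' was already provided.
#'
#' @param records expression records (may lack rows, or carry NA values, for
#'   genes covered by `status`).
#' @param status data.frame with columns `gene_id` and `status`, one of
#'   `"expressed"`, `"unexpressed"`, `"nodule_specific"`, `"root_specific"`.
#'   A gene flagged both nodule- and root-specific is an error.
#' @param species_id species tag for rows created from `status` alone.
#' @return completed expression records.
#' @export
normalize_tissue_specific <- function(records, status, species_id = "Mt") {
  stopifnot(all(c("gene_id", "status") %in% names(status)))
  ok <- c("expressed", "unexpressed", "nodule_specific", "root_specific")
  if (!all(status$status %in% ok)) {
    stop("unknown status value(s): ",
         paste(setdiff(unique(status$status), ok), collapse = ", "))
  }
  spl <- split(status$status, status$gene_id)
  conflict <- names(spl)[vapply(spl, function(s)
    all(c("nodule_specific", "root_specific") %in% s), logical(1))]
  if (length(conflict) > 0) {
    stop("gene flagged both nodule- and root-specific: ", conflict[1])
  }
  status <- status[!duplicated(status$gene_id), , drop = FALSE]

  new_genes <- setdiff(status$gene_id, records$gene_id)
  if (length(new_genes) > 0) {
    records <- rbind(records,
                     expression_records(new_genes, species_id,
                                        NA_real_, NA_real_))
  }
  idx <- match(records$gene_id, status$gene_id)
  st <- status$status[idx]
  st[is.na(st)] <- "expressed"

  unexp <- st == "unexpressed"
  records$log2fc[unexp] <- 0
  records$adj_p[unexp] <- 1
  nod <- st == "nodule_specific"
  records$log2fc[nod] <- 15
  rt <- st == "root_specific"
  records$log2fc[rt] <- -15
  fill_p <- (nod | rt) & is.na(records$adj_p)
  records$adj_p[fill_p] <- 1
  na_left <- is.na(records$log2fc) | is.na(records$adj_p)
  if (any(na_left)) {
    stop("record(s) still incomplete after normalization, e.g. gene ",
         records$gene_id[which(na_left)[1]])
  }
  expression_records(records$gene_id, records$species_id,
                     records$log2fc, records$adj_p)
}

# ---------------------------------------------------------------------------

#' In-frame codon alignment container
#'
#' @param sequences named character vector of equal-length, in-frame
#'   nucleotide sequences (gaps `-` and ambiguity codes allowed; any codon
#'   that is not an unambiguous sense codon is treated as fully missing).
#' @return object of class `codon_alignment` with elements `states`
#'   (taxa x codon integer matrix, 1..61 or NA), `n_codons`, and the raw
#'   `sequences`.
#' @export
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("sequences must be named by taxon")
  }
  if (anyDuplicated(names(sequences))) stop("duplicate taxon labels")
  seqs <- toupper(gsub("U", "T", sequences, ignore.case = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("ragged alignment: unequal sequence lengths")
  if (lens[1] %% 3L != 0L) stop("alignment length not divisible by 3")
  n_codons <- unname(lens[1]) %/% 3L
  tab <- codon_table()
  stops <- c("TAA", "TAG", "TGA")
  states <- matrix(NA_integer_, length(seqs), n_codons,
                   dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cod <- substring(seqs[i], 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    hit <- match(cod, stops)
    if (any(!is.na(hit))) {
      j <- which(!is.na(hit))[1]
      stop("stop codon ", cod[j], " in taxon ", names(seqs)[i],
           " at codon ", j)
    }
    states[i, ] <- match(cod, tab$codons)
  }
  structure(list(states = states, n_codons = n_codons, sequences = seqs),
            class = "codon_alignment")
}

as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  if (is.character(x)) return(codon_alignment(x))
  stop("cannot interpret object of class ", class(x)[1], " as a codon alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d taxa x %d codons (%.1f%% missing)\n",
              nrow(x$states), x$n_codons, 100 * mean(is.na(x$states))))
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA file of equal-length in-frame sequences.
#' @return a [codon_alignment()]. Internal stop codons are fatal.
#' @export
read_codon_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(set), names(set)))
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output path.
#' @export
write_codon_fasta <- function(aln, path) {
  aln <- as_codon_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$sequences), path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with the validation the downstream analyses
#' assume: unique tip labels, non-negative branch lengths; absent branch
#' lengths default to 0.1 with a warning.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick in ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1])
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0.1")
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
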