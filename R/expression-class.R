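# Nodule/root enhancement calls for genes and merged ortholog groups, core
# group identification, and the RNS pathway gene summary.

#' Classify one gene's differential expression
#'
#' A gene is nodule-enhanced when `log2fc > fc_cutoff` and
#' `adj_p < p_cutoff`, root-enhanced when `log2fc < -fc_cutoff` and
#' `adj_p < p_cutoff`, and not significant (`"ns"`) otherwise. Both
#' inequalities are strict.
#'
#' @param log2fc,adj_p numeric vectors (recycled against each other).
#' @param p_cutoff,fc_cutoff positive thresholds.
#' @return character vector in `c("nodule", "root", "ns")`; `NA` inputs give
#'   `NA` calls.
#' @export
classify_gene <- function(log2fc, adj_p, p_cutoff, fc_cutoff = 1) {
  stopifnot(p_cutoff > 0, fc_cutoff > 0)
  out <- ifelse(is.na(log2fc) | is.na(adj_p), NA_character_,
         ifelse(adj_p < p_cutoff & log2fc > fc_cutoff, "nodule",
         ifelse(adj_p < p_cutoff & log2fc < -fc_cutoff, "root", "ns")))
  out
}

#' Add per-gene enhancement calls to expression records
#'
#' @param records expression records (see [expression_records()]).
#' @param config an [rns_config()]; per-species p cutoffs are taken from
#'   `config$p_cutoffs` and must cover every species present.
#' @return the records with a `call` column.
#' @export
classify_records <- function(records, config = rns_config()) {
  sp <- unique(records$species_id)
  miss <- setdiff(sp, names(config$p_cutoffs))
  if (length(miss) > 0) {
    stop("no p-value cutoff configured for species: ", paste(miss, collapse = ", "))
  }
  records$call <- classify_gene(records$log2fc, records$adj_p,
                                p_cutoff = unname(config$p_cutoffs[records$species_id]),
                                fc_cutoff = config$fc_cutoff)
  records
}

#' Combine paralog calls into one group-by-species call
#'
#' A group is nodule-enhanced in a species if at least one paralog is
#' nodule-enhanced and none is root-enhanced (and vice versa); it is
#' `"both"` when paralogs conflict, and `"none"` when no paralog is
#' significant.
#'
#' @param calls character vector of per-paralog calls
#'   (`"nodule"`/`"root"`/`"ns"`); must be non-empty.
#' @return one of `"nodule"`, `"root"`, `"both"`, `"none"`.
#' @export
classify_group_species <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("no gene calls supplied")
  has_n <- any(calls == "nodule")
  has_r <- any(calls == "root")
  if (has_n && has_r) "both" else if (has_n) "nodule" else if (has_r) "root" else "none"
}

#' Enhancement calls for merged groups
#'
#' Applies [classify_gene()] to every member with an expression record and
#' [classify_group_species()] per (group, species).
#'
#' @param groups named list of member gene-id vectors (e.g.
#'   [representative_groups()]).
#' @param records expression records covering the members (genes without a
#'   record contribute presence only).
#' @param config an [rns_config()].
#' @return data.frame with columns `group_id`, `species_id`, `call`,
#'   `n_genes`, `supporting_genes` (comma-separated significant paralogs).
#' @export
classify_groups <- function(groups, records, config = rns_config()) {
  records <- classify_records(records, config)
  idx <- split(seq_len(nrow(records)), records$gene_id)
  rows <- list()
  for (id in names(groups)) {
    members <- groups[[id]]
    hit <- unlist(idx[members], use.names = FALSE)
    if (length(hit) == 0) next
    sub <- records[hit, , drop = FALSE]
    for (sp in unique(sub$species_id)) {
      g <- sub[sub$species_id == sp, , drop = FALSE]
      call <- classify_group_species(g$call)
      sig <- g$gene_id[g$call %in% c("nodule", "root")]
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = id, species_id = sp, call = call,
        n_genes = nrow(g),
        supporting_genes = paste(sig, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(group_id = character(), species_id = character(),
                      call = character(), n_genes = integer(),
                      supporting_genes = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Core merged ortholog groups
#'
#' Core groups are representative groups enhanced in the same tissue in all
#' focal species. By default a `"both"` call counts toward either tissue
#' (`config$both_counts_both_cores`).
#'
#' @param calls output of [classify_groups()].
#' @param group_ids representative group ids to evaluate.
#' @param focal_species the focal species triple.
#' @param config an [rns_config()].
#' @return list with character vectors `nodule_core` and `root_core`.
#' @export
find_core_groups <- function(calls, group_ids,
                             focal_species = c("Ct", "Dg", "Mt"),
                             config = rns_config()) {
  nodule_core <- character()
  root_core <- character()
  nod_ok <- if (config$both_counts_both_cores) c("nodule", "both") else "nodule"
  root_ok <- if (config$both_counts_both_cores) c("root", "both") else "root"
  for (id in group_ids) {
    cc <- calls[calls$group_id == id, , drop = FALSE]
    got <- stats::setNames(cc$call, cc$species_id)[focal_species]
    if (anyNA(got)) {
      stop("missing call for group ", id, ", species ",
           focal_species[which(is.na(got))[1]])
    }
    if (all(got %in% nod_ok)) nodule_core <- c(nodule_core, id)
    if (all(got %in% root_ok)) root_core <- c(root_core, id)
  }
  list(nodule_core = nodule_core, root_core = root_core)
}

# ---------------------------------------------------------------------------

#' Curated RNS pathway gene expression table
#'
#' The packaged fold-change/adjusted-p table for the 19 genes required for
#' nodule initiation and development in the model legumes, as scored in the
#' three focal species. `type` distinguishes predicted orthologs from
#' homolog-only hits (no expression values); *L. japonicus* ortholog rows
#' carry no fold changes and contribute presence only.
#'
#' @return data.frame with columns `gene_name`, `group_id` (NA when the gene
#'   is not represented in a merged group), `species_id`, `gene_id`, `type`,
#'   `log2fc`, `adj_p`.
#' @export
rns_pathway_table <- function() {
  path <- system.file("extdata", "rns_pathway_expression.tsv",
                      package = "nodevol", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df
}

#' Presence and universal-enhancement summary of pathway genes
#'
#' For each pathway gene: whether a predicted ortholog exists in all three
#' lineages (*C. thyrsiflorus*, *D. glomerata*, and a legume — *M.
#' truncatula* or *L. japonicus*), and whether its expression is universally
#' enhanced in one tissue across the three lineages. Calls use only rows
#' with expression values (legume calls therefore come from *M. truncatula*
#' records).
#'
#' @param pathway data.frame in the layout of [rns_pathway_table()].
#' @param config an [rns_config()].
#' @return data.frame with one row per gene: `gene_name`, `group_id`,
#'   `has_group`, `ortholog_in_all`, `universal_call`
#'   (`"nodule"`/`"root"`/`"none"`).
#' @export
pathway_presence_summary <- function(pathway = rns_pathway_table(),
                                     config = rns_config()) {
  legume <- c("Mt", "Lj")
  out <- list()
  for (gn in unique(pathway$gene_name)) {
    sub <- pathway[pathway$gene_name == gn, , drop = FALSE]
    orth <- sub[sub$type == "ortholog", , drop = FALSE]
    present <- unique(orth$species_id)
    in_all <- all(c("Ct", "Dg") %in% present) && any(legume %in% present)

    lineage_calls <- vapply(list("Ct", "Dg", legume), function(sp) {
      g <- orth[orth$species_id %in% sp & !is.na(orth$log2fc) & !is.na(orth$adj_p), ,
                drop = FALSE]
      if (nrow(g) == 0) return("none")
      calls <- classify_gene(g$log2fc, g$adj_p,
                             p_cutoff = unname(config$p_cutoffs[g$species_id]),
                             fc_cutoff = config$fc_cutoff)
      classify_group_species(calls)
    }, character(1))
    universal <- if (all(lineage_calls %in% c("nodule", "both"))) "nodule"
      else if (all(lineage_calls %in% c("root", "both"))) "root"
      else "none"
    gid <- sub$group_id[!is.na(sub$group_id)][1]
    out[[gn]] <- data.frame(gene_name = gn,
                            group_id = if (is.na(gid)) NA_character_ else gid,
                            has_group = !is.na(gid),
                            ortholog_in_all = in_all,
                            universal_call = universal,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
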