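# Collapse per-gene ortholog predictions into mutually exclusive merged
# ortholog groups and select the representative whole/subset groups used by
# the cross-species analyses.

#' Species tag of a gene id
#'
#' Gene ids are species-tagged strings of the form `"<species>_<id>"`
#' (e.g. `"Ct_CtTrNR12221"`, `"Mt_Medtr5g099060"`); the species is the
#' prefix before the first underscore.
#'
#' @param gene_id character vector of gene ids.
#' @return character vector of species tags.
#' @export
species_of <- function(gene_id) sub("_.*$", "", gene_id)

#' Union per-isoform ortholog predictions into per-gene predictions
#'
#' Orthologs are predicted independently for each isoform of a gene; the
#' gene's prediction is the union over its isoforms.
#'
#' @param predictions named list, one character vector of predicted ortholog
#'   gene ids per isoform.
#' @param gene_of named character vector mapping isoform id to parent gene id;
#'   an isoform without a parent is an error.
#' @return named list of per-gene predictions (sorted, unique, each
#'   containing its own query gene).
#' @export
union_isoform_predictions <- function(predictions, gene_of) {
  if (is.null(names(predictions))) stop("predictions must be named by isoform")
  parent <- gene_of[names(predictions)]
  orphan <- names(predictions)[is.na(parent)]
  if (length(orphan) > 0) {
    stop("isoform with unknown parent gene: ", orphan[1])
  }
  merged <- lapply(split(predictions, unname(parent)), function(sets) {
    sort(unique(unlist(sets, use.names = FALSE)))
  })
  merged[] <- Map(function(g, m) sort(unique(c(g, m))), names(merged), merged)
  merged
}

#' Merge overlapping ortholog sets into mutually exclusive groups
#'
#' Per-gene ortholog predictions are not mutually exclusive; sets sharing at
#' least one gene are merged transitively (connected components of the
#' overlap graph) so that every gene belongs to exactly one merged ortholog
#' group. Group ids `MergedOrthoGroupNNNNNN` are assigned by the
#' lexicographic order of each group's smallest member, so the partition and
#' its naming are invariant to input order.
#'
#' @param predictions named list of per-gene ortholog predictions (character
#'   vectors of gene ids); each query gene is implicitly a member of its own
#'   set.
#' @return named list of class `merged_groups`: sorted member vectors keyed
#'   by group id.
#' @export
merge_ortholog_sets <- function(predictions) {
  if (length(predictions) == 0) stop("no predictions supplied")
  sets <- Map(function(q, m) unique(c(q, m)), names(predictions), predictions)
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  edges <- lapply(sets, function(m) {
    if (length(m) < 2L) return(NULL)
    cbind(m[1L], m[-1L])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, genes), ncol = 2)))
  }
  comp <- igraph::components(g)$membership
  groups <- split(genes, comp)
  groups <- lapply(groups, sort)
  ord <- order(vapply(groups, `[`, character(1), 1L))
  groups <- groups[ord]
  names(groups) <- sprintf("MergedOrthoGroup%06d", seq_along(groups))
  class(groups) <- c("merged_groups", "list")
  groups
}

#' Merged groups as a long data.frame
#'
#' @param groups a `merged_groups` list (or the combined representative set).
#' @param provenance provenance label recycled over groups.
#' @return data.frame with columns `group_id`, `species_id`, `gene_id`,
#'   `provenance`.
#' @export
groups_to_df <- function(groups, provenance = "whole") {
  provenance <- rep_len(provenance, length(groups))
  do.call(rbind, Map(function(id, members, prov) {
    data.frame(group_id = id, species_id = species_of(members),
               gene_id = members, provenance = prov,
               stringsAsFactors = FALSE)
  }, names(groups), groups, provenance))
}

#' Select representative whole and subset groups
#'
#' A merged group is a *whole* representative when (1) it contains at least
#' one member from each focal species and (2) it is identical to the
#' ortholog set predicted from some single gene. Within the remaining
#' groups, *subset* representatives are formed from single-gene predictions
#' restricted to the focal species: candidates satisfying the per-species
#' presence criterion are unioned transitively when they overlap, and the
#' resulting disjoint subsets are numbered `Sub001`, `Sub002`, ... in the
#' order of their smallest member.
#'
#' @param groups output of [merge_ortholog_sets()].
#' @param predictions the per-gene predictions the groups were merged from.
#' @param focal_species character vector of focal species tags
#'   (default `c("Ct", "Dg", "Mt")`).
#' @return object of class `representative_set`: lists `whole` and `subset`
#'   (member vectors keyed by group id), `subset_parent` (parent group id per
#'   subset), and `focal_species`.
#' @export
select_representatives <- function(groups, predictions,
                                   focal_species = c("Ct", "Dg", "Mt")) {
  sets <- Map(function(q, m) sort(unique(c(q, m))), names(predictions), predictions)
  group_of <- stats::setNames(rep(names(groups), lengths(groups)),
                              unlist(groups, use.names = FALSE))
  has_focal <- function(members) {
    all(focal_species %in% species_of(members))
  }
  whole <- list()
  rest <- character()
  for (id in names(groups)) {
    members <- groups[[id]]
    queries <- intersect(members, names(sets))
    is_whole <- has_focal(members) &&
      any(vapply(queries, function(q) identical(sets[[q]], members), logical(1)))
    if (is_whole) whole[[id]] <- members else rest <- c(rest, id)
  }

  subset <- list()
  subset_parent <- character()
  for (id in rest) {
    members <- groups[[id]]
    queries <- intersect(members, names(sets))
    cand <- lapply(sets[queries], function(s) s[species_of(s) %in% focal_species])
    cand <- cand[vapply(cand, has_focal, logical(1))]
    if (length(cand) == 0) next
    # transitively union overlapping candidates
    merged <- list()
    for (s in cand) {
      hit <- which(vapply(merged, function(m) length(intersect(m, s)) > 0, logical(1)))
      if (length(hit) == 0) {
        merged[[length(merged) + 1L]] <- s
      } else {
        merged[[hit[1]]] <- sort(unique(c(unlist(merged[hit]), s)))
        merged[setdiff(hit, hit[1])] <- NULL
      }
    }
    merged <- lapply(merged, sort)
    merged <- merged[order(vapply(merged, `[`, character(1), 1L))]
    ids <- sprintf("%sSub%03d", id, seq_along(merged))
    subset[ids] <- merged
    subset_parent[ids] <- id
  }

  structure(list(whole = whole, subset = subset,
                 subset_parent = subset_parent,
                 focal_species = focal_species),
            class = "representative_set")
}

#' All representative groups as one named list
#'
#' @param reps a `representative_set`.
#' @return named list of member vectors (whole groups first).
#' @export
representative_groups <- function(reps) {
  stopifnot(inherits(reps, "representative_set"))
  c(reps$whole, reps$subset)
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("Representative set: %d whole + %d subset groups (focal: %s)\n",
              length(x$whole), length(x$subset),
              paste(x$focal_species, collapse = ", ")))
  invisible(x)
}
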