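# End-to-end orchestration: merge -> classify -> similarity (-> scenarios),
# with a reproducibility manifest.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparative pipeline
#'
#' Executes the stages in dependency order: read the ortholog edge list and
#' expression tables, merge predictions into groups, select representatives,
#' classify enhancement and find core groups, and run the pairwise
#' similarity analysis for every focal species pair. Each stage's outputs
#' are written under `out_dir` and a JSON manifest records the
#' configuration, input digests, seed and package version, so a rerun with
#' identical inputs reproduces identical outputs.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `ortholog_edges` (TSV path with columns `query_gene`, `ortholog_gene`),
#'   `expression` (named list species -> TSV path), optional
#'   `focal_species` (default `c("Ct","Dg","Mt")`), and optional entries
#'   overriding [rns_config()] arguments (e.g. `n_perm`, `seed`).
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  focal <- config$focal_species %||% c("Ct", "Dg", "Mt")
  cfg_args <- config[intersect(names(config), names(formals(rns_config)))]
  cfg <- do.call(rns_config, cfg_args)

  inputs <- c(ortholog_edges = config$ortholog_edges,
              unlist(config$expression))
  digests <- stage("inputs", {
    miss <- inputs[!file.exists(inputs)]
    if (length(miss) > 0) stop("missing input file(s): ",
                               paste(miss, collapse = ", "))
    tools::md5sum(inputs)
  })

  predictions <- stage("merge", {
    edges <- utils::read.delim(config$ortholog_edges, stringsAsFactors = FALSE)
    if (!all(c("query_gene", "ortholog_gene") %in% names(edges))) {
      stop("ortholog edge list needs columns query_gene, ortholog_gene")
    }
    lapply(split(edges$ortholog_gene, edges$query_gene), unique)
  })
  groups <- stage("merge", merge_ortholog_sets(predictions))
  reps <- stage("merge", select_representatives(groups, predictions, focal))
  rep_groups <- representative_groups(reps)
  utils::write.table(groups_to_df(rep_groups,
                                  provenance = rep(c("whole", "subset"),
                                                   c(length(reps$whole),
                                                     length(reps$subset)))),
                     file.path(out_dir, "representative_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  records <- stage("classify", {
    recs <- Map(function(sp, path) read_expression_table(path, sp),
                names(config$expression), config$expression)
    do.call(rbind, unname(recs))
  })
  calls <- stage("classify", classify_groups(rep_groups, records, cfg))
  utils::write.table(calls, file.path(out_dir, "enhancement_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  core <- stage("classify", {
    # core membership is defined over representative groups with calls in
    # every focal species; groups lacking a call in some species cannot be core
    have_all <- names(rep_groups)[vapply(names(rep_groups), function(id) {
      sp <- calls$species_id[calls$group_id == id]
      all(focal %in% sp)
    }, logical(1))]
    find_core_groups(calls, have_all, focal, cfg)
  })
  writeLines(jsonlite::toJSON(core, pretty = TRUE),
             file.path(out_dir, "core_groups.json"))

  similarity <- stage("similarity", {
    pairs <- utils::combn(focal, 2, simplify = FALSE)
    out <- list()
    for (p in pairs) {
      key <- paste(p, collapse = "_")
      res <- compare_species_pair(rep_groups, records, p[1], p[2],
                                  calls = calls, config = cfg)
      out[[key]] <- list(
        pair = res$pair,
        correlations = lapply(res$correlations, function(cr) {
          cr[c("subset", "r", "p_value", "n_groups")]
        }),
        dissonance = res$dissonance[c("observed", "p_value", "p_plus_one",
                                      "n_perm", "seed")])
    }
    out
  })
  writeLines(jsonlite::toJSON(similarity, pretty = TRUE, auto_unbox = TRUE,
                              digits = NA),
             file.path(out_dir, "similarity.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("nodevol")),
    seed = cfg$seed,
    config = config[setdiff(names(config), "expression")],
    expression_inputs = as.list(config$expression),
    input_md5 = as.list(digests),
    outputs = list(groups = "representative_groups.tsv",
                   calls = "enhancement_calls.tsv",
                   core = "core_groups.json",
                   similarity = "similarity.json"))
  writeLines(jsonlite::toJSON(manifest, pretty = TRUE, auto_unbox = TRUE),
             file.path(out_dir, "manifest.json"))

  invisible(list(groups = groups, representatives = reps, calls = calls,
                 core = core, similarity = similarity, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
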