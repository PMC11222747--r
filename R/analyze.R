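#' End-to-end phylogeographic analysis
#'
#' Runs the full pipeline on a sample set: concatenation and inversion
#' recoding, haplotype collapsing (outgroup included, so a disconnected
#' outgroup is visible in the network), statistical-parsimony network,
#' per-island diversity table, and the minimum inter-island colonization
#' event count for every candidate ancestral haplotype. Optionally writes the
#' complete results bundle, with the resolved configuration echoed to JSON,
#' to an output directory.
#'
#' @param samples a `sample_set` (see [read_sample_set()]).
#' @param cfg an [island_unit_config()].
#' @param blocks recode blocks, see [concatenate_and_recode()].
#' @param roots candidate ancestral haplotypes for event counting; `NULL`
#'   tries every sampled ingroup haplotype.
#' @param limit connection limit override; `NULL` computes it at `alpha`.
#' @param alpha confidence level for the computed connection limit.
#' @param out_dir if non-`NULL`, directory to write the results bundle to.
#' @return an object of class `colonization_analysis`: list with `ht`
#'   (haplotype table), `net`, `limit`, `diversity`, `occupancy`, `counts`
#'   (per root), `min_events`, `best_roots`, `ancestral_ranking`.
#' @export
analyze_colonization <- function(samples, cfg, blocks = NULL, roots = NULL,
                                 limit = NULL, alpha = 0.95, out_dir = NULL) {
  stopifnot(inherits(samples, "sample_set"), inherits(cfg, "island_unit_config"))
  if (nrow(samples$meta) == 0L) stop("empty sample set")
  cm <- concatenate_and_recode(samples, blocks)
  ht <- collapse_haplotypes(cm, scope = rownames(cm$states),
                            characters = extract_variable_characters(
                              cm, rownames(cm$states)))
  if (is.null(limit)) limit <- parsimony_connection_limit(ncol(cm$states), alpha)
  net <- build_network(pairwise_steps(ht), limit, ht)
  div <- diversity_table(ht, cfg$merges)
  occupancy <- apply_island_units(ht, cfg)
  mor <- min_over_roots(net, occupancy)
  if (!is.null(roots)) {
    missing_roots <- setdiff(roots, names(mor$counts))
    if (length(missing_roots))
      stop("root not countable (absent or empty occupancy): ", missing_roots[1L])
    mor$counts <- mor$counts[roots]
    totals <- vapply(mor$counts, `[[`, 0L, "total")
    mor$min_total <- min(totals)
    mor$best_roots <- names(totals)[totals == min(totals)]
  }
  res <- structure(list(ht = ht, net = net, limit = as.integer(limit),
                        diversity = div, occupancy = occupancy,
                        counts = mor$counts, min_events = mor$min_total,
                        best_roots = mor$best_roots,
                        ancestral_ranking = rank_ancestral_candidates(net),
                        cfg = cfg, blocks = blocks),
                   class = "colonization_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.colonization_analysis <- function(x, ...) {
  cat(sprintf("colonization_analysis: %d haplotypes, limit %d, min events %d (roots: %s)\n",
              length(x$ht$labels), x$limit, x$min_events,
              paste(x$best_roots, collapse = ", ")))
  cat("diversity table:\n")
  d <- x$diversity
  d$H <- round(d$H, 3L)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write an analysis results bundle
#'
#' Emits the haplotype table, network edge/node tables, diversity table,
#' per-root colonization counts and a JSON echo of the resolved
#' configuration.
#'
#' @param res a `colonization_analysis`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_haplotype_table(res$ht, file.path(dir, "haplotypes.tsv"))
  write_network(res$net, file.path(dir, "network_edges.tsv"),
                file.path(dir, "network_nodes.tsv"))
  write_diversity_table(res$diversity, file.path(dir, "diversity.tsv"))
  counts <- do.call(rbind, lapply(names(res$counts), function(r) {
    cc <- res$counts[[r]]
    data.frame(root = r, total = cc$total,
               breakdown = paste(sprintf("%s:%d@%s", names(cc$per_haplotype),
                                         as.integer(cc$per_haplotype),
                                         cc$origin_assignment), collapse = ";"))
  }))
  utils::write.table(counts, file.path(dir, "colonization_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_echo <- list(limit = res$limit,
                   merges = as.list(res$cfg$merges),
                   exclusions = res$cfg$exclusions,
                   blocks = res$blocks,
                   min_events = res$min_events,
                   best_roots = res$best_roots,
                   ancestral_ranking = res$ancestral_ranking)
  jsonlite::write_json(cfg_echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
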