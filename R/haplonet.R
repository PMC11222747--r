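#' Pairwise mutational steps between haplotypes
#'
#' One step per character at which both haplotypes carry a (non-missing)
#' state and the states differ; missing positions are skipped.
#'
#' @param table a `haplotype_table`.
#' @return symmetric integer matrix with haplotype labels as dimnames.
#' @export
pairwise_steps <- function(table) {
  stopifnot(inherits(table, "haplotype_table"), length(table$labels) >= 1L)
  k <- length(table$labels)
  d <- matrix(0L, k, k, dimnames = list(table$labels, table$labels))
  if (k > 1L) {
    S <- table$states
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      both <- !is.na(S[i, ]) & !is.na(S[j, ])
      d[i, j] <- d[j, i] <- sum(S[i, both] != S[j, both])
    }
  }
  d
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps that can still be attributed to
#' non-superimposed change with confidence `alpha`. The approximation assumes
#' mutations hit the `m` characters uniformly at random, so the probability
#' that `j` mutations all strike distinct characters (no superimposed change)
#' is `prod(1 - i/m)` for `i = 1, ..., j-1`; the limit is the largest `j`
#' keeping that probability at or above `alpha`. As `alpha` approaches 1 only
#' single-step connections qualify, and the result is always at least 1.
#'
#' @param n_characters number of characters in the matrix (`m`).
#' @param alpha confidence level, default 0.95.
#' @param override if given, returned as the limit unchanged (useful to pin a
#'   published analysis to a fixed value).
#' @return integer connection limit, >= 1.
#' @export
parsimony_connection_limit <- function(n_characters, alpha = 0.95, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(n_characters >= 1L, alpha > 0, alpha < 1)
  m <- as.numeric(n_characters)
  j <- 1L
  p <- 1
  while (j < m) {
    p_next <- p * (1 - j / m)
    if (p_next < alpha) break
    p <- p_next
    j <- j + 1L
  }
  j
}

# Minimal union-find used by the network construction.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build a haplotype network under a connection limit
#'
#' Candidate edges are taken in ascending step order (ties broken by label
#' pair) and an edge is kept only when its endpoints are not yet connected, so
#' each component is a tree (the genealogy downstream analyses require) and a
#' frequency star collapses to its spokes rather than to all pairwise links.
#' Edges above the limit are never considered, which is what leaves a distant
#' outgroup disconnected.
#'
#' @param dist symmetric step matrix from [pairwise_steps()].
#' @param limit integer connection limit (>= 1), e.g. from
#'   [parsimony_connection_limit()].
#' @param table optional `haplotype_table` used to annotate nodes with
#'   frequency, island occupancy and ingroup status.
#' @return an object of class `haplotype_network`: list with `nodes` (data
#'   frame: haplotype, n, degree, n_islands, ingroup), `edges` (data frame:
#'   from, to, steps), `limit`, `components` (named integer membership) and
#'   `occupancy` (named list).
#' @export
build_network <- function(dist, limit, table = NULL) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist), limit >= 1L)
  ids <- rownames(dist)
  k <- length(ids)
  cand <- which(upper.tri(dist) & dist <= limit, arr.ind = TRUE)
  edges <- data.frame(from = character(0), to = character(0), steps = integer(0))
  parent <- seq_len(k)
  if (nrow(cand)) {
    ord <- order(dist[cand], ids[cand[, 1L]], ids[cand[, 2L]])
    cand <- cand[ord, , drop = FALSE]
    keep <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      a <- uf_find(parent, cand[e, 1L])
      b <- uf_find(parent, cand[e, 2L])
      if (a != b) {
        parent[a] <- b
        keep[e] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    edges <- data.frame(from = ids[cand[, 1L]], to = ids[cand[, 2L]],
                        steps = as.integer(dist[cand]))
  }
  comp_root <- vapply(seq_len(k), function(i) uf_find(parent, i), 0L)
  components <- stats::setNames(match(comp_root, unique(comp_root)), ids)
  degree <- stats::setNames(integer(k), ids)
  if (nrow(edges)) {
    tb <- table(c(edges$from, edges$to))
    degree[names(tb)] <- as.integer(tb)
  }
  if (!is.null(table)) {
    stopifnot(identical(sort(ids), sort(table$labels)))
    n <- table$n[ids]
    occ <- table$occupancy[ids]
    ingroup <- vapply(ids, function(h) {
      reg <- table$meta$region[match(table$members[[h]], table$meta$individual_id)]
      any(reg != "outgroup")
    }, TRUE)
  } else {
    n <- stats::setNames(rep(NA_integer_, k), ids)
    occ <- stats::setNames(rep(list(character(0)), k), ids)
    ingroup <- stats::setNames(rep(TRUE, k), ids)
  }
  nodes <- data.frame(haplotype = ids, n = as.integer(n), degree = degree,
                      n_islands = lengths(occ), ingroup = ingroup,
                      row.names = NULL)
  structure(list(nodes = nodes, edges = edges, limit = as.integer(limit),
                 components = components, occupancy = occ),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges, limit %d, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), x$limit, length(unique(x$components))))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Rank candidate ancestral haplotypes
#'
#' Ingroup haplotypes ordered by network centrality, the usual argument for
#' calling a haplotype ancestral: degree (descending), islands occupied
#' (descending), frequency (descending), label (ascending).
#'
#' @param net a `haplotype_network` built with node annotations.
#' @return character vector of ingroup haplotype labels, best candidate first.
#' @export
rank_ancestral_candidates <- function(net) {
  stopifnot(inherits(net, "haplotype_network"), nrow(net$nodes) >= 1L)
  nd <- net$nodes[net$nodes$ingroup, , drop = FALSE]
  nd$haplotype[order(-nd$degree, -nd$n_islands, -nd$n, nd$haplotype)]
}

#' Write a network as edge-list and node-table files
#'
#' @param net a `haplotype_network`.
#' @param edges_path,nodes_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- net$nodes
  nd$islands <- vapply(net$occupancy[nd$haplotype], paste, "", collapse = ",")
  nd$component <- net$components[nd$haplotype]
  utils::write.table(nd, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges_path, nodes_path))
}
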