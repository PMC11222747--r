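# Independent oracles kept deliberately naive: exhaustive enumeration and
# double loops, never sharing code with the implementation they check.

# Exhaustive minimum over all origination assignments: root originates on one
# of its own units; every other haplotype on a unit of its parent's occupancy
# or its parent's origin; cost = sum over haplotypes of
# |occupancy(x) union {origin(x)}| - 1.
brute_min_events <- function(root, parent, occupancy) {
  nodes <- root
  remaining <- names(parent)
  while (length(remaining)) {
    nxt <- remaining[parent[remaining] %in% nodes]
    nodes <- c(nodes, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  best <- Inf
  origins <- character(0)
  rec <- function(i, cost) {
    if (i > length(nodes)) {
      best <<- min(best, cost)
      return()
    }
    x <- nodes[i]
    allowed <- if (x == root) occupancy[[x]] else
      union(occupancy[[parent[[x]]]], origins[[parent[[x]]]])
    for (o in allowed) {
      origins[x] <<- o
      occ_x <- occupancy[[x]]
      if (is.null(occ_x)) occ_x <- character(0)
      rec(i + 1L, cost + length(union(occ_x, o)) - 1L)
    }
  }
  rec(1L, 0L)
  best
}

# Random countable instance: random tree, random occupancy (root non-empty,
# internal nodes may be empty).
random_count_instance <- function(n_hap, n_units) {
  haps <- paste0("h", seq_len(n_hap))
  units <- paste0("u", seq_len(n_units))
  parent <- character(0)
  if (n_hap > 1L)
    for (i in 2L:n_hap) parent[haps[i]] <- haps[sample.int(i - 1L, 1L)]
  occupancy <- lapply(seq_len(n_hap), function(i) {
    k <- sample(0:min(3L, n_units), 1L)
    sort(units[sample.int(n_units, k)])
  })
  names(occupancy) <- haps
  if (!length(occupancy[[haps[1L]]]))
    occupancy[[haps[1L]]] <- units[sample.int(n_units, 1L)]
  list(root = haps[1L], parent = parent, occupancy = occupancy)
}

# Haplotypic diversity as a literal double loop over individuals: the
# probability that two draws without replacement differ.
brute_H <- function(counts) {
  inds <- rep(seq_along(counts), counts)
  n <- length(inds)
  diff_pairs <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (inds[i] != inds[j]) diff_pairs <- diff_pairs + 1L
  diff_pairs / choose(n, 2)
}

# Brute-force haplotype collapse for complete data: group by the exact state
# string over the chosen characters.
brute_collapse_complete <- function(states, scope, characters) {
  key <- apply(states[scope, characters, drop = FALSE], 1L, paste, collapse = "|")
  split(scope, key)
}
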