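#' Island-unit configuration for colonization counting
#'
#' Declares how sampled islands map onto analysis units (e.g. merging
#' Lanzarote and Fuerteventura into the paleoisland Mahan, so that
#' within-paleoisland spread is not counted as colonization) and which groups
#' are excluded before counting (e.g. a mainland population, because only
#' within-archipelago events are of interest).
#'
#' @param merges named character vector, island name -> unit name. Must cover
#'   every non-excluded island observed in the data: geography is explicit.
#' @param exclusions island or unit names dropped before counting.
#' @return an object of class `island_unit_config`.
#' @export
island_unit_config <- function(merges, exclusions = character(0)) {
  stopifnot(is.character(merges), !is.null(names(merges)), all(nzchar(names(merges))))
  structure(list(merges = merges, exclusions = exclusions),
            class = "island_unit_config")
}

#' Haplotype occupancy over merged island units
#'
#' Maps each ingroup haplotype's member islands through the merge map, after
#' dropping excluded islands/units and all outgroup records. Haplotypes whose
#' members are all excluded are retained with empty occupancy (they still
#' carry genealogical information).
#'
#' @param table a `haplotype_table`.
#' @param cfg an [island_unit_config()].
#' @return named list: haplotype -> sorted character vector of units.
#' @export
apply_island_units <- function(table, cfg) {
  stopifnot(inherits(table, "haplotype_table"), inherits(cfg, "island_unit_config"))
  meta <- table$meta
  ingroup_hap <- vapply(table$labels, function(h) {
    reg <- meta$region[match(table$members[[h]], meta$individual_id)]
    any(reg != "outgroup")
  }, TRUE)
  occ <- lapply(table$labels[ingroup_hap], function(h) {
    ids <- table$members[[h]]
    rows <- match(ids, meta$individual_id)
    isl <- meta$island[rows]
    reg <- meta$region[rows]
    isl <- isl[reg != "outgroup" & !(isl %in% cfg$exclusions)]
    if (!length(isl)) return(character(0))
    unmapped <- setdiff(unique(isl), names(cfg$merges))
    if (length(unmapped))
      stop("island absent from merge map: ", unmapped[1L])
    units <- cfg$merges[isl]
    units <- units[!(units %in% cfg$exclusions)]
    sort(unique(unname(units)))
  })
  stats::setNames(occ, table$labels[ingroup_hap])
}

#' Construct a rooted genealogy directly
#'
#' Useful for counting events on a genealogy stated by hand (e.g. a published
#' haplotype network with known occupancies) without building it from
#' sequences.
#'
#' @param root root haplotype id.
#' @param parent named character vector: haplotype -> parent haplotype, for
#'   every non-root haplotype.
#' @param occupancy named list: haplotype -> character vector of island units
#'   (may be empty for unsampled intermediates).
#' @return an object of class `rooted_genealogy`.
#' @export
rooted_genealogy <- function(root, parent, occupancy) {
  nodes <- unique(c(root, names(parent), unlist(parent)))
  stopifnot(root %in% nodes, !root %in% names(parent))
  if (!setequal(setdiff(nodes, root), names(parent)))
    stop("every non-root haplotype needs a parent")
  # walk up from every node: must reach root without revisiting (tree check)
  for (x in names(parent)) {
    seen <- x
    cur <- x
    while (cur != root) {
      cur <- parent[[cur]]
      if (cur %in% seen) stop("parent map contains a cycle")
      seen <- c(seen, cur)
    }
  }
  occ <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (h in intersect(names(occupancy), nodes))
    occ[[h]] <- sort(unique(occupancy[[h]]))
  children <- lapply(stats::setNames(nodes, nodes), function(x)
    sort(names(parent)[parent == x]))
  structure(list(root = root, parent = parent, children = children,
                 occupancy = occ, nodes = nodes),
            class = "rooted_genealogy")
}

#' Root a haplotype network at a chosen ancestral haplotype
#'
#' Orients the component containing `root` away from the root. The component
#' must be a tree (networks from [build_network()] always are); nodes outside
#' the component (e.g. a disconnected outgroup) are dropped.
#'
#' @param net a `haplotype_network`.
#' @param root haplotype label to use as hypothetical ancestral haplotype.
#' @param occupancy named list from [apply_island_units()]; haplotypes of the
#'   component missing from it get empty occupancy.
#' @return a `rooted_genealogy`.
#' @export
root_genealogy <- function(net, root, occupancy = NULL) {
  stopifnot(inherits(net, "haplotype_network"))
  if (!root %in% names(net$components))
    stop("root haplotype not in network: ", root)
  comp <- names(net$components)[net$components == net$components[root]]
  ed <- net$edges[net$edges$from %in% comp & net$edges$to %in% comp, , drop = FALSE]
  if (nrow(ed) != length(comp) - 1L)
    stop("component containing the root is not a tree; revise the connection limit or tie-breaks")
  adj <- stats::setNames(rep(list(character(0)), length(comp)), comp)
  for (e in seq_len(nrow(ed))) {
    adj[[ed$from[e]]] <- c(adj[[ed$from[e]]], ed$to[e])
    adj[[ed$to[e]]] <- c(adj[[ed$to[e]]], ed$from[e])
  }
  parent <- character(0)
  queue <- root
  visited <- root
  while (length(queue)) {
    x <- queue[1L]
    queue <- queue[-1L]
    for (nb in adj[[x]]) if (!(nb %in% visited)) {
      parent[nb] <- x
      visited <- c(visited, nb)
      queue <- c(queue, nb)
    }
  }
  occ <- if (is.null(occupancy)) net$occupancy[comp] else occupancy
  rooted_genealogy(root, parent, occ[intersect(names(occ), comp)])
}

# Dynamic program over the genealogy. For each haplotype x an origination
# unit o(x) is chosen: the root's origin must lie in its own occupancy (the
# arrival from outside the archipelago is never counted); a non-root
# haplotype originates where its parent is available, i.e. in
# occupancy(parent) or on the parent's own origination unit. A haplotype then
# pays one colonization event per occupied unit beyond its origination unit:
# cost(x, o) = |occupancy(x) union {o}| - 1. Haplotypes with empty occupancy
# (unsampled intermediates) cost nothing and pass on only their origin unit.
# h[x, o] = cost of x's subtree when x originates on o; ties among optimal
# origins are broken by unit name order.
#' Minimum number of inter-island colonization events
#'
#' Exact minimization over all origination-unit assignments consistent with
#' the rooted genealogy, by dynamic programming with the parent's origin as
#' state.
#'
#' @param gen a `rooted_genealogy` with unit occupancy attached; the root's
#'   occupancy must be non-empty.
#' @return an object of class `colonization_count`: list with `total`,
#'   `per_haplotype` (events attributed to each haplotype), and
#'   `origin_assignment` (an optimal origination unit per haplotype).
#' @export
count_min_events <- function(gen) {
  stopifnot(inherits(gen, "rooted_genealogy"))
  units <- sort(unique(unlist(gen$occupancy)))
  if (!length(gen$occupancy[[gen$root]]))
    stop("root haplotype has empty occupancy; choose a sampled root")
  nodes <- gen$nodes
  nu <- length(units)
  occ_idx <- lapply(gen$occupancy[nodes], function(u) match(u, units))
  names(occ_idx) <- nodes
  H <- matrix(NA_real_, nrow = length(nodes), ncol = nu,
              dimnames = list(nodes, units))
  # post-order: children before parents
  order_nodes <- character(0)
  stack <- gen$root
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_nodes <- c(x, order_nodes)
    stack <- c(stack, gen$children[[x]])
  }
  for (x in order_nodes) {
    ox <- occ_idx[[x]]
    kids <- gen$children[[x]]
    for (o in seq_len(nu)) {
      cost <- length(union(ox, o)) - 1L
      for (c_ in kids) {
        allowed <- sort(union(ox, o))
        cost <- cost + min(H[c_, allowed])
      }
      H[x, o] <- cost
    }
  }
  root_allowed <- sort(occ_idx[[gen$root]])
  total <- min(H[gen$root, root_allowed])
  # reconstruct origins, preferring the smallest unit name at every tie
  origin <- stats::setNames(character(length(nodes)), nodes)
  per_hap <- stats::setNames(numeric(length(nodes)), nodes)
  pick <- function(allowed, x) allowed[which.min(H[x, allowed])]
  o_root <- pick(root_allowed, gen$root)
  assign_down <- list(list(node = gen$root, o = o_root))
  while (length(assign_down)) {
    it <- assign_down[[1L]]
    assign_down <- assign_down[-1L]
    x <- it$node
    o <- it$o
    origin[x] <- units[o]
    per_hap[x] <- length(union(occ_idx[[x]], o)) - 1L
    allowed <- sort(union(occ_idx[[x]], o))
    for (c_ in gen$children[[x]])
      assign_down[[length(assign_down) + 1L]] <- list(node = c_, o = pick(allowed, c_))
  }
  structure(list(total = as.integer(total),
                 per_haplotype = per_hap,
                 origin_assignment = origin),
            class = "colonization_count")
}

#' @export
print.colonization_count <- function(x, ...) {
  cat(sprintf("minimum inter-island colonization events: %d\n", x$total))
  df <- data.frame(haplotype = names(x$per_haplotype),
                   events = as.integer(x$per_haplotype),
                   origin = x$origin_assignment)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Minimum events for every candidate root
#'
#' Repeats [count_min_events()] with each sampled ingroup haplotype as the
#' hypothetical ancestral haplotype (the sensitivity analysis used when the
#' outgroup cannot root the network) and reports the overall minimum.
#'
#' @param net a `haplotype_network`.
#' @param occupancy named list from [apply_island_units()].
#' @return list with `counts` (named list of `colonization_count`),
#'   `min_total`, and `best_roots` (roots achieving it).
#' @export
min_over_roots <- function(net, occupancy) {
  roots <- names(occupancy)[lengths(occupancy) > 0L]
  roots <- intersect(net$nodes$haplotype[net$nodes$ingroup], roots)
  if (!length(roots)) stop("no sampled ingroup haplotype to root at")
  counts <- lapply(stats::setNames(roots, roots), function(r)
    count_min_events(root_genealogy(net, r, occupancy)))
  totals <- vapply(counts, `[[`, 0L, "total")
  list(counts = counts, min_total = min(totals),
       best_roots = names(totals)[totals == min(totals)])
}
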