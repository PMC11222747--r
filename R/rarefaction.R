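#' Settings for rarefaction and asymptotic estimation
#'
#' @param ancestral hypothetical ancestral haplotype label; `NULL` uses the
#'   dataset's default (the top-ranked candidate, see
#'   [rank_ancestral_candidates()]).
#' @param seed master seed; every replicate derives its own stream from it.
#' @param replicates_multiplier replicates per sampling level (default 5, so a
#'   five-level genetic axis gets 25 replicates and a 36-level field axis 180).
#' @param del fraction of extreme replicate asymptotes removed before the
#'   point estimate and confidence interval (default 0.05, split across tails).
#' @param level confidence-interval coverage (default 0.95).
#' @param method `"fallback"` fits a straight line (infinite asymptote) when
#'   the saturating model cannot be fitted; `"strict"` reports such fits as
#'   non-converged.
#' @param swap_nesting reverse the inner/outer axis roles of the
#'   two-dimensional correction (see the methods vignette).
#' @return an object of class `rarefaction_settings`.
#' @export
rarefaction_settings <- function(ancestral = NULL, seed = 1L,
                                 replicates_multiplier = 5L,
                                 del = 0.05, level = 0.95,
                                 method = c("fallback", "strict"),
                                 swap_nesting = FALSE) {
  method <- match.arg(method)
  stopifnot(replicates_multiplier >= 1L, del >= 0, del < 1,
            level > 0, level < 1)
  structure(list(ancestral = ancestral, seed = as.integer(seed),
                 replicates_multiplier = as.integer(replicates_multiplier),
                 del = del, level = level, method = method,
                 swap_nesting = isTRUE(swap_nesting)),
            class = "rarefaction_settings")
}

#' Prepare a dataset for colonization rarefaction
#'
#' Precomputes everything the resampling engine needs: the ingroup haplotype
#' table over the characters variable within the ingroup, the haplotype
#' network, unit occupancy, the per-individual state matrix restricted to the
#' analysis scope (archipelago individuals on non-excluded islands), and the
#' full-data minimum event count.
#'
#' @param samples a `sample_set`.
#' @param cfg an [island_unit_config()].
#' @param blocks recode blocks (see [concatenate_and_recode()]).
#' @param ancestral default ancestral haplotype; `NULL` picks the top-ranked
#'   candidate.
#' @param limit connection limit; `NULL` computes it with
#'   [parsimony_connection_limit()] at `alpha`.
#' @param alpha confidence for the computed connection limit.
#' @return an object of class `colonization_data`.
#' @export
colonization_data <- function(samples, cfg, blocks = NULL, ancestral = NULL,
                              limit = NULL, alpha = 0.95) {
  stopifnot(inherits(samples, "sample_set"), inherits(cfg, "island_unit_config"))
  cm <- concatenate_and_recode(samples, blocks)
  meta <- samples$meta
  ingroup_ids <- meta$individual_id[meta$region != "outgroup"]
  varchars <- extract_variable_characters(cm, ingroup_ids)
  ht <- collapse_haplotypes(cm, ingroup_ids, varchars)
  if (is.null(limit)) limit <- parsimony_connection_limit(ncol(cm$states), alpha)
  net <- build_network(pairwise_steps(ht), limit, ht)
  occupancy <- apply_island_units(ht, cfg)
  if (is.null(ancestral)) ancestral <- rank_ancestral_candidates(net)[1L]
  if (!ancestral %in% ht$labels) stop("ancestral haplotype not found: ", ancestral)

  excl <- cfg$exclusions
  keep <- meta$region != "outgroup" & !(meta$island %in% excl)
  units_all <- cfg$merges[meta$island[keep]]
  keep2 <- !(units_all %in% excl)
  ids <- meta$individual_id[keep][keep2]
  unit <- unname(units_all[keep2])
  pop <- meta$population_id[keep][keep2]
  V <- cm$states[ids, varchars, drop = FALSE]
  rows_by_pop <- split(seq_along(ids), pop)
  hap_rows <- lapply(ht$members, function(m) which(ids %in% m))
  cd <- structure(list(cm = cm, ht = ht, net = net, occupancy = occupancy,
                       limit = as.integer(limit), varchars = varchars,
                       ids = ids, unit = unit, pop = pop, V = V,
                       rows_by_pop = rows_by_pop, hap_rows = hap_rows,
                       pop_ids = sort(names(rows_by_pop)),
                       G = length(varchars), P = length(rows_by_pop),
                       ancestral = ancestral, cfg = cfg),
                  class = "colonization_data")
  cd$full_min <- count_events_sub(cd, seq_along(ids), seq_len(cd$G),
                                  root_spec(cd, ancestral))
  cd
}

#' @export
print.colonization_data <- function(x, ...) {
  cat(sprintf(paste0("colonization_data: %d individuals, %d populations, ",
                     "%d variable characters, %d haplotypes\n",
                     "ancestral: %s; full-data minimum events: %d\n"),
              length(x$ids), x$P, x$G, length(x$ht$labels),
              x$ancestral, x$full_min))
  invisible(x)
}

# Root lookup used under subsampling: the class containing the ancestral
# haplotype's retained members inherits the root role; if none are retained,
# the nearest haplotype on the full genealogy with retained members is used
# (ties: higher frequency, then label).
root_spec <- function(cd, ancestral) {
  if (!ancestral %in% cd$ht$labels) stop("ancestral haplotype not found: ", ancestral)
  comp <- names(cd$net$components)[cd$net$components == cd$net$components[ancestral]]
  depth <- stats::setNames(rep(NA_integer_, length(comp)), comp)
  depth[ancestral] <- 0L
  queue <- ancestral
  ed <- cd$net$edges
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    nb <- c(ed$to[ed$from == x], ed$from[ed$to == x])
    new <- nb[is.na(depth[nb])]
    depth[new] <- depth[x] + 1L
    queue <- c(queue, new)
  }
  pri <- comp[order(depth[comp], -cd$ht$n[comp], comp)]
  list(anc_rows = cd$hap_rows[[ancestral]],
       priority = pri)
}

# Minimum-events count on a subsample: rows (indices into cd$ids) and chars
# (indices into the variable characters). Re-collapses haplotypes, rebuilds
# the genealogy (no connection limit: subsampling only removes information,
# and an artificial disconnection would leave the count undefined), maps the
# root, and runs the dynamic program.
count_events_sub <- function(cd, rows, chars, rs) {
  uu <- unique(cd$unit[rows])
  if (length(uu) <= 1L) return(0L)
  if (!length(chars)) return(length(uu) - 1L)
  cp <- suppressWarnings(collapse_patterns(cd$V[rows, chars, drop = FALSE]))
  k <- nrow(cp$states)
  if (k == 1L) return(length(uu) - 1L)
  units <- sort(uu)
  uidx <- match(cd$unit[rows], units)
  occ <- lapply(seq_len(k), function(i) sort(unique(uidx[cp$assign == i])))
  # root class: ancestral members if retained, else nearest retained haplotype
  anc_in <- rs$anc_rows[match(TRUE, rs$anc_rows %in% rows)]
  if (!is.na(anc_in)) {
    rc <- cp$assign[match(anc_in, rows)]
  } else {
    rc <- NA_integer_
    for (h in rs$priority) {
      hr <- cd$hap_rows[[h]]
      hit <- hr[match(TRUE, hr %in% rows)]
      if (!is.na(hit)) { rc <- cp$assign[match(hit, rows)]; break }
    }
    if (is.na(rc)) stop("no retained haplotype to root at")
  }
  # pairwise conflicts between class state vectors
  S <- cp$states
  D <- matrix(0L, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    both <- !is.na(S[i, ]) & !is.na(S[j, ])
    D[i, j] <- D[j, i] <- sum(S[i, both] != S[j, both])
  }
  # deterministic Kruskal spanning tree
  pr <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[pr], pr[, 1L], pr[, 2L])
  pr <- pr[ord, , drop = FALSE]
  parent <- seq_len(k)
  adj <- rep(list(integer(0)), k)
  kept <- 0L
  for (e in seq_len(nrow(pr))) {
    a <- uf_find(parent, pr[e, 1L]); b <- uf_find(parent, pr[e, 2L])
    if (a != b) {
      parent[a] <- b
      adj[[pr[e, 1L]]] <- c(adj[[pr[e, 1L]]], pr[e, 2L])
      adj[[pr[e, 2L]]] <- c(adj[[pr[e, 2L]]], pr[e, 1L])
      kept <- kept + 1L
      if (kept == k - 1L) break
    }
  }
  # orient at the root class
  kids <- rep(list(integer(0)), k)
  ord_nodes <- integer(k)
  ord_nodes[1L] <- rc
  seen <- logical(k); seen[rc] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    x <- ord_nodes[head]
    for (nb in adj[[x]]) if (!seen[nb]) {
      seen[nb] <- TRUE
      kids[[x]] <- c(kids[[x]], nb)
      tail <- tail + 1L
      ord_nodes[tail] <- nb
    }
    head <- head + 1L
  }
  # DP over parent-origin state, children before parents
  nu <- length(units)
  H <- matrix(0, k, nu)
  for (x in rev(ord_nodes)) {
    ox <- occ[[x]]
    cs <- kids[[x]]
    for (o in seq_len(nu)) {
      inx <- o %in% ox
      cost <- length(ox) - inx
      if (length(cs)) {
        allowed <- if (inx) ox else c(ox, o)
        for (cc in cs) cost <- cost + min(H[cc, allowed])
      }
      H[x, o] <- cost
    }
  }
  as.integer(min(H[rc, occ[[rc]]]))
}

#' Subsample field effort (populations)
#'
#' Keeps a uniform sample of `f` archipelago populations without replacement,
#' with all their individuals; mainland and outgroup records are retained
#' unchanged. Uses the current RNG state, so results are reproducible under
#' `set.seed()`.
#'
#' @param samples a `sample_set`.
#' @param f number of archipelago populations to keep, `1 <= f <= P`.
#' @return a `sample_set` restricted to the subsample.
#' @export
subsample_field <- function(samples, f) {
  stopifnot(inherits(samples, "sample_set"))
  meta <- samples$meta
  pops <- sort(unique(meta$population_id[meta$region == "archipelago"]))
  if (f < 1L || f > length(pops))
    stop(sprintf("f must be between 1 and %d", length(pops)))
  keep_pops <- pops[sample.int(length(pops), f)]
  keep <- meta$region != "archipelago" | meta$population_id %in% keep_pops
  new_sample_set(meta[keep, , drop = FALSE],
                 lapply(samples$seqs, function(m) m[meta$individual_id[keep], , drop = FALSE]))
}

#' Subsample genetic effort (variable characters)
#'
#' Uniform subset of `g` characters without replacement; `g = 0` returns the
#' empty set (the species is treated as a single haplotype). Uses the current
#' RNG state.
#'
#' @param characters vector of character indices.
#' @param g subset size, `0 <= g <= length(characters)`.
#' @return integer vector of `g` character indices, ascending.
#' @export
subsample_genetic <- function(characters, g) {
  if (g < 0L || g > length(characters))
    stop(sprintf("g must be between 0 and %d", length(characters)))
  sort(characters[sample.int(length(characters), g)])
}

derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Rarefaction curves of colonization events
#'
#' For each replicate, the chosen axis is accumulated in a nested random
#' order (so curves are nondecreasing within a replicate) while the other
#' axis stays at full sampling; at every level the haplotypes are
#' re-collapsed, the genealogy rebuilt and re-rooted, and the minimum event
#' count recomputed. The genetic axis has levels `0..G` (level 0 = no genetic
#' information: one haplotype, events = occupied units - 1); the field axis
#' has levels `1..P`. Replicates = `replicates_multiplier` times the number
#' of levels.
#'
#' @param data a `colonization_data`.
#' @param axis `"genetic"` or `"field"`.
#' @param settings a [rarefaction_settings()].
#' @return data frame with columns axis, replicate, level, value.
#' @export
rarefaction_curves <- function(data, axis = c("genetic", "field"),
                               settings = rarefaction_settings()) {
  stopifnot(inherits(data, "colonization_data"))
  axis <- match.arg(axis)
  anc <- if (is.null(settings$ancestral)) data$ancestral else settings$ancestral
  rs <- root_spec(data, anc)
  all_rows <- seq_along(data$ids)
  if (axis == "genetic") {
    levels <- 0L:data$G
  } else {
    levels <- seq_len(data$P)
  }
  R <- settings$replicates_multiplier * length(levels)
  seeds <- derive_seeds(settings$seed, R)
  out <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    if (axis == "genetic") {
      perm <- sample.int(data$G)
      vals <- vapply(levels, function(g)
        count_events_sub(data, all_rows, sort(perm[seq_len(g)]), rs), 0L)
    } else {
      perm <- data$pop_ids[sample.int(data$P)]
      rows <- integer(0)
      vals <- integer(length(levels))
      for (f in levels) {
        rows <- c(rows, data$rows_by_pop[[perm[f]]])
        vals[f] <- count_events_sub(data, rows, seq_len(data$G), rs)
      }
    }
    out[[r]] <- data.frame(axis = axis, replicate = r, level = levels,
                           value = vals)
  }
  do.call(rbind, out)
}

#' Fit an accumulation curve and extract its asymptote
#'
#' Least-squares fit of the saturating two-parameter (Clench-type) model
#' `value(x) = a x / (1 + b x)`, whose asymptote is `a/b`. When the fit fails
#' or yields `b <= 0` — a curve with no detectable curvature — the
#' `"fallback"` method fits the one-parameter line through the origin
#' `value(x) = a x` and reports an infinite asymptote; `"strict"` reports a
#' non-converged fit instead. An all-zero curve has asymptote 0; a constant
#' positive curve is the saturated limit of the model and returns that
#' constant.
#'
#' @param x sampling levels (at least two distinct).
#' @param y colonization counts at each level (finite).
#' @param method `"fallback"` or `"strict"`.
#' @return an object of class `accumulation_fit`: list with `model`
#'   (`"saturating"` or `"linear"`), `a`, `b`, `asymptote`, `converged`.
#' @export
fit_accumulation <- function(x, y, method = c("fallback", "strict")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(unique(x)) >= 2L, all(is.finite(y)))
  if (all(y == 0))
    return(structure(list(model = "saturating", a = 0, b = NA_real_,
                          asymptote = 0, converged = TRUE),
                     class = "accumulation_fit"))
  if (length(unique(y)) == 1L)  # saturated limit: a = c*b, b -> large
    return(structure(list(model = "saturating", a = NA_real_, b = NA_real_,
                          asymptote = y[1L], converged = TRUE),
                     class = "accumulation_fit"))
  i1 <- which(y > 0)[1L]
  a0 <- y[i1] / x[i1]
  b0 <- a0 / max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x / (1 + b * x),
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf[["b"]]) && cf[["b"]] > 0 && cf[["a"]] > 0)
      return(structure(list(model = "saturating", a = unname(cf[["a"]]),
                            b = unname(cf[["b"]]),
                            asymptote = unname(cf[["a"]] / cf[["b"]]),
                            converged = TRUE),
                       class = "accumulation_fit"))
  }
  if (method == "fallback") {
    a_lin <- sum(x * y) / sum(x * x)
    structure(list(model = "linear", a = a_lin, b = 0,
                   asymptote = Inf, converged = TRUE),
              class = "accumulation_fit")
  } else {
    structure(list(model = "saturating", a = NA_real_, b = NA_real_,
                   asymptote = NA_real_, converged = FALSE),
              class = "accumulation_fit")
  }
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat(sprintf("accumulation_fit: model %s, asymptote %s (a=%.4g, b=%.4g)\n",
              x$model, format(x$asymptote), x$a, x$b))
  invisible(x)
}

# Trimmed pooling of replicate asymptotes: drop the del fraction of extremes
# (split across tails, low tail rounded down), then take the mean of the
# finite retained values and type-1 empirical quantiles (infinite asymptotes
# sort above every finite value). Status is undetermined when fewer than half
# of the retained fits are finite.
pool_asymptotes <- function(values, del, level) {
  R <- length(values)
  xs <- sort(values, na.last = TRUE)
  xs[is.na(xs)] <- Inf
  k <- round(R * del)
  k_lo <- floor(k / 2)
  k_hi <- k - k_lo
  retained <- xs[seq.int(k_lo + 1L, R - k_hi)]
  m <- length(retained)
  finite <- is.finite(retained)
  n_finite <- sum(finite)
  q <- (1 - level) / 2
  ci <- c(retained[max(1L, ceiling(q * m))],
          retained[min(m, ceiling((1 - q) * m))])
  ok <- n_finite >= m / 2
  list(point = if (ok) mean(retained[finite]) else NA_real_,
       ci_low = ci[1L], ci_high = ci[2L],
       status = if (ok) "ok" else "undetermined",
       n_finite_fits = n_finite, n_retained = m)
}

# One two-dimensional estimator: the outer axis is accumulated and fitted
# through values already corrected along the inner axis (each inner value is
# the asymptote of an inner-axis accumulation at that outer level). One
# asymptote per outer replicate; genetic levels are indexed 1..G+1 for
# fitting so that level 0 (no genetic information) sits at x = 1.
two_dim_estimate <- function(cd, outer, settings, rs) {
  G <- cd$G; P <- cd$P
  all_rows <- seq_along(cd$ids)
  n_levels <- if (outer == "genetic") G + 1L else P
  R <- settings$replicates_multiplier * n_levels
  seeds <- derive_seeds(settings$seed + if (outer == "genetic") 1L else 2L, R)
  asym <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    corrected <- numeric(n_levels)
    if (outer == "genetic") {
      perm_chars <- sample.int(G)
      for (g in 0L:G) {
        chars <- sort(perm_chars[seq_len(g)])
        perm_pops <- cd$pop_ids[sample.int(P)]
        rows <- integer(0)
        yv <- integer(P)
        for (f in seq_len(P)) {
          rows <- c(rows, cd$rows_by_pop[[perm_pops[f]]])
          yv[f] <- count_events_sub(cd, rows, chars, rs)
        }
        corrected[g + 1L] <- fit_accumulation(seq_len(P), yv, settings$method)$asymptote
      }
      xs <- seq_len(G + 1L)
    } else {
      perm_pops <- cd$pop_ids[sample.int(P)]
      rows <- integer(0)
      for (f in seq_len(P)) {
        rows <- c(rows, cd$rows_by_pop[[perm_pops[f]]])
        perm_chars <- sample.int(G)
        yv <- integer(G + 1L)
        for (g in 0L:G)
          yv[g + 1L] <- count_events_sub(cd, rows, sort(perm_chars[seq_len(g)]), rs)
        corrected[f] <- fit_accumulation(seq_len(G + 1L), yv, settings$method)$asymptote
      }
      xs <- seq_len(P)
    }
    if (all(is.finite(corrected))) {
      asym[r] <- fit_accumulation(xs, corrected, settings$method)$asymptote
    } else {
      asym[r] <- Inf  # inner axis already unbounded at some outer level
    }
  }
  asym
}

#' Sampling-effort-corrected colonization estimates
#'
#' Two-dimensional rarefaction: the genetic estimator corrects field sampling
#' inside each genetic level (the corrected value at a genetic level is the
#' asymptote of the field-axis accumulation at that character subset) and then
#' fits the genetic-axis accumulation through the corrected values, one
#' asymptote per replicate; the field estimator swaps the axes. Replicate
#' asymptotes are pooled with trimming (see `del`), giving a point estimate
#' (mean of the finite retained values), an empirical confidence interval
#' whose upper bound may be infinite, and a status that is `"undetermined"`
#' when fewer than half the retained fits are finite — the operational form
#' of "impossible to calculate".
#'
#' @param data a `colonization_data`.
#' @param settings a [rarefaction_settings()].
#' @param estimators which estimators to compute (both by default).
#' @return list of class `colonization_estimate` with elements `genetic`
#'   and/or `field`, each a list: estimator, point, ci_low, ci_high, status,
#'   n_finite_fits, n_retained, n_replicates, asymptotes.
#' @export
estimate_colonization <- function(data, settings = rarefaction_settings(),
                                  estimators = c("genetic", "field")) {
  stopifnot(inherits(data, "colonization_data"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  anc <- if (is.null(settings$ancestral)) data$ancestral else settings$ancestral
  rs <- root_spec(data, anc)
  mk <- function(outer, label) {
    a <- two_dim_estimate(data, outer, settings, rs)
    res <- pool_asymptotes(a, settings$del, settings$level)
    c(list(estimator = label, ancestral = anc), res,
      list(n_replicates = length(a), asymptotes = a))
  }
  out <- list()
  if ("genetic" %in% estimators)
    out$genetic <- mk(if (settings$swap_nesting) "field" else "genetic", "genetic")
  if ("field" %in% estimators)
    out$field <- mk(if (settings$swap_nesting) "genetic" else "field", "field")
  structure(out, class = "colonization_estimate")
}

#' @export
print.colonization_estimate <- function(x, ...) {
  for (e in x) {
    cat(sprintf("%s estimator (ancestral %s): ", e$estimator, e$ancestral))
    if (e$status == "ok") {
      cat(sprintf("%.1f (CI %.1f-%s), %d/%d finite fits\n",
                  e$point, e$ci_low,
                  ifelse(is.finite(e$ci_high), sprintf("%.1f", e$ci_high), "Inf"),
                  e$n_finite_fits, e$n_retained))
    } else {
      cat(sprintf("undetermined (%d/%d finite fits)\n",
                  e$n_finite_fits, e$n_retained))
    }
  }
  invisible(x)
}
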