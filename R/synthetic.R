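#' Parameters for simulated colonization histories
#'
#' Defaults mirror the scale of a small-archipelago plastid study: a handful
#' of island units, a few haplotypes in a shallow genealogy, populations of at
#' most five sampled individuals.
#'
#' @param n_units number of island units.
#' @param n_haplotypes number of ingroup haplotypes.
#' @param units_per_haplotype number of units each haplotype ends up
#'   occupying (recycled); capped at `n_units`.
#' @param populations_per_unit sampled populations on each occupied unit.
#' @param individuals_per_population individuals sampled per population
#'   (up to five mimics the field design emulated here).
#' @param locus_lengths named integer vector of aligned locus lengths.
#' @param n_variable_sites variable alignment sites carrying the genealogy's
#'   mutations; must be at least `n_haplotypes - 1`.
#' @param n_outgroup outgroup sequences to emit (0 for none).
#' @param outgroup_distance mutational steps separating the outgroup from the
#'   ingroup (placed on sites that are invariant within the ingroup).
#' @param seed integer seed making the whole generation deterministic.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_units = 5L, n_haplotypes = 4L,
                              units_per_haplotype = 2L,
                              populations_per_unit = 4L,
                              individuals_per_population = 5L,
                              locus_lengths = c(locus1 = 400L, locus2 = 350L),
                              n_variable_sites = max(n_haplotypes - 1L, 1L),
                              n_outgroup = 0L,
                              outgroup_distance = 30L,
                              seed = 1L) {
  stopifnot(n_units >= 1L, n_haplotypes >= 1L,
            all(units_per_haplotype >= 1L),
            populations_per_unit >= 1L, individuals_per_population >= 1L,
            n_variable_sites >= n_haplotypes - 1L,
            sum(locus_lengths) >= n_variable_sites + outgroup_distance + 2L)
  structure(list(n_units = as.integer(n_units),
                 n_haplotypes = as.integer(n_haplotypes),
                 units_per_haplotype = pmin(as.integer(units_per_haplotype),
                                            as.integer(n_units)),
                 populations_per_unit = as.integer(populations_per_unit),
                 individuals_per_population = as.integer(individuals_per_population),
                 locus_lengths = locus_lengths,
                 n_variable_sites = as.integer(n_variable_sites),
                 n_outgroup = as.integer(n_outgroup),
                 outgroup_distance = as.integer(outgroup_distance),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a haplotype genealogy with a known colonization history
#'
#' A random rooted tree over haplotypes (uniform attachment); the root
#' originates on a uniform unit, every other haplotype on a unit its parent
#' already occupies (mutation requires the parent present, and costs no
#' dispersal). Each haplotype then spreads to further distinct units through
#' explicit colonization events, recorded in order, so the true inter-island
#' event count is known exactly.
#'
#' @param params a [simulation_params()].
#' @return an object of class `truth_history`: list with `parent` (integer
#'   vector, 0 for the root), `origin`, `occupancy` (unit names per
#'   haplotype), `events` (data frame haplotype/source/target),
#'   `true_event_count`, `units`, `params`.
#' @export
simulate_history <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  H <- params$n_haplotypes
  units <- sprintf("U%02d", seq_len(params$n_units))
  k <- rep_len(params$units_per_haplotype, H)
  parent <- integer(H)  # 0 = root
  if (H > 1L) for (i in 2L:H) parent[i] <- sample.int(i - 1L, 1L)
  occupancy <- vector("list", H)
  origin <- character(H)
  events <- list()
  for (x in seq_len(H)) {
    origin[x] <- if (parent[x] == 0L) {
      units[sample.int(length(units), 1L)]
    } else {
      occ_p <- occupancy[[parent[x]]]
      occ_p[sample.int(length(occ_p), 1L)]
    }
    occ <- origin[x]
    while (length(occ) < k[x]) {
      free <- setdiff(units, occ)
      if (!length(free)) break
      target <- free[sample.int(length(free), 1L)]
      source <- occ[sample.int(length(occ), 1L)]
      events[[length(events) + 1L]] <-
        data.frame(haplotype = x, source = source, target = target)
      occ <- c(occ, target)
    }
    occupancy[[x]] <- occ
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(haplotype = integer(0), source = character(0), target = character(0))
  structure(list(parent = parent, origin = origin,
                 occupancy = lapply(occupancy, sort),
                 events = events, true_event_count = nrow(events),
                 units = units, params = params),
            class = "truth_history")
}

#' Materialize a simulated history as a sample set
#'
#' Sequences are built by placing one substitution per genealogy edge on a
#' distinct variable site (extra variable sites beyond the edges repeat an
#' existing edge's split, i.e. parallel change); the remaining columns are an
#' invariant random background. Populations are laid on every occupied unit
#' and individuals drawn uniformly among the haplotypes present there.
#' Outgroup sequences, if requested, differ from the root haplotype at
#' `outgroup_distance` background sites (the second outgroup at one site
#' more).
#'
#' @param truth a `truth_history`.
#' @param params the same [simulation_params()] used to simulate it.
#' @return a list: `samples` (a `sample_set`), `haplotype_of` (named vector,
#'   individual -> simulated haplotype index), `sites` (variable site columns
#'   used).
#' @export
realize_dataset <- function(truth, params = truth$params) {
  set.seed(params$seed + 1L)
  H <- params$n_haplotypes
  n_edges <- sum(truth$parent > 0L)
  if (params$n_variable_sites < n_edges)
    stop("n_variable_sites too small for the genealogy's edges")
  total <- sum(params$locus_lengths)
  base <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  sites <- sort(sample.int(total, params$n_variable_sites +
                             params$n_outgroup * params$outgroup_distance + 2L))
  var_sites <- sites[seq_len(params$n_variable_sites)]
  out_sites <- setdiff(sites, var_sites)
  seqs <- matrix(rep(base, H), nrow = H, byrow = TRUE)
  alt <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
  # one substitution per edge on its own site; descendants inherit it
  edge_nodes <- which(truth$parent > 0L)
  desc <- function(x) {
    out <- x
    kids <- which(truth$parent == x)
    for (kk in kids) out <- c(out, desc(kk))
    out
  }
  for (i in seq_along(edge_nodes)) {
    s <- var_sites[i]
    seqs[desc(edge_nodes[i]), s] <- alt(base[s])
  }
  extra <- params$n_variable_sites - n_edges
  if (extra > 0L && n_edges > 0L) for (j in seq_len(extra)) {
    s <- var_sites[n_edges + j]
    e <- edge_nodes[((j - 1L) %% n_edges) + 1L]
    seqs[desc(e), s] <- alt(base[s])
  }
  # sampling design
  meta <- list()
  hap_of <- character(0)
  rows <- list()
  pop_no <- 0L
  for (u in truth$units) {
    here <- which(vapply(truth$occupancy, function(o) u %in% o, TRUE))
    if (!length(here)) next
    for (p in seq_len(params$populations_per_unit)) {
      pop_no <- pop_no + 1L
      pid <- sprintf("P%03d", pop_no)
      for (i in seq_len(params$individuals_per_population)) {
        hap <- here[sample.int(length(here), 1L)]
        iid <- sprintf("%s-%d", pid, i)
        meta[[length(meta) + 1L]] <-
          data.frame(individual_id = iid, population_id = pid,
                     island = u, region = "archipelago")
        rows[[length(rows) + 1L]] <- seqs[hap, ]
        hap_of[iid] <- hap
      }
    }
  }
  if (params$n_outgroup > 0L) {
    og <- matrix(rep(base, params$n_outgroup), nrow = params$n_outgroup, byrow = TRUE)
    flip <- out_sites[seq_len(params$outgroup_distance)]
    for (o in seq_len(params$n_outgroup)) {
      og[o, flip] <- vapply(base[flip], alt, "")
      if (o > 1L) {
        s2 <- out_sites[params$outgroup_distance + o - 1L]
        og[o, s2] <- alt(base[s2])
      }
      iid <- sprintf("OUT-%d", o)
      meta[[length(meta) + 1L]] <-
        data.frame(individual_id = iid, population_id = "OUT",
                   island = "outgroup", region = "outgroup")
      rows[[length(rows) + 1L]] <- og[o, ]
      hap_of[iid] <- NA
    }
  }
  meta <- do.call(rbind, meta)
  allseq <- do.call(rbind, rows)
  rownames(allseq) <- meta$individual_id
  seqs_by_locus <- list()
  off <- 0L
  for (locus in names(params$locus_lengths)) {
    L <- params$locus_lengths[[locus]]
    seqs_by_locus[[locus]] <- allseq[, off + seq_len(L), drop = FALSE]
    off <- off + L
  }
  list(samples = new_sample_set(meta, seqs_by_locus),
       haplotype_of = hap_of, sites = var_sites)
}

#' Write a simulated dataset to FASTA + metadata files
#'
#' @param truth a `truth_history`.
#' @param params its [simulation_params()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (one FASTA per locus, `metadata`).
#' @export
emit_dataset <- function(truth, params = truth$params, dir = tempfile("simdata")) {
  rd <- realize_dataset(truth, params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (locus in names(rd$samples$seqs)) {
    p <- file.path(dir, paste0(locus, ".fasta"))
    write_fasta_matrix(rd$samples$seqs[[locus]], p)
    paths[[locus]] <- p
  }
  meta_path <- file.path(dir, "samples.tsv")
  utils::write.table(rd$samples$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$metadata <- meta_path
  paths
}

write_fasta_matrix <- function(m, path) {
  dna <- ape::as.DNAbin(tolower(m))
  ape::write.FASTA(dna, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Fixed Astydamia-like fixture ------------------------------------------------

# Per-island haplotype composition. n/h/ph/H per island match the published
# per-island totals exactly (the count multisets are the partitions those
# totals force); the assignment of counts to haplotype labels within islands
# is a documented stand-in, as is the per-population composition. 36
# archipelago populations (Tenerife holds 8; see the methods vignette).
astydamia_layout <- function() {
  list(
    # island, region, pop sizes, haplotype counts (named by lineage tag)
    list(island = "Morocco", region = "mainland", prefix = "MO",
         pops = c(3L), counts = c(B = 3L)),
    list(island = "Lanzarote", region = "archipelago", prefix = "LZ",
         pops = c(5L, 5L), counts = c(B = 10L)),
    list(island = "Fuerteventura", region = "archipelago", prefix = "FV",
         pops = c(3L), counts = c(B = 3L)),
    list(island = "Gran Canaria", region = "archipelago", prefix = "GC",
         pops = c(rep(5L, 9L), 4L, 3L), counts = c(Cgc = 38L, A = 9L, B = 5L)),
    list(island = "Tenerife", region = "archipelago", prefix = "TF",
         pops = c(rep(5L, 7L), 2L), counts = c(A = 26L, Dtl = 10L, B = 1L)),
    list(island = "La Gomera", region = "archipelago", prefix = "LG",
         pops = c(5L, 5L, 4L), counts = c(Dtl = 8L, B = 5L, A = 1L)),
    list(island = "La Palma", region = "archipelago", prefix = "LP",
         pops = c(4L, rep(3L, 7L)), counts = c(A = 25L)),
    list(island = "El Hierro", region = "archipelago", prefix = "EH",
         pops = c(5L, 5L, 4L), counts = c(B = 12L, A = 2L))
  )
}

#' Island-unit configuration for the Astydamia-like fixture
#'
#' Lanzarote and Fuerteventura merge into the paleoisland Mahan; the mainland
#' (Morocco) population is excluded from colonization counting.
#'
#' @return an [island_unit_config()].
#' @export
astydamia_config <- function() {
  island_unit_config(
    merges = c(Lanzarote = "Mahan", Fuerteventura = "Mahan",
               "Gran Canaria" = "Gran Canaria", Tenerife = "Tenerife",
               "La Gomera" = "La Gomera", "La Palma" = "La Palma",
               "El Hierro" = "El Hierro", Morocco = "Morocco"),
    exclusions = "Morocco")
}

#' Fixed Astydamia-like dataset
#'
#' A deterministic two-locus dataset (792 + 705 aligned columns) with 158
#' ingroup individuals in 36 archipelago populations (at most five individuals
#' each) plus one mainland population and two distant outgroup sequences. Four
#' ingroup lineages form a star around the widespread central haplotype: a
#' 3-bp inversion (locus 1, positions 133-135, to be recoded as one step),
#' two substitutions, and an indel column at which the central haplotype
#' carries a gap — four ingroup-variable characters but three single-step
#' spokes. Island-level haplotype counts reproduce the published per-island
#' n/h/ph/H exactly.
#'
#' @param dir output directory (created).
#' @return list with `fasta` (named paths), `metadata`, `manifest` (path to a
#'   JSON manifest of expected statistics), `blocks` (the inversion recode
#'   block), `cfg` ([astydamia_config()]), and `dir`.
#' @export
astydamia_fixture <- function(dir = tempfile("astydamia")) {
  set.seed(1497L)
  lens <- c("psaI-aacD" = 792L, "psbK-trnS" = 705L)
  total <- sum(lens)
  base <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  inv <- 133:135
  snp_bc <- 450L    # locus 1: central haplotype vs Gran Canaria lineage
  snp_bd <- 992L    # locus 2 col 200: central vs Tenerife/La Gomera lineage
  indel <- 1292L    # locus 2 col 500: gap in the central haplotype
  base[inv] <- c("T", "A", "C")
  base[snp_bc] <- "G"
  base[snp_bd] <- "C"
  base[indel] <- "T"

  hap_seq <- list()
  hap_seq$B <- base
  hap_seq$B[indel] <- "-"
  hap_seq$A <- base
  hap_seq$A[inv] <- rev(base[inv])          # the recoded inversion
  hap_seq$Cgc <- base
  hap_seq$Cgc[snp_bc] <- "A"
  hap_seq$Cgc[indel] <- "G"
  hap_seq$Dtl <- base
  hap_seq$Dtl[snp_bd] <- "T"

  # outgroup: far beyond any plausible connection limit
  bg <- setdiff(seq_len(total), c(inv, snp_bc, snp_bd, indel))
  flip <- sort(sample(bg, 31L))
  alt <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
  out1 <- base
  out1[flip[1:30]] <- vapply(base[flip[1:30]], alt, "")
  out2 <- out1
  out2[flip[31]] <- alt(base[flip[31]])

  meta <- list()
  seq_rows <- list()
  for (isl in astydamia_layout()) {
    # deal haplotypes into populations in a fixed order
    deal <- rep(names(isl$counts), times = isl$counts)
    at <- 0L
    for (p in seq_along(isl$pops)) {
      pid <- sprintf("%s-%02d", isl$prefix, p)
      for (i in seq_len(isl$pops[p])) {
        at <- at + 1L
        iid <- sprintf("%s-%d", pid, i)
        meta[[length(meta) + 1L]] <-
          data.frame(individual_id = iid, population_id = pid,
                     island = isl$island, region = isl$region)
        seq_rows[[iid]] <- hap_seq[[deal[at]]]
      }
    }
    stopifnot(at == sum(isl$counts))
  }
  for (o in 1:2) {
    iid <- sprintf("OUT-%d", o)
    meta[[length(meta) + 1L]] <-
      data.frame(individual_id = iid, population_id = "OUT",
                 island = "outgroup", region = "outgroup")
    seq_rows[[iid]] <- if (o == 1L) out1 else out2
  }
  meta <- do.call(rbind, meta)
  allseq <- do.call(rbind, seq_rows)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- character(0)
  off <- 0L
  for (locus in names(lens)) {
    p <- file.path(dir, paste0(locus, ".fasta"))
    write_fasta_matrix(allseq[, off + seq_len(lens[[locus]]), drop = FALSE], p)
    fasta[locus] <- p
    off <- off + lens[[locus]]
  }
  meta_path <- file.path(dir, "samples.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    n_ingroup = 158L,
    n_archipelago_populations = 36L,
    n_ingroup_haplotypes = 4L,
    n_variable_characters_ingroup = 4L,
    minimum_events = 9L,
    expected_H = list(Morocco = 0, Mahan = 0, "Gran Canaria" = 0.435,
                      Tenerife = 0.444, "La Gomera" = 0.582,
                      "La Palma" = 0, "El Hierro" = 0.264),
    expected_h = list(Morocco = 1L, Mahan = 1L, "Gran Canaria" = 3L,
                      Tenerife = 3L, "La Gomera" = 3L,
                      "La Palma" = 1L, "El Hierro" = 2L))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  list(fasta = fasta, metadata = meta_path, manifest = manifest_path,
       blocks = recode_block("psaI-aacD", 133L, 135L),
       cfg = astydamia_config(), dir = dir)
}
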