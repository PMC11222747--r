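# The fixed Astydamia-like dataset is expensive enough to build once and
# share across test files.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    fx <- astydamia_fixture(file.path(tempdir(), "astydamia-fixture"))
    ss <- read_sample_set(fx$fasta, fx$metadata)
    cm <- concatenate_and_recode(ss, fx$blocks)
    .fixture_cache$fx <- list(
      fx = fx, ss = ss, cm = cm,
      ingroup = ss$meta$individual_id[ss$meta$region != "outgroup"])
  }
  .fixture_cache$fx
}

get_fixture_analysis <- function() {
  if (is.null(.fixture_cache$res)) {
    f <- get_fixture()
    .fixture_cache$res <- analyze_colonization(f$ss, f$fx$cfg, blocks = f$fx$blocks)
  }
  .fixture_cache$res
}

get_fixture_cd <- function(ancestral = "A") {
  key <- paste0("cd_", ancestral)
  if (is.null(.fixture_cache[[key]])) {
    f <- get_fixture()
    .fixture_cache[[key]] <- colonization_data(f$ss, f$fx$cfg, blocks = f$fx$blocks,
                                               ancestral = ancestral)
  }
  .fixture_cache[[key]]
}

# The published occupancy pattern (island units per haplotype) and star
# genealogy, stated directly for tests that count events on known inputs.
published_occupancy <- function() {
  list(A = c("GC", "T", "LG", "LP", "EH"),
       B = c("Mahan", "GC", "T", "LG", "EH"),
       C = c("T", "LG"),
       D = c("GC"))
}

published_star <- function(root) {
  occ <- published_occupancy()
  if (root == "B") {
    parent <- stats::setNames(rep("B", 3L), c("A", "C", "D"))
  } else {
    others <- setdiff(names(occ), c(root, "B"))
    parent <- stats::setNames(rep("B", length(others)), others)
    parent["B"] <- root
  }
  rooted_genealogy(root, parent, occ)
}
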