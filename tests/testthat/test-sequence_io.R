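test_that("fixture dataset reads into a validated sample set", {
  f <- get_fixture()
  expect_s3_class(f$ss, "sample_set")
  expect_equal(nrow(f$ss$meta), 160L)  # 158 ingroup + 2 outgroup
  ingroup_meta <- f$ss$meta[f$ss$meta$region != "outgroup", ]
  expect_equal(nrow(ingroup_meta), 158L)
  expect_equal(length(unique(ingroup_meta$population_id)), 37L)  # 36 + Morocco
  expect_equal(vapply(f$ss$seqs, ncol, 0L),
               c("psaI-aacD" = 792L, "psbK-trnS" = 705L))
})

test_that("reader rejects malformed inputs naming the offender", {
  dir <- withr::local_tempdir()
  writeLines(c(">ind1", "ACGT", ">ind2", "ACGT"), file.path(dir, "loc.fasta"))
  writeLines(c("individual_id\tpopulation_id\tisland\tregion",
               "ind1\tp1\tisl1\tarchipelago",
               "ind2\tp1\tisl1\tarchipelago",
               "ind3\tp2\tisl1\tarchipelago"),
             file.path(dir, "meta.tsv"))
  expect_error(read_sample_set(c(loc = file.path(dir, "loc.fasta")),
                               file.path(dir, "meta.tsv")),
               "ind3")

  writeLines(c("individual_id\tpopulation_id\tisland\tregion",
               "ind1\tp1\tisl1\tarchipelago",
               "ind1\tp1\tisl1\tarchipelago"),
             file.path(dir, "dup.tsv"))
  expect_error(read_sample_set(c(loc = file.path(dir, "loc.fasta")),
                               file.path(dir, "dup.tsv")),
               "duplicated")

  writeLines(c(">ind1", "ACGT", ">ind2", "ACG"), file.path(dir, "ragged.fasta"))
  expect_error(read_sample_set(c(loc = file.path(dir, "ragged.fasta")),
                               file.path(dir, "dup.tsv")),
               "length mismatch")
})

test_that("a single individual and locus form a valid sample set", {
  meta <- data.frame(individual_id = "x1", population_id = "p1",
                     island = "isl", region = "archipelago")
  ss <- new_sample_set(meta, list(loc = matrix(c("A", "C"), 1,
                                               dimnames = list("x1", NULL))))
  expect_equal(nrow(ss$meta), 1L)
})

test_that("concatenation preserves columns and recoding collapses blocks", {
  f <- get_fixture()
  cm <- f$cm
  expect_equal(ncol(cm$states), 1495L)  # 1497 columns - (3 - 1) for the block
  expect_equal(sum(cm$column_index$end - cm$column_index$start + 1L), 1497L)
  # no blocks: characters = columns
  cm0 <- concatenate_and_recode(f$ss)
  expect_equal(ncol(cm0$states), 1497L)
  # recoding conservation on an arbitrary second block
  blocks2 <- rbind(f$fx$blocks, recode_block("psbK-trnS", 10L, 14L))
  cm2 <- concatenate_and_recode(f$ss, blocks2)
  expect_equal(ncol(cm2$states), 1497L - 2L - 4L)
  expect_error(concatenate_and_recode(
    f$ss, rbind(f$fx$blocks, recode_block("psaI-aacD", 134L, 140L))),
    "overlapping")
  expect_error(concatenate_and_recode(f$ss, recode_block("psaI-aacD", 790L, 800L)),
               "outside")
})

test_that("individuals differing only by the full inversion are one step apart", {
  f <- get_fixture()
  # A and B differ by the inversion plus B's gap column; restrict to the
  # block character alone via two bespoke individuals
  meta <- data.frame(individual_id = c("i1", "i2"), population_id = "p",
                     island = "isl", region = "archipelago")
  s <- rbind(i1 = c("T", "A", "C", "G"), i2 = c("C", "A", "T", "G"))
  ss <- new_sample_set(meta, list(loc = s))
  cm <- concatenate_and_recode(ss, recode_block("loc", 1L, 3L))
  expect_equal(ncol(cm$states), 2L)
  ht <- collapse_haplotypes(cm, characters = 1:2)
  expect_equal(unname(pairwise_steps(ht)["A", "B"]), 1L)
})

test_that("variable characters require two non-missing states in scope", {
  f <- get_fixture()
  expect_equal(length(extract_variable_characters(f$cm, f$ingroup)), 4L)
  # gaps are missing: an A/A/-/- column is not variable
  meta <- data.frame(individual_id = paste0("i", 1:4), population_id = "p",
                     island = "isl", region = "archipelago")
  s <- matrix(c("A", "A", "-", "-",
                "C", "C", "C", "T"), ncol = 2,
              dimnames = list(meta$individual_id, NULL))
  cm <- concatenate_and_recode(new_sample_set(meta, list(loc = s)))
  expect_equal(extract_variable_characters(cm, meta$individual_id), 2L)
  # all-identical matrix: no variable characters
  s2 <- matrix("A", 4, 2, dimnames = list(meta$individual_id, NULL))
  cm2 <- concatenate_and_recode(new_sample_set(meta, list(loc = s2)))
  expect_length(extract_variable_characters(cm2, meta$individual_id), 0L)
})

test_that("haplotype collapsing matches counts, labels and occupancy", {
  f <- get_fixture()
  ht <- collapse_haplotypes(f$cm, scope = f$ingroup)
  expect_equal(length(ht$labels), 4L)
  expect_equal(unname(ht$n), c(63L, 39L, 38L, 18L))  # A > B > C > D
  expect_equal(sum(ht$n), 158L)
  expect_equal(ht$occupancy$C, "Gran Canaria")
  expect_equal(ht$occupancy$D, c("La Gomera", "Tenerife"))
  # empty character set: one haplotype holding everyone
  ht0 <- collapse_haplotypes(f$cm, scope = f$ingroup, characters = integer(0))
  expect_equal(length(ht0$labels), 1L)
  expect_equal(unname(ht0$n), 158L)
})

test_that("dropping the inversion character merges its two lineages", {
  f <- get_fixture()
  vc <- extract_variable_characters(f$cm, f$ingroup)
  # keep the two substitution characters only: the A-B split disappears
  keep <- vc[2:3]
  ht <- collapse_haplotypes(f$cm, scope = f$ingroup, characters = keep)
  expect_equal(length(ht$labels), 3L)
  # occupancy agrees with a brute-force re-collapse (complete data on keep)
  oracle <- brute_collapse_complete(f$cm$states, f$ingroup, keep)
  sizes <- sort(vapply(oracle, length, 0L))
  expect_equal(sort(as.integer(ht$n)), unname(sizes))
  meta <- f$cm$meta
  oracle_occ <- lapply(oracle, function(ids)
    sort(unique(meta$island[match(ids, meta$individual_id)])))
  expect_true(all(vapply(ht$labels, function(h)
    any(vapply(oracle_occ, identical, TRUE, ht$occupancy[[h]])), TRUE)))
})

test_that("collapse refines as characters are added (complete data)", {
  set.seed(11)
  for (rep in 1:20) {
    params <- simulation_params(n_units = 4L, n_haplotypes = 5L,
                                n_variable_sites = 6L,
                                populations_per_unit = 2L,
                                individuals_per_population = 3L,
                                locus_lengths = c(l1 = 80L, l2 = 60L),
                                seed = rep)
    rd <- realize_dataset(simulate_history(params))
    cm <- concatenate_and_recode(rd$samples)
    ids <- rd$samples$meta$individual_id
    vc <- extract_variable_characters(cm, ids)
    if (length(vc) < 2L) next
    s1 <- sort(sample(vc, max(1L, length(vc) %/% 2L)))
    s2 <- sort(union(s1, sample(vc, 2L)))
    ht1 <- collapse_haplotypes(cm, ids, s1)
    ht2 <- collapse_haplotypes(cm, ids, s2)
    cls1 <- rep(NA_character_, length(ids))
    names(cls1) <- ids
    for (h in ht1$labels) cls1[ht1$members[[h]]] <- h
    for (h in ht2$labels) {
      expect_length(unique(cls1[ht2$members[[h]]]), 1L)
    }
  }
})

test_that("haplotype tables round-trip through their text format", {
  f <- get_fixture()
  ht <- collapse_haplotypes(f$cm, scope = rownames(f$cm$states))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(ht, path)
  back <- read_haplotype_table(path)
  expect_equal(back$labels, ht$labels)
  expect_equal(back$n, ht$n)
  expect_equal(back$occupancy, stats::setNames(ht$occupancy, ht$labels))
  expect_equal(back$pop_counts[, colnames(ht$pop_counts)], ht$pop_counts)
})
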