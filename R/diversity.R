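#' Nei-Tajima unbiased haplotypic diversity
#'
#' `H = n (1 - sum(p_i^2)) / (n - 1)` with `p_i` the sample frequency of
#' haplotype `i`: the probability that two individuals drawn without
#' replacement carry different haplotypes. The `n/(n-1)` factor makes the
#' estimator unbiased; published tables typically round it to three decimals,
#' which is left to the caller (full precision is returned).
#'
#' @param counts positive integer haplotype counts, `sum(counts) >= 2`.
#' @return `H` in `[0, 1]`; `NA` when fewer than two individuals.
#' @export
haplotypic_diversity <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1L, all(counts > 0), all(counts == round(counts)))
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  n * (1 - sum((counts / n)^2)) / (n - 1)
}

#' Per-group haplotype diversity table
#'
#' One row per island unit (plus the mainland as its own group), with the
#' number of individuals sequenced (`n`), populations (`p`), haplotypes (`h`),
#' private haplotypes (`ph`, haplotypes found in no other group) and
#' Nei-Tajima haplotypic diversity (`H`, full precision; round to 3 decimals
#' for presentation). Outgroup records never enter the table. Groups appear in
#' the order their members first appear in the metadata.
#'
#' @param table a `haplotype_table`.
#' @param merges optional named character vector mapping island names to
#'   analysis units (e.g. `c(Lanzarote = "Mahan", Fuerteventura = "Mahan")`);
#'   unmapped islands keep their own name.
#' @return data frame with columns group, n, p, h, ph, H.
#' @export
diversity_table <- function(table, merges = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  meta <- table$meta
  keep <- meta$region != "outgroup"
  meta <- meta[keep, , drop = FALSE]
  unit <- meta$island
  if (!is.null(merges)) {
    mapped <- !is.na(match(unit, names(merges)))
    unit[mapped] <- merges[unit[mapped]]
  }
  hap_of <- rep(NA_character_, nrow(meta))
  for (h in table$labels)
    hap_of[match(intersect(table$members[[h]], meta$individual_id),
                 meta$individual_id)] <- h
  groups <- unique(unit)
  pres <- lapply(groups, function(g) unique(hap_of[unit == g]))
  names(pres) <- groups
  rows <- lapply(groups, function(g) {
    in_g <- unit == g
    cnt <- table(hap_of[in_g])
    others <- unique(unlist(pres[setdiff(groups, g)]))
    data.frame(group = g,
               n = sum(in_g),
               p = length(unique(meta$population_id[in_g])),
               h = length(cnt),
               ph = sum(!(names(cnt) %in% others)),
               H = if (sum(in_g) >= 2) haplotypic_diversity(as.integer(cnt)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the diversity table with table-style rounding
#'
#' Tab-separated, `H` rounded to three decimals (round-half-even).
#'
#' @param div data frame from [diversity_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(div, path) {
  div$H <- round(div$H, 3L)
  utils::write.table(div, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
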