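#' Read per-locus alignments and sample metadata
#'
#' Builds a `sample_set` from one aligned FASTA file per locus plus a
#' tab-separated metadata table. Every individual listed in the metadata must
#' have exactly one sequence in every locus, FASTA headers must match
#' `individual_id`, and all sequences within a locus must have equal (aligned)
#' length.
#'
#' @param fasta_paths named character vector of FASTA file paths; names are
#'   locus identifiers and define the concatenation order downstream.
#' @param metadata_path path to a tab-separated table with header columns
#'   `individual_id`, `population_id`, `island`, `region`. `region` must be one
#'   of `"archipelago"`, `"mainland"` or `"outgroup"`.
#' @return an object of class `sample_set`: a list with elements `meta`
#'   (data frame) and `seqs` (named list of character matrices, rows =
#'   individuals in metadata order, columns = alignment positions, uppercase
#'   bases with `-`/`N` preserved).
#' @export
read_sample_set <- function(fasta_paths, metadata_path) {
  if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths))))
    stop("fasta_paths must be a named vector (names = locus ids)")
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            colClasses = "character", stringsAsFactors = FALSE)
  seqs <- lapply(fasta_paths, read_locus_alignment)
  names(seqs) <- names(fasta_paths)
  new_sample_set(meta, seqs)
}

read_locus_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  chr <- lapply(as.character(dna), toupper)
  lens <- lengths(chr)
  if (length(unique(lens)) > 1L) {
    bad <- names(chr)[lens != stats::median(lens)][1L]
    stop(sprintf("alignment '%s': sequence length mismatch (e.g. record '%s')",
                 basename(path), bad))
  }
  m <- do.call(rbind, chr)
  rownames(m) <- names(chr)
  m
}

#' Construct a sample set from in-memory components
#'
#' Same validation as [read_sample_set()], for programmatically built data
#' (e.g. the synthetic generator).
#'
#' @param meta metadata data frame (see [read_sample_set()]).
#' @param seqs named list of character matrices, one per locus, rows named by
#'   `individual_id`.
#' @return a `sample_set`.
#' @export
new_sample_set <- function(meta, seqs) {
  req <- c("individual_id", "population_id", "island", "region")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  ids <- meta$individual_id
  if (anyDuplicated(ids))
    stop("duplicated individual_id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad_region <- setdiff(unique(meta$region), c("archipelago", "mainland", "outgroup"))
  if (length(bad_region))
    stop("unknown region value(s): ", paste(bad_region, collapse = ", "))
  if (!length(seqs) || is.null(names(seqs)))
    stop("seqs must be a non-empty named list of alignment matrices")
  seqs <- lapply(seqs, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "character"
    m[] <- toupper(m)
    m
  })
  for (locus in names(seqs)) {
    m <- seqs[[locus]]
    missing_ids <- setdiff(ids, rownames(m))
    if (length(missing_ids))
      stop(sprintf("locus '%s': missing sequence for individual '%s'",
                   locus, missing_ids[1L]))
    extra <- setdiff(rownames(m), ids)
    if (length(extra))
      stop(sprintf("locus '%s': FASTA record '%s' absent from metadata",
                   locus, extra[1L]))
    if (anyDuplicated(rownames(m)))
      stop(sprintf("locus '%s': duplicated FASTA record", locus))
    seqs[[locus]] <- m[ids, , drop = FALSE]
  }
  structure(list(meta = meta, seqs = seqs), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d individuals, %d populations, loci: %s\n",
              nrow(x$meta), length(unique(x$meta$population_id)),
              paste(sprintf("%s (%d bp)", names(x$seqs),
                            vapply(x$seqs, ncol, 0L)), collapse = ", ")))
  invisible(x)
}

#' Declare an inversion (or other block) to recode as one character
#'
#' Coordinates are 1-based and inclusive, matching the usual way alignment
#' positions are reported.
#'
#' @param locus locus identifier (must match a name in the sample set).
#' @param start,end first and last alignment column of the block.
#' @return a one-row data frame usable in the `blocks` argument of
#'   [concatenate_and_recode()]; rows from several calls can be `rbind`ed.
#' @export
recode_block <- function(locus, start, end) {
  stopifnot(length(locus) == 1L, start >= 1L, end >= start)
  data.frame(locus = locus, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

MISSING_SYMBOLS <- c("-", "N", "?")

#' Concatenate loci and recode mutational blocks
#'
#' Loci are concatenated in the order they appear in the sample set. Each
#' recode block is collapsed into a single multistate character whose state is
#' the literal substring spanned by the block (distinct substrings = distinct
#' states, one mutational step apart); a gap or `N` anywhere inside the block
#' makes the whole block state missing. Outside blocks, every alignment column
#' is one character, with `-`, `N` and `?` mapped to missing.
#'
#' @param samples a `sample_set`.
#' @param blocks data frame with columns `locus`, `start`, `end` (see
#'   [recode_block()]), or `NULL` for no recoding.
#' @return an object of class `character_matrix`: list with `states`
#'   (character matrix, rows = individuals, `NA` = missing), `column_index`
#'   (data frame locus/start/end per character) and `meta`.
#' @export
concatenate_and_recode <- function(samples, blocks = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  if (!is.null(blocks)) {
    stopifnot(all(c("locus", "start", "end") %in% names(blocks)))
    unknown <- setdiff(blocks$locus, names(samples$seqs))
    if (length(unknown))
      stop("recode block references unknown locus: ", unknown[1L])
  }
  state_cols <- list()
  index_rows <- list()
  for (locus in names(samples$seqs)) {
    m <- samples$seqs[[locus]]
    L <- ncol(m)
    bl <- if (is.null(blocks)) NULL else blocks[blocks$locus == locus, , drop = FALSE]
    if (!is.null(bl) && nrow(bl)) {
      if (any(bl$start < 1L | bl$end > L))
        stop(sprintf("recode block outside locus '%s' (length %d)", locus, L))
      bl <- bl[order(bl$start), , drop = FALSE]
      if (nrow(bl) > 1L && any(bl$start[-1L] <= bl$end[-nrow(bl)]))
        stop(sprintf("overlapping recode blocks in locus '%s'", locus))
    }
    pos <- 1L
    bi <- 1L
    while (pos <= L) {
      if (!is.null(bl) && bi <= nrow(bl) && pos == bl$start[bi]) {
        span <- bl$start[bi]:bl$end[bi]
        sub <- m[, span, drop = FALSE]
        tok <- apply(sub, 1L, paste0, collapse = "")
        has_missing <- apply(sub, 1L, function(r) any(r %in% MISSING_SYMBOLS))
        tok[has_missing] <- NA_character_
        state_cols[[length(state_cols) + 1L]] <- tok
        index_rows[[length(index_rows) + 1L]] <-
          data.frame(locus = locus, start = bl$start[bi], end = bl$end[bi])
        pos <- bl$end[bi] + 1L
        bi <- bi + 1L
      } else {
        nxt <- if (!is.null(bl) && bi <= nrow(bl)) bl$start[bi] - 1L else L
        span <- pos:nxt
        sub <- m[, span, drop = FALSE]
        sub[sub %in% MISSING_SYMBOLS] <- NA_character_
        for (k in seq_along(span)) {
          state_cols[[length(state_cols) + 1L]] <- sub[, k]
          index_rows[[length(index_rows) + 1L]] <-
            data.frame(locus = locus, start = span[k], end = span[k])
        }
        pos <- nxt + 1L
      }
    }
  }
  states <- do.call(cbind, state_cols)
  rownames(states) <- samples$meta$individual_id
  colnames(states) <- NULL
  structure(list(states = states,
                 column_index = do.call(rbind, index_rows),
                 meta = samples$meta),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d individuals x %d characters (%d alignment columns)\n",
              nrow(x$states), ncol(x$states), sum(x$column_index$end - x$column_index$start + 1L)))
  invisible(x)
}

#' Variable characters within a scope of individuals
#'
#' A character is variable when at least two distinct non-missing states are
#' observed among the scoped individuals; missing never counts as a state.
#'
#' @param matrix a `character_matrix`.
#' @param scope character vector of individual ids (non-empty).
#' @return integer vector of character indices, ascending.
#' @export
extract_variable_characters <- function(matrix, scope) {
  stopifnot(inherits(matrix, "character_matrix"), length(scope) > 0L)
  miss <- setdiff(scope, rownames(matrix$states))
  if (length(miss)) stop("scope individual not in matrix: ", miss[1L])
  sub <- matrix$states[scope, , drop = FALSE]
  which(apply(sub, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}

# Pattern-level collapse shared by collapse_haplotypes() and the fast
# resampling path. V: character matrix (NA = missing) of the scoped
# individuals over the selected characters. Returns integer class assignment
# per row plus the class state matrix (classes may retain NA where no member
# carries data). Classes are seeded from complete patterns (largest first),
# then partial patterns join, in order of (fewest missing, most carriers,
# state-string), the compatible class with most members at join time
# (ties: lexicographically smallest class state string); incompatible
# partial patterns found their own class.
collapse_patterns <- function(V) {
  n <- nrow(V)
  if (ncol(V) == 0L)
    return(list(assign = rep(1L, n),
                states = matrix(character(0), nrow = 1L, ncol = 0L)))
  keys <- do.call(paste, c(lapply(seq_len(ncol(V)), function(j) {
    v <- V[, j]
    v[is.na(v)] <- "\x01"
    v
  }), sep = "\r"))
  ukeys <- unique(keys)
  pat_idx <- match(keys, ukeys)
  first <- match(ukeys, keys)
  P <- V[first, , drop = FALSE]
  if (!is.matrix(P)) P <- matrix(P, nrow = length(first))
  counts <- tabulate(pat_idx, nbins = length(ukeys))
  n_missing <- rowSums(is.na(P))
  pat_str <- function(i) paste(ifelse(is.na(P[i, ]), "?", P[i, ]), collapse = "\r")

  cls_states <- list()   # state vectors (may contain NA)
  cls_size <- integer(0)
  pat_class <- integer(length(ukeys))

  complete <- which(n_missing == 0L)
  if (length(complete)) {
    ord <- complete[order(-counts[complete],
                          vapply(complete, pat_str, ""))]
    for (i in ord) {
      cls_states[[length(cls_states) + 1L]] <- P[i, ]
      cls_size <- c(cls_size, counts[i])
      pat_class[i] <- length(cls_states)
    }
  }
  partial <- which(n_missing > 0L)
  if (length(partial)) {
    ord <- partial[order(n_missing[partial], -counts[partial],
                         vapply(partial, pat_str, ""))]
    for (i in ord) {
      v <- P[i, ]
      if (all(is.na(v)) && !length(cls_states)) {
        warning("individual with no observed states assigned its own haplotype")
        cls_states[[1L]] <- v
        cls_size <- 1 * counts[i]
        pat_class[i] <- 1L
        next
      }
      compat <- which(vapply(cls_states, function(s) {
        both <- !is.na(s) & !is.na(v)
        !any(s[both] != v[both])
      }, TRUE))
      if (!length(compat)) {
        cls_states[[length(cls_states) + 1L]] <- v
        cls_size <- c(cls_size, counts[i])
        pat_class[i] <- length(cls_states)
      } else {
        best <- compat[cls_size[compat] == max(cls_size[compat])]
        if (length(best) > 1L) {
          strs <- vapply(best, function(k)
            paste(ifelse(is.na(cls_states[[k]]), "?", cls_states[[k]]), collapse = "\r"), "")
          best <- best[order(strs)][1L]
        } else best <- best[1L]
        s <- cls_states[[best]]
        fill <- is.na(s) & !is.na(v)
        s[fill] <- v[fill]
        cls_states[[best]] <- s
        cls_size[best] <- cls_size[best] + counts[i]
        pat_class[i] <- best
      }
    }
  }
  states <- do.call(rbind, cls_states)
  list(assign = pat_class[pat_idx], states = states)
}

#' Collapse individuals into haplotypes
#'
#' Individuals identical at every non-missing position of the selected
#' characters are merged. Individuals with missing states join the compatible
#' haplotype with most members (tie: lexicographically smallest state vector);
#' an individual with all states missing and no haplotype to join founds its
#' own haplotype with a warning. Labels `A`, `B`, `C`, ... are assigned in
#' decreasing total frequency (tie: state-vector order).
#'
#' @param matrix a `character_matrix`.
#' @param scope individual ids to collapse (default: all).
#' @param characters character indices to use (default: characters variable
#'   within `scope`). An empty set collapses everyone into one haplotype.
#' @return an object of class `haplotype_table`.
#' @export
collapse_haplotypes <- function(matrix, scope = NULL,
                                characters = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (is.null(scope)) scope <- rownames(matrix$states)
  if (is.null(characters)) characters <- extract_variable_characters(matrix, scope)
  characters <- as.integer(characters)
  if (length(characters) && (min(characters) < 1L || max(characters) > ncol(matrix$states)))
    stop("character index out of range")
  V <- matrix$states[scope, characters, drop = FALSE]
  cp <- collapse_patterns(V)
  sizes <- tabulate(cp$assign, nbins = nrow(cp$states))
  str_of <- apply(cp$states, 1L, function(s) paste(ifelse(is.na(s), "?", s), collapse = "\r"))
  if (ncol(cp$states) == 0L) str_of <- rep("", nrow(cp$states))
  ord <- order(-sizes, str_of)
  labels <- hap_labels(length(ord))
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  assign_lab <- labels[relabel[cp$assign]]
  meta <- matrix$meta[match(scope, matrix$meta$individual_id), , drop = FALSE]
  members <- split(scope, factor(assign_lab, levels = labels))
  states <- cp$states[ord, , drop = FALSE]
  rownames(states) <- labels
  occupancy <- lapply(members, function(ids)
    sort(unique(meta$island[match(ids, meta$individual_id)])))
  pops <- sort(unique(meta$population_id))
  pop_counts <- matrix(0L, nrow = length(labels), ncol = length(pops),
                       dimnames = list(labels, pops))
  tb <- table(assign_lab, meta$population_id)
  pop_counts[rownames(tb), colnames(tb)] <- tb
  structure(list(labels = labels,
                 states = states,
                 n = stats::setNames(lengths(members), labels),
                 members = members,
                 occupancy = occupancy,
                 pop_counts = pop_counts,
                 characters = characters,
                 meta = meta),
            class = "haplotype_table")
}

hap_labels <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, function(a, b) paste0(a, b))))[seq_len(k)]
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes over %d characters\n",
              length(x$labels), length(x$characters)))
  df <- data.frame(haplotype = x$labels, n = as.integer(x$n),
                   islands = vapply(x$occupancy, paste, "", collapse = ","))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write / read a haplotype table as tab-separated text
#'
#' Columns: haplotype, state vector (comma-separated, `?` = missing), n,
#' islands (comma-separated), populations (`pop:count` pairs,
#' semicolon-separated). [read_haplotype_table()] restores labels, states,
#' counts, occupancy and per-population counts.
#'
#' @param table a `haplotype_table`.
#' @param path output file.
#' @return `path`, invisibly; for the reader, a list mirroring the table.
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "haplotype_table"))
  states <- apply(table$states, 1L, function(s)
    paste(ifelse(is.na(s), "?", s), collapse = ","))
  if (!length(table$characters)) states <- rep("", length(table$labels))
  pops <- vapply(table$labels, function(h) {
    cnt <- table$pop_counts[h, ]
    cnt <- cnt[cnt > 0L]
    paste(sprintf("%s:%d", names(cnt), cnt), collapse = ";")
  }, "")
  df <- data.frame(haplotype = table$labels,
                   states = states,
                   n = as.integer(table$n),
                   islands = vapply(table$occupancy, paste, "", collapse = ","),
                   populations = pops)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_table
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  states <- lapply(strsplit(df$states, ",", fixed = TRUE), function(s) {
    s[s == "?"] <- NA_character_
    s
  })
  ncol_s <- max(lengths(states))
  if (all(df$states == "")) {
    sm <- matrix(character(0), nrow = nrow(df), ncol = 0L)
  } else {
    sm <- do.call(rbind, states)
  }
  rownames(sm) <- df$haplotype
  pc_list <- lapply(strsplit(df$populations, ";", fixed = TRUE), function(p) {
    p <- p[nzchar(p)]
    parts <- strsplit(p, ":", fixed = TRUE)
    stats::setNames(vapply(parts, function(q) as.integer(q[2L]), 0L),
                    vapply(parts, `[`, "", 1L))
  })
  pops <- sort(unique(unlist(lapply(pc_list, names))))
  pop_counts <- matrix(0L, nrow = nrow(df), ncol = length(pops),
                       dimnames = list(df$haplotype, pops))
  for (i in seq_len(nrow(df))) pop_counts[i, names(pc_list[[i]])] <- pc_list[[i]]
  list(labels = df$haplotype,
       states = sm,
       n = stats::setNames(as.integer(df$n), df$haplotype),
       occupancy = stats::setNames(
         lapply(strsplit(df$islands, ",", fixed = TRUE), sort), df$haplotype),
       pop_counts = pop_counts)
}
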