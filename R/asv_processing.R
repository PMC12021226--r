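#' ASV count tables
#'
#' An `asv_table` holds per-sample counts of exact amplicon sequence variants
#' (ASVs) plus a per-stage read-accounting log. The processing pipeline is
#' order-fixed: [dereplicate()] -> [remove_chimeras()] ->
#' [filter_low_frequency()] -> [rarefy_table()]; no stage ever creates a new
#' ASV.
#'
#' @param counts integer matrix, samples in rows, ASVs in columns; column
#'   names are ASV ids and `asv_seq` maps them to sequences.
#' @param asv_seq named character vector ASV id -> sequence.
#' @param stage one of raw, nochim, lowfreq_filtered, rarefied.
#' @param log data.frame of per-sample read accounting.
#' @return an `asv_table`.
#' @keywords internal
new_asv_table <- function(counts, asv_seq, stage, log) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            identical(colnames(counts), names(asv_seq)) ||
              (ncol(counts) == 0L && length(asv_seq) == 0L))
  structure(list(counts = counts, asv_seq = asv_seq, stage = stage,
                 log = log), class = "asv_table")
}

#' Dereplicate reads into an exact-sequence ASV table
#'
#' Groups identical read sequences per sample; no error-model merging is
#' performed, so every distinct sequence (including single-substitution
#' variants) is its own ASV. Reads containing N are excluded and logged.
#' Empty samples are retained as all-zero rows with a warning.
#'
#' @param reads named list: sample id -> character vector of uppercase reads.
#' @return an `asv_table` at stage `raw`. ASV ids (`asv_0001`, ...) are
#'   assigned in order of decreasing total abundance, ties broken by sequence.
#' @export
dereplicate <- function(reads) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  reads <- lapply(reads, toupper)
  n_in <- vapply(reads, length, integer(1))
  has_n <- lapply(reads, function(r) grepl("N", r, fixed = TRUE))
  n_dropped <- vapply(has_n, sum, integer(1))
  clean <- Map(function(r, h) r[!h], reads, has_n)
  if (any(vapply(clean, length, integer(1)) == 0L))
    warning("sample(s) with no usable reads retained as zero rows")
  seqs <- sort(unique(unlist(clean, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(reads), ncol = length(seqs),
                   dimnames = list(names(reads), NULL))
  for (i in seq_along(clean)) {
    tb <- table(factor(clean[[i]], levels = seqs))
    counts[i, ] <- as.integer(tb)
  }
  ord <- order(-colSums(counts), seqs)
  counts <- counts[, ord, drop = FALSE]
  seqs <- seqs[ord]
  ids <- sprintf("asv_%04d", seq_along(seqs))
  colnames(counts) <- ids
  log <- data.frame(sample_id = names(reads), input = n_in,
                    n_excluded = n_dropped,
                    raw = as.integer(rowSums(counts)),
                    stringsAsFactors = FALSE, row.names = NULL)
  new_asv_table(counts, stats::setNames(seqs, ids), "raw", log)
}

#' Remove two-parent (bimera) chimeras
#'
#' Within each sample, an ASV is removed iff two parents exist in the same
#' sample, each at no less than `min_fold` times its abundance, and a split
#' point k such that the ASV equals the first parent over positions 1..k and
#' the second parent over k+1..end (exact matches, equal lengths).
#'
#' @param tab an `asv_table` at stage `raw`.
#' @param min_fold parent-abundance multiplier (default 2).
#' @return an `asv_table` at stage `nochim`; removals are zeroed per sample
#'   and ASVs with no remaining reads are dropped.
#' @export
remove_chimeras <- function(tab, min_fold = 2) {
  stopifnot(inherits(tab, "asv_table"))
  counts <- tab$counts
  seqs <- tab$asv_seq
  removed <- integer(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    present <- which(counts[i, ] > 0L)
    if (length(present) < 3L) next
    for (a in present) {
      parents <- present[counts[i, present] >= min_fold * counts[i, a] &
                           present != a]
      parents <- parents[nchar(seqs[parents]) == nchar(seqs[a])]
      if (length(parents) < 2L) next
      if (is_bimera(seqs[a], seqs[parents])) {
        removed[i] <- removed[i] + counts[i, a]
        counts[i, a] <- 0L
      }
    }
  }
  keep <- colSums(counts) > 0L
  counts <- counts[, keep, drop = FALSE]
  log <- tab$log
  log$chimera_removed <- removed
  log$nonchim <- as.integer(rowSums(counts))
  new_asv_table(counts, tab$asv_seq[keep], "nochim", log)
}

# TRUE iff `a` splits as prefix of one candidate parent + suffix of another.
is_bimera <- function(a, parents) {
  L <- nchar(a)
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  pref <- suf <- integer(length(parents))
  for (j in seq_along(parents)) {
    pc <- strsplit(parents[[j]], "", fixed = TRUE)[[1]]
    neq <- which(ac != pc)
    pref[j] <- if (length(neq)) neq[1L] - 1L else L
    suf[j] <- if (length(neq)) L - neq[length(neq)] else L
  }
  # need k in 1..L-1 with some parent matching 1..k and another k+1..L;
  # a parent identical to `a` cannot occur (distinct ASVs), so the best
  # prefix and best suffix come from genuinely different decompositions.
  max(pref) >= 1L && max(suf) >= 1L && max(pref) + max(suf) >= L
}

#' Exclude low-frequency ASVs per sample
#'
#' Zeroes any cell whose count is strictly below `threshold` of that sample's
#' total (the "fewer than 1.0% of the total number of sequences in each
#' sample" rule; a count at exactly the threshold is retained). ASVs with no
#' remaining reads are dropped.
#'
#' @param tab an `asv_table`.
#' @param threshold per-sample relative-abundance threshold (default 0.01).
#' @return an `asv_table` at stage `lowfreq_filtered`.
#' @export
filter_low_frequency <- function(tab, threshold = 0.01) {
  stopifnot(inherits(tab, "asv_table"), threshold >= 0, threshold <= 1)
  counts <- tab$counts
  totals <- rowSums(counts)
  removed <- integer(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    if (totals[i] == 0) next
    low <- counts[i, ] / totals[i] < threshold & counts[i, ] > 0L
    removed[i] <- sum(counts[i, low])
    counts[i, low] <- 0L
  }
  keep <- colSums(counts) > 0L
  counts <- counts[, keep, drop = FALSE]
  log <- tab$log
  log$lowfreq_removed <- removed
  log$lowfreq_filtered <- as.integer(rowSums(counts))
  new_asv_table(counts, tab$asv_seq[keep], "lowfreq_filtered", log)
}

#' Rarefy an ASV table to a fixed per-sample depth
#'
#' Subsamples exactly `depth` reads per sample, uniformly without replacement
#' from the multiset of reads implied by the counts. Samples below `depth`
#' are dropped with a warning. Deterministic given `seed`.
#'
#' @param tab an `asv_table`.
#' @param depth target reads per sample (default 1000).
#' @param seed integer seed.
#' @return an `asv_table` at stage `rarefied`; every retained row sums to
#'   exactly `depth`.
#' @export
rarefy_table <- function(tab, depth = 1000L, seed) {
  stopifnot(inherits(tab, "asv_table"))
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (missing(seed)) stop("rarefaction requires a seed", call. = FALSE)
  counts <- tab$counts
  totals <- rowSums(counts)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below rarefaction depth: ",
            paste(rownames(counts)[drop], collapse = ", "))
    counts <- counts[!drop, , drop = FALSE]
  }
  with_seed(seed, {
    for (i in seq_len(nrow(counts))) {
      n <- sum(counts[i, ])
      if (n == depth) next
      pool <- rep.int(seq_len(ncol(counts)), counts[i, ])
      take <- sample(pool, depth)
      counts[i, ] <- tabulate(take, nbins = ncol(counts))
    }
    keep <- colSums(counts) > 0L
    counts <- counts[, keep, drop = FALSE]
    log <- tab$log[match(rownames(counts), tab$log$sample_id), , drop = FALSE]
    log$rarefied <- as.integer(rowSums(counts))
    new_asv_table(counts, tab$asv_seq[keep], "rarefied", log)
  })
}

#' Exact rarefaction curve (expected ASV richness)
#'
#' Expected number of distinct ASVs in a uniform subsample of size m without
#' replacement: E[S_m] = sum_i [1 - C(n - n_i, m) / C(n, m)], computed exactly
#' on the log-choose scale (not Monte Carlo).
#'
#' @param counts non-negative integer count vector for one sample.
#' @param sizes integer grid of subsample sizes, each <= sum(counts).
#' @return data.frame with columns size and richness.
#' @export
rarefaction_curve <- function(counts, sizes) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (any(sizes < 0 | sizes > n))
    stop("subsample sizes must lie in [0, total reads]", call. = FALSE)
  rich <- vapply(sizes, function(m) {
    sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
  }, numeric(1))
  data.frame(size = sizes, richness = rich)
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table [%s]: %d samples x %d ASVs\n", x$stage,
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  reads: total %d, per-sample median %.0f\n",
              sum(x$counts), stats::median(rowSums(x$counts))))
  invisible(x)
}

#' Write an ASV table (counts TSV + ASV FASTA + accounting TSV)
#'
#' @param tab an `asv_table`.
#' @param prefix path prefix; writes `<prefix>_counts.tsv` (rows = ASV ids,
#'   columns = samples), `<prefix>_asvs.fasta` and `<prefix>_accounting.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_asv_table <- function(tab, prefix) {
  m <- t(tab$counts)
  utils::write.table(data.frame(asv_id = rownames(m), m,
                                check.names = FALSE),
                     paste0(prefix, "_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  x <- Biostrings::DNAStringSet(tab$asv_seq)
  Biostrings::writeXStringSet(x, paste0(prefix, "_asvs.fasta"))
  utils::write.table(tab$log, paste0(prefix, "_accounting.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
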