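#' Count canonical k-mers across a set of sequences
#'
#' Counts strand-collapsed (canonical) k-mers: each window is keyed by the
#' lexicographic minimum of itself and its reverse complement. Windows
#' containing non-ACGT symbols are skipped. The table is held in native code
#' (sequences at genome scale produce millions of keys); use
#' [kmer_counts_table()] to materialise small tables and [kmer_lookup()] to
#' query individual k-mers.
#'
#' @param sequences named character vector of sequences, or a FASTA path.
#' @param k k-mer length, 2..31 (default 31).
#' @return A `KmerCountTable` (list with `k`, `n_kmers`, `total` and an
#'   external pointer `ptr`).
#' @examples
#' tab <- count_kmers(c(s = "ACGTACGT"), k = 8)
#' tab$n_kmers
#' @export
count_kmers <- function(sequences, k = 31L) {
  if (is.list(sequences)) sequences <- unlist(sequences)
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && is.null(names(sequences)))
    sequences <- read_fasta(sequences)
  if (length(sequences) == 0 || all(nchar(sequences) == 0))
    stop("no sequences to count")
  stopifnot(k >= 2, k <= 31)
  ptr <- .cm_kmer_table(sequences, as.integer(k))
  structure(list(k = as.integer(k), ptr = ptr,
                 n_kmers = .cm_kmer_table_size(ptr),
                 total = .cm_kmer_total(ptr)),
            class = "KmerCountTable")
}

#' @export
print.KmerCountTable <- function(x, ...) {
  cat("KmerCountTable: k =", x$k, ",", format(x$n_kmers, big.mark = ","),
      "distinct canonical kmers,", format(x$total, big.mark = ","),
      "windows counted\n")
  invisible(x)
}

#' Materialise a k-mer count table as a data frame
#'
#' Only sensible for small tables (guarded at 1e6 keys).
#'
#' @param table a `KmerCountTable`.
#' @return Data frame with columns `kmer`, `count`, sorted by key.
#' @export
kmer_counts_table <- function(table) {
  stopifnot(inherits(table, "KmerCountTable"))
  if (table$n_kmers > 1e6) stop("table too large to materialise")
  d <- .cm_kmer_dump(table$ptr, table$k)
  df <- data.frame(kmer = d$kmer, count = d$count, stringsAsFactors = FALSE)
  df[order(df$kmer), , drop = FALSE]
}

#' Look up canonical counts for specific k-mers
#'
#' @param table a `KmerCountTable`.
#' @param kmers character vector of k-mers (length must equal `table$k`;
#'   non-ACGT k-mers return NA).
#' @return Integer vector of counts (0 where absent).
#' @export
kmer_lookup <- function(table, kmers) {
  stopifnot(inherits(table, "KmerCountTable"))
  .cm_kmer_lookup(table$ptr, kmers, table$k)
}

#' Mask repetitive sequence by k-mer frequency
#'
#' Every base covered by at least one k-mer window whose canonical count
#' exceeds `max_freq` is replaced with 'N'; all other bases are unchanged,
#' so output lengths equal input lengths. Sequences shorter than k are
#' returned unchanged.
#'
#' Counting scope: with `scope = "per_genome"` (the default) each sequence
#' is masked against a k-mer table built from that sequence alone, so the
#' frequency threshold describes repetitiveness within one genome - a
#' single-copy locus shared by every assembly stays unmasked. A pooled
#' corpus (`scope = "pooled"`, or an explicit `table`) counts across all
#' input sequences jointly, which at a threshold of 2 masks everything
#' present in three or more genomes; it is only meaningful for intra-genome
#' corpora.
#'
#' @param sequences named character vector of sequences, or a FASTA path.
#' @param table optional `KmerCountTable` built with the same k on a custom
#'   masking corpus (overrides `scope`).
#' @param max_freq maximum allowed canonical frequency (default 2).
#' @param k k-mer length used when `table` is NULL.
#' @param scope `"per_genome"` (default) or `"pooled"`.
#' @return Named character vector of masked sequences.
#' @examples
#' mask_repeats(c(u = strrep("ACGT", 20)), max_freq = 2, k = 31)
#' @export
mask_repeats <- function(sequences, table = NULL, max_freq = 2L, k = 31L,
                         scope = c("per_genome", "pooled")) {
  scope <- match.arg(scope)
  if (is.list(sequences)) sequences <- unlist(sequences)
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && is.null(names(sequences)))
    sequences <- read_fasta(sequences)
  if (is.null(table) && scope == "per_genome" && length(sequences) > 1) {
    out <- vapply(seq_along(sequences), function(i)
      mask_repeats(sequences[i], max_freq = max_freq, k = k), "")
    names(out) <- names(sequences)
    return(out)
  }
  if (is.null(table)) table <- count_kmers(sequences, k = k)
  stopifnot(inherits(table, "KmerCountTable"))
  out <- .cm_mask_seqs(sequences, table$ptr, table$k, as.integer(max_freq))
  names(out) <- names(sequences)
  out
}

# Per-window canonical counts along one sequence (NA at skipped windows);
# used by the primer-uniqueness check and tests.
window_kmer_counts <- function(sequence, table) {
  .cm_window_counts(sequence, table$ptr, table$k)
}
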