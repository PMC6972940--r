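#' Multi-assembly coverage profile and core genome
#'
#' Counts, at every reference position, how many assemblies have a syntenic
#' block covering it (each assembly counts at most once per position), and
#' extracts the core genome: maximal intervals where the count equals the
#' number of assemblies.
#'
#' @param blocks syntenic block data frame from [select_one_to_one()] (or
#'   several assemblies' worth row-bound together).
#' @param ref_lengths named numeric vector of reference sequence lengths.
#' @param n_assemblies number of assemblies considered; defaults to the
#'   number of distinct assemblies present in `blocks`.
#' @return A list of class `CoverageProfile` with `profile` (run-length
#'   data frame: chrom, start, end, count; 0-based half-open, partitioning
#'   the reference exactly), `core` (interval data frame: chrom, start, end,
#'   sorted and merged) and `n_assemblies`.
#' @export
coverage_and_core <- function(blocks, ref_lengths, n_assemblies = NULL) {
  stopifnot(length(ref_lengths) >= 1)
  if (is.null(n_assemblies)) n_assemblies <- length(unique(blocks$assembly))
  if (n_assemblies < 1) stop("need at least one assembly")
  bad <- which(!(blocks$chrom %in% names(ref_lengths)) |
                 blocks$end > ref_lengths[blocks$chrom])
  if (length(bad))
    stop("block exceeds reference bounds: ", blocks$chrom[bad[1]], ":",
         blocks$start[bad[1]], "-", blocks$end[bad[1]])
  prof <- list(); core <- list()
  for (chrom in names(ref_lengths)) {
    len <- as.integer(ref_lengths[[chrom]])
    b <- blocks[blocks$chrom == chrom, , drop = FALSE]
    cov_total <- S4Vectors::Rle(0L, len)
    for (a in unique(b$assembly)) {
      ba <- b[b$assembly == a, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(ba$start + 1L,
                                             as.integer(ba$end)))
      cov_total <- cov_total + IRanges::coverage(ir, width = len)
    }
    rl <- data.frame(chrom = chrom,
                     start = cumsum(c(0L, S4Vectors::runLength(cov_total))),
                     stringsAsFactors = FALSE)
    rl <- rl[seq_along(S4Vectors::runLength(cov_total)), , drop = FALSE]
    rl$end <- rl$start + S4Vectors::runLength(cov_total)
    rl$count <- S4Vectors::runValue(cov_total)
    prof[[chrom]] <- rl
    sl <- IRanges::slice(cov_total, lower = n_assemblies,
                         rangesOnly = TRUE)
    if (length(sl))
      core[[chrom]] <- data.frame(chrom = chrom,
                                  start = IRanges::start(sl) - 1,
                                  end = as.numeric(IRanges::end(sl)),
                                  stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, prof); rownames(profile) <- NULL
  core <- if (length(core)) do.call(rbind, core) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(core) <- NULL
  structure(list(profile = profile, core = core,
                 n_assemblies = n_assemblies, ref_lengths = ref_lengths),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat("CoverageProfile:", x$n_assemblies, "assemblies over",
      length(x$ref_lengths), "reference sequence(s)\n")
  core_len <- sum(x$core$end - x$core$start)
  cat("  core:", nrow(x$core), "intervals,", core_len, "bp (",
      round(100 * core_len / sum(x$ref_lengths), 2), "% )\n")
  invisible(x)
}

#' Mean core-genome size as assemblies accumulate
#'
#' For each k = 1..n, averages the length of the intersection of the covered
#' intervals of the first k assemblies over random orderings of the available
#' assemblies.
#'
#' @param covered_by_assembly named list; per assembly, an interval data
#'   frame (start, end; 0-based half-open) of reference positions covered by
#'   its syntenic blocks. Use [blocks_to_intervals()] to build it.
#' @param n_orderings number of random orderings to average over
#'   (default 100).
#' @param seed integer seed for the orderings.
#' @return Data frame with columns k, mean_size.
#' @export
core_size_by_k <- function(covered_by_assembly, n_orderings = 100,
                           seed = 1) {
  n <- length(covered_by_assembly)
  stopifnot(n >= 1)
  sizes <- matrix(0, n_orderings, n)
  with_seed(derive_seed(seed, "core_size_orderings"), {
    for (r in seq_len(n_orderings)) {
      ord <- sample(n)
      cur <- covered_by_assembly[[ord[1]]]
      sizes[r, 1] <- iv_length(cur)
      for (k in seq_len(n)[-1]) {
        cur <- iv_intersect(cur, covered_by_assembly[[ord[k]]])
        sizes[r, k] <- iv_length(cur)
      }
    }
  })
  data.frame(k = seq_len(n), mean_size = colMeans(sizes))
}

#' Per-assembly covered reference intervals from syntenic blocks
#'
#' @param blocks block data frame from [select_one_to_one()].
#' @return Named list of merged interval data frames (single-chromosome
#'   references; for multi-chromosome input the chrom column is retained).
#' @export
blocks_to_intervals <- function(blocks) {
  lapply(split(blocks, blocks$assembly), function(b) {
    iv_union(new_intervals(b$start, b$end))
  })
}
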