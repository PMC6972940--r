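#' Simulate paired-end amplicon sequencing reads for a family
#'
#' Per-marker mean depth is drawn lognormally (base-10 parameters), then each
#' haplotype of each sample contributes Poisson(depth/2) read pairs from its
#' allele's amplicon. R1 starts with the forward primer, R2 with the reverse
#' primer (reads are the two ends of the amplicon, as from a paired-end
#' sequencer). Substitution errors are applied per base at `sub_error`;
#' single-base insertions/deletions are applied inside homopolymer runs of
#' length >= 4 at `homopolymer_indel` per run. Null alleles (index 0) yield no
#' reads. Quality strings are constant 'I' (Q30).
#'
#' @param fam a `FamilyTruth` from [simulate_family()].
#' @param depth_log10_mean,depth_log10_sd parameters of the per-marker
#'   log10 mean-depth distribution.
#' @param sub_error per-base substitution error rate.
#' @param homopolymer_indel per-run indel probability in homopolymer runs
#'   of length >= 4.
#' @param read_len read length in bases.
#' @param seed integer seed.
#' @param dir output directory for gzipped FASTQ (two files per sample).
#' @param samples which samples to sequence (default parents + progeny).
#' @return Invisibly, a list with `dir`, `files` (sample, r1, r2), and
#'   `marker_depth` (simulated per-marker mean depth).
#' @export
simulate_amplicon_reads <- function(fam, depth_log10_mean = 1.5,
                                    depth_log10_sd = 0.5,
                                    sub_error = 0.005,
                                    homopolymer_indel = 0.002,
                                    read_len = 150, seed = 1,
                                    dir = tempfile("reads"),
                                    samples = NULL) {
  stopifnot(inherits(fam, "FamilyTruth"))
  panel <- fam$markers$panel
  alleles <- fam$markers$alleles
  plen <- fam$markers$primer_len
  if (read_len < plen + 20)
    stop("read_len must be at least primer length + 20")
  if (any(panel$amplicon_len <= 2 * plen))
    stop("amplicon shorter than its primers")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(samples))
    samples <- c(unique(fam$parent_names), fam$progeny_names)
  M <- nrow(panel)

  depth <- with_seed(derive_seed(seed, "marker_depths"),
                     10^rnorm(M, depth_log10_mean, depth_log10_sd))

  # Precompute read templates and homopolymer runs per marker x allele.
  r1_tpl <- vector("list", M); r2_tpl <- vector("list", M)
  r1_runs <- vector("list", M); r2_runs <- vector("list", M)
  for (m in seq_len(M)) {
    amp <- paste0(panel$fwd[m], alleles[[m]], revcomp(panel$rev[m]))
    r1 <- substr(amp, 1, read_len)
    r2 <- substr(revcomp(amp), 1, read_len)
    r1_tpl[[m]] <- r1; r2_tpl[[m]] <- r2
    r1_runs[[m]] <- lapply(r1, find_homopolymer_runs)
    r2_runs[[m]] <- lapply(r2, find_homopolymer_runs)
  }

  h1 <- fam$genotypes$hap1; h2 <- fam$genotypes$hap2
  files <- data.frame(sample = samples,
                      r1 = file.path(dir, paste0(samples, "_R1.fastq.gz")),
                      r2 = file.path(dir, paste0(samples, "_R2.fastq.gz")),
                      stringsAsFactors = FALSE)
  for (s in seq_along(samples)) {
    smp <- samples[s]
    with_seed(derive_seed(seed, paste0("reads_", smp)), {
      out1 <- character(0); out2 <- character(0); ids <- character(0)
      for (m in seq_len(M)) {
        for (al in c(h1[smp, m], h2[smp, m])) {
          if (al == 0L) next # null allele: no amplification
          n <- rpois(1, depth[m] / 2)
          if (n == 0) next
          a1 <- rep(r1_tpl[[m]][al], n)
          a2 <- rep(r2_tpl[[m]][al], n)
          if (homopolymer_indel > 0) {
            a1 <- apply_homopolymer_indels(a1, r1_runs[[m]][[al]],
                                           homopolymer_indel)
            a2 <- apply_homopolymer_indels(a2, r2_runs[[m]][[al]],
                                           homopolymer_indel)
          }
          if (sub_error > 0) {
            a1 <- mutate_subs(a1, rbinom(n, nchar(a1), sub_error))
            a2 <- mutate_subs(a2, rbinom(n, nchar(a2), sub_error))
          }
          out1 <- c(out1, a1); out2 <- c(out2, a2)
          ids <- c(ids, sprintf("%s:%s:%d:%d", smp, panel$marker_id[m], al,
                                seq_len(n)))
        }
      }
      write_fastq(ids, out1, files$r1[s])
      write_fastq(ids, out2, files$r2[s])
    })
  }
  invisible(list(dir = dir, files = files, marker_depth = depth))
}

# Start/length of homopolymer runs of length >= 4 in a sequence.
find_homopolymer_runs <- function(x) {
  m <- gregexpr("([ACGT])\\1{3,}", x, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), len = integer()))
  data.frame(start = as.integer(m), len = attr(m, "match.length"))
}

# For each read, each homopolymer run independently suffers a single-base
# insertion or deletion with probability `rate`.
apply_homopolymer_indels <- function(reads, runs, rate) {
  if (nrow(runs) == 0 || rate <= 0) return(reads)
  n <- length(reads)
  hit <- matrix(runif(n * nrow(runs)) < rate, nrow = n)
  for (i in which(rowSums(hit) > 0)) {
    x <- reads[i]
    # apply right-to-left so earlier run coordinates stay valid
    for (j in rev(which(hit[i, ]))) {
      s <- runs$start[j]
      b <- substr(x, s, s)
      if (runif(1) < 0.5) {
        x <- paste0(substr(x, 1, s), b, substr(x, s + 1, nchar(x)))
      } else {
        x <- paste0(substr(x, 1, s - 1), substr(x, s + 1, nchar(x)))
      }
    }
    reads[i] <- x
  }
  reads
}
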