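#' Load a multi-sample VCF for marker design
#'
#' Thin wrapper around [vcfR::read.vcfR()] returning the site table and
#' per-site missing-genotype counts used by [region_stats()] and
#' [design_amplicons()].
#'
#' @param path VCF path (plain or bgzipped).
#' @return List with `chrom`, `pos` (1-based), `ref`, `n_missing`,
#'   `n_samples`, `samples`.
#' @export
load_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  n_missing <- if (is.null(gt)) rep(0L, nrow(fix)) else
    rowSums(is.na(gt) | gt == "./." | gt == ".|.")
  list(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
       ref = fix[, "REF"], n_missing = unname(n_missing),
       n_samples = if (is.null(gt)) 0L else ncol(gt),
       samples = colnames(gt))
}

#' Per-region length, diversity and missing-rate statistics
#'
#' For each core-genome region computes: `diversity`, the number of panel
#' variant sites starting in the region divided by its length;
#' `missing_rate`, the mean over the region's variant sites of the fraction
#' of missing panel genotypes (0 where the region has no sites);
#' `core_coverage`, the mean assembly count over the region; and
#' `gene_density`, the fraction of bases overlapping gene annotations.
#'
#' @param core core intervals: data frame with chrom, start, end (0-based
#'   half-open), e.g. `coverage_and_core(...)$core`.
#' @param panel_vcf VCF path or the result of [load_panel_vcf()].
#' @param genes optional gene intervals (chrom, start, end).
#' @param profile optional `CoverageProfile` for `core_coverage`.
#' @return Data frame: chrom, start, end, length, n_sites, diversity,
#'   missing_rate, core_coverage, gene_density.
#' @export
region_stats <- function(core, panel_vcf, genes = NULL, profile = NULL) {
  vcf <- if (is.character(panel_vcf)) load_panel_vcf(panel_vcf) else panel_vcf
  missing_chrom <- setdiff(unique(core$chrom), unique(vcf$chrom))
  if (length(missing_chrom))
    stop("chromosomes absent from the VCF: ",
         paste(missing_chrom, collapse = ", "))
  out <- core
  out$length <- core$end - core$start
  out$n_sites <- 0L
  out$diversity <- 0
  out$missing_rate <- 0
  out$core_coverage <- NA_real_
  out$gene_density <- NA_real_
  for (chrom in unique(core$chrom)) {
    ci <- which(core$chrom == chrom)
    vp <- vcf$pos[vcf$chrom == chrom] - 1 # 0-based site starts
    vm <- vcf$n_missing[vcf$chrom == chrom]
    o <- order(vp); vp <- vp[o]; vm <- vm[o]
    cum_m <- cumsum(c(0, vm))
    for (i in ci) {
      lo <- findInterval(core$start[i] - 0.5, vp)
      hi <- findInterval(core$end[i] - 0.5, vp)
      n <- hi - lo
      out$n_sites[i] <- n
      out$diversity[i] <- n / out$length[i]
      if (n > 0 && vcf$n_samples > 0)
        out$missing_rate[i] <-
          (cum_m[hi + 1] - cum_m[lo + 1]) / (n * vcf$n_samples)
    }
    if (!is.null(profile)) {
      prof <- profile$profile[profile$profile$chrom == chrom, , drop = FALSE]
      pir <- IRanges::IRanges(prof$start + 1L, as.integer(prof$end))
      rir <- IRanges::IRanges(core$start[ci] + 1L, as.integer(core$end[ci]))
      ov <- IRanges::findOverlaps(rir, pir)
      w <- IRanges::width(IRanges::pintersect(
        rir[S4Vectors::queryHits(ov)], pir[S4Vectors::subjectHits(ov)]))
      s <- tapply(w * prof$count[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), sum)
      out$core_coverage[ci[as.integer(names(s))]] <-
        s / out$length[ci[as.integer(names(s))]]
    }
    if (!is.null(genes)) {
      ge <- genes[genes$chrom == chrom, , drop = FALSE]
      gir <- IRanges::reduce(IRanges::IRanges(ge$start + 1L,
                                              as.integer(ge$end)))
      rir <- IRanges::IRanges(core$start[ci] + 1L, as.integer(core$end[ci]))
      out$gene_density[ci] <- 0
      if (length(gir)) {
        ov <- IRanges::findOverlaps(rir, gir)
        w <- IRanges::width(IRanges::pintersect(
          rir[S4Vectors::queryHits(ov)], gir[S4Vectors::subjectHits(ov)]))
        s <- tapply(w, S4Vectors::queryHits(ov), sum)
        out$gene_density[ci[as.integer(names(s))]] <-
          s / out$length[ci[as.integer(names(s))]]
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Filter candidate regions on length, diversity and missing rate
#'
#' Removal uses strict inequalities: regions shorter than `min_len`, with
#' diversity larger than `div_hi` or smaller than `div_lo`, or with mean
#' missing rate larger than `max_missing` are removed. In `"percentile"`
#' mode the diversity bounds are replaced by the empirical 25th and 75th
#' percentiles of the input regions' diversity.
#'
#' @param stats region statistics from [region_stats()].
#' @param min_len minimum region length (default 200 bp).
#' @param div_lo,div_hi diversity bounds (defaults 0.02 and 0.07).
#' @param max_missing maximum mean missing rate (default 0.5).
#' @param mode `"absolute"` (default) or `"percentile"`.
#' @return The retained rows of `stats`.
#' @export
filter_candidates <- function(stats, min_len = 200, div_lo = 0.02,
                              div_hi = 0.07, max_missing = 0.5,
                              mode = c("absolute", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(div_lo < div_hi)
  if (mode == "percentile") {
    q <- quantile(stats$diversity, c(0.25, 0.75), names = FALSE, type = 7)
    div_lo <- q[1]; div_hi <- q[2]
  }
  keep <- !(stats$length < min_len |
              stats$diversity > div_hi | stats$diversity < div_lo |
              stats$missing_rate > max_missing)
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select genomically spaced candidate regions
#'
#' Tiles the reference into `spacing`-sized bins and draws one qualified
#' candidate per bin with probability proportional to
#' `1 + gene_weight * gene_density` (seeded). Any `fallback_window`-sized
#' window containing no qualified candidate admits instead the core region
#' with maximum `core_coverage` in that window, even if it failed the
#' polymorphism filters.
#'
#' @param candidates qualified regions from [filter_candidates()].
#' @param all_regions the unfiltered region statistics (fallback pool).
#' @param spacing bin size in bases (default 200 kb).
#' @param fallback_window window size triggering the coverage fallback
#'   (default 1 Mb).
#' @param gene_weight weight of gene density in the sampling probability
#'   (default 1).
#' @param seed integer seed.
#' @param ref_len reference length; defaults to the maximum region end.
#' @return Selected regions sorted by position, with a `source` column
#'   (`"selected"` or `"fallback"`).
#' @export
select_spaced_markers <- function(candidates, all_regions = candidates,
                                  spacing = 2e5, fallback_window = 1e6,
                                  gene_weight = 1, seed = 1,
                                  ref_len = NULL) {
  stopifnot(spacing > 0)
  if (is.null(ref_len)) ref_len <- max(all_regions$end, candidates$end, 0)
  picked <- list()
  with_seed(derive_seed(seed, "marker_selection"), {
    for (chrom in unique(all_regions$chrom)) {
      cand <- candidates[candidates$chrom == chrom, , drop = FALSE]
      allr <- all_regions[all_regions$chrom == chrom, , drop = FALSE]
      bins <- seq(0, ref_len - 1, by = spacing)
      for (b in bins) {
        in_bin <- cand[cand$start >= b & cand$start < b + spacing, ,
                       drop = FALSE]
        if (nrow(in_bin)) {
          w <- 1 + gene_weight * ifelse(is.na(in_bin$gene_density), 0,
                                        in_bin$gene_density)
          i <- sample.int(nrow(in_bin), 1, prob = w)
          row <- in_bin[i, , drop = FALSE]
          row$source <- "selected"
          picked[[length(picked) + 1L]] <- row
        }
      }
      # coverage fallback for marker deserts
      fwins <- seq(0, ref_len - 1, by = fallback_window)
      for (fw in fwins) {
        has_cand <- any(cand$start >= fw & cand$start < fw + fallback_window)
        if (has_cand) next
        pool <- allr[allr$start >= fw & allr$start < fw + fallback_window, ,
                     drop = FALSE]
        if (nrow(pool) == 0 || all(is.na(pool$core_coverage))) next
        row <- pool[which.max(pool$core_coverage), , drop = FALSE]
        row$source <- "fallback"
        picked[[length(picked) + 1L]] <- row
      }
    }
  })
  if (length(picked) == 0) {
    warning("no candidate regions selected")
    out <- candidates[0, , drop = FALSE]
    out$source <- character(0)
    return(out)
  }
  out <- do.call(rbind, picked)
  out <- out[!duplicated(out[c("chrom", "start", "end")]), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design amplicons with conserved, unique primer windows
#'
#' Scans each selected region for a forward/reverse primer window pair such
#' that both windows are free of panel variants (indel-aware: a variant
#' intersects a window if its reference-allele span does), contain no masked
#' ('N') bases, have unique k-mer context in the masked reference, and
#' enclose an amplicon whose total length lies within `amplicon_range`.
#' Among feasible pairs the one maximizing the number of enclosed variant
#' sites is chosen (ties resolved leftmost). Regions with no feasible pair
#' are reported with `status = "failed"` rather than raising an error.
#'
#' Primer windows use the minimum length of `primer_len_range` (primer
#' thermodynamics and exact lengths are the synthesis vendor's concern; this
#' stage enforces conservation, uniqueness and amplicon size only).
#'
#' @param selected selected regions from [select_spaced_markers()].
#' @param masked_ref masked reference: named character vector or FASTA path.
#' @param panel_vcf VCF path or [load_panel_vcf()] result.
#' @param primer_len_range allowed primer lengths (default 18-27).
#' @param amplicon_range allowed amplicon lengths, primers included
#'   (default 270-330).
#' @param kmer_table optional `KmerCountTable` built on `masked_ref` (built
#'   internally when NULL).
#' @param k k-mer length for the uniqueness check (default 31).
#' @return Data frame with one row per region: marker_id (`chrom_pos`,
#'   1-based amplicon start), chrom, amplicon_start (1-based),
#'   amplicon_end (1-based inclusive), amplicon_len, fwd_primer, rev_primer,
#'   n_target_variants, status.
#' @export
design_amplicons <- function(selected, masked_ref, panel_vcf,
                             primer_len_range = c(18, 27),
                             amplicon_range = c(270, 330),
                             kmer_table = NULL, k = 31L) {
  if (is.character(masked_ref) && length(masked_ref) == 1 &&
      file.exists(masked_ref) && is.null(names(masked_ref)))
    masked_ref <- read_fasta(masked_ref)
  vcf <- if (is.character(panel_vcf)) load_panel_vcf(panel_vcf) else panel_vcf
  if (is.null(kmer_table)) kmer_table <- count_kmers(masked_ref, k = k)
  plen <- as.integer(primer_len_range[1])
  amp_min <- amplicon_range[1]; amp_max <- amplicon_range[2]
  stopifnot(amp_min > 2 * plen, amp_max >= amp_min)

  res <- vector("list", nrow(selected))
  wc_cache <- list()
  for (i in seq_len(nrow(selected))) {
    chrom <- selected$chrom[i]
    s <- selected$start[i]; e <- selected$end[i]
    seqc <- masked_ref[[chrom]]
    if (is.null(wc_cache[[chrom]]))
      wc_cache[[chrom]] <- window_kmer_counts(seqc, kmer_table)
    wc <- wc_cache[[chrom]]
    vp <- vcf$pos[vcf$chrom == chrom] - 1 # 0-based variant starts
    vw <- nchar(vcf$ref[vcf$chrom == chrom]) # reference-allele spans
    o <- order(vp); vp <- vp[o]; vw <- vw[o]
    d <- design_one_region(seqc, wc, s, e, vp, vw, plen, amp_min, amp_max,
                           kmer_table$k)
    if (is.null(d)) {
      res[[i]] <- data.frame(marker_id = NA_character_, chrom = chrom,
                             amplicon_start = NA_real_,
                             amplicon_end = NA_real_,
                             amplicon_len = NA_real_,
                             fwd_primer = NA_character_,
                             rev_primer = NA_character_,
                             n_target_variants = NA_real_,
                             status = "failed", stringsAsFactors = FALSE)
    } else {
      astart1 <- d$L + 1 # 1-based amplicon start
      aend1 <- d$R + plen # 1-based inclusive end
      res[[i]] <- data.frame(
        marker_id = sprintf("%s_%d", chrom, astart1), chrom = chrom,
        amplicon_start = astart1, amplicon_end = aend1,
        amplicon_len = aend1 - astart1 + 1,
        fwd_primer = substr(seqc, d$L + 1, d$L + plen),
        rev_primer = revcomp(substr(seqc, d$R + 1, d$R + plen)),
        n_target_variants = d$n_var, status = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Best feasible primer pair in one region; coordinates 0-based on the
# chromosome. Returns NULL when no pair is feasible.
design_one_region <- function(seqc, wc, s, e, vp, vw, plen, amp_min,
                              amp_max, k) {
  if (e - s < amp_min) return(NULL)
  starts <- s:(e - plen) # candidate primer-window starts
  # N-free windows (masked repeats excluded)
  sub <- substring(seqc, starts + 1, starts + plen)
  ok <- !grepl("N", sub, fixed = TRUE)
  # variant-free windows: any variant span [vp, vp+vw) intersecting
  if (length(vp)) {
    ir_w <- IRanges::IRanges(starts + 1L, width = plen)
    ir_v <- IRanges::IRanges(vp + 1L, width = pmax(vw, 1L))
    ok <- ok & IRanges::countOverlaps(ir_w, ir_v) == 0
  }
  # unique k-mer context: all non-skipped k-windows containing the primer
  # window must have canonical count 1 (and at least one must exist)
  nwc <- length(wc)
  bad_cum <- cumsum(c(0L, !is.na(wc) & wc != 1L))
  good_cum <- cumsum(c(0L, !is.na(wc) & wc == 1L))
  lo <- pmax(0L, starts + plen - k) + 1L # 1-based window index range
  hi <- pmin(starts, nwc - 1L) + 1L
  kctx <- hi >= lo &
    (bad_cum[pmin(hi, nwc) + 1L] - bad_cum[pmax(lo, 1L)]) == 0L &
    (good_cum[pmin(hi, nwc) + 1L] - good_cum[pmax(lo, 1L)]) > 0L
  ok <- ok & kctx
  feas <- starts[ok]
  if (length(feas) < 2) return(NULL)
  # cumulative count of variant starts before each position
  n_before <- function(pos) findInterval(pos - 0.5, vp)
  # for each feasible L, rightmost feasible R within the length window
  Lv <- feas
  R_hi <- Lv + amp_max - plen # inclusive upper bound for R (0-based start)
  R_lo <- Lv + amp_min - plen
  idx_hi <- findInterval(R_hi, feas)
  best <- NULL
  cnt <- rep(-1, length(Lv))
  Rpick <- rep(NA_real_, length(Lv))
  valid <- idx_hi >= 1 & feas[pmax(idx_hi, 1)] >= R_lo
  for (j in which(valid)) {
    R <- feas[idx_hi[j]]
    if (R <= Lv[j] + plen) next
    cnt[j] <- n_before(R) - n_before(Lv[j] + plen)
    Rpick[j] <- R
  }
  if (all(cnt < 0)) return(NULL)
  jbest <- which.max(cnt) # which.max returns first (leftmost) maximum
  L <- Lv[jbest]
  # leftmost feasible R achieving the same enclosed-variant count
  target <- cnt[jbest]
  Rcand <- feas[feas >= R_lo[jbest] & feas <= R_hi[jbest] & feas > L + plen]
  for (R in Rcand) {
    if (n_before(R) - n_before(L + plen) == target)
      return(list(L = L, R = R, n_var = target))
  }
  list(L = L, R = Rpick[jbest], n_var = target)
}
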