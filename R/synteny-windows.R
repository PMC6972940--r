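#' Windowed coverage vs feature-density correlation
#'
#' Tiles the reference into fixed windows, computes per-window mean assembly
#' coverage from the profile and per-window feature density (fraction of
#' bases overlapped by feature intervals, e.g. genes or TE annotations), and
#' reports the two-sided Spearman rank correlation (midranks for ties).
#'
#' @param profile a `CoverageProfile` from [coverage_and_core()].
#' @param features feature intervals: data frame with chrom, start, end
#'   (0-based half-open), e.g. read from a BED file.
#' @param window window size in bases (>= 10 kb; default 1 Mb).
#' @return List with `table` (chrom, start, end, mean_coverage,
#'   feature_density), `rho` and `p`.
#' @export
window_feature_correlation <- function(profile, features, window = 1e6) {
  stopifnot(inherits(profile, "CoverageProfile"), window >= 1e4)
  tabs <- list()
  for (chrom in names(profile$ref_lengths)) {
    len <- profile$ref_lengths[[chrom]]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    prof <- profile$profile[profile$profile$chrom == chrom, , drop = FALSE]
    fe <- features[features$chrom == chrom, , drop = FALSE]
    fir <- IRanges::reduce(IRanges::IRanges(fe$start + 1L,
                                            as.integer(fe$end)))
    pir <- IRanges::IRanges(prof$start + 1L, as.integer(prof$end))
    wir <- IRanges::IRanges(starts + 1L, as.integer(ends))
    mean_cov <- feat_den <- numeric(length(starts))
    ovp <- IRanges::findOverlaps(wir, pir)
    wid <- IRanges::width(IRanges::pintersect(
      wir[S4Vectors::queryHits(ovp)], pir[S4Vectors::subjectHits(ovp)]))
    cov_sum <- tapply(wid * prof$count[S4Vectors::subjectHits(ovp)],
                      S4Vectors::queryHits(ovp), sum)
    mean_cov[as.integer(names(cov_sum))] <- cov_sum / (ends - starts)[
      as.integer(names(cov_sum))]
    if (length(fir)) {
      ovf <- IRanges::findOverlaps(wir, fir)
      widf <- IRanges::width(IRanges::pintersect(
        wir[S4Vectors::queryHits(ovf)], fir[S4Vectors::subjectHits(ovf)]))
      fsum <- tapply(widf, S4Vectors::queryHits(ovf), sum)
      feat_den[as.integer(names(fsum))] <- fsum / (ends - starts)[
        as.integer(names(fsum))]
    }
    tabs[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                mean_coverage = mean_cov,
                                feature_density = feat_den,
                                stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs); rownames(tab) <- NULL
  if (nrow(tab) == 0) stop("zero windows: check window size vs reference")
  ct <- suppressWarnings(cor.test(tab$mean_coverage, tab$feature_density,
                                  method = "spearman", exact = FALSE))
  list(table = tab, rho = unname(ct$estimate), p = ct$p.value)
}
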