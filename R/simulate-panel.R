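#' Simulate a diversity-panel VCF over a simulated reference
#'
#' Draws biallelic SNP sites uniformly along the reference at a target
#' genome-wide density, assigns each site a population allele frequency, and
#' samples diploid genotypes for a panel of accessions with independent
#' per-genotype missingness. The realised density equals
#' `round(target_density * ref_len) / ref_len` exactly.
#'
#' @param truth a `PanGenomeTruth` from [simulate_pangenome()].
#' @param n_samples number of panel accessions.
#' @param target_density variants per base, in `(0, 0.1]`.
#' @param missing_rate per-genotype missing probability, in `[0, 1)`.
#' @param seed integer seed.
#' @param path output VCF path (plain text, VCF 4.2, sorted, 1-based).
#' @return Invisibly, a list with `path`, `records` (chrom, pos, id, ref,
#'   alt) and `gt` (site x sample genotype matrix of `"0/0"`-style strings).
#' @export
simulate_panel_variants <- function(truth, n_samples = 40,
                                    target_density = 0.032,
                                    missing_rate = 0.1, seed = 1,
                                    path = tempfile(fileext = ".vcf")) {
  stopifnot(inherits(truth, "PanGenomeTruth"),
            target_density > 0, target_density <= 0.1,
            missing_rate >= 0, missing_rate < 1, n_samples >= 1)
  ref_len <- truth$ref_len
  n_sites <- round(target_density * ref_len)
  samples <- sprintf("acc%03d", seq_len(n_samples))

  out <- with_seed(derive_seed(seed, "panel_vcf"), {
    pos <- sort(sample.int(ref_len, n_sites)) # 1-based
    ref_al <- substring(truth$reference, pos, pos)
    alt_al <- vapply(ref_al, function(b) sample(setdiff(DNA, b), 1), "",
                     USE.NAMES = FALSE)
    p_alt <- runif(n_sites, 0.05, 0.95)
    a1 <- matrix(rbinom(n_sites * n_samples, 1, p_alt),
                 nrow = n_sites)
    a2 <- matrix(rbinom(n_sites * n_samples, 1, p_alt),
                 nrow = n_sites)
    gt <- matrix(paste0(pmin(a1, a2), "/", pmax(a1, a2)), nrow = n_sites)
    if (missing_rate > 0) {
      miss <- matrix(runif(n_sites * n_samples) < missing_rate,
                     nrow = n_sites)
      gt[miss] <- "./."
    }
    list(pos = pos, ref = ref_al, alt = alt_al, gt = gt)
  })

  records <- data.frame(chrom = truth$ref_name, pos = out$pos,
                        id = sprintf("%s_%d", truth$ref_name, out$pos),
                        ref = out$ref, alt = out$alt,
                        stringsAsFactors = FALSE)
  write_vcf(records, out$gt, samples, path)
  invisible(list(path = path, records = records, gt = out$gt,
                 samples = samples))
}
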