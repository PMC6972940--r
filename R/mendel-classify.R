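#' Classify markers by family performance
#'
#' Applies the class hierarchy: `failed` (mean read depth below
#' `min_mean_depth` across the family), then `monomorphic` (at most one
#' allele among called genotypes), then `distorted` (segregation chi-squared
#' below tolerance, or progeny classes impossible under the nominal parental
#' genotypes), else `mappable`. Distorted and monomorphic markers are
#' additionally scanned for hemizygous rescue with [hemizygosity_scan()].
#'
#' @param gm a `GenotypeMatrix`.
#' @param pedigree pedigree data frame (child, mother, father, family).
#' @param cross_type `"F1"`, `"F2"` or `"BC"`.
#' @param tolerance chi-squared tolerance; defaults to 1e-3 for F1/BC and
#'   1e-10 for F2 families.
#' @param min_mean_depth depth threshold for the `failed` class (default 1).
#' @param err_class_frac fraction of progeny tolerated in genotype classes
#'   impossible under the parental model before the marker counts as
#'   distorted (default 0.1; such calls are genotyping errors, e.g. allele
#'   dropout at low depth).
#' @return Data frame: marker, mean_depth, n_alleles, chi2, p, class,
#'   rescued, best_model.
#' @export
classify_markers <- function(gm, pedigree, cross_type = "F1",
                             tolerance = NULL, min_mean_depth = 1,
                             err_class_frac = 0.1) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  if (is.null(tolerance))
    tolerance <- if (cross_type == "F2") 1e-10 else 1e-3
  mother <- pedigree$mother[1]; father <- pedigree$father[1]
  children <- intersect(pedigree$child, gm$samples)
  out <- data.frame(marker = gm$markers, mean_depth = rowMeans(gm$depth),
                    n_alleles = NA_integer_, chi2 = NA_real_, p = NA_real_,
                    class = NA_character_, rescued = FALSE,
                    best_model = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(gm$markers)) {
    mk <- gm$markers[i]
    als <- stats::na.omit(c(gm$a1[mk, ], gm$a2[mk, ]))
    out$n_alleles[i] <- length(unique(als))
    if (out$mean_depth[i] < min_mean_depth) {
      out$class[i] <- "failed"; next
    }
    gt_lab <- function(s) {
      if (is.na(gm$a1[mk, s])) return(NA_character_)
      paste(gm$a1[mk, s], gm$a2[mk, s], sep = "/")
    }
    p1 <- gt_lab(mother); p2 <- gt_lab(father)
    prog <- vapply(children, gt_lab, "")
    obs <- table(prog[!is.na(prog)])
    if (out$n_alleles[i] <= 1) {
      out$class[i] <- "monomorphic"
    } else if (!is.na(p1) && !is.na(p2) && length(obs)) {
      al1 <- strsplit(p1, "/")[[1]]; al2 <- strsplit(p2, "/")[[1]]
      model <- if (cross_type == "F2") cross_model(al1, al1, cross_type)
        else cross_model(al1, al2, cross_type)
      seg <- segregation_chi2(obs, expected_offspring_ratios(model),
                              tolerance, err_class_frac)
      out$chi2[i] <- seg$chi2; out$p[i] <- seg$p
      out$class[i] <- if (seg$verdict %in% c("distorted", "failed"))
        "distorted" else "mappable"
    } else {
      out$class[i] <- "mappable" # parents uncallable: no segregation test
    }
    if (out$class[i] %in% c("distorted", "monomorphic") &&
        !is.na(p1) && !is.na(p2) && length(obs)) {
      scan <- hemizygosity_scan(obs, strsplit(p1, "/")[[1]],
                                strsplit(p2, "/")[[1]], cross_type,
                                tolerance, err_class_frac)
      out$rescued[i] <- scan$rescued
      out$best_model[i] <- paste(scan$models$parent1[scan$best], "x",
                                 scan$models$parent2[scan$best])
    }
  }
  out
}

#' Audit primer windows for parental variants
#'
#' Flags marker/parent combinations where at least one variant record in the
#' parent's whole-genome VCF intersects either primer window of the marker
#' (reference-allele span, indel-aware). Used to test whether hemizygous
#' (null-allele) markers are explained by primer-site mismatch.
#'
#' @param parent_vcfs named list/vector of per-parent VCF paths.
#' @param panel primer panel with genomic coordinates (see
#'   [as_primer_panel()]).
#' @return Logical matrix markers x parents.
#' @export
primer_variant_check <- function(parent_vcfs, panel) {
  panel <- as_primer_panel(panel)
  flen <- nchar(panel$fwd); rlen <- nchar(panel$rev)
  flags <- matrix(FALSE, nrow(panel), length(parent_vcfs),
                  dimnames = list(panel$marker_id, names(parent_vcfs)))
  fwd_ir <- IRanges::IRanges(panel$amplicon_start,
                             panel$amplicon_start + flen - 1)
  rev_ir <- IRanges::IRanges(panel$amplicon_end - rlen + 1,
                             panel$amplicon_end)
  for (p in names(parent_vcfs)) {
    vcf <- load_panel_vcf(parent_vcfs[[p]])
    for (chrom in unique(panel$chrom)) {
      rows <- which(panel$chrom == chrom)
      sel <- vcf$chrom == chrom
      if (!any(sel)) next
      vir <- IRanges::IRanges(vcf$pos[sel],
                              vcf$pos[sel] + nchar(vcf$ref[sel]) - 1)
      hit <- IRanges::countOverlaps(fwd_ir[rows], vir) > 0 |
        IRanges::countOverlaps(rev_ir[rows], vir) > 0
      flags[rows, p] <- hit
    }
  }
  flags
}

#' Summarise primer-mismatch enrichment among rescued markers
#'
#' @param flags logical matrix from [primer_variant_check()].
#' @param rescued character vector of marker ids flagged hemizygous-rescued.
#' @return List with `frac_rescued` and `frac_other`: the fraction of
#'   markers with a primer-window variant in either group.
#' @export
primer_mismatch_summary <- function(flags, rescued) {
  any_flag <- rowSums(flags) > 0
  in_rescued <- rownames(flags) %in% rescued
  list(frac_rescued = if (any(in_rescued)) mean(any_flag[in_rescued])
         else NA_real_,
       frac_other = if (any(!in_rescued)) mean(any_flag[!in_rescued])
         else NA_real_)
}

#' Identity-by-state distances and classical MDS
#'
#' IBS between two samples is the mean, over markers non-missing in both, of
#' the shared-allele fraction (0, 1/2 or 1 per marker). The distance is
#' 1 - IBS; coordinates come from classical metric MDS (double-centering +
#' eigendecomposition), ordered by eigenvalue.
#'
#' @param gm a `GenotypeMatrix` (>= 3 samples).
#' @param k number of principal coordinates (default 3).
#' @return List with `ibs`, `dist` (matrices), `points` (samples x k) and
#'   `eig`. Sample pairs sharing no markers yield NA distances; the samples
#'   involved are dropped from the MDS with a warning.
#' @export
ibs_mds <- function(gm, k = 3) {
  stopifnot(inherits(gm, "GenotypeMatrix"), length(gm$samples) >= 3)
  n <- length(gm$samples)
  ibs <- matrix(NA_real_, n, n, dimnames = list(gm$samples, gm$samples))
  diag(ibs) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- pair_ibs(gm$a1[, i], gm$a2[, i], gm$a1[, j], gm$a2[, j])
    ibs[i, j] <- ibs[j, i] <- s
  }
  d <- 1 - ibs
  use <- rep(TRUE, n)
  if (anyNA(d)) {
    warning("sample pairs with no shared markers excluded from MDS")
    while (anyNA(d[use, use])) {
      na_count <- rowSums(is.na(d[use, use, drop = FALSE]))
      use[which(use)[which.max(na_count)]] <- FALSE
    }
  }
  mds <- cmdscale(stats::as.dist(d[use, use]), k = k, eig = TRUE)
  list(ibs = ibs, dist = d, points = mds$points, eig = mds$eig)
}

pair_ibs <- function(a1, a2, b1, b2) {
  ok <- !is.na(a1) & !is.na(b1)
  if (!any(ok)) return(NA_real_)
  a1 <- a1[ok]; a2 <- a2[ok]; b1 <- b1[ok]; b2 <- b2[ok]
  exact <- a1 == b1 & a2 == b2
  partial <- a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2
  mean(ifelse(exact, 1, ifelse(partial, 0.5, 0)))
}
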