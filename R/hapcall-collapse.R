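#' Collapse error-derived haplotype variants
#'
#' Per marker, every observed haplotype is aligned to the most frequent
#' haplotype (global alignment, unit gap costs) and projected onto its
#' coordinates. Candidate variant columns are derived from haplotypes seen at
#' least `min_hap_count` times family-wide (singleton error haplotypes do not
#' nominate columns but are still re-keyed). Columns are then dropped if they
#' fall inside a homopolymer run of length >= `homopolymer_min` in the
#' dominant haplotype, or if the column's called genotypes across progeny
#' deviate from the Mendelian expectation implied by the parents' column
#' genotypes (chi-squared test at `seg_alpha`). If no candidate column
#' passes, the single column with the largest minor allele frequency is
#' retained. Haplotypes are re-keyed on the retained columns, summing read
#' counts; each collapsed allele is reported as the full-length haplotype
#' string of its highest-count member.
#'
#' @param hc a `HaplotypeCounts` from [demultiplex_reads()].
#' @param pedigree data frame (child, mother, father, family), e.g.
#'   [family_pedigree()].
#' @param homopolymer_min minimum homopolymer run length to blacklist
#'   (default 4).
#' @param seg_alpha Mendelian chi-squared tolerance for columns
#'   (default 1e-3).
#' @param min_hap_count minimum family-wide count for a haplotype to
#'   nominate variant columns (default 3).
#' @param min_depth,min_frac genotype-calling thresholds used for the
#'   per-column segregation test.
#' @return A collapsed `HaplotypeCounts`; per marker, total counts are
#'   conserved exactly.
#' @export
collapse_haplotypes <- function(hc, pedigree, homopolymer_min = 4,
                                seg_alpha = 1e-3, min_hap_count = 3,
                                min_depth = 5, min_frac = 0.2) {
  stopifnot(inherits(hc, "HaplotypeCounts"))
  mother <- pedigree$mother[1]; father <- pedigree$father[1]
  children <- intersect(pedigree$child, hc$samples)
  out <- hc
  for (mk in names(hc$counts)) {
    percell <- hc$counts[[mk]]
    if (length(percell) == 0) next
    haps <- unique(unlist(lapply(percell, names), use.names = FALSE))
    if (length(haps) <= 1) next
    smp <- names(percell)
    C <- matrix(0, length(smp), length(haps),
                dimnames = list(smp, haps))
    for (s in smp) C[s, names(percell[[s]])] <- percell[[s]]
    total <- colSums(C)
    dom <- haps[order(-total, haps, method = "radix")][1]
    P <- project_onto(haps, dom)
    freq <- total >= min_hap_count | haps == dom
    cand <- which(colSums(P[freq, , drop = FALSE] !=
                            matrix(P[haps == dom, ], sum(freq),
                                   ncol(P), byrow = TRUE)) > 0)
    # homopolymer blacklist on the dominant haplotype
    if (length(cand)) {
      runs <- find_homopolymer_runs(gsub("+", "", dom, fixed = TRUE))
      runs <- runs[runs$len >= homopolymer_min, , drop = FALSE]
      if (nrow(runs)) {
        in_run <- unlist(lapply(seq_len(nrow(runs)), function(i)
          seq(runs$start[i], runs$start[i] + runs$len[i] - 1)))
        cand <- setdiff(cand, in_run)
      }
    }
    retained <- integer()
    maf <- numeric(length(cand))
    tC <- t(C)
    for (ci in seq_along(cand)) {
      col <- cand[ci]
      bc <- t(rowsum(tC, group = P[, col]))
      tot <- colSums(bc)
      maf[ci] <- if (length(tot) > 1) sort(tot, decreasing = TRUE)[2] /
        sum(tot) else 0
      gt <- column_genotypes(bc, min_depth, min_frac)
      # a column must segregate among called genotypes: constant columns
      # are error noise (or uninformative in this family) and re-keying on
      # them would keep every error haplotype distinct
      if (length(unique(gt[!is.na(gt)])) < 2) next
      keep <- TRUE
      g1 <- gt[mother]; g2 <- gt[father]
      if (!is.na(g1) && !is.na(g2)) {
        model <- cross_model(strsplit(g1, "/")[[1]],
                             strsplit(g2, "/")[[1]])
        exp_p <- expected_offspring_ratios(model)
        obs <- table(gt[children])
        if (sum(obs) > 0) {
          seg <- segregation_chi2(obs, exp_p, tolerance = seg_alpha,
                                  err_class_frac = 0.1)
          keep <- seg$verdict == "mendelian"
        }
      }
      if (keep) retained <- c(retained, col)
    }
    if (length(retained) == 0 && length(cand))
      retained <- cand[which.max(maf)]
    # re-key on retained columns, summing counts ('*' = the single group
    # left when no informative column exists; empty names break indexing)
    key <- if (length(retained))
      paste0("*", apply(P[, retained, drop = FALSE], 1, paste,
                        collapse = "")) else
        rep("*", length(haps))
    rep_of <- vapply(split(seq_along(haps), key), function(ix)
      haps[ix][order(-total[ix], haps[ix], method = "radix")][1], "")
    new_counts <- lapply(percell, function(v) {
      g <- rowsum(as.numeric(v), group = rep_of[key[match(names(v), haps)]])
      setNames(as.integer(g[, 1]), rownames(g))
    })
    out$counts[[mk]] <- new_counts
  }
  out
}

# Align haplotypes to the dominant one (global, unit gap costs) and project
# onto its coordinates; returns a (haplotype x dominant-position) character
# matrix ('-' where the haplotype has a deletion; insertions relative to
# the dominant are dropped). The '+' pair-join sentinel is removed prior to
# alignment.
project_onto <- function(haps, dom) {
  dom_nj <- gsub("+", "", dom, fixed = TRUE)
  haps_nj <- gsub("+", "", haps, fixed = TRUE)
  proj <- .cm_project_onto(haps_nj, dom_nj)
  matrix(unlist(strsplit(proj, ""), use.names = FALSE),
         nrow = length(haps), byrow = TRUE)
}

# call a diploid genotype per sample from per-base counts at one column
column_genotypes <- function(bc, min_depth, min_frac) {
  depth <- rowSums(bc)
  out <- rep(NA_character_, nrow(bc))
  names(out) <- rownames(bc)
  for (i in which(depth >= min_depth)) {
    v <- bc[i, ]
    v <- v[v / depth[i] >= min_frac]
    v <- sort(v, decreasing = TRUE)
    if (length(v) == 1) out[i] <- paste(names(v), names(v), sep = "/")
    else if (length(v) >= 2) {
      al <- sort(names(v)[1:2], method = "radix")
      out[i] <- paste(al[1], al[2], sep = "/")
    }
  }
  out
}
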