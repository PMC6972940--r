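#' Simulate a multiplex amplicon marker panel with known allele series
#'
#' Builds a panel of haplotype amplicon markers on one chromosome: each marker
#' has a forward/reverse primer pair and a small catalog of insert alleles
#' differing at a few polymorphic positions, mimicking multiallelic
#' microhaplotype markers.
#'
#' @param n_markers number of markers.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bases (markers are evenly spaced).
#' @param amplicon_range min/max amplicon length (primers included).
#' @param primer_len primer length in bases.
#' @param n_alleles alleles per marker.
#' @param n_var polymorphic positions per marker insert.
#' @return A `MarkerPanelSim` list with `panel` (data frame: marker_id, chrom,
#'   amplicon_start (1-based), amplicon_end, fwd, rev, amplicon_len) and
#'   `alleles` (per-marker character vector of insert allele sequences).
#' @export
simulate_marker_panel <- function(n_markers, seed = 1, chrom = "chr1",
                                  chrom_len = n_markers * 2e5,
                                  amplicon_range = c(270, 330),
                                  primer_len = 20, n_alleles = 4, n_var = 8) {
  stopifnot(n_markers >= 1, n_alleles >= 1)
  with_seed(derive_seed(seed, "marker_panel"), {
    pos <- round(seq(1e4, chrom_len - 1e4, length.out = n_markers))
    amp_len <- sample(seq(amplicon_range[1], amplicon_range[2]), n_markers,
                      replace = TRUE)
    ins_len <- amp_len - 2 * primer_len
    alleles <- vector("list", n_markers)
    fwd <- character(n_markers); rev <- character(n_markers)
    for (m in seq_len(n_markers)) {
      fwd[m] <- random_dna(primer_len)
      rev[m] <- random_dna(primer_len)
      base <- random_dna(ins_len[m])
      var_pos <- sort(sample.int(ins_len[m], min(n_var, ins_len[m])))
      al <- character(n_alleles)
      seen <- character()
      for (j in seq_len(n_alleles)) {
        repeat {
          r <- charToRaw(base)
          for (p in var_pos) r[p] <- charToRaw(sample(DNA, 1))
          cand <- rawToChar(r)
          if (!cand %in% seen) break
        }
        seen <- c(seen, cand)
        al[j] <- cand
      }
      alleles[[m]] <- al
    }
    panel <- data.frame(
      marker_id = sprintf("%s_%d", chrom, pos), chrom = chrom,
      amplicon_start = pos, amplicon_end = pos + amp_len - 1,
      fwd = fwd, rev = rev, amplicon_len = amp_len,
      stringsAsFactors = FALSE)
    structure(list(panel = panel, alleles = alleles,
                   primer_len = primer_len, chrom_len = chrom_len),
              class = "MarkerPanelSim")
  })
}

#' Simulate a biparental family with recombination and optional null alleles
#'
#' Forms gametes by Poisson-count crossovers along the chromosome and records
#' truth diploid genotypes for every progeny at every marker. `F1` crosses the
#' two parents directly; `F2` selfs a single F1 individual; `BC` backcrosses
#' an F1 to parent 1. Null (non-amplifying) alleles are encoded as allele
#' index 0: they transmit Mendelian-ly but yield no sequencing reads
#' downstream.
#'
#' @param markers a `MarkerPanelSim` from [simulate_marker_panel()].
#' @param cross_type one of `"F1"`, `"F2"`, `"BC"`.
#' @param n_progeny number of progeny.
#' @param recomb_rate recombination rate in cM/Mb.
#' @param null_spec optional data frame with columns `parent` (`"p1"`/`"p2"`),
#'   `marker` (index) and `hap` (1 or 2) marking founder alleles as null.
#' @param seed integer seed.
#' @param parent_haps optional list `p1`, `p2`, each a 2 x n_markers integer
#'   matrix of allele indices; defaults give parent 1 alleles 1/2 and parent 2
#'   alleles 3/4 (recycled if the catalog is smaller).
#' @return A `FamilyTruth` list; `genotypes$hap1`/`hap2` are sample x marker
#'   allele-index matrices covering parents (`p1`, `p2`, `f1` when formed) and
#'   progeny; `parent_names` names the two genotypes that actually parent the
#'   progeny.
#' @export
simulate_family <- function(markers, cross_type = c("F1", "F2", "BC"),
                            n_progeny = 100, recomb_rate = 3,
                            null_spec = NULL, seed = 1, parent_haps = NULL) {
  stopifnot(inherits(markers, "MarkerPanelSim"), n_progeny >= 1)
  cross_type <- match.arg(cross_type)
  M <- nrow(markers$panel)
  n_al <- lengths(markers$alleles)
  if (is.null(parent_haps)) {
    parent_haps <- list(
      p1 = rbind(pmin(1, n_al), pmin(2, n_al)),
      p2 = rbind(pmin(3, n_al), pmin(4, n_al)))
  }
  p1 <- parent_haps$p1; p2 <- parent_haps$p2
  stopifnot(ncol(p1) == M, ncol(p2) == M)
  if (!is.null(null_spec)) {
    for (i in seq_len(nrow(null_spec))) {
      tgt <- null_spec$parent[i]
      if (tgt == "p1") p1[null_spec$hap[i], null_spec$marker[i]] <- 0L
      else if (tgt == "p2") p2[null_spec$hap[i], null_spec$marker[i]] <- 0L
      else stop("null_spec parent must be 'p1' or 'p2'")
    }
  }
  pos <- markers$panel$amplicon_start
  L <- markers$chrom_len

  with_seed(derive_seed(seed, paste0("family_", cross_type)), {
    gamete <- function(hapmat) {
      lambda <- recomb_rate * (L / 1e6) / 100
      nco <- rpois(1, lambda)
      co <- sort(runif(nco, 0, L))
      phase <- (sample(0:1, 1) + findInterval(pos, co)) %% 2 + 1
      hapmat[cbind(phase, seq_len(M))]
    }
    f1 <- NULL
    if (cross_type %in% c("F2", "BC"))
      f1 <- rbind(gamete(p1), gamete(p2))
    mk_progeny <- function() switch(cross_type,
      F1 = rbind(gamete(p1), gamete(p2)),
      F2 = rbind(gamete(f1), gamete(f1)),
      BC = rbind(gamete(f1), gamete(p1)))
    prog_names <- sprintf("prog%03d", seq_len(n_progeny))
    hap1 <- matrix(0L, n_progeny, M, dimnames = list(prog_names, NULL))
    hap2 <- hap1
    for (i in seq_len(n_progeny)) {
      g <- mk_progeny()
      hap1[i, ] <- g[1, ]; hap2[i, ] <- g[2, ]
    }
    founders1 <- rbind(p1 = p1[1, ], p2 = p2[1, ])
    founders2 <- rbind(p1 = p1[2, ], p2 = p2[2, ])
    if (!is.null(f1)) {
      founders1 <- rbind(founders1, f1 = f1[1, ])
      founders2 <- rbind(founders2, f1 = f1[2, ])
    }
    genotypes <- list(hap1 = rbind(founders1, hap1),
                      hap2 = rbind(founders2, hap2))
    parent_names <- switch(cross_type,
      F1 = c("p1", "p2"), F2 = c("f1", "f1"), BC = c("f1", "p1"))
    structure(list(cross_type = cross_type, markers = markers,
                   parents = list(p1 = p1, p2 = p2), f1 = f1,
                   genotypes = genotypes,
                   progeny_names = prog_names,
                   parent_names = parent_names,
                   null_spec = null_spec, recomb_rate = recomb_rate,
                   seed = seed),
              class = "FamilyTruth")
  })
}

#' @export
print.FamilyTruth <- function(x, ...) {
  cat("FamilyTruth:", x$cross_type, "cross,", length(x$progeny_names),
      "progeny,", nrow(x$markers$panel), "markers\n")
  invisible(x)
}

#' Truth diploid genotypes as observable allele pairs
#'
#' Null alleles (index 0) are unobservable: a genotype with one null allele
#' appears homozygous for the visible allele; null/null appears missing (NA).
#'
#' @param fam a `FamilyTruth`.
#' @param samples sample names (default: all).
#' @return A list of two sample x marker matrices `a1`, `a2` (sorted allele
#'   indices, NA where unobservable).
#' @export
truth_observable_genotypes <- function(fam, samples = NULL) {
  h1 <- fam$genotypes$hap1; h2 <- fam$genotypes$hap2
  if (!is.null(samples)) { h1 <- h1[samples, , drop = FALSE]
                           h2 <- h2[samples, , drop = FALSE] }
  a1 <- pmin(h1, h2); a2 <- pmax(h1, h2)
  one_null <- a1 == 0L & a2 > 0L
  a1[one_null] <- a2[one_null]
  both_null <- a2 == 0L
  a1[both_null] <- NA_integer_; a2[both_null] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

#' Pedigree table for a simulated family
#'
#' @param fam a `FamilyTruth`.
#' @param family family label.
#' @return Data frame with columns child, mother, father, family.
#' @export
family_pedigree <- function(fam, family = "fam1") {
  data.frame(child = fam$progeny_names,
             mother = fam$parent_names[1],
             father = fam$parent_names[2],
             family = family, stringsAsFactors = FALSE)
}

#' Simulate per-parent whole-genome variant VCFs for the primer audit
#'
#' Emits one single-sample VCF per parent containing heterozygous background
#' variants plus, for every null allele in `fam$null_spec`, a variant placed
#' inside a primer window of the corresponding marker (emulating primer-site
#' mismatch as the cause of amplification failure).
#'
#' @param fam a `FamilyTruth`.
#' @param dir output directory.
#' @param background_per_marker expected count of background variants placed
#'   near each marker (outside primer windows).
#' @param seed integer seed.
#' @return Named list of VCF paths per parent, invisibly.
#' @export
simulate_parent_vcfs <- function(fam, dir, background_per_marker = 0.3,
                                 seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- fam$markers$panel
  plen <- fam$markers$primer_len
  paths <- list()
  for (p in c("p1", "p2")) {
    recs <- with_seed(derive_seed(seed, paste0("parent_vcf_", p)), {
      out <- list()
      if (!is.null(fam$null_spec)) {
        ns <- fam$null_spec[fam$null_spec$parent == p, , drop = FALSE]
        for (i in seq_len(nrow(ns))) {
          m <- ns$marker[i]
          # variant at the 3rd base of the forward primer window
          out[[length(out) + 1L]] <- data.frame(
            chrom = panel$chrom[m], pos = panel$amplicon_start[m] + 2,
            stringsAsFactors = FALSE)
        }
      }
      for (m in seq_len(nrow(panel))) {
        if (runif(1) < background_per_marker) {
          # inside the insert, clear of both primer windows
          lo <- panel$amplicon_start[m] + plen
          hi <- panel$amplicon_end[m] - plen
          out[[length(out) + 1L]] <- data.frame(
            chrom = panel$chrom[m], pos = sample(lo:hi, 1),
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, out) %||% data.frame(chrom = character(), pos = numeric())
    })
    if (nrow(recs)) {
      recs <- recs[order(recs$pos), , drop = FALSE]
      recs <- recs[!duplicated(recs$pos), , drop = FALSE]
    }
    recs$id <- rep(".", nrow(recs))
    recs$ref <- rep("A", nrow(recs))
    recs$alt <- rep("T", nrow(recs))
    path <- file.path(dir, paste0(p, ".vcf"))
    gt <- matrix("0/1", nrow = nrow(recs), ncol = 1)
    write_vcf(recs, gt, p, path)
    paths[[p]] <- path
  }
  invisible(paths)
}
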