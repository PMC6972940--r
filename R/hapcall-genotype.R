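#' Call diploid haplotype genotypes from collapsed counts
#'
#' Per sample and marker: total depth below `min_depth` gives a missing
#' call; alleles with count fraction >= `min_frac` are kept and the top two
#' by count define the genotype (one surviving allele = homozygote, more
#' than two above threshold = missing with an "ambiguous" flag). The
#' per-marker allele catalog is ordered by descending family-wide read count
#' (ties broken lexicographically by haplotype string).
#'
#' @param hc a (collapsed) `HaplotypeCounts`.
#' @param min_depth minimum total read depth to call (default 5).
#' @param min_frac minimum count fraction for an allele (default 0.2).
#' @return A `GenotypeMatrix` list: `a1`, `a2` (marker x sample matrices of
#'   allele indices, a1 <= a2, NA = missing), `depth` (total reads),
#'   `ambiguous` (logical matrix), `catalog` (per-marker character vector of
#'   haplotype strings in rank order), `markers`, `samples`.
#' @export
call_genotypes <- function(hc, min_depth = 5, min_frac = 0.2) {
  stopifnot(inherits(hc, "HaplotypeCounts"))
  markers <- names(hc$counts); samples <- hc$samples
  dm <- function(init) matrix(init, length(markers), length(samples),
                              dimnames = list(markers, samples))
  a1 <- dm(NA_integer_); a2 <- dm(NA_integer_)
  d1 <- dm(0L); d2 <- dm(0L)
  depth <- dm(0); ambiguous <- dm(FALSE)
  catalog <- setNames(vector("list", length(markers)), markers)
  for (mk in markers) {
    percell <- hc$counts[[mk]]
    alleles <- unique(unlist(lapply(percell, names), use.names = FALSE))
    if (length(alleles) == 0) { catalog[[mk]] <- character(); next }
    total <- setNames(numeric(length(alleles)), alleles)
    for (v in percell) total[names(v)] <- total[names(v)] + v
    cat_ord <- alleles[order(-total, alleles, method = "radix")]
    catalog[[mk]] <- cat_ord
    for (s in names(percell)) {
      v <- percell[[s]]
      depth[mk, s] <- sum(v)
      if (sum(v) < min_depth) next
      keep <- v[v / sum(v) >= min_frac]
      if (length(keep) == 0) next
      if (length(keep) > 2) { ambiguous[mk, s] <- TRUE; next }
      idx <- sort(match(names(keep)[order(-keep, names(keep))], cat_ord))
      if (length(idx) == 1) idx <- c(idx, idx)
      a1[mk, s] <- idx[1]; a2[mk, s] <- idx[2]
      d1[mk, s] <- as.integer(v[cat_ord[idx[1]]])
      d2[mk, s] <- as.integer(v[cat_ord[idx[2]]])
    }
  }
  structure(list(a1 = a1, a2 = a2, d1 = d1, d2 = d2,
                 depth = depth, ambiguous = ambiguous,
                 catalog = catalog, markers = markers, samples = samples),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$markers), "markers x",
      length(x$samples), "samples; missing rate",
      round(mean(is.na(x$a1)), 3), "\n")
  invisible(x)
}

#' Flag markers by missingness and polymorphism
#'
#' Markers whose missing fraction exceeds `max_missing` are flagged
#' `removed`; markers with a single allele family-wide are flagged
#' `monomorphic` (retained in the matrix but excluded from mapping exports);
#' all others are `ok`.
#'
#' @param gm a `GenotypeMatrix`.
#' @param max_missing maximum missing fraction (default 0.75).
#' @return List with `matrix` (the input) and `status` (data frame: marker,
#'   missing_frac, n_alleles, status).
#' @export
filter_marker_matrix <- function(gm, max_missing = 0.75) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  miss <- rowMeans(is.na(gm$a1))
  n_alleles <- vapply(gm$markers, function(mk) {
    length(unique(stats::na.omit(c(gm$a1[mk, ], gm$a2[mk, ]))))
  }, 0L)
  status <- ifelse(miss > max_missing, "removed",
                   ifelse(n_alleles <= 1, "monomorphic", "ok"))
  list(matrix = gm,
       status = data.frame(marker = gm$markers, missing_frac = miss,
                           n_alleles = n_alleles, status = status,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Write and read the hapgeno genotype matrix dialect
#'
#' Header `marker<TAB>sample...`; cells are `I/J:dI,dJ` with allele indices
#' `I <= J` into the sidecar allele catalog (`<path>.alleles.tsv`: marker,
#' rank, haplotype), or `./.` for missing. The serialization round-trips
#' losslessly.
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hapgeno <- function(gm, path) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  cells <- matrix("./.", length(gm$markers), length(gm$samples))
  called <- !is.na(gm$a1)
  if (any(called)) {
    cells[called] <- paste0(gm$a1[called], "/", gm$a2[called], ":",
                            gm$d1[called], ",", gm$d2[called])
  }
  df <- data.frame(marker = gm$markers, cells, stringsAsFactors = FALSE)
  names(df) <- c("marker", gm$samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  al <- do.call(rbind, lapply(gm$markers, function(mk) {
    cat_mk <- gm$catalog[[mk]]
    if (length(cat_mk) == 0) return(NULL)
    data.frame(marker = mk, rank = seq_along(cat_mk), haplotype = cat_mk,
               stringsAsFactors = FALSE)
  }))
  write.table(al, paste0(path, ".alleles.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_hapgeno
#' @export
read_hapgeno <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  al <- read.table(paste0(path, ".alleles.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  markers <- df$marker
  samples <- names(df)[-1]
  parse_part <- function(x, field, part) {
    miss <- x == "./."
    out <- rep(if (field == 1) NA_integer_ else 0L, length(x))
    piece <- vapply(strsplit(x[!miss], ":", fixed = TRUE), `[`, "", field)
    sep <- if (field == 1) "/" else ","
    out[!miss] <- as.integer(vapply(strsplit(piece, sep, fixed = TRUE),
                                    `[`, "", part))
    out
  }
  grab <- function(field, part) {
    m <- t(vapply(seq_along(markers), function(i)
      parse_part(unlist(df[i, -1]), field, part),
      integer(length(samples))))
    dimnames(m) <- list(markers, samples)
    m
  }
  a1 <- grab(1, 1); a2 <- grab(1, 2)
  d1 <- grab(2, 1); d2 <- grab(2, 2)
  catalog <- lapply(setNames(markers, markers), function(mk) {
    al$haplotype[al$marker == mk][order(al$rank[al$marker == mk])]
  })
  # total depth is not serialized; the called-allele depths give a usable
  # lower bound for downstream depth-based classification (homozygotes
  # carry one allele's count, heterozygotes the sum)
  depth <- ifelse(!is.na(a1) & a1 == a2, d1, d1 + d2)
  structure(list(a1 = a1, a2 = a2, d1 = d1, d2 = d2,
                 depth = depth,
                 ambiguous = matrix(FALSE, length(markers),
                                    length(samples),
                                    dimnames = list(markers, samples)),
                 catalog = catalog, markers = markers, samples = samples),
            class = "GenotypeMatrix")
}

#' Export called genotypes as a pseudo-allele VCF
#'
#' The four most frequent haplotype alleles of each marker (family-wide, ties
#' broken lexicographically by haplotype string - the catalog order of
#' [call_genotypes()]) are mapped to pseudo-bases A, C, G, T in descending
#' frequency; REF is A. Samples carrying any rarer allele are set missing at
#' that marker. CHROM and POS are parsed from the marker id (`chrom_pos`).
#' Markers with zero called samples are skipped with a warning.
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_pseudo_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  bases <- c("A", "C", "G", "T")
  recs <- list(); gts <- list()
  for (mk in gm$markers) {
    a1 <- gm$a1[mk, ]; a2 <- gm$a2[mk, ]
    if (all(is.na(a1))) {
      warning("marker ", mk, " has no called samples; skipped")
      next
    }
    gt <- rep("./.", length(gm$samples))
    ok <- !is.na(a1) & a1 <= 4 & a2 <= 4
    gt[ok] <- paste0(a1[ok] - 1L, "/", a2[ok] - 1L)
    used <- sort(unique(c(a1[ok], a2[ok])))
    n_alt <- max(c(used, 1L)) - 1L
    alt <- if (n_alt >= 1) paste(bases[2:(n_alt + 1)], collapse = ",")
      else "."
    chrom <- sub("_[0-9]+$", "", mk)
    pos <- as.numeric(sub("^.*_", "", mk))
    recs[[mk]] <- data.frame(chrom = chrom, pos = pos, id = mk, ref = "A",
                             alt = alt, stringsAsFactors = FALSE)
    gts[[mk]] <- gt
  }
  if (length(recs) == 0) stop("no markers with called samples")
  records <- do.call(rbind, recs)
  gt <- do.call(rbind, gts)
  o <- order(records$chrom, records$pos)
  write_vcf(records[o, , drop = FALSE], gt[o, , drop = FALSE],
            gm$samples, path)
  invisible(path)
}
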