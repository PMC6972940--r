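#' Simulate a pan-genome with dispensable segments and known truth
#'
#' Generates a single-chromosome reference containing tandem-repeat tracts,
#' plus diverged assemblies that carry SNPs and lack assembly-specific
#' dispensable (presence/absence) segments. Alongside the sequences it emits
#' truth alignments in PAF form (anchors split wherever a dispensable segment
#' interrupts collinearity) and the truth core genome - the reference
#' intervals present in every assembly - so the synteny stage can be validated
#' end to end without an external aligner.
#'
#' Dispensable segments are sampled uniformly along the reference with lengths
#' drawn between `min_dispensable` and `max_dispensable` (merged by union
#' within an assembly) until their total reaches `dispensable_frac * ref_len`.
#' All intervals are 0-based half-open.
#'
#' @param seed master integer seed; every output stream derives from it via
#'   [derive_seed()], so runs are byte-reproducible.
#' @param ref_len reference length in bases (>= 10 kb).
#' @param n_assemblies number of assemblies to derive.
#' @param snp_rate per-base substitution probability in each assembly.
#' @param dispensable_frac fraction of the reference absent from each
#'   assembly (drawn independently per assembly).
#' @param repeat_frac fraction of the reference built as tandem-repeat tracts
#'   (unit length <= 100 bp).
#' @param min_dispensable,max_dispensable length bounds (bases) for one
#'   dispensable segment.
#' @param anchor_len target length of one truth alignment anchor; each kept
#'   segment is split into at least `min_anchors_per_segment` anchors so it
#'   remains chainable.
#' @param min_anchors_per_segment minimum anchors per collinear segment.
#' @return A `PanGenomeTruth` list with elements `reference` (sequence),
#'   `ref_name`, `ref_len`, `assemblies` (named sequences), `dispensable`
#'   (per-assembly interval data frames), `repeat_intervals`,
#'   `truth_alignments` (per-assembly PAF-style data frames), `truth_core`
#'   (interval data frame) and `params`.
#' @examples
#' pg <- simulate_pangenome(seed = 1, ref_len = 1e5, n_assemblies = 2,
#'                          dispensable_frac = 0.2)
#' pg$truth_core
#' @export
simulate_pangenome <- function(seed, ref_len = 2e6, n_assemblies = 5,
                               snp_rate = 0.01, dispensable_frac = 0.3,
                               repeat_frac = 0.05,
                               min_dispensable = 2e4, max_dispensable = 1e5,
                               anchor_len = 2e4, min_anchors_per_segment = 3) {
  stopifnot(ref_len >= 1e4, n_assemblies >= 1,
            snp_rate >= 0, snp_rate < 0.2,
            dispensable_frac >= 0, dispensable_frac < 1,
            repeat_frac >= 0, repeat_frac < 1)
  if (dispensable_frac > 0 && dispensable_frac * ref_len < min_dispensable)
    stop("ref_len too small to place dispensable segments of at least ",
         min_dispensable, " bases at fraction ", dispensable_frac)
  if (repeat_frac > 0 && repeat_frac * ref_len < 200)
    stop("ref_len too small for the requested repeat fraction")

  ref_name <- "chr1"
  ref <- with_seed(derive_seed(seed, "reference"), {
    base <- random_dna(ref_len)
    rep_iv <- place_repeat_tracts(ref_len, repeat_frac)
    if (nrow(rep_iv)) {
      r <- strsplit(base, "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(rep_iv))) {
        len <- rep_iv$end[i] - rep_iv$start[i]
        unit <- random_dna(sample(10:100, 1))
        tract <- substr(strrep(unit, ceiling(len / nchar(unit))), 1, len)
        r[(rep_iv$start[i] + 1):rep_iv$end[i]] <- strsplit(tract, "")[[1]]
      }
      base <- paste(r, collapse = "")
    }
    list(seq = base, repeats = rep_iv)
  })

  asm_names <- sprintf("asm%d", seq_len(n_assemblies))
  assemblies <- list(); dispensable <- list(); alignments <- list()
  kept_all <- list()
  for (a in asm_names) {
    res <- with_seed(derive_seed(seed, paste0("assembly_", a)), {
      disp <- draw_dispensable(ref_len, dispensable_frac,
                               min_dispensable, max_dispensable)
      kept <- iv_complement(disp, ref_len)
      build_assembly(ref$seq, ref_name, a, kept, snp_rate,
                     anchor_len, min_anchors_per_segment)
    })
    assemblies[[a]] <- res$seq
    dispensable[[a]] <- res$disp
    alignments[[a]] <- res$paf
    kept_all[[a]] <- res$kept
  }

  core <- kept_all[[1]]
  for (iv in kept_all[-1]) core <- iv_intersect(core, iv)

  structure(list(reference = ref$seq, ref_name = ref_name, ref_len = ref_len,
                 assemblies = assemblies, dispensable = dispensable,
                 repeat_intervals = ref$repeats,
                 truth_alignments = alignments, truth_core = core,
                 params = list(seed = seed, snp_rate = snp_rate,
                               dispensable_frac = dispensable_frac,
                               repeat_frac = repeat_frac)),
            class = "PanGenomeTruth")
}

#' @export
print.PanGenomeTruth <- function(x, ...) {
  cat("PanGenomeTruth:", x$ref_len, "bp reference,",
      length(x$assemblies), "assemblies\n")
  cat("  truth core:", nrow(x$truth_core), "intervals,",
      iv_length(x$truth_core), "bp (",
      round(100 * iv_length(x$truth_core) / x$ref_len, 1), "% )\n")
  invisible(x)
}

# Non-overlapping tandem-repeat tracts totalling ~frac * len.
place_repeat_tracts <- function(len, frac) {
  if (frac <= 0) return(new_intervals())
  target <- frac * len
  placed <- data.frame(start = numeric(), end = numeric())
  total <- 0; tries <- 0
  while (total < target && tries < 10000) {
    tries <- tries + 1
    w <- sample(2000:10000, 1)
    s <- sample.int(len - w, 1) - 1
    if (nrow(placed) &&
        any(pmax(placed$start, s) < pmin(placed$end, s + w))) next
    placed <- rbind(placed, data.frame(start = s, end = s + w))
    total <- total + w
  }
  new_intervals(placed$start, placed$end)
}

# Uniformly placed dispensable intervals, merged by union, totalling
# ~frac * len.
draw_dispensable <- function(len, frac, min_len, max_len) {
  if (frac <= 0) return(new_intervals())
  target <- frac * len
  iv <- data.frame(start = numeric(), end = numeric())
  while (iv_length(if (nrow(iv)) iv_union(iv) else iv) < target) {
    w <- round(runif(1, min_len, min(max_len, len / 2)))
    s <- sample.int(len - w, 1) - 1
    iv <- rbind(iv, data.frame(start = s, end = s + w))
  }
  iv_union(iv)
}

# Assemble one query: SNP-mutated reference minus dispensable intervals,
# with PAF truth anchors tiling each kept segment.
build_assembly <- function(ref_seq, ref_name, asm_name, kept, snp_rate,
                           anchor_len, min_anchors) {
  ref_len <- nchar(ref_seq)
  segs <- character(nrow(kept))
  paf <- vector("list", nrow(kept))
  qoff <- 0
  for (i in seq_len(nrow(kept))) {
    s <- kept$start[i]; e <- kept$end[i]
    seg <- substr(ref_seq, s + 1, e)
    n_snp <- rbinom(1, e - s, snp_rate)
    snp_pos <- if (n_snp > 0) sort(sample.int(e - s, n_snp)) else integer()
    if (n_snp > 0) {
      r <- charToRaw(seg)
      for (p in snp_pos) {
        cur <- rawToChar(r[p])
        r[p] <- charToRaw(sample(setdiff(DNA, cur), 1))
      }
      seg <- rawToChar(r)
    }
    segs[i] <- seg
    # split into anchors
    n_anchor <- max(min_anchors, ceiling((e - s) / anchor_len))
    bounds <- round(seq(0, e - s, length.out = n_anchor + 1))
    bounds <- unique(bounds)
    n_anchor <- length(bounds) - 1
    anc <- data.frame(
      qname = asm_name, qlen = NA_real_,
      qstart = qoff + bounds[-length(bounds)], qend = qoff + bounds[-1],
      strand = "+", tname = ref_name, tlen = ref_len,
      tstart = s + bounds[-length(bounds)], tend = s + bounds[-1],
      n_matches = NA_real_, aln_len = diff(bounds), mapq = 60,
      stringsAsFactors = FALSE)
    mism <- vapply(seq_len(n_anchor), function(j)
      sum(snp_pos > bounds[j] & snp_pos <= bounds[j + 1]), 0)
    anc$n_matches <- anc$aln_len - mism
    paf[[i]] <- anc
    qoff <- qoff + (e - s)
  }
  paf <- do.call(rbind, paf)
  if (is.null(paf)) {
    paf <- data.frame(qname = character(), qlen = numeric(),
                      qstart = numeric(), qend = numeric(),
                      strand = character(), tname = character(),
                      tlen = numeric(), tstart = numeric(), tend = numeric(),
                      n_matches = numeric(), aln_len = numeric(),
                      mapq = numeric())
  } else {
    paf$qlen <- qoff
  }
  list(seq = paste(segs, collapse = ""),
       disp = iv_complement(kept, ref_len), kept = kept, paf = paf)
}

#' Write the simulated pan-genome to disk
#'
#' Writes the reference and assembly FASTAs, per-assembly truth PAF files, a
#' reference `.fai`-style length table and a JSON truth file (dispensable,
#' repeat and core intervals).
#'
#' @param pg a `PanGenomeTruth` from [simulate_pangenome()].
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_pangenome <- function(pg, dir) {
  stopifnot(inherits(pg, "PanGenomeTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(reference = file.path(dir, "reference.fa"))
  write_fasta(setNames(pg$reference, pg$ref_name), paths$reference)
  writeLines(paste(pg$ref_name, pg$ref_len, sep = "\t"),
             file.path(dir, "reference.fa.fai"))
  paths$fai <- file.path(dir, "reference.fa.fai")
  for (a in names(pg$assemblies)) {
    fa <- file.path(dir, paste0(a, ".fa"))
    write_fasta(setNames(pg$assemblies[[a]], a), fa)
    paf <- file.path(dir, paste0(a, ".paf"))
    write_paf(pg$truth_alignments[[a]], paf)
    paths[[paste0(a, "_fa")]] <- fa
    paths[[paste0(a, "_paf")]] <- paf
  }
  truth <- list(truth_core = pg$truth_core,
                dispensable = pg$dispensable,
                repeat_intervals = pg$repeat_intervals)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
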