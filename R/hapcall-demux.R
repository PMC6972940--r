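#' Normalise a primer panel definition
#'
#' Accepts panels from [simulate_marker_panel()] (`fwd`/`rev` columns) or
#' [design_amplicons()] (`fwd_primer`/`rev_primer`) and returns the common
#' shape used by the genotyping stage.
#'
#' @param panel data frame containing marker_id and primer columns.
#' @return Data frame with marker_id, chrom, amplicon_start, amplicon_end,
#'   fwd, rev, amplicon_len (coordinates 1-based where present).
#' @export
as_primer_panel <- function(panel) {
  out <- data.frame(marker_id = panel$marker_id, stringsAsFactors = FALSE)
  out$chrom <- panel$chrom %||% NA_character_
  out$amplicon_start <- panel$amplicon_start %||% NA_real_
  out$amplicon_end <- panel$amplicon_end %||% NA_real_
  out$fwd <- panel$fwd %||% panel$fwd_primer
  out$rev <- panel$rev %||% panel$rev_primer
  out$amplicon_len <- panel$amplicon_len %||%
    (out$amplicon_end - out$amplicon_start + 1)
  if (is.null(out$fwd) || is.null(out$rev))
    stop("panel must provide forward and reverse primer sequences")
  if (anyDuplicated(paste(out$fwd, out$rev)))
    stop("primer pairs must be unique across the panel")
  out
}

#' Demultiplex amplicon read pairs by primer sequence
#'
#' A read pair is assigned to a marker iff R1 begins with the marker's
#' forward primer and R2 with its reverse primer, each within `max_mismatch`
#' substitutions (no indels) and with the 5 3'-terminal primer bases matching
#' exactly (mirroring RNase H2 3' specificity). Primers are trimmed; the
#' haplotype string is the R1 insert followed by the reverse-complemented R2
#' insert, merged when they overlap by at least 10 bases with at most one
#' mismatch, otherwise joined with the sentinel `'+'`.
#'
#' @param files data frame with columns sample, r1, r2 (FASTQ paths, gz ok),
#'   e.g. `simulate_amplicon_reads(...)$files`.
#' @param panel primer panel (see [as_primer_panel()]).
#' @param max_mismatch allowed substitutions per primer (default 1).
#' @param merge_min_overlap,merge_max_mismatch read-merging parameters.
#' @return A `HaplotypeCounts` list: `counts[[marker_id]][[sample]]` is a
#'   named integer vector of read counts per haplotype string;
#'   `unassigned` counts pairs matching no marker; `panel`, `samples`.
#' @export
demultiplex_reads <- function(files, panel, max_mismatch = 1,
                              merge_min_overlap = 10,
                              merge_max_mismatch = 1) {
  panel <- as_primer_panel(panel)
  M <- nrow(panel)
  flen <- nchar(panel$fwd); rlen <- nchar(panel$rev)
  counts <- setNames(vector("list", M), panel$marker_id)
  for (m in seq_len(M)) counts[[m]] <- list()
  unassigned <- setNames(integer(nrow(files)), files$sample)
  # exact lookup on concatenated primer prefixes, per (flen, rlen) class
  len_classes <- unique(data.frame(f = flen, r = rlen))
  exact <- list()
  for (i in seq_len(nrow(len_classes))) {
    sel <- which(flen == len_classes$f[i] & rlen == len_classes$r[i])
    exact[[i]] <- setNames(sel, paste0(panel$fwd[sel], panel$rev[sel]))
  }

  for (s in seq_len(nrow(files))) {
    r1 <- read_fastq(files$r1[s]); r2 <- read_fastq(files$r2[s])
    if (length(r1$seq) != length(r2$seq) || !identical(r1$id, r2$id))
      stop("unsynchronized FASTQ pair for sample ", files$sample[s])
    n <- length(r1$seq)
    assign_m <- rep(NA_integer_, n)
    for (i in seq_len(nrow(len_classes))) {
      fl <- len_classes$f[i]; rl <- len_classes$r[i]
      key <- paste0(substr(r1$seq, 1, fl), substr(r2$seq, 1, rl))
      hit <- exact[[i]][key]
      assign_m[is.na(assign_m) & !is.na(hit)] <-
        hit[is.na(assign_m) & !is.na(hit)]
    }
    todo <- which(is.na(assign_m))
    if (length(todo) && max_mismatch > 0) {
      best_mm <- rep(Inf, length(todo))
      for (m in seq_len(M)) {
        mm1 <- hamming_to(substr(r1$seq[todo], 1, flen[m]), panel$fwd[m])
        mm2 <- hamming_to(substr(r2$seq[todo], 1, rlen[m]), panel$rev[m])
        # 3'-terminal 5 bases must match exactly
        t1 <- substr(r1$seq[todo], flen[m] - 4, flen[m]) ==
          substr(panel$fwd[m], flen[m] - 4, flen[m])
        t2 <- substr(r2$seq[todo], rlen[m] - 4, rlen[m]) ==
          substr(panel$rev[m], rlen[m] - 4, rlen[m])
        ok <- mm1 <= max_mismatch & mm2 <= max_mismatch & t1 & t2
        better <- ok & (mm1 + mm2) < best_mm
        assign_m[todo[better]] <- m
        best_mm[better] <- (mm1 + mm2)[better]
      }
    }
    unassigned[s] <- sum(is.na(assign_m))
    hit <- which(!is.na(assign_m))
    if (length(hit)) {
      ins1 <- substr(r1$seq[hit], flen[assign_m[hit]] + 1,
                     nchar(r1$seq[hit]))
      ins2 <- revcomp(substr(r2$seq[hit], rlen[assign_m[hit]] + 1,
                             nchar(r2$seq[hit])))
      exp_ins <- panel$amplicon_len[assign_m[hit]] -
        flen[assign_m[hit]] - rlen[assign_m[hit]]
      haps <- merge_read_pair(ins1, ins2, exp_ins,
                              merge_min_overlap, merge_max_mismatch)
      tab <- table(assign_m[hit], haps)
      for (mi in rownames(tab)) {
        v <- setNames(as.integer(tab[mi, ]), colnames(tab))
        v <- v[v > 0]
        counts[[as.integer(mi)]][[files$sample[s]]] <- v
      }
    }
  }
  structure(list(counts = counts, unassigned = unassigned,
                 panel = panel, samples = files$sample),
            class = "HaplotypeCounts")
}

#' @export
print.HaplotypeCounts <- function(x, ...) {
  cat("HaplotypeCounts:", length(x$counts), "markers,",
      length(x$samples), "samples,", sum(x$unassigned),
      "unassigned pairs\n")
  invisible(x)
}

# Hamming distance of each string in x (equal length) to primer p;
# length mismatches count as Inf.
hamming_to <- function(x, p) {
  pr <- charToRaw(p)
  L <- length(pr)
  out <- rep(Inf, length(x))
  ok <- nchar(x) == L
  if (any(ok)) {
    m <- matrix(unlist(lapply(x[ok], charToRaw), use.names = FALSE),
                nrow = L)
    out[ok] <- colSums(m != pr)
  }
  out
}

# Merge R1 insert with reverse-complemented R2 insert. The expected overlap
# (from the panel's amplicon length) is tried first, then nearby shifts,
# then a full scan; failing all, the two are joined with '+'.
merge_read_pair <- function(ins1, ins2, exp_ins, min_overlap,
                            max_mismatch) {
  exp_ov <- as.integer(nchar(ins1) + nchar(ins2) - exp_ins)
  exp_ov[is.na(exp_ov)] <- -1L
  .cm_merge_pairs(ins1, ins2, exp_ov, as.integer(min_overlap),
                  as.integer(max_mismatch))
}
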