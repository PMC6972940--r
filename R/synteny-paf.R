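#' Read pairwise alignments from a PAF file
#'
#' Parses the first 12 tab-separated PAF columns into alignment records with
#' coordinates preserved exactly (PAF is 0-based half-open on both genomes).
#' Malformed lines and coordinate-invariant violations raise an error naming
#' the offending line.
#'
#' @param path PAF file path.
#' @param min_mapq drop records with mapping quality below this (default 0,
#'   i.e. keep everything).
#' @return Data frame of alignment records with columns qname, qlen, qstart,
#'   qend, strand, tname, tlen, tstart, tend, n_matches, aln_len, mapq.
#' @export
read_paf <- function(path, min_mapq = 0) {
  if (!file.exists(path)) stop("no such PAF file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- paf_cols
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("malformed PAF line ", which(nf < 12)[1], ": fewer than 12 columns")
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  out <- data.frame(qname = m[, 1], qlen = num(2), qstart = num(3),
                    qend = num(4), strand = m[, 5], tname = m[, 6],
                    tlen = num(7), tstart = num(8), tend = num(9),
                    n_matches = num(10), aln_len = num(11), mapq = num(12),
                    stringsAsFactors = FALSE)
  bad_num <- which(!stats::complete.cases(
    out[c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
          "n_matches", "aln_len", "mapq")]))
  if (length(bad_num))
    stop("malformed PAF line ", bad_num[1], ": non-numeric coordinate")
  bad <- which(!(out$qstart >= 0 & out$qstart < out$qend &
                   out$qend <= out$qlen &
                   out$tstart >= 0 & out$tstart < out$tend &
                   out$tend <= out$tlen &
                   out$strand %in% c("+", "-")))
  if (length(bad))
    stop("invalid PAF record at line ", bad[1],
         ": coordinates must satisfy 0 <= start < end <= length")
  out[out$mapq >= min_mapq, , drop = FALSE]
}
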