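## Readers/writers for the plain-text formats the pipeline exchanges:
## FASTA, gzipped FASTQ, PAF, BED, VCF 4.2 and the hapgeno TSV dialect.

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Write one FASTQ file (optionally gzipped by extension) with constant
# quality symbol.
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  stopifnot(length(ids) == length(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    quals <- vapply(nchar(seqs), function(n) strrep(qual_char, n), "")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  }
  invisible(path)
}

read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  n <- length(lines) / 4
  list(id = sub("^@", "", sub("\\s.*$", "", lines[seq(1, by = 4, length.out = n)])),
       seq = lines[seq(2, by = 4, length.out = n)])
}

# BED (0-based half-open). Extra columns appended verbatim.
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed <- function(path, col_names = c("chrom", "start", "end")) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[seq_along(col_names)] <- col_names
  df
}

paf_cols <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "n_matches",
              "aln_len", "mapq")

write_paf <- function(df, path) {
  write.table(df[, paf_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Minimal multi-sample VCF 4.2 writer. `records` needs chrom, pos (1-based),
# id, ref, alt; `gt` is a character matrix (records x samples) of GT strings.
write_vcf <- function(records, gt, samples, path, source = "coremark") {
  stopifnot(nrow(records) == nrow(gt) || nrow(gt) == 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", source),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(records)) {
    body <- paste(records$chrom, records$pos, records$id, records$ref,
                  records$alt, ".", "PASS", ".", "GT", sep = "\t")
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
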