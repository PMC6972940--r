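write_pair_fastq <- function(r1, r2, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  ids <- sprintf("read%03d", seq_along(r1))
  coremark:::write_fastq(ids, r1, file.path(dir, "s_R1.fastq.gz"))
  coremark:::write_fastq(ids, r2, file.path(dir, "s_R2.fastq.gz"))
  data.frame(sample = "s1", r1 = file.path(dir, "s_R1.fastq.gz"),
             r2 = file.path(dir, "s_R2.fastq.gz"),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing applies primer matching and 3' exactness", {
  set.seed(4)
  # amplicons short enough that the 150 bp mates overlap by >= 10 bases
  mk <- simulate_marker_panel(n_markers = 2, seed = 4,
                              amplicon_range = c(270, 290))
  panel <- mk$panel
  allele <- mk$alleles[[1]][1]
  amp <- paste0(panel$fwd[1], allele, coremark:::revcomp(panel$rev[1]))
  r1 <- substr(amp, 1, 150)
  r2 <- substr(coremark:::revcomp(amp), 1, 150)

  flip <- function(s, i) {
    b <- substr(s, i, i)
    paste0(substr(s, 1, i - 1), chartr("ACGT", "CATG", b),
           substr(s, i + 1, nchar(s)))
  }

  # clean pair reconstructs the truth allele exactly
  files <- write_pair_fastq(r1, r2)
  hc <- demultiplex_reads(files, panel)
  expect_equal(sum(hc$unassigned), 0)
  expect_equal(names(hc$counts[[1]]$s1), allele)

  # a pair matching no primer is tallied unassigned
  junk <- paste(rep("A", 150), collapse = "")
  hc2 <- demultiplex_reads(write_pair_fastq(junk, junk), panel)
  expect_equal(unname(hc2$unassigned), 1)

  # one substitution in the forward primer body is tolerated...
  r1_mm1 <- flip(r1, 3)
  hc3 <- demultiplex_reads(write_pair_fastq(r1_mm1, r2), panel)
  expect_equal(sum(hc3$unassigned), 0)
  # ...two are not (Hamming rule)
  r1_mm2 <- flip(flip(r1, 3), 7)
  hc4 <- demultiplex_reads(write_pair_fastq(r1_mm2, r2), panel)
  expect_equal(unname(hc4$unassigned), 1)
  # a single mismatch in the 3'-terminal 5 primer bases blocks assignment
  plen <- nchar(panel$fwd[1])
  r1_3p <- flip(r1, plen - 1)
  hc5 <- demultiplex_reads(write_pair_fastq(r1_3p, r2), panel)
  expect_equal(unname(hc5$unassigned), 1)

  # unsynchronized FASTQ pairs are an error
  d <- tempfile(); dir.create(d)
  coremark:::write_fastq(c("a", "b"), c(r1, r1),
                         file.path(d, "x_R1.fastq.gz"))
  coremark:::write_fastq("a", r2, file.path(d, "x_R2.fastq.gz"))
  bad <- data.frame(sample = "x", r1 = file.path(d, "x_R1.fastq.gz"),
                    r2 = file.path(d, "x_R2.fastq.gz"))
  expect_error(demultiplex_reads(bad, panel), "unsynchronized")
})

test_that("haplotype variants differing only in a homopolymer run merge", {
  base <- "ACGTCGTAGAAAAAGCTTACGATCGTTGCACT"
  indel <- sub("AAAAA", "AAAA", base) # single-base deletion in the run
  counts <- list(m1 = list(s1 = c(setNames(30L, base),
                                  setNames(10L, indel))))
  hc <- structure(list(counts = counts, unassigned = c(s1 = 0L),
                       panel = NULL, samples = "s1"),
                  class = "HaplotypeCounts")
  ped <- data.frame(child = "s1", mother = "p1", father = "p2",
                    family = "f")
  out <- collapse_haplotypes(hc, ped)
  expect_equal(names(out$counts[[1]]$s1), base)
  expect_equal(unname(out$counts[[1]]$s1), 40L)
})

test_that("max-MAF fallback retains a single column when none segregates", {
  # construct three haplotypes whose variant columns all fail Mendelian
  # segregation; the column with the largest minor allele frequency stays
  h0 <- strrep("ACGTACGTAC", 5)
  h1 <- paste0("T", substr(h0, 2, 50)) # col 1, minor freq 0.30
  h2 <- paste0(substr(h0, 1, 9), "A", substr(h0, 11, 50)) # col 10, 0.10
  smp <- function(a, b, c) {
    v <- c(a, b, c); names(v) <- c(h0, h1, h2); v[v > 0]
  }
  # parents homozygous dominant; "progeny" show the variants -> distorted
  counts <- list(m1 = list(p1 = smp(30, 0, 0), p2 = smp(30, 0, 0),
                           c1 = smp(0, 30, 0), c2 = smp(30, 0, 10),
                           c3 = smp(10, 30, 0)))
  hc <- structure(list(counts = counts, unassigned = integer(),
                       panel = NULL, samples = c("p1", "p2", "c1", "c2",
                                                 "c3")),
                  class = "HaplotypeCounts")
  ped <- data.frame(child = c("c1", "c2", "c3"), mother = "p1",
                    father = "p2", family = "f")
  out <- collapse_haplotypes(hc, ped, seg_alpha = 0.9)
  # after re-keying on one column there are exactly two allele groups
  all_alleles <- unique(unlist(lapply(out$counts$m1, names)))
  expect_lte(length(all_alleles), 2)
  # counts conserved per cell
  expect_equal(vapply(out$counts$m1, sum, 0),
               vapply(counts$m1, sum, 0))
})

test_that("genotype calling applies depth and fraction thresholds", {
  mkc <- function(...) {
    v <- c(...)
    structure(list(counts = list(m = list(s1 = v)), unassigned = c(s1 = 0L),
                   panel = NULL, samples = "s1"),
              class = "HaplotypeCounts")
  }
  # zero reads: missing
  hc0 <- structure(list(counts = list(m = list()), unassigned = c(s1 = 0L),
                        panel = NULL, samples = "s1"),
                   class = "HaplotypeCounts")
  gm0 <- call_genotypes(hc0)
  expect_true(is.na(gm0$a1["m", "s1"]))

  # {50, 45, 5}: the 5-read allele falls below min_frac -> het of the top 2
  gm1 <- call_genotypes(mkc(h1 = 50L, h2 = 45L, h3 = 5L))
  expect_equal(unname(c(gm1$a1[1, 1], gm1$a2[1, 1])), c(1L, 2L))
  expect_equal(unname(c(gm1$d1[1, 1], gm1$d2[1, 1])), c(50L, 45L))

  # {98, 2}: homozygote
  gm2 <- call_genotypes(mkc(h1 = 98L, h2 = 2L))
  expect_equal(unname(c(gm2$a1[1, 1], gm2$a2[1, 1])), c(1L, 1L))

  # below min_depth: missing
  gm3 <- call_genotypes(mkc(h1 = 3L))
  expect_true(is.na(gm3$a1[1, 1]))

  # three alleles above the fraction: ambiguous, missing
  gm4 <- call_genotypes(mkc(h1 = 10L, h2 = 10L, h3 = 10L))
  expect_true(is.na(gm4$a1[1, 1]))
  expect_true(gm4$ambiguous[1, 1])
})

test_that("marker matrix filtering flags missingness and monomorphism", {
  a1 <- rbind(c(1L, 1L, NA, NA), c(1L, 1L, 1L, 1L), c(1L, 2L, 1L, 2L))
  a2 <- rbind(c(1L, 2L, NA, NA), c(1L, 1L, 1L, 1L), c(2L, 2L, 1L, 2L))
  gm <- make_gm(a1, a2)
  st <- filter_marker_matrix(gm, max_missing = 0.4)$status
  expect_equal(st$status, c("removed", "monomorphic", "ok"))

  # random matrices against an independent column-scan oracle
  set.seed(12)
  for (i in 1:5) {
    a1r <- matrix(sample(c(1L, 2L, NA), 60, TRUE), 6, 10)
    a2r <- pmax(a1r, matrix(sample(c(1L, 2L), 60, TRUE), 6, 10))
    a2r[is.na(a1r)] <- NA
    gmr <- make_gm(a1r, a2r)
    str <- filter_marker_matrix(gmr, max_missing = 0.5)$status
    for (m in 1:6) {
      miss <- mean(is.na(a1r[m, ]))
      nal <- length(unique(na.omit(c(a1r[m, ], a2r[m, ]))))
      want <- if (miss > 0.5) "removed" else if (nal <= 1) "monomorphic"
        else "ok"
      expect_equal(str$status[m], want)
    }
  }
})

test_that("hapgeno serialization round-trips", {
  a1 <- rbind(c(1L, NA), c(2L, 1L))
  a2 <- rbind(c(2L, NA), c(2L, 1L))
  gm <- make_gm(a1, a2)
  path <- tempfile(fileext = ".tsv")
  write_hapgeno(gm, path)
  back <- read_hapgeno(path)
  expect_identical(back$a1, gm$a1)
  expect_identical(back$a2, gm$a2)
  expect_identical(back$d1, gm$d1)
  expect_identical(back$catalog, gm$catalog)
  # cell syntax
  lines <- readLines(path)
  expect_match(lines[2], "1/2:20,20")
  expect_match(lines[2], "\\./\\.")
})

test_that("pseudo-VCF maps the top four alleles to A/C/G/T", {
  # biallelic marker: REF A, ALT C
  a1 <- matrix(c(1L, 1L, 1L, 2L), 1)
  a2 <- matrix(c(1L, 2L, 2L, 2L), 1)
  gm <- make_gm(a1, a2)
  rownames(gm$a1) <- rownames(gm$a2) <- gm$markers <- "chr2_4825658"
  path <- tempfile(fileext = ".vcf")
  write_pseudo_vcf(gm, path)
  body <- grep("^[^#]", readLines(path), value = TRUE)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(f[1], "chr2")
  expect_equal(f[2], "4825658")
  expect_equal(f[4], "A")
  expect_equal(f[5], "C")
  expect_equal(f[10:13], c("0/0", "0/1", "0/1", "1/1"))

  # a sample carrying a 5th allele becomes missing
  a1b <- matrix(c(1L, 2L, 3L, 4L, 5L), 1)
  a2b <- matrix(c(1L, 2L, 3L, 4L, 5L), 1)
  gmb <- make_gm(a1b, a2b)
  pb <- tempfile(fileext = ".vcf")
  write_pseudo_vcf(gmb, pb)
  fb <- strsplit(grep("^[^#]", readLines(pb), value = TRUE), "\t")[[1]]
  expect_equal(fb[14], "./.")
  expect_equal(fb[5], "C,G,T")

  # marker with no called samples is skipped with a warning
  gme <- make_gm(rbind(c(1L, 1L), c(NA, NA)), rbind(c(1L, 2L), c(NA, NA)))
  pe <- tempfile(fileext = ".vcf")
  expect_warning(write_pseudo_vcf(gme, pe), "skipped")
})
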