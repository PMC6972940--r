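paf_line <- function(qs = 100, qe = 200, strand = "+", ts = 500, te = 600,
                     mapq = 60) {
  paste("q", 1000, qs, qe, strand, "t", 5000, ts, te, te - ts, te - ts,
        mapq, sep = "\t")
}

test_that("PAF parsing preserves coordinates and rejects bad records", {
  f <- tempfile()
  writeLines(character(), f)
  expect_equal(nrow(read_paf(f)), 0)

  writeLines(paf_line(qs = 100, qe = 200), f)
  rec <- read_paf(f)
  expect_equal(rec$qstart, 100)
  expect_equal(rec$qend, 200)
  expect_equal(rec$tstart, 500)

  writeLines(c(paf_line(), paf_line(qs = 300, qe = 250)), f)
  expect_error(read_paf(f), "line 2")

  writeLines("q\t1000\t100", f)
  expect_error(read_paf(f), "12 columns")

  writeLines(c(paf_line(mapq = 5), paf_line(mapq = 60)), f)
  expect_equal(nrow(read_paf(f, min_mapq = 10)), 1)
})

make_anchors <- function(tstarts, qstarts, w = 100, strand = "+",
                         n_matches = w) {
  data.frame(qname = "q", qlen = 1e6, qstart = qstarts,
             qend = qstarts + w, strand = strand, tname = "t", tlen = 1e6,
             tstart = tstarts, tend = tstarts + w,
             n_matches = n_matches, aln_len = w, mapq = 60,
             stringsAsFactors = FALSE)
}

test_that("chaining respects min_anchors, gaps, collinearity and strand", {
  # two anchors cannot reach min_anchors = 3
  a2 <- make_anchors(c(0, 200), c(0, 200))
  expect_length(chain_anchors(a2, min_anchors = 3), 0)

  # five collinear anchors plus one off-diagonal outlier
  a6 <- rbind(make_anchors(seq(0, 800, 200), seq(0, 800, 200)),
              make_anchors(400, 5000))
  ch <- chain_anchors(a6, max_gap = 1e3, min_anchors = 3)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$anchors), 5)
  expect_equal(ch[[1]]$score,
               oracle_best_chain_score(a6, max_gap = 1e3))

  # minus-strand anchors chain when query decreases as target increases
  am <- make_anchors(c(0, 200, 400), c(400, 200, 0), strand = "-")
  expect_length(chain_anchors(am, min_anchors = 3), 1)
  ap <- am; ap$strand <- "+"
  expect_length(chain_anchors(ap, min_anchors = 3), 0)

  # gap rule: a gap beyond max_gap splits the chain
  ag <- make_anchors(c(0, 200, 400, 5000, 5200, 5400),
                     c(0, 200, 400, 5000, 5200, 5400))
  expect_length(chain_anchors(ag, max_gap = 1e3, min_anchors = 3), 2)
})

test_that("one-to-one selection enforces the quota rule", {
  mk_chain <- function(t1, t2, q1, q2, score, qname = "q") {
    list(anchors = make_anchors(t1, q1, w = t2 - t1), score = score,
         strand = "+", tname = "t", qname = qname,
         t_span = c(t1, t2), q_span = c(q1, q2))
  }
  # disjoint chains are both kept
  ch <- list(mk_chain(0, 2e4, 0, 2e4, 900),
             mk_chain(5e4, 8e4, 5e4, 8e4, 700))
  out <- select_one_to_one(ch, min_block_len = 1e3)
  expect_equal(nrow(out), 2)

  # identical reference spans: only the higher score survives
  ch2 <- list(mk_chain(0, 2e4, 0, 2e4, 900),
              mk_chain(0, 2e4, 6e4, 8e4, 700))
  out2 <- select_one_to_one(ch2, min_block_len = 1e3)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$score, 900)

  # short blocks are dropped (strictly-larger rule)
  ch3 <- list(mk_chain(0, 1e4, 0, 1e4, 500))
  expect_equal(nrow(select_one_to_one(ch3, min_block_len = 1e4)), 0)
})

test_that("chaining and selection match independent oracles on random instances", {
  n_inst <- 60
  for (s in seq_len(n_inst)) {
    recs <- rand_anchor_recs(sample(4:10, 1), seed = 3000 + s,
                             strand = c("+", "+", "-"))
    ch <- chain_anchors(recs, max_gap = 2e3, min_anchors = 1)
    top <- if (length(ch)) ch[[1]]$score else 0
    expect_equal(top, oracle_best_chain_score(recs, max_gap = 2e3),
                 label = paste("chain instance", s))
    if (length(ch)) {
      got <- select_one_to_one(ch, overlap_tol = 0.1, min_block_len = 0)
      want <- oracle_quota_selection(ch, tol = 0.1, min_block_len = 0)
      expect_equal(nrow(got), length(want),
                   label = paste("selection size, instance", s))
      want_spans <- sort(vapply(want, function(x) x$t_span[1], 0))
      expect_equal(sort(got$start), want_spans,
                   label = paste("selection spans, instance", s))
    }
  }
})

test_that("coverage profile partitions the reference and extracts the core", {
  blocks <- data.frame(
    chrom = "chr1", start = c(0, 400), end = c(600, 1000),
    assembly = c("a1", "a2"), q_start = 0, q_end = 1,
    strand = "+", score = 1)
  cc <- coverage_and_core(blocks, c(chr1 = 1000))
  expect_equal(cc$core, data.frame(chrom = "chr1", start = 400, end = 600))
  # partition property: per-count lengths sum to the reference length
  expect_equal(sum(cc$profile$end - cc$profile$start), 1000)
  expect_equal(cc$profile$count, c(1L, 2L, 1L))

  one <- coverage_and_core(blocks[1, ], c(chr1 = 1000), n_assemblies = 1)
  expect_equal(one$core, data.frame(chrom = "chr1", start = 0, end = 600))

  bad <- blocks; bad$end[2] <- 2000
  expect_error(coverage_and_core(bad, c(chr1 = 1000)), "bounds")
})

test_that("core recovery from truth alignments is near-exact", {
  pg <- simulate_pangenome(seed = 31, ref_len = 5e5, n_assemblies = 4,
                           dispensable_frac = 0.3)
  blocks <- do.call(rbind, lapply(names(pg$assemblies), function(a)
    select_one_to_one(chain_anchors(pg$truth_alignments[[a]]))))
  prof <- coverage_and_core(blocks, setNames(pg$ref_len, pg$ref_name))
  jac <- coremark:::iv_jaccard(prof$core[c("start", "end")],
                               pg$truth_core)
  expect_gte(jac, 0.95)
})

test_that("decay fit recovers parameters and convergence analytically", {
  k <- 1:9
  # degenerate constant series
  flat <- fit_core_decay(data.frame(k = k, mean_size = 40))
  expect_equal(flat$A, 40)
  expect_equal(flat$B, 0)
  expect_identical(flat$converged, "constant")

  # noiseless self-inversion
  y <- 40 + 200 * exp(-0.5 * k)
  fit <- fit_core_decay(data.frame(k = k, mean_size = y), eps = 0.01)
  expect_equal(fit$A, 40, tolerance = 0.01 / 40)
  expect_equal(fit$c, 0.5, tolerance = 0.001 / 0.5)
  # analytic: 200 exp(-0.5 k) <= 0.4  <=>  k >= 2 ln(500) = 12.43
  expect_identical(fit$n_converge, 13L)

  expect_error(fit_core_decay(data.frame(k = 1:3, mean_size = 1:3)),
               "at least 4")
})

test_that("mean core size by k decreases and feeds the decay fit", {
  pg <- simulate_pangenome(seed = 17, ref_len = 3e5, n_assemblies = 5,
                           dispensable_frac = 0.25)
  kept <- lapply(pg$dispensable, function(d)
    coremark:::iv_complement(d, pg$ref_len))
  sizes <- core_size_by_k(kept, n_orderings = 40, seed = 1)
  expect_equal(sizes$k, 1:5)
  expect_true(all(diff(sizes$mean_size) <= 0))
  expect_equal(sizes$mean_size[5],
               coremark:::iv_length(pg$truth_core))
})

test_that("windowed feature correlation matches a midrank oracle", {
  pg_len <- 2e6
  prof <- structure(list(
    profile = data.frame(chrom = "chr1",
                         start = seq(0, pg_len - 1e5, 1e5),
                         end = seq(1e5, pg_len, 1e5),
                         count = rep(c(1L, 3L), 10)),
    core = data.frame(), n_assemblies = 3,
    ref_lengths = c(chr1 = pg_len)), class = "CoverageProfile")
  # features proportional to coverage -> rho = 1
  feats <- do.call(rbind, lapply(which(rep(c(TRUE, FALSE), 10)), function(i)
    data.frame(chrom = "chr1", start = (i - 1) * 1e5,
               end = (i - 1) * 1e5 + 1e4)))
  w0 <- window_feature_correlation(prof, feats, window = 1e5)
  expect_equal(w0$rho, -1) # features sit in the low-coverage windows
  # midrank oracle on the emitted table
  oracle <- cor(rank(w0$table$mean_coverage),
                rank(w0$table$feature_density))
  expect_equal(w0$rho, oracle)
  expect_error(window_feature_correlation(prof, feats, window = 5e3),
               "window")
})
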