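test_that("pan-genome simulation is deterministic and truth-consistent", {
  pg1 <- simulate_pangenome(seed = 7, ref_len = 2e5, n_assemblies = 3,
                            dispensable_frac = 0.3, repeat_frac = 0.05)
  pg2 <- simulate_pangenome(seed = 7, ref_len = 2e5, n_assemblies = 3,
                            dispensable_frac = 0.3, repeat_frac = 0.05)
  expect_identical(pg1, pg2)
  d1 <- tempfile(); d2 <- tempfile()
  write_pangenome(pg1, d1); write_pangenome(pg2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  # nothing removed: core is the whole reference
  pg0 <- simulate_pangenome(seed = 1, ref_len = 5e4, n_assemblies = 2,
                            dispensable_frac = 0, repeat_frac = 0)
  expect_equal(pg0$truth_core, data.frame(start = 0, end = 5e4))

  # truth core equals an independently coded per-base intersection of the
  # emitted dispensable intervals
  present <- rep(TRUE, pg1$ref_len)
  for (a in names(pg1$assemblies)) {
    iv <- pg1$dispensable[[a]]
    for (i in seq_len(nrow(iv)))
      present[(iv$start[i] + 1):iv$end[i]] <- FALSE
  }
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  oracle <- data.frame(start = starts[r$values],
                       end = as.numeric(ends[r$values]))
  rownames(oracle) <- NULL
  expect_equal(pg1$truth_core, oracle)

  # truth alignments tile exactly the non-dispensable reference
  for (a in names(pg1$assemblies)) {
    paf <- pg1$truth_alignments[[a]]
    covered <- coremark:::iv_union(data.frame(start = paf$tstart,
                                              end = paf$tend))
    kept <- coremark:::iv_complement(pg1$dispensable[[a]], pg1$ref_len)
    expect_equal(covered, kept)
    expect_equal(sum(paf$qend - paf$qstart), nchar(pg1$assemblies[[a]]))
  }
})

test_that("pan-genome simulation rejects infeasible sizing", {
  expect_error(simulate_pangenome(seed = 1, ref_len = 5e3),
               "ref_len")
  expect_error(simulate_pangenome(seed = 1, ref_len = 3e4,
                                  dispensable_frac = 0.1),
               "dispensable")
})

test_that("panel VCF has requested density, missingness and determinism", {
  pg <- simulate_pangenome(seed = 2, ref_len = 1e6, n_assemblies = 2,
                           dispensable_frac = 0, repeat_frac = 0)
  v <- simulate_panel_variants(pg, n_samples = 12, target_density = 0.032,
                               missing_rate = 0.1, seed = 5)
  expect_equal(nrow(v$records), 32000, tolerance = 0.1)
  expect_true(all(diff(v$records$pos) > 0)) # sorted, unique, 1-based
  expect_true(all(v$records$ref != v$records$alt))
  expect_equal(mean(v$gt == "./."), 0.1, tolerance = 0.05)

  v0 <- simulate_panel_variants(pg, n_samples = 5, target_density = 0.01,
                                missing_rate = 0, seed = 5)
  expect_false(any(v0$gt == "./."))

  va <- simulate_panel_variants(pg, n_samples = 5, target_density = 0.01,
                                missing_rate = 0.2, seed = 9)
  vb <- simulate_panel_variants(pg, n_samples = 5, target_density = 0.01,
                                missing_rate = 0.2, seed = 9)
  expect_identical(readLines(va$path), readLines(vb$path))
})

test_that("family gametes honour recombination and cross structure", {
  mk <- simulate_marker_panel(n_markers = 8, seed = 11)
  # zero recombination: every gamete is an intact parental haplotype
  fam0 <- simulate_family(mk, "F1", n_progeny = 30, recomb_rate = 0,
                          seed = 11)
  for (i in seq_len(30)) {
    h1 <- fam0$genotypes$hap1[fam0$progeny_names[i], ]
    h2 <- fam0$genotypes$hap2[fam0$progeny_names[i], ]
    expect_true(all(h1 == fam0$parents$p1[1, ]) ||
                  all(h1 == fam0$parents$p1[2, ]))
    expect_true(all(h2 == fam0$parents$p2[1, ]) ||
                  all(h2 == fam0$parents$p2[2, ]))
  }
  expect_error(simulate_family(mk, "F3", 10), "arg")

  # F2 selfing of a known heterozygote segregates 3:1 at the sex locus
  mk1 <- simulate_marker_panel(n_markers = 1, seed = 1, n_alleles = 2)
  fam2 <- simulate_family(mk1, "F2", n_progeny = 10000, seed = 1,
                          parent_haps = list(p1 = rbind(1, 1),
                                             p2 = rbind(2, 2)))
  expect_equal(unname(fam2$f1[, 1]), c(1, 2)) # F1 is Hf
  g <- cbind(fam2$genotypes$hap1[fam2$progeny_names, 1],
             fam2$genotypes$hap2[fam2$progeny_names, 1])
  frac_ff <- mean(g[, 1] == 2 & g[, 2] == 2)
  expect_lt(abs(frac_ff - 0.25), 0.013) # 3 SE at n = 10,000

  # null-allele cross A/null x A/B: observable classes 2:1:1, against the
  # exhaustive gamete enumeration oracle
  ns <- data.frame(parent = "p1", marker = 1, hap = 2)
  fam3 <- simulate_family(mk1, "F1", n_progeny = 10000, seed = 2,
                          null_spec = ns,
                          parent_haps = list(p1 = rbind(1, 1),
                                             p2 = rbind(1, 2)))
  tru <- truth_observable_genotypes(fam3, fam3$progeny_names)
  cls <- paste(tru$a1[, 1], tru$a2[, 1])
  obs <- table(cls) / length(cls)
  # oracle: gametes {A, 0} x {A, B} -> A/A 1/4, A/B 1/4, 0/A -> A/A 1/4,
  # 0/B -> B/B 1/4
  expect_equal(unname(obs["1 1"]), 0.5, tolerance = 0.05)
  expect_equal(unname(obs["1 2"]), 0.25, tolerance = 0.1)
  expect_equal(unname(obs["2 2"]), 0.25, tolerance = 0.1)
})

test_that("amplicon reads reproduce truth alleles and depth model", {
  mk <- simulate_marker_panel(n_markers = 4, seed = 21)
  fam <- simulate_family(mk, "F1", n_progeny = 3, seed = 21)
  rd <- simulate_amplicon_reads(fam, depth_log10_mean = 1.2,
                                depth_log10_sd = 0, sub_error = 0,
                                homopolymer_indel = 0, seed = 21)
  # with zero error rates every read is a substring of a truth amplicon
  amps <- unlist(lapply(seq_len(4), function(m)
    paste0(mk$panel$fwd[m], mk$alleles[[m]],
           coremark:::revcomp(mk$panel$rev[m]))))
  amps <- c(amps, coremark:::revcomp(amps))
  for (i in seq_len(nrow(rd$files))) {
    r1 <- coremark:::read_fastq(rd$files$r1[i])
    ok <- vapply(r1$seq, function(s) any(grepl(s, amps, fixed = TRUE)),
                 logical(1))
    expect_true(all(ok))
  }

  # null allele: het truth A/null yields reads from A only
  ns <- data.frame(parent = "p1", marker = 1, hap = 1)
  mk1 <- simulate_marker_panel(n_markers = 1, seed = 5, n_alleles = 2)
  fam1 <- simulate_family(mk1, "F1", n_progeny = 2, recomb_rate = 0,
                          null_spec = ns, seed = 5,
                          parent_haps = list(p1 = rbind(2, 1),
                                             p2 = rbind(2, 2)))
  rd1 <- simulate_amplicon_reads(fam1, depth_log10_mean = 1.5,
                                 depth_log10_sd = 0, sub_error = 0,
                                 homopolymer_indel = 0, seed = 5,
                                 samples = "p1")
  r1 <- coremark:::read_fastq(rd1$files$r1[1])
  # p1 is truly 2/1 with allele 2 nulled: reads come from allele 1 only
  expect_true(length(r1$seq) > 0)
  a1 <- paste0(mk1$panel$fwd[1], mk1$alleles[[1]][1])
  expect_true(all(startsWith(a1, r1$seq) |
                    vapply(r1$seq, function(s)
                      grepl(s, a1, fixed = TRUE), logical(1))))

  # lognormal depth: most markers between 1x and 100x
  mk2 <- simulate_marker_panel(n_markers = 300, seed = 6)
  fam2 <- simulate_family(mk2, "F1", n_progeny = 1, seed = 6)
  rd2 <- simulate_amplicon_reads(fam2, depth_log10_mean = 1,
                                 depth_log10_sd = 0.5, seed = 6,
                                 samples = "p1")
  expect_gte(mean(rd2$marker_depth >= 1 & rd2$marker_depth <= 100), 0.85)
})
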