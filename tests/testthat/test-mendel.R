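test_that("expected offspring ratios follow gamete enumeration", {
  # homozygous hermaphrodite x male at the sex locus: 1 MH : 1 Hf
  sex <- expected_offspring_ratios(cross_model(c("H", "H"), c("M", "f")))
  expect_equal(sex, c(`H/M` = 0.5, `H/f` = 0.5))

  # selfed Hf: 1 HH : 2 Hf : 1 ff; 3:1 hermaphrodite:female under M>H>f
  self <- expected_offspring_ratios(cross_model(c("H", "f"), c("H", "f"),
                                                "F2"))
  expect_equal(self, c(`H/H` = 0.25, `H/f` = 0.5, `f/f` = 0.25))
  herm <- self["H/H"] + self["H/f"]
  expect_equal(unname(herm / self["f/f"]), 3)

  # Aa x A/null: null-masked homozygotes fold into visible classes
  null <- expected_offspring_ratios(cross_model(c("A", "a"), c("A", "0")))
  expect_equal(null, c(`A/A` = 0.5, `A/a` = 0.25, `a/a` = 0.25))

  # a fully null parent is rejected
  expect_error(cross_model(c("0", "0"), c("A", "a")), "null")

  # probabilities always sum to one, including after null/null
  # renormalization
  set.seed(3)
  for (i in 1:25) {
    al <- function() sample(c("A", "B", "C", "0"), 2, TRUE)
    p1 <- al(); p2 <- al()
    if (all(p1 == "0") || all(p2 == "0")) next
    r <- expected_offspring_ratios(cross_model(p1, p2))
    expect_equal(sum(r), 1)
  }
})

test_that("segregation chi-squared matches textbook computation", {
  # perfect fit
  s0 <- segregation_chi2(c(`A/A` = 50, `A/B` = 50),
                         c(`A/A` = 0.5, `A/B` = 0.5))
  expect_equal(s0$chi2, 0)
  expect_equal(s0$p, 1)
  expect_equal(s0$verdict, "mendelian")

  # 30:70 vs 1:1 -> chi2 = 16, p ~ 6.3e-5, distorted at 1e-3
  s1 <- segregation_chi2(c(`A/A` = 30, `A/B` = 70),
                         c(`A/A` = 0.5, `A/B` = 0.5))
  expect_equal(s1$chi2, 16)
  expect_equal(s1$p, pchisq(16, 1, lower.tail = FALSE))
  expect_equal(s1$p, 6.3e-5, tolerance = 0.01)
  expect_equal(s1$verdict, "distorted")

  # 45:55 vs 1:1 -> chi2 = 1, p ~ 0.317, mendelian
  s2 <- segregation_chi2(c(`A/A` = 45, `A/B` = 55),
                         c(`A/A` = 0.5, `A/B` = 0.5))
  expect_equal(s2$chi2, 1)
  expect_equal(s2$p, 0.317, tolerance = 0.01)
  expect_equal(s2$verdict, "mendelian")

  # textbook oracle on random tables
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    p <- rep(1 / k, k)
    names(p) <- LETTERS[1:k]
    o <- setNames(rpois(k, 30) + 1, LETTERS[1:k])
    got <- segregation_chi2(o, p)
    e <- p * sum(o)
    expect_equal(got$chi2, sum((o - e)^2 / e))
    expect_equal(got$p, pchisq(sum((o - e)^2 / e), k - 1,
                               lower.tail = FALSE))
  }

  # unexpected observed class fails unless within the error tolerance
  sf <- segregation_chi2(c(`A/A` = 50, `B/B` = 50),
                         c(`A/A` = 0.5, `A/B` = 0.5))
  expect_equal(sf$verdict, "failed")
  se <- segregation_chi2(c(`A/A` = 48, `A/B` = 49, `B/B` = 3),
                         c(`A/A` = 0.5, `A/B` = 0.5),
                         err_class_frac = 0.1)
  expect_equal(se$verdict, "mendelian")
})

test_that("hemizygosity scan rescues null-allele segregation patterns", {
  # 2:1:1 from nominal Aa x AA is explained by Aa x A/null
  sc <- hemizygosity_scan(c(`A/A` = 52, `A/a` = 24, `a/a` = 24),
                          c("A", "a"), c("A", "A"))
  expect_true(sc$rescued)
  best <- sc$models[sc$best, ]
  expect_equal(best$null_count, 1)
  expect_gte(best$p, 1e-3)

  # a clean 1:2:1 F2 is not better explained by any null model
  sc2 <- hemizygosity_scan(c(`A/A` = 26, `A/a` = 50, `a/a` = 24),
                           c("A", "a"), c("A", "a"), cross_type = "F2")
  best2 <- sc2$models[sc2$best, ]
  expect_equal(best2$null_count, 0)
  expect_false(sc2$rescued)

  # monomorphic A under AA x A/null has p = 1
  sc3 <- hemizygosity_scan(c(`A/A` = 80), c("A", "A"), c("A", "B"))
  m <- sc3$models
  expect_true(any(m$null_count == 1 & m$p == 1))
})

test_that("marker classification applies the class hierarchy", {
  # two parents + progeny; marker 1 zero depth, marker 2 monomorphic,
  # marker 3 segregates 1:1, marker 4 grossly distorted
  samples <- c("p1", "p2", sprintf("c%02d", 1:40))
  n <- length(samples)
  a1 <- rbind(rep(NA_integer_, n),
              rep(1L, n),
              c(1L, 1L, rep(c(1L, 1L), 20)),
              c(1L, 1L, rep(1L, 40)))
  a2 <- rbind(rep(NA_integer_, n),
              rep(1L, n),
              c(2L, 1L, rep(c(1L, 2L), 20)),
              c(2L, 1L, c(rep(1L, 39), 2L)))
  colnames(a1) <- colnames(a2) <- samples
  depth <- matrix(20, 4, n, dimnames = list(NULL, samples))
  depth[1, ] <- 0
  gm <- make_gm(a1, a2, depth = depth)
  ped <- data.frame(child = sprintf("c%02d", 1:40), mother = "p1",
                    father = "p2", family = "f")
  cls <- classify_markers(gm, ped, "F1")
  expect_equal(cls$class,
               c("failed", "monomorphic", "mappable", "distorted"))
  expect_lt(cls$p[4], 1e-3)
})

test_that("primer variant audit flags windows containing parent variants", {
  mk <- simulate_marker_panel(n_markers = 5, seed = 13)
  ns <- data.frame(parent = c("p1", "p2"), marker = c(2, 4), hap = 1)
  fam <- simulate_family(mk, "F1", n_progeny = 5, null_spec = ns,
                         seed = 13)
  d <- tempfile()
  paths <- simulate_parent_vcfs(fam, d, background_per_marker = 0.3,
                                seed = 13)
  flags <- primer_variant_check(paths, mk$panel)
  # the truth null set is contained in the flagged set
  expect_true(flags[mk$panel$marker_id[2], "p1"])
  expect_true(flags[mk$panel$marker_id[4], "p2"])
  # no variants anywhere: no flags
  empty <- tempfile()
  dir.create(empty)
  fam0 <- simulate_family(mk, "F1", n_progeny = 2, seed = 13)
  p0 <- simulate_parent_vcfs(fam0, empty, background_per_marker = 0,
                             seed = 13)
  expect_false(any(primer_variant_check(p0, mk$panel)))
  s <- primer_mismatch_summary(flags, rescued = mk$panel$marker_id[c(2, 4)])
  expect_gte(s$frac_rescued, s$frac_other)
})

test_that("IBS distances and MDS behave geometrically", {
  # identical samples have distance zero; hand-computed 3-sample toy
  a1 <- rbind(c(1L, 1L, 1L), c(1L, 1L, 2L), c(1L, 1L, 1L))
  a2 <- rbind(c(1L, 1L, 2L), c(2L, 2L, 2L), c(1L, 1L, 2L))
  # markers x samples: s1 = (1/1, 1/2, 1/1); s2 = (1/1, 1/2, 1/1);
  # s3 = (1/2, 2/2, 1/2)
  gm <- make_gm(a1, a2)
  r <- ibs_mds(gm, k = 2)
  expect_equal(unname(r$dist[1, 2]), 0)
  # s1 vs s3: markers share (1 vs 2 alleles...)
  # m1: {1,1} vs {1,2} -> 1/2; m2: {1,2} vs {2,2} -> 1/2; m3: same -> 1/2
  expect_equal(unname(r$ibs[1, 3]), 0.5)

  # an unrelated sample lies farthest from the family centroid
  mk <- simulate_marker_panel(n_markers = 30, seed = 15)
  fam <- simulate_family(mk, "F1", n_progeny = 12, seed = 15)
  g <- fam$genotypes
  # construct the genotype matrix directly from truth (alleles as indices)
  a1t <- t(pmin(g$hap1, g$hap2)); a2t <- t(pmax(g$hap1, g$hap2))
  set.seed(15)
  outsider <- matrix(sample(5:6, 2 * 30, TRUE), 2)
  a1t <- cbind(a1t, out = pmin(outsider[1, ], outsider[2, ]))
  a2t <- cbind(a2t, out = pmax(outsider[1, ], outsider[2, ]))
  gm2 <- make_gm(a1t, a2t)
  m <- ibs_mds(gm2)
  centroid <- colMeans(m$points[rownames(m$points) != "out", ])
  dists <- sqrt(rowSums(sweep(m$points, 2, centroid)^2))
  expect_equal(names(which.max(dists)), "out")
})
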