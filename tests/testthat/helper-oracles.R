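## Independent oracles and small fixture builders shared by the suite.

# Brute-force repeat masking: count canonical k-mers by dictionary lookup
# over substrings, then mark every base covered by a frequent window.
brute_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

brute_mask <- function(seqs, k, max_freq) {
  counts <- new.env(parent = emptyenv())
  win <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }
  canon <- function(w) pmin(w, unname(brute_revcomp(w)))
  for (s in seqs) {
    for (w in win(s)) {
      if (grepl("[^ACGT]", w)) next
      cw <- canon(w)
      counts[[cw]] <- (if (is.null(counts[[cw]])) 0 else counts[[cw]]) + 1
    }
  }
  out <- seqs
  for (i in seq_along(seqs)) {
    s <- seqs[i]; n <- nchar(s)
    if (n < k) next
    mask <- rep(FALSE, n)
    ws <- win(s)
    for (j in seq_along(ws)) {
      if (grepl("[^ACGT]", ws[j])) next
      if (counts[[canon(ws[j])]] > max_freq) mask[j:(j + k - 1)] <- TRUE
    }
    ch <- strsplit(s, "")[[1]]
    ch[mask] <- "N"
    out[i] <- paste(ch, collapse = "")
  }
  out
}

# Exhaustive best collinear subsequence (chaining oracle) within one
# (tname, qname, strand) group.
oracle_best_chain_score <- function(recs, max_gap) {
  best <- 0
  for (st in unique(recs$strand)) {
    sub <- recs[recs$strand == st, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) next
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      g <- sub[idx, , drop = FALSE]
      g <- g[order(g$tstart), , drop = FALSE]
      ok <- TRUE
      if (nrow(g) > 1) for (i in 2:nrow(g)) {
        a <- g[i - 1, ]; b <- g[i, ]
        if (b$tstart <= a$tstart || b$tstart - a$tend > max_gap) {
          ok <- FALSE; break
        }
        if (st == "+") {
          if (b$qstart <= a$qstart || b$qstart - a$qend > max_gap) {
            ok <- FALSE; break
          }
        } else {
          if (b$qstart >= a$qstart || a$qstart - b$qend > max_gap) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) best <- max(best, sum(g$n_matches))
    }
  }
  best
}

# Naive independent re-derivation of the one-to-one quota rule.
oracle_quota_selection <- function(chains, tol, min_block_len) {
  sc <- vapply(chains, `[[`, 0, "score")
  tn <- vapply(chains, `[[`, "", "tname")
  ts <- vapply(chains, function(ch) ch$t_span[1], 0)
  qn <- vapply(chains, `[[`, "", "qname")
  ord <- order(-sc, tn, ts, qn)
  acc <- list()
  for (i in ord) {
    ch <- chains[[i]]
    ovT <- 0; ovQ <- 0
    for (a in acc) {
      if (a$qname != ch$qname) next
      if (a$tname == ch$tname)
        ovT <- ovT + max(0, min(a$t_span[2], ch$t_span[2]) -
                           max(a$t_span[1], ch$t_span[1]))
      ovQ <- ovQ + max(0, min(a$q_span[2], ch$q_span[2]) -
                         max(a$q_span[1], ch$q_span[1]))
    }
    if (ovT <= tol * (ch$t_span[2] - ch$t_span[1]) &&
        ovQ <= tol * (ch$q_span[2] - ch$q_span[1]))
      acc <- c(acc, list(ch))
  }
  acc <- Filter(function(ch) ch$t_span[2] - ch$t_span[1] > min_block_len,
                acc)
  acc
}

# Random anchor sets on one target/query pair.
rand_anchor_recs <- function(n, seed, strand = "+") {
  set.seed(seed)
  ts <- sort(sample(0:200, n)) * 100
  w <- sample(50:90, n, replace = TRUE) * 10
  qs <- sample(0:200, n) * 100
  data.frame(qname = "q", qlen = 1e6, qstart = qs, qend = qs + w,
             strand = if (length(strand) == 1) strand else
               sample(strand, n, TRUE),
             tname = "t", tlen = 1e6, tstart = ts, tend = ts + w,
             n_matches = w - sample(0:20, n, TRUE), aln_len = w,
             mapq = 60, stringsAsFactors = FALSE)
}

# Build a GenotypeMatrix directly from allele-index matrices.
make_gm <- function(a1, a2, depth = NULL, catalog = NULL) {
  markers <- rownames(a1) %||% sprintf("chr1_%d", seq_len(nrow(a1)) * 1000)
  samples <- colnames(a1) %||% sprintf("s%02d", seq_len(ncol(a1)))
  dimnames(a1) <- dimnames(a2) <- list(markers, samples)
  if (is.null(depth))
    depth <- matrix(ifelse(is.na(a1), 0L, 20L), nrow(a1), ncol(a1),
                    dimnames = dimnames(a1))
  storage.mode(depth) <- "integer"
  if (is.null(catalog))
    catalog <- lapply(setNames(markers, markers), function(m)
      paste0("HAP", 1:8))
  structure(list(a1 = a1, a2 = a2, d1 = depth, d2 = depth, depth = depth,
                 ambiguous = matrix(FALSE, nrow(a1), ncol(a1),
                                    dimnames = dimnames(a1)),
                 catalog = catalog, markers = markers, samples = samples),
            class = "GenotypeMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotype concordance of a called GenotypeMatrix against family truth.
# Called allele strings are assigned to truth alleles by minimum edit
# distance ('+' stripped first): where the two mates do not overlap the
# haplotype tag lacks the unread middle bases, so exact string equality is
# not attainable, but the nearest truth allele is unambiguous.
genotype_concordance <- function(gm, fam) {
  tru <- truth_observable_genotypes(fam)
  conc <- 0; tot <- 0
  for (m in seq_along(gm$markers)) {
    truth_al <- fam$markers$alleles[[m]]
    used <- sort(unique(stats::na.omit(c(gm$a1[m, ], gm$a2[m, ]))))
    if (length(used) == 0) next
    cat_str <- gsub("+", "", gm$catalog[[m]][used], fixed = TRUE)
    D <- utils::adist(cat_str, truth_al)
    map <- rep(NA_integer_, length(gm$catalog[[m]]))
    map[used] <- apply(D, 1, function(r) {
      w <- which(r == min(r))
      if (length(w) == 1) w else NA_integer_
    })
    for (s in gm$samples) {
      if (is.na(gm$a1[m, s])) next
      called <- sort(map[c(gm$a1[m, s], gm$a2[m, s])], na.last = TRUE)
      tr <- sort(c(tru$a1[s, m], tru$a2[s, m]))
      tot <- tot + 1
      if (!anyNA(called) && length(called) == length(tr) &&
          all(called == tr))
        conc <- conc + 1
    }
  }
  list(concordance = conc / tot, n = tot)
}
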