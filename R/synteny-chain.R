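#' Chain collinear alignment anchors
#'
#' Groups anchors per (target, query, strand) and finds maximal-score
#' collinear chains by sparse dynamic programming: anchor starts must be
#' strictly increasing on the target and strictly increasing (+ strand) or
#' strictly decreasing (- strand) on the query, with inter-anchor gaps at most
#' `max_gap` on both genomes. Chains are extracted greedily by descending
#' score (each anchor belongs to at most one chain); chains with fewer than
#' `min_anchors` anchors are discarded.
#'
#' @param records alignment records as from [read_paf()].
#' @param max_gap maximum inter-anchor gap in bases on either genome
#'   (default 10 kb). Gaps larger than this break a chain, so blocks never
#'   bridge sizeable unaligned (presence/absence) segments; smaller gaps -
#'   local tandem duplications, small indels - are smoothed over when the
#'   chain is later collapsed to its bounding interval.
#' @param min_anchors minimum anchors per retained chain (default 3).
#' @return List of chains; each chain is a list with `anchors` (data frame),
#'   `score` (summed n_matches), `strand`, `tname`, `qname`, `t_span` and
#'   `q_span` (0-based half-open bounds). Sorted by descending score with
#'   ties broken by (tname, tstart, qname).
#' @export
chain_anchors <- function(records, max_gap = 1e4, min_anchors = 3) {
  stopifnot(max_gap > 0, min_anchors >= 1)
  if (nrow(records) == 0) return(list())
  key <- paste(records$tname, records$qname, records$strand, sep = "\r")
  chains <- list()
  for (grp in split(records, key)) {
    chains <- c(chains, chain_group(grp, max_gap))
  }
  chains <- Filter(function(ch) nrow(ch$anchors) >= min_anchors, chains)
  if (length(chains) == 0) return(chains)
  ord <- order(-vapply(chains, `[[`, 0, "score"),
               vapply(chains, `[[`, "", "tname"),
               vapply(chains, function(ch) ch$t_span[1], 0),
               vapply(chains, `[[`, "", "qname"))
  chains[ord]
}

# DP chain extraction within one (tname, qname, strand) group.
chain_group <- function(grp, max_gap) {
  strand <- grp$strand[1]
  grp <- grp[order(grp$tstart, grp$qstart), , drop = FALSE]
  out <- list()
  active <- rep(TRUE, nrow(grp))
  repeat {
    idx <- which(active)
    if (length(idx) == 0) break
    g <- grp[idx, , drop = FALSE]
    n <- nrow(g)
    score <- g$n_matches
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      best <- score[j]
      for (i in seq_len(j - 1)) {
        if (g$tstart[j] <= g$tstart[i]) next
        gap_t <- g$tstart[j] - g$tend[i]
        if (gap_t > max_gap) next
        if (strand == "+") {
          if (g$qstart[j] <= g$qstart[i]) next
          gap_q <- g$qstart[j] - g$qend[i]
        } else {
          if (g$qstart[j] >= g$qstart[i]) next
          gap_q <- g$qstart[i] - g$qend[j]
        }
        if (gap_q > max_gap) next
        cand <- score[i] + g$n_matches[j]
        if (cand > best) { best <- cand; prev[j] <- i }
      }
      score[j] <- best
    }
    end <- which.max(score)
    path <- end
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    anchors <- g[path, , drop = FALSE]
    out[[length(out) + 1L]] <- list(
      anchors = anchors, score = sum(anchors$n_matches), strand = strand,
      tname = anchors$tname[1], qname = anchors$qname[1],
      t_span = c(min(anchors$tstart), max(anchors$tend)),
      q_span = c(min(anchors$qstart), max(anchors$qend)))
    active[idx[path]] <- FALSE
  }
  out
}

#' Select one-to-one syntenic blocks from chains
#'
#' Processes chains in descending score order; a chain is accepted only if its
#' reference span and its query span each overlap the already-accepted spans
#' of the same assembly by at most `overlap_tol` of the chain's own span
#' length. Accepted chains are collapsed to their bounding intervals (which
#' smooths over small local tandem duplications), and blocks whose reference
#' span is not larger than `min_block_len` are dropped.
#'
#' @param chains list of chains from [chain_anchors()].
#' @param overlap_tol allowed overlap fraction, in `[0, 1)` (default 0.1).
#' @param min_block_len minimum reference span in bases (default 10 kb;
#'   blocks must be strictly larger to survive).
#' @return Data frame of syntenic blocks: chrom, start, end (reference,
#'   0-based half-open), assembly, q_start, q_end, strand, score.
#' @export
select_one_to_one <- function(chains, overlap_tol = 0.1,
                              min_block_len = 1e4) {
  stopifnot(overlap_tol >= 0, overlap_tol < 1)
  if (length(chains) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), assembly = character(),
                      q_start = numeric(), q_end = numeric(),
                      strand = character(), score = numeric()))
  ord <- order(-vapply(chains, `[[`, 0, "score"),
               vapply(chains, `[[`, "", "tname"),
               vapply(chains, function(ch) ch$t_span[1], 0),
               vapply(chains, `[[`, "", "qname"))
  chains <- chains[ord]
  acc_t <- list(); acc_q <- list() # per assembly: accepted span data frames
  keep <- logical(length(chains))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    a <- ch$qname
    t_len <- ch$t_span[2] - ch$t_span[1]
    q_len <- ch$q_span[2] - ch$q_span[1]
    t_ov <- span_overlap(acc_t[[a]], ch$tname, ch$t_span)
    q_ov <- span_overlap(acc_q[[a]], a, ch$q_span)
    if (t_ov <= overlap_tol * t_len && q_ov <= overlap_tol * q_len) {
      keep[i] <- TRUE
      acc_t[[a]] <- rbind(acc_t[[a]],
                          data.frame(name = ch$tname, s = ch$t_span[1],
                                     e = ch$t_span[2]))
      acc_q[[a]] <- rbind(acc_q[[a]],
                          data.frame(name = a, s = ch$q_span[1],
                                     e = ch$q_span[2]))
    }
  }
  kept <- chains[keep]
  blocks <- do.call(rbind, lapply(kept, function(ch) data.frame(
    chrom = ch$tname, start = ch$t_span[1], end = ch$t_span[2],
    assembly = ch$qname, q_start = ch$q_span[1], q_end = ch$q_span[2],
    strand = ch$strand, score = ch$score, stringsAsFactors = FALSE)))
  blocks <- blocks[blocks$end - blocks$start > min_block_len, , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

span_overlap <- function(acc, name, span) {
  if (is.null(acc)) return(0)
  acc <- acc[acc$name == name, , drop = FALSE]
  if (nrow(acc) == 0) return(0)
  sum(pmax(0, pmin(acc$e, span[2]) - pmax(acc$s, span[1])))
}
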