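## Shared helpers: deterministic RNG streams and 0-based half-open interval
## arithmetic (backed by IRanges).

#' Derive a reproducible sub-seed for a named output stream
#'
#' Each simulator output draws from its own RNG stream, seeded from the master
#' seed plus a stable hash of the stream's role, so adding an output never
#' perturbs existing ones.
#'
#' @param seed master integer seed.
#' @param role character scalar naming the stream (e.g. `"reference"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, role) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(role))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (b in utf8ToInt(role)) h <- (h * 131 + b) %% m
  s <- abs(seed) %% m
  s <- (s * 69069 + h + 1) %% m
  as.integer(s)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## ---- intervals: data.frame(start, end), 0-based half-open ----------------

new_intervals <- function(start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  if (any(start >= end)) stop("intervals must satisfy start < end")
  o <- order(start, end)
  data.frame(start = as.numeric(start)[o], end = as.numeric(end)[o])
}

iv_to_iranges <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

iranges_to_iv <- function(ir) {
  ir <- IRanges::reduce(ir)
  data.frame(start = as.numeric(IRanges::start(ir)) - 1,
             end = as.numeric(IRanges::end(ir)))
}

iv_union <- function(iv) iranges_to_iv(iv_to_iranges(iv))

iv_intersect <- function(a, b) {
  iranges_to_iv(IRanges::intersect(iv_to_iranges(a), iv_to_iranges(b)))
}

iv_complement <- function(iv, len) {
  if (nrow(iv) == 0) return(data.frame(start = 0, end = len))
  iranges_to_iv(IRanges::setdiff(IRanges::IRanges(1L, as.integer(len)),
                                 iv_to_iranges(iv)))
}

iv_length <- function(iv) if (nrow(iv) == 0) 0 else sum(iv$end - iv$start)

# Jaccard index of two interval sets over the same reference.
iv_jaccard <- function(a, b) {
  ia <- iv_to_iranges(a); ib <- iv_to_iranges(b)
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  uni <- sum(IRanges::width(IRanges::union(ia, ib)))
  if (uni == 0) return(1)
  inter / uni
}

## ---- sequence helpers ----------------------------------------------------

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised substitution mutation: returns x with `k[i]` random substitutions
# applied to x[i] (k may be 0).
mutate_subs <- function(x, k) {
  idx <- which(k > 0)
  for (i in idx) {
    r <- charToRaw(x[i])
    pos <- sample.int(length(r), min(k[i], length(r)))
    for (p in pos) {
      cur <- rawToChar(r[p])
      r[p] <- charToRaw(sample(setdiff(DNA, cur), 1))
    }
    x[i] <- rawToChar(r)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
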