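#' Centered identity-by-state kinship matrix
#'
#' Computes pairwise IBS (as in [ibs_mds()]) and double-centers it (row and
#' column means removed, grand mean added back), yielding a symmetric
#' kinship matrix with rows and columns summing to ~0.
#'
#' @param x a `GenotypeMatrix`, or an IBS matrix.
#' @return The centered kinship matrix K.
#' @export
centered_ibs_kinship <- function(x) {
  ibs <- if (inherits(x, "GenotypeMatrix")) {
    all_missing <- colSums(!is.na(x$a1)) == 0
    if (any(all_missing))
      stop("sample(s) with no called genotypes: ",
           paste(x$samples[all_missing], collapse = ", "))
    n <- length(x$samples)
    m <- matrix(NA_real_, n, n, dimnames = list(x$samples, x$samples))
    diag(m) <- 1
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- pair_ibs(x$a1[, i], x$a2[, i],
                                     x$a1[, j], x$a2[, j])
    m
  } else as.matrix(x)
  rm_ <- rowMeans(ibs); gm_ <- mean(ibs)
  K <- ibs - outer(rm_, rep(1, ncol(ibs))) -
    outer(rep(1, nrow(ibs)), rm_) + gm_
  (K + t(K)) / 2
}

#' Mixed linear model marker-trait association
#'
#' Fits, per marker, the mixed model `y = X a + P b + u + e` with
#' `Var(u) = sg2 K` and `Var(e) = se2 I`, solved through the spectral
#' decomposition of K. The variance ratio `delta = sg2/se2` is estimated
#' once by REML on the null (covariate-only) model over a log-spaced grid
#' with local refinement, then held fixed for the per-marker tests
#' (population parameters previously determined). Markers are tested by an
#' F-test on their fixed effects; R-squared is the reduction in generalized
#' residual sum of squares relative to the null model.
#'
#' Marker coding: `"indicator"` (default) codes genotype classes as
#' indicator columns against the most frequent class, suiting multiallelic
#' haplotype markers; `"dosage"` expects a numeric sample x marker matrix.
#' Samples with a missing genotype at a marker have that marker's columns
#' mean-imputed.
#'
#' @param y named numeric phenotype vector (samples with missing phenotype
#'   are dropped listwise).
#' @param genotypes a `GenotypeMatrix` or (for dosage coding) a numeric
#'   sample x marker matrix.
#' @param covariates optional sample x q numeric matrix of fixed covariates
#'   (e.g. the first two MDS coordinates).
#' @param K kinship matrix from [centered_ibs_kinship()]; NULL fits
#'   ordinary least squares.
#' @param coding `"indicator"` or `"dosage"`.
#' @return List of class `AssocResult`: `table` (marker, p, minus_log10_p,
#'   effect, r2, note), `delta` (REML variance ratio), `samples`.
#' @export
mlm_associate <- function(y, genotypes, covariates = NULL, K = NULL,
                          coding = c("indicator", "dosage")) {
  coding <- match.arg(coding)
  y <- y[!is.na(y)]
  samples <- names(y)
  if (is.null(samples)) stop("y must be a named vector")
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates))
    C <- cbind(C, as.matrix(covariates)[samples, , drop = FALSE])

  if (is.null(K)) {
    U <- diag(n); dvals <- rep(0, n); delta <- 0
  } else {
    K <- as.matrix(K)[samples, samples]
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors
    dvals <- pmax(eig$values, 0)
    delta <- reml_delta(crossprod(U, y), crossprod(U, C), dvals)
  }
  Uty <- crossprod(U, y)
  UtC <- crossprod(U, C)
  ws <- 1 / sqrt(delta * dvals + 1)
  ys <- Uty * ws
  Cs <- UtC * ws
  fit0 <- stats::lm.fit(Cs, ys)
  rss0 <- sum(fit0$residuals^2)
  p0 <- fit0$rank

  designs <- marker_designs(genotypes, samples, coding)
  rows <- lapply(names(designs), function(mk) {
    X <- designs[[mk]]
    if (is.null(X))
      return(data.frame(marker = mk, p = NA_real_,
                        minus_log10_p = NA_real_, effect = NA_real_,
                        r2 = NA_real_, note = "monomorphic",
                        stringsAsFactors = FALSE))
    Xs <- crossprod(U, X) * ws
    fit1 <- stats::lm.fit(cbind(Cs, Xs), ys)
    q <- fit1$rank - p0
    if (q < 1)
      return(data.frame(marker = mk, p = NA_real_,
                        minus_log10_p = NA_real_, effect = NA_real_,
                        r2 = NA_real_, note = "singular",
                        stringsAsFactors = FALSE))
    rss1 <- sum(fit1$residuals^2)
    df2 <- n - fit1$rank
    Fstat <- ((rss0 - rss1) / q) / (rss1 / df2)
    p <- pf(Fstat, q, df2, lower.tail = FALSE)
    beta <- fit1$coefficients[-seq_len(ncol(Cs))]
    beta <- beta[!is.na(beta)]
    data.frame(marker = mk, p = p, minus_log10_p = -log10(p),
               effect = beta[which.max(abs(beta))],
               r2 = (rss0 - rss1) / rss0, note = "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, delta = delta, samples = samples),
            class = "AssocResult")
}

#' @export
print.AssocResult <- function(x, ...) {
  cat("AssocResult:", nrow(x$table), "markers tested; delta =",
      signif(x$delta, 4), "\n")
  top <- x$table[order(x$table$p), ][1, ]
  cat("  top marker:", top$marker, "p =", signif(top$p, 3), "\n")
  invisible(x)
}

# REML profile over the variance ratio delta, on the null model.
reml_delta <- function(Uty, UtC, dvals) {
  n <- length(Uty); p <- qr(UtC)$rank
  ll <- function(log10d) {
    delta <- 10^log10d
    w <- delta * dvals + 1
    ws <- 1 / sqrt(w)
    fit <- stats::lm.fit(UtC * ws, Uty * ws)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    xtx <- crossprod(UtC * ws)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              as.numeric(determinant(xtx)$modulus))
  }
  grid <- seq(-6, 6, length.out = 25)
  vals <- vapply(grid, ll, 0)
  # delta = 0 (pure OLS) competes with the grid
  w0 <- rep(1, n)
  fit <- stats::lm.fit(UtC, Uty)
  s2 <- sum(fit$residuals^2) / (n - p)
  ll0 <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                   as.numeric(determinant(crossprod(UtC))$modulus))
  best <- which.max(vals)
  if (ll0 >= vals[best]) return(0)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE)
  if (ll0 >= opt$objective) 0 else 10^opt$maximum
}

# per-marker fixed-effect design matrices (rows = samples)
marker_designs <- function(genotypes, samples, coding) {
  if (coding == "dosage" && is.matrix(genotypes)) {
    out <- lapply(colnames(genotypes), function(mk) {
      x <- genotypes[samples, mk]
      if (length(unique(stats::na.omit(x))) < 2) return(NULL)
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      matrix(x, ncol = 1)
    })
    return(setNames(out, colnames(genotypes)))
  }
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  out <- lapply(genotypes$markers, function(mk) {
    a1 <- genotypes$a1[mk, samples]; a2 <- genotypes$a2[mk, samples]
    lab <- ifelse(is.na(a1), NA, paste(a1, a2, sep = "/"))
    cls <- names(sort(table(lab), decreasing = TRUE))
    if (length(cls) < 2) return(NULL)
    X <- vapply(cls[-1], function(cl) as.numeric(lab == cl),
                numeric(length(lab)))
    X <- as.matrix(X)
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    X
  })
  setNames(out, genotypes$markers)
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param n_markers number of markers tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return `-log10(alpha / n_markers)`.
#' @examples
#' bonferroni_threshold(1712) # 4.53
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  stopifnot(n_markers >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_markers)
}

#' Genotype-phenotype concordance of a categorical trait marker
#'
#' Enumerates all mappings from observed genotype classes to the phenotype
#' classes (given in dominance order, most dominant first) and returns the
#' mapping maximizing agreement together with its agreement fraction.
#'
#' @param genotype_classes character vector of per-sample genotype class
#'   labels (NA = missing).
#' @param phenotypes character vector of per-sample phenotype classes.
#' @param dominance character vector of phenotype classes in dominance
#'   order (default `c("M", "H", "f")`).
#' @return List with `concordance` (fraction), `mapping` (named character
#'   vector genotype class -> phenotype class) and `n` (pairs compared).
#' @export
sex_concordance <- function(genotype_classes, phenotypes,
                            dominance = c("M", "H", "f")) {
  ok <- !is.na(genotype_classes) & !is.na(phenotypes)
  g <- genotype_classes[ok]; ph <- phenotypes[ok]
  gcls <- unique(g)
  pcls <- dominance[dominance %in% c(ph, dominance)]
  if (length(gcls)^length(pcls) > 1e6 || length(gcls) > 8)
    stop("too many genotype classes to enumerate")
  combos <- expand.grid(rep(list(pcls), length(gcls)),
                        stringsAsFactors = FALSE)
  best <- -1; best_map <- NULL
  for (i in seq_len(nrow(combos))) {
    map <- setNames(unlist(combos[i, ]), gcls)
    agree <- sum(map[g] == ph)
    if (agree > best) { best <- agree; best_map <- map }
  }
  list(concordance = best / length(g), mapping = best_map, n = length(g))
}
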