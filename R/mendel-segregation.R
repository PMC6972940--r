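#' Define a cross model with optional null (hemizygous) alleles
#'
#' Parental genotypes are ordered allele pairs over observed allele symbols
#' plus the null symbol `"0"` (a non-amplifying or deleted allele). `F1`
#' crosses parent1 x parent2; `F2` selfs parent1 (pass the F1 genotype as
#' parent1); `BC` is handled identically to F1 (the backcross parent is
#' simply one of the two).
#'
#' @param parent1,parent2 character vectors of length 2 (allele symbols;
#'   `"0"` = null).
#' @param cross_type `"F1"`, `"F2"` or `"BC"`.
#' @return A `CrossModel` list.
#' @export
cross_model <- function(parent1, parent2 = parent1,
                        cross_type = c("F1", "F2", "BC")) {
  cross_type <- match.arg(cross_type)
  parent1 <- as.character(parent1); parent2 <- as.character(parent2)
  stopifnot(length(parent1) == 2, length(parent2) == 2)
  if (all(parent1 == "0") || all(parent2 == "0"))
    stop("a parent cannot be null for both alleles")
  null_count <- sum(parent1 == "0") + sum(parent2 == "0")
  structure(list(parent1 = parent1, parent2 = parent2,
                 cross_type = cross_type, null_count = null_count),
            class = "CrossModel")
}

#' Expected observable offspring genotype ratios
#'
#' Enumerates the four gamete unions at probability 1/4 each. A genotype
#' carrying one null allele is observed as homozygous for its visible
#' allele; null/null offspring are unobservable (missing) and the remaining
#' probabilities are renormalized. Identical observable genotypes are
#' merged.
#'
#' @param model a `CrossModel`.
#' @return Named numeric vector of probabilities; names are sorted allele
#'   pairs like `"A/B"`. Sums to 1.
#' @examples
#' expected_offspring_ratios(cross_model(c("H", "H"), c("M", "f")))
#' @export
expected_offspring_ratios <- function(model) {
  stopifnot(inherits(model, "CrossModel"))
  p <- list()
  for (g1 in model$parent1) for (g2 in model$parent2) {
    al <- c(g1, g2)
    vis <- al[al != "0"]
    key <- if (length(vis) == 0) NA_character_
      else if (length(vis) == 1) paste(vis, vis, sep = "/")
      else paste(sort(vis, method = "radix"), collapse = "/")
    if (!is.na(key)) p[[key]] <- (p[[key]] %||% 0) + 0.25
  }
  if (length(p) == 0) stop("no observable offspring class")
  out <- unlist(p)
  out / sum(out)
}

#' Pearson chi-squared goodness-of-fit test of segregation
#'
#' @param observed named counts of observable genotype classes.
#' @param expected named class probabilities (e.g. from
#'   [expected_offspring_ratios()]); classes absent from `observed` count
#'   as zero.
#' @param tolerance significance tolerance for the `distorted` verdict
#'   (1e-3 is typical for F1/BC families, 1e-10 for F2).
#' @param err_class_frac observed classes impossible under `expected` are
#'   tolerated as genotyping errors and excluded from the test when their
#'   combined fraction is at most this value (default 0: any impossible
#'   class fails the test).
#' @return A `SegregationResult` list: `observed`, `expected`, `chi2`,
#'   `df`, `p`, `verdict` in `{mendelian, distorted, monomorphic, failed}`.
#'   An observed class not present in `expected` (or with expected
#'   probability zero) yields verdict `failed` rather than an exception.
#' @export
segregation_chi2 <- function(observed, expected, tolerance = 1e-3,
                             err_class_frac = 0) {
  observed <- observed[observed > 0]
  n <- sum(observed)
  stopifnot(n > 0)
  res <- list(observed = observed, expected = expected)
  bad <- setdiff(names(observed), names(expected)[expected > 0])
  if (length(bad)) {
    if (sum(observed[bad]) / n <= err_class_frac) {
      observed <- observed[setdiff(names(observed), bad)]
      n <- sum(observed)
      if (n == 0) {
        res <- c(res, list(chi2 = NA_real_, df = NA_integer_,
                           p = NA_real_, verdict = "failed",
                           diagnostic = "no progeny in expected classes"))
        return(structure(res, class = "SegregationResult"))
      }
    } else {
      res <- c(res, list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                         verdict = "failed",
                         diagnostic = paste("unexpected class:",
                                            paste(bad, collapse = ", "))))
      return(structure(res, class = "SegregationResult"))
    }
  }
  obs <- setNames(rep(0, length(expected)), names(expected))
  obs[names(observed)] <- observed
  e <- expected * n
  chi2 <- sum((obs - e)^2 / e)
  df <- length(expected) - 1L
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  verdict <- if (df == 0) "monomorphic"
    else if (p < tolerance) "distorted" else "mendelian"
  structure(c(res, list(chi2 = chi2, df = df, p = p, verdict = verdict)),
            class = "SegregationResult")
}

#' @export
print.SegregationResult <- function(x, ...) {
  cat("SegregationResult:", x$verdict)
  if (!is.na(x$p)) cat(sprintf(" (chi2 = %.3g, df = %d, p = %.3g)",
                               x$chi2, x$df, x$p))
  cat("\n")
  invisible(x)
}

#' Scan hemizygous (null-allele) models for a distorted marker
#'
#' Evaluates every cross model obtained from the nominal parental genotypes
#' by replacing one parental allele with the null symbol (each parent), or
#' one allele in each parent, and reports the model maximizing the
#' segregation p-value. The marker is "rescued" if that maximum reaches
#' `tolerance`.
#'
#' @param observed named counts of observable progeny genotype classes.
#' @param parent1,parent2 nominal parental genotypes (length-2 character).
#' @param cross_type cross type (F2 = selfing of parent1).
#' @param tolerance rescue threshold on the p-value (default 1e-3).
#' @param err_class_frac impossible-class tolerance passed to
#'   [segregation_chi2()].
#' @return List with `models` (data frame: parent1, parent2, null_count,
#'   chi2, p, verdict), `best` (row index), `rescued` (logical).
#' @export
hemizygosity_scan <- function(observed, parent1, parent2,
                              cross_type = "F1", tolerance = 1e-3,
                              err_class_frac = 0) {
  variants1 <- unique(list(parent1,
                           c(parent1[1], "0"), c("0", parent1[2])))
  variants2 <- unique(list(parent2,
                           c(parent2[1], "0"), c("0", parent2[2])))
  rows <- list()
  for (v1 in variants1) for (v2 in variants2) {
    if (all(v1 == "0") || all(v2 == "0")) next
    model <- tryCatch(cross_model(v1, v2, cross_type), error = function(e) NULL)
    if (is.null(model)) next
    if (cross_type == "F2" && !identical(v1, v2)) {
      # selfing: both gamete sources are the same individual
      model <- cross_model(v1, v1, cross_type)
    }
    exp_p <- expected_offspring_ratios(model)
    seg <- segregation_chi2(observed, exp_p, tolerance, err_class_frac)
    rows[[length(rows) + 1L]] <- data.frame(
      parent1 = paste(model$parent1, collapse = "/"),
      parent2 = paste(model$parent2, collapse = "/"),
      null_count = model$null_count,
      chi2 = seg$chi2, p = if (is.na(seg$p)) 0 else seg$p,
      verdict = seg$verdict, stringsAsFactors = FALSE)
  }
  models <- unique(do.call(rbind, rows))
  rownames(models) <- NULL
  # best = max p; ties favour fewer null alleles
  best <- order(-models$p, models$null_count)[1]
  list(models = models, best = best,
       rescued = models$p[best] >= tolerance & models$null_count[best] > 0)
}
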