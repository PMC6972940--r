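#' Fit an exponential-decay model of core-genome convergence
#'
#' Least-squares fit of `y(k) = A + B * exp(-c * k)` to mean core size as a
#' function of the number of assemblies k. `A` is the plateau the core genome
#' converges to; `n_converge` is the smallest integer k at which the predicted
#' excess over the plateau drops to at most `eps * A`.
#'
#' @param core_sizes data frame with columns `k` and `mean_size` (>= 4
#'   distinct k values), e.g. from [core_size_by_k()].
#' @param eps convergence tolerance as a fraction of the plateau
#'   (default 0.01).
#' @return A list of class `DecayFit` with `A`, `B`, `c`, `n_converge`,
#'   `rmse` and `converged` (`TRUE`, `FALSE` for an optimizer failure, or
#'   `"constant"` for a degenerate flat series where `c` is NA).
#' @examples
#' k <- 1:9
#' fit <- fit_core_decay(data.frame(k = k, mean_size = 40 + 200 * exp(-0.5 * k)))
#' fit$A; fit$n_converge
#' @export
fit_core_decay <- function(core_sizes, eps = 0.01) {
  stopifnot(is.data.frame(core_sizes),
            all(c("k", "mean_size") %in% names(core_sizes)))
  k <- core_sizes$k; y <- core_sizes$mean_size
  if (length(unique(k)) < 4)
    stop("need at least 4 distinct k values to fit the decay model")
  if (any(y <= 0)) stop("core sizes must be positive")

  if (sd(y) < 1e-9 * mean(y)) {
    return(structure(list(A = mean(y), B = 0, c = NA_real_, n_converge = 1L,
                          rmse = 0, converged = "constant"),
                     class = "DecayFit"))
  }
  a0 <- max(min(y) * 0.9, 1e-9)
  b0 <- max(max(y) - a0, 1e-9)
  # crude rate start from the first and last excess over a0
  c0 <- {
    e1 <- max(y[which.min(k)] - a0, 1e-9)
    e2 <- max(y[which.max(k)] - a0, 1e-9)
    max((log(e1) - log(e2)) / max(max(k) - min(k), 1), 1e-3)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + B * exp(-cc * k),
                      start = list(A = a0, B = b0, cc = c0),
                      lower = c(0, 0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, B = NA_real_, c = NA_real_,
                          n_converge = NA_integer_, rmse = NA_real_,
                          converged = FALSE),
                     class = "DecayFit"))
  }
  p <- coef(fit)
  A <- unname(p["A"]); B <- unname(p["B"]); cc <- unname(p["cc"])
  rmse <- sqrt(mean((y - (A + B * exp(-cc * k)))^2))
  n_converge <- if (B <= eps * A || B == 0) 1L
    else if (A <= 0) NA_integer_ # plateau on the zero boundary
    else as.integer(ceiling(log(B / (eps * A)) / cc))
  structure(list(A = A, B = B, c = cc, n_converge = n_converge,
                 rmse = rmse, converged = TRUE),
            class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  if (identical(x$converged, FALSE)) {
    cat("DecayFit: optimizer did not converge\n")
  } else {
    cat(sprintf("DecayFit: plateau A = %.4g, B = %.4g, rate c = %.4g\n",
                x$A, x$B, x$c))
    cat("  converges (excess <= eps*A) at k =", x$n_converge, "\n")
  }
  invisible(x)
}
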