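# Convergence and model-adequacy diagnostics.

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window (first `frac_early` of the chain)
#' with a late window (last `frac_late`) via
#' `z = (m_early - m_late) / sqrt(se_early^2 + se_late^2)`, with each
#' window's variance estimated by batch means (`ceiling(sqrt(n))`
#' batches) to absorb autocorrelation. |z| > 1.6 is the conventional flag
#' that a chain has not been run long enough.
#'
#' @param chain numeric chain of length >= 100.
#' @param frac_early,frac_late window fractions (classic 0.1 / 0.5).
#' @return A `camsecr_geweke` list with `z`, `frac_early`, `frac_late`.
#' @export
geweke_z <- function(chain, frac_early = 0.1, frac_late = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic (n < 100)")
  stopifnot(frac_early > 0, frac_late > 0, frac_early + frac_late <= 1)
  if (stats::sd(chain) == 0) {
    warning("zero-variance chain: Geweke z defined as 0")
    return(structure(list(z = 0, frac_early = frac_early,
                          frac_late = frac_late),
                     class = "camsecr_geweke"))
  }
  early <- chain[seq_len(floor(frac_early * n))]
  late <- chain[(n - floor(frac_late * n) + 1L):n]
  se2 <- function(x) {
    nb <- max(2L, ceiling(sqrt(length(x))))
    b <- floor(length(x) / nb)
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    stats::var(bm) / nb
  }
  z <- (mean(early) - mean(late)) / sqrt(se2(early) + se2(late))
  structure(list(z = z, frac_early = frac_early, frac_late = frac_late),
            class = "camsecr_geweke")
}

#' @export
print.camsecr_geweke <- function(x, ...) {
  cat(sprintf("Geweke z = %.3f (windows %.0f%%/%.0f%%)%s\n", x$z,
              100 * x$frac_early, 100 * x$frac_late,
              if (abs(x$z) > 1.6) "  [|z| > 1.6: not converged]" else ""))
  invisible(x)
}

#' Freeman-Tukey discrepancy
#'
#' `T = sum((sqrt(obs) - sqrt(exp))^2)`, a variance-stabilised
#' goodness-of-fit statistic for count tables, used as the posterior
#' predictive discrepancy.
#'
#' @param observed,expected non-negative arrays of equal shape.
#' @return Scalar statistic.
#' @export
freeman_tukey <- function(observed, expected) {
  if (!identical(dim(observed), dim(expected)) ||
      length(observed) != length(expected)) {
    stop("observed and expected must have the same shape")
  }
  if (any(observed < 0) || any(expected < 0)) {
    stop("counts must be non-negative")
  }
  sum((sqrt(observed) - sqrt(expected))^2)
}

#' Bayesian p-value from the posterior predictive check
#'
#' During sampling (see [mcmc_config()]'s `pvalue_every`) a replicate
#' capture array is simulated from the current parameters and latent state
#' at regular intervals, and the Freeman-Tukey discrepancy of observed and
#' replicate individual-by-trap encounter counts against their expectation
#' is recorded. The Bayesian p-value is the fraction of draws with
#' `T_rep >= T_obs` (ties count toward adequacy): values near 0 or 1
#' indicate the model is inadequate.
#'
#' @param fit a `camsecr_fit` with recorded discrepancies.
#' @return A `camsecr_fitcheck` list with `p_value`, `statistic`,
#'   `n_draws`.
#' @export
bayesian_pvalue <- function(fit) {
  stopifnot(inherits(fit, "camsecr_fit"))
  d <- fit$discrepancy
  if (is.null(d) || nrow(d) == 0) {
    stop("no posterior predictive discrepancies recorded; ",
         "refit with pvalue_every > 0")
  }
  structure(list(p_value = mean(d$T_rep >= d$T_obs),
                 statistic = "freeman_tukey", n_draws = nrow(d)),
            class = "camsecr_fitcheck")
}

#' @export
print.camsecr_fitcheck <- function(x, ...) {
  cat(sprintf("Bayesian p-value = %.3f (%s, %d draws)%s\n", x$p_value,
              x$statistic, x$n_draws,
              if (x$p_value < 0.05 || x$p_value > 0.95)
                "  [extreme: model inadequate]" else ""))
  invisible(x)
}
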