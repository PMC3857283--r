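# Hierarchical SECR model: encounter function, priors, likelihoods and an
# exact small-instance oracle.

#' SECR detection / population parameters
#'
#' @param lambda0 baseline encounter rate per occasion at zero distance
#'   (> 0).
#' @param sigma spatial scale of the half-normal encounter function, km
#'   (> 0); interpretable as a home-range range parameter.
#' @param b1 behavioural-response coefficient on the log encounter-rate
#'   scale: after an individual's first capture in a trap, its rate there is
#'   multiplied by `exp(b1)`.
#' @param psi data-augmentation inclusion probability in (0, 1): the ratio
#'   of animals actually present in the state space to the augmented
#'   maximum.
#' @return A `camsecr_params` list.
#' @examples
#' p <- secr_params(lambda0 = 0.029, sigma = 1.69, b1 = 1.10, psi = 0.54)
#' encounter_probability(p, d = 0, c = 0)  # ~0.0286
#' @export
secr_params <- function(lambda0, sigma, b1 = 0, psi = 0.5) {
  stopifnot(is.finite(lambda0), lambda0 > 0,
            is.finite(sigma), sigma > 0,
            is.finite(b1),
            is.finite(psi), psi > 0, psi < 1)
  structure(list(lambda0 = lambda0, sigma = sigma, b1 = b1, psi = psi),
            class = "camsecr_params")
}

#' Half-normal encounter rate
#'
#' The expected per-occasion encounter rate of an animal whose activity
#' centre lies at distance `d` from a trap:
#' `lambda = lambda0 * exp(-d^2 / (2 sigma^2)) * exp(b1 * c)`,
#' where `c` is the prior-capture indicator for the trap-specific
#' behavioural response.
#'
#' @param params a `camsecr_params`.
#' @param d distance(s) in km, >= 0.
#' @param c prior-capture flag(s), 0 or 1.
#' @return Encounter rate(s), same length as `d`.
#' @export
encounter_rate <- function(params, d, c = 0) {
  if (any(d < 0)) stop("distance must be non-negative")
  params$lambda0 * exp(-d^2 / (2 * params$sigma^2)) * exp(params$b1 * c)
}

#' Per-occasion encounter probability
#'
#' Under the Bernoulli observation model the capture probability on one
#' occasion is `p = 1 - exp(-lambda)` with `lambda` the encounter rate, so
#' `p` lies in `[0, 1)` and is monotone in each rate component.
#'
#' @inheritParams encounter_rate
#' @return Probability in `[0, 1)`.
#' @export
encounter_probability <- function(params, d, c = 0) {
  -expm1(-encounter_rate(params, d, c))
}

#' Convert between sigma and the quadratic decay coefficient b
#'
#' Two conventions circulate for the half-normal encounter function written
#' as `lambda0 * exp(-b d^2)`. The conventional relation is
#' `b = 1 / (2 sigma^2)` (so `sigma = sqrt(1/(2b))`); some software output
#' instead documents `sigma = sqrt(1/b^2)` i.e. `b = 1/sigma`. `camsecr`
#' stores `sigma` as primary and uses the conventional relation throughout;
#' both conversions are provided so published coefficients under either
#' convention can be translated.
#'
#' @param sigma,b scale parameter (km) / decay coefficient.
#' @param convention `"half-normal"` (`b = 1/(2 sigma^2)`, default) or
#'   `"reciprocal"` (`b = 1/sigma`).
#' @return The converted parameter.
#' @export
sigma_to_b <- function(sigma, convention = c("half-normal", "reciprocal")) {
  convention <- match.arg(convention)
  stopifnot(all(sigma > 0))
  switch(convention, "half-normal" = 1 / (2 * sigma^2), reciprocal = 1 / sigma)
}

#' @rdname sigma_to_b
#' @export
b_to_sigma <- function(b, convention = c("half-normal", "reciprocal")) {
  convention <- match.arg(convention)
  stopifnot(all(b > 0))
  switch(convention, "half-normal" = sqrt(1 / (2 * b)), reciprocal = 1 / b)
}

#' Prior specification for the SECR model
#'
#' Vague proper defaults standard for data-augmented SECR: `psi` uniform on
#' (0, 1) (handled conjugately in the sampler), `log(lambda0)` and
#' `log(sigma)` normal, `b1` normal.
#'
#' @param lambda0_meanlog,lambda0_sdlog normal prior on `log(lambda0)`.
#' @param sigma_meanlog,sigma_sdlog normal prior on `log(sigma)`.
#' @param b1_mean,b1_sd normal prior on `b1`.
#' @return A `camsecr_priors` list.
#' @export
secr_priors <- function(lambda0_meanlog = 0, lambda0_sdlog = 10,
                        sigma_meanlog = 0, sigma_sdlog = 10,
                        b1_mean = 0, b1_sd = 10) {
  stopifnot(lambda0_sdlog > 0, sigma_sdlog > 0, b1_sd > 0)
  structure(list(lambda0_meanlog = lambda0_meanlog,
                 lambda0_sdlog = lambda0_sdlog,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 b1_mean = b1_mean, b1_sd = b1_sd),
            class = "camsecr_priors")
}

# distance matrix (km) between mesh points (rows) and traps (cols)
.mesh_trap_dist2 <- function(ss, traps) {
  mx <- ss$points$x; my <- ss$points$y
  tx <- traps$stations$x; ty <- traps$stations$y
  outer(mx, tx, "-")^2 + outer(my, ty, "-")^2
}

#' Complete-data log-likelihood of the augmented model
#'
#' The Bernoulli encounter model: `y[i,j,k] ~ Bernoulli(z_i * p_ijk)` with
#' `p_ijk` from [encounter_probability()] at the distance between
#' individual `i`'s activity centre and trap `j`, switched by the
#' prior-capture indicator `C[i,j,k]`. Augmented individuals (beyond the
#' observed rows of `arr`) have all-zero histories. Occasions on which a
#' trap was inactive contribute nothing. An individual with `z = 0` but a
#' recorded capture has likelihood zero; this is signalled with a warning
#' and `-Inf`.
#'
#' @param params a `camsecr_params`.
#' @param latent list with `z` (binary inclusion vector, length M) and
#'   `centres` (indices into `ss$points`, length M, suitable points only).
#' @param arr a `camsecr_capture_array` of the observed individuals.
#' @param C prior-capture indicator from [prior_capture_indicator()].
#' @param ss a `camsecr_statespace`.
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(params, latent, arr,
                                 C = prior_capture_indicator(arr), ss) {
  stopifnot(inherits(params, "camsecr_params"),
            inherits(arr, "camsecr_capture_array"),
            inherits(ss, "camsecr_statespace"))
  M <- length(latent$z)
  n <- dim(arr$y)[1]
  if (M < n) stop("latent state shorter than the number of observed individuals")
  if (length(latent$centres) != M) stop("z and centres must have equal length")
  if (any(!ss$suitable[latent$centres])) {
    stop("activity centres must lie on suitable mesh points")
  }
  obs_cap <- apply(arr$y, 1, sum) > 0
  if (any(obs_cap & latent$z[seq_len(n)] == 0)) {
    warning("observed individual with z = 0: likelihood is zero")
    return(-Inf)
  }
  d2 <- .mesh_trap_dist2(ss, arr$traps)
  act <- arr$traps$active
  J <- dim(arr$y)[2]; K <- dim(arr$y)[3]
  ll <- 0
  for (i in seq_len(M)) {
    if (latent$z[i] == 0) next
    dists <- sqrt(d2[latent$centres[i], ])
    for (j in seq_len(J)) {
      a <- act[j, ] == 1L
      if (!any(a)) next
      yy <- if (i <= n) arr$y[i, j, a] else rep(0L, sum(a))
      cc <- if (i <= n) C[i, j, a] else rep(0L, sum(a))
      p <- encounter_probability(params, dists[j], cc)
      ll <- ll + sum(ifelse(yy == 1L, log(p), log1p(-p)))
    }
  }
  ll
}

#' Exact marginal log-likelihood by enumeration (small-instance oracle)
#'
#' Marginalises the data-augmented model over all latent configurations:
#' inclusion vectors `z` weighted `psi^z (1-psi)^(1-z)` and activity
#' centres uniform over the suitable mesh. Because the likelihood
#' factorises over individuals, centres are summed out per individual
#' within each `z` configuration; the sum over `z` is a full enumeration.
#' Intended as an independent check of the sampler on tiny instances;
#' refuses problems too large to enumerate.
#'
#' @param params a `camsecr_params` (its `psi` is used for the z weights).
#' @param arr a `camsecr_capture_array` (observed individuals; augmented
#'   individuals have all-zero histories).
#' @param ss a `camsecr_statespace`.
#' @param M total augmented population size (>= observed count).
#' @param max_config guard on `2^M * G` enumeration cost.
#' @return Scalar log marginal likelihood.
#' @export
marginal_loglik_bruteforce <- function(params, arr, ss, M,
                                       max_config = 1e6) {
  stopifnot(inherits(params, "camsecr_params"),
            inherits(arr, "camsecr_capture_array"))
  n <- dim(arr$y)[1]
  if (M < n) stop("M must be at least the number of observed individuals")
  G <- sum(ss$suitable)
  if (2^M * G > max_config) {
    stop("instance too large for exact enumeration (2^M * G = ",
         2^M * G, ")")
  }
  lbar <- .individual_centre_logliks(params, arr, ss, M)  # M x 2 matrix
  psi <- params$psi
  total <- -Inf
  for (code in 0:(2^M - 1)) {
    z <- as.integer(intToBits(code)[seq_len(M)])
    lw <- sum(z) * log(psi) + (M - sum(z)) * log1p(-psi)
    ll <- sum(ifelse(z == 1L, lbar[, "included"], lbar[, "excluded"]))
    total <- .logsumexp2(total, lw + ll)
  }
  total
}

# Per-individual log-likelihood components: "included" = log mean over
# suitable centres of P(y_i | centre); "excluded" = log 1{y_i == 0}.
.individual_centre_logliks <- function(params, arr, ss, M) {
  n <- dim(arr$y)[1]
  st <- capture_suffstats(arr)
  d2 <- .mesh_trap_dist2(ss, arr$traps)[ss$suitable, , drop = FALSE]
  G <- nrow(d2)
  rate0 <- params$lambda0 * exp(-d2 / (2 * params$sigma^2))  # G x J
  eb1 <- exp(params$b1)
  lp0 <- log(-expm1(-rate0))
  lp1 <- log(-expm1(-rate0 * eb1))
  out <- matrix(0, M, 2, dimnames = list(NULL, c("included", "excluded")))
  Aj <- st$trap_nights_per_trap
  zero_ll <- -rate0 %*% Aj  # log P(all-zero history | centre g)
  for (i in seq_len(M)) {
    if (i <= n) {
      ll_g <- lp0 %*% st$y0[i, ] + (-rate0) %*% (st$K0[i, ] - st$y0[i, ]) +
        lp1 %*% st$y1[i, ] + (-rate0 * eb1) %*% (st$K1[i, ] - st$y1[i, ])
      out[i, "included"] <- .logsumexp(ll_g) - log(G)
      out[i, "excluded"] <- if (sum(arr$y[i, , ]) == 0) 0 else -Inf
    } else {
      out[i, "included"] <- .logsumexp(zero_ll) - log(G)
      out[i, "excluded"] <- 0
    }
  }
  out
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.logsumexp2 <- function(a, b) .logsumexp(c(a, b))

#' Exact posterior of the included population size Ns (small instances)
#'
#' Enumerates all inclusion vectors `z`, integrating `psi` under its
#' uniform prior (giving each configuration the Beta-function weight
#' `B(sum(z)+1, M-sum(z)+1)`) and marginalising activity centres uniformly
#' over the suitable mesh. Returns the exact posterior distribution of
#' `Ns = sum(z)` against which long sampler runs with fixed detection
#' parameters can be checked.
#'
#' @inheritParams marginal_loglik_bruteforce
#' @return List with `mean` and `pmf` (named vector over Ns values).
#' @export
exact_ns_posterior <- function(params, arr, ss, M, max_config = 1e6) {
  n <- dim(arr$y)[1]
  G <- sum(ss$suitable)
  if (2^M * G > max_config) {
    stop("instance too large for exact enumeration")
  }
  lbar <- .individual_centre_logliks(params, arr, ss, M)
  logpost <- rep(-Inf, M + 1)  # index Ns = 0..M
  for (code in 0:(2^M - 1)) {
    z <- as.integer(intToBits(code)[seq_len(M)])
    n1 <- sum(z)
    lw <- lbeta(n1 + 1, M - n1 + 1)
    ll <- sum(ifelse(z == 1L, lbar[, "included"], lbar[, "excluded"]))
    if (is.finite(ll)) {
      logpost[n1 + 1] <- .logsumexp2(logpost[n1 + 1], lw + ll)
    }
  }
  logpost <- logpost - .logsumexp(logpost)
  pmf <- exp(logpost)
  names(pmf) <- 0:M
  list(mean = sum((0:M) * pmf), pmf = pmf)
}
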