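# Shared helpers: information criteria, Akaike weights, seeded RNG scopes.

#' Second-order Akaike information criterion
#'
#' @param logL log-likelihood at the maximum.
#' @param k number of free parameters.
#' @param n_obs number of observations (tips or species, by convention of the
#'   analysis stage).
#' @return AICc value. Infinite when `n_obs <= k + 1` (the correction blows up).
#' @export
aicc <- function(logL, k, n_obs) {
  if (n_obs - k - 1 <= 0) return(Inf)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Akaike weights from AICc values
#'
#' Weights are `exp(-delta/2)` normalized to sum to one, where `delta` is the
#' AICc difference from the best model.
#'
#' @param aicc_values numeric vector of AICc (or a vector of pre-computed
#'   delta-AICc values; the minimum is subtracted either way).
#' @return numeric vector of weights summing to 1, same order as input.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(is.numeric(aicc_values), length(aicc_values) >= 1L)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so package functions do not trample user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Draw one multivariate normal sample by Cholesky factorization.
rmvn_chol <- function(mu, V) {
  L <- chol(V)
  drop(mu + crossprod(L, rnorm(length(mu))))
}

# Log-density of y ~ N(mu, V) with V supplied as a Cholesky factor (upper).
mvn_loglik_chol <- function(y, mu, cholV) {
  n <- length(y)
  z <- backsolve(cholV, y - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(cholV))) - 0.5 * sum(z^2)
}
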