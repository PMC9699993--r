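#' Negative binomial probability mass function (mean/dispersion form)
#'
#' Probability of observing `k` read counts for a fragment pair whose
#' background ("Brownian") component has expected count `mu` and dispersion
#' `r`, i.e. \eqn{f_{NB}(k; \mu, r) = \frac{\Gamma(r+k)}{k!\,\Gamma(r)}
#' \left(\frac{\mu}{r+\mu}\right)^k \left(\frac{r}{r+\mu}\right)^r}.
#' Variance is \eqn{\mu + \mu^2/r}, so large `r` approaches Poisson.
#'
#' @param k Non-negative integer count (vectorised).
#' @param mu Positive expected count.
#' @param r Positive dispersion (size) parameter.
#' @param log If `TRUE`, return the log probability.
#' @return Probability (or log probability), same length as `k`.
#' @examples
#' nb_pmf(0, mu = 3, r = 2) # (2/5)^2
#' @export
nb_pmf <- function(k, mu, r, log = FALSE) {
  if (any(mu <= 0) || any(r <= 0)) {
    stop("`mu` and `r` must be strictly positive", call. = FALSE)
  }
  stats::dnbinom(k, size = r, mu = mu, log = log)
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Delaporte probability mass function
#'
#' The Delaporte distribution is the sum of independent negative binomial
#' (Brownian background, mean `mu`, dispersion `r`) and Poisson (technical
#' noise, mean `lam`) components; its pmf is the discrete convolution
#' \eqn{\sum_{j=0}^{k} \mathrm{Pois}(j; \lambda)\, f_{NB}(k - j; \mu, r)}.
#' With `lam = 0` it reduces exactly to [nb_pmf()].
#'
#' @param k Non-negative integer count (vectorised).
#' @param mu Positive mean of the negative binomial component.
#' @param r Positive dispersion of the negative binomial component.
#' @param lam Non-negative mean of the Poisson component.
#' @param log If `TRUE`, return the log probability.
#' @return Probability (or log probability), same length as `k`.
#' @examples
#' delaporte_pmf(2, mu = 1, r = 1, lam = 1)
#' @export
delaporte_pmf <- function(k, mu, r, lam, log = FALSE) {
  if (any(mu <= 0) || any(r <= 0)) {
    stop("`mu` and `r` must be strictly positive", call. = FALSE)
  }
  if (any(lam < 0)) stop("`lam` must be non-negative", call. = FALSE)
  if (lam == 0) {
    lp <- stats::dnbinom(k, size = r, mu = mu, log = TRUE)
  } else {
    lp <- vapply(k, function(ki) {
      j <- 0:ki
      logsumexp(stats::dpois(j, lam, log = TRUE) +
                  stats::dnbinom(ki - j, size = r, mu = mu, log = TRUE))
    }, numeric(1))
  }
  if (log) lp else exp(lp)
}

#' Upper-tail log p-value under the Delaporte null
#'
#' Natural log of \eqn{P(X \ge \mathrm{count})} where
#' \eqn{X \sim \mathrm{NB}(\mu, r) + \mathrm{Pois}(\lambda)}. This is the
#' per-pair evidence statistic the score is built from: it is 0 at count 0
#' (the certain event) and strictly decreasing in the observed count.
#'
#' Computed in log space. For `lam > 0` the tail is decomposed over the
#' Poisson component: \eqn{P(X \ge k) = \sum_{j=0}^{k-1}
#' \mathrm{Pois}(j;\lambda) P(\mathrm{NB} \ge k - j) + P(\mathrm{Pois} \ge k)},
#' which is exact (no truncation).
#'
#' @param count Non-negative integer count (vectorised).
#' @param mu Positive expected background count.
#' @param r Positive dispersion.
#' @param lam Non-negative technical-noise mean.
#' @return Non-positive log p-value(s).
#' @examples
#' upper_tail_log_p(3, mu = 2, r = 1, lam = 0)
#' @export
upper_tail_log_p <- function(count, mu, r, lam = 0) {
  if (any(mu <= 0) || any(r <= 0)) {
    stop("`mu` and `r` must be strictly positive", call. = FALSE)
  }
  if (any(lam < 0)) stop("`lam` must be non-negative", call. = FALSE)
  n <- max(length(count), length(mu), length(r), length(lam))
  count <- rep_len(count, n); mu <- rep_len(mu, n)
  r <- rep_len(r, n); lam <- rep_len(lam, n)
  out <- numeric(n)
  pos <- count > 0
  if (!any(pos)) return(out)

  nolam <- pos & lam == 0
  out[nolam] <- stats::pnbinom(count[nolam] - 1, size = r[nolam],
                               mu = mu[nolam], lower.tail = FALSE,
                               log.p = TRUE)
  wl <- which(pos & lam > 0)
  if (length(wl) > 0) {
    k <- count[wl]; lamv <- lam[wl]; muv <- mu[wl]; rv <- r[wl]
    # log-space accumulation over the Poisson index j. A row finishes
    # either by exhausting j = 0..k-1 (then the exact Poisson tail
    # P(Pois >= k) is added) or by truncation once the Poisson mass at
    # the next index is negligible relative to the accumulated sum
    # (dpois(j) bounds the term, so the dropped mass is < 1e-16 of acc).
    acc <- stats::dpois(0, lamv, log = TRUE) +
      stats::pnbinom(k - 1, size = rv, mu = muv,
                     lower.tail = FALSE, log.p = TRUE)
    active <- k - 1 >= 1
    j <- 1
    while (any(active)) {
      idx <- which(active)
      lterm <- stats::dpois(j, lamv[idx], log = TRUE) +
        stats::pnbinom(k[idx] - 1 - j, size = rv[idx], mu = muv[idx],
                       lower.tail = FALSE, log.p = TRUE)
      a <- acc[idx]
      m <- pmax(a, lterm)
      acc[idx] <- m + log1p(exp(-abs(a - lterm)))
      # truncate rows whose remaining Poisson mass cannot matter
      nxt <- stats::dpois(j + 1, lamv[idx], log = TRUE)
      stop_now <- (j + 1 > k[idx] - 1) |
        (j > 2 * lamv[idx] + 5 & nxt < acc[idx] - 40)
      active[idx[stop_now]] <- FALSE
      j <- j + 1
    }
    # the j >= k portion of the mixture, where the NB tail is certain
    pois_tail <- stats::ppois(k - 1, lamv, lower.tail = FALSE, log.p = TRUE)
    m <- pmax(acc, pois_tail)
    out[wl] <- pmin(0, m + log1p(exp(-abs(acc - pois_tail))))
  }
  out
}
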