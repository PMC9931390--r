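#' Clone-size distribution of observed mutant colonies under partial plating
#'
#' In the Lea--Coulson formulation of the Luria--Delbruck model, a single
#' mutational event arising during exponential growth leaves a mutant clone
#' whose size \eqn{j} follows \eqn{P(j) = 1/(j(j+1))}, \eqn{j \ge 1}. When
#' only a fraction \eqn{\epsilon} of the culture is plated, each clone
#' member is observed independently with probability \eqn{\epsilon}, so the
#' number of colonies contributed by one event is the binomial thinning
#' \deqn{q_k = \sum_{j \ge \max(k,1)} \frac{1}{j(j+1)}
#'       \binom{j}{k} \epsilon^k (1-\epsilon)^{j-k}.}
#'
#' The coefficients are obtained exactly from the thinned probability
#' generating function
#' \eqn{g(z) = 1 + \epsilon(1-z)(\ln\epsilon + \ln(1-z)) / (1-\epsilon(1-z))},
#' whose power-series coefficients satisfy a stable two-term recurrence for
#' \eqn{\epsilon < 1/2}; for \eqn{\epsilon \ge 1/2} a directly summed
#' (windowed) evaluation of the defining series is used, and for
#' \eqn{\epsilon = 1} the closed form \eqn{q_k = 1/(k(k+1))} applies.
#'
#' @param epsilon plating efficiency, in (0, 1].
#' @param kmax largest colony count for which a probability is returned.
#' @return An object of class `clone_pmf`: list with `epsilon` and `q`, a
#'   numeric vector of length `kmax + 1` giving \eqn{q_0, \ldots, q_{kmax}}.
#' @examples
#' clone_pmf(1, 3)$q          # 0, 1/2, 1/6, 1/12
#' clone_pmf(0.5, 0)$q        # 1 + ln(1/2) = 0.3069
#' @export
clone_pmf <- function(epsilon, kmax) {
  gs_assert(is_scalar_num(epsilon) && epsilon > 0 && epsilon <= 1,
            "`epsilon` must be a single number in (0, 1]")
  gs_assert(is_scalar_num(kmax) && kmax >= 0 && kmax == floor(kmax),
            "`kmax` must be a non-negative integer")
  k <- 0:kmax
  if (epsilon == 1) {
    q <- c(0, if (kmax >= 1) 1 / (k[-1] * (k[-1] + 1)))
  } else if (epsilon < 0.5) {
    # series coefficients of N(z)/D(z) with
    #   N(z) = eps*(1-z)*(log(eps) + log(1-z)),  D(z) = (1-eps) + eps*z
    n <- numeric(kmax + 2L)
    n[1] <- epsilon * log(epsilon)
    if (kmax >= 1) n[2] <- -epsilon * log(epsilon) - epsilon
    if (kmax >= 2) {
      kk <- 2:kmax
      n[kk + 1L] <- epsilon / (kk * (kk - 1))
    }
    cvec <- numeric(kmax + 1L)
    cvec[1] <- n[1] / (1 - epsilon)
    if (kmax >= 1) {
      for (i in 2:(kmax + 1L)) {
        cvec[i] <- (n[i] - epsilon * cvec[i - 1L]) / (1 - epsilon)
      }
    }
    q <- cvec
    q[1] <- 1 + q[1]
  } else {
    # direct windowed summation; binomial mass in j is concentrated near
    # k/epsilon with width ~ sqrt(k)/epsilon
    q <- vapply(k, function(ki) {
      jlo <- max(ki, 1)
      jhi <- ceiling((ki + 14 * sqrt(ki + 25) + 25) / epsilon)
      j <- jlo:jhi
      sum(stats::dbinom(ki, j, epsilon) / (j * (j + 1)))
    }, numeric(1))
  }
  q[q < 0] <- 0   # guard against -eps rounding in the recurrence
  structure(list(epsilon = epsilon, q = q), class = "clone_pmf")
}

#' Luria--Delbruck mutant-count distribution with plating efficiency
#'
#' Probability mass function of the number of mutant colonies observed on a
#' selective plate, for `m` expected mutational events per culture and
#' plating efficiency `epsilon`. The count is a compound Poisson sum of
#' per-event colony counts ([clone_pmf()]) and its pmf follows the
#' recursion
#' \deqn{p_0 = e^{-m(1-q_0)}, \qquad
#'       p_n = \frac{m}{n} \sum_{k=1}^{n} k\, q_k\, p_{n-k}.}
#' With `epsilon = 1` this reduces to the classic form
#' \eqn{p_n = (m/n) \sum_{i=0}^{n-1} p_i/(n-i+1)}.
#'
#' @param m expected number of mutational events per culture (>= 0).
#' @param epsilon plating efficiency in (0, 1].
#' @param nmax largest count for which a probability is returned.
#' @param deriv if TRUE, also return first and second derivatives of the
#'   pmf with respect to `m` (used by the likelihood machinery).
#' @return numeric vector `p_0 ... p_nmax` (or a list with `p`, `dp`,
#'   `d2p` when `deriv = TRUE`).
#' @examples
#' count_pmf(1, 1, 2)   # exp(-1), exp(-1)/2, 0.10730
#' @export
count_pmf <- function(m, epsilon, nmax, deriv = FALSE) {
  gs_assert(is_scalar_num(m) && m >= 0, "`m` must be a single number >= 0")
  q <- clone_pmf(epsilon, nmax)$q
  count_pmf_q(m, q, nmax, deriv)
}

# pmf recursion with precomputed clone probabilities (hot path)
count_pmf_q <- function(m, q, nmax, deriv = FALSE) {
  p <- numeric(nmax + 1L)
  p[1] <- exp(-m * (1 - q[1]))
  kq <- if (nmax >= 1) (1:nmax) * q[2:(nmax + 1L)] else numeric(0)
  if (nmax >= 1) {
    for (n in 1:nmax) {
      p[n + 1L] <- (m / n) * sum(kq[1:n] * p[n:1])
    }
  }
  if (!deriv) return(p)
  dp <- numeric(nmax + 1L); d2p <- numeric(nmax + 1L)
  a <- 1 - q[1]
  dp[1] <- -a * p[1]
  d2p[1] <- a * a * p[1]
  if (nmax >= 1) {
    for (n in 1:nmax) {
      s0 <- sum(kq[1:n] * p[n:1]) / n      # p_n / m
      s1 <- sum(kq[1:n] * dp[n:1]) / n
      s2 <- sum(kq[1:n] * d2p[n:1]) / n
      dp[n + 1L] <- s0 + m * s1
      d2p[n + 1L] <- 2 * s1 + m * s2
    }
  }
  list(p = p, dp = dp, d2p = d2p)
}

# log-likelihood (and optionally score/hessian) of m for observed counts.
# Counts above `cap` contribute as right-censored observations (>= cap).
ld_loglik <- function(m, counts, q, cap, deriv = FALSE) {
  cens <- counts >= cap
  obs <- counts[!cens]
  nmax <- if (length(obs)) max(obs) else 0L
  nmax <- max(nmax, if (any(cens)) cap - 1L else 0L)
  if (!deriv) {
    p <- count_pmf_q(m, q, nmax)
    ll <- sum(log(pmax(p[obs + 1L], 1e-300)))
    if (any(cens)) {
      tail <- max(1 - sum(p[1:cap]), 1e-300)
      ll <- ll + sum(cens) * log(tail)
    }
    return(ll)
  }
  pd <- count_pmf_q(m, q, nmax, deriv = TRUE)
  pi <- pmax(pd$p[obs + 1L], 1e-300)
  dpi <- pd$dp[obs + 1L]; d2pi <- pd$d2p[obs + 1L]
  ll <- sum(log(pi))
  score <- sum(dpi / pi)
  hess <- sum(d2pi / pi - (dpi / pi)^2)
  if (any(cens)) {
    tail <- max(1 - sum(pd$p[1:cap]), 1e-300)
    dtail <- -sum(pd$dp[1:cap]); d2tail <- -sum(pd$d2p[1:cap])
    nc <- sum(cens)
    ll <- ll + nc * log(tail)
    score <- score + nc * dtail / tail
    hess <- hess + nc * (d2tail / tail - (dtail / tail)^2)
  }
  list(loglik = ll, score = score, hess = hess)
}

#' Maximum-likelihood estimate of the expected number of mutations per culture
#'
#' Fits the Luria--Delbruck model with plating efficiency to per-culture
#' mutant-colony counts by maximising the compound-Poisson likelihood built
#' on [count_pmf()]. Newton--Raphson on the score function is safeguarded
#' by bisection within a maintained bracket; convergence requires a
#' relative step below `tol`. Counts of `cap` or more enter the likelihood
#' as right-censored (probability of `cap` or more colonies), which bounds
#' the cost of the pmf recursion when a jackpot culture is present.
#'
#' @param counts non-negative integer vector, one mutant-colony count per
#'   parallel culture (>= 2 cultures).
#' @param epsilon plating efficiency in (0, 1].
#' @param cap counts at or above this value are treated as right-censored.
#' @param tol relative convergence tolerance for the Newton iteration.
#' @return An object of class `fluctuation_fit`: list with elements `m`
#'   (MLE), `loglik`, `epsilon`, `counts`, `cap`, `converged`, `iterations`,
#'   and `ci` (NULL until [profile_ci()] is run).
#' @examples
#' mle_m(c(0, 0, 0, 1), epsilon = 1)$m   # 0.25
#' @export
mle_m <- function(counts, epsilon, cap = 1000L, tol = 1e-8) {
  gs_assert(is.numeric(counts) && length(counts) >= 2 &&
              all(counts >= 0) && all(counts == floor(counts)),
            "`counts` must be >= 2 non-negative integers")
  counts <- as.integer(counts)
  q <- clone_pmf(epsilon, max(c(counts[counts < cap], cap - 1L, 1L)))$q
  fit <- function(m, deriv = FALSE) ld_loglik(m, counts, q, cap, deriv)

  if (all(counts == 0)) {
    out <- list(m = 0, loglik = 0, epsilon = epsilon, counts = counts,
                cap = cap, converged = TRUE, iterations = 0L, ci = NULL)
    class(out) <- "fluctuation_fit"
    return(out)
  }
  # p0-method initial value when zero counts exist, else 1
  zfrac <- mean(counts == 0)
  q0 <- q[1]
  m0 <- if (zfrac > 0) max(-log(zfrac) / (1 - q0), 1e-4) else 1

  # bracket the root of the score: score > 0 below the MLE, < 0 above
  lo <- 1e-8; hi <- max(m0 * 4, 1)
  while (fit(hi, TRUE)$score > 0 && hi < 1e8) hi <- hi * 4
  gs_assert(hi < 1e8, "mle_m failed to bracket the maximum",
            "gemscreen_estimation_error")
  m <- min(max(m0, lo), hi)
  converged <- FALSE
  iters <- 0L
  for (it in 1:200) {
    iters <- it
    d <- fit(m, TRUE)
    if (d$score > 0) lo <- max(lo, m) else hi <- min(hi, m)
    step <- if (is.finite(d$hess) && d$hess < 0) -d$score / d$hess else NA
    m_new <- m + if (is.na(step)) 0 else step
    if (is.na(step) || m_new <= lo || m_new >= hi) m_new <- (lo + hi) / 2
    if (abs(m_new - m) / max(m_new, 1e-12) < tol) {
      m <- m_new; converged <- TRUE; break
    }
    m <- m_new
  }
  out <- list(m = m, loglik = fit(m), epsilon = epsilon,
              counts = counts, cap = cap, converged = converged,
              iterations = iters, ci = NULL)
  class(out) <- "fluctuation_fit"
  out
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat("Luria-Delbruck fit:", length(x$counts), "cultures, epsilon =",
      format(x$epsilon), "\n")
  cat("  m =", format(x$m, digits = 6),
      if (!is.null(x$ci)) sprintf(" [%.4g, %.4g] (95%% profile)",
                                  x$ci[1], x$ci[2]), "\n")
  invisible(x)
}

#' Profile-likelihood confidence interval for m
#'
#' Endpoints solve \eqn{2\{\ell(\hat m) - \ell(m)\} = \chi^2_1(level)} by
#' bisection; the lower endpoint is 0 when the likelihood-ratio statistic
#' does not reach the threshold at the boundary (e.g. all-zero counts).
#'
#' @param counts per-culture mutant-colony counts, or a `fluctuation_fit`.
#' @param epsilon plating efficiency (ignored when a fit is supplied).
#' @param level confidence level (default 0.95).
#' @param cap censoring cap, as in [mle_m()].
#' @return the `fluctuation_fit` with `ci` set to `c(lower, upper)`.
#' @export
profile_ci <- function(counts, epsilon = NULL, level = 0.95, cap = 1000L) {
  fit <- if (inherits(counts, "fluctuation_fit")) counts
         else mle_m(counts, epsilon, cap = cap)
  gs_assert(fit$converged, "profile_ci requires a converged fit",
            "gemscreen_estimation_error")
  counts <- fit$counts; epsilon <- fit$epsilon; cap <- fit$cap
  q <- clone_pmf(epsilon, max(c(counts[counts < cap], cap - 1L, 1L)))$q
  crit <- stats::qchisq(level, df = 1)
  f <- function(m) 2 * (fit$loglik - ld_loglik(m, counts, q, cap)) - crit

  bisect <- function(a, b) {
    # f(a), f(b) of opposite signs; returns the root
    fa <- f(a)
    for (i in 1:200) {
      mid <- (a + b) / 2
      fm <- f(mid)
      if (abs(b - a) / max(mid, 1e-12) < 1e-7) return(mid)
      if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
    }
    mid
  }

  # lower endpoint
  lower <- if (fit$m == 0) 0 else {
    eps0 <- fit$m * 1e-9
    if (any(counts > 0) || f(eps0) > 0) bisect(max(eps0, 1e-300), fit$m) else 0
  }
  if (fit$m > 0 && all(counts == 0)) lower <- 0
  # upper endpoint: expand then bisect
  hi <- max(fit$m * 2, 0.5)
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  gs_assert(hi < 1e9, "profile_ci: flat likelihood, no upper endpoint",
            "gemscreen_estimation_error")
  upper <- bisect(max(fit$m, 1e-12), hi)
  fit$ci <- c(lower = lower, upper = upper)
  fit$level <- level
  fit
}

#' Convert the fitted m into mutation rates
#'
#' The per-division mutation rate is \eqn{\mu = \hat m / (N_t - N_0)},
#' the number of mutational events divided by the number of cell divisions
#' the culture underwent; with typical designs \eqn{N_0 \ll N_t} this is
#' numerically indistinguishable from dividing by \eqn{N_t}, and
#' `divisor = "nt"` selects that convention. The per-kilobase rate rescales
#' to a reference gene of 1000 bp.
#'
#' @param fit a `fluctuation_fit` (from [mle_m()] / [profile_ci()]).
#' @param design list or `fluctuation_design` with `N0`, `Nt`,
#'   `gene_length` (bp).
#' @param divisor `"divisions"` (Nt - N0, default) or `"nt"`.
#' @return list with `mu`, `mu_per_kb`, and when the fit carries a profile
#'   interval, `mu_ci` and `mu_per_kb_ci` scaled the same way.
#' @export
mutation_rate <- function(fit, design, divisor = c("divisions", "nt")) {
  divisor <- match.arg(divisor)
  gs_assert(is_pos_num(design$Nt) && is_pos_num(design$N0) &&
              design$Nt > design$N0, "design must satisfy 0 < N0 < Nt")
  gs_assert(is_pos_num(design$gene_length), "gene_length must be > 0")
  den <- if (divisor == "divisions") design$Nt - design$N0 else design$Nt
  mu <- fit$m / den
  out <- list(mu = mu, mu_per_kb = mu * 1000 / design$gene_length)
  if (!is.null(fit$ci)) {
    out$mu_ci <- fit$ci / den
    out$mu_per_kb_ci <- out$mu_ci * 1000 / design$gene_length
  }
  out
}

#' Fold-ratio of mutation rates between two loci
#'
#' Ratio of per-kilobase mutation rates with a propagated interval by
#' interval arithmetic on the two profile bounds. A zero denominator rate
#' yields an `Inf` sentinel rather than an error.
#'
#' @param fit_a,fit_b converged `fluctuation_fit`s for the two loci.
#' @param design_a,design_b matching designs (see [mutation_rate()]).
#' @param divisor passed to [mutation_rate()].
#' @return list with `ratio` and, when both fits carry intervals,
#'   `ratio_ci`.
#' @export
rate_ratio <- function(fit_a, fit_b, design_a, design_b,
                       divisor = c("divisions", "nt")) {
  divisor <- match.arg(divisor)
  gs_assert(fit_a$converged && fit_b$converged,
            "rate_ratio requires converged fits")
  ra <- mutation_rate(fit_a, design_a, divisor)
  rb <- mutation_rate(fit_b, design_b, divisor)
  ratio <- if (rb$mu_per_kb == 0) Inf else ra$mu_per_kb / rb$mu_per_kb
  out <- list(ratio = ratio)
  if (!is.null(ra$mu_per_kb_ci) && !is.null(rb$mu_per_kb_ci)) {
    lo <- if (rb$mu_per_kb_ci[2] == 0) Inf
          else ra$mu_per_kb_ci[1] / rb$mu_per_kb_ci[2]
    hi <- if (rb$mu_per_kb_ci[1] == 0) Inf
          else ra$mu_per_kb_ci[2] / rb$mu_per_kb_ci[1]
    out$ratio_ci <- c(lower = lo, upper = hi)
  }
  out
}
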