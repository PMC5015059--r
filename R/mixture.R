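#' @include AllClasses.R AllGenerics.R
#' @importFrom stats dnorm quantile sd
NULL

#' Fit a two-component Gaussian mixture by EM
#'
#' Fits \eqn{\lambda_1 N(\mu_1,\sigma_1^2) + \lambda_2 N(\mu_2,\sigma_2^2)}
#' to a sample by expectation-maximisation. In the heterogeneity analysis the
#' sample is the pooled expressing-cell counts N of all windowed genes
#' (lncRNAs and mRNAs together), and the two components are the
#' high-heterogeneity (few expressing cells) and low-heterogeneity (many
#' expressing cells) gene populations.
#'
#' Initialisation follows the standard analysis: weights 0.5/0.5 and both
#' standard deviations 0.5. Means start at the 25th and 75th percentiles of
#' the data by default (\code{init = "quartile"}, deterministic);
#' \code{init = "random"} draws them from the data using \code{config@seed},
#' reproducing stochastic-restart behaviour. A variance floor of 1e-6 guards
#' against singular spike solutions: hitting it, or a component weight
#' falling below 1/n, raises a non-convergence error rather than returning a
#' degenerate fit. The observed-data log-likelihood is non-decreasing across
#' iterations; iteration stops when its relative change falls below
#' \code{config@emTolerance} or after \code{config@emMaxIter} iterations.
#' Components are relabelled so that \code{mu[1] <= mu[2]}.
#'
#' @param N numeric sample (at least 10 points, at least 2 distinct values).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{MixtureModel}.
#' @seealso \code{\link{posteriorHigh}}, \code{\link{assignFlag}}
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, 5, 2), rnorm(100, 60, 10))
#' fitMixture(x)
#' @export
fitMixture <- function(N, config = analysisConfig()) {
  x <- as.numeric(N)
  n <- length(x)
  if (n < 10L) stop("mixture fit needs at least 10 data points, got ", n)
  if (length(unique(x)) < 2L)
    stop("degenerate data: all ", n, " values are identical")
  if (any(!is.finite(x))) stop("non-finite values in mixture input")

  lambda <- c(0.5, 0.5)
  sigma <- c(0.5, 0.5)
  if (config@init == "quartile") {
    mu <- unname(quantile(x, c(0.25, 0.75)))
    if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * max(sd(x), 1)
  } else {
    set.seed(config@seed)
    mu <- sort(sample(x, 2L)) + c(-0.25, 0.25)
    if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * max(sd(x), 1)
  }

  varFloor <- 1e-6
  llOld <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    ## E step in log space for numerical stability
    ld1 <- log(lambda[1]) + dnorm(x, mu[1], sigma[1], log = TRUE)
    ld2 <- log(lambda[2]) + dnorm(x, mu[2], sigma[2], log = TRUE)
    mx <- pmax(ld1, ld2)
    lden <- mx + log(exp(ld1 - mx) + exp(ld2 - mx))
    ll <- sum(lden)
    trace[it] <- ll
    if (is.finite(llOld) &&
        abs(ll - llOld) < config@emTolerance * abs(llOld)) {
      converged <- TRUE
      break
    }
    if (it >= config@emMaxIter) break
    llOld <- ll
    g1 <- exp(ld1 - lden)

    ## M step: responsibility-weighted moments
    w1 <- sum(g1)
    w2 <- n - w1
    if (min(w1, w2) < 1) {
      stop("mixture did not converge: component weight collapsed below 1/n ",
           sprintf("(weights %.3g, %.3g at iteration %d)", w1 / n, w2 / n, it))
    }
    lambda <- c(w1, w2) / n
    mu <- c(sum(g1 * x) / w1, sum((1 - g1) * x) / w2)
    v <- c(sum(g1 * (x - mu[1])^2) / w1, sum((1 - g1) * (x - mu[2])^2) / w2)
    if (min(v) < varFloor) {
      stop("mixture did not converge: component variance hit the 1e-6 floor ",
           sprintf("(variances %.3g, %.3g at iteration %d)", v[1], v[2], it))
    }
    sigma <- sqrt(v)
  }

  if (mu[1] > mu[2]) {
    lambda <- rev(lambda); mu <- rev(mu); sigma <- rev(sigma)
  }
  new("MixtureModel", lambda = lambda, mu = mu, sigma = sigma,
      logLik = trace[it], logLikTrace = trace, nIter = it,
      converged = converged)
}

#' Posterior probability of the high-heterogeneity component
#'
#' For an expressing-cell count n, the probability that the gene belongs to
#' component 1 (the lower-mean, high-heterogeneity population):
#' \deqn{\lambda_1 \phi(n;\mu_1,\sigma_1) /
#'   [\lambda_1 \phi(n;\mu_1,\sigma_1) + \lambda_2 \phi(n;\mu_2,\sigma_2)]}
#' Computed in log space; the complementary posterior is 1 minus this value.
#'
#' @param model a converged \linkS4class{MixtureModel}.
#' @param n numeric vector of query points.
#' @return Posterior probabilities in [0, 1], one per query point.
#' @export
posteriorHigh <- function(model, n) {
  stopifnot(is(model, "MixtureModel"))
  ld1 <- log(model@lambda[1]) + dnorm(n, model@mu[1], model@sigma[1], log = TRUE)
  ld2 <- log(model@lambda[2]) + dnorm(n, model@mu[2], model@sigma[2], log = TRUE)
  p <- 1 / (1 + exp(ld2 - ld1))
  if (any(!is.finite(p)))
    stop("non-finite posterior density at query point(s) ",
         paste(n[!is.finite(p)], collapse = ", "))
  p
}

#' Assign H/L/U heterogeneity flags
#'
#' H (high heterogeneity) when the posterior of the high-heterogeneity
#' component strictly exceeds the cutoff; L (low) when the complementary
#' posterior strictly exceeds it; U (uncertain) otherwise. At a cutoff of
#' 0.99 a posterior of exactly 0.99 is therefore U.
#'
#' @param posterior posterior probabilities in [0, 1].
#' @param cutoff flag cutoff, strictly between 0.5 and 1 (default 0.99).
#' @return Character vector of flags in \code{c("H", "L", "U")}.
#' @export
assignFlag <- function(posterior, cutoff = 0.99) {
  if (length(cutoff) != 1L || cutoff <= 0.5 || cutoff >= 1)
    stop("flag cutoff must lie strictly between 0.5 and 1")
  if (any(posterior < 0 | posterior > 1))
    stop("posterior probabilities must lie in [0, 1]")
  ifelse(posterior > cutoff, "H",
         ifelse((1 - posterior) > cutoff, "L", "U"))
}
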