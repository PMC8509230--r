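# Moment-matched sampling of bounded predictors.
#
# Catalog moments describe the *observed* (bounded) scales, so the sampling
# distributions are chosen to reproduce those moments on the bounded support:
# a truncated normal whose parent parameters are solved so the truncated mean
# and SD hit the targets, falling back to a shifted gamma for floor-hugging
# skewed predictors where no truncated normal can (SD above the floor larger
# than the mean above the floor), and a range-truncated Poisson for counts.

# mean and sd of N(mu, sigma) truncated to [a, b]
.truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  if (Z < 1e-12) return(c(mean = NA_real_, sd = NA_real_))
  lam <- (dnorm(al) - dnorm(be)) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (ifelse(is.infinite(al), 0, al * dnorm(al)) -
                       ifelse(is.infinite(be), 0, be * dnorm(be))) / Z - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve parent (mu, sigma) so the [a,b]-truncated moments equal the targets.
# Returns NULL if no adequate solution exists (residual above tol).
.match_truncnorm <- function(target_mean, target_sd, a, b, tol = 1e-4) {
  obj <- function(par) {
    mo <- .truncnorm_moments(par[1], exp(par[2]), a, b)
    if (anyNA(mo)) return(1e6)
    ((mo["mean"] - target_mean) / target_sd)^2 + ((mo["sd"] - target_sd) / target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > tol^2) return(NULL)
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF truncated normal draws
.rtruncnorm <- function(n, mu, sigma, a, b) {
  pa <- pnorm(a, mu, sigma); pb <- pnorm(b, mu, sigma)
  qnorm(runif(n, pa, pb), mu, sigma)
}

# Draws with mean/sd matched on [a, b]. Falls back to a moment-matched scaled
# beta when no truncated normal attains the targets — skewed floor-hugging
# scales (dissociation) and near-uniform or bimodal spreads (childhood-trauma
# subscales, where SD above the floor can exceed what any truncated normal
# admits) both land here.
.rbounded_continuous <- function(n, target_mean, target_sd, a, b) {
  par <- .match_truncnorm(target_mean, target_sd, a, b)
  if (!is.null(par)) return(.rtruncnorm(n, par$mu, par$sigma, a, b))
  m <- (target_mean - a) / (b - a)
  v <- (target_sd / (b - a))^2
  if (v >= m * (1 - m))
    stop(sprintf("moments mean=%g sd=%g unattainable on [%g, %g]",
                 target_mean, target_sd, a, b), call. = FALSE)
  k <- m * (1 - m) / v - 1
  a + (b - a) * rbeta(n, shape1 = m * k, shape2 = (1 - m) * k)
}

# lambda such that a Poisson truncated to [0, b] has the target mean
.match_truncpois <- function(target_mean, b) {
  tm <- function(lambda) {
    k <- 0:b
    p <- dpois(k, lambda); p <- p / sum(p)
    sum(k * p)
  }
  if (target_mean <= 0) return(1e-8)
  uniroot(function(l) tm(l) - target_mean, c(1e-8, b * 5))$root
}

.rtruncpois <- function(n, target_mean, b) {
  lambda <- .match_truncpois(target_mean, b)
  k <- 0:b
  p <- dpois(k, lambda); p <- p / sum(p)
  sample(k, n, replace = TRUE, prob = p)
}
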