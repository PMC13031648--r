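#' Specify a group-comparison outcome model
#'
#' Count outcomes (`chunks`, `nesting`, `phrase_length`, `max_nesting`)
#' pair with a Poisson likelihood and log link; bounded outcomes
#' (`entropy`, `gini`, `tnt_ratio`, values in `[0, 1)`) with a
#' zero-inflated beta likelihood and logit link for the mean. The group
#' predictor uses treatment coding: the reference group's level is the
#' intercept (its alpha) and other groups enter as contrasts. Priors are
#' flat on the intercept and normal(0, 10) on contrast coefficients (and
#' on the auxiliary log-precision and zero-inflation logit of the beta
#' model, which keeps them proper while remaining weak).
#'
#' @param outcome one of `"chunks"`, `"max_nesting"`, `"nesting"`,
#'   `"phrase_length"`, `"entropy"`, `"gini"`, `"tnt_ratio"` (any column of
#'   a metrics table works; the family is inferred, or set it explicitly).
#' @param family `"poisson"` or `"zib"`; default inferred from `outcome`.
#' @param reference reference group level (default `"chimpanzee"`; falls
#'   back to the first group present when absent from the data).
#' @param chains,iter,warmup MCMC configuration: number of chains, number
#'   of post-warmup iterations per chain, and warmup iterations (defaults
#'   4, 2000, 1000).
#' @param seed integer sampler seed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome,
                       family = NULL,
                       reference = "chimpanzee",
                       chains = 4L, iter = 2000L, warmup = 1000L,
                       seed = 1L) {
  count_like <- c("chunks", "max_nesting", "nesting", "phrase_length",
                  "length", "compressed_length", "count")
  bounded <- c("entropy", "gini", "tnt_ratio")
  if (is.null(family)) {
    family <- if (outcome %in% bounded) "zib"
      else if (outcome %in% count_like) "poisson"
      else stop("cannot infer family for outcome '", outcome,
                "'; pass family explicitly")
  }
  family <- match.arg(family, c("poisson", "zib"))
  structure(list(outcome = outcome, family = family, reference = reference,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 prior_sd = 10),
            class = "model_spec")
}

# ---- likelihoods -----------------------------------------------------------

.loglik_poisson <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  if (any(eta > 30)) return(-Inf)  # guard against overflow excursions
  sum(stats::dpois(y, exp(eta), log = TRUE))
}

# theta = c(beta..., log_phi, logit_pi); pi is the P(y == 0) mass
.loglik_zib <- function(theta, y, X) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  phi <- exp(theta[p + 1])
  pi0 <- stats::plogis(theta[p + 2])
  if (!is.finite(phi) || phi <= 0) return(-Inf)
  mu <- stats::plogis(drop(X %*% beta))
  ll <- 0
  z <- y == 0
  if (any(z)) ll <- ll + sum(z) * log(pi0)
  if (any(!z)) {
    a <- mu[!z] * phi
    b <- (1 - mu[!z]) * phi
    ll <- ll + sum(log(1 - pi0) + stats::dbeta(y[!z], a, b, log = TRUE))
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

# flat intercept, normal(0, prior_sd) on everything else
.logprior <- function(theta, prior_sd) {
  if (length(theta) <= 1) return(0)
  sum(stats::dnorm(theta[-1], 0, prior_sd, log = TRUE))
}

# ---- adaptive random-walk Metropolis --------------------------------------

# One chain. logpost is a function(theta); returns draws matrix
# (iter x length(init)) after warmup, with Haario-style covariance
# adaptation during warmup only.
.mh_chain <- function(logpost, init, iter, warmup, chain_seed) {
  withr_seed(chain_seed, {
    d <- length(init)
    theta <- init
    lp <- logpost(theta)
    if (!is.finite(lp)) stop("initial value has zero posterior density")
    scale <- 2.38 / sqrt(d)
    sigma <- diag(pmax(abs(init) * 0.1, 0.1), d)
    chol_s <- chol(sigma)
    draws <- matrix(NA_real_, iter, d)
    hist <- matrix(NA_real_, warmup, d)
    acc_window <- 0L
    total <- warmup + iter
    for (t in seq_len(total)) {
      prop <- theta + scale * drop(crossprod(chol_s, stats::rnorm(d)))
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc_window <- acc_window + 1L
      }
      if (t <= warmup) {
        hist[t, ] <- theta
        if (t %% 50 == 0) {
          rate <- acc_window / 50
          scale <- scale * exp(rate - 0.234)
          acc_window <- 0L
          if (t >= 200) {  # empirical covariance, regularized
            cv <- stats::var(hist[seq_len(t), , drop = FALSE])
            cv <- cv + diag(1e-8 + 1e-4 * mean(diag(cv)), d)
            ok <- tryCatch({chol_s <- chol(cv); TRUE}, error = function(e) FALSE)
          }
        }
      } else {
        draws[t - warmup, ] <- theta
      }
    }
    draws
  })
}

# split-half Rhat per parameter over a list of draws matrices
.split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  d <- ncol(halves[[1]])
  vapply(seq_len(d), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# ---- fitting ---------------------------------------------------------------

#' Fit a Bayesian group-comparison model
#'
#' Fits the outcome named in `spec` against the `group` column of `data`
#' with treatment coding, by adaptive random-walk Metropolis (default) or
#' maximum likelihood (`method = "mle"`, same families, no priors,
#' asymptotic-normal intervals). Posterior summaries are means with
#' central 95% credible intervals; a warning is raised if any split-Rhat
#' exceeds 1.05.
#'
#' @param data data.frame containing the outcome column and a `group`
#'   column; typically the `rules` or `sequences` table of
#'   [set_metrics()].
#' @param spec a [model_spec()].
#' @param method `"mcmc"` (default) or `"mle"`.
#' @return data.frame of class `model_estimates`: one row per term with
#'   `outcome, term, role, mean, ci_low, ci_high, rhat, method`. `role` is
#'   `"intercept"` (the reference group's alpha on the link scale),
#'   `"contrast"` or `"aux"`.
#' @examples
#' d <- data.frame(chunks = c(5, 6, 7), group = "g")
#' fit <- fit_group_model(d, model_spec("chunks", reference = "g",
#'                                      chains = 2, iter = 500, warmup = 300))
#' @export
fit_group_model <- function(data, spec, method = c("mcmc", "mle")) {
  method <- match.arg(method)
  if (!spec$outcome %in% names(data)) {
    stop("outcome column '", spec$outcome, "' not found")
  }
  if (!"group" %in% names(data)) stop("data needs a 'group' column")
  y <- data[[spec$outcome]]
  grp <- as.character(data$group)
  if (anyNA(y)) stop("outcome contains NA")
  glevels <- unique(grp)
  tab <- table(grp)
  if (any(tab < 2)) {
    stop("every group needs at least 2 observations; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  ref <- if (spec$reference %in% glevels) spec$reference else glevels[1]
  others <- setdiff(glevels, ref)
  X <- matrix(1, length(grp), 1)
  for (g in others) X <- cbind(X, as.numeric(grp == g))
  colnames(X) <- c(ref, others)

  if (spec$family == "poisson") {
    if (any(y < 0) || any(y != floor(y))) stop("Poisson outcome must be non-negative integers")
    loglik <- function(th) .loglik_poisson(th, y, X)
    init <- tryCatch(
      unname(stats::coef(stats::glm.fit(X, y, family = stats::poisson()))),
      error = function(e) c(log(mean(y) + 0.5), rep(0, length(others))))
    par_names <- colnames(X)
    roles <- c("intercept", rep("contrast", length(others)))
  } else {
    if (any(y < 0) || any(y >= 1)) {
      stop("zero-inflated beta outcome must lie in [0, 1)")
    }
    loglik <- function(th) .loglik_zib(th, y, X)
    pos <- y[y > 0]
    mu0 <- if (length(pos)) mean(pos) else 0.5
    v0 <- if (length(pos) > 1) max(stats::var(pos), 1e-4) else 0.01
    phi0 <- max(mu0 * (1 - mu0) / v0 - 1, 1)
    p0 <- min(max(mean(y == 0), 1 / (length(y) + 2)), 1 - 1 / (length(y) + 2))
    init <- c(stats::qlogis(min(max(mu0, 0.01), 0.99)),
              rep(0, length(others)), log(phi0), stats::qlogis(p0))
    par_names <- c(colnames(X), "phi_log", "zi_logit")
    roles <- c("intercept", rep("contrast", length(others)), "aux", "aux")
  }
  logpost <- function(th) loglik(th) + .logprior(th, spec$prior_sd)

  if (method == "mle") {
    est <- .fit_mle(loglik, init, par_names, roles)
  } else {
    chain_seeds <- spec$seed + 1000L * seq_len(spec$chains)
    draws <- lapply(seq_len(spec$chains), function(c) {
      jit <- withr_seed(chain_seeds[c] + 500L,
                        init + stats::rnorm(length(init), 0, 0.05))
      .mh_chain(logpost, jit, spec$iter, spec$warmup, chain_seeds[c])
    })
    all_draws <- do.call(rbind, draws)
    rhat <- .split_rhat(draws)
    if (any(rhat > 1.05)) {
      warning("convergence flag: split-Rhat > 1.05 for ",
              paste(par_names[rhat > 1.05], collapse = ", "))
    }
    est <- data.frame(
      term = par_names, role = roles,
      mean = colMeans(all_draws),
      ci_low = apply(all_draws, 2, stats::quantile, 0.025),
      ci_high = apply(all_draws, 2, stats::quantile, 0.975),
      rhat = rhat, method = "mcmc", stringsAsFactors = FALSE)
  }
  est <- cbind(outcome = spec$outcome, est)
  rownames(est) <- NULL
  class(est) <- c("model_estimates", "data.frame")
  attr(est, "reference") <- ref
  attr(est, "family") <- spec$family
  est
}

.fit_mle <- function(loglik, init, par_names, roles) {
  fit <- stats::optim(init, function(th) -loglik(th), method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  se <- tryCatch(sqrt(diag(solve(fit$hessian))),
                 error = function(e) rep(NA_real_, length(init)))
  data.frame(term = par_names, role = roles, mean = fit$par,
             ci_low = fit$par - 1.96 * se, ci_high = fit$par + 1.96 * se,
             rhat = NA_real_, method = "mle", stringsAsFactors = FALSE)
}

#' Combine model estimates into a comparison report
#'
#' Stacks per-outcome estimate tables and flags, for each contrast term,
#' whether its 95% interval excludes 0 (`differs`; a boundary exactly at 0
#' does not count as exclusion). Intercepts and auxiliary terms carry
#' `differs = NA`.
#'
#' @param estimates a `model_estimates` object or list of them (one per
#'   outcome).
#' @return data.frame: `outcome, term, role, mean, ci_low, ci_high,
#'   differs, rhat, method`.
#' @export
compare_report <- function(estimates) {
  if (inherits(estimates, "model_estimates")) estimates <- list(estimates)
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  tab$differs <- ifelse(tab$role == "contrast",
                        tab$ci_low > 0 | tab$ci_high < 0, NA)
  tab[, c("outcome", "term", "role", "mean", "ci_low", "ci_high",
          "differs", "rhat", "method")]
}
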