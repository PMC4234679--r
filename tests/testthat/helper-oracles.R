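# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately avoid the code paths they check: direct likelihood
# optimisation instead of IRLS, all-pairs counting instead of rank formulas,
# explicit risk-set enumeration instead of survival::coxph.

# --- likelihood oracles -----------------------------------------------------

# Logistic regression by direct Newton/quasi-Newton optimisation of the
# Bernoulli log-likelihood.
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, y - p))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# Gamma GLM with log link: the coefficient MLE maximises the likelihood
# kernel sum(-log(mu) - y/mu) regardless of the shape parameter. Newton
# iterations with the observed information X' diag(y/mu) X (distinct from
# the unit-weight IRLS route used by the implementation).
oracle_gamma_log <- function(X, y, tol = 1e-12, maxit = 200) {
  b <- stats::lm.fit(X, log(y))$coefficients
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% b))
    score <- drop(crossprod(X, (y - mu) / mu))
    info <- crossprod(X * (y / mu), X)
    step <- solve(info, score)
    b <- b + step
    if (max(abs(score)) < tol) break
  }
  b
}

# --- concordance / binning oracles -----------------------------------------

# AUC as the explicit all-pairs concordance count, ties scoring 1/2.
oracle_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Empirical logit curve computed by explicit counting on a small table.
oracle_empirical_logit <- function(r_pos, q, w) {
  k <- ifelse(q == 0, 0, floor(q / w) + 1)
  out <- lapply(sort(unique(k)), function(ki) {
    n <- sum(k == ki)
    y <- sum(r_pos[k == ki])
    c(n = n, y = y, logit = log((y + 0.5) / (n - y + 0.5)))
  })
  do.call(rbind, out)
}

# --- Cox partial likelihood oracle ------------------------------------------

# Log partial likelihood at a fixed beta with Efron tie handling, by direct
# risk-set enumeration (single stratum).
oracle_cox_loglik <- function(beta, time, status, x) {
  eta <- drop(as.matrix(x) %*% beta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    dead <- which(time == t & status == 1)
    risk <- which(time >= t)
    d <- length(dead)
    s_risk <- sum(exp(eta[risk]))
    s_dead <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1)
      ll <- ll - log(s_risk - (l / d) * s_dead)
  }
  ll
}

# --- fixture builders --------------------------------------------------------

# Minimal calibration-like table: numeric covariates x1, x2, a factor g,
# questionnaire Q >= 0, and a reference R with the requested consumer
# fraction. All functions under test accept plain data.frames.
make_calib_fixture <- function(n, consumer_frac = 0.6, seed = 42,
                               beta_q1 = 1.2, beta_q2 = 0.02) {
  set.seed(seed)
  x1 <- stats::rnorm(n)
  x2 <- stats::runif(n, 40, 70)
  g <- factor(sample(c("a", "b"), n, replace = TRUE))
  q <- stats::rgamma(n, shape = 1.5, scale = 40)
  p <- stats::plogis(stats::qlogis(consumer_frac) + beta_q1 * scale(log1p(q))[, 1])
  consumed <- stats::rbinom(n, 1, p)
  mu <- exp(3.5 + beta_q2 * sqrt(q) + 0.1 * x1)
  r <- ifelse(consumed == 1, stats::rgamma(n, shape = 2, scale = mu / 2), 0)
  data.frame(subject_id = sprintf("F%04d", seq_len(n)),
             x1 = x1, x2 = x2, g = g, age = x2, sex = g,
             Q = q, R = r, stringsAsFactors = FALSE)
}

# Small survival fixture with tied event times for the Cox oracle.
make_surv_fixture <- function() {
  data.frame(
    subject_id = sprintf("S%02d", 1:15),
    Q = c(10, 0, 25, 40, 5, 60, 15, 0, 35, 80, 20, 50, 8, 30, 12),
    x1 = c(0.5, -1, 0.3, 1.2, -0.7, 0.9, 0, -0.2, 1.5, -1.1,
           0.4, 0.8, -0.5, 0.1, 0.6),
    time = c(5, 3, 8, 3, 10, 2, 7, 5, 4, 1, 9, 5, 6, 2, 11),
    event = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0),
    stringsAsFactors = FALSE
  )
}

# Group template with exact sample mean m and sample SD s (length n >= 3).
exact_mean_sd_group <- function(m, s, n = 12) {
  set.seed(7)
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}
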