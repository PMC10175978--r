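test_that("intercept-only multinomial fit returns exact sample proportions", {
  d <- data.frame(t = factor(rep(c("a", "b", "c"), c(10, 6, 4))))
  fit <- fit_multinomial_logit(t ~ 1, d)
  expect_equal(unname(fit$probabilities[1, ]), c(0.5, 0.3, 0.2),
               tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("saturated multinomial fit reproduces within-stratum proportions", {
  set.seed(21)
  d <- data.frame(x = rep(c(0, 1), c(60, 40)))
  d$t <- factor(ifelse(stats::runif(100) < 0.3 + 0.3 * d$x, "hi",
                       ifelse(stats::runif(100) < 0.5, "mid", "lo")))
  fit <- fit_multinomial_logit(t ~ x, d)
  for (xx in c(0, 1)) {
    emp <- prop.table(table(d$t[d$x == xx]))
    got <- fit$probabilities[match(xx, d$x), levels(d$t)]
    expect_equal(unname(got), unname(as.numeric(emp)), tolerance = 1e-8)
  }
})

test_that("multinomial log-likelihood matches an independent optimiser", {
  set.seed(77)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
  eta1 <- -0.3 + 0.8 * d$x1 - 0.5 * d$x3
  eta2 <- -1.0 - 0.4 * d$x2 + 0.7 * d$x3
  den <- 1 + exp(eta1) + exp(eta2)
  u <- runif(n)
  d$t <- factor(ifelse(u < exp(eta1) / den, "b",
                       ifelse(u < (exp(eta1) + exp(eta2)) / den, "c", "a")))
  fit <- fit_multinomial_logit(t ~ x1 + x2 + x3, d)

  # oracle: nlm with analytic gradient on the stacked negative log-likelihood
  X <- cbind(1, d$x1, d$x2, d$x3)
  Y <- outer(d$t, levels(d$t), "==") * 1
  negll <- function(b) {
    B <- matrix(b, 4, 2)
    eta <- X %*% B
    den <- 1 + rowSums(exp(eta))
    val <- -(sum(eta * Y[, -1]) - sum(log(den)))
    P <- exp(eta) / den
    attr(val, "gradient") <- -as.vector(crossprod(X, Y[, -1] - P))
    val
  }
  orc <- stats::nlm(negll, rep(0, 8), gradtol = 1e-12, iterlim = 500)
  expect_lt(abs(fit$loglik - (-orc$minimum)), 1e-6)

  skip_if_not_installed("nnet")
  nn <- nnet::multinom(t ~ x1 + x2 + x3, d, trace = FALSE,
                       reltol = 1e-14, maxit = 500)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(nn))), 1e-4)
})

test_that("predict on new data reproduces in-sample probabilities", {
  set.seed(5)
  d <- data.frame(x = rnorm(80),
                  g = factor(sample(c("u", "v"), 80, TRUE)))
  d$t <- factor(sample(c("a", "b", "c"), 80, TRUE, prob = c(.5, .3, .2)))
  fit <- fit_multinomial_logit(t ~ x + g, d)
  expect_equal(predict(fit, d), fit$probabilities, tolerance = 1e-12)
})

test_that("outcome models recover exact and noisy linear structure", {
  d <- data.frame(treatment = factor(rep(c("none", "short_term"), each = 6)),
                  x = rep(1:6, 2))
  d$y <- ifelse(d$treatment == "none", 2 + 3 * d$x, 7)
  om <- fit_outcome_models(d, ~ x, "y")
  expect_equal(unname(om$coefficients$none), c(2, 3), tolerance = 1e-10)
  expect_equal(unname(om$coefficients$short_term), c(7, 0),
               tolerance = 1e-10)

  set.seed(12)
  d2 <- data.frame(treatment = factor(rep("none", 100)), x = rnorm(100),
                   z = rnorm(100))
  d2$y <- 1 + 2 * d2$x - d2$z + rnorm(100)
  om2 <- fit_outcome_models(d2, ~ x + z, "y")
  X <- cbind(1, d2$x, d2$z)
  oracle <- solve(crossprod(X), crossprod(X, d2$y)) # normal equations
  expect_equal(unname(om2$coefficients$none), as.numeric(oracle),
               tolerance = 1e-8)
})

test_that("AIPW collapses to the difference of means under null models", {
  set.seed(8)
  d <- simulate_analysis_rows(400, seed = 8)
  shares <- prop.table(table(d$treatment))
  P <- matrix(rep(as.numeric(shares), each = 400), 400, 3,
              dimnames = list(NULL, names(shares)))
  om <- fit_outcome_models(d, ~ 1, "outcome_sbp")
  est <- aipw_ate(d, P, om, "outcome_sbp", cluster = NULL, prob_floor = 0)
  means <- tapply(d$outcome_sbp, d$treatment, mean)
  expect_equal(est$ate, as.numeric(means[2:3] - means[1]),
               tolerance = 1e-10)
})

test_that("AIPW equals a hand-evaluated potential-outcome formula on 8 rows", {
  d <- data.frame(
    patient_id = 1:8, practice_id = rep(c("A", "B"), 4),
    treatment = factor(rep(c("none", "short_term"), 4),
                       levels = c("none", "short_term")),
    x = rep(c(0, 0, 1, 1), each = 2),
    y = c(100, 104, 110, 112, 120, 118, 133, 135))
  ps <- fit_multinomial_logit(treatment ~ x, d)
  om <- fit_outcome_models(d, ~ x, "y")
  est <- aipw_ate(d, ps, om, "y", cluster = NULL, prob_floor = 0)
  # hand evaluation of mu_t = mean[ 1{T=t}(Y - m_t)/p_t + m_t ]
  p <- ps$probabilities
  m <- om$mhat
  mu <- sapply(1:2, function(k) {
    ind <- as.numeric(d$treatment == levels(d$treatment)[k])
    mean(ind * (d$y - m[, k]) / p[, k] + m[, k])
  })
  expect_equal(est$ate, mu[2] - mu[1], tolerance = 1e-12)
  # and because both models are saturated in x, it is the g-formula value
  gf <- sapply(levels(d$treatment), function(t)
    mean(sapply(c(0, 1), function(v) mean(d$y[d$treatment == t & d$x == v]))))
  expect_equal(est$ate, unname(gf[2] - gf[1]), tolerance = 1e-10)
})

test_that("clustered OLS comparator SEs match a direct sandwich oracle", {
  fx <- make_fixture("null_cluster")
  est <- ols_comparators(fx, ~ x, "outcome_sbp")
  fit <- stats::lm(outcome_sbp ~ .t + x,
                   data = transform(fx, .t = treatment))
  X <- stats::model.matrix(fit); u <- stats::resid(fit)
  Gs <- rowsum(X * u, fx$practice_id)
  G <- nrow(Gs); n <- nrow(X); k <- ncol(X)
  bread <- solve(crossprod(X))
  V <- G / (G - 1) * (n - 1) / (n - k) * bread %*% crossprod(Gs) %*% bread
  adj <- est[est$estimator == "ols_adjusted", ]
  expect_equal(adj$se,
               unname(sqrt(diag(V)[c(".tshort_term", ".tlong_term")])),
               tolerance = 1e-8)
})

test_that("AIPW clustered variance matches a brute-force cluster sum", {
  fx <- make_fixture("null_cluster")
  ps <- fit_multinomial_logit(treatment ~ x, fx)
  om <- fit_outcome_models(fx, ~ x, "outcome_sbp")
  est <- aipw_ate(fx, ps, om, "outcome_sbp", prob_floor = 0)
  p <- ps$probabilities; m <- om$mhat; n <- nrow(fx)
  A <- sapply(1:3, function(k) {
    ind <- as.numeric(fx$treatment == levels(fx$treatment)[k])
    ind * (fx$outcome_sbp - m[, k]) / p[, k] + m[, k]
  })
  for (k in 2:3) {
    ate <- mean(A[, k]) - mean(A[, 1])
    phi <- A[, k] - A[, 1] - ate
    cl_sums <- sapply(split(phi, fx$practice_id), sum)
    G <- length(cl_sums)
    oracle <- sqrt(G / (G - 1) * sum(cl_sums^2) / n^2)
    expect_equal(est$se[k - 1], oracle, tolerance = 1e-12)
  }
})

test_that("crude OLS is confounded where adjusted and AIPW are not", {
  d <- simulate_analysis_rows(30000, confounding_strength = 1.2, seed = 99)
  est <- ols_comparators(d, ~ x, "outcome_sbp")
  crude <- est[est$estimator == "ols_crude" & est$level == "long_term", ]
  adj <- est[est$estimator == "ols_adjusted" & est$level == "long_term", ]
  expect_gt(crude$ate, 0.5)  # planted confounding pushes upward
  expect_lt(abs(adj$ate), 3 * adj$se)
})

test_that("stratified analysis is order-invariant and degenerate-safe", {
  d <- simulate_analysis_rows(3000, ate_long_sbp = -2, seed = 55)
  d$band <- "all"
  s1 <- stratified_ate(d, "band", ~ x, ~ x, "outcome_sbp")
  direct <- aipw_estimate(d, ~ x, ~ x, "outcome_sbp")
  expect_equal(s1$ate, direct$ate, tolerance = 1e-12)
  set.seed(1)
  s2 <- stratified_ate(d[sample(nrow(d)), ], "band", ~ x, ~ x,
                       "outcome_sbp")
  expect_equal(sort(s2$ate), sort(s1$ate), tolerance = 1e-10)
  # a stratum missing a treatment level is skipped with a reason
  d$band2 <- ifelse(d$treatment == "long_term", "B", "A")
  s3 <- stratified_ate(d, "band2", ~ x, ~ x, "outcome_sbp")
  expect_true(length(attr(s3, "skipped")) >= 1L)
})
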