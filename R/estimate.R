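#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood multinomial logit for a multi-valued treatment, with
#' the first factor level as the reference. Fitting is full Newton on the
#' stacked score with the analytic block Hessian and step-halving, run until
#' the score norm drops below \code{tol}; an intercept-only fit therefore
#' returns the sample proportions to machine precision. Aliased design
#' columns are dropped (and recorded) before fitting.
#'
#' @param formula model formula; the response must be a factor (treatment
#'   levels), e.g. \code{treatment ~ age_group + sex + baseline_sbp}.
#' @param data data.frame.
#' @param tol convergence threshold on the Euclidean norm of the score
#'   (default \code{1e-8}).
#' @param max_iter maximum Newton iterations (default 100).
#' @return An object of class \code{multinom_fit}: coefficient matrix
#'   (\code{p x (K-1)}, one column per non-reference level), fitted
#'   probability matrix (\code{n x K}, columns in level order, rows summing
#'   to one), log-likelihood, convergence diagnostics (\code{converged},
#'   \code{iterations}, \code{score_norm}, \code{separation} flag,
#'   \code{dropped} aliased columns).
#' @examples
#' d <- data.frame(t = factor(c(0, 0, 1, 2)))
#' fit <- fit_multinomial_logit(t ~ 1, d)
#' fit$probabilities[1, ]   # 0.50 0.25 0.25
#' @export
fit_multinomial_logit <- function(formula, data, tol = 1e-8, max_iter = 100) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  K <- nlevels(y)
  if (K < 2L) stop("treatment must have at least 2 observed levels")
  trms <- attr(mf, "terms")
  X <- stats::model.matrix(trms, mf)

  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  Yind <- matrix(0, n, K); Yind[cbind(seq_len(n), as.integer(y))] <- 1

  B <- matrix(0, p, K - 1L)
  probs_of <- function(B) {
    eta <- X %*% B
    eta <- pmin(pmax(eta, -30), 30)
    E <- exp(eta)
    denom <- 1 + rowSums(E)
    cbind(1 / denom, E / denom)
  }
  loglik_of <- function(P) sum(log(pmax(P[Yind == 1], 1e-300)))

  P <- probs_of(B)
  ll <- loglik_of(P)
  converged <- FALSE; it <- 0L; gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    R <- Yind[, -1L, drop = FALSE] - P[, -1L, drop = FALSE]
    g <- as.vector(crossprod(X, R))               # stacked score, level-major
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) { converged <- TRUE; break }
    H <- matrix(0, p * (K - 1L), p * (K - 1L))    # negative Hessian blocks
    for (k in seq_len(K - 1L)) {
      for (l in seq_len(k)) {
        w <- P[, k + 1L] * ((k == l) - P[, l + 1L])
        blk <- crossprod(X, X * w)
        ri <- (k - 1L) * p + seq_len(p); ci <- (l - 1L) * p + seq_len(p)
        H[ri, ci] <- blk
        if (l < k) H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, nrow(H)), g))
    step <- matrix(step, p, K - 1L)
    lambda <- 1
    repeat {
      Bn <- B + lambda * step
      Pn <- probs_of(Bn)
      lln <- loglik_of(Pn)
      if (lln >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    B <- Bn; P <- Pn; ll <- lln
  }
  if (converged) { # score norm at the accepted iterate
    R <- Yind[, -1L, drop = FALSE] - P[, -1L, drop = FALSE]
    gnorm <- sqrt(sum(as.vector(crossprod(X, R))^2))
  }
  separation <- any(P < 1e-10) || max(abs(X %*% B)) > 29.5
  dimnames(B) <- list(colnames(X), levels(y)[-1L])
  colnames(P) <- levels(y)
  structure(list(coefficients = B, probabilities = P, loglik = ll,
                 levels = levels(y), terms = trms,
                 xlevels = stats::.getXlevels(trms, mf),
                 kept_columns = colnames(X), dropped = dropped,
                 converged = converged, iterations = it,
                 score_norm = gnorm, separation = separation),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("<multinom_fit>", length(x$levels), "levels, ref =", x$levels[1],
      "| logLik", format(x$loglik), "| iter", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @rdname fit_multinomial_logit
#' @param object a \code{multinom_fit}.
#' @param newdata data.frame to predict class probabilities for.
#' @param ... unused.
#' @export
predict.multinom_fit <- function(object, newdata, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)[, object$kept_columns, drop = FALSE]
  eta <- pmin(pmax(X %*% object$coefficients, -30), 30)
  E <- exp(eta)
  denom <- 1 + rowSums(E)
  P <- cbind(1 / denom, E / denom)
  colnames(P) <- object$levels
  P
}

#' Per-treatment-level linear outcome models
#'
#' Fits an ordinary least-squares regression of the outcome on the
#' confounder design separately within each treatment level, and predicts
#' every row's conditional mean under every level (the g-formula
#' regressions that the AIPW estimator augments with). Aliased columns
#' within a level (e.g. a factor level absent from that arm) get a zero
#' contribution and are recorded.
#'
#' @param rows analysis data.frame.
#' @param formula RHS confounder formula, e.g. \code{~ age_group + sex +
#'   baseline_sbp + baseline_dbp}.
#' @param outcome name of the outcome column.
#' @param treatment name of the treatment column (factor or coercible).
#' @return An object of class \code{outcome_fit}: list with
#'   \code{coefficients} (per level), \code{mhat} (\code{n x K} matrix of
#'   predicted means, columns in treatment level order), \code{levels},
#'   \code{aliased} (per-level dropped columns).
#' @export
fit_outcome_models <- function(rows, formula, outcome, treatment = "treatment") {
  tr <- factor(rows[[treatment]])
  y <- rows[[outcome]]
  stopifnot(is.numeric(y), !anyNA(y))
  X <- stats::model.matrix(formula, rows)
  K <- nlevels(tr)
  mhat <- matrix(NA_real_, nrow(rows), K, dimnames = list(NULL, levels(tr)))
  coefs <- list(); aliased <- list()
  for (k in seq_len(K)) {
    idx <- which(tr == levels(tr)[k])
    if (length(idx) <= ncol(X))
      stop("treatment level ", levels(tr)[k],
           " has fewer rows than outcome-model parameters")
    fit <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
    beta <- fit$coefficients
    bad <- is.na(beta)
    aliased[[levels(tr)[k]]] <- names(beta)[bad]
    beta[bad] <- 0
    coefs[[levels(tr)[k]]] <- beta
    mhat[, k] <- drop(X %*% beta)
  }
  structure(list(coefficients = coefs, mhat = mhat, levels = levels(tr),
                 aliased = aliased),
            class = "outcome_fit")
}

#' Augmented inverse-probability-weighted average treatment effects
#'
#' The doubly robust AIPW estimator for a multi-valued treatment. For each
#' treatment level \eqn{t} the potential-outcome mean is estimated as
#' \deqn{\hat\mu_t = n^{-1} \sum_i \big[ 1\{T_i=t\}\,(Y_i - \hat m_t(X_i)) /
#'   \hat p_t(X_i) + \hat m_t(X_i) \big],}
#' where \eqn{\hat p_t} are the treatment-model (multinomial logit)
#' probabilities — their reciprocals are the weights applied to the
#' outcome-model residuals — and \eqn{\hat m_t} the per-level outcome
#' regressions. The average treatment effect of level \eqn{t} versus the
#' reference is \eqn{\hat\mu_t - \hat\mu_0}. The estimate is consistent when
#' either model is correctly specified (double robustness).
#'
#' The variance is the plug-in influence-function variance aggregated over
#' practice clusters: with per-row contributions \eqn{\varphi_i} (the
#' bracketed term for level \eqn{t} minus the one for the reference minus
#' the ATE), \eqn{\widehat{se}^2 = \frac{G}{G-1} \sum_c (\sum_{i \in c}
#' \varphi_i)^2 / n^2} over the \eqn{G} clusters, with the conventional
#' small-sample factor and \eqn{t_{G-1}} critical values for the 95\%
#' interval. With every row its own cluster this reduces to the ordinary
#' heteroskedasticity-robust influence-function variance.
#'
#' Probabilities below \code{prob_floor} are winsorised (floored, never
#' dropped) before weighting; the number of floored cells is reported.
#'
#' @param rows analysis data.frame (one row per patient).
#' @param propensity a \code{\link{fit_multinomial_logit}} fit (or a
#'   probability matrix with columns in treatment-level order).
#' @param outcome_models a \code{\link{fit_outcome_models}} fit.
#' @param outcome outcome column name (reporting only).
#' @param treatment treatment column name.
#' @param cluster cluster (practice) column name, or \code{NULL} for
#'   row-level independence.
#' @param prob_floor winsorisation floor for fitted probabilities
#'   (default 0.001).
#' @return data.frame of class \code{ate_estimates}, one row per
#'   non-reference level: \code{level}, \code{outcome}, \code{estimator}
#'   (\code{"aipw"}), \code{ate}, \code{se}, \code{ci_lo}, \code{ci_hi}
#'   (normal 95\% interval), \code{n}, \code{n_floored}.
#' @export
aipw_ate <- function(rows, propensity, outcome_models, outcome,
                     treatment = "treatment", cluster = "practice_id",
                     prob_floor = 0.001) {
  tr <- factor(rows[[treatment]])
  y <- rows[[outcome]]
  P <- if (inherits(propensity, "multinom_fit")) propensity$probabilities
       else as.matrix(propensity)
  stopifnot(nrow(P) == nrow(rows), ncol(P) == nlevels(tr))
  mhat <- outcome_models$mhat
  stopifnot(identical(colnames(mhat), levels(tr)))
  n <- nrow(rows)
  n_floored <- sum(P < prob_floor)
  P <- pmax(P, prob_floor)

  # per-level augmented contributions a_{it}
  A <- vapply(seq_len(nlevels(tr)), function(k) {
    ind <- as.numeric(tr == levels(tr)[k])
    ind * (y - mhat[, k]) / P[, k] + mhat[, k]
  }, numeric(n))
  mu <- colMeans(A)

  cl <- if (is.null(cluster)) seq_len(n) else rows[[cluster]]
  G <- length(unique(cl))
  tcrit <- stats::qt(0.975, max(G - 1L, 1L))
  out <- lapply(2:nlevels(tr), function(k) {
    ate <- mu[k] - mu[1L]
    phi <- A[, k] - A[, 1L] - ate
    se <- sqrt(G / max(G - 1L, 1L) * sum(tapply(phi, cl, sum)^2) / n^2)
    data.frame(level = levels(tr)[k], outcome = outcome, estimator = "aipw",
               ate = ate, se = se,
               ci_lo = ate - tcrit * se,
               ci_hi = ate + tcrit * se,
               n = n, n_floored = n_floored, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("ate_estimates", "data.frame"))
}

#' Crude and covariate-adjusted linear-regression comparators
#'
#' Traditional regression analogues of the AIPW contrasts: the crude model
#' regresses the outcome on treatment indicators alone; the adjusted model
#' adds the full confounder design. Standard errors are cluster-robust
#' (practice-level sandwich, \code{sandwich::vcovCL}).
#'
#' @param rows analysis data.frame.
#' @param formula RHS confounder formula for the adjusted model.
#' @param outcome outcome column name.
#' @param treatment treatment column name.
#' @param cluster cluster column name, or \code{NULL} for the
#'   heteroskedasticity-robust (HC1) variance.
#' @return \code{ate_estimates} data.frame with estimators
#'   \code{"ols_crude"} and \code{"ols_adjusted"}, one row per
#'   non-reference treatment level each.
#' @export
ols_comparators <- function(rows, formula, outcome, treatment = "treatment",
                            cluster = "practice_id") {
  rows$.t <- factor(rows[[treatment]])
  fml_crude <- stats::as.formula(paste(outcome, "~ .t"))
  fml_adj <- stats::update(formula, paste(outcome, "~ .t + ."))
  res <- lapply(list(ols_crude = fml_crude, ols_adjusted = fml_adj),
                function(f) {
    fit <- stats::lm(f, data = rows)
    V <- if (is.null(cluster)) sandwich::vcovHC(fit, type = "HC1")
         else sandwich::vcovCL(fit, cluster = rows[[cluster]])
    want <- paste0(".t", levels(rows$.t)[-1L])
    b <- stats::coef(fit)[want]
    se <- sqrt(diag(V)[want])
    dfc <- if (is.null(cluster)) stats::df.residual(fit)
           else length(unique(rows[[cluster]])) - 1L
    tcrit <- stats::qt(0.975, max(dfc, 1L))
    data.frame(level = levels(rows$.t)[-1L], outcome = outcome,
               ate = unname(b), se = unname(se),
               ci_lo = unname(b - tcrit * se),
               ci_hi = unname(b + tcrit * se),
               n = nrow(rows), n_floored = 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Map(function(d, nm) {
    d$estimator <- nm
    d[c("level", "outcome", "estimator", "ate", "se", "ci_lo", "ci_hi",
        "n", "n_floored")]
  }, res, names(res)))
  rownames(out) <- NULL
  structure(out, class = c("ate_estimates", "data.frame"))
}

#' One-call AIPW analysis of an analysis table
#'
#' Convenience wrapper: fits the multinomial-logit treatment model and the
#' per-level outcome regressions, then computes AIPW ATEs (and optionally
#' the OLS comparators) for one outcome.
#'
#' @param rows analysis data.frame.
#' @param ps_formula RHS formula for the treatment model (may include
#'   treatment-model-only covariates such as the consultation count).
#' @param om_formula RHS formula for the outcome model (confounders only).
#' @param outcome outcome column name.
#' @param treatment,cluster column names.
#' @param comparators also compute \code{\link{ols_comparators}}?
#' @param prob_floor passed to \code{\link{aipw_ate}}.
#' @return \code{ate_estimates} data.frame (AIPW rows first), with the
#'   treatment-model diagnostics attached as attribute
#'   \code{"propensity_diagnostics"}.
#' @export
aipw_estimate <- function(rows, ps_formula, om_formula, outcome,
                          treatment = "treatment", cluster = "practice_id",
                          comparators = FALSE, prob_floor = 0.001) {
  ps_full <- stats::update(ps_formula, paste(treatment, "~ ."))
  ps <- fit_multinomial_logit(ps_full, rows)
  om <- fit_outcome_models(rows, om_formula, outcome, treatment)
  est <- aipw_ate(rows, ps, om, outcome, treatment, cluster, prob_floor)
  if (comparators)
    est <- structure(rbind(est, ols_comparators(rows, om_formula, outcome,
                                                treatment, cluster)),
                     class = c("ate_estimates", "data.frame"))
  attr(est, "propensity_diagnostics") <-
    list(converged = ps$converged, iterations = ps$iterations,
         score_norm = ps$score_norm, separation = ps$separation,
         dropped = ps$dropped)
  est
}

#' Age-stratified (or arbitrary) stratified AIPW analysis
#'
#' Reruns the full AIPW machinery — treatment and outcome models refit from
#' scratch — within each stratum of \code{stratifier} (canonically age
#' 18-64 versus 65+). Strata missing a treatment level are skipped with a
#' recorded reason.
#'
#' @param rows analysis data.frame.
#' @param stratifier column name defining strata.
#' @inheritParams aipw_estimate
#' @return \code{ate_estimates} data.frame with an extra \code{stratum}
#'   column; skipped strata appear in attribute \code{"skipped"}.
#' @export
stratified_ate <- function(rows, stratifier, ps_formula, om_formula, outcome,
                           treatment = "treatment", cluster = "practice_id",
                           prob_floor = 0.001) {
  strata <- sort(unique(as.character(rows[[stratifier]])))
  lev <- levels(factor(rows[[treatment]]))
  out <- list(); skipped <- list()
  for (s in strata) {
    sub <- rows[as.character(rows[[stratifier]]) == s, , drop = FALSE]
    present <- lev %in% unique(as.character(sub[[treatment]]))
    if (!all(present)) {
      skipped[[s]] <- paste("missing treatment level(s):",
                            paste(lev[!present], collapse = ", "))
      next
    }
    est <- aipw_estimate(sub, ps_formula, om_formula, outcome, treatment,
                         cluster, comparators = FALSE,
                         prob_floor = prob_floor)
    est$stratum <- s
    out[[s]] <- est
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(level = character(0), outcome = character(0),
               estimator = character(0), ate = numeric(0), se = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0), n = integer(0),
               n_floored = integer(0), stratum = character(0))
  rownames(res) <- NULL
  structure(res, class = c("ate_estimates", "data.frame"), skipped = skipped)
}
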