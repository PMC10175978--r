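#' Multiple-imputation settings
#'
#' @param m number of imputed datasets (default 20).
#' @param n_cycles chained-equation sweeps per dataset (default 10).
#' @param methods optional named character vector mapping variable names to
#'   conditional-model families: \code{"pmm"} (predictive-mean matching,
#'   continuous), \code{"norm"} (plain normal draw, continuous),
#'   \code{"logreg"} (binary), \code{"polyreg"} (multi-category). Variables
#'   with missingness not named here get a default by type (continuous
#'   \code{pmm}, binary \code{logreg}, factor \code{polyreg}).
#' @param pmm_k donor-pool size for predictive-mean matching (default 5).
#' @return A list of class \code{imputation_spec}.
#' @export
imputation_spec <- function(m = 20, n_cycles = 10, methods = NULL,
                            pmm_k = 5) {
  stopifnot(m >= 2, n_cycles >= 1, pmm_k >= 1)
  structure(list(m = as.integer(m), n_cycles = as.integer(n_cycles),
                 methods = methods, pmm_k = as.integer(pmm_k)),
            class = "imputation_spec")
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells by cycling per-variable conditional models: each
#' variable with missingness is regressed on all other predictor columns
#' (using current completed values) and its missing cells redrawn, for
#' \code{n_cycles} sweeps, independently \code{m} times. Conditional
#' families: continuous variables use predictive-mean matching (Bayesian
#' parameter draw, \code{pmm_k} nearest observed donors, so imputed values
#' are always observed values) or plain normal draws; binary variables a
#' logistic model with a normal approximation posterior draw; multi-category
#' variables a multinomial logit refit on a bootstrap resample (as is
#' conventional for proper imputation with categorical conditionals).
#' Missing cells are initialised by random draws from the observed
#' marginals. Observed cells are never altered. Runs are deterministic
#' given \code{seed}.
#'
#' @param data data.frame; missingness is allowed only in variables covered
#'   by a conditional model.
#' @param spec an \code{\link{imputation_spec}}.
#' @param predictors character vector of columns used as model predictors
#'   (confounders plus auxiliaries such as the consultation count or a
#'   practice identifier). Default: every column with a declared or
#'   defaulted model plus every complete column except obvious id columns
#'   is NOT assumed — pass this explicitly in pipelines; the default uses
#'   all columns.
#' @param seed integer seed.
#' @return List of \code{m} completed data.frames; attribute \code{"events"}
#'   collects fallback notes (e.g. separation in a conditional model).
#' @export
chained_impute <- function(data, spec = imputation_spec(),
                           predictors = names(data), seed = 1L) {
  stopifnot(inherits(spec, "imputation_spec"))
  miss_vars <- names(data)[vapply(data, anyNA, logical(1))]
  methods <- if (is.null(spec$methods)) character(0) else spec$methods
  for (v in setdiff(miss_vars, names(methods))) {
    col <- data[[v]]
    methods[v] <- if (is.numeric(col)) "pmm"
      else if (is.logical(col) || nlevels(factor(col)) == 2L) "logreg"
      else "polyreg"
  }
  if (!all(methods[miss_vars] %in% c("pmm", "norm", "logreg", "polyreg")))
    stop("missingness in variable(s) without a known conditional-model family")
  if (length(miss_vars) == 0L)
    return(structure(replicate(spec$m, data, simplify = FALSE),
                     events = character(0)))

  events <- character(0)
  na_idx <- lapply(data[miss_vars], function(col) which(is.na(col)))
  out <- vector("list", spec$m)
  for (j in seq_len(spec$m)) {
    set.seed(seed + 7919L * j)
    d <- data
    for (v in miss_vars) { # marginal initialisation
      obs <- d[[v]][!is.na(d[[v]])]
      d[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]), replace = TRUE)
    }
    for (cyc in seq_len(spec$n_cycles)) {
      for (v in miss_vars) {
        preds <- setdiff(intersect(predictors, names(d)), v)
        rhs <- stats::as.formula(
          paste("~", paste(sprintf("`%s`", preds), collapse = " + ")))
        X <- stats::model.matrix(rhs, d)
        mis <- na_idx[[v]]
        obs <- setdiff(seq_len(nrow(d)), mis)
        imp <- switch(methods[v],
          pmm = impute_pmm(X, data[[v]], obs, mis, spec$pmm_k),
          norm = impute_norm(X, data[[v]], obs, mis),
          logreg = impute_logreg(X, data[[v]], obs, mis),
          polyreg = impute_polyreg(X, data[[v]], obs, mis))
        if (!is.null(attr(imp, "event")))
          events <- c(events, sprintf("m=%d cycle=%d %s: %s", j, cyc, v,
                                      attr(imp, "event")))
        if (is.integer(data[[v]]) && all(imp == round(imp)))
          imp <- as.integer(imp)
        d[[v]][mis] <- imp
      }
    }
    out[[j]] <- d
  }
  structure(out, events = events)
}

# Bayesian linear draw shared by pmm and norm
.blin_draw <- function(X, y, obs) {
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  XtX <- crossprod(Xo)
  bhat <- solve(XtX, crossprod(Xo, yo))
  res <- yo - Xo %*% bhat
  df <- max(length(obs) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  R <- chol(solve(XtX + diag(1e-10, ncol(XtX))))
  bstar <- bhat + sqrt(sigma2) * crossprod(R, stats::rnorm(ncol(Xo)))
  list(keep = keep, bhat = bhat, bstar = bstar, sigma = sqrt(sigma2))
}

impute_pmm <- function(X, y, obs, mis, k) {
  dr <- .blin_draw(X, y, obs)
  pred_obs <- drop(X[obs, dr$keep, drop = FALSE] %*% dr$bhat)
  pred_mis <- drop(X[mis, dr$keep, drop = FALSE] %*% dr$bstar)
  ord <- order(pred_obs)
  po <- pred_obs[ord]; yo <- y[obs][ord]
  n <- length(po)
  pos <- findInterval(pred_mis, po)
  vapply(seq_along(mis), function(i) {
    lo <- max(1L, pos[i] - k); hi <- min(n, pos[i] + k)
    cand <- lo:hi
    dist <- abs(po[cand] - pred_mis[i])
    donors <- cand[order(dist)][seq_len(min(k, length(cand)))]
    yo[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

impute_norm <- function(X, y, obs, mis) {
  dr <- .blin_draw(X, y, obs)
  drop(X[mis, dr$keep, drop = FALSE] %*% dr$bstar) +
    stats::rnorm(length(mis), 0, dr$sigma)
}

impute_logreg <- function(X, y, obs, mis) {
  yf <- factor(y[obs])
  lv <- levels(yf)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE],
                                    as.integer(yf) - 1L,
                                    family = stats::binomial())),
    error = function(e) NULL)
  event <- NULL
  if (is.null(fit) || !fit$converged || any(fit$fitted.values < 1e-8) ||
      any(fit$fitted.values > 1 - 1e-8)) {
    event <- "separation or non-convergence; marginal fallback"
    p <- mean(as.integer(yf) - 1L)
    draw <- stats::rbinom(length(mis), 1L, p)
  } else {
    beta <- fit$coefficients
    ok <- !is.na(beta)
    Xo <- X[obs, ok, drop = FALSE]
    W <- fit$weights
    V <- solve(crossprod(Xo, Xo * W) + diag(1e-10, sum(ok)))
    bstar <- beta[ok] + drop(crossprod(chol(V), stats::rnorm(sum(ok))))
    eta <- drop(X[mis, ok, drop = FALSE] %*% bstar)
    draw <- stats::rbinom(length(mis), 1L, stats::plogis(eta))
  }
  out <- lv[draw + 1L]
  if (is.logical(y)) out <- as.logical(out)
  if (is.numeric(y)) out <- as.numeric(out)
  structure(out, event = event)
}

impute_polyreg <- function(X, y, obs, mis) {
  yf <- factor(y[obs])
  boot <- sample(seq_along(obs), length(obs), replace = TRUE)
  d <- data.frame(.y = yf[boot])
  Xb <- X[obs[boot], , drop = FALSE]
  fit <- tryCatch({
    f <- fit_multinomial_logit_xy(Xb, d$.y)
    P <- multinom_xy_predict(f, X[mis, , drop = FALSE])
    apply(P, 1L, function(p) sample(levels(yf), 1L, prob = p))
  }, error = function(e) NULL)
  event <- NULL
  if (is.null(fit)) {
    event <- "multinomial conditional failed; marginal fallback"
    fit <- sample(as.character(yf), length(mis), replace = TRUE)
  }
  out <- fit
  if (is.numeric(y)) out <- as.numeric(out)
  structure(out, event = event)
}

# design-matrix-level multinomial fit (no formula), reusing the Newton core
fit_multinomial_logit_xy <- function(X, y, tol = 1e-6, max_iter = 50) {
  d <- as.data.frame(X[, -1, drop = FALSE])
  names(d) <- paste0("x", seq_len(ncol(d)))
  d$.y <- y
  fml <- stats::as.formula(paste(".y ~", if (ncol(d) > 1L)
    paste(names(d)[-ncol(d)], collapse = " + ") else "1"))
  fit_multinomial_logit(fml, d, tol = tol, max_iter = max_iter)
}

multinom_xy_predict <- function(fit, X) {
  d <- as.data.frame(X[, -1, drop = FALSE])
  names(d) <- paste0("x", seq_len(ncol(d)))
  if (ncol(d) == 0L) d <- data.frame(row.names = seq_len(nrow(X)))
  predict(fit, d)
}

#' Rubin's-rule pooling of per-imputation estimates
#'
#' Combines \code{m} per-imputation point estimates and variances:
#' pooled point \eqn{\bar q} = mean of the points; within-imputation
#' variance \eqn{w} = mean of the variances; between-imputation variance
#' \eqn{b} = sample variance of the points; total variance
#' \eqn{t = w + (1 + 1/m)\,b}; degrees of freedom
#' \eqn{\nu = (m-1)\,(1 + w / ((1+1/m) b))^2} (infinite when \eqn{b = 0},
#' in which case the interval uses the normal quantile); 95\% interval
#' \eqn{\bar q \pm t_{0.975,\nu} \sqrt t}.
#'
#' @param points numeric vector of per-imputation point estimates
#'   (\code{m >= 2}).
#' @param variances numeric vector of per-imputation squared standard
#'   errors.
#' @return List of class \code{pooled_estimate}: \code{qbar}, \code{w},
#'   \code{b}, \code{t}, \code{se}, \code{df}, \code{ci95} (length-2),
#'   \code{m}.
#' @examples
#' rubin_pool(c(1, 2), c(0.5, 0.5))   # qbar 1.5, t 1.25
#' @export
rubin_pool <- function(points, variances) {
  m <- length(points)
  if (m < 2L) stop("Rubin pooling needs at least 2 imputations")
  stopifnot(length(variances) == m, all(variances >= 0), !anyNA(points))
  qbar <- mean(points)
  w <- mean(variances)
  b <- stats::var(points)
  t <- w + (1 + 1 / m) * b
  if (b > 0) {
    df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
    q <- stats::qt(0.975, df)
  } else {
    df <- Inf
    q <- stats::qnorm(0.975)
  }
  structure(list(qbar = qbar, w = w, b = b, t = t, se = sqrt(t), df = df,
                 ci95 = c(qbar - q * sqrt(t), qbar + q * sqrt(t)), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> %.3f (95%% CI %.3f, %.3f) m=%d\n",
              x$qbar, x$ci95[1], x$ci95[2], x$m))
  invisible(x)
}
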