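#' Fit a binary logit model by IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares, written for the decision-matrix setting where the outcome is
#' a deterministic function of the predictors and quasi-complete separation is
#' therefore expected rather than exceptional: coefficient magnitudes are
#' capped (default 25 on the linear-predictor scale), a `separation_warning`
#' is raised when the cap binds or fitted probabilities degenerate, and the
#' deviance/AIC at the capped solution are still reported.
#'
#' Conventions: the reported `deviance` is `-2 * logLik`; `aic = deviance +
#' 2 * (n_predictors + 1)` (the parameter count includes the intercept); the
#' likelihood-ratio chi-square compares against the intercept-only model with
#' `df = n_predictors`; classification accuracy cuts fitted probabilities at
#' 0.5.
#'
#' @param design Numeric matrix or data.frame of predictors (no intercept
#'   column; one is added internally).
#' @param outcome 0/1 vector (or logical), length `nrow(design)`.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the deviance change.
#' @param coef_cap Cap on |coefficient| (intercept included).
#' @return An object of class `logit_fit` with fields `predictor_names`,
#'   `coefficients` (slopes), `intercept`, `log_likelihood`, `deviance`,
#'   `null_deviance`, `aic`, `lr_chi2`, `lr_df`, `lr_p`, `pct_correct`,
#'   `converged`, `separation_warning`, `degenerate`, `fitted`, `n`.
#' @seealso [ascent_logit()] for a formula interface, [hosmer_lemeshow()],
#'   [subset_model_table()].
#' @export
fit_logit <- function(design, outcome, max_iter = 100L, tol = 1e-8,
                      coef_cap = 25) {
  design <- as.matrix(design)
  if (!is.numeric(design)) abort_input("`design` must be numeric")
  if (ncol(design) < 1L) abort_input("need at least one predictor")
  y <- as.numeric(outcome)
  if (length(y) != nrow(design)) {
    abort_input("`outcome` length must match rows of `design`")
  }
  if (!all(y %in% c(0, 1))) abort_input("`outcome` must be 0/1")
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  n <- length(y)
  k <- ncol(design)
  X <- cbind(`(Intercept)` = 1, design)

  eps <- 1e-12
  loglik <- function(p) sum(y * log(pmax(p, eps)) +
                              (1 - y) * log(pmax(1 - p, eps)))
  pbar <- mean(y)
  null_ll <- loglik(rep(pbar, n))
  null_dev <- -2 * null_ll

  degenerate <- pbar %in% c(0, 1)
  if (degenerate) {
    # one-class outcome: slopes unidentified; report the capped intercept-only
    # fit rather than erroring
    intercept <- sign(pbar - 0.5 + 1e-16) * coef_cap
    p <- rep(plogis(intercept), n)
    ll <- loglik(p)
    out <- new_logit_fit(
      predictor_names = colnames(design),
      coefficients = setNames(rep(0, k), colnames(design)),
      intercept = intercept, log_likelihood = ll,
      null_deviance = null_dev, lr_df = k,
      pct_correct = 100 * mean((p > 0.5) == y),
      converged = FALSE, separation_warning = TRUE, degenerate = TRUE,
      fitted = p, n = n, coef_cap = coef_cap
    )
    out$outcome_ <- y
    return(out)
  }

  beta <- c(log(pbar / (1 - pbar)), rep(0, k))
  dev_of <- function(b) -2 * loglik(plogis(drop(X %*% b)))
  dev_old <- dev_of(beta)
  converged <- FALSE
  capped <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    prop <- tryCatch(
      {
        XtW <- t(X * w)
        drop(solve(XtW %*% X, XtW %*% z))
      },
      error = function(e) NULL
    )
    if (is.null(prop)) break
    # step-halve so the deviance never increases (guards divergence under
    # near-separation)
    step <- 1
    beta_new <- prop
    dev_new <- dev_of(beta_new)
    halvings <- 0L
    while (dev_new > dev_old + 1e-12 && halvings < 30L) {
      step <- step / 2
      beta_new <- beta + step * (prop - beta)
      dev_new <- dev_of(beta_new)
      halvings <- halvings + 1L
    }
    if (dev_new > dev_old + 1e-12) break
    beta <- beta_new
    if (max(abs(beta)) > coef_cap) {
      # separation: the MLE diverges along a fixed direction. Rescaling the
      # whole vector (intercept included) onto the cap preserves the decision
      # boundary, so this is the reported capped solution.
      beta <- beta * (coef_cap / max(abs(beta)))
      capped <- TRUE
      dev_old <- dev_of(beta)
      break
    }
    if (abs(dev_old - dev_new) < tol) {
      converged <- TRUE
      dev_old <- dev_new
      break
    }
    dev_old <- dev_new
  }
  p <- plogis(drop(X %*% beta))
  sep <- capped || any(abs(beta) >= coef_cap - 1e-6) ||
    any(p > 1 - 1e-8) || any(p < 1e-8)
  if (sep && !capped && max(abs(beta)) > 0) {
    # perfectly separated data: the likelihood keeps improving along the
    # current direction, so the reported solution sits on the cap
    beta_up <- beta * (coef_cap / max(abs(beta)))
    if (dev_of(beta_up) <= dev_of(beta) + tol) {
      beta <- beta_up
      p <- plogis(drop(X %*% beta))
    }
  }
  ll <- loglik(p)
  out <- new_logit_fit(
    predictor_names = colnames(design),
    coefficients = setNames(beta[-1L], colnames(design)),
    intercept = unname(beta[1L]),
    log_likelihood = ll, null_deviance = null_dev, lr_df = k,
    pct_correct = 100 * mean((p > 0.5) == y),
    converged = converged, separation_warning = sep, degenerate = FALSE,
    fitted = p, n = n, coef_cap = coef_cap
  )
  out$outcome_ <- y
  out
}

new_logit_fit <- function(predictor_names, coefficients, intercept,
                          log_likelihood, null_deviance, lr_df, pct_correct,
                          converged, separation_warning, degenerate, fitted,
                          n, coef_cap) {
  deviance <- -2 * log_likelihood
  lr_chi2 <- max(null_deviance - deviance, 0)
  structure(
    list(predictor_names = predictor_names,
         coefficients = coefficients, intercept = intercept,
         log_likelihood = log_likelihood, deviance = deviance,
         null_deviance = null_deviance,
         aic = deviance + 2 * (length(coefficients) + 1),
         lr_chi2 = lr_chi2, lr_df = lr_df,
         lr_p = pchisq(lr_chi2, lr_df, lower.tail = FALSE),
         pct_correct = pct_correct,
         converged = converged, separation_warning = separation_warning,
         degenerate = degenerate, fitted = fitted, n = n,
         coef_cap = coef_cap),
    class = "logit_fit"
  )
}

#' Formula interface to the binary logit fit
#'
#' Builds the design matrix from a formula and data.frame (factors expanded
#' the usual way, intercept handled internally) and calls [fit_logit()].
#'
#' @param formula Model formula, e.g. `overall ~ tl_cm + boldness`.
#' @param data Data.frame containing the variables.
#' @param ... Passed to [fit_logit()].
#' @return A `logit_fit`.
#' @export
ascent_logit <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- fit_logit(X, y, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Binary logit fit (IRLS)\n")
  if (!is.null(x$call)) cat("  call:", deparse(x$call), "\n")
  cat("  coefficients:\n")
  print(round(coef(x), 4))
  cat(sprintf("  deviance %.3f on %d obs; AIC %.3f; LR chi2 %.3f (df %d, p %.3g)\n",
              x$deviance, x$n, x$aic, x$lr_chi2, x$lr_df, x$lr_p))
  cat(sprintf("  %.1f%% classified correctly at p = 0.5\n", x$pct_correct))
  if (x$degenerate) cat("  NOTE: one-class outcome; fit is degenerate\n")
  else if (x$separation_warning)
    cat("  NOTE: (quasi-)separation; coefficients at cap", x$coef_cap, "\n")
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
summary.logit_fit <- function(object, ...) {
  out <- object
  out$coef_table <- data.frame(
    estimate = coef(object),
    row.names = names(coef(object))
  )
  class(out) <- c("summary.logit_fit", "logit_fit")
  out
}

#' @export
print.summary.logit_fit <- function(x, ...) {
  print.logit_fit(x, ...)
  cat(sprintf("  logLik %.4f; null deviance %.3f; converged: %s\n",
              x$log_likelihood, x$null_deviance, x$converged))
  invisible(x)
}

#' Predict from a fitted logit model
#' @param object A `logit_fit`.
#' @param newdata Matrix or data.frame with the fitted predictors as columns;
#'   omitted returns fitted values.
#' @param type `"response"` (probability), `"link"` (linear predictor), or
#'   `"class"` (0/1 at 0.5).
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.logit_fit <- function(object, newdata = NULL,
                              type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- object$fitted
    eta <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  } else {
    newdata <- as.matrix(as.data.frame(newdata)[, object$predictor_names,
                                                drop = FALSE])
    eta <- drop(newdata %*% object$coefficients) + object$intercept
    p <- plogis(eta)
  }
  switch(type, response = p, link = eta, class = as.numeric(p > 0.5))
}

#' Simulate outcomes from a fitted logit model
#' @param object A `logit_fit`.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed.
#' @param ... Ignored.
#' @return Data.frame with `nsim` columns of 0/1 draws at the fitted
#'   probabilities.
#' @export
simulate.logit_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(
    replicate(nsim, rbinom(object$n, 1, object$fitted))
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.logit_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  # residuals need the observed outcome, recoverable from fitted + accuracy
  # only when stored; response residuals use the stored fitted values
  if (is.null(object$outcome_)) {
    stop("fit does not carry the outcome; refit with fit_logit() via ",
         "ascent_logit() on a data.frame to keep it", call. = FALSE)
  }
  y <- object$outcome_
  p <- object$fitted
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(pmax(p, 1e-12)) +
                             (1 - y) * log(pmax(1 - p, 1e-12))))
}

#' Hosmer–Lemeshow goodness-of-fit test
#'
#' Groups observations into deciles of predicted risk (equal-count groups by
#' sorted fitted probability), compares observed and expected event counts,
#' and refers `sum((O - E)^2 / (E * (1 - E/n_g)))` to a chi-square with
#' `n_groups - 2` degrees of freedom. Groups whose expected counts have zero
#' variance (all predicted probabilities 0 or 1) are merged into their
#' neighbor, with a message.
#'
#' @param p_hat Predicted probabilities.
#' @param outcome 0/1 outcomes, same length.
#' @param n_groups Number of risk groups (default 10).
#' @return Object of class `gof_result`: `statistic`, `df`, `p_value`,
#'   `group_table` (per group: `n`, `observed`, `expected`).
#' @export
hosmer_lemeshow <- function(p_hat, outcome, n_groups = 10L) {
  y <- as.numeric(outcome)
  if (length(p_hat) != length(y)) abort_input("lengths differ")
  n <- length(y)
  if (n < n_groups) abort_input("need at least `n_groups` observations")
  ord <- order(p_hat)
  group <- ceiling(seq_len(n) / n * n_groups)[order(ord)]  # equal-count groups
  tab <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    idx <- group == g
    data.frame(group = g, n = sum(idx), observed = sum(y[idx]),
               expected = sum(p_hat[idx]))
  }))
  # merge degenerate groups (zero expected variance) into the nearest neighbor
  merged <- 0L
  repeat {
    v <- tab$expected * (1 - tab$expected / tab$n)
    bad <- which(v <= 1e-12)
    if (length(bad) == 0L || nrow(tab) <= 2L) break
    i <- bad[1L]
    j <- if (i == 1L) 2L else i - 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, , drop = FALSE]
    merged <- merged + 1L
  }
  if (merged > 0L) {
    message("hosmer_lemeshow: merged ", merged,
            " degenerate risk group(s) into neighbors")
  }
  v <- tab$expected * (1 - tab$expected / tab$n)
  statistic <- sum((tab$observed - tab$expected)^2 / v)
  df <- nrow(tab) - 2L
  structure(
    list(statistic = statistic, df = df,
         p_value = pchisq(statistic, df, lower.tail = FALSE),
         group_table = tab, n_merged = merged),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3g (%d groups)\n",
              x$statistic, x$df, x$p_value, nrow(x$group_table)))
  invisible(x)
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman coefficients computed as the Pearson correlation of
#' average ranks (midranks for ties). Constant columns yield `NA` entries and
#' are reported in the `constant_columns` attribute rather than propagating
#' silently.
#'
#' @param columns Data.frame or named list of equal-length numeric vectors,
#'   n >= 3.
#' @return Correlation matrix with attribute `constant_columns`.
#' @export
spearman_matrix <- function(columns) {
  columns <- as.data.frame(columns)
  if (ncol(columns) < 2L) abort_input("need at least two columns")
  n <- nrow(columns)
  if (n < 3L) abort_input("need n >= 3")
  ranks <- lapply(columns, rank, ties.method = "average")
  constant <- vapply(columns, function(x) length(unique(x)) == 1L, logical(1))
  k <- ncol(columns)
  out <- matrix(NA_real_, k, k,
                dimnames = list(names(columns), names(columns)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        out[i, j] <- if (constant[i]) NA_real_ else 1
      } else if (!constant[i] && !constant[j]) {
        ri <- ranks[[i]] - mean(ranks[[i]])
        rj <- ranks[[j]] - mean(ranks[[j]])
        out[i, j] <- sum(ri * rj) / sqrt(sum(ri^2) * sum(rj^2))
      }
    }
  }
  if (any(constant)) {
    warning("constant column(s): ",
            paste(names(columns)[constant], collapse = ", "),
            "; entries set to NA", call. = FALSE)
  }
  attr(out, "constant_columns") <- names(columns)[constant]
  out
}

#' All-subset logit model-selection table
#'
#' Fits a logit model for every nonempty subset of the predictors (at most 12,
#' i.e. up to 4095 fits) and tabulates subset size (`df`), AIC,
#' likelihood-ratio chi-square against the intercept-only model, and its
#' p-value. Rows are ordered by subset size descending, then AIC ascending —
#' the conventional presentation for comparing nested families.
#'
#' @param design Predictor matrix/data.frame (named columns).
#' @param outcome 0/1 vector.
#' @param ... Passed to [fit_logit()].
#' @return Data.frame with columns `variables`, `df`, `deviance`, `aic`,
#'   `lr_chi2`, `p_value`, `converged`, `separation_warning`, `degenerate`.
#' @export
subset_model_table <- function(design, outcome, ...) {
  design <- as.matrix(design)
  k <- ncol(design)
  if (k > 12L) abort_input("at most 12 predictors (2^k - 1 fits)")
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(k))
  }
  rows <- list()
  for (size in seq_len(k)) {
    subsets <- combn(colnames(design), size, simplify = FALSE)
    for (vars in subsets) {
      fit <- fit_logit(design[, vars, drop = FALSE], outcome, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        variables = paste(vars, collapse = "+"),
        df = size, deviance = fit$deviance, aic = fit$aic,
        lr_chi2 = fit$lr_chi2,
        p_value = fit$lr_p, converged = fit$converged,
        separation_warning = fit$separation_warning,
        degenerate = fit$degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$df, out$aic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample moments and a symmetry check
#'
#' Sample skewness `m3 / m2^(3/2)` and excess kurtosis `m4 / m2^2 - 3`
#' (central-moment estimators), with the mean and median, used to check
#' whether the arithmetic mean is a defensible population summary before it
#' is promoted to a decision threshold. |skewness| > 1 flags the mean as
#' possibly unrepresentative of the center.
#'
#' @param values Numeric vector, n >= 4.
#' @return List of class `moment_check`: `mean`, `median`, `skewness`,
#'   `excess_kurtosis`, `n`, `flag` (character, `NA` if unflagged).
#' @export
moment_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) abort_input("need at least 4 non-missing values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  flag <- NA_character_
  if (m2 == 0) {
    skew <- NA_real_
    exkurt <- NA_real_
    flag <- "zero variance"
  } else {
    skew <- mean((values - m)^3) / m2^1.5
    exkurt <- mean((values - m)^4) / m2^2 - 3
    if (abs(skew) > 1) flag <- "mean may not represent center (|skewness| > 1)"
  }
  structure(
    list(mean = m, median = median(values), skewness = skew,
         excess_kurtosis = exkurt, n = n, flag = flag),
    class = "moment_check"
  )
}

#' @export
print.moment_check <- function(x, ...) {
  cat(sprintf("n = %d  mean %.4g  median %.4g  skewness %.3f  excess kurtosis %.3f\n",
              x$n, x$mean, x$median, x$skewness, x$excess_kurtosis))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Write Table-style statistical outputs
#'
#' Convenience writers for the correlation matrix and the subset model table.
#' @param corr Matrix from [spearman_matrix()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(corr, path) {
  write.csv(as.data.frame(corr), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @param table Data.frame from [subset_model_table()].
#' @export
write_subset_table_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
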