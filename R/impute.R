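#' Multiple imputation of independent variables by chained equations
#'
#' Fills missing values in the independent variables of a coded panel with
#' `m` stochastic completions. Each incomplete variable is visited in turn:
#' continuous variables are imputed by Bayesian linear regression on the
#' other predictors (coefficients and residual variance drawn from their
#' posterior, imputations drawn with residual noise); binary variables by
#' logistic regression with a large-sample normal draw of the coefficients.
#' The outcome is never imputed; rows with a missing outcome are excluded
#' from the imputation model with a warning.
#'
#' @param coded a `coded_panel` (missingness allowed only in independent
#'   variables).
#' @param m number of completed datasets.
#' @param seed RNG seed.
#' @param maxit chained-equation sweeps per completion.
#' @param outcome outcome column name (excluded from imputation).
#' @return list of `m` completed `coded_panel` data frames.
#' @export
impute_missing <- function(coded, m = 5, seed = 1L, maxit = 5,
                           outcome = "dalys") {
  set.seed(seed)
  d <- as.data.frame(coded)
  if (outcome %in% names(d) && anyNA(d[[outcome]])) {
    warning("outcome contains missing values; those rows are excluded ",
            "from the imputation models and the outcome is not imputed")
  }
  id_cols <- c("person_id", "wave_year", "birth_year", "age")
  num_ok <- vapply(d, is.numeric, logical(1))
  pred_cols <- setdiff(names(d)[num_ok], c(outcome, id_cols))
  target <- pred_cols[vapply(pred_cols, function(v) anyNA(d[[v]]), logical(1))]
  if (!length(target)) {
    return(replicate(m, {
      out <- coded
      out
    }, simplify = FALSE))
  }

  is_binary <- vapply(target, function(v) {
    u <- unique(d[[v]][!is.na(d[[v]])])
    all(u %in% c(0, 1))
  }, logical(1))

  lapply(seq_len(m), function(rep) {
    dd <- d
    # mean / mode initialization
    for (v in target) {
      miss <- is.na(dd[[v]])
      fill <- if (is_binary[v]) round(mean(dd[[v]], na.rm = TRUE))
              else mean(dd[[v]], na.rm = TRUE)
      dd[[v]][miss] <- fill
    }
    for (it in seq_len(maxit)) {
      for (v in target) {
        miss <- is.na(d[[v]])
        rhs <- setdiff(pred_cols, v)
        Xmat <- as.matrix(dd[rhs])
        keep_col <- apply(Xmat, 2, function(col) stats::sd(col) > 0)
        Xmat <- cbind(1, Xmat[, keep_col, drop = FALSE])
        # drop exactly collinear columns (e.g. complementary dummies)
        qd <- qr(Xmat)
        if (qd$rank < ncol(Xmat))
          Xmat <- Xmat[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
        obs <- !miss
        if (is_binary[v]) {
          fit <- suppressWarnings(
            glm.fit(Xmat[obs, , drop = FALSE], d[[v]][obs],
                    family = binomial()))
          cf <- coef(fit)
          cf[is.na(cf)] <- 0
          # large-sample draw around the MLE
          vc <- tryCatch(chol2inv(chol(crossprod(
            Xmat[obs, , drop = FALSE] *
              sqrt(fit$weights)))), error = function(e) NULL)
          if (!is.null(vc))
            cf <- cf + as.numeric(chol(vc + 1e-12 * diag(ncol(Xmat))) %*%
                                    rnorm(ncol(Xmat)))
          pr <- plogis(as.numeric(Xmat[miss, , drop = FALSE] %*% cf))
          dd[[v]][miss] <- rbinom(sum(miss), 1, pr)
        } else {
          xo <- Xmat[obs, , drop = FALSE]
          yo <- d[[v]][obs]
          qr_x <- qr(xo)
          bhat <- qr.coef(qr_x, yo)
          bhat[is.na(bhat)] <- 0
          res <- yo - as.numeric(xo %*% bhat)
          df <- max(length(yo) - qr_x$rank, 1)
          s2 <- sum(res^2) / rchisq(1, df)   # posterior draw of sigma^2
          XtXinv <- tryCatch(chol2inv(qr.R(qr_x)), error = function(e) NULL)
          bstar <- if (!is.null(XtXinv)) {
            bhat + as.numeric(chol(s2 * (XtXinv + 1e-12 * diag(ncol(xo)))) %*%
                                rnorm(ncol(xo)))
          } else bhat
          dd[[v]][miss] <- as.numeric(Xmat[miss, , drop = FALSE] %*% bstar) +
            rnorm(sum(miss), 0, sqrt(s2))
        }
      }
    }
    attr(dd, "codebook") <- attr(coded, "codebook")
    class(dd) <- class(coded)
    dd
  })
}

#' Pool growth-model fits across imputations by Rubin's rules
#'
#' Point estimates are the mean over imputations; total variance combines
#' the within-imputation variance with the between-imputation variance
#' inflated by `(1 + 1/m)`. Degrees of freedom follow the classic
#' Rubin (1987) formula; with `m = 1` pooling returns the single fit's
#' estimates unchanged.
#'
#' @param fits list of `growth_fit` objects from the `m` completed panels.
#' @return data frame (term, estimate, se, ci_lo, ci_hi, p, df).
#' @export
pool_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  m <- length(fits)
  terms <- fits[[1]]$fixed_effects$term
  est <- sapply(fits, function(f) f$fixed_effects$estimate)
  ses <- sapply(fits, function(f) f$fixed_effects$se)
  if (m == 1) {
    fe <- fits[[1]]$fixed_effects
    fe$df <- Inf
    return(fe)
  }
  est <- matrix(est, ncol = m)
  ses <- matrix(ses, ncol = m)
  qbar <- rowMeans(est)
  ubar <- rowMeans(ses^2)
  b <- apply(est, 1, var)
  tvar <- ubar + (1 + 1 / m) * b
  se <- sqrt(tvar)
  r <- (1 + 1 / m) * b / ubar
  df <- ifelse(b > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  half <- qt(0.975, df) * se
  data.frame(term = terms, estimate = qbar, se = se,
             ci_lo = qbar - half, ci_hi = qbar + half,
             p = 2 * pt(-abs(qbar / se), df), df = df,
             stringsAsFactors = FALSE)
}
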