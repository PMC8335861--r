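# Maximum-likelihood estimation of the two-level growth model.
#
# The random-effect covariance is parameterized through its relative
# Cholesky factor Lambda (Sigma = sigma^2 Lambda Lambda'), which keeps the
# estimate positive semi-definite by construction; beta and sigma^2 are
# profiled out in compiled code, and nlminb minimizes the profiled deviance
# over Lambda from several starting points.

theta_diag_idx <- function(q) {
  idx <- integer(q)
  k <- 1L
  for (j in seq_len(q)) {
    idx[j] <- k
    k <- k + (q - j + 1L)
  }
  idx
}

default_theta_starts <- function(q) {
  nt <- q * (q + 1L) / 2L
  di <- theta_diag_idx(q)
  mk <- function(diag_val) {
    th <- rep(0, nt)
    th[di] <- diag_val
    th
  }
  list(mk(1), mk(0.1), mk(5))
}

#' Fit the hierarchical growth-curve model
#'
#' Estimates the two-level linear mixed model implied by the quadratic
#' growth specification: fixed effects for the intercept, centered age, its
#' square and all configured moderator products, a person-level random
#' intercept and age slope (optionally also a random curvature), and an
#' i.i.d. Gaussian residual. Estimation maximizes the profiled (restricted)
#' likelihood; the default is full ML so -2LL/AIC/BIC comparisons across
#' fixed-effect sets are coherent. Wald standard errors, 95% confidence
#' intervals and large-sample z p-values are reported for the fixed
#' effects; variance-component standard errors come from the observed
#' information (numerical Hessian of -2LL in the variance parameters).
#'
#' @param coded a `coded_panel`, or a prebuilt design list from
#'   [build_design()].
#' @param spec a [growth_spec()] (ignored when `coded` is a design list).
#' @param starts list of starting vectors for the relative Cholesky factor;
#'   defaults to three spread starting points.
#' @param se_random compute variance-component standard errors (numerical
#'   Hessian; skip for speed in large simulation loops).
#' @param reltol relative convergence tolerance on the profiled deviance.
#' @return a `growth_fit` with elements `fixed_effects` (term, estimate,
#'   se, ci_lo, ci_hi, p), `random_cov`, `random_se`, `residual_var`,
#'   `residual_se`, `neg2ll`, `aic`, `bic`, `n_obs`, `n_persons`,
#'   `converged`, `boundary`, `gradient_norm` and metadata (`estimation`,
#'   `param_count_convention`).
#' @export
fit_growth <- function(coded, spec = growth_spec(), starts = NULL,
                       se_random = TRUE, reltol = 1e-10) {
  des <- if (is.list(coded) && !is.data.frame(coded) && !is.null(coded$X)) coded
         else build_design(coded, spec)
  spec <- des$spec
  y <- des$y
  X <- des$X
  Z <- des$Z
  p <- ncol(X)
  q <- ncol(Z)
  n <- length(y)
  J <- length(des$persons)
  reml <- spec$estimation == "REML"
  if (mean(des$grp_len >= 2) < 0.1)
    warning("fewer than 10% of persons have repeated measures; ",
            "variance components may be weakly identified")

  xp <- .lmm_precompute_cpp(y, X, Z, des$grp_start, des$grp_len)
  obj <- function(th) {
    r <- .lmm_profile_cpp(xp, th, reml)
    if (isTRUE(r$singular)) return(1e10)
    r$deviance
  }
  nt <- q * (q + 1L) / 2L
  lower <- rep(-Inf, nt)
  lower[theta_diag_idx(q)] <- 0
  if (is.null(starts)) starts <- default_theta_starts(q)

  best <- NULL
  for (th0 in starts) {
    opt <- nlminb(th0, obj, lower = lower,
                  control = list(iter.max = 1000, eval.max = 2000,
                                 rel.tol = reltol))
    if (is.null(best) || opt$objective < best$objective - 1e-10) best <- opt
  }
  # polish from the winner
  opt <- nlminb(best$par, obj, lower = lower,
                control = list(iter.max = 1000, eval.max = 2000,
                               rel.tol = reltol))
  if (opt$objective > best$objective) opt <- best
  theta <- opt$par

  prof <- .lmm_profile_cpp(xp, theta, reml)
  beta <- as.numeric(prof$beta)
  sigma2 <- prof$sigma2
  Lam <- matrix(0, q, q)
  Lam[lower.tri(Lam, diag = TRUE)] <- theta
  Sigma <- sigma2 * (Lam %*% t(Lam))
  rn <- colnames(Z)
  dimnames(Sigma) <- list(rn, rn)

  vcov_beta <- sigma2 * solve(prof$XtWX)
  se <- sqrt(diag(vcov_beta))
  zval <- beta / se
  ci_half <- qnorm(0.975) * se
  fixed <- data.frame(term = colnames(X), estimate = beta, se = se,
                      ci_lo = beta - ci_half, ci_hi = beta + ci_half,
                      p = 2 * pnorm(-abs(zval)), stringsAsFactors = FALSE)

  # numerical gradient of the profiled deviance at the solution
  gr <- vapply(seq_len(nt), function(k) {
    h <- max(1e-6, abs(theta[k]) * 1e-6)
    thp <- theta; thp[k] <- thp[k] + h
    thm <- theta; thm[k] <- max(thm[k] - h, if (k %in% theta_diag_idx(q)) 0 else -Inf)
    (obj(thp) - obj(thm)) / (thp[k] - thm[k])
  }, numeric(1))
  boundary <- any(theta[theta_diag_idx(q)] < 1e-6)

  neg2ll <- if (reml) opt$objective else opt$objective
  k_par <- p + nt + 1L  # fixed effects + covariance parameters + residual
  aic <- neg2ll + 2 * k_par
  bic <- neg2ll + log(n) * k_par

  random_se <- NULL
  resid_se <- NA_real_
  if (se_random && !reml) {
    vp <- c(Sigma[lower.tri(Sigma, diag = TRUE)], sigma2)
    hess <- num_hessian(function(par) {
      S <- matrix(0, q, q)
      S[lower.tri(S, diag = TRUE)] <- par[seq_len(nt)]
      S <- S + t(S) - diag(diag(S), q)
      .lmm_neg2ll_at_cpp(xp, S, par[nt + 1L])
    }, vp)
    vc <- tryCatch(2 * solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      ses <- sqrt(diag(vc))
      Sse <- matrix(NA_real_, q, q, dimnames = list(rn, rn))
      Sse[lower.tri(Sse, diag = TRUE)] <- ses[seq_len(nt)]
      Sse[upper.tri(Sse)] <- t(Sse)[upper.tri(Sse)]
      random_se <- Sse
      resid_se <- ses[nt + 1L]
    }
  }

  # nlminb occasionally reports "false convergence" when restarted at the
  # optimum; accept the solution when the numerical gradient has vanished
  converged <- opt$convergence == 0 || sqrt(sum(gr^2)) < 0.1

  fit <- list(fixed_effects = fixed, vcov_fixed = vcov_beta,
              random_cov = Sigma, random_se = random_se,
              residual_var = sigma2, residual_se = resid_se,
              theta = theta, neg2ll = neg2ll, aic = aic, bic = bic,
              n_obs = n, n_persons = J,
              converged = converged, boundary = boundary,
              gradient_norm = sqrt(sum(gr^2)),
              estimation = spec$estimation,
              param_count_convention =
                "fixed effects + random-covariance parameters + residual variance",
              ci_method = "Wald, large-sample z",
              spec = spec,
              outcome_checksum = signif(sum(y) + sum(y^2), 12))
  class(fit) <- "growth_fit"
  fit
}

num_hessian <- function(f, x, rel_h = 1e-4) {
  n <- length(x)
  h <- pmax(abs(x) * rel_h, 1e-7)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Two-level growth-curve model (", x$estimation, ")\n", sep = "")
  cat(sprintf("  %d observations, %d persons%s\n", x$n_obs, x$n_persons,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat("\nFixed effects:\n")
  fe <- x$fixed_effects
  fe_print <- data.frame(term = fe$term,
                         estimate = signif(fe$estimate, digits),
                         ci = sprintf("(%s, %s)", signif(fe$ci_lo, digits),
                                      signif(fe$ci_hi, digits)),
                         p = format.pval(fe$p, digits = 3, eps = 1e-4))
  print(fe_print, row.names = FALSE)
  cat("\nRandom effects:\n")
  cat(sprintf("  Intercept variance %.4g", x$random_cov[1, 1]))
  if (!is.null(x$random_se)) cat(sprintf(" (%.3g)", x$random_se[1, 1]))
  cat("\n")
  if (nrow(x$random_cov) >= 2) {
    cat(sprintf("  Slope variance     %.4g", x$random_cov[2, 2]))
    if (!is.null(x$random_se)) cat(sprintf(" (%.3g)", x$random_se[2, 2]))
    cat("\n")
    cat(sprintf("  Co-variance        %.4g", x$random_cov[2, 1]))
    if (!is.null(x$random_se)) cat(sprintf(" (%.3g)", x$random_se[2, 1]))
    cat("\n")
  }
  cat(sprintf("  Residual           %.4g", x$residual_var))
  if (!is.na(x$residual_se)) cat(sprintf(" (%.3g)", x$residual_se))
  cat("\n")
  cat(sprintf("\n-2LL %.1f   AIC %.1f   BIC %.1f\n", x$neg2ll, x$aic, x$bic))
  invisible(x)
}

#' Export a fit as a CSV coefficient table
#'
#' Writes the fixed-effect table (term, estimate, SE, CI bounds, p) followed
#' by the random-effect variances and fit statistics, mirroring the layout
#' of published growth-model tables.
#'
#' @param fit a `growth_fit`.
#' @param path output file.
#' @export
write_fit_csv <- function(fit, path) {
  fe <- fit$fixed_effects
  extra <- data.frame(
    term = c("var_intercept", "var_slope", "covariance", "residual",
             "neg2ll", "aic", "bic"),
    estimate = c(fit$random_cov[1, 1],
                 if (nrow(fit$random_cov) >= 2) fit$random_cov[2, 2] else NA,
                 if (nrow(fit$random_cov) >= 2) fit$random_cov[2, 1] else NA,
                 fit$residual_var, fit$neg2ll, fit$aic, fit$bic),
    se = c(if (!is.null(fit$random_se)) fit$random_se[1, 1] else NA,
           if (!is.null(fit$random_se) && nrow(fit$random_cov) >= 2)
             fit$random_se[2, 2] else NA,
           if (!is.null(fit$random_se) && nrow(fit$random_cov) >= 2)
             fit$random_se[2, 1] else NA,
           fit$residual_se, NA, NA, NA),
    ci_lo = NA, ci_hi = NA, p = NA)
  write.csv(rbind(fe, extra), path, row.names = FALSE)
  invisible(path)
}

#' Compare nested growth-model fits by information criteria
#'
#' Tabulates -2LL, AIC and BIC (and their deltas against the best model per
#' criterion) for a set of fits of the same data, and names the preferred
#' model under each criterion. Refuses to compare REML fits whose
#' fixed-effect sets differ, since the restricted likelihood is not
#' comparable across mean structures.
#'
#' @param fits named list of `growth_fit` objects.
#' @return data frame with one row per model.
#' @export
compare_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  est <- vapply(fits, function(f) f$estimation, character(1))
  nobs <- vapply(fits, function(f) f$n_obs, numeric(1))
  chk <- vapply(fits, function(f) f$outcome_checksum, numeric(1))
  if (length(unique(nobs)) != 1 || length(unique(chk)) != 1)
    stop("fits were not estimated on the same data")
  terms <- lapply(fits, function(f) sort(f$fixed_effects$term))
  same_fixed <- all(vapply(terms, identical, logical(1), terms[[1]]))
  if (any(est == "REML") && !same_fixed)
    stop("REML fits with different fixed-effect sets cannot be compared by ",
         "likelihood; refit with ML")
  out <- data.frame(
    model = names(fits),
    neg2ll = vapply(fits, function(f) f$neg2ll, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    row.names = NULL)
  out$delta_neg2ll <- out$neg2ll - min(out$neg2ll)
  out$delta_aic <- out$aic - min(out$aic)
  out$delta_bic <- out$bic - min(out$bic)
  out$preferred_aic <- out$aic == min(out$aic)
  out$preferred_bic <- out$bic == min(out$bic)
  out
}
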