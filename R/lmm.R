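#' Fit a linear mixed model with random intercept (and optionally slope)
#'
#' Maximum-likelihood fit of one of two nested models for a longitudinal
#' response \eqn{y_{it}}:
#' \describe{
#'   \item{`intercept_only` (model 1)}{\eqn{y_{it} = x_{it}'\beta + b_{0i} + e_{it}}}
#'   \item{`intercept_slope` (model 2)}{\eqn{y_{it} = x_{it}'\beta + b_{0i} +
#'     b_{1i}\,a_{it} + e_{it}}}
#' }
#' where \eqn{a_{it}} is centred age, \eqn{(b_{0i}, b_{1i})} is bivariate
#' normal with free covariance \eqn{\Psi}, and \eqn{e_{it} \sim N(0,
#' \sigma_e^2)}. The fixed effects and residual variance are profiled out of
#' the marginal Gaussian likelihood; the relative covariance factor
#' (Cholesky-parameterised, diagonal bounded at zero so the no-slope-variance
#' boundary is attainable) is optimised numerically. The `intercept_slope`
#' fit is always started from the `intercept_only` solution with the slope
#' block at the boundary, so its log-likelihood can never fall below model
#' 1's beyond numerical noise.
#'
#' Per-subject best linear unbiased predictors (BLUPs) of the random effects
#' are returned; under `intercept_slope`, `blups$b1` is the subject-specific
#' deviation of the methylation (or phenotype) change rate, in response units
#' per year.
#'
#' @param design a [longitudinal_design()].
#' @param response numeric vector aligned with `design$data` rows.
#' @param model_kind `"intercept_slope"` or `"intercept_only"`.
#' @param reml use the REML criterion instead of ML. ML is the default and is
#'   what model comparison (likelihood-ratio, AIC) uses, since the two models
#'   share fixed effects.
#' @param init optional starting value for the relative covariance factor of
#'   the intercept block (skips the internal model-1 pre-fit).
#' @return An object of class `lmm_fit` with elements `beta`, `se`, `sigma2`,
#'   `Psi`, `logLik`, `AIC`, `k` (free parameters), `blups`, `converged`.
#' @examples
#' sheet <- data.frame(
#'   sample_id = paste0("s", 1:9), subject_id = rep(c("a", "b", "c"), each = 3),
#'   age = rep(c(70, 72.5, 75), 3), sex = rep(c(0, 1, 0), each = 3)
#' )
#' d <- longitudinal_design(sheet, covariates = "sex")
#' y <- 0.5 + 0.002 * (sheet$age - mean(sheet$age)) + rnorm(9, sd = 0.01)
#' fit <- fit_lmm(d, y, "intercept_slope")
#' fit$beta[["age"]]
#' @export
fit_lmm <- function(design, response,
                    model_kind = c("intercept_slope", "intercept_only"),
                    reml = FALSE, init = NULL) {
  stopifnot(inherits(design, "longitudinal_design"))
  model_kind <- match.arg(model_kind)
  y <- as.numeric(response)
  if (length(y) != design$n) {
    stop("response length (", length(y), ") does not match design rows (",
         design$n, ")")
  }
  if (anyNA(y) || !all(is.finite(y))) stop("response contains missing/non-finite values")
  if (model_kind == "intercept_slope") {
    n_per <- design$ends0 - design$starts0 + 1L
    if (sum(n_per >= 2L) < 2L) {
      stop("intercept_slope requires at least 2 subjects with >= 2 observations")
    }
  }

  prob <- lmm_problem_cpp(design$X, design$Z, y, design$starts0, design$ends0)
  p <- ncol(design$X)

  dev1 <- function(th) lmm_deviance_cpp(th, prob, reml)

  fit_m1 <- function() {
    opt <- stats::optimize(dev1, interval = c(0, 50), tol = 1e-7)
    # widen if the optimum sits at the upper end (tiny residual variance)
    if (opt$minimum > 45) {
      opt2 <- stats::optimize(dev1, interval = c(40, 1e4), tol = 1e-5)
      if (opt2$objective < opt$objective) opt <- opt2
    }
    opt
  }

  if (model_kind == "intercept_only") {
    opt <- fit_m1()
    theta <- opt$minimum
    det <- lmm_details_cpp(theta, prob, reml)
    k_var <- 2L
    converged <- TRUE
  } else {
    th1 <- if (is.null(init)) fit_m1()$minimum else init[1]
    dev2 <- function(th) lmm_deviance_cpp(th, prob, reml)
    lower <- c(0, -1e5, 0)
    upper <- c(1e5, 1e5, 1e5)
    o <- stats::optim(c(th1, 0, 0), dev2, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 500, factr = 1e8))
    if (o$convergence != 0) {
      # restart once from a perturbed interior point
      o2 <- stats::optim(c(max(0.5, 0.7 * th1), 0, 0.5), dev2,
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = 500, factr = 1e8))
      if (o2$value < o$value) o <- o2
    }
    theta <- o$par
    converged <- o$convergence == 0
    det <- lmm_details_cpp(theta, prob, reml)
    k_var <- 4L
  }

  beta <- drop(det$beta)
  names(beta) <- colnames(design$X)
  se <- sqrt(pmax(diag(det$vcov), 0))
  names(se) <- colnames(design$X)
  ll <- det$loglik
  k <- p + k_var
  q <- if (model_kind == "intercept_only") 1L else 2L
  blups <- data.frame(subject_id = design$subjects,
                      b0 = det$blups[, 1],
                      stringsAsFactors = FALSE)
  if (q == 2L) blups$b1 <- det$blups[, 2]
  Psi <- det$Psi
  dn <- c("(Intercept)", "age")[seq_len(q)]
  dimnames(Psi) <- list(dn, dn)

  structure(list(
    model_kind = model_kind, beta = beta, se = se,
    sigma2 = det$sigma2, Psi = Psi, theta = theta,
    logLik = ll, AIC = 2 * k - 2 * ll, k = k, p_fixed = p,
    blups = blups, converged = converged, reml = reml,
    n = design$n, n_subjects = design$n_subjects,
    design_fingerprint = c(design$n, p, sum(abs(design$X)))
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("linear mixed model (", x$model_kind, if (x$reml) ", REML" else ", ML",
      ")\n", sep = "")
  cat("  logLik", format(x$logLik), " AIC", format(x$AIC), "\n")
  cat("  beta[age] =", format(x$beta[["age"]]),
      "(se", format(x$se[["age"]]), ")\n")
  cat("  sigma_e^2 =", format(x$sigma2), "\n")
  invisible(x)
}

#' Boundary likelihood-ratio test for the random slope
#'
#' Compares the random-intercept model (model 1) against the
#' random-intercept + random-slope model (model 2). The null hypothesis pins
#' the slope variance to zero (a boundary) together with the
#' intercept--slope covariance, so the likelihood-ratio statistic
#' \eqn{\Lambda = 2(\ell_2 - \ell_1)} is referred to the mixture
#' \eqn{0.5\chi^2_1 + 0.5\chi^2_2} rather than a plain chi-square.
#' The AIC difference \eqn{AIC_1 - AIC_2} is recorded so that a
#' best-model-by-AIC criterion can be applied instead.
#'
#' @param fit1 an `intercept_only` [fit_lmm()] result.
#' @param fit2 an `intercept_slope` fit on the same data and fixed effects.
#' @return list with `lambda` (clipped at 0), `p_value` (mixture tail),
#'   `delta_aic` (AIC1 - AIC2), `criterion`, and `refit` flag set when the
#'   raw statistic is negative beyond tolerance.
#' @export
lrt_random_slope <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "lmm_fit"), inherits(fit2, "lmm_fit"))
  if (fit1$model_kind != "intercept_only" || fit2$model_kind != "intercept_slope") {
    stop("fit1 must be intercept_only and fit2 intercept_slope")
  }
  if (!isTRUE(all.equal(fit1$design_fingerprint, fit2$design_fingerprint,
                        tolerance = 1e-8))) {
    stop("mismatched designs between fit1 and fit2")
  }
  raw <- 2 * (fit2$logLik - fit1$logLik)
  refit <- raw < -1e-6
  lambda <- max(0, raw)
  p <- 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(lambda, df = 2, lower.tail = FALSE)
  list(lambda = lambda, p_value = p, delta_aic = fit1$AIC - fit2$AIC,
       criterion = "lrt_mixture", refit = refit)
}

#' Wald test for the fixed age effect
#'
#' Two-sided p-value for \eqn{H_0: \beta_{age} = 0} from
#' \eqn{z = \hat\beta_{age} / SE(\hat\beta_{age})} against the standard
#' normal (large-sample reference; no small-sample df correction).
#'
#' @param fit an [fit_lmm()] result.
#' @return two-sided p-value.
#' @export
wald_age_p <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  se <- fit$se[["age"]]
  if (!is.finite(se) || se <= 0) stop("degenerate fit: zero standard error for age")
  z <- fit$beta[["age"]] / se
  2 * stats::pnorm(-abs(z))
}
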