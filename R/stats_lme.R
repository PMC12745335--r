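## Mixed-effects models for regional growth-rate prediction.
##
## The regional model is GR_im = b0 + b1 x_im + b0m + b1m x_im + eps_im,
## with fixed intercept/slope (b0, b1), independent per-patient random
## intercepts and slopes (diagonal covariance: the reported quantities are
## separate SDs with separate CIs, no correlation parameter), and i.i.d.
## residuals. Estimation is maximum likelihood via lme4; inference on the
## fixed slope uses an F-test (F = t^2) with Satterthwaite denominator
## degrees of freedom by default -- with 9 patients the residual-df
## approximation is badly anticonservative when random-slope variance is
## present -- with the residual-df convention available as an option.

#' Fit the random-slope mixed-effects growth model
#'
#' @param x predictor per region (stress kPa, WSS Pa, pressure mmHg, or a
#'   0/1 thrombus indicator).
#' @param y response per region (growth rate %/year, or stress for the
#'   thrombus-stress model).
#' @param patient_ids patient identifier per observation.
#' @param quadratic add a fixed quadratic term beta2 x^2.
#' @param covariate optional additional fixed covariate (e.g. follow-up
#'   years per observation).
#' @param sd_ci compute profile-likelihood 95% CIs for the random-effect
#'   SDs (slower; off by default).
#' @param df denominator-df method for the slope test.
#' @return object of class `growth_lme`: fixed effects with Wald-t 95%
#'   CIs, random-effect SDs (with optional profile CIs), per-patient BLUPs,
#'   sigma, logLik/AIC/BIC, F-test of the fixed slope, the fixed-effects-only
#'   least-squares fit, and a singular-fit flag (an SD estimated at the
#'   boundary, reported as 0).
#' @export
fit_lme <- function(x, y, patient_ids, quadratic = FALSE, covariate = NULL,
                    sd_ci = FALSE, df = c("satterthwaite", "residual")) {
  df <- match.arg(df)
  keep <- is.finite(x) & is.finite(y) & !is.na(patient_ids)
  if (!is.null(covariate)) keep <- keep & is.finite(covariate)
  d <- data.frame(x = x[keep], y = y[keep],
                  pid = factor(patient_ids[keep]))
  if (!is.null(covariate)) d$cov <- covariate[keep]
  if (nlevels(d$pid) < 2) stop("need at least 2 patients")
  if (length(unique(d$x)) < 2) stop("need at least 2 distinct x values")

  rhs <- "x + (1 | pid) + (0 + x | pid)"
  if (quadratic) rhs <- paste("x + I(x^2) +", sub("^x \\+ ", "", rhs))
  if (!is.null(covariate)) rhs <- paste("cov +", rhs)
  form <- as.formula(paste("y ~", rhs))

  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d, REML = FALSE,
                   control = lme4::lmerControl(
                     optimizer = "bobyqa",
                     check.conv.singular = "ignore")),
    warning = function(w) {
      ## estimation diagnostics that do not affect the reported estimates:
      ## convergence chatter at boundary fits and the predictor-scaling
      ## hint (kPa-scale predictors are fine for the profiled deviance)
      if (grepl("converge|Hessian|boundary|scale", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit, tol = 1e-5)

  sm <- summary(fit)
  ct <- coef(sm)  # Estimate, SE, df (Satterthwaite), t, p
  slope_row <- "x"
  n_obs <- nrow(d); n_grp <- nlevels(d$pid)
  n_fixed <- nrow(ct)
  df_resid <- as.integer(n_obs - n_fixed - 2L * n_grp)
  tdf <- if (df == "satterthwaite") ct[, "df"] else rep(df_resid, n_fixed)
  ci <- cbind(lower = ct[, "Estimate"] - qt(0.975, tdf) * ct[, "Std. Error"],
              upper = ct[, "Estimate"] + qt(0.975, tdf) * ct[, "Std. Error"])

  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_b0 <- vc$sdcor[vc$grp == "pid" & vc$var1 == "(Intercept)"]
  sd_b1 <- vc$sdcor[vc$grp == "pid.1" & vc$var1 == "x"]
  if (length(sd_b1) == 0)
    sd_b1 <- vc$sdcor[vc$grp != "Residual" & vc$var1 == "x"]
  sigma_eps <- vc$sdcor[vc$grp == "Residual"]

  sd_ci_tab <- NULL
  if (sd_ci) {
    sd_ci_tab <- tryCatch(
      suppressWarnings(confint(fit, parm = "theta_", method = "profile",
                               quiet = TRUE)),
      error = function(e) NULL)
  }

  re <- lme4::ranef(fit)
  blup <- data.frame(patient = rownames(re$pid),
                     b0 = re$pid[, "(Intercept)"])
  b1col <- grep("^x$", colnames(re[[which(names(re) != "pid")[1] %||% 1]]))
  blup$b1 <- tryCatch({
    other <- re[[setdiff(seq_along(re), which(names(re) == "pid"))[1]]]
    if (!is.null(other) && "x" %in% colnames(other)) other[rownames(re$pid), "x"]
    else if ("x" %in% colnames(re$pid)) re$pid[, "x"] else 0
  }, error = function(e) 0)

  ## fixed-effects-only comparison fit
  ols_form <- as.formula(paste("y ~", sub(" \\+ \\(1.*$", "", rhs)))
  ols <- lm(ols_form, data = d)
  ols_ci <- confint(ols)

  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  out <- structure(list(
    beta = data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"], df = tdf,
                      lower = ci[, "lower"], upper = ci[, "upper"],
                      row.names = NULL),
    sd_b0 = if (length(sd_b0)) sd_b0 else 0,
    sd_b1 = if (length(sd_b1)) sd_b1 else 0,
    sd_eps = sigma_eps,
    sd_ci = sd_ci_tab,
    blup = blup,
    logLik = ll, AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n_obs),
    n_obs = n_obs, n_patients = n_grp, df_method = df,
    df_residual = df_resid,
    singular = singular,
    fixed_only = list(beta = coef(ols), ci = ols_ci,
                      p_slope = suppressWarnings(
                        summary(ols)$coefficients["x", 4])),
    model = fit), class = "growth_lme")
  ft <- ftest_fixed_slope(out)
  out$F <- ft$F; out$p <- ft$p; out$df2 <- ft$df2
  out
}

#' F-test of the fixed-effect slope
#'
#' Tests H0: beta1 = 0 with F = (beta1 / SE)^2; denominator df are
#' Satterthwaite (default, from the fit) or the residual-df convention
#' n_obs - n_fixed - n_groups * n_random.
#'
#' @param fit a `growth_lme`.
#' @param df override the df method of the fit.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
ftest_fixed_slope <- function(fit, df = NULL) {
  b <- fit$beta[fit$beta$term == "x", ]
  if (nrow(b) == 0) stop("no slope term in the fit")
  if (b$se <= 0) stop("zero standard error")
  df2 <- if (identical(df, "residual") ||
             (is.null(df) && fit$df_method == "residual"))
    fit$df_residual else b$df
  Fv <- (b$estimate / b$se)^2
  list(F = Fv, df1 = 1, df2 = df2, p = pf(Fv, 1, df2, lower.tail = FALSE))
}

#' @export
print.growth_lme <- function(x, ...) {
  b <- x$beta[x$beta$term == "x", ]
  cat(sprintf("growth_lme: beta1 = %.4g [%.4g, %.4g], F = %.3g, p = %.4g (%s df)\n",
              b$estimate, b$lower, b$upper, x$F, x$p, x$df_method))
  cat(sprintf("  random-effect SDs: intercept %.4g, slope %.4g, residual %.4g%s\n",
              x$sd_b0, x$sd_b1, x$sd_eps,
              if (x$singular) "  [boundary fit: an SD is ~0]" else ""))
  cat(sprintf("  logLik %.2f, AIC %.1f, BIC %.1f, n = %d obs / %d patients\n",
              x$logLik, x$AIC, x$BIC, x$n_obs, x$n_patients))
  invisible(x)
}

#' Per-patient Pearson correlation
#'
#' @param x,y observation vectors; `patient_ids` grouping.
#' @return data frame with patient, n, r, p (two-sided, t-based);
#'   zero-variance patients get `NA` with `degenerate = TRUE`.
#' @export
pearson_by_patient <- function(x, y, patient_ids) {
  ids <- unique(patient_ids)
  out <- lapply(ids, function(id) {
    sel <- patient_ids == id & is.finite(x) & is.finite(y)
    xi <- x[sel]; yi <- y[sel]
    if (sum(sel) < 3) stop("need at least 3 points per patient")
    if (sd(xi) < 1e-12 || sd(yi) < 1e-12)
      return(data.frame(patient = id, n = sum(sel), r = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    ct <- cor.test(xi, yi)
    data.frame(patient = id, n = sum(sel), r = unname(ct$estimate),
               p = ct$p.value, degenerate = FALSE)
  })
  do.call(rbind, out)
}
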