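# Mean-scaled nested variance decomposition. Feature values are divided
# by the per-material mean so the mean-squared variance scaling
# (sigma^2 x f_m^2 on the absolute scale) becomes homoscedastic, then a
# linear mixed-effects model with material and thickness fixed effects
# and manufacturer / scanner random intercepts is fit by REML.

.quietFit <- function(expr) suppressWarnings(suppressMessages(expr))

# REML log-likelihood of an lmer or lm fit (same fixed effects assumed).
.remlLogLik <- function(fit) {
  if (inherits(fit, "merMod")) as.numeric(logLik(fit, REML = TRUE))
  else as.numeric(logLik(fit, REML = TRUE))
}

# One-sided p-value for a variance component from the 50:50 chi2_0/chi2_1
# mixture reference.
.lrtMixtureP <- function(ll_full, ll_reduced) {
  D <- 2 * (ll_full - ll_reduced)
  if (!is.finite(D) || D <= 0) return(1)
  0.5 * pchisq(D, df = 1, lower.tail = FALSE)
}

.fitWithTerms <- function(dat, fixed_rhs, rand_terms) {
  if (length(rand_terms)) {
    fml <- as.formula(paste("y ~", fixed_rhs, "+",
                            paste(rand_terms, collapse = " + ")))
    .quietFit(lme4::lmer(fml, data = dat, REML = TRUE,
                         control = lme4::lmerControl(calc.derivs = FALSE)))
  } else {
    stats::lm(as.formula(paste("y ~", fixed_rhs)), data = dat)
  }
}

.randSD <- function(fit, group) {
  if (!inherits(fit, "merMod")) return(0)
  vc <- as.data.frame(lme4::VarCorr(fit))
  row <- vc$grp == group & vc$var1 == "(Intercept)"
  if (!any(row)) return(0)
  vc$sdcor[row][1]
}

.residSD <- function(fit) {
  if (inherits(fit, "merMod")) stats::sigma(fit) else stats::sigma(fit)
}

#' Fit the mean-scaled variance-components model for one feature
#'
#' Values are divided by the estimated per-material mean \eqn{\hat f_m},
#' then \code{y ~ material + thickness + (1 | manufacturer) +
#' (1 | scanner)} is fit by REML. Each random component is tested with a
#' likelihood-ratio test against the 50:50 \eqn{\chi^2_0/\chi^2_1}
#' mixture at \code{alpha}; non-significant components are set to 0,
#' removed, and the model refit so their variance is absorbed into the
#' residual. Data with a single manufacturer (e.g. a one-vendor
#' sensitivity refit) automatically drop the manufacturer component.
#'
#' @param table \linkS4class{FeatureTable} or data.frame.
#' @param feature Feature to fit (default: the single feature present).
#' @param protocol Protocol to subset to (default: all records given).
#' @param alpha Significance level of the collapse test; default 0.05.
#' @param collapse Apply the component-collapse rule (default TRUE).
#' @param t_ref Thickness (mm) at which the fixed effect is centered;
#'   default 3.
#' @param keep_fit Keep the underlying lme4/lm object in the result.
#' @return A \linkS4class{VarianceModelFit}.
#' @examples
#' cfg <- featureSimConfig(material_means = c(a = 100, b = 400), seed = 2)
#' fit <- fitVarianceModel(simulateFeatureTable(cfg, seed = 2))
#' relativeSigmas(fit)
#' @export
fitVarianceModel <- function(table, feature = NULL, protocol = NULL,
                             alpha = 0.05, collapse = TRUE, t_ref = 3,
                             keep_fit = FALSE) {
  rec <- if (is(table, "FeatureTable")) table@records else
    as.data.frame(table)
  if (!is.null(feature)) rec <- rec[rec$feature == feature, ]
  if (!is.null(protocol)) rec <- rec[rec$protocol == protocol, ]
  .stopifnot1(nrow(rec) > 0, "no records to fit")
  feat <- unique(rec$feature)
  .stopifnot1(length(feat) == 1,
              "fitVarianceModel fits one feature at a time")
  prot <- paste(unique(rec$protocol), collapse = "+")

  f_hat <- vapply(split(rec$value, rec$material), mean, numeric(1))
  .stopifnot1(all(f_hat != 0), "a material mean of 0 cannot be scaled")
  dat <- data.frame(
    y = rec$value / f_hat[rec$material],
    material = factor(rec$material),
    manufacturer = factor(rec$manufacturer),
    scanner = factor(rec$scanner),
    tc = rec$thickness_mm - t_ref)
  n_manu <- nlevels(dat$manufacturer)
  n_scan <- nlevels(dat$scanner)
  use_thick <- length(unique(dat$tc)) >= 2
  fixed_rhs <- paste(c("1",
                       if (nlevels(dat$material) > 1) "material",
                       if (use_thick) "tc"), collapse = " + ")

  terms <- c(manufacturer = "(1 | manufacturer)",
             scanner = "(1 | scanner)")
  active <- c(manufacturer = n_manu >= 2, scanner = n_scan >= 2)
  collapsed <- names(active)[!active]
  full <- .fitWithTerms(dat, fixed_rhs, terms[active])

  if (collapse && any(active)) {
    pvals <- vapply(names(terms)[active], function(comp) {
      keep <- active; keep[comp] <- FALSE
      red <- .fitWithTerms(dat, fixed_rhs, terms[keep])
      .lrtMixtureP(.remlLogLik(full), .remlLogLik(red))
    }, numeric(1))
    drop <- names(pvals)[pvals >= alpha]
    if (length(drop)) {
      active[drop] <- FALSE
      collapsed <- c(collapsed, drop)
      full <- .fitWithTerms(dat, fixed_rhs, terms[active])
    }
  }

  sigma_gamma <- if (active["manufacturer"]) .randSD(full, "manufacturer")
    else 0
  sigma_beta <- if (active["scanner"]) .randSD(full, "scanner") else 0
  sigma_eps <- .residSD(full)

  fe <- if (inherits(full, "merMod")) lme4::fixef(full) else coef(full)
  mu <- unname(fe["(Intercept)"])
  mat_fx <- fe[grep("^material", names(fe))]
  mat_levels <- levels(dat$material)
  material_effects <- setNames(numeric(length(mat_levels)), mat_levels)
  if (length(mat_fx))
    material_effects[sub("^material", "", names(mat_fx))] <- mat_fx
  slope <- if (use_thick && "tc" %in% names(fe)) unname(fe["tc"])
    else NA_real_
  slope_se <- NA_real_
  if (!is.na(slope)) {
    vcv <- if (inherits(full, "merMod")) as.matrix(stats::vcov(full))
      else stats::vcov(full)
    slope_se <- sqrt(vcv["tc", "tc"])
  }
  vendor <- setNames(numeric(n_manu), levels(dat$manufacturer))
  if (inherits(full, "merMod") && active["manufacturer"]) {
    re <- lme4::ranef(full)$manufacturer
    vendor[rownames(re)] <- re[["(Intercept)"]]
  }
  new("VarianceModelFit", feature = feat, protocol = prot, mu = mu,
      material_effects = material_effects, thickness_slope = slope,
      thickness_slope_se = slope_se, vendor_effects = vendor,
      components = VarianceComponents(sigma_gamma, sigma_beta, sigma_eps,
                                      material_means = f_hat),
      collapsed = sort(unique(collapsed)), n_obs = nrow(dat),
      fit = if (keep_fit) full else NULL)
}

#' Total variability and component shares for one material
#'
#' Absolute-scale SDs recover as \eqn{\sigma_{\cdot,m} = \sigma_\cdot
#' \hat f_m}; the total is \eqn{\sigma_{t,m} = \sqrt{\sigma_{\beta,m}^2 +
#' \sigma_{\gamma,m}^2 + \sigma_{\varepsilon,m}^2}} and the proportions
#' are the squared shares, summing to 1.
#'
#' @param x A \linkS4class{VarianceModelFit} or
#'   \linkS4class{VarianceComponents}.
#' @param material Material whose \eqn{\hat f_m} scales the SDs (default:
#'   first material).
#' @return List with \code{sigma_gamma_m, sigma_beta_m, sigma_eps_m,
#'   sigma_total_m} (absolute scale), \code{sigma_total_rel} and
#'   \code{proportions} (named, squared shares).
#' @examples
#' vc <- VarianceComponents(4, 3, 0, c(m = 1))
#' summarizeVariability(vc)$sigma_total_m  # 5
#' @export
summarizeVariability <- function(x, material = NULL) {
  comp <- if (is(x, "VarianceModelFit")) x@components else x
  fm <- comp@material_means
  if (is.null(material)) material <- names(fm)[1]
  f <- abs(fm[[material]])
  s <- relativeSigmas(comp)
  s[is.na(s)] <- 0
  abs_s <- s * f
  tot <- sqrt(sum(abs_s^2))
  prop <- if (tot > 0) abs_s^2 / tot^2 else setNames(rep(NA_real_, 3),
                                                     names(s))
  list(sigma_gamma_m = unname(abs_s["sigma_gamma"]),
       sigma_beta_m = unname(abs_s["sigma_beta"]),
       sigma_eps_m = unname(abs_s["sigma_eps"]),
       sigma_total_m = tot,
       sigma_total_rel = sqrt(sum(s^2)),
       proportions = setNames(as.numeric(prop),
                              c("manufacturer", "scanner", "residual")))
}

#' Imaging variability relative to a patient cohort
#'
#' \deqn{IV_{total} = \frac{\sigma_{t,m} / \hat f_m}{\sigma_p / \mu_p},
#' \qquad IV_{residual} = \frac{\sigma_{\varepsilon,m} / \hat f_m}
#' {\sigma_p / \mu_p}.}
#' The material mean cancels, so both are the relative model SD over the
#' cohort's coefficient of variation. Flags use a strict \code{>} at the
#' cutoff (a value exactly at 1/3 is not flagged).
#'
#' @param fit \linkS4class{VarianceModelFit} or
#'   \linkS4class{VarianceComponents}.
#' @param cohort \linkS4class{PatientCohortStats}.
#' @param feature Feature name (defaults to the fit's feature).
#' @param cutoff Flagging cutoff; default 1/3.
#' @return data.frame row: \code{feature, cohort, iv_total, iv_residual,
#'   above_cutoff_total, above_cutoff_residual}.
#' @export
imagingVariability <- function(fit, cohort, feature = NULL,
                               cutoff = 1 / 3) {
  comp <- if (is(fit, "VarianceModelFit")) fit@components else fit
  if (is.null(feature))
    feature <- if (is(fit, "VarianceModelFit")) fit@feature else
      stop("feature must be given with bare VarianceComponents")
  st <- cohort@stats
  row <- st[st$feature == feature, ]
  .stopifnot1(nrow(row) == 1,
              paste("cohort stats missing feature", feature))
  if (row$mu_p == 0) {
    return(data.frame(feature = feature, cohort = cohort@cohort,
                      iv_total = NA_real_, iv_residual = NA_real_,
                      above_cutoff_total = NA, above_cutoff_residual = NA))
  }
  cohort_cov <- row$sigma_p / abs(row$mu_p)
  s <- relativeSigmas(comp)
  s[is.na(s)] <- 0
  iv_total <- sqrt(sum(s^2)) / cohort_cov
  iv_residual <- s[["sigma_eps"]] / cohort_cov
  # strict > at the cutoff; a tiny relative tolerance keeps values that
  # are numerically equal to the cutoff unflagged
  tol <- cutoff * 1e-9
  data.frame(feature = feature, cohort = cohort@cohort,
             iv_total = iv_total, iv_residual = iv_residual,
             above_cutoff_total = iv_total > cutoff + tol,
             above_cutoff_residual = iv_residual > cutoff + tol)
}

# Coerce fits / components lists or data.frames to a per-feature sigma
# frame with columns feature, sigma_gamma, sigma_beta, sigma_eps.
.sigmaFrame <- function(x) {
  if (is.data.frame(x)) {
    .stopifnot1(all(c("feature", "sigma_gamma", "sigma_beta",
                      "sigma_eps") %in% names(x)),
                "sigma frame needs feature + sigma columns")
    return(x)
  }
  do.call(rbind, lapply(x, function(f) {
    s <- relativeSigmas(f)
    data.frame(feature = if (is(f, "VarianceModelFit")) f@feature else NA,
               sigma_gamma = s[["sigma_gamma"]],
               sigma_beta = s[["sigma_beta"]],
               sigma_eps = s[["sigma_eps"]], row.names = NULL)
  }))
}

# Paired one-sided t-test that tolerates degenerate (zero-variance)
# difference vectors: p = 0.5 when all differences are 0, 0 / 1 at the
# one-sided extremes.
.pairedOneSidedP <- function(a, b, alternative = "less") {
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    m <- mean(d)
    if (m == 0) return(0.5)
    less <- m < 0
    return(if ((alternative == "less") == less) 0 else 1)
  }
  tstat <- mean(d) / (sd(d) / sqrt(n))
  if (alternative == "less") pt(tstat, n - 1)
  else pt(tstat, n - 1, lower.tail = FALSE)
}

#' Compare variance components between two protocols
#'
#' Paired one-sided t-tests over features, separately for each component
#' (\eqn{\sigma_\gamma, \sigma_\beta, \sigma_\varepsilon}), testing
#' whether protocol A (e.g. controlled) has smaller variability than
#' protocol B (e.g. a local protocol). Also serves the one-vendor
#' sensitivity comparison (all scanners vs one manufacturer's scanners),
#' where only \eqn{\sigma_\beta} and \eqn{\sigma_\varepsilon} are
#' defined.
#'
#' @param fits_a,fits_b Lists of \linkS4class{VarianceModelFit}s (or
#'   data.frames with columns \code{feature, sigma_gamma, sigma_beta,
#'   sigma_eps}) for the same features.
#' @param components Components to compare.
#' @param alternative "less" (A < B, default) or "greater".
#' @return data.frame: \code{component, n_features, mean_a, mean_b,
#'   p_value}.
#' @export
compareProtocolVariability <- function(fits_a, fits_b,
                                       components = c("sigma_gamma",
                                                      "sigma_beta",
                                                      "sigma_eps"),
                                       alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  a <- .sigmaFrame(fits_a); b <- .sigmaFrame(fits_b)
  common <- intersect(a$feature, b$feature)
  .stopifnot1(length(common) >= 2,
              "need >= 2 paired features to compare")
  a <- a[match(common, a$feature), ]
  b <- b[match(common, b$feature), ]
  do.call(rbind, lapply(components, function(comp) {
    av <- a[[comp]]; bv <- b[[comp]]
    ok <- !is.na(av) & !is.na(bv)
    data.frame(component = comp, n_features = sum(ok),
               mean_a = mean(av[ok]), mean_b = mean(bv[ok]),
               p_value = .pairedOneSidedP(av[ok], bv[ok], alternative))
  }))
}
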