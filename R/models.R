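# Repeated-measures mixed models of diffusion metrics vs log-distance.
#
# Two families, fitted with lme4:
#   gradient:   outcome ~ log(distance_mm + 1), tract-WMH records only
#               (distance 0 = the lesion region itself), REML, with
#               uncorrelated random intercept + log-distance slope for
#               participant and (all-tract scope) tract, crossed.
#   comparison: outcome ~ log(distance_mm) + WMH type (+ interaction if it
#               lowers the ML BIC), distances 2-10 mm only, both lesion
#               types; tract_wmh is the reference level so the "nearby"
#               coefficient is the nearby-vs-intersecting offset.
#
# MD is rescaled (x 1e4) before fitting so variance components are
# well-conditioned; the scale is stamped into every result. Denominator df
# for Type III Wald F tests use a Satterthwaite approximation implemented
# here via the variance-parameter delta method (numeric Hessian of the
# REML deviance in (theta, sigma); numeric Jacobian of each contrast
# variance). Kenward-Roger is not implemented and raises an explicit
# error; residual df is available and is the recorded fallback when the
# variance-parameter Hessian is degenerate.

fit_lmm <- function(formula, data, REML = TRUE) {
  parsed <- lme4::lFormula(formula, data = data, REML = REML,
                           control = lme4::lmerControl(calc.derivs = FALSE))
  devfun <- do.call(lme4::mkLmerDevfun, parsed)
  opt <- lme4::optimizeLmer(devfun)
  model <- lme4::mkMerMod(environment(devfun), opt, parsed$reTrms,
                          fr = parsed$fr)
  list(model = model, devfun = devfun,
       converged = isTRUE(opt$conv == 0L),
       singular = lme4::isSingular(model))
}

# REML/ML deviance as a function of varpar = c(theta, sigma), i.e. the
# non-profiled deviance, needed for the curvature of the variance
# parameters (the profiled devfun has sigma maximized out).
devfun_varpar <- function(varpar, devfun, reml = TRUE) {
  p <- length(varpar)
  sigma2 <- varpar[p]^2
  theta <- varpar[-p]
  devfun(theta)
  env <- environment(devfun)
  n <- nrow(env$pp$V)
  if (reml) n <- n - ncol(env$pp$X)
  dev <- env$pp$ldL2() + (env$resp$wrss() + env$pp$sqrL(1)) / sigma2 +
    n * log(2 * pi * sigma2)
  if (reml) dev <- dev + env$pp$ldRX2()
  dev
}

covbeta_at <- function(varpar, devfun) {
  p <- length(varpar)
  sigma <- varpar[p]
  devfun(varpar[-p])
  env <- environment(devfun)
  sigma^2 * tcrossprod(env$pp$RXi())
}

num_hessian <- function(f, x, rel_h = 1e-4) {
  p <- length(x)
  h <- rel_h * (abs(x) + 1e-2)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- rep(0, p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

num_gradient <- function(f, x, rel_h = 1e-4) {
  p <- length(x)
  h <- rel_h * (abs(x) + 1e-2)
  g <- numeric(p)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h[i]
    g[i] <- (f(x + ei) - f(x - ei)) / (2 * h[i])
  }
  g
}

mp_inverse <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), 1e-300)
  if (!any(keep)) return(NULL)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Satterthwaite denominator df for each single-df contrast (rows of L).
# Returns NULL when the variance-parameter curvature is unusable
# (boundary / singular fits); the caller then falls back to residual df.
satterthwaite_df <- function(fitted, L) {
  model <- fitted$model
  devfun <- fitted$devfun
  reml <- lme4::isREML(model)
  vp <- c(lme4::getME(model, "theta"), stats::sigma(model))
  on.exit(devfun(vp[-length(vp)]), add = TRUE)  # restore optimum state
  H <- tryCatch(num_hessian(function(x) devfun_varpar(x, devfun, reml), vp),
                error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(NULL)
  A <- mp_inverse(H / 2)  # asymptotic covariance of varpar
  if (is.null(A)) return(NULL)
  df <- numeric(nrow(L))
  for (r in seq_len(nrow(L))) {
    l <- L[r, ]
    vfun <- function(x) drop(t(l) %*% covbeta_at(x, devfun) %*% l)
    v <- vfun(vp)
    g <- num_gradient(vfun, vp)
    denom <- drop(t(g) %*% A %*% g)
    df[r] <- if (is.finite(denom) && denom > 0) 2 * v^2 / denom else NA_real_
  }
  if (any(!is.finite(df)) || any(df <= 0)) return(NULL)
  df
}

#' Type III Wald F tests for a fitted penumbra model
#'
#' Every fixed-effect term in the models of this package is single-df, so
#' the Type III (marginal) F statistic reduces to the Wald identity
#' `F = (estimate / SE)^2`; the denominator df come from the requested
#' approximation. `"kenward_roger"` is not implemented and raises an
#' error rather than silently substituting another method.
#'
#' @param fit a `penumbra_fit` from [fit_gradient_model()] or
#'   [fit_type_comparison_model()].
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @return data.frame with term, estimate, std_error, F, df_den, p, and
#'   the df method actually used per term.
#' @export
type3_wald_f <- function(fit, df_method = c("satterthwaite", "residual",
                                            "kenward_roger")) {
  df_method <- match.arg(df_method)
  if (df_method == "kenward_roger")
    stop("df method 'kenward_roger' is not implemented; use 'satterthwaite' or 'residual'")
  stopifnot(inherits(fit, "penumbra_fit"))
  est <- fit$coefficients
  se <- fit$std_errors
  k <- length(est)
  used <- df_method
  if (fit$degenerate) {
    dfs <- rep(fit$df_residual, k)
    used <- "residual"
  } else if (df_method == "satterthwaite") {
    L <- diag(k)
    dfs <- satterthwaite_df(fit$engine, L)
    if (is.null(dfs)) {
      dfs <- rep(fit$df_residual, k)
      used <- "residual_fallback"
    }
  } else {
    dfs <- rep(fit$df_residual, k)
  }
  Fv <- (est / se)^2
  # an estimate at numerical zero with a numerically zero SE (perfectly
  # constant outcome) carries no evidence: report F = 0, not 0/0 noise
  numzero <- abs(est) < 1e-10 & se < 1e-10
  Fv[!is.finite(Fv) & numzero] <- 0
  Fv[numzero] <- 0
  data.frame(term = names(est), estimate = unname(est),
             std_error = unname(se), F = unname(Fv), df_den = unname(dfs),
             p = stats::pf(unname(Fv), 1, unname(dfs), lower.tail = FALSE),
             df_method = used, stringsAsFactors = FALSE, row.names = NULL)
}

new_penumbra_fit <- function(family, outcome, scope, formula_str, engine,
                             degenerate, md_scale, n_obs, df_method,
                             extra = list()) {
  if (degenerate) {
    model <- engine
    # a noiseless planted table is an "essentially perfect fit"; that is
    # the point of the degenerate path, so the summary warning is noise
    sm <- suppressWarnings(summary(model)$coefficients)
    est <- sm[, 1L]; se <- sm[, 2L]
    df_res <- stats::df.residual(model)
    converged <- TRUE; singular <- FALSE
    bic <- stats::BIC(model)
    varcor <- NULL
  } else {
    model <- engine$model
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    df_res <- nrow(model@frame) - length(est)
    converged <- engine$converged
    singular <- engine$singular
    bic <- stats::BIC(model)
    vc <- as.data.frame(lme4::VarCorr(model))
    varcor <- vc[, c("grp", "var1", "vcov", "sdcor")]
  }
  fit <- structure(list(
    family = family, outcome = outcome, scope = scope,
    formula = formula_str, engine = engine, model = model,
    coefficients = est, std_errors = se, df_residual = df_res,
    degenerate = degenerate, converged = converged, singular = singular,
    bic = bic, varcor = varcor, md_scale = md_scale, n_obs = n_obs,
    df_method = df_method), class = "penumbra_fit")
  fit[names(extra)] <- extra
  fit$terms <- type3_wald_f(fit, df_method)
  fit
}

#' @export
print.penumbra_fit <- function(x, ...) {
  cat(sprintf("<penumbra_fit %s / %s / scope=%s>\n", x$family, x$outcome,
              x$scope))
  cat(sprintf("  %s\n", x$formula))
  cat(sprintf("  n_obs=%d, BIC=%.2f, converged=%s%s%s%s\n", x$n_obs, x$bic,
              x$converged, if (x$singular) ", singular" else "",
              if (x$degenerate) ", degenerate (fixed-effects fit)" else "",
              if (x$outcome == "md") sprintf(", MD scale x%g", x$md_scale)
              else ""))
  print(x$terms, digits = 4)
  invisible(x)
}

prepare_model_data <- function(records, outcome, md_scale,
                               exclusion_scope = "contour") {
  d <- model_input(records, outcome, exclusion_scope)
  d$y <- if (outcome == "fa") d$mean_fa else d$mean_md * md_scale
  d$participant <- factor(d$participant)
  d$tract <- factor(d$tract)
  d
}

re_formula <- function(base, data, crossed_tract) {
  n_part <- nlevels(droplevels(data$participant))
  n_tract <- nlevels(droplevels(data$tract))
  notes <- character()
  if (n_part < 2L) {
    return(list(formula = stats::as.formula(base), degenerate = TRUE,
                notes = "single participant: degenerate fixed-effects fit"))
  }
  if (stats::var(data$y) == 0) {
    # constant outcome: variance components are undefined; a plain line
    # fit returns slope 0 (and F is reported as 0, see type3_wald_f)
    return(list(formula = stats::as.formula(base), degenerate = TRUE,
                notes = "constant outcome: degenerate fixed-effects fit"))
  }
  rhs <- " + (1 + logd || participant)"
  if (crossed_tract) {
    if (n_tract >= 2L) {
      rhs <- paste0(rhs, " + (1 + logd || tract)")
    } else {
      notes <- "single tract: tract random effects dropped"
    }
  }
  list(formula = stats::as.formula(paste0(base, rhs)), degenerate = FALSE,
       notes = notes)
}

#' Fit the log-distance gradient model
#'
#' Models the tract-WMH trajectory: the outcome in the lesion itself
#' (distance 0) and in the tract-NAWM shells at 2-10 mm against
#' `log(distance_mm + 1)`, by REML, with uncorrelated random intercepts
#' and log-distance slopes for participant and --- in the all-tract scope
#' --- tract (crossed). CSF-excluded and empty records must already be
#' flagged ([apply_csf_exclusion()]); they are dropped here. With fewer
#' than two participants the fit degenerates to a fixed-effects `lm`
#' (flagged `degenerate`), which reproduces a noiseless planted slope
#' exactly.
#'
#' @param records shell-record data.frame.
#' @param outcome `"fa"` or `"md"` (MD is rescaled by `md_scale`).
#' @param scope `"all"` for the all-tract model, or one tract name.
#' @param df_method denominator-df method for the Wald F table.
#' @param md_scale MD rescaling factor (default 1e4; estimates are on the
#'   rescaled scale and the factor is recorded in the result).
#' @param exclusion_scope `"contour"` (default: CSF-flagged records are
#'   dropped for both outcomes) or `"md_only"` (sensitivity option: kept
#'   for FA).
#' @param simplify_on_singular opt in to refitting with intercept-only
#'   random effects when the full structure is singular; the
#'   simplification is stamped into the result, never silent.
#' @return A `penumbra_fit`.
#' @export
fit_gradient_model <- function(records, outcome = c("fa", "md"),
                               scope = "all",
                               df_method = c("satterthwaite", "residual",
                                             "kenward_roger"),
                               md_scale = 1e4,
                               exclusion_scope = "contour",
                               simplify_on_singular = FALSE) {
  outcome <- match.arg(outcome)
  df_method <- match.arg(df_method)
  d <- prepare_model_data(records, outcome, md_scale, exclusion_scope)
  d <- d[d$wmh_type == "tract_wmh", , drop = FALSE]
  if (scope != "all") d <- d[d$tract == scope, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable tract-WMH records for this scope")
  if (length(unique(d$distance_mm)) < 2L)
    stop("gradient model needs records at >= 2 distinct distances")
  d$logd <- log(d$distance_mm + 1)
  rf <- re_formula("y ~ logd", d, crossed_tract = scope == "all")
  if (rf$degenerate) {
    engine <- stats::lm(y ~ logd, data = d)
    return(new_penumbra_fit("gradient", outcome, scope, "y ~ logd [lm]",
                            engine, TRUE, md_scale, nrow(d), df_method,
                            extra = list(notes = rf$notes)))
  }
  engine <- fit_lmm(rf$formula, d, REML = TRUE)
  notes <- rf$notes
  if (engine$singular && simplify_on_singular) {
    rf2 <- re_formula_intercepts("y ~ logd", d,
                                 crossed_tract = scope == "all")
    engine <- fit_lmm(rf2$formula, d, REML = TRUE)
    rf <- rf2
    notes <- c(notes, "singular full structure: refitted with intercept-only random effects (opt-in)")
  }
  new_penumbra_fit("gradient", outcome, scope,
                   paste(deparse(rf$formula), collapse = " "),
                   engine, FALSE, md_scale, nrow(d), df_method,
                   extra = list(notes = notes))
}

re_formula_intercepts <- function(base, data, crossed_tract) {
  rhs <- " + (1 | participant)"
  if (crossed_tract && nlevels(droplevels(data$tract)) >= 2L)
    rhs <- paste0(rhs, " + (1 | tract)")
  list(formula = stats::as.formula(paste0(base, rhs)), degenerate = FALSE,
       notes = character())
}

#' Fit the tract-WMH vs nearby-WMH comparison model
#'
#' Compares the two lesion types over the common 2-10 mm range:
#' `outcome ~ log(distance_mm) + wmh_type`, with the
#' `log(distance):wmh_type` interaction included only if it lowers the ML
#' BIC (tie goes to the simpler model). Both candidates are fitted by ML
#' for the BIC comparison; the chosen structure is refitted by REML for
#' reporting. `wmh_type` is coded with `tract_wmh` as reference, so the
#' `nearby` coefficient is the nearby-vs-intersecting offset.
#'
#' @inheritParams fit_gradient_model
#' @return A `penumbra_fit` with `bic_without_interaction`,
#'   `bic_with_interaction` (ML scale) and `interaction_included`.
#' @export
fit_type_comparison_model <- function(records, outcome = c("fa", "md"),
                                      scope = "all",
                                      df_method = c("satterthwaite",
                                                    "residual",
                                                    "kenward_roger"),
                                      md_scale = 1e4,
                                      exclusion_scope = "contour") {
  outcome <- match.arg(outcome)
  df_method <- match.arg(df_method)
  d <- prepare_model_data(records, outcome, md_scale, exclusion_scope)
  d <- d[d$distance_mm >= 2, , drop = FALSE]
  if (scope != "all") d <- d[d$tract == scope, , drop = FALSE]
  present <- unique(d$wmh_type)
  for (lev in c("tract_wmh", "nearby")) {
    if (!lev %in% present)
      stop(sprintf("comparison model needs both WMH types; level '%s' is absent",
                   lev))
  }
  d$wmh_type <- factor(d$wmh_type, levels = c("tract_wmh", "nearby"))
  d$logd <- log(d$distance_mm)
  rf0 <- re_formula("y ~ logd + wmh_type", d,
                    crossed_tract = scope == "all")
  if (rf0$degenerate) {
    m0 <- stats::lm(y ~ logd + wmh_type, data = d)
    m1 <- stats::lm(y ~ logd * wmh_type, data = d)
    b0 <- stats::BIC(m0); b1 <- stats::BIC(m1)
    use1 <- b1 < b0
    engine <- if (use1) m1 else m0
    return(new_penumbra_fit(
      "comparison", outcome, scope,
      paste0(if (use1) "y ~ logd * wmh_type" else "y ~ logd + wmh_type",
             " [lm]"),
      engine, TRUE, md_scale, nrow(d), df_method,
      extra = list(notes = rf0$notes, bic_without_interaction = b0,
                   bic_with_interaction = b1, interaction_included = use1)))
  }
  rf1 <- re_formula("y ~ logd * wmh_type", d,
                    crossed_tract = scope == "all")
  m0_ml <- fit_lmm(rf0$formula, d, REML = FALSE)
  m1_ml <- fit_lmm(rf1$formula, d, REML = FALSE)
  b0 <- stats::BIC(m0_ml$model)
  b1 <- stats::BIC(m1_ml$model)
  use1 <- b1 < b0                      # tie -> simpler model
  chosen <- if (use1) rf1 else rf0
  engine <- fit_lmm(chosen$formula, d, REML = TRUE)
  new_penumbra_fit("comparison", outcome, scope,
                   paste(deparse(chosen$formula), collapse = " "),
                   engine, FALSE, md_scale, nrow(d), df_method,
                   extra = list(notes = rf0$notes,
                                bic_without_interaction = b0,
                                bic_with_interaction = b1,
                                interaction_included = use1))
}

fit_row <- function(fit) {
  tr <- fit$terms
  data.frame(family = fit$family, outcome = fit$outcome, scope = fit$scope,
             term = tr$term, estimate = tr$estimate,
             std_error = tr$std_error, F = tr$F, df_res = tr$df_den,
             p = tr$p, df_method = tr$df_method, bic = fit$bic,
             n_obs = fit$n_obs, converged = fit$converged,
             singular = fit$singular, degenerate = fit$degenerate,
             md_scale = if (fit$outcome == "md") fit$md_scale else 1,
             interaction_included =
               if (!is.null(fit$interaction_included))
                 fit$interaction_included else NA,
             stringsAsFactors = FALSE)
}

#' Write fit report tables and a run manifest
#'
#' Emits one CSV per table family (gradient all-tract, gradient per-tract,
#' comparison all-tract, comparison per-tract), each with the Estimate /
#' Std. error / F / Df.res / p columns, plus a JSON manifest recording the
#' configuration echo, seed, exclusion counts, MD scale, df method and BIC
#' choices. The interpretive threshold p < 0.01 is annotated in the
#' manifest but never used to filter rows, and no multiplicity correction
#' is applied.
#'
#' @param fits list of `penumbra_fit` objects.
#' @param out_dir output directory.
#' @param manifest_extra named list merged into the manifest (e.g. config,
#'   exclusion counts).
#' @return Invisible list with the four tables and the manifest.
#' @export
report_tables <- function(fits, out_dir, manifest_extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- if (length(fits) > 0L) do.call(rbind, lapply(fits, fit_row)) else
    fit_row_empty()
  groups <- list(
    gradient_all = rows$family == "gradient" & rows$scope == "all",
    gradient_per_tract = rows$family == "gradient" & rows$scope != "all",
    comparison_all = rows$family == "comparison" & rows$scope == "all",
    comparison_per_tract = rows$family == "comparison" & rows$scope != "all")
  tables <- list()
  for (g in names(groups)) {
    tab <- rows[groups[[g]], , drop = FALSE]
    utils::write.csv(tab, file.path(out_dir, paste0(g, ".csv")),
                     row.names = FALSE)
    tables[[g]] <- tab
  }
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("penumbra")),
    n_fits = length(fits),
    significance_note = "interpretive threshold p < 0.01; no multiplicity correction applied; rows are never filtered by p",
    bic_choices = lapply(fits, function(f) {
      if (is.null(f$interaction_included)) return(NULL)
      list(outcome = f$outcome, scope = f$scope,
           bic_without_interaction = f$bic_without_interaction,
           bic_with_interaction = f$bic_with_interaction,
           interaction_included = f$interaction_included)
    })), manifest_extra)
  manifest$bic_choices <-
    manifest$bic_choices[!vapply(manifest$bic_choices, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(tables = tables, manifest = manifest))
}

fit_row_empty <- function() {
  data.frame(family = character(), outcome = character(), scope = character(),
             term = character(), estimate = numeric(), std_error = numeric(),
             F = numeric(), df_res = numeric(), p = numeric(),
             df_method = character(), bic = numeric(), n_obs = integer(),
             converged = logical(), singular = logical(),
             degenerate = logical(), md_scale = numeric(),
             interaction_included = logical(), stringsAsFactors = FALSE)
}
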