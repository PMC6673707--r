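# Mixed-model fits, Wald F machinery, BIC gate, reporting.

test_that("noiseless planted tables give the slope back exactly", {
  rec <- planted_records(1, b0 = 0.3, b1 = 0.024)
  fit <- fit_gradient_model(rec, "fa", "all")
  expect_true(fit$degenerate)             # single participant -> line fit
  expect_equal(unname(fit$coefficients["logd"]), 0.024, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.3,
               tolerance = 1e-10)
  rec$mean_md <- (9 - 0.85 * log(rec$distance_mm + 1)) * 1e-4
  fitm <- fit_gradient_model(rec, "md", "all")
  expect_equal(unname(fitm$coefficients["logd"]), -0.85, tolerance = 1e-8)
  expect_equal(fitm$md_scale, 1e4)
})

test_that("constant outcome gives a zero slope and F near zero", {
  rec <- planted_records(4, b1 = 0)
  fit <- fit_gradient_model(rec, "fa", "all")
  tr <- fit$terms[fit$terms$term == "logd", ]
  expect_equal(tr$estimate, 0, tolerance = 1e-8)
  expect_lt(tr$F, 1e-6)
})

test_that("gradient model recovers a planted slope with random effects", {
  set.seed(5)
  rec <- planted_records(30, b1 = 0.024, sd_int = 0.02, sd_slope = 0.005,
                         sd_resid = 0.01)
  fit <- fit_gradient_model(rec, "fa", scope = "t1")
  expect_false(fit$degenerate)
  expect_true(fit$converged)
  tr <- fit$terms[fit$terms$term == "logd", ]
  expect_lt(abs(tr$estimate - 0.024), 3 * tr$std_error)
  expect_gt(tr$df_den, 2)
  # Wald identity F = (est/SE)^2 for every term
  expect_equal(fit$terms$F,
               (fit$terms$estimate / fit$terms$std_error)^2,
               tolerance = 1e-8)
})

test_that("gradient model enforces its preconditions", {
  rec <- planted_records(3, distances = c(2, 2, 2))
  expect_error(fit_gradient_model(rec, "fa"), "2 distinct distances")
  rec2 <- planted_records(3)
  rec2$wmh_type <- "nearby"
  expect_error(fit_gradient_model(rec2, "fa"), "no usable tract-WMH")
})

test_that("kenward_roger is an explicit unsupported method", {
  rec <- planted_records(4, sd_resid = 0.01)
  fit <- fit_gradient_model(rec, "fa")
  expect_error(type3_wald_f(fit, "kenward_roger"), "not implemented")
})

test_that("residual and Satterthwaite df are both available and recorded", {
  set.seed(9)
  rec <- planted_records(10, sd_int = 0.01, sd_slope = 0.003,
                         sd_resid = 0.01)
  fit <- fit_gradient_model(rec, "fa", scope = "t1",
                            df_method = "satterthwaite")
  expect_true(all(fit$terms$df_method %in%
                    c("satterthwaite", "residual_fallback")))
  tab_r <- type3_wald_f(fit, "residual")
  expect_true(all(tab_r$df_method == "residual"))
  expect_equal(tab_r$df_den, rep(nrow(penumbra:::model_input(rec)) - 2, 2))
  # identical estimates and F regardless of df method
  expect_equal(tab_r$estimate, fit$terms$estimate)
  expect_equal(tab_r$F, fit$terms$F)
})

test_that("Satterthwaite df approximate the balanced-design truth", {
  # balanced random-intercept+slope design: the slope test is equivalent
  # to a one-sample t-test on per-participant OLS slopes with n-1 df
  set.seed(31)
  n_p <- 16
  rec <- planted_records(n_p, b1 = 0, sd_int = 0.02, sd_slope = 0.006,
                         sd_resid = 0.005)
  fit <- fit_gradient_model(rec, "fa", scope = "t1")
  tr <- fit$terms[fit$terms$term == "logd", ]
  sl <- vapply(split(rec, rec$participant), function(dd)
    stats::coef(stats::lm(mean_fa ~ log(distance_mm + 1), dd))[2], numeric(1))
  expect_equal(tr$estimate, mean(sl), tolerance = 1e-6)
  expect_equal(tr$df_den, n_p - 1, tolerance = 0.35 * n_p)
  oracle_p <- stats::t.test(sl)$p.value
  expect_equal(tr$p, oracle_p, tolerance = 0.15)
})

test_that("two-group fixed-effects F matches the classical ANOVA oracle", {
  # balanced 2 x 10 design, single participant -> degenerate lm path;
  # the type III F for the group factor must equal the one-way ANOVA F
  set.seed(12)
  y <- c(rnorm(10, 0.40, 0.02), rnorm(10, 0.43, 0.02))
  rec <- data.frame(
    participant = "p1", tract = "t1",
    wmh_type = rep(c("tract_wmh", "nearby"), each = 10),
    distance_mm = rep(c(2, 4, 6, 8, 10), 4),
    n_voxels = 20L, mean_fa = y, mean_md = 8e-4, excluded_csf = FALSE,
    stringsAsFactors = FALSE)
  fit <- fit_type_comparison_model(rec, "fa", "all")
  expect_true(fit$degenerate)
  tr <- fit$terms[fit$terms$term == "wmh_typenearby", ]
  # classical balanced-ANCOVA oracle, computed from first principles:
  # pooled within-group slope, within-group SSE on 17 df, group contrast
  g1 <- y[1:10]; g2 <- y[11:20]
  x <- log(c(2, 4, 6, 8, 10))[rep(1:5, 2)]
  xc <- x - mean(x)
  b_common <- (sum(xc * g1) + sum(xc * g2)) / (2 * sum(xc^2))
  sse <- sum((g1 - mean(g1) - b_common * xc)^2) +
    sum((g2 - mean(g2) - b_common * xc)^2)
  f_oracle <- (mean(g2) - mean(g1))^2 / (sse / 17 * (2 / 10))
  expect_equal(tr$F, f_oracle, tolerance = 1e-8)
  expect_equal(tr$df_den, 17)
})

test_that("comparison model needs both types and codes tract_wmh as reference", {
  rec <- planted_records(3)
  expect_error(fit_type_comparison_model(rec, "fa"), "level 'nearby'")
  set.seed(2)
  both <- rbind(planted_records(6, distances = c(2, 4, 6, 8, 10),
                                sd_resid = 0.01),
                transform(planted_records(6, distances = c(2, 4, 6, 8, 10),
                                          b0 = 0.315, sd_resid = 0.01),
                          wmh_type = "nearby"))
  fit <- fit_type_comparison_model(both, "fa", "all")
  expect_true("wmh_typenearby" %in% fit$terms$term)
  tr <- fit$terms[fit$terms$term == "wmh_typenearby", ]
  expect_gt(tr$estimate, 0)               # nearby is offset upward
  expect_lt(abs(tr$estimate - 0.015), 3 * tr$std_error)
})

test_that("identical planted curves for both types give a zero type effect", {
  a <- planted_records(4, distances = c(2, 4, 6, 8, 10))
  b <- transform(a, wmh_type = "nearby")
  fit <- fit_type_comparison_model(rbind(a, b), "fa", "all")
  tr <- fit$terms[fit$terms$term == "wmh_typenearby", ]
  expect_equal(tr$estimate, 0, tolerance = 1e-10)
  expect_false(fit$interaction_included)
})

test_that("BIC gate selection frequency rises with interaction size", {
  sim_one <- function(delta, seed) {
    set.seed(seed)
    n_p <- 12
    base <- expand.grid(participant = sprintf("p%02d", 1:n_p),
                        distance_mm = c(2, 4, 6, 8, 10),
                        wmh_type = c("tract_wmh", "nearby"),
                        stringsAsFactors = FALSE)
    base$tract <- "t1"
    logd <- log(base$distance_mm)
    nearby <- base$wmh_type == "nearby"
    pi_ <- as.integer(factor(base$participant))
    bi <- rnorm(n_p, 0, 0.01)[pi_]
    base$mean_fa <- 0.35 + 0.01 * logd + 0.015 * nearby +
      delta * nearby * logd + bi + rnorm(nrow(base), 0, 0.008)
    base$mean_md <- 8e-4; base$n_voxels <- 30L; base$excluded_csf <- FALSE
    fit_type_comparison_model(base, "fa", "all")$interaction_included
  }
  freqs <- vapply(c(0, 0.01, 0.04), function(delta)
    mean(vapply(1:10, function(s) sim_one(delta, 1000 + s), logical(1))),
    numeric(1))
  expect_lte(freqs[1], 0.5)               # null: mostly not selected
  expect_gte(freqs[3], 0.8)               # strong interaction: selected
  expect_true(freqs[3] >= freqs[1])       # monotone within MC error
  expect_true(freqs[2] >= freqs[1] - 0.2 && freqs[2] <= freqs[3] + 0.2)
})

test_that("report_tables writes the four families and a manifest", {
  set.seed(4)
  rec <- planted_records(5, sd_resid = 0.01)
  fits <- list(fit_gradient_model(rec, "fa", "all"),
               fit_gradient_model(rec, "fa", scope = "t1"))
  out <- file.path(tempdir(), "report_test")
  unlink(out, recursive = TRUE)
  rep_ <- report_tables(fits, out, manifest_extra = list(seed = 4))
  files <- list.files(out)
  expect_setequal(files, c("gradient_all.csv", "gradient_per_tract.csv",
                           "comparison_all.csv", "comparison_per_tract.csv",
                           "manifest.json"))
  tab <- utils::read.csv(file.path(out, "gradient_all.csv"))
  expect_equal(nrow(tab), 2)              # intercept + slope
  expect_true(all(c("estimate", "std_error", "F", "df_res", "p") %in%
                    names(tab)))
  # empty collection still writes headers + manifest
  out2 <- file.path(tempdir(), "report_empty")
  unlink(out2, recursive = TRUE)
  report_tables(list(), out2)
  expect_true(file.exists(file.path(out2, "manifest.json")))
  expect_equal(nrow(utils::read.csv(file.path(out2, "comparison_all.csv"))), 0)
  # manifest round-trips through its reader
  m <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(m$seed, 4)
  expect_equal(m$n_fits, 2)
  unlink(c(out, out2), recursive = TRUE)
})

test_that("estimator bias shrinks with cohort size on phantom cohorts", {
  # consistency of the fixed slope: |mean bias| at n=24 participants is
  # no larger than at n=6 beyond Monte-Carlo error (scaled-down grid and
  # n to keep runtime reasonable; one tract, 12 seeds)
  bias_at <- function(n_p, seeds) {
    ests <- vapply(seeds, function(s) {
      cfg <- phantom_config(
        n_participants = n_p, grid_shape = c(44, 24, 20), seed = s,
        tract_specs = list(list(name = "t1",
                                control_points = rbind(c(11, 12, 10),
                                                       c(34, 12, 10)),
                                radius_mm = 4)),
        lesion_plan = list(n_nearby = 0L, semi_axes_range_mm = c(2, 4)))
      co <- simulate_cohort(cfg)
      rec <- apply_csf_exclusion(assemble_table(co))
      fit <- fit_gradient_model(rec, "fa", "all", df_method = "residual")
      unname(fit$coefficients["logd"])
    }, numeric(1))
    c(bias = mean(ests) - 0.024, se = stats::sd(ests) / sqrt(length(ests)))
  }
  b_small <- bias_at(6, 3000 + 1:12)
  b_large <- bias_at(24, 4000 + 1:12)
  expect_lte(abs(b_large["bias"]),
             abs(b_small["bias"]) + 2 * sqrt(b_small["se"]^2 +
                                               b_large["se"]^2))
  # both are near zero in absolute terms
  expect_lt(abs(b_large["bias"]), 0.005)
})
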