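# small balanced split-plot toy built in code
toy_splitplot <- function(seed = 1, plot_sd = 0, resid_sd = 1,
                          snow_delta = 0, n_per_subplot = 4) {
  set.seed(seed)
  d <- expand.grid(plot_id = sprintf("P%d", 1:6), subplot_id = 1:4,
                   rep = seq_len(n_per_subplot))
  d$subplot_id <- paste0(d$plot_id, "-S", d$subplot_id)
  d$snow_treatment <- factor(ifelse(d$plot_id %in% c("P1", "P2", "P3"),
                                    "early", "control"),
                             levels = c("control", "early"))
  d$precip_treatment <- factor(sub(".*-S", "", d$subplot_id),
                               labels = c("control", "mock", "reduced",
                                          "addition"))
  plot_fx <- rnorm(6, 0, plot_sd)
  names(plot_fx) <- sprintf("P%d", 1:6)
  d$y <- 10 + snow_delta * (d$snow_treatment == "early") +
    plot_fx[as.character(d$plot_id)] + rnorm(nrow(d), 0, resid_sd)
  d
}

test_that("REML reduces to OLS when variance components are zero", {
  d <- toy_splitplot(seed = 2, plot_sd = 0, snow_delta = 1)
  fit <- suppressWarnings(
    fit_splitplot_lmm(d, ~ snow_treatment + precip_treatment, "y"))
  expect_true(fit$singular)
  ols <- lm(y ~ snow_treatment + precip_treatment, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 0.02)
  expect_true(all(fit$varcomp >= 0))
})

test_that("intraclass correlation is recovered in a plot-variance world", {
  icc_hat <- vapply(1:20, function(i) {
    d <- toy_splitplot(seed = 100 + i, plot_sd = 2, resid_sd = 1,
                       n_per_subplot = 8)
    fit <- suppressWarnings(fit_splitplot_lmm(d, ~ 1, "y"))
    vc <- fit$varcomp
    vc[".plot"] / sum(vc)
  }, 0)
  icc_true <- 4 / 5   # plot_sd^2 / (plot_sd^2 + resid_sd^2)
  expect_lt(abs(mean(icc_hat) - icc_true), 0.1)
})

test_that("treatment-effect coverage in a generator world with plot noise", {
  hits <- vapply(1:40, function(i) {
    d <- toy_splitplot(seed = 200 + i, plot_sd = 0.5, resid_sd = 1,
                       snow_delta = 1)
    fit <- suppressWarnings(
      fit_splitplot_lmm(d, ~ snow_treatment, "y"))
    co <- fit$coefficients[fit$coefficients$term == "snow_treatmentearly", ]
    abs(co$estimate - 1) <= 2 * co$se
  }, TRUE)
  expect_gte(mean(hits), 0.85)
})

test_that("non-nested grouping labels are rejected", {
  d <- toy_splitplot()
  d$subplot_id <- sub("P[0-9]-", "S", d$subplot_id)  # shared across plots
  expect_error(fit_splitplot_lmm(d, ~ snow_treatment, "y",
                                 subplot = "subplot_id"), "nested")
})

test_that("EMMs equal raw means when balanced, hand average when not", {
  d <- toy_splitplot(seed = 5, snow_delta = 2)
  fit <- suppressWarnings(
    fit_splitplot_lmm(d, ~ snow_treatment + precip_treatment, "y"))
  em_ <- emm(fit, "snow_treatment")
  raw <- tapply(d$y, d$snow_treatment, mean)
  expect_equal(em_$emmean, c(raw[em_$level]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # unbalanced two-factor toy: EMM is the equal-weight average of cell
  # means, not the raw mean
  du <- data.frame(
    g = factor(c("a", "a", "a", "a", "b", "b", "b", "b")),
    h = factor(c("x", "x", "x", "y", "x", "y", "y", "y")),
    y = c(1, 1, 1, 5, 2, 6, 6, 6))
  ols <- lm(y ~ g + h, du)
  mod <- list(fit = ols, data = du, fixed = ~ g + h)
  # additive-model EMM via the same machinery as the mixed path
  em2 <- suppressWarnings(scentselect:::emm_any(mod, "g", mixed = FALSE))
  cell <- predict(ols, expand.grid(g = factor(c("a", "b")),
                                   h = factor(c("x", "y"))))
  hand_a <- mean(cell[c(1, 3)])
  expect_equal(em2$emmean[em2$level == "a"], hand_a, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(em2$emmean[em2$level == "a"],
                                mean(du$y[du$g == "a"]))))
  # invariance to the reference level
  du2 <- du; du2$g <- relevel(du2$g, "b")
  mod2 <- list(fit = lm(y ~ g + h, du2), data = du2, fixed = ~ g + h)
  em3 <- suppressWarnings(scentselect:::emm_any(mod2, "g", mixed = FALSE))
  expect_equal(sort(em3$emmean), sort(em2$emmean), tolerance = 1e-10)
  expect_error(emm(fit, "nonexistent"), "not in")
})

test_that("Cohen's d effect sizes and group comparison", {
  d <- data.frame(year = rep(2018, 8),
                  tr = factor(rep(c("new", "old"), each = 4)),
                  t1 = c(2, 2, 2, 2, 1, 1, 1, 1),
                  t2 = c(5, 6, 5, 6, 5, 6, 5, 6),
                  t3 = c(1, 1, 1, 1, 1, 1, 1, 1))
  es <- plasticity_effect_sizes(d, c("t1", "t2", "t3"), "tr", "new", "old")
  pt <- es$per_trait
  # pooled SD of t1 is 0 within groups -> zero_sd flagged
  expect_true(pt$zero_sd[pt$trait == "t1"])
  expect_equal(pt$d[pt$trait == "t2"], 0)       # equal means
  expect_true(pt$zero_sd[pt$trait == "t3"])
  # means 1 vs 2, pooled SD 1 -> d = 1
  d2 <- data.frame(year = 2018,
                   tr = factor(rep(c("new", "old"), each = 4)),
                   t = c(0.8, 2.8, 1.2, 3.2, -0.2, 1.8, 0.2, 2.2))
  es2 <- plasticity_effect_sizes(d2, "t", "tr", "new", "old")
  sp <- sqrt(mean(c(var(d2$t[1:4]), var(d2$t[5:8]))))
  expect_equal(es2$per_trait$d, (2 - 1) / sp, tolerance = 1e-12)
  # generator with 0.2-SD shifts on volatiles only
  cat_ <- compound_catalog()
  shift <- exp(0.2 * cat_$log_sd)   # +0.2 SD on the log scale
  tr_eff <- true_params(plasticity = list(
    snow_early = setNames(shift, cat_$compound)))
  st <- simulate_study(seed = 99, truth = tr_eff, n_total = 600)
  lg <- log(st$emissions + 1)
  dd <- cbind(st$trait_table, lg)
  es3 <- plasticity_effect_sizes(dd, c(cat_$compound,
                                       morphology_catalog()$trait),
                                 "snow_treatment", "early", "control",
                                 volatile_traits = cat_$compound)
  expect_gt(es3$group_summary["volatile"], es3$group_summary["other"])
  expect_lt(abs(es3$group_summary["volatile"] - 0.2), 0.08)
  expect_lt(es3$group_summary["other"], 0.1)
})

test_that("plasticity correlation basics", {
  expect_equal(plasticity_correlation(1:5, 1:5)$r, 1)
  x <- c(1, 2, 3, 4)
  y <- c(1, -1, 1, -1) - mean(c(1, -1, 1, -1))
  expect_lt(abs(plasticity_correlation(x, resid(lm(y ~ x)))$r), 1e-10)
  expect_error(plasticity_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(plasticity_correlation(1:2, 1:2), ">= 3")
  # shared moisture-driven plasticity induces a positive correlation
  # between snowmelt and precipitation plasticity vectors
  cat_ <- compound_catalog()
  vols <- cat_$compound[1:12]
  set.seed(8)
  slope <- setNames(runif(12, 0.1, 0.3), vols)
  det <- vapply(1:15, function(i) {
    st <- simulate_study(seed = 400 + i, truth = true_params(
      plasticity = list(moisture = slope)), n_total = 360)
    dd <- cbind(st$trait_table, log(st$emissions[, vols] + 1))
    d_snow <- plasticity_effect_sizes(dd, vols, "snow_treatment",
                                      "early", "control")
    d_prec <- plasticity_effect_sizes(dd, vols, "precip_treatment",
                                      "reduced", "control")
    a <- tapply(d_snow$per_trait$d, d_snow$per_trait$trait, mean)
    b <- tapply(d_prec$per_trait$d, d_prec$per_trait$trait, mean)
    plasticity_correlation(a[vols], b[vols])$r > 0
  }, TRUE)
  expect_gte(mean(det), 0.6)
})
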