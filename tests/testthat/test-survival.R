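test_that("product-limit estimates match the hand calculation", {
  d <- data.frame(
    t = c(5, 10, 15, 20), e = c(0, 1, 0, 1), g = "all"
  )
  km <- kaplan_meier(d, "t", "e", "g")
  s <- km$curves
  expect_equal(s$estimate[s$time == 10], 2 / 3)
  expect_equal(s$estimate[s$time == 20], 0)
  expect_true(is.na(km$logrank$p_value))
  expect_identical(km$logrank$flag, "single_group")
})

test_that("log-rank is exactly null on duplicated groups", {
  d <- data.frame(
    t = rep(c(3, 6, 9, 12, 15), 2),
    e = rep(c(1, 0, 1, 1, 0), 2),
    g = rep(c("A", "B"), each = 5)
  )
  km <- kaplan_meier(d, "t", "e", "g")
  expect_equal(km$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(km$logrank$p_value, 1)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(2)
  t <- rexp(40)
  d <- data.frame(t = t, e = 1, g = "all")
  km <- kaplan_meier(d, "t", "e", "g")
  for (i in seq_len(nrow(km$curves))) {
    expect_equal(km$curves$estimate[i], mean(t > km$curves$time[i]), tolerance = 1e-12)
  }
})

test_that("zero events are flagged rather than tested", {
  d <- data.frame(t = 1:6, e = 0, g = rep(c("A", "B"), 3))
  km <- kaplan_meier(d, "t", "e", "g")
  expect_identical(km$logrank$flag, "no_events")
  expect_error(cox_univariate(d, "t", "e", "g"), "no events")
})

test_that("univariate Cox matches an independent partial-likelihood root", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 60
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = 0.1 * exp(0.8 * x))
    # no ties (continuous times), no censoring
    d <- data.frame(t = t, e = 1, g = factor(x, levels = c(0, 1)))
    fit <- cox_univariate(d, "t", "e", "g")
    expect_equal(fit$log_hr, oracle_cox_loghr(t, rep(1, n), x), tolerance = 1e-6)
  }
})

test_that("label swap inverts the hazard ratio", {
  set.seed(4)
  n <- 80
  x <- rbinom(n, 1, 0.4)
  d <- data.frame(
    t = rexp(n, 0.1 * exp(0.7 * x)),
    e = rbinom(n, 1, 0.8),
    g = factor(x, levels = c(0, 1))
  )
  a <- cox_univariate(d, "t", "e", "g")
  d$g <- factor(1 - x, levels = c(0, 1))
  b <- cox_univariate(d, "t", "e", "g")
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-6)
})

test_that("log-rank P equals the Cox score-test P on two-group tie-free data", {
  set.seed(5)
  x <- rbinom(50, 1, 0.5)
  t <- rexp(50, 0.1 * exp(0.5 * x))
  d <- data.frame(t = t, e = 1, g = factor(x))
  km <- kaplan_meier(d, "t", "e", "g")
  fit <- survival::coxph(survival::Surv(t, e) ~ g, data = d)
  sc <- summary(fit)$sctest
  expect_equal(km$logrank$p_value, unname(sc["pvalue"]), tolerance = 1e-6)
})

test_that("complete separation is flagged, not silently estimated", {
  d <- data.frame(
    t = c(1, 2, 3, 4, 10, 11, 12, 13),
    e = c(1, 1, 1, 1, 1, 1, 1, 1),
    g = factor(rep(c("bad", "good"), each = 4))
  )
  fit <- cox_univariate(d, "t", "e", "g")
  expect_identical(fit$flag, "separation")
})

test_that("multivariate fit drops constant covariates and reports retained terms", {
  set.seed(6)
  n <- 120
  d <- data.frame(
    os_months = rexp(n, 0.05), os_event = rbinom(n, 1, 0.7),
    group = factor(rbinom(n, 1, 0.5)),
    t_stage = sample(1:4, n, replace = TRUE),
    n_stage = sample(0:3, n, replace = TRUE),
    m_stage = 0, # constant on purpose
    mki67_expr = exp(rnorm(n, 6))
  )
  expect_warning(fit <- cox_multivariate(d), "m_stage")
  expect_false("m_stage" %in% fit$covariates$term)
  expect_true(all(c("t_stage", "n_stage", "mki67") %in% fit$covariates$term))
  expect_true(all(fit$covariates$p_value[fit$covariates$term %in% fit$retained] < 0.05))
})

test_that("without confounding the adjusted and unadjusted HRs agree", {
  cfg <- simulation_config(
    n_samples = 600, n_expression_genes = 40, seed = 9,
    driver_specs = list(
      driver_spec("GM001", "coding", 0.4, sprintf("G%04d", 1:10),
        effect_size = 1, survival_log_hr = log(2)
      )
    ),
    stage_effect = 0, censoring_rate = 0.3, n_gene_models = 2
  )
  bundle <- simulate_cohort(cfg)
  high <- bundle$truth$signature_high[["GM001|coding"]]
  d <- dplyr::mutate(bundle$clinical,
    group = factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  )
  uni <- cox_univariate(d)
  multi <- cox_multivariate(d)
  expect_equal(multi$indicator$log_hr, uni$log_hr, tolerance = 0.15)
})

test_that("the screen tests each recurrent gene twice and keeps skip bookkeeping", {
  cfg <- toy_config(seed = 13)
  bundle <- simulate_cohort(cfg)
  ann <- classify_variants(bundle$variants, bundle$gene_models)
  samples <- colnames(bundle$expression)
  rec <- recurrence_filter(recurrence_table(ann, samples), 0.02)
  labels <- tibble::tibble(sample_id = samples, subtype = factor("all"))
  res <- screen_survival(bundle, rec, labels, "all")
  expect_equal(nrow(res), 2 * nrow(rec))
  expect_setequal(unique(res$unit), c("gene-variant", "signature"))
  tested <- is.na(res$skip_reason)
  expect_true(all(res$hr_multivariate[tested] > 0))
  expect_true(all(res$p_multivariate[tested] > 0 & res$p_multivariate[tested] <= 1))
  expect_identical(
    res$significant,
    !is.na(res$p_multivariate) & res$p_multivariate < 0.05 & is.na(res$skip_reason)
  )
  # ordered by multivariate P with skips last
  p <- res$p_multivariate[!is.na(res$p_multivariate)]
  expect_false(is.unsorted(p))
})

test_that("a planted prognostic driver reaches significance in the screen", {
  cfg <- simulation_config(
    n_samples = 300, n_expression_genes = 120, seed = 17,
    driver_specs = list(
      driver_spec("GM001", "coding", 0.35, sprintf("G%04d", 1:25),
        effect_size = 1.2, survival_log_hr = log(3)
      )
    ),
    censoring_rate = 0.4, n_gene_models = 2,
    subtype_fractions = c(1, 0, 0)
  )
  bundle <- simulate_cohort(cfg)
  ann <- classify_variants(bundle$variants, bundle$gene_models)
  samples <- colnames(bundle$expression)
  rec <- recurrence_filter(recurrence_table(ann, samples), 0.02)
  labels <- assign_subtypes(
    marker_expression(bundle$expression), cfg$er_cutoff, cfg$her2_cutoff
  )
  res <- screen_survival(bundle, rec, labels, "ER-positive/HER2-negative")
  sig_row <- dplyr::filter(res, unit == "signature", gene == "GM001")
  expect_true(sig_row$significant)
  expect_gt(sig_row$hr_multivariate, 1)
})
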