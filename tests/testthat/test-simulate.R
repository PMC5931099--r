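test_that("configs are validated", {
  expect_error(simulation_config(subtype_fractions = c(0.5, 0.5, 0.5)))
  expect_error(simulation_config(censoring_rate = 1))
  expect_error(driver_spec("G", "coding", 1.2, "G0001"))
  # an unknown driver gene against supplied models is an error naming the gene
  models <- simulate_gene_models(2, 1e5, seed = 1)
  expect_error(
    simulate_cohort(
      simulation_config(driver_specs = list(
        driver_spec("NOT_A_GENE", "coding", 0.2, "G0001")
      ), n_samples = 20, n_expression_genes = 10),
      gene_models = models
    ),
    "NOT_A_GENE"
  )
  expect_error(
    simulate_cohort(simulation_config(
      n_samples = 20, n_expression_genes = 10,
      driver_specs = list(driver_spec("GM001", "coding", 0.2, "NOPE"))
    )),
    "NOPE"
  )
})

test_that("identical config and seed give a bit-identical bundle", {
  cfg <- toy_config(seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$variants, b$variants)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$gene_models, b$gene_models)
  # and a different seed gives a different cohort
  c2 <- simulate_cohort(toy_config(seed = 6))
  expect_false(identical(a$expression, c2$expression))
})

test_that("sample universes agree across the three layers", {
  bundle <- simulate_cohort(toy_config())
  samples <- colnames(bundle$expression)
  expect_identical(bundle$clinical$sample_id, samples)
  expect_true(all(bundle$variants$sample_id %in% samples))
  expect_true(all(bundle$clinical$os_months >= 0))
  expect_true(all(bundle$clinical$os_event %in% 0:1))
})

test_that("carrier counts match the binomial model and variants land in scope", {
  cfg <- simulation_config(
    n_samples = 500, n_expression_genes = 20, seed = 3,
    driver_specs = list(driver_spec("GM001", "coding", 0.2, "G0001")),
    n_gene_models = 3
  )
  bundle <- simulate_cohort(cfg)
  n_car <- length(bundle$truth$carrier_sets[["GM001|coding"]])
  ci <- qbinom(c(0.005, 0.995), 500, 0.2)
  expect_gte(n_car, ci[1])
  expect_lte(n_car, ci[2])
  # placement: every variant of the coding driver classifies as coding
  ann <- classify_variants(bundle$variants, bundle$gene_models)
  drv <- dplyr::filter(ann, gene == "GM001")
  expect_true(all(drv$region_class == "coding"))

  nc <- simulate_cohort(simulation_config(
    n_samples = 100, n_expression_genes = 20, seed = 4,
    driver_specs = list(driver_spec("GM002", "noncoding", 0.3, "G0002")),
    n_gene_models = 3
  ))
  ann2 <- classify_variants(nc$variants, nc$gene_models)
  drv2 <- dplyr::filter(ann2, gene == "GM002")
  expect_gt(nrow(drv2), 0)
  expect_true(all(drv2$region_class %in% c("promoter", "intron", "utr5", "utr3")))
})

test_that("planted expression shifts have the configured size and sign", {
  cfg <- simulation_config(
    n_samples = 400, n_expression_genes = 50, seed = 8,
    driver_specs = list(
      driver_spec("GM001", "coding", 0.5, c("G0001", "G0002"),
        effect_size = c(1.5, -1.5)
      )
    ),
    n_gene_models = 2
  )
  bundle <- simulate_cohort(cfg)
  carriers <- bundle$truth$carrier_sets[["GM001|coding"]]
  wt <- setdiff(colnames(bundle$expression), carriers)
  lfc_up <- mean(log(bundle$expression["G0001", carriers])) -
    mean(log(bundle$expression["G0001", wt]))
  lfc_down <- mean(log(bundle$expression["G0002", carriers])) -
    mean(log(bundle$expression["G0002", wt]))
  sdlog <- cfg$sdlog
  expect_equal(lfc_up / sdlog, 1.5, tolerance = 0.25)
  expect_equal(lfc_down / sdlog, -1.5, tolerance = 0.25)
})

test_that("subtype fractions are met in expectation relative to the cut-offs", {
  cfg <- simulation_config(
    n_samples = 1000, n_expression_genes = 10, seed = 12,
    subtype_fractions = c(0.5, 0.2, 0.3)
  )
  bundle <- simulate_cohort(cfg)
  labs <- assign_subtypes(
    marker_expression(bundle$expression), cfg$er_cutoff, cfg$her2_cutoff
  )
  frac <- prop.table(table(labs$subtype))[1:3]
  expect_equal(unname(frac["ER-positive/HER2-negative"]), 0.5, tolerance = 0.12)
  expect_equal(unname(frac["ER-negative/HER2-negative"]), 0.2, tolerance = 0.25)
  expect_equal(unname(frac["HER2-positive"]), 0.3, tolerance = 0.2)
  # classifier labels agree with the generating labels almost everywhere
  agree <- mean(as.character(labs$subtype) == bundle$truth$subtype$subtype)
  expect_gt(agree, 0.97)
})

test_that("the censoring solver hits the target fraction", {
  cfg <- simulation_config(
    n_samples = 2000, n_expression_genes = 5, seed = 21,
    censoring_rate = 0.7
  )
  bundle <- simulate_cohort(cfg)
  observed <- 1 - mean(bundle$clinical$os_event)
  expect_equal(observed, 0.7, tolerance = 0.05)
  # no censoring when the target is zero
  cfg0 <- simulation_config(
    n_samples = 200, n_expression_genes = 5, seed = 22, censoring_rate = 0
  )
  expect_equal(mean(simulate_cohort(cfg0)$clinical$os_event), 1)
})

test_that("stage confounding tilts stages only for signature-high samples", {
  cfg <- simulation_config(
    n_samples = 1500, n_expression_genes = 30, seed = 31,
    driver_specs = list(
      driver_spec("GM001", "coding", 0.3, sprintf("G%04d", 1:10), effect_size = 1)
    ),
    stage_confounding = 0.8, n_gene_models = 2
  )
  bundle <- simulate_cohort(cfg)
  high <- bundle$truth$signature_high[["GM001|coding"]]
  mean_stage <- function(idx) {
    with(bundle$clinical[idx, ], mean(t_stage + n_stage + m_stage))
  }
  expect_gt(mean_stage(high) - mean_stage(!high), 0.5)
})
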