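make_variant <- function(pos, chrom = "chr1", sample = "S1", ref = "A", alt = "T") {
  tibble::tibble(sample_id = sample, chrom = chrom, pos = pos, ref = ref, alt = alt)
}

test_that("promoter boundary is -2.5 kb inclusive, exclusive beyond", {
  models <- simulate_gene_models(5, 5e5, seed = 3)
  plus <- dplyr::filter(models, strand == "+") |> dplyr::distinct(gene_id, tss)
  tss <- plus$tss[1]
  inside <- classify_variants(make_variant(tss - 1), models)
  expect_equal(inside$region_class, "promoter")
  expect_equal(inside$gene, plus$gene_id[1])
  edge <- classify_variants(make_variant(tss - 2500), models)
  expect_equal(edge$region_class, "promoter")
  outside <- classify_variants(make_variant(tss - 2501), models)
  expect_equal(outside$region_class, "intergenic")
  expect_true(is.na(outside$gene))
})

test_that("minus-strand promoters mirror to the other side of the TSS", {
  models <- simulate_gene_models(8, 8e5, seed = 11)
  minus <- dplyr::filter(models, strand == "-") |> dplyr::distinct(gene_id, tss)
  expect_gt(nrow(minus), 0)
  tss <- minus$tss[1]
  expect_equal(classify_variants(make_variant(tss + 1), models)$region_class, "promoter")
  expect_equal(classify_variants(make_variant(tss + 2500), models)$region_class, "promoter")
  expect_equal(classify_variants(make_variant(tss + 2501), models)$region_class, "intergenic")
  # upstream on the genome = downstream of a minus-strand gene: not promoter
  expect_false(
    classify_variants(make_variant(tss - 1), models)$region_class == "promoter"
  )
})

test_that("random positions agree with the exhaustive interval-membership oracle", {
  models <- simulate_gene_models(12, 1.2e6, seed = 2)
  set.seed(4)
  positions <- sample.int(1.2e6, 300)
  v <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", pos = positions, ref = "A", alt = "C"
  )
  got <- classify_variants(v, models)
  for (p in positions) {
    want <- oracle_region("chr1", p, models)
    have <- got[got$pos == p, c("gene", "region_class")]
    expect_equal(
      sort(paste(have$gene, have$region_class)),
      sort(paste(want$gene, want$region_class))
    )
  }
})

test_that("labels are invariant under translation and unknown chromosomes warn", {
  models <- simulate_gene_models(6, 6e5, seed = 8)
  set.seed(9)
  v <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", pos = sample.int(6e5, 200),
    ref = "A", alt = "G"
  )
  base <- classify_variants(v, models)
  shift <- 1234L
  models2 <- dplyr::mutate(models, start = start + shift, end = end + shift, tss = tss + shift)
  v2 <- dplyr::mutate(v, pos = pos + shift)
  shifted <- classify_variants(v2, models2)
  expect_equal(base$region_class, shifted$region_class)
  expect_equal(base$gene, shifted$gene)

  expect_warning(
    res <- classify_variants(make_variant(100, chrom = "chrX"), models),
    "chrX"
  )
  expect_equal(res$region_class, "intergenic")
})

test_that("variant classes follow allele lengths", {
  expect_equal(
    variant_class(c("A", "A", "AT", "A", "-"), c("T", "AT", "A", "-", "G")),
    c("substitution", "insertion", "deletion", "deletion", "insertion")
  )
})

test_that("recurrence fractions and threshold modes behave as documented", {
  samples <- sprintf("S%03d", 1:930)
  ann <- tibble::tibble(
    sample_id = samples[1:19], chrom = "chr1", pos = 1:19, ref = "A", alt = "T",
    variant_id = 1:19, gene = "TP53", region_class = "coding",
    variant_class = "substitution"
  )
  rec <- recurrence_table(ann, samples)
  expect_equal(rec$n_carriers, 19L)
  expect_equal(rec$carrier_fraction, 19 / 930)
  # 19/930 = 2.04%: retained by the inclusive 2% rule
  expect_equal(nrow(recurrence_filter(rec, 0.02, mode = "at_least")), 1)
  # but not by a strict > 5% rule
  expect_equal(nrow(recurrence_filter(rec, 0.05, mode = "greater")), 0)
  # boundary: exactly at the threshold drops under "greater"
  rec$carrier_fraction <- 0.05
  expect_equal(nrow(recurrence_filter(rec, 0.05, mode = "greater")), 0)
  expect_equal(nrow(recurrence_filter(rec, 0.05, mode = "at_least")), 1)
})

test_that("planted carrier fractions are filtered by direct count", {
  set.seed(10)
  samples <- sprintf("S%03d", 1:200)
  frac <- c(A = 0.01, B = 0.03, C = 0.08)
  rows <- purrr::map(names(frac), function(g) {
    carriers <- sample(samples, round(frac[[g]] * 200))
    tibble::tibble(
      sample_id = carriers, chrom = "chr1", pos = seq_along(carriers),
      ref = "A", alt = "T", variant_id = seq_along(carriers), gene = g,
      region_class = "coding", variant_class = "substitution"
    )
  })
  ann <- dplyr::bind_rows(rows) |> dplyr::mutate(variant_id = dplyr::row_number())
  rec <- recurrence_table(ann, samples)
  kept <- recurrence_filter(rec, 0.05, mode = "greater")
  expect_equal(kept$gene, "C")
})

test_that("census filtering is a case-insensitive intersection", {
  expect_equal(census_filter(c("TP53", "FAKE1"), c("TP53", "PIK3CA")), "TP53")
  expect_equal(census_filter(c("tp53", "Pik3ca"), c("TP53", "PIK3CA")), c("tp53", "Pik3ca"))
  expect_warning(out <- census_filter(c("TP53"), character(0)), "empty")
  expect_length(out, 0)
  # random sets match the naive double loop
  set.seed(11)
  a <- replicate(100, paste(sample(LETTERS, 4), collapse = ""))
  b <- replicate(100, paste(sample(LETTERS, 4), collapse = ""))
  naive <- a[vapply(a, function(g) any(toupper(g) == toupper(b)), logical(1))]
  expect_equal(census_filter(a, b), naive)
})

test_that("per-sample burden conserves totals and fills zeros", {
  cfg <- toy_config()
  bundle <- simulate_cohort(cfg)
  ann <- classify_variants(bundle$variants, bundle$gene_models)
  samples <- colnames(bundle$expression)
  cod <- burden_per_sample(ann, samples, "coding")
  ncod <- burden_per_sample(ann, samples, "noncoding")
  expect_equal(nrow(cod), length(samples))
  expect_true(all(cod$n_variants >= 0))
  in_scope <- sum(!is.na(region_scope(ann$region_class)))
  expect_equal(sum(cod$n_variants) + sum(ncod$n_variants), in_scope)
  # samples without variants are present with zero
  quiet <- setdiff(samples, ann$sample_id)
  expect_true(all(cod$n_variants[cod$sample_id %in% quiet] == 0))
})
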