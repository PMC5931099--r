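sig_fixture <- function(n_genes = 80, n_car = 10, n_wt = 30, shift_genes = 8,
                        shift = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_car + n_wt))
  expr <- matrix(rnorm(n_genes * length(samples)),
    nrow = n_genes,
    dimnames = list(genes, samples)
  )
  expr[seq_len(shift_genes), seq_len(n_car)] <-
    expr[seq_len(shift_genes), seq_len(n_car)] + shift
  list(expr = expr, carriers = samples[seq_len(n_car)], wildtype = samples[-seq_len(n_car)])
}

test_that("genotype split partitions the subtype universe", {
  samples <- sprintf("S%03d", 1:100)
  rec <- tibble::tibble(
    gene = "TP53", scope = "coding", n_carriers = 10L,
    carrier_fraction = 0.1, carriers = list(samples[1:10])
  )
  sp <- split_by_genotype(rec, "TP53", "coding", samples)
  expect_length(sp$carriers, 10)
  expect_length(sp$wildtype, 90)
  expect_length(intersect(sp$carriers, sp$wildtype), 0)
  expect_setequal(c(sp$carriers, sp$wildtype), samples)
  expect_error(split_by_genotype(rec, "NOPE", "coding", samples), "NOPE")
})

test_that("signatures keep only significant genes, ranked and capped", {
  f <- sig_fixture()
  sig <- build_signature(f$expr, f$carriers, f$wildtype)
  expect_s3_class(sig, "mutation_signature")
  expect_true(all(sig$members$p_value <= 0.01))
  expect_false(is.unsorted(sig$members$p_value))
  # every strongly shifted gene is recovered as "up"
  hits <- dplyr::filter(sig$members, gene_id %in% sprintf("G%03d", 1:8))
  expect_equal(nrow(hits), 8)
  expect_true(all(hits$direction == "up"))

  # cap property: |members| = min(cap, #significant)
  all_p <- somaticsig:::mwu_by_gene(f$expr, f$carriers, f$wildtype)
  n_sig <- sum(all_p$p_value <= 0.01 & !is.na(all_p$direction))
  expect_equal(nrow(sig$members), min(100, n_sig))
  capped <- build_signature(f$expr, f$carriers, f$wildtype, cap = 3)
  expect_equal(nrow(capped$members), min(3, n_sig))
  expect_equal(capped$members$p_value, sort(all_p$p_value)[1:3], tolerance = 1e-12)
})

test_that("label swap flips every direction but leaves P-values unchanged", {
  f <- sig_fixture(n_genes = 40, shift_genes = 5)
  a <- somaticsig:::mwu_by_gene(f$expr, f$carriers, f$wildtype)
  b <- somaticsig:::mwu_by_gene(f$expr, f$wildtype, f$carriers)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  flip <- c(up = "down", down = "up")
  comparable <- !is.na(a$direction)
  expect_equal(unname(flip[a$direction[comparable]]), b$direction[comparable])
})

test_that("too-small splits and empty signatures error as documented", {
  f <- sig_fixture(n_car = 3)
  expect_error(build_signature(f$expr, f$carriers, f$wildtype), "too small")
  null_f <- sig_fixture(shift = 0, n_genes = 10, seed = 99)
  sig <- build_signature(null_f$expr, null_f$carriers, null_f$wildtype)
  if (nrow(sig$members) == 0) {
    expect_error(score_samples(null_f$expr, sig), "no member genes")
  }
})

test_that("scores equal a naive per-gene recomputation and invert cleanly", {
  f <- sig_fixture(n_genes = 30, shift_genes = 5)
  sig <- build_signature(f$expr, f$carriers, f$wildtype, cap = 5)
  sc <- score_samples(f$expr, sig)

  # naive recomputation: z-score each member, flip downs, average
  naive <- rep(0, ncol(f$expr))
  for (i in seq_len(nrow(sig$members))) {
    g <- sig$members$gene_id[i]
    z <- (f$expr[g, ] - mean(f$expr[g, ])) / sd(f$expr[g, ])
    naive <- naive + if (sig$members$direction[i] == "down") -z else z
  }
  naive <- naive / nrow(sig$members)
  expect_equal(sc$score, unname(naive), tolerance = 1e-12)

  # median dichotomy: strictly above the median is high
  med <- median(sc$score)
  expect_equal(as.character(sc$group), ifelse(sc$score > med, "high", "low"))
  expect_lte(abs(sum(sc$group == "high") - sum(sc$group == "low")), 2)

  # all-down version reverses the score order exactly
  sig_down <- sig
  sig_down$members$direction <- "down"
  sig_up <- sig
  sig_up$members$direction <- "up"
  expect_equal(
    score_samples(f$expr, sig_down)$score,
    -score_samples(f$expr, sig_up)$score,
    tolerance = 1e-12
  )

  # single-member signature is that gene's transformed expression
  one <- sig
  one$members <- sig$members[1, ]
  sc1 <- score_samples(f$expr, one)
  g <- one$members$gene_id
  z <- (f$expr[g, ] - mean(f$expr[g, ])) / sd(f$expr[g, ])
  expect_equal(sc1$score, unname(if (one$members$direction == "down") -z else z))
})

test_that("raw-scale scoring negates raw values of down genes", {
  f <- sig_fixture(n_genes = 20, shift_genes = 3)
  sig <- build_signature(f$expr, f$carriers, f$wildtype, cap = 3)
  sc <- score_samples(f$expr, sig, method = "raw")
  signs <- ifelse(sig$members$direction == "down", -1, 1)
  naive <- colMeans(f$expr[sig$members$gene_id, , drop = FALSE] * signs)
  expect_equal(sc$score, unname(naive), tolerance = 1e-12)
})

test_that("signature JSON round trip preserves definitions", {
  f <- sig_fixture()
  sig <- build_signature(f$expr, f$carriers, f$wildtype,
    source_gene = "TP53", region_scope = "coding"
  )
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(list(sig), json_path = json, tsv_path = tsv)
  back <- read_signatures(json)[[1]]
  expect_equal(back$members, sig$members, tolerance = 1e-12)
  expect_equal(back$source_gene, "TP53")
  expect_equal(back$n_carriers, sig$n_carriers)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(sig$members))
})
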