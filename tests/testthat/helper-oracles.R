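# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: the MWU oracle counts pairs instead of
# ranking, the region oracle scans every interval of every gene, the
# normalization oracle re-sorts from scratch.

# Exhaustive two-sided Mann-Whitney P by pair counting over every assignment
# of the pooled observations to the first group.
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) {
      u <- u + sum(ai > b) + 0.5 * sum(ai == b)
    }
    u
  }
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(x, y) - mu)
  combs <- utils::combn(n, n1)
  hits <- 0
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    u <- u_of(pooled[idx], pooled[-idx])
    if (abs(u - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(combs)
}

# Region label(s) of one position by scanning every interval of every gene.
# Returns a data.frame (gene, region_class), one row per touched gene, or a
# single intergenic row.
oracle_region <- function(chrom, pos, models) {
  prec <- c(cds = 1, utr5 = 2, utr3 = 3, intron = 4, promoter = 5, exon = 6)
  lab <- c(
    cds = "coding", utr5 = "utr5", utr3 = "utr3", intron = "intron",
    promoter = "promoter", exon = "coding"
  )
  out <- list()
  for (g in unique(models$gene_id)) {
    feats <- models[models$gene_id == g & models$chrom == chrom, ]
    best <- Inf
    best_feat <- NA
    for (i in seq_len(nrow(feats))) {
      if (pos >= feats$start[i] && pos <= feats$end[i] &&
        prec[[feats$feature[i]]] < best) {
        best <- prec[[feats$feature[i]]]
        best_feat <- feats$feature[i]
      }
    }
    if (is.finite(best)) {
      out[[length(out) + 1]] <- data.frame(gene = g, region_class = lab[[best_feat]])
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = NA_character_, region_class = "intergenic"))
  }
  do.call(rbind, out)
}

# Naive quantile normalization: sort each column, average across columns,
# hand values back by sorted position (ties get their block's mean).
oracle_quantile_normalize <- function(m) {
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    vals <- ref
    x <- m[o, j]
    for (v in unique(x)) {
      idx <- which(x == v)
      vals[idx] <- mean(ref[idx])
    }
    out[o, j] <- vals
  }
  out
}

# Naive probe collapse: per gene, recompute every probe's range and keep the
# argmax (ties by probe id).
oracle_collapse <- function(m, map) {
  map <- map[!is.na(map$gene_id), ]
  genes <- sort(unique(map$gene_id))
  rows <- lapply(genes, function(g) {
    probes <- sort(map$probe_id[map$gene_id == g])
    rng <- sapply(probes, function(p) max(m[p, ]) - min(m[p, ]))
    m[probes[which.max(rng)], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- genes
  out
}

# Cox partial-likelihood score for a binary covariate (no ties assumed);
# the root of the score function is the MLE, found independently of coxph.
oracle_cox_loghr <- function(time, event, x) {
  score <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(beta * x[risk])
      s <- s + x[i] - sum(x[risk] * w) / sum(w)
    }
    s
  }
  stats::uniroot(score, c(-10, 10), tol = 1e-10)$root
}

# Small deterministic cohort for interface tests.
toy_config <- function(seed = 42, ...) {
  simulation_config(
    n_samples = 80,
    n_expression_genes = 60,
    n_gene_models = 4,
    driver_specs = list(
      driver_spec("GM001", "coding", 0.3, sprintf("G%04d", 1:10),
        effect_size = 1.2, survival_log_hr = log(2)
      ),
      driver_spec("GM002", "noncoding", 0.25, sprintf("G%04d", 11:18),
        effect_size = -1
      )
    ),
    censoring_rate = 0.5,
    seed = seed,
    ...
  )
}

expect_same_tibble <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
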