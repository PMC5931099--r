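#' Specification of one planted driver
#'
#' A driver is a mutated gene with a region scope, a carrier fraction, a set
#' of target expression genes shifted in carriers, and a log hazard ratio
#' attached to the (constructed) signature-high status.
#'
#' @param gene Gene-model identifier carrying the variants.
#' @param region_scope `"coding"` or `"noncoding"`: where in the gene the
#'   variants are placed.
#' @param carrier_fraction Probability a sample carries a variant (0 < f < 1).
#' @param target_genes Character vector of expression-gene IDs shifted in
#'   carriers.
#' @param effect_size Shift in per-gene (log-scale) SD units; either one
#'   number recycled over targets or one signed number per target.
#' @param survival_log_hr Log hazard ratio attached to signature-high status
#'   (default 0).
#' @return A `driver_spec` list.
#' @export
driver_spec <- function(gene, region_scope = c("coding", "noncoding"),
                        carrier_fraction, target_genes,
                        effect_size = 1, survival_log_hr = 0) {
  region_scope <- match.arg(region_scope)
  stopifnot(
    carrier_fraction > 0, carrier_fraction < 1,
    length(target_genes) >= 1,
    length(effect_size) %in% c(1L, length(target_genes))
  )
  structure(
    list(
      gene = gene, region_scope = region_scope,
      carrier_fraction = carrier_fraction,
      target_genes = target_genes,
      effect_size = rep_len(effect_size, length(target_genes)),
      survival_log_hr = survival_log_hr
    ),
    class = "driver_spec"
  )
}

#' Simulation configuration for a synthetic breast-cancer cohort
#'
#' Collects every tunable of the generator, validated once. The defaults
#' emulate a TCGA-like cohort: subtype mix 50/20/30
#' (ER+/HER2-, ER-/HER2-, HER2+), marker expression on the classical
#' RNA-seq scale around the ER 3,700 and HER2 27,000 cut-offs, heavy-tailed
#' log-normal expression, a baseline hazard of 0.01 events/month (median
#' survival around 69 months for a baseline patient) and around 70% of
#' samples censored by independent exponential follow-up.
#'
#' @param n_samples Number of samples.
#' @param n_expression_genes Number of background expression genes (marker
#'   genes `ESR1`, `ERBB2`, `MKI67` are appended on top of these).
#' @param subtype_fractions Named or unnamed length-3 probabilities for
#'   ER+/HER2-, ER-/HER2-, HER2+; must sum to 1.
#' @param driver_specs List of [driver_spec()] objects.
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censoring_rate Target fraction of samples censored (0 <= c < 1).
#' @param stage_effect Log-hazard per unit of the combined ordinal stage
#'   (T + N + M).
#' @param stage_confounding Log-odds tilt making higher T/N stages more
#'   likely in signature-high samples (0 = no confounding).
#' @param seed Integer seed; fully determines the cohort.
#' @param n_gene_models,chrom_length Gene-model layout passed to
#'   [simulate_gene_models()] when no models are supplied.
#' @param er_cutoff,her2_cutoff Marker cut-offs the subtype fractions are
#'   anchored to.
#' @param marker_delta,marker_sd Log-scale offset and spread of marker
#'   expression around its cut-off (delta 1, sd 0.4 gives < 1%
#'   misclassification against the cut-off).
#' @param meanlog,sdlog Log-normal parameters of background expression
#'   (per-gene mean levels are drawn around `meanlog`).
#' @param indel_fraction Fraction of simulated variants that are indels
#'   (the rest are single-base substitutions).
#' @param t_stage_probs,n_stage_probs,m_stage_probs Categorical stage
#'   distributions (T in 1..4, N in 0..3, M in 0/1).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 200L,
                              n_expression_genes = 500L,
                              subtype_fractions = c(0.5, 0.2, 0.3),
                              driver_specs = list(),
                              baseline_hazard = 0.01,
                              censoring_rate = 0.7,
                              stage_effect = 0,
                              stage_confounding = 0,
                              seed = 1L,
                              n_gene_models = 10L,
                              chrom_length = NULL,
                              er_cutoff = 3700,
                              her2_cutoff = 27000,
                              marker_delta = 1,
                              marker_sd = 0.4,
                              meanlog = 6,
                              sdlog = 0.6,
                              indel_fraction = 0.15,
                              t_stage_probs = c(0.25, 0.55, 0.12, 0.08),
                              n_stage_probs = c(0.5, 0.32, 0.12, 0.06),
                              m_stage_probs = c(0.97, 0.03)) {
  stopifnot(
    n_samples >= 1, n_expression_genes >= 1, n_gene_models >= 1,
    length(subtype_fractions) == 3,
    abs(sum(subtype_fractions) - 1) <= 1e-9,
    all(subtype_fractions >= 0),
    baseline_hazard > 0,
    censoring_rate >= 0, censoring_rate < 1,
    indel_fraction >= 0, indel_fraction <= 1,
    length(t_stage_probs) == 4, length(n_stage_probs) == 4,
    length(m_stage_probs) == 2
  )
  for (d in driver_specs) {
    if (!inherits(d, "driver_spec")) abort("driver_specs must be driver_spec objects")
  }
  if (is.null(chrom_length)) {
    # generous default: ~20 kb worst-case footprint per gene
    chrom_length <- max(1e5, n_gene_models * 2e4)
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_expression_genes = as.integer(n_expression_genes),
      subtype_fractions = setNames(
        as.numeric(subtype_fractions),
        c("ER-positive/HER2-negative", "ER-negative/HER2-negative", "HER2-positive")
      ),
      driver_specs = driver_specs,
      baseline_hazard = baseline_hazard,
      censoring_rate = censoring_rate,
      stage_effect = stage_effect,
      stage_confounding = stage_confounding,
      seed = as.integer(seed),
      n_gene_models = as.integer(n_gene_models),
      chrom_length = chrom_length,
      er_cutoff = er_cutoff, her2_cutoff = her2_cutoff,
      marker_delta = marker_delta, marker_sd = marker_sd,
      meanlog = meanlog, sdlog = sdlog,
      indel_fraction = indel_fraction,
      t_stage_probs = t_stage_probs / sum(t_stage_probs),
      n_stage_probs = n_stage_probs / sum(n_stage_probs),
      m_stage_probs = m_stage_probs / sum(m_stage_probs)
    ),
    class = "simulation_config"
  )
}

#' Simulate a cohort bundle with known ground truth
#'
#' Generates, in a fixed random order (gene models, subtype markers,
#' variants, expression, survival) from a single seeded stream:
#'
#' * gene models (unless supplied), with the driver genes required to exist;
#' * per-sample subtype labels drawn from the configured fractions, and ER /
#'   HER2 marker expression drawn log-normally on the matching side of the
#'   configured cut-offs;
#' * for each driver, Bernoulli carrier status and one variant per carrier
#'   placed uniformly inside the gene's coding (CDS) or non-coding
#'   (promoter/UTR/intron) intervals;
#' * log-normal expression with each target gene shifted by its effect size
#'   (in log-scale SD units) in carriers;
#' * a constructed signature-high flag per driver (median split of the
#'   signed mean z-score of its target genes), exponential survival with
#'   linear predictor `sum(log HR * high) + stage_effect * (T + N + M)`,
#'   and independent exponential censoring whose rate is solved numerically
#'   to achieve the target censoring fraction.
#'
#' @param config A [simulation_config()].
#' @param gene_models Optional gene-model tibble; simulated when `NULL`.
#' @return A `cohort_bundle`: list with `expression` (genes x samples
#'   matrix), `variants`, `clinical`, `gene_models`, and a `truth` record
#'   (driver specs, carrier sets, signature-high flags, subtype labels,
#'   solved censoring rate).
#' @examples
#' cfg <- simulation_config(n_samples = 50, n_expression_genes = 40, seed = 3)
#' bundle <- simulate_cohort(cfg)
#' bundle
#' @export
simulate_cohort <- function(config, gene_models = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  withr::local_seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  # 1. gene models
  if (is.null(gene_models)) {
    driver_genes <- unique(purrr::map_chr(config$driver_specs, "gene"))
    if (length(driver_genes) > config$n_gene_models) {
      abort("more driver genes than gene models; raise n_gene_models")
    }
    defaults <- sprintf("GM%03d", seq_len(2L * config$n_gene_models))
    ids <- c(driver_genes, setdiff(defaults, driver_genes))[
      seq_len(config$n_gene_models)
    ]
    gene_models <- simulate_gene_models(
      config$n_gene_models, config$chrom_length,
      seed = sample.int(.Machine$integer.max, 1),
      gene_ids = ids
    )
  }
  for (d in config$driver_specs) {
    if (!d$gene %in% gene_models$gene_id) {
      abort(sprintf("driver gene %s absent from the gene models", d$gene))
    }
  }

  # 2. subtype labels and marker expression around the cut-offs
  subtype <- sample(names(config$subtype_fractions), n,
    replace = TRUE, prob = config$subtype_fractions
  )
  her2_pos <- subtype == "HER2-positive"
  er_pos_given <- ifelse(
    her2_pos,
    # HER2-positive tumours include ER+ and ER- cases; split evenly
    runif(n) < 0.5,
    subtype == "ER-positive/HER2-negative"
  )
  draw_marker <- function(positive, cutoff) {
    mu <- log(cutoff) + ifelse(positive, config$marker_delta, -config$marker_delta)
    exp(rnorm(n, mean = mu, sd = config$marker_sd))
  }
  er_expr <- draw_marker(er_pos_given, config$er_cutoff)
  her2_expr <- draw_marker(her2_pos, config$her2_cutoff)

  # 3. variants: Bernoulli carriers, one variant per carrier in scope
  scope_features <- list(
    coding = "cds", noncoding = c("promoter", "intron", "utr5", "utr3")
  )
  bases <- c("A", "C", "G", "T")
  carrier_sets <- list()
  variant_rows <- list()
  for (d in config$driver_specs) {
    is_carrier <- runif(n) < d$carrier_fraction
    carriers <- samples[is_carrier]
    carrier_sets[[paste(d$gene, d$region_scope, sep = "|")]] <- carriers
    if (length(carriers) == 0) next
    feats <- dplyr::filter(
      gene_models,
      .data$gene_id == d$gene, .data$feature %in% scope_features[[d$region_scope]]
    )
    if (nrow(feats) == 0) {
      abort(sprintf("gene %s has no %s intervals to place variants in", d$gene, d$region_scope))
    }
    widths <- feats$end - feats$start + 1
    iv <- sample.int(nrow(feats), length(carriers), replace = TRUE, prob = widths)
    pos <- feats$start[iv] +
      floor(runif(length(carriers)) * widths[iv])
    is_indel <- runif(length(carriers)) < config$indel_fraction
    ref <- sample(bases, length(carriers), replace = TRUE)
    alt <- purrr::map_chr(seq_along(carriers), function(i) {
      if (!is_indel[i]) {
        sample(setdiff(bases, ref[i]), 1)
      } else if (runif(1) < 0.5) {
        paste0(ref[i], sample(bases, 1)) # insertion
      } else {
        "-" # deletion of the ref base
      }
    })
    variant_rows[[length(variant_rows) + 1]] <- tibble(
      sample_id = carriers, gene = d$gene,
      chrom = feats$chrom[iv], pos = as.integer(pos), ref = ref, alt = alt
    )
  }
  variants <- bind_rows(variant_rows)
  if (nrow(variants) == 0) {
    variants <- tibble(
      sample_id = character(0), gene = character(0), chrom = character(0),
      pos = integer(0), ref = character(0), alt = character(0)
    )
  } else {
    variants <- arrange(variants, .data$sample_id, .data$gene, .data$pos)
  }

  # 4. expression: log-normal background, planted shifts on the log scale
  gene_ids <- sprintf("G%04d", seq_len(config$n_expression_genes))
  gene_mu <- rnorm(config$n_expression_genes, mean = config$meanlog, sd = 1)
  log_expr <- matrix(
    rnorm(config$n_expression_genes * n, mean = gene_mu, sd = config$sdlog),
    nrow = config$n_expression_genes, ncol = n,
    dimnames = list(gene_ids, samples)
  )
  for (d in config$driver_specs) {
    bad <- setdiff(d$target_genes, gene_ids)
    if (length(bad) > 0) {
      abort(sprintf(
        "driver %s targets unknown expression gene(s): %s",
        d$gene, paste(bad, collapse = ", ")
      ))
    }
    carriers <- carrier_sets[[paste(d$gene, d$region_scope, sep = "|")]]
    if (length(carriers) == 0) next
    log_expr[d$target_genes, carriers] <-
      log_expr[d$target_genes, carriers] +
      d$effect_size * config$sdlog
  }
  mki67 <- exp(rnorm(n, mean = config$meanlog + 1, sd = config$sdlog))
  expression <- rbind(
    exp(log_expr),
    ESR1 = er_expr, ERBB2 = her2_expr, MKI67 = mki67
  )

  # 5. survival: constructed signature-high flags, exponential PH model
  high_flags <- purrr::map(config$driver_specs, function(d) {
    z <- scale(t(log_expr[d$target_genes, , drop = FALSE]))
    truth_score <- as.numeric(z %*% sign(d$effect_size)) / length(d$target_genes)
    truth_score > median(truth_score)
  })
  names(high_flags) <- purrr::map_chr(
    config$driver_specs,
    ~ paste(.x$gene, .x$region_scope, sep = "|")
  )
  lp <- rep(0, n)
  for (i in seq_along(config$driver_specs)) {
    lp <- lp + config$driver_specs[[i]]$survival_log_hr * high_flags[[i]]
  }
  stage <- draw_stages(config, n, high_flags)
  lp <- lp + config$stage_effect *
    (stage$t_stage + stage$n_stage + stage$m_stage)
  rate <- config$baseline_hazard * exp(lp)
  event_time <- rexp(n, rate = rate)
  cens <- solve_censoring(rate, config$censoring_rate)
  cens_time <- if (is.finite(cens$rate) && cens$rate > 0) {
    rexp(n, rate = cens$rate)
  } else {
    rep(Inf, n)
  }
  os_months <- pmin(event_time, cens_time)
  os_event <- as.integer(event_time <= cens_time)

  clinical <- tibble(
    sample_id = samples,
    os_months = os_months, os_event = os_event,
    t_stage = stage$t_stage, n_stage = stage$n_stage, m_stage = stage$m_stage,
    mki67_expr = mki67
  )

  structure(
    list(
      expression = expression,
      variants = variants,
      clinical = clinical,
      gene_models = gene_models,
      truth = list(
        driver_specs = config$driver_specs,
        carrier_sets = carrier_sets,
        signature_high = high_flags,
        subtype = tibble(sample_id = samples, subtype = subtype),
        censoring_rate_solved = cens$rate,
        config = config
      )
    ),
    class = "cohort_bundle"
  )
}

# Stage covariates from fixed categorical distributions; an optional
# logistic tilt (stage_confounding, log-odds per category step) makes
# higher T/N stages more likely in samples that are signature-high for any
# driver, inducing confounding between score and stage.
draw_stages <- function(config, n, high_flags) {
  any_high <- if (length(high_flags) > 0) {
    Reduce(`|`, high_flags)
  } else {
    rep(FALSE, n)
  }
  tilt <- function(probs, levels, tilted) {
    if (!tilted || config$stage_confounding == 0) {
      return(probs)
    }
    w <- probs * exp(config$stage_confounding * seq_along(levels))
    w / sum(w)
  }
  draw <- function(levels, probs) {
    out <- integer(n)
    for (grp in c(FALSE, TRUE)) {
      idx <- which(any_high == grp)
      if (length(idx) == 0) next
      out[idx] <- sample(levels, length(idx),
        replace = TRUE, prob = tilt(probs, levels, grp)
      )
    }
    out
  }
  list(
    t_stage = draw(1:4, config$t_stage_probs),
    n_stage = draw(0:3, config$n_stage_probs),
    m_stage = draw(0:1, config$m_stage_probs)
  )
}

# Censoring rate c for independent exponential censoring: a subject with
# event rate r is censored with probability c / (c + r); solve the mean over
# subjects for the target fraction.
solve_censoring <- function(rates, target) {
  if (target <= 0) {
    return(list(rate = 0))
  }
  f <- function(cc) mean(cc / (cc + rates)) - target
  hi <- max(rates) * 1e4
  lo <- min(rates) * 1e-8
  list(rate = uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d samples, %d expression genes, %d variant(s), %d gene model(s)%s\n",
    ncol(x$expression), nrow(x$expression), nrow(x$variants),
    length(unique(x$gene_models$gene_id)),
    if (is.null(x$truth)) "" else " [with simulation truth]"
  ))
  invisible(x)
}

#' @export
glance.cohort_bundle <- function(x, ...) {
  tibble(
    n_samples = ncol(x$expression),
    n_expression_genes = nrow(x$expression),
    n_variants = nrow(x$variants),
    n_gene_models = length(unique(x$gene_models$gene_id)),
    n_events = sum(x$clinical$os_event),
    has_truth = !is.null(x$truth)
  )
}
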