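#' Write a cohort bundle to the standard file formats
#'
#' Expression as a genes-by-samples TSV (first column `gene_id`), variants
#' as a MAF-like TSV (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`), the clinical
#' table as TSV and the gene models as GTF. The simulation truth record is
#' not written. All TSVs are tab-separated UTF-8 with a header row.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    variants = file.path(dir, "variants.maf.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gene_models = file.path(dir, "gene_models.gtf")
  )
  expr_tbl <- as_tibble(bundle$expression, rownames = "gene_id")
  readr::write_tsv(expr_tbl, paths$expression)
  maf <- transmute(bundle$variants,
    Tumor_Sample_Barcode = .data$sample_id,
    Hugo_Symbol = .data$gene,
    Chromosome = .data$chrom,
    Start_Position = .data$pos,
    Reference_Allele = .data$ref,
    Tumor_Seq_Allele2 = .data$alt
  )
  readr::write_tsv(maf, paths$variants)
  readr::write_tsv(bundle$clinical, paths$clinical)
  write_gene_models(bundle$gene_models, paths$gene_models)
  invisible(paths)
}

#' Read a MAF-like variant table
#'
#' Accepts either the MAF column names (`Tumor_Sample_Barcode`,
#' `Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`) or the package's plain names (`sample_id`, `gene`,
#' `chrom`, `pos`, `ref`, `alt`). `Hugo_Symbol`/`gene` may be absent.
#'
#' @param path TSV file path.
#' @return Tibble with plain column names.
#' @export
read_variants <- function(path) {
  raw <- readr::read_tsv(path,
    show_col_types = FALSE, na = c("", "NA", "."),
    col_types = readr::cols(.default = readr::col_character())
  )
  rename_map <- c(
    sample_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
    chrom = "Chromosome", pos = "Start_Position",
    ref = "Reference_Allele", alt = "Tumor_Seq_Allele2"
  )
  for (plain in names(rename_map)) {
    maf <- rename_map[[plain]]
    if (maf %in% names(raw) && !plain %in% names(raw)) {
      names(raw)[names(raw) == maf] <- plain
    }
  }
  needed <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "variant file %s lacks column(s): %s", path,
      paste(missing, collapse = ", ")
    ))
  }
  if (!"gene" %in% names(raw)) raw$gene <- NA_character_
  bad <- which(is.na(suppressWarnings(as.integer(raw$pos))))
  if (length(bad) > 0) {
    abort(sprintf(
      "variant file %s: non-integer Start_Position at data line(s) %s",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  transmute(raw,
    sample_id = .data$sample_id, gene = .data$gene, chrom = .data$chrom,
    pos = as.integer(.data$pos), ref = .data$ref, alt = .data$alt
  )
}

#' Read a genes-by-samples expression TSV
#'
#' First column = gene IDs, remaining columns = samples.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  m <- as.matrix(tbl[, -1])
  if (!is.numeric(m)) abort(sprintf("expression file %s has non-numeric cells", path))
  rownames(m) <- as.character(tbl[[1]])
  m
}

#' Read a clinical TSV
#'
#' Requires `sample_id`, `os_months`, `os_event`, `t_stage`, `n_stage`,
#' `m_stage`, `mki67_expr`.
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  needed <- c(
    "sample_id", "os_months", "os_event", "t_stage", "n_stage",
    "m_stage", "mki67_expr"
  )
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf(
      "clinical file %s lacks column(s): %s", path,
      paste(missing, collapse = ", ")
    ))
  }
  if (!all(tbl$os_months >= 0)) abort("negative os_months in clinical table")
  if (!all(tbl$os_event %in% c(0, 1))) abort("os_event must be 0/1")
  tbl
}

#' Run configuration for a file-backed analysis
#'
#' @param expression,variants,clinical,gene_models File paths of the four
#'   inputs.
#' @param census Optional path to a plain-text census gene list.
#' @param er_cutoff,her2_cutoff Fixed marker cut-offs (used when no
#'   reference labels are given).
#' @param reference_labels Optional path to a TSV with `sample_id`, `er_status`,
#'   `her2_status` (0/1) for ROC-derived cut-offs.
#' @param recurrence_fraction,recurrence_mode Recurrence filter settings
#'   (default: at least 2% of total samples).
#' @param alpha,cap,min_carriers Signature construction settings.
#' @param screen_alpha Survival-screen significance level.
#' @param seed Integer seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(expression, variants, clinical, gene_models,
                       census = NULL,
                       er_cutoff = 3700, her2_cutoff = 27000,
                       reference_labels = NULL,
                       recurrence_fraction = 0.02,
                       recurrence_mode = c("at_least", "greater"),
                       alpha = 0.01, cap = 100L, min_carriers = 5L,
                       screen_alpha = 0.05, seed = 1L) {
  recurrence_mode <- match.arg(recurrence_mode)
  stopifnot(
    recurrence_fraction >= 0, recurrence_fraction <= 1,
    alpha > 0, alpha <= 1, cap >= 1, min_carriers >= 1,
    screen_alpha > 0, screen_alpha <= 1
  )
  structure(
    list(
      expression = expression, variants = variants, clinical = clinical,
      gene_models = gene_models, census = census,
      er_cutoff = er_cutoff, her2_cutoff = her2_cutoff,
      reference_labels = reference_labels,
      recurrence_fraction = recurrence_fraction,
      recurrence_mode = recurrence_mode,
      alpha = alpha, cap = as.integer(cap),
      min_carriers = as.integer(min_carriers),
      screen_alpha = screen_alpha, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Load a cohort bundle from the standard files
#'
#' Reads the four tables and takes the sample-ID intersection of
#' expression, variants and clinical (variant samples are allowed to be a
#' subset; variants referencing unknown samples are dropped with a
#' warning). Samples are ordered deterministically (sorted IDs).
#'
#' @param config A `run_config` (or a list of the four paths).
#' @return A `cohort_bundle` with `truth = NULL`.
#' @export
load_bundle <- function(config) {
  expr <- read_expression(config$expression)
  variants <- read_variants(config$variants)
  clinical <- read_clinical(config$clinical)
  models <- read_gene_models(config$gene_models)

  shared <- sort(intersect(colnames(expr), clinical$sample_id))
  if (length(shared) == 0) {
    abort(sprintf(
      "no shared sample IDs between expression (%d samples) and clinical (%d samples)",
      ncol(expr), nrow(clinical)
    ))
  }
  dropped <- length(union(colnames(expr), clinical$sample_id)) - length(shared)
  if (dropped > 0) {
    inform(sprintf(
      "load_bundle: %d sample(s) outside the expression/clinical intersection dropped (%d kept)",
      dropped, length(shared)
    ))
  }
  orphan <- setdiff(unique(variants$sample_id), shared)
  if (length(orphan) > 0) {
    warn(sprintf(
      "%d variant sample ID(s) not in the cohort: their %d variant(s) dropped",
      length(orphan), sum(variants$sample_id %in% orphan)
    ))
    variants <- dplyr::filter(variants, !.data$sample_id %in% orphan)
  }
  structure(
    list(
      expression = expr[, shared, drop = FALSE],
      variants = arrange(variants, .data$sample_id, .data$gene, .data$pos),
      clinical = clinical[match(shared, clinical$sample_id), ],
      gene_models = models,
      truth = NULL
    ),
    class = "cohort_bundle"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: load (or simulate) the cohort,
#' classify variants, assign subtypes (fixed cut-offs, or ROC-derived when
#' reference labels are supplied), filter gene recurrence (optionally
#' through a census list), build the mutation-associated signatures per
#' subtype and region scope, and screen everything against overall
#' survival. All tabular results plus a machine-readable manifest (package
#' version, seed, thresholds, a config hash and the counts at every filter
#' stage) are written under `out_dir`; no timestamps are embedded, so a
#' rerun with the same config is byte-identical.
#'
#' @param config A `simulation_config` (the cohort is simulated) or a
#'   `run_config` (the cohort is loaded from files).
#' @param out_dir Output directory.
#' @param recurrence_fraction,recurrence_mode,alpha,cap,min_carriers,screen_alpha
#'   Analysis thresholds (for a `run_config` the config's values are the
#'   defaults).
#' @param census Optional character vector of census symbols restricting
#'   the screened genes.
#' @param subtypes Subtype labels to screen (default: the three molecular
#'   subtypes).
#' @return Invisibly, a list with the `bundle`, `subtype_labels`,
#'   `recurrence`, `screen` tibble, `signatures` and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         recurrence_fraction = NULL, recurrence_mode = NULL,
                         alpha = NULL, cap = NULL, min_carriers = NULL,
                         screen_alpha = NULL, census = NULL,
                         subtypes = c(
                           "ER-positive/HER2-negative",
                           "ER-negative/HER2-negative",
                           "HER2-positive"
                         )) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  from_files <- inherits(config, "run_config")
  pick <- function(override, cfg_field, default) {
    override %||% (if (from_files) config[[cfg_field]] else NULL) %||% default
  }
  recurrence_fraction <- pick(recurrence_fraction, "recurrence_fraction", 0.02)
  recurrence_mode <- pick(recurrence_mode, "recurrence_mode", "at_least")
  alpha <- pick(alpha, "alpha", 0.01)
  cap <- pick(cap, "cap", 100L)
  min_carriers <- pick(min_carriers, "min_carriers", 5L)
  screen_alpha <- pick(screen_alpha, "screen_alpha", 0.05)
  if (is.null(census) && from_files && !is.null(config$census)) {
    census <- read_census_list(config$census)
  }

  # stage 1: cohort
  bundle <- if (from_files) load_bundle(config) else simulate_cohort(config)
  samples <- colnames(bundle$expression)
  counts <- list(n_samples = length(samples), n_variants = nrow(bundle$variants))

  # stage 2: annotate
  annotated <- classify_variants(bundle$variants, bundle$gene_models)
  counts$n_variant_gene_assignments <- sum(annotated$region_class != "intergenic")

  # stage 3: subtype
  er_cut <- if (from_files) config$er_cutoff else config$er_cutoff
  her2_cut <- config$her2_cutoff
  if (from_files && !is.null(config$reference_labels)) {
    labs <- readr::read_tsv(config$reference_labels, show_col_types = FALSE)
    mk <- marker_expression(bundle$expression)
    mk <- dplyr::left_join(mk, labs, by = "sample_id")
    er_cut <- roc_cutoff(mk$er, mk$er_status, marker = "ER")
    her2_cut <- roc_cutoff(mk$her2, mk$her2_status, marker = "HER2")
  }
  subtype_labels <- assign_subtypes(
    marker_expression(bundle$expression), er_cut, her2_cut
  )
  counts$n_classified <- sum(subtype_labels$subtype != "unclassified")

  # stage 4: recurrence (whole cohort) + optional census restriction
  recurrence <- recurrence_table(annotated, samples)
  counts$n_gene_scope_pairs <- nrow(recurrence)
  recurrent <- recurrence_filter(recurrence, recurrence_fraction,
    mode = recurrence_mode
  )
  counts$n_recurrent <- nrow(recurrent)
  if (!is.null(census)) {
    keep <- census_filter(unique(recurrent$gene), census)
    recurrent <- dplyr::filter(recurrent, .data$gene %in% keep)
    counts$n_after_census <- nrow(recurrent)
  }

  # stage 5-6: signatures + survival screen per subtype
  screens <- purrr::map(intersect(subtypes, unique(as.character(subtype_labels$subtype))),
    function(st) {
      screen_survival(bundle, recurrent, subtype_labels, st,
        alpha = alpha, cap = cap, min_carriers = min_carriers,
        screen_alpha = screen_alpha
      )
    }
  )
  screen <- bind_rows(screens)
  counts$n_units_tested <- sum(is.na(screen$skip_reason))
  counts$n_significant <- sum(screen$significant)

  # signatures of the significant units, serialized for transfer
  sig_rows <- dplyr::filter(screen, .data$unit == "signature", is.na(.data$skip_reason))
  signatures <- purrr::map(seq_len(nrow(sig_rows)), function(i) {
    st <- sig_rows$subtype[i]
    st_samples <- subtype_labels$sample_id[subtype_labels$subtype == st]
    split <- split_by_genotype(
      recurrent, sig_rows$gene[i], sig_rows$scope[i], st_samples
    )
    build_signature(
      bundle$expression[, st_samples, drop = FALSE],
      split$carriers, split$wildtype,
      alpha = alpha, cap = cap, min_carriers = min_carriers,
      source_gene = sig_rows$gene[i], region_scope = sig_rows$scope[i]
    )
  })
  names(signatures) <- paste(sig_rows$gene, sig_rows$scope, sig_rows$subtype,
    sep = "|"
  )

  manifest <- list(
    package = "somaticsig",
    version = as.character(packageVersion("somaticsig")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    thresholds = list(
      recurrence_fraction = recurrence_fraction,
      recurrence_mode = recurrence_mode,
      alpha = alpha, cap = cap, min_carriers = min_carriers,
      screen_alpha = screen_alpha
    ),
    counts = counts
  )

  readr::write_tsv(subtype_labels, file.path(out_dir, "subtypes.tsv"))
  readr::write_tsv(
    select(recurrence, -"carriers"),
    file.path(out_dir, "recurrence_all.tsv")
  )
  readr::write_tsv(
    select(recurrent, -"carriers"),
    file.path(out_dir, "recurrence_filtered.tsv")
  )
  readr::write_tsv(screen, file.path(out_dir, "screen.tsv"))
  write_signatures(signatures,
    json_path = file.path(out_dir, "signatures.json"),
    tsv_path = file.path(out_dir, "signatures.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    bundle = bundle, annotated = annotated, subtype_labels = subtype_labels,
    recurrence = recurrence, recurrent = recurrent, screen = screen,
    signatures = signatures, manifest = manifest
  ))
}
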