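#' Classify somatic variants into coding and non-coding region classes
#'
#' Each variant position is intersected with every gene's features and given
#' a region class per touched gene with precedence
#' coding (CDS) > UTR5/UTR3 > intron > promoter, so that the classes form a
#' disjoint partition of a gene's footprint. A variant touching no gene
#' footprint (including variants on chromosomes absent from the models) is
#' labelled `intergenic` with no owning gene. A variant inside the footprints
#' of two overlapping genes is reported once per gene, so that both genes'
#' carrier tables see it.
#'
#' The variant class is derived from the alleles: single-base equal-length
#' change is a `substitution`, longer alternate (or `-` reference) an
#' `insertion`, longer reference (or `-` alternate) a `deletion`.
#'
#' @param variants Tibble with columns `sample_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` (a pre-annotation `gene` column, e.g. from a MAF, is
#'   ignored and replaced).
#' @param models Gene-model feature tibble (see [simulate_gene_models()]);
#'   intron/promoter rows are derived automatically when missing.
#' @param promoter_length Promoter window used if promoter rows must be
#'   derived.
#' @return A tibble with one row per variant-gene assignment: the input
#'   columns plus `variant_id`, `gene` (NA when intergenic), `region_class`
#'   (`coding`, `utr5`, `utr3`, `intron`, `promoter`, `intergenic`) and
#'   `variant_class`.
#' @examples
#' models <- simulate_gene_models(2, 1e5, seed = 1)
#' v <- tibble::tibble(
#'   sample_id = "S1", chrom = "chr1",
#'   pos = models$tss[1], ref = "A", alt = "T"
#' )
#' classify_variants(v, models)
#' @export
classify_variants <- function(variants, models, promoter_length = 2500L) {
  stopifnot(all(c("sample_id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!any(models$feature == "promoter")) {
    models <- derive_model_features(models, promoter_length = promoter_length)
  }
  variants <- variants %>%
    ungroup() %>%
    select(-any_of(c("gene", "region_class", "variant_class", "variant_id"))) %>%
    mutate(variant_id = dplyr::row_number())

  unknown <- setdiff(unique(variants$chrom), unique(models$chrom))
  if (length(unknown) > 0) {
    warn(sprintf(
      "chromosome(s) %s not present in gene models; their variants are labelled intergenic",
      paste(unknown, collapse = ", ")
    ))
  }

  # precedence: smaller rank wins within a gene; plain exon rows only matter
  # for models lacking a CDS/UTR decomposition and then count as coding
  prec <- c(cds = 1L, utr5 = 2L, utr3 = 3L, intron = 4L, promoter = 5L, exon = 6L)
  label <- c(
    cds = "coding", utr5 = "utr5", utr3 = "utr3",
    intron = "intron", promoter = "promoter", exon = "coding"
  )

  hits_by_chrom <- purrr::map(split(variants, variants$chrom), function(v) {
    feats <- filter(models, .data$chrom == v$chrom[1])
    if (nrow(feats) == 0) {
      return(NULL)
    }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = v$pos, width = 1L),
      IRanges::IRanges(start = feats$start, end = feats$end)
    )
    if (length(ov) == 0) {
      return(NULL)
    }
    tibble(
      variant_id = v$variant_id[S4Vectors_from(ov)],
      gene = feats$gene_id[S4Vectors_to(ov)],
      feature = feats$feature[S4Vectors_to(ov)]
    )
  })
  hits <- bind_rows(hits_by_chrom)

  assigned <- if (nrow(hits) > 0) {
    hits %>%
      mutate(.prec = prec[.data$feature]) %>%
      group_by(.data$variant_id, .data$gene) %>%
      slice_min(.data$.prec, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      transmute(.data$variant_id, .data$gene,
        region_class = unname(label[.data$feature])
      )
  } else {
    tibble(
      variant_id = integer(0), gene = character(0),
      region_class = character(0)
    )
  }

  out <- variants %>%
    left_join(assigned, by = "variant_id", relationship = "many-to-many") %>%
    mutate(
      region_class = if_else(is.na(.data$region_class), "intergenic",
        .data$region_class
      ),
      variant_class = variant_class(.data$ref, .data$alt)
    ) %>%
    arrange(.data$variant_id, .data$gene)
  out
}

# Hits accessors kept in one place (they live in S4Vectors, not IRanges)
S4Vectors_from <- function(ov) S4Vectors::queryHits(ov)
S4Vectors_to <- function(ov) S4Vectors::subjectHits(ov)

#' Derive the variant class from reference and alternate alleles
#'
#' @param ref,alt Character vectors of alleles; `-` denotes the empty allele
#'   (MAF indel convention).
#' @return Character vector: `substitution`, `insertion` or `deletion`.
#' @export
variant_class <- function(ref, alt) {
  lr <- ifelse(ref == "-", 0L, nchar(ref))
  la <- ifelse(alt == "-", 0L, nchar(alt))
  dplyr::case_when(
    la > lr ~ "insertion",
    lr > la ~ "deletion",
    TRUE ~ "substitution"
  )
}

#' Region scope of a region class
#'
#' Collapses the fine region classes into the two scopes carrier status is
#' defined on: `coding`, or `noncoding` for promoter/UTR/intron. Intergenic
#' variants have no scope (`NA`).
#'
#' @param region_class Character vector of region classes.
#' @return Character vector of scopes.
#' @export
region_scope <- function(region_class) {
  dplyr::case_when(
    region_class == "coding" ~ "coding",
    region_class %in% c("promoter", "utr5", "utr3", "intron") ~ "noncoding",
    TRUE ~ NA_character_
  )
}

#' Per-gene carrier recurrence table
#'
#' Collapses all variants of a sample within one gene and region scope to a
#' single carrier flag and tabulates, per (gene, scope), the carrier set and
#' its fraction of the cohort.
#'
#' @param annotated Classified variants from [classify_variants()].
#' @param samples Character vector: the full cohort sample universe (the
#'   denominator; samples without variants count).
#' @return A tibble with columns `gene`, `scope`, `n_carriers`,
#'   `carrier_fraction` and a list-column `carriers`.
#' @export
recurrence_table <- function(annotated, samples) {
  n <- length(samples)
  stopifnot(n > 0)
  annotated %>%
    mutate(scope = region_scope(.data$region_class)) %>%
    filter(!is.na(.data$scope), .data$sample_id %in% samples) %>%
    group_by(.data$gene, .data$scope) %>%
    summarise(
      carriers = list(sort(unique(.data$sample_id))), .groups = "drop"
    ) %>%
    mutate(
      n_carriers = purrr::map_int(.data$carriers, length),
      carrier_fraction = .data$n_carriers / n
    ) %>%
    select("gene", "scope", "n_carriers", "carrier_fraction", "carriers") %>%
    arrange(.data$gene, .data$scope)
}

#' Filter a recurrence table by carrier fraction
#'
#' Two threshold modes mirror the two filters used in practice: an inclusive
#' "at least" rule (e.g. at least 2% of samples, so 19/930 = 2.04% passes a
#' 2% threshold) and a strict "greater than" rule (e.g. > 5% of cases).
#'
#' @param table Recurrence table from [recurrence_table()].
#' @param min_fraction Carrier-fraction threshold in `[0, 1]`.
#' @param mode `"at_least"` (`>=`, default) or `"greater"` (`>`).
#' @return The retained rows of `table`.
#' @export
recurrence_filter <- function(table, min_fraction,
                              mode = c("at_least", "greater")) {
  mode <- match.arg(mode)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (nrow(table) == 0) {
    return(table)
  }
  keep <- if (mode == "at_least") {
    table$carrier_fraction >= min_fraction
  } else {
    table$carrier_fraction > min_fraction
  }
  # genes with zero carriers are never recurrent, whatever the threshold
  table[keep & table$n_carriers > 0, , drop = FALSE]
}

#' Restrict genes to a cancer gene census list
#'
#' Case-insensitive intersection of gene symbols with a user-supplied census
#' list (e.g. the Cancer Gene Census symbols, read from a plain text file).
#' No census data is bundled.
#'
#' @param genes Character vector of gene symbols.
#' @param census_list Character vector of census symbols.
#' @return The elements of `genes` whose upper-cased symbol appears in the
#'   upper-cased census list, in input order.
#' @export
census_filter <- function(genes, census_list) {
  if (length(census_list) == 0) {
    warn("empty census list: no genes retained")
    return(genes[0])
  }
  genes[toupper(genes) %in% toupper(census_list)]
}

#' Read a plain-text census gene list
#'
#' One symbol per line; blank lines and lines starting with `#` ignored.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_census_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Per-sample variant burden within a region scope
#'
#' Counts distinct variants (not variant-gene assignments) per sample whose
#' region class falls in the requested scope. Samples with no variant in
#' scope get an explicit zero.
#'
#' @param annotated Classified variants from [classify_variants()].
#' @param samples Sample universe (zeros are filled in for these).
#' @param scope `"coding"` or `"noncoding"`.
#' @return Tibble with `sample_id` and integer `n_variants`.
#' @export
burden_per_sample <- function(annotated, samples, scope = c("coding", "noncoding")) {
  scope <- match.arg(scope)
  counts <- annotated %>%
    mutate(.scope = region_scope(.data$region_class)) %>%
    filter(.data$.scope == scope, .data$sample_id %in% samples) %>%
    distinct(.data$sample_id, .data$variant_id) %>%
    count(.data$sample_id, name = "n_variants")
  tibble(sample_id = samples) %>%
    left_join(counts, by = "sample_id") %>%
    mutate(n_variants = as.integer(tidyr::replace_na(.data$n_variants, 0L)))
}

#' Pairwise burden comparison between subtypes
#'
#' Two-sided Mann-Whitney U comparison of per-sample variant counts for
#' every pair of groups (or the requested pairs). Groups with fewer than two
#' samples are skipped with a warning.
#'
#' @param burden Tibble with columns `sample_id`, `n_variants` and `group`.
#' @param pairs Optional list of length-2 character vectors naming the
#'   comparisons; default all unordered pairs.
#' @return Tibble with `group1`, `group2`, `n1`, `n2`, `p_value`, `method`.
#' @export
compare_burden <- function(burden, pairs = NULL) {
  stopifnot(all(c("sample_id", "n_variants", "group") %in% names(burden)))
  groups <- split(burden$n_variants, burden$group)
  if (is.null(pairs)) {
    nm <- names(groups)
    pairs <- combn(nm, 2, simplify = FALSE)
  }
  rows <- purrr::map(pairs, function(p) {
    x <- groups[[p[1]]]
    y <- groups[[p[2]]]
    if (length(x) < 2 || length(y) < 2) {
      warn(sprintf("comparison %s vs %s skipped: group with < 2 samples", p[1], p[2]))
      return(NULL)
    }
    res <- mwu_test(x, y)
    tibble(
      group1 = p[1], group2 = p[2], n1 = res$n1, n2 = res$n2,
      statistic = res$statistic, p_value = res$p_value, method = res$method
    )
  })
  bind_rows(rows)
}
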