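#' Simulate strand-aware gene models
#'
#' Lays out non-overlapping gene models along a single synthetic chromosome.
#' Each gene has one or more exons, a 5' and a 3' UTR at the transcript ends,
#' a CDS in between, introns whenever there are two or more exons, a random
#' strand, and a promoter window covering the `promoter_length` bases
#' immediately upstream of the transcription start site (TSS) on the gene's
#' strand. Footprints (gene body plus promoter, plus a promoter-sized guard
#' on the downstream side) never overlap between genes.
#'
#' Coordinates are 1-based inclusive throughout (MAF convention).
#'
#' @param n_genes Number of genes to place (>= 1).
#' @param chrom_length Length of the synthetic chromosome in bases.
#' @param seed Integer seed; fully determines the output.
#' @param gene_ids Optional character vector of gene identifiers (length
#'   `n_genes`); defaults to `GM001, GM002, ...`.
#' @param chrom Chromosome name.
#' @param n_exons_range,exon_length_range,intron_length_range,utr_length_range
#'   Integer ranges (length-2 vectors) the per-gene structure is drawn from.
#' @param promoter_length Promoter window size upstream of the TSS (default
#'   2500 bases, i.e. -2.5 kb).
#' @param min_gap Minimum spacing between consecutive gene footprints.
#' @return A tibble of gene features with columns `gene_id`, `chrom`,
#'   `strand`, `tss`, `feature` (one of `exon`, `cds`, `utr5`, `utr3`,
#'   `intron`, `promoter`), `start`, `end`. Intron and promoter rows are
#'   derived features: they are recomputed, not stored, when models are
#'   round-tripped through GTF.
#' @examples
#' models <- simulate_gene_models(3, 1e5, seed = 7)
#' dplyr::count(models, feature)
#' @export
simulate_gene_models <- function(n_genes,
                                 chrom_length,
                                 seed,
                                 gene_ids = NULL,
                                 chrom = "chr1",
                                 n_exons_range = c(1L, 5L),
                                 exon_length_range = c(200L, 600L),
                                 intron_length_range = c(300L, 2000L),
                                 utr_length_range = c(60L, 180L),
                                 promoter_length = 2500L,
                                 min_gap = 500L) {
  stopifnot(n_genes >= 1, chrom_length >= 1)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("GM%03d", seq_len(n_genes))
  }
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))

  # worst-case footprint, used for the capacity check up front
  worst_span <- max(n_exons_range) * max(exon_length_range) +
    (max(n_exons_range) - 1) * max(intron_length_range)
  worst_footprint <- worst_span + 2L * promoter_length + 2L * min_gap
  if (n_genes * worst_footprint > chrom_length) {
    abort(sprintf(
      "chrom_length %d cannot hold %d genes (worst-case footprint %d bases each); increase chrom_length",
      as.integer(chrom_length), n_genes, as.integer(worst_footprint)
    ))
  }

  withr::local_seed(seed)
  cursor <- 1L
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_ex <- sample(seq(n_exons_range[1], n_exons_range[2]), 1L)
    ex_len <- sample(seq(exon_length_range[1], exon_length_range[2]), n_ex,
      replace = TRUE
    )
    in_len <- if (n_ex > 1) {
      sample(seq(intron_length_range[1], intron_length_range[2]), n_ex - 1L,
        replace = TRUE
      )
    } else {
      integer(0)
    }
    strand <- sample(c("+", "-"), 1L)
    gap <- sample(seq(min_gap, 2L * min_gap), 1L)
    gene_start <- cursor + promoter_length + gap
    starts <- gene_start + cumsum(c(0L, head(ex_len, -1) + in_len))
    ends <- starts + ex_len - 1L
    gene_end <- ends[n_ex]
    cursor <- gene_end + promoter_length

    # UTR lengths, capped so at least 30 transcript bases remain for the CDS
    tl <- sum(ex_len)
    u_cap <- max(utr_length_range[1], min(utr_length_range[2], (tl - 30L) %/% 2L))
    u5 <- sample(seq(utr_length_range[1], u_cap), 1L)
    u3 <- sample(seq(utr_length_range[1], u_cap), 1L)

    exons <- tibble(start = starts, end = ends)
    utr5_g <- transcript_to_genomic(1L, u5, exons, strand)
    cds_g <- transcript_to_genomic(u5 + 1L, tl - u3, exons, strand)
    utr3_g <- transcript_to_genomic(tl - u3 + 1L, tl, exons, strand)
    tss <- if (strand == "+") gene_start else gene_end
    prom <- promoter_window(tss, strand, promoter_length)
    introns <- if (n_ex > 1) {
      tibble(start = ends[-n_ex] + 1L, end = starts[-1] - 1L)
    } else {
      tibble(start = integer(0), end = integer(0))
    }

    feat <- bind_rows(
      mutate(exons, feature = "exon"),
      mutate(utr5_g, feature = "utr5"),
      mutate(cds_g, feature = "cds"),
      mutate(utr3_g, feature = "utr3"),
      mutate(introns, feature = "intron"),
      mutate(prom, feature = "promoter")
    )
    rows[[g]] <- mutate(feat,
      gene_id = gene_ids[g], chrom = chrom, strand = strand, tss = tss
    )
  }

  out <- bind_rows(rows)
  if (max(out$end) > chrom_length || min(out$start) < 1) {
    abort("gene layout exceeded chrom_length; increase chrom_length")
  }
  arrange(
    select(out, "gene_id", "chrom", "strand", "tss", "feature", "start", "end"),
    .data$gene_id, factor(.data$feature, levels = feature_levels()), .data$start
  )
}

feature_levels <- function() c("exon", "cds", "utr5", "utr3", "intron", "promoter")

#' Promoter window of a transcription start site
#'
#' The `length`-base window immediately upstream of the TSS on the given
#' strand: `[tss - length, tss - 1]` on `+`, `[tss + 1, tss + length]` on `-`.
#' The downstream side is excluded.
#'
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param length Window size in bases (default 2500).
#' @return A one-row tibble with `start` and `end` (1-based inclusive).
#' @export
promoter_window <- function(tss, strand, length = 2500L) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") {
    tibble(start = tss - length, end = tss - 1L)
  } else {
    tibble(start = tss + 1L, end = tss + length)
  }
}

# Map a transcript-coordinate interval [t_start, t_end] (1-based along the
# mRNA, 5'->3') onto genomic intervals given the exon set and strand. On the
# minus strand the transcript starts at the highest genomic coordinate.
transcript_to_genomic <- function(t_start, t_end, exons, strand) {
  lens <- exons$end - exons$start + 1L
  n_ex <- nrow(exons)
  ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  offs <- cumsum(c(0L, lens[ord][-n_ex]))
  pieces <- list()
  for (j in seq_len(n_ex)) {
    k <- ord[j]
    a <- max(t_start, offs[j] + 1L)
    b <- min(t_end, offs[j] + lens[k])
    if (a > b) next
    if (strand == "+") {
      g1 <- exons$start[k] + (a - offs[j] - 1L)
      g2 <- exons$start[k] + (b - offs[j] - 1L)
    } else {
      g2 <- exons$end[k] - (a - offs[j] - 1L)
      g1 <- exons$end[k] - (b - offs[j] - 1L)
    }
    pieces[[length(pieces) + 1L]] <- tibble(start = g1, end = g2)
  }
  arrange(bind_rows(pieces), .data$start)
}

# Recompute derived intron and promoter rows from stored exon/cds/utr rows.
derive_model_features <- function(models, promoter_length = 2500L) {
  stored <- filter(models, .data$feature %in% c("exon", "cds", "utr5", "utr3"))
  meta <- distinct(stored, .data$gene_id, .data$chrom, .data$strand, .data$tss)
  derived <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    ex <- arrange(
      filter(stored, .data$gene_id == m$gene_id, .data$feature == "exon"),
      .data$start
    )
    introns <- if (nrow(ex) > 1) {
      tibble(
        start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L,
        feature = "intron"
      )
    } else {
      NULL
    }
    prom <- mutate(promoter_window(m$tss, m$strand, promoter_length),
      feature = "promoter"
    )
    mutate(bind_rows(introns, prom),
      gene_id = m$gene_id, chrom = m$chrom, strand = m$strand, tss = m$tss
    )
  })
  arrange(
    select(
      bind_rows(stored, derived),
      "gene_id", "chrom", "strand", "tss", "feature", "start", "end"
    ),
    .data$gene_id, factor(.data$feature, levels = feature_levels()), .data$start
  )
}

#' Write and read gene models as GTF
#'
#' Only the stored features (exon, CDS, UTRs) are written; introns and
#' promoter windows are derived on read, so a write/read round trip
#' reproduces the model table exactly.
#'
#' @param models Gene-model feature tibble as returned by
#'   [simulate_gene_models()].
#' @param path File path of the GTF.
#' @param promoter_length Promoter window used when re-deriving features.
#' @return `write_gene_models()` returns `path` invisibly;
#'   `read_gene_models()` returns the feature tibble.
#' @export
write_gene_models <- function(models, path) {
  stored <- filter(models, .data$feature %in% c("exon", "cds", "utr5", "utr3"))
  type_map <- c(
    exon = "exon", cds = "CDS",
    utr5 = "five_prime_utr", utr3 = "three_prime_utr"
  )
  gr <- GenomicRanges::GRanges(
    seqnames = stored$chrom,
    ranges = IRanges::IRanges(start = stored$start, end = stored$end),
    strand = stored$strand,
    type = unname(type_map[stored$feature]),
    gene_id = stored$gene_id
  )
  # CDS phase is irrelevant here (no translation is ever done)
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path, promoter_length = 2500L) {
  gr <- rtracklayer::import(path, format = "gtf")
  type_map <- c(
    exon = "exon", CDS = "cds",
    five_prime_utr = "utr5", three_prime_utr = "utr3"
  )
  feats <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = unname(type_map[as.character(gr$type)]),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  feats <- filter(feats, !is.na(.data$feature))
  # TSS = 5' end of the gene span on its strand
  tss_tbl <- feats %>%
    group_by(.data$gene_id) %>%
    summarise(
      tss = if (first(.data$strand) == "+") min(.data$start) else max(.data$end),
      .groups = "drop"
    )
  feats <- left_join(feats, tss_tbl, by = "gene_id")
  derive_model_features(feats, promoter_length = promoter_length)
}
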