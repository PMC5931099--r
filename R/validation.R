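#' Quantile-normalize an expression matrix
#'
#' Forces every column onto the common reference distribution formed by the
#' row-wise means of the column-sorted matrix, preserving within-column
#' ranks. Tied values receive the mean of the reference values of their tied
#' block, so the operation is deterministic; without ties every column ends
#' up with the identical sorted value multiset and the map is idempotent.
#'
#' @param m Numeric matrix (rows = features, columns = samples) with at
#'   least two columns and no missing values.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' m <- matrix(c(1, 5, 3, 2, 8, 4), ncol = 2)
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    abort(sprintf("matrix contains %d missing value(s); impute or drop first", n_missing))
  }
  if (ncol(m) < 2) {
    warn("single-column matrix: quantile normalization is the identity")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    o <- order(x)
    blocks <- cumsum(c(TRUE, diff(x[o]) != 0)) # tie blocks in sorted order
    block_mean <- tapply(ref, blocks, mean)
    y <- numeric(length(x))
    y[o] <- block_mean[blocks]
    y
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse a probe-level matrix to one row per gene
#'
#' Probes without a gene mapping are removed; for genes targeted by several
#' probes the probe with the largest detection range across samples is kept
#' verbatim (no averaging). The detection range is max - min by default; an
#' inter-quartile variant is available since the notion of "highest
#' detection range" admits both readings. Range ties are broken by probe ID
#' so the collapse is deterministic.
#'
#' @param m Probes-by-samples numeric matrix with probe IDs as row names.
#' @param probe_map Tibble/data frame with columns `probe_id` and `gene_id`
#'   (`NA` gene = unmapped, removed).
#' @param stat `"range"` (max - min, default) or `"iqr"`.
#' @return Genes-by-samples matrix; genes with no mapped probe are absent.
#' @export
collapse_probes <- function(m, probe_map, stat = c("range", "iqr")) {
  stat <- match.arg(stat)
  stopifnot(
    is.matrix(m), !is.null(rownames(m)),
    all(c("probe_id", "gene_id") %in% names(probe_map))
  )
  map <- probe_map %>%
    filter(!is.na(.data$gene_id), .data$probe_id %in% rownames(m)) %>%
    distinct(.data$probe_id, .keep_all = TRUE)
  if (nrow(map) == 0) {
    return(m[0, , drop = FALSE])
  }
  spread <- vapply(map$probe_id, function(p) {
    x <- m[p, ]
    if (stat == "range") max(x) - min(x) else stats::IQR(x)
  }, numeric(1))
  chosen <- map %>%
    mutate(spread = unname(spread)) %>%
    arrange(.data$gene_id, dplyr::desc(.data$spread), .data$probe_id) %>%
    group_by(.data$gene_id) %>%
    slice(1) %>%
    ungroup()
  out <- m[chosen$probe_id, , drop = FALSE]
  rownames(out) <- chosen$gene_id
  out[order(rownames(out)), , drop = FALSE]
}

#' Transfer a discovery signature to an independent cohort
#'
#' Rescoring only: the discovery gene list and directions are frozen; no
#' signature is rebuilt in the target cohort. Member genes absent from the
#' target matrix (e.g. not covered by the array's probes) are dropped, and
#' when the surviving fraction falls below `min_overlap_fraction` the
#' signature is returned as untestable rather than scored on too thin an
#' overlap - mirroring signatures that cannot be validated for lack of
#' specific probe sets.
#'
#' @param sig A `mutation_signature` from the discovery cohort.
#' @param target Genes-by-samples matrix of the validation cohort (after
#'   probe collapse / normalization).
#' @param min_overlap_fraction Minimum fraction of member genes that must be
#'   present (default 0.5).
#' @param method Scoring scale passed to [score_samples()].
#' @return A `signature_transfer`: list with `testable`,
#'   `overlap_fraction`, `n_members`, `n_present`, `source_gene`,
#'   `region_scope` and (when testable) `scores`, a `signature_score`
#'   tibble.
#' @export
transfer_signature <- function(sig, target, min_overlap_fraction = 0.5,
                               method = c("zscore", "raw")) {
  method <- match.arg(method)
  stopifnot(inherits(sig, "mutation_signature"))
  present <- intersect(sig$members$gene_id, rownames(target))
  n_members <- nrow(sig$members)
  overlap <- if (n_members == 0) 0 else length(present) / n_members
  base <- list(
    testable = FALSE, overlap_fraction = overlap,
    n_members = n_members, n_present = length(present),
    source_gene = sig$source_gene, region_scope = sig$region_scope,
    scores = NULL
  )
  if (n_members == 0 || overlap < min_overlap_fraction) {
    return(structure(base, class = "signature_transfer"))
  }
  sub <- sig
  sub$members <- dplyr::filter(sig$members, .data$gene_id %in% present)
  base$testable <- TRUE
  base$scores <- score_samples(target, sub, method = method)
  structure(base, class = "signature_transfer")
}

#' @export
print.signature_transfer <- function(x, ...) {
  cat(sprintf(
    "<signature_transfer> %s (%s): %d/%d member gene(s) present (%.0f%%): %s\n",
    x$source_gene, x$region_scope, x$n_present, x$n_members,
    100 * x$overlap_fraction,
    if (x$testable) "scored" else "untestable"
  ))
  invisible(x)
}

#' @export
glance.signature_transfer <- function(x, ...) {
  tibble(
    source_gene = x$source_gene, region_scope = x$region_scope,
    n_members = x$n_members, n_present = x$n_present,
    overlap_fraction = x$overlap_fraction, testable = x$testable
  )
}
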