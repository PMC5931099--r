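#' ROC-derived expression cut-off for a binary marker status
#'
#' Chooses the expression cut-off that maximises Youden's J
#' (sensitivity + specificity - 1) against a binary reference status (e.g.
#' immunohistochemistry ER status), scanning every midpoint between
#' consecutive sorted unique values plus open-ended thresholds below and
#' above the data. A sample is called positive when its value is at or above
#' the cut-off. Ties in J are broken toward the lower cut-off (maximising
#' sensitivity). The AUC is the rank (Mann-Whitney) statistic of positive vs
#' negative values.
#'
#' @param values Numeric per-sample marker expression.
#' @param labels Logical (or 0/1) per-sample reference status; both classes
#'   must be present.
#' @param marker Marker name stored in the result (e.g. `"ER"`).
#' @return A `cutoff_model`: list with `marker`, `cutoff`, `auc`,
#'   `sensitivity`, `specificity`, `j`, `derivation = "roc"`.
#' @examples
#' roc_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), marker = "ER")
#' @export
roc_cutoff <- function(values, labels, marker = "marker") {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.logical(labels[keep])
  if (length(unique(labels)) < 2) {
    abort("reference labels contain a single class; a ROC cut-off is undefined")
  }
  pos <- values[labels]
  neg <- values[!labels]
  uniq <- sort(unique(values))
  thresholds <- c(
    uniq[1] - 1,
    (head(uniq, -1) + tail(uniq, -1)) / 2,
    uniq[length(uniq)] + 1
  )
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1] # lowest threshold among J ties
  auc <- (sum(rank(c(pos, neg))[seq_along(pos)]) -
    length(pos) * (length(pos) + 1) / 2) / (length(pos) * length(neg))
  structure(
    list(
      marker = marker, cutoff = thresholds[best], auc = auc,
      sensitivity = sens[best], specificity = spec[best], j = j[best],
      derivation = "roc"
    ),
    class = "cutoff_model"
  )
}

#' Fixed (externally supplied) marker cut-off
#'
#' @param cutoff Expression cut-off on the scale of the input matrix.
#' @param marker Marker name.
#' @return A `cutoff_model` with `derivation = "fixed"` and `auc = NA`.
#' @export
fixed_cutoff <- function(cutoff, marker = "marker") {
  structure(
    list(
      marker = marker, cutoff = cutoff, auc = NA_real_,
      sensitivity = NA_real_, specificity = NA_real_, j = NA_real_,
      derivation = "fixed"
    ),
    class = "cutoff_model"
  )
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf(
    "<cutoff_model> %s: cutoff %.4g (%s)%s\n",
    x$marker, x$cutoff, x$derivation,
    if (is.na(x$auc)) "" else sprintf(", AUC %.3f, J %.3f", x$auc, x$j)
  ))
  invisible(x)
}

#' @export
glance.cutoff_model <- function(x, ...) {
  tibble(
    marker = x$marker, cutoff = x$cutoff, auc = x$auc,
    sensitivity = x$sensitivity, specificity = x$specificity, j = x$j,
    derivation = x$derivation
  )
}

#' Assign molecular breast-cancer subtypes from ER and HER2 expression
#'
#' HER2 expression at or above its cut-off assigns `HER2-positive`
#' regardless of ER (the HER2-positive group includes ER-positive and
#' ER-negative tumours); otherwise ER at or above its cut-off assigns
#' `ER-positive/HER2-negative`, else `ER-negative/HER2-negative`. A value
#' exactly at the cut-off counts as positive. Samples missing either marker
#' are labelled `unclassified` with a warning and should be excluded
#' downstream.
#'
#' @param markers Tibble with columns `sample_id`, `er`, `her2` (expression
#'   on the same scale as the cut-offs; the classical RNA-seq cut-offs are
#'   3,700 for ER and 27,000 for HER2).
#' @param er_cut,her2_cut `cutoff_model` objects (or bare numbers).
#' @return Tibble with `sample_id` and factor `subtype`.
#' @export
assign_subtypes <- function(markers, er_cut, her2_cut) {
  stopifnot(all(c("sample_id", "er", "her2") %in% names(markers)))
  ec <- if (inherits(er_cut, "cutoff_model")) er_cut$cutoff else er_cut
  hc <- if (inherits(her2_cut, "cutoff_model")) her2_cut$cutoff else her2_cut
  lev <- c(
    "ER-positive/HER2-negative", "ER-negative/HER2-negative",
    "HER2-positive", "unclassified"
  )
  out <- markers %>%
    mutate(subtype = dplyr::case_when(
      is.na(.data$er) | is.na(.data$her2) ~ "unclassified",
      .data$her2 >= hc ~ "HER2-positive",
      .data$er >= ec ~ "ER-positive/HER2-negative",
      TRUE ~ "ER-negative/HER2-negative"
    )) %>%
    transmute(.data$sample_id, subtype = factor(.data$subtype, levels = lev))
  n_un <- sum(out$subtype == "unclassified")
  if (n_un > 0) {
    warn(sprintf("%d sample(s) missing a marker value: labelled unclassified", n_un))
  }
  out
}

#' Extract marker expression rows from an expression matrix
#'
#' @param expr Genes-by-samples matrix.
#' @param er_gene,her2_gene Row names of the ER and HER2 marker genes.
#' @return Tibble with `sample_id`, `er`, `her2`.
#' @export
marker_expression <- function(expr, er_gene = "ESR1", her2_gene = "ERBB2") {
  missing <- setdiff(c(er_gene, her2_gene), rownames(expr))
  if (length(missing) > 0) {
    abort(sprintf(
      "marker gene(s) %s absent from the expression matrix",
      paste(missing, collapse = ", ")
    ))
  }
  tibble(
    sample_id = colnames(expr),
    er = unname(expr[er_gene, ]),
    her2 = unname(expr[her2_gene, ])
  )
}
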