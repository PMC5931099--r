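#' Split a sample universe by genotype (carrier vs wild-type)
#'
#' @param recurrence Recurrence table from [recurrence_table()].
#' @param gene,scope The (gene, region scope) whose carrier set defines the
#'   genotype.
#' @param samples Sample universe (typically one molecular subtype).
#' @return List with character vectors `carriers` and `wildtype`: a disjoint,
#'   exhaustive partition of `samples`.
#' @export
split_by_genotype <- function(recurrence, gene, scope, samples) {
  row <- dplyr::filter(recurrence, .data$gene == !!gene, .data$scope == !!scope)
  if (nrow(row) != 1) {
    abort(sprintf("gene %s with scope %s not present in the recurrence table", gene, scope))
  }
  carriers <- intersect(samples, row$carriers[[1]])
  list(carriers = carriers, wildtype = setdiff(samples, carriers))
}

#' Build a mutation-associated expression signature
#'
#' For one genotype split (carriers vs wild-type of a gene in a region
#' scope), every expression gene is tested with a two-sided Mann-Whitney U
#' test. Genes significant at `alpha` (raw P, no multiplicity correction:
#' the screen is deliberately run at an uncorrected P <= 0.01) are ranked by
#' ascending P-value and truncated to at most `cap` members. Each member
#' carries a direction: `up` when carriers express it higher than wild-type,
#' `down` otherwise. P-value ties at the cap boundary are broken by gene ID
#' so the output is deterministic.
#'
#' @param expr Genes-by-samples expression matrix (named rows/columns).
#' @param carriers,wildtype Character vectors of sample IDs (disjoint).
#' @param alpha Per-gene significance threshold on the raw P (default 0.01).
#' @param cap Maximum number of member genes (default 100).
#' @param min_carriers Minimum size of either group (default 5).
#' @param source_gene,region_scope Metadata stored on the signature.
#' @param exclude_source Drop the source gene's own expression row from the
#'   candidate members (default `FALSE`: the mutated gene may join its own
#'   signature).
#' @return A `mutation_signature`: list with a `members` tibble (`gene_id`,
#'   `p_value`, `direction`, sorted by P then gene ID), `source_gene`,
#'   `region_scope`, `n_carriers`, `n_wildtype`, `alpha`, `cap`. An empty
#'   `members` tibble marks a signature that is untestable downstream.
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(50 * 30), 50, 30,
#'   dimnames = list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:30))
#' )
#' expr[1:5, 1:10] <- expr[1:5, 1:10] + 3
#' sig <- build_signature(expr, colnames(expr)[1:10], colnames(expr)[11:30])
#' tidy(sig)
#' @export
build_signature <- function(expr, carriers, wildtype,
                            alpha = 0.01, cap = 100L, min_carriers = 5L,
                            source_gene = NA_character_,
                            region_scope = NA_character_,
                            exclude_source = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (length(intersect(carriers, wildtype)) > 0) {
    abort("carriers and wildtype overlap")
  }
  missing <- setdiff(c(carriers, wildtype), colnames(expr))
  if (length(missing) > 0) {
    abort(sprintf("%d sample(s) absent from the expression matrix", length(missing)))
  }
  if (length(carriers) < min_carriers || length(wildtype) < min_carriers) {
    abort(sprintf(
      "genotype split too small (%d carriers / %d wild-type, minimum %d)",
      length(carriers), length(wildtype), min_carriers
    ))
  }
  if (exclude_source && !is.na(source_gene)) {
    expr <- expr[setdiff(rownames(expr), source_gene), , drop = FALSE]
  }
  tests <- mwu_by_gene(expr, carriers, wildtype)
  members <- tests %>%
    filter(.data$p_value <= alpha, !is.na(.data$direction)) %>%
    arrange(.data$p_value, .data$gene_id) %>%
    head(cap) %>%
    select("gene_id", "p_value", "direction")
  structure(
    list(
      members = members,
      source_gene = source_gene, region_scope = region_scope,
      n_carriers = length(carriers), n_wildtype = length(wildtype),
      alpha = alpha, cap = cap
    ),
    class = "mutation_signature"
  )
}

#' @export
print.mutation_signature <- function(x, ...) {
  cat(sprintf(
    "<mutation_signature> %s (%s): %d member gene(s), %d carriers / %d wild-type\n",
    x$source_gene, x$region_scope, nrow(x$members), x$n_carriers, x$n_wildtype
  ))
  invisible(x)
}

#' @describeIn build_signature Member genes as a tibble.
#' @param x A `mutation_signature`.
#' @param ... Unused.
#' @export
tidy.mutation_signature <- function(x, ...) {
  mutate(x$members,
    source_gene = x$source_gene, region_scope = x$region_scope,
    .before = 1
  )
}

#' @describeIn build_signature One-row summary.
#' @export
glance.mutation_signature <- function(x, ...) {
  tibble(
    source_gene = x$source_gene, region_scope = x$region_scope,
    n_members = nrow(x$members), n_up = sum(x$members$direction == "up"),
    n_down = sum(x$members$direction == "down"),
    n_carriers = x$n_carriers, n_wildtype = x$n_wildtype,
    alpha = x$alpha, cap = x$cap
  )
}

#' Score samples against a signature and dichotomise at the median
#'
#' The signature score of a sample is the mean over member genes of the
#' gene's expression with downregulated members inverted. By default each
#' member is first z-scored across the cohort (so inversion is a sign flip
#' on a centred scale and no high-magnitude gene dominates the mean); with
#' `method = "raw"` the raw expression is used and down genes enter negated.
#' Samples strictly above the cohort-median score are `high`, the rest
#' `low`.
#'
#' @param expr Genes-by-samples expression matrix containing every member
#'   gene.
#' @param sig A `mutation_signature` with at least one member.
#' @param method `"zscore"` (default) or `"raw"`.
#' @return A `signature_score` tibble with columns `sample_id`, `score` and
#'   factor `group` (`high`/`low`); the median is stored as an attribute.
#' @export
score_samples <- function(expr, sig, method = c("zscore", "raw")) {
  method <- match.arg(method)
  stopifnot(inherits(sig, "mutation_signature"))
  if (nrow(sig$members) == 0) {
    abort(sprintf(
      "signature %s (%s) has no member genes and cannot be scored",
      sig$source_gene, sig$region_scope
    ))
  }
  missing <- setdiff(sig$members$gene_id, rownames(expr))
  if (length(missing) > 0) {
    abort(sprintf(
      "member gene(s) absent from the expression matrix: %s",
      paste(missing, collapse = ", ")
    ))
  }
  m <- expr[sig$members$gene_id, , drop = FALSE]
  if (method == "zscore") {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1 # constant gene: centred value is 0 either way
    m <- (m - mu) / s
  }
  signs <- ifelse(sig$members$direction == "down", -1, 1)
  score <- colMeans(m * signs)
  med <- median(score)
  out <- tibble(
    sample_id = colnames(expr),
    score = unname(score),
    group = factor(ifelse(score > med, "high", "low"), levels = c("low", "high"))
  )
  attr(out, "median") <- med
  attr(out, "method") <- method
  class(out) <- c("signature_score", class(out))
  out
}

#' Serialize signatures to JSON and a gene/direction TSV
#'
#' The JSON keeps the full definition (source gene, scope, members with P
#' and direction, group sizes); the TSV is the minimal two-column transfer
#' format (gene, direction) for rescoring in another cohort.
#'
#' @param sigs A list of `mutation_signature` objects.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of paths written.
#' @export
write_signatures <- function(sigs, json_path = NULL, tsv_path = NULL) {
  payload <- purrr::map(sigs, function(s) {
    list(
      source_gene = s$source_gene, region_scope = s$region_scope,
      n_carriers = s$n_carriers, n_wildtype = s$n_wildtype,
      alpha = s$alpha, cap = s$cap,
      members = s$members
    )
  })
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path,
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  if (!is.null(tsv_path)) {
    tab <- purrr::map_dfr(sigs, tidy)
    readr::write_tsv(
      select(tab, "source_gene", "region_scope", "gene_id", "direction"),
      tsv_path
    )
  }
  invisible(c(json_path, tsv_path))
}

#' @rdname write_signatures
#' @param json_path Path of a JSON written by [write_signatures()].
#' @export
read_signatures <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (length(payload) == 0) {
    return(list())
  }
  purrr::map(seq_len(nrow(payload)), function(i) {
    s <- payload[i, ]
    members <- as_tibble(s$members[[1]])
    if (nrow(members) == 0) {
      members <- tibble(
        gene_id = character(0), p_value = numeric(0), direction = character(0)
      )
    }
    structure(
      list(
        members = members,
        source_gene = s$source_gene, region_scope = s$region_scope,
        n_carriers = s$n_carriers, n_wildtype = s$n_wildtype,
        alpha = s$alpha, cap = s$cap
      ),
      class = "mutation_signature"
    )
  })
}
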