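#' Two-sided Mann-Whitney U test
#'
#' The rank test used throughout the package: to compare variant burden
#' between subtypes and, gene by gene, to find expression genes associated
#' with a somatic genotype. For small samples (combined n at or below
#' `exact_limit`) the two-sided P-value is computed by exhaustive enumeration
#' of all assignments of the pooled mid-ranks to the two groups, so it is
#' exact even in the presence of ties. Larger samples use the normal
#' approximation with the usual tie correction of the rank variance and a
#' continuity correction.
#'
#' The two-sided exact P is the proportion of assignments whose U statistic
#' is at least as far from its null mean `n1*n2/2` as the observed one.
#' Because the null distribution of U is symmetric about its mean (also under
#' ties), this coincides with the doubled one-sided tail.
#'
#' @param x,y Numeric vectors, the two groups. `NA`s are dropped.
#' @param exact_limit Combined sample size at or below which the exact
#'   enumeration is used (default 16; `choose(16, 8)` = 12,870 assignments).
#' @return A list with elements `statistic` (U for the first group),
#'   `p_value`, `n1`, `n2`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' mwu_test(c(1, 2, 3), c(10, 11, 12))
#' @export
mwu_test <- function(x, y, exact_limit = 16L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    abort("both groups need at least one non-missing observation")
  }
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n <= exact_limit) {
    p <- mwu_exact_p(r, n1, u)
    method <- "exact"
  } else {
    tie_counts <- tabulate(match(r, unique(r)))
    tie_term <- sum(tie_counts^3 - tie_counts)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all observations tied: no information, P = 1
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal"
  }
  list(statistic = u, p_value = p, n1 = n1, n2 = n2, method = method)
}

# Exhaustive two-sided P over all choose(n, n1) assignments of the observed
# mid-ranks. Rank sums are multiples of 1/2, so the >= comparison is exact
# in double precision.
mwu_exact_p <- function(r, n1, u_obs) {
  n <- length(r)
  mu <- n1 * (n - n1) / 2
  dev <- abs(u_obs - mu)
  combs <- combn(n, n1)
  rs <- colSums(matrix(r[combs], nrow = n1))
  u_all <- rs - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= dev - 1e-9)
}

# Direction of the carrier-vs-wildtype shift: sign of the median difference,
# falling back to the mean difference on a median tie; NA when both tie.
mwu_direction <- function(x, y) {
  d <- median(x) - median(y)
  if (d == 0) d <- mean(x) - mean(y)
  if (d > 0) "up" else if (d < 0) "down" else NA_character_
}

# Row-wise MWU over an expression matrix for a fixed two-group split.
# Returns a tibble (gene_id, p_value, direction, statistic).
mwu_by_gene <- function(expr, carriers, wildtype, exact_limit = 16L) {
  stopifnot(is.matrix(expr))
  out_p <- numeric(nrow(expr))
  out_u <- numeric(nrow(expr))
  out_dir <- character(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, carriers]
    y <- expr[i, wildtype]
    res <- mwu_test(x, y, exact_limit = exact_limit)
    out_p[i] <- res$p_value
    out_u[i] <- res$statistic
    out_dir[i] <- mwu_direction(x, y) %||% NA_character_
  }
  tibble(
    gene_id = rownames(expr),
    p_value = out_p,
    statistic = out_u,
    direction = out_dir
  )
}
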