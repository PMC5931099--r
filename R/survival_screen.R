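#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates per group with right censoring, plus the
#' two-sided log-rank chi-square P-value when at least two groups and one
#' event are present. Thin wrapper over [survival::survfit()] /
#' [survival::survdiff()].
#'
#' @param data Data frame with the survival columns.
#' @param time,event,group Column names (strings) of follow-up time, event
#'   indicator (0/1) and group.
#' @return A `km_fit`: list with `curves` (tibble: `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate`), `logrank` (list with
#'   `chisq`, `df`, `p_value`; `p_value` is `NA` with `flag` set when the
#'   test is undefined) and the group sizes.
#' @examples
#' d <- data.frame(t = c(5, 10, 15, 20), e = c(0, 1, 0, 1), g = "all")
#' kaplan_meier(d, "t", "e", "g")$curves
#' @export
kaplan_meier <- function(data, time = "os_months", event = "os_event",
                         group = "group") {
  d <- data.frame(
    time = data[[time]], event = data[[event]],
    group = as.factor(data[[group]])
  )
  stopifnot(all(d$time >= 0), all(d$event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(levels(d$group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble(
    group = strata, time = fit$time,
    n_risk = fit$n.risk, n_event = fit$n.event, n_censor = fit$n.censor,
    estimate = fit$surv
  )
  logrank <- list(chisq = NA_real_, df = NA_integer_, p_value = NA_real_, flag = NA_character_)
  if (nlevels(d$group) >= 2) {
    if (sum(d$event) == 0) {
      logrank$flag <- "no_events"
    } else {
      sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
      logrank <- list(
        chisq = sd$chisq, df = length(sd$n) - 1L,
        p_value = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE),
        flag = NA_character_
      )
    }
  } else {
    logrank$flag <- "single_group"
  }
  structure(
    list(curves = curves, logrank = logrank, n = table(d$group)),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf(
    "<km_fit> %d group(s); log-rank P = %s\n",
    length(x$n),
    ifelse(is.na(x$logrank$p_value), sprintf("NA (%s)", x$logrank$flag),
      format(x$logrank$p_value, digits = 3)
    )
  ))
  invisible(x)
}

#' @export
tidy.km_fit <- function(x, ...) x$curves

#' @export
glance.km_fit <- function(x, ...) {
  tibble(
    n_groups = length(x$n), chisq = x$logrank$chisq,
    df = x$logrank$df, p_value = x$logrank$p_value, flag = x$logrank$flag
  )
}

#' Univariate Cox model for a two-level indicator
#'
#' Partial-likelihood fit with Efron tie handling and a Wald P-value.
#' Monotone-likelihood fits (complete separation, detected by a diverging
#' standard error or a non-converged fit) are flagged instead of silently
#' reported.
#'
#' @param data Data frame.
#' @param time,event,indicator Column names; the indicator must have exactly
#'   two levels and at least one event in total.
#' @return One-row tibble: `term`, `hr`, `log_hr`, `se`, `p_value`, `n`,
#'   `n_events`, `flag` (`NA` when clean).
#' @export
cox_univariate <- function(data, time = "os_months", event = "os_event",
                           indicator = "group") {
  d <- data.frame(
    time = data[[time]], event = data[[event]],
    x = as.factor(data[[indicator]])
  )
  if (nlevels(d$x) != 2) abort("indicator must have exactly two observed levels")
  if (sum(d$event) == 0) abort("no events: Cox model undefined")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = d, ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  s <- summary(fit)
  flag <- cox_fit_flag(fit)
  tibble(
    term = paste0(indicator, levels(d$x)[2]),
    hr = unname(exp(stats::coef(fit)[1])),
    log_hr = unname(stats::coef(fit)[1]),
    se = unname(sqrt(diag(fit$var))[1]),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    n = nrow(d), n_events = sum(d$event),
    flag = flag
  )
}

cox_fit_flag <- function(fit) {
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(se)) || any(se > 100) || any(abs(stats::coef(fit)) > 15)) {
    "separation"
  } else if (!is.null(fit$info) && !is.null(fit$info$convergence) &&
    fit$info$convergence != 0) {
    "nonconvergence"
  } else {
    NA_character_
  }
}

#' Multivariate Cox model adjusted for stage and proliferation
#'
#' Joint Efron-tie Cox fit of the indicator with T stage (1-4) and N stage
#' (0-3) as ordinal numeric terms, M stage as binary, and MKI67 entered as
#' z-scored log expression (a continuous proliferation measure). Covariates
#' constant across samples are dropped with a warning. Adjusting covariates
#' with Wald P < 0.05 are reported as retained.
#'
#' @param data Data frame with `t_stage`, `n_stage`, `m_stage`,
#'   `mki67_expr` columns besides time/event/indicator.
#' @param time,event,indicator Column names.
#' @return A `cox_screen` list: `indicator` (one-row tibble as in
#'   [cox_univariate()]), `covariates` (tibble of adjusting terms with `hr`
#'   and `p_value`), `retained` (covariate terms at P < 0.05) and `flag`.
#' @export
cox_multivariate <- function(data, time = "os_months", event = "os_event",
                             indicator = "group") {
  needed <- c("t_stage", "n_stage", "m_stage", "mki67_expr")
  stopifnot(all(needed %in% names(data)))
  d <- data.frame(
    time = data[[time]], event = data[[event]],
    x = as.factor(data[[indicator]]),
    t_stage = as.numeric(data$t_stage),
    n_stage = as.numeric(data$n_stage),
    m_stage = as.numeric(data$m_stage),
    mki67 = as.numeric(scale(log(data$mki67_expr)))
  )
  if (nlevels(d$x) != 2) abort("indicator must have exactly two observed levels")
  if (sum(d$event) == 0) abort("no events: Cox model undefined")
  covars <- c("t_stage", "n_stage", "m_stage", "mki67")
  constant <- covars[vapply(covars, function(v) {
    length(unique(d[[v]][!is.na(d[[v]])])) < 2
  }, logical(1))]
  if (length(constant) > 0) {
    warn(sprintf(
      "covariate(s) constant across samples dropped: %s",
      paste(constant, collapse = ", ")
    ))
    covars <- setdiff(covars, constant)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ x",
    if (length(covars) > 0) paste("+", paste(covars, collapse = " + ")) else ""
  ))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  s <- summary(fit)$coefficients
  flag <- cox_fit_flag(fit)
  cov_tbl <- tibble(
    term = rownames(s)[-1],
    hr = unname(exp(s[-1, "coef"])),
    p_value = unname(s[-1, "Pr(>|z|)"])
  )
  structure(
    list(
      indicator = tibble(
        term = paste0(indicator, levels(d$x)[2]),
        hr = unname(exp(s[1, "coef"])),
        log_hr = unname(s[1, "coef"]),
        se = unname(s[1, "se(coef)"]),
        p_value = unname(s[1, "Pr(>|z|)"]),
        n = nrow(d), n_events = sum(d$event),
        flag = flag
      ),
      covariates = cov_tbl,
      retained = cov_tbl$term[cov_tbl$p_value < 0.05],
      flag = flag
    ),
    class = "cox_screen"
  )
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf(
    "<cox_screen> adjusted HR %.3f (P = %.3g)%s; retained: %s\n",
    x$indicator$hr, x$indicator$p_value,
    ifelse(is.na(x$flag), "", paste0(" [", x$flag, "]")),
    if (length(x$retained) == 0) "none" else paste(x$retained, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.cox_screen <- function(x, ...) {
  bind_rows(
    mutate(select(x$indicator, "term", "hr", "p_value"), role = "indicator"),
    mutate(x$covariates, role = "covariate")
  )
}

#' Survival screen of recurrent genes and their signatures within a subtype
#'
#' For every (gene, region scope) in the filtered recurrence table, two
#' units are evaluated against overall survival in the given subtype's
#' samples: (a) the direct carrier-vs-wildtype split of the gene, and (b)
#' the median split of the gene's mutation-associated expression signature.
#' Each unit gets a univariate Cox fit, a multivariate fit adjusted for
#' T/N/M stage and MKI67, and a log-rank P. A unit is significant when its
#' multivariate indicator P is below `screen_alpha` (raw, no multiplicity
#' correction across units). Units that cannot be tested (too few carriers,
#' empty signature, degenerate survival data) are kept as rows with a
#' machine-readable `skip_reason`.
#'
#' @param bundle A `cohort_bundle` (simulated or loaded).
#' @param recurrence Filtered recurrence table ([recurrence_filter()]).
#' @param subtype_labels Tibble `sample_id`/`subtype` from
#'   [assign_subtypes()].
#' @param subtype Subtype label to screen within.
#' @param signatures Optional named list of prebuilt `mutation_signature`s
#'   (names `"gene|scope"`); built on the fly when `NULL`.
#' @param alpha,cap,min_carriers Signature-building parameters.
#' @param screen_alpha Significance level of the screen (default 0.05).
#' @param score_method Scoring scale passed to [score_samples()].
#' @return Tibble ordered by multivariate P: one row per (gene, scope,
#'   unit), columns `unit`, `gene`, `scope`, `subtype`, `n`, `n_carriers`,
#'   `n_events`, `n_signature_genes`, `hr_univariate`, `p_univariate`,
#'   `logrank_p`, `hr_multivariate`, `p_multivariate`,
#'   `retained_covariates`, `significant`, `skip_reason`.
#' @export
screen_survival <- function(bundle, recurrence, subtype_labels, subtype,
                            signatures = NULL,
                            alpha = 0.01, cap = 100L, min_carriers = 5L,
                            screen_alpha = 0.05,
                            score_method = c("zscore", "raw")) {
  score_method <- match.arg(score_method)
  samples <- subtype_labels$sample_id[subtype_labels$subtype == subtype]
  samples <- intersect(samples, colnames(bundle$expression))
  clin <- dplyr::filter(bundle$clinical, .data$sample_id %in% samples)
  clin <- clin[match(samples, clin$sample_id), ]
  expr <- bundle$expression[, samples, drop = FALSE]

  empty_row <- function(unit, gene, scope, reason, n_carriers = NA_integer_,
                        n_sig = NA_integer_) {
    tibble(
      unit = unit, gene = gene, scope = scope, subtype = subtype,
      n = length(samples), n_carriers = n_carriers,
      n_events = sum(clin$os_event), n_signature_genes = n_sig,
      hr_univariate = NA_real_, p_univariate = NA_real_,
      logrank_p = NA_real_,
      hr_multivariate = NA_real_, p_multivariate = NA_real_,
      retained_covariates = NA_character_,
      significant = FALSE, skip_reason = reason
    )
  }

  fit_unit <- function(unit, gene, scope, group, n_carriers, n_sig) {
    d <- mutate(clin, group = group)
    if (nlevels(droplevels(as.factor(group))) != 2) {
      return(empty_row(unit, gene, scope, "single_group", n_carriers, n_sig))
    }
    if (sum(d$os_event) == 0) {
      return(empty_row(unit, gene, scope, "no_events", n_carriers, n_sig))
    }
    km <- kaplan_meier(d, "os_months", "os_event", "group")
    uni <- cox_univariate(d, "os_months", "os_event", "group")
    multi <- cox_multivariate(d, "os_months", "os_event", "group")
    flag <- multi$flag %||% NA_character_
    tibble(
      unit = unit, gene = gene, scope = scope, subtype = subtype,
      n = nrow(d), n_carriers = n_carriers,
      n_events = sum(d$os_event), n_signature_genes = n_sig,
      hr_univariate = uni$hr, p_univariate = uni$p_value,
      logrank_p = km$logrank$p_value,
      hr_multivariate = multi$indicator$hr,
      p_multivariate = multi$indicator$p_value,
      retained_covariates = if (length(multi$retained) == 0) {
        NA_character_
      } else {
        paste(multi$retained, collapse = ",")
      },
      significant = is.na(flag) && multi$indicator$p_value < screen_alpha,
      skip_reason = if (is.na(flag)) NA_character_ else flag
    )
  }

  if (nrow(recurrence) == 0) {
    return(empty_row(character(0), character(0), character(0), character(0)))
  }

  rows <- purrr::map(seq_len(nrow(recurrence)), function(i) {
    gene <- recurrence$gene[i]
    scope <- recurrence$scope[i]
    key <- paste(gene, scope, sep = "|")
    split <- split_by_genotype(recurrence, gene, scope, samples)
    n_c <- length(split$carriers)
    variant_unit <- if (n_c < min_carriers ||
      length(split$wildtype) < min_carriers) {
      empty_row("gene-variant", gene, scope, "too_few_carriers", n_c)
    } else {
      grp <- factor(ifelse(samples %in% split$carriers, "carrier", "wildtype"),
        levels = c("wildtype", "carrier")
      )
      fit_unit("gene-variant", gene, scope, grp, n_c, NA_integer_)
    }

    signature_unit <- if (n_c < min_carriers ||
      length(split$wildtype) < min_carriers) {
      empty_row("signature", gene, scope, "too_few_carriers", n_c)
    } else {
      sig <- if (!is.null(signatures) && key %in% names(signatures)) {
        signatures[[key]]
      } else {
        build_signature(expr, split$carriers, split$wildtype,
          alpha = alpha, cap = cap, min_carriers = min_carriers,
          source_gene = gene, region_scope = scope
        )
      }
      if (nrow(sig$members) == 0) {
        empty_row("signature", gene, scope, "empty_signature", n_c, 0L)
      } else {
        sc <- score_samples(expr, sig, method = score_method)
        fit_unit("signature", gene, scope, sc$group, n_c, nrow(sig$members))
      }
    }
    bind_rows(variant_unit, signature_unit)
  })
  arrange(bind_rows(rows), is.na(.data$p_multivariate), .data$p_multivariate)
}
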