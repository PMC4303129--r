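#' Two-group Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Two-sided throughout. Rank tests operate on raw
#' beta values (they are invariant under the monotone logit transform).
#'
#' @param x,y Numeric vectors for the two groups (both non-empty).
#' @return List with \code{statistic} (the Mann-Whitney U, i.e. rank sum of
#'   \code{x} minus its minimum) and \code{p}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis test across several groups
#'
#' Tie-corrected H statistic with a chi-square p-value on (g - 1) degrees of
#' freedom. When every observation is identical the statistic is defined as 0
#' with p = 1.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("need at least two non-empty groups")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p = 1))
  }
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up q-values: \code{q_(i) = min_(j >= i) p_(j) m / j}, capped at 1 and
#' mapped back to input order.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted linear model for one probe
#'
#' Ordinary least squares of logit-transformed beta on a group factor plus
#' adjustment covariates, complete cases only. The reported coefficient is
#' the contrast of the factor's second level against its reference level,
#' with a two-sided t-test p-value.
#'
#' @param y Numeric response (logit beta), one value per tumor.
#' @param data Data frame of covariates aligned with \code{y}.
#' @param factor_var Name of the group variable in \code{data}; character
#'   columns are converted to factors (first level = reference unless already
#'   a factor with explicit levels).
#' @param covariates Character vector of adjustment covariate names.
#' @return List with \code{coefficient}, \code{p}, \code{n} (complete cases
#'   used), or \code{NULL} when the design is rank-deficient in the factor
#'   contrast.
#' @export
fit_probe_model <- function(y, data, factor_var, covariates = character()) {
  df <- data.frame(.y = y, data, check.names = FALSE)
  vars <- c(factor_var, covariates)
  df <- df[stats::complete.cases(df[, c(".y", vars), drop = FALSE]), ,
           drop = FALSE]
  for (v in vars) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  if (is.factor(df[[factor_var]]) && nlevels(df[[factor_var]]) < 2L) {
    return(NULL)
  }
  fml <- stats::reformulate(vars, response = ".y")
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  target <- if (is.factor(df[[factor_var]])) {
    paste0(factor_var, levels(df[[factor_var]])[2L])
  } else {
    factor_var
  }
  if (!target %in% rownames(sm) || is.na(fit$coefficients[target])) {
    return(NULL)     # rank-deficient in the contrast of interest
  }
  list(coefficient = unname(sm[target, "Estimate"]),
       p = unname(sm[target, "Pr(>|t|)"]),
       n = nrow(df))
}

#' Differential methylation across all probes for one comparison
#'
#' For each probe, fits the covariate-adjusted linear model on logit beta
#' (two-level factors) or, when \code{method = "rank"}, runs the Wilcoxon
#' rank-sum (two groups) or Kruskal-Wallis (more groups) test on raw beta.
#' Benjamini-Hochberg q-values are computed within the comparison (the
#' multiple-testing family is the set of probes tested here). Direction is
#' \code{"hyper"} when methylation is higher in the non-reference group.
#'
#' @param beta Probes x tumors beta matrix.
#' @param annotation Data frame with \code{tumor_id} plus the comparison and
#'   adjustment covariates.
#' @param comparison Name of the grouping column in \code{annotation}.
#' @param covariates Adjustment covariate names (ignored for rank tests).
#' @param method \code{"linear"} (logit-scale OLS, default) or \code{"rank"}.
#' @param ref Optional reference level for the comparison variable.
#' @param eps Logit clamp width.
#' @return Data frame of class \code{diff_result}: \code{probe_id},
#'   \code{comparison}, \code{estimate}, \code{raw_p}, \code{q},
#'   \code{direction}; skipped probes are recorded in the
#'   \code{"skipped"} attribute, dropped incomplete cases in
#'   \code{"n_dropped"}.
#' @export
diff_methylation <- function(beta, annotation, comparison,
                             covariates = character(),
                             method = c("linear", "rank"),
                             ref = NULL, eps = 1e-3) {
  method <- match.arg(method)
  tumors <- colnames(beta)
  ann <- annotation[match(tumors, annotation$tumor_id), , drop = FALSE]
  grp <- ann[[comparison]]
  if (is.null(grp)) stop("annotation lacks column ", comparison)
  grp <- factor(grp)
  if (!is.null(ref)) grp <- stats::relevel(grp, ref = ref)
  ann[[comparison]] <- grp

  n_complete <- sum(stats::complete.cases(
    ann[, c(comparison, covariates), drop = FALSE]))
  skipped <- character()
  rows <- vector("list", nrow(beta))
  lbeta <- logit_transform(beta, eps)
  for (i in seq_len(nrow(beta))) {
    pid <- rownames(beta)[i]
    if (method == "rank") {
      vals <- split(beta[i, ], grp)
      vals <- vals[lengths(vals) > 0L]
      if (length(vals) < 2L) { skipped <- c(skipped, pid); next }
      res <- if (length(vals) == 2L) {
        w <- wilcoxon_rank_sum(vals[[2L]], vals[[1L]])
        list(estimate = mean(vals[[2L]]) - mean(vals[[1L]]), p = w$p)
      } else {
        kw <- kruskal_wallis(vals)
        list(estimate = kw$statistic, p = kw$p)
      }
    } else {
      fit <- fit_probe_model(lbeta[i, ], ann, comparison, covariates)
      if (is.null(fit)) { skipped <- c(skipped, pid); next }
      res <- list(estimate = fit$coefficient, p = fit$p)
    }
    rows[[i]] <- data.frame(probe_id = pid, comparison = comparison,
                            estimate = res$estimate, raw_p = res$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) stop("no probe could be tested")
  out$q <- bh_fdr(out$raw_p)
  out$direction <- ifelse(out$estimate >= 0, "hyper", "hypo")
  attr(out, "skipped") <- skipped
  attr(out, "n_dropped") <- length(tumors) - n_complete
  class(out) <- c("diff_result", class(out))
  out
}

#' Count hyper- and hypomethylated discoveries
#'
#' Partitions the probes significant at \code{q < alpha} by direction.
#'
#' @param results A \code{diff_result} data frame.
#' @param alpha FDR threshold (default 0.05).
#' @return Named integer vector \code{c(n_hyper, n_hypo)}.
#' @export
direction_summary <- function(results, alpha = 0.05) {
  sig <- results[results$q < alpha, , drop = FALSE]
  c(n_hyper = sum(sig$direction == "hyper"),
    n_hypo = sum(sig$direction == "hypo"))
}

#' Exclusive Venn-region counts for significant probe sets
#'
#' For two or more named probe sets, counts the probes in each exclusive
#' region (membership pattern); the regions partition the union.
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector; names are membership patterns like
#'   \code{"A&B"}.
#' @export
overlap_sets <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  u <- unique(unlist(sets))
  memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) memb <- matrix(memb, nrow = 1L,
                                      dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  patterns <- unlist(lapply(seq_along(sets), function(m)
    utils::combn(names(sets), m, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(patterns)), patterns)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Fisher's exact enrichment test between two probe signatures
#'
#' One-sided (enrichment) hypergeometric tail test of the overlap between a
#' significant-probe set and an external signature against a common probe
#' background.
#'
#' @param sig_probes,external_signature Character vectors, subsets of
#'   \code{background}.
#' @param background Character vector, the probe universe.
#' @return List with the 2x2 \code{table}, \code{odds_ratio}, and one-sided
#'   \code{p}.
#' @export
signature_overlap_test <- function(sig_probes, external_signature,
                                   background) {
  if (!all(sig_probes %in% background) ||
      !all(external_signature %in% background)) {
    stop("both sets must be subsets of the background")
  }
  a <- sum(sig_probes %in% external_signature)
  b <- length(sig_probes) - a
  c_ <- length(external_signature) - a
  d <- length(background) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2L, 2L,
                dimnames = list(in_sig = c("yes", "no"),
                                in_signature = c("yes", "no")))
  ht <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ht$estimate), p = ht$p.value)
}

#' Methylation-expression correlation, overall and by stratum
#'
#' Pearson correlation (with a two-sided t-based p-value) between each
#' probe's beta values and the matched gene's expression, computed over all
#' tumors and within each stratum with at least three paired observations.
#'
#' @param beta Probes x tumors beta matrix (one probe per gene of interest).
#' @param expression Genes x tumors expression matrix.
#' @param probe_gene Named character vector mapping probe id to gene symbol.
#' @param strata Optional factor of stratum labels named by tumor.
#' @return Data frame with \code{probe_id}, \code{gene}, \code{stratum}
#'   (\code{"all"} or the stratum level), \code{n}, \code{r}, \code{p}.
#' @export
methylation_expression_correlation <- function(beta, expression, probe_gene,
                                               strata = NULL) {
  tumors <- intersect(colnames(beta), colnames(expression))
  if (length(tumors) < 3L) stop("need at least three matched tumors")
  strata_list <- list(all = tumors)
  if (!is.null(strata)) {
    s <- strata[tumors]
    strata_list <- c(strata_list, split(tumors, s))
  }
  rows <- list()
  for (pid in names(probe_gene)) {
    g <- probe_gene[[pid]]
    if (!pid %in% rownames(beta) || !g %in% rownames(expression)) next
    for (snm in names(strata_list)) {
      tt <- strata_list[[snm]]
      b <- beta[pid, tt]; e <- expression[g, tt]
      ok <- is.finite(b) & is.finite(e)
      if (sum(ok) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = pid, gene = g, stratum = snm, n = sum(ok),
          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(b[ok], e[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, gene = g, stratum = snm, n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Standard adjustment sets per comparison
#'
#' The default adjustment set is age, race, menopausal status, and stage,
#' with the documented special cases: the stage comparison adjusts for age,
#' race, and menopausal status only; tumor size adjusts for age, race,
#' menopausal status, and lymph node status; lymph node status adjusts for
#' size instead of node. No comparison adjusts for its own outcome. The p53
#' comparison optionally adds intrinsic subtype as a categorical covariate.
#'
#' @param comparison One of \code{"hr_status"}, \code{"subtype"},
#'   \code{"p53_status"}, \code{"grade"}, \code{"tumor_size"},
#'   \code{"stage"}, \code{"node_status"}, \code{"cluster"}.
#' @param p53_adjust_subtype Add \code{subtype} to the p53 adjustment set.
#' @return Character vector of adjustment covariate names.
#' @export
covariate_spec <- function(comparison, p53_adjust_subtype = FALSE) {
  base <- c("age", "race", "menopausal_status", "stage")
  out <- switch(comparison,
    stage = c("age", "race", "menopausal_status"),
    tumor_size = c("age", "race", "menopausal_status", "node_status"),
    node_status = c("age", "race", "menopausal_status", "tumor_size"),
    base)
  if (comparison == "p53_status" && p53_adjust_subtype) {
    out <- c(out, "subtype")
  }
  stopifnot(!comparison %in% out)
  out
}
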