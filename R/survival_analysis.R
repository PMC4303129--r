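#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates of the survivor function for each group, with
#' at-risk and event counts at every observed time. Censored times do not
#' decrease the estimate.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Optional group labels (a single curve when omitted).
#' @return Data frame with \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group)))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(factor(group)), length(s$time))
         else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor,
             survival = s$surv, stringsAsFactors = FALSE)
}

#' Log-rank comparison of survival between groups
#'
#' Observed-minus-expected chi-square statistic with the hypergeometric
#' variance at each distinct event time; degrees of freedom are the number of
#' groups minus one.
#'
#' @inheritParams kaplan_meier
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
log_rank <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (sum(event) == 0L) stop("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g,
                            data = data.frame(time = time, event = event,
                                              g = g))
  df <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with a tidy coefficient table
#'
#' Maximizes the partial likelihood (Efron ties by default, Breslow
#' optional) and reports, per model term, the log hazard ratio, hazard ratio,
#' normal-approximation 95\% confidence interval on the hazard-ratio scale,
#' and Wald p-value. Non-convergence or an infinite coefficient is flagged
#' rather than silently returned.
#'
#' @param data Data frame containing \code{time}, \code{event}, and the model
#'   terms.
#' @param terms Character vector of covariate names entering the linear
#'   predictor.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return Object of class \code{cox_fit}: \code{table} (term, coef, hr,
#'   ci_lower, ci_upper, p), \code{n}, \code{n_event}, \code{ties},
#'   \code{converged}, and the underlying \code{fit}.
#' @export
cox_fit <- function(data, terms, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  if (sum(data$event, na.rm = TRUE) < 1) stop("need at least one event")
  for (v in terms) {
    if (length(unique(stats::na.omit(data[[v]]))) < 2L) {
      stop("term constant across records: ", v)
    }
  }
  fml <- stats::reformulate(terms,
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = data, ties = ties,
                         control = survival::coxph.control(iter.max = 50L))
  sm <- summary(fit)
  co <- sm$coefficients
  converged <- is.null(fit$info) &&
    all(is.finite(co[, "coef"])) && all(abs(co[, "coef"]) < 15)
  tab <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(table = tab, n = fit$n, n_event = fit$nevent, ties = ties,
              converged = converged, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), n = %d, events = %d%s\n",
              x$ties, x$n, x$n_event,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- x$table
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Per-term slope test of the scaled Schoenfeld residuals against event-time
#' rank, plus the global test. With fewer than two events the check is
#' skipped with a diagnostic rather than failing.
#'
#' @param coxfit A \code{\link{cox_fit}}.
#' @return Data frame with \code{term}, \code{chisq}, \code{df}, \code{p}
#'   (last row is \code{GLOBAL}), or \code{NULL} with a warning when the
#'   check cannot run.
#' @export
ph_check <- function(coxfit) {
  stopifnot(inherits(coxfit, "cox_fit"))
  if (coxfit$n_event < 2L) {
    warning("fewer than two events; proportional-hazards check skipped")
    return(NULL)
  }
  z <- survival::cox.zph(coxfit$fit, transform = "rank")
  tab <- z$table
  data.frame(term = rownames(tab), chisq = tab[, "chisq"],
             df = tab[, "df"], p = tab[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate and multivariate Cox models for methylation clusters
#'
#' Fits the cluster indicator alone (univariate) and together with the
#' standard clinical adjustment set (multivariate), with the reference
#' cluster configurable. Covariates absent from the data are dropped with a
#' message.
#'
#' @param annotation Data frame with \code{tumor_id}, \code{time},
#'   \code{event} and clinical covariates.
#' @param assignment Cluster labels named by tumor id.
#' @param ref_cluster Reference cluster label (default the largest cluster).
#' @param adjust Covariates for the multivariate model.
#' @param ties Ties method passed to \code{\link{cox_fit}}.
#' @return List with \code{univariate} and \code{multivariate}
#'   \code{cox_fit} objects.
#' @export
cluster_survival <- function(annotation, assignment, ref_cluster = NULL,
                             adjust = c("age", "menopausal_status", "race",
                                        "stage_ordinal", "hr_status",
                                        "grade_high", "node_status",
                                        "tumor_size"),
                             ties = "efron") {
  dat <- annotation[annotation$tumor_id %in% names(assignment), ,
                    drop = FALSE]
  cl <- assignment[dat$tumor_id]
  if (is.null(ref_cluster)) {
    ref_cluster <- names(which.max(table(cl)))
  }
  dat$cluster <- stats::relevel(factor(cl), ref = as.character(ref_cluster))
  # stage enters Cox models as an ordinal 1-4 trend term; grade as 1 vs 2+3
  if ("stage" %in% names(dat)) dat$stage_ordinal <- as.numeric(dat$stage)
  if ("grade" %in% names(dat)) dat$grade_high <- as.integer(dat$grade != "1")
  adjust <- intersect(adjust, names(dat))
  uni <- cox_fit(dat, "cluster", ties = ties)
  multi <- cox_fit(dat, c("cluster", adjust), ties = ties)
  list(univariate = uni, multivariate = multi)
}
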