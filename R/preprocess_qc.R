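#' Compute methylation beta values from two-channel intensities
#'
#' The methylation fraction at a CpG site is the ratio of the methylated-allele
#' (Cy5) signal to the total signal from both alleles plus a stabilising
#' offset:
#' \deqn{\beta = \max(Cy5, 0) / (|Cy5| + |Cy3| + 100)}
#' Negative background-subtracted signals are clipped in the numerator only, so
#' the result always lies in \code{[0, 1)}.
#'
#' @param cy5 Numeric vector of methylated-channel signals (may be negative).
#' @param cy3 Numeric vector of unmethylated-channel signals (recycled against
#'   \code{cy5}).
#' @return Numeric vector of beta values in \code{[0, 1)}.
#' @examples
#' compute_beta(900, 100)   # 900/1100
#' compute_beta(-50, 200)   # 0
#' @export
compute_beta <- function(cy5, cy3) {
  if (!is.numeric(cy5) || !is.numeric(cy3)) {
    stop("cy5 and cy3 must be numeric")
  }
  if (any(!is.finite(cy5)) || any(!is.finite(cy3))) {
    stop("non-finite intensity values")
  }
  pmax(cy5, 0) / (abs(cy5) + abs(cy3) + 100)
}

#' Remove samples with unreliable detection
#'
#' A sample is removed when strictly more than \code{max_fail_frac} of its
#' probes have a detection p-value strictly greater than \code{p_thresh}.
#' Both comparisons are strict, so a sample with exactly 25\% failing probes
#' is retained under the defaults.
#'
#' @param detection_p Numeric matrix of detection p-values, probes in rows,
#'   samples in columns.
#' @param p_thresh Detection p-value above which a probe call is unreliable
#'   (default \code{1e-5}).
#' @param max_fail_frac Tolerated fraction of unreliable probes per sample
#'   (default 0.25).
#' @return A list with \code{keep} and \code{removed} (character vectors of
#'   sample ids) and \code{fail_frac}, the named per-sample failure fraction.
#' @export
filter_samples <- function(detection_p, p_thresh = 1e-5, max_fail_frac = 0.25) {
  if (!is.matrix(detection_p) || nrow(detection_p) == 0L ||
      ncol(detection_p) == 0L) {
    stop("detection_p must be a non-empty probes x samples matrix")
  }
  if (is.null(colnames(detection_p))) {
    colnames(detection_p) <- paste0("sample", seq_len(ncol(detection_p)))
  }
  fail_frac <- colMeans(detection_p > p_thresh)
  removed <- colnames(detection_p)[fail_frac > max_fail_frac]
  list(
    keep = setdiff(colnames(detection_p), removed),
    removed = removed,
    fail_frac = fail_frac
  )
}

#' Flag probes failing detection across samples
#'
#' Aggregates per-sample detection p-values to a per-probe decision: a probe
#' fails when its median detection p-value across the retained samples exceeds
#' \code{p_thresh}. The median rule is this package's declared aggregation for
#' a probe-level detection call.
#'
#' @param detection_p Probes x samples matrix of detection p-values (already
#'   restricted to QC-passing samples).
#' @inheritParams filter_samples
#' @return Character vector of failing probe ids.
#' @export
detect_failed_probes <- function(detection_p, p_thresh = 1e-5) {
  med <- apply(detection_p, 1L, stats::median, na.rm = TRUE)
  rownames(detection_p)[med > p_thresh]
}

#' Filter probes by SNP/repeat overlap, detection, and variability
#'
#' Applies the three probe-level filters in a fixed order: (i) probes flagged
#' in the manifest as overlapping a SNP or repeat, (ii) probes failing
#' detection, (iii) probes whose standard deviation across the retained
#' samples is strictly less than \code{sd_min}. The "less than" comparison is
#' strict: a probe with SD exactly \code{sd_min} is retained. Counts removed at
#' each stage are recorded in the provenance table.
#'
#' @param beta Probes x samples beta matrix with rownames.
#' @param manifest Data frame with columns \code{probe_id}, \code{gene_symbol},
#'   \code{snp_repeat_flag}; must cover every probe in \code{beta}.
#' @param detection_fail Character vector of probe ids failing detection (see
#'   \code{\link{detect_failed_probes}}).
#' @param sd_min Minimum probe standard deviation (default 0.06), computed
#'   with the n-1 denominator over non-missing cells.
#' @return A list with \code{beta} (the filtered matrix) and \code{provenance},
#'   a data frame of stage, removed and retained counts.
#' @export
filter_probes <- function(beta, manifest, detection_fail = character(),
                          sd_min = 0.06) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes) > 0L) {
    stop("manifest missing probe(s): ",
         paste(utils::head(missing_probes, 5L), collapse = ", "))
  }
  n_in <- nrow(beta)
  prov <- data.frame(stage = character(), removed = integer(),
                     retained = integer(), stringsAsFactors = FALSE)
  log_stage <- function(stage, removed, retained) {
    rbind(prov, data.frame(stage = stage, removed = removed,
                           retained = retained, stringsAsFactors = FALSE))
  }

  flagged <- manifest$probe_id[as.logical(manifest$snp_repeat_flag)]
  beta <- beta[setdiff(rownames(beta), flagged), , drop = FALSE]
  prov <- log_stage("snp_repeat", n_in - nrow(beta), nrow(beta))

  before <- nrow(beta)
  beta <- beta[setdiff(rownames(beta), detection_fail), , drop = FALSE]
  prov <- log_stage("detection", before - nrow(beta), nrow(beta))

  before <- nrow(beta)
  sds <- apply(beta, 1L, stats::sd, na.rm = TRUE)
  beta <- beta[sds >= sd_min, , drop = FALSE]
  prov <- log_stage("low_sd", before - nrow(beta), nrow(beta))

  list(beta = beta, provenance = prov)
}

#' Average replicate samples into one profile per tumor
#'
#' Collapses technical replicate samples by the per-probe arithmetic mean.
#' Tumors with a single surviving sample pass through unchanged; tumors with no
#' surviving sample are dropped and reported.
#'
#' @param beta Probes x samples beta matrix (QC-passing samples).
#' @param replicate_map Data frame with columns \code{sample_id},
#'   \code{tumor_id} covering at least the samples in \code{beta}.
#' @return A list with \code{beta} (probes x tumors matrix, columns named by
#'   tumor id) and \code{dropped} (tumor ids with zero surviving samples).
#' @export
average_replicates <- function(beta, replicate_map) {
  stopifnot(all(c("sample_id", "tumor_id") %in% names(replicate_map)))
  map <- replicate_map[replicate_map$sample_id %in% colnames(beta), ,
                       drop = FALSE]
  dropped <- setdiff(unique(replicate_map$tumor_id), map$tumor_id)
  tumors <- unique(map$tumor_id)
  out <- vapply(tumors, function(tid) {
    cols <- map$sample_id[map$tumor_id == tid]
    rowMeans(beta[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(beta)))
  out <- matrix(out, nrow = nrow(beta),
                dimnames = list(rownames(beta), tumors))
  list(beta = out, dropped = dropped)
}

#' Pearson concordance between replicate samples
#'
#' Computes, for every unordered pair of replicate samples of the same tumor,
#' the Pearson correlation of their beta profiles over shared non-missing
#' probes. Pairs with fewer than three shared probes are reported as missing.
#'
#' @inheritParams average_replicates
#' @return Data frame with columns \code{tumor_id}, \code{sample_a},
#'   \code{sample_b}, \code{r}.
#' @export
replicate_concordance <- function(beta, replicate_map) {
  map <- replicate_map[replicate_map$sample_id %in% colnames(beta), ,
                       drop = FALSE]
  counts <- table(map$tumor_id)
  rep_tumors <- names(counts)[counts >= 2L]
  rows <- list()
  for (tid in rep_tumors) {
    ids <- map$sample_id[map$tumor_id == tid]
    for (pair in utils::combn(ids, 2L, simplify = FALSE)) {
      a <- beta[, pair[1L]]
      b <- beta[, pair[2L]]
      ok <- is.finite(a) & is.finite(b)
      r <- if (sum(ok) < 3L) NA_real_ else stats::cor(a[ok], b[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = tid, sample_a = pair[1L], sample_b = pair[2L], r = r,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tumor_id = character(), sample_a = character(),
                      sample_b = character(), r = numeric()))
  }
  do.call(rbind, rows)
}

#' Select the most variant probes
#'
#' Probes whose standard deviation across tumors is strictly less than
#' \code{sd_cut} are excluded; a probe with SD exactly at the cut is retained.
#'
#' @param beta Probes x tumors beta matrix.
#' @param sd_cut Standard-deviation cutoff (default 0.2).
#' @return Character vector of retained probe ids.
#' @export
select_variant_probes <- function(beta, sd_cut = 0.2) {
  sds <- apply(beta, 1L, stats::sd, na.rm = TRUE)
  rownames(beta)[sds >= sd_cut]
}

#' Clamped logit transform of beta values
#'
#' Maps beta to \code{log(b/(1-b))} after clamping into
#' \code{[eps, 1-eps]} so that boundary values remain finite.
#'
#' @param beta Numeric vector or matrix of beta values in \code{[0, 1]}.
#' @param eps Clamp width in \code{(0, 0.5)}; default \code{1e-3}.
#' @return Transformed values, same shape as the input.
#' @export
logit_transform <- function(beta, eps = 1e-3) {
  stopifnot(eps > 0, eps < 0.5)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log(b / (1 - b))
  if (is.matrix(beta)) out <- matrix(out, nrow = nrow(beta),
                                     dimnames = dimnames(beta))
  out
}

#' Inverse of the logit transform
#' @param x Numeric vector or matrix on the logit scale.
#' @return Values in (0, 1).
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Run the full QC chain on a raw intensity set
#'
#' Computes beta values, removes unreliable samples, drops ineligible tumors,
#' applies the probe filters, and averages replicates, returning a tumor-keyed
#' beta matrix together with a provenance log mirroring each stage's counts.
#'
#' @param raw A raw intensity set as produced by \code{\link{generate_dataset}}
#'   or read from disk: a list with matrices \code{cy5}, \code{cy3},
#'   \code{detection_p} (probes x samples) and a \code{replicate_map} data
#'   frame (\code{sample_id}, \code{tumor_id}).
#' @param manifest Probe manifest (see \code{\link{filter_probes}}).
#' @param ineligible Character vector of tumor ids excluded for
#'   non-technical reasons before probe filtering.
#' @param p_thresh,max_fail_frac,sd_min QC thresholds, see the individual
#'   filter functions.
#' @return A list with \code{beta} (probes x tumors), \code{provenance}
#'   (named list of per-stage counts), \code{removed_samples},
#'   \code{concordance}.
#' @export
preprocess_qc <- function(raw, manifest, ineligible = character(),
                          p_thresh = 1e-5, max_fail_frac = 0.25,
                          sd_min = 0.06) {
  beta <- compute_beta(raw$cy5, raw$cy3)
  beta <- matrix(beta, nrow = nrow(raw$cy5), dimnames = dimnames(raw$cy5))

  sfilt <- filter_samples(raw$detection_p, p_thresh, max_fail_frac)
  beta <- beta[, sfilt$keep, drop = FALSE]

  map <- raw$replicate_map
  inel_samples <- map$sample_id[map$tumor_id %in% ineligible]
  beta <- beta[, setdiff(colnames(beta), inel_samples), drop = FALSE]

  dp <- raw$detection_p[, colnames(beta), drop = FALSE]
  det_fail <- detect_failed_probes(dp, p_thresh)
  pfilt <- filter_probes(beta, manifest, det_fail, sd_min)

  conc <- replicate_concordance(pfilt$beta, map)
  avg <- average_replicates(pfilt$beta, map)

  list(
    beta = avg$beta,
    provenance = list(
      samples_in = ncol(raw$cy5),
      samples_removed_qc = length(sfilt$removed),
      samples_removed_ineligible = length(inel_samples),
      probe_stages = pfilt$provenance,
      probes_in = nrow(raw$cy5),
      probes_retained = nrow(pfilt$beta),
      tumors_out = ncol(avg$beta),
      tumors_dropped = avg$dropped
    ),
    removed_samples = sfilt$removed,
    concordance = conc
  )
}
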