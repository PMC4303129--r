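#' Default cluster-conditional clinical covariate model
#'
#' Per-cluster category probabilities for the clinical covariates attached to
#' each synthetic tumor. Defaults reproduce the composition of a
#' population-based breast-tumor cohort in which one cluster is enriched for
#' hormone-receptor-negative, basal-like, p53-mutant, high-grade tumors and
#' two clusters are luminal-enriched, one of them globally hypermethylated
#' with poorer clinicopathologic features.
#'
#' @param n_clusters Number of latent clusters (only 4 has tabulated
#'   defaults; other values get uniform category probabilities).
#' @return Named list; each element is a clusters x levels probability matrix
#'   whose rows sum to 1.
#' @export
default_covariate_model <- function(n_clusters = 4) {
  pm <- function(...) {
    m <- rbind(...)
    sweep(m, 1L, rowSums(m), "/")
  }
  if (n_clusters == 4) {
    list(
      age_band = structure(pm(c(59, 41), c(76, 24), c(55, 45), c(58, 42)),
                           dimnames = list(NULL, c("<50", "50+"))),
      race = structure(pm(c(54, 46), c(49, 51), c(59, 41), c(66, 34)),
                       dimnames = list(NULL, c("white_other", "african_american"))),
      menopausal_status = structure(pm(c(50, 50), c(64, 36), c(48, 52), c(51, 49)),
                                    dimnames = list(NULL, c("pre", "post"))),
      stage = structure(pm(c(58, 48, 12, 1), c(26, 58, 9, 4),
                           c(24, 56, 11, 3), c(70, 83, 13, 5)),
                        dimnames = list(NULL, c("1", "2", "3", "4"))),
      tumor_size = structure(pm(c(72, 39, 9), c(35, 53, 11),
                                c(36, 49, 11), c(107, 64, 11)),
                             dimnames = list(NULL, c("le2cm", "2to5cm", "gt5cm"))),
      node_status = structure(pm(c(44, 76), c(40, 62), c(48, 48), c(75, 105)),
                              dimnames = list(NULL, c("positive", "negative"))),
      grade = structure(pm(c(29, 34, 58), c(3, 16, 87),
                           c(17, 40, 42), c(77, 66, 41)),
                        dimnames = list(NULL, c("1", "2", "3"))),
      hr_status = structure(pm(c(69, 51), c(20, 81), c(83, 13), c(166, 18)),
                            dimnames = list(NULL, c("positive", "negative"))),
      subtype = structure(pm(c(48, 12, 25, 6, 8), c(12, 5, 54, 7, 10),
                             c(52, 17, 3, 8, 1), c(100, 31, 4, 5, 5)),
                          dimnames = list(NULL, c("luminal_A", "luminal_B",
                                                  "basal_like", "her2_hr_neg",
                                                  "unclassified"))),
      p53_status = structure(pm(c(59, 64), c(90, 18), c(25, 74), c(44, 141)),
                             dimnames = list(NULL, c("mutant", "wild_type")))
    )
  } else {
    lvls <- list(age_band = c("<50", "50+"),
                 race = c("white_other", "african_american"),
                 menopausal_status = c("pre", "post"),
                 stage = c("1", "2", "3", "4"),
                 hr_status = c("positive", "negative"))
    lapply(lvls, function(l) {
      matrix(1 / length(l), n_clusters, length(l),
             dimnames = list(NULL, l))
    })
  }
}

#' Default per-cluster per-block mean beta values
#'
#' Six probe blocks: four variant blocks whose means separate the clusters
#' (block \code{v4} is shared-variant, highest in the hypermethylated
#' cluster across all variant blocks) and two stable blocks whose mixture
#' variance keeps their SD between the probe-QC floor and the variant cut.
#'
#' @param n_clusters Number of clusters (defaults tabulated for 4).
#' @param hyper_cluster_index Which cluster is globally hypermethylated.
#' @return Blocks x clusters matrix of mean beta values in \code{[0,1]}.
#' @export
default_block_means <- function(n_clusters = 4, hyper_cluster_index = 3) {
  stopifnot(n_clusters == 4, hyper_cluster_index == 3)
  m <- rbind(
    v1 = c(0.70, 0.10, 0.85, 0.10),
    v2 = c(0.10, 0.70, 0.85, 0.10),
    v3 = c(0.10, 0.10, 0.85, 0.70),
    v4 = c(0.15, 0.40, 0.90, 0.60),
    s1 = c(0.20, 0.30, 0.40, 0.30),
    s2 = c(0.60, 0.70, 0.55, 0.65)
  )
  colnames(m) <- paste0("cluster", seq_len(n_clusters))
  m
}

#' Configuration for the synthetic methylation cohort
#'
#' Bundles and validates every generative parameter: cohort and array size,
#' latent-cluster mixture, per-block mean beta profiles, beta-distribution
#' concentrations for biological and technical variation, replicate and QC
#' failure structure, the cluster-conditional covariate model, the
#' cluster-dependent survival model, and the target
#' methylation-expression correlation.
#'
#' @param n_tumors Number of tumors entering profiling.
#' @param n_probes Total CpG probes on the array, including those designated
#'   to fail QC.
#' @param n_clusters Number of latent tumor clusters.
#' @param cluster_proportions Mixture weights, summing to 1.
#' @param block_means Blocks x clusters matrix of mean beta values; rownames
#'   starting with "v" are variant blocks.
#' @param n_variant_probes Probes allocated to the variant blocks (default
#'   167); the rest of the QC-surviving probes fall in the stable blocks.
#' @param precision Beta-distribution concentration for between-tumor
#'   variation around the block mean (default 50).
#' @param replicate_precision Concentration for technical (within-tumor)
#'   measurement noise; the default 200 yields replicate Pearson r above 0.9.
#' @param hyper_cluster_index Cluster with globally elevated methylation.
#' @param n_replicated_tumors Tumors assayed in duplicate.
#' @param n_triplicated_tumors Tumors assayed in triplicate.
#' @param n_fail_samples Singleton samples designed to fail the 25\%
#'   detection rule.
#' @param n_ineligible Tumors flagged ineligible and dropped before probe
#'   filtering.
#' @param qc_fail_counts Named integer vector \code{(snp_flagged,
#'   detect_fail, low_sd)} of probes designed to fail each probe filter;
#'   mutually exclusive sets.
#' @param covariate_model See \code{\link{default_covariate_model}}.
#' @param survival_model List with \code{base_hazard} (events per month in the
#'   reference cluster), \code{log_hr} (per-cluster log hazard ratios, 0 for
#'   the reference), \code{censoring_rate} in \code{[0,1)}.
#' @param expression_r Target Pearson correlation between methylation and
#'   expression at the designated gene subset (negative for silencing).
#' @param n_expression_genes Number of variant-block genes given
#'   methylation-coupled expression.
#' @param total_signal Total fluorescence per array cell used when inverting
#'   the beta formula into channel intensities.
#' @param seed Integer master seed; all draws flow from it.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_tumors = 500,
                       n_probes = 1000,
                       n_clusters = 4,
                       cluster_proportions = c(123, 108, 99, 187) / 517,
                       block_means = default_block_means(),
                       n_variant_probes = 167,
                       precision = 50,
                       replicate_precision = 200,
                       hyper_cluster_index = 3,
                       n_replicated_tumors = 20,
                       n_triplicated_tumors = 0,
                       n_fail_samples = 4,
                       n_ineligible = 0,
                       qc_fail_counts = c(snp_flagged = 80, detect_fail = 10,
                                          low_sd = 60),
                       covariate_model = default_covariate_model(n_clusters),
                       survival_model = list(
                         base_hazard = 0.003,
                         log_hr = log(c(1.11, 1.91, 1.71, 1.00)),
                         censoring_rate = 0.3),
                       expression_r = -0.6,
                       n_expression_genes = 50,
                       total_signal = 10000,
                       seed = 1L) {
  cfg <- list(n_tumors = n_tumors, n_probes = n_probes,
              n_clusters = n_clusters,
              cluster_proportions = cluster_proportions,
              block_means = block_means,
              n_variant_probes = n_variant_probes,
              precision = precision,
              replicate_precision = replicate_precision,
              hyper_cluster_index = hyper_cluster_index,
              n_replicated_tumors = n_replicated_tumors,
              n_triplicated_tumors = n_triplicated_tumors,
              n_fail_samples = n_fail_samples,
              n_ineligible = n_ineligible,
              qc_fail_counts = qc_fail_counts,
              covariate_model = covariate_model,
              survival_model = survival_model,
              expression_r = expression_r,
              n_expression_genes = n_expression_genes,
              total_signal = total_signal,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9) {
    fail("cluster_proportions", "must sum to 1")
  }
  if (length(cfg$cluster_proportions) != cfg$n_clusters) {
    fail("cluster_proportions", "length must equal n_clusters")
  }
  if (any(cfg$block_means < 0 | cfg$block_means > 1)) {
    fail("block_means", "all entries must lie in [0, 1]")
  }
  if (ncol(cfg$block_means) != cfg$n_clusters) {
    fail("block_means", "needs one column per cluster")
  }
  if (cfg$precision <= 0) fail("precision", "must be > 0")
  if (cfg$replicate_precision <= 0) fail("replicate_precision", "must be > 0")
  if (cfg$hyper_cluster_index < 1 || cfg$hyper_cluster_index > cfg$n_clusters) {
    fail("hyper_cluster_index", "must index a cluster")
  }
  qc <- cfg$qc_fail_counts
  if (!all(c("snp_flagged", "detect_fail", "low_sd") %in% names(qc))) {
    fail("qc_fail_counts", "needs snp_flagged, detect_fail, low_sd")
  }
  if (sum(qc) + cfg$n_variant_probes >= cfg$n_probes) {
    fail("qc_fail_counts",
         "qc-designated plus variant probes must leave stable probes")
  }
  sm <- cfg$survival_model
  if (!all(is.finite(sm$log_hr))) fail("survival_model", "log_hr must be finite")
  if (length(sm$log_hr) != cfg$n_clusters) {
    fail("survival_model", "one log_hr per cluster")
  }
  if (sm$censoring_rate < 0 || sm$censoring_rate >= 1) {
    fail("survival_model", "censoring_rate must lie in [0, 1)")
  }
  n_extra <- cfg$n_fail_samples + cfg$n_ineligible +
    cfg$n_replicated_tumors + cfg$n_triplicated_tumors
  if (n_extra > cfg$n_tumors) {
    fail("n_tumors", "too few tumors for the designated replicate/QC roles")
  }
  invisible(cfg)
}

rbeta_mean <- function(n, mean, conc) {
  mean <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Invert the beta formula into two-channel intensities
#'
#' Emits Cy5/Cy3 signals such that
#' \code{compute_beta(cy5, cy3)} recovers the target beta exactly (to float
#' precision): with total signal \code{S}, \code{cy5 = beta * (S + 100)} and
#' \code{cy3 = S - cy5}. The +100 offset in the denominator means beta = 1 is
#' unattainable; targets at or above \code{S/(S+100)} get a per-cell enlarged
#' total.
#'
#' @param beta_target Matrix (or vector) of target beta values in
#'   \code{[0, 1)}.
#' @param total_signal Baseline total fluorescence per cell.
#' @return List of \code{cy5} and \code{cy3} with the same shape as the
#'   target.
#' @export
generate_intensities <- function(beta_target, total_signal = 10000) {
  if (any(beta_target >= 1)) {
    stop("beta targets must be < 1: the +100 offset makes beta = 1 unattainable")
  }
  if (any(beta_target < 0)) stop("beta targets must be >= 0")
  s <- array(total_signal, dim = dim(beta_target) %||% length(beta_target))
  need <- beta_target > s / (s + 100)
  if (any(need)) {
    s[need] <- 2 * 100 * beta_target[need] / (1 - beta_target[need]) + 100
  }
  cy5 <- beta_target * (s + 100)
  cy3 <- s - cy5
  if (!is.null(dim(beta_target))) {
    dim(cy5) <- dim(beta_target); dimnames(cy5) <- dimnames(beta_target)
    dim(cy3) <- dim(beta_target); dimnames(cy3) <- dimnames(beta_target)
  }
  list(cy5 = cy5, cy3 = cy3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw cluster-dependent survival outcomes
#'
#' Event times are exponential with rate
#' \code{base_hazard * exp(log_hr[cluster])}; censoring is an independent
#' exponential with rate \code{base_hazard * c/(1-c)} for censoring rate
#' \code{c} (rate 0, i.e. no censoring, when \code{c = 0}).
#'
#' @param truth_labels Integer vector of latent cluster labels per tumor.
#' @param survival_model List with \code{base_hazard}, \code{log_hr},
#'   \code{censoring_rate}.
#' @param seed Optional seed; when \code{NULL} the current RNG stream is used
#'   (as inside \code{\link{generate_dataset}}).
#' @return Data frame with \code{time} (months) and \code{event} (1 = event
#'   observed, 0 = censored).
#' @export
generate_survival <- function(truth_labels, survival_model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth_labels)
  rate <- survival_model$base_hazard * exp(survival_model$log_hr[truth_labels])
  t_event <- stats::rexp(n, rate)
  cr <- survival_model$censoring_rate
  if (cr > 0) {
    c_rate <- survival_model$base_hazard * cr / (1 - cr)
    t_cens <- stats::rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Generate a complete synthetic methylation dataset
#'
#' Draws a cohort with the full statistical structure the pipeline assumes:
#' latent tumor clusters with block-structured beta profiles (one globally
#' hypermethylated cluster), beta-distributed biological and technical noise,
#' duplicate/triplicate samples, probes designed to fail each QC filter in
#' controlled numbers, samples designed to fail the detection rule,
#' cluster-conditional clinical covariates, cluster-dependent exponential
#' survival, and expression values anticorrelated with methylation at a
#' designated gene subset. Deterministic given \code{cfg$seed}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with elements \code{intensities} (cy5/cy3/detection_p
#'   matrices plus \code{replicate_map}), \code{manifest}, \code{annotation},
#'   \code{expression}, and \code{truth} (latent labels, probe blocks,
#'   designated QC sets).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  n_t <- cfg$n_tumors
  tumor_ids <- sprintf("T%04d", seq_len(n_t))
  cluster <- sample.int(cfg$n_clusters, n_t, replace = TRUE,
                        prob = cfg$cluster_proportions)
  names(cluster) <- tumor_ids

  ## --- probe roles and blocks ----------------------------------------------
  qc <- cfg$qc_fail_counts
  n_p <- cfg$n_probes
  probe_ids <- sprintf("cpg%05d", seq_len(n_p))
  role <- rep("stable", n_p)
  idx <- sample.int(n_p)                      # randomize placement on array
  take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
  snp_idx <- take(qc[["snp_flagged"]])
  det_idx <- take(qc[["detect_fail"]])
  lsd_idx <- take(qc[["low_sd"]])
  var_idx <- take(cfg$n_variant_probes)
  role[snp_idx] <- "snp_flagged"
  role[det_idx] <- "detect_fail"
  role[lsd_idx] <- "low_sd"
  role[var_idx] <- "variant"

  blocks <- rownames(cfg$block_means)
  vblocks <- blocks[startsWith(blocks, "v")]
  sblocks <- blocks[!startsWith(blocks, "v")]
  block <- rep(NA_character_, n_p)
  block[var_idx] <- rep(vblocks, length.out = length(var_idx))
  stable_like <- which(role %in% c("stable", "snp_flagged", "detect_fail"))
  block[stable_like] <- rep(sblocks, length.out = length(stable_like))
  block[lsd_idx] <- "flat"

  gene <- sprintf("G%04d", ceiling(seq_len(n_p) / 1.55))
  manifest <- data.frame(probe_id = probe_ids, gene_symbol = gene,
                         snp_repeat_flag = role == "snp_flagged",
                         stringsAsFactors = FALSE)

  ## --- tumor-level true beta -----------------------------------------------
  mean_mat <- matrix(0.3, n_p, n_t)           # flat (low-SD) default
  conc_mat <- matrix(5000, n_p, n_t)
  normal <- block != "flat"
  mean_mat[normal, ] <- cfg$block_means[cbind(
    rep(match(block[normal], blocks), n_t),
    rep(cluster, each = sum(normal)))]
  conc_mat[normal, ] <- cfg$precision
  true_beta <- matrix(rbeta_mean(n_p * n_t, mean_mat, conc_mat), n_p, n_t,
                      dimnames = list(probe_ids, tumor_ids))

  ## --- replicate structure --------------------------------------------------
  ## Roles are assigned to disjoint tumor index ranges; sample-QC failures and
  ## ineligibles are singleton tumors so the printed filter arithmetic holds.
  n_rep <- cfg$n_replicated_tumors
  n_tri <- cfg$n_triplicated_tumors
  rep_tumors <- tumor_ids[seq_len(n_rep)]
  tri_tumors <- tumor_ids[n_rep + seq_len(n_tri)]
  fail_tumors <- if (cfg$n_fail_samples > 0)
    tumor_ids[n_rep + n_tri + seq_len(cfg$n_fail_samples)] else character()
  ineligible <- if (cfg$n_ineligible > 0)
    tumor_ids[n_rep + n_tri + cfg$n_fail_samples + seq_len(cfg$n_ineligible)]
    else character()

  n_copies <- stats::setNames(rep(1L, n_t), tumor_ids)
  n_copies[rep_tumors] <- 2L
  n_copies[tri_tumors] <- 3L
  replicate_map <- data.frame(
    sample_id = unlist(lapply(tumor_ids, function(t)
      paste0(t, "_r", seq_len(n_copies[t])))),
    tumor_id = rep(tumor_ids, times = n_copies),
    stringsAsFactors = FALSE)

  ## --- per-sample measured beta --------------------------------------------
  n_s <- nrow(replicate_map)
  tcol <- match(replicate_map$tumor_id, tumor_ids)
  mu <- true_beta[, tcol, drop = FALSE]
  conc_s <- conc_mat[, tcol, drop = FALSE]
  conc_s[conc_s < 5000] <- cfg$replicate_precision
  beta_obs <- matrix(rbeta_mean(length(mu), mu, conc_s), n_p, n_s,
                     dimnames = list(probe_ids, replicate_map$sample_id))
  beta_obs <- pmin(beta_obs, 0.995)
  beta_obs <- matrix(beta_obs, n_p, n_s,
                     dimnames = list(probe_ids, replicate_map$sample_id))

  ints <- generate_intensities(beta_obs, cfg$total_signal)

  detection_p <- matrix(1e-8, n_p, n_s,
                        dimnames = list(probe_ids, replicate_map$sample_id))
  detection_p[det_idx, ] <- 1e-3              # probe-level detection failures
  if (length(fail_tumors) > 0) {
    bad_cols <- match(paste0(fail_tumors, "_r1"), colnames(detection_p))
    n_bad <- ceiling(0.30 * n_p)              # strictly above the 25% rule
    for (j in bad_cols) {
      detection_p[sample.int(n_p, n_bad), j] <- 1e-3
    }
  }

  ## --- clinical covariates ---------------------------------------------------
  draw_cat <- function(pmat) {
    lv <- colnames(pmat)
    vapply(cluster, function(cl)
      sample(lv, 1L, prob = pmat[cl, ]), character(1))
  }
  ann <- data.frame(tumor_id = tumor_ids, stringsAsFactors = FALSE)
  for (nm in names(cfg$covariate_model)) {
    ann[[nm]] <- draw_cat(cfg$covariate_model[[nm]])
  }
  if (!is.null(ann$age_band)) {
    ann$age <- ifelse(ann$age_band == "<50",
                      stats::runif(n_t, 28, 49.99),
                      stats::runif(n_t, 50, 74))
  }
  surv <- generate_survival(cluster, cfg$survival_model)
  ann$time <- surv$time
  ann$event <- surv$event
  ann$eligible <- !(tumor_ids %in% ineligible)

  ## --- expression coupled to methylation ------------------------------------
  vprobes <- probe_ids[var_idx]
  vgenes <- unique(manifest$gene_symbol[match(vprobes, manifest$probe_id)])
  n_eg <- min(cfg$n_expression_genes, length(vgenes))
  eg <- vgenes[seq_len(n_eg)]
  eg_probe <- vapply(eg, function(g)
    vprobes[manifest$gene_symbol[match(vprobes, manifest$probe_id)] == g][1L],
    character(1))
  r <- cfg$expression_r
  expr_sig <- t(vapply(eg_probe, function(p) {
    z <- as.numeric(scale(true_beta[p, ]))
    r * z + sqrt(1 - r^2) * stats::rnorm(n_t)
  }, numeric(n_t)))
  null_genes <- sprintf("NG%03d", seq_len(n_eg))
  expr_null <- matrix(stats::rnorm(n_eg * n_t), n_eg, n_t)
  expression <- 8 + 2 * rbind(expr_sig, expr_null)
  dimnames(expression) <- list(c(eg, null_genes), tumor_ids)

  list(
    intensities = list(cy5 = ints$cy5, cy3 = ints$cy3,
                       detection_p = detection_p,
                       replicate_map = replicate_map),
    manifest = manifest,
    annotation = ann,
    expression = expression,
    truth = list(
      cluster = cluster,
      probe_block = stats::setNames(block, probe_ids),
      probe_role = stats::setNames(role, probe_ids),
      variant_probes = probe_ids[var_idx],
      snp_probes = probe_ids[snp_idx],
      detect_fail_probes = probe_ids[det_idx],
      low_sd_probes = probe_ids[lsd_idx],
      fail_samples = paste0(fail_tumors, "_r1"),
      ineligible_tumors = ineligible,
      expression_genes = eg,
      expression_probe = eg_probe,
      true_beta = true_beta
    )
  )
}
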