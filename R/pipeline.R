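#' Pipeline configuration with study-standard defaults
#'
#' Collects every tunable threshold of the analysis chain: detection
#' p-value cutoff, tolerated per-sample failure fraction, probe SD floor,
#' variant-probe SD cut, consensus subsampling fraction and iteration count,
#' candidate k range, cluster-consensus threshold, FDR level, logit clamp,
#' Cox ties method, and the master seed.
#'
#' @param detection_p_thresh Detection p-value above which a call is
#'   unreliable (default 1e-5).
#' @param max_fail_frac Tolerated fraction of unreliable probes per sample
#'   (default 0.25).
#' @param probe_sd_min Probe SD floor in QC (default 0.06).
#' @param variant_sd_cut SD cut defining the most variant probes (default
#'   0.2).
#' @param subsample_frac Consensus subsampling fraction (default 0.8).
#' @param n_iter Consensus iterations (default 100).
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param consensus_threshold Cluster-consensus threshold (default 0.9).
#' @param fdr FDR significance level (default 0.05).
#' @param logit_eps Logit clamp width (default 1e-3).
#' @param ties Cox ties method (default "efron").
#' @param seed Master seed.
#' @param sim Optional \code{\link{sim_config}} enabling the simulate stage.
#' @param paths Optional named list of input paths (see
#'   \code{\link{validate_inputs}}); ignored when \code{sim} is given.
#' @param gmt Optional GMT file path for the enrichment stage.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(detection_p_thresh = 1e-5,
                            max_fail_frac = 0.25,
                            probe_sd_min = 0.06,
                            variant_sd_cut = 0.2,
                            subsample_frac = 0.8,
                            n_iter = 100L,
                            k_range = 2:10,
                            consensus_threshold = 0.9,
                            fdr = 0.05,
                            logit_eps = 1e-3,
                            ties = "efron",
                            seed = 1L,
                            sim = NULL,
                            paths = NULL,
                            gmt = NULL) {
  stopifnot(detection_p_thresh > 0, detection_p_thresh < 1,
            max_fail_frac >= 0, max_fail_frac < 1,
            probe_sd_min >= 0, variant_sd_cut >= 0,
            subsample_frac > 0, subsample_frac <= 1,
            n_iter >= 1, all(k_range >= 2),
            consensus_threshold >= 0, consensus_threshold <= 1,
            fdr > 0, fdr < 1, logit_eps > 0, logit_eps < 0.5,
            ties %in% c("efron", "breslow"))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_msg <- function(...) message("[cpgclust] ", sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> QC -> consensus clustering ->
#' differential methylation -> survival -> enrichment (optional), writing
#' each stage's tables plus a JSON run manifest (config, seed, per-stage
#' counts) under \code{out_dir}. Deterministic given an identical
#' configuration and seed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory for artifacts.
#' @param comparisons Annotation columns to test for differential
#'   methylation (restricted to those present).
#' @return Invisibly, a list of in-memory stage results (\code{qc},
#'   \code{clustering}, \code{diff}, \code{survival}, \code{enrichment},
#'   \code{manifest}).
#' @export
run_all <- function(config, out_dir,
                    comparisons = c("hr_status", "p53_status")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  ## --- inputs ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    stage_msg("simulate: %d tumors x %d probes (seed %d)",
              config$sim$n_tumors, config$sim$n_probes, config$sim$seed)
    ds <- generate_dataset(config$sim)
    write_dataset(ds, file.path(out_dir, "inputs"))
    raw <- ds$intensities
    manifest <- ds$manifest
    annotation <- ds$annotation
    ineligible <- ds$truth$ineligible_tumors
  } else {
    if (is.null(config$paths)) stop("stage inputs: neither sim nor paths given")
    probs <- validate_inputs(config$paths)
    if (length(probs) > 0L) {
      stop("stage inputs: ", paste(probs, collapse = "; "))
    }
    raw <- read_intensities(config$paths$intensities,
                            config$paths$replicate_map)
    manifest <- read_tsv(config$paths$manifest)
    annotation <- read_tsv(config$paths$annotation)
    ineligible <- if (!is.null(annotation$eligible))
      annotation$tumor_id[!annotation$eligible] else character()
    ds <- NULL
  }
  if (!is.null(annotation$eligible)) {
    ineligible <- annotation$tumor_id[!annotation$eligible]
  }

  ## --- QC -------------------------------------------------------------------
  qc <- preprocess_qc(raw, manifest, ineligible = ineligible,
                      p_thresh = config$detection_p_thresh,
                      max_fail_frac = config$max_fail_frac,
                      sd_min = config$probe_sd_min)
  counts$qc <- qc$provenance[c("samples_in", "samples_removed_qc",
                               "samples_removed_ineligible", "probes_in",
                               "probes_retained", "tumors_out")]
  stage_msg("qc: %d/%d probes, %d tumors retained",
            qc$provenance$probes_retained, qc$provenance$probes_in,
            qc$provenance$tumors_out)
  write_tsv(qc$beta, file.path(out_dir, "beta_filtered.tsv"),
            rownames_as = "probe_id")
  jsonlite::write_json(qc$provenance, file.path(out_dir, "qc_provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  ## --- consensus clustering -------------------------------------------------
  variant <- select_variant_probes(qc$beta, config$variant_sd_cut)
  counts$variant_probes <- length(variant)
  beta_var <- qc$beta[variant, , drop = FALSE]
  clustering <- consensus_cluster(beta_var, k_range = config$k_range,
                                  n_iter = config$n_iter,
                                  subsample_frac = config$subsample_frac,
                                  threshold = config$consensus_threshold,
                                  seed = config$seed)
  counts$chosen_k <- clustering$chosen_k
  stage_msg("cluster: %d variant probes, chosen k = %d",
            length(variant), clustering$chosen_k)
  write_tsv(data.frame(tumor_id = names(clustering$assignment),
                       cluster = unname(clustering$assignment)),
            file.path(out_dir, "assignment.tsv"))
  cc_tab <- do.call(rbind, lapply(names(clustering$by_k), function(k) {
    cc <- clustering$by_k[[k]]$cluster_consensus
    data.frame(k = as.integer(k), cluster = names(cc),
               consensus = unname(cc), stringsAsFactors = FALSE)
  }))
  write_tsv(cc_tab, file.path(out_dir, "cluster_consensus.tsv"))
  ck <- as.character(max(2L, clustering$chosen_k))
  write_tsv(clustering$by_k[[ck]]$consensus_matrix,
            file.path(out_dir, paste0("consensus_k", ck, ".tsv")),
            rownames_as = "tumor_id")

  summ <- summarize_clusters(beta_var, clustering$assignment, annotation,
                             covariates = intersect(
                               c("hr_status", "subtype", "p53_status",
                                 "grade", "stage", "race",
                                 "menopausal_status", "age"),
                               names(annotation)))
  write_tsv(data.frame(cluster = names(summ$mean_beta),
                       mean_beta = unname(summ$mean_beta)),
            file.path(out_dir, "cluster_mean_beta.tsv"))

  ## --- differential methylation ---------------------------------------------
  comparisons <- intersect(comparisons, names(annotation))
  diff_res <- list()
  for (cmp in comparisons) {
    covs <- intersect(covariate_spec(cmp), names(annotation))
    res <- diff_methylation(qc$beta, annotation, cmp, covariates = covs,
                            eps = config$logit_eps)
    diff_res[[cmp]] <- res
    counts[[paste0("sig_", cmp)]] <- sum(res$q < config$fdr)
    write_tsv(res, file.path(out_dir, paste0("diff_", cmp, ".tsv")))
    volcano <- data.frame(probe_id = res$probe_id, estimate = res$estimate,
                          neg_log10_p = -log10(res$raw_p))
    write_tsv(volcano, file.path(out_dir, paste0("volcano_", cmp, ".tsv")))
  }
  # hypermethylated-cluster signature: chosen cluster vs rest, rank test
  hyper_cl <- names(which.max(summ$mean_beta))
  ann_cl <- annotation
  ann_cl$hyper_cluster <- ifelse(
    clustering$assignment[ann_cl$tumor_id] == as.integer(hyper_cl),
    "hyper", "rest")
  sig_res <- diff_methylation(beta_var, ann_cl, "hyper_cluster",
                              method = "rank", ref = "rest")
  diff_res$hyper_cluster <- sig_res
  counts$sig_hyper_cluster <- sum(sig_res$q < config$fdr)
  write_tsv(sig_res, file.path(out_dir, "diff_hyper_cluster.tsv"))
  stage_msg("diff: %s",
            paste(sprintf("%s=%d", names(diff_res),
                          vapply(diff_res, function(r)
                            sum(r$q < config$fdr), integer(1))),
                  collapse = ", "))

  ## --- survival ---------------------------------------------------------------
  surv_res <- NULL
  if (all(c("time", "event") %in% names(annotation)) &&
      clustering$chosen_k > 1L) {
    ann_s <- annotation[annotation$tumor_id %in%
                          names(clustering$assignment), , drop = FALSE]
    cl <- clustering$assignment[ann_s$tumor_id]
    km <- kaplan_meier(ann_s$time, ann_s$event, cl)
    lr <- log_rank(ann_s$time, ann_s$event, cl)
    cx <- cluster_survival(annotation, clustering$assignment,
                           ties = config$ties)
    surv_res <- list(km = km, log_rank = lr, cox = cx)
    write_tsv(km, file.path(out_dir, "km_curves.tsv"))
    jsonlite::write_json(lr, file.path(out_dir, "log_rank.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(cx$univariate$table, file.path(out_dir, "cox_univariate.tsv"))
    write_tsv(cx$multivariate$table,
              file.path(out_dir, "cox_multivariate.tsv"))
    counts$log_rank_p <- lr$p
    stage_msg("survival: log-rank p = %.3g over %d clusters", lr$p,
              clustering$chosen_k)
  }

  ## --- enrichment -------------------------------------------------------------
  enr <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    background <- dedupe_genes(rownames(qc$beta), manifest)
    sig_probes <- sig_res$probe_id[sig_res$q < config$fdr]
    genes <- dedupe_genes(sig_probes, manifest)
    if (length(genes) > 0L) {
      enr <- enrich(genes, sets, background, alpha = config$fdr)
      write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      counts$enriched_terms <- sum(enr$significant)
      stage_msg("enrich: %d/%d terms significant", sum(enr$significant),
                nrow(enr))
    }
  }

  ## --- manifest ---------------------------------------------------------------
  cfg_out <- config
  cfg_out$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  manifest_json <- list(seed = config$seed,
                        config = unclass(cfg_out)[setdiff(names(cfg_out),
                                                          c("paths"))],
                        stage_counts = counts)
  jsonlite::write_json(manifest_json,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = 10)
  invisible(list(qc = qc, clustering = clustering, diff = diff_res,
                 survival = surv_res, enrichment = enr,
                 manifest = manifest_json, dataset = ds))
}
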