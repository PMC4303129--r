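#' k-means++ seeding
#'
#' Chooses initial centers by D^2 weighting: the first center uniformly at
#' random, each subsequent one with probability proportional to the squared
#' Euclidean distance to the nearest center already chosen.
#'
#' @param x Numeric matrix, observations in rows.
#' @param k Number of centers.
#' @return A k x ncol(x) matrix of initial centers.
#' @keywords internal
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  ci <- sample.int(n, 1L)
  centers[1L, ] <- x[ci, ]
  if (k > 1L) {
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        ci <- sample.int(n, 1L)
      } else {
        ci <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[ci, ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

run_kmeans <- function(x, k) {
  # Lloyd iterations can empty a cluster for unlucky seedings; re-seed and
  # retry a few times before giving up.
  for (attempt in 1:5) {
    init <- kmeanspp_centers(x, k)
    init <- init + 1e-9 * stats::rnorm(length(init)) # centers must be distinct
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 300L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit$cluster)
  }
  stats::kmeans(x, centers = k, iter.max = 300L)$cluster
}

#' Build a subsampled consensus matrix
#'
#' Repeatedly subsamples a fraction of the tumors without replacement,
#' partitions the subsample with k-means (squared Euclidean distance,
#' k-means++ seeding), and tallies, for every tumor pair, the number of
#' iterations in which the pair was co-sampled and in which it was assigned
#' to the same cluster. The consensus entry is the ratio of the two tallies.
#' Pairs never co-sampled are imputed as 0 with a warning. The diagonal is 1.
#'
#' @param x Tumors x features numeric matrix (rows are clustered).
#' @param k Number of clusters for the base k-means.
#' @param n_iter Number of subsampling iterations (default 100).
#' @param subsample_frac Fraction of tumors drawn each iteration (default
#'   0.8).
#' @param seed Integer seed making the whole tally deterministic.
#' @param keep_assignments Store the per-iteration subsample indices and
#'   labels as the \code{"assignments"} attribute (for auditing).
#' @return Symmetric tumors x tumors consensus matrix with entries in
#'   \code{[0, 1]}.
#' @export
build_consensus <- function(x, k, n_iter = 100L, subsample_frac = 0.8,
                            seed = 1L, keep_assignments = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of tumors")
  if (ncol(x) < 2L) stop("need at least two features")
  set.seed(seed)
  m <- floor(subsample_frac * n)
  if (m < k) stop("subsample smaller than k")
  co_clustered <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  assignments <- if (keep_assignments) vector("list", n_iter) else NULL
  for (it in seq_len(n_iter)) {
    sub <- sort(sample.int(n, m))
    labels <- run_kmeans(x[sub, , drop = FALSE], k)
    ind <- matrix(0, n, 1L); ind[sub] <- 1
    co_sampled <- co_sampled + tcrossprod(ind)
    lab_ind <- matrix(0, n, k)
    lab_ind[cbind(sub, labels)] <- 1
    co_clustered <- co_clustered + tcrossprod(lab_ind)
    if (keep_assignments) assignments[[it]] <- list(sub = sub, labels = labels)
  }
  never <- co_sampled == 0
  diag(never) <- FALSE
  cm <- co_clustered / pmax(co_sampled, 1)
  cm[never] <- 0
  if (any(never)) {
    warning(sum(never) / 2, " tumor pair(s) never co-sampled; consensus imputed as 0")
  }
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(x), rownames(x))
  if (keep_assignments) attr(cm, "assignments") <- assignments
  cm
}

#' Derive final cluster labels from a consensus matrix
#'
#' Hierarchically agglomerates tumors (average linkage) on the dissimilarity
#' \code{1 - consensus} and cuts the tree at \code{k} clusters. Labels are
#' renumbered so that cluster 1 is the largest (ties broken by first
#' occurrence).
#'
#' @param consensus_matrix Symmetric consensus matrix.
#' @param k Number of clusters to cut.
#' @return Integer vector of cluster labels 1..k, named by tumor.
#' @export
consensus_assign <- function(consensus_matrix, k) {
  d <- 1 - consensus_matrix
  if (max(d) - min(d[upper.tri(d)]) < 1e-12 && nrow(d) > 1) {
    warning("degenerate consensus matrix (all entries equal); split is arbitrary")
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- relabel[as.character(raw)]
  stats::setNames(as.integer(out), names(raw))
}

#' Mean within-cluster consensus
#'
#' For each cluster, the mean of the consensus entries over all unordered
#' within-cluster tumor pairs; a singleton cluster is assigned consensus 1.
#'
#' @param consensus_matrix Symmetric consensus matrix.
#' @param assignment Integer cluster labels as from
#'   \code{\link{consensus_assign}}.
#' @return Named numeric vector, one consensus value in \code{[0, 1]} per
#'   cluster.
#' @export
cluster_consensus <- function(consensus_matrix, assignment) {
  ks <- sort(unique(assignment))
  vapply(ks, function(cl) {
    idx <- which(assignment == cl)
    if (length(idx) < 2L) return(1)
    sub <- consensus_matrix[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1)) -> out
  stats::setNames(out, ks)
}

#' Choose the number of clusters by the cluster-consensus rule
#'
#' The chosen k is the greatest number of clusters for which every cluster's
#' consensus is at least \code{threshold} (equivalently, the minimum over
#' clusters reaches the threshold). If no k in the range qualifies, 1 is
#' returned with a warning.
#'
#' @param cluster_consensus_by_k Named list (names = k) of per-cluster
#'   consensus vectors.
#' @param threshold Minimum cluster consensus (default 0.9).
#' @return Integer, the chosen k.
#' @export
select_k <- function(cluster_consensus_by_k, threshold = 0.9) {
  ks <- as.integer(names(cluster_consensus_by_k))
  ok <- vapply(cluster_consensus_by_k,
               function(cc) min(cc) >= threshold, logical(1))
  if (!any(ok)) {
    warning("no k in range reaches the cluster-consensus threshold; returning 1")
    return(1L)
  }
  max(ks[ok])
}

#' Subsampled consensus clustering over a range of k
#'
#' Runs \code{\link{build_consensus}} for each k in \code{k_range}, derives
#' labels and per-cluster consensus, and selects the final k by the
#' cluster-consensus rule. Clustering operates on untransformed beta values of
#' the variant probes.
#'
#' @param beta Probes x tumors beta matrix restricted to the variant probes
#'   (tumors are clustered).
#' @param k_range Candidate cluster numbers (default 2:10).
#' @inheritParams build_consensus
#' @param threshold Cluster-consensus threshold for k selection (default
#'   0.9).
#' @return Object of class \code{consensus_result}: per-k consensus matrices,
#'   assignments and cluster consensus, the chosen k, the final assignment,
#'   and the parameters used.
#' @export
consensus_cluster <- function(beta, k_range = 2:10, n_iter = 100L,
                              subsample_frac = 0.8, threshold = 0.9,
                              seed = 1L) {
  x <- t(beta)
  res <- list()
  for (k in k_range) {
    cm <- build_consensus(x, k, n_iter = n_iter,
                          subsample_frac = subsample_frac,
                          seed = seed + k)
    assignment <- consensus_assign(cm, k)
    res[[as.character(k)]] <- list(
      consensus_matrix = cm,
      assignment = assignment,
      cluster_consensus = cluster_consensus(cm, assignment))
  }
  cc_by_k <- lapply(res, `[[`, "cluster_consensus")
  chosen <- select_k(cc_by_k, threshold)
  out <- list(
    by_k = res,
    chosen_k = chosen,
    assignment = if (chosen > 1L) res[[as.character(chosen)]]$assignment
                 else stats::setNames(rep(1L, ncol(beta)), colnames(beta)),
    params = list(subsample_frac = subsample_frac, n_iter = n_iter,
                  k_range = k_range, distance = "squared Euclidean",
                  consensus_threshold = threshold, seed = seed))
  class(out) <- "consensus_result"
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =",
      paste(range(x$params$k_range), collapse = ".."),
      sprintf("(%d iterations, %.0f%% subsampling)\n",
              x$params$n_iter, 100 * x$params$subsample_frac))
  cat("Chosen k:", x$chosen_k, "\n")
  if (x$chosen_k > 1L) {
    cat("Cluster sizes:", table(x$assignment), "\n")
    cat("Cluster consensus:",
        round(x$by_k[[as.character(x$chosen_k)]]$cluster_consensus, 3), "\n")
  }
  invisible(x)
}

#' Summarize clusters: mean methylation and covariate composition
#'
#' Per-cluster mean beta over the variant probes (with a Kruskal-Wallis test
#' of per-tumor mean beta across clusters) and, for each annotation
#' covariate, a cluster x level contingency table with a chi-square p-value
#' (continuous covariates get a Kruskal-Wallis p instead).
#'
#' @param beta Probes x tumors beta matrix (variant probes).
#' @param assignment Cluster labels named by tumor.
#' @param annotation Data frame with \code{tumor_id} and covariate columns.
#' @param covariates Covariate column names to cross-tabulate (default: all
#'   except \code{tumor_id}).
#' @return List with \code{mean_beta} (per-cluster mean), \code{mean_beta_p}
#'   (Kruskal-Wallis p across clusters), and \code{crosstabs}, a named list
#'   of \code{table}/\code{p} pairs.
#' @export
summarize_clusters <- function(beta, assignment, annotation,
                               covariates = NULL) {
  tumors <- colnames(beta)
  stopifnot(all(tumors %in% annotation$tumor_id),
            all(tumors %in% names(assignment)))
  cl <- assignment[tumors]
  ann <- annotation[match(tumors, annotation$tumor_id), , drop = FALSE]
  per_tumor_mean <- colMeans(beta, na.rm = TRUE)
  mean_beta <- tapply(per_tumor_mean, cl, mean)
  kw <- if (length(unique(cl)) > 1L)
    stats::kruskal.test(per_tumor_mean, factor(cl))$p.value else NA_real_

  if (is.null(covariates)) {
    covariates <- setdiff(names(ann), "tumor_id")
  }
  crosstabs <- lapply(covariates, function(v) {
    x <- ann[[v]]
    if (is.numeric(x)) {
      p <- if (length(unique(cl)) > 1L)
        stats::kruskal.test(x, factor(cl))$p.value else NA_real_
      list(table = tapply(x, cl, mean, na.rm = TRUE), p = p)
    } else {
      tab <- table(cluster = cl, level = x)
      p <- if (nrow(tab) > 1L && ncol(tab) > 1L)
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        else NA_real_
      list(table = tab, p = p)
    }
  })
  names(crosstabs) <- covariates
  list(mean_beta = mean_beta, mean_beta_p = kw, crosstabs = crosstabs)
}
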