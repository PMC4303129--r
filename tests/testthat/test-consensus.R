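make_blobs <- function(n_per = c(10, 10), centers = list(c(0, 0), c(10, 10)),
                       sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(n_per), function(i) {
    matrix(rnorm(n_per[i] * 2, rep(centers[[i]], each = n_per[i]), sd),
           n_per[i], 2)
  }))
  rownames(x) <- paste0("t", seq_len(nrow(x)))
  x
}

test_that("identical tumors always share consensus 1", {
  x <- make_blobs(c(6, 6), sd = 0.3)
  x <- rbind(x, dup1 = x[1, ], dup2 = x[1, ])   # exact duplicates of t1
  for (k in 2:4) {
    cm <- build_consensus(x, k, n_iter = 30, seed = 5)
    expect_equal(cm["dup1", "dup2"], 1)
    expect_equal(cm["t1", "dup1"], 1)
  }
})

test_that("consensus matrix equals the brute-force co-clustering tally", {
  set.seed(8)
  x <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("t", 1:6), NULL))
  cm <- build_consensus(x, k = 2, n_iter = 20, subsample_frac = 0.8,
                        seed = 17, keep_assignments = TRUE)
  oracle <- consensus_tally_oracle(attr(cm, "assignments"), 6)
  expect_equal(unname(cm[, ]), oracle, tolerance = 1e-12)
})

test_that("well-separated blobs give near 0/1 consensus structure", {
  x <- make_blobs(c(12, 12), sd = 0.1)
  cm <- build_consensus(x, 2, n_iter = 60, seed = 2)
  within <- c(cm[1:12, 1:12][upper.tri(diag(12))],
              cm[13:24, 13:24][upper.tri(diag(12))])
  between <- cm[1:12, 13:24]
  expect_true(all(within >= 0.99))
  expect_true(all(between <= 0.01))

  # full-sample consensus with trivially separable data is exactly 0/1
  cm_full <- build_consensus(x, 2, n_iter = 20, subsample_frac = 1, seed = 3)
  expect_true(all(cm_full %in% c(0, 1)))
})

test_that("assignment recovers block-diagonal consensus exactly", {
  blocks <- c(3, 4, 5)
  cm <- matrix(0, 12, 12)
  start <- cumsum(c(1, blocks))
  for (i in seq_along(blocks)) {
    idx <- start[i]:(start[i] + blocks[i] - 1)
    cm[idx, idx] <- 1
  }
  dimnames(cm) <- list(paste0("t", 1:12), paste0("t", 1:12))
  a <- consensus_assign(cm, 3)
  truth <- rep(seq_along(blocks), blocks)
  expect_equal(length(unique(paste(a, truth))), 3)
  # labels ordered by decreasing size
  expect_equal(as.vector(table(a)), c(5, 4, 3))

  # permuting tumors permutes labels consistently
  perm <- sample(12)
  a_perm <- consensus_assign(cm[perm, perm], 3)
  expect_equal(length(unique(paste(a_perm, truth[perm]))), 3)

  expect_warning(consensus_assign(matrix(0.5, 4, 4), 2), "degenerate")
})

test_that("cluster consensus equals the within-cluster pair mean", {
  # perfect blocks -> 1; constant matrix -> the constant
  cm1 <- diag(6); cm1[1:3, 1:3] <- 1; cm1[4:6, 4:6] <- 1
  expect_equal(unname(cluster_consensus(cm1, rep(1:2, each = 3))), c(1, 1))
  cm2 <- matrix(0.5, 6, 6); diag(cm2) <- 1
  expect_equal(unname(cluster_consensus(cm2, rep(1:2, 3))), c(0.5, 0.5))
  # singleton cluster -> 1
  expect_equal(unname(cluster_consensus(cm2, c(1, 2, 2, 2, 2, 2)))[1], 1)

  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:9, 1)
    cm <- matrix(runif(n * n), n, n)
    cm <- (cm + t(cm)) / 2; diag(cm) <- 1
    a <- sample(1:3, n, replace = TRUE)
    expect_equal(unname(cluster_consensus(cm, a)), pair_mean_oracle(cm, a))
  }
})

test_that("k selection follows the cluster-consensus rule", {
  x <- make_blobs(c(12, 12, 12, 12),
                  centers = list(c(0, 0), c(8, 0), c(0, 8), c(8, 8)),
                  sd = 0.3, seed = 4)
  res <- consensus_cluster(t(x), k_range = 2:6, n_iter = 30, seed = 9)
  expect_equal(res$chosen_k, 4)

  # threshold 0 always admits the top of the range
  cc_by_k <- lapply(res$by_k, `[[`, "cluster_consensus")
  expect_equal(select_k(cc_by_k, threshold = 0), 6L)

  # a single homogeneous blob supports no k
  y <- make_blobs(c(24), centers = list(c(0, 0)), sd = 1, seed = 6)
  expect_warning(
    res1 <- consensus_cluster(t(y), k_range = 2:4, n_iter = 25, seed = 10),
    "returning 1")
  expect_warning(
    k1 <- select_k(lapply(res1$by_k, `[[`, "cluster_consensus"), 0.9),
    "returning 1")
  expect_equal(k1, 1L)
})

test_that("consensus labels beat random labels on block-structured matrices", {
  set.seed(12)
  x <- make_blobs(c(10, 10), sd = 0.2)
  cm <- build_consensus(x, 2, n_iter = 40, seed = 13)
  a <- consensus_assign(cm, 2)
  for (i in 1:10) {
    rand <- sample(1:2, 20, replace = TRUE)
    if (length(unique(rand)) < 2) next
    expect_gte(mean(cluster_consensus(cm, a)),
               mean(cluster_consensus(cm, rand)))
  }
})

test_that("doubling iterations perturbs consensus entries only slightly", {
  x <- make_blobs(c(10, 10, 10),
                  centers = list(c(0, 0), c(6, 0), c(0, 6)), sd = 0.8,
                  seed = 14)
  cm1 <- build_consensus(x, 3, n_iter = 100, seed = 15)
  cm2 <- build_consensus(x, 3, n_iter = 200, seed = 16)
  expect_lt(max(abs(cm1 - cm2)), 0.1)
})

test_that("cluster summaries cross-tabulate covariates with test p-values", {
  set.seed(20)
  n <- 60
  beta <- matrix(runif(5 * n, 0.3, 0.7), 5, n,
                 dimnames = list(paste0("p", 1:5), paste0("T", 1:n)))
  cl <- setNames(rep(1:2, each = n / 2), colnames(beta))
  beta[, cl == 2] <- beta[, cl == 2] + 0.2
  ann <- data.frame(tumor_id = colnames(beta),
                    grp = rep(c("a", "b", "a", "b"), n / 4),
                    age = rnorm(n, 50, 5))
  s <- summarize_clusters(beta, cl, ann, covariates = c("grp", "age"))
  expect_equal(names(s$mean_beta), c("1", "2"))
  expect_gt(s$mean_beta[["2"]], s$mean_beta[["1"]])
  expect_lt(s$mean_beta_p, 1e-6)

  # all tumors in one cluster: cross-tab equals the marginal counts
  s1 <- summarize_clusters(beta, setNames(rep(1L, n), colnames(beta)), ann,
                           covariates = "grp")
  expect_equal(as.vector(s1$crosstabs$grp$table), as.vector(table(ann$grp)))

  # cross-tab chi-square p matches the 2x2 closed form on random cohorts
  set.seed(21)
  for (i in 1:100) {
    tab <- matrix(sample(3:30, 4, replace = TRUE), 2, 2)
    m <- sum(tab)
    ids <- paste0("x", seq_len(m))
    cl2 <- setNames(rep(c(1L, 2L), rowSums(tab)), ids)
    lev <- c(rep(c("a", "b"), tab[1, ]), rep(c("a", "b"), tab[2, ]))
    ann2 <- data.frame(tumor_id = ids, grp = lev)
    b2 <- matrix(0.5, 1, m, dimnames = list("p1", ids))
    got <- summarize_clusters(b2, cl2, ann2, covariates = "grp")$crosstabs$grp$p
    expected <- pchisq(chisq_2x2_oracle(tab), 1, lower.tail = FALSE)
    expect_equal(got, expected, tolerance = 1e-12)
  }
})
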