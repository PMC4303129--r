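test_that("Wilcoxon rank-sum matches exact enumeration on small samples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)          # 2 extreme splits x 2 tails / C(6,3)
  expect_equal(r$statistic, 0)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1), "non-empty")

  set.seed(30)
  for (i in 1:100) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    vals <- sample(1000, nx + ny)        # tie-free
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$p, wilcox_exact_oracle(x, y))
    # statistic equals the rank-sum of x minus its minimum
    w_direct <- sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2
    expect_equal(got$statistic, w_direct)
  }
})

test_that("Kruskal-Wallis handles ties, degeneracy, and the 2-group identity", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1))),
               list(statistic = 0, df = 1L, p = 1))

  # two groups: chi-square(1) H test equals the squared-z normal Wilcoxon
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12, 0.5)
    kw <- kruskal_wallis(list(x, y))
    pw <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    expect_equal(kw$p, pw, tolerance = 1e-6)
  }

  # three-group toy with hand-worked ranks:
  # groups {1,2},{3,4},{5,6}; rank sums 3, 7, 11
  # H = 12/(6*7) * (3^2/2 + 7^2/2 + 11^2/2) - 3*7 = 12/42*89.5 - 21
  kw3 <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw3$statistic, 12 / 42 * 89.5 - 21)
  expect_equal(kw3$df, 2L)
})

test_that("BH q-values equal the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(32)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("probe model reduces to the unadjusted contrast when orthogonal", {
  set.seed(33)
  n <- 40
  grp <- rep(c("a", "b"), each = n / 2)
  cov_bal <- rep(c(0, 1), n / 2)          # orthogonal to grp, effect 0
  y <- rnorm(n) + 0.8 * (grp == "b")
  fit <- fit_probe_model(y, data.frame(grp = grp, z = cov_bal), "grp", "z")
  expect_equal(fit$coefficient, mean(y[grp == "b"]) - mean(y[grp == "a"]),
               tolerance = 1e-8)
  expect_equal(fit$n, n)

  # a covariate collinear with the factor is aliased; the contrast survives
  bad <- data.frame(grp = grp, z = as.numeric(grp == "b"))
  fit_alias <- fit_probe_model(y, bad, "grp", "z")
  expect_equal(fit_alias$coefficient,
               mean(y[grp == "b"]) - mean(y[grp == "a"]), tolerance = 1e-8)

  # but a factor left with one level after complete cases is unusable
  d_one <- data.frame(grp = grp, z = ifelse(grp == "b", NA, 1.0))
  expect_null(fit_probe_model(y, d_one, "grp", "z"))

  # incomplete cases are dropped
  d2 <- data.frame(grp = grp, z = c(NA, cov_bal[-1]))
  expect_equal(fit_probe_model(y, d2, "grp", "z")$n, n - 1)
})

test_that("differential testing controls the FDR under the global null", {
  set.seed(34)
  n <- 100; n_probes <- 400
  beta <- matrix(rbeta(n_probes * n, 5, 5), n_probes, n,
                 dimnames = list(sprintf("p%03d", 1:n_probes),
                                 sprintf("T%03d", 1:n)))
  ann <- data.frame(tumor_id = colnames(beta),
                    grp = sample(c("a", "b"), n, replace = TRUE),
                    age = rnorm(n, 50, 8))
  res <- diff_methylation(beta, ann, "grp", covariates = "age")
  expect_equal(nrow(res), n_probes)
  expect_lte(mean(res$q < 0.05), 0.01)
  expect_true(all(res$q >= res$raw_p - 1e-15))
})

test_that("planted effects are detected with the planted direction", {
  set.seed(35)
  n <- 400; n_probes <- 150; n_planted <- 50
  grp <- rep(c("a", "b"), each = n / 2)
  beta <- matrix(rbeta(n_probes * n, 8, 12), n_probes, n,
                 dimnames = list(sprintf("p%03d", 1:n_probes),
                                 sprintf("T%03d", 1:n)))
  planted <- rownames(beta)[1:n_planted]
  beta[planted, grp == "b"] <- beta[planted, grp == "b"] + 0.3
  beta <- pmin(beta, 0.999)
  ann <- data.frame(tumor_id = colnames(beta), grp = grp,
                    age = rnorm(n, 50, 8),
                    race = sample(c("w", "aa"), n, replace = TRUE))
  res <- diff_methylation(beta, ann, "grp",
                          covariates = c("age", "race"), ref = "a")
  sig <- res[res$q < 0.05, ]
  hits <- intersect(sig$probe_id, planted)
  expect_gte(length(hits) / n_planted, 0.9)
  expect_true(all(sig[sig$probe_id %in% planted, "direction"] == "hyper"))

  # coefficient sign matches the adjusted logit-scale group difference
  lb <- logit_transform(beta)
  for (pid in sample(rownames(beta), 20)) {
    d <- mean(lb[pid, grp == "b"]) - mean(lb[pid, grp == "a"])
    est <- res$estimate[res$probe_id == pid]
    if (abs(d) > 0.05) expect_equal(sign(est), sign(d))
  }

  # direction counts partition the significant set
  ds <- direction_summary(res)
  expect_equal(sum(ds), nrow(sig))
  expect_equal(unname(direction_summary(res[res$q >= 0.05, ])),
               c(0L, 0L))
})

test_that("Venn region counts equal brute-force membership tallies", {
  expect_equal(sum(overlap_sets(list(A = "x", B = "y", C = "z"))[
    c("A&B", "A&C", "B&C", "A&B&C")]), 0)
  s <- paste0("p", 1:5)
  ident <- overlap_sets(list(A = s, B = s, C = s))
  expect_equal(unname(ident["A&B&C"]), 5L)
  expect_equal(sum(ident), 5L)

  set.seed(36)
  for (i in 1:100) {
    u <- paste0("p", 1:15)
    sets <- list(A = sample(u, sample(0:10, 1)),
                 B = sample(u, sample(0:10, 1)),
                 C = sample(u, sample(0:10, 1)))
    got <- overlap_sets(sets)
    expect_equal(sum(got), length(unique(unlist(sets))))
    # brute-force each element's membership pattern
    for (el in unique(unlist(sets))) {
      pat <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                      logical(1))], collapse = "&")
      expect_gte(got[[pat]], 1L)
    }
    ab <- sum(vapply(u, function(el)
      el %in% sets$A && el %in% sets$B && !(el %in% sets$C), logical(1)))
    expect_equal(unname(got["A&B"]), ab)
  }
})

test_that("signature overlap test equals the hypergeometric tail sum", {
  bg <- paste0("p", 1:100)
  sig <- bg[1:10]
  ext <- bg[c(1:8, 11, 12)]           # overlap 8 -> table (8, 2, 2, 88)
  res <- signature_overlap_test(sig, ext, bg)
  expect_equal(as.vector(res$table), c(8, 2, 2, 88))
  expect_equal(res$p, hyper_tail_oracle(8, 10, 100, 10), tolerance = 1e-12)

  # signature = set = background -> p = 1
  expect_equal(signature_overlap_test(bg, bg, bg)$p, 1)
  # empty overlap with a large expected one -> p near 1 for enrichment
  expect_gt(signature_overlap_test(bg[1:40], bg[41:90], bg)$p, 0.999)
  expect_error(signature_overlap_test(c(bg[1], "zz"), bg[1:5], bg), "subsets")
})

test_that("methylation-expression correlation recovers planted structure", {
  set.seed(37)
  n <- 60
  beta <- matrix(runif(2 * n, 0.1, 0.9), 2, n,
                 dimnames = list(c("p1", "p2"), paste0("T", 1:n)))
  expr <- rbind(g1 = -beta["p1", ], g2 = rnorm(n))
  colnames(expr) <- colnames(beta)
  res <- methylation_expression_correlation(
    beta, expr, c(p1 = "g1", p2 = "g2"))
  expect_equal(res$r[res$probe_id == "p1" & res$stratum == "all"], -1)
  expect_gt(res$p[res$probe_id == "p2" & res$stratum == "all"], 0.001)

  # planted generator correlation is recovered within 0.1
  ds <- generate_dataset(small_cfg(n_tumors = 300))
  pg <- setNames(ds$truth$expression_genes, ds$truth$expression_probe)
  qc <- preprocess_qc(ds$intensities, ds$manifest)
  res2 <- methylation_expression_correlation(
    qc$beta[intersect(rownames(qc$beta), names(pg)), , drop = FALSE],
    ds$expression[, colnames(qc$beta)], pg)
  all_r <- res2$r[res2$stratum == "all"]
  expect_lt(abs(mean(all_r) - (-0.6)), 0.1)
})

test_that("adjustment sets never include the comparison itself", {
  for (cmp in c("hr_status", "subtype", "p53_status", "grade",
                "tumor_size", "stage", "node_status")) {
    expect_false(cmp %in% covariate_spec(cmp))
  }
  expect_equal(covariate_spec("stage"),
               c("age", "race", "menopausal_status"))
  expect_true("node_status" %in% covariate_spec("tumor_size"))
  expect_true("tumor_size" %in% covariate_spec("node_status"))
  expect_true("subtype" %in% covariate_spec("p53_status",
                                            p53_adjust_subtype = TRUE))
})
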