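test_that("compute_beta follows the clipped-ratio formula", {
  expect_equal(compute_beta(-50, 200), 0)
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(900, 100), 900 / 1100)
  expect_equal(compute_beta(c(900, -50), c(100, 200)), c(900 / 1100, 0))
  expect_error(compute_beta(NA_real_, 1), "non-finite")
  expect_error(compute_beta(Inf, 1), "non-finite")
})

test_that("compute_beta is monotone in cy5 and bounded in [0, 1)", {
  set.seed(1)
  for (rep in 1:20) {
    cy3 <- runif(1, 0, 5000)
    cy5 <- sort(runif(50, -500, 50000))
    b <- compute_beta(cy5, rep(cy3, 50))
    expect_true(all(diff(b) >= 0))
    expect_true(all(b >= 0 & b < 1))
  }
})

test_that("sample filter uses strict comparisons on both thresholds", {
  n_probes <- 100
  dp <- matrix(1e-8, n_probes, 3,
               dimnames = list(paste0("p", 1:n_probes), c("s_fail", "s_edge", "s_ok")))
  dp[1:26, "s_fail"] <- 1e-3   # 26% above threshold -> removed
  dp[1:25, "s_edge"] <- 1e-3   # exactly 25% -> retained
  res <- filter_samples(dp)
  expect_identical(res$removed, "s_fail")
  expect_setequal(res$keep, c("s_edge", "s_ok"))

  all_ok <- matrix(1e-8, 10, 4)
  expect_length(filter_samples(all_ok)$removed, 0)
  expect_error(filter_samples(matrix(numeric(), 0, 0)), "non-empty")
})

test_that("probe filters apply in order with reconciling provenance", {
  set.seed(2)
  n_p <- 60; n_s <- 40
  beta <- matrix(runif(n_p * n_s, 0.2, 0.8), n_p, n_s,
                 dimnames = list(sprintf("p%02d", 1:n_p), paste0("s", 1:n_s)))
  beta["p05", ] <- 0.5                         # SD 0 -> low-SD removal
  manifest <- data.frame(probe_id = rownames(beta),
                         gene_symbol = paste0("g", 1:n_p),
                         snp_repeat_flag = c(rep(TRUE, 4), rep(FALSE, n_p - 4)))
  res <- filter_probes(beta, manifest, detection_fail = c("p10", "p11"))
  prov <- res$provenance
  expect_equal(prov$removed, c(4, 2, 1))
  expect_equal(prov$retained, c(56, 54, 53))
  expect_equal(nrow(beta) - sum(prov$removed), nrow(res$beta))
  expect_false("p05" %in% rownames(res$beta))

  # probe at exactly the SD floor is retained
  k <- 20
  b2 <- matrix(0.5, 2, k, dimnames = list(c("edge", "flat"), paste0("s", 1:k)))
  target <- 0.06
  dev <- rep(c(-1, 1), k / 2)
  b2["edge", ] <- 0.5 + dev * target * sqrt((k - 1) / k)
  expect_equal(sd(b2["edge", ]), 0.06)
  m2 <- data.frame(probe_id = c("edge", "flat"), gene_symbol = c("a", "b"),
                   snp_repeat_flag = FALSE)
  res2 <- filter_probes(b2, m2, sd_min = sd(b2["edge", ]))
  expect_true("edge" %in% rownames(res2$beta))
  expect_false("flat" %in% rownames(res2$beta))

  # no flags, no failures, everything variable -> identity
  res3 <- filter_probes(beta[6:20, ], manifest)
  expect_identical(res3$beta, beta[6:20, ])
  expect_error(filter_probes(beta, manifest[-1, ]), "p01")
})

test_that("replicate averaging collapses tumors and is idempotent", {
  beta <- matrix(c(0.2, 0.4, 0.1, 0.2, 0.6, 0.3), nrow = 1,
                 dimnames = list("p1", paste0("s", 1:6)))
  map <- data.frame(sample_id = paste0("s", 1:6),
                    tumor_id = c("A", "A", "B", "B", "B", "C"))
  res <- average_replicates(beta, map)
  expect_equal(unname(res$beta["p1", c("A", "B", "C")]), c(0.3, 0.3, 0.3))

  # identical replicate vectors: averaging changes nothing
  b2 <- matrix(c(0.7, 0.7), 1, 2, dimnames = list("p1", c("x1", "x2")))
  m2 <- data.frame(sample_id = c("x1", "x2"), tumor_id = c("T", "T"))
  expect_equal(unname(average_replicates(b2, m2)$beta[1, 1]), 0.7)

  # tumor with no surviving sample is dropped and reported
  m3 <- rbind(map, data.frame(sample_id = "gone", tumor_id = "D"))
  res3 <- average_replicates(beta, m3)
  expect_identical(res3$dropped, "D")
})

test_that("replicate concordance is Pearson r per pair", {
  beta <- cbind(a1 = c(0.1, 0.2, 0.3), a2 = c(0.1, 0.2, 0.3),
                b1 = c(0.1, 0.2, 0.3), b2 = c(0.3, 0.2, 0.1))
  rownames(beta) <- paste0("p", 1:3)
  map <- data.frame(sample_id = colnames(beta),
                    tumor_id = c("A", "A", "B", "B"))
  res <- replicate_concordance(beta, map)
  expect_equal(res$r[res$tumor_id == "A"], 1)
  expect_equal(res$r[res$tumor_id == "B"], -1)

  # fewer than 3 shared probes -> missing
  b2 <- beta[1:2, ]
  expect_true(all(is.na(replicate_concordance(b2, map)$r)))
})

test_that("variant-probe selection excludes SD strictly below the cut", {
  k <- 18
  dev <- rep(c(-1, 1), k / 2)
  beta <- rbind(
    constant = rep(0.5, k),
    edge = 0.5 + dev * 0.2 * sqrt((k - 1) / k),   # SD exactly 0.2
    high = rep(c(0.05, 0.95), k / 2))
  colnames(beta) <- paste0("t", 1:k)
  expect_equal(sd(beta["edge", ]), 0.2)
  expect_setequal(select_variant_probes(beta, sd_cut = sd(beta["edge", ])),
                  c("edge", "high"))
})

test_that("logit transform clamps, inverts, and is strictly increasing", {
  expect_equal(logit_transform(0.5), 0)
  eps <- 1e-3
  expect_equal(logit_transform(0, eps), log(eps / (1 - eps)))
  expect_true(is.finite(logit_transform(1)))
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(inv_logit(logit_transform(b)), b, tolerance = 1e-12)
  expect_true(all(diff(logit_transform(b)) > 0))
  expect_error(logit_transform(1.2), "\\[0, 1\\]")
})

test_that("full QC chain reproduces designed stage counts", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  qc <- preprocess_qc(ds$intensities, ds$manifest)
  expect_equal(qc$provenance$probe_stages$removed, c(20, 5, 15))
  expect_equal(qc$provenance$probes_retained, 300 - 40)
  expect_equal(qc$provenance$samples_removed_qc, 2)
  expect_equal(qc$provenance$tumors_out, 120 - 2)
  expect_true(all(qc$beta >= 0 & qc$beta <= 1))
  expect_gt(median(qc$concordance$r), 0.9)
})
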