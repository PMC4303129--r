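# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Wilcoxon p by enumerating all C(n, nx) group splits of the
# pooled sample (tie-free inputs only).
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  ws <- apply(splits, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Hypergeometric upper-tail by direct summation.
hyper_tail_oracle <- function(overlap, term_size, bg_size, list_size) {
  xs <- overlap:min(term_size, list_size)
  sum(choose(term_size, xs) * choose(bg_size - term_size, list_size - xs)) /
    choose(bg_size, list_size)
}

# Pearson chi-square for a 2x2 table by the closed form
# n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
chisq_2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Mean within-cluster consensus by explicit pair enumeration.
pair_mean_oracle <- function(cm, assignment) {
  out <- c()
  for (cl in sort(unique(assignment))) {
    idx <- which(assignment == cl)
    if (length(idx) < 2) { out <- c(out, 1); next }
    vals <- c()
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (i < j) vals <- c(vals, cm[idx[i], idx[j]])
      }
    }
    out <- c(out, mean(vals))
  }
  out
}

# Consensus matrix by direct tally over logged per-iteration assignments.
consensus_tally_oracle <- function(assignments, n) {
  co_cl <- matrix(0, n, n)
  co_s <- matrix(0, n, n)
  for (a in assignments) {
    for (i in a$sub) {
      for (j in a$sub) {
        co_s[i, j] <- co_s[i, j] + 1
        li <- a$labels[match(i, a$sub)]
        lj <- a$labels[match(j, a$sub)]
        if (li == lj) co_cl[i, j] <- co_cl[i, j] + 1
      }
    }
  }
  cm <- ifelse(co_s > 0, co_cl / pmax(co_s, 1), 0)
  diag(cm) <- 1
  cm
}

# Breslow partial log-likelihood for a single covariate (tie-free data);
# equals Efron's when no event times are tied.
cox_loglik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-group log-rank chi-square from the observed-minus-expected event table.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

write_toy_gmt <- function(path, sets) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

small_cfg <- function(n_tumors = 120, n_probes = 300, n_variant_probes = 60,
                      qc_fail_counts = c(snp_flagged = 20, detect_fail = 5,
                                         low_sd = 15),
                      n_replicated_tumors = 8, n_fail_samples = 2,
                      seed = 7, ...) {
  sim_config(n_tumors = n_tumors, n_probes = n_probes,
             n_variant_probes = n_variant_probes,
             qc_fail_counts = qc_fail_counts,
             n_replicated_tumors = n_replicated_tumors,
             n_fail_samples = n_fail_samples, seed = seed, ...)
}
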