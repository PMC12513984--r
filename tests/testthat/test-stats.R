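test_that("wilcoxon signed-rank: exact small-sample behavior", {
  # identical pairs: degenerate, p = 1
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1.0)
  # n = 6, all positive differences: p = 2 / 2^6
  res6 <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(res6$p_value, 0.03125)
  expect_equal(res6$method, "exact-enumeration")

  set.seed(10)
  for (case in 1:12) {
    n <- sample(6:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- wilcoxon_signed_rank(a, b)
    expect_equal(mine$p_value, wilcoxon_oracle_p(a, b), tolerance = 1e-12)
    # symmetry under swapping the samples
    expect_equal(mine$p_value, wilcoxon_signed_rank(b, a)$p_value)
    # tie-free data: agree with the reference exact implementation
    expect_equal(mine$p_value, wilcox.test(a, b, paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon falls back to a corrected normal approximation for large n", {
  set.seed(11)
  a <- rnorm(23); b <- rnorm(23) + 0.8
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$method, "normal-approximation")
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("ICC(2,1) matches its mean-squares definition and invariances", {
  # identical columns: perfect agreement
  m <- matrix(rnorm(10), 10, 3)
  expect_equal(icc2(cbind(m[, 1], m[, 1], m[, 1]))$icc, 1.0)

  set.seed(12)
  for (case in 1:10) {
    v <- matrix(rnorm(15), 5, 3) + rnorm(5)
    res <- icc2(v)
    expect_equal(res$icc, icc2_oracle(v), tolerance = 1e-10)
    expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
    expect_lte(res$icc, 1)
    # invariant to shift and positive scaling
    expect_equal(icc2(v + 100)$icc, res$icc, tolerance = 1e-9)
    expect_equal(icc2(v * 3.7)$icc, res$icc, tolerance = 1e-9)
  }

  # zero subject variance: ICC near zero
  set.seed(13)
  noise_only <- matrix(rnorm(300), 100, 3)
  expect_lt(abs(icc2(noise_only)$icc), 0.1)
  expect_error(icc2(matrix(1, 5, 3)), "zero total variance")
})

test_that("repeated-measures ANOVA matches a from-scratch decomposition", {
  # 4 subjects x 3 conditions toy table
  v <- matrix(c(10, 12, 11, 13,
                14, 15, 13, 16,
                12, 13, 12, 14), 4, 3)
  colnames(v) <- c("a", "b", "c")
  n <- 4; k <- 3
  g <- mean(v)
  ss_subj <- k * sum((rowMeans(v) - g)^2)
  ss_cond <- n * sum((colMeans(v) - g)^2)
  ss_err <- sum((v - g)^2) - ss_subj - ss_cond
  f_hand <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  fit <- repeated_measures_comparison(v)
  expect_equal(fit$effects$statistic, f_hand, tolerance = 1e-10)
  expect_equal(fit$effects$df1, k - 1)
  expect_equal(fit$effects$df2, (n - 1) * (k - 1))
  expect_error(repeated_measures_comparison(cbind(v, NA)), "complete")
})

test_that("null and planted-effect configurations behave as expected", {
  # subject offsets + pure noise: condition factor not significant
  set.seed(14)
  v <- matrix(rnorm(23 * 5, sd = 1), 23, 5) + rnorm(23, sd = 10)
  colnames(v) <- paste0("s", 1:5)
  fit <- repeated_measures_comparison(v)
  expect_gt(fit$effects$p_value, 0.05)
  # subject stratum absorbs the between-subject spread: condition error MS << subject MS
  expect_lt(fit$error_terms[[1]]$ms, 5)

  # one condition shifted by +10: significant in nearly all seeded replicates
  hits <- sapply(1:100, function(i) {
    set.seed(1000 + i)
    m <- matrix(rnorm(23 * 5, sd = 3), 23, 5) + rnorm(23, sd = 5)
    m[, 3] <- m[, 3] + 10
    colnames(m) <- paste0("s", 1:5)
    repeated_measures_comparison(m)$effects$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("two-factor within-subject model reports both factors", {
  set.seed(15)
  conds <- expand.grid(device = c("ss", "v1", "v4"), slab = c("auto", "mid"),
                       stringsAsFactors = FALSE)
  v <- matrix(rnorm(12 * 6, sd = 1), 12, 6) + rnorm(12, sd = 4)
  v[, conds$device == "v1"] <- v[, conds$device == "v1"] + 8
  colnames(v) <- paste(conds$device, conds$slab, sep = ".")
  fit <- repeated_measures_comparison(v, factors = conds)
  eff <- fit$effects
  expect_true(all(c("device", "slab") %in% eff$effect))
  expect_lt(eff$p_value[eff$effect == "device"], 0.001)
  expect_gt(eff$p_value[eff$effect == "slab"], 0.05)
})

test_that("tukey post-hoc uses the studentized range correctly", {
  # tail probabilities agree with direct numerical integration
  for (case in list(c(q = 3, k = 3, df = 10), c(q = 4.2, k = 5, df = 20))) {
    expect_equal(ptukey(case["q"], case["k"], case["df"], lower.tail = FALSE),
                 ptukey_oracle(case["q"], case["k"], case["df"]),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }

  # zero noise, equal means: nothing flagged
  v0 <- matrix(rep(c(3, 7, 5, 6), 3), 4, 3)
  colnames(v0) <- c("a", "b", "c")
  th0 <- tukey_posthoc(v0)
  expect_false(any(th0$significant))

  # one clearly shifted group: exactly its two pairs flagged
  set.seed(16)
  v <- matrix(rnorm(30, sd = 0.5), 10, 3) + rnorm(10, sd = 1)
  v[, 2] <- v[, 2] + 15
  colnames(v) <- c("a", "b", "c")
  th <- tukey_posthoc(v)
  flagged <- th[th$significant, ]
  expect_equal(nrow(flagged), 2)
  expect_true(all(apply(flagged, 1, function(r) "b" %in% r[c("condition_a", "condition_b")])))
  expect_error(tukey_posthoc(v[, 1:2]), "fewer than 3")
})

test_that("comparison tables summarize a cohort and flag planted device effects", {
  set.seed(17)
  eyes <- 1:12; slabs <- c("auto", "11-21", "21-31", "31-41", "16-31")
  df <- expand.grid(eye_id = eyes, device = c("SS", "SD_V1", "SD_V4"),
                    slab = slabs, stringsAsFactors = FALSE)
  base <- rnorm(length(eyes), 45, 5)[df$eye_id]
  df$fd_percent <- base + rnorm(nrow(df), sd = 2) + ifelse(df$device == "SD_V1", 10, 0)
  df$fd_count <- round(df$fd_percent * 30)
  df$mean_fd_size_um2 <- 9e6 * df$fd_percent / 100 / df$fd_count * 1e0
  df$total_fd_area_mm2 <- df$fd_percent / 100 * 9

  tabs <- build_comparison_tables(df)
  t1 <- tabs$table1
  expect_true(all(grepl("^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$", t1$SS)))
  fd_rows <- t1[t1$metric == "fd_percent", ]
  expect_true(all(fd_rows$p_SS_vs_SD_V1 < 0.05))
  expect_true(all(fd_rows$p_SS_vs_SD_V4 > 0.05))
  expect_equal(nrow(t1), 4 * length(slabs))
  # table 2: symmetric slab p-value matrix per device
  expect_equal(dim(tabs$table2_matrices$SS), c(5, 5))
  expect_equal(tabs$table2_matrices$SS["auto", "21-31"],
               tabs$table2_matrices$SS["21-31", "auto"])
  # icc table covers all device x metric combinations
  expect_equal(nrow(tabs$icc), 12)
  expect_true(all(tabs$icc$icc <= 1))

  df_inc <- df[-5, ]
  expect_error(build_comparison_tables(df_inc), "missing cells")
})
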