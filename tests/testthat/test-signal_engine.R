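# frozen oracle values for table (10, 20, 5, 40), each verified by direct
# closed-form computation (see the expressions in-line)
ORACLE_T <- fourfold(10, 20, 5, 40)

test_that("ROR point estimate and Wald interval match the closed form", {
  r <- ror_statistic(ORACLE_T)
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 5 + 1 / 40)
  expect_equal(r$ror, 4)
  expect_equal(r$lower, exp(log(4) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$upper, exp(log(4) + 1.96 * se), tolerance = 1e-12)
  expect_equal(round(r$lower, 3), 1.204)
  expect_equal(round(r$upper, 3), 13.284)
})

test_that("PRR and its chi-squared match hand-computed margins", {
  p <- prr_statistic(ORACLE_T, continuity_correction = FALSE)
  expect_equal(p$prr, 3)
  expect_equal(p$chi2, 5.5556, tolerance = 1e-4)
  py <- prr_statistic(ORACLE_T, continuity_correction = TRUE)
  expect_equal(py$chi2, 4.2535, tolerance = 1e-4)
})

test_that("chi-squared agrees with stats::chisq.test on random tables", {
  set.seed(11)
  for (i in 1:25) {
    m <- matrix(sample(1:80, 4, replace = TRUE), 2)
    t <- fourfold(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    for (cc in c(TRUE, FALSE)) {
      ref <- suppressWarnings(stats::chisq.test(m, correct = cc))
      expect_equal(prr_statistic(t, cc)$chi2, unname(ref$statistic),
                   tolerance = 1e-10)
    }
  }
})

test_that("information component and EBGM match the closed form", {
  b <- bcpnn_statistic(ORACLE_T)
  expect_equal(b$ic, log2(10 * 75 / (30 * 15)), tolerance = 1e-12)
  expect_equal(round(b$ic, 4), 0.737)
  m <- mgps_statistic(ORACLE_T)
  expect_equal(m$ebgm, 10 * 75 / (30 * 15), tolerance = 1e-12)
  expect_equal(round(m$ebgm, 4), 1.6667)
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 5 + 1 / 40)
  expect_equal(m$ebgm05, exp(log(m$ebgm) - 1.64 * se), tolerance = 1e-12)
  expect_equal(round(m$ebgm05, 4), 0.6105)
})

test_that("independence tables give ROR = PRR = EBGM = 1, IC = 0, chi2 = 0", {
  for (k in c(1, 7, 100)) {
    t <- fourfold(k, k, k, k)
    expect_equal(ror_statistic(t)$ror, 1)
    expect_equal(prr_statistic(t, FALSE)$prr, 1)
    expect_equal(prr_statistic(t, FALSE)$chi2, 0)
    expect_equal(bcpnn_statistic(t)$ic, 0)
    expect_equal(mgps_statistic(t)$ebgm, 1)
  }
  # any table with ad = bc behaves the same
  t <- fourfold(6, 3, 10, 5)
  expect_equal(ror_statistic(t)$ror, 1)
  expect_equal(prr_statistic(t, FALSE)$prr, 1)
  expect_equal(bcpnn_statistic(t)$ic, 0)
  expect_equal(mgps_statistic(t)$ebgm, 1)
})

test_that("zero cells leave statistics undefined rather than corrected", {
  r <- ror_statistic(fourfold(0, 5, 5, 5))
  expect_false(r$defined)
  expect_true(is.na(r$ror))
  # optional correction path
  rc <- ror_statistic(fourfold(0, 5, 5, 5), correction = TRUE)
  expect_true(rc$defined)
  # degenerate but computable PRR margin: d = 0 is allowed
  p <- prr_statistic(fourfold(3, 0, 1, 0))
  expect_equal(p$prr, 1)
  # c = 0 undefined
  expect_false(prr_statistic(fourfold(3, 1, 0, 5))$defined)
  expect_false(mgps_statistic(fourfold(3, 0, 1, 2))$defined)
  expect_equal(bcpnn_statistic(fourfold(0, 5, 5, 5))$ic, -Inf)
})

test_that("with fixed margins the statistics increase strictly in a", {
  # margins: a+b = 30, a+c = 15, N = 75
  vals <- lapply(5:14, function(a) {
    t <- fourfold(a, 30 - a, 15 - a, 75 - 30 - (15 - a))
    c(ror = ror_statistic(t)$ror, prr = prr_statistic(t)$prr,
      ic = bcpnn_statistic(t)$ic, ebgm = mgps_statistic(t)$ebgm)
  })
  m <- do.call(rbind, vals)
  for (col in colnames(m)) expect_true(all(diff(m[, col]) > 0), label = col)
})

test_that("shrinkage ordering and the IC-EBGM identity hold on random tables", {
  set.seed(21)
  for (i in 1:50) {
    t <- fourfold(sample(1:50, 1), sample(1:500, 1), sample(1:200, 1),
                  sample(100:5000, 1))
    b <- bcpnn_statistic(t); m <- mgps_statistic(t)
    expect_equal(b$ic, log2(m$ebgm), tolerance = 1e-12)
    r <- ror_statistic(t)$ror
    if (r > 1) {
      p <- prr_statistic(t)$prr
      expect_true(m$ebgm <= p + 1e-12 && p <= r + 1e-12)
    }
  }
})

test_that("printed-style consistency: IC = log2(EBGM) and EBGM <= PRR", {
  # point estimates published for sevoflurane-class pediatric signals follow
  # the same estimator identities the implementation guarantees
  published <- data.frame(
    ebgm = c(14.81, 6.33, 113.9, 244.38, 3.2, 64.12),
    ic   = c(3.89, 2.66, 6.83, 7.93, 1.68, 6.00),
    prr  = c(14.98, 6.36, 125.06, 302.58, 3.2, 67.49),
    ror  = c(15.39, 6.47, 126.62, 310.04, 3.23, 67.88))
  expect_true(all(abs(log2(published$ebgm) - published$ic) < 0.01))
  expect_true(all(published$ebgm <= published$prr))
  expect_true(all(published$prr <= published$ror))
})

test_that("Bate E(IC) converges to log2(RRR) in the large-N limit", {
  # fixed cell fractions, N = 1e6
  N <- 1e6
  t <- fourfold(round(N * 0.004), round(N * 0.016), round(N * 0.046),
                round(N * 0.934))
  b <- bcpnn_statistic(t)
  expect_equal(b$e_ic, b$ic, tolerance = 1e-3)
  expect_lt(b$v_ic, 1e-3)
})

test_that("ln-ROR Wald interval attains nominal coverage on simulated tables", {
  set.seed(1007)
  or_true <- 3; p0 <- 0.05
  p1 <- or_true * p0 / (1 - p0 + or_true * p0)
  n_e <- 500; n_u <- 5000; B <- 2000
  a <- stats::rbinom(B, n_e, p1); c <- stats::rbinom(B, n_u, p0)
  covered <- vapply(seq_len(B), function(i) {
    if (a[i] == 0 || c[i] == 0 || a[i] == n_e || c[i] == n_u) return(NA)
    r <- ror_statistic(fourfold(a[i], n_e - a[i], c[i], n_u - c[i]))
    r$lower <= or_true && r$upper >= or_true
  }, logical(1))
  cov <- mean(covered, na.rm = TRUE)
  expect_gte(cov, 0.93)
  expect_lte(cov, 0.97)
})

test_that("build_contingency counts report-PT pairs at PT and SOC level", {
  cohort <- data.table::data.table(primaryid = c("r1", "r1", "r2"),
                                   pt = c("X", "Y", "X"))
  background <- rbind(cohort,
                      data.table::data.table(primaryid = c("r3", "r3"),
                                             pt = c("X", "Z")))
  t <- build_contingency("X", "PT", cohort, background)
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 1, 1))
  # absent term
  t0 <- build_contingency("Q", "PT", cohort, background)
  expect_equal(c(t0$a, t0$b), c(0, 3))
  # SOC level: X and Y share a SOC
  mp <- data.table::data.table(pt = c("X", "Y", "Z"),
                               soc = c("SOC1", "SOC1", "SOC2"))
  ts <- build_contingency("SOC1", "SOC", cohort, background, mp)
  expect_equal(c(ts$a, ts$b, ts$c, ts$d), c(3, 0, 1, 1))
  expect_error(build_contingency("SOC1", "SOC", cohort, background,
                                 mp[pt != "Y"]), "Y")
})

test_that("the four-way gate needs every flag plus the minimum count", {
  crit <- signal_criteria()
  # strong association, ample count
  cohort <- data.table::data.table(
    primaryid = c(sprintf("e%d", 1:60), sprintf("f%d", 1:100)),
    pt = c(rep("Target PT", 60), rep("Other PT", 100)))
  bg <- rbind(cohort, data.table::data.table(
    primaryid = sprintf("b%d", 1:2000),
    pt = rep(c("Target PT", "Other PT"), c(100, 1900))))
  mp <- data.table::data.table(pt = c("Target PT", "Other PT"),
                               soc = c("SOC A", "SOC B"))
  res <- evaluate_signals(cohort, bg, mp, crit)
  row <- res[term == "Target PT"]
  expect_true(row$flag_ror && row$flag_prr && row$flag_bcpnn && row$flag_mgps)
  expect_true(row$overall_signal)
  # a = 2 below min_a: never a signal no matter how large the ratios
  cohort2 <- data.table::data.table(primaryid = c("e1", "e2", "e3"),
                                    pt = c("Rare PT", "Rare PT", "Other PT"))
  bg2 <- rbind(cohort2, data.table::data.table(
    primaryid = sprintf("b%d", 1:3000),
    pt = rep(c("Rare PT", "Other PT"), c(1, 2999))))
  mp2 <- data.table::data.table(pt = c("Rare PT", "Other PT"),
                                soc = c("SOC A", "SOC B"))
  res2 <- evaluate_signals(cohort2, bg2, mp2, crit)
  row2 <- res2[term == "Rare PT"]
  expect_equal(row2$a, 2L)
  expect_false(row2$overall_signal)
})

test_that("unmapped PTs fall under the sentinel SOC with a warning", {
  cohort <- data.table::data.table(primaryid = c("r1", "r2"),
                                   pt = c("Known PT", "Mystery PT"))
  bg <- rbind(cohort, data.table::data.table(primaryid = "r3",
                                             pt = "Known PT"))
  mp <- data.table::data.table(pt = "Known PT", soc = "SOC A")
  expect_warning(res <- evaluate_signals(cohort, bg, mp), "Unmapped")
  expect_true("Unmapped" %in% res[level == "SOC"]$term)
  expect_equal(attr(res, "unmapped_pts"), "Mystery PT")
})

test_that("SOC-level margin equals the cohort pair count", {
  b <- tiny_bundle()
  coh <- build_cohort(b, c("SEVOFLURANE", "ULTANE"), stratum = "pediatric")
  bg <- stratum_pairs(b, "pediatric")
  res <- evaluate_signals(coh, bg, tiny_mapping())
  expect_true(all(res$a + res$b == coh$n_report_pt_pairs))
  expect_true(all(res$a + res$b + res$c + res$d == nrow(bg)))
})
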