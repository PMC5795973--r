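test_that("effect contrasts implement the first-named-class convention", {
  ctr <- effect_contrasts()
  cells <- treatment_cells()
  for (w in ctr) expect_equal(sum(w), 0)
  expect_equal(unname(ctr$breed[cells$breed == "Iberian"]), rep(1 / 4, 4))
  expect_equal(unname(ctr$breed[cells$breed == "Duroc"]), rep(-1 / 4, 4))
  expect_equal(unname(ctr$status[cells$status == "fed"]), rep(1 / 4, 4))
  expect_equal(unname(ctr$diet[cells$diet == "HO"]), rep(1 / 4, 4))
  # interactions are differences of differences
  bs <- ctr$`breed:status`
  expect_equal(sum(bs[cells$breed == "Iberian" & cells$status == "fed"]), 0.5)
  expect_equal(sum(bs[cells$breed == "Iberian" & cells$status == "fasting"]), -0.5)
})

test_that("fold-change back-transform has the documented geometry", {
  # diff = 0: unit fold change, interval symmetric on the log scale
  d0 <- to_fold_change(data.frame(diff = 0, se = 0.3, df = 20))
  expect_equal(d0$fc, 1)
  expect_equal(d0$ci_low * d0$ci_high, 1, tolerance = 1e-12)
  # quantile-oracle case: diff = -1, se = 0.5, df = 10
  d1 <- to_fold_change(data.frame(diff = -1, se = 0.5, df = 10))
  tq <- qt(0.975, 10)
  expect_equal(d1$fc, 2)
  expect_equal(d1$ci_low, 2^(1 - tq * 0.5), tolerance = 1e-12)
  expect_equal(d1$ci_high, 2^(1 + tq * 0.5), tolerance = 1e-12)
  # consistency properties on random rows
  set.seed(31)
  d <- data.frame(diff = rnorm(50), se = runif(50, 0.05, 1),
                  df = runif(50, 3, 130))
  fc <- to_fold_change(d)
  expect_equal(sqrt(fc$ci_low * fc$ci_high), fc$fc, tolerance = 1e-9)
  expect_equal(log2(fc$ci_high / fc$ci_low),
               2 * qt(0.975, d$df) * d$se, tolerance = 1e-9)
  expect_true(all((fc$fc > 1) == (d$diff < 0)))
  expect_error(to_fold_change(data.frame(diff = 0, se = 0, df = 5)), "positive")
})

test_that("effective number of tests follows the eigenvalue-dispersion formula", {
  expect_equal(effective_tests(diag(13)), 13)
  ones <- matrix(1, 6, 6)
  expect_equal(effective_tests(ones), 1)
  # 2x2 closed form: eigenvalues 1 +/- r
  r <- 0.5
  m2 <- matrix(c(1, r, r, 1), 2)
  expect_equal(effective_tests(m2), 1 + (2 - 1) * (1 - var(c(1.5, 0.5)) / 2))
  expect_equal(effective_tests(m2), 1.75)
  bad <- diag(3); bad[1, 2] <- 0.5
  expect_error(effective_tests(bad), "symmetric")
  bad2 <- diag(3); bad2[1, 1] <- 2
  expect_error(effective_tests(bad2), "unit diagonal")
})

test_that("BH with an effective test count adjusts as specified", {
  expect_equal(adjust_pvalues(0.2, 1), 0.2)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), 3), rep(0.03, 3))
  expect_error(adjust_pvalues(c(0.5, 1.2), 2), "0, 1")
  expect_error(adjust_pvalues(0.5, 0.5), "at least 1")
  set.seed(13)
  for (i in 1:10) {
    p <- runif(15)
    m_eff <- runif(1, 1, 15)
    q <- adjust_pvalues(p, m_eff)
    expect_true(all(q >= p))                      # never undercuts nominal
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in rank
    bonf <- pmin(pmax(p * m_eff, p), 1)
    expect_true(all(bonf >= q - 1e-12))           # sandwich
  }
})

test_that("the normalised correlation matrix behaves on co-regulated and independent genes", {
  set.seed(17)
  n <- 96
  shared <- rnorm(n)
  load <- rnorm(n, sd = 0.5)   # sample loading, removed by the references
  y <- rbind(T1 = shared + load + rnorm(n, sd = 0.05),
             T2 = shared + load + rnorm(n, sd = 0.05),
             T3 = rnorm(n) + load,
             T4 = rnorm(n) + load,
             REF = load + rnorm(n, sd = 0.02))
  tr <- data.frame(gene = rep(rownames(y), n),
                   animal = rep(paste0("A", 1:n), each = 5),
                   status = "fed", y = as.vector(y))
  corr <- correlation_matrix(tr, targets = c("T1", "T2", "T3", "T4"),
                             references = "REF")
  expect_equal(corr, t(corr))
  expect_equal(unname(diag(corr)), rep(1, 4))
  expect_gt(corr["T1", "T2"], 0.98)
  expect_lt(abs(corr["T3", "T4"]), 0.3)
  # constant gene: zeroed with a warning
  tr0 <- tr; tr0$y[tr0$gene == "T3"] <- 5
  expect_warning(c0 <- correlation_matrix(tr0, c("T1", "T3"), "REF"), "constant")
  expect_equal(c0["T1", "T3"], 0)
  expect_error(correlation_matrix(tr[tr$animal %in% c("A1", "A2"), ],
                                  c("T1", "T2"), "REF"), "3 samples")
})

test_that("run_all_contrasts validates its inputs", {
  sim <- small_qpcr_sim(seed = 23)
  tr <- transform_wells(sim$wells, sim$efficiencies)
  fit <- fit_expression_model(tr)
  expect_error(run_all_contrasts(fit, "SCD", character(0), normalize = TRUE),
               "empty")
  expect_error(run_all_contrasts(fit, c("SCD", "ACTB"), "ACTB"), "disjoint")
  expect_error(run_all_contrasts(fit, "NOPE", "ACTB"), "NOPE")
  res <- run_all_contrasts(fit, c("SCD", "LEP"), c("ACTB", "PPIA"))
  expect_equal(nrow(res), 12)
  expect_setequal(unique(res$effect), names(effect_contrasts()))
})

test_that("normalising against flat references leaves target effects unchanged", {
  # references simulated with identical cell means in every cell (the
  # default), so normalised and unnormalised breed/status diffs must
  # agree up to Monte-Carlo error
  diffs <- vapply(1:5, function(s) {
    sim <- small_qpcr_sim(seed = 300 + s,
                          effects = list(list(gene = "SCD", effect = "status",
                                              diff = -0.8)))
    tr <- transform_wells(sim$wells, sim$efficiencies)
    fit <- fit_expression_model(tr)
    on_ <- run_all_contrasts(fit, "SCD", c("ACTB", "PPIA"), normalize = TRUE)
    off <- run_all_contrasts(fit, "SCD", normalize = FALSE)
    on_$diff[on_$effect == "status"] - off$diff[off$effect == "status"]
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.15)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("the full analysis recovers an injected status effect", {
  sim <- small_qpcr_sim(seed = 77,
                        animals = small_animals(10, 10),
                        effects = list(list(gene = "SCD", effect = "status",
                                            diff = -log2(1.5))))
  out <- qpcr_analysis(sim$wells, sim$efficiencies, targets = c("SCD", "LEP"))
  row <- out$results[out$results$gene == "SCD" & out$results$effect == "status", ]
  expect_gt(row$fc, 1.3); expect_lt(row$fc, 1.75)
  expect_lt(row$p_nominal, 0.01)
  expect_true(all(out$results$p_adjusted >= out$results$p_nominal - 1e-12))
  expect_true(out$m_eff >= 1 && out$m_eff <= 2)
})
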