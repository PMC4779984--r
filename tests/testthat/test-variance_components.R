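test_that("balanced 4x4x3 design gives the classical EMS coefficients", {
  ds <- simulate_stratum(simulation_spec(24, 0.45, 0.73, 0.32, seed = 1))
  an <- nested_anova(ds)
  expect_equal(unname(an$coefficients), c(3, 3, 12))
  expect_equal(an$table$df, c(3L, 12L, 32L))
})

test_that("unbalanced EMS coefficients match hand-evaluated values", {
  # 2 extractions with (2, 3) RTs, every RT with 2 qPCRs:
  # N = 10, n_i. = (4, 6), sum_j n_ij^2 / n_i. = 8/4 + 12/6 = 4
  # c1 = (10 - 4)/(5 - 2) = 2; c2 = (4 - 20/10)/1 = 2; c3 = 10 - 52/10 = 4.8
  rna <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  rt <- c(1, 1, 2, 2, 1, 1, 2, 2, 3, 3)
  qp <- rep(1:2, 5)
  ds <- make_stratum(rna, rt, qp, cq = 20 + (1:10) / 3)
  an <- nested_anova(ds)
  expect_equal(unname(an$coefficients), c(2, 2, 4.8))
  expect_equal(an$table$df, c(1L, 3L, 5L))
  orc <- oracle_components(ds)
  expect_equal(unname(an$coefficients), c(orc$c1, orc$c2, orc$c3))
})

test_that("constant Cq gives zero sums of squares and zero components", {
  ds <- make_balanced_stratum(rep(23.5, 24), 2, 4, 3)
  an <- nested_anova(ds)
  expect_equal(an$table$ss, c(0, 0, 0))
  vc <- estimate_components(ds)
  expect_equal(c(vc$var_sampling, vc$var_rt, vc$var_qpcr), c(0, 0, 0))
  expect_equal(vc$mu, 23.5)
})

test_that("estimates equal an explicit-loop method-of-moments oracle", {
  for (seed in 1:5) {
    ds <- withr::with_seed(seed, {
      rna <- c(1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
      rt <- c(1, 1, 2, 2, 2, 1, 1, 2, 1, 1, 2, 2)
      qp <- c(1, 2, 1, 2, 3, 1, 2, 1, 1, 2, 1, 2)
      make_stratum(rna, rt, qp, cq = 24 + rnorm(12, 0, 0.8))
    })
    vc <- estimate_components(ds, truncate = FALSE)
    orc <- oracle_components(ds)
    expect_equal(vc$var_sampling, orc$var_sampling)
    expect_equal(vc$var_rt, orc$var_rt)
    expect_equal(vc$var_qpcr, orc$var_qpcr)
    expect_equal(vc$mu, orc$mu)
  }
})

test_that("generic unbalanced path matches the closed-form balanced solution", {
  for (seed in 1:5) {
    ds <- simulate_stratum(simulation_spec(24, 0.5, 0.4, 0.3, seed = seed,
                                           n_sampling = 3, n_rt = 4,
                                           n_qpcr = 2))
    an <- nested_anova(ds)
    ms <- an$table$ms
    nj <- 4; nk <- 2
    closed <- c(
      qpcr = ms[3],
      rt = (ms[2] - ms[3]) / nk,
      sampling = (ms[1] - ms[2]) / (nj * nk)
    )
    vc <- estimate_components(ds, truncate = FALSE)
    expect_equal(vc$var_qpcr, closed[["qpcr"]], tolerance = 1e-10)
    expect_equal(vc$var_rt, closed[["rt"]], tolerance = 1e-10)
    expect_equal(vc$var_sampling, closed[["sampling"]], tolerance = 1e-10)
  }
})

test_that("REML agrees with method of moments on a balanced interior stratum", {
  ds <- simulate_stratum(simulation_spec(24, 0.9, 0.7, 0.4, seed = 2,
                                         n_sampling = 6, n_rt = 4, n_qpcr = 3))
  vc <- estimate_components(ds, truncate = FALSE)
  # interior case (all raw estimates positive): REML on the balanced nested
  # layout reproduces the ANOVA estimators
  expect_true(all(c(vc$var_sampling, vc$var_rt, vc$var_qpcr) > 0))
  df <- as.data.frame(ds)
  df$rt_id <- interaction(df$rna_rep, df$rt_rep)
  fit <- lme4::lmer(cq ~ 1 + (1 | rna_rep) + (1 | rt_id), data = df,
                    REML = TRUE)
  vcv <- as.data.frame(lme4::VarCorr(fit))
  reml <- setNames(vcv$vcov, vcv$grp)
  expect_equal(vc$var_sampling, unname(reml["rna_rep"]), tolerance = 1e-4)
  expect_equal(vc$var_rt, unname(reml["rt_id"]), tolerance = 1e-4)
  expect_equal(vc$var_qpcr, unname(reml["Residual"]), tolerance = 1e-4)
})

test_that("truncation fires exactly when a raw solution is negative", {
  hits <- 0
  for (seed in 1:30) {
    # tiny sampling effect relative to downstream noise produces frequent
    # negative raw sampling solutions
    ds <- simulate_stratum(simulation_spec(24, sd_sampling = 0.01,
                                           sd_rt = 0.1, sd_qpcr = 0.8,
                                           seed = seed))
    raw <- estimate_components(ds, truncate = FALSE)
    trunc <- estimate_components(ds, truncate = TRUE)
    for (lev in c("sampling", "rt", "qpcr")) {
      raw_v <- raw[[paste0("var_", lev)]]
      trunc_v <- trunc[[paste0("var_", lev)]]
      if (raw_v < 0) {
        hits <- hits + 1
        expect_equal(trunc_v, 0)
        expect_true(lev %in% trunc$truncated)
      } else {
        expect_equal(trunc_v, raw_v)
        expect_false(lev %in% trunc$truncated)
      }
    }
    expect_equal(length(raw$truncated), 0)
  }
  expect_gt(hits, 0)  # the regime must actually exercise truncation
})

test_that("missing records are handled by complete-case reanalysis", {
  ds <- simulate_stratum(simulation_spec(24, 0.5, 0.5, 0.3, seed = 9))
  df <- as.data.frame(ds)
  drop_idx <- c(2, 7, 20, 33, 41)
  marked <- df; marked$cq[drop_idx] <- NA
  absent <- df[-drop_idx, ]
  vc_marked <- estimate_components(cq_dataset(marked))
  vc_absent <- estimate_components(cq_dataset(absent))
  expect_equal(vc_marked$var_sampling, vc_absent$var_sampling)
  expect_equal(vc_marked$var_rt, vc_absent$var_rt)
  expect_equal(vc_marked$var_qpcr, vc_absent$var_qpcr)
  expect_equal(vc_marked$anova$n, 43)
})

test_that("Monte-Carlo recovery: estimates are unbiased at the pilot design", {
  truth <- c(sampling = 0.45, rt = 0.73, qpcr = 0.32)
  n_rep <- 500
  est <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    ds <- simulate_stratum(simulation_spec(
      mu = 25, sd_sampling = truth[["sampling"]], sd_rt = truth[["rt"]],
      sd_qpcr = truth[["qpcr"]], seed = 1000 + r))
    vc <- estimate_components(ds)
    est[r, ] <- c(vc$var_sampling, vc$var_rt, vc$var_qpcr)
  }
  recovered_sd <- sqrt(colMeans(est))
  expect_lt(max(abs(recovered_sd / truth - 1)), 0.10)
})

test_that("estimates converge to the simulation truth as the design grows", {
  truth_var <- c(0.45, 0.73, 0.32)^2
  rmse_at <- function(ni, nj, nk, n_rep) {
    err <- matrix(NA_real_, n_rep, 3)
    for (r in seq_len(n_rep)) {
      ds <- simulate_stratum(simulation_spec(
        25, 0.45, 0.73, 0.32, n_sampling = ni, n_rt = nj, n_qpcr = nk,
        seed = 5000 + r))
      vc <- estimate_components(ds)
      err[r, ] <- c(vc$var_sampling, vc$var_rt, vc$var_qpcr) - truth_var
    }
    sqrt(colMeans(err^2))
  }
  small <- rmse_at(4, 4, 3, 30)
  large <- rmse_at(20, 20, 10, 30)
  expect_true(all(large < small))
})

test_that("per-group estimation keeps groups, flags failures, and averages", {
  study <- simulate_pilot_study(tissues = "leaves", seed = 21)
  by_group <- estimate_by_group(study)
  expect_equal(nrow(by_group), 6)  # 2 subjects x 3 genes x 1 tissue
  expect_true(all(by_group$note == ""))

  avg <- average_components(by_group)
  expect_equal(nrow(avg), 3)
  expect_equal(avg$n_subjects, rep(2L, 3))

  # single-group dataset: estimate_by_group equals estimate_components
  one <- simulate_stratum(simulation_spec(24, 0.5, 0.5, 0.3, seed = 2))
  bg1 <- estimate_by_group(one)
  vc1 <- estimate_components(one)
  expect_equal(bg1$var_sampling, vc1$var_sampling)
  expect_equal(bg1$mu, vc1$mu)

  # a stratum with a single extraction is reported, not dropped
  degenerate <- rbind(
    as.data.frame(one),
    data.frame(subject = "P2", tissue = "tissue1", gene = "gene1",
               rna_rep = 1L, rt_rep = rep(1:2, each = 2),
               qpcr_rep = rep(1:2, 2), cq = 24 + 1:4 / 10))
  bg2 <- estimate_by_group(cq_dataset(degenerate))
  expect_equal(nrow(bg2), 2)
  bad <- bg2[bg2$subject == "P2", ]
  expect_match(bad$note, "sampling")
  expect_true(is.na(bad$var_sampling))
})

test_that("averaging SD estimates across subjects reduces estimation error", {
  truth_sd <- c(0.5, 0.5, 0.35)
  n_rep <- 60
  err_single <- numeric(0)
  err_avg <- numeric(0)
  for (r in seq_len(n_rep)) {
    ds <- simulate_stratum(simulation_spec(
      24, truth_sd[1], truth_sd[2], truth_sd[3], n_subjects = 2,
      seed = 7000 + r, subject = "plant"))
    bg <- estimate_by_group(ds)
    avg <- average_components(bg)
    err_single <- c(err_single, abs(bg$sd_sampling - truth_sd[1]),
                    abs(bg$sd_rt - truth_sd[2]))
    err_avg <- c(err_avg, abs(avg$sd_sampling - truth_sd[1]),
                 abs(avg$sd_rt - truth_sd[2]))
  }
  expect_lt(mean(err_avg), mean(err_single))
})
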