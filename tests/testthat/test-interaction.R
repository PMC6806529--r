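test_that("reference per-dose statistics use sample SD and name missing strata", {
  # hand arithmetic on two doses: values {10,12} and {5,7}
  cpps <- data.frame(
    strain_id = "REF", medium = "glycolytic",
    dose = rep(c(0, 5), each = 2), replicate = rep(1:2, 2),
    K = c(100, 102, 97, 95), r = c(0.30, 0.32, 0.30, 0.28),
    l = c(10, 12, 7, 5), auc = c(3000, 3100, 2900, 2800), rss = 1,
    growth_flag = "growth", stringsAsFactors = FALSE)
  class(cpps) <- c("cpp_table", "data.frame")
  # l at dose 5 of {5, 7} is odd biologically but exercises the arithmetic
  rs <- reference_stats(cpps)
  pd <- rs$per_dose
  expect_equal(pd$mean[pd$cpp == "L" & pd$dose == 0], 11)
  expect_equal(pd$mean[pd$cpp == "L" & pd$dose == 5], 6)
  expect_equal(pd$sd[pd$cpp == "L" & pd$dose == 0], sqrt(2))
  expect_equal(pd$sd[pd$cpp == "L" & pd$dose == 5], sqrt(2))
  # identical reference cultures make z-scores undefined
  cpps_id <- cpps
  cpps_id$l <- 10; cpps_id$K <- 100; cpps_id$r <- 0.3; cpps_id$auc <- 3000
  expect_error(reference_stats(cpps_id), "zero spread")
  # a dose stratum with < 2 reference cultures is reported by name
  expect_error(reference_stats(cpps[-1, ]), "dose 0")
})

test_that("a strain identical to the reference scores zero everywhere", {
  doses <- c(0, 2.5, 5, 7.5, 15)
  cpps <- toy_cpp_table(list(S1 = rep(10, 5)), doses = doses)
  rs <- reference_stats(cpps)
  sc <- score_interactions(cpps, rs)
  expect_equal(sc$shift_L, 0, tolerance = 1e-12)
  expect_equal(sc$int_L, 0, tolerance = 1e-12)
  expect_equal(sc$z_L, 0, tolerance = 1e-10)
  expect_identical(sc$call, "none")
})

test_that("a perfectly linear interaction series gives exact A, B, INT", {
  doses <- c(0, 2.5, 5, 7.5, 15)
  # Y = ref mean (10) + shift (2) + L_i where L_i = 0.4 * dose
  cpps <- toy_cpp_table(list(S1 = 10 + 2 + 0.4 * doses), doses = doses)
  rs <- reference_stats(cpps)
  sc <- score_interactions(cpps, rs)
  expect_equal(sc$shift_L, 2, tolerance = 1e-12)
  expect_equal(sc$a_L, 0, tolerance = 1e-12)
  expect_equal(sc$b_L, 0.4, tolerance = 1e-12)
  expect_equal(sc$int_L, 6, tolerance = 1e-12)
})

test_that("the interaction OLS matches an independent regression oracle", {
  doses <- c(0, 2.5, 5, 7.5, 15)
  set.seed(31)
  for (i in 1:20) {
    li <- c(0, rnorm(4, 0, 3))  # L_0 = 0 by construction
    sc <- phenogi:::.score_series(10 + li, rep(TRUE, 5), doses,
                                  ref_mean = rep(10, 5),
                                  yi_max = rep(1e6, 5), cpp = "L")
    or <- lm(li ~ doses)
    expect_equal(sc$A, unname(coef(or)[1]), tolerance = 1e-10)
    expect_equal(sc$B, unname(coef(or)[2]), tolerance = 1e-10)
    expect_equal(sc$INT, unname(predict(or, data.frame(doses = 15))),
                 tolerance = 1e-10)
  }
})

test_that("Y_i max follows the 2-SD carrying-capacity filter", {
  doses <- c(0, 5)
  # reference K mean 100, sd ~ just over 1; strains with K 99 (qualifies)
  # and K 80 (excluded) at dose 5
  cpps <- toy_cpp_table(list(A = c(10, 14), B = c(10, 12), C = c(10, 16)),
                        doses = doses,
                        strain_k = list(A = c(100, 99), B = c(100, 99),
                                        C = c(100, 80)))
  rs <- reference_stats(cpps)
  ymax <- compute_yi_max(cpps, rs, "glycolytic", 5)
  # brute-force oracle over the table rows
  kref <- rs$per_dose[rs$per_dose$cpp == "K" & rs$per_dose$dose == 5, ]
  rows <- cpps[cpps$dose == 5 & cpps$growth_flag == "growth" &
                 cpps$K >= kref$mean - 2 * kref$sd, ]
  expect_equal(ymax, max(rows$l))
  # C's outlying L = 16 is excluded because its K fails the filter
  expect_lt(ymax, 16)
  expect_equal(ymax, 14)
  # fallback when no culture qualifies: reference mean + 2 SD
  empty <- cpps[cpps$strain_id == "REF", ]
  class(empty) <- c("cpp_table", "data.frame")
  lref <- rs$per_dose[rs$per_dose$cpp == "L" & rs$per_dose$dose == 5, ]
  shrunk <- empty
  shrunk$K[shrunk$dose == 5] <- 0
  shrunk$growth_flag[shrunk$dose == 5] <- "no_growth"
  expect_equal(compute_yi_max(shrunk, rs, "glycolytic", 5),
               lref$mean + 2 * lref$sd)
})

test_that("no-growth imputation assigns Y_i max to L and zero to K", {
  doses <- c(0, 2.5, 5, 7.5, 15)
  strains <- list(DEAD15 = c(10, 10, 10, 10, NA), HEALTHY = 10 + 0.2 * doses)
  growth <- list(DEAD15 = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                 HEALTHY = rep(TRUE, 5))
  cpps <- toy_cpp_table(strains, doses = doses, growth = growth)
  rs <- reference_stats(cpps)
  ymax15 <- compute_yi_max(cpps, rs, "glycolytic", 15)
  sc <- score_interactions(cpps, rs)
  dead <- sc[sc$strain_id == "DEAD15", ]
  # the imputed L at dose 15 is Y_i max; earlier doses are unchanged, so
  # the regression sees L_i = 0,0,0,0,(ymax - 10)
  li <- c(0, 0, 0, 0, ymax15 - 10)
  or <- lm(li ~ doses)
  expect_equal(dead$int_L, unname(predict(or, data.frame(doses = 15))),
               tolerance = 1e-10)
  # K is imputed as 0 at the dead dose: K_i = -ref_K there
  expect_lt(dead$int_K, 0)
  expect_false(dead$no_growth_d0)
})

test_that("no growth at dose 0 yields no z-score and the sentinel flag", {
  doses <- c(0, 2.5, 5, 7.5, 15)
  growth <- list(PETITE = c(FALSE, rep(TRUE, 4)))
  cpps <- toy_cpp_table(list(PETITE = c(NA, 10, 10, 10, 10)), doses = doses,
                        growth = growth)
  rs <- reference_stats(cpps)
  sc <- score_interactions(cpps, rs)
  pet <- sc[sc$strain_id == "PETITE", ]
  expect_true(pet$no_growth_d0)
  expect_true(is.na(pet$z_L) && is.na(pet$z_K))
  expect_true(is.na(pet$call))
})

test_that("enhancer/suppressor calls follow the threshold rules", {
  expect_identical(classify_interaction(2.5, 0), "enhancer")
  expect_identical(classify_interaction(-3.1, 0), "suppressor")
  expect_identical(classify_interaction(1.0, -1.0), "none")
  expect_identical(classify_interaction(0, -2.2), "enhancer")
  expect_identical(classify_interaction(0, 2.2), "suppressor")
  expect_identical(classify_interaction(2.5, 2.5), "conflict")
  # the threshold magnitude is configurable
  expect_identical(classify_interaction(1.5, 0, threshold = 1), "enhancer")
  expect_identical(classify_interaction(1.5, 0, threshold = 3), "none")
  expect_error(classify_interaction(1, 1, threshold = 0), "> 0")
})

test_that("Warburg classes compare calls across media", {
  sc <- data.frame(
    strain_id = rep(c("A", "B", "C", "D", "E"), 2),
    medium = rep(c("respiratory", "glycolytic"), each = 5),
    call = c("enhancer", "enhancer", "none", "enhancer", "suppressor",
             "enhancer", "none", "enhancer", "suppressor", "none"),
    stringsAsFactors = FALSE)
  wb <- classify_warburg(sc)
  expect_identical(wb$warburg[wb$strain_id == "A"], "NS-Enh")
  expect_identical(wb$warburg[wb$strain_id == "B"], "R-Enh")
  expect_identical(wb$warburg[wb$strain_id == "C"], "G-Enh")
  expect_identical(wb$warburg[wb$strain_id == "D"], "conflict")
  expect_identical(wb$warburg[wb$strain_id == "E"], "R-Sup")
})

test_that("z_L increases strictly with the planted interaction slope", {
  doses <- c(0, 2.5, 5, 7.5, 15)
  slopes <- c(0.05, 0.1, 0.2, 0.4)
  strains <- lapply(slopes, function(b) 10 + b * doses)
  names(strains) <- paste0("S", seq_along(slopes))
  cpps <- toy_cpp_table(strains, doses = doses)
  rs <- reference_stats(cpps)
  sc <- score_interactions(cpps, rs)
  z <- sc$z_L[match(names(strains), sc$strain_id)]
  expect_true(all(diff(z) > 0))
})

test_that("reference interactions are null and their z-scores standard", {
  run <- shared_run()
  ri <- run$refstats$ref_int
  # mean(REF_INT) approximately zero relative to its SD, for every CPP
  expect_true(all(abs(ri$mean) < 0.1 * ri$sd))
  # re-scoring the reference series as pseudo-strains against the same
  # reference statistics gives z-scores with mean ~ 0 and sample SD ~ 1
  cpps <- run$cpps
  ref <- cpps[cpps$strain_id == "REF", ]
  ref$strain_id <- sprintf("PSEUDO%03d", ref$replicate)
  ref$replicate <- 1
  both <- rbind(ref, cpps[cpps$strain_id == "REF", ])
  class(both) <- c("cpp_table", "data.frame")
  sc <- score_interactions(both, run$refstats)
  for (m in unique(sc$medium)) {
    z <- sc$z_L[sc$medium == m & is.finite(sc$z_L)]
    expect_equal(mean(z), 0, tolerance = 0.15)
    expect_equal(sd(z), 1, tolerance = 0.1)
  }
})

test_that("planted sign conventions propagate to the z-scores", {
  run <- shared_run()
  m <- merge(run$scores, run$bundle$truth$strains,
             by = c("strain_id", "medium"))
  enh <- m[m$effect_l_dmax > 0 & !m$no_growth, ]
  sup <- m[m$effect_l_dmax < 0 & !m$no_growth, ]
  # slower-with-dose strains: positive L z and negative K z (median over
  # planted strains; individual strains keep the sign for calls)
  expect_gt(median(enh$z_L), 2)
  expect_lt(median(enh$z_K), -2)
  expect_lt(median(sup$z_L), -2)
  expect_gt(median(sup$z_K), 2)
})

test_that("retest runs correlate with the original far above a shuffled null", {
  run <- shared_run()
  cfg <- run$config
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1000L
  retest <- simulate_phenomics(cfg2, truth = run$bundle$truth$strains)
  cpps2 <- fit_cpps(retest$timeseries)
  rs2 <- reference_stats(cpps2)
  sc2 <- score_interactions(cpps2, rs2)
  rep_cor <- compare_runs(run$scores, sc2)
  # Pearson is dominated by the planted tail; Spearman is diluted by the
  # rank noise of the unplanted bulk and is only required to be positive
  expect_true(all(rep_cor$pearson > 0.8))
  expect_true(all(rep_cor$spearman > 0.2))
  # identical runs are perfectly correlated
  self_cor <- compare_runs(run$scores, run$scores)
  expect_equal(self_cor$pearson, rep(1, nrow(self_cor)))
  # truth-shuffled comparison is near zero
  shuf <- run$scores
  set.seed(1)
  for (m in unique(shuf$medium)) {
    i <- which(shuf$medium == m)
    shuf$z_L[i] <- sample(shuf$z_L[i])
  }
  null_cor <- compare_runs(run$scores, shuf)
  expect_true(all(abs(null_cor$pearson) < 0.4))
  expect_true(all(rep_cor$pearson > null_cor$pearson))
})
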