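test_that("z-transform standardizes, round-trips, and refuses zero SD", {
  z <- ztransform(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(z_inverse(z), c(1, 2, 3))
  expect_error(ztransform(rep(5, 4)), "SD")
  # supplied reference is honoured
  z2 <- ztransform(c(1, 2, 3), reference_mean = 0, reference_sd = 2)
  expect_equal(as.numeric(z2), c(0.5, 1, 1.5))
})

test_that("intercept-only fit reproduces the sample mean (flat-hierarchy limit)", {
  set.seed(10)
  d <- data.frame(y = rnorm(80, 1.7, 0.6))
  f <- fit_mlm(d, model_spec("y", character(0)), chains = 2, iter = 800,
               seed = 2)
  est <- f$summary$estimate[f$summary$term == "(Intercept)"]
  expect_equal(est, mean(d$y), tolerance = 3 * 0.6 / sqrt(80))
  expect_true(f$converged)
})

test_that("rank-deficient population designs are refused", {
  d <- make_records(J = 6, nper = 4)
  d$Group.c <- 0.5  # constant predictor
  expect_error(fit_mlm(d, model_spec("MedianLC", "Group.c")),
               "rank deficient|non-identified")
})

test_that("fixed seed and data give identical summaries", {
  d <- make_records(J = 8, nper = 5, seed = 3)
  f1 <- fit_mlm(d, smoothness_model(1), chains = 2, iter = 500, seed = 9,
                rhat_limit = Inf)
  f2 <- fit_mlm(d, smoothness_model(1), chains = 2, iter = 500, seed = 9,
                rhat_limit = Inf)
  expect_identical(f1$summary$estimate, f2$summary$estimate)
  expect_identical(f1$draws, f2$draws)
})

test_that("partial pooling shrinks sparse patients toward the grand mean", {
  set.seed(4)
  # one patient with a single far-off record, others with 15 each
  id <- c(rep(sprintf("P%02d", 1:8), each = 15), "P09")
  y <- c(rnorm(120, 0, 1), 4)
  d <- data.frame(MedianLC = y, IDanon = id)
  f <- fit_mlm(d, model_spec("MedianLC", character(0), "1"),
               chains = 2, iter = 1000, seed = 5, rhat_limit = Inf)
  b <- colMeans(f$b_draws)
  i9 <- which(f$group_levels == "P09")
  mu <- f$summary$estimate[f$summary$term == "(Intercept)"]
  est9 <- mu + b[i9]
  # estimate lies strictly between the grand mean and the patient's own value
  expect_gt(est9, mu)
  expect_lt(est9, 4)
  # and a data-rich far-off patient is shrunk less than a sparse one
  d2 <- rbind(d, data.frame(MedianLC = rnorm(14, 4, 0.3),
                            IDanon = "P10"))
  f2 <- fit_mlm(d2, model_spec("MedianLC", character(0), "1"),
                chains = 2, iter = 1000, seed = 5, rhat_limit = Inf)
  b2 <- colMeans(f2$b_draws)
  expect_gt(b2[which(f2$group_levels == "P10")],
            b2[which(f2$group_levels == "P09")])
})

test_that("prior-only slope draws match the Student-t(3, 0, scale) shape", {
  d <- make_records(J = 6, nper = 4, seed = 6)
  f <- fit_mlm(d, smoothness_model(1), chains = 2, iter = 4000,
               seed = 11, prior_only = TRUE, save_loglik = FALSE)
  dr <- f$draws[, "Group.c"]
  # compare quartiles and the 90% quantile to the analytic t(3) values
  expect_equal(unname(quantile(dr, 0.75)), 3 * qt(0.75, 3), tolerance = 0.12)
  expect_equal(unname(quantile(dr, 0.9)), 3 * qt(0.9, 3), tolerance = 0.2)
  expect_lt(abs(median(dr)), 0.25)
})

test_that("pre-intervention difference model recovers a large-n offset", {
  tab <- gen_clinical_table(200, offsets = c(BBT = 1), seed = 21)
  res <- fit_pre_difference(tab, "BBT", chains = 2, iter = 800, seed = 3)
  expect_equal(res$median, 1, tolerance = 0.15)
  expect_gt(res$tail_mass, 0.4)
  null <- fit_pre_difference(tab, "ARAT", chains = 2, iter = 800, seed = 3)
  expect_gt(null$conf.high, 0)
  expect_lt(null$conf.low, 0)
  tab$group <- "treatment"
  expect_error(fit_pre_difference(tab, "BBT"), "constant|non-identified")
})

test_that("90% intervals have roughly nominal coverage under the null", {
  # null multilevel cohorts, group-only model; small n on purpose
  covered <- 0
  n_sim <- 60
  for (k in seq_len(n_sim)) {
    d <- make_records(J = 8, nper = 4, group_effect = 0, patient_sd = 0.4,
                      seed = 1000 + k)
    f <- fit_mlm(d, smoothness_model(1), chains = 1, iter = 700, seed = k,
                 save_loglik = FALSE, rhat_limit = Inf)
    s <- f$summary[f$summary$term == "Group.c", ]
    if (s$conf.low <= 0 && s$conf.high >= 0) covered <- covered + 1
  }
  expect_gte(covered / n_sim, 0.85)
  expect_lte(covered / n_sim, 0.99)
})

test_that("the model ladder specs map to the stated formulas", {
  m1 <- smoothness_model(1)
  expect_equal(m1$population_terms, "Group.c")
  expect_equal(m1$varying_terms, "1")
  m5 <- smoothness_model(5)
  expect_true(all(c("pre.z", "MoCap.c", "Group.c:Session.c") %in%
                    m5$population_terms))
  expect_equal(m5$varying_terms, c("1", "Session.c", "pre.z"))
  m6 <- smoothness_model(6)
  expect_true("Group.c:MoCap.c" %in% m6$population_terms)
  m7 <- smoothness_model(7)
  expect_true("pre.z:MoCap.c" %in% m7$population_terms)
  expect_error(smoothness_model(8), "1..7")
})
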