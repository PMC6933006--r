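test_that("cohort generation is deterministic and validates its design", {
  de <- cohort_design(n_treatment = 2, n_control = 2, n_sessions = 2,
                      task = task_spec(repetitions = 1), seed = 5)
  c1 <- gen_cohort(de)
  c2 <- gen_cohort(de)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$sets[[3]]$trajectory, c2$sets[[3]]$trajectory)
  expect_error(cohort_design(n_treatment = 0), "n_treatment")
  expect_error(cohort_design(patient_sd = -1), "patient_sd")
})

test_that("the calibration inverse map is monotone and clamped", {
  cal <- corruption_calibration()
  expect_setequal(unique(cal$dialect), c("inertial", "optical"))
  targets <- seq(5.5, 8, by = 0.25)
  corr <- smoothness_to_corruption(targets, "inertial", cal)
  expect_true(all(diff(corr) <= 0))   # smoother targets need less corruption
  # outside the calibrated range: clamped, never extrapolated
  expect_equal(smoothness_to_corruption(100, "inertial", cal), 0)
  expect_equal(smoothness_to_corruption(-100, "inertial", cal),
               max(cal$corruption))
})

test_that("cohort records carry the injected group structure", {
  de <- cohort_design(n_treatment = 6, n_control = 6, n_sessions = 3,
                      group_effect = 1.5, patient_sd = 0.05,
                      pre_smoothness_sd = 0.1, mocap_effect = 0,
                      task = task_spec(repetitions = 2), seed = 31)
  coh <- gen_cohort(de)
  rec <- cohort_records(coh)
  # every patient contributes, baseline session excluded
  expect_equal(length(unique(rec$IDanon)), 12)
  expect_false(0 %in% rec$session)
  d_obs <- mean(rec$MedianLC[rec$Group.c > 0]) -
    mean(rec$MedianLC[rec$Group.c < 0])
  expect_gt(d_obs, 0.8)   # large injected effect shows up on the z scale
})

test_that("a null design produces no systematic group difference", {
  de <- cohort_design(n_treatment = 5, n_control = 5, n_sessions = 2,
                      group_effect = 0, session_slope = 0, patient_sd = 0,
                      pre_smoothness_sd = 0, mocap_effect = 0,
                      task = task_spec(repetitions = 2), seed = 77)
  rec <- cohort_records(gen_cohort(de))
  d_obs <- mean(rec$MedianLC[rec$Group.c > 0]) -
    mean(rec$MedianLC[rec$Group.c < 0])
  # outcome is z-scored; Monte-Carlo error with ~80 strokes/group
  expect_lt(abs(d_obs), 0.35)
})

test_that("clinical tables have the full scale set and injected offsets", {
  tab <- gen_clinical_table(50, offsets = c(`SIS.1` = 1), seed = 4)
  expect_equal(nrow(tab), 100)
  expect_true(all(clinical_scales() %in% names(tab)))
  expect_identical(tab, gen_clinical_table(50, offsets = c(`SIS.1` = 1),
                                           seed = 4))
  d1 <- mean(tab$SIS.1[tab$group == "treatment"]) -
    mean(tab$SIS.1[tab$group == "control"])
  expect_equal(d1, 1, tolerance = 0.45)
  d0 <- mean(tab$BBT[tab$group == "treatment"]) -
    mean(tab$BBT[tab$group == "control"])
  expect_lt(abs(d0), 0.45)
  # SIS total is the sum of its subscales
  expect_equal(tab$SIS.total, rowSums(tab[, paste0("SIS.", 1:9)]))
  expect_error(gen_clinical_table(1), "at least 2")
})

test_that("ephys generation is deterministic with the stated layout", {
  de <- coupling_design(n_trials = 5, seed = 9)
  r1 <- gen_ephys(de); r2 <- gen_ephys(de)
  expect_identical(r1$eeg, r2$eeg)
  expect_equal(length(r1$events), 5)
  expect_equal(nrow(r1$eeg), 20)
  expect_true(all(rownames(r1$eeg) %in% montage_1020()$channel))
  expect_equal(rownames(r1$emg), "DELT")
  expect_equal(r1$rate, 200)
  # events ~5 s apart
  expect_equal(mean(diff(r1$events)) / 200, 5, tolerance = 0.2)
  expect_error(coupling_design(coupled_channels = "XX9"), "montage")
  expect_error(coupling_design(coupling_strength = 2), "0, 1")
  expect_error(coupling_design(beta_freq = 30), "14-20")
})
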