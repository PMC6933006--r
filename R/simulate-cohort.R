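#' Cohort simulation design
#'
#' Effect structure of a simulated two-group rehabilitation cohort. All
#' effects are expressed in outcome SD units: the generator converts them to
#' the raw smoothness scale with a unit chosen so that the total SD of the
#' resulting per-stroke records (within-stroke spread from the corruption
#' calibration plus the injected between-patient and effect variance)
#' matches one unit. An effect of 0.5 therefore recovers as ~0.5 on the
#' z-scored modelling outcome.
#'
#' @param n_treatment,n_control Patients per group.
#' @param n_sessions Modelled training sessions per patient; a baseline
#'   (pre-intervention) session 0 is generated in addition.
#' @param group_effect Treatment-vs-control smoothness difference (SD units);
#'   applied from session 1 on, never to the baseline session.
#' @param session_slope Per-session smoothness drift (SD units/session).
#' @param patient_sd SD of the stable patient intercept beyond the baseline
#'   heterogeneity.
#' @param pre_smoothness_sd SD of the persistent baseline (pre-intervention)
#'   smoothness component across patients.
#' @param mocap_effect Inertial-minus-optical smoothness offset (SD units)
#'   injected on top of whatever intrinsic difference the two noise dialects
#'   produce.
#' @param seed Integer seed.
#' @param task Task performed each session (default: the first daily task,
#'   four up-down scales; its 8 strokes per session give the baseline
#'   smoothness estimate a usable reliability).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_treatment = 14, n_control = 14, n_sessions = 15,
                          group_effect = 0.5, session_slope = 0,
                          patient_sd = 0.1, pre_smoothness_sd = 0.4,
                          mocap_effect = -0.35, seed = 1,
                          task = task_spec()) {
  stopifnot(n_treatment >= 1, n_control >= 1, n_sessions >= 1,
            patient_sd >= 0, pre_smoothness_sd >= 0)
  structure(list(n_treatment = as.integer(n_treatment),
                 n_control = as.integer(n_control),
                 n_sessions = as.integer(n_sessions),
                 group_effect = group_effect, session_slope = session_slope,
                 patient_sd = patient_sd,
                 pre_smoothness_sd = pre_smoothness_sd,
                 mocap_effect = mocap_effect, seed = as.integer(seed),
                 task = task),
            class = "cohort_design")
}

#' Build the corruption-to-smoothness calibration table
#'
#' Simulates strokes over a corruption grid for both capture dialects and
#' records the mean and SD of the per-stroke smoothness statistic. The
#' packaged copy of this table (`inst/extdata/corruption_calibration.csv`)
#' is rebuilt from 1,000 strokes per dialect with this function and versioned
#' with the package; [gen_cohort()] inverts it to realize target smoothness
#' values through the corruption knob.
#'
#' @param corruption_grid Corruption levels to calibrate.
#' @param n_strokes Total strokes per dialect (split over the grid).
#' @param seed Integer seed.
#' @return data.frame with columns `dialect`, `corruption`, `mean_lc`,
#'   `sd_lc`, `n_strokes`.
#' @export
build_corruption_calibration <- function(corruption_grid = c(0, 0.5, 1, 2, 3, 4, 6, 8),
                                         n_strokes = 1000, seed = 20240901) {
  task <- task_spec(note_sequence = c(1, 6), repetitions = 1)  # one up-stroke
  per_cell <- max(ceiling(n_strokes / length(corruption_grid)), 20)
  rows <- list()
  for (dialect in c("inertial", "optical")) {
    for (ci in seq_along(corruption_grid)) {
      corr <- corruption_grid[ci]
      vals <- numeric(0)
      k <- 0
      while (length(vals) < per_cell && k < 3 * per_cell) {
        k <- k + 1
        sd_seed <- (seed + 7919L * ci + 104729L * k +
                      (dialect == "optical") * 15485863L) %% .Machine$integer.max
        tr <- gen_trajectory(task, corruption = corr, dialect = dialect,
                             seed = sd_seed)
        tr <- resample_trajectory(tr)
        st <- segment_strokes(tr)
        vals <- c(vals, vapply(st, function(s) as.numeric(stroke_smoothness(s)), 0))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dialect = dialect, corruption = corr,
        mean_lc = mean(vals), sd_lc = stats::sd(vals),
        n_strokes = length(vals))
    }
  }
  do.call(rbind, rows)
}

#' Load the packaged corruption calibration
#' @return The calibration data.frame (see [build_corruption_calibration()]).
#' @export
corruption_calibration <- function() {
  path <- system.file("extdata", "corruption_calibration.csv",
                      package = "sonirehab")
  if (!nzchar(path)) stop("packaged calibration table not found")
  utils::read.csv(path, comment.char = "#")
}

#' Invert the calibration: corruption level realizing a target smoothness
#'
#' Monotone linear interpolation of the calibration table (smoothness is
#' strictly decreasing in corruption); targets outside the calibrated range
#' are clamped to the nearest calibrated level.
#'
#' @param target Target raw smoothness value(s).
#' @param dialect Capture dialect.
#' @param calib Calibration table.
#' @return Corruption level(s).
#' @export
smoothness_to_corruption <- function(target, dialect = "inertial",
                                     calib = corruption_calibration()) {
  cal <- calib[calib$dialect == dialect, ]
  cal <- cal[order(cal$corruption), ]
  # enforce monotone decreasing mean (guard against calibration noise)
  m <- cummin(cal$mean_lc)
  m <- m - seq_along(m) * 1e-9  # strict for approx()
  stats::approx(x = rev(m), y = rev(cal$corruption), xout = target,
                rule = 2)$y
}

#' Generate a simulated cohort of trajectories with known ground truth
#'
#' Draws per-patient latent smoothness values under the design's effect
#' structure
#' `latent = baseline + patient intercept + group_effect * Group.c +
#' session_slope * (session - centre) + mocap_effect * MoCap.c`
#' (group and session terms from session 1 on; session 0 is the
#' pre-intervention baseline), converts each patient-session latent value to
#' a corruption level through the inverted calibration map, and generates one
#' task trajectory per patient-session. Capture devices are assigned
#' alternately within each group so `MoCap.c` is balanced.
#'
#' @param design A [cohort_design()].
#' @param calib Calibration table (see [corruption_calibration()]).
#' @return List with `sets` — a list of `list(trajectory, meta)` usable by
#'   [cohort_records()] — and `truth`, a data.frame of the latent values and
#'   corruption levels actually used.
#' @export
gen_cohort <- function(design, calib = corruption_calibration()) {
  set.seed(design$seed)
  n_pat <- design$n_treatment + design$n_control
  groups <- c(rep("treatment", design$n_treatment),
              rep("control", design$n_control))
  # device balanced within group
  device <- unlist(lapply(c(design$n_treatment, design$n_control), function(n)
    rep_len(c("inertial", "optical"), n)))

  # raw-scale unit: chosen so the predicted total record SD equals one unit.
  # Within-stroke spread comes from the calibration's working corruption
  # region; the injected latent variance (patients, group, device, slope)
  # is added self-consistently: u^2 = within^2 + u^2 * V_latent.
  working <- calib[calib$corruption >= 1.5 & calib$corruption <= 4.5, ]
  within <- mean(working$sd_lc)
  v_lat <- design$patient_sd^2 + design$pre_smoothness_sd^2 +
    design$group_effect^2 / 4 + design$mocap_effect^2 / 4 +
    design$session_slope^2 * stats::var(seq_len(design$n_sessions))
  unit <- within / sqrt(max(1 - v_lat, 0.25))
  center <- mean(working$mean_lc)

  alpha <- stats::rnorm(n_pat, 0, design$patient_sd) +
    stats::rnorm(n_pat, 0, design$pre_smoothness_sd)

  sessions <- 0:design$n_sessions
  sess_center <- (1 + design$n_sessions) / 2
  truth <- expand.grid(patient = seq_len(n_pat), session = sessions)
  truth$group <- groups[truth$patient]
  truth$device <- device[truth$patient]
  g_c <- ifelse(truth$group == "treatment", 0.5, -0.5)
  m_c <- ifelse(truth$device == "inertial", 0.5, -0.5)
  active <- truth$session >= 1
  latent_sd_units <- alpha[truth$patient] +
    design$group_effect * g_c * active +
    design$session_slope * (truth$session - sess_center) * active +
    design$mocap_effect * m_c
  truth$latent_raw <- center + unit * latent_sd_units
  truth$corruption <- smoothness_to_corruption(truth$latent_raw,
                                               dialect = "inertial",
                                               calib = calib)
  opt <- truth$device == "optical"
  truth$corruption[opt] <- smoothness_to_corruption(truth$latent_raw[opt],
                                                    dialect = "optical",
                                                    calib = calib)
  traj_seeds <- sample.int(.Machine$integer.max - 1L, nrow(truth))

  sets <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- gen_trajectory(design$task, corruption = truth$corruption[i],
                         dialect = truth$device[i], seed = traj_seeds[i])
    sets[[i]] <- list(
      trajectory = tr,
      meta = list(patient = sprintf("P%02d", truth$patient[i]),
                  group = truth$group[i], session = truth$session[i],
                  device = truth$device[i], task = 1)
    )
  }
  list(sets = sets, truth = truth, unit = unit, center = center)
}

#' Run the kinematics stage over a simulated cohort
#'
#' Resamples and segments every cohort trajectory, scores stroke smoothness,
#' and assembles the modelling records via [build_records()].
#'
#' @param cohort Output of [gen_cohort()].
#' @param ... Passed to [build_records()].
#' @return The records data.frame (see [build_records()]).
#' @export
cohort_records <- function(cohort, ...) {
  stroke_sets <- lapply(cohort$sets, function(s) {
    tr <- resample_trajectory(s$trajectory)
    list(strokes = segment_strokes(tr), meta = s$meta)
  })
  build_records(stroke_sets, ...)
}

#' Generate a synthetic clinical outcome table
#'
#' One row per patient with numeric columns for each clinical scale, a group
#' label, and injected treatment-group offsets. Scores are standard-normal
#' deviates on the z scale (the pre-intervention regressions z-score their
#' outcome anyway); `SIS.total` is the sum of the nine SIS subscales.
#'
#' @param n_per_group Patients per group (>= 2).
#' @param offsets Named numeric vector of per-scale treatment offsets in SD
#'   units, e.g. `c(SIS.1 = 1)`; scales not named get offset 0.
#' @param seed Integer seed.
#' @return data.frame with columns `patient`, `group` and one column per
#'   scale.
#' @export
gen_clinical_table <- function(n_per_group = 14, offsets = numeric(0),
                               seed = 1) {
  if (n_per_group < 2) stop("need at least 2 patients per group")
  set.seed(as.integer(seed))
  scales <- clinical_scales()
  n <- 2L * n_per_group
  group <- rep(c("treatment", "control"), each = n_per_group)
  out <- data.frame(patient = sprintf("P%02d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  base <- setdiff(scales, "SIS.total")
  for (sc in base) {
    off <- if (sc %in% names(offsets)) offsets[[sc]] else 0
    out[[sc]] <- stats::rnorm(n) + off * (group == "treatment")
  }
  sis <- grep("^SIS\\.[0-9]$", names(out), value = TRUE)
  out[["SIS.total"]] <- rowSums(out[, sis])
  out
}

#' Clinical scale column names
#' @return Character vector of scale names used by [gen_clinical_table()].
#' @export
clinical_scales <- function() {
  c("FM.A-D", "FM.H", "FM.I", "FM.J",
    paste0("SIS.", 1:9), "SIS.total",
    "ARAT", "BBT", "invNHPT", "TLT", "BI", "DSS")
}
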