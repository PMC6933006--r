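#' Z-transform a numeric vector
#'
#' Standardizes against a supplied or computed reference mean and SD and
#' stores the reference in attributes so the transform can be inverted
#' exactly with [z_inverse()].
#'
#' @param values Numeric vector.
#' @param reference_mean,reference_sd Optional reference statistics; computed
#'   from `values` when omitted.
#' @return Standardized vector with attributes `reference_mean`,
#'   `reference_sd`.
#' @export
ztransform <- function(values, reference_mean = NULL, reference_sd = NULL) {
  m <- if (is.null(reference_mean)) mean(values, na.rm = TRUE) else reference_mean
  s <- if (is.null(reference_sd)) stats::sd(values, na.rm = TRUE) else reference_sd
  if (!is.finite(s) || s <= 0) {
    stop("z-transform undefined: reference SD is zero or not finite")
  }
  out <- (values - m) / s
  attr(out, "reference_mean") <- m
  attr(out, "reference_sd") <- s
  out
}

#' Invert a z-transform
#' @param z Output of [ztransform()] (attributes carry the reference).
#' @return Vector on the original scale.
#' @export
z_inverse <- function(z) {
  m <- attr(z, "reference_mean"); s <- attr(z, "reference_sd")
  if (is.null(m) || is.null(s)) stop("no stored reference to invert with")
  as.numeric(z) * s + m
}

#' Prior specification for the regression models
#'
#' Heavy-tailed informative priors: central Student-t for slopes and the
#' intercept, half Student-t (left-bounded at zero) for the residual SD and
#' the random-effect SDs, and an LKJ prior for random-effect correlation
#' matrices.
#'
#' @param slope_df,slope_scale Student-t df and scale for population slopes.
#' @param intercept_scale Scale of the intercept prior (same df as slopes).
#' @param sigma_df,sigma_scale Half-t prior on the residual SD.
#' @param sd_df,sd_scale Half-t prior on random-effect SDs.
#' @param lkj_eta LKJ shape for correlation matrices (eta = 2 favours
#'   moderate correlations).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(slope_df = 3, slope_scale = 3, intercept_scale = 3,
                       sigma_df = 3, sigma_scale = 3,
                       sd_df = 3, sd_scale = 3, lkj_eta = 2) {
  stopifnot(slope_df > 0, slope_scale > 0, sigma_scale > 0, sd_scale > 0,
            lkj_eta > 0)
  structure(list(slope_df = slope_df, slope_scale = slope_scale,
                 intercept_scale = intercept_scale,
                 sigma_df = sigma_df, sigma_scale = sigma_scale,
                 sd_df = sd_df, sd_scale = sd_scale, lkj_eta = lkj_eta),
            class = "prior_spec")
}

#' Model specification for the multilevel smoothness regressions
#'
#' @param outcome Outcome column name.
#' @param population_terms Character vector of population-level terms
#'   (interactions as `"A:B"`); the intercept is always included.
#' @param varying_terms Character vector of per-group varying terms; `"1"`
#'   is the varying intercept. Empty for a single-level regression.
#' @param group Grouping column (default `"IDanon"`).
#' @param correlated Model correlations between varying terms (LKJ prior)?
#' @param priors A [prior_spec()].
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, population_terms, varying_terms = character(0),
                       group = "IDanon", correlated = TRUE,
                       priors = prior_spec()) {
  structure(list(outcome = outcome, population_terms = population_terms,
                 varying_terms = varying_terms, group = group,
                 correlated = correlated, priors = priors),
            class = "model_spec")
}

#' The smoothness model ladder
#'
#' The increasingly complex multilevel models fitted to the z-scored
#' smoothness records: group only (#1), group-by-session (#2), varying
#' session slopes (#3), baseline smoothness as covariate with varying
#' loading (#4), capture device added (#5), and the post-hoc interaction
#' extensions group-by-device (#6) and baseline-by-device (#7).
#'
#' @param number Model number 1..7.
#' @param priors A [prior_spec()].
#' @return A [model_spec()].
#' @export
smoothness_model <- function(number, priors = prior_spec()) {
  pop <- switch(as.character(number),
    `1` = c("Group.c"),
    `2` = c("Group.c", "Session.c", "Group.c:Session.c"),
    `3` = c("Group.c", "Session.c", "Group.c:Session.c"),
    `4` = c("Group.c", "Session.c", "Group.c:Session.c", "pre.z"),
    `5` = c("Group.c", "Session.c", "Group.c:Session.c", "pre.z", "MoCap.c"),
    `6` = c("Group.c", "Session.c", "Group.c:Session.c", "pre.z", "MoCap.c",
            "Group.c:MoCap.c"),
    `7` = c("Group.c", "Session.c", "Group.c:Session.c", "pre.z", "MoCap.c",
            "pre.z:MoCap.c"),
    stop("model number must be 1..7"))
  vary <- switch(as.character(number),
    `1` = "1", `2` = "1",
    `3` = c("1", "Session.c"),
    c("1", "Session.c", "pre.z"))
  model_spec("MedianLC", pop, vary, priors = priors)
}

# population design matrix (intercept always included)
pop_design <- function(records, spec) {
  terms <- if (length(spec$population_terms)) spec$population_terms else "1"
  stats::model.matrix(stats::reformulate(terms), data = records)
}

#' Fit a Bayesian (multilevel) Gaussian regression by MCMC
#'
#' Blocked Gibbs sampler with Student-t priors on population coefficients,
#' half-t priors on SDs and an LKJ prior on the correlation matrix of
#' correlated varying coefficients (see [prior_spec()]). Partial pooling of
#' the per-group varying coefficients shrinks sparse groups toward the
#' population estimates.
#'
#' @param records Data frame with all columns the spec references.
#' @param spec A [model_spec()].
#' @param chains,iter,warmup MCMC configuration (defaults 4 chains of 2,000
#'   iterations, half warm-up).
#' @param seed Integer seed; fixed seed and data give identical summaries.
#' @param save_loglik Store the pointwise log-likelihood matrix needed by
#'   [psis_loo()] (can be switched off for large fits).
#' @param prior_only Sample from the prior instead of the posterior (for
#'   prior predictive checks).
#' @param rhat_limit Convergence gate: parameters with split-Rhat above this
#'   set `converged = FALSE` (returned with a warning, never silently).
#' @return A `model_fit`: list with `draws` (matrix, samples x parameters),
#'   `summary` (median, 50% and 90% intervals, Rhat, ESS per parameter),
#'   `b_draws`, `loglik`, `converged`, plus the model data for reuse.
#' @export
fit_mlm <- function(records, spec, chains = 4, iter = 2000,
                    warmup = floor(iter / 2), seed = 1,
                    save_loglik = TRUE, prior_only = FALSE,
                    rhat_limit = 1.01) {
  pr <- spec$priors
  y <- records[[spec$outcome]]
  if (is.null(y)) stop("outcome column not found: ", spec$outcome)
  X <- pop_design(records, spec)
  if (qr(X)$rank < ncol(X)) {
    stop("population design matrix is rank deficient; ",
         "a predictor is constant or collinear (non-identified coefficient)")
  }
  q <- length(spec$varying_terms)
  Z <- NULL; gfac <- NULL
  if (q > 0) {
    gfac <- factor(records[[spec$group]])
    if (nlevels(gfac) < 2) stop("need at least 2 groups for varying terms")
    Z <- vapply(spec$varying_terms, function(tm)
      if (tm == "1") rep(1, nrow(records)) else records[[tm]],
      numeric(nrow(records)))
    Z <- matrix(Z, nrow = nrow(records),
                dimnames = list(NULL, ifelse(spec$varying_terms == "1",
                                             "Intercept", spec$varying_terms)))
  }
  beta_scales <- c(pr$intercept_scale,
                   rep(pr$slope_scale, ncol(X) - 1))
  priors <- list(beta_scales = beta_scales, beta_df = pr$slope_df,
                 sigma_df = pr$sigma_df, sigma_scale = pr$sigma_scale,
                 sd_df = pr$sd_df, sd_scale = pr$sd_scale,
                 lkj_eta = pr$lkj_eta)

  res <- gibbs_mlm(y, X, Z, gfac, priors, chains = chains, iter = iter,
                   warmup = warmup, seed = seed, save_loglik = save_loglik,
                   prior_only = prior_only)

  keep <- dim(res$draws)[1]
  P <- dim(res$draws)[2]
  flat <- apply(res$draws, 2, as.numeric)   # (keep*chains) x P
  summ <- data.frame(
    term = res$par_names,
    estimate = apply(flat, 2, stats::median),
    std.error = apply(flat, 2, stats::sd),
    conf.low25 = apply(flat, 2, stats::quantile, 0.25),
    conf.high75 = apply(flat, 2, stats::quantile, 0.75),
    conf.low = apply(flat, 2, stats::quantile, 0.05),
    conf.high = apply(flat, 2, stats::quantile, 0.95),
    rhat = vapply(seq_len(P), function(j) split_rhat(res$draws[, j, ]), 0),
    ess = vapply(seq_len(P), function(j) ess_basic(res$draws[, j, ]), 0),
    row.names = NULL
  )
  converged <- all(is.finite(summ$rhat)) && max(summ$rhat) < rhat_limit
  if (!converged && !prior_only) {
    warning(sprintf("convergence gate failed: max split-Rhat = %.3f",
                    max(summ$rhat)))
  }
  ll <- NULL
  if (!is.null(res$loglik)) {
    ll <- do.call(rbind, lapply(seq_len(dim(res$loglik)[3]),
                                function(ch) res$loglik[, , ch, drop = TRUE]))
  }
  b_flat <- NULL
  if (!is.null(res$b_draws)) {
    b_flat <- do.call(rbind, lapply(seq_len(dim(res$b_draws)[3]),
                                    function(ch) res$b_draws[, , ch]))
  }
  structure(list(draws = flat, summary = summ, b_draws = b_flat,
                 loglik = ll, converged = converged,
                 spec = spec, n_obs = length(y),
                 data = list(y = y, X = X, Z = Z, g = gfac),
                 group_levels = res$group_levels,
                 chains = chains, iter = iter, warmup = warmup, seed = seed),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s regression: %s ~ %s\n",
              if (length(x$spec$varying_terms)) "multilevel" else "simple",
              x$spec$outcome, paste(x$spec$population_terms, collapse = " + ")))
  if (length(x$spec$varying_terms)) {
    cat(sprintf("  varying (%s): %s\n", x$spec$group,
                paste(x$spec$varying_terms, collapse = " + ")))
  }
  cat(sprintf("  %d obs, %d chains x %d iter (%d warmup), converged: %s\n",
              x$n_obs, x$chains, x$iter, x$warmup, x$converged))
  print(x$summary[, c("term", "estimate", "std.error", "conf.low",
                      "conf.high", "rhat")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Pre-intervention group-difference regression for one clinical scale
#'
#' Z-scores the scale and regresses it on a 0/1 treatment indicator with a
#' Student-t(3, 0, 1) slope prior and half-t(3, 1) residual prior. Reports
#' the posterior median, 50% and 90% intervals of the treatment coefficient
#' and the posterior mass lying further than `tail_sd` SDs from zero (the
#' shading criterion of the group-difference panels).
#'
#' @param table Clinical table (see [gen_clinical_table()]); needs a `group`
#'   column with both `"treatment"` and `"control"`.
#' @param scale Column name of the scale to model.
#' @param tail_sd Tail-mass threshold in SD units.
#' @param ... Passed to [fit_mlm()] (chains, iter, seed, ...).
#' @return List with the treatment-coefficient summary (`median`,
#'   `conf.low25/75`, `conf.low/high` 90%, `tail_mass`) and the full
#'   `model_fit` as `fit`.
#' @export
fit_pre_difference <- function(table, scale, tail_sd = 0.9, ...) {
  if (!scale %in% names(table)) stop("scale column not found: ", scale)
  dat <- data.frame(y = as.numeric(ztransform(table[[scale]])),
                    Treatment = as.numeric(table$group == "treatment"))
  if (length(unique(dat$Treatment)) < 2) {
    stop("treatment indicator is constant; coefficient non-identified")
  }
  spec <- model_spec("y", "Treatment",
                     priors = prior_spec(slope_scale = 1, intercept_scale = 1,
                                         sigma_scale = 1, sd_scale = 1))
  fit <- fit_mlm(dat, spec, ...)
  dr <- fit$draws[, "Treatment"]
  s <- fit$summary[fit$summary$term == "Treatment", ]
  list(scale = scale,
       median = s$estimate,
       conf.low25 = s$conf.low25, conf.high75 = s$conf.high75,
       conf.low = s$conf.low, conf.high = s$conf.high,
       tail_mass = mean(abs(dr) > tail_sd),
       fit = fit)
}
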