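# Blocked Gibbs sampler for the Gaussian multilevel regression
#
#   y = X beta + Z b_{g} + e,   e ~ N(0, sigma^2)
#   beta_j ~ Student-t(df, 0, scale_j)        (scale-mixture augmentation)
#   b_i ~ N_q(0, D R D), D = diag(tau), tau_j ~ half-t(sd_df, sd_scale),
#   R ~ LKJ(eta), sigma ~ half-t(sigma_df, sigma_scale) (Huang-Wand mixture)
#
# Conjugate draws for beta, the mixture scales, b, and sigma^2; adaptive
# random-walk Metropolis for log tau (q >= 2) and the free correlations of R.
# For q = 1 the tau update is conjugate via the Huang-Wand mixture as well.

gibbs_mlm <- function(y, X, Z, g, priors, chains = 4, iter = 2000,
                      warmup = floor(iter / 2), seed = 1,
                      save_loglik = TRUE, prior_only = FALSE) {
  n <- length(y)
  p <- ncol(X)
  q <- if (is.null(Z)) 0L else ncol(Z)
  J <- if (q > 0) nlevels(g) else 0L

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  if (q > 0) {
    gi <- as.integer(g)
    idx_by_g <- split(seq_len(n), gi)
    ZtZ_by_g <- lapply(idx_by_g, function(ix)
      crossprod(Z[ix, , drop = FALSE]))
    XtZ_by_g <- lapply(idx_by_g, function(ix)
      crossprod(X[ix, , drop = FALSE], Z[ix, , drop = FALSE]))
    Zty_by_g <- lapply(idx_by_g, function(ix)
      crossprod(Z[ix, , drop = FALSE], y[ix]))
    XtX_by_g <- lapply(idx_by_g, function(ix)
      crossprod(X[ix, , drop = FALSE]))
    Xty_by_g <- lapply(idx_by_g, function(ix)
      crossprod(X[ix, , drop = FALSE], y[ix]))
    yty_by_g <- vapply(idx_by_g, function(ix) sum(y[ix]^2), 0)
    n_by_g <- lengths(idx_by_g)
  }

  # marginal log-likelihood of y | beta, tau, R, sigma2 with the random
  # effects integrated out (per-group Woodbury / determinant lemma)
  marg_ll <- function(beta, tau, R, sigma2) {
    Sigma_b <- diag(tau, q) %*% R %*% diag(tau, q)
    Uo <- tryCatch(chol(Sigma_b), error = function(e) NULL)
    if (is.null(Uo)) return(-Inf)
    Omega <- chol2inv(Uo)
    ldet_S <- 2 * sum(log(diag(Uo)))
    total <- 0
    for (i in seq_len(J)) {
      A <- sigma2 * Omega + ZtZ_by_g[[i]]
      Ua <- tryCatch(chol(A), error = function(e) return(NULL))
      if (is.null(Ua)) return(-Inf)
      ldet <- (n_by_g[i] - q) * log(sigma2) + ldet_S + 2 * sum(log(diag(Ua)))
      Zte <- Zty_by_g[[i]] - t(XtZ_by_g[[i]]) %*% beta
      ete <- yty_by_g[i] - 2 * sum(beta * Xty_by_g[[i]]) +
        as.numeric(t(beta) %*% XtX_by_g[[i]] %*% beta)
      v <- backsolve(Ua, Zte, transpose = TRUE)
      quad <- (ete - sum(v^2)) / sigma2
      total <- total - 0.5 * (ldet + quad)
    }
    total
  }
  beta_scales <- priors$beta_scales            # length p
  beta_df <- priors$beta_df
  nu_s <- priors$sigma_df; A_s <- priors$sigma_scale
  nu_t <- priors$sd_df;    A_t <- priors$sd_scale
  eta <- priors$lkj_eta
  n_cor <- if (q >= 2) q * (q - 1) / 2 else 0L

  keep <- iter - warmup
  par_names <- c(colnames(X),
                 if (q > 0) paste0("sd__", colnames(Z)),
                 if (n_cor > 0) paste0("cor__", seq_len(n_cor)),
                 "sigma")
  draws <- array(NA_real_, c(keep, length(par_names), chains),
                 dimnames = list(NULL, par_names, NULL))
  b_draws <- if (q > 0) array(NA_real_, c(keep, J * q, chains)) else NULL
  ll <- if (save_loglik && !prior_only)
    array(NA_real_, c(keep, n, chains)) else NULL

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + 1000L * (ch - 1L))
    # initial state
    beta <- stats::rnorm(p, 0, 0.5)
    lam <- rep(1, p)
    sigma2 <- stats::runif(1, 0.5, 1.5)
    a_sig <- 1
    if (q > 0) {
      b <- matrix(stats::rnorm(J * q, 0, 0.2), J, q)
      tau <- rep(0.5 + stats::runif(1, 0, 0.5), q)
      a_tau <- rep(1, q)
      R <- diag(q)
      rho <- rep(0, n_cor)
      ls_tau <- rep(log(0.3), q)   # adaptive MH log-scales
      ls_rho <- log(0.2)
    }

    for (it in seq_len(iter)) {
      adapt <- it <= warmup

      ## beta | tau, R, sigma2 with the random effects integrated out
      ## (Woodbury on the per-group blocks of V = sigma^2 I + Z Sigma_b Z');
      ## collapsing removes the slow beta <-> mean(b) random walk
      if (prior_only) {
        beta <- stats::rnorm(p, 0, beta_scales * sqrt(lam))
      } else if (q > 0) {
        D <- diag(tau, q)
        Sigma_b <- D %*% R %*% D
        Omega <- chol2inv(chol(Sigma_b))
        XtVX <- XtX
        XtVy <- Xty
        W_by_g <- vector("list", J)
        for (i in seq_len(J)) {
          W <- chol2inv(chol(sigma2 * Omega + ZtZ_by_g[[i]]))
          W_by_g[[i]] <- W
          XtVX <- XtVX - XtZ_by_g[[i]] %*% W %*% t(XtZ_by_g[[i]])
          XtVy <- XtVy - XtZ_by_g[[i]] %*% W %*% Zty_by_g[[i]]
        }
        prec <- XtVX / sigma2 + diag(1 / (beta_scales^2 * lam), p)
        U <- chol(prec)
        beta <- as.numeric(backsolve(U, backsolve(U, XtVy / sigma2,
                                                  transpose = TRUE) +
                                       stats::rnorm(p)))
      } else {
        prec <- XtX / sigma2 + diag(1 / (beta_scales^2 * lam), p)
        U <- chol(prec)
        beta <- as.numeric(backsolve(U, backsolve(U, Xty / sigma2,
                                                  transpose = TRUE) +
                                       stats::rnorm(p)))
      }

      ## t-mixture scales
      lam <- 1 / stats::rgamma(p, (beta_df + 1) / 2,
                               (beta_df + (beta / beta_scales)^2) / 2)

      ## random effects b_i | beta, tau, R, sigma2 (conjugate; covariance
      ## sigma^2 W_i reuses the Woodbury blocks from the beta step)
      if (q > 0) {
        if (prior_only) {
          D <- diag(tau, q)
          Sigma_b <- D %*% R %*% D
          Lb <- t(chol(Sigma_b))
          b <- t(Lb %*% matrix(stats::rnorm(J * q), q, J))
        } else {
          for (i in seq_len(J)) {
            ix <- idx_by_g[[i]]
            mb <- Zty_by_g[[i]] - t(XtZ_by_g[[i]]) %*% beta
            W <- W_by_g[[i]]
            mu_b <- W %*% mb
            Lc <- t(chol(sigma2 * W))
            b[i, ] <- mu_b + Lc %*% stats::rnorm(q)
          }
        }

        ## tau and R
        if (q == 1) {
          # Huang-Wand conjugate half-t
          tau2 <- 1 / stats::rgamma(1, (nu_t + J) / 2,
                                    nu_t / a_tau[1] + sum(b^2) / 2)
          tau <- sqrt(tau2)
          a_tau[1] <- 1 / stats::rgamma(1, (nu_t + 1) / 2,
                                        nu_t / tau2 + 1 / A_t^2)
        } else {
          # adaptive MH on log tau_j and the free correlations, against the
          # marginal likelihood (b integrated out) to avoid the b <-> tau
          # funnel; half-t / LKJ(eta) priors
          cur_ml <- marg_ll(beta, tau, R, sigma2)
          for (j in seq_len(q)) {
            prop <- tau
            prop[j] <- tau[j] * exp(stats::rnorm(1, 0, exp(ls_tau[j])))
            prop_ml <- marg_ll(beta, prop, R, sigma2)
            lr <- prop_ml - cur_ml +
              half_t_lpdf(prop[j], nu_t, A_t) -
              half_t_lpdf(tau[j], nu_t, A_t) +
              log(prop[j]) - log(tau[j])   # log-scale Jacobian
            acc <- is.finite(lr) && log(stats::runif(1)) < lr
            if (acc) { tau <- prop; cur_ml <- prop_ml }
            if (adapt) ls_tau[j] <- ls_tau[j] +
                ((if (acc) 1 else 0) - 0.44) / sqrt(it)
          }
          prop_rho <- rho + stats::rnorm(n_cor, 0, exp(ls_rho))
          R_prop <- cor_from_free(prop_rho, q)
          if (!is.null(R_prop)) {
            prop_ml <- marg_ll(beta, tau, R_prop, sigma2)
            lr <- prop_ml - cur_ml +
              (eta - 1) * (log_det_pd(R_prop) - log_det_pd(R))
            acc <- is.finite(lr) && log(stats::runif(1)) < lr
            if (acc) { rho <- prop_rho; R <- R_prop; cur_ml <- prop_ml }
          } else acc <- FALSE
          if (adapt) ls_rho <- ls_rho + ((if (acc) 1 else 0) - 0.3) / sqrt(it)
          # refresh b under the (possibly) new variances
          Omega2 <- chol2inv(chol(diag(tau, q) %*% R %*% diag(tau, q)))
          for (i in seq_len(J)) {
            W <- chol2inv(chol(sigma2 * Omega2 + ZtZ_by_g[[i]]))
            mb <- Zty_by_g[[i]] - t(XtZ_by_g[[i]]) %*% beta
            b[i, ] <- W %*% mb + t(chol(sigma2 * W)) %*% stats::rnorm(q)
          }
        }
      }

      ## sigma^2 (Huang-Wand half-t); prior-only draws from the prior mixture
      if (prior_only) {
        sigma2 <- 1 / stats::rgamma(1, nu_s / 2, nu_s / a_sig)
      } else {
        resid <- y - as.numeric(X %*% beta) -
          (if (q > 0) rowSums(Z * b[gi, , drop = FALSE]) else 0)
        sigma2 <- 1 / stats::rgamma(1, (nu_s + n) / 2,
                                    nu_s / a_sig + sum(resid^2) / 2)
      }
      a_sig <- 1 / stats::rgamma(1, (nu_s + 1) / 2,
                                 nu_s / sigma2 + 1 / A_s^2)

      ## store
      if (it > warmup) {
        k <- it - warmup
        row <- c(beta,
                 if (q > 0) tau,
                 if (n_cor > 0) free_cors(if (q >= 2) R else NULL),
                 sqrt(sigma2))
        draws[k, , ch] <- row
        if (q > 0) b_draws[k, , ch] <- as.numeric(b)
        if (!is.null(ll)) {
          mu <- as.numeric(X %*% beta) +
            (if (q > 0) rowSums(Z * b[gi, , drop = FALSE]) else 0)
          ll[k, , ch] <- stats::dnorm(y, mu, sqrt(sigma2), log = TRUE)
        }
      }
    }
  }

  list(draws = draws, b_draws = b_draws, loglik = ll,
       par_names = par_names, q = q, J = J,
       group_levels = if (q > 0) levels(g) else NULL)
}

# multivariate-normal log-likelihood of the random-effect rows
b_loglik <- function(b, tau, R) {
  Sigma <- diag(tau, length(tau)) %*% R %*% diag(tau, length(tau))
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  J <- nrow(b)
  quad <- sum(backsolve(U, t(b), transpose = TRUE)^2)
  -J * sum(log(diag(U))) - 0.5 * quad
}

half_t_lpdf <- function(x, df, scale) {
  if (x <= 0) return(-Inf)
  stats::dt(x / scale, df, log = TRUE) - log(scale) + log(2)
}

log_det_pd <- function(M) 2 * sum(log(diag(chol(M))))

# build a correlation matrix from unconstrained free parameters via tanh;
# returns NULL if not positive definite
cor_from_free <- function(rho_free, q) {
  R <- diag(q)
  R[lower.tri(R)] <- tanh(rho_free)
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (ok) R else NULL
}

free_cors <- function(R) R[lower.tri(R)]

## ---- convergence diagnostics -------------------------------------------

# split-Rhat and a crude effective sample size for one parameter,
# draws: matrix keep x chains
split_rhat <- function(x) {
  x <- as.matrix(x)
  keep <- nrow(x); m <- ncol(x)
  half <- floor(keep / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(keep - half + 1):keep, , drop = FALSE])
  nM <- ncol(xs); nN <- nrow(xs)
  mns <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  B <- nN * stats::var(mns)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nN - 1) / nN * W + B / nN) / W)
}

ess_basic <- function(x) {
  # pooled-chain ESS from lag-summed autocorrelation (initial positive seq.)
  xc <- as.numeric(scale(as.numeric(x), scale = FALSE))
  n <- length(xc)
  if (stats::sd(xc) == 0) return(n)
  acf_v <- stats::acf(xc, lag.max = min(200, n - 2), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(acf_v)) {
    if (acf_v[k] < 0.05) break
    s <- s + acf_v[k]
  }
  max(n / (1 + 2 * s), 1)
}
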