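# Exact Gaussian-process regression with a sum kernel
#   k((a,s),(a',s')) = sf^2 exp(-(a-a')^2 / (2 l^2)) + ss^2 1[s = s']
#                      + sn^2 1[i = j]
# over (age in years, sex dummy). Hyperparameters are fitted by maximising
# the log marginal likelihood with L-BFGS-B on log-parameters, with seeded
# restarts. The additive form gives a smooth age trend plus a constant
# per-sex offset, which is the structure a normative model of predicted
# age needs; the white-noise term absorbs individual scatter.

gp_kernel <- function(age1, sex1, age2, sex2, par) {
  d2 <- outer(age1, age2, `-`)^2
  par$sf^2 * exp(-0.5 * d2 / par$ell^2) +
    par$ss^2 * outer(sex1, sex2, `==`)
}

gp_nlml <- function(theta, d2, S, yc) {
  par <- list(sf = exp(theta[1]), ell = exp(theta[2]),
              ss = exp(theta[3]), sn = exp(theta[4]))
  n <- length(yc)
  A <- exp(-0.5 * d2 / par$ell^2)
  K <- par$sf^2 * A + par$ss^2 * S + diag(par$sn^2 + 1e-8 * par$sf^2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  as.numeric(0.5 * crossprod(yc, alpha) + sum(log(diag(L))) +
               0.5 * n * log(2 * pi))
}

# Analytic gradient of the negative log marginal likelihood wrt the
# log-parameters: dNLML/dt_i = 0.5 tr((K^-1 - aa') dK/dt_i).
gp_nlml_grad <- function(theta, d2, S, yc) {
  par <- list(sf = exp(theta[1]), ell = exp(theta[2]),
              ss = exp(theta[3]), sn = exp(theta[4]))
  n <- length(yc)
  A <- exp(-0.5 * d2 / par$ell^2)
  K <- par$sf^2 * A + par$ss^2 * S + diag(par$sn^2 + 1e-8 * par$sf^2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(rep(0, 4))
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  W <- chol2inv(L) - tcrossprod(alpha)          # K^-1 - aa'
  g_sf <- 0.5 * sum(W * (2 * par$sf^2 * A)) +
    0.5 * sum(diag(W)) * 2e-8 * par$sf^2
  g_ell <- 0.5 * sum(W * (par$sf^2 * A * (d2 / par$ell^2)))
  g_ss <- 0.5 * sum(W * (2 * par$ss^2 * S))
  g_sn <- 0.5 * sum(diag(W)) * 2 * par$sn^2
  c(g_sf, g_ell, g_ss, g_sn)
}

gp_fit <- function(age, sex, y, opts = list(), seed = 1L) {
  n <- length(y)
  ybar <- mean(y)
  yc <- y - ybar
  sdy <- sd(y)
  ols <- lm(yc ~ age + sex)
  r <- sd(ols$residuals)
  if (!is.finite(r) || r <= 0) r <- max(sdy * 0.05, 1e-3)

  init <- log(c(sf = max(sdy, 1e-3),
                ell = min(max(opts$ell_init %||% (0.5 * sd(age)), 1), 50),
                ss = max(abs(coef(ols)[["sex"]]), 0.1),
                sn = r))
  lower <- log(c(1e-3 * sdy, opts$ell_lower %||% 1, 1e-6, 0.05 * r))
  upper <- log(c(10 * sdy, opts$ell_upper %||% 50, 10 * sdy, 10 * sdy))
  n_restarts <- opts$n_restarts %||% 5L

  d2 <- outer(age, age, `-`)^2
  S <- outer(sex, sex, `==`) * 1
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    th0 <- if (rs == 1L) init else pmin(pmax(init + rnorm(4, 0, 0.5), lower),
                                        upper)
    res <- tryCatch(
      optim(th0, gp_nlml, gr = gp_nlml_grad, d2 = d2, S = S, yc = yc,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop_computation("GP marginal-likelihood optimisation failed")

  par <- list(sf = exp(best$par[1]), ell = exp(best$par[2]),
              ss = exp(best$par[3]), sn = exp(best$par[4]))
  K <- gp_kernel(age, sex, age, sex, par) +
    diag(par$sn^2 + 1e-8 * par$sf^2, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  list(par = par, age = age, sex = sex, ybar = ybar, L = L, alpha = alpha,
       nlml = best$value)
}

# Posterior predictive moments; sd is the TOTAL predictive SD
# (latent variance + observation noise), i.e. the spread of individual
# predicted ages among peers, not just of the latent mean.
gp_predict <- function(fit, age, sex) {
  Ks <- gp_kernel(fit$age, fit$sex, age, sex, fit$par)   # n x m
  mean <- drop(crossprod(Ks, fit$alpha)) + fit$ybar
  V <- forwardsolve(t(fit$L), Ks)                         # n x m
  prior_var <- fit$par$sf^2 + fit$par$ss^2
  lat_var <- pmax(prior_var - colSums(V^2), 0)
  sd <- sqrt(lat_var + fit$par$sn^2)
  list(mean = mean, sd = sd)
}
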