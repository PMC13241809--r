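# Normal location-scale normative model with fractional-polynomial age
# smooths:
#
#   LI_i ~ Normal(mu_i, sigma_i)
#   mu_i        = b0 + f_mu(age_i)    + b_sex [male_i] + u_mu[cohort_i]
#   log sigma_i = g0 + f_sigma(age_i) + g_sex [male_i] + u_sigma[cohort_i]
#
# Maximum likelihood by alternating a weighted least-squares update of the
# mu-side coefficients with Fisher-scoring updates of the log-sigma side.
# Cohort offsets are ridge-penalized (Gaussian shrinkage, one penalty
# variance tau^2 per predictor, estimated by an EM update that maximizes the
# Laplace marginal likelihood), with an unpenalized sum-to-zero fixed-effects
# fallback. BIC = -2 loglik + k log(n) with every counted coefficient -
# including sex terms and cohort offsets - contributing one to k.

#' Fitting controls for the normative model
#'
#' @param age_offset years added to age before FP transforms (ages may be 0).
#' @param cohort how cohort enters: `"auto"` (ridge when >= 2 cohorts, else
#'   none), `"ridge"` (penalized offsets, tau^2 estimated), `"fixed"`
#'   (unpenalized sum-to-zero offsets), `"none"`.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum outer iterations.
#' @param max_inner maximum Fisher-scoring steps per log-sigma update.
#' @param tau2_floor lower bound on the estimated cohort-offset variances.
#' @param tau_updates number of outer iterations during which the
#'   cohort-penalty variances are re-estimated by their EM update; afterwards
#'   they are frozen so the coefficient iteration can converge even when the
#'   marginal-likelihood optimum for tau^2 sits at the zero boundary (where
#'   the EM approach is sublinear).
#' @param n_restarts extra jittered starts tried on non-convergence.
#' @param seed seed for the jittered restarts.
#' @return list of controls.
#' @export
fit_control <- function(age_offset = 1, cohort = c("auto", "ridge", "fixed", "none"),
                        tol = 1e-8, max_iter = 200L, max_inner = 10L,
                        tau2_floor = 1e-6, tau_updates = 30L,
                        n_restarts = 3L, seed = 1L) {
  list(age_offset = age_offset, cohort = match.arg(cohort), tol = tol,
       max_iter = as.integer(max_iter), max_inner = as.integer(max_inner),
       tau2_floor = tau2_floor, tau_updates = as.integer(tau_updates),
       n_restarts = as.integer(n_restarts),
       seed = as.integer(seed))
}

#' Fit the normal location-scale normative model
#'
#' Maximizes the Gaussian log-likelihood
#' `sum(-log(2*pi)/2 - log(sigma_i) - (li_i - mu_i)^2 / (2*sigma_i^2))` with
#' `mu` and `log sigma` linear in an intercept, the FP basis of age, a sex
#' indicator (male vs. female reference; dropped automatically when only one
#' sex level is present), and per-cohort offsets.
#'
#' @param observations data.frame with columns `li`, `age_years`, `sex`,
#'   `cohort_id` (a laterality table).
#' @param spec_mu,spec_sigma [fp_spec()] objects (or power vectors) for the
#'   age smooths of the mean and the log-SD.
#' @param control a [fit_control()] list.
#' @return an object of class `normative_model`.
#' @export
fit_location_scale <- function(observations, spec_mu, spec_sigma,
                               control = fit_control()) {
  if (!inherits(spec_mu, "fp_spec")) spec_mu <- fp_spec(spec_mu)
  if (!inherits(spec_sigma, "fp_spec")) spec_sigma <- fp_spec(spec_sigma)
  need <- c("li", "age_years", "sex", "cohort_id")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns: ", paste(need, collapse = ", "))
  }
  y <- as.numeric(observations$li)
  age <- as.numeric(observations$age_years)
  if (anyNA(y) || anyNA(age)) stop("li and age_years must be complete")
  n <- length(y)

  sex_levels <- sort(unique(as.character(observations$sex)))
  has_sex <- length(sex_levels) > 1L
  if (has_sex && !all(sex_levels %in% c("female", "male"))) {
    stop("sex must be coded female/male")
  }
  male <- as.numeric(observations$sex == "male")

  cohorts <- sort(unique(as.character(observations$cohort_id)))
  method <- control$cohort
  if (method == "auto") method <- if (length(cohorts) >= 2L) "ridge" else "none"
  if (method != "none" && length(cohorts) < 2L) method <- "none"

  Bmu <- fp_basis(age, spec_mu, control$age_offset)
  Bsg <- fp_basis(age, spec_sigma, control$age_offset)
  Xmu <- cbind("(Intercept)" = 1, Bmu)
  Xsg <- cbind("(Intercept)" = 1, Bsg)
  if (has_sex) {
    Xmu <- cbind(Xmu, sex_male = male)
    Xsg <- cbind(Xsg, sex_male = male)
  }
  p_mu <- ncol(Xmu); p_sg <- ncol(Xsg)

  C <- length(cohorts)
  ci <- match(observations$cohort_id, cohorts)
  if (method == "ridge") {
    Z <- matrix(0, n, C, dimnames = list(NULL, cohorts))
    Z[cbind(seq_len(n), ci)] <- 1
    q <- C
  } else if (method == "fixed") {
    # sum-to-zero coding: C - 1 free columns, offsets recovered afterwards
    Cmat <- stats::contr.sum(C)
    Z <- matrix(0, n, C, dimnames = list(NULL, cohorts))
    Z[cbind(seq_len(n), ci)] <- 1
    Z <- Z %*% Cmat
    q <- C - 1L
  } else {
    Z <- NULL; q <- 0L
  }
  Amu <- if (q > 0) cbind(Xmu, Z) else Xmu
  Asg <- if (q > 0) cbind(Xsg, Z) else Xsg

  if (n <= p_mu + p_sg + 2L * q) {
    stop("too few observations (", n, ") for ", p_mu + p_sg + 2L * q,
         " parameters")
  }

  # rescale the FP basis columns to unit RMS for numerical conditioning
  # (age^3 spans ~1e6 over a lifespan grid); coefficients and covariance are
  # transformed back afterwards. Intercept, sex and cohort columns untouched.
  scale_fp <- function(A, n_fp) {
    s <- rep(1, ncol(A))
    if (n_fp > 0) {
      i <- 1L + seq_len(n_fp)
      s[i] <- sqrt(colMeans(A[, i, drop = FALSE]^2))
      s[i][s[i] == 0] <- 1
    }
    s
  }
  s_mu <- scale_fp(Amu, ncol(Bmu))
  s_sg <- scale_fp(Asg, ncol(Bsg))
  Amu_s <- sweep(Amu, 2, s_mu, "/")
  Asg_s <- sweep(Asg, 2, s_sg, "/")

  run <- function(init_jitter) {
    fit_irls(y, Amu_s, Asg_s, p_mu, p_sg, q, method, control, init_jitter)
  }
  fit <- run(NULL)
  if (!fit$converged && control$n_restarts > 0L) {
    with_seed(derive_seed(control$seed, "fit_restarts"), {
      for (r in seq_len(control$n_restarts)) {
        jit <- list(mu = stats::rnorm(p_mu + q, 0, 0.05),
                    sg = stats::rnorm(p_sg + q, 0, 0.2))
        cand <- run(jit)
        if (cand$converged ||
            (!fit$converged && cand$loglik > fit$loglik)) fit <- cand
        if (fit$converged) break
      }
    })
  }

  # transform back to the original basis scale
  fit$theta_mu <- fit$theta_mu / s_mu
  fit$theta_sg <- fit$theta_sg / s_sg
  fit$vcov_mu <- fit$vcov_mu / tcrossprod(s_mu)

  # unpack coefficient blocks
  th_mu <- fit$theta_mu; th_sg <- fit$theta_sg
  coef_mu <- th_mu[seq_len(p_mu)]; names(coef_mu) <- colnames(Xmu)
  coef_sg <- th_sg[seq_len(p_sg)]; names(coef_sg) <- colnames(Xsg)
  if (method == "ridge") {
    u_mu <- th_mu[p_mu + seq_len(q)]
    u_sg <- th_sg[p_sg + seq_len(q)]
    names(u_mu) <- names(u_sg) <- cohorts
  } else if (method == "fixed") {
    Cmat <- stats::contr.sum(C)
    u_mu <- drop(Cmat %*% th_mu[p_mu + seq_len(q)])
    u_sg <- drop(Cmat %*% th_sg[p_sg + seq_len(q)])
    names(u_mu) <- names(u_sg) <- cohorts
  } else {
    u_mu <- u_sg <- stats::setNames(numeric(0), character(0))
  }

  # parameter count: every estimated location/scale coefficient counts one,
  # including sex terms and cohort offsets (ridge: C each; fixed: C - 1 free)
  k <- p_mu + p_sg + 2L * q
  bic <- -2 * fit$loglik + k * log(n)

  structure(list(
    spec_mu = spec_mu, spec_sigma = spec_sigma,
    coef_mu = coef_mu, coef_sigma = coef_sg,
    u_mu = u_mu, u_sigma = u_sg,
    tau2_mu = fit$tau2_mu, tau2_sigma = fit$tau2_sg,
    cohort_method = method, cohorts = cohorts,
    has_sex = has_sex, age_offset = control$age_offset,
    age_range = range(age),
    n = n, k = k, loglik = fit$loglik, bic = bic,
    converged = fit$converged, iterations = fit$iterations,
    grad_norm = fit$grad_norm,
    vcov_mu = fit$vcov_mu, vcov_mu_names = colnames(Amu)
  ), class = "normative_model")
}

# alternating penalized-WLS / Fisher-scoring maximizer
fit_irls <- function(y, Amu, Asg, p_mu, p_sg, q, method, control, init_jitter) {
  n <- length(y)
  ridge <- method == "ridge"

  # initialization: OLS for mu, constant log-SD from residuals
  th_mu <- qr.coef(qr(Amu), y)
  th_mu[is.na(th_mu)] <- 0
  r <- y - drop(Amu %*% th_mu)
  th_sg <- c(log(stats::sd(r) + 1e-12), rep(0, ncol(Asg) - 1L))
  if (!is.null(init_jitter)) {
    th_mu <- th_mu + init_jitter$mu[seq_along(th_mu)]
    th_sg <- th_sg + init_jitter$sg[seq_along(th_sg)]
  }
  tau2_mu <- tau2_sg <- if (ridge) 0.01 else Inf

  pen_mu <- function() c(rep(0, p_mu), rep(if (ridge) 1 / tau2_mu else 0, q))
  pen_sg <- function() c(rep(0, p_sg), rep(if (ridge) 1 / tau2_sg else 0, q))
  clamp_eta <- function(e) pmin(pmax(e, log(1e-8)), log(1e3))

  loglik_at <- function(mu, eta) {
    sum(-0.5 * log(2 * pi) - eta - (y - mu)^2 / (2 * exp(2 * eta)))
  }

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  Vmu <- NULL
  for (it in seq_len(control$max_iter)) {
    eta <- clamp_eta(drop(Asg %*% th_sg))
    w <- exp(-2 * eta)  # 1 / sigma^2

    # --- mu step: penalized weighted least squares
    AW <- Amu * w
    H <- crossprod(AW, Amu)
    diag(H) <- diag(H) + pen_mu()
    Vmu <- tryCatch(chol2inv(chol(H)), error = function(e) solve(H))
    th_mu <- drop(Vmu %*% crossprod(AW, y))
    mu <- drop(Amu %*% th_mu)
    r <- y - mu

    if (ridge && q > 0 && it <= control$tau_updates) {
      u <- th_mu[p_mu + seq_len(q)]
      tau2_mu <- max(control$tau2_floor,
                     (sum(u^2) + sum(diag(Vmu)[p_mu + seq_len(q)])) / q)
    }

    # --- sigma step: Fisher scoring on the log-sigma coefficients
    for (inner in seq_len(control$max_inner)) {
      eta <- clamp_eta(drop(Asg %*% th_sg))
      s2 <- exp(2 * eta)
      g_i <- r^2 / s2 - 1                      # d loglik / d eta_i
      G <- drop(crossprod(Asg, g_i)) - pen_sg() * th_sg
      Hs <- 2 * crossprod(Asg)                 # expected information
      diag(Hs) <- diag(Hs) + pen_sg()
      Vsg <- tryCatch(chol2inv(chol(Hs)), error = function(e) solve(Hs))
      step <- drop(Vsg %*% G)
      # step halving on the penalized objective
      obj <- function(th) {
        e <- clamp_eta(drop(Asg %*% th))
        loglik_at(mu, e) - 0.5 * sum(pen_sg() * th^2)
      }
      o0 <- obj(th_sg); alpha <- 1
      for (h in 1:20) {
        th_new <- th_sg + alpha * step
        if (obj(th_new) >= o0 - 1e-12) break
        alpha <- alpha / 2
      }
      th_sg <- th_sg + alpha * step
      if (sqrt(sum((alpha * step)^2)) < 1e-10) break
    }

    if (ridge && q > 0 && it <= control$tau_updates) {
      u <- th_sg[p_sg + seq_len(q)]
      tau2_sg <- max(control$tau2_floor,
                     (sum(u^2) + sum(diag(Vsg)[p_sg + seq_len(q)])) / q)
    }

    eta <- clamp_eta(drop(Asg %*% th_sg))
    ll <- loglik_at(mu, eta)
    if (is.finite(ll) && abs(ll - ll_old) < control$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  eta <- clamp_eta(drop(Asg %*% th_sg))
  mu <- drop(Amu %*% th_mu)
  ll <- loglik_at(mu, eta)

  # gradient norm of the penalized objective at the optimum
  w <- exp(-2 * eta)
  g_mu <- drop(crossprod(Amu, (y - mu) * w)) - pen_mu() * th_mu
  g_sg <- drop(crossprod(Asg, (y - mu)^2 * w - 1)) - pen_sg() * th_sg
  grad_norm <- sqrt(sum(g_mu^2) + sum(g_sg^2))

  list(theta_mu = th_mu, theta_sg = th_sg,
       tau2_mu = if (ridge) tau2_mu else NA_real_,
       tau2_sg = if (ridge) tau2_sg else NA_real_,
       loglik = ll, converged = converged && grad_norm < 1e-3,
       iterations = it, grad_norm = grad_norm, vcov_mu = Vmu)
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative location-scale model (normal family)\n")
  cat("  mu:        ", format(x$spec_mu), "\n")
  cat("  log sigma: ", format(x$spec_sigma), "\n")
  cat(sprintf("  n = %d, k = %d, loglik = %.4f, BIC = %.4f\n",
              x$n, x$k, x$loglik, x$bic))
  cat(sprintf("  cohorts: %d (%s), converged: %s (%d iterations)\n",
              length(x$cohorts), x$cohort_method, x$converged, x$iterations))
  invisible(x)
}

#' Predict the mean and SD of the LI distribution from a fitted model
#'
#' @param object a `normative_model`.
#' @param age ages in years.
#' @param sex `"female"`, `"male"`, or `"average"` (equal-weight average of
#'   the two sex-specific values of `mu` and of `sigma`).
#' @param cohort `"population"` (cohort offsets set to zero) or a fitted
#'   cohort id.
#' @param se whether to also return the standard error of `mu` (delta-method
#'   from the final weighted-least-squares covariance).
#' @param ... unused.
#' @return list with `mu`, `sigma`, and optionally `se_mu`.
#' @export
predict.normative_model <- function(object, age, sex = "average",
                                    cohort = "population", se = FALSE, ...) {
  sex <- match.arg(sex, c("average", "female", "male"))
  one <- function(male_val) {
    Bmu <- fp_basis(age, object$spec_mu, object$age_offset)
    Bsg <- fp_basis(age, object$spec_sigma, object$age_offset)
    xm <- cbind(1, Bmu)
    xs <- cbind(1, Bsg)
    if (object$has_sex) {
      xm <- cbind(xm, male_val)
      xs <- cbind(xs, male_val)
    }
    off_mu <- 0; off_sg <- 0
    if (!identical(cohort, "population")) {
      if (!cohort %in% names(object$u_mu)) stop("unknown cohort: ", cohort)
      off_mu <- object$u_mu[[cohort]]; off_sg <- object$u_sigma[[cohort]]
    }
    list(mu = drop(xm %*% object$coef_mu) + off_mu,
         sigma = exp(drop(xs %*% object$coef_sigma) + off_sg),
         xm = xm)
  }
  res <- if (sex == "average") {
    f <- one(0); m <- one(1)
    list(mu = (f$mu + m$mu) / 2, sigma = (f$sigma + m$sigma) / 2,
         xm = (f$xm + m$xm) / 2)
  } else {
    one(as.numeric(sex == "male"))
  }
  out <- list(mu = res$mu, sigma = res$sigma)
  if (se) {
    # pad with zeros for the cohort-offset columns (population context)
    X <- cbind(res$xm, matrix(0, nrow(res$xm),
                              length(object$vcov_mu_names) - ncol(res$xm)))
    out$se_mu <- sqrt(pmax(0, rowSums((X %*% object$vcov_mu) * X)))
  }
  out
}

#' Select FP specifications for mu and log-sigma by BIC
#'
#' Enumerates fractional-polynomial candidates and returns the converged fit
#' with the lowest BIC. `"staged"` first selects the mu smooth with the
#' log-sigma smooth fixed at a linear age term, then selects the log-sigma
#' smooth with the chosen mu smooth frozen. `"full_grid"` fits every
#' (mu, sigma) pair. Ties are broken by fewer parameters, then by enumeration
#' (lexicographic) order. A per-candidate report is attached as attribute
#' `"selection_report"`.
#'
#' @param observations laterality table (see [fit_location_scale()]).
#' @param power_set permitted FP powers.
#' @param max_order maximum FP order (1-3).
#' @param strategy `"staged"` or `"full_grid"`.
#' @param control a [fit_control()].
#' @return the winning `normative_model`.
#' @export
select_model <- function(observations, power_set = FP_POWER_SET,
                         max_order = 3, strategy = c("staged", "full_grid"),
                         control = fit_control()) {
  strategy <- match.arg(strategy)
  specs <- enumerate_fp_specs(power_set, max_order)
  if (length(specs) < 2L) stop("need at least 2 candidate specifications")

  rows <- list()
  best <- NULL; best_key <- NULL
  try_fit <- function(sm, ss, stage) {
    m <- tryCatch(fit_location_scale(observations, sm, ss, control),
                  error = function(e) NULL)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, spec_mu = format(sm), spec_sigma = format(ss),
      k = if (is.null(m)) NA_integer_ else m$k,
      loglik = if (is.null(m)) NA_real_ else m$loglik,
      bic = if (is.null(m)) NA_real_ else m$bic,
      converged = !is.null(m) && m$converged,
      stringsAsFactors = FALSE
    )
    if (!is.null(m) && m$converged) {
      key <- c(m$bic, m$k, length(rows))   # bic, then fewer params, then order
      if (is.null(best_key) ||
          key[1] < best_key[1] - 1e-12 ||
          (abs(key[1] - best_key[1]) <= 1e-12 && key[2] < best_key[2])) {
        best <<- m; best_key <<- key
      }
    }
    m
  }

  if (strategy == "staged") {
    lin <- fp_spec(1, power_set = union(power_set, 1))
    for (sm in specs) try_fit(sm, lin, "mu")
    if (is.null(best)) stop("no candidate model converged in the mu stage")
    sm_best <- best$spec_mu
    best <- NULL; best_key <- NULL
    for (ss in specs) try_fit(sm_best, ss, "sigma")
  } else {
    for (sm in specs) for (ss in specs) try_fit(sm, ss, "grid")
  }
  if (is.null(best)) stop("no candidate model converged")

  report <- do.call(rbind, rows)
  attr(best, "selection_report") <- report
  best
}
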