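#' Generalized least-squares estimate of the phylogenetic mean
#'
#' \eqn{\hat\mu = (X^T V^{-1} X)^{-1} X^T V^{-1} y} with `X` a column of ones.
#'
#' @param V Positive-definite covariance structure (`n x n`).
#' @param y Trait values, ordered as the rows of `V`.
#' @return The scalar GLS mean.
#' @export
gls_mean <- function(V, y) {
  cs <- chol_stats(V, y)
  if (is.null(cs)) stop("V is singular or not positive definite")
  cs$mu
}

# Cholesky workhorse: whitened solves for the GLS mean, the quadratic form
# Q = (y - mu)' V^{-1} (y - mu), and log|V|. Returns NULL if factorization
# fails (caller decides how to penalize).
chol_stats <- function(V, y) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  z <- backsolve(R, y, transpose = TRUE)
  o <- backsolve(R, rep(1, length(y)), transpose = TRUE)
  oo <- sum(o * o)
  mu <- sum(o * z) / oo
  Q <- sum((z - mu * o)^2)
  list(mu = mu, Q = Q, logdet = 2 * sum(log(diag(R))))
}

#' Exact log-likelihood of traits under a Gaussian phylogenetic model
#'
#' The log-density of \eqn{y \sim \mathrm{MVN}(\mu \mathbf{1}, \sigma^2 V)}:
#' \deqn{-\tfrac12\left[n\ln(2\pi\sigma^2) + \ln|V| +
#'   (y-\mu\mathbf 1)^T V^{-1} (y-\mu\mathbf 1)/\sigma^2\right].}
#' The determinant term is always included so likelihoods are comparable
#' across differently transformed `V`.
#'
#' @param V Covariance structure (unit rate).
#' @param y Trait values ordered as `V`.
#' @param sigma2 Brownian rate variance (> 0).
#' @param mu Phylogenetic mean.
#' @return Log-likelihood (scalar).
#' @export
trait_loglik <- function(V, y, sigma2, mu) {
  stopifnot(sigma2 > 0)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("covariance factorization failed")
  e <- backsolve(R, y - mu, transpose = TRUE)
  n <- length(y)
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + sum(e^2) / sigma2)
}

#' Quadratic-form estimator of the Brownian rate
#'
#' \eqn{\hat\sigma^2 = Q / d} with
#' \eqn{Q = (y-\mu\mathbf 1)^T V^{-1}(y-\mu\mathbf 1)}. The `n - 1`
#' denominator is the conventional reported estimator; the `n` denominator is
#' the maximum-likelihood profile used inside the likelihood search.
#'
#' @param V Covariance structure (already transformed and, for rate-scaled
#'   models, including the \eqn{\theta}-scaled clade part).
#' @param y Trait values ordered as `V`.
#' @param mu Mean (defaults to the GLS estimate).
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return Rate estimate; 0 for a constant trait (boundary, with a warning).
#' @export
sigma2_estimate <- function(V, y, mu = NULL, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  n <- length(y)
  if (n <= 1) stop("need at least two tips")
  cs <- chol_stats(V, y)
  if (is.null(cs)) stop("V is singular or not positive definite")
  if (!is.null(mu)) {
    R <- chol(V)
    e <- backsolve(R, y - mu, transpose = TRUE)
    Q <- sum(e^2)
  } else Q <- cs$Q
  if (Q == 0) warning("constant trait: rate estimate at the zero boundary")
  Q / if (denominator == "n-1") n - 1 else n
}

#' Small-sample Akaike information criterion
#'
#' \eqn{\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param logL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of tips.
#' @return AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc scores
#'
#' @param aiccs Numeric vector of AICc values.
#' @return Weights \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}
#'   summing to 1, names preserved.
#' @export
aicc_weights <- function(aiccs) {
  stopifnot(length(aiccs) >= 1)
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Control settings for maximum-likelihood fitting
#'
#' @param maxit Iteration cap for the bounded quasi-Newton search
#'   (default 100, one run).
#' @param profile_sigma2 If `TRUE` (default) the rate \eqn{\sigma^2} is
#'   profiled analytically at each step (clamped to its bounds) and only the
#'   shape parameters are searched numerically; if `FALSE`, \eqn{\sigma^2}
#'   joins the numerical search, one L-BFGS-B run as in the original method
#'   description. Both routes reach the same optimum on regular problems.
#' @param multi_start If `TRUE`, a small set of extra starting values is
#'   tried and the best kept (default `FALSE`: a single run).
#' @param fixed Named list pinning parameters (e.g. `list(theta = 1)`);
#'   pinned parameters are excluded from the search but still counted in `k`.
#' @return List of class `"fit_control"`.
#' @export
fit_control <- function(maxit = 100L, profile_sigma2 = TRUE,
                        multi_start = FALSE, fixed = list()) {
  structure(list(maxit = as.integer(maxit), profile_sigma2 = profile_sigma2,
                 multi_start = multi_start, fixed = fixed),
            class = "fit_control")
}

SIGMA2_BOUNDS <- c(1e-8, 20)
ALPHA_BOUNDS <- c(1e-8, 2.71)
THETA_BOUNDS_SHIFT <- c(1e-8, 20)
THETA_BOUNDS_EBRATE <- c(1, 20)
R_UPPER <- -1e-6

# parameter table for one model on one tree/clade: start values and bounds
param_setup <- function(model, y, tree_age, clade_age = NULL) {
  s2_start <- min(max(stats::var(y) / tree_age, SIGMA2_BOUNDS[1]), SIGMA2_BOUNDS[2])
  age <- if (model %in% c("nested_EB", "nested_EB_rate", "nested_OU")) clade_age else tree_age
  out <- list()
  if (model %in% c("EB", "nested_EB", "nested_EB_rate")) {
    out$r <- list(start = -0.01, lower = log(1e-5) / age, upper = R_UPPER)
  }
  if (model %in% c("OU", "nested_OU")) {
    out$alpha <- list(start = 0.05, lower = ALPHA_BOUNDS[1], upper = ALPHA_BOUNDS[2])
  }
  if (model %in% c("nested_shift", "nested_EB_rate")) {
    b <- if (model == "nested_shift") THETA_BOUNDS_SHIFT else THETA_BOUNDS_EBRATE
    out$theta <- list(start = min(max(stats::var(y) / tree_age, b[1]), b[2]),
                      lower = b[1], upper = b[2])
  }
  attr(out, "sigma2") <- list(start = s2_start,
                              lower = SIGMA2_BOUNDS[1], upper = SIGMA2_BOUNDS[2])
  out
}

# fast transformer: precomputed pieces -> function(shape params) -> V'
# cl is a clade_selection or NULL for whole-tree models.
make_transformer <- function(V, tree_age, model, cl = NULL) {
  if (model == "BM") return(function(p) V)
  if (model == "EB") return(function(p) eb_map(V, 0, p$r))
  if (model == "OU") return(function(p) ou_map(V, tree_age, p$alpha))
  idx <- cl$tip_idx
  Hc <- V[idx, idx, drop = FALSE] - cl$node_height
  h_par <- cl$node_height - cl$stem
  stem <- cl$stem
  Tc <- cl$stem + cl$crown_depth
  switch(model,
    nested_shift = function(p) {
      V[idx, idx] <- h_par + p$theta * (stem + Hc); V
    },
    nested_OU = function(p) {
      V[idx, idx] <- h_par + ou_map(stem + Hc, Tc, p$alpha); V
    },
    nested_EB = function(p) {
      V[idx, idx] <- h_par + eb_map(Hc, -stem, p$r); V
    },
    nested_EB_rate = function(p) {
      V[idx, idx] <- h_par + p$theta * eb_map(Hc, -stem, p$r); V
    }
  )
}

BIG_NEGLOGLIK <- 1e10

# core ML search shared by fit_model() and the model-comparison engine.
# Returns list(params, logL, converged).
ml_search <- function(trans, y, model, psetup, control) {
  n <- length(y)
  s2b <- attr(psetup, "sigma2")
  fixed <- control$fixed
  free <- setdiff(names(psetup), names(fixed))
  profile <- control$profile_sigma2 && is.null(fixed$sigma2)

  loglik_at <- function(shape, sigma2 = NULL) {
    p <- c(shape, fixed)
    Vt <- trans(p)
    cs <- chol_stats(Vt, y)
    if (is.null(cs)) return(list(logL = -BIG_NEGLOGLIK))
    if (is.null(sigma2)) {
      sigma2 <- min(max(cs$Q / n, s2b$lower), s2b$upper)
    }
    logL <- -0.5 * (n * log(2 * pi * sigma2) + cs$logdet + cs$Q / sigma2)
    list(logL = logL, mu = cs$mu, sigma2 = sigma2)
  }

  starts <- vapply(psetup[free], `[[`, numeric(1), "start")
  lower <- vapply(psetup[free], `[[`, numeric(1), "lower")
  upper <- vapply(psetup[free], `[[`, numeric(1), "upper")
  if (!profile) {
    starts <- c(sigma2 = if (is.null(fixed$sigma2)) s2b$start else NULL, starts)
    if (is.null(fixed$sigma2)) {
      lower <- c(sigma2 = s2b$lower, lower)
      upper <- c(sigma2 = s2b$upper, upper)
    }
  }

  objective <- function(par) {
    par <- as.list(par)
    names(par) <- names(starts)
    s2 <- par$sigma2
    shape <- par[setdiff(names(par), "sigma2")]
    -loglik_at(shape, s2)$logL
  }

  run_one <- function(st) {
    if (!length(st)) {
      return(list(par = numeric(0), value = objective(numeric(0)), convergence = 0L))
    }
    stats::optim(st, objective, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = control$maxit))
  }

  fit <- run_one(starts)
  if (isTRUE(control$multi_start) && length(starts)) {
    for (frac in c(0.1, 0.9)) {
      st <- lower + frac * (upper - lower)
      names(st) <- names(starts)
      alt <- tryCatch(run_one(st), error = function(e) NULL)
      if (!is.null(alt) && alt$value < fit$value) fit <- alt
    }
  }

  par <- as.list(fit$par)
  names(par) <- names(starts)
  shape <- par[setdiff(names(par), "sigma2")]
  best <- loglik_at(shape, par$sigma2)
  params <- c(shape, fixed)
  params$sigma2 <- best$sigma2
  params$mu <- best$mu
  list(params = params, logL = best$logL,
       converged = identical(fit$convergence, 0L) && best$logL > -BIG_NEGLOGLIK)
}

#' Fit one trait-evolution model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) search over the model's shape parameters,
#' with the phylogenetic mean \eqn{\mu} profiled by GLS at every step and the
#' rate \eqn{\sigma^2} either profiled analytically (default) or searched
#' numerically (see [fit_control()]). Starting values and bounds:
#' \eqn{\sigma^2} starts at `var(y) / age` in `[1e-8, 20]`; `r` starts at
#' `-0.01` in `[log(1e-5)/age, -1e-6]` (clade age for the nested EB forms);
#' \eqn{\alpha} starts at `0.05` in `[1e-8, 2.71]`; \eqn{\theta} is bounded
#' `[1, 20]` for `nested_EB_rate` and `[1e-8, 20]` for `nested_shift`.
#'
#' @param phy A `"phylo"` object.
#' @param traits Named numeric vector of tip trait values (names are tip
#'   labels; all tips must be present).
#' @param spec A `"model_spec"`, or a model name for whole-tree models.
#' @param control A [fit_control()] list.
#' @return Object of class `"burst_fit"`: model, shift node (or `NA`), ML
#'   parameter list, `logL`, `k`, `AICc`, `converged`, `n`.
#' @examples
#' phy <- read_newick("((A:1,B:1):1,C:2);")
#' fit_model(phy, c(A = 1, B = 1, C = 0), "BM")
#' @export
fit_model <- function(phy, traits, spec, control = fit_control()) {
  if (is.character(spec)) spec <- model_spec(spec)
  y <- align_traits(phy, traits)
  model <- spec$model
  cl <- spec$clade
  if (!is.null(cl) && !inherits(cl, "clade_selection")) cl <- clade_selection(phy, cl)
  if (model %in% c("OU", "nested_OU")) assert_ultrametric(phy, paste("the", model, "model"))
  V <- vcv_shared_time(phy)
  H <- tree_height(phy)
  clade_age <- if (!is.null(cl)) cl$stem + cl$crown_depth
  psetup <- param_setup(model, y, H, clade_age)
  res <- ml_search(make_transformer(V, H, model, cl), y, model, psetup, control)
  new_burst_fit(model, if (!is.null(cl)) cl$node else NA_integer_,
                res$params, res$logL, length(y), res$converged)
}

new_burst_fit <- function(model, node, params, logL, n, converged) {
  k <- model_k(model)
  ic <- if (n > k + 1) aicc(logL, k, n) else NA_real_  # undefined on tiny trees
  structure(list(model = model, node = node, params = params, logL = logL,
                 k = k, AICc = ic, n = n, converged = converged),
            class = "burst_fit")
}

align_traits <- function(phy, traits) {
  if (is.null(names(traits))) stop("traits must be named by tip label")
  missing <- setdiff(phy$tip.label, names(traits))
  if (length(missing)) {
    stop("traits missing for tips: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(traits), phy$tip.label)
  if (length(extra)) {
    stop("traits given for tips absent from the tree: ",
         paste(extra, collapse = ", "))
  }
  y <- as.numeric(traits[phy$tip.label])
  if (anyNA(y)) stop("traits contain missing values")
  names(y) <- phy$tip.label
  y
}

#' @export
print.burst_fit <- function(x, ...) {
  cat("Model:", x$model,
      if (!is.na(x$node)) paste0("(shift node ", x$node, ")"), "\n")
  pars <- unlist(x$params)
  cat("Parameters:", paste(sprintf("%s = %.6g", names(pars), pars), collapse = ", "), "\n")
  cat(sprintf("logL = %.4f  k = %d  AICc = %.4f  converged = %s\n",
              x$logL, x$k, x$AICc, x$converged))
  invisible(x)
}
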