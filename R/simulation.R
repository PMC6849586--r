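#' Simulate a birth-death tree conditioned on its tip count
#'
#' Draws an ultrametric birth-death tree with exactly `n_tips` extant tips
#' (extinct lineages pruned) and, by default, rescales it to unit height so
#' rate and shape parameters are comparable across trees.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param lambda Speciation rate (default 1).
#' @param mu Extinction rate (default 0.5); must satisfy `lambda > mu >= 0`.
#' @param seed Optional integer seed.
#' @param unit_height Rescale to height 1 (default `TRUE`).
#' @return A `"phylo"` object.
#' @export
simulate_bd_tree <- function(n_tips, lambda = 1, mu = 0.5, seed = NULL,
                             unit_height = TRUE) {
  stopifnot(n_tips >= 3, lambda > mu, mu >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  phy <- NULL
  for (try in 1:25) {
    phy <- tryCatch(ape::rphylo(n_tips, birth = lambda, death = mu, fossils = FALSE),
                    error = function(e) NULL)
    if (!is.null(phy) && ape::Ntip(phy) == n_tips) break
    phy <- NULL
  }
  if (is.null(phy)) stop("birth-death simulation failed after 25 attempts")
  if (unit_height) phy <- scale_to_unit_height(phy)
  phy
}

#' Simulate tip traits under any model of the family
#'
#' One multivariate-normal draw with mean \eqn{\mu\mathbf 1} and covariance
#' \eqn{\sigma^2 V'} where `V'` is the model's transformed shared-time matrix
#' (see [transform_vcv()]); nested transforms therefore need no per-branch
#' recursion.
#'
#' @param phy A `"phylo"` object.
#' @param spec A `"model_spec"` (or model name for whole-tree models).
#' @param params Named list: `sigma2` (default 1), `mu` (default 0), plus the
#'   shape parameters the model needs (`r`, `alpha`, `theta`).
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_traits <- function(phy, spec, params = list(), seed = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sigma2 <- if (is.null(params$sigma2)) 1 else params$sigma2
  mu <- if (is.null(params$mu)) 0 else params$mu
  Vt <- transform_vcv(phy, spec, params)
  R <- tryCatch(chol(sigma2 * Vt), error = function(e) {
    stop("transformed covariance matrix is not positive definite")
  })
  y <- drop(crossprod(R, stats::rnorm(nrow(Vt)))) + mu
  names(y) <- rownames(Vt)
  y
}

#' Draw a random shift node
#'
#' Uniform draw over internal non-root nodes whose descendant tip count
#' satisfies the rule: at least `ceiling(frac * n)` tips
#' (`"at_least_frac"`, the power studies) or at most `floor(frac * n)` tips
#' (`"at_most_frac"`, the misplacement/violation studies).
#'
#' @param phy A `"phylo"` object.
#' @param rule `"at_least_frac"` or `"at_most_frac"`.
#' @param frac Clade-size fraction threshold.
#' @param seed Optional integer seed.
#' @param min_tips Minimum clade size in either rule (default 2).
#' @return A `"clade_selection"`.
#' @export
pick_shift_node <- function(phy, rule = c("at_least_frac", "at_most_frac"),
                            frac = 0.25, seed = NULL, min_tips = 2L) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- ape::Ntip(phy)
  counts <- tip_counts_per_node(phy)
  nodes <- setdiff(seq.int(n + 1L, n + phy$Nnode), n + 1L)
  keep <- if (rule == "at_least_frac") {
    counts[nodes] >= max(ceiling(frac * n), min_tips) & counts[nodes] < n
  } else {
    counts[nodes] <= floor(frac * n) & counts[nodes] >= min_tips
  }
  nodes <- nodes[keep]
  if (!length(nodes)) stop("no node satisfies the clade-size rule")
  clade_selection(phy, if (length(nodes) == 1L) nodes else sample(nodes, 1L))
}

#' Configuration for a simulation study
#'
#' The defaults are the study conditions of the package's validation design:
#' birth-death trees (speciation 1, extinction 0.5) rescaled to unit height;
#' Brownian rate 1; the early-burst exponent expressed as fractions of its
#' maximum magnitude `log(1e-5) / 1` on a unit tree; the OU attraction as the
#' same fractions of its maximum `exp(1)`; clade rate scalars 2, 5 and 10;
#' shift clades holding at least 25\% of the tips (the violation design
#' instead draws clades of at most 5\% while the search still only considers
#' nodes of 25\% and up).
#'
#' @param tree_sizes Tip counts of the simulated trees.
#' @param lambda,mu Birth and death rates.
#' @param gen_models Generating models to study.
#' @param r_fracs Fractions of the maximum \eqn{|r|}.
#' @param theta_levels Clade rate scalars for the rate-shift forms.
#' @param alpha_fracs Fractions of the maximum \eqn{\alpha}.
#' @param n_reps Replicates per cell (default 100; increase towards 1000 for
#'   publication-grade error rates).
#' @param calib_sims Brownian null simulations for penalty calibration per
#'   tree (default 200).
#' @param target_rate Null selection rate the penalties are calibrated to.
#' @param shift_rule,shift_frac Clade-size rule for the generating shift node.
#' @param search_min_frac Candidate-node fraction used by the model search.
#' @param seed Master seed; every tree, calibration and replicate derives its
#'   own stream from it, so reruns and cell subsets reproduce exactly.
#' @return List of class `"sim_study_config"`.
#' @export
sim_study_config <- function(tree_sizes = c(50, 100, 200, 500),
                             lambda = 1, mu = 0.5,
                             gen_models = model_names(),
                             r_fracs = c(0.05, 0.25, 0.5, 0.75, 0.95, 1),
                             theta_levels = c(2, 5, 10),
                             alpha_fracs = c(0.05, 0.25, 0.5, 0.75, 0.95, 1),
                             n_reps = 100L, calib_sims = 200L,
                             target_rate = 0.05,
                             shift_rule = "at_least_frac", shift_frac = 0.25,
                             search_min_frac = 0.25, seed = 1L) {
  structure(list(tree_sizes = tree_sizes, lambda = lambda, mu = mu,
                 gen_models = gen_models, r_fracs = r_fracs,
                 theta_levels = theta_levels, alpha_fracs = alpha_fracs,
                 n_reps = as.integer(n_reps), calib_sims = as.integer(calib_sims),
                 target_rate = target_rate, shift_rule = shift_rule,
                 shift_frac = shift_frac, search_min_frac = search_min_frac,
                 seed = as.integer(seed)),
            class = "sim_study_config")
}

# maximum |r| on a unit-height tree and maximum OU attraction
r_max <- function(height = 1) log(1e-5) / height
alpha_max <- function() exp(1)

# parameter grid (one row per cell) for a generating model
gen_param_grid <- function(model, cfg) {
  switch(model,
    BM = data.frame(row = 1),
    EB = data.frame(r_frac = cfg$r_fracs),
    nested_EB = data.frame(r_frac = cfg$r_fracs),
    OU = data.frame(alpha_frac = cfg$alpha_fracs),
    nested_OU = data.frame(alpha_frac = cfg$alpha_fracs),
    nested_shift = data.frame(theta = cfg$theta_levels),
    nested_EB_rate = expand.grid(r_frac = cfg$r_fracs, theta = cfg$theta_levels)
  )
}

cell_params <- function(model, cell) {
  p <- list(sigma2 = 1, mu = 0)
  if (!is.null(cell$r_frac)) p$r <- cell$r_frac * r_max()
  if (!is.null(cell$alpha_frac)) p$alpha <- cell$alpha_frac * alpha_max()
  if (!is.null(cell$theta)) p$theta <- cell$theta
  p
}

derive_seeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a model-selection simulation study
#'
#' For every tree size: simulates one seeded birth-death tree, calibrates the
#' per-model AICc penalties from Brownian null simulations on that tree, and
#' then for every generating model and parameter cell simulates replicate
#' trait sets (drawing a fresh shift node per replicate for nested models),
#' runs the full calibrated seven-model comparison, and tabulates the winning
#' model proportions.
#'
#' @param config A [sim_study_config()].
#' @param control A [fit_control()].
#' @param verbose Print per-cell progress (default `FALSE`).
#' @return A `"support_table"` data frame: one row per
#'   (generating model, tree size, parameter cell) with the proportion of
#'   replicates won by each candidate model (rows sum to 1 over the model
#'   columns), the replicate count, and the count of failed replicates.
#' @export
run_sim_study <- function(config = sim_study_config(), control = fit_control(),
                          verbose = FALSE) {
  cfg <- config
  models <- model_names()
  rows <- list()
  tree_seeds <- derive_seeds(cfg$seed, 2L * length(cfg$tree_sizes))
  for (ti in seq_along(cfg$tree_sizes)) {
    n_tips <- cfg$tree_sizes[ti]
    phy <- simulate_bd_tree(n_tips, cfg$lambda, cfg$mu, seed = tree_seeds[2 * ti - 1])
    prep <- prepare_tree(phy, cfg$search_min_frac)
    pen <- calibrate_penalties(phy, n_sims = cfg$calib_sims,
                               target_rate = cfg$target_rate,
                               seed = tree_seeds[2 * ti],
                               min_frac = cfg$search_min_frac, control = control)
    for (gm in cfg$gen_models) {
      grid <- gen_param_grid(gm, cfg)
      cell_seeds <- derive_seeds(tree_seeds[2 * ti] + match(gm, models), nrow(grid))
      for (ci in seq_len(nrow(grid))) {
        cell <- as.list(grid[ci, , drop = FALSE])
        res <- run_sim_cell(prep, gm, cell, cfg, pen, control,
                            seed = cell_seeds[ci])
        row <- data.frame(gen_model = gm, n_tips = n_tips,
                          r_frac = if (is.null(cell$r_frac)) NA else cell$r_frac,
                          theta = if (is.null(cell$theta)) NA else cell$theta,
                          alpha_frac = if (is.null(cell$alpha_frac)) NA else cell$alpha_frac,
                          t(res$props), n_reps = res$n_ok, n_failed = res$n_failed)
        rows[[length(rows) + 1L]] <- row
        if (verbose) {
          message(sprintf("%s n=%d cell %d/%d: %s", gm, n_tips, ci, nrow(grid),
                          paste(sprintf("%s=%.2f", models, res$props), collapse = " ")))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("support_table", class(out))
  out
}

# one (generating model, parameter cell): n_reps simulate + calibrated
# comparison; returns winner proportions over the candidate model set
run_sim_cell <- function(prep, gen_model, cell, cfg, penalties, control, seed) {
  models <- model_names()
  pen <- penalty_vector(penalties, models)
  wins <- stats::setNames(numeric(length(models)), models)
  n_failed <- 0L
  rep_seeds <- derive_seeds(seed, cfg$n_reps)
  for (rep in seq_len(cfg$n_reps)) {
    set.seed(rep_seeds[rep])
    params <- cell_params(gen_model, cell)
    spec <- if (gen_model %in% nested_models()) {
      cl <- pick_shift_node(prep$phy, cfg$shift_rule, cfg$shift_frac)
      model_spec(gen_model, cl)
    } else model_spec(gen_model)
    w <- tryCatch({
      y <- simulate_traits(prep$phy, spec, params)
      a <- aicc_all_prepared(prep, y, models, control)
      if (anyNA(a)) stop("fit failure")
      pick_winner(a + pen)
    }, error = function(e) NA_character_)
    if (is.na(w)) n_failed <- n_failed + 1L else wins[w] <- wins[w] + 1
  }
  n_ok <- cfg$n_reps - n_failed
  list(props = if (n_ok > 0) wins / n_ok else wins,
       n_ok = n_ok, n_failed = n_failed)
}
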