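#' Names of the supported trait-evolution models
#'
#' Three whole-tree models (`BM`, `EB`, `OU`) and four nested models in which
#' the background Brownian process switches at the stem of one monophyletic
#' clade: `nested_shift` (clade rate scaled by \eqn{\theta}), `nested_OU`
#' (clade attracted to an optimum with strength \eqn{\alpha}), `nested_EB`
#' (clade rate decays as \eqn{e^{rt}} from the crown node, stem stretched),
#' and `nested_EB_rate` (nested EB with an additional clade rate scalar
#' \eqn{\theta \ge 1}).
#'
#' @return Character vector of the seven model names.
#' @export
model_names <- function() {
  c("BM", "EB", "OU", "nested_shift", "nested_OU", "nested_EB", "nested_EB_rate")
}

nested_models <- function() {
  c("nested_shift", "nested_OU", "nested_EB", "nested_EB_rate")
}

# free-parameter counts (sigma2 and mu always; shift-node position not counted)
model_k <- function(model) {
  k <- c(BM = 2, EB = 3, OU = 3, nested_shift = 3, nested_OU = 3,
         nested_EB = 3, nested_EB_rate = 4)
  unname(k[model])
}

#' Specify a model, optionally with its nested clade
#'
#' @param model One of [model_names()].
#' @param clade A `"clade_selection"` (or shift-node number resolved against
#'   `phy` at fit time); required for the `nested_*` models, disallowed
#'   otherwise.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(model, clade = NULL) {
  model <- match.arg(model, model_names())
  nested <- model %in% nested_models()
  if (nested && is.null(clade)) stop("nested models require a shift clade")
  if (!nested && !is.null(clade)) stop("whole-tree models carry no shift clade")
  structure(list(model = model, clade = clade), class = "model_spec")
}

#' Early-burst transformed length of a branch segment
#'
#' Integrates the exponentially decaying rate \eqn{e^{rt}} over a branch
#' segment running from clade-relative time `t0` to `t1` (the clock starts at
#' the crown node of the burst, so a stem branch has a negative start time and
#' its transformed length exceeds its true length — the "burst"). Returns
#' \eqn{(e^{r t_1} - e^{r t_0})/r}, with the Brownian limit `t1 - t0` used
#' when `|r| * (t1 - t0)` underflows.
#'
#' @param t0,t1 Segment endpoints, `t0 < t1`, in tree time units.
#' @param r Early-burst exponent, strictly negative (1/time).
#' @return Transformed segment length.
#' @examples
#' eb_segment_length(0, 1, -1)        # 1 - exp(-1)
#' eb_segment_length(-0.5, 0, -1)     # exp(0.5) - 1 > 0.5: stem stretched
#' @export
eb_segment_length <- function(t0, t1, r) {
  stopifnot(t0 < t1)
  if (r >= 0) stop("the early-burst exponent r must be negative")
  if (abs(r) * (t1 - t0) < 1e-9) return(t1 - t0)
  (exp(r * t1) - exp(r * t0)) / r
}

# elementwise EB map for a matrix of shared times on a clock starting at 0:
# transformed shared time of a path [t0, s] is (exp(r s) - exp(r t0)) / r
eb_map <- function(S, t0, r) {
  if (abs(r) * max(S - t0) < 1e-9) return(S - t0)
  (exp(r * S) - exp(r * t0)) / r
}

# elementwise OU map: stationary-start OU covariance on an ultrametric clock
# of total depth Tmax; S holds shared times from the clock origin.
ou_map <- function(S, Tmax, alpha) {
  if (alpha < 1e-9) return(S)
  exp(-2 * alpha * (Tmax - S)) * (1 - exp(-2 * alpha * S)) / (2 * alpha)
}

#' Transform the shared-time matrix under a model
#'
#' Produces the unit-rate covariance structure `V'` of each model; tip traits
#' are modelled as multivariate normal with mean \eqn{\mu \mathbf{1}} and
#' covariance \eqn{\sigma^2 V'}. Whole-tree `EB`/`OU` transform every entry on
#' the root clock; nested models leave the background part `V0` untouched and
#' transform (and/or scale by \eqn{\theta}) only the clade-accrued part, with
#' the clade clock starting at the crown node so the stem branch occupies
#' negative time.
#'
#' @param phy A `"phylo"` object.
#' @param spec A `"model_spec"`.
#' @param params Named list with the parameters the model needs: `r` (< 0)
#'   for the EB forms, `alpha` (>= 0) for the OU forms, `theta` (> 0) for
#'   `nested_shift` and `nested_EB_rate`. `sigma2` and `mu` do not enter `V'`.
#' @return `n x n` transformed matrix with tip-label dimnames.
#' @examples
#' phy <- read_newick("((A:1,B:1):1,C:2);")
#' cl <- clade_selection(phy, ape::getMRCA(phy, c("A", "B")))
#' transform_vcv(phy, model_spec("nested_EB", cl), list(r = -1))
#' @export
transform_vcv <- function(phy, spec, params = list()) {
  stopifnot(inherits(spec, "model_spec"))
  V <- vcv_shared_time(phy)
  model <- spec$model
  need <- function(p) {
    if (is.null(params[[p]])) stop("model ", model, " requires parameter '", p, "'")
    params[[p]]
  }
  if (model %in% c("EB", "nested_EB", "nested_EB_rate")) {
    r <- need("r")
    if (r >= 0) stop("the early-burst exponent r must be negative")
  }
  if (model %in% c("OU", "nested_OU")) {
    alpha <- need("alpha")
    if (alpha < 0) stop("alpha must be non-negative")
    assert_ultrametric(phy, paste("the", model, "model"))
  }
  if (model %in% c("nested_shift", "nested_EB_rate")) {
    theta <- need("theta")
    if (theta <= 0) stop("theta must be positive")
    if (model == "nested_EB_rate" && theta < 1) {
      stop("theta must be at least 1 in the nested_EB_rate model")
    }
  }

  if (model == "BM") return(V)
  if (model == "EB") return(eb_map(V, 0, r))
  if (model == "OU") return(ou_map(V, tree_height(phy), alpha))

  cl <- spec$clade
  if (!inherits(cl, "clade_selection")) cl <- clade_selection(phy, cl)
  idx <- cl$tip_idx
  h_par <- cl$node_height - cl$stem          # background time under the clade
  Hc <- V[idx, idx, drop = FALSE] - cl$node_height  # crown-clock shared times
  block <- switch(model,
    nested_shift   = theta * (cl$stem + Hc),
    nested_EB      = eb_map(Hc, -cl$stem, r),
    nested_EB_rate = theta * eb_map(Hc, -cl$stem, r),
    nested_OU      = {
      assert_ultrametric(phy, "the nested_OU model")
      ou_map(cl$stem + Hc, cl$stem + cl$crown_depth, alpha)
    }
  )
  V[idx, idx] <- h_par + block
  V
}
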