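#' Phylogenetic independent contrasts with node heights
#'
#' Felsenstein's standardized contrasts by the pruning algorithm: at each
#' internal node the contrast is \eqn{(x_i - x_j)/\sqrt{b_i + b_j}}, the
#' ancestral value is the branch-length-weighted average, and the parent
#' branch is extended by \eqn{b_i b_j/(b_i + b_j)}. A fully bifurcating
#' `n`-tip tree yields exactly `n - 1` contrasts.
#'
#' @param phy A fully bifurcating `"phylo"` object (polytomies are rejected).
#' @param traits Named trait vector covering every tip.
#' @return Object of class `"contrast_set"`: data frame with `node`,
#'   `height` (time from the root of the contrast node), and `contrast`.
#' @export
pic_contrasts <- function(phy, traits) {
  if (!ape::is.rooted(phy) || !ape::is.binary(phy)) {
    stop("independent contrasts require a rooted, fully bifurcating tree")
  }
  y <- align_traits(phy, traits)
  pics <- ape::pic(y, phy, scaled = TRUE, var.contrasts = FALSE)
  if (any(!is.finite(pics))) {
    stop("contrast undefined: zero-length sister branches give a zero denominator")
  }
  n <- ape::Ntip(phy)
  node <- as.integer(names(pics))
  if (!length(node) || anyNA(node)) node <- seq.int(n + 1L, n + phy$Nnode)
  out <- data.frame(node = node,
                    height = node_heights(phy)[node],
                    contrast = unname(pics))
  class(out) <- c("contrast_set", class(out))
  out
}

#' The node-height test for early-burst signal
#'
#' Regresses the log absolute standardized contrasts on the height (time from
#' the root) of their nodes. Under a constant-rate Brownian process the slope
#' is centred on zero; a significantly negative slope — larger contrasts near
#' the root — is the classic early-burst signature. Contrasts further than
#' `trim_sd` standard deviations from their mean (on the raw contrast scale)
#' can be trimmed before fitting, and an M-estimated robust regression with
#' Huber weights is available in place of ordinary least squares.
#'
#' @param x A `"contrast_set"` from [pic_contrasts()], or a `"phylo"` object
#'   (then `traits` must be supplied).
#' @param traits Named trait vector when `x` is a tree.
#' @param method `"ols"` (default) or `"robust"` (Huber M-regression via
#'   \code{MASS::rlm}; two-sided p-value from the asymptotic normal of the
#'   slope t-statistic).
#' @param trim_sd Optional outlier cut in standard deviations on the raw
#'   contrasts (e.g. 3); `Inf` or `NULL` disables trimming.
#' @return Object of class `"node_height_test"`: `slope`, `intercept`,
#'   `p_value`, `method`, `n_used`, `n_trimmed`, `n_zero_dropped`, and the
#'   underlying regression `fit`.
#' @export
node_height_test <- function(x, traits = NULL, method = c("ols", "robust"),
                             trim_sd = NULL) {
  method <- match.arg(method)
  cs <- if (inherits(x, "contrast_set")) x else pic_contrasts(x, traits)
  keep <- rep(TRUE, nrow(cs))
  n_trimmed <- 0L
  if (!is.null(trim_sd) && is.finite(trim_sd)) {
    m <- mean(cs$contrast); s <- stats::sd(cs$contrast)
    if (s > 0) {
      keep <- abs(cs$contrast - m) <= trim_sd * s
      n_trimmed <- sum(!keep)
    }
  }
  zero <- cs$contrast == 0 & keep
  if (any(zero)) {
    warning(sum(zero), " zero contrast(s) dropped before taking logs")
    keep <- keep & !zero
  }
  d <- data.frame(lc = log(abs(cs$contrast[keep])), h = cs$height[keep])
  if (nrow(d) < 3) stop("fewer than 3 usable contrasts")
  if (method == "ols") {
    fit <- stats::lm(lc ~ h, data = d)
    co <- summary(fit)$coefficients
    p <- co["h", "Pr(>|t|)"]
  } else {
    fit <- MASS::rlm(lc ~ h, data = d, psi = MASS::psi.huber, maxit = 100)
    co <- summary(fit)$coefficients  # columns: Value, Std. Error, t value
    p <- 2 * stats::pnorm(-abs(co["h", "t value"]))
  }
  structure(list(slope = unname(co["h", 1]),
                 intercept = unname(co["(Intercept)", 1]),
                 p_value = unname(p), method = method,
                 n_used = nrow(d), n_trimmed = n_trimmed,
                 n_zero_dropped = sum(zero), fit = fit),
            class = "node_height_test")
}

#' @export
print.node_height_test <- function(x, ...) {
  cat(sprintf("Node-height test (%s): slope = %.5f, intercept = %.5f, p = %.4g\n",
              x$method, x$slope, x$intercept, x$p_value))
  cat(sprintf("contrasts used: %d (trimmed %d, zero dropped %d)\n",
              x$n_used, x$n_trimmed, x$n_zero_dropped))
  invisible(x)
}
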