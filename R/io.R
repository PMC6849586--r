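#' Read a tip-trait table
#'
#' Two-column delimited text with a header (`tip,value` or tab-separated;
#' the delimiter is autodetected from the header line unless given).
#'
#' @param path File path.
#' @param tree Optional `"phylo"`; when supplied the label sets are checked
#'   and every mismatched tip is named in the error.
#' @param sep Optional explicit delimiter overriding autodetection.
#' @return Named numeric vector of trait values.
#' @export
read_traits <- function(path, tree = NULL, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2L) stop("trait table must have exactly two columns (tip, value)")
  tips <- as.character(tab[[1]])
  vals <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(vals)) {
    stop("non-numeric trait values for tips: ",
         paste(tips[is.na(vals)], collapse = ", "))
  }
  if (anyDuplicated(tips)) {
    stop("duplicate tips in trait table: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  y <- stats::setNames(vals, tips)
  if (!is.null(tree)) {
    miss <- setdiff(tree$tip.label, tips)
    extra <- setdiff(tips, tree$tip.label)
    if (length(miss) || length(extra)) {
      stop("trait/tree label mismatch; missing from table: [",
           paste(miss, collapse = ", "), "]; absent from tree: [",
           paste(extra, collapse = ", "), "]")
    }
    y <- y[tree$tip.label]
  }
  y
}

#' Flatten a fit to a one-row table
#'
#' @param fit A `"burst_fit"`.
#' @return One-row data frame: model, node, parameters, logL, k, AICc,
#'   convergence flag.
#' @export
fit_to_row <- function(fit) {
  stopifnot(inherits(fit, "burst_fit"))
  pars <- c(sigma2 = NA_real_, mu = NA_real_, r = NA_real_,
            alpha = NA_real_, theta = NA_real_)
  pars[names(fit$params)] <- unlist(fit$params)
  data.frame(model = fit$model, node = fit$node, t(pars), logL = fit$logL,
             k = fit$k, AICc = fit$AICc, converged = fit$converged,
             row.names = NULL)
}

#' Serialize results to JSON
#'
#' `"burst_fit"`, `"model_selection"` and `"penalty_table"` objects all have
#' a flat JSON form used by the command-line tools.
#'
#' @param x Object to serialize.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "burst_fit")) {
    list(model = x$model, node = x$node, params = x$params, logL = x$logL,
         k = x$k, AICc = x$AICc, converged = x$converged)
  } else if (inherits(x, "model_selection")) {
    list(winner = x$winner, table = x$table, penalties = as.list(x$penalties),
         errors = as.list(x$errors))
  } else if (inherits(x, "penalty_table")) {
    list(penalties = as.list(x$penalties), beta = x$beta,
         null_error_rate = x$null_error_rate, n_sims = x$n_sims,
         target_rate = x$target_rate, seed = x$seed, min_frac = x$min_frac)
  } else x
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Generate a deterministic bundle of example trees and trait sets
#'
#' Writes small birth-death trees (8, 50 and 100 tips, unit height) as Newick
#' and one trait set per model as CSV, with a JSON manifest recording the
#' generating model, parameters and shift node of every file. The same seed
#' reproduces the bundle byte for byte.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 20L)
  sizes <- c(8, 50, 100)
  trees <- list()
  for (i in seq_along(sizes)) {
    phy <- simulate_bd_tree(sizes[i], seed = seeds[i])
    ape::write.tree(phy, file.path(out_dir, sprintf("tree_%dtip.nwk", sizes[i])))
    trees[[as.character(sizes[i])]] <- phy
  }
  phy <- trees[["50"]]
  manifest <- list(seed = seed, trees = sprintf("tree_%dtip.nwk", sizes),
                   traits = list())
  gen <- list(
    BM = list(),
    EB = list(r = 0.5 * r_max()),
    OU = list(alpha = 0.5 * alpha_max()),
    nested_shift = list(theta = 5),
    nested_OU = list(alpha = 0.5 * alpha_max()),
    nested_EB = list(r = 0.75 * r_max()),
    nested_EB_rate = list(r = 0.5 * r_max(), theta = 5)
  )
  for (i in seq_along(gen)) {
    m <- names(gen)[i]
    set.seed(seeds[5L + i])
    spec <- if (m %in% nested_models()) {
      model_spec(m, pick_shift_node(phy, "at_least_frac", 0.25))
    } else model_spec(m)
    params <- c(gen[[m]], list(sigma2 = 1, mu = 0))
    y <- simulate_traits(phy, spec, params)
    f <- sprintf("traits_%s.csv", m)
    utils::write.csv(data.frame(tip = names(y), value = unname(y)),
                     file.path(out_dir, f), row.names = FALSE, quote = FALSE)
    manifest$traits[[m]] <- list(
      file = f, tree = "tree_50tip.nwk", params = params,
      shift_node = if (m %in% nested_models()) spec$clade$node else NULL)
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# machine-readable provenance record for command-line runs
write_provenance <- function(path, args, seed, extra = list()) {
  rec <- c(list(package = "burstshift",
                version = as.character(utils::packageVersion("burstshift")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed, args = args), extra)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(rec)
}
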