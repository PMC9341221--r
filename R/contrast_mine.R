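#' Mine and prioritize contrasted subgroup pairs
#'
#' The top-level fitting function: runs the guided cascading shotgun search
#' over all population variables of \code{data}, evaluating every visited
#' subgroup pair by its effective contrast patterns and J value, then ranks
#' the candidate pool with the Bayesian-average size-modified J against a
#' random-subgroup baseline drawn before path expansion.
#'
#' @param data A \code{cm_data} (see \code{\link{encode_dataset}}).
#' @param control An \code{\link{explore_control}}.
#' @param store_patterns Keep the effective patterns of every evaluated pair
#'   in the result (default TRUE; they live in the evaluation registry).
#' @return Object of class \code{"contrast_mine"} with components
#'   \code{pool} (ranked candidate data.frame), \code{baseline},
#'   \code{growth_max}, \code{control}, \code{counts} and the registry.
#' @examples
#' def <- as_definition(list(
#'   sex = list(role = "population", categories = c("F", "M")),
#'   age = list(role = "population", categories = c("young", "old")),
#'   g1  = list(role = "measurement", categories = c("A", "B"))))
#' set.seed(7)
#' tab <- data.frame(sex = sample(c("F", "M"), 120, TRUE),
#'                   age = sample(c("young", "old"), 120, TRUE),
#'                   g1 = sample(c("A", "B"), 120, TRUE))
#' tab$g1[tab$sex == "F"] <- "A"   # plant a trivial contrast
#' d <- encode_dataset(tab, def)
#' fit <- contrast_mine(d, explore_control(max_vars = 2, expand_p = 1,
#'                      mining = mining_control(min_side = 5, growth_max = 10),
#'                      baseline_k = 10))
#' head(summary(fit))
#' @export
contrast_mine <- function(data, control = explore_control(),
                          store_patterns = TRUE) {
  stopifnot(inherits(data, "cm_data"), inherits(control, "explore_control"))
  set.seed(control$seed)
  registry <- new_registry()
  mc <- control$mining
  if (is.null(mc$growth_max)) {
    mc$growth_max <- estimate_growth_max(data, mc, control$max_vars)
    control$mining$growth_max <- mc$growth_max
  }
  control$mining <- mc
  baseline <- sample_baseline(data, control$baseline_k, mc,
                              control$max_vars, seed = NULL,
                              registry = registry)
  gcs <- gcs_expand(data, control, registry)
  pool <- gcs_pool(gcs)
  evaluated <- pool[pool$status != "pruned-trivial", , drop = FALSE]
  ok <- evaluated$n_pair > 0
  evaluated$j_mod <- NA_real_
  evaluated$j_mod[ok] <- size_modified_j(evaluated$j_ori[ok],
                                         evaluated$n_pair[ok], baseline,
                                         control$size_preference)
  evaluated$j_mod[!ok] <- 0
  ranked <- rank_subgroups(evaluated)
  ranked$definition <- vapply(ranked$key, function(k)
    format(subgroup_from_key(k)), "")
  structure(list(pool = ranked, baseline = baseline,
                 growth_max = mc$growth_max, control = control,
                 counts = list(evaluated = nrow(evaluated),
                               mining_calls = registry$mining_calls,
                               registry = registry_size(registry)),
                 registry = if (store_patterns) registry else NULL),
            class = "contrast_mine")
}

# estimated maximal growth of patterns appearing in random subgroup pairs;
# a user-supplied growth_max overrides this
estimate_growth_max <- function(data, control, max_vars, k = 20L) {
  lmax <- min(max_vars, length(data$pop_vars))
  x <- data$x[, data$meas_vars, drop = FALSE]
  gmax <- 0
  for (i in seq_len(k)) {
    scg <- random_subgroup(data, lmax)
    sp <- split_population(data, scg)
    n1 <- length(sp$side1); n2 <- length(sp$side2)
    if (n1 < control$min_side || n2 < control$min_side) next
    f1 <- freq_itemsets_int(x[sp$side1, , drop = FALSE],
                            control$alpha_support, control$max_pattern_len)
    f2 <- freq_itemsets_int(x[sp$side2, , drop = FALSE],
                            control$alpha_support, control$max_pattern_len)
    for (s in c(f1, f2)) {
      c1 <- count_pattern_rows(x, s$col, s$code, sp$side1)
      c2 <- count_pattern_rows(x, s$col, s$code, sp$side2)
      if (c1 > 0 && c2 > 0)
        gmax <- max(gmax, (max(c1 / n1, c2 / n2)) / (min(c1 / n1, c2 / n2)))
    }
  }
  max(gmax, 2 * control$beta_growth)
}

#' @export
print.contrast_mine <- function(x, ...) {
  cat("Contrast subgroup mining\n")
  cat("  evaluated subgroup pairs:", x$counts$evaluated,
      "( mining calls:", x$counts$mining_calls, ")\n")
  cat("  growth cap:", signif(x$growth_max, 4),
      " baseline J-bar:", signif(x$baseline$j_bar, 4), "\n")
  top <- utils::head(x$pool, 3L)
  if (nrow(top)) {
    cat("  top candidates:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("   %2d. J=%d  J_mod=%.3f  n=%d  %s\n", i, top$j_ori[i],
                  top$j_mod[i], as.integer(top$n_pair[i]),
                  top$definition[i]))
  }
  invisible(x)
}

#' @export
summary.contrast_mine <- function(object, n = 10L, ...) {
  out <- utils::head(object$pool[, c("rank", "definition", "layer", "n_pair",
                                     "j_ori", "j_mod", "n_patterns")], n)
  rownames(out) <- NULL
  out
}

#' @export
plot.contrast_mine <- function(x, ...) {
  pool <- x$pool
  graphics::plot(pool$rank, pool$j_mod, type = "h",
                 xlab = "candidate rank", ylab = "size-modified J",
                 main = "Ranked contrast subgroup candidates", ...)
  graphics::points(pool$rank, pool$j_ori, pch = 20, cex = 0.4,
                   col = "grey40")
  invisible(x)
}

#' Effective patterns of one mined candidate
#' @param fit A \code{contrast_mine} object (built with
#'   \code{store_patterns = TRUE}).
#' @param key Canonical key of the candidate (or its rank as an integer).
#' @return A \code{contrast_patterns} data.frame.
#' @export
cohort_patterns <- function(fit, key) {
  stopifnot(inherits(fit, "contrast_mine"))
  if (is.null(fit$registry)) stop("fit was built with store_patterns = FALSE")
  if (is.numeric(key)) key <- fit$pool$key[fit$pool$rank == key]
  hit <- get0(key, envir = fit$registry$store)
  if (is.null(hit)) stop("no such candidate: ", key)
  hit$patterns
}

#' Write the ranked cohort table
#' @param fit A \code{contrast_mine} object.
#' @param path Output TSV path; a JSON mirror is written next to it.
#' @export
write_ranked_cohorts <- function(fit, path) {
  df <- fit$pool[, c("rank", "key", "definition", "layer", "n_pair",
                     "j_ori", "j_mod", "n_patterns")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, sub("\\.tsv$", ".json", path), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
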