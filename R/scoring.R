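#' J value of a set of normalized growths
#'
#' A g-index-style score: sort the values in decreasing order; J is the
#' largest integer such that the top J values sum to at least J^2.
#'
#' @param growth_norms Non-negative numeric vector (one value per effective
#'   contrast pattern).
#' @return Non-negative integer (0 for empty input).
#' @export
j_value <- function(growth_norms) {
  if (length(growth_norms) == 0L) return(0L)
  if (any(growth_norms < 0)) stop("normalized growths must be non-negative")
  cs <- cumsum(sort(growth_norms, decreasing = TRUE))
  j <- seq_along(cs)
  ok <- which(j^2 <= cs + 1e-9)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Baseline statistics from random contrast subgroups
#'
#' Draws \code{k} uniformly random valid contrast subgroup pairs (1 to
#' \code{max_vars} population variables, a random pair of distinct non-NA
#' categories per variable), evaluates each with the full contrast-mining
#' pipeline, and returns the mean J and mean population size used by the
#' Bayesian-average size modification.
#'
#' @param data A \code{cm_data}.
#' @param k Number of random subgroup pairs (default 100).
#' @param control A \code{\link{mining_control}}.
#' @param max_vars Maximal number of population variables per draw.
#' @param seed Optional seed for reproducibility; when \code{NULL} the current
#'   RNG state is used.
#' @param registry Optional evaluation registry (see
#'   \code{\link{new_registry}}) shared with a surrounding search.
#' @return List of class \code{"baseline_stats"} with \code{j_bar},
#'   \code{m_bar}, \code{k}, \code{seed}, and the per-draw values.
#' @export
sample_baseline <- function(data, k = 100L, control = mining_control(),
                            max_vars = 3L, seed = NULL, registry = NULL) {
  stopifnot(inherits(data, "cm_data"), k >= 1L)
  if (length(data$pop_vars) == 0L)
    stop("dataset has no population variables")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(registry)) registry <- new_registry()
  lmax <- min(max_vars, length(data$pop_vars))
  js <- numeric(k); sizes <- numeric(k)
  for (i in seq_len(k)) {
    scg <- random_subgroup(data, lmax)
    ev <- evaluate_subgroup(data, scg, control, registry)
    js[i] <- ev$j$j_ori
    sizes[i] <- ev$j$n_pair
  }
  structure(list(j_bar = mean(js), m_bar = mean(sizes), k = k,
                 seed = seed, j = js, sizes = sizes),
            class = "baseline_stats")
}

random_subgroup <- function(data, lmax) {
  nv <- sample.int(lmax, 1L)
  vars <- sample(data$pop_vars, nv)
  pairs <- lapply(vars, function(v) {
    cats <- setdiff(data$schema[[v]]$categories, NA_LABEL)
    cc <- sample(cats, 2L)
    contrast_pair(v, cc[1L], cc[2L])
  })
  contrast_subgroup(pairs)
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat("Baseline over", x$k, "random subgroup pairs: J-bar =",
      signif(x$j_bar, 4), " mean size =", signif(x$m_bar, 5), "\n")
  invisible(x)
}

#' Size-modified J value (Bayesian average)
#'
#' Blends a subgroup pair's J with the random baseline mean, weighted by the
#' pair's population size \code{n_pair} (preference \code{"larger"}) or its
#' reciprocal (preference \code{"smaller"}):
#' \code{(N * j_ori + m_bar * j_bar) / (N + m_bar)}.
#'
#' @param j_ori Original J value.
#' @param n_pair Population size of the pair (|side1| + |side2| > 0).
#' @param baseline A \code{baseline_stats} object (or a list with
#'   \code{j_bar} and \code{m_bar}).
#' @param preference \code{"larger"} or \code{"smaller"}.
#' @return Numeric score between \code{min(j_ori, j_bar)} and
#'   \code{max(j_ori, j_bar)}.
#' @export
size_modified_j <- function(j_ori, n_pair, baseline,
                            preference = c("larger", "smaller")) {
  preference <- match.arg(preference)
  if (any(n_pair <= 0)) stop("n_pair must be positive")
  N <- if (preference == "larger") n_pair else 1 / n_pair
  (N * j_ori + baseline$m_bar * baseline$j_bar) / (N + baseline$m_bar)
}

#' Rank candidate subgroup pairs
#'
#' Sorts a candidate pool by decreasing score (\code{j_mod} when present,
#' otherwise \code{j_ori}); ties are broken by canonical key so the order is
#' total and deterministic.
#'
#' @param candidates data.frame with columns \code{key}, \code{j_ori} and
#'   optionally \code{j_mod}.
#' @return The same data.frame, reordered, with a \code{rank} column.
#' @export
rank_subgroups <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  score <- if (!is.null(candidates$j_mod)) candidates$j_mod else candidates$j_ori
  ord <- order(-score, candidates$key)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
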