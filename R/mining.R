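#' Mining thresholds and options
#'
#' Bundles the thresholds of the effective-contrast-pattern extraction:
#' minimum support \code{alpha_support} (a pattern must be frequent in at
#' least one side), minimum growth \code{beta_growth} (normally > 2 so a
#' pattern appears at least twice as often on one side), the normalization
#' cap \code{growth_max}, the maximum pattern length, and the outer-group
#' significance screen.
#'
#' @param alpha_support Minimum support in (0, 1]; default 0.5.
#' @param beta_growth Minimum growth ratio >= 1; default 2.
#' @param growth_max Normalization cap (> \code{beta_growth}); \code{NULL}
#'   means "estimate from random subgroup pairs" inside
#'   \code{\link{contrast_mine}} (default 10 when used standalone).
#' @param max_pattern_len Maximum number of items per pattern; default 3.
#' @param outer_filter Apply the outer-group Fisher screen before J
#'   computation (default TRUE).
#' @param outer_p_cutoff Two-sided significance level for the outer screen.
#' @param bh_adjust Apply Benjamini-Hochberg adjustment across the patterns
#'   of one subgroup pair before thresholding (default FALSE; the screen is
#'   per-pattern with no multiplicity correction).
#' @param min_side Minimum records per side; smaller splits score J = 0.
#' @return List of class \code{"mining_control"}.
#' @export
mining_control <- function(alpha_support = 0.5, beta_growth = 2,
                           growth_max = NULL, max_pattern_len = 3L,
                           outer_filter = TRUE, outer_p_cutoff = 0.05,
                           bh_adjust = FALSE, min_side = 20L) {
  stopifnot(alpha_support > 0, alpha_support <= 1, beta_growth >= 1,
            max_pattern_len >= 1L, outer_p_cutoff > 0, min_side >= 1L)
  if (!is.null(growth_max) && growth_max <= beta_growth)
    stop("growth_max must exceed beta_growth")
  structure(list(alpha_support = alpha_support, beta_growth = beta_growth,
                 growth_max = growth_max,
                 max_pattern_len = as.integer(max_pattern_len),
                 outer_filter = isTRUE(outer_filter),
                 outer_p_cutoff = outer_p_cutoff,
                 bh_adjust = isTRUE(bh_adjust),
                 min_side = as.integer(min_side)),
            class = "mining_control")
}

# coerce user-facing record containers (data.frame / character matrix /
# cm_data rows) to an integer-coded matrix with per-column category levels
as_record_matrix <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      !is.null(records$x) && is.matrix(records$x))
    return(list(x = records$x,
                levels = lapply(colnames(records$x), function(v)
                  records$schema[[v]]$categories)))
  if (is.data.frame(records)) {
    nm <- names(records)
    records <- vapply(records, as.character, character(nrow(records)))
    if (is.null(dim(records)))
      records <- matrix(records, ncol = length(nm), dimnames = list(NULL, nm))
    if (nrow(records) == 0L)
      return(list(x = matrix(0L, 0L, ncol(records),
                             dimnames = list(NULL, nm)),
                  levels = rep(list(character(0)), ncol(records))))
  }
  if (is.matrix(records) && is.character(records)) {
    lev <- lapply(seq_len(ncol(records)), function(j)
      sort(unique(records[, j])))
    x <- vapply(seq_len(ncol(records)), function(j)
      match(records[, j], lev[[j]]), integer(nrow(records)))
    if (is.null(dim(x))) x <- matrix(x, nrow = nrow(records))
    colnames(x) <- colnames(records)
    return(list(x = x, levels = lev))
  }
  if (is.matrix(records) && is.numeric(records)) {
    lev <- lapply(seq_len(ncol(records)), function(j)
      as.character(seq_len(max(records[, j], 1L))))
    return(list(x = records, levels = lev))
  }
  stop("records must be a data.frame, character matrix or integer matrix")
}

pattern_id <- function(vars, cats) {
  ord <- order(vars)
  paste0(vars[ord], "=", cats[ord], collapse = "&")
}

# pattern as named character vector -> (col idx, code) on a record matrix
pattern_codes <- function(pattern, rm) {
  vars <- names(pattern)
  if (is.null(vars)) stop("a pattern is a named character vector (var = category)")
  col <- match(vars, colnames(rm$x))
  if (anyNA(col)) stop("pattern variable(s) absent: ",
                       paste(vars[is.na(col)], collapse = ", "))
  code <- vapply(seq_along(col), function(i)
    match(pattern[i], rm$levels[[col[i]]]), integer(1L))
  list(col = col, code = code)
}

count_pattern_rows <- function(x, col, code, rows) {
  if (length(rows) == 0L) return(0L)
  m <- x[rows, col[1L]] == code[1L]
  if (length(col) > 1L) for (i in 2L:length(col))
    m <- m & (x[rows, col[i]] == code[i])
  sum(m, na.rm = TRUE)
}

#' Support of a pattern in a record group
#'
#' The fraction of the group's records containing every item of the pattern.
#'
#' @param pattern Named character vector: \code{c(var = category, ...)}, at
#'   most one item per measurement variable.
#' @param group Records: a data.frame or character matrix of categorical
#'   columns (one row per record).
#' @return Support in [0, 1].
#' @export
pattern_support <- function(pattern, group) {
  rm <- as_record_matrix(group)
  n <- nrow(rm$x)
  if (n == 0L) stop("support is undefined for an empty group")
  pc <- pattern_codes(pattern, rm)
  if (anyNA(pc$code)) return(0)   # item category absent from the group
  count_pattern_rows(rm$x, pc$col, pc$code, seq_len(n)) / n
}

# ---- frequent itemset mining (levelwise, Apriori property) ----------------
# x: integer record matrix (rows = records of one group). Returns a list of
# itemsets: each a list(col = int vec, code = int vec, count = int).
freq_itemsets_int <- function(x, alpha, max_len) {
  n <- nrow(x)
  if (n == 0L) stop("cannot mine an empty group")
  eps <- 1e-12
  # frequent single items
  items <- list(); k <- 0L
  for (j in seq_len(ncol(x))) {
    tab <- tabulate(x[, j])
    for (cat in which(tab / n >= alpha - eps)) {
      k <- k + 1L
      items[[k]] <- list(col = j, code = cat, count = tab[cat])
    }
  }
  if (k == 0L) return(list())
  # indicator matrix over frequent items, ordered by (col, code)
  ord <- order(vapply(items, `[[`, 0L, "col"), vapply(items, `[[`, 0L, "code"))
  items <- items[ord]
  ind <- vapply(items, function(it) x[, it$col] == it$code, logical(n))
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = n)
  item_col <- vapply(items, `[[`, 0L, "col")

  res <- lapply(items, function(it)
    list(col = it$col, code = it$code, count = it$count, set = NULL))
  for (i in seq_along(items)) res[[i]]$set <- i

  level <- lapply(seq_along(items), function(i) i)  # item-index vectors
  all_levels <- list(level)
  len <- 1L
  while (len < max_len && length(level) > 1L) {
    keys <- vapply(level, paste, "", collapse = ",")
    keyset <- new.env(parent = emptyenv())
    for (kk in keys) assign(kk, TRUE, envir = keyset)
    nxt <- list(); cnt <- 0L
    for (a in seq_along(level)) {
      sa <- level[[a]]
      for (b in seq_along(level)) {
        if (b <= a) next
        sb <- level[[b]]
        # join: share the first len-1 items
        if (len > 1L && !identical(sa[-len], sb[-len])) next
        cand <- sort(unique(c(sa, sb)))
        if (length(cand) != len + 1L) next
        if (anyDuplicated(item_col[cand])) next   # one item per variable
        # Apriori prune: all len-subsets frequent
        ok <- TRUE
        if (len >= 2L) for (d in seq_along(cand)) {
          if (!exists(paste(cand[-d], collapse = ","), envir = keyset)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        m <- ind[, cand[1L]]
        for (d in 2L:length(cand)) m <- m & ind[, cand[d]]
        cm <- sum(m)
        if (cm / n >= alpha - eps) {
          cnt <- cnt + 1L
          nxt[[cnt]] <- cand
          res[[length(res) + 1L]] <- list(col = item_col[cand],
                                          code = vapply(items[cand], `[[`,
                                                        0L, "code"),
                                          count = cm, set = cand)
        }
      }
    }
    level <- nxt
    len <- len + 1L
  }
  res
}

#' Mine frequent measurement patterns in a group
#'
#' Returns exactly the patterns of length at most \code{max_len} whose support
#' in the group is at least \code{alpha}, together with their supports. The
#' result satisfies the Apriori property: every shorter subset of a returned
#' pattern is also returned.
#'
#' @param group Records (data.frame or character matrix).
#' @param alpha Minimum support in (0, 1].
#' @param max_len Maximum items per pattern.
#' @return data.frame with columns \code{pattern} (list of named character
#'   vectors), \code{id}, \code{len}, \code{support}.
#' @export
mine_frequent_patterns <- function(group, alpha, max_len = 3L) {
  stopifnot(alpha > 0, alpha <= 1)
  rm <- as_record_matrix(group)
  sets <- freq_itemsets_int(rm$x, alpha, as.integer(max_len))
  n <- nrow(rm$x)
  vars <- colnames(rm$x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(rm$x)))
  pats <- lapply(sets, function(s) {
    p <- vapply(seq_along(s$col), function(i)
      rm$levels[[s$col[i]]][s$code[i]], "")
    names(p) <- vars[s$col]
    p[order(names(p))]
  })
  data.frame(
    pattern = I(pats),
    id = vapply(pats, function(p) pattern_id(names(p), unname(p)), ""),
    len = vapply(sets, function(s) length(s$col), 0L),
    support = vapply(sets, `[[`, 0L, "count") / n,
    stringsAsFactors = FALSE)
}

#' Growth rate of a contrast pattern
#'
#' \code{Max(s1, s2) / Min(s1, s2)}. When one support is zero (a "jumping"
#' pattern) the finite cap \code{growth_max} is returned; finite ratios above
#' the cap are likewise capped when \code{growth_max} is finite.
#'
#' @param s1,s2 Supports of the pattern in the two sides (not both zero).
#' @param growth_max Cap; default \code{Inf} (no capping of finite ratios).
#' @return Growth ratio >= 1.
#' @export
growth_rate <- function(s1, s2, growth_max = Inf) {
  if (any(s1 < 0) || any(s2 < 0)) stop("supports must be non-negative")
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  if (any(hi == 0)) stop("growth is undefined when both supports are zero")
  g <- ifelse(lo > 0, hi / lo, growth_max)
  pmin(g, growth_max)
}

#' Tanh-normalized growth
#'
#' \code{tanh(g / growth_max) * growth_max}: strictly increasing in \code{g}
#' and bounded above by \code{growth_max}.
#'
#' @param g Growth ratio(s) (>= 1, possibly capped).
#' @param growth_max Positive normalization cap.
#' @return Normalized growth in (0, growth_max).
#' @export
growth_norm <- function(g, growth_max) {
  if (growth_max <= 0) stop("growth_max must be positive")
  tanh(g / growth_max) * growth_max
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities (via
#' \code{stats::dhyper}, conditioning on the margins) no larger than that of
#' the observed table — the same convention as
#' \code{stats::fisher.test(alternative = "two.sided")}, computed without the
#' conditional-odds-ratio machinery so it is cheap enough for per-pattern
#' screening.
#'
#' @param table 2x2 matrix (or 4 counts, column-major) of non-negative counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- matrix(as.numeric(table), 2L, 2L)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("table must have a positive total")
  # degenerate margins: only one table possible
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  m <- tab[1L, 1L] + tab[1L, 2L]
  n2 <- tab[2L, 1L] + tab[2L, 2L]
  k <- tab[1L, 1L] + tab[2L, 1L]
  probs <- stats::dhyper(max(0, k - n2):min(k, m), m, n2, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Outer-group significance of a pattern
#'
#' Tests whether the pattern is significantly more prevalent inside the
#' subgroup pair than in the remaining population, via a two-sided Fisher
#' exact test on presence/absence by inner/outer membership. An empty outer
#' group passes by definition.
#'
#' @param pattern Named character vector.
#' @param inner Records of side1 and side2 combined.
#' @param outer Records of the outer group.
#' @param p_cutoff Significance level (default 0.05).
#' @return TRUE iff p < p_cutoff and the inner prevalence exceeds the outer.
#' @export
outer_significant <- function(pattern, inner, outer, p_cutoff = 0.05) {
  rmi <- as_record_matrix(inner)
  ni <- nrow(rmi$x)
  if (ni == 0L) stop("inner group must be non-empty")
  rmo <- as_record_matrix(outer)
  no <- nrow(rmo$x)
  if (no == 0L) return(TRUE)
  pci <- pattern_codes(pattern, rmi)
  ci <- if (anyNA(pci$code)) 0L else
    count_pattern_rows(rmi$x, pci$col, pci$code, seq_len(ni))
  pco <- pattern_codes(pattern, rmo)
  co <- if (anyNA(pco$code)) 0L else
    count_pattern_rows(rmo$x, pco$col, pco$code, seq_len(no))
  p <- fisher_exact_2x2(matrix(c(ci, ni - ci, co, no - co), 2L))
  (p < p_cutoff) && (ci / ni > co / no)
}

# internal: fisher screen on counts
outer_screen_counts <- function(ci, ni, co, no) {
  vapply(seq_along(ci), function(i)
    fisher_exact_2x2(matrix(c(ci[i], ni - ci[i], co[i], no - co[i]), 2L)),
    0)
}

#' Extract effective contrast patterns for a subgroup split
#'
#' Mines frequent patterns in each side, computes both-side supports, growth
#' and tanh-normalized growth for the union, and keeps the patterns that (i)
#' are frequent in at least one side (support >= alpha), (ii) reach the
#' growth threshold beta, (iii) are not dominated by a proper subset with
#' strictly greater growth, and (iv) optionally pass the outer-group Fisher
#' screen.
#'
#' @param split A \code{subgroup_split} (both sides non-empty).
#' @param control A \code{\link{mining_control}}.
#' @return data.frame of class \code{"contrast_patterns"} with columns
#'   \code{pattern}, \code{id}, \code{len}, \code{s1}, \code{s2},
#'   \code{growth}, \code{growth_norm}, \code{direction}, and \code{outer_p}
#'   when the screen ran; ordered by decreasing normalized growth.
#' @export
extract_effective_patterns <- function(split, control = mining_control()) {
  stopifnot(inherits(split, "subgroup_split"),
            inherits(control, "mining_control"))
  n1 <- length(split$side1); n2 <- length(split$side2)
  if (n1 == 0L || n2 == 0L) stop("both sides of the split must be non-empty")
  gmax <- control$growth_max %||% 10
  x <- split$data$x[, split$data$meas_vars, drop = FALSE]
  alpha <- control$alpha_support

  f1 <- freq_itemsets_int(x[split$side1, , drop = FALSE], alpha,
                          control$max_pattern_len)
  f2 <- freq_itemsets_int(x[split$side2, , drop = FALSE], alpha,
                          control$max_pattern_len)
  if (length(f1) + length(f2) == 0L) return(empty_patterns())

  key_of <- function(s) paste(s$col, s$code, sep = ":", collapse = ",")
  tab <- new.env(parent = emptyenv())
  add <- function(sets, side) {
    for (s in sets) {
      k <- key_of(s)
      cur <- get0(k, envir = tab)
      if (is.null(cur)) cur <- list(col = s$col, code = s$code,
                                    c1 = NA_integer_, c2 = NA_integer_)
      if (side == 1L) cur$c1 <- s$count else cur$c2 <- s$count
      assign(k, cur, envir = tab)
    }
  }
  add(f1, 1L); add(f2, 2L)

  keys <- ls(tab)
  rows1 <- split$side1; rows2 <- split$side2
  entries <- lapply(keys, function(k) {
    e <- get(k, envir = tab)
    if (is.na(e$c1)) e$c1 <- count_pattern_rows(x, e$col, e$code, rows1)
    if (is.na(e$c2)) e$c2 <- count_pattern_rows(x, e$col, e$code, rows2)
    e
  })
  s1 <- vapply(entries, function(e) e$c1 / n1, 0)
  s2 <- vapply(entries, function(e) e$c2 / n2, 0)
  both0 <- s1 == 0 & s2 == 0
  entries <- entries[!both0]; s1 <- s1[!both0]; s2 <- s2[!both0]
  if (length(entries) == 0L) return(empty_patterns())
  g <- growth_rate(s1, s2, gmax)

  # canonical ids and subset-dominance pruning over all computed patterns
  meas <- split$data$meas_vars
  ids <- vapply(entries, function(e)
    pattern_id(meas[e$col], as.character(e$code)), "")
  gmap <- stats::setNames(g, ids)
  dominated <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]; L <- length(e$col)
    if (L < 2L) return(FALSE)
    for (d in seq_len(L)) {
      for (sub in utils::combn(L, d, simplify = FALSE)) {
        if (length(sub) == L) next
        sid <- pattern_id(meas[e$col[sub]], as.character(e$code[sub]))
        gs <- gmap[sid]
        if (!is.na(gs) && gs > g[i] + 1e-12) return(TRUE)
      }
    }
    FALSE
  }, TRUE)

  eps <- 1e-12
  keep <- !dominated & g >= control$beta_growth - eps &
    (s1 >= alpha - eps | s2 >= alpha - eps)
  entries <- entries[keep]; s1 <- s1[keep]; s2 <- s2[keep]; g <- g[keep]
  if (length(entries) == 0L) return(empty_patterns())

  outer_p <- rep(NA_real_, length(entries))
  if (control$outer_filter && length(split$outer) > 0L) {
    rows_in <- c(rows1, rows2); n_in <- length(rows_in)
    n_out <- length(split$outer)
    ci <- vapply(entries, function(e)
      count_pattern_rows(x, e$col, e$code, rows_in), 0L)
    co <- vapply(entries, function(e)
      count_pattern_rows(x, e$col, e$code, split$outer), 0L)
    outer_p <- outer_screen_counts(ci, n_in, co, n_out)
    pv <- if (control$bh_adjust) stats::p.adjust(outer_p, "BH") else outer_p
    keep2 <- pv < control$outer_p_cutoff & (ci / n_in > co / n_out)
    entries <- entries[keep2]; s1 <- s1[keep2]; s2 <- s2[keep2]
    g <- g[keep2]; outer_p <- outer_p[keep2]
    if (length(entries) == 0L) return(empty_patterns())
  }

  lev <- lapply(meas, function(v) split$data$schema[[v]]$categories)
  pats <- lapply(entries, function(e) {
    p <- vapply(seq_along(e$col), function(i) lev[[e$col[i]]][e$code[i]], "")
    names(p) <- meas[e$col]
    p[order(names(p))]
  })
  out <- data.frame(
    pattern = I(pats),
    id = vapply(pats, function(p) pattern_id(names(p), unname(p)), ""),
    len = vapply(entries, function(e) length(e$col), 0L),
    s1 = s1, s2 = s2, growth = g,
    growth_norm = growth_norm(g, gmax),
    direction = ifelse(s1 >= s2, "side1", "side2"),
    outer_p = outer_p,
    stringsAsFactors = FALSE)
  out <- out[order(-out$growth_norm, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contrast_patterns", "data.frame")
  out
}

.empty_patterns_cache <- local({
  out <- data.frame(pattern = I(list()), id = character(0), len = integer(0),
                    s1 = numeric(0), s2 = numeric(0), growth = numeric(0),
                    growth_norm = numeric(0), direction = character(0),
                    outer_p = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("contrast_patterns", "data.frame")
  out
})

empty_patterns <- function() .empty_patterns_cache

#' Write a contrast-pattern report as TSV
#' @param patterns A \code{contrast_patterns} data.frame.
#' @param path Output path.
#' @export
write_pattern_report <- function(patterns, path) {
  df <- as.data.frame(patterns)
  df$pattern <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
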