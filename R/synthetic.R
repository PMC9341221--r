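#' Specification of a planted-cohort benchmark
#'
#' Describes a synthetic categorical dataset with \code{n_cohorts} planted
#' contrast subgroup pairs of inclusion length 1..\code{max_len}
#' (\code{n_cohorts / max_len} pairs per length, remainder assigned to length
#' 1), planted high-growth measurement patterns, and Gaussian-shaped
#' background categories. Defaults are a desk-scale benchmark; the published
#' full-scale setting (1e6 records, 100 measurement variables, cardinality
#' 10, length up to 5, |T| between 1 and 10 percent of the data) is reachable
#' through the same fields.
#'
#' Planted pairs form refinement chains: each pair of length l >= 2 extends a
#' planted pair of length l - 1 by one population variable, with members
#' nested per side. Planted category values are reserved (background records
#' never take them), so a planted definition selects exactly its designated
#' members and planted supports are not diluted by chance matches; chain
#' refinement is the benchmark's controlled form of subject overlap between
#' pairs, on top of the \code{overlap_level} sharing between chains.
#'
#' @param n_records Number of records |D|.
#' @param n_pop_vars,n_meas_vars Numbers of population / measurement
#'   variables.
#' @param pop_cardinality,meas_cardinality Categories per population /
#'   measurement variable.
#' @param max_len Maximal planted inclusion length k.
#' @param n_cohorts Total number of planted subgroup pairs N.
#' @param size_range Per-side cohort size |T| as a fraction of |D|, drawn
#'   uniformly (default c(0.01, 0.1)).
#' @param overlap_level Expected fraction of a new chain's members drawn from
#'   subjects already belonging to other planted pairs (default 0.1).
#' @param pattern_len_range Item-count range of planted patterns.
#' @param patterns_per_cohort Planted patterns per pair (default 2).
#' @param support_range Range of the designed support on a pattern's favored
#'   side (default c(0.6, 0.9); must clear the mining support threshold).
#' @param growth_range Range of designed growth ratios (default c(4, 8) =
#'   [2 * beta, 0.8 * growth_max] for beta = 2, growth_max = 10).
#' @param growth_max Normalization cap the designed growths are set against.
#' @param seed Integer seed.
#' @return List of class \code{"benchmark_spec"}.
#' @export
benchmark_spec <- function(n_records = 10000L, n_pop_vars = 5L,
                           n_meas_vars = 20L, pop_cardinality = 5L,
                           meas_cardinality = 5L, max_len = 3L,
                           n_cohorts = 6L, size_range = c(0.01, 0.1),
                           overlap_level = 0.1,
                           pattern_len_range = c(1L, 2L),
                           patterns_per_cohort = 2L,
                           support_range = c(0.6, 0.9),
                           growth_range = c(4, 8), growth_max = 10,
                           seed = 1L) {
  stopifnot(n_records >= 10L, n_pop_vars >= 1L, n_meas_vars >= 1L,
            pop_cardinality >= 2L, meas_cardinality >= 2L, max_len >= 1L,
            n_cohorts >= 1L, length(size_range) == 2L,
            size_range[1] > 0, size_range[2] < 1,
            size_range[1] <= size_range[2],
            overlap_level >= 0, overlap_level <= 1,
            support_range[1] > 0, support_range[2] <= 1,
            growth_range[1] >= 1, growth_max > 0)
  structure(as.list(environment()), class = "benchmark_spec")
}

#' Generate a planted-cohort benchmark dataset
#'
#' Builds the synthetic dataset described by \code{spec}: plants
#' \code{n_cohorts} contrast subgroup pairs with designed member sets and
#' high-growth measurement patterns (carrier counts chosen so the designed
#' supports and growths are realized exactly), then fills all remaining
#' measurement cells from a bell-shaped (discretized unit-normal) category
#' distribution and all remaining population cells uniformly over the
#' unreserved categories. Planted pattern families obey the Apriori property
#' by construction. Byte-identical output for a fixed seed.
#'
#' @param spec A \code{\link{benchmark_spec}}.
#' @param verify Recompute realized supports/growths of every planted pattern
#'   on the emitted dataset and attach them to the truth (default TRUE).
#' @return List of class \code{"cm_benchmark"}: \code{data} (a
#'   \code{cm_data}) and \code{truth} (planted cohorts: subgroup, canonical
#'   key, member ids per side, planted patterns with designed and realized
#'   statistics), plus the background-distribution manifest.
#' @export
simulate_benchmark <- function(spec = benchmark_spec(), verify = TRUE) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  n <- as.integer(spec$n_records)
  npop <- as.integer(spec$n_pop_vars); nmeas <- as.integer(spec$n_meas_vars)
  Pc <- as.integer(spec$pop_cardinality)
  Mc <- as.integer(spec$meas_cardinality)
  pop_names <- paste0("pv", seq_len(npop))
  meas_names <- paste0("mv", seq_len(nmeas))
  cat_labels <- function(k) paste0("c", seq_len(k))

  # planted pairs per length: N/k per length, remainder to length 1
  k <- spec$max_len; N <- spec$n_cohorts
  counts <- rep(N %/% k, k)
  counts[1L] <- counts[1L] + N - sum(counts)
  if (any(counts[-1L] > 0) && counts[1L] == 0L)
    stop("infeasible spec: deeper cohorts without length-1 ancestors")

  claimed <- vector("list", npop)            # claimed category codes per var
  for (i in seq_len(npop)) claimed[[i]] <- integer(0)
  A <- matrix(NA_integer_, n, npop)          # population assignments
  touched <- rep(FALSE, n)
  lo <- spec$size_range[1]; hi <- spec$size_range[2]

  resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

  claim_var <- function(exclude, need_rows = NULL) {
    free <- vapply(seq_len(npop), function(i) Pc - length(claimed[[i]]), 0L)
    ok <- setdiff(which(free >= 3L), exclude)
    if (!is.null(need_rows))   # enough unassigned parent members on the var
      ok <- ok[vapply(ok, function(v)
        all(vapply(need_rows, function(rows)
          sum(is.na(A[rows, v])) >= 2L, TRUE)), TRUE)]
    if (length(ok) == 0L)
      stop("infeasible spec: no population variable with enough unclaimed categories")
    # draw uniformly among the least-claimed eligible variables: keeps the
    # category budget feasible for larger N and avoids artificial coupling
    # between unrelated planted pairs through a shared variable
    ok <- ok[free[ok] == max(free[ok])]
    v <- resample(ok, 1L)
    cats <- resample(setdiff(seq_len(Pc), claimed[[v]]), 2L)
    claimed[[v]] <<- c(claimed[[v]], cats)
    list(var = v, a = cats[1L], b = cats[2L])
  }

  draw_members <- function(size, avoid = integer(0), prefer_overlap = TRUE) {
    eligible <- setdiff(seq_len(n), avoid)
    inb <- eligible[touched[eligible]]
    outb <- eligible[!touched[eligible]]
    n_ov <- if (prefer_overlap) min(round(spec$overlap_level * size),
                                    length(inb)) else 0L
    if (size - n_ov > length(outb)) {
      n_ov <- size - length(outb)
      if (n_ov > length(inb)) stop("infeasible spec: cohort sizes exceed |D|")
    }
    c(if (n_ov > 0L) resample(inb, n_ov) else integer(0),
      resample(outb, size - n_ov))
  }

  cohorts <- list(); ci <- 0L
  for (len in seq_len(k)) {
    for (rep_i in seq_len(counts[len])) {
      ci <- ci + 1L
      if (len == 1L) {
        cl <- claim_var(integer(0))
        Ta <- max(2L, round(stats::runif(1, lo, hi) * n))
        Tb <- max(2L, round(stats::runif(1, lo, hi) * n))
        rows_blocked <- which(!is.na(A[, cl$var]))
        s1 <- draw_members(Ta, avoid = rows_blocked)
        s2 <- draw_members(Tb, avoid = c(rows_blocked, s1))
        A[s1, cl$var] <- cl$a; A[s2, cl$var] <- cl$b
        touched[c(s1, s2)] <- TRUE
        cohorts[[ci]] <- list(len = len, vars = cl$var, a = cl$a, b = cl$b,
                              side1 = s1, side2 = s2, parent = NA_integer_)
      } else {
        parents <- which(vapply(cohorts, `[[`, 0L, "len") == len - 1L)
        pidx <- resample(parents, 1L)
        par <- cohorts[[pidx]]
        cl <- claim_var(exclude = par$vars,
                        need_rows = list(par$side1, par$side2))
        pick_sub <- function(members) {
          elig <- members[is.na(A[members, cl$var])]
          # |T| ~ U[lo, hi] * |D|, truncated to the available parent members
          ub <- min(hi * n, length(elig))
          lb <- min(lo * n, ub)
          Tc <- max(2L, round(stats::runif(1, lb, ub)))
          Tc <- min(Tc, length(elig))
          if (Tc < 2L) stop("infeasible spec: nested cohort too small")
          resample(elig, Tc)
        }
        s1 <- pick_sub(par$side1); s2 <- pick_sub(par$side2)
        A[s1, cl$var] <- cl$a; A[s2, cl$var] <- cl$b
        cohorts[[ci]] <- list(len = len,
                              vars = c(par$vars, cl$var),
                              a = c(par$a, cl$a), b = c(par$b, cl$b),
                              side1 = s1, side2 = s2, parent = pidx)
      }
    }
  }

  # background population fill: uniform over the unreserved categories
  for (v in seq_len(npop)) {
    freecat <- setdiff(seq_len(Pc), claimed[[v]])
    rows <- which(is.na(A[, v]))
    A[rows, v] <- freecat[sample.int(length(freecat), length(rows),
                                     replace = TRUE)]
  }

  # measurement planting -----------------------------------------------------
  Xm <- matrix(0L, n, nmeas)
  Fb <- matrix(0L, n, nmeas)     # forbidden category per cell (0 = none)
  # bell-shaped background: unit normal partitioned into Mc equal-width bins
  zb <- seq(-2.5, 2.5, length.out = Mc + 1L)
  zb[1L] <- -Inf; zb[Mc + 1L] <- Inf
  bg_probs <- diff(stats::pnorm(zb))
  bg_probs <- bg_probs / sum(bg_probs)
  modal <- which.max(bg_probs)

  if (floor(nmeas / N) < 1L)
    stop("infeasible spec: more planted cohorts than measurement variables")
  chunk_size <- nmeas %/% N
  chunk_order <- sample.int(nmeas)
  truth <- vector("list", N)
  for (i in seq_len(N)) {
    co <- cohorts[[i]]
    chunk <- chunk_order[((i - 1L) * chunk_size + 1L):(i * chunk_size)]
    avail <- chunk
    pats <- list()
    for (pj in seq_len(spec$patterns_per_cohort)) {
      if (length(avail) == 0L) break
      plen <- resample(seq(spec$pattern_len_range[1L],
                           spec$pattern_len_range[2L]), 1L)
      plen <- min(plen, length(avail))
      pvars <- avail[seq_len(plen)]
      avail <- avail[-seq_len(plen)]
      pcats <- resample(setdiff(seq_len(Mc), modal), plen, replace = TRUE)
      hi_side <- resample(1:2, 1L)
      H <- if (hi_side == 1L) co$side1 else co$side2
      L <- if (hi_side == 1L) co$side2 else co$side1
      s_hi <- stats::runif(1, spec$support_range[1L], spec$support_range[2L])
      g <- stats::runif(1, spec$growth_range[1L], spec$growth_range[2L])
      s_lo <- s_hi / g
      n_hi <- max(1L, round(s_hi * length(H)))
      n_lo <- round(s_lo * length(L))
      carr_h <- resample(H, n_hi)
      carr_l <- if (n_lo == 0L) integer(0) else resample(L, n_lo)
      carriers <- c(carr_h, carr_l)
      noncar <- setdiff(c(H, L), carriers)
      for (q in seq_len(plen)) {
        Xm[carriers, pvars[q]] <- pcats[q]
        Fb[noncar, pvars[q]] <- pcats[q]
      }
      pats[[pj]] <- list(vars = pvars, cats = pcats,
                         direction = if (hi_side == 1L) "side1" else "side2",
                         s_hi = n_hi / length(H), s_lo = n_lo / length(L),
                         designed_growth = g)
    }
    truth[[i]] <- list(len = co$len,
                       vars = pop_names[co$vars],
                       side1_cats = cat_labels(Pc)[co$a],
                       side2_cats = cat_labels(Pc)[co$b],
                       side1 = sort(co$side1), side2 = sort(co$side2),
                       parent = co$parent, patterns = pats)
  }

  # Gaussian background fill with per-cell forbidden categories
  empty <- which(Xm == 0L)
  Xm[empty] <- sample.int(Mc, length(empty), replace = TRUE, prob = bg_probs)
  bad <- which(Xm == Fb & Fb > 0L)
  for (cat in seq_len(Mc)) {
    sel <- bad[Fb[bad] == cat]
    if (length(sel) == 0L) next
    pr <- bg_probs[-cat] / sum(bg_probs[-cat])
    Xm[sel] <- (seq_len(Mc)[-cat])[sample.int(Mc - 1L, length(sel),
                                              replace = TRUE, prob = pr)]
  }

  # assemble cm_data ----------------------------------------------------------
  def <- c(
    lapply(pop_names, function(v) list(role = "population",
                                       categories = cat_labels(Pc),
                                       na_allowed = FALSE)),
    lapply(meas_names, function(v) list(role = "measurement",
                                        categories = cat_labels(Mc),
                                        na_allowed = FALSE)))
  names(def) <- c(pop_names, meas_names)
  definition <- as_definition(def)
  x <- cbind(A, Xm)
  colnames(x) <- c(pop_names, meas_names)
  data <- structure(list(x = x, schema = definition, pop_vars = pop_names,
                         meas_vars = meas_names, n = n, dropped = 0L),
                    class = "cm_data")

  # canonical subgroup objects + keys
  for (i in seq_len(N)) {
    tr <- truth[[i]]
    scg <- contrast_subgroup(lapply(seq_along(tr$vars), function(q)
      contrast_pair(tr$vars[q], tr$side1_cats[q], tr$side2_cats[q])))
    truth[[i]]$subgroup <- scg
    truth[[i]]$key <- canonical_key(scg)
    truth[[i]]$patterns <- lapply(truth[[i]]$patterns, function(p) {
      items <- stats::setNames(cat_labels(Mc)[p$cats], meas_names[p$vars])
      p$items <- items[order(names(items))]
      p
    })
  }

  if (verify) {
    for (i in seq_len(N)) {
      sp <- split_population(data, truth[[i]]$subgroup)
      stopifnot(identical(sort(sp$side1), truth[[i]]$side1),
                identical(sort(sp$side2), truth[[i]]$side2))
      truth[[i]]$patterns <- lapply(truth[[i]]$patterns, function(p) {
        s1 <- pattern_support(p$items, decode_rows(data, sp$side1))
        s2 <- pattern_support(p$items, decode_rows(data, sp$side2))
        p$realized_s1 <- s1; p$realized_s2 <- s2
        p$realized_growth <- growth_rate(s1, s2, spec$growth_max)
        p
      })
    }
  }

  structure(list(data = data,
                 truth = structure(list(cohorts = truth, spec = spec,
                                        background = list(
                                          distribution = "discretized unit normal",
                                          z_breaks = zb, probs = bg_probs)),
                                   class = "planted_truth")),
            class = "cm_benchmark")
}

decode_rows <- function(data, rows) {
  x <- data$x[rows, data$meas_vars, drop = FALSE]
  structure(list(x = x, schema = data$schema), class = "cm_data_rows")
}

#' @export
print.cm_benchmark <- function(x, ...) {
  cat("Planted-cohort benchmark:", x$data$n, "records,",
      length(x$truth$cohorts), "planted subgroup pairs (lengths",
      paste(sort(unique(vapply(x$truth$cohorts, `[[`, 0L, "len"))),
            collapse = ","), ")\n")
  invisible(x)
}

#' Coverage of planted cohorts by a discovered candidate pool
#'
#' Primary metric: the fraction of planted subgroup pairs whose canonical key
#' appears in the discovered pool (exact definition match). The secondary
#' \code{"jaccard"} mode counts a planted pair as covered when some
#' discovered pair's member set has Jaccard similarity at least
#' \code{threshold} with the planted member set, crediting legitimate
#' near-miss discoveries.
#'
#' @param discovered A \code{contrast_mine} fit, a character vector of
#'   canonical keys, or a data.frame with a \code{key} column.
#' @param truth A \code{planted_truth} (from \code{\link{simulate_benchmark}}).
#' @param mode \code{"exact"} (default) or \code{"jaccard"}.
#' @param data The \code{cm_data} the pool was mined from (jaccard mode only).
#' @param threshold Jaccard threshold (default 0.8).
#' @return Coverage fraction in [0, 1].
#' @export
coverage <- function(discovered, truth, mode = c("exact", "jaccard"),
                     data = NULL, threshold = 0.8) {
  mode <- match.arg(mode)
  keys <- if (inherits(discovered, "contrast_mine")) discovered$pool$key
          else if (is.data.frame(discovered)) discovered$key
          else as.character(discovered)
  cohorts <- truth$cohorts
  if (length(cohorts) == 0L) return(NA_real_)
  planted <- vapply(cohorts, `[[`, "", "key")
  if (mode == "exact") return(mean(planted %in% keys))
  if (is.null(data)) stop("jaccard mode needs the mined cm_data")
  members <- lapply(keys, function(k) {
    sp <- split_population(data, subgroup_from_key(k))
    c(sp$side1, sp$side2)
  })
  covered <- vapply(cohorts, function(co) {
    pm <- c(co$side1, co$side2)
    any(vapply(members, function(m)
      length(intersect(m, pm)) / length(union(m, pm)) >= threshold, TRUE))
  }, TRUE)
  mean(covered)
}
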