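#' Exploration configuration
#'
#' Settings of the subgroup search: the floating-selection stopping threshold
#' \code{alpha_stop} (relative J gain; distinct from the support threshold of
#' the pattern miner), the maximal subgroup length, the expansion factor of
#' the multi-path search, the mining thresholds, the baseline used for size
#' modification, and tie/guard settings.
#'
#' @param alpha_stop Relative-J-gain stopping threshold (>= 0). A floating
#'   iteration stops once \code{(J(k) - J(k-1)) / J(k) <= alpha_stop}; a zero
#'   J is treated as "no gain information yet" and the search continues up to
#'   \code{max_vars}.
#' @param max_vars Maximal number of population variables per subgroup.
#' @param expand_p Expansion factor p in [0, 1] controlling how many candidate
#'   paths survive each layer (see \code{\link{n_track}}).
#' @param mining A \code{\link{mining_control}}.
#' @param baseline_k Random subgroup pairs drawn for the size-modification
#'   baseline (default 100).
#' @param size_preference \code{"larger"} or \code{"smaller"} populations
#'   preferred in ranking.
#' @param exclusion_moves Should expansion also spawn pellets from exclusion
#'   moves beyond layer 2 (default TRUE)?
#' @param blacklist Character vector of canonical keys of known/trivial
#'   subgroup definitions that must not be explored.
#' @param verbose Emit a progress line per layer (frontier size, best J,
#'   evaluations so far) via \code{message()}.
#' @param seed Integer seed driving every stochastic component (baseline
#'   sampling, growth-cap estimation).
#' @return List of class \code{"explore_control"}.
#' @export
explore_control <- function(alpha_stop = 0, max_vars = 5L, expand_p = 0.1,
                            mining = mining_control(), baseline_k = 100L,
                            size_preference = c("larger", "smaller"),
                            exclusion_moves = TRUE, blacklist = NULL,
                            verbose = FALSE, seed = 1L) {
  stopifnot(alpha_stop >= 0, expand_p >= 0, expand_p <= 1, max_vars >= 1L)
  structure(list(alpha_stop = alpha_stop, max_vars = as.integer(max_vars),
                 expand_p = expand_p, mining = mining,
                 baseline_k = as.integer(baseline_k),
                 size_preference = match.arg(size_preference),
                 exclusion_moves = isTRUE(exclusion_moves),
                 blacklist = blacklist, verbose = isTRUE(verbose),
                 seed = as.integer(seed)),
            class = "explore_control")
}

#' Create an evaluation registry
#'
#' The registry memoizes subgroup evaluations by canonical key, guaranteeing
#' that no subgroup pair is mined twice and that the search cannot enter an
#' oscillation cycle.
#' @return Environment with a counter of mining invocations.
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$store <- new.env(parent = emptyenv())
  reg$mining_calls <- 0L
  reg
}

#' Number of distinct evaluations recorded in a registry
#' @param registry A registry from \code{\link{new_registry}}.
#' @return Integer count.
#' @export
registry_size <- function(registry) length(ls(registry$store))

# split with per-(variable, category) row masks cached in the registry;
# semantics identical to split_population
split_fast <- function(data, scg, registry) {
  if (is.null(registry$masks))
    registry$masks <- new.env(parent = emptyenv())
  get_mask <- function(v, cat) {
    mk <- paste0(v, ":", cat)
    m <- get0(mk, envir = registry$masks)
    if (is.null(m)) {
      code <- match(cat, data$schema[[v]]$categories)
      m <- if (is.na(code)) rep(FALSE, data$n) else data$x[, v] == code
      assign(mk, m, envir = registry$masks)
    }
    m
  }
  m1 <- get_mask(scg$vars[1L], scg$a[1L])
  m2 <- get_mask(scg$vars[1L], scg$b[1L])
  if (length(scg) > 1L) for (i in 2L:length(scg$vars)) {
    m1 <- m1 & get_mask(scg$vars[i], scg$a[i])
    m2 <- m2 & get_mask(scg$vars[i], scg$b[i])
  }
  structure(list(side1 = which(m1), side2 = which(m2),
                 outer = which(!(m1 | m2)), data = data),
            class = "subgroup_split")
}

#' Evaluate one subgroup pair
#'
#' Splits the population, extracts effective contrast patterns and computes
#' the J value; results are memoized by canonical key. Splits with a side
#' smaller than \code{min_side} score J = 0 with no patterns.
#'
#' @param data A \code{cm_data}.
#' @param scg A non-empty \code{contrast_subgroup}.
#' @param control A \code{\link{mining_control}}.
#' @param registry Registry from \code{\link{new_registry}}; created ad hoc
#'   when NULL.
#' @return List with \code{j} (fields \code{j_ori}, \code{n_pair}, \code{n1},
#'   \code{n2}, \code{n_patterns}) and \code{patterns}.
#' @export
evaluate_subgroup <- function(data, scg, control = mining_control(),
                              registry = NULL) {
  if (is.null(registry)) registry <- new_registry()
  key <- canonical_key(scg)
  hit <- get0(key, envir = registry$store)
  if (!is.null(hit)) return(hit)
  sp <- split_fast(data, scg, registry)
  n1 <- length(sp$side1); n2 <- length(sp$side2)
  if (n1 < control$min_side || n2 < control$min_side) {
    res <- list(j = list(j_ori = 0L, n_pair = n1 + n2, n1 = n1, n2 = n2,
                         n_patterns = 0L),
                patterns = empty_patterns(), key = key)
  } else {
    registry$mining_calls <- registry$mining_calls + 1L
    pats <- extract_effective_patterns(sp, control)
    res <- list(j = list(j_ori = j_value(pats$growth_norm),
                         n_pair = n1 + n2, n1 = n1, n2 = n2,
                         n_patterns = nrow(pats)),
                patterns = pats, key = key)
  }
  assign(key, res, envir = registry$store)
  res
}

# enumerate extension moves of scg over the given variables; for a non-empty
# scg both alignments of a category pair (which category joins side 1) are
# distinct subgroups and both are candidate moves
extension_moves <- function(data, scg, vars) {
  out <- list(); k <- 0L
  for (v in vars) {
    for (pr in make_contrast_pairs(data$schema[[v]])) {
      k <- k + 1L
      out[[k]] <- list(scg = extend_subgroup(scg, pr), var = v, pair = pr)
      if (length(scg) > 0L) {
        swp <- contrast_pair(pr$variable, pr$cat_b, pr$cat_a)
        k <- k + 1L
        out[[k]] <- list(scg = extend_subgroup(scg, swp), var = v, pair = swp)
      }
    }
  }
  out
}

score_moves <- function(data, moves, control, registry) {
  if (length(moves) == 0L)
    return(data.frame(key = character(0), j = integer(0), var = character(0)))
  evs <- lapply(moves, function(m)
    evaluate_subgroup(data, m$scg, control, registry))
  data.frame(key = vapply(evs, `[[`, "", "key"),
             j = vapply(evs, function(e) e$j$j_ori, 0L),
             n_pair = vapply(evs, function(e) e$j$n_pair, 0),
             var = vapply(moves, `[[`, "", "var"),
             stringsAsFactors = FALSE)
}

#' One inclusion step
#'
#' Evaluates the extension of \code{scg} by every contrast pair of every
#' remaining population variable and identifies the highest-J candidate
#' (ties broken by canonical key).
#'
#' @param data A \code{cm_data}.
#' @param scg Current \code{contrast_subgroup} (possibly empty).
#' @param remaining_vars Population variables still available.
#' @param control A \code{\link{mining_control}}.
#' @param registry Evaluation registry.
#' @return List with \code{candidates} (data.frame key/j/var), \code{best}
#'   (the winning subgroup), \code{best_j}, and \code{var} to retire from the
#'   pool; \code{NULL} if there is no candidate.
#' @export
inclusion_step <- function(data, scg, remaining_vars,
                           control = mining_control(), registry = NULL) {
  if (length(remaining_vars) == 0L) return(NULL)
  if (is.null(registry)) registry <- new_registry()
  moves <- extension_moves(data, scg, remaining_vars)
  cand <- score_moves(data, moves, control, registry)
  ord <- order(-cand$j, cand$key)
  best <- ord[1L]
  list(candidates = cand, best = moves[[best]]$scg,
       best_j = cand$j[best], var = cand$var[best],
       best_key = cand$key[best])
}

#' One exclusion step
#'
#' Evaluates \code{scg} minus each of its pairs and identifies the best
#' removal by J (ties broken by canonical key).
#'
#' @inheritParams inclusion_step
#' @return List with \code{candidates}, \code{best} (subgroup after removal),
#'   \code{best_j}, and \code{var} returned to the pool.
#' @export
exclusion_step <- function(data, scg, control = mining_control(),
                           registry = NULL) {
  if (length(scg) < 2L)
    stop("exclusion requires a subgroup with at least 2 pairs")
  if (is.null(registry)) registry <- new_registry()
  moves <- lapply(seq_along(scg$vars), function(i) {
    pr <- contrast_pair(scg$vars[i], scg$a[i], scg$b[i])
    list(scg = remove_pair(scg, pr), var = scg$vars[i], pair = pr)
  })
  cand <- score_moves(data, moves, control, registry)
  ord <- order(-cand$j, cand$key)
  best <- ord[1L]
  list(candidates = cand, best = moves[[best]]$scg,
       best_j = cand$j[best], var = cand$var[best],
       best_key = cand$key[best])
}

#' Number of candidate paths to track
#'
#' \code{Ntrack = max(ceiling(n * p), |{i : J_i >= J_highest * (1 - p)}|)}:
#' the larger of a quantity quota (the top \code{100 p} percent of all
#' \code{n} paths) and a quality quota (paths whose J is within \code{100 p}
#' percent of the best).
#'
#' @param j_values J values of all candidate paths (non-empty).
#' @param p Expansion factor in [0, 1].
#' @return Integer count.
#' @export
n_track <- function(j_values, p) {
  n <- length(j_values)
  if (n == 0L) stop("j_values must be non-empty")
  stopifnot(p >= 0, p <= 1)
  jmax <- max(j_values)
  max(as.integer(ceiling(n * p)),
      sum(j_values >= jmax * (1 - p) - 1e-12))
}

# expansion variant: zero-J moves never count toward the quality quota, so
# zero-signal paths consume only the ceiling(n*p) quantity slots
n_track_live <- function(j_values, p) {
  n <- length(j_values)
  jmax <- max(j_values)
  q <- if (jmax > 0) sum(j_values >= jmax * (1 - p) - 1e-12 & j_values > 0)
       else 0L
  min(n, max(as.integer(ceiling(n * p)), q))
}

#' Floating contrast subgroup selection
#'
#' The single-path floating search: an initiation of two inclusion steps
#' followed by alternating inclusion and (continued) exclusion, stopping when
#' the relative J gain drops to \code{alpha_stop}, when the subgroup reaches
#' \code{max_vars} variables, or when the visited registry blocks all moves.
#' An exclusion is applied only when it strictly improves on the best J
#' recorded at the smaller size and does not simply undo the inclusion just
#' made; this keeps the procedure free of oscillation cycles.
#'
#' @param data A \code{cm_data} with at least 2 population variables.
#' @param control An \code{\link{explore_control}}.
#' @param registry Optional shared registry.
#' @return List of class \code{"floating_path"}: \code{subgroup} (the best
#'   subgroup on the path), \code{j}, and \code{trace} (data.frame of steps).
#' @export
floating_selection <- function(data, control = explore_control(),
                               registry = NULL) {
  stopifnot(inherits(data, "cm_data"))
  if (length(data$pop_vars) < 2L)
    stop("floating selection needs at least 2 population variables")
  if (is.null(registry)) registry <- new_registry()
  mc <- control$mining
  if (is.null(mc$growth_max)) mc$growth_max <- 10
  pool <- data$pop_vars
  trace <- list()
  push <- function(action, key, k, j) {
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action, key = key, k = k, j = j, stringsAsFactors = FALSE)
  }
  scg <- contrast_subgroup()
  jk <- c(0)   # jk[k+1] = J(k)
  accepted <- character(0)

  # initiation: two inclusions
  for (step in 1:2) {
    inc <- inclusion_step(data, scg, pool, mc, registry)
    if (is.null(inc)) stop("dead end at initiation: no valid subgroup")
    scg <- inc$best
    pool <- setdiff(pool, inc$var)
    jk[length(scg) + 1L] <- inc$best_j
    accepted <- c(accepted, inc$best_key)
    push("inclusion", inc$best_key, length(scg), inc$best_j)
  }

  continue_rule <- function(jnow, jprev) {
    if (jnow == 0) return(TRUE)           # no gain information yet
    (jnow - jprev) / jnow > control$alpha_stop
  }

  k <- length(scg)
  while (k < control$max_vars && continue_rule(jk[k + 1L], jk[k])) {
    inc <- inclusion_step(data, scg, pool, mc, registry)
    if (is.null(inc)) break
    scg_inc <- inc$best; var_inc <- inc$var
    push("inclusion", inc$best_key, length(scg_inc), inc$best_j)
    exc <- exclusion_step(data, scg_inc, mc, registry)
    undo <- exc$var == var_inc
    improves <- exc$best_j > jk[length(scg_inc)] &&   # beats best at size-1
      !(exc$best_key %in% accepted)
    if (undo || !improves) {
      # the inclusion stands
      scg <- scg_inc; pool <- setdiff(pool, var_inc)
      k <- length(scg)
      jk[k + 1L] <- inc$best_j
      accepted <- c(accepted, inc$best_key)
    } else {
      # floating back: apply the exclusion, then continue excluding while
      # it keeps strictly improving and does not revisit an accepted key
      pool <- setdiff(pool, var_inc)
      scg <- exc$best; pool <- c(pool, exc$var)
      accepted <- c(accepted, exc$best_key)
      jk[length(scg) + 1L] <- exc$best_j
      push("exclusion", exc$best_key, length(scg), exc$best_j)
      while (length(scg) > 2L) {
        exc2 <- exclusion_step(data, scg, mc, registry)
        if (exc2$best_j > jk[length(scg)] &&
            !(exc2$best_key %in% accepted)) {
          scg <- exc2$best; pool <- c(pool, exc2$var)
          accepted <- c(accepted, exc2$best_key)
          jk[length(scg) + 1L] <- exc2$best_j
          push("exclusion", exc2$best_key, length(scg), exc2$best_j)
        } else break
      }
      k <- length(scg)
    }
  }

  trace <- do.call(rbind, trace)
  best_row <- trace[trace$k <= control$max_vars, , drop = FALSE]
  best_row <- best_row[order(-best_row$j, best_row$key), , drop = FALSE][1L, ]
  structure(list(subgroup = subgroup_from_key(best_row$key),
                 j = best_row$j, trace = trace,
                 registry_size = registry_size(registry)),
            class = "floating_path")
}

#' @export
print.floating_path <- function(x, ...) {
  cat("Floating selection path (", nrow(x$trace), "steps )\n")
  cat("Best subgroup:", format(x$subgroup), " J =", x$j, "\n")
  invisible(x)
}

# ---- guided cascading shotgun ---------------------------------------------

# Breadth-wise multi-path expansion. Every move of an expanded node is
# evaluated (and enters the node table); only the top n_track_live children
# per node become live pellets for the next layer. Duplicate keys and
# blacklisted keys are pruned from expansion.
gcs_expand <- function(data, control, registry) {
  mc <- control$mining
  nodes <- new.env(parent = emptyenv())   # key -> node record
  order_seen <- character(0)
  add_node <- function(key, parent, layer, j, n_pair, n_patterns, status) {
    if (!is.null(get0(key, envir = nodes))) return(FALSE)
    assign(key, list(key = key, parent = parent, layer = layer, j = j,
                     n_pair = n_pair, n_patterns = n_patterns,
                     status = status), envir = nodes)
    order_seen <<- c(order_seen, key)
    TRUE
  }
  blacklist <- control$blacklist %||% character(0)

  expand_node <- function(scg, parent_key, layer) {
    # candidate moves: inclusions over unused variables, plus exclusions
    # beyond layer 2
    vars_left <- setdiff(data$pop_vars, scg$vars)
    moves <- extension_moves(data, scg, vars_left)
    if (control$exclusion_moves && length(scg) >= 3L) {
      exc <- lapply(seq_along(scg$vars), function(i) {
        pr <- contrast_pair(scg$vars[i], scg$a[i], scg$b[i])
        list(scg = remove_pair(scg, pr), var = scg$vars[i], pair = pr)
      })
      moves <- c(moves, exc)
    }
    if (length(moves) == 0L) return(list())
    keys <- vapply(moves, function(m) canonical_key(m$scg), "")
    fresh <- !vapply(keys, function(k)
      !is.null(get0(k, envir = nodes)), TRUE)
    trivial <- keys %in% blacklist
    live <- list()
    cand_j <- numeric(0); cand_idx <- integer(0)
    for (i in seq_along(moves)) {
      if (trivial[i]) {
        if (fresh[i])
          add_node(keys[i], parent_key, layer + 1L, NA_integer_, NA, NA,
                   "pruned-trivial")
        next
      }
      if (!fresh[i]) next   # duplicate: already evaluated, prune this path
      ev <- evaluate_subgroup(data, moves[[i]]$scg, mc, registry)
      child_layer <- length(moves[[i]]$scg$vars)
      add_node(keys[i], parent_key, child_layer, ev$j$j_ori, ev$j$n_pair,
               ev$j$n_patterns, "open")
      cand_j <- c(cand_j, ev$j$j_ori); cand_idx <- c(cand_idx, i)
    }
    if (length(cand_idx) == 0L) return(list())
    keep <- n_track_live(cand_j, control$expand_p)
    ord <- order(-cand_j, keys[cand_idx])[seq_len(keep)]
    lapply(cand_idx[ord], function(i)
      list(scg = moves[[i]]$scg, key = keys[i]))
  }

  frontier <- expand_node(contrast_subgroup(), "<root>", 0L)
  layer <- 1L
  while (length(frontier) > 0L) {
    if (isTRUE(control$verbose)) {
      fj <- vapply(frontier, function(nd) get(nd$key, envir = nodes)$j, 0L)
      message(sprintf("layer %d: frontier %d, best J %d, %d nodes evaluated",
                      layer, length(frontier), max(fj), length(order_seen)))
    }
    nxt <- list()
    for (node in frontier) {
      st <- get(node$key, envir = nodes)
      if (length(node$scg$vars) >= control$max_vars) next
      st$status <- "expanded"
      assign(node$key, st, envir = nodes)
      # gain-based abandonment only when alpha_stop is positive
      kids <- expand_node(node$scg, node$key, layer)
      if (control$alpha_stop > 0 && st$j > 0) {
        kids <- Filter(function(kid) {
          cj <- get(kid$key, envir = nodes)$j
          cj == 0 || (cj - st$j) / cj > control$alpha_stop
        }, kids)
      }
      nxt <- c(nxt, kids)
    }
    # registry dedup across the layer: a key may be spawned by two parents
    if (length(nxt) > 1L) {
      kk <- vapply(nxt, `[[`, "", "key")
      nxt <- nxt[!duplicated(kk)]
    }
    frontier <- nxt
    layer <- layer + 1L
  }
  list(nodes = nodes, order = order_seen)
}

gcs_pool <- function(gcs) {
  recs <- lapply(gcs$order, function(k) get(k, envir = gcs$nodes))
  recs <- Filter(function(r) r$status != "pruned-trivial", recs)
  data.frame(key = vapply(recs, `[[`, "", "key"),
             parent = vapply(recs, `[[`, "", "parent"),
             layer = vapply(recs, `[[`, 0L, "layer"),
             j_ori = vapply(recs, function(r) as.integer(r$j), 0L),
             n_pair = vapply(recs, function(r) as.numeric(r$n_pair), 0),
             n_patterns = vapply(recs, function(r)
               as.integer(r$n_patterns), 0L),
             status = vapply(recs, `[[`, "", "status"),
             stringsAsFactors = FALSE)
}
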