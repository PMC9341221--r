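# Shared fixtures and independent oracles for the test suite.

# build a cm_data from a data.frame of character columns + role assignment
toy_data <- function(df, pop_vars, na_allowed = FALSE) {
  def <- lapply(names(df), function(v) {
    list(role = if (v %in% pop_vars) "population" else "measurement",
         categories = sort(unique(df[[v]][df[[v]] != "NA"])),
         na_allowed = na_allowed)
  })
  names(def) <- names(df)
  encode_dataset(df, as_definition(def), max_missing = 1)
}

# random small categorical data.frame
random_toy <- function(n, pop = 2, meas = 3, cats = 3, seed = 1) {
  set.seed(seed)
  cols <- c(paste0("p", seq_len(pop)), paste0("m", seq_len(meas)))
  df <- as.data.frame(lapply(cols, function(v)
    sample(paste0("c", seq_len(cats)), n, replace = TRUE)),
    optional = TRUE, stringsAsFactors = FALSE)
  names(df) <- cols
  toy_data(df, paste0("p", seq_len(pop)))
}

# oracle: enumerate every itemset of length <= max_len over the observed
# (variable, category) combinations and count supports by scanning
oracle_itemsets <- function(df, alpha, max_len) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  items <- do.call(rbind, lapply(names(df), function(v)
    data.frame(var = v, cat = unique(df[[v]]), stringsAsFactors = FALSE)))
  out <- list()
  for (len in seq_len(max_len)) {
    if (len > nrow(items)) break
    for (sel in utils::combn(nrow(items), len, simplify = FALSE)) {
      vars <- items$var[sel]
      if (anyDuplicated(vars)) next
      m <- rep(TRUE, n)
      for (i in seq_along(sel))
        m <- m & (df[[vars[i]]] == items$cat[sel[i]])
      s <- sum(m) / n
      if (s >= alpha - 1e-12) {
        p <- items$cat[sel]; names(p) <- vars
        p <- p[order(names(p))]
        out[[length(out) + 1L]] <-
          list(id = paste0(names(p), "=", p, collapse = "&"), support = s)
      }
    }
  }
  out
}

# oracle: brute-force J by scanning every candidate value
oracle_j <- function(values) {
  v <- sort(values, decreasing = TRUE)
  best <- 0L
  for (j in seq_along(v)) if (j^2 <= sum(v[seq_len(j)]) + 1e-9) best <- j
  best
}

# oracle: two-sided Fisher p by full hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# oracle: exhaustive enumeration of every valid contrast subgroup with at
# most max_vars variables; returns data.frame of canonical keys and J values
oracle_all_subgroups <- function(data, control, max_vars) {
  pairs_by_var <- lapply(data$pop_vars, function(v)
    make_contrast_pairs(data$schema[[v]]))
  names(pairs_by_var) <- data$pop_vars
  res <- new.env(parent = emptyenv())
  registry <- new_registry()
  recurse <- function(scg, vars_left) {
    if (length(scg) > 0L) {
      key <- canonical_key(scg)
      if (is.null(get0(key, envir = res))) {
        ev <- evaluate_subgroup(data, scg, control, registry)
        assign(key, ev$j$j_ori, envir = res)
      }
    }
    if (length(scg) >= max_vars || length(vars_left) == 0L) return()
    for (vi in seq_along(vars_left)) {
      v <- vars_left[vi]
      rest <- vars_left[-seq_len(vi)]   # avoid revisiting var orders
      for (pr in pairs_by_var[[v]]) {
        recurse(extend_subgroup(scg, pr), rest)
        if (length(scg) > 0L)
          recurse(extend_subgroup(
            scg, contrast_pair(pr$variable, pr$cat_b, pr$cat_a)), rest)
      }
    }
  }
  recurse(contrast_subgroup(), data$pop_vars)
  keys <- ls(res)
  data.frame(key = keys,
             j = vapply(keys, function(k) get(k, envir = res), 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

# a tiny dataset with one strongly contrasted planted subgroup pair
planted_toy <- function(n = 120, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = sample(c("young", "old"), n, replace = TRUE),
    g1 = sample(paste0("c", 1:3), n, replace = TRUE),
    g2 = sample(paste0("c", 1:3), n, replace = TRUE),
    stringsAsFactors = FALSE)
  side1 <- df$sex == "F" & df$age == "young"
  side2 <- df$sex == "M" & df$age == "old"
  df$g1[side1] <- "c1"
  df$g1[side2] <- sample(c("c2", "c3"), sum(side2), replace = TRUE)
  df$g2[side1] <- "c2"
  df$g2[side2] <- "c3"
  list(data = toy_data(df, c("sex", "age")),
       truth = contrast_subgroup(contrast_pair("sex", "F", "M"),
                                 contrast_pair("age", "young", "old")))
}

fast_mining <- function(...) {
  mining_control(growth_max = 10, min_side = 5, outer_filter = FALSE, ...)
}
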