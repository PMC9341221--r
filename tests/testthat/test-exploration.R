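test_that("n_track combines the quantity and quality quotas", {
  # 20 paths, p = 0.1, three J's within 10% of the best -> max(2, 3) = 3
  j <- c(10, 9.5, 9.2, rep(5, 17))
  expect_equal(n_track(j, 0.1), 3L)
  # p = 1 keeps every path
  expect_equal(n_track(j, 1), 20L)
  # p = 0 keeps the paths tied with the best
  expect_equal(n_track(c(7, 7, 3), 0), 2L)
  expect_equal(n_track(c(5), 0), 1L)
  expect_error(n_track(numeric(0), 0.5), "non-empty")
})

test_that("evaluation guards small sides and memoizes by canonical key", {
  toy <- planted_toy()
  d <- toy$data
  reg <- new_registry()
  ctl <- fast_mining()
  ev <- evaluate_subgroup(d, toy$truth, ctl, reg)
  expect_gte(ev$j$j_ori, 1L)            # planted contrast is detected
  calls <- reg$mining_calls
  # same canonical key under side swap: served from the registry
  swp <- contrast_subgroup(contrast_pair("sex", "M", "F"),
                           contrast_pair("age", "old", "young"))
  ev2 <- evaluate_subgroup(d, swp, ctl, reg)
  expect_identical(reg$mining_calls, calls)
  expect_identical(ev2$j$j_ori, ev$j$j_ori)
  # a side below min_side scores zero with no patterns
  strict <- fast_mining()
  strict$min_side <- 1000L
  ev3 <- evaluate_subgroup(d, toy$truth, strict, new_registry())
  expect_equal(ev3$j$j_ori, 0L)
  expect_equal(ev3$j$n_patterns, 0L)
})

test_that("inclusion evaluates every pair of every remaining variable", {
  # 2 population variables with {3, 2} categories: C(3,2) + C(2,2) = 4
  df <- data.frame(p1 = rep(c("a", "b", "c"), 8),
                   p2 = rep(c("x", "y"), 12),
                   m = sample(c("u", "v"), 24, replace = TRUE),
                   stringsAsFactors = FALSE)
  d <- toy_data(df, c("p1", "p2"))
  reg <- new_registry()
  inc <- inclusion_step(d, contrast_subgroup(), c("p1", "p2"),
                        fast_mining(), reg)
  expect_equal(nrow(inc$candidates), 4L)
  # single remaining binary variable: exactly one candidate
  inc2 <- inclusion_step(d, contrast_subgroup(), "p2", fast_mining(),
                         new_registry())
  expect_equal(nrow(inc2$candidates), 1L)
  # the reported best matches the argmax over the scored candidates
  ord <- order(-inc$candidates$j, inc$candidates$key)
  expect_equal(inc$best_key, inc$candidates$key[ord[1]])
})

test_that("exclusion scores one removal per pair and reuses the registry", {
  toy <- planted_toy()
  d <- toy$data
  reg <- new_registry()
  scg3 <- extend_subgroup(toy$truth, contrast_pair("g1", "c1", "c2"))
  # g1 is a measurement variable in the fixture; rebuild with population vars
  df <- decode_dataset(d)
  df$extra <- rep(c("e1", "e2"), length.out = nrow(df))
  d2 <- toy_data(df, c("sex", "age", "extra"))
  scg3 <- contrast_subgroup(contrast_pair("sex", "F", "M"),
                            contrast_pair("age", "young", "old"),
                            contrast_pair("extra", "e1", "e2"))
  exc <- exclusion_step(d2, scg3, fast_mining(), reg)
  expect_equal(nrow(exc$candidates), 3L)
  calls <- reg$mining_calls
  # removing a pair recreates a 2-variable key; re-query hits the registry
  exc2 <- exclusion_step(d2, scg3, fast_mining(), reg)
  expect_identical(reg$mining_calls, calls)
  expect_equal(exc2$best_key, exc$best_key)
  expect_error(exclusion_step(
    d2, contrast_subgroup(contrast_pair("sex", "F", "M")), fast_mining()),
    "at least 2")
})

test_that("floating selection honours its stopping rules and finds the plant", {
  toy <- planted_toy()
  d <- toy$data
  ctl <- explore_control(alpha_stop = 0, max_vars = 2, expand_p = 1,
                         mining = fast_mining(), baseline_k = 5, seed = 2)
  fp <- floating_selection(d, ctl)
  # exhaustive oracle over all <= 2-variable subgroups
  orc <- oracle_all_subgroups(d, fast_mining(), 2)
  expect_equal(fp$j, max(orc$j))
  expect_equal(canonical_key(fp$subgroup), canonical_key(toy$truth))
  # a huge alpha_stop stops right after initiation (k = 2)
  ctl2 <- explore_control(alpha_stop = 1e6, max_vars = 4,
                          mining = fast_mining(), baseline_k = 5, seed = 2)
  fp2 <- floating_selection(d, ctl2)
  expect_lte(max(fp2$trace$k), 2L)
  # max_vars bounds every subgroup on the trace
  df <- decode_dataset(d)
  df$extra <- rep(c("e1", "e2"), length.out = nrow(df))
  d3 <- toy_data(df, c("sex", "age", "extra"))
  fp3 <- floating_selection(d3, explore_control(
    alpha_stop = 0, max_vars = 2, mining = fast_mining(), seed = 3))
  expect_true(all(fp3$trace$k <= 2L))
})

test_that("GCS at full expansion equals the exhaustive-search maximum", {
  d <- random_toy(90, pop = 3, meas = 3, cats = 3, seed = 17)
  # plant a contrast on a 2-variable conjunction
  df <- decode_dataset(d)
  side1 <- df$p1 == "c1" & df$p2 == "c2"
  side2 <- df$p1 == "c2" & df$p2 == "c3"
  df$m1[side1] <- "c1"; df$m1[side2] <- "c2"
  d <- toy_data(df, paste0("p", 1:3))
  ctl <- explore_control(alpha_stop = 0, max_vars = 3, expand_p = 1,
                         mining = fast_mining(), baseline_k = 5, seed = 4)
  fit <- contrast_mine(d, ctl)
  orc <- oracle_all_subgroups(d, ctl$mining, 3)
  expect_equal(max(fit$pool$j_ori), max(orc$j))
  # every valid subgroup is present in the pool at expand_p = 1
  expect_setequal(fit$pool$key, orc$key)
})

test_that("the evaluated pool grows monotonically with the expansion factor", {
  toy <- planted_toy(n = 150, seed = 12)
  d <- toy$data
  keys <- list()
  for (p in c(0.05, 0.2, 1)) {
    ctl <- explore_control(alpha_stop = 0, max_vars = 2, expand_p = p,
                           mining = fast_mining(), baseline_k = 5, seed = 6)
    keys[[as.character(p)]] <- contrast_mine(d, ctl)$pool$key
  }
  expect_true(all(keys[["0.05"]] %in% keys[["0.2"]]))
  expect_true(all(keys[["0.2"]] %in% keys[["1"]]))
  # the global best subgroup is found even at a small expansion factor
  expect_true(canonical_key(toy$truth) %in% keys[["0.05"]])
})

test_that("GCS terminates and its nodes all satisfy the structural conditions", {
  d <- random_toy(60, pop = 3, meas = 2, cats = 3, seed = 23)
  ctl <- explore_control(alpha_stop = 0, max_vars = 3, expand_p = 0.3,
                         mining = fast_mining(), baseline_k = 5, seed = 8)
  fit <- contrast_mine(d, ctl)
  expect_gt(nrow(fit$pool), 0L)
  for (k in fit$pool$key) {
    scg <- subgroup_from_key(k)
    expect_lte(length(scg), 3L)
    expect_equal(anyDuplicated(scg$vars), 0L)
  }
  # memo contract: distinct canonical keys evaluated >= mining invocations
  expect_lte(fit$counts$mining_calls, fit$counts$registry)
})

test_that("blacklisted subgroup definitions are pruned from the search", {
  toy <- planted_toy()
  trivial_key <- canonical_key(contrast_subgroup(
    contrast_pair("sex", "F", "M")))
  ctl <- explore_control(alpha_stop = 0, max_vars = 2, expand_p = 1,
                         mining = fast_mining(), baseline_k = 5,
                         blacklist = trivial_key, seed = 9)
  fit <- contrast_mine(toy$data, ctl)
  expect_false(trivial_key %in% fit$pool$key)
})
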