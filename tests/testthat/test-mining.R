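test_that("pattern support counts matching records", {
  df <- data.frame(m1 = c(rep("a", 3), rep("b", 7)),
                   m2 = rep(c("x", "y"), 5), stringsAsFactors = FALSE)
  expect_equal(pattern_support(c(m1 = "a"), df), 0.3)
  expect_equal(pattern_support(c(m2 = "x"), df[df$m2 == "x", , drop = FALSE]),
               1.0)
  expect_equal(pattern_support(c(m1 = "z"), df), 0.0)
  expect_error(pattern_support(c(m1 = "a"), df[0, , drop = FALSE]), "empty")
})

test_that("frequent-pattern mining equals exhaustive enumeration on toys", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:12, 1)
    nm <- sample(2:6, 1)
    df <- as.data.frame(lapply(seq_len(nm), function(j)
      sample(paste0("c", 1:3), n, replace = TRUE)),
      optional = TRUE, stringsAsFactors = FALSE)
    names(df) <- paste0("m", seq_len(nm))
    for (alpha in c(0.25, 0.5, 1.0)) {
      got <- mine_frequent_patterns(df, alpha, max_len = 3)
      want <- oracle_itemsets(df, alpha, 3)
      expect_setequal(got$id, vapply(want, `[[`, "", "id"))
      ws <- vapply(want, `[[`, 0, "support")
      names(ws) <- vapply(want, `[[`, "", "id")
      expect_equal(got$support, unname(ws[got$id]), tolerance = 1e-12)
    }
  }
})

test_that("mining respects the Apriori property and the degenerate cases", {
  # single record: all 1- and 2-item subsets at support 1
  df1 <- data.frame(m1 = "a", m2 = "b", m3 = "c", stringsAsFactors = FALSE)
  got <- mine_frequent_patterns(df1, alpha = 0.5, max_len = 2)
  expect_equal(sort(got$id),
               sort(c("m1=a", "m2=b", "m3=c", "m1=a&m2=b", "m1=a&m3=c",
                      "m2=b&m3=c")))
  expect_true(all(got$support == 1))
  # alpha = 1: only patterns present in every record
  df2 <- data.frame(m1 = c("a", "a", "a"), m2 = c("x", "y", "x"),
                    stringsAsFactors = FALSE)
  got2 <- mine_frequent_patterns(df2, alpha = 1, max_len = 2)
  expect_equal(got2$id, "m1=a")
  # monotonicity: support of a superset never exceeds any subset
  d <- random_toy(30, pop = 1, meas = 4, cats = 2, seed = 5)
  df3 <- decode_dataset(d)[, d$meas_vars]
  got3 <- mine_frequent_patterns(df3, 0.2, 3)
  sup <- stats::setNames(got3$support, got3$id)
  for (i in which(got3$len > 1)) {
    p <- got3$pattern[[i]]
    for (drop in seq_along(p)) {
      sid <- paste0(names(p)[-drop], "=", p[-drop], collapse = "&")
      expect_gte(sup[[sid]], got3$support[i])
    }
  }
})

test_that("growth reproduces the published worked ratios and the capping rule", {
  expect_equal(round(growth_rate(0.208, 0.052), 2), 4.00)
  expect_equal(round(growth_rate(0.078, 0.237), 2), 3.04)
  expect_equal(round(growth_rate(0.078, 0.217), 2), 2.78)
  expect_equal(round(growth_rate(0.240, 0.092), 1), 2.6)
  expect_equal(round(growth_rate(0.327, 0.078), 2), 4.19)
  expect_equal(round(growth_rate(0.214, 0.078), 1), 2.7)
  expect_equal(growth_rate(0.3, 0.3), 1.0)
  expect_equal(growth_rate(0.2, 0, growth_max = 10), 10)
  expect_error(growth_rate(0, 0), "both supports")
})

test_that("normalized growth is monotone, bounded and matches direct evaluation", {
  expect_equal(growth_norm(10, 10), tanh(1) * 10, tolerance = 1e-12)
  expect_equal(round(growth_norm(10, 10), 4), 7.6159)
  expect_equal(round(growth_norm(1, 10), 4), 0.9967)
  g <- seq(1, 60, by = 0.5)
  gn <- growth_norm(g, 10)
  expect_true(all(diff(gn) > 0))
  expect_true(all(gn > 0 & gn < 10))
  expect_equal(growth_norm(1e9, 10), 10, tolerance = 1e-6)
  expect_error(growth_norm(2, 0), "positive")
})

test_that("Fisher wrapper matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               oracle_fisher(10, 0, 0, 10), tolerance = 1e-9)
  expect_equal(round(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)), 9),
               round(2 / choose(20, 10), 9))
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 0), 2)), 1.0)
  for (seed in 1:10) {
    set.seed(seed)
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab),
                 oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("outer significance demands enrichment inside the pair", {
  inner <- data.frame(m = rep("a", 10), stringsAsFactors = FALSE)
  outer <- data.frame(m = rep("b", 10), stringsAsFactors = FALSE)
  expect_true(outer_significant(c(m = "a"), inner, outer))
  half <- data.frame(m = rep(c("a", "b"), 5), stringsAsFactors = FALSE)
  expect_false(outer_significant(c(m = "a"), half, half))
  expect_true(outer_significant(c(m = "a"), inner,
                                outer[0, , drop = FALSE]))
})

test_that("effective-pattern extraction applies thresholds and subset dominance", {
  # planted pattern {m1=a}: s1 = 0.8, s2 = 0.2 -> growth 4, direction side1
  df <- data.frame(p = rep(c("g1", "g2"), each = 10),
                   m1 = c(rep("a", 8), rep("b", 2), rep("a", 2), rep("b", 8)),
                   m2 = rep(c("x", "y"), 10), stringsAsFactors = FALSE)
  d <- toy_data(df, "p")
  sp <- split_population(d, contrast_subgroup(contrast_pair("p", "g1", "g2")))
  pats <- extract_effective_patterns(sp, fast_mining(alpha_support = 0.5,
                                                     beta_growth = 2))
  row <- pats[pats$id == "m1=a", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$s1, 0.8)
  expect_equal(row$s2, 0.2)
  expect_equal(row$growth, 4.0)
  expect_equal(row$direction, "side1")
  # a pattern below the growth threshold is excluded
  expect_false("m2=x" %in% pats$id)   # s1 = s2 = 0.5, growth 1 < 2

  # superset dominated by a subset with strictly greater growth is dropped
  df2 <- data.frame(
    p = rep(c("g1", "g2"), each = 10),
    m1 = c(rep("a", 8), rep("z", 2), rep("a", 2), rep("z", 8)),
    m2 = c(rep("b", 6), rep("z", 4), rep("b", 2), rep("z", 8)),
    stringsAsFactors = FALSE)
  d2 <- toy_data(df2, "p")
  sp2 <- split_population(d2, contrast_subgroup(contrast_pair("p", "g1", "g2")))
  pats2 <- extract_effective_patterns(sp2, fast_mining(alpha_support = 0.5,
                                                       beta_growth = 2))
  g1 <- pats2$growth[pats2$id == "m1=a"]
  expect_length(g1, 1L)
  if ("m1=a&m2=b" %in% pats2$id)
    expect_gte(pats2$growth[pats2$id == "m1=a&m2=b"], g1)
  # construct an explicit dominance case: {m1=a} growth 4 vs {m1=a,m2=b}
  # growth 3 -> superset dropped
  sup1 <- pattern_support(c(m1 = "a", m2 = "b"),
                          decode_dataset(d2)[sp2$side1, d2$meas_vars])
  sup2 <- pattern_support(c(m1 = "a", m2 = "b"),
                          decode_dataset(d2)[sp2$side2, d2$meas_vars])
  if (sup2 > 0 && sup1 / sup2 < g1)
    expect_false("m1=a&m2=b" %in% pats2$id)
})

test_that("swapping the sides flips directions and preserves growth", {
  d <- planted_toy()$data
  scg <- contrast_subgroup(contrast_pair("sex", "F", "M"),
                           contrast_pair("age", "young", "old"))
  swp <- contrast_subgroup(contrast_pair("sex", "M", "F"),
                           contrast_pair("age", "old", "young"))
  ctl <- fast_mining()
  sp1 <- split_population(d, scg)
  # build the swapped split manually (canonical identity would dedupe)
  sp2 <- sp1; sp2$side1 <- sp1$side2; sp2$side2 <- sp1$side1
  class(sp2) <- "subgroup_split"
  pa <- extract_effective_patterns(sp1, ctl)
  pb <- extract_effective_patterns(sp2, ctl)
  expect_setequal(pa$id, pb$id)
  m <- match(pa$id, pb$id)
  expect_equal(pa$growth, pb$growth[m], tolerance = 1e-12)
  nt <- abs(pa$s1 - pa$s2) > 1e-12
  expect_true(all(pa$direction[nt] != pb$direction[m][nt]))
})
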