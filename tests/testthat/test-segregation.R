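test_that("group divergence follows the KL formula", {
  expect_equal(group_divergence(c(3, 3), c(0.5, 0.5)), 0)
  expect_equal(group_divergence(c(4, 0), c(0.5, 0.5)), 1)
  # 5M/1F group against a 6M/4F network of 10 nodes
  d <- group_divergence(c(M = 5, F = 1), c(M = 0.6, F = 0.4))
  expect_equal(d, 5 / 6 * log2((5 / 6) / 0.6) + 1 / 6 * log2((1 / 6) / 0.4))
  expect_equal(d, 0.184, tolerance = 5e-3)
  expect_error(group_divergence(c(0, 0), c(0.5, 0.5)), "empty group")
  expect_error(group_divergence(c(1, 1), c(1, 0)), "inconsistent")
})

test_that("total segregation is the size-weighted divergence sum", {
  ids <- paste0("s", 1:10)
  at <- make_attrs(ids, gender = c(rep("M", 5), "F", "M", rep("F", 3)))
  # groups: first six nodes (5M 1F), last four (1M 3F)
  part <- setNames(c(rep(1, 6), rep(2, 4)), ids)
  S <- total_segregation(part, at, "gender")
  d1 <- group_divergence(c(5, 1), c(0.6, 0.4))
  d2 <- group_divergence(c(1, 3), c(0.6, 0.4))
  expect_equal(S, 0.6 * d1 + 0.4 * d2, tolerance = 1e-12)
  expect_equal(S, 0.256, tolerance = 5e-3)

  # one group covering everything -> 0
  expect_equal(total_segregation(setNames(rep(1, 10), ids), at, "gender"), 0)
  expect_error(total_segregation(setNames(integer(0), character(0)), at, "gender"),
               "empty partition")
})

test_that("segregation is invariant to community and category relabeling", {
  ids <- paste0("s", 1:12)
  set.seed(3)
  at <- make_attrs(ids, gender = sample(c("F", "M"), 12, TRUE))
  part <- random_partition(ids, 3)
  S1 <- total_segregation(part, at, "gender")
  relab <- setNames(c(9, 1, 5)[part], names(part))
  expect_equal(total_segregation(relab, at, "gender"), S1, tolerance = 1e-12)
  flipped <- make_attrs(ids, gender = ifelse(at$gender == "F", "M", "F"))
  expect_equal(total_segregation(part, flipped, "gender"), S1, tolerance = 1e-12)
})

test_that("perfect segregation attains the entropy maximum exactly", {
  ids <- paste0("s", 1:20)
  sect <- rep(c("1", "2", "3", "4"), each = 5)
  at <- make_attrs(ids, section = sect,
                   vocab = list(section = as.character(1:4)))
  part <- setNames(as.integer(factor(sect)), ids)
  S <- total_segregation(part, at, "section")
  expect_equal(S, max_segregation(rep(0.25, 4)), tolerance = 1e-14)
  expect_equal(S, 2)
  # bounds hold for arbitrary partitions
  set.seed(8)
  for (i in 1:20) {
    p <- random_partition(ids, 5)
    s <- total_segregation(p, at, "section")
    expect_gte(s, 0)
    expect_lte(s, 2 + 1e-12)
  }
})

test_that("maximum segregation is the Shannon entropy", {
  expect_equal(max_segregation(c(0.5, 0.5)), 1)
  expect_equal(max_segregation(c(1, 0)), 0)
  expect_equal(max_segregation(c(0.6, 0.4)), 0.971, tolerance = 1e-3)
  expect_error(max_segregation(c(0.5, 0.3)), "sum to 1")
})

test_that("permutation Z-scores flag segregation and signal degenerate nulls", {
  ids <- sprintf("s%02d", 1:40)
  at_const <- make_attrs(ids)          # constant gender
  part <- setNames(rep(1:4, each = 10), ids)
  expect_warning(z0 <- segregation_zscore(part, at_const, "gender",
                                          m_perms = 50, seed = 1),
                 "zero variance")
  expect_true(is.na(z0$Z))
  expect_equal(z0$S, 0)

  # perfectly segregated balanced two-group case
  at_seg <- make_attrs(ids, gender = rep(c("F", "M"), each = 20))
  part2 <- setNames(rep(1:2, each = 20), ids)
  z1 <- segregation_zscore(part2, at_seg, "gender", m_perms = 1000, seed = 2)
  expect_gt(z1$Z, 1.96)
  expect_true(z1$significant)
  expect_equal(z1$S, z1$S_max, tolerance = 1e-12)

  # same seed, same result
  z2 <- segregation_zscore(part2, at_seg, "gender", m_perms = 1000, seed = 2)
  expect_identical(z1$Z, z2$Z)
})

test_that("per-group Z-scores identify which communities segregate", {
  ids <- sprintf("s%02d", 1:60)
  gender <- c(rep("F", 15), rep("M", 15), sample(rep(c("F", "M"), 15)))
  at <- make_attrs(ids, gender = gender)
  part <- setNames(rep(1:4, each = 15), ids)
  z <- segregation_zscore(part, at, "gender", m_perms = 500, seed = 5,
                          level = "per_group")
  expect_s3_class(z$groups, "data.frame")
  expect_equal(nrow(z$groups), 4L)
  expect_true(all(z$groups$significant[1:2]))  # the two pure communities
  expect_equal(z$groups$size, rep(15L, 4))
  expect_gte(min(z$groups$D_k), 0)
})

test_that("weekly Z-score series has one row per week and attribute", {
  cfg <- cohort_config(n_students = 50, n_sections = 4, n_weeks = 2,
                       participation = c(0.9, 0.9), seed = 6)
  coh <- generate_cohort(cfg)
  parts <- lapply(seq_along(coh$networks), function(t) {
    detect_communities(coh$networks[[t]], n_runs = 2, seed = t)
  })
  ser <- weekly_zscore_series(coh$networks, parts, coh$attrs, m_perms = 200,
                              seed = 3)
  expect_equal(nrow(ser), 2L * 3L)
  expect_setequal(unique(ser$attribute), c("gender", "section", "grade"))
  expect_true(all(ser$S >= 0 & ser$S <= ser$S_max + 1e-12))
  one <- weekly_zscore_series(coh$networks[1], parts[1], coh$attrs,
                              attributes = "section", m_perms = 100, seed = 1)
  expect_equal(nrow(one), 1L)
})
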