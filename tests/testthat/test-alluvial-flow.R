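test_that("identical consecutive partitions give only diagonal streamlines", {
  p <- c(A = 1, B = 1, C = 2, D = 2, E = 3)
  d <- build_alluvial(list(p, p))
  expect_equal(streamline_count(d, 1), 3L)
  expect_true(all(d$streams$from_community == d$streams$to_community))
  expect_true(all(d$boxes$color_class == "none"))
})

test_that("streamlines visualize the confusion matrix and conserve nodes", {
  px <- c(A = 1, B = 1, C = 2, D = 2)
  py <- c(A = 1, C = 1, B = 2, D = 2)
  d <- build_alluvial(list(px, py))
  expect_equal(streamline_count(d, 1), 4L)
  expect_true(all(d$streams$count == 1L))
  expect_equal(sum(d$streams$count), 4L)  # overlap conserved

  singles <- setNames(1:4, names(px))
  block <- setNames(rep(1, 4), names(px))
  d2 <- build_alluvial(list(singles, block))
  expect_equal(streamline_count(d2, 1), 4L)

  set.seed(14)
  nodes <- paste0("n", 1:30)
  parts <- lapply(1:3, function(i) random_partition(nodes, 4))
  d3 <- build_alluvial(parts)
  for (j in 1:2) {
    expect_equal(sum(d3$streams$count[d3$streams$from_column == j]), 30L)
  }
  expect_error(build_alluvial(list(c(A = 1), c(B = 1))), "no nodes")
})

test_that("box geometry is proportional to community size with one scale", {
  p1 <- c(A = 1, B = 1, C = 1, D = 2)
  p2 <- c(A = 1, B = 2, C = 2, D = 2)
  d <- build_alluvial(list(p1, p2), scale = 2)
  h <- d$boxes$y1 - d$boxes$y0
  expect_equal(h, d$boxes$size * 2)
  expect_true(all(diff(d$boxes$size[d$boxes$column == 1]) <= 0))
})

test_that("segregation flags color boxes by attribute", {
  p <- c(A = 1, B = 1, C = 2, D = 2)
  flags <- list(
    data.frame(community = 1:2, gender = c(TRUE, FALSE), section = c(TRUE, TRUE)),
    data.frame(community = 1:2, gender = c(FALSE, FALSE), section = c(FALSE, TRUE)))
  d <- build_alluvial(list(p, p), seg_flags = flags)
  b1 <- d$boxes[d$boxes$column == 1, ]
  expect_setequal(b1$color_class, c("both", "section"))
  b2 <- d$boxes[d$boxes$column == 2, ]
  expect_setequal(b2$color_class, c("none", "section"))
})

test_that("aggregated flows match the dense transition-matrix oracle", {
  chain <- weekly_network(data.frame(s = c("A", "B"), t = c("B", "C")), 1)
  part <- c(A = 1, B = 1, C = 2)
  fm <- aggregate_flow(chain, part, tau = 0.15)
  fl <- dense_flow(chain, tau = 0.15)
  memb <- unname(part[fl$names])
  want_12 <- sum(fl$p[memb == 1] * rowSums(fl$Tfull[memb == 1, memb == 2, drop = FALSE]))
  want_21 <- sum(fl$p[memb == 2] * rowSums(fl$Tfull[memb == 2, memb == 1, drop = FALSE]))
  got_12 <- fm$flows$flow[fm$flows$from == "1" & fm$flows$to == "2"]
  got_21 <- fm$flows$flow[fm$flows$from == "2" & fm$flows$to == "1"]
  expect_equal(got_12, want_12, tolerance = 1e-10)
  expect_equal(got_21, want_21, tolerance = 1e-10)
  expect_equal(fm$communities$visit_rate,
               c(sum(fl$p[memb == 1]), sum(fl$p[memb == 2])), tolerance = 1e-10)
})

test_that("flow maps respect symmetry and the one-module degenerate case", {
  g <- two_cliques()
  one <- setNames(rep(1, 8), paste0("n", 1:8))
  fm1 <- aggregate_flow(g, one)
  expect_equal(nrow(fm1$flows), 0L)
  expect_equal(sum(fm1$communities$visit_rate), 1, tolerance = 1e-10)

  two <- setNames(rep(1:2, each = 4), paste0("n", 1:8))
  fm2 <- aggregate_flow(g, two)
  expect_equal(fm2$flows$flow[1], fm2$flows$flow[2], tolerance = 1e-12)
  expect_gt(min(fm2$flows$flow), 0)  # teleportation flow crosses the cut
})

test_that("community size correlates positively but imperfectly with flow", {
  cfg <- cohort_config(n_students = 120, seed = 9)
  coh <- generate_cohort(cfg)
  net <- coh$networks[[3]]
  det <- detect_communities(net, n_runs = 3, seed = 2)
  fm <- aggregate_flow(net, det)
  keep <- fm$communities$size > 0
  rho <- suppressWarnings(
    stats::cor(fm$communities$size, fm$communities$visit_rate,
               method = "spearman"))
  expect_gt(rho, 0)
  expect_lt(rho, 1)
})

test_that("SVG rendering writes proportional geometry", {
  p1 <- c(A = 1, B = 1, C = 2)
  p2 <- c(A = 1, B = 1, C = 1)
  d <- build_alluvial(list(p1, p2))
  f <- withr::local_tempfile(fileext = ".svg")
  render_svg(d, f)
  svg <- readLines(f)
  expect_true(any(grepl("<svg", svg)))
  expect_equal(sum(grepl("<rect", svg)), 3L)          # three boxes
  expect_equal(sum(grepl("data-count", svg)), 2L)     # two streamlines
  # geometry metadata round trip: sizes recoverable from the file
  sizes <- as.integer(sub('.*data-size="(\\d+)".*', "\\1", grep("data-size", svg, value = TRUE)))
  expect_setequal(sizes, c(2L, 1L, 3L))

  fm <- aggregate_flow(two_cliques(), setNames(rep(1:2, each = 4), paste0("n", 1:8)))
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_svg(fm, f2)
  expect_equal(sum(grepl("<circle", readLines(f2))), 2L)

  expect_error(render_svg(structure(list(), class = "alluvial_diagram"), f),
               "empty|subscript")
  expect_error(render_svg(42, f), "cannot render")
})
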