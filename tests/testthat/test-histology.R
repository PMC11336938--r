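test_that("section rendering is seeded and respects the canvas", {
  spec <- grid_section(10, radius = 6)
  img1 <- render_section(spec, seed = 4)
  img2 <- render_section(spec, seed = 4)
  expect_identical(img1, img2)
  expect_false(identical(img1, render_section(spec, seed = 5)))
  expect_true(all(img1 >= 0 & img1 <= 1))

  # droplet protruding beyond the canvas is rejected
  expect_error(section_spec(64, cbind(2, 32), 5), "outside canvas")
  expect_error(section_spec(64, cbind(32, 32), -1), "positive")
})

test_that("segmentation recovers exact counts and sizes on clean fixtures", {
  # blank image -> empty table
  blank <- render_section(section_spec(128), seed = 1)
  expect_equal(nrow(segment_droplets(blank)), 0L)

  # 10 non-overlapping high-contrast disks -> exactly 10 objects
  spec <- grid_section(10, radius = 6)
  tab <- segment_droplets(render_section(spec, seed = 2))
  expect_equal(nrow(tab), 10L)

  # equivalent diameter within 10% of 2 * radius for disks >= 5 px radius
  for (r in c(5, 8, 12)) {
    spec_r <- grid_section(4, radius = r, spacing = 60)
    tab_r <- segment_droplets(render_section(spec_r, seed = 3))
    expect_equal(nrow(tab_r), 4L)
    expect_true(all(abs(tab_r$equiv_diameter - 2 * r) / (2 * r) < 0.1))
  }

  expect_error(segment_droplets(matrix(c(0, NA, 1, 1), 2)), "finite")
})

test_that("size binning is half-open and conserves counts", {
  tab <- data.frame(equiv_diameter = c(2.0, 6.9, 7.0),
                    area = 1:3, cx = 0, cy = 0)
  h <- size_distribution(tab, bins = c(2, 7, 13))
  expect_equal(unname(h$counts), c(2L, 1L))
  expect_equal(sum(h$counts), nrow(tab))

  empty <- size_distribution(tab[0, ], bins = c(2, 7, 13))
  expect_equal(unname(empty$counts), c(0L, 0L))

  # conservation on a segmented fixture whose diameters lie inside the bins
  spec <- grid_section(8, radius = 4)
  seg <- segment_droplets(render_section(spec, seed = 6))
  hh <- size_distribution(seg, bins = c(2, 7, 13))
  expect_equal(sum(hh$counts), nrow(seg))

  expect_error(size_distribution(tab, bins = c(7, 2)), "increasing")
})

test_that("per-bin ANOVA matches the textbook mean-square formula", {
  mk <- function(counts) {
    structure(list(counts = c("[2,7)" = counts[1], "[7,13)" = counts[2]),
                   bins = c(2, 7, 13), group = NA),
              class = "size_histogram")
  }
  # groups (1,2,3) vs (4,5,6) in the small bin:
  # SSB = 3*((2-3.5)^2 + (5-3.5)^2) = 13.5 on 1 df,
  # SSW = 2 + 2 = 4 on 4 df -> F = 13.5 / 1 = 13.5
  ga <- lapply(1:3, function(i) mk(c(i, 5)))
  gb <- lapply(4:6, function(i) mk(c(i, 5)))
  res <- compare_groups(ga, gb)
  expect_equal(res$F[1], 13.5, tolerance = 1e-9)
  expect_equal(res$p[1],
               stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical second bin: degenerate variance convention F = 0, p = 1
  expect_equal(res$F[2], 0)
  expect_equal(res$p[2], 1)

  # identical groups -> F = 0 everywhere
  same <- compare_groups(ga, ga)
  expect_equal(same$F[1], 0)

  # p decreases monotonically as separation grows at fixed spread
  ps <- vapply(c(1, 3, 6), function(shift) {
    compare_groups(ga, lapply(1:3, function(i) mk(c(i + shift, 5))))$p[1]
  }, 0)
  expect_true(all(diff(ps) < 0))

  # two-way decomposition is available
  tw <- attr(compare_groups(ga, gb, two_way = TRUE), "two_way")
  expect_true(all(c("group", "bin", "group:bin") %in% rownames(tw)))

  expect_error(compare_groups(ga[1], gb), "at least 2")
})

test_that("droplet labelling rule is a monotone threshold on small-droplet counts", {
  mk <- function(small, large) {
    structure(list(counts = c("[2,7)" = small, "[7,13)" = large),
                   bins = c(2, 7, 13), group = NA),
              class = "size_histogram")
  }
  expect_equal(label_from_droplets(mk(0, 0)), "healthy")
  expect_equal(label_from_droplets(mk(500, 0)), "nafld")

  # sweeping the threshold flips the label exactly once
  h <- mk(55, 10)
  labels <- vapply(0:120, function(th) label_from_droplets(h, th), "")
  flips <- sum(labels[-1] != labels[-length(labels)])
  expect_equal(flips, 1L)
  expect_equal(labels[1], "nafld")
  expect_equal(labels[length(labels)], "healthy")

  expect_error(label_from_droplets(mk(5, 5), small_range = c(3, 9)),
               "bins")
})

test_that("generated cohorts show the fatty-liver small-droplet surge end to end", {
  sections <- generate_sections(n_per_group = 6, seed = 8, size = 192)
  hist_of <- function(spec, seed) {
    size_distribution(segment_droplets(render_section(spec, seed)),
                      bins = c(2, 7, 13))
  }
  hh <- lapply(seq_along(sections$healthy),
               function(i) hist_of(sections$healthy[[i]], 100 + i))
  hn <- lapply(seq_along(sections$nafld),
               function(i) hist_of(sections$nafld[[i]], 200 + i))

  small_h <- vapply(hh, function(h) h$counts[[1]], 0)
  small_n <- vapply(hn, function(h) h$counts[[1]], 0)
  # stochastic dominance of the small-droplet bin under shipped defaults
  expect_gt(min(small_n), max(small_h))

  # ANOVA flags the small-droplet difference
  res <- compare_groups(hh, hn)
  expect_lt(res$p[1], 0.001)

  # the labelling rule recovers the generating groups
  expect_true(all(vapply(hn, label_from_droplets, "") == "nafld"))
  expect_true(all(vapply(hh, label_from_droplets, "") == "healthy"))

  # reproducibility of the generator
  sections2 <- generate_sections(n_per_group = 6, seed = 8, size = 192)
  expect_identical(sections, sections2)
})
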