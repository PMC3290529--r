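test_that("figure-ground textures are complementary with the right sums", {
  fg <- make_fg_texture(64, 16)
  expect_equal(sum(fg$feat1), 256)
  expect_equal(sum(fg$feat2), 3840)
  expect_true(all(unclass(fg$feat1) + unclass(fg$feat2) == 1))
  # centring convention on a tiny grid: rows/cols {2, 3} (1-based)
  fg4 <- make_fg_texture(4, 2)
  expect_equal(which(unclass(fg4$feat1) == 1, arr.ind = TRUE)[, "row"],
               rep(c(2L, 3L), 2), ignore_attr = TRUE)
  expect_error(make_fg_texture(16, 16))
  expect_error(make_fg_texture(16, 5))
})

test_that("pattern masks are Bernoulli, seeded and reproducible", {
  expect_equal(sum(make_pattern_mask(16, p = 0)), 0)
  expect_equal(sum(make_pattern_mask(16, p = 1)), 16^2)
  m1 <- make_pattern_mask(64, 0.5, seed = 42)
  m2 <- make_pattern_mask(64, 0.5, seed = 42)
  expect_identical(unclass(m1), unclass(m2))
  expect_true(abs(mean(m1) - 0.5) < 0.05)  # binomial 3-sigma is ~0.023
  # the session RNG state is untouched
  set.seed(7); before <- stats::runif(1)
  set.seed(7); invisible(make_pattern_mask(8, seed = 1)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("pattern-mask ones-counts match the binomial distribution", {
  n <- 300
  counts <- vapply(seq_len(n), function(s) sum(make_pattern_mask(32, 0.5, seed = s)),
                   numeric(1))
  mu <- 32^2 * 0.5
  sigma2 <- 32^2 * 0.25
  expect_lt(abs(mean(counts) - mu) / sqrt(sigma2 / n), 4)
  expect_gt(stats::var(counts) / sigma2, 0.7)
  expect_lt(stats::var(counts) / sigma2, 1.4)
  # chi-square sanity on standardized counts against a normal reference
  z <- (counts - mu) / sqrt(sigma2)
  br <- c(-Inf, -1, -0.5, 0, 0.5, 1, Inf)
  obs <- table(cut(z, br))
  expected <- diff(stats::pnorm(br)) * n
  chi <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_lt(chi, stats::qchisq(0.999, df = length(expected) - 1))
})

test_that("uniform masks are all ones and equal a p = 1 pattern mask", {
  u <- make_uniform_mask(16)
  expect_equal(sum(u), 256)
  expect_equal(unclass(u), unclass(make_pattern_mask(16, 1, seed = 3)),
               ignore_attr = TRUE)
  expect_true(all((1 - unclass(u)) == 0))
})

test_that("metacontrast target and mask have disjoint supports", {
  mp <- make_metacontrast_pair(64, 16)
  expect_equal(sum(mp$target), 256)
  expect_true(all(unclass(mp$target) * unclass(mp$mask) == 0))
  expect_equal(sum(mp$target) + sum(mp$mask), 64^2)
})

test_that("binary frames reject non-binary pixels", {
  expect_error(binary_frame(matrix(0.5, 4, 4)), "binary")
})

test_that("schedules discretize event times onto Euler steps", {
  fg <- make_fg_texture(8, 2)
  sch <- build_schedule(list(stim_event(1, fg$feat1, 0, 50)),
                        duration_ms = 100, dt = 0.2)
  expect_equal(schedule_drive(sch, 1, 0), unclass(fg$feat1), ignore_attr = TRUE)
  expect_equal(schedule_drive(sch, 1, 49.8), unclass(fg$feat1), ignore_attr = TRUE)
  expect_true(all(schedule_drive(sch, 1, 50) == 0))
  expect_true(all(schedule_drive(sch, 2, 10) == 0))
  expect_error(stim_event(1, fg$feat1, -5, 10))
})

test_that("overlapping events on one channel combine by pixel-wise OR", {
  a <- binary_frame(matrix(c(1, 1, 0, 0), 2, 2))
  b <- binary_frame(matrix(c(0, 1, 1, 0), 2, 2))
  sch <- build_schedule(list(stim_event(1, a, 0, 10, weight = 2),
                             stim_event(1, b, 0, 10, weight = 2)),
                        duration_ms = 10)
  expect_equal(schedule_drive(sch, 1, 5), 2 * matrix(c(1, 1, 1, 0), 2, 2))
})

test_that("schedules round-trip through YAML and JSON", {
  fg <- make_fg_texture(8, 2)
  sch <- build_schedule(list(stim_event(1, fg$feat1, 0, 50, weight = 2.5),
                             stim_event(2, fg$feat2, 10, 40)),
                        duration_ms = 120)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_schedule(sch, path)
    back <- read_schedule(path)
    expect_equal(back$duration_ms, sch$duration_ms)
    expect_equal(length(back$events), 2L)
    expect_equal(unclass(back$events[[1]]$frame), unclass(sch$events[[1]]$frame),
                 ignore_attr = TRUE)
    expect_equal(back$events[[1]]$weight, 2.5)
  }
})
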