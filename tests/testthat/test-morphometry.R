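test_that("particle records canonicalize dimensions and reject bad ones", {
  p <- particle_records(width = c(437, 100), length = c(59, 100))
  expect_equal(p$width, c(59, 100))
  expect_equal(p$length, c(437, 100))
  expect_error(particle_records(width = c(-1, 5)), "positive")
})

test_that("rod classification follows the width-and-aspect rule", {
  p <- particle_records(width = c(59, 100, 74, 74),
                        length = c(437, 100, 100, 148))
  cl <- classify_particles(p)$class
  expect_equal(cl, c("rod",          # 59 x 437: narrow and elongated
                     "carboxysome",  # isometric 100 nm
                     "carboxysome",  # narrow but aspect 1.35 < 2
                     "rod"))         # 74 x 148: aspect exactly 2
  # invariant under swapping the supplied dimensions
  p_swapped <- particle_records(width = c(437, 100, 100, 148),
                                length = c(59, 100, 74, 74))
  expect_equal(classify_particles(p_swapped)$class, cl)
})

test_that("class proportions reproduce the reported section and extract percentages", {
  sections <- particle_records(width = c(rep(100, 565), rep(59, 24)),
                               length = c(rep(100, 565), rep(437, 24)),
                               source = "section")
  tab <- class_proportions(classify_particles(sections))
  expect_equal(tab$n[tab$class == "rod"], 24L)
  expect_equal(tab$percent[tab$class == "rod"], 100 * 24 / 589,
               tolerance = 1e-12)
  expect_equal(tab$percent_rounded[tab$class == "rod"], 4)

  purified <- particle_records(width = c(rep(100, 412), rep(59, 78)),
                               length = c(rep(100, 412), rep(437, 78)),
                               source = "purified")
  tab2 <- class_proportions(classify_particles(purified))
  expect_equal(tab2$percent_rounded[tab2$class == "rod"], 16)
  # proportions sum to 100 and counts are conserved
  expect_equal(sum(tab2$percent), 100, tolerance = 1e-12)
  expect_equal(sum(tab2$n), 490L)
})

test_that("single-class and empty inputs are handled", {
  one <- classify_particles(particle_records(width = rep(100, 5)))
  tab <- class_proportions(one)
  expect_equal(tab$percent, 100)
  empty <- particle_records(width = 100)[0, ]
  class(empty) <- c("particle_records", "data.frame")
  expect_error(class_proportions(empty), "no particle")
})

test_that("distribution mode handles degenerate and two-replicate cases", {
  expect_error(size_distribution(numeric(0)), "empty")
  d <- size_distribution(rep(100, 60))
  m <- distribution_mode(d)
  expect_equal(m$mode, 100)
  expect_equal(m$sem, 0)
  two <- list(size_distribution(rep(100, 60), 1),
              size_distribution(rep(102, 60), 2))
  m2 <- distribution_mode(two)
  expect_equal(m2$mode, 101)
  expect_equal(m2$sem, 1)
})

test_that("replicate-mode estimation recovers the generating mode", {
  reps <- make_tracking_replicates(n_replicates = 19, seed = 11)
  m <- distribution_mode(reps)
  expect_equal(m$n_replicates, 19L)
  expect_lt(abs(m$mode - 100.3), 3 * m$sem)
})

test_that("mode estimation is scale-equivariant up to grid resolution", {
  set.seed(21)
  x <- stats::rlnorm(400, log(100), 0.1)
  m1 <- distribution_mode(size_distribution(x))$mode
  m3 <- distribution_mode(size_distribution(3 * x))$mode
  expect_equal(m3, 3 * m1, tolerance = 2 / (3 * m1))
})
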