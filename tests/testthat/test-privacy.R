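test_that("k-anonymity checks class-size histograms", {
  expect_true(check_k_anonymity(c(3, 3, 4), 3))
  expect_false(check_k_anonymity(c(3, 3, 4), 5))
  expect_true(check_k_anonymity(integer(), 7))
  expect_error(check_k_anonymity(c(3, 3), 0), ">= 1")
})

test_that("is_satisfied dispatches on the model and accepts empty output", {
  ctx <- toy_ctx()
  expect_true(is_satisfied(apply_scheme(ctx, c(2L, 0L)), k_anonymity(3)))
  expect_false(is_satisfied(apply_scheme(ctx, c(0L, 0L)), k_anonymity(5)))
  empty <- apply_scheme(ctx, c(0L, 0L))
  empty$suppressed[] <- TRUE
  expect_true(is_satisfied(empty, k_anonymity(99)))
  expect_true(is_satisfied(empty, population_uniqueness(0.01, 0.1)))
})

test_that("k-anonymity is monotone on the lattice without suppression", {
  for (seed in 41:55) {
    ctx <- random_instance(seed)
    k <- ctx$privacy$k
    g <- random_scheme(ctx$heights)
    lift <- lift_scheme(g, ctx$heights)
    sat_g <- check_k_anonymity(
      equivalence_classes(apply_scheme(ctx, g))$sizes, k)
    sat_l <- check_k_anonymity(
      equivalence_classes(apply_scheme(ctx, lift))$sizes, k)
    if (sat_g) expect_true(sat_l)
  }
})

test_that("Pitman moment expectations match a sequential-sampler oracle", {
  set.seed(71)
  for (p in list(c(5, 0.4), c(2, 0), c(0.5, 0.7))) {
    n <- 30L
    sims <- replicate(1500, {
      s <- crp_sample(p[1], p[2], n)
      c(length(s), sum(s == 1))
    })
    expect_equal(latticeanon:::pitman_expected_classes(p[1], p[2], n),
                 mean(sims[1, ]), tolerance = 0.05)
    expect_equal(latticeanon:::pitman_expected_singletons(p[1], p[2], n),
                 mean(sims[2, ]), tolerance = 0.08)
  }
})

test_that("fit_pitman solves the moment system and survives degeneracy", {
  # moment equations hold at the fitted parameters
  sizes <- c(rep(1L, 12), rep(2L, 6), rep(3L, 3), 10L, 25L)
  f <- fit_pitman(sizes)
  expect_true(f$converged)
  expect_equal(latticeanon:::pitman_expected_classes(f$theta, f$alpha, f$n),
               f$u, tolerance = 1e-6)
  expect_equal(latticeanon:::pitman_expected_singletons(f$theta, f$alpha, f$n),
               f$u1, tolerance = 1e-6)
  expect_true(f$alpha >= 0 && f$alpha < 1 && f$theta > -f$alpha)

  # no singletons: degenerate, downstream estimate 0
  f0 <- fit_pitman(c(2L, 3L, 4L))
  expect_true(f0$degenerate)
  expect_false(f0$converged)
  expect_equal(estimate_population_uniqueness(c(2, 3, 4), 0.5), 0)

  # all singletons: boundary case must not crash, fallback applied
  f1 <- fit_pitman(rep(1L, 40))
  expect_false(f1$converged)
  est <- estimate_population_uniqueness(rep(1, 40), 0.5)
  expect_true(est >= 0 && est <= 1)

  expect_error(fit_pitman(integer()), "empty")
})

test_that("population-uniqueness estimate is exact at full sampling", {
  expect_identical(estimate_population_uniqueness(c(1, 1, 2), 1), 0.5)
  expect_identical(estimate_population_uniqueness(c(5, 5), 1), 0)
  expect_identical(estimate_population_uniqueness(integer(), 0.3), 0)
  expect_error(estimate_population_uniqueness(c(1, 2), 0), "\\(0, 1\\]")
  expect_error(estimate_population_uniqueness(c(1, 2), 1.2), "\\(0, 1\\]")
})

test_that("suppressing singletons never raises the uniqueness estimate", {
  set.seed(72)
  for (r in 1:60) {
    sizes <- c(rep(1L, sample(1:20, 1)),
               sample(2:30, sample(1:15, 1), replace = TRUE))
    pi <- runif(1, 0.05, 0.9)
    e_before <- estimate_population_uniqueness(sizes, pi)
    e_after <- estimate_population_uniqueness(sizes[-match(1L, sizes)], pi)
    expect_lte(e_after, e_before + 1e-9)
  }
})

test_that("fitted parameters recover simulation truth at moderate size", {
  set.seed(73)
  ests <- replicate(8, {
    f <- fit_pitman(crp_sample(80, 0.25, 2000))
    c(f$theta, f$alpha)
  })
  expect_lt(abs(median(ests[1, ]) - 80) / 80, 0.3)
  expect_lt(abs(median(ests[2, ]) - 0.25), 0.15)
})
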