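test_that("scheme evaluation = recode, suppress, score", {
  ctx <- toy_ctx(k_anonymity(3))
  e20 <- evaluate_scheme(ctx, c(2L, 0L))
  expect_equal(e20$quality, 50)
  expect_equal(e20$n_suppressed, 0L)
  e00 <- evaluate_scheme(ctx, c(0L, 0L))
  expect_equal(e00$quality, 0)
  expect_equal(e00$n_suppressed, 8L)
  ctx2 <- toy_ctx(k_anonymity(2))
  e2 <- evaluate_scheme(ctx2, c(0L, 0L))
  expect_equal(e2$quality, 100)
  expect_equal(e2$n_suppressed, 0L)
})

test_that("exhaustive search returns the lattice optimum with lexicographic ties", {
  ctx <- toy_ctx(k_anonymity(3))
  res <- search_exhaustive(ctx)
  expect_identical(res$scheme, c(2L, 0L))
  expect_equal(res$quality, 50)
  expect_equal(res$evaluations, 6L)

  res2 <- search_exhaustive(toy_ctx(k_anonymity(2)))
  expect_identical(res2$scheme, c(0L, 0L))
  expect_equal(res2$quality, 100)

  # single-attribute lattice, k = 1: nothing is ever suppressed
  syn <- generate_dataset(20, list(list(domain_size = 4)), seed = 5)
  ctx1 <- anon_context(syn$data, syn$hierarchies, k_anonymity(1))
  r1 <- search_exhaustive(ctx1)
  expect_identical(r1$scheme, 0L)
  expect_equal(r1$quality, 100)

  expect_error(search_exhaustive(ctx, cap = 3), "cap")
})

test_that("greedy best-first reaches the exhaustive optimum at exhaustion", {
  ctx <- toy_ctx(k_anonymity(3))
  for (dir in c("bottom_up", "top_down")) {
    res <- search_greedy(ctx, dir)
    expect_identical(res$scheme, c(2L, 0L))
    expect_equal(res$quality, 50)
    expect_equal(res$evaluations, 6L)  # whole 6-node lattice evaluated
  }
})

test_that("greedy respects evaluation budgets between evaluations", {
  ctx <- toy_ctx(k_anonymity(3))
  res <- search_greedy(ctx, "bottom_up",
                       budget = search_budget(max_evaluations = 1))
  expect_equal(res$evaluations, 1L)
  expect_identical(res$scheme, c(0L, 0L))
  res3 <- search_greedy(ctx, "top_down",
                        budget = search_budget(max_evaluations = 3))
  expect_equal(res3$evaluations, 3L)
})

test_that("triangle initialization follows the cumulative pattern", {
  expect_equal(triangle_init(c(3, 1, 5, 3, 1), 10),
               rbind(c(0, 0, 0, 0, 0), c(3, 0, 0, 0, 0), c(3, 1, 0, 0, 0),
                     c(3, 1, 5, 0, 0), c(3, 1, 5, 3, 0), c(3, 1, 5, 3, 1)))
  expect_equal(triangle_init(2, 5), rbind(0L, 2L))
  expect_equal(triangle_init(c(3, 2), 1), matrix(c(0L, 0L), nrow = 1))
})

test_that("next_generation fills elite, crossover, and mutant blocks", {
  heights <- rep(3L, 16)
  set.seed(80)
  pop <- latticeanon:::random_schemes(heights, 50L)
  fitness <- seq(100, 2, length.out = 50)
  cfg <- ga_config()
  set.seed(81)
  nxt <- next_generation(pop, fitness, cfg, heights)
  expect_equal(dim(nxt), dim(pop))
  # defaults at s = 50: 10 elite copied unchanged (fitness already sorted)
  expect_identical(nxt[1:10, ], pop[1:10, ])
  # every individual stays within the lattice bounds
  expect_true(all(nxt >= 0L) && all(sweep(nxt, 2, heights, "<=")))
  # mutation bound for m = 16, p = 0.05: exactly one gene changes per mutant
  n_changed <- vapply(31:50, function(i)
    min(vapply(seq_len(50), function(j) sum(pop[j, ] != nxt[i, ]),
               integer(1))), integer(1))
  expect_true(all(n_changed <= 1L))
  # fixed seed reproduces the generation bit for bit
  set.seed(81)
  expect_identical(next_generation(pop, fitness, cfg, heights), nxt)
})

test_that("genetic search finds the optimum of a tiny lattice for any seed", {
  for (seed in c(1L, 7L, 123L)) {
    res <- search_genetic(toy_ctx(k_anonymity(3)), seed = seed)
    expect_equal(res$quality, 50)
    expect_identical(res$scheme, c(2L, 0L))
  }
})

test_that("a pure-elite configuration freezes the population", {
  cfg <- ga_config(elite_fraction = 1, crossover_fraction = 0,
                   subpopulation_size = 10, iterations = 5)
  ctx <- toy_ctx(k_anonymity(3))
  res <- search_genetic(ctx, cfg, seed = 3L)
  # all evaluations happen during initialization; iterating adds none
  expect_lte(res$evaluations, 20L)
  expect_equal(res$quality, 50)  # 6-node lattice: init alone finds the top
})

test_that("genetic search is deterministic per seed and traces monotonically", {
  ctx <- toy_ctx(k_anonymity(3))
  a <- search_genetic(ctx, ga_config(iterations = 5), seed = 11L)
  b <- search_genetic(ctx, ga_config(iterations = 5), seed = 11L)
  expect_identical(a$scheme, b$scheme)
  expect_identical(a$trace$quality, b$trace$quality)
  expect_identical(a$trace$scheme, b$trace$scheme)
  expect_true(all(diff(a$trace$quality) >= 0))
})

test_that("subpopulation best fitness never decreases across generations", {
  syn <- generate_dataset(80, lapply(c(8, 8, 4, 4), function(d)
    list(domain_size = d, distribution = "zipf")), seed = 17)
  ctx <- anon_context(syn$data, syn$hierarchies, k_anonymity(3))
  st <- latticeanon:::new_search_state(ctx)
  cfg <- ga_config(subpopulation_size = 12, iterations = 8)
  set.seed(90)
  pop <- latticeanon:::random_schemes(ctx$heights, 12L)
  fit <- latticeanon:::pop_fitness(st, pop)
  best <- max(fit)
  for (i in 1:8) {
    pop <- next_generation(pop, fit, cfg, ctx$heights)
    fit <- latticeanon:::pop_fitness(st, pop)
    expect_gte(max(fit), best)
    best <- max(fit)
  }
})

test_that("heuristics never beat the exhaustive oracle and memoization is sound", {
  for (seed in 101:115) {
    ctx <- random_instance(seed, max_attrs = 4L)
    ex <- search_exhaustive(ctx, cap = 2000)
    ga <- search_genetic(ctx, ga_config(subpopulation_size = 10,
                                        iterations = 5), seed = seed)
    bu <- search_greedy(ctx, "bottom_up",
                        budget = search_budget(max_evaluations = 20))
    expect_lte(ga$quality, ex$quality + 1e-9)
    expect_lte(bu$quality, ex$quality + 1e-9)
    # evaluating the same scheme twice yields the identical quality
    e1 <- evaluate_scheme(ctx, ex$scheme)
    e2 <- evaluate_scheme(ctx, ex$scheme)
    expect_identical(e1$quality, e2$quality)
    expect_equal(ex$quality, e1$quality)
  }
})
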