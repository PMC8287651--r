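test_that("harmonic inertia weight follows its closed form", {
  expect_equal(inertia_weight(1, 0.9, 0.4, 100), 0.9)        # m = 1
  expect_equal(inertia_weight(101, 0.9, 0.4, 100), 0.4)      # m = t + 1
  expect_equal(inertia_weight(51, 0.9, 0.4, 100), 0.775)     # interior
  # monotone non-increasing and bounded on [omega2, omega1]
  w <- inertia_weight(1:101, 0.9, 0.4, 100)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0.4 & w <= 0.9))
  expect_error(inertia_weight(1, 0.9, 0.4, 0), "positive")
  expect_error(inertia_weight(0, 0.9, 0.4, 10), "must lie")
})

test_that("pso update matches the velocity/position equations by hand", {
  cfg <- pso_config(c1 = 2, c2 = 2)
  # scalar case: v = 0.8*0.5 + 2*0.5*(2-1) + 2*0.25*(3-1) = 2.4; x = 3.4
  p <- list(position = 1, velocity = 0.5, best_position = 2,
            best_fitness = 0, fitness = 0)
  up <- pso_update(p, gbest_position = 3, omega = 0.8, config = cfg,
                   bounds = NULL, r1 = 0.5, r2 = 0.25)
  expect_equal(up$velocity, 2.4)
  expect_equal(up$position, 3.4)
  # r1 = r2 = 0: velocity only decays by inertia, position advances by it
  up0 <- pso_update(p, 3, omega = 1, cfg, bounds = NULL, r1 = 0, r2 = 0)
  expect_equal(up0$velocity, 0.5)
  expect_equal(up0$position, 1.5)
  # x = p_i = p_g with zero velocity is a fixed point
  pfix <- list(position = c(2, 2), velocity = c(0, 0),
               best_position = c(2, 2), best_fitness = 1, fitness = 1)
  upf <- pso_update(pfix, c(2, 2), 0.9, cfg, bounds = NULL, r1 = 0.7, r2 = 0.3)
  expect_equal(upf$position, c(2, 2))
  expect_equal(upf$velocity, c(0, 0))
})

test_that("pso update clamps velocity and position to the bounds", {
  b <- bounds_spec()
  cfg <- pso_config()
  p <- list(position = c(99, 2.9), velocity = c(50, 3),
            best_position = c(100, 3), best_fitness = 1, fitness = 1)
  up <- pso_update(p, c(100, 3), 1, cfg, bounds = b, r1 = 1, r2 = 1)
  expect_true(all(up$position >= b$lower & up$position <= b$upper))
  expect_true(all(abs(up$velocity) <= b$vmax + 1e-12))
})

test_that("metropolis acceptance is always true for non-worsening moves", {
  set.seed(1)
  expect_true(sa_accept(0, 0.5))
  expect_true(sa_accept(0.2, 1e-6))
  expect_error(sa_accept(-0.1, 0), "positive")
  # near-zero temperature rejects essentially all worsening moves
  set.seed(2)
  rej <- replicate(1000, sa_accept(-0.1, 1e-8))
  expect_equal(sum(rej), 0)
})

test_that("metropolis acceptance frequency matches exp(df/t) within 3 sigma", {
  n <- 1e5
  for (case in list(c(df = -log(2), t = 1),       # p = 0.5
                    c(df = -0.05, t = 0.1),       # p = exp(-0.5)
                    c(df = -0.2, t = 0.5))) {
    p_true <- exp(case["df"] / case["t"])
    set.seed(round(1000 * p_true))
    acc <- replicate(n, sa_accept(case[["df"]], case[["t"]]))
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(acc) - p_true), 3 * se)
  }
})

test_that("a GA generation preserves size, elitism and bounds", {
  b <- bounds_spec()
  f <- injected_fitness(10, 1)
  set.seed(4)
  pop <- lapply(1:10, function(i) {
    z <- runif(2, b$lower, b$upper)
    list(genes = z, fitness = f(z[1], 10^z[2]))
  })
  # identity generation: no crossover, no mutation, full elitism
  cfg_id <- ga_config(pop_size = 10, crossover_prob = 0, mutation_prob = 0,
                      elitism = 10)
  out <- ga_generation(pop, cfg_id, b, f)
  expect_setequal(sapply(out$population, function(p) p$fitness),
                  sapply(pop, function(p) p$fitness))
  expect_equal(out$evaluations, 0L)
  # normal generation: size kept, best kept, genes in bounds
  cfg <- ga_config(pop_size = 10)
  set.seed(5)
  out2 <- ga_generation(pop, cfg, b, f)
  expect_length(out2$population, 10)
  expect_gte(max(sapply(out2$population, `[[`, "fitness")),
             max(sapply(pop, `[[`, "fitness")))
  for (p in out2$population) {
    expect_true(all(p$genes >= b$lower & p$genes <= b$upper))
  }
})

test_that("migration moves the better incumbent into the other population", {
  chrom <- function(g, f) list(genes = g, fitness = f)
  part <- function(x, f) list(position = x, velocity = c(1, 1), fitness = f,
                              best_position = x, best_fitness = f)
  pop <- list(chrom(c(1, 0), 0.95), chrom(c(2, 0), 0.5))
  swarm <- list(part(c(3, 1), 0.99), part(c(4, 1), 0.6))
  # swarm ahead: worst chromosome takes the global best position
  m <- migrate(pop, swarm)
  expect_equal(m$population[[2]]$genes, c(3, 1))
  expect_equal(m$population[[2]]$fitness, 0.99)
  expect_length(m$swarm, 2)
  # GA ahead: worst particle moves to the best chromosome, velocity zeroed
  pop2 <- list(chrom(c(1, 0), 0.99), chrom(c(2, 0), 0.5))
  swarm2 <- list(part(c(3, 1), 0.95), part(c(4, 1), 0.6))
  m2 <- migrate(pop2, swarm2)
  expect_equal(m2$swarm[[2]]$position, c(1, 0))
  expect_equal(m2$swarm[[2]]$velocity, c(0, 0))
  expect_equal(m2$swarm[[2]]$best_fitness, 0.99)
  # exact tie resolves in the swarm-to-GA direction
  pop3 <- list(chrom(c(1, 0), 0.9), chrom(c(2, 0), 0.5))
  swarm3 <- list(part(c(3, 1), 0.9))
  m3 <- migrate(pop3, swarm3)
  expect_equal(m3$population[[2]]$genes, c(3, 1))
})

test_that("the fused engine recovers an injected peak and is deterministic", {
  f <- injected_fitness(10, 1)
  r1 <- run_gsp(f, generations = 30, seed = 7)
  r2 <- run_gsp(f, generations = 30, seed = 7)
  expect_identical(r1, r2)
  # within 5% of the peak (c linear, g on log scale over its 5-decade span)
  expect_lt(abs(r1$best_params$c - 10) / 10, 0.05)
  expect_lt(abs(log10(r1$best_params$g)) / 5, 0.05)
  r3 <- run_gsp(f, generations = 30, seed = 8)
  expect_false(identical(r1$best_params, r3$best_params))
})

test_that("constant fitness yields a flat history at that constant", {
  f <- function(c, g) 0.42
  r <- run_gsp(f, generations = 5, patience = NULL, seed = 1)
  expect_equal(r$best_fitness, 0.42)
  expect_true(all(r$history$best_fitness == 0.42))
  expect_error(run_gsp(f, generations = 0), "positive")
})

test_that("best-fitness history is non-decreasing for every engine", {
  f <- injected_fitness(3, 0.2, curvature = 0.5)
  for (r in list(run_gsp(f, generations = 20, seed = 3),
                 run_ga(f, generations = 20, seed = 3),
                 run_pso(f, generations = 20, seed = 3))) {
    expect_true(all(diff(r$history$best_fitness) >= 0))
    b <- bounds_spec()
    expect_true(r$best_params$c >= b$c_min && r$best_params$c <= b$c_max)
    expect_true(r$best_params$g >= b$g_min && r$best_params$g <= b$g_max)
  }
})

test_that("emitted parameters respect arbitrary bounds (property)", {
  set.seed(77)
  for (i in 1:5) {
    cmin <- runif(1, 0.1, 1); cmax <- cmin * runif(1, 5, 50)
    gmin <- 10^runif(1, -2, -1); gmax <- gmin * 10^runif(1, 1, 4)
    b <- bounds_spec(cmin, cmax, gmin, gmax)
    peak_c <- runif(1, cmin, cmax)
    peak_g <- 10^runif(1, log10(gmin), log10(gmax))
    f <- injected_fitness(peak_c, peak_g)
    r <- run_gsp(f, bounds = b, generations = 10, seed = i)
    expect_true(r$best_params$c >= cmin && r$best_params$c <= cmax)
    expect_true(r$best_params$g >= gmin - 1e-12 &&
                r$best_params$g <= gmax + 1e-12)
  }
})

test_that("single-engine baselines near-match the exhaustive grid optimum", {
  f <- injected_fitness(10, 1)
  grid_best <- grid_search(f, resolution = 200)$best_fitness
  ga_best <- run_ga(f, generations = 20, seed = 11)$best_fitness
  pso_best <- run_pso(f, generations = 20, seed = 11)$best_fitness
  expect_gte(ga_best, 0.95 * grid_best)
  expect_gte(pso_best, 0.95 * grid_best)
})

test_that("a lone stationary particle stays put with a flat history", {
  f <- function(c, g) 0.5
  cfg <- pso_config(swarm_size = 1)
  r <- run_pso(f, pso = cfg, generations = 5, patience = NULL, seed = 1)
  expect_true(all(r$history$best_fitness == 0.5))
  expect_equal(length(unique(r$history$best_c)), 1L)
})

test_that("grid search scans the lattice exactly and breaks ties low", {
  f <- injected_fitness(10, 1)
  r <- grid_search(f, resolution = c(50, 50))
  # independent exhaustive scan
  cg <- 10^seq(log10(0.1), log10(100), length.out = 50)
  gg <- 10^seq(log10(0.01), log10(1000), length.out = 50)
  vals <- outer(cg, gg, f)
  expect_equal(r$best_fitness, max(vals))
  expect_equal(r$evaluations, 2500L)
  # tiny lattice with distinct values finds the exact argmax
  f2 <- function(c, g) c + log10(g)
  r2 <- grid_search(f2, resolution = 2)
  expect_equal(r2$best_params$c, 100)
  expect_equal(r2$best_params$g, 1000)
  # all-equal fitness resolves to the smallest (c, g) lattice point
  r3 <- grid_search(function(c, g) 1, resolution = 4)
  expect_equal(r3$best_params$c, 0.1)
  expect_equal(r3$best_params$g, 0.01)
  expect_error(grid_search(f, resolution = 1), ">= 2")
})

test_that("convergence histories export as CSV", {
  r <- run_ga(injected_fitness(10, 1), generations = 5, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_history_csv(r, path)
  df <- read.csv(path)
  expect_named(df, c("generation", "best_fitness", "mean_fitness",
                     "best_c", "best_g"))
})
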