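#' Search bounds for the (c, g) plane
#'
#' The penalty parameter `c` is searched linearly; the kernel coefficient
#' `g` spans five decades so it is searched on the log10 scale internally
#' (reported values are always back-transformed). Velocity limits for the
#' swarm default to +/- `velocity_frac` of each internal dimension's span.
#'
#' @param c_min,c_max Bounds on the penalty parameter (default 0.1, 100).
#' @param g_min,g_max Bounds on the kernel coefficient (default 0.01, 1000).
#' @param velocity_frac Velocity limit as a fraction of each span.
#' @return A `gsp_bounds` object.
#' @export
bounds_spec <- function(c_min = 0.1, c_max = 100, g_min = 0.01, g_max = 1000,
                        velocity_frac = 0.2) {
  if (c_min >= c_max || g_min >= g_max) {
    stop("bounds must satisfy min < max", call. = FALSE)
  }
  if (c_min <= 0 || g_min <= 0) stop("bounds must be positive", call. = FALSE)
  lower <- c(c_min, log10(g_min))
  upper <- c(c_max, log10(g_max))
  vmax <- velocity_frac * (upper - lower)
  structure(list(c_min = c_min, c_max = c_max, g_min = g_min, g_max = g_max,
                 lower = lower, upper = upper, vmax = vmax),
            class = "gsp_bounds")
}

# internal <-> user space: z = (c, log10 g)
.to_params <- function(z) list(c = z[1], g = 10^z[2])
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
.eval_z <- function(fn, z) {
  p <- .to_params(z)
  fn(p$c, p$g)
}

#' PSO engine configuration
#' @param swarm_size Number of particles (default 20).
#' @param c1,c2 Self- and global-learning acceleration factors (default 2).
#' @param omega1,omega2 Initial and final inertia weights of the harmonic
#'   schedule (defaults 0.9 and 0.4); requires `omega1 >= omega2 > 0`.
#' @return A `pso_config` list.
#' @export
pso_config <- function(swarm_size = 20L, c1 = 2, c2 = 2,
                       omega1 = 0.9, omega2 = 0.4) {
  if (!(omega1 >= omega2 && omega2 > 0)) {
    stop("need omega1 >= omega2 > 0", call. = FALSE)
  }
  if (c1 <= 0 || c2 <= 0) stop("acceleration factors must be positive",
                               call. = FALSE)
  structure(list(swarm_size = as.integer(swarm_size), c1 = c1, c2 = c2,
                 omega1 = omega1, omega2 = omega2), class = "pso_config")
}

#' Simulated-annealing configuration
#'
#' Geometric cooling `T_{k+1} = alpha * T_k`. When `T0` is `NULL` the
#' initial temperature is calibrated from the initial swarm so that the
#' median fitness deficit from the incumbent best is accepted with
#' probability one half.
#' @param T0 Initial temperature (positive), or `NULL` to auto-calibrate.
#' @param alpha Cooling factor in (0, 1) (default 0.95).
#' @param K Scale constant multiplying the temperature in the acceptance
#'   exponent (default 1).
#' @return An `sa_config` list.
#' @export
sa_config <- function(T0 = NULL, alpha = 0.95, K = 1) {
  if (!is.null(T0) && T0 <= 0) stop("`T0` must be positive", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (K <= 0) stop("`K` must be positive", call. = FALSE)
  structure(list(T0 = T0, alpha = alpha, K = K), class = "sa_config")
}

#' GA engine configuration
#' @param pop_size Population size (default 20).
#' @param crossover_prob Probability a child is produced by arithmetic
#'   (blend) crossover rather than copied from one parent (default 0.8).
#' @param mutation_prob Per-gene Gaussian mutation probability (default 0.1);
#'   mutation noise is scaled to 10\% of each bound's span.
#' @param elitism Number of best chromosomes carried over unchanged
#'   (default 1; must be below `pop_size`).
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 20L, crossover_prob = 0.8,
                      mutation_prob = 0.1, elitism = 1L) {
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (elitism >= pop_size && pop_size > 1L && elitism != pop_size) {
    stop("`elitism` must be below `pop_size`", call. = FALSE)
  }
  structure(list(pop_size = as.integer(pop_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism)), class = "ga_config")
}

#' Harmonic inertia weight schedule
#'
#' `omega_m = omega1 - (omega1 - omega2) * (m - 1)^2 / t^2`: the swarm
#' starts exploratory (large inertia) and shifts quadratically toward
#' exploitation, reaching `omega2` at generation `t + 1`.
#'
#' @param m Generation index, `1 <= m <= t + 1`.
#' @param omega1,omega2 Initial and final inertia weights, `omega1 >= omega2`.
#' @param t Maximum number of generations (positive).
#' @return The inertia weight at generation `m`.
#' @examples
#' inertia_weight(51, 0.9, 0.4, 100)
#' @export
inertia_weight <- function(m, omega1, omega2, t) {
  if (t <= 0) stop("`t` must be positive", call. = FALSE)
  if (omega1 < omega2) stop("need omega1 >= omega2", call. = FALSE)
  if (any(m < 1 | m > t + 1)) stop("`m` must lie in [1, t + 1]", call. = FALSE)
  omega1 - (omega1 - omega2) * (m - 1)^2 / t^2
}

#' One PSO velocity/position update
#'
#' `v <- omega * v + c1 * r1 * (p_i - x) + c2 * r2 * (p_g - x)` followed by
#' `x <- x + v`, with the velocity clamped to the bounds' limits and the
#' position clamped into the search box. Operates in the internal search
#' space (`c` linear, `g` on log10).
#'
#' @param particle List with `position`, `velocity`, `best_position`,
#'   `best_fitness`, `fitness` (internal coordinates).
#' @param gbest_position Global best position (internal coordinates).
#' @param omega Inertia weight for this generation.
#' @param config A [pso_config()].
#' @param bounds A [bounds_spec()]; pass `NULL` to skip clamping (useful for
#'   checking the raw update rule).
#' @param r1,r2 Uniform(0,1) draws; drawn from the current RNG stream when
#'   omitted.
#' @return The updated particle (fitness fields untouched).
#' @export
pso_update <- function(particle, gbest_position, omega, config,
                       bounds = NULL, r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- stats::runif(1)
  if (is.null(r2)) r2 <- stats::runif(1)
  v <- omega * particle$velocity +
    config$c1 * r1 * (particle$best_position - particle$position) +
    config$c2 * r2 * (gbest_position - particle$position)
  if (!is.null(bounds)) v <- .clamp(v, -bounds$vmax, bounds$vmax)
  x <- particle$position + v
  if (!is.null(bounds)) x <- .clamp(x, bounds$lower, bounds$upper)
  particle$velocity <- v
  particle$position <- x
  particle
}

#' Metropolis acceptance rule
#'
#' Fitness-improving or neutral moves (`delta_f >= 0`) are always accepted;
#' a worsening move is accepted with probability `exp(delta_f / t_temp)`,
#' by comparison with a Uniform(0,1) draw. This lets the swarm escape local
#' optima early (high temperature) while becoming greedy as the temperature
#' cools.
#'
#' @param delta_f Fitness change of the proposed move (new minus old).
#' @param t_temp Current temperature control value `K * T`, positive.
#' @return `TRUE` to accept the move.
#' @export
sa_accept <- function(delta_f, t_temp) {
  if (t_temp <= 0) stop("`t_temp` must be positive", call. = FALSE)
  if (delta_f >= 0) return(TRUE)
  exp(delta_f / t_temp) > stats::runif(1)
}

# tournament selection, size 2: index of the fitter of two random picks
.tournament <- function(fitness) {
  i <- sample.int(length(fitness), 2L, replace = TRUE)
  i[which.max(fitness[i])]
}

#' One genetic-algorithm generation
#'
#' Real-coded GA step: the top `elitism` chromosomes survive unchanged;
#' the rest of the population is refilled with tournament-selected (size 2)
#' parents recombined by arithmetic blend crossover and perturbed by
#' Gaussian mutation with standard deviation 10\% of each bound's span.
#' All genes are clamped into the bounds; children are evaluated before
#' return.
#'
#' @param population List of chromosomes, each `list(genes, fitness)`
#'   (genes in internal coordinates).
#' @param config A [ga_config()].
#' @param bounds A [bounds_spec()].
#' @param fitness_fn Function of `(c, g)` returning a scalar fitness.
#' @return List with the new `population` and the number of fitness
#'   `evaluations` spent.
#' @export
ga_generation <- function(population, config, bounds, fitness_fn) {
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  fit <- vapply(population, `[[`, 0, "fitness")
  n <- length(population)
  n_elite <- min(config$elitism, n)
  elite_idx <- order(fit, decreasing = TRUE)[seq_len(n_elite)]
  new_pop <- population[elite_idx]
  evals <- 0L
  span <- bounds$upper - bounds$lower
  while (length(new_pop) < n) {
    p1 <- population[[.tournament(fit)]]$genes
    p2 <- population[[.tournament(fit)]]$genes
    if (stats::runif(1) < config$crossover_prob) {
      a <- stats::runif(length(p1))
      child <- a * p1 + (1 - a) * p2
    } else {
      child <- p1
    }
    mut <- stats::runif(length(child)) < config$mutation_prob
    if (any(mut)) {
      child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = 0.1 * span[mut])
    }
    child <- .clamp(child, bounds$lower, bounds$upper)
    f <- .eval_z(fitness_fn, child)
    evals <- evals + 1L
    new_pop[[length(new_pop) + 1L]] <- list(genes = child, fitness = f)
  }
  list(population = new_pop, evaluations = evals)
}

#' Migration between the GA population and the PSO swarm
#'
#' The better of the two incumbents overwrites the other population's worst
#' member: if the swarm's global best fitness is at least the GA's best
#' (ties resolve in this direction), the worst chromosome's genes are
#' replaced by the global best position; otherwise the worst particle moves
#' to the best chromosome's genes with velocity reset to zero and its
#' personal best updated.
#'
#' @param population GA chromosome list (evaluated).
#' @param swarm Particle list (evaluated).
#' @return List with the updated `population` and `swarm` (sizes unchanged).
#' @export
migrate <- function(population, swarm) {
  ga_fit <- vapply(population, `[[`, 0, "fitness")
  ps_fit <- vapply(swarm, `[[`, 0, "best_fitness")
  ga_best <- which.max(ga_fit)
  ps_best <- which.max(ps_fit)
  if (ps_fit[ps_best] >= ga_fit[ga_best]) {
    worst <- which.min(ga_fit)
    population[[worst]] <- list(genes = swarm[[ps_best]]$best_position,
                                fitness = ps_fit[ps_best])
  } else {
    worst <- which.min(vapply(swarm, `[[`, 0, "fitness"))
    genes <- population[[ga_best]]$genes
    f <- ga_fit[ga_best]
    p <- swarm[[worst]]
    p$position <- genes
    p$velocity <- rep(0, length(genes))
    p$fitness <- f
    if (f > p$best_fitness) {
      p$best_fitness <- f
      p$best_position <- genes
    }
    swarm[[worst]] <- p
  }
  list(population = population, swarm = swarm)
}

.init_population <- function(n, bounds, fitness_fn) {
  lapply(seq_len(n), function(i) {
    z <- stats::runif(2L, bounds$lower, bounds$upper)
    list(genes = z, fitness = .eval_z(fitness_fn, z))
  })
}

.init_swarm <- function(n, bounds, fitness_fn) {
  lapply(seq_len(n), function(i) {
    z <- stats::runif(2L, bounds$lower, bounds$upper)
    v <- stats::runif(2L, -bounds$vmax, bounds$vmax)
    f <- .eval_z(fitness_fn, z)
    list(position = z, velocity = v, fitness = f,
         best_position = z, best_fitness = f)
  })
}

.result <- function(best_z, best_fit, history, evaluations, seed, engine) {
  structure(
    list(best_params = svm_params(best_z[1], 10^best_z[2]),
         best_fitness = best_fit,
         history = history, evaluations = evaluations,
         seed = seed, engine = engine),
    class = "optimizer_result"
  )
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result:%s> best c = %.5g, g = %.5g, fitness = %.5g (%d evaluations, %d generations)\n",
              x$engine, x$best_params$c, x$best_params$g, x$best_fitness,
              x$evaluations, nrow(x$history)))
  invisible(x)
}

#' Export a convergence history as CSV
#' @param result An `optimizer_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.history_row <- function(history, m, best_fit, mean_fit, best_z) {
  rbind(history, data.frame(generation = m, best_fitness = best_fit,
                            mean_fitness = mean_fit,
                            best_c = best_z[1], best_g = 10^best_z[2]))
}

.auto_T0 <- function(fits) {
  best <- max(fits)
  dev <- stats::median(abs(fits - best))
  max(dev, 1e-3) / log(2)
}

#' Run the fused GA + PSO + SA optimizer
#'
#' Each generation runs, in order: one GA generation, one PSO sweep in
#' which every particle's proposed move passes the Metropolis gate
#' ([sa_accept()]) at the current temperature (rejected moves revert the
#' particle entirely), then migration between the two populations
#' ([migrate()]). The global best over both populations is tracked
#' elitistically, the inertia weight follows the harmonic schedule
#' ([inertia_weight()]), and the temperature cools geometrically. Stops
#' after `generations` generations or once `patience` consecutive
#' generations bring no improvement.
#'
#' @param fitness_fn Function of `(c, g)` returning a scalar fitness to
#'   maximise (e.g. from [make_svm_fitness()] or [injected_fitness()]).
#' @param bounds A [bounds_spec()].
#' @param ga A [ga_config()].
#' @param pso A [pso_config()].
#' @param sa An [sa_config()].
#' @param generations Maximum generations (default 50, positive).
#' @param patience Early-stop window: `NULL` disables, otherwise stop after
#'   this many generations without improvement (default 10).
#' @param seed Integer seed; identical seeds give identical results.
#' @return An `optimizer_result`: `best_params` (`c`, `g`), `best_fitness`,
#'   per-generation `history` (best/mean fitness and incumbent parameters),
#'   `evaluations`, `seed`.
#' @export
run_gsp <- function(fitness_fn, bounds = bounds_spec(), ga = ga_config(),
                    pso = pso_config(), sa = sa_config(),
                    generations = 50L, patience = 10L, seed = 1L) {
  if (generations < 1L) stop("`generations` must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  population <- .init_population(ga$pop_size, bounds, fitness_fn)
  swarm <- .init_swarm(pso$swarm_size, bounds, fitness_fn)
  evals <- ga$pop_size + pso$swarm_size

  all_fits <- c(vapply(population, `[[`, 0, "fitness"),
                vapply(swarm, `[[`, 0, "fitness"))
  temp <- if (is.null(sa$T0)) .auto_T0(all_fits) else sa$T0
  temp <- temp * sa$K

  best_idx <- which.max(all_fits)
  best_fit <- all_fits[best_idx]
  best_z <- if (best_idx <= ga$pop_size) population[[best_idx]]$genes
            else swarm[[best_idx - ga$pop_size]]$position
  history <- .history_row(NULL, 0L, best_fit, mean(all_fits), best_z)
  stall <- 0L

  for (m in seq_len(generations)) {
    g <- ga_generation(population, ga, bounds, fitness_fn)
    population <- g$population
    evals <- evals + g$evaluations

    om <- inertia_weight(m, pso$omega1, pso$omega2, generations)
    for (i in seq_along(swarm)) {
      p_old <- swarm[[i]]
      p_new <- pso_update(p_old, best_z, om, pso, bounds)
      f_new <- .eval_z(fitness_fn, p_new$position)
      evals <- evals + 1L
      if (sa_accept(f_new - p_old$fitness, temp)) {
        p_new$fitness <- f_new
        if (f_new > p_new$best_fitness) {
          p_new$best_fitness <- f_new
          p_new$best_position <- p_new$position
        }
        swarm[[i]] <- p_new
      }  # rejected: particle reverts entirely (position and velocity)
    }

    mig <- migrate(population, swarm)
    population <- mig$population
    swarm <- mig$swarm

    fits <- c(vapply(population, `[[`, 0, "fitness"),
              vapply(swarm, `[[`, 0, "fitness"))
    gen_best <- which.max(fits)
    if (fits[gen_best] > best_fit) {
      best_fit <- fits[gen_best]
      best_z <- if (gen_best <= ga$pop_size) population[[gen_best]]$genes
                else swarm[[gen_best - ga$pop_size]]$position
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history <- .history_row(history, m, best_fit, mean(fits), best_z)
    temp <- temp * sa$alpha
    if (!is.null(patience) && stall >= patience) break
  }
  .result(best_z, best_fit, history, evals, as.integer(seed), "gsp")
}

#' Run the GA engine standalone
#'
#' Same result contract as [run_gsp()], using only the genetic algorithm.
#' @inheritParams run_gsp
#' @return An `optimizer_result`.
#' @export
run_ga <- function(fitness_fn, bounds = bounds_spec(), ga = ga_config(),
                   generations = 50L, patience = 10L, seed = 1L) {
  if (generations < 1L) stop("`generations` must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  population <- .init_population(ga$pop_size, bounds, fitness_fn)
  evals <- ga$pop_size
  fits <- vapply(population, `[[`, 0, "fitness")
  best_fit <- max(fits)
  best_z <- population[[which.max(fits)]]$genes
  history <- .history_row(NULL, 0L, best_fit, mean(fits), best_z)
  stall <- 0L
  for (m in seq_len(generations)) {
    g <- ga_generation(population, ga, bounds, fitness_fn)
    population <- g$population
    evals <- evals + g$evaluations
    fits <- vapply(population, `[[`, 0, "fitness")
    if (max(fits) > best_fit) {
      best_fit <- max(fits)
      best_z <- population[[which.max(fits)]]$genes
      stall <- 0L
    } else stall <- stall + 1L
    history <- .history_row(history, m, best_fit, mean(fits), best_z)
    if (!is.null(patience) && stall >= patience) break
  }
  .result(best_z, best_fit, history, evals, as.integer(seed), "ga")
}

#' Run the PSO engine standalone
#'
#' Harmonic-inertia PSO without the annealing gate or migration: every
#' proposed move is taken, personal and global bests tracked as usual.
#' @inheritParams run_gsp
#' @return An `optimizer_result`.
#' @export
run_pso <- function(fitness_fn, bounds = bounds_spec(), pso = pso_config(),
                    generations = 50L, patience = 10L, seed = 1L) {
  if (generations < 1L) stop("`generations` must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  swarm <- .init_swarm(pso$swarm_size, bounds, fitness_fn)
  evals <- pso$swarm_size
  fits <- vapply(swarm, `[[`, 0, "fitness")
  best_fit <- max(fits)
  best_z <- swarm[[which.max(fits)]]$position
  history <- .history_row(NULL, 0L, best_fit, mean(fits), best_z)
  stall <- 0L
  for (m in seq_len(generations)) {
    om <- inertia_weight(m, pso$omega1, pso$omega2, generations)
    for (i in seq_along(swarm)) {
      p <- pso_update(swarm[[i]], best_z, om, pso, bounds)
      p$fitness <- .eval_z(fitness_fn, p$position)
      evals <- evals + 1L
      if (p$fitness > p$best_fitness) {
        p$best_fitness <- p$fitness
        p$best_position <- p$position
      }
      swarm[[i]] <- p
    }
    fits <- vapply(swarm, `[[`, 0, "fitness")
    if (max(fits) > best_fit) {
      best_fit <- max(fits)
      best_z <- swarm[[which.max(fits)]]$position
      stall <- 0L
    } else stall <- stall + 1L
    history <- .history_row(history, m, best_fit, mean(fits), best_z)
    if (!is.null(patience) && stall >= patience) break
  }
  .result(best_z, best_fit, history, evals, as.integer(seed), "pso")
}

#' Exhaustive grid search over (c, g)
#'
#' Evaluates the full log-spaced lattice (both dimensions) and returns its
#' argmax; exact ties resolve toward the smaller `(c, g)` pair,
#' lexicographically. Deterministic.
#'
#' @param fitness_fn Function of `(c, g)`.
#' @param bounds A [bounds_spec()].
#' @param resolution Lattice points per dimension (scalar or length 2,
#'   each >= 2).
#' @return An `optimizer_result` whose history holds the single scan.
#' @export
grid_search <- function(fitness_fn, bounds = bounds_spec(), resolution = 20L) {
  resolution <- rep_len(as.integer(resolution), 2L)
  if (any(resolution < 2L)) stop("`resolution` must be >= 2", call. = FALSE)
  c_grid <- 10^seq(log10(bounds$c_min), log10(bounds$c_max),
                   length.out = resolution[1])
  g_grid <- 10^seq(log10(bounds$g_min), log10(bounds$g_max),
                   length.out = resolution[2])
  # row order = c ascending, then g ascending, so which.max's first-match
  # rule is the smaller-(c, g) lexicographic tie-break
  lattice <- expand.grid(g = g_grid, c = c_grid)[, c("c", "g")]
  vals <- mapply(fitness_fn, lattice$c, lattice$g)
  k <- which.max(vals)
  best_z <- c(lattice$c[k], log10(lattice$g[k]))
  history <- data.frame(generation = 1L, best_fitness = vals[k],
                        mean_fitness = mean(vals),
                        best_c = lattice$c[k], best_g = lattice$g[k])
  .result(best_z, vals[k], history, length(vals), NA_integer_, "grid")
}
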