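# Binary PSO: update equations, sigmoid binarization, wrapper fitness and
# selection behaviour on small benchmarks (the full planted-recovery study
# runs in the acceptance suite).

test_that("velocity update degenerates and clamps as the equations dictate", {
  params <- swarm_params(c1 = 0, c2 = 0)
  v <- c(-2, 0.5, 3)
  pos <- c(0, 1, 0); pb <- c(1, 0, 1); gb <- c(1, 1, 1)
  expect_equal(update_velocity(v, pos, pb, gb, w = 1, params), v)
  # position == pbest == gbest: difference terms vanish
  p2 <- swarm_params(c1 = 2, c2 = 2)
  expect_equal(update_velocity(v, pos, pos, pos, w = 0.7, p2), 0.7 * v)
  # any update stays within the clamp
  set.seed(61)
  for (i in 1:20) {
    vv <- update_velocity(runif(30, -10, 10), rbinom(30, 1, 0.5),
                          rbinom(30, 1, 0.5), rbinom(30, 1, 0.5),
                          w = 0.9, p2)
    expect_true(all(abs(vv) <= p2$v_max))
  }
  expect_error(update_velocity(v, pos[1:2], pb, gb, 1, p2), "dimension")
})

test_that("sigmoid binarization has the right marginal rates and repair", {
  # long vectors so the all-zero repair never triggers and the marginal
  # rate is the pure sigmoid probability
  set.seed(62)
  draws0 <- replicate(500, binarize_position(numeric(20)))
  expect_lt(abs(mean(draws0) - 0.5), 0.02)
  draws6 <- replicate(500, binarize_position(rep(6, 20)))
  expect_gte(mean(draws6), 0.99)
  # forced all-zero sample: exactly one repaired bit
  set.seed(63)
  res <- replicate(200, sum(binarize_position(rep(-50, 25))))
  expect_true(all(res == 1))
})

test_that("fitness rewards accuracy and parsimony", {
  set.seed(64)
  n <- 100
  X <- cbind(matrix(rnorm(n * 10, rep(c(0, 8), each = n / 2)), n, 10),
             matrix(rnorm(n * 40), n, 40))
  y <- rep(c("MI", "healthy"), each = n / 2)
  params <- swarm_params(seed = 64)
  full <- rep(1, 50)
  f_full <- pso_fitness(full, X, y, params)
  expect_equal(f_full, 0.01, tolerance = 1e-9)  # perfect inner classifier
  small <- c(rep(1, 10), rep(0, 40))
  f_small <- pso_fitness(small, X, y, params)
  expect_lt(f_small, f_full)  # same accuracy, fewer features
  expect_error(pso_fitness(rep(0, 50), X, y, params), "empty")
  expect_error(pso_fitness(full, X, rep("MI", n), params), "class")
})

test_that("fitness separates informative from random masks", {
  pm <- make_planted_matrix(n = 200, p = 30, n_informative = 5, snr = 2,
                            seed = 65)
  params <- swarm_params(seed = 65)
  wins <- 0
  set.seed(65)
  for (i in 1:20) {
    informative <- c(rep(1, 5), rep(0, 25))
    random_mask <- rep(0, 30)
    random_mask[sample(30, 5)] <- 1
    f_inf <- pso_fitness(informative, pm$X, pm$y, params)
    f_rnd <- pso_fitness(random_mask, pm$X, pm$y, params)
    if (f_inf < f_rnd) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("a short PSO run is deterministic with monotone gbest history", {
  pm <- make_planted_matrix(n = 120, p = 20, n_informative = 3, snr = 2,
                            seed = 66)
  params <- swarm_params(n_particles = 10, n_iterations = 12, seed = 66)
  r1 <- run_pso(pm$X, pm$y, params)
  r2 <- run_pso(pm$X, pm$y, params)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) <= 0))
  expect_gte(r1$n_selected, 1)
  expect_equal(r1$fitness, min(r1$history))
  expect_error(run_pso(pm$X, rep("MI", 120), params), "single class")
})
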