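test_that("step_euler implements the clamped forward update", {
  # absorbing origin under zero forcing
  m0 <- network_model(c("a", "b"), J = c(0, 0), d = c(1, 1),
                      A = matrix(c(0, 1, -1, 0), 2))
  expect_equal(unname(step_euler(c(0, 0), m0, dt = 0.1)), c(0, 0))

  # six-node model at the standard initial state: node-1 rate by direct
  # substitution is J1 - x1 + (-1 * 1.2 + 0.5 * 1.6 + 0.7 * 2) = 1.5
  m <- ar_nfkb_model()
  x0 <- c(1, 1.2, 1.4, 1.6, 1.8, 2)
  x1 <- step_euler(x0, m, dt = 0.001)
  expect_equal(unname(x1["AR"] - x0[1]) / 0.001, 1.5)

  # a component that would go negative is clamped at exactly 0
  mneg <- network_model("a", J = -10, d = 1, A = matrix(0, 1, 1))
  expect_identical(unname(step_euler(0.5, mneg, dt = 1)), 0)

  expect_error(step_euler(c(NaN, 1, 1, 1, 1, 1), m, 0.001), "AR")
})

test_that("a decoupled node at its fixed point stays there", {
  m <- network_model("a", J = 1, d = 1, A = matrix(0, 1, 1))
  tr <- simulate_network(m, x0 = 1, t_end = 5, dt = 0.01, output_stride = 10)
  expect_true(all(abs(tr$states - 1) < 1e-12))
})

test_that("noise-free Euler converges to the closed form at first order", {
  J <- 2; d <- 0.7; x0 <- 3
  m <- network_model("a", J = J, d = d, A = matrix(0, 1, 1))
  err_at <- function(dt) {
    tr <- simulate_network(m, x0 = x0, t_end = 5, dt = dt,
                           output_stride = round(5 / dt))
    abs(tr$states[nrow(tr$states), 1] - decoupled_closed_form(5, J, d, x0))
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01)
  expect_gt(e1 / e2, 1.8)
  expect_lt(e1 / e2, 2.2)
})

test_that("simulation is deterministic under a seed and varies across seeds", {
  m <- ar_nfkb_model()
  x0 <- c(1, 1.2, 1.4, 1.6, 1.8, 2)
  a <- simulate_network(m, x0, t_end = 2, dt = 0.01, noise_amplitude = 0.01,
                        seed = 42, output_stride = 10)
  b <- simulate_network(m, x0, t_end = 2, dt = 0.01, noise_amplitude = 0.01,
                        seed = 42, output_stride = 10)
  c_ <- simulate_network(m, x0, t_end = 2, dt = 0.01, noise_amplitude = 0.01,
                         seed = 43, output_stride = 10)
  expect_identical(a$states, b$states)
  expect_false(identical(a$states, c_$states))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_network(ar_nfkb_model(), rep(1, 6), t_end = 0.5,
                             dt = 0.01, noise_amplitude = 0.01, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("drawn noise respects the amplitude bound", {
  # recover sigma from consecutive full-resolution states of a decoupled,
  # clamp-free node: sigma = (x' - x)/dt - (J - d x)
  J <- 5; d <- 1; amp <- 0.01
  m <- network_model("a", J = J, d = d, A = matrix(0, 1, 1))
  tr <- simulate_network(m, x0 = 5, t_end = 1, dt = 0.01,
                         noise_amplitude = amp, seed = 3, output_stride = 1)
  x <- tr$states[, 1]
  sigma <- diff(x) / 0.01 - (J - d * x[-length(x)])
  expect_true(all(abs(sigma) <= amp + 1e-12))
  expect_gt(max(abs(sigma)), 0)  # noise actually present
})

test_that("states remain nonnegative for arbitrary models and strong noise", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    A <- matrix(stats::rnorm(n * n), n)
    m <- network_model(paste0("n", 1:n), J = stats::rnorm(n),
                       d = stats::runif(n, 0.5, 2), A = A)
    tr <- tryCatch(
      simulate_network(m, x0 = stats::runif(n, 0, 2), t_end = 2, dt = 0.01,
                       noise_amplitude = 0.5, seed = i, output_stride = 1),
      error = function(e) NULL)  # divergent draws abort cleanly; skip those
    if (!is.null(tr)) expect_true(all(tr$states >= 0))
  }
})

test_that("perturbation events switch J at the scheduled step and are logged", {
  m <- network_model("a", J = 1, d = 1, A = matrix(0, 1, 1))
  tr <- simulate_network(m, x0 = 1, t_end = 2, dt = 0.01,
                         events = perturbation_event(1, "a", 0.5),
                         output_stride = 1)
  expect_equal(tr$events_applied$old, 1)
  expect_equal(tr$events_applied$new, 0.5)
  expect_equal(tr$events_applied$time, 1)
  # after the switch the node relaxes toward the new fixed point J/d = 0.5
  expect_lt(tr$states[nrow(tr$states), 1], 1)
  # state at t = 1 is still pre-switch (event acts on the step leaving t = 1)
  expect_equal(unname(tr$states[tr$times == 1, 1]), 1)

  expect_error(
    simulate_network(m, 1, t_end = 2, dt = 0.01,
                     events = perturbation_event(1, "nope", 0.5)),
    "unknown node")
  expect_error(
    simulate_network(m, 1, t_end = 2, dt = 0.01,
                     events = perturbation_event(5, "a", 0.5)),
    "within")
  expect_error(perturbation_event(1, "a", 0), "> 0")
})

test_that("phase_summary averages stored states over half-open windows", {
  m <- network_model("a", J = 1, d = 1, A = matrix(0, 1, 1))
  tr <- simulate_network(m, x0 = 1, t_end = 2, dt = 0.01, output_stride = 10)
  expect_equal(unname(phase_summary(tr, list(c(0, 2)))[1, 1]), 1)
  # window covering exactly one stored point returns that state
  one <- phase_summary(tr, list(c(0.5, 0.55)))
  expect_equal(unname(one[1, 1]), 1)
  expect_error(phase_summary(tr, list(c(3, 4))), "no stored time points")
  expect_error(phase_summary(tr, list(c(1, 1))), "t_hi > t_lo")
})
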