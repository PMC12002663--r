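## A pure-decay species is obtained by zeroing the synthesis inputs of the
## WEE1 protein: dW/dt = -dw * W exactly, with closed form W = exp(-k t).
decay_model <- function(dw = 0.1) {
  build_model(2, calibrate = FALSE,
              overrides = c(vbw = 0, ksw = 0, dw = dw, scc = 1))
}

decay_init <- function(m) {
  x <- rep(0, length(m$species))
  names(x) <- m$species
  x["wee1"] <- 1
  x
}

test_that("deterministic mode reproduces exponential decay", {
  for (dt in c(0.01, 0.005)) {
    m <- decay_model()
    traj <- integrate_model(m, noise_spec("none"), init = decay_init(m),
                            config = integrator_config(dt = dt, t_max = 10,
                                                       record_every = 1))
    w_end <- unname(traj$states[nrow(traj$states), "wee1"])
    expect_equal(w_end, exp(-1), tolerance = 2 * dt)
  }
})

test_that("halving dt halves the deterministic endpoint error", {
  m <- decay_model()
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    traj <- integrate_model(m, noise_spec("none"), init = decay_init(m),
                            config = integrator_config(dt = dt, t_max = 10,
                                                       record_every = 1))
    abs(traj$states[nrow(traj$states), "wee1"] - exp(-1))
  }, numeric(1))
  expect_equal(err[1] / err[2], 2, tolerance = 0.2)
  expect_equal(err[2] / err[3], 2, tolerance = 0.2)
})

test_that("zero-sigma constant noise is bit-identical to deterministic", {
  m <- model2_default()
  cfg <- integrator_config(t_max = 50, seed = 11)
  t1 <- integrate_model(m, noise_spec("none"), config = cfg)
  t2 <- integrate_model(m, noise_spec("constant", sigma = 0), config = cfg)
  expect_identical(t1$states, t2$states)
})

test_that("trajectories are seed-reproducible and seed-sensitive", {
  m <- model2_default()
  ns <- noise_spec("constant", sigma = 0.04)
  a <- integrate_model(m, ns, config = integrator_config(t_max = 40,
                                                         seed = 5))
  b <- integrate_model(m, ns, config = integrator_config(t_max = 40,
                                                         seed = 5))
  c <- integrate_model(m, ns, config = integrator_config(t_max = 40,
                                                         seed = 6))
  expect_identical(a$states, b$states)
  expect_gt(max(abs(a$states - c$states)), 1e-3)
})

test_that("state-dependent noise matches linear birth-death moments", {
  ## W receives birth flux b = ksw * Mw (Mw held noiseless at its fixed
  ## point) and death k * W; the chemical Langevin stationary law has mean
  ## b/k and variance b/(k * omega).
  b <- 1
  k <- 0.1
  omega <- 100
  m <- build_model(2, calibrate = FALSE,
                   overrides = c(vbw = 0.8, dmw = 0.8, ksw = b, dw = k,
                                 scc = 1))
  x0 <- rep(0, length(m$species))
  names(x0) <- m$species
  x0["wee1_mrna"] <- 1   # fixed point of vbw/dmw
  x0["wee1"] <- b / k
  gmult <- as.numeric(m$species == "wee1")
  pvec <- unname(clocklineage:::model_param_vector(m))
  set.seed(99)
  ends <- vapply(1:150, function(i) {
    out <- clocklineage:::cl_integrate_cpp(
      2, pvec, unname(x0), 0.01, 6000, 100, 2L,
      rep(0, length(x0)), omega, gmult)
    out[nrow(out), match("wee1", m$species)]
  }, numeric(1))
  se_mean <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - b / k), 3 * se_mean)
  v <- b / (k * omega)
  se_var <- v * sqrt(2 / (length(ends) - 1))
  expect_lt(abs(var(ends) - v), 3 * se_var)
})

test_that("noise-free integration matches an independent stiff solver", {
  skip_if_not_installed("deSolve")
  m <- model2_default()
  x0 <- m$init
  f <- function(t, y, p) list(unname(rhs(m, y)))
  times <- seq(0, 24, by = 0.1)
  ref <- deSolve::ode(unname(x0), times, f, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  traj <- integrate_model(m, noise_spec("none"), init = x0,
                          config = integrator_config(dt = 0.005,
                                                     t_max = 24,
                                                     record_every = 20))
  rel <- max(abs(traj$states - ref[, -1])) / max(abs(ref[, -1]))
  expect_lt(rel, 0.01)
})

test_that("burn-in ensembles are phase-randomised over the limit cycle", {
  m <- model2_default()
  set.seed(123)
  states <- burn_in_ensemble(m, noise_spec("none"),
                             config = integrator_config(t_max = 480),
                             n = 200)
  expect_equal(dim(states), c(200, length(m$species)))
  expect_true(all(states >= 0))
  ## MPF values span the cycle range
  traj <- integrate_model(m, noise_spec("none"),
                          config = integrator_config(t_max = 480))
  cyc <- traj$states[seq(nrow(traj$states) / 2, nrow(traj$states)), "mpf"]
  expect_lt(min(states[, "mpf"]), min(cyc) + 0.05 * diff(range(cyc)))
  expect_gt(max(states[, "mpf"]), max(cyc) - 0.05 * diff(range(cyc)))
  ## clock phases uniform: project states onto the deterministic cycle and
  ## apply a Rayleigh test
  period <- 24
  idx <- which(traj$times >= max(traj$times) - period)
  cyc_pts <- traj$states[idx, c("per_cry_n", "bmal1_clock")]
  phases <- apply(states[, c("per_cry_n", "bmal1_clock")], 1, function(s) {
    d <- colSums((t(cyc_pts) - s)^2)
    2 * pi * (which.min(d) - 1) / length(idx)
  })
  rbar <- Mod(mean(exp(1i * phases)))
  p_rayleigh <- exp(-nrow(states) * rbar^2)
  expect_gt(p_rayleigh, 0.01)
})

test_that("single-state burn-in returns a valid state", {
  m <- model2_default()
  set.seed(5)
  s <- burn_in_ensemble(m, noise_spec("none"),
                        config = integrator_config(t_max = 480), n = 1)
  expect_equal(nrow(s), 1)
  expect_true(all(is.finite(s)) && all(s >= 0))
})

test_that("short burn-in horizons are rejected", {
  m <- model2_default()
  expect_error(burn_in_ensemble(m, config = integrator_config(t_max = 100)),
               "burn-in horizon")
})

test_that("tidy trajectory export is long-format", {
  m <- model2_default()
  traj <- integrate_model(m, noise_spec("none"),
                          config = integrator_config(t_max = 5))
  df <- as_tibble(traj)
  expect_named(df, c("time", "species", "value"))
  expect_equal(nrow(df), nrow(traj$states) * length(m$species))
})
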