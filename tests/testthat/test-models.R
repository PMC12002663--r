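test_that("calibration hits the clock and cell cycle period targets", {
  m <- model2_default()
  traj <- integrate_model(m, noise_spec("none"),
                          config = integrator_config(t_max = 480))
  clk <- clocklineage:::peak_period(traj$times, traj$states[, "per_cry_n"])
  cc <- clocklineage:::peak_period(traj$times, traj$states[, "mpf"])
  expect_lt(abs(clk$period - 24), 0.5)
  expect_lt(abs(cc$period - 20), 0.5)
})

test_that("model constructor enforces its invariants", {
  expect_error(build_model(4), "unknown model_id")
  expect_error(build_model(1, C2 = 0.5), "no reverse-coupling")
  expect_error(build_model(2, autonomous_TCC = 40), "\\[10, 36\\]")
  expect_error(build_model(2, overrides = c(nonsense = 1)),
               "unknown parameter")
  expect_error(build_model(2, overrides = c(vsp = -1)), "nonnegative")
})

test_that("set_autonomous_period recalibrates across the TCC range", {
  m <- model2_default()
  for (tcc in c(12, 24)) {
    m2 <- set_autonomous_period(m, tcc)
    traj <- integrate_model(m2, noise_spec("none"),
                            config = integrator_config(t_max = 16 * tcc))
    cc <- clocklineage:::peak_period(traj$times, traj$states[, "mpf"])
    expect_lt(abs(cc$period - tcc), 0.5)
    ## clock parameters untouched
    clk_pars <- setdiff(names(m$params), c("scc"))
    expect_identical(m2$params[clk_pars], m$params[clk_pars])
  }
})

test_that("time rescaling multiplies the module period by the inverse factor", {
  m <- model2_default()
  s <- 1.25
  m2 <- m
  m2$params["scc"] <- m$params["scc"] * s
  measure <- function(mod) {
    traj <- integrate_model(mod, noise_spec("none"),
                            config = integrator_config(t_max = 400))
    clocklineage:::peak_period(traj$times, traj$states[, "mpf"])$period
  }
  expect_equal(measure(m2), measure(m) / s, tolerance = 0.01)
})

test_that("rhs at the all-zero state reduces to basal synthesis", {
  m <- model2_default()
  zero <- rep(0, length(m$species))
  pd <- rhs(m, zero, decompose = TRUE)
  expect_true(all(pd$degradation == 0))
  p <- m$params
  ## repressors at zero leave repression terms at 1; activators at zero kill
  ## Hill activation terms
  expect_equal(unname(pd$production["per_cry_mrna"]),
               unname(p["scl"] * p["vbp"]))
  expect_equal(unname(pd$production["bmal1_mrna"]),
               unname(p["scl"] * (p["vbb"] + p["vsb"])))
  expect_equal(unname(pd$production["wee1_mrna"]),
               unname(p["scc"] * p["vbw"]))
  expect_equal(unname(pd$production["cyclin_b"]),
               unname(p["scc"] * p["vsc"]))
})

test_that("with C1 = 0 Wee1 mRNA production ignores BMAL1-CLOCK", {
  m <- build_model(2, C1 = 0, calibrate = FALSE)
  s1 <- m$init
  s2 <- s1
  s2["bmal1_clock"] <- 10 * s1["bmal1_clock"] + 1
  d1 <- rhs(m, s1)
  d2 <- rhs(m, s2)
  expect_equal(d1["wee1_mrna"], d2["wee1_mrna"])
})

test_that("rhs vanishes at a root-finder fixed point", {
  ## a WEE1-arrested, clock-flattened variant has a stable fixed point:
  ## strong MPF inhibition parks the cell cycle and a saturating KL001 dose
  ## parks the clock
  m <- apply_kl001(build_model(2, overrides = c(kwee = 2),
                               calibrate = FALSE), 1000)
  f <- function(x) rhs(m, x)
  traj <- integrate_model(m, noise_spec("none"),
                          config = integrator_config(t_max = 2000))
  x0 <- traj$states[nrow(traj$states), ]
  xstar <- newton_fixed_point(f, x0)
  expect_lt(max(abs(f(xstar))), 1e-8)
})

test_that("nonnegative orthant is forward-invariant for all models", {
  set.seed(42)
  for (id in 1:3) {
    m <- build_model(id, calibrate = FALSE)
    ns <- length(m$species)
    for (rep in 1:20) {
      x <- runif(ns, 0, 3)
      x[sample(ns, sample(ns, 1))] <- 0
      d <- rhs(m, x)
      expect_true(all(d[x == 0] >= 0))
    }
  }
})

test_that("clock and cell cycle separate when uncoupled", {
  set.seed(7)
  for (id in 1:3) {
    m <- build_model(id, C1 = 0, C2 = 0, calibrate = FALSE)
    clk <- m$species %in%
      clocklineage:::cl_clock_species[[as.character(id)]]
    for (rep in 1:10) {
      x <- runif(length(m$species), 0.1, 2)
      d0 <- rhs(m, x)
      xp <- x
      xp[!clk] <- xp[!clk] + runif(sum(!clk), 0, 1)  # perturb cell cycle
      expect_equal(rhs(m, xp)[clk], d0[clk])
      xq <- x
      xq[clk] <- xq[clk] + runif(sum(clk), 0, 1)     # perturb clock
      dq <- rhs(m, xq)
      ## cell-cycle species other than the Wee1 branch read no clock species
      cc_only <- !clk & !m$species %in% c("wee1_mrna")
      expect_equal(dq[cc_only], d0[cc_only])
    }
  }
})

test_that("coupling terms are monotone in strength and driver", {
  m <- build_model(2, calibrate = FALSE)
  x <- m$init
  wee1_prod <- function(C1, B) {
    mm <- m
    mm$C1 <- C1
    xx <- x
    xx["bmal1_clock"] <- B
    rhs(mm, xx, decompose = TRUE)$production["wee1_mrna"]
  }
  reverb_prod <- function(C2, mpf) {
    mm <- m
    mm$C2 <- C2
    xx <- x
    xx["mpf"] <- mpf
    rhs(mm, xx, decompose = TRUE)$production["reverb_mrna"]
  }
  c1s <- seq(0, 1.2, by = 0.2)
  expect_true(!is.unsorted(vapply(c1s, wee1_prod, numeric(1), B = 1)))
  bs <- seq(0, 3, by = 0.5)
  expect_true(!is.unsorted(vapply(bs, wee1_prod, numeric(1), C1 = 0.5)))
  c2s <- seq(0, 4, by = 0.5)
  expect_true(!is.unsorted(rev(vapply(c2s, reverb_prod, numeric(1),
                                      mpf = 0.5))))
  mpfs <- seq(0, 1, by = 0.2)
  expect_true(!is.unsorted(rev(vapply(mpfs, reverb_prod, numeric(1),
                                      C2 = 2))))
})

test_that("KL001 transform divides only PER-CRY degradation and composes", {
  m <- model2_default()
  expect_identical(apply_kl001(m, 1)$params, m$params)
  m10 <- apply_kl001(m, 10)
  expect_equal(unname(m10$params["vdpc"]), unname(m$params["vdpc"] / 10))
  expect_equal(unname(m10$params["vdpn"]), unname(m$params["vdpn"] / 10))
  others <- setdiff(names(m$params), c("vdpc", "vdpn"))
  expect_identical(m10$params[others], m$params[others])
  expect_equal(m10$kl001_factor, 10)
  ## multiplicative composition
  mab <- apply_kl001(apply_kl001(m, 4), 2.5)
  expect_equal(mab$params, apply_kl001(m, 10)$params)
  expect_error(apply_kl001(m, 0.5), ">= 1")
})

test_that("extreme KL001 doses flatten the clock oscillation", {
  m <- model2_default()
  ctrl <- integrate_model(m, noise_spec("none"),
                          config = integrator_config(t_max = 1200))
  ctrl_amp <- glance(spectral_summary(ctrl, "bmal1_clock",
                                      discard = 0.6))$amplitude
  hi <- integrate_model(apply_kl001(m, 1000), noise_spec("none"),
                        config = integrator_config(t_max = 1200))
  hi_ss <- spectral_summary(hi, "bmal1_clock", discard = 0.6)
  expect_lt(hi_ss$amplitude, 0.01 * ctrl_amp)
  ## clock proteins settle at nonzero levels (coupling persists)
  expect_gt(mean(tail(hi$states[, "bmal1_clock"], 100)), 0.05)
})

test_that("BMAL1-CLOCK and PER-CRY oscillate in near anti-phase", {
  m <- model2_default()
  traj <- integrate_model(m, noise_spec("none"),
                          config = integrator_config(t_max = 720))
  last_peak <- function(sp) {
    pk <- clocklineage:::peak_period(traj$times, traj$states[, sp])
    tail(pk$peaks, 1)
  }
  offset <- (last_peak("bmal1_clock") - last_peak("per_cry_n")) %% 24
  expect_gt(min(offset, 24 - offset), 6)  # within a quarter period of 12 h
})

test_that("model configs round-trip through YAML", {
  m <- build_model(2, C1 = 0.55, autonomous_TCC = 15,
                   overrides = c(vsp = 1.3))
  m <- apply_kl001(m, 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$C1, m$C1)
  expect_equal(m2$C2, m$C2)
  expect_equal(m2$kl001_factor, m$kl001_factor)
  expect_equal(m2$autonomous_TCC, m$autonomous_TCC)
})

test_that("Models 1 and 3 calibrate and oscillate like Model 2", {
  for (id in c(1, 3)) {
    m <- build_model(id, autonomous_TCC = 20)
    traj <- integrate_model(m, noise_spec("none"),
                            config = integrator_config(t_max = 480))
    clk <- clocklineage:::peak_period(traj$times,
                                      traj$states[, "per_cry_n"])
    cc <- clocklineage:::peak_period(traj$times, traj$states[, "mpf"])
    expect_lt(abs(clk$period - 24), 0.5)
    expect_lt(abs(cc$period - 20), 0.5)
  }
  ## Model 1 keeps a constant BMAL1-CLOCK level
  m1 <- build_model(1, calibrate = FALSE)
  traj <- integrate_model(m1, noise_spec("none"),
                          config = integrator_config(t_max = 200))
  b <- tail(traj$states[, "bmal1_clock"], 500)
  expect_lt(diff(range(b)), 1e-3)
})

test_that("Model 3 wires REV-ERBa to p21 through the forward coupling", {
  m <- build_model(3, C1 = 0.5, calibrate = FALSE)
  x <- m$init
  p21_prod <- function(R) {
    xx <- x
    xx["reverb"] <- R
    rhs(m, xx, decompose = TRUE)$production["p21"]
  }
  rs <- seq(0, 3, by = 0.5)
  expect_true(!is.unsorted(rev(vapply(rs, p21_prod, numeric(1)))))
  ## with C1 = 0 the link is silent (clock/cell-cycle separability)
  m0 <- build_model(3, C1 = 0, calibrate = FALSE)
  expect_equal(rhs(m0, x, decompose = TRUE)$production[["p21"]],
               unname(m0$params["scc"] * m0$params["vp"]))
  ## p21 slows Cdk activation
  hi <- x
  hi["p21"] <- 5
  expect_lt(rhs(m, hi, decompose = TRUE)$production[["mpf"]],
            rhs(m, x, decompose = TRUE)$production[["mpf"]])
})
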