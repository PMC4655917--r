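test_that("population derivatives vanish for the null state and at reversal potentials", {
  p <- uncoupled_source(channels = solo_channels(character(0)))
  st <- population_state(-55, c("NA" = 0, "CA_NA" = 0, "CL" = 0, "KIR" = 0))
  d <- population_derivatives(st, c("NA" = 0, "CA_NA" = 0, "CL" = 0, "KIR" = 0), p)
  expect_lt(abs(d$dV), 1e-9)
  expect_true(all(abs(d$dg) < 1e-9))
  # zero driving force: at a channel's reversal potential its current vanishes
  p2 <- uncoupled_source()
  at_rev <- population_state(60, c("NA" = 1, "CA_NA" = 0, "CL" = 0, "KIR" = 0))
  no_g <- population_state(60, c("NA" = 0, "CA_NA" = 0, "CL" = 0, "KIR" = 0))
  expect_equal(population_derivatives(at_rev, NULL, p2)$dV,
               population_derivatives(no_g, NULL, p2)$dV)
  expect_error(population_state(NaN), "finite")
  expect_error(population_state(-70, c("NA" = -1, "CA_NA" = 0, "CL" = 0, "KIR" = 0)),
               "nonnegative")
})

test_that("conductances follow first-order kinetics toward the gain-scaled drive", {
  p <- uncoupled_source()
  st <- population_state(-70, c("NA" = 0.2, "CA_NA" = 0, "CL" = 0, "KIR" = 0.4))
  d <- population_derivatives(st, c("NA" = 1, "KIR" = 1), p)
  a_na <- p$channels[["NA"]]$gain_scale
  expect_equal(d$dg[["NA"]], (a_na * 1 - 0.2) / 4)
  expect_equal(d$dg[["CA_NA"]], 0)
  expect_equal(d$dg[["KIR"]], (p$channels[["KIR"]]$gain_scale - 0.4) / 18)
})

test_that("two frozen-gate channels equilibrate at the conductance-weighted mean", {
  # g_NA = g_CL = 1, reversals +60 / -90, everything else negligible:
  # V* = (60 - 90) / 2 = -15 mV
  p <- uncoupled_source(channels = solo_channels(character(0)))
  st <- function(V) population_state(V, c("NA" = 1, "CA_NA" = 0, "CL" = 1, "KIR" = 0))
  expect_lt(abs(population_derivatives(st(-15), NULL, p)$dV), 1e-9)
  expect_gt(population_derivatives(st(-20), NULL, p)$dV, 0)
  expect_lt(population_derivatives(st(-10), NULL, p)$dV, 0)
})

test_that("an uncoupled source sits exactly at its potassium equilibrium", {
  p <- uncoupled_source()
  tr <- integrate_source(p, dt = 0.5, duration = 100)
  for (pop in c("spiny_stellate", "pyramidal", "interneuron")) {
    expect_lt(max(abs(tr[[pop]][, "V"] - tr[[pop]][1, "V"])), 1e-8)
    expect_equal(as.numeric(tr[[pop]][1, "V"]), -70)
  }
  expect_equal(tr$time, seq(0, 99.5, by = 0.5))
})

test_that("sustained single-channel drive pulls the membrane to the printed reversal", {
  n <- 4000  # 2000 ms at dt 0.5
  drive_to <- function(keep, col, value = 5) {
    p <- uncoupled_source(channels = solo_channels(keep))
    dr <- matrix(0, n, 3, dimnames = list(NULL, c("NA", "CA_NA", "CL")))
    if (!is.na(col)) dr[, col] <- value
    tr <- integrate_source(p, drives = list(spiny_stellate = dr), dt = 0.5,
                           duration = 2000)
    tr$spiny_stellate[n, "V"]
  }
  expect_lt(abs(drive_to("CL", "CL") - (-90)), 0.1)
  expect_lt(abs(drive_to("NA", "NA") - 60), 0.1)
  expect_lt(abs(drive_to("KL", NA) - (-70)), 0.1)
})

test_that("conductance impulse responses e-fold at the printed time constants", {
  p <- uncoupled_source()
  n <- round(40 / 0.05)
  dr <- matrix(0, n, 3, dimnames = list(NULL, c("NA", "CA_NA", "CL")))
  dr[1, "NA"] <- 1
  tr <- integrate_source(p, drives = list(spiny_stellate = dr), dt = 0.05,
                         duration = 40)
  expect_equal(efold_time(tr$time, tr$spiny_stellate[, "g_NA"]), 4,
               tolerance = 0.02)
  # NMDA with the voltage gate clamped open
  n2 <- round(600 / 0.1)
  dr2 <- matrix(0, n2, 3, dimnames = list(NULL, c("NA", "CA_NA", "CL")))
  dr2[1, "CA_NA"] <- 1
  tr2 <- integrate_source(p, drives = list(spiny_stellate = dr2), dt = 0.1,
                          duration = 600, clamp_nmda = TRUE)
  expect_equal(efold_time(tr2$time, tr2$spiny_stellate[, "g_CA_NA"]), 100,
               tolerance = 0.02)
  # GABA-A chloride conductance: 16 ms
  dr3 <- matrix(0, n, 3, dimnames = list(NULL, c("NA", "CA_NA", "CL")))
  dr3[1, "CL"] <- 1
  tr3 <- integrate_source(p, drives = list(spiny_stellate = dr3), dt = 0.05,
                          duration = 40)
  expect_equal(efold_time(tr3$time, tr3$spiny_stellate[, "g_CL"]), 16,
               tolerance = 0.02)
})

test_that("a wildly out-of-range state triggers the blow-up guard", {
  p <- uncoupled_source()
  bad <- rep(c(1000, 0, 0, 0, 0.4), 3)
  expect_error(integrate_source(p, dt = 0.5, duration = 10, init = bad),
               "blow-up at step")
})

test_that("compiled network derivatives match the R reference implementation", {
  net <- cohort_network(0.3)
  pars <- channeldcm:::.nmm_pars(net, "standard")
  S <- 6
  set.seed(99)
  x <- rep(c(-70, 0, 0, 0, 0.4), 3 * S) + rnorm(15 * S, 0, c(3, .05, .05, .05, .05))
  x <- pmax(x, rep(c(-Inf, 0, 0, 0, 0), 3 * S))
  dx_cpp <- channeldcm:::nmm_rhs_cpp(50, x, pars)
  # independent R evaluation of the same equations via the exported pieces
  p <- net$params
  H <- function(V) firing_rate(V, p$firing)
  u <- exogenous_input(50, net$input)
  dx_ref <- numeric(15 * S)
  A <- pars$A_fwd; B <- pars$A_bwd
  Vof <- function(s, pop) x[((s - 1) * 3 + pop - 1) * 5 + 1]
  for (s in 1:S) {
    Hpy_all <- sapply(1:S, function(j) H(Vof(j, 2)))
    extf <- sum(A[s, ] * Hpy_all); extb <- sum(B[s, ] * Hpy_all)
    e <- c(p$intrinsic[["ps"]] * H(Vof(s, 2)) + extf + pars$C_in[s] * u,
           p$intrinsic[["sp"]] * H(Vof(s, 1)) + extb,
           p$intrinsic[["si"]] * H(Vof(s, 1)) + extb)
    inh <- c(p$intrinsic[["is"]] * H(Vof(s, 3)),
             p$intrinsic[["ip"]] * H(Vof(s, 3)), 0)
    for (pop in 1:3) {
      b <- ((s - 1) * 3 + pop - 1) * 5
      st <- population_state(x[b + 1], c("NA" = x[b + 2], "CA_NA" = x[b + 3],
                                         "CL" = x[b + 4], "KIR" = x[b + 5]))
      d <- population_derivatives(st, c("NA" = e[pop], "CA_NA" = e[pop],
                                        "CL" = inh[pop], "KIR" = 1), p)
      dx_ref[b + 1] <- d$dV
      dx_ref[b + 2:5] <- d$dg
    }
  }
  expect_equal(as.numeric(dx_cpp), dx_ref, tolerance = 1e-12)
})
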