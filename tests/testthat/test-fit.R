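test_that("log-scale parameters act multiplicatively on the template", {
  net <- assemble_network()
  same <- apply_theta(net, setNames(numeric(0), character(0)))
  expect_equal(same, net)
  sh <- apply_theta(net, c(alpha_KL = -1, omega = 0.5, onset = 0.1))
  expect_equal(sh$params$channels[["KL"]]$gain_scale,
               net$params$channels[["KL"]]$gain_scale * exp(-1))
  expect_equal(sh$params$firing$precision,
               net$params$firing$precision * exp(0.5))
  expect_equal(sh$input$onset_mean, 64 * exp(0.1))
  expect_error(apply_theta(net, c(bogus = 1)), "unknown parameter")
})

test_that("the prior set contains each fitted parameter exactly once", {
  pr <- dcm_priors(assemble_network())
  expect_false(anyDuplicated(names(pr$mean)) > 0)
  expect_true(all(param_names_interest() %in% names(pr$mean)))
  expect_equal(unname(pr$var[c("onset", "duration")]), c(1 / 32, 1 / 32))
  expect_equal(unname(pr$var["alpha_KL"]), 1 / 16)
  expect_true(all(pr$var > 0))
  expect_error(dcm_priors(variances = c(nope = 1)), "unknown parameter")
})

test_that("predictions at theta = 0 reproduce the template and scale with the observation gain", {
  d <- make_direct_data()
  th0 <- dcm_priors(d$net)$mean
  p0 <- predict_response(th0, d)
  expect_equal(p0, predict_response(th0[0], d))  # absent = zero
  # data here were generated at the template, so the prior prediction fits
  expect_equal(as.numeric(p0), as.numeric(d$Y), tolerance = 1e-6)
  # observation gain scales the output linearly
  p1 <- predict_response(c(obs = log(2)), d)
  expect_equal(p1, 2 * p0, tolerance = 1e-8)
  # potassium-leak sensitivity is nonzero
  pk <- predict_response(c(alpha_KL = -1), d)
  expect_gt(sqrt(mean((pk - p0)^2)), 0)
  expect_error(predict_response(c(alpha_KL = NaN), d), "finite")
})

test_that("free energy balances accuracy against prior complexity", {
  d <- make_direct_data()
  pr <- dcm_priors(d$net)
  th <- pr$mean
  pred <- predict_response(th, d)
  F1 <- free_energy(th, 2, d, pr, pred = pred)
  # off-prior theta under a wider prior: KL penalty shrinks, F rises
  th_off <- th; th_off["alpha_KL"] <- -1
  pred_off <- predict_response(th_off, d)
  pr_wide <- dcm_priors(d$net, variances = c(alpha_KL = 1))
  expect_gt(free_energy(th_off, 2, d, pr_wide, pred = pred_off),
            free_energy(th_off, 2, d, pr, pred = pred_off))
  # closed form for the difference: only the alpha_KL prior term changes
  dF <- free_energy(th_off, 2, d, pr_wide, pred = pred_off) -
    free_energy(th_off, 2, d, pr, pred = pred_off)
  dF_closed <- (-0.5 * 1 / 1 - 0.5 * log(2 * pi * 1)) -
    (-0.5 * 1 / (1 / 16) - 0.5 * log(2 * pi / 16))
  expect_equal(dF, dF_closed, tolerance = 1e-9)
  # duplicating data and residuals doubles the likelihood term
  d2 <- d
  d2$Y <- array(c(d$Y, d$Y), c(dim(d$Y)[1], 2 * dim(d$Y)[2], 2))
  pred2 <- array(c(pred, pred), dim(d2$Y))
  prior_terms <- free_energy(th, 2, d, pr, pred = d$Y)  # zero-residual reference
  lik1 <- free_energy(th, 2, d, pr, pred = pred) - prior_terms
  prior_terms2 <- free_energy(th, 2, d2, pr, pred = d2$Y)
  lik2 <- free_energy(th, 2, d2, pr, pred = pred2) - prior_terms2
  expect_equal(lik2, 2 * lik1, tolerance = 1e-9)
})

test_that("noiseless data at the prior mean is a fixed point of the inversion", {
  d <- make_direct_data()
  fit <- dcm_fit(d, settings = dcm_settings(max_iter = 8))
  expect_gt(fit$pve, 99)
  expect_lt(max(abs(fit$theta)), 0.05)
  expect_true(fit$converged)
})

test_that("accepted free-energy trace is nondecreasing and the posterior is positive definite", {
  d <- make_direct_data(truth = c(alpha_KL = -0.4), noise_sd = 3, seed = 21)
  fit <- dcm_fit(d)
  acc <- fit$trace$F[fit$trace$accepted]
  expect_true(all(diff(acc) >= 0))
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(fit$Sigma, t(fit$Sigma))
  # percent variance explained is 100 * (1 - RSS/TSS) on the reduced data
  r <- as.numeric(d$Y) - as.numeric(fitted(fit))
  y <- as.numeric(d$Y)
  expect_equal(fit$pve, 100 * (1 - sum(r^2) / sum((y - mean(y))^2)),
               tolerance = 1e-8)
})

test_that("with all but one parameter pinned the optimum matches a grid-search oracle", {
  d <- make_direct_data(truth = c(alpha_KL = -0.3))
  pr <- dcm_priors(d$net)
  tight <- setNames(rep(1e-8, length(pr$mean)), names(pr$mean))
  tight["alpha_KL"] <- 1 / 16
  pr_t <- dcm_priors(d$net, variances = tight)
  fit <- dcm_fit(d, priors = pr_t)
  grid <- seq(-0.5, 0, by = 0.01)
  Fg <- vapply(grid, function(v)
    free_energy(replace(pr$mean, "alpha_KL", v), fit$h, d, pr_t), 0)
  expect_lt(abs(fit$theta[["alpha_KL"]] - grid[which.max(Fg)]), 0.011)
})

test_that("fitted-model methods are coherent", {
  d <- make_direct_data(truth = c(alpha_KL = -0.4), noise_sd = 3, seed = 31)
  fit <- dcm_fit(d)
  expect_s3_class(fit, "dcm")
  expect_named(coef(fit), names(dcm_priors(d$net)$mean))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  expect_equal(residuals(fit), d$Y - fitted(fit))
  expect_output(print(fit), "variance explained")
  s <- summary(fit)
  expect_s3_class(s, "summary.dcm")
  expect_equal(s$coefficients["alpha_KL", "estimate"],
               unname(coef(fit)["alpha_KL"]))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_equal(dim(attr(sims, "theta")), c(2, length(coef(fit))))
  expect_identical(attr(simulate(fit, nsim = 2, seed = 4), "theta"),
                   attr(sims, "theta"))
})

test_that("two-stage cohort fitting shares its initialisation across sessions", {
  d <- make_direct_data(truth = c(alpha_KL = -0.3), noise_sd = 3, seed = 41)
  expect_error(cohort_two_stage_fit(list(d)), "at least 2")
  coh <- cohort_two_stage_fit(list(d, d), settings = dcm_settings(max_iter = 12))
  # identical sessions give identical stage-2 posteriors
  expect_equal(coh$fits[[1]]$theta, coh$fits[[2]]$theta)
  expect_equal(coh$init, rowMeans(cbind(coh$stage1[[1]]$theta,
                                        coh$stage1[[2]]$theta)))
})
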