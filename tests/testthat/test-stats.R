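# fabricate a parameter table (and posterior covariances) directly from the
# generative assumptions, without running the expensive inversion
fake_table <- function(n_sub, between_sd = 0.25, within_sd = 0.1, seed = 1,
                       n_sessions = 2, patient_shift = NULL,
                       corr_subject = NULL, corr_value = 0.999) {
  nm <- param_names_interest()
  set.seed(seed)
  p_all <- c(nm, "fwd1", "obs")  # interest + two nuisance parameters
  fits <- list(); meta <- list()
  for (i in seq_len(n_sub)) {
    sub_eff <- rnorm(6, 0, between_sd)
    if (!is.null(patient_shift) && i == n_sub)
      sub_eff <- sub_eff + patient_shift
    for (k in seq_len(n_sessions)) {
      th <- setNames(c(sub_eff + rnorm(6, 0, within_sd), 0, 0), p_all)
      S <- diag(0.05^2, 8)
      if (!is.null(corr_subject) && i == corr_subject)
        S[1, 7] <- S[7, 1] <- corr_value * 0.05^2
      dimnames(S) <- list(p_all, p_all)
      fits[[length(fits) + 1]] <- list(theta = th, sd = sqrt(diag(S)), Sigma = S)
      meta[[length(meta) + 1]] <- list(
        subject = i, session = k,
        group = if (!is.null(patient_shift) && i == n_sub) "patient" else "control")
    }
  }
  parameter_table(fits, meta)
}

test_that("the parameter table carries the six parameters with positive spreads", {
  tab <- fake_table(5)
  expect_s3_class(tab, "parameter_table")
  expect_equal(nrow(tab), 10)
  expect_true(all(paste0(param_names_interest(), "_mean") %in% names(tab)))
  expect_true(all(tab$alpha_KL_sd > 0))
  expect_length(attr(tab, "covariances"), 10)
})

test_that("the covariance screen trims by the fraction rule and targets the worst offender", {
  tab <- fake_table(10)
  out <- screen_outliers(tab, retain_fraction = 0.9)
  # diagonal posteriors everywhere: exactly ceil(0.1 * 10) = 1 subject dropped
  expect_equal(sum(!out$keep_alpha_NA[out$session == 1]), 1)
  # a planted near-singular posterior is dropped first
  tab2 <- fake_table(10, corr_subject = 4)
  out2 <- screen_outliers(tab2, retain_fraction = 0.9)
  expect_false(out2$keep_alpha_NA[out2$subject == 4 & out2$session == 1])
  # retain everything
  out3 <- screen_outliers(tab, retain_fraction = 1)
  expect_true(all(out3$keep_alpha_KL))
})

test_that("the intraclass correlation matches a hand-computed ANOVA oracle", {
  # worked 3-subject table: sessions (1, 1.1), (2, 1.9), (3, 3.2)
  y <- rbind(c(1, 1.1), c(2, 1.9), c(3, 3.2))
  # one-way ANOVA decomposition by hand
  grand <- mean(y)
  msb <- 2 * sum((rowMeans(y) - grand)^2) / 2
  msw <- sum((y - rowMeans(y))^2) / 3
  icc_oracle <- (msb - msw) / (msb + msw)
  fits <- list(); meta <- list()
  for (i in 1:3) for (k in 1:2) {
    th <- setNames(c(rep(y[i, k], 6), 0, 0),
                   c(param_names_interest(), "fwd1", "obs"))
    S <- diag(0.01, 8); dimnames(S) <- list(names(th), names(th))
    fits[[length(fits) + 1]] <- list(theta = th, sd = sqrt(diag(S)), Sigma = S)
    meta[[length(meta) + 1]] <- list(subject = i, session = k, group = "control")
  }
  res <- icc_between_sessions(parameter_table(fits, meta))
  expect_equal(res$icc[res$parameter == "alpha_KL"], icc_oracle, tolerance = 1e-12)
  expect_equal(res$F[res$parameter == "alpha_KL"], msb / msw, tolerance = 1e-12)
})

test_that("the intraclass correlation is 1 for duplicated sessions and near 0 under independence", {
  tab_dup <- fake_table(8, within_sd = 0)
  res <- icc_between_sessions(tab_dup)
  expect_true(all(res$icc > 0.999))
  tab_null <- fake_table(500, between_sd = 0, within_sd = 1, seed = 3)
  res0 <- icc_between_sessions(tab_null)
  expect_true(all(abs(res0$icc) < 0.1))
})

test_that("canonical variates analysis recovers exact dependence and its dimension bound", {
  set.seed(6)
  X <- cbind(patient = rep(c(0, 1), each = 10), mean = 1)
  B <- matrix(rnorm(6), 1)
  Y <- X[, 1, drop = FALSE] %*% B  # exact linear dependence
  res <- cva_wilks(Y + 0, X)
  expect_equal(max(res$cor), 1, tolerance = 1e-6)
  expect_length(res$cor, 1)  # min(rank(X centred), 6)
  Y2 <- matrix(rnorm(20 * 6), 20)
  expect_length(cva_wilks(Y2, cbind(rnorm(20), rnorm(20), 1))$cor, 2)
  # eigen-decomposition oracle for the canonical correlations
  Xc <- scale(cbind(rnorm(40), rnorm(40)), scale = FALSE)
  Yc <- scale(matrix(rnorm(40 * 3), 40), scale = FALSE)
  r_pkg <- cva_wilks(Yc, Xc)$cor
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  r_oracle <- sqrt(sort(Re(eigen(M)$values), decreasing = TRUE)[1:2])
  expect_equal(sort(r_pkg, decreasing = TRUE), r_oracle, tolerance = 1e-8)
})

test_that("the non-overlap probability matches the equal-variance closed form", {
  expect_equal(difference_probability(gaussian_density(0, 1),
                                      gaussian_density(0, 1)), 0,
               tolerance = 1e-9)
  # N(0,1) vs N(2,1): 1 - 2 * pnorm(-1)
  expect_equal(difference_probability(gaussian_density(0, 1),
                                      gaussian_density(2, 1)),
               1 - 2 * pnorm(-1), tolerance = 1e-6)
  # general equal-variance closed form 1 - 2 * pnorm(-d / (2 * s))
  for (d in c(0.5, 1, 3)) {
    expect_equal(difference_probability(gaussian_density(0, 4),
                                        gaussian_density(d, 4)),
                 1 - 2 * pnorm(-d / 4), tolerance = 1e-6)
  }
  # symmetry, extreme separation, bounds
  p <- gaussian_density(1, 0.3); q <- gaussian_density(-0.4, 1.7)
  expect_equal(difference_probability(p, q), difference_probability(q, p),
               tolerance = 1e-9)
  expect_gt(difference_probability(gaussian_density(0, 1),
                                   gaussian_density(10, 1)), 0.9999)
  # monotone in mean separation at fixed variances
  seps <- seq(0, 4, by = 0.5)
  vals <- vapply(seps, function(m)
    difference_probability(gaussian_density(0, 1), gaussian_density(m, 2)), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(gaussian_density(0, 0), "positive")
})

test_that("leave-one-out specificity is high for a homogeneous cohort and flags a planted outlier", {
  tab <- fake_table(50, seed = 12)
  res <- loo_specificity(tab)
  expect_true(all(res$tnr >= 0.9))
  # subject shifted by six between-subject SDs is flagged
  tab2 <- fake_table(30, seed = 13)
  tab2$alpha_KL_mean[tab2$subject == 30] <-
    tab2$alpha_KL_mean[tab2$subject == 30] + 6 * 0.25
  res2 <- loo_specificity(tab2)
  expect_true(res2$flags["30", "alpha_KL"])
  tiny <- fake_table(2)
  expect_error(loo_specificity(tiny), "at least 3")
})

test_that("ROC sweep gives chance for identical densities and near-perfect for wide separation", {
  same <- roc_auc(gaussian_density(0.5, 0.04), gaussian_density(0.5, 0.04))
  expect_equal(same$auc, 0.5, tolerance = 0.01)
  ctrl <- gaussian_density(0, 0.04)
  pat <- gaussian_density(-6 * 0.2, 0.04)  # six patient-SDs below
  expect_gt(roc_auc(ctrl, pat)$auc, 0.95)
  # monotone nondecreasing in separation (numeric oracle sweep)
  aucs <- vapply(seq(0, 1.5, by = 0.25), function(d)
    roc_auc(gaussian_density(0.5, 0.04), gaussian_density(0.5 - d, 0.04))$auc, 0)
  expect_true(all(diff(aucs) >= -1e-9))
  expect_equal(nrow(same$curve), 50)
})

test_that("confidence ellipsoids are centred on the posterior with one-SD semi-axes", {
  tab <- fake_table(4)
  pars <- c("alpha_NA", "alpha_CA_NA", "alpha_KL")
  ell <- ellipsoid_region(tab, pars)
  expect_equal(nrow(ell), nrow(tab))
  expect_equal(ell$center_alpha_KL, tab$alpha_KL_mean)
  expect_true(all(ell$semi_alpha_KL == 0.05))  # unit construction: sd = 0.05
  # a -5 SD outlier on one axis lies outside every other subject's interval
  tab2 <- fake_table(6, between_sd = 0.05, seed = 5)
  tab2$alpha_KL_mean[tab2$subject == 6] <- -5
  ell2 <- ellipsoid_region(tab2, pars)
  out_lo <- ell2$center_alpha_KL[ell2$subject == 6][1]
  others <- ell2[ell2$subject != 6, ]
  expect_true(all(out_lo < others$center_alpha_KL - others$semi_alpha_KL))
  expect_error(ellipsoid_region(tab, c("alpha_NA", "alpha_KL", "nope")),
               "three of the six")
})
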