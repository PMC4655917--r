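# shared fixtures: an uncoupled single source (clean channel kinetics),
# the default network, and a small sensor array

uncoupled_source <- function(...) {
  source_params(intrinsic = c(sp = 0, si = 0, ip = 0, is = 0, ps = 0), ...)
}

# channels with all but `keep` made negligible (gain 1e-12); KL cannot be
# removed structurally so it is shrunk the same way
solo_channels <- function(keep) {
  ch <- default_channels()
  for (nm in setdiff(names(ch), keep)) ch[[nm]]$gain_scale <- 1e-12
  ch
}

# time for a conductance trace to fall from its peak to peak/e (linear
# interpolation between samples)
efold_time <- function(time, g) {
  ip <- which.max(g)
  target <- g[ip] / exp(1)
  after <- which(g <= target & seq_along(g) > ip)[1]
  t1 <- time[after - 1]; t2 <- time[after]
  g1 <- g[after - 1]; g2 <- g[after]
  (t1 + (g1 - target) / (g1 - g2) * (t2 - t1)) - time[ip]
}

test_gain <- function(seed = 1) sensor_gain(n_sensors = 32, seed = seed)

# noiseless reduced-mode data simulated at `truth` on the 200 Hz grid
make_direct_data <- function(truth = c(alpha_KL = 0), net = cohort_network(),
                             gain = test_gain(), noise_sd = 0, seed = 1) {
  nets <- apply_theta(net, truth)
  tt <- seq(0, 345, by = 5)
  idx <- round(tt / 0.5) + 1
  es <- simulate_erp(nets, gain, "standard")$sensors[, idx]
  ed <- simulate_erp(nets, gain, "deviant")$sensors[, idx]
  if (noise_sd > 0) {
    set.seed(seed)
    es <- es + matrix(rnorm(length(es), 0, noise_sd), nrow(es))
    ed <- ed + matrix(rnorm(length(ed), 0, noise_sd), nrow(ed))
  }
  dcm_data(es, ed, tt, net = net, gain = gain)
}
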