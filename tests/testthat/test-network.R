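# Integration core: closed-form oscillator limit, spike bookkeeping,
# synaptic drives, determinism, and agreement between the compiled
# plasticity path and the pure-R one.

test_that("free firing rate matches the closed form", {
  expect_equal(free_firing_rate((pi * 0.02)^2), 1)
  expect_equal(free_firing_rate(0, I = (50 * pi * 0.02)^2), 50)
  expect_equal(free_firing_rate(-0.01), 0)
  expect_equal(free_firing_rate(c(-1, 0, (2 * pi * 0.02)^2)), c(0, 0, 2))
})

test_that("uncoupled noise-free oscillator period agrees with the closed form", {
  for (rate in c(1, 2, 8)) {
    eta <- (rate * pi * 0.02)^2
    st <- single_neuron_state(eta)
    sim <- run_simulation(st, NULL, max(4, 3 / rate), plasticity = FALSE)
    isi <- diff(sim$raster$time)
    expect_gt(length(isi), 1)
    expect_lt(abs(mean(isi) - pi * 0.02 / sqrt(eta)) / (pi * 0.02 / sqrt(eta)),
              0.02)
  }
})

test_that("network construction validates populations and weight classes", {
  expect_error(network_params(N = 100, n_exc = 70, n_hebb = 10, n_anti = 10),
               "must equal N")
  expect_error(network_params(N = 10, n_exc = -5, n_hebb = 10, n_anti = 5),
               "non-negative")
  p <- network_params()
  st <- init_network(p, "small-random", seed = 5)
  expect_equal(diag(st$weights), rep(0, 100))
  cls <- neuron_classes(p)
  expect_true(all(st$weights[, cls == "e"] >= 0 & st$weights[, cls == "e"] <= 1))
  expect_true(all(st$weights[, cls != "e"] <= 0 & st$weights[, cls != "e"] >= -1))
  # explicit matrix with wrong class signs is rejected
  bad <- matrix(0.5, 100, 100)
  expect_error(init_network(p, bad), "inhibitory")
  expect_error(init_network(p, matrix(0, 10, 10)), "must be")
})

test_that("identical seeds give identical excitabilities, weights and rasters", {
  p <- network_params()
  st1 <- init_network(p, "small-random", seed = 42)
  st2 <- init_network(p, "small-random", seed = 42)
  expect_identical(st1$eta, st2$eta)
  expect_identical(st1$weights, st2$weights)
  s1 <- run_simulation(st1, NULL, 3, seed = 43)
  s2 <- run_simulation(st2, NULL, 3, seed = 43)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$weights, s2$weights)
})

test_that("synaptic drives jump by w/Nq on a spike and decay exponentially", {
  # neuron 1 fires; neuron 2 is silent and only receives
  p <- network_params(N = 2L, n_exc = 2L, n_hebb = 0L, n_anti = 0L,
                      noise_sigma = 0, ge = 0)
  st <- init_network(p, "zero", seed = 1)
  st$eta <- c((2 * pi * 0.02)^2, -1)  # 2 Hz oscillator + silent neuron
  st$V <- c(p$Vr, p$Vr)
  st$weights[2, 1] <- 0.5
  sim <- run_simulation(st, NULL, 1, plasticity = FALSE,
                        record = record_options(drive_neurons = 2,
                                                drive_dt = p$dt))
  d <- sim$drives
  expect_equal(nrow(sim$raster), 2)
  # drive jumps to exactly w / Ne = 0.5 / 2 at the spike step
  expect_equal(max(d$Se_2), 0.25, tolerance = 1e-12)
  # pure decay between spikes: ratio of consecutive samples = exp(-dt/tau_de)
  i0 <- which.max(d$Se_2)
  seg <- d$Se_2[(i0 + 1):(i0 + 20)]
  expect_equal(seg / d$Se_2[i0:(i0 + 19)],
               rep(exp(-p$dt / p$tau_de), 20), tolerance = 1e-9)
  expect_true(all(d$Se_2 >= 0))
})

test_that("inhibitory drive jump uses the inhibitory normalisation and sign", {
  p <- network_params(N = 3L, n_exc = 1L, n_hebb = 2L, n_anti = 0L,
                      noise_sigma = 0, ge = 0, ghi = 0)
  st <- init_network(p, "zero", seed = 1)
  st$eta <- c(-1, (2 * pi * 0.02)^2, -1)  # only neuron 2 (hi class) fires
  st$V <- rep(p$Vr, 3)
  st$weights[1, 2] <- -1
  sim <- run_simulation(st, NULL, 1, plasticity = FALSE,
                        record = record_options(drive_neurons = 1,
                                                drive_dt = p$dt))
  expect_equal(min(sim$drives$Shi_1), -1 / 2, tolerance = 1e-12) # w / Nhi
  expect_true(all(sim$drives$Shi_1 <= 0))
})

test_that("doubling the weights doubles the drive increments (plasticity off)", {
  p <- network_params(N = 2L, n_exc = 2L, n_hebb = 0L, n_anti = 0L,
                      noise_sigma = 0, ge = 0)
  base <- init_network(p, "zero", seed = 1)
  base$eta <- c((2 * pi * 0.02)^2, -1)
  base$V <- c(p$Vr, p$Vr)
  base$weights[2, 1] <- 0.3
  doubled <- base
  doubled$weights[2, 1] <- 0.6
  r1 <- run_simulation(base, NULL, 1, plasticity = FALSE,
                       record = record_options(drive_neurons = 2, drive_dt = 0.001))
  r2 <- run_simulation(doubled, NULL, 1, plasticity = FALSE,
                       record = record_options(drive_neurons = 2, drive_dt = 0.001))
  expect_equal(r2$drives$Se_2, 2 * r1$drives$Se_2, tolerance = 1e-12)
})

test_that("refractory hold prevents immediate re-firing", {
  # strongly driven neuron: ISIs can never be shorter than the reset hold
  st <- single_neuron_state(0)
  p2 <- st$params
  a <- structure(list(M = 1, N = 1,
                      modules = list(list(e = 1L, hi = integer(0),
                                          ai = integer(0))),
                      hubs = integer(0), untrained = integer(0), params = p2),
                 class = "qif_assignment")
  pr <- build_stimulus_schedule(a, "strict", n_epochs = 1, stim_on = 1,
                                epoch_len = 1, amplitude = (200 * pi * 0.02)^2)
  sim <- run_simulation(st, pr, 1, plasticity = FALSE)
  expect_gt(nrow(sim$raster), 50)
  expect_true(all(diff(sim$raster$time) > 2 * p2$dt))
})

test_that("plasticity off leaves the weight matrix untouched", {
  p <- network_params()
  st <- init_network(p, "small-random", seed = 9)
  sim <- run_simulation(st, NULL, 2, plasticity = FALSE, seed = 10)
  expect_identical(sim$weights, st$weights)
})

test_that("compiled plasticity agrees with the pure-R replay on a pair", {
  # dynamics decoupled from the weights (g = 0), so the raster is fixed
  # and the weight trajectory can be replayed exactly through R
  p <- two_neuron_params()
  st <- init_network(p, "zero", seed = 2)
  st$eta <- c((3.1 * pi * 0.02)^2, (2.3 * pi * 0.02)^2)
  st$V <- c(p$Vr, 0)
  st$weights <- matrix(c(0, 0.4, 0.6, 0), 2, 2)
  sp <- stdp_params(f = 0.1)
  sim <- run_simulation(st, NULL, 5, plasticity = TRUE, stdp = sp)
  # replay
  w <- st$weights
  ledger <- rep(NA_real_, 2)
  ras <- sim$raster
  for (k in seq_len(nrow(ras))) {
    out <- on_spike_plasticity(ledger, w, c("e", "e"), ras$neuron[k],
                               ras$time[k], stdp = sp)
    w <- out$weights; ledger <- out$ledger
  }
  expect_equal(sim$weights, w, tolerance = 1e-12)
})

test_that("sparse connectivity masks are respected by drives and plasticity", {
  p <- network_params(connectivity = 0.3)
  st <- init_network(p, "small-random", seed = 12)
  expect_true(all(st$weights[!st$mask] == 0))
  sim <- run_simulation(st, NULL, 5, plasticity = TRUE, seed = 13)
  expect_true(all(sim$weights[!st$mask] == 0))
  expect_false(isTRUE(all.equal(sim$weights, st$weights))) # unmasked ones moved
})

test_that("weight bounds and Dale signs survive stimulated activity", {
  p <- network_params()
  a <- population_assignment(p, 2)
  st <- init_network(p, "small-random", seed = 14)
  pr <- build_stimulus_schedule(a, "strict", n_epochs = 4, seed = 15)
  sim <- run_simulation(st, pr, 4, plasticity = TRUE, seed = 16)
  cls <- neuron_classes(p)
  expect_true(all(sim$weights[, cls == "e"] >= 0 &
                    sim$weights[, cls == "e"] <= 1))
  expect_true(all(sim$weights[, cls != "e"] <= 0 &
                    sim$weights[, cls != "e"] >= -1))
  expect_equal(diag(sim$weights), rep(0, 100))
})

test_that("a protocol extending past the duration is rejected", {
  p <- network_params()
  a <- population_assignment(p, 2)
  st <- init_network(p, "small-random", seed = 17)
  pr <- build_stimulus_schedule(a, "strict", n_epochs = 4)
  expect_error(run_simulation(st, pr, 2), "extends past")
})
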