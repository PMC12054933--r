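# Rates, ISI statistics, spike-phase order parameters, weight-change
# rate, recall detection, stability classification and block statistics.

test_that("instantaneous rates count spikes per window", {
  r <- make_raster(c(0.01, 0.03, 0.06), c(1L, 1L, 2L))
  rs <- instantaneous_rate(r, N = 2, window = 0.05, t_start = 0, t_end = 0.1)
  expect_equal(rs$rates[1, ], c(40, 0))  # two spikes in the first window
  expect_equal(rs$rates[2, ], c(0, 20))
  expect_equal(population_rate(rs), c(20, 10))
  empty <- instantaneous_rate(make_raster(numeric(0), integer(0)), N = 3,
                              t_start = 0, t_end = 0.2)
  expect_true(all(empty$rates == 0))
})

test_that("coefficient of variation distinguishes periodic from Poisson", {
  periodic <- make_raster(seq(0, 20, by = 0.5), 1L)
  expect_equal(coefficient_of_variation(periodic, 1)[1], 0)
  set.seed(3)
  pois <- make_raster(cumsum(rexp(3000, 5)), 1L)
  expect_equal(coefficient_of_variation(pois, 1)[1], 1, tolerance = 0.08)
  two <- make_raster(c(0.1, 0.4), 1L)
  expect_true(is.na(coefficient_of_variation(two, 1)[1]))
  # low min_isi makes short trains defined
  expect_false(is.na(coefficient_of_variation(
    make_raster(c(0.1, 0.2, 0.4), 1L), 1, min_isi = 2)[1]))
})

test_that("spike phases interpolate linearly between spikes", {
  r <- make_raster(c(1, 2), c(1L, 1L))
  th <- spike_phases(r, 1, c(1, 1.5, 2, 0.5, 2.5))
  expect_equal(th[1, 1:3], c(0, pi, 2 * pi))
  expect_true(all(is.na(th[1, 4:5])))  # outside first/last spike
})

test_that("kuramoto order parameter hits the synchrony extremes", {
  # identical trains: R = 1 at all covered times
  times <- seq(0.5, 4.5, by = 0.1)
  sync <- make_raster(rep(0:5, each = 4), rep(1:4, times = 6))
  ks <- kuramoto(spike_phases(sync, 4, times), times)
  expect_true(all(abs(ks$R - 1) < 1e-12))
  # uniformly staggered oscillators: R ~ 0
  N <- 20
  stag <- do.call(rbind, lapply(1:N, function(j)
    make_raster(seq(0, 10, by = 1) + (j - 1) / N, j)))
  ku <- kuramoto(spike_phases(stag, N, seq(2, 8, by = 0.05)))
  expect_true(all(ku$R < 1e-10))
  # single neuron: R = 1 where defined
  single <- kuramoto(spike_phases(make_raster(c(1, 2, 3), 1L), 1, c(1.2, 2.7)))
  expect_equal(single$R, c(1, 1))
  expect_true(all(ku$R >= 0 & ku$R <= 1))
})

test_that("weight change rate reproduces the worked normalisation", {
  N <- 100
  w0 <- matrix(0, N, N)
  w1 <- w0; w1[2, 1] <- 0.01
  k <- weight_change_rate(list(w0, w1), dt_pair = 0.1)
  expect_equal(k$K, 0.01 / 0.1 / (N * (N - 1)), tolerance = 1e-12)
  expect_equal(weight_change_rate(list(w0, w0), dt_pair = 0.1)$K, 0)
  # uniform increment: normalisation cancels, K = delta / dt
  w2 <- w0 + 0.004; diag(w2) <- 0
  expect_equal(weight_change_rate(list(w0, w2), dt_pair = 0.1)$K, 0.04,
               tolerance = 1e-12)
  # net potentiation gives positive K
  expect_gt(weight_change_rate(list(w0, w1))$K[1], 0)
})

test_that("recall detector attributes constructed events and rejects noise", {
  a <- default_assignment()
  m1 <- a$modules[[1]]$e
  # 90% of module 1 fires within 0.15 s, everything else silent
  burst <- make_raster(seq(5.0, 5.15, length.out = 36), sample(m1, 36))
  rec <- detect_recalls(burst, a, t_start = 4, t_end = 6)
  expect_equal(unique(rec$label), "1")
  expect_equal(nrow(rec), 1)
  expect_gte(rec$peak_fraction, 0.9)
  # homogeneous sparse Poisson: no events at threshold 0.5
  set.seed(8)
  pois <- make_raster(sort(runif(100 * 10, 0, 10)), sample(100, 1000, TRUE))
  expect_equal(nrow(detect_recalls(pois, a, t_start = 0, t_end = 10)), 0)
  # two modules synchronous in the same window -> joint, not attributed
  m2 <- a$modules[[2]]$e
  both <- make_raster(seq(2.0, 2.1, length.out = 80),
                      as.vector(rbind(m1, m2)))
  recj <- detect_recalls(both, a, t_start = 1.5, t_end = 2.5)
  expect_true(all(recj$label == "joint"))
})

test_that("recall detector has no false positives below half-threshold synchrony", {
  a <- default_assignment()
  set.seed(9)
  for (rep in 1:5) {
    # per-module synchrony kept below threshold/2: at most 20% of a module
    # spikes within any window
    r <- do.call(rbind, lapply(1:10, function(k) {
      mod <- a$modules[[(k %% 2) + 1]]$e
      make_raster(k + runif(8, 0, 0.1), sample(mod, 8))
    }))
    r <- r[order(r$time), ]
    expect_equal(nrow(detect_recalls(r, a, t_start = 0, t_end = 11)), 0)
  }
})

test_that("stability classification requires recalls in every module", {
  a <- default_assignment()
  m1 <- a$modules[[1]]$e; m2 <- a$modules[[2]]$e
  background <- make_raster(sort(runif(600, 0, 30)), sample(100, 600, TRUE))
  burst1 <- make_raster(seq(10, 10.1, length.out = 40), m1)
  burst2 <- make_raster(seq(20, 20.1, length.out = 40), m2)
  r <- rbind(background, burst1, burst2)
  r <- r[order(r$time), ]
  v <- classify_stability(r, a, t_start = 0, t_end = 30)
  expect_true(v$stable)
  expect_true(all(v$recall_counts >= 1))
  # remove module 2's recall -> unstable
  r2 <- rbind(background, burst1); r2 <- r2[order(r2$time), ]
  expect_false(classify_stability(r2, a, t_start = 0, t_end = 30)$stable)
  # persistent global synchrony fails the asynchrony check
  sync <- do.call(rbind, lapply(seq(0.2, 29.8, by = 0.2), function(t0)
    make_raster(rep(t0, 100), 1:100)))
  vs <- classify_stability(sync, a, t_start = 0, t_end = 30)
  expect_false(vs$asynchronous)
  expect_false(vs$stable)
})

test_that("module weight stats recover template blocks and relabel cleanly", {
  p <- network_params()
  a <- population_assignment(p, 2)
  set.seed(10)
  w <- build_modular_matrix(a)
  cls <- neuron_classes(p)
  mod <- module_vector(a)
  st <- module_weight_stats(w, cls, mod)
  expect_equal(st$intra[st$pre == "E" & st$post == "E"], 0.7)
  expect_equal(st$intra[st$pre == "H" & st$post == "E"], -0.7)
  # permuting module labels permutes nothing in the intra/inter split
  st2 <- module_weight_stats(w, cls, 3 - mod)
  expect_equal(st$intra, st2$intra)
  expect_equal(st$inter, st2$inter)
  z <- module_weight_stats(matrix(0, 100, 100), cls, mod)
  expect_true(all(z$intra == 0 & z$inter == 0))
})

test_that("forgetting-time estimate scales with the forgetting term", {
  t_f <- forgetting_time_estimate(stdp_params(f = 0.1), seed = 20)
  t_2f <- forgetting_time_estimate(stdp_params(f = 0.2), seed = 21)
  expect_true(is.finite(t_f$time) && t_f$time > 0)
  # doubling f approximately halves the estimate
  expect_gt(t_2f$time / t_f$time, 0.33)
  expect_lt(t_2f$time / t_f$time, 0.67)
  # no forgetting -> no net depression -> infinite retention
  expect_equal(forgetting_time_estimate(stdp_params(f = 0), seed = 22)$time, Inf)
})
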