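# Stimulation schedules, population assignments, template matrices,
# perturbations and the capacity counting rule.

test_that("population assignment splits classes into balanced blocks", {
  p <- network_params()
  a <- population_assignment(p, 4)
  sizes_hi <- vapply(a$modules, function(m) length(m$hi), integer(1))
  expect_equal(sort(sizes_hi), c(2L, 2L, 3L, 3L))  # 10 Hebbian over 4 memories
  all_e <- sort(unlist(lapply(a$modules, `[[`, "e")))
  expect_equal(all_e, 1:80)
  # infeasible: more memories than inhibitory neurons per class
  expect_error(population_assignment(p, 11), "infeasible")
  # overlap declared only among excitatory indices
  ao <- population_assignment(p, 2, overlap = 8)
  expect_length(ao$hubs, 8)
  expect_true(all(ao$hubs %in% 1:80))
  expect_true(all(ao$hubs %in% ao$modules[[1]]$e))
  expect_true(all(ao$hubs %in% ao$modules[[2]]$e))
  expect_length(intersect(ao$modules[[1]]$hi, ao$modules[[2]]$hi), 0)
})

test_that("stimulus schedules have exact epoch structure", {
  a <- default_assignment()
  pr <- build_stimulus_schedule(a, "random", n_epochs = 35, seed = 30)
  expect_equal(nrow(pr$epochs), 35)
  expect_equal(pr$epochs$t_off - pr$epochs$t_on, rep(0.8, 35))
  expect_equal(diff(pr$epochs$t_on), rep(1, 34))   # epochs tile exactly 1 s
  expect_setequal(unique(pr$epochs$memory), 1:2)   # every memory present
  strict <- build_stimulus_schedule(a, "strict", n_epochs = 4)
  expect_equal(strict$epochs$memory, c(1L, 2L, 1L, 2L))
  expect_error(build_stimulus_schedule(a, "random", n_epochs = 1), "at least M")
})

test_that("random-subset and amplitude-jitter options modulate epochs", {
  a <- default_assignment()
  pr <- build_stimulus_schedule(a, "strict", n_epochs = 6,
                                subset_fraction = 0.8, seed = 31)
  full <- length(unlist(a$modules[[1]]))
  sizes <- vapply(pr$targets, length, integer(1))
  expect_true(all(sizes == round(0.8 * full)))
  expect_gt(length(unique(lapply(pr$targets[c(1, 3, 5)], sort))), 1)
  prj <- build_stimulus_schedule(a, "strict", n_epochs = 6,
                                 amplitude_jitter = 0.2, seed = 32)
  amp0 <- a$params$stim_amplitude
  expect_true(all(abs(prj$epochs$amplitude / amp0 - 1) <= 0.2))
  expect_gt(sd(prj$epochs$amplitude), 0)
})

test_that("modular template has exact intra blocks and truncated inter noise", {
  p <- network_params()
  a <- population_assignment(p, 2)
  w <- build_modular_matrix(a, seed = 33)
  cls <- neuron_classes(p)
  m1 <- unlist(a$modules[[1]])
  intra_ee <- w[intersect(m1, which(cls == "e")), intersect(m1, which(cls == "e"))]
  expect_true(all(intra_ee[row(intra_ee) != col(intra_ee)] == 0.7))
  intra_ie <- w[intersect(m1, 1:80), intersect(m1, which(cls != "e"))]
  expect_true(all(intra_ie == -0.7))
  expect_equal(diag(w), rep(0, 100))
  m2 <- unlist(a$modules[[2]])
  inter <- w[m2, intersect(m1, which(cls == "e"))]
  expect_true(all(inter >= 0))           # excitatory inter weights truncated up
  expect_true(all(abs(inter) <= 1))
  inter_i <- w[m2, intersect(m1, which(cls != "e"))]
  expect_true(all(inter_i <= 0))
  # deterministic given seed
  expect_identical(w, build_modular_matrix(a, seed = 33))
})

test_that("weight-subset randomisation is surgical", {
  p <- network_params()
  cls <- neuron_classes(p)
  a <- population_assignment(p, 2)
  w <- build_modular_matrix(a, seed = 34)
  exc <- cls == "e"
  we <- randomize_weight_subset(w, cls, "e-out", seed = 35)
  expect_true(all(we[, exc] >= 0 & we[, exc] <= 1))
  expect_identical(we[, !exc], w[, !exc])
  expect_false(isTRUE(all.equal(we[, exc], w[, exc])))
  wi <- randomize_weight_subset(w, cls, "i-out", seed = 36)
  expect_true(all(wi[, !exc] >= -1 & wi[, !exc] <= 0))
  expect_identical(wi[, exc], w[, exc])
  wee <- randomize_weight_subset(w, cls, "all-but-ee", seed = 37)
  expect_identical(wee[exc, exc], w[exc, exc])
  expect_false(isTRUE(all.equal(wee[!exc, exc], w[!exc, exc])))
  expect_identical(randomize_weight_subset(w, cls, "none"), w)
  expect_error(randomize_weight_subset(w, cls, "everything"))
})

test_that("capacity rule: triplet counting and the N/3 limit", {
  expect_equal(capacity_limit(100)$M_star, 33)
  expect_equal(capacity_limit(100)$NI_star, 66)
  grid <- capacity_scan(N = 100, M_list = c(4, 34), NI_list = c(6, 8, 68))
  # M=4, NI=8 (4+4): feasible and predicted stable
  expect_true(grid$feasible[grid$M == 4 & grid$NI == 8])
  # M=4, NI=6 (3+3): below the 2M inhibitory requirement
  expect_false(grid$feasible[grid$M == 4 & grid$NI == 6])
  # M=34 needs NI >= 68, leaving NE = 32 < 34: not accessible
  expect_false(grid$accessible[grid$M == 34 & grid$NI == 68])
  # mask matches the counting rule everywhere
  expect_equal(grid$feasible,
               grid$M <= pmin(grid$NE, floor(grid$NI / 2)))
})

test_that("training experiment phases and snapshots line up", {
  exp <- training_experiment("mixed", seed = 40, n_epochs = 6, rest = 2,
                             consolidation = 2)
  expect_equal(unname(exp$phases), c(2, 8, 10))
  expect_equal(exp$snapshot_times, c(0, 5, 8))
  expect_equal(dim(exp$snapshots[[1]]), c(100, 100))
  expect_s3_class(exp$stats, "data.frame")
  # learning epochs sit inside the learning phase
  expect_gte(min(exp$protocol$epochs$t_on), 2)
  expect_lte(max(exp$protocol$epochs$t_off), 8)
})

test_that("frozen recovery control is flat; i-out recovery rebuilds inhibition", {
  p <- network_params()
  a <- population_assignment(p, 2)
  set.seed(44)
  tmpl <- build_modular_matrix(a)
  w0 <- randomize_weight_subset(tmpl, neuron_classes(p), "i-out")
  ctrl <- recovery_experiment(w0, a, duration = 3, seed = 45,
                              plasticity = FALSE, noise = FALSE)
  expect_equal(diff(range(ctrl$similarity$ee_contrast)), 0)
  expect_equal(diff(range(ctrl$similarity$hebb_contrast)), 0)
  rec <- recovery_experiment(w0, a, duration = 90, seed = 46)
  n <- nrow(rec$similarity)
  # inhibitory modular contrast grows as recalls re-impose structure
  expect_gt(rec$similarity$hebb_contrast[n], rec$similarity$hebb_contrast[1])
  expect_gt(rec$similarity$anti_contrast[n], rec$similarity$anti_contrast[1])
})

test_that("overlap training yields exactly the shared neurons as hubs", {
  exp <- overlap_experiment(n_overlap = 8, seed = 81)
  expect_setequal(exp$hubs_detected, exp$assignment$hubs)
  # recall log includes hub-only events alongside module events
  expect_true("hubs" %in% exp$recalls$label)
  # no overlap -> no hubs
  e0 <- training_experiment("mixed", seed = 82, n_epochs = 10, rest = 2,
                            consolidation = 2)
  hr <- hub_report(e0$weights, e0$assignment)
  expect_length(qifstdp:::hub_neurons(hr, 0.5), 0)
})
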