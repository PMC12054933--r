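#' Assign neurons to memory populations
#'
#' Splits the excitatory and the two inhibitory sub-populations into `M`
#' memory populations. Excitatory and inhibitory indices are divided into
#' `M` contiguous blocks of as-equal-as-possible size (so, e.g., 10
#' Hebbian-inhibitory neurons over 4 memories give pools of 3, 3, 2, 2).
#' Optionally a set of `overlap` excitatory neurons is shared between two
#' adjacent memories (supported for `M = 2`), and a trailing fraction of
#' each sub-population can be left untrained.
#'
#' @param params a [network_params()] object.
#' @param M number of memories.
#' @param overlap number of excitatory neurons shared between the two
#'   memories (`M = 2` only). The shared set is taken from the boundary
#'   between the two excitatory blocks.
#' @param untrained_fraction fraction of each sub-population excluded
#'   from every memory.
#' @return an object of class `qif_assignment`: list with `M`, `N`,
#'   `modules` (per memory: `e`, `hi`, `ai` index vectors), `hubs`
#'   (shared excitatory indices), `untrained`, and `params`.
#' @export
population_assignment <- function(params, M, overlap = 0,
                                  untrained_fraction = 0) {
  if (M < 1) stop("M must be at least 1")
  if (overlap > 0 && M != 2)
    stop("overlapping stimuli are supported for M = 2")
  take_trained <- function(idx) {
    n_un <- floor(length(idx) * untrained_fraction)
    if (n_un > 0) list(trained = head(idx, -n_un), untrained = tail(idx, n_un))
    else list(trained = idx, untrained = integer(0))
  }
  e_all <- take_trained(seq_len(params$n_exc))
  hi_all <- take_trained(params$n_exc + seq_len(params$n_hebb))
  ai_all <- take_trained(params$n_exc + params$n_hebb + seq_len(params$n_anti))

  blocks <- function(idx, M) {
    if (length(idx) < M) return(NULL)
    split(idx, rep(seq_len(M), times = diff(round(
      seq(0, length(idx), length.out = M + 1)))))
  }
  hubs <- integer(0)
  e_pool <- e_all$trained
  if (overlap > 0) {
    if (length(e_pool) < 2 + overlap)
      stop("not enough excitatory neurons for the requested overlap")
    n_ex <- length(e_pool) - overlap
    half <- floor(n_ex / 2)
    hubs <- e_pool[half + seq_len(overlap)]
    e_blocks <- list(`1` = c(e_pool[seq_len(half)], hubs),
                     `2` = c(hubs, e_pool[(half + overlap + 1):length(e_pool)]))
  } else {
    e_blocks <- blocks(e_pool, M)
  }
  hi_blocks <- blocks(hi_all$trained, M)
  ai_blocks <- blocks(ai_all$trained, M)
  if (is.null(e_blocks) || is.null(hi_blocks) || is.null(ai_blocks))
    stop("infeasible assignment: each memory needs at least one excitatory, ",
         "one Hebbian-inhibitory and one anti-Hebbian-inhibitory neuron")
  modules <- lapply(seq_len(M), function(m)
    list(e = unname(e_blocks[[m]]), hi = unname(hi_blocks[[m]]),
         ai = unname(ai_blocks[[m]])))
  structure(list(M = M, N = params$N, modules = modules, hubs = hubs,
                 untrained = c(e_all$untrained, hi_all$untrained,
                               ai_all$untrained),
                 params = params), class = "qif_assignment")
}

#' Per-neuron module id vector
#'
#' @param assignment a [population_assignment()] object.
#' @return integer vector of length `N`: module id, or `NA` for untrained
#'   neurons and hub neurons belonging to more than one module.
#' @export
module_vector <- function(assignment) {
  mod <- rep(NA_integer_, assignment$N)
  for (m in seq_len(assignment$M)) {
    idx <- unlist(assignment$modules[[m]], use.names = FALSE)
    mod[idx] <- ifelse(is.na(mod[idx]), m, NA_integer_)
  }
  mod[assignment$hubs] <- NA_integer_
  mod
}

detection_sets <- function(assignment) {
  sets <- lapply(seq_len(assignment$M), function(m)
    setdiff(assignment$modules[[m]]$e, assignment$hubs))
  names(sets) <- as.character(seq_len(assignment$M))
  if (length(assignment$hubs) > 0) sets$hubs <- assignment$hubs
  sets[vapply(sets, length, integer(1)) > 0]
}

#' Build a stimulation schedule
#'
#' Constructs the timed stimulation protocol: `n_epochs` epochs of
#' `epoch_len` seconds each, with the DC stimulus applied to the target
#' memory population for the first `stim_on` seconds (reference: 800 ms
#' on, 200 ms relaxation) and nothing for the remainder. In `"random"`
#' mode the stimulated memory is drawn at random each epoch (every memory
#' is guaranteed to appear at least once); `"strict"` mode cycles through
#' the memories in order. Options: stimulate only a fresh random fraction
#' of the target population each epoch (`subset_fraction`), or jitter the
#' stimulus amplitude multiplicatively by up to `amplitude_jitter`
#' (uniform).
#'
#' @param assignment a [population_assignment()] object.
#' @param mode `"random"` or `"strict"` alternation.
#' @param n_epochs number of stimulation epochs (must be >= `M`).
#' @param t_start onset of the first epoch (s).
#' @param stim_on stimulus-on duration per epoch (s).
#' @param epoch_len epoch length (s).
#' @param amplitude stimulus current; defaults to the `stim_amplitude` of
#'   the assignment's network parameters.
#' @param subset_fraction fraction of the target population stimulated
#'   each epoch (1 = all).
#' @param amplitude_jitter relative amplitude jitter, uniform in
#'   `[-amplitude_jitter, +amplitude_jitter]`.
#' @param seed optional seed for the protocol randomness.
#' @return an object of class `qif_protocol`: list with `epochs` (data
#'   frame `memory`, `t_on`, `t_off`, `amplitude`), `targets` (neuron
#'   index vector per epoch), `epoch_len` and `t_end`.
#' @export
build_stimulus_schedule <- function(assignment, mode = c("random", "strict"),
                                    n_epochs = 35, t_start = 0,
                                    stim_on = 0.8, epoch_len = 1,
                                    amplitude = NULL, subset_fraction = 1,
                                    amplitude_jitter = 0, seed = NULL) {
  mode <- match.arg(mode)
  M <- assignment$M
  if (n_epochs < M) stop("n_epochs must be at least M")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amplitude)) amplitude <- assignment$params$stim_amplitude
  order <- if (mode == "strict") {
    rep_len(seq_len(M), n_epochs)
  } else {
    sample(c(seq_len(M), sample.int(M, n_epochs - M, replace = TRUE)))
  }
  t_on <- t_start + (seq_len(n_epochs) - 1) * epoch_len
  amp <- amplitude * (1 + runif(n_epochs, -amplitude_jitter,
                                amplitude_jitter))
  targets <- lapply(seq_len(n_epochs), function(k) {
    mod <- assignment$modules[[order[k]]]
    ids <- c(mod$e, mod$hi, mod$ai)
    if (subset_fraction < 1)
      ids <- sort(sample(ids, max(1L, round(length(ids) * subset_fraction))))
    ids
  })
  structure(list(
    epochs = data.frame(memory = order, t_on = t_on, t_off = t_on + stim_on,
                        amplitude = amp),
    targets = targets, epoch_len = epoch_len,
    t_end = t_start + n_epochs * epoch_len), class = "qif_protocol")
}

#' Build a modular template weight matrix
#'
#' Constructs the "imperfectly learned" two-module (or `M`-module) weight
#' matrix used as the starting point of the consolidation, recovery and
#' capacity experiments: synapses within a memory population are set to
#' `intra_e` (0.7) for excitatory and `intra_i` (-0.7) for inhibitory
#' pre-synaptic neurons, while all remaining entries are drawn from a
#' zero-mean Gaussian of standard deviation `inter_sd` (0.15) truncated
#' to the sign of the synapse class. Hub neurons shared between two
#' modules receive intra-module weights with both.
#'
#' @param assignment a [population_assignment()] object.
#' @param intra_e,intra_i intra-module weights for excitatory and
#'   inhibitory pre-synaptic neurons.
#' @param inter_sd standard deviation of the truncated-Gaussian
#'   inter-module weights.
#' @param mask optional logical connectivity mask.
#' @param seed optional seed.
#' @return an `N x N` weight matrix with zero diagonal.
#' @export
build_modular_matrix <- function(assignment, intra_e = 0.7, intra_i = -0.7,
                                 inter_sd = 0.15, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- assignment$params
  N <- params$N
  cls <- neuron_classes(params)
  exc <- cls == "e"
  membership <- matrix(FALSE, N, assignment$M)
  for (m in seq_len(assignment$M))
    membership[unlist(assignment$modules[[m]], use.names = FALSE), m] <- TRUE
  same <- tcrossprod(membership) > 0

  w <- matrix(0, N, N)
  w[, exc] <- abs(rnorm(N * sum(exc), 0, inter_sd))
  w[, !exc] <- -abs(rnorm(N * sum(!exc), 0, inter_sd))
  w[w > 1] <- 1   # guard: keep the truncated tails inside the class bounds
  w[w < -1] <- -1
  w[same & matrix(exc, N, N, byrow = TRUE)] <- intra_e
  w[same & matrix(!exc, N, N, byrow = TRUE)] <- intra_i
  diag(w) <- 0
  if (!is.null(mask)) w[!mask] <- 0
  w
}

#' Randomise a subset of the weight matrix
#'
#' Redraws the selected synapse groups uniformly within their class
#' bounds, leaving every other entry bit-identical. Subsets:
#' `"e-out"` = all synapses with excitatory pre-synaptic neuron (E->E and
#' E->I), `"i-out"` = all synapses with inhibitory pre-synaptic neuron,
#' `"all-but-ee"` = everything except the E->E block, `"none"` = identity.
#'
#' @param weights `N x N` weight matrix.
#' @param class_of per-neuron synapse classes (`"e"`, `"hi"`, `"ai"`).
#' @param subset one of `"e-out"`, `"i-out"`, `"all-but-ee"`, `"none"`.
#' @param mask optional logical connectivity mask (masked-out entries
#'   stay 0).
#' @param seed optional seed.
#' @return the perturbed weight matrix.
#' @export
randomize_weight_subset <- function(weights, class_of,
                                    subset = c("e-out", "i-out",
                                               "all-but-ee", "none"),
                                    mask = NULL, seed = NULL) {
  subset <- match.arg(subset)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(weights)
  exc <- class_of == "e"
  pre_exc <- matrix(exc, N, N, byrow = TRUE)
  post_exc <- matrix(exc, N, N)
  sel <- switch(subset,
                "e-out" = pre_exc,
                "i-out" = !pre_exc,
                "all-but-ee" = !(pre_exc & post_exc),
                "none" = matrix(FALSE, N, N))
  diag(sel) <- FALSE
  if (!is.null(mask)) sel <- sel & mask
  w <- weights
  n_e <- sum(sel & pre_exc); n_i <- sum(sel & !pre_exc)
  w[sel & pre_exc] <- runif(n_e, 0, 1)
  w[sel & !pre_exc] <- runif(n_i, -1, 0)
  w
}

#' Run the full training experiment
#'
#' Executes the three-stage protocol that makes modular connectivity
#' emerge: an initial resting phase (default 5 s), a learning phase of
#' `n_epochs` one-second stimulation epochs (800 ms on / 200 ms
#' relaxation, randomly alternating over the `M` memories), and a final
#' consolidation phase (default 20 s) with no stimuli. Plasticity is
#' active throughout. The inhibition regime selects how the 20% of
#' inhibitory neurons are split between the symmetric Hebbian and
#' anti-Hebbian plasticity rules: `"mixed"` (half/half), `"hebbian"`
#' (all Hebbian) or `"anti-hebbian"` (all anti-Hebbian).
#'
#' @param regime inhibition regime.
#' @param M number of memories.
#' @param N,n_exc network size and excitatory count (inhibitory count is
#'   `N - n_exc`).
#' @param n_epochs number of stimulation epochs.
#' @param rest,consolidation durations (s) of the first and last phase.
#' @param mode stimulus alternation mode.
#' @param overlap number of excitatory neurons shared between the two
#'   memories (`M = 2`).
#' @param snapshot_times times of weight-matrix snapshots (default:
#'   start, middle and end of learning).
#' @param stdp an [stdp_params()] object; defaults to `stdp_params(M)`.
#' @param seed integer seed (excitabilities, initial weights, protocol
#'   randomness and noise all derive from it).
#' @param params optional [network_params()] overriding `N`/`n_exc`.
#' @param ... further options passed to [build_stimulus_schedule()]
#'   (e.g. `subset_fraction`, `amplitude_jitter`).
#' @return an object of class `qif_experiment`: the `qif_sim` fields plus
#'   `assignment`, `phases` (rest/learning/consolidation boundaries) and
#'   `regime`.
#' @export
training_experiment <- function(regime = c("mixed", "hebbian",
                                           "anti-hebbian"),
                                M = 2, N = 100, n_exc = 80, n_epochs = 35,
                                rest = 5, consolidation = 20,
                                mode = c("random", "strict"), overlap = 0,
                                snapshot_times = NULL, stdp = NULL,
                                seed = NULL, params = NULL, ...) {
  regime <- match.arg(regime)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) {
    n_inh <- N - n_exc
    split <- switch(regime,
                    mixed = c(ceiling(n_inh / 2), floor(n_inh / 2)),
                    hebbian = c(n_inh, 0L),
                    "anti-hebbian" = c(0L, n_inh))
    params <- network_params(N = N, n_exc = n_exc, n_hebb = split[1],
                             n_anti = split[2])
  }
  if (is.null(stdp)) stdp <- stdp_params(M = M)
  assignment <- population_assignment_regime(params, M, regime, overlap)
  state <- init_network(params, "small-random")
  protocol <- build_stimulus_schedule(assignment, mode = mode,
                                      n_epochs = n_epochs, t_start = rest,
                                      ...)
  duration <- rest + n_epochs * protocol$epoch_len + consolidation
  if (is.null(snapshot_times))
    snapshot_times <- c(0, rest + n_epochs * protocol$epoch_len / 2,
                        rest + n_epochs * protocol$epoch_len)
  sim <- run_simulation(state, protocol, duration, plasticity = TRUE,
                        stdp = stdp,
                        record = record_options(
                          snapshot_times = snapshot_times, stats_dt = 1,
                          stats_module = module_vector(assignment)))
  sim$assignment <- assignment
  sim$phases <- c(rest = rest,
                  learning_end = rest + n_epochs * protocol$epoch_len,
                  total = duration)
  sim$regime <- regime
  class(sim) <- c("qif_experiment", class(sim))
  sim
}

# assignment helper coping with regimes lacking one inhibitory class:
# the missing pool is simply absent from every module
population_assignment_regime <- function(params, M, regime, overlap = 0) {
  if (regime == "mixed")
    return(population_assignment(params, M, overlap = overlap))
  # build on a fictitious mixed split, then relabel pools that exist
  a <- tryCatch(population_assignment(params, M, overlap = overlap),
                error = function(e) NULL)
  if (!is.null(a)) return(a)
  # one inhibitory class empty: split the available pools only
  blocks <- function(idx, M) split(idx, rep(seq_len(M), times = diff(round(
    seq(0, length(idx), length.out = M + 1)))))
  e_blocks <- blocks(seq_len(params$n_exc), M)
  hi_idx <- params$n_exc + seq_len(params$n_hebb)
  ai_idx <- params$n_exc + params$n_hebb + seq_len(params$n_anti)
  hi_blocks <- if (params$n_hebb >= M) blocks(hi_idx, M) else
    replicate(M, integer(0), simplify = FALSE)
  ai_blocks <- if (params$n_anti >= M) blocks(ai_idx, M) else
    replicate(M, integer(0), simplify = FALSE)
  modules <- lapply(seq_len(M), function(m)
    list(e = unname(e_blocks[[m]]), hi = unname(hi_blocks[[m]]),
         ai = unname(ai_blocks[[m]])))
  structure(list(M = M, N = params$N, modules = modules, hubs = integer(0),
                 untrained = integer(0), params = params),
            class = "qif_assignment")
}

#' Recovery of a damaged modular connectivity
#'
#' Starting from a (partially randomised) learned weight matrix, lets the
#' network evolve spontaneously -- driven only by the background noise,
#' with plasticity on -- and tracks whether spontaneous recalls
#' regenerate the modular structure. Returns the block-mean weight
#' trajectories (intra/inter per synapse class), a modular-contrast
#' similarity series and the detected recall events.
#'
#' @param weights0 initial (perturbed) weight matrix.
#' @param assignment a [population_assignment()] object.
#' @param duration simulated time (s).
#' @param stdp an [stdp_params()] object.
#' @param stats_dt cadence of the block-mean recorder (s).
#' @param seed optional seed.
#' @param plasticity logical (for frozen controls).
#' @param noise logical; `FALSE` switches off the background noise.
#' @return list of class `qif_recovery`: `sim`, `stats`, `similarity`
#'   (data frame: time and intra-minus-inter contrast for the E->E and
#'   inhibitory blocks) and `recalls`.
#' @export
recovery_experiment <- function(weights0, assignment, duration = 120,
                                stdp = stdp_params(M = assignment$M),
                                stats_dt = 1, seed = NULL,
                                plasticity = TRUE, noise = TRUE) {
  params <- assignment$params
  if (!noise) params$noise_sigma <- 0
  if (!is.null(seed)) set.seed(seed)
  state <- init_network(params, "zero")
  state$weights <- validate_weights(weights0, params, state$mask)
  diag(state$weights) <- 0
  sim <- run_simulation(state, NULL, duration, plasticity = plasticity,
                        stdp = stdp,
                        record = record_options(
                          stats_dt = stats_dt,
                          stats_module = module_vector(assignment)))
  st <- sim$stats
  similarity <- data.frame(
    time_s = st$time_s,
    ee_contrast = st$EE_intra - st$EE_inter,
    hebb_contrast = st$HE_inter - st$HE_intra,   # Hebbian-I concentrates intra
    anti_contrast = st$AE_intra - st$AE_inter)   # anti-Hebbian concentrates inter
  recalls <- detect_recalls(sim, assignment)
  structure(list(sim = sim, stats = st, similarity = similarity,
                 recalls = recalls), class = "qif_recovery")
}

#' Memory-capacity feasibility rule
#'
#' Each stored memory needs a triplet of at least one excitatory, one
#' Hebbian-inhibitory and one anti-Hebbian-inhibitory neuron; with the
#' inhibitory pool split evenly, `M` memories are stable only if
#' `M <= min(N_E, floor(N_I / 2))`. At fixed `N` the capacity is
#' maximised at `N_I = 2M`, giving `M* = floor(N / 3)`.
#'
#' @param N network size.
#' @return list with `M_star` and the optimal inhibitory count `NI_star`.
#' @export
capacity_limit <- function(N) {
  M_star <- floor(N / 3)
  list(M_star = M_star, NI_star = 2 * M_star)
}

#' Scan the stability diagram over (M, N_I)
#'
#' For each combination of stored-memory count `M` and inhibitory count
#' `NI` (with `NE = N - NI` and the inhibitory pool split evenly between
#' Hebbian and anti-Hebbian), applies the triplet counting rule and,
#' optionally, classifies stability by simulating the pre-built modular
#' template for `horizon` seconds of resting dynamics and requiring
#' asynchronous firing plus at least one spontaneous recall per module.
#'
#' @param N network size.
#' @param M_list,NI_list grid values.
#' @param horizon simulated duration per simulated grid point (s).
#' @param simulate logical; run the simulation-based classification for
#'   the feasible points.
#' @param replicates simulated realisations per grid point (a point is
#'   stable if any realisation is classified stable).
#' @param seed optional seed.
#' @param ... passed to [classify_stability()].
#' @return data frame with columns `M`, `NI`, `NE`, `n_hebb`, `n_anti`,
#'   `accessible` (`NE >= M`), `feasible` (triplet rule),
#'   `predicted_stable`, and (when simulated) `stable` plus
#'   `min_recalls`.
#' @export
capacity_scan <- function(N = 100, M_list, NI_list, horizon = 120,
                          simulate = FALSE, replicates = 1, seed = NULL,
                          ...) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(M = M_list, NI = NI_list)
  grid$NE <- N - grid$NI
  grid$n_hebb <- ceiling(grid$NI / 2)
  grid$n_anti <- floor(grid$NI / 2)
  grid$accessible <- grid$NE >= grid$M & grid$NE >= 1
  grid$feasible <- grid$M <= pmin(grid$NE, grid$n_hebb, grid$n_anti)
  grid$predicted_stable <- grid$feasible
  if (simulate) {
    grid$stable <- NA
    grid$min_recalls <- NA_integer_
    for (r in which(grid$feasible)) {
      ok <- FALSE; minrec <- 0L
      for (rep in seq_len(replicates)) {
        v <- simulate_capacity_point(N, grid$M[r], grid$n_hebb[r],
                                     grid$n_anti[r], horizon, ...)
        minrec <- max(minrec, min(v$recall_counts))
        if (v$stable) { ok <- TRUE; break }
      }
      grid$stable[r] <- ok
      grid$min_recalls[r] <- minrec
    }
  }
  grid
}

simulate_capacity_point <- function(N, M, n_hebb, n_anti, horizon, ...) {
  params <- network_params(N = N, n_exc = N - n_hebb - n_anti,
                           n_hebb = n_hebb, n_anti = n_anti)
  assignment <- population_assignment(params, M)
  w0 <- build_modular_matrix(assignment)
  state <- init_network(params, "zero")
  state$weights <- w0
  sim <- run_simulation(state, NULL, horizon, plasticity = TRUE,
                        stdp = stdp_params(M = M))
  classify_stability(sim, assignment, ...)
}

#' Training with overlapping stimuli and hub detection
#'
#' Trains a network with two stimuli sharing `n_overlap` excitatory
#' neurons under strict alternation, then reports the hub neurons:
#' excitatory neurons whose mean outgoing weight towards the exclusive
#' excitatory sets of at least two modules exceeds `hub_threshold`.
#' Recall events are classified over the exclusive population sets and
#' the hub set, so events of type "one population including the hubs",
#' "population without the hubs" and "hubs alone" can all appear in the
#' log.
#'
#' @param n_overlap number of shared excitatory neurons.
#' @param hub_threshold outgoing-weight threshold for hub classification.
#' @param ... passed to [training_experiment()] (e.g. `seed`,
#'   `n_epochs`).
#' @return a `qif_experiment` with extra fields `hubs_detected`,
#'   `hub_report` (per excitatory neuron: mean outgoing weight to each
#'   module) and `recalls`.
#' @export
overlap_experiment <- function(n_overlap = 8, hub_threshold = 0.5, ...) {
  exp <- training_experiment(regime = "mixed", M = 2, mode = "strict",
                             overlap = n_overlap, ...)
  exp$hub_report <- hub_report(exp$weights, exp$assignment)
  exp$hubs_detected <- hub_neurons(exp$hub_report, hub_threshold)
  exp$recalls <- detect_recalls(exp, exp$assignment,
                                t_start = exp$phases["learning_end"])
  exp
}

#' Mean outgoing excitatory weight per module
#'
#' @param weights `N x N` weight matrix.
#' @param assignment a [population_assignment()] object.
#' @return data frame, one row per excitatory neuron, with the mean
#'   outgoing weight towards each module's exclusive excitatory set.
#' @export
hub_report <- function(weights, assignment) {
  e_idx <- which(neuron_classes(assignment$params) == "e")
  sets <- lapply(seq_len(assignment$M), function(m)
    setdiff(assignment$modules[[m]]$e, assignment$hubs))
  out <- data.frame(neuron = e_idx)
  for (m in seq_len(assignment$M)) {
    tgt <- sets[[m]]
    out[[paste0("to_module_", m)]] <- vapply(e_idx, function(j)
      mean(weights[setdiff(tgt, j), j]), numeric(1))
  }
  out
}

hub_neurons <- function(report, threshold = 0.5) {
  strong <- rowSums(as.matrix(report[, -1, drop = FALSE]) > threshold)
  report$neuron[strong >= 2]
}
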