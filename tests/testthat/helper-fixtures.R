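# Shared fixtures and independent oracles.

# equal-fraction archetype simulation (no flat proteins)
equal_archetype_fractions <- function(f = 0.2) {
  c(C1_decrease = f, C2_dip_recover = f, C3_peak_EM = f,
    C4_gradual_up = f, C5_early_jump = f)
}

# small simulated experiment, normalized and bridged; channel_norm = FALSE
# gives the bridge-only path (no loading effects are planted, and totals
# scaling is composition-confounded under unbalanced planted regulation)
make_bridged <- function(n = 300, noise = 0.25, seed = 11,
                         channel_norm = TRUE, ...) {
  cfg <- sim_config(n_proteins = n, noise_sd_log2 = noise, seed = seed, ...)
  truth <- generate_ground_truth(cfg)
  sim <- simulate_multiplexes(truth, cfg)
  bridged <- if (channel_norm) {
    normalize_experiment(sim$matrices, sim$design)
  } else {
    bridge_correct(sim$matrices, sim$design)
  }
  list(bridged = bridged, truth = truth, sim = sim, config = cfg)
}

# brute-force step-up BH oracle, straight from the definition:
# adj(i) = min over j with p(j) >= p(i)... computed via ranks
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj_sorted[i] <- min(1, min(candidates))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# pooled-variance two-tailed t oracle via stats::t.test
t_oracle <- function(x, y) {
  fit <- stats::t.test(x, y, var.equal = TRUE)
  list(p = fit$p.value, t = unname(fit$statistic), df = unname(fit$parameter),
       estimate = mean(x) - mean(y))
}

# exhaustive minimum assignment cost over all k! permutations
assignment_brute_force <- function(dmat) {
  k <- nrow(dmat)
  perms <- bridgeTMT:::permutations(seq_len(k))
  min(vapply(perms, function(p) sum(dmat[cbind(seq_len(k), p)]), numeric(1)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# archetype labels aligned to a named assignment vector
planted_archetypes <- function(truth, ids) {
  truth$archetype[match(ids, truth$protein_id)]
}
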