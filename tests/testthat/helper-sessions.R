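# Shared fixture builders; everything is generated in code at test time.

# A tiny deterministic session with hand-made kinematics and counts.
tiny_session <- function(nb = 40, n_units = 3, seed = 1) {
  set.seed(seed)
  tt <- (seq_len(nb) - 1) * 0.05
  kin <- kinematics_frame(px = 5 * sin(tt), py = 3 * cos(tt),
                          tx = rep(2, nb), ty = rep(-1, nb),
                          target_radius = 2.5)
  counts <- matrix(rpois(n_units * nb, 2), n_units, nb)
  spikes <- spike_count_block(counts,
                              channel_of_unit = rep_len(1:2, n_units))
  trials <- trial_table("center", 1L, nb, TRUE, 0, 0)
  binned_session(kin, spikes, trials)
}

# A simulated hand-control session from the generative population.
sim_session <- function(duration = 120, n_units = 12, seed = 7, ...) {
  simulate_hand_session(
    task_config("center_out", duration = duration),
    population_config(n_units = n_units, seed = seed + 100, ...),
    seed = seed)
}

# Random symmetric positive definite matrix.
rand_spd <- function(d, jitter = 0.3) {
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) / d + diag(jitter, d)
}

expect_symmetric_psd <- function(P, tol = 1e-8) {
  expect_lt(max(abs(P - t(P))), tol)
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
            -tol * max(1, max(abs(P))))
}
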