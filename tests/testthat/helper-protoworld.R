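# Shared fixtures: all built in code, no data files.

default_p <- default_params()

# A parameter set in which nothing happens spontaneously; individual rates
# are switched back on per test to isolate one event type.
quiet_params <- function(...) {
  p <- default_params()
  probs <- c("P_AT", "P_BB", "P_FLR", "P_FP", "P_MV", "P_ND", "P_NDE",
             "P_NF", "P_NFR", "P_RBT", "P_RD", "P_RL", "P_RTT", "P_TL",
             "P_TLR", "P_AD", "P_ADM", "P_AF", "P_AJM", "P_ALM", "P_APP",
             "P_CB", "P_CC", "P_CD", "P_CF", "P_MC", "P_MF", "P_NPP")
  for (nm in probs) p[[nm]] <- 0
  p$P_SP <- 0.38
  over <- list(...)
  p[names(over)] <- over
  p
}

# quiet_params zeroes whole rate groups, which trips the ordering warnings
# by design; simulations built on it suppress them
new_sim_quiet <- function(...) suppressWarnings(new_simulation(...))

# 99% two-sided binomial confidence check for an empirical frequency.
# `m` is the number of simultaneous checks in the family: the level is
# Bonferroni-adjusted so the whole family holds at 99% (a genuine wiring
# error shows up at z of tens to thousands, far beyond either bound).
expect_freq_in_ci <- function(successes, attempts, p, label = "", m = 1) {
  expect_gt(attempts, 0, label = paste(label, "attempts"))
  if (p == 0) {
    expect_equal(successes, 0, label = label)
    return(invisible())
  }
  z <- stats::qnorm(1 - 0.01 / (2 * m))
  half <- z * sqrt(p * (1 - p) / attempts)
  expect_lt(abs(successes / attempts - p), max(half, 1e-12),
            label = sprintf("%s freq %.3g vs nominal %.3g (n=%d)", label,
                            successes / attempts, p, attempts))
}

# Small two-region simulation with protocell-friendly settings used by the
# conservation and protocell suites.
make_busy_sim <- function(seed = 42, stress = TRUE) {
  p <- default_params()
  if (stress) {
    # push the rare protocell events hard so divisions, fusions, breaks and
    # cytophagy all occur within a short run (conservation must hold at any
    # rates, so these are legitimate stress settings)
    p$P_CD <- 0.05
    p$P_CF <- 0.05
    p$P_CB <- 0.002
    p$P_CC <- 0.02
    p$P_MC <- 0.01
    p$P_MF <- 0.05
    p$L_AM <- 30
    p$P_NF <- 0.01
    p$P_RL <- 1e-3
    p$P_TL <- 0.01
  }
  sim <- suppressWarnings(
    new_simulation(p, N = 6, region_layout = "core", seed = seed))
  seed_pools(sim, 2000, 1500)
  ms <- minimal_sequences(p)
  sol_rooms <- which(sim$region == 1L) - 1L
  inoculate_strands(sim, ms$rep_spreadable, rep(sol_rooms[1], 3))
  inoculate_strands(sim, ms$nsr_spreadable, rep(sol_rooms[2], 3))
  inoculate_protocell(sim, sol_rooms[5], b = 80,
                      interior_seqs = c(ms$rep_spreadable,
                                        ms$nsr_spreadable),
                      interior_np = 50)
  inoculate_protocell(sim, sol_rooms[8], b = 90, interior_np = 30)
  sim
}
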