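# Empirical Bernoulli frequencies of the engine's event types against their
# nominal probabilities (99% binomial confidence). Each world isolates one
# or a few event types by zeroing the rest; the check validates that every
# rule is wired to the intended rate, including region modifiers.

# the file runs 20 simultaneous interval checks; hold the family at 99%
freq_ci <- function(...) expect_freq_in_ci(..., m = 20)

freq <- function(ev, name) {
  c(ev[[paste0(name, ".successes")]], ev[[paste0(name, ".attempts")]])
}

test_that("small-molecule chemistry events run at their nominal rates", {
  p <- quiet_params(P_NF = 2e-4, P_ND = 5e-3, P_AF = 1e-3, P_AD = 2e-4)
  sim <- new_sim_quiet(p, N = 6, seed = 101)
  seed_pools(sim, 360000, 360000)
  invisible(run_steps(sim, 120, 120))
  ev <- event_stats(sim)
  f <- freq(ev, "nucleotide_formation")
  freq_ci(f[1], f[2], 2e-4, "nucleotide formation")
  f <- freq(ev, "nucleotide_decay")
  freq_ci(f[1], f[2], 5e-3, "nucleotide decay")
  f <- freq(ev, "amphiphile_formation")
  freq_ci(f[1], f[2], 1e-3, "amphiphile formation")
  f <- freq(ev, "amphiphile_decay")
  freq_ci(f[1], f[2], 2e-4, "amphiphile decay")
})

test_that("NSR catalysis switches nucleotide formation to P_NFR", {
  p <- quiet_params(P_NFR = 0.9)
  sim <- new_sim_quiet(p, N = 4, seed = 102)
  seed_pools(sim, 200000, 0)
  inoculate_strands(sim, default_p$CS_NSR, 0:15)  # one free NSR per room
  invisible(run_steps(sim, 6, 6))
  ev <- event_stats(sim)
  f <- freq(ev, "nucleotide_formation_nsr")
  freq_ci(f[1], f[2], 0.9, "catalyzed nucleotide formation")
  expect_equal(ev[["nucleotide_formation.attempts"]], 0)
})

test_that("chain-end residues decay at P_NDE per end", {
  p <- quiet_params(P_NDE = 2e-4)
  sim <- new_sim_quiet(p, N = 6, seed = 103)
  inoculate_strands(sim, strrep("AC", 25), rep(0:35, each = 20))
  invisible(run_steps(sim, 300, 300))
  ev <- event_stats(sim)
  f <- freq(ev, "end_residue_decay")
  expect_gt(f[2], 4e5)   # two trials per free strand per step
  freq_ci(f[1], f[2], 2e-4, "end residue decay")
})

test_that("random ligation of colliding mononucleotides runs at P_RL", {
  p <- quiet_params(P_RL = 1e-3)
  sim <- new_sim_quiet(p, N = 6, seed = 104)
  npv <- rep(0, 36)
  protoworld:::cpp_restore_pools(sim$ptr, npv, rep(2000, 36), npv, npv)
  invisible(run_steps(sim, 100, 100))
  ev <- event_stats(sim)
  f <- freq(ev, "random_ligation")
  freq_ci(f[1], f[2], 1e-3, "random ligation")
})

test_that("template attraction, the template decision and separation track P_AT, P_RTT and P_SP^((r+1)/2)", {
  # rooms holding one 10-mer template and full-length complementary
  # partners churn through attract / anneal / separate cycles
  tpl <- "AAGGCUACAG"
  p <- quiet_params(P_AT = 0.4, P_RTT = 0.5)
  p$P_SP <- 0.38
  sim <- new_sim_quiet(p, N = 10, seed = 105)
  rooms <- 0:99
  inoculate_strands(sim, tpl, rooms)
  inoculate_strands(sim, reverse_complement(tpl), rooms)
  invisible(run_steps(sim, 1000, 1000))
  ev <- event_stats(sim)
  f <- freq(ev, "attract")
  freq_ci(f[1], f[2], 0.4, "substrate attraction")
  f <- freq(ev, "turn_to_template")
  freq_ci(f[1], f[2], 0.5, "turn to template")
  f <- freq(ev, "separation")
  freq_ci(f[1], f[2], 0.38^5.5, "separation of a 10-bp duplex")
})

test_that("REP binding and dropping track P_RBT and P_RD", {
  p <- quiet_params(P_RBT = 0.4, P_RD = 0.01)
  rep <- minimal_sequences(default_p)$rep_spreadable
  sim <- new_sim_quiet(p, N = 10, seed = 106)
  inoculate_strands(sim, rep, rep(0:99, each = 2))
  invisible(run_steps(sim, 400, 400))
  ev <- event_stats(sim)
  f <- freq(ev, "rep_bind")
  freq_ci(f[1], f[2], 0.4, "REP binding")
  f <- freq(ev, "rep_drop")
  freq_ci(f[1], f[2], 0.01, "REP dropping")
})

test_that("template-directed ligation of adjacent substrates runs at P_TL", {
  tpl <- "AAGGCUACAG"
  halves <- c(substr(reverse_complement(tpl), 1, 5),
              substr(reverse_complement(tpl), 6, 10))
  p <- quiet_params(P_AT = 1, P_RTT = 1, P_TL = 0.02)
  p$P_SP <- 0.05   # recycle assembled duplexes now and then
  sim <- new_sim_quiet(p, N = 10, seed = 107)
  rooms <- 0:99
  inoculate_strands(sim, tpl, rooms)
  inoculate_strands(sim, halves[1], rooms)
  inoculate_strands(sim, halves[2], rooms)
  invisible(run_steps(sim, 800, 800))
  ev <- event_stats(sim)
  f <- freq(ev, "template_ligation")
  expect_gt(f[2], 5000)
  freq_ci(f[1], f[2], 0.02, "template-directed ligation")
})

test_that("pool movement uses P_MV, ten-fold faster in the solution region", {
  p <- quiet_params(P_MV = 1e-3)
  sim <- new_sim_quiet(p, N = 8, region_layout = "core", seed = 108)
  seed_pools(sim, 64000, 0)
  invisible(run_steps(sim, 2000, 2000))
  ev <- event_stats(sim)
  f <- freq(ev, "pool_move_rocky")
  freq_ci(f[1], f[2], 1e-3, "movement in rocky region")
  f <- freq(ev, "pool_move_solution")
  freq_ci(f[1], f[2], 1e-2, "movement in solution region")
})

test_that("protocell-level events track their nominal rates", {
  p <- quiet_params(P_CB = 2e-3, P_CC = 0.05, P_MC = 0.02, P_CF = 0,
                    P_AJM = 0.8, P_ADM = 1e-3)
  sim <- new_sim_quiet(p, N = 8, region_layout = "core", seed = 109)
  sol <- which(sim$region == 1L) - 1L
  for (r in sol[seq(1, length(sol), by = 4)])
    inoculate_protocell(sim, r, b = 4000, interior_np = 10,
                        interior_am = 300)
  invisible(run_steps(sim, 400, 400))
  ev <- event_stats(sim)
  f <- freq(ev, "cell_break")
  freq_ci(f[1], f[2], 2e-3, "protocell breaking")
  f <- freq(ev, "cytophagy")
  freq_ci(f[1], f[2], 0.05, "cytophagy")
  f <- freq(ev, "cell_move")
  freq_ci(f[1], f[2], 0.02, "protocell movement")
  f <- freq(ev, "membrane_join")
  freq_ci(f[1], f[2], 0.8, "amphiphile joining the membrane")
  f <- freq(ev, "membrane_amphiphile_decay")
  freq_ci(f[1], f[2], 1e-3, "membrane amphiphile decay")
})
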