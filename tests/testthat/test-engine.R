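test_that("an empty system advances its counter and nothing else", {
  sim <- new_simulation(default_params(), N = 6, seed = 1)
  before <- sim_counts(sim)
  s <- run_steps(sim, 50, 10)
  after <- sim_counts(sim)
  expect_equal(sim_step_count(sim), 50)
  expect_equal(after[-1], before[-1])
  expect_true(all(s$np == 0 & s$strands == 0))
})

test_that("identical configuration and seed give identical trajectories", {
  run_once <- function() {
    res <- run_scenario("tiny_fig2", seed = 5, stop_step = 3000,
                        sample_every = 250)
    res$series
  }
  expect_identical(run_once(), run_once())
})

test_that("different seeds diverge", {
  a <- run_scenario("tiny_fig2", seed = 5, stop_step = 5000,
                    sample_every = 250)$series
  b <- run_scenario("tiny_fig2", seed = 6, stop_step = 5000,
                    sample_every = 250)$series
  expect_false(identical(a, b))
})

test_that("conservation ledgers hold over an event-rich run with protocells", {
  sim <- make_busy_sim(seed = 42)
  led0 <- sim_ledger(sim)
  expect_equal(led0[["nt_equivalents"]], led0[["nt_expected"]])
  expect_equal(led0[["am_equivalents"]], led0[["am_expected"]])
  protoworld:::cpp_set_ledger_every(sim$ptr, 500)  # hard check inside C++
  invisible(run_steps(sim, 10000, 2000))
  expect_true(check_ledgers(sim))
  led <- sim_ledger(sim)
  expect_equal(led[["nt_equivalents"]], led0[["nt_expected"]])
  expect_equal(led[["am_equivalents"]], led0[["am_expected"]])
  # the stress run really exercised the protocell event set
  ev <- event_stats(sim)
  expect_gt(ev[["cell_division.successes"]], 0)
  expect_gt(ev[["cell_fusion.successes"]], 0)
  expect_gt(ev[["cell_break.successes"]], 0)
  expect_gt(ev[["cytophagy.successes"]], 0)
})

test_that("region layouts wrap on a torus and the core sits in a solution frame", {
  sim <- new_simulation(default_params(), N = 8, region_layout = "core",
                        seed = 1)
  reg <- matrix(sim$region, 8, 8)
  expect_equal(sum(reg == 0), 16)           # 4x4 rocky core
  expect_true(all(reg[1, ] == 1))           # frame is solution
  snap <- sim_snapshot(sim)
  expect_equal(nrow(snap), 64)
  expect_equal(sort(unique(snap$region)), c("rocky", "solution"))
})

test_that("movement respects the interface policy", {
  # strands seeded into the rocky core must stay there under
  # precursors_only, while precursor pools may leak out
  p <- quiet_params(P_MV = 0.05)
  run_policy <- function(policy) {
    sim <- new_sim_quiet(p, N = 6, region_layout = "core",
                         interface_policy = policy, seed = 3)
    rocky <- which(sim$region == 0L) - 1L
    npv <- numeric(36)
    npv[rocky + 1] <- 100
    protoworld:::cpp_restore_pools(sim$ptr, npv, numeric(36), numeric(36),
                                   numeric(36))
    inoculate_strands(sim, "ACGUACGUACGUACGUACGU", rep(rocky, 2))
    invisible(run_steps(sim, 400, 400))
    st <- sim_strand_table(sim)
    snap <- sim_snapshot(sim)
    list(strands_in_solution = sum(snap$region[st$room + 1] == "solution"),
         np_in_solution = sum(snap$np[snap$region == "solution"]))
  }
  sealed <- run_policy("precursors_only")
  open <- run_policy("all_molecules")
  expect_equal(sealed$strands_in_solution, 0)
  expect_gt(sealed$np_in_solution, 0)     # raw materials still cross
  expect_gt(open$strands_in_solution, 0)
})

test_that("protocells exist only where the region permits them", {
  sim <- make_busy_sim(seed = 7)
  invisible(run_steps(sim, 4000, 1000))
  snap <- sim_snapshot(sim)
  expect_true(all(snap$region[snap$has_cell] == "solution"))
})

test_that("checkpoints restore a mass-consistent state", {
  sim <- make_busy_sim(seed = 21)
  invisible(run_steps(sim, 1500, 500))
  led <- sim_ledger(sim)
  dir <- withr::local_tempdir()
  save_checkpoint(sim, dir)
  sim2 <- load_checkpoint(dir, seed = 99)
  led2 <- sim_ledger(sim2)
  expect_equal(led2[["nt_equivalents"]], led[["nt_equivalents"]])
  expect_equal(led2[["am_equivalents"]], led[["am_equivalents"]])
  expect_true(check_ledgers(sim2))
  invisible(run_steps(sim2, 500, 500))
  expect_true(check_ledgers(sim2))
})
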