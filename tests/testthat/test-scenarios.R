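test_that("presets resolve to their documented setups", {
  f2 <- build_scenario("fig2_rep_spread")
  expect_equal(f2$N, 20)
  expect_equal(f2$T_NPB, 80000)
  expect_equal(f2$T_APB, 0)
  expect_equal(f2$schedule[[1]]$step, 1e5)
  expect_equal(f2$schedule[[1]]$count, 50)
  expect_equal(f2$schedule[[1]]$rooms_n, 10)

  f9 <- build_scenario("fig9_two_region")
  expect_equal(f9$N, 40)
  expect_true(f9$near_reality)
  expect_equal(f9$interface_policy, "all_molecules")
  cells <- f9$schedule[[3]]
  expect_equal(cells$step, 6e6)
  expect_equal(c(cells$n_cells, cells$rep_each, cells$nsr_each),
               c(10, 5, 5))

  f10 <- build_scenario("fig10_cytophagy")
  expect_equal(f10$params$P_CC, 1e-5)   # hundred-fold enhanced cytophagy
  expect_equal(f10$schedule[[3]]$rep_each, 0)

  f11 <- build_scenario("fig11_fair_competition")
  expect_false(f11$near_reality)
  expect_equal(f11$interface_policy, "precursors_only")
  expect_equal(f11$params$P_NPP, 1)
  expect_equal(f11$schedule[[3]]$step, 3e6)

  f13 <- build_scenario("fig13_parasite_pulse")
  expect_equal(f13$params$P_FP, 0)
  pulses <- Filter(function(ev) identical(ev$role, "parasite"),
                   f13$schedule)
  expect_equal(length(pulses), 8)   # four pulse times x two subsystems
  expect_equal(sort(unique(vapply(pulses, `[[`, 0, "step"))),
               seq(1e7, 2.5e7, by = 5e6))
  expect_error(build_scenario("fig99"), "unknown")
})

test_that("tiny presets keep probabilities at defaults and scale the counts", {
  t2 <- build_scenario("tiny_fig2")
  expect_equal(t2$N, 14)
  expect_equal(t2$T_NPB, 40000)
  expect_true(all(!grepl("^P_", names(t2$params))))
  # per-room inoculation density matches the full-scale setup (5 per room)
  expect_equal(t2$schedule[[1]]$count / t2$schedule[[1]]$rooms_n, 5)
  t11 <- build_scenario("tiny_fig11")
  expect_equal(t11$N, 10)
  expect_equal(setdiff(names(t11$params), "P_NPP"), character())
})

test_that("a run produces a consistent series and honours the inoculation schedule", {
  res <- run_scenario("tiny_fig2", seed = 2, stop_step = 4000,
                      sample_every = 500)
  s <- res$series
  expect_equal(s$rep_naked[s$step <= 2000], rep(0, sum(s$step <= 2000)))
  post <- s[s$step > 2000, ]
  expect_true(all(post$rep_naked > 0))
  expect_equal(tail(s$step, 1), 4000)
  # series counts agree with a full recount of the final state
  ct <- sim_counts(res$sim)
  expect_equal(unname(tail(s$np, 1)), unname(ct[["np"]]))
  expect_equal(unname(tail(s$rep_naked, 1)), unname(ct[["rep_naked"]]))
})

test_that("record() matches sim_counts and series files round-trip", {
  res <- run_scenario("tiny_fig2", seed = 3, stop_step = 1500,
                      sample_every = 500)
  one <- record(res$sim)
  expect_equal(unlist(one), sim_counts(res$sim))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(res$series, path, scenario = "tiny_fig2", seed = 3)
  back <- read_series(path)
  expect_equal(back, res$series)
})

test_that("scenario output files are written and byte-identical across reruns", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_scenario("tiny_fig2", seed = 4, stop_step = 3000, sample_every = 500,
               out_dir = d1)
  run_scenario("tiny_fig2", seed = 4, stop_step = 3000, sample_every = 500,
               out_dir = d2)
  for (f in c("series.csv", "snapshot.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  manifest <- readLines(file.path(d1, "manifest.cfg"))
  expect_true(any(grepl("seed = 4", manifest)))
  expect_true(any(grepl("P_SP = 0.38", manifest)))
})

test_that("the command line prints defaults and runs a tiny scenario", {
  out <- capture.output(status <- cli_run("--print-defaults"))
  expect_equal(status, 0L)
  expect_true(any(grepl("^P_SP = 0.38$", out)))
  expect_true(any(grepl("^CS_Tag = ACGU$", out)))
  dir <- withr::local_tempdir()
  suppressMessages(
    cli_run(c("--scenario", "tiny_fig2", "--seed", "1", "--steps", "2000",
              "--out", dir, "--sample-every", "500")))
  expect_true(file.exists(file.path(dir, "series.csv")))
  expect_true(file.exists(file.path(dir, "manifest.cfg")))
  expect_error(cli_run(c("--scenario", "a", "--config", "b")),
               "mutually exclusive")
})

test_that("a config file drives a custom run", {
  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("[parameters]", "N = 6", "T_NPB = 3600", "T_APB = 1",
               "P_NF = 0.001",
               "[scenario]", "stop_step = 2000", "sample_every = 500",
               "inoculate_rep_at = 500", "inoculum = 6",
               "inoculum_rooms = 2"), cfg)
  dir <- withr::local_tempdir()
  suppressMessages(cli_run(c("--config", cfg, "--seed", "2", "--out", dir)))
  s <- read_series(file.path(dir, "series.csv"))
  expect_equal(tail(s$step, 1), 2000)
  expect_gt(tail(s$rep_naked, 1) + tail(s$strands, 1), 0)
})

test_that("periodic checkpoints are written and reloadable", {
  dir <- withr::local_tempdir()
  run_scenario("tiny_fig2", seed = 9, stop_step = 3000, sample_every = 500,
               out_dir = dir, checkpoint_every = 1500)
  cp <- file.path(dir, "checkpoint_1500")
  expect_true(file.exists(file.path(cp, "rooms.csv")))
  sim <- load_checkpoint(cp, seed = 1)
  expect_true(check_ledgers(sim))
})
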