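test_that("membranes assemble where amphiphiles gather, and only in solution", {
  p <- quiet_params(P_MF = 0.05)
  p$L_AM <- 50
  sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = 31)
  # pile amphiphiles above the limit in one solution and one rocky room
  amv <- numeric(36)
  sol <- which(sim$region == 1L) - 1L
  rocky <- which(sim$region == 0L) - 1L
  amv[sol[1] + 1] <- 200
  amv[rocky[1] + 1] <- 200
  protoworld:::cpp_restore_pools(sim$ptr, numeric(36), numeric(36),
                                 numeric(36), amv)
  invisible(run_steps(sim, 200, 200))
  snap <- sim_snapshot(sim)
  expect_true(snap$has_cell[snap$y * 6 + snap$x == sol[1]])
  expect_false(any(snap$has_cell[snap$region == "rocky"]))
  # all room amphiphiles went into the membrane
  expect_equal(snap$cell_b[snap$y * 6 + snap$x == sol[1]], 200)
})

test_that("interior molecules partition roughly evenly at division", {
  # a large cell divides with probability P_CD (1 - 2 L_AM / b) < 1, so we
  # condition on the one-step runs in which exactly one division happened
  # and pool the mother/daughter splits of 200 interior precursors
  p <- quiet_params(P_CD = 1)
  p$L_AM <- 50
  fracs <- c()
  for (sd in 1:60) {
    sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = sd)
    sol <- which(sim$region == 1L) - 1L
    inoculate_protocell(sim, sol[6], b = 400, interior_np = 200)
    invisible(run_steps(sim, 1, 1))
    snap <- sim_snapshot(sim)
    cells <- snap[snap$has_cell, ]
    if (nrow(cells) != 2) next
    expect_equal(sum(cells$cell_np), 200)     # nothing lost in the split
    expect_equal(sort(cells$cell_b), c(200, 200))
    fracs <- c(fracs, cells$cell_np[1] / 200)
  }
  expect_gt(length(fracs), 25)
  se <- sqrt(0.25 / (length(fracs) * 200))
  expect_lt(abs(mean(fracs) - 0.5), 2.576 * se * 3)
})

test_that("a division with no free adjacent room aborts", {
  p <- quiet_params(P_CD = 1)
  p$L_AM <- 50
  sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = 77)
  sol <- which(sim$region == 1L) - 1L
  # fill every solution room with a cell; nobody can divide
  for (r in sol) inoculate_protocell(sim, r, b = 400)
  n0 <- sum(sim_snapshot(sim)$has_cell)
  invisible(run_steps(sim, 5, 5))
  expect_equal(sum(sim_snapshot(sim)$has_cell), n0)
})

test_that("a closed cell's nucleotide equivalents change only by internal chemistry", {
  p <- quiet_params(P_NF = 0.01, P_ND = 0.01)   # internal churn only
  p$P_NPP <- 0
  p$P_APP <- 0
  sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = 5)
  seed_pools(sim, 3600, 0)
  sol <- which(sim$region == 1L) - 1L
  inoculate_protocell(sim, sol[4], b = 300, interior_np = 120)
  invisible(run_steps(sim, 500, 500))
  snap <- sim_snapshot(sim)
  cell <- snap[snap$has_cell, ]
  expect_equal(cell$cell_np + cell$cell_nt, 120)  # np <-> nt churn only
  expect_true(check_ledgers(sim))
})

test_that("permeation feeds interior precursors and is shut off by P_NPP = 0", {
  base <- quiet_params()
  run_cell <- function(pnpp) {
    p <- base
    p$P_NPP <- pnpp
    sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = 6)
    seed_pools(sim, 7200, 0)   # 200 per room
    sol <- which(sim$region == 1L) - 1L
    inoculate_protocell(sim, sol[4], b = 600)
    invisible(run_steps(sim, 200, 200))
    snap <- sim_snapshot(sim)
    snap$cell_np[snap$has_cell]
  }
  expect_equal(run_cell(0), 0)
  expect_gt(run_cell(0.5), 0)
})

test_that("interior ribozymes replicate on permeating raw material (the protocell scene)", {
  p <- default_params()
  p$P_NF <- 0.01   # generous feedstock conversion for a short test
  sim <- suppressWarnings(
    new_simulation(p, N = 6, region_layout = "core", seed = 8))
  seed_pools(sim, 14400, 0)
  ms <- minimal_sequences(p)
  sol <- which(sim$region == 1L) - 1L
  inoculate_protocell(sim, sol[4], b = 800,
                      interior_seqs = rep(ms$rep_spreadable, 3),
                      interior_np = 100)
  s <- run_steps(sim, 12000, 3000)
  expect_gt(tail(s$rep_cell, 1) + tail(s$nsr_cell, 1), 3)
  expect_true(check_ledgers(sim))
})

test_that("fused membranes add up and the vacated room empties", {
  p <- quiet_params(P_CF = 1)
  sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = 9)
  sol <- which(sim$region == 1L) - 1L
  # two adjacent solution rooms
  adj <- NULL
  for (r in sol) {
    right <- (r %/% 6) * 6 + (r %% 6 + 1) %% 6
    if (right %in% sol) { adj <- c(r, right); break }
  }
  inoculate_protocell(sim, adj[1], b = 300, interior_np = 40)
  inoculate_protocell(sim, adj[2], b = 500, interior_np = 60)
  invisible(run_steps(sim, 1, 1))
  snap <- sim_snapshot(sim)
  cells <- snap[snap$has_cell, ]
  expect_equal(nrow(cells), 1)
  expect_equal(cells$cell_b, 800)
  expect_equal(cells$cell_np, 100)
  expect_true(check_ledgers(sim))
})

test_that("osmotic swelling slows amphiphile loss in the engine", {
  p <- quiet_params(P_ALM = 0.01)
  run_leave <- function(n_inside) {
    sim <- new_sim_quiet(p, N = 6, region_layout = "core", seed = 10)
    sol <- which(sim$region == 1L) - 1L
    inoculate_protocell(sim, sol[4], b = 400, interior_nt = n_inside)
    invisible(run_steps(sim, 100, 100))
    snap <- sim_snapshot(sim)
    snap$cell_b[snap$has_cell]
  }
  b_empty <- run_leave(0)     # loses amphiphiles at full P_ALM
  b_swollen <- run_leave(3000)
  expect_gt(b_swollen, b_empty)
})
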