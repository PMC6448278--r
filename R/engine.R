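# R-facing surface of the C++ simulation core. A simulation object keeps an
# external pointer to the compiled state plus the resolved configuration,
# seed and accumulated series.

#' Create a simulation
#'
#' Builds an N x N toroidal grid of rooms. Each room belongs to a region
#' (`rocky` or `solution`), whose profile modifies the base rates (see
#' [region_profile()]). All randomness flows from one 64-bit seeded stream;
#' identical (configuration, seed) pairs give identical trajectories.
#'
#' @param params An `rw_params` object.
#' @param N Grid side; defaults to `params$N`.
#' @param region_layout `"uniform"` (all rocky), or `"core"` for a centred
#'   rocky core occupying half the grid side within a solution frame, or an
#'   integer matrix/vector of 0 (rocky) / 1 (solution) values of length N^2.
#' @param profiles List with `rocky` and `solution` region profiles.
#' @param interface_policy `"all_molecules"` (default; anything may diffuse
#'   across the rocky/solution interface) or `"precursors_only"` (only raw
#'   materials — nucleotide and amphiphile precursors — may cross).
#'   Protocells never enter the rocky region in either policy.
#' @param seed Integer seed for the simulation's random stream.
#' @return An `rw_sim` object.
#' @export
new_simulation <- function(params = default_params(), N = params$N,
                           region_layout = "uniform",
                           profiles = default_region_profiles(),
                           interface_policy = c("all_molecules",
                                                "precursors_only"),
                           seed = 1L) {
  validate_params(params)
  interface_policy <- match.arg(interface_policy)
  region <- .build_region_layout(region_layout, N)
  prof_list <- list(unclass(profiles$rocky), unclass(profiles$solution))
  ptr <- cpp_sim_new(unclass(params), as.integer(region), prof_list,
                     if (interface_policy == "precursors_only") 0L else 1L,
                     as.numeric(seed), as.integer(N))
  sim <- new.env(parent = emptyenv())
  sim$ptr <- ptr
  sim$params <- params
  sim$N <- as.integer(N)
  sim$region <- region
  sim$profiles <- profiles
  sim$interface_policy <- interface_policy
  sim$seed <- as.integer(seed)
  class(sim) <- "rw_sim"
  sim
}

.build_region_layout <- function(layout, N) {
  if (is.numeric(layout)) {
    stopifnot(length(layout) == N * N, all(layout %in% c(0, 1)))
    return(as.integer(layout))
  }
  if (identical(layout, "uniform")) return(integer(N * N))
  if (identical(layout, "core")) {
    side <- floor(N / 2)
    lo <- floor((N - side) / 2)
    region <- matrix(1L, N, N)
    region[lo + seq_len(side), lo + seq_len(side)] <- 0L
    return(as.integer(region))  # column-major: room i = y*N + x, x = i %% N
  }
  stop("unknown region layout")
}

#' Seed the initial precursor pools
#'
#' Distributes `T_NPB` nucleotide precursors and `T_APB` amphiphile
#' precursors as evenly as possible over the grid (remainders go to the
#' first rooms in index order, deterministically).
#'
#' @param sim An `rw_sim` object.
#' @param T_NPB,T_APB Totals; default from the simulation's parameters.
#' @export
seed_pools <- function(sim, T_NPB = sim$params$T_NPB,
                       T_APB = sim$params$T_APB) {
  NN <- sim$N^2
  even <- function(total) {
    base <- rep(floor(total / NN), NN)
    rem <- total - sum(base)
    if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1
    base
  }
  cpp_seed_pools(sim$ptr, even(T_NPB), even(T_APB))
  invisible(sim)
}

#' Inoculate strands into rooms
#'
#' @param sim An `rw_sim` object.
#' @param seqs Character vector of sequences, recycled against `rooms`.
#' @param rooms Integer room indices (0-based, row-major `y * N + x`).
#' @param interior If `TRUE` the strands go into the protocell occupying
#'   each room (an error if a room holds none).
#' @export
inoculate_strands <- function(sim, seqs, rooms, interior = FALSE) {
  n <- max(length(seqs), length(rooms))
  seqs <- rep_len(seqs, n)
  rooms <- rep_len(as.integer(rooms), n)
  cpp_add_strands(sim$ptr, rooms, seqs, isTRUE(interior))
  invisible(sim)
}

#' Inoculate a protocell
#'
#' Places a protocell with membrane size `b` and the given interior contents
#' into a room; the room's previous free molecules are pushed into adjacent
#' rooms.
#'
#' @param sim An `rw_sim` object.
#' @param room Room index (0-based).
#' @param b Membrane amphiphile count.
#' @param interior_seqs Character vector of interior strand sequences.
#' @param interior_np,interior_ap Interior precursor pools.
#' @param interior_nt,interior_am Interior free nucleotide / amphiphile
#'   counts (nucleotide letters are split evenly).
#' @export
inoculate_protocell <- function(sim, room, b, interior_seqs = character(),
                                interior_np = 0, interior_ap = 0,
                                interior_nt = 0, interior_am = 0) {
  cpp_add_cell(sim$ptr, as.integer(room), as.numeric(b), interior_seqs,
               as.numeric(interior_np), as.numeric(interior_ap),
               as.numeric(interior_nt), as.numeric(interior_am))
  invisible(sim)
}

#' Advance the simulation
#'
#' Runs `steps` Monte Carlo steps. Each step executes, in a fixed documented
#' order: (1) compartment chemistry, (2) `C_T` collision rounds, (3) polymer
#' events (REP extension, template-directed ligation, separations, bond
#' breaking, end decay), (4) membrane/protocell events, (5) movement of
#' molecules then protocells (interface rules enforced during movement).
#' Room processing order is reshuffled every step. Conservation ledgers are
#' verified periodically; a violation is a hard failure.
#'
#' @param sim An `rw_sim` object.
#' @param steps Number of steps.
#' @param sample_every Sampling interval for the returned series.
#' @return A data.frame time series of molecule counts (one row per sample,
#'   including the state before the first of these steps).
#' @export
run_steps <- function(sim, steps, sample_every = 1000) {
  m <- cpp_run(sim$ptr, as.numeric(steps), as.numeric(sample_every))
  as.data.frame(m)
}

#' Current molecule counts
#'
#' @param sim An `rw_sim` object.
#' @return Named numeric vector (step, pools, ribozyme/parasite counts naked
#'   and in cells, protocell count, per-region splits).
#' @export
sim_counts <- function(sim) cpp_counts(sim$ptr)

#' Per-room snapshot table
#'
#' One row per room: coordinates, region, pool counts, protocell presence
#' and membrane size — the layer-by-layer view used for spatial plots.
#'
#' @param sim An `rw_sim` object.
#' @return A data.frame.
#' @export
sim_snapshot <- function(sim) cpp_rooms(sim$ptr)

#' All strands in the system
#'
#' @param sim An `rw_sim` object.
#' @return A data.frame with room, compartment, sequence and status (`free`,
#'   `template`, `substrate`, `bound_rep`, `product`).
#' @export
sim_strand_table <- function(sim) cpp_strands(sim$ptr)

#' Conservation ledgers
#'
#' @param sim An `rw_sim` object.
#' @return Named vector of current and expected nucleotide- and
#'   amphiphile-equivalent totals.
#' @export
sim_ledger <- function(sim) cpp_ledger(sim$ptr)

#' Verify conservation now
#'
#' Recomputes both mass ledgers and every protocell's cached ion tally;
#' stops with a diagnostic on any mismatch.
#'
#' @param sim An `rw_sim` object.
#' @export
check_ledgers <- function(sim) {
  cpp_check_ledgers(sim$ptr)
  invisible(TRUE)
}

#' Change a parameter mid-run
#'
#' Used by scenario schedules (e.g. switching the non-enzymatic nucleotide
#' synthesis rate, or turning mutation off with `P_FP = 0`). Sequences and
#' grid geometry cannot change mid-run.
#'
#' @param sim An `rw_sim` object.
#' @param name Parameter name.
#' @param value New value.
#' @export
set_param <- function(sim, name, value) {
  sim$params[[name]] <- value
  cpp_set_param(sim$ptr, name, as.numeric(value))
  invisible(sim)
}

#' Step counter
#' @param sim An `rw_sim` object.
#' @return Number of completed Monte Carlo steps.
#' @export
sim_step_count <- function(sim) cpp_step_count(sim$ptr)

#' Event-frequency statistics
#'
#' The engine counts every Bernoulli trial it performs for the major event
#' types, together with the successes. Comparing `successes / attempts`
#' against the nominal probability checks that each rule is wired to the
#' right rate.
#'
#' @param sim An `rw_sim` object.
#' @param reset If `TRUE`, zero the counters instead of reading them.
#' @return Named vector of `<event>.attempts` / `<event>.successes`, or
#'   `NULL` after a reset.
#' @export
event_stats <- function(sim, reset = FALSE) {
  if (reset) {
    cpp_reset_event_stats(sim$ptr)
    return(invisible(NULL))
  }
  cpp_event_stats(sim$ptr)
}

#' @export
print.rw_sim <- function(x, ...) {
  cat(sprintf("<rw_sim> %dx%d torus, step %d, seed %d\n", x$N, x$N,
              as.integer(sim_step_count(x)), x$seed))
  ct <- sim_counts(x)
  cat(sprintf("  np=%d nt=%d strands=%d cells=%d\n", as.integer(ct["np"]),
              as.integer(ct["nt"]), as.integer(ct["strands"]),
              as.integer(ct["cells"])))
  invisible(x)
}

#' Save a checkpoint
#'
#' Writes the full resolved configuration, pools and strand inventory as
#' plain text (config + CSV). Template complexes are recorded as their
#' member strands; on reload they start free, so a resumed run is a valid
#' state of the same system, not a bit-identical continuation.
#'
#' @param sim An `rw_sim` object.
#' @param dir Directory to write into (created if needed).
#' @export
save_checkpoint <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(sim$params, file.path(dir, "params.cfg"))
  write.csv(sim_snapshot(sim), file.path(dir, "rooms.csv"),
            row.names = FALSE)
  write.csv(sim_strand_table(sim), file.path(dir, "strands.csv"),
            row.names = FALSE)
  meta <- c(sprintf("seed = %d", sim$seed),
            sprintf("step = %d", as.integer(sim_step_count(sim))),
            sprintf("N = %d", sim$N),
            sprintf("interface_policy = %s", sim$interface_policy),
            paste0("region = ", paste(sim$region, collapse = ",")))
  writeLines(meta, file.path(dir, "meta.cfg"))
  invisible(dir)
}

#' Load a checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @param seed Seed for the resumed random stream.
#' @return A new `rw_sim` with the checkpointed pools, strands and
#'   protocells (complexes dissolved into free strands).
#' @export
load_checkpoint <- function(dir, seed = 1L) {
  params <- load_parameters(file.path(dir, "params.cfg"))
  meta <- readLines(file.path(dir, "meta.cfg"))
  getv <- function(key) {
    ln <- grep(paste0("^", key, " = "), meta, value = TRUE)
    sub(paste0("^", key, " = "), "", ln)
  }
  N <- as.integer(getv("N"))
  region <- as.integer(strsplit(getv("region"), ",")[[1]])
  sim <- new_simulation(params, N = N, region_layout = region,
                        interface_policy = getv("interface_policy"),
                        seed = seed)
  rooms <- read.csv(file.path(dir, "rooms.csv"))
  idx <- rooms$y * N + rooms$x
  vec <- function(col) {
    v <- numeric(N * N)
    v[idx + 1] <- col
    v
  }
  cpp_restore_pools(sim$ptr, vec(rooms$np), vec(rooms$nt), vec(rooms$ap),
                    vec(rooms$am))
  for (i in seq_len(nrow(rooms))) {
    if (rooms$has_cell[i]) {
      inoculate_protocell(sim, idx[i], rooms$cell_b[i],
                          interior_np = rooms$cell_np[i],
                          interior_ap = rooms$cell_ap[i],
                          interior_nt = rooms$cell_nt[i],
                          interior_am = rooms$cell_am[i])
    }
  }
  strands <- read.csv(file.path(dir, "strands.csv"),
                      stringsAsFactors = FALSE)
  if (nrow(strands)) {
    free <- strands[!strands$in_cell, , drop = FALSE]
    if (nrow(free))
      inoculate_strands(sim, free$seq, free$room)
    inc <- strands[strands$in_cell, , drop = FALSE]
    if (nrow(inc))
      inoculate_strands(sim, inc$seq, inc$room, interior = TRUE)
  }
  sim
}
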