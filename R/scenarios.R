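# Scenario presets reproducing the study's experimental setups, plus the
# recorder / CSV plumbing shared by the CLI.

#' Build a scenario preset
#'
#' Each preset bundles grid size, region layout, initial precursor totals,
#' parameter overrides, an inoculation/override schedule and a stop step.
#' Full-scale presets:
#' \describe{
#'   \item{fig2_rep_spread}{20x20 rocky grid, 80,000 nucleotide precursors;
#'     50 spreadable REP inoculated at step 1e5 into 10 central rooms.}
#'   \item{fig4_nsr_into_rep}{as above, plus 50 spreadable NSR at step 2e6
#'     into 10 random REP-containing rooms.}
#'   \item{fig5_co_spread}{50 REP + 50 NSR together at step 1e5.}
#'   \item{fig9_two_region}{40x40 with a 20x20 rocky core in a solution
#'     frame (near-reality region profiles, everything may cross the
#'     interface); naked ribozymes at 1e5 into the core, 10 protocells each
#'     holding 5 REP + 5 NSR at 6e6 into the solution.}
#'   \item{fig10_cytophagy}{as fig9 but the inoculated protocells are empty
#'     and cytophagy is 100-fold enhanced (`P_CC = 1e-5`).}
#'   \item{fig11_fair_competition}{two-region grid with *no* region rate
#'     differences, `P_NPP = 1`, and only raw materials crossing the
#'     interface; ribozyme-bearing protocells inoculated at 3e6.}
#'   \item{fig13_parasite_pulse}{the near-balance competition case
#'     (`P_NF = 1e-4`, `P_MC = 5e-6`, `P_FP = 0`); from step 1e7 on, 50
#'     minimal parasites are injected every 5e6 steps into both subsystems.}
#' }
#' The `tiny_*` family keeps every probability at its default but shrinks
#' the system, scaling material totals and inocula by the grid-area factor
#' so per-room densities match the full-scale setups. `tiny_fig2` and
#' `tiny_fig5` run at half scale (14x14, 40,000 precursors, inocula of 25)
#' — the smallest grid on which a spreading replicator still has room to
#' colonize well beyond its inoculation block; `tiny_fig11` runs the
#' two-region competition at quarter scale (10x10 with a 5x5 rocky core).
#'
#' @param name Preset name.
#' @return An `rw_scenario` object.
#' @export
build_scenario <- function(name) {
  scn <- switch(
    name,
    fig2_rep_spread = list(
      N = 20, region_layout = "uniform", near_reality = FALSE,
      interface_policy = "all_molecules",
      T_NPB = 80000, T_APB = 0, params = list(),
      schedule = list(
        list(step = 1e5, action = "strands", role = "rep", count = 50,
             placement = "center_block", rooms_n = 10)),
      stop_step = 3e6, sample_every = 1000),
    fig4_nsr_into_rep = list(
      N = 20, region_layout = "uniform", near_reality = FALSE,
      interface_policy = "all_molecules",
      T_NPB = 80000, T_APB = 0, params = list(),
      schedule = list(
        list(step = 1e5, action = "strands", role = "rep", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 2e6, action = "strands", role = "nsr", count = 50,
             placement = "random_rep_rooms", rooms_n = 10)),
      stop_step = 4e6, sample_every = 1000),
    fig5_co_spread = list(
      N = 20, region_layout = "uniform", near_reality = FALSE,
      interface_policy = "all_molecules",
      T_NPB = 80000, T_APB = 0, params = list(),
      schedule = list(
        list(step = 1e5, action = "strands", role = "rep", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 1e5, action = "strands", role = "nsr", count = 50,
             placement = "center_block", rooms_n = 10)),
      stop_step = 3e6, sample_every = 1000),
    fig9_two_region = list(
      N = 40, region_layout = "core", near_reality = TRUE,
      interface_policy = "all_molecules",
      T_NPB = 320000, T_APB = 240000, params = list(),
      schedule = list(
        list(step = 1e5, action = "strands", role = "rep", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 1e5, action = "strands", role = "nsr", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 6e6, action = "cells", n_cells = 10, b = 750,
             rep_each = 5, nsr_each = 5)),
      stop_step = 1e7, sample_every = 1000),
    fig10_cytophagy = list(
      N = 40, region_layout = "core", near_reality = TRUE,
      interface_policy = "all_molecules",
      T_NPB = 320000, T_APB = 240000, params = list(P_CC = 1e-5),
      schedule = list(
        list(step = 1e5, action = "strands", role = "rep", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 1e5, action = "strands", role = "nsr", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 6e6, action = "cells", n_cells = 10, b = 750,
             rep_each = 0, nsr_each = 0)),
      stop_step = 1e7, sample_every = 1000),
    fig11_fair_competition = list(
      N = 40, region_layout = "core", near_reality = FALSE,
      interface_policy = "precursors_only",
      T_NPB = 320000, T_APB = 240000, params = list(P_NPP = 1),
      schedule = list(
        list(step = 1e5, action = "strands", role = "rep", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 1e5, action = "strands", role = "nsr", count = 50,
             placement = "center_block", rooms_n = 10),
        list(step = 3e6, action = "cells", n_cells = 10, b = 750,
             rep_each = 5, nsr_each = 5)),
      stop_step = 1e7, sample_every = 1000),
    fig13_parasite_pulse = list(
      N = 40, region_layout = "core", near_reality = FALSE,
      interface_policy = "precursors_only",
      T_NPB = 320000, T_APB = 240000,
      params = list(P_NPP = 1, P_NF = 1e-4, P_MC = 5e-6, P_FP = 0),
      schedule = c(
        list(
          list(step = 1e5, action = "strands", role = "rep", count = 50,
               placement = "center_block", rooms_n = 10),
          list(step = 1e5, action = "strands", role = "nsr", count = 50,
               placement = "center_block", rooms_n = 10),
          list(step = 3e6, action = "cells", n_cells = 10, b = 750,
               rep_each = 5, nsr_each = 5)),
        unlist(lapply(seq(1e7, 2.5e7, by = 5e6), function(s) {
          list(list(step = s, action = "strands", role = "parasite",
                    count = 50, placement = "random_ribozyme_rooms",
                    rooms_n = 10),
               list(step = s, action = "strands", role = "parasite",
                    count = 50, placement = "random_ribozyme_cells",
                    rooms_n = 10))
        }), recursive = FALSE)),
      stop_step = 3e7, sample_every = 1000),
    tiny_fig2 = list(
      N = 14, region_layout = "uniform", near_reality = FALSE,
      interface_policy = "all_molecules",
      T_NPB = 40000, T_APB = 0, params = list(),
      schedule = list(
        list(step = 2000, action = "strands", role = "rep", count = 25,
             placement = "center_block", rooms_n = 5)),
      stop_step = 2.6e6, sample_every = 2000),
    tiny_fig5 = list(
      N = 14, region_layout = "uniform", near_reality = FALSE,
      interface_policy = "all_molecules",
      T_NPB = 40000, T_APB = 0, params = list(),
      schedule = list(
        list(step = 2000, action = "strands", role = "rep", count = 25,
             placement = "center_block", rooms_n = 5),
        list(step = 2000, action = "strands", role = "nsr", count = 25,
             placement = "center_block", rooms_n = 5)),
      stop_step = 1e6, sample_every = 2000),
    tiny_fig11 = list(
      N = 10, region_layout = "core", near_reality = FALSE,
      interface_policy = "precursors_only",
      T_NPB = 20000, T_APB = 15000, params = list(P_NPP = 1),
      schedule = list(
        list(step = 2000, action = "strands", role = "rep", count = 12,
             placement = "center_block", rooms_n = 4),
        list(step = 2000, action = "strands", role = "nsr", count = 12,
             placement = "center_block", rooms_n = 4),
        list(step = 4e4, action = "cells", n_cells = 3, b = 750,
             rep_each = 3, nsr_each = 3)),
      stop_step = 1e5, sample_every = 500),
    stop(sprintf("unknown scenario preset '%s'", name))
  )
  scn$name <- name
  class(scn) <- "rw_scenario"
  scn
}

#' Names of all scenario presets
#' @return Character vector.
#' @export
scenario_names <- function() {
  c("fig2_rep_spread", "fig4_nsr_into_rep", "fig5_co_spread",
    "fig9_two_region", "fig10_cytophagy", "fig11_fair_competition",
    "fig13_parasite_pulse", "tiny_fig2", "tiny_fig5", "tiny_fig11")
}

.resolve_role_seq <- function(role, params) {
  ms <- minimal_sequences(params)
  switch(role,
         rep = ms$rep_spreadable,
         nsr = ms$nsr_spreadable,
         parasite = ms$parasite,
         role)  # anything else is taken as a literal sequence
}

.center_block_rooms <- function(N, k) {
  # k adjacent rooms at the grid centre, as a 2-row block
  cx <- floor(N / 2)
  cy <- floor(N / 2)
  w <- ceiling(k / 2)
  xs <- (cx - floor(w / 2)) + seq_len(w) - 1
  rooms <- as.vector(outer(xs, c(cy - 1, cy), function(x, y) y * N + x))
  rooms[seq_len(k)]
}

.strand_room_table <- function(sim, params) {
  st <- sim_strand_table(sim)
  if (!nrow(st)) return(st)
  flags <- cpp_classify(st$seq, params$CS_Tag, params$CS_REP, params$CS_NSR)
  st$rep <- bitwAnd(flags, 1L) != 0
  st$nsr <- bitwAnd(flags, 4L) != 0
  st
}

.placement_rooms <- function(sim, placement, rooms_n, params) {
  N <- sim$N
  if (placement == "center_block") return(.center_block_rooms(N, rooms_n))
  st <- .strand_room_table(sim, params)
  if (placement == "random_rep_rooms") {
    cand <- unique(st$room[st$rep & !st$in_cell])
  } else if (placement == "random_ribozyme_rooms") {
    rep_rooms <- unique(st$room[st$rep & !st$in_cell])
    nsr_rooms <- unique(st$room[st$nsr & !st$in_cell])
    cand <- intersect(rep_rooms, nsr_rooms)
  } else if (placement == "random_ribozyme_cells") {
    rep_rooms <- unique(st$room[st$rep & st$in_cell])
    nsr_rooms <- unique(st$room[st$nsr & st$in_cell])
    cand <- intersect(rep_rooms, nsr_rooms)
  } else if (placement == "random_solution_rooms") {
    snap <- sim_snapshot(sim)
    cand <- (snap$y * N + snap$x)[snap$region == "solution" & !snap$has_cell]
  } else {
    stop(sprintf("unknown placement rule '%s'", placement))
  }
  if (!length(cand)) return(integer())
  sample(cand, min(rooms_n, length(cand)))
}

.apply_event <- function(sim, ev, params) {
  if (ev$action == "set_param") {
    set_param(sim, ev$name, ev$value)
    return(invisible(sim))
  }
  if (ev$action == "strands") {
    rooms <- .placement_rooms(sim, ev$placement, ev$rooms_n, params)
    if (!length(rooms)) return(invisible(sim))
    seqv <- .resolve_role_seq(ev$role, params)
    per <- ceiling(ev$count / length(rooms))
    alloc <- rep(rooms, each = per)[seq_len(ev$count)]
    interior <- identical(ev$placement, "random_ribozyme_cells")
    inoculate_strands(sim, seqv, alloc, interior = interior)
    return(invisible(sim))
  }
  if (ev$action == "cells") {
    rooms <- .placement_rooms(sim, "random_solution_rooms", ev$n_cells,
                              params)
    seqs <- c(rep(.resolve_role_seq("rep", params), ev$rep_each),
              rep(.resolve_role_seq("nsr", params), ev$nsr_each))
    for (r in rooms) inoculate_protocell(sim, r, ev$b, seqs)
    return(invisible(sim))
  }
  stop(sprintf("unknown schedule action '%s'", ev$action))
}

#' Run a scenario
#'
#' Executes a preset (or hand-built) scenario under one seed: builds the
#' simulation, seeds the precursor pools, walks the inoculation/override
#' schedule, and samples the count series. Placement randomness (which rooms
#' receive an inoculum) is drawn from R's RNG, seeded from `seed`, so the
#' whole run is reproducible from `(scenario, seed)`.
#'
#' @param scn An `rw_scenario` (or the name of a preset).
#' @param seed Integer seed.
#' @param stop_step Optional override of the scenario's stop step.
#' @param sample_every Optional override of the sampling interval.
#' @param out_dir If non-NULL, `series.csv`, a final `snapshot.csv` and a
#'   `manifest.cfg` are written there.
#' @param snapshot_every If non-NULL (with `out_dir`), additionally writes
#'   `snapshot_<step>.csv` at this interval.
#' @param checkpoint_every If non-NULL (with `out_dir`), writes a plain-text
#'   checkpoint directory `checkpoint_<step>/` at this interval (see
#'   [save_checkpoint()]).
#' @return List with `series` (data.frame), `sim` (the final simulation
#'   object) and `scenario`.
#' @export
run_scenario <- function(scn, seed = 1L, stop_step = NULL,
                         sample_every = NULL, out_dir = NULL,
                         snapshot_every = NULL, checkpoint_every = NULL) {
  if (is.character(scn)) scn <- build_scenario(scn)
  stopifnot(inherits(scn, "rw_scenario"))
  if (is.null(stop_step)) stop_step <- scn$stop_step
  if (is.null(sample_every)) sample_every <- scn$sample_every
  set.seed(seed)
  params <- default_params()
  params[names(scn$params)] <- scn$params
  params$N <- scn$N
  params$T_NPB <- scn$T_NPB
  params$T_APB <- max(scn$T_APB, 1)
  validate_params(params)
  sim <- new_simulation(params, N = scn$N,
                        region_layout = scn$region_layout,
                        profiles = default_region_profiles(scn$near_reality),
                        interface_policy = scn$interface_policy,
                        seed = seed)
  seed_pools(sim, T_NPB = scn$T_NPB, T_APB = scn$T_APB)

  sched <- scn$schedule[order(vapply(scn$schedule, `[[`, 0, "step"))]
  sched <- Filter(function(ev) ev$step <= stop_step, sched)
  breaks <- unique(c(vapply(sched, `[[`, 0, "step"), stop_step))
  if (!is.null(snapshot_every) && !is.null(out_dir))
    breaks <- sort(unique(c(breaks,
                            seq(snapshot_every, stop_step,
                                by = snapshot_every))))
  if (!is.null(checkpoint_every) && !is.null(out_dir))
    breaks <- sort(unique(c(breaks,
                            seq(checkpoint_every, stop_step,
                                by = checkpoint_every))))
  chunks <- list()
  cur <- 0
  for (b in breaks) {
    if (b > cur) {
      s <- run_steps(sim, b - cur, sample_every)
      chunks[[length(chunks) + 1]] <- if (cur == 0) s else s[-1, ,
                                                             drop = FALSE]
      cur <- b
    }
    for (ev in sched)
      if (ev$step == b) .apply_event(sim, ev, params)
    if (!is.null(snapshot_every) && !is.null(out_dir) &&
        b %% snapshot_every == 0 && b < stop_step) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(sim_snapshot(sim),
                file.path(out_dir, sprintf("snapshot_%d.csv", as.integer(b))),
                row.names = FALSE)
    }
    if (!is.null(checkpoint_every) && !is.null(out_dir) &&
        b %% checkpoint_every == 0 && b < stop_step) {
      save_checkpoint(sim, file.path(out_dir,
                                     sprintf("checkpoint_%d", as.integer(b))))
    }
  }
  series <- do.call(rbind, chunks)
  rownames(series) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_series(series, file.path(out_dir, "series.csv"),
                 scenario = scn$name, seed = seed)
    write.csv(sim_snapshot(sim), file.path(out_dir, "snapshot.csv"),
              row.names = FALSE)
    manifest <- c(sprintf("scenario = %s", scn$name),
                  sprintf("seed = %d", as.integer(seed)),
                  sprintf("stop_step = %d", as.integer(stop_step)),
                  sprintf("package_version = %s",
                          as.character(utils::packageVersion("protoworld"))),
                  "", write_config(params))
    writeLines(manifest, file.path(out_dir, "manifest.cfg"))
  }
  list(series = series, sim = sim, scenario = scn)
}

#' Record the current state as a one-row observation
#'
#' @param sim An `rw_sim` object.
#' @return A one-row data.frame with the same columns as the run series.
#' @export
record <- function(sim) {
  as.data.frame(t(sim_counts(sim)))
}

#' Write / read a count series as CSV
#'
#' The writer prepends `#`-comment header lines naming the scenario and
#' seed; the reader skips them, so the round trip is exact.
#'
#' @param series Data.frame from [run_steps()] or [run_scenario()].
#' @param path File path.
#' @param scenario,seed Optional header metadata.
#' @export
write_series <- function(series, path, scenario = NA, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# scenario: %s", scenario),
               sprintf("# seed: %s", seed),
               paste0("# columns: ", paste(names(series), collapse = ","))),
             con)
  write.csv(series, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  read.csv(path, comment.char = "#")
}
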