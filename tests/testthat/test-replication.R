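# The REP polymerase cycle and non-enzymatic template-directed synthesis.

# Build a one-room world holding a REP catalyst, one tagged template and an
# ample nucleotide supply, with rates arranged so that exactly the copying
# pathway runs deterministically.
copy_world <- function(template, seed = 1) {
  p <- quiet_params(P_AT = 1, P_RBT = 1, P_TLR = 1)
  p$P_SP <- 0   # products stay annealed so we can read them off
  sim <- new_sim_quiet(p, N = 4, seed = seed)
  ntv <- numeric(16)
  ntv[1] <- 60   # enough letters without drowning the pairwise collisions
  protoworld:::cpp_restore_pools(sim$ptr, numeric(16), ntv, numeric(16),
                                 numeric(16))
  rep <- minimal_sequences(default_p)$rep_spreadable
  inoculate_strands(sim, c(rep, template), c(0, 0))
  sim
}

test_that("a completed REP-catalyzed copy is the exact reverse complement, for every short tagged template", {
  # exhaustive over the whole REP-copyable space up to 8 nt: the 4-nt tag
  # followed by every 1-4 nt extension
  p <- default_p
  exts <- unlist(lapply(1:4, function(k) {
    apply(expand.grid(rep(list(c("A", "C", "G", "U")), k)), 1, paste,
          collapse = "")
  }))
  templates <- paste0(p$CS_Tag, exts)
  for (tpl in templates) {
    sim <- copy_world(tpl)
    invisible(run_steps(sim, 150, 150))
    st <- sim_strand_table(sim)
    prods <- st$seq[st$status %in% c("substrate", "product") &
                      nchar(st$seq) == nchar(tpl)]
    expect_true(reverse_complement(tpl) %in% prods,
                label = sprintf("full copy of %s", tpl))
  }
})

test_that("copying an 18-nt spreadable REP yields its tag-flanked complement", {
  rep <- minimal_sequences(default_p)$rep_spreadable
  sim <- copy_world(rep)
  invisible(run_steps(sim, 250, 250))
  st <- sim_strand_table(sim)
  comp <- reverse_complement(rep)
  expect_true(comp %in% st$seq)
  cl <- classify_strand(comp, default_p)
  expect_true(startsWith(comp, default_p$CS_Tag) &&
                endsWith(comp, default_p$CS_Tag))
  expect_false(cl[["parasite"]])  # a replication intermediate, not a freeloader
})

test_that("a REP stalls without mononucleotides but does not err", {
  p <- quiet_params(P_AT = 1, P_RBT = 1, P_TLR = 1)
  p$P_SP <- 0
  sim <- new_sim_quiet(p, N = 4, seed = 2)
  rep <- minimal_sequences(default_p)$rep_spreadable
  inoculate_strands(sim, c(rep, rep), c(0, 0))
  invisible(run_steps(sim, 50, 50))
  st <- sim_strand_table(sim)
  expect_true("bound_rep" %in% st$status)       # bound and waiting
  expect_false("product" %in% st$status)        # nothing incorporated
})

test_that("untagged templates are never REP-bound", {
  p <- quiet_params(P_AT = 1, P_RBT = 1, P_TLR = 1)
  p$P_SP <- 0
  sim <- new_sim_quiet(p, N = 4, seed = 3)
  ntv <- numeric(16); ntv[1] <- 200
  protoworld:::cpp_restore_pools(sim$ptr, numeric(16), ntv, numeric(16),
                                 numeric(16))
  rep <- minimal_sequences(default_p)$rep_spreadable
  inoculate_strands(sim, c(rep, "CCCCCCCC"), c(0, 0))
  invisible(run_steps(sim, 30, 30))
  ev <- event_stats(sim)
  expect_equal(ev[["rep_bind.successes"]], 0)
})

test_that("short strands may not act as templates", {
  p <- quiet_params(P_AT = 1, P_RTT = 1)
  sim <- new_sim_quiet(p, N = 4, seed = 4)
  ntv <- numeric(16); ntv[1] <- 100
  protoworld:::cpp_restore_pools(sim$ptr, numeric(16), ntv, numeric(16),
                                 numeric(16))
  inoculate_strands(sim, "ACGU", 0)   # 4-mer: below the 5-nt template floor
  invisible(run_steps(sim, 200, 200))
  st <- sim_strand_table(sim)
  expect_false(any(st$status == "template"))
})

test_that("non-enzymatic synthesis admits oligomer substrates and ligates adjacent ones", {
  # a 10-mer template plus its two 5-mer complement halves assemble into
  # the full complement once P_TL fires
  p <- quiet_params(P_AT = 1, P_RTT = 1, P_TL = 0.2)
  p$P_SP <- 0
  tpl <- "AAGGCUACAG"   # aperiodic, so each half has a unique register
  halves <- c(
    substr(reverse_complement(tpl), 1, 5),   # pairs the template's 3' half
    substr(reverse_complement(tpl), 6, 10))  # pairs the template's 5' half
  sim <- new_sim_quiet(p, N = 4, seed = 6)
  inoculate_strands(sim, c(tpl, halves), c(0, 0, 0))
  invisible(run_steps(sim, 300, 300))
  st <- sim_strand_table(sim)
  expect_true(reverse_complement(tpl) %in%
                st$seq[st$status == "substrate"])
})

test_that("with mutation off, every copy in a running system is a perfect complement", {
  p <- quiet_params(P_AT = default_p$P_AT, P_RBT = default_p$P_RBT,
                    P_TLR = default_p$P_TLR, P_RTT = default_p$P_RTT,
                    P_NF = 0.01, P_ND = default_p$P_ND,
                    P_TL = default_p$P_TL)
  sim <- new_sim_quiet(p, N = 4, seed = 8)
  seed_pools(sim, 4000, 0)
  rep <- minimal_sequences(default_p)$rep_spreadable
  inoculate_strands(sim, rep, rep(0, 4))
  invisible(run_steps(sim, 4000, 2000))
  st <- sim_strand_table(sim)
  full <- st$seq[nchar(st$seq) == 18]
  expect_gt(length(full), 4)
  expect_true(all(full %in% c(rep, reverse_complement(rep))))
})

test_that("duplex states render as readable alignment blocks", {
  p <- quiet_params(P_AT = 1, P_RTT = 1)
  p$P_SP <- 0
  tpl <- "AAGGCUACAG"
  sub <- substr(reverse_complement(tpl), 1, 5)
  sim <- new_sim_quiet(p, N = 4, seed = 12)
  inoculate_strands(sim, c(tpl, sub), c(0, 0))
  invisible(run_steps(sim, 50, 50))
  out <- capture.output(lines <- dump_duplex_alignments(sim))
  expect_true(any(grepl(tpl, out, fixed = TRUE)))
  expect_true(any(grepl("substrate", out)))
  # the partner is drawn at its register: reversed, padded by its offset
  subline <- grep("substrate", out, value = TRUE)[1]
  expect_match(subline, paste(rev(strsplit(sub, "")[[1]]), collapse = ""),
               fixed = TRUE)
})
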