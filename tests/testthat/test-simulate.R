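test_that("sequence simulation is deterministic and respects planted truth", {
  cfg <- seq_sim_config(
    species = list(
      list(name = "sp a", n_specimens = 4,
           planted = data.frame(position = c(3, 9), base = "C")),
      list(name = "sp b", n_specimens = 4, planted = NULL)),
    root_length = 60, intraspecific_rate = 0.02,
    root_states = c(`3` = "A", `9` = "A"))
  s1 <- simulate_alignment(cfg, seed = 42)
  s2 <- simulate_alignment(cfg, seed = 42)
  expect_identical(alignment_strings(s1$alignment),
                   alignment_strings(s2$alignment))
  expect_identical(s1$truth$root, s2$truth$root)
  s3 <- simulate_alignment(cfg, seed = 43)
  expect_false(identical(alignment_strings(s1$alignment),
                         alignment_strings(s3$alignment)))
  # zero rate: every specimen equals its species consensus
  cfg0 <- seq_sim_config(cfg$species, 60, intraspecific_rate = 0,
                         root_states = cfg$root_states)
  s0 <- simulate_alignment(cfg0, seed = 1)
  strs <- alignment_strings(s0$alignment)
  expect_true(all(strs[1:4] == s0$truth$consensus[["sp a"]]))
  expect_true(all(strs[5:8] == s0$truth$consensus[["sp b"]]))
})

test_that("planted substitutions at rate zero give exact k/L p-distances", {
  k <- 4; L <- 100
  cfg <- seq_sim_config(
    species = list(
      list(name = "sp a", n_specimens = 3,
           planted = data.frame(position = 1:k, base = "C")),
      list(name = "sp b", n_specimens = 3, planted = NULL)),
    root_length = L, intraspecific_rate = 0,
    root_states = setNames(rep("A", k), 1:k))
  sim <- simulate_alignment(cfg, seed = 5)
  dm <- distance_matrix(sim$alignment, "p")
  inter <- dm$d[sim$alignment$species == "sp a", sim$alignment$species == "sp b"]
  expect_true(all(inter == k / L))
  intra <- dm$d[1:3, 1:3]
  expect_true(all(intra == 0))
})

test_that("a planted no-op substitution is a configuration error", {
  cfg <- seq_sim_config(
    species = list(
      list(name = "sp a", n_specimens = 2,
           planted = data.frame(position = 5, base = "A")),
      list(name = "sp b", n_specimens = 2, planted = NULL)),
    root_length = 20, root_states = c(`5` = "A"))
  expect_error(simulate_alignment(cfg, seed = 1), "equals the root base")
})

test_that("the barcode gap closes as intraspecific noise overtakes divergence", {
  mk <- function(rate) seq_sim_config(
    species = list(
      list(name = "sp a", n_specimens = 8, planted = NULL),
      list(name = "sp b", n_specimens = 8,
           planted = data.frame(position = seq(5, by = 10, length.out = 20),
                                base = "C"))),
    root_length = 500, intraspecific_rate = rate,
    root_states = setNames(rep("A", 20), seq(5, by = 10, length.out = 20)))
  gaps <- lapply(c(0, 0.02, 0.08), function(r) {
    sim <- simulate_alignment(mk(r), seed = 9)
    species_summaries(distance_matrix(sim$alignment, "K2P"))$barcode_gap
  })
  expect_true(all(!is.na(gaps[[1]])))      # clean 4% divergence: gap present
  expect_true(all(is.na(gaps[[3]])))       # noise above divergence: no gap
  # gap magnitude shrinks before it disappears
  expect_lt(max(gaps[[2]], na.rm = TRUE), min(gaps[[1]]))
})

test_that("morphology simulation is deterministic and honours zero SDs", {
  cfg <- sandlance_morph_config(n = 5)
  m1 <- simulate_morphology(cfg, seed = 11)
  m2 <- simulate_morphology(cfg, seed = 11)
  expect_identical(as.data.frame(m1$table), as.data.frame(m2$table))
  t <- m1$table
  # zero-SD counts are exact; composites derive from their parts
  expect_true(all(t$CR == 15))
  expect_true(all(t$GR == t$UR + t$LR))
  expect_true(all(t$TV == t$PV + t$CV))
  # meristics stay inside configured ranges (clamping)
  at <- t[t$species == "Ammodytes tobianus", ]
  expect_true(all(at$DP >= 123 & at$DP <= 135))
  expect_true(all(t$SL_mm > 0))
  # qualitative states copied through
  expect_true(all(at$BSTC == "yes"))
  expect_true(all(t$BSTC[t$species == "Hyperoplus lanceolatus"] == "unknown"))
})

test_that("simulated morphology reproduces configured means at large n", {
  cfg <- sandlance_morph_config(n = 200)
  t <- simulate_morphology(cfg, seed = 13)$table
  for (s in cfg$species) {
    sub <- t[t$species == s$name, ]
    # meristic means within 3 SE (rounding/clamping bias kept small)
    for (mn in c("DP", "DR", "PV")) {
      m <- s$meristics[[mn]]
      se <- m$sd / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[mn]]) - m$mean), 3 * se + 0.15)
    }
    # measurement means in %SL within 3 SE
    for (mm in c("HL", "PFL")) {
      v <- sub[[mm]] * 100 / sub$SL_mm
      expect_lt(abs(mean(v) - s$measurements[[mm]][1]),
                3 * s$measurements[[mm]][2] / sqrt(nrow(sub)) + 1e-9)
    }
  }
})

test_that("the default COI-style configuration mirrors the published failure mode", {
  sim <- simulate_alignment(sandlance_coi_config(), seed = 11)
  dm <- distance_matrix(sim$alignment, "K2P")
  gs <- species_summaries(dm)
  am <- gs[gs$species == "Ammodytes marinus", ]
  hi <- gs[gs$species == "Hyperoplus immaculatus", ]
  at <- gs[gs$species == "Ammodytes tobianus", ]
  hl <- gs[gs$species == "Hyperoplus lanceolatus", ]
  # marinus and immaculatus: mutual nearest neighbours with clear gaps
  expect_equal(am$nearest_neighbor, "Hyperoplus immaculatus")
  expect_equal(hi$nearest_neighbor, "Ammodytes marinus")
  expect_gt(am$barcode_gap, 1)
  expect_gt(hi$barcode_gap, 1)
  # tobianus and lanceolatus: no gap, and they share an OTU at 2.2%
  expect_true(is.na(at$barcode_gap))
  expect_true(is.na(hl$barcode_gap))
  part <- single_linkage_otus(dm, 2.2)
  expect_equal(length(part$clusters), 3)
  conc <- concordance_report(part)
  bad <- conc[!conc$concordant, ]
  expect_equal(nrow(bad), 1)
  expect_match(bad$species_tally, "tobianus")
  expect_match(bad$species_tally, "lanceolatus")
})
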