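test_that("percent-SL standardization is plain proportional scaling", {
  expect_equal(standardize_percent_sl(43.4, 200), 21.7)
  expect_equal(standardize_percent_sl(150, 150), 100)
  expect_error(standardize_percent_sl(-1, 100), "positive")
  expect_error(standardize_percent_sl(10, 0), "positive")
})

test_that("character summaries render range; mean +/- sd; n", {
  t <- data.frame(specimen_id = c("x1", "x2", "x3"),
                  species = "sp a", SL_mm = c(100, 100, 100),
                  DP = c(1, 2, 3), DR = c(4, 4, 4),
                  stringsAsFactors = FALSE)
  s <- summarize_characters(t)
  dp <- s[s$character == "DP", ]
  expect_equal(dp$summary, "1–3; 2.0 ± 1.0 (3)")
  expect_equal(dp$sd, 1)
  dr <- s[s$character == "DR", ]
  expect_equal(dr$sd, 0)           # constant column
  t1 <- t[1, ]
  s1 <- summarize_characters(t1)
  expect_true(is.na(s1$sd[s1$character == "DP"]))  # single value: no SD
  expect_equal(s1$summary[s1$character == "DP"], "1 (1)")
})

test_that("measurements are summarized in percent of standard length", {
  t <- data.frame(specimen_id = c("y1", "y2"), species = "sp a",
                  SL_mm = c(200, 100), HL = c(43.4, 21.7),
                  stringsAsFactors = FALSE)
  s <- summarize_characters(t)
  hl <- s[s$character == "HL", ]
  expect_equal(c(hl$min, hl$max), c(21.7, 21.7))
})

test_that("variable selection drops composites, constants and qualitative columns", {
  sim <- simulate_morphology(sandlance_morph_config(n = 12), seed = 2)
  vars <- select_dfa_variables(sim$table, "meristic")
  dropped <- attr(vars, "dropped")
  expect_false(any(c("GR", "TV") %in% vars))   # composite counts
  expect_false("CR" %in% vars)                 # constant 15 in all species
  expect_match(dropped[["GR"]], "composite")
  expect_match(dropped[["CR"]], "no variation")
  expect_true(all(vars %in% c("DP", "DR", "AR", "PR", "UR", "LR", "PV", "CV")))
  mvars <- select_dfa_variables(sim$table, "morphometric")
  expect_equal(length(mvars), 19)
  # an artificially constant measurement is excluded
  t2 <- as.data.frame(sim$table)
  t2$BDD <- t2$SL_mm * 0.09       # constant 9 %SL
  expect_false("BDD" %in% select_dfa_variables(t2, "morphometric"))
})

test_that("morphology table validation catches layout errors", {
  expect_error(read_morph_table(data.frame(specimen_id = "a", species = "s")),
               "SL_mm")
  t <- data.frame(specimen_id = c("a", "a"), species = "s", SL_mm = 1)
  expect_error(read_morph_table(t), "duplicate")
  t2 <- data.frame(specimen_id = "a", species = "s", SL_mm = 10,
                   GR = 30, UR = 5, LR = 20)
  expect_warning(read_morph_table(t2), "GR != UR \\+ LR")
  t3 <- data.frame(specimen_id = "a", species = "s", SL_mm = 10, PCP = "maybe")
  expect_error(read_morph_table(t3), "yes/no/unknown")
})

test_that("the key resolves the published genus and species rules", {
  call1 <- identification_key(list(PCP = "yes", VTP = "no", DP = 130,
                                   BSTC = "yes"))
  expect_equal(call1$genus, "Ammodytes")
  expect_equal(call1$species, "Ammodytes tobianus")
  expect_equal(call1$status, "ok")

  call2 <- identification_key(list(PCP = "no", VTP = "yes", DSSS = "yes"))
  expect_equal(call2$species, "Hyperoplus lanceolatus")

  call3 <- identification_key(list(LR = 24, PCP = "no"))
  expect_equal(call3$species, "Hyperoplus immaculatus")

  # PFL is standardized internally when raw mm + SL are given
  call4 <- identification_key(list(PCP = "yes", VTP = "no", DP = 145,
                                   PFL = 19.8, SL_mm = 200, BSTC = "no"))
  expect_equal(call4$species, "Ammodytes marinus")
  expect_true(any(call4$evidence$character == "PFL"))
})

test_that("missing or conflicting characters yield indeterminate calls", {
  none <- identification_key(list(HL = 20))
  expect_equal(none$status, "indeterminate")
  expect_true(is.na(none$species))
  clash <- identification_key(list(PCP = "yes", VTP = "yes"))
  expect_equal(clash$status, "indeterminate")
  genus_only <- identification_key(list(PCP = "no", VTP = "yes"))
  expect_equal(genus_only$genus, "Hyperoplus")
  expect_equal(genus_only$status, "indeterminate")  # no species character
})

test_that("the key recovers simulated specimens at high accuracy", {
  sim <- simulate_morphology(sandlance_morph_config(n = 15), seed = 6)
  calls <- identify_specimens(sim$table)
  ok <- calls$status == "ok" & calls$species_call == calls$species
  expect_gte(mean(ok), 0.95)
})
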