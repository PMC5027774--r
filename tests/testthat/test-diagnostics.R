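# four-species fixture reproducing the published nuclear-marker site pattern:
# sites 82/433/460 variable on a 464-bp fragment; per-site states
#   marinus C,G,C / tobianus C,G,A / lanceolatus T,G,A / immaculatus C,A,A
rhodopsin_fixture <- function(rate = 0, seed = 5) {
  simulate_alignment(sandlance_rhodopsin_config(intraspecific_rate = rate),
                     seed = seed)
}

test_that("the reconstructed nuclear fragment yields the published diagnostics", {
  sim <- rhodopsin_fixture()
  dt <- diagnostic_sites(sim$alignment)
  expect_equal(dt$position, c(82, 433, 460))
  expect_equal(dt$`Hyperoplus lanceolatus`[dt$position == 82], "T")
  expect_equal(dt$`Hyperoplus immaculatus`[dt$position == 433], "A")
  expect_equal(dt$`Ammodytes marinus`[dt$position == 460], "C")
  expect_equal(dt$diagnostic_for,
               c("Hyperoplus lanceolatus", "Hyperoplus immaculatus",
                 "Ammodytes marinus"))
  counts <- count_diagnostics(dt)
  expect_equal(counts[["Ammodytes marinus"]], 1L)
  expect_equal(counts[["Ammodytes tobianus"]], 0L)
  expect_equal(counts[["Hyperoplus lanceolatus"]], 1L)
  expect_equal(counts[["Hyperoplus immaculatus"]], 1L)
})

test_that("a species without pure diagnostics can carry a unique combination", {
  sim <- rhodopsin_fixture()
  dt <- diagnostic_sites(sim$alignment)
  sig <- combination_signature(dt, "Ammodytes tobianus")
  expect_equal(as.character(sig), c("C", "G", "A"))
  expect_true(attr(sig, "identifiable"))
  expect_error(combination_signature(dt, "no such species"), "not in table")
})

test_that("identical-vector species are flagged non-identifiable", {
  aln <- bk_alignment(
    c(a1 = "AACC", a2 = "AACC", b1 = "AACC", c1 = "GACC"),
    species = c("sp a", "sp a", "sp b", "sp c"))
  dt <- diagnostic_sites(aln)
  sig_a <- combination_signature(dt, "sp a")
  expect_false(attr(sig_a, "identifiable"))  # same vector as sp b
  sig_c <- combination_signature(dt, "sp c")
  expect_true(attr(sig_c, "identifiable"))
})

test_that("an invariant alignment has no variable sites", {
  aln <- bk_alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                      species = c("s1", "s2", "s3"))
  dt <- diagnostic_sites(aln)
  expect_equal(nrow(dt), 0)
  expect_equal(unname(count_diagnostics(dt)), c(0L, 0L, 0L))
})

test_that("detector equals the brute-force per-column scan on random data", {
  set.seed(71)
  for (rep in 1:20) {
    sp <- rep(paste("sp", 1:4), times = sample(1:3, 4, replace = TRUE))
    aln <- random_alignment(length(sp), 30, mut = 0.15,
                            amb = if (rep %% 2) 0.05 else 0, species = sp)
    dt <- diagnostic_sites(aln)
    oracle <- oracle_diagnostics(aln)
    expect_equal(dt$position, vapply(oracle, `[[`, 0L, "position"))
    for (k in seq_along(oracle)) {
      expect_setequal(
        if (nzchar(dt$diagnostic_for[k]))
          strsplit(dt$diagnostic_for[k], "; ")[[1]] else character(0),
        oracle[[k]]$diagnostic)
    }
  }
})

test_that("planted diagnostic sites are recovered exactly under mutation noise", {
  cfg <- seq_sim_config(
    species = list(
      list(name = "sp a", n_specimens = 6,
           planted = data.frame(position = c(10, 20, 30), base = "C")),
      list(name = "sp b", n_specimens = 6, planted = NULL)),
    root_length = 200, intraspecific_rate = 0.01,
    protect_planted_sites = TRUE,
    root_states = setNames(rep("A", 3), c(10, 20, 30)))
  sim <- simulate_alignment(cfg, seed = 3)
  dt <- diagnostic_sites(sim$alignment)
  found <- dt$position[grepl("sp a", dt$diagnostic_for)]
  expect_true(all(c(10, 20, 30) %in% found))
  # planted columns carry exactly the planted state in every sp-a sequence
  expect_true(all(sim$alignment$seq[sim$alignment$species == "sp a",
                                    c(10, 20, 30)] == "C"))
})

test_that("a compatible ambiguity in another species disqualifies a site", {
  # sp b carries Y (C or T) where sp a is fixed for C: not diagnostic for a
  aln <- bk_alignment(c(a1 = "CAAA", a2 = "CAAA", b1 = "YAAA", b2 = "TAAA"),
                      species = c("sp a", "sp a", "sp b", "sp b"))
  dt <- diagnostic_sites(aln)
  expect_equal(nrow(dt), 0)  # sp b has no fixed unambiguous state either
  # sp c's R (A/G) is incompatible with sp a's C but compatible with sp b's A:
  # the site stays diagnostic for a and is disqualified for b
  aln2 <- bk_alignment(c(a1 = "CAAA", a2 = "CAAA", b1 = "AAAA", b2 = "AAAA",
                         c1 = "RAAA", c2 = "GAAA"),
                       species = c("sp a", "sp a", "sp b", "sp b",
                                   "sp c", "sp c"))
  dt2 <- diagnostic_sites(aln2)
  expect_equal(dt2$diagnostic_for, "sp a")
})

test_that("adding a conflicting sequence removes, never adds, diagnostics", {
  aln <- bk_alignment(c(a1 = "CAAA", a2 = "CAAA", b1 = "TAAA", b2 = "TAAA"),
                      species = c("sp a", "sp a", "sp b", "sp b"))
  before <- count_diagnostics(diagnostic_sites(aln))
  aln2 <- bk_alignment(c(a1 = "CAAA", a2 = "CAAA", b1 = "TAAA", b2 = "TAAA",
                         b3 = "CAAA"),
                       species = c("sp a", "sp a", "sp b", "sp b", "sp b"))
  after <- count_diagnostics(diagnostic_sites(aln2))
  expect_equal(before[["sp a"]], 1L)
  expect_equal(before[["sp b"]], 1L)
  expect_equal(unname(after), c(0L, 0L))
})
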