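test_that("1-D two-group fixture matches the hand-computed scatter solution", {
  # groups {0,1} and {10,11}: B = 100, W = 1, lambda = 100, Wilks = 1/101
  t <- data.frame(specimen_id = sprintf("s%d", 1:4),
                  species = rep(c("g1", "g2"), each = 2),
                  SL_mm = 100, DP = c(0, 1, 10, 11), stringsAsFactors = FALSE)
  fit <- suppressWarnings(discriminant_analysis(t, "DP"))
  expect_equal(unname(fit$eigenvalues), 100)
  expect_equal(fit$wilks_lambda, 1 / 101)
  expect_equal(unname(fit$explained_pct), 100)
  expect_equal(length(fit$eigenvalues), 1)  # min(g-1, p) = 1
})

test_that("identical group means give no separation", {
  set.seed(81)
  t <- data.frame(specimen_id = sprintf("s%d", 1:40),
                  species = rep(c("g1", "g2"), each = 20),
                  SL_mm = 100,
                  DP = c(stats::rnorm(20, 50, 5), stats::rnorm(20, 50, 5)),
                  DR = c(stats::rnorm(20, 20, 2), stats::rnorm(20, 20, 2)),
                  stringsAsFactors = FALSE)
  fit <- discriminant_analysis(t, c("DP", "DR"))
  expect_lt(max(fit$eigenvalues), 0.5)
  expect_gt(fit$wilks_lambda, 0.7)
})

test_that("DFA matches the brute-force scatter-matrix oracle", {
  t <- morph_fixture(n = 10, seed = 91)
  fit <- discriminant_analysis(t, c("BDD", "HL"))
  X <- cbind(BDD = t$BDD * 100 / t$SL_mm, HL = t$HL * 100 / t$SL_mm)
  ora <- oracle_dfa(X, t$species)
  expect_equal(unname(fit$eigenvalues), ora$eigenvalues, tolerance = 1e-8)
  expect_equal(unname(fit$explained_pct), ora$explained, tolerance = 1e-8)
  expect_equal(fit$wilks_lambda, ora$wilks, tolerance = 1e-8)
  expect_equal(sum(fit$explained_pct), 100, tolerance = 1e-6)
  # two functions for 3 groups, 2 variables
  expect_equal(length(fit$eigenvalues), 2)
})

test_that("eigen-structure agrees with an established LDA implementation", {
  skip_if_not_installed("MASS")
  t <- morph_fixture(n = 12, seed = 92)
  fit <- discriminant_analysis(t, c("BDD", "HL"))
  X <- data.frame(BDD = t$BDD * 100 / t$SL_mm, HL = t$HL * 100 / t$SL_mm)
  ld <- MASS::lda(X, grouping = t$species)
  g <- 3; N <- nrow(t)
  expect_equal(unname(fit$eigenvalues),
               unname(ld$svd^2 * (g - 1) / (N - g)), tolerance = 1e-8)
  # nearest-centroid calls agree with lda posterior calls on separated data
  expect_equal(fit$classification$predicted,
               as.character(stats::predict(ld)$class))
})

test_that("Wilks' lambda and eigenvalues are invariant to linear maps of X", {
  t <- morph_fixture(n = 9, seed = 93)
  fit <- discriminant_analysis(t, c("BDD", "HL"))
  # invertible linear transform of the two variables (in %SL space)
  t2 <- t
  bdd <- t$BDD * 100 / t$SL_mm; hl <- t$HL * 100 / t$SL_mm
  a <- 2 * bdd + 0.5 * hl + 3
  b <- -bdd + 4 * hl - 1
  t2$BDD <- a * t2$SL_mm / 100; t2$HL <- b * t2$SL_mm / 100
  fit2 <- discriminant_analysis(t2, c("BDD", "HL"))
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-8)
  expect_equal(fit2$wilks_lambda, fit$wilks_lambda, tolerance = 1e-8)
})

test_that("rank property: positive eigenvalues never exceed min(g-1, p)", {
  set.seed(94)
  for (rep in 1:5) {
    g <- sample(2:4, 1); p <- sample(2:5, 1); n <- 8
    t <- data.frame(specimen_id = sprintf("r%d_%d", rep, 1:(g * n)),
                    species = rep(paste("g", 1:g), each = n),
                    SL_mm = 100, stringsAsFactors = FALSE)
    for (v in seq_len(p)) t[[paste0("DP", v)]] <- stats::rnorm(g * n, 50, 5)
    names(t)[4:(3 + p)] <- c("DP", "DR", "AR", "PR", "LR")[1:p]
    fit <- discriminant_analysis(t, names(t)[4:(3 + p)])
    expect_lte(sum(fit$eigenvalues > 1e-8), min(g - 1, p))
    expect_equal(length(fit$eigenvalues), min(g - 1, p))
  }
})

test_that("standardized coefficients follow the sign convention", {
  t <- morph_fixture(n = 10, seed = 95)
  fit <- discriminant_analysis(t, c("BDD", "HL"))
  for (j in seq_len(ncol(fit$std_coefficients))) {
    i_max <- which.max(abs(fit$std_coefficients[, j]))
    expect_gt(fit$std_coefficients[i_max, j], 0)
  }
})

test_that("Box's M matches a direct computation on a smooth fixture", {
  t <- morph_fixture(n = 12, seed = 96)
  fit <- discriminant_analysis(t, c("BDD", "HL"))
  X <- cbind(t$BDD * 100 / t$SL_mm, t$HL * 100 / t$SL_mm)
  groups <- sort(unique(t$species))
  Sp <- matrix(0, 2, 2); lds <- numeric(3); sizes <- integer(3)
  for (i in 1:3) {
    Xi <- X[t$species == groups[i], ]
    sizes[i] <- nrow(Xi)
    Sp <- Sp + (sizes[i] - 1) * stats::cov(Xi)
    lds[i] <- log(det(stats::cov(Xi)))
  }
  N <- sum(sizes)
  Sp <- Sp / (N - 3)
  M <- (N - 3) * log(det(Sp)) - sum((sizes - 1) * lds)
  expect_equal(fit$boxm$M, M, tolerance = 1e-10)
  expect_gt(fit$boxm$p, 0)
  expect_equal(fit$boxm$df, 2 * 3 * 2 / 2)  # p(p+1)(g-1)/2
})

test_that("degenerate inputs fail with the documented errors", {
  t <- data.frame(specimen_id = sprintf("s%d", 1:8),
                  species = rep(c("g1", "g2"), each = 4),
                  SL_mm = 100, DP = 5, DR = 7, stringsAsFactors = FALSE)
  expect_error(discriminant_analysis(t, c("DP", "DR")), "singular")
  t2 <- data.frame(specimen_id = sprintf("s%d", 1:3),
                   species = c("g1", "g1", "g2"), SL_mm = 100,
                   DP = c(1, 2, 3), stringsAsFactors = FALSE)
  expect_error(discriminant_analysis(t2, "DP"), "2 groups")
})

test_that("leave-one-out reclassification is high on well-separated groups", {
  sim <- simulate_morphology(sandlance_morph_config(n = 20), seed = 1)
  vars <- select_dfa_variables(sim$table, "meristic")
  acc <- suppressWarnings(dfa_loo(sim$table, vars))
  expect_gte(as.numeric(acc), 0.9)
})
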