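#' Multi-group discriminant function analysis
#'
#' Canonical discriminant analysis of species groups: the discriminant
#' functions are the eigenvectors of `W^-1 B`, where `W` is the pooled
#' within-group scatter matrix and `B` the between-group scatter (weighted
#' by group sizes).  The number of functions is `min(groups - 1, variables)`.
#' Reported alongside: standardized coefficients (raw coefficients scaled by
#' the pooled within-group standard deviation of each variable, so that
#' coefficient magnitude reflects a variable's weight in the function),
#' percentage of explained variance per function, Wilks' lambda
#' `prod(1/(1+lambda_k))` with Bartlett's chi-squared approximation, Box's M
#' test of equal group covariance matrices (chi-squared approximation),
#' specimen scores, group centroids, and a nearest-centroid classification
#' (Euclidean distance in discriminant space, equal priors).
#'
#' Only specimens with a complete suite of the selected variables are used
#' (complete-case deletion); measurements enter as %SL, meristic counts as
#' recorded.
#'
#' @param t A [read_morph_table()] data frame (or CSV path).
#' @param variables Character vector of variable columns, e.g. from
#'   [select_dfa_variables()].
#' @param group_col Grouping column, default `"species"`.
#' @return An object of class `dfa_result`; see Details.  Fields:
#'   `variables`, `groups`, `n_used`, `n_dropped`, `eigenvalues`,
#'   `explained_pct`, `cumulative_pct`, `raw_coefficients`,
#'   `std_coefficients`, `wilks_lambda`, `bartlett` (`chi2`, `df`, `p`),
#'   `boxm` (`M`, `chi2`, `df`, `p`), `scores`, `centroids`,
#'   `classification`.
#' @export
discriminant_analysis <- function(t, variables, group_col = "species") {
  t <- read_morph_table(t)
  tp <- percent_sl_columns(t)
  if (length(variables) == 0L) stop("no variables to analyse after selection")
  miss <- setdiff(variables, names(tp))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(tp[variables]) & !is.na(tp[[group_col]]) &
    tp[[group_col]] != "unknown"
  n_dropped <- sum(!cc)
  X <- as.matrix(tp[cc, variables, drop = FALSE])
  storage.mode(X) <- "double"
  g_lab <- as.character(tp[[group_col]][cc])
  ids <- tp$specimen_id[cc]
  groups <- sort(unique(g_lab))
  sizes <- vapply(groups, function(s) sum(g_lab == s), 0L)
  if (sum(sizes >= 2L) < 2L) {
    stop("need at least 2 groups with at least 2 complete specimens")
  }
  g <- length(groups)
  p <- length(variables)
  N <- nrow(X)

  grand <- colMeans(X)
  means <- do.call(rbind, lapply(groups, function(s)
    colMeans(X[g_lab == s, , drop = FALSE])))
  rownames(means) <- groups
  W <- matrix(0, p, p)
  for (s in groups) {
    Xi <- sweep(X[g_lab == s, , drop = FALSE], 2L, means[s, ])
    W <- W + crossprod(Xi)
  }
  B <- matrix(0, p, p)
  for (s in groups) {
    dmu <- means[s, ] - grand
    B <- B + sizes[[s]] * tcrossprod(dmu)
  }
  if (rcond_sym(W) < 1e-12) {
    stop("pooled within-group scatter is singular; reduce the variable set")
  }

  es <- eigen(solve(W, B))
  ord <- order(Re(es$values), decreasing = TRUE)
  k <- min(g - 1L, p)
  lambda <- pmax(Re(es$values)[ord][seq_len(k)], 0)
  V <- Re(es$vectors)[, ord, drop = FALSE][, seq_len(k), drop = FALSE]

  Sw <- W / (N - g)  # pooled within-group covariance
  # scale eigenvectors so scores have unit pooled within-group variance
  for (j in seq_len(k)) {
    sj <- sqrt(drop(t(V[, j]) %*% Sw %*% V[, j]))
    if (sj > 0) V[, j] <- V[, j] / sj
  }
  std <- V * sqrt(diag(Sw))
  # sign convention: dominant variable of each function loads positively
  for (j in seq_len(k)) {
    i_max <- which.max(abs(std[, j]))
    if (std[i_max, j] < 0) {
      std[, j] <- -std[, j]
      V[, j] <- -V[, j]
    }
  }
  dimnames(V) <- dimnames(std) <- list(variables, paste0("DF", seq_len(k)))

  explained <- 100 * lambda / sum(lambda)
  wilks <- prod(1 / (1 + lambda))
  bart_chi2 <- -(N - 1 - (p + g) / 2) * log(wilks)
  bart_df <- p * (g - 1)
  bartlett <- list(chi2 = bart_chi2, df = bart_df,
                   p = stats::pchisq(bart_chi2, bart_df, lower.tail = FALSE))
  boxm <- box_m(X, g_lab)

  scores <- sweep(X, 2L, grand) %*% V
  rownames(scores) <- ids
  centroids <- sweep(means, 2L, grand) %*% V
  rownames(centroids) <- groups
  pred <- groups[apply(scores, 1L, function(z)
    which.min(colSums((t(centroids) - z)^2)))]

  structure(list(
    variables = variables, groups = groups, group_sizes = sizes,
    n_used = N, n_dropped = n_dropped, grand_mean = grand,
    eigenvalues = stats::setNames(lambda, paste0("DF", seq_len(k))),
    explained_pct = stats::setNames(explained, paste0("DF", seq_len(k))),
    cumulative_pct = stats::setNames(cumsum(explained), paste0("DF", seq_len(k))),
    raw_coefficients = V, std_coefficients = std,
    wilks_lambda = wilks, bartlett = bartlett, boxm = boxm,
    scores = scores, centroids = centroids,
    classification = data.frame(specimen_id = ids, species = g_lab,
                                predicted = pred, stringsAsFactors = FALSE)),
    class = "dfa_result")
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

# Box's M test of homogeneity of group covariance matrices
# (chi-squared approximation; groups with n < 2 excluded with a warning)
box_m <- function(X, g_lab) {
  groups <- sort(unique(g_lab))
  sizes <- vapply(groups, function(s) sum(g_lab == s), 0L)
  small <- groups[sizes < 2L]
  if (length(small)) {
    warning("Box's M: excluding group(s) with n = 1: ",
            paste(small, collapse = ", "))
    keep <- g_lab %in% groups[sizes >= 2L]
    X <- X[keep, , drop = FALSE]
    g_lab <- g_lab[keep]
    groups <- groups[sizes >= 2L]
    sizes <- sizes[sizes >= 2L]
  }
  g <- length(groups)
  p <- ncol(X)
  N <- nrow(X)
  Sp <- matrix(0, p, p)
  logdets <- numeric(g)
  for (i in seq_along(groups)) {
    Xi <- X[g_lab == groups[i], , drop = FALSE]
    Si <- stats::cov(Xi)
    Sp <- Sp + (sizes[i] - 1) * Si
    logdets[i] <- determinant(Si, logarithm = TRUE)$modulus
  }
  Sp <- Sp / (N - g)
  if (any(!is.finite(logdets))) {
    warning("Box's M undefined: singular covariance in group(s) ",
            paste(groups[!is.finite(logdets)], collapse = ", "))
    return(list(M = NA_real_, chi2 = NA_real_, df = p * (p + 1) * (g - 1) / 2,
                p = NA_real_))
  }
  M <- (N - g) * determinant(Sp, logarithm = TRUE)$modulus -
    sum((sizes - 1) * logdets)
  c1 <- (sum(1 / (sizes - 1)) - 1 / (N - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  chi2 <- as.numeric(M * (1 - c1))
  df <- p * (p + 1) * (g - 1) / 2
  list(M = as.numeric(M), chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' @export
print.dfa_result <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("<dfa_result> %d groups, %d variables, %d specimens (%d dropped)\n",
              length(x$groups), length(x$variables), x$n_used, x$n_dropped))
  tab <- rbind(`Eigenvalue` = x$eigenvalues,
               `Explained %` = x$explained_pct,
               `Cumulative %` = x$cumulative_pct)
  print(round(tab, 3))
  cat(sprintf("Wilks' lambda = %.4g (Bartlett chi2 = %.3f, df = %d, p = %.3g)\n",
              x$wilks_lambda, x$bartlett$chi2, x$bartlett$df, x$bartlett$p))
  if (is.finite(x$boxm$chi2)) {
    cat(sprintf("Box's M chi2 = %.3f, df = %.0f, p = %.3g\n",
                x$boxm$chi2, x$boxm$df, x$boxm$p))
  } else {
    cat("Box's M undefined (singular group covariance)\n")
  }
  acc <- mean(x$classification$predicted == x$classification$species)
  cat(sprintf("Nearest-centroid reclassification: %.1f%% correct\n", 100 * acc))
  invisible(x)
}

#' Leave-one-out reclassification accuracy of a discriminant analysis
#'
#' Refits the discriminant analysis without each specimen in turn and
#' classifies the held-out specimen by the nearest group centroid in the
#' refitted discriminant space.
#'
#' @inheritParams discriminant_analysis
#' @return Fraction of specimens whose species is recovered, with attribute
#'   `calls` (per-specimen predictions).
#' @export
dfa_loo <- function(t, variables, group_col = "species") {
  t <- read_morph_table(t)
  tp <- percent_sl_columns(t)
  cc <- stats::complete.cases(tp[variables]) & !is.na(tp[[group_col]]) &
    tp[[group_col]] != "unknown"
  sub <- t[cc, , drop = FALSE]
  n <- nrow(sub)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- discriminant_analysis(sub[-i, , drop = FALSE], variables, group_col)
    xi <- as.numeric(percent_sl_columns(sub[i, , drop = FALSE])[, variables])
    z <- drop((xi - fit$grand_mean) %*% fit$raw_coefficients)
    pred[i] <- fit$groups[which.min(colSums((t(fit$centroids) - z)^2))]
  }
  acc <- mean(pred == sub[[group_col]])
  attr(acc, "calls") <- data.frame(specimen_id = sub$specimen_id,
                                   species = sub[[group_col]],
                                   predicted = pred, stringsAsFactors = FALSE)
  acc
}
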