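# Independent brute-force oracles and small data builders used across tests.

# literal per-site scan, independent of the package's coded-base engine
oracle_compare <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  bases <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(va)) {
    if (!(va[i] %in% bases) || !(vb[i] %in% bases)) next
    n <- n + 1L
    if (va[i] == vb[i]) next
    pair <- sort(c(va[i], vb[i]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
      ts <- ts + 1L
    } else {
      tv <- tv + 1L
    }
  }
  list(n = n, ts = ts, tv = tv)
}

oracle_k2p <- function(a, b) {
  sc <- oracle_compare(a, b)
  if (sc$n == 0) return(NA_real_)
  P <- sc$ts / sc$n; Q <- sc$tv / sc$n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

oracle_p <- function(a, b) {
  sc <- oracle_compare(a, b)
  if (sc$n == 0) return(NA_real_)
  (sc$ts + sc$tv) / sc$n
}

# random alignment derived from a shared root so distances stay unsaturated
random_alignment <- function(n = 10, L = 50, mut = 0.06, amb = 0,
                             species = NULL) {
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- root
    hit <- which(stats::runif(L) < mut)
    for (p in hit) s[p] <- sample(setdiff(bases, s[p]), 1)
    if (amb > 0) {
      h2 <- which(stats::runif(L) < amb)
      s[h2] <- sample(c("N", "-", "R", "Y", "W"), length(h2), replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("s%02d", seq_len(n))
  if (is.null(species)) species <- rep("spX", n)
  bk_alignment(seqs, species = species)
}

# graph-components clustering oracle (breadth-first search on d <= thr)
oracle_components <- function(d, thr) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(d[v, ] <= thr & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

# per-column exhaustive diagnostic-site scan (set logic, no vectorization)
oracle_diagnostics <- function(aln) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"), "-" = character(0))
  sp_names <- sort(unique(aln$species))
  out <- list()
  for (pos in seq_len(aln$length)) {
    cons <- sapply(sp_names, function(s) {
      col <- aln$seq[aln$species == s, pos]
      u <- unique(col)
      if (length(u) == 1 && u %in% c("A", "C", "G", "T")) u else NA_character_
    })
    if (length(unique(cons[!is.na(cons)])) < 2) next
    diag_sp <- character(0)
    for (s in sp_names) {
      b <- cons[[s]]
      if (is.na(b)) next
      others <- aln$seq[aln$species != s, pos]
      if (!any(vapply(others, function(ch) b %in% iupac[[ch]], TRUE))) {
        diag_sp <- c(diag_sp, s)
      }
    }
    out[[length(out) + 1]] <- list(position = pos, cons = cons,
                                   diagnostic = diag_sp)
  }
  out
}

# brute-force canonical discriminant analysis through the symmetric
# whitened problem (Cholesky route), independent of the eigen(W^-1 B) path
oracle_dfa <- function(X, g_lab) {
  groups <- sort(unique(g_lab))
  p <- ncol(X); N <- nrow(X); g <- length(groups)
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (s in groups) {
    Xi <- X[g_lab == s, , drop = FALSE]
    mu <- colMeans(Xi)
    for (r in seq_len(nrow(Xi))) {
      dv <- Xi[r, ] - mu
      W <- W + outer(dv, dv)
    }
    dmu <- mu - grand
    B <- B + nrow(Xi) * outer(dmu, dmu)
  }
  Lc <- t(chol(W))
  M <- forwardsolve(Lc, t(forwardsolve(Lc, B)))
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(g - 1, p)
  lambda <- pmax(es$values[seq_len(k)], 0)
  list(eigenvalues = lambda,
       explained = 100 * lambda / sum(lambda),
       wilks = prod(1 / (1 + lambda)),
       W = W, B = B)
}

# bootstrap support of the bipartition separating `tips` from the rest
support_for_split <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  all_idx <- seq_along(tree$tip.label)
  want <- sort(match(tips, tree$tip.label))
  hit <- which(vapply(pp, function(s)
    setequal(s, want) || setequal(setdiff(all_idx, s), want), TRUE))
  if (!length(hit)) return(0)
  sup <- tree$node.label[hit]
  max(as.numeric(sup), na.rm = TRUE)
}

# small well-separated morphology fixture with smooth within-group spread
morph_fixture <- function(n = 8, seed = 99) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(1:3, function(gi) {
    data.frame(
      specimen_id = sprintf("g%d_%02d", gi, seq_len(n)),
      species = sprintf("species %d", gi),
      SL_mm = stats::rnorm(n, 150, 10),
      BDD = stats::rnorm(n, c(12, 15, 18)[gi], 0.8),
      HL = stats::rnorm(n, c(30, 28, 33)[gi], 1.0),
      stringsAsFactors = FALSE)
  }))
  # store measurements in mm so %SL conversion reproduces the drawn values
  rows$BDD <- rows$BDD * rows$SL_mm / 100
  rows$HL <- rows$HL * rows$SL_mm / 100
  rows
}
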