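#' Compare two aligned sequences site by site under pairwise deletion
#'
#' A site contributes to the comparison only when both sequences carry an
#' unambiguous base (`A`, `C`, `G`, `T`) there; gaps and IUPAC ambiguity
#' codes exclude the site for this pair only (pairwise deletion, the
#' treatment MEGA applies by default).  Differing sites are classified as
#' transitions (A<->G, C<->T) or transversions.
#'
#' @param seq_a,seq_b Equal-length sequences: single strings or character
#'   vectors of residues.
#' @return A list of class `site_comparison` with integer fields
#'   `n_compared`, `n_transitions`, `n_transversions`.
#' @examples
#' compare_sites("AAAAAAAAAA", "GAAAAAAAAC")  # 10 sites, 1 ts, 1 tv
#' @export
compare_sites <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b)) {
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  }
  site_comparison_codes(match(a, c("A", "C", "G", "T")),
                        match(b, c("A", "C", "G", "T")))
}

# core comparison on integer-coded bases (A=1, C=2, G=3, T=4, NA = excluded)
site_comparison_codes <- function(ca, cb) {
  ok <- !is.na(ca) & !is.na(cb)
  diff <- ok & ca != cb
  # purines code to odd (A=1, G=3); a difference within purines or within
  # pyrimidines is a transition
  ts <- diff & ((ca %% 2L) == (cb %% 2L))
  structure(list(n_compared = sum(ok),
                 n_transitions = sum(ts),
                 n_transversions = sum(diff) - sum(ts)),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> %d sites compared: %d transitions, %d transversions\n",
              x$n_compared, x$n_transitions, x$n_transversions))
  invisible(x)
}

#' Kimura two-parameter distance from a site comparison
#'
#' Computes `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q`
#' are the observed proportions of transition and transversion differences
#' among the jointly resolved sites.  Saturated comparisons (a log argument
#' at or below zero) and empty comparisons yield `NA`, which downstream
#' stages must treat as undefined rather than zero.
#'
#' @param sc A [compare_sites()] result.
#' @return Distance as a proportion (`NA` if undefined).
#' @examples
#' k2p_distance(compare_sites("AAAAAAAAAA", "GAAAAAAAAA"))  # -0.5*log(0.8)
#' @export
k2p_distance <- function(sc) {
  if (sc$n_compared == 0L) return(NA_real_)
  P <- sc$n_transitions / sc$n_compared
  Q <- sc$n_transversions / sc$n_compared
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  max(0, -0.5 * log(w1) - 0.25 * log(w2))
}

#' Uncorrected p-distance from a site comparison
#'
#' @param sc A [compare_sites()] result.
#' @return Proportion of differing sites among jointly resolved sites
#'   (`NA` when no site is comparable).
#' @export
p_distance <- function(sc) {
  if (sc$n_compared == 0L) return(NA_real_)
  (sc$n_transitions + sc$n_transversions) / sc$n_compared
}

#' Pairwise distance matrix under pairwise deletion
#'
#' Computes all pairwise K2P or p-distances for an alignment.  Undefined
#' pairs (zero comparable sites, or K2P saturation) are recorded as `NA` and
#' listed in the `undefined` attribute instead of being silently dropped.
#'
#' @param aln A [bk_alignment].
#' @param model `"K2P"` (default) or `"p"`.
#' @return An object of class `bk_dist`: list with `labels`, `model`,
#'   `d` (symmetric matrix of proportions, zero diagonal, `NA` where
#'   undefined), `sites` (matrix of jointly resolved site counts), and a
#'   data frame attribute `undefined` naming undefined pairs.
#' @examples
#' aln <- bk_alignment(c(a = "ACGTACGTAC", b = "ACGAACGTAC", c = "TCGAACGTAC"),
#'                     species = c("sp1", "sp1", "sp2"))
#' dm <- distance_matrix(aln, "K2P")
#' round(dm$d * 100, 2)
#' @export
distance_matrix <- function(aln, model = c("K2P", "p")) {
  stopifnot(inherits(aln, "bk_alignment"))
  model <- match.arg(model)
  n <- length(aln$specimen_id)
  codes <- matrix(match(aln$seq, c("A", "C", "G", "T")), nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$specimen_id, aln$specimen_id))
  sites <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(sites) <- as.integer(rowSums(!is.na(codes)))
  fun <- if (model == "K2P") k2p_distance else p_distance
  und <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sc <- site_comparison_codes(codes[i, ], codes[j, ])
      v <- fun(sc)
      d[i, j] <- d[j, i] <- v
      sites[i, j] <- sites[j, i] <- sc$n_compared
      if (is.na(v)) und[[length(und) + 1L]] <-
          c(aln$specimen_id[i], aln$specimen_id[j])
    }
  }
  undef <- if (length(und)) {
    data.frame(a = vapply(und, `[`, "", 1L), b = vapply(und, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0))
  }
  structure(list(labels = aln$specimen_id, species = aln$species,
                 model = model, d = d, sites = sites),
            undefined = undef, class = "bk_dist")
}

#' @export
print.bk_dist <- function(x, ...) {
  und <- attr(x, "undefined")
  cat(sprintf("<bk_dist> %s distances, %d specimens, %d undefined pairs\n",
              x$model, length(x$labels), nrow(und)))
  invisible(x)
}

#' @export
as.matrix.bk_dist <- function(x, ...) x$d

#' Write a labelled square distance matrix as CSV
#'
#' Distances are written as percentages.  Values are rounded half-up to two
#' decimals unless `full_precision` is set.
#'
#' @param dm A [distance_matrix()] result.
#' @param path Output CSV path.
#' @param full_precision Write full double precision instead of the
#'   two-decimal report convention.
#' @return Invisibly, the matrix written (in percent).
#' @export
write_distance_csv <- function(dm, path, full_precision = FALSE) {
  m <- dm$d * 100
  if (!full_precision) m <- round_half_up(m, 2)
  out <- data.frame(specimen_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(m)
}

# Round half away from zero (report convention; R's round() is banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
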