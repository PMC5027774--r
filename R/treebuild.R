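#' Neighbour-joining tree from a distance matrix
#'
#' Canonical Saitou–Nei neighbour joining.  Negative branch lengths, an
#' artefact of the agglomeration on non-additive matrices, are clamped to
#' zero (display convention of common barcoding software); the total clamped
#' deficit is attached as attribute `clamped`.
#'
#' @param dm A [distance_matrix()] result, or a labelled square numeric
#'   matrix of distances.
#' @return An unrooted `phylo` tree whose tip labels are the specimen ids.
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- nj_tree(d)
#' @export
nj_tree <- function(dm) {
  m <- if (inherits(dm, "bk_dist")) dm$d else as.matrix(dm)
  if (nrow(m) < 3L) stop("neighbour joining needs at least 3 specimens")
  if (anyNA(m)) {
    idx <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    pairs <- paste(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]], sep = "~")
    stop("undefined distances among inputs: ", paste(pairs, collapse = ", "))
  }
  tr <- ape::nj(stats::as.dist(m))
  neg <- tr$edge.length < 0
  clamped <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Non-parametric bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate with the same distance engine (pairwise deletion within
#' each replicate), and writes onto each internal edge of the original tree
#' the percentage of replicates containing the same leaf bipartition
#' (Felsenstein's procedure).  Replicates in which any pairwise distance is
#' undefined are skipped and counted; more than 50% skipped is an error.
#'
#' @param aln A [bk_alignment].
#' @param model Distance model, `"K2P"` or `"p"`.
#' @param replicates Number of bootstrap replicates (the classical full-scale
#'   setting is 10000; desk-scale analyses use 100–1000).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @return The NJ tree of the full alignment, with `node.label` holding
#'   bootstrap percentages (`NA` on the trivial basal node) and attributes
#'   `replicates_used` and `replicates_skipped`.
#' @export
bootstrap_support <- function(aln, model = c("K2P", "p"), replicates = 10000,
                              seed = NULL) {
  stopifnot(inherits(aln, "bk_alignment"))
  model <- match.arg(model)
  if (replicates < 1) stop("replicates must be >= 1")
  dm <- distance_matrix(aln, model)
  main <- nj_tree(dm)
  if (!is.null(seed)) set.seed(seed)
  boots <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(aln$length, aln$length, replace = TRUE)
    rep_aln <- aln
    rep_aln$seq <- aln$seq[, cols, drop = FALSE]
    rep_dm <- distance_matrix(rep_aln, model)
    if (anyNA(rep_dm$d)) {
      skipped <- skipped + 1L
      next
    }
    boots[[r]] <- nj_tree(rep_dm)
  }
  boots <- boots[!vapply(boots, is.null, TRUE)]
  if (skipped > replicates / 2) {
    stop(skipped, " of ", replicates,
         " bootstrap replicates had undefined distances")
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- 100 * counts / length(boots)
  sup[1L] <- NA_real_  # basal node of the unrooted representation: trivial split
  main$node.label <- sup
  attr(main, "replicates_used") <- length(boots)
  attr(main, "replicates_skipped") <- skipped
  main
}
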