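#' Threshold single-linkage clustering of barcodes into OTUs
#'
#' Two specimens share an OTU iff they are connected by a chain of pairwise
#' distances at or below the threshold (single linkage), the initial linkage
#' step behind BOLD's BIN assignment.  Cluster labels are the smallest
#' member specimen id, giving stable, deterministic output.
#'
#' @param dm A [distance_matrix()] result (no undefined pairs allowed).
#' @param threshold Linkage threshold in percent (default 2.2, the seed
#'   threshold BOLD uses for its initial single-linkage pass; the subsequent
#'   refinement is a BOLD-internal step not reproduced here).
#' @return An object of class `otu_partition`: list with `assignments`
#'   (data frame `specimen_id`, `species`, `otu`), `clusters` (named list of
#'   specimen-id vectors), and `threshold`.
#' @examples
#' aln <- bk_alignment(
#'   c(a = "AAAAAAAAAA", b = "AAAAAAAAAT", c = "GGGGGAAAAA"),
#'   species = c("sp1", "sp1", "sp2"))
#' single_linkage_otus(distance_matrix(aln, "p"), threshold = 15)
#' @export
single_linkage_otus <- function(dm, threshold = 2.2) {
  stopifnot(inherits(dm, "bk_dist"))
  if (threshold <= 0) stop("threshold must be positive")
  if (anyNA(dm$d)) {
    und <- attr(dm, "undefined")
    stop("undefined distances prevent clustering: ",
         paste(und$a, und$b, sep = "~", collapse = ", "))
  }
  d <- dm$d * 100
  n <- nrow(d)
  memb <- if (n == 1L) {
    1L
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    stats::cutree(hc, h = threshold)
  }
  ids <- dm$labels
  clusters <- split(ids, memb)
  names(clusters) <- vapply(clusters, function(m) min(m), "")
  clusters <- clusters[order(names(clusters))]
  otu <- rep(NA_character_, n)
  for (nm in names(clusters)) otu[ids %in% clusters[[nm]]] <- nm
  structure(
    list(assignments = data.frame(specimen_id = ids,
                                  species = if (is.null(dm$species)) NA_character_ else dm$species,
                                  otu = otu, stringsAsFactors = FALSE),
         clusters = clusters, threshold = threshold),
    class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("<otu_partition> %d OTUs at %.2f%% (single linkage)\n",
              length(x$clusters), x$threshold))
  invisible(x)
}

#' Taxonomic concordance report for an OTU partition
#'
#' One row per OTU: its size, the tally of species names it contains, and a
#' concordance flag.  An OTU is concordant iff exactly one species name
#' occurs in it; `"unknown"` specimens are ignored for the flag (an OTU of
#' only unknowns gets `NA`).  Discordant OTUs — several species sharing one
#' cluster — are the signature of barcode-based identification failure.
#'
#' @param partition A [single_linkage_otus()] result.
#' @param species Optional named specimen-to-species map overriding the one
#'   carried by the partition.
#' @return Data frame with columns `otu`, `n_specimens`, `n_species`,
#'   `species_tally` (e.g. `"sp A:14; sp B:43"`), `concordant`.
#' @export
concordance_report <- function(partition, species = NULL) {
  stopifnot(inherits(partition, "otu_partition"))
  asg <- partition$assignments
  sp <- if (is.null(species)) {
    stats::setNames(asg$species, asg$specimen_id)
  } else {
    species
  }
  rows <- lapply(names(partition$clusters), function(nm) {
    members <- partition$clusters[[nm]]
    labs <- sp[members]
    named <- labs[!is.na(labs) & labs != "unknown"]
    tab <- sort(table(named), decreasing = TRUE)
    data.frame(
      otu = nm,
      n_specimens = length(members),
      n_species = length(tab),
      species_tally = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                            collapse = "; "),
      concordant = if (length(tab) == 0L) NA else length(tab) == 1L,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
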