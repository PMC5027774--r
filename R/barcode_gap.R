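#' Barcode gap from a species' distance extremes
#'
#' The barcode gap is the excess of the minimum interspecific
#' (nearest-neighbour) distance over the maximum intraspecific distance.
#' A positive excess enables distance-based identification; otherwise the
#' species has "no gap".
#'
#' @param max_intra Maximum intraspecific distance (any unit, typically %).
#' @param nn_distance Minimum distance to the nearest-neighbour species, in
#'   the same unit.
#' @return The gap (`nn_distance - max_intra`) when positive, else `NA`
#'   ("no gap").
#' @examples
#' barcoding_gap(0.77, 3.50)  # 2.73
#' barcoding_gap(0.15, 0.15)  # NA: no gap
#' @export
barcoding_gap <- function(max_intra, nn_distance) {
  gap <- nn_distance - max_intra
  ifelse(!is.na(gap) & gap > 0, gap, NA_real_)
}

#' Per-species intra/interspecific distance summaries and barcode gaps
#'
#' For every named species: the mean, SD, minimum and maximum over all
#' unordered within-species specimen pairs; the nearest-neighbour species
#' (the species containing the closest heterospecific specimen); and the
#' barcode gap.  All distances are reported in percent.  Specimens labelled
#' `"unknown"` are excluded.  Singleton species have undefined (`NA`)
#' intraspecific statistics but a defined nearest neighbour.  Ties for
#' nearest neighbour report all tied species, joined alphabetically.
#'
#' @param dm A [distance_matrix()] result.
#' @param species Optional named character vector mapping specimen id to
#'   species; defaults to the species labels carried by the alignment.
#' @return Data frame of class `species_gap_summary` with one row per
#'   species: `species`, `n_specimens`, `mean_intra`, `sd_intra`,
#'   `min_intra`, `max_intra`, `nearest_neighbor`, `nn_distance`,
#'   `barcode_gap` (all distances in percent; `NA` gap means "no gap").
#' @export
species_summaries <- function(dm, species = NULL) {
  stopifnot(inherits(dm, "bk_dist"))
  sp <- resolve_species(dm, species)
  keep <- !is.na(sp) & sp != "unknown"
  if (!any(keep)) stop("no specimens with a known species label")
  d <- dm$d[keep, keep, drop = FALSE] * 100
  sp <- sp[keep]
  species_list <- sort(unique(sp))
  if (length(species_list) < 2L) {
    stop("nearest-neighbour statistics need at least 2 species")
  }
  rows <- lapply(species_list, function(s) {
    own <- sp == s
    intra <- d[own, own, drop = FALSE][upper.tri(d[own, own, drop = FALSE])]
    inter <- d[own, !own, drop = FALSE]
    nn_d <- min(inter, na.rm = TRUE)
    nn_sp <- sort(unique(sp[!own][which(
      apply(inter, 2, function(col) any(!is.na(col) & col == nn_d)))]))
    max_i <- if (length(intra)) max(intra, na.rm = TRUE) else NA_real_
    data.frame(
      species = s, n_specimens = sum(own),
      mean_intra = if (length(intra)) mean(intra, na.rm = TRUE) else NA_real_,
      sd_intra = if (length(intra) > 1L) stats::sd(intra) else NA_real_,
      min_intra = if (length(intra)) min(intra, na.rm = TRUE) else NA_real_,
      max_intra = max_i,
      nearest_neighbor = paste(nn_sp, collapse = ", "),
      nn_distance = nn_d,
      barcode_gap = barcoding_gap(max_i, nn_d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("species_gap_summary", "data.frame")
  out
}

resolve_species <- function(dm, species) {
  if (is.null(species)) {
    if (is.null(dm$species)) stop("no species labels available")
    return(stats::setNames(dm$species, dm$labels))
  }
  out <- species[dm$labels]
  if (anyNA(names(out)) || any(is.na(out))) {
    miss <- dm$labels[!dm$labels %in% names(species)]
    if (length(miss)) stop("species unknown for: ", paste(miss, collapse = ", "))
  }
  out
}

#' Pooled distance summaries at the congeneric and intergeneric level
#'
#' Pools interspecific pairwise distances into two relationship classes —
#' between species of the same genus, and between species of different
#' genera — and reports the minimum, mean and maximum of each (in percent).
#' Within-species pairs are excluded.  An empty class is omitted with a
#' message.
#'
#' @param dm A [distance_matrix()] result.
#' @param species Optional specimen-to-species map (see
#'   [species_summaries()]).
#' @param genus Optional named character vector mapping species to genus;
#'   defaults to the first word of the binomial.
#' @return Data frame with columns `level`, `n_pairs`, `min`, `mean`, `max`.
#' @export
level_summaries <- function(dm, species = NULL, genus = NULL) {
  stopifnot(inherits(dm, "bk_dist"))
  sp <- resolve_species(dm, species)
  keep <- !is.na(sp) & sp != "unknown"
  d <- dm$d[keep, keep, drop = FALSE] * 100
  sp <- sp[keep]
  if (is.null(genus)) {
    genus <- stats::setNames(vapply(strsplit(unique(sp), "\\s+"), `[`, "", 1L),
                             unique(sp))
  }
  ge <- genus[sp]
  n <- length(sp)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  same_sp <- sp[ut[, 1]] == sp[ut[, 2]]
  same_ge <- ge[ut[, 1]] == ge[ut[, 2]]
  vals <- d[ut]
  classes <- list(
    `within-genus-between-species` = vals[!same_sp & same_ge],
    `between-genera` = vals[!same_ge])
  rows <- lapply(names(classes), function(lv) {
    v <- classes[[lv]][!is.na(classes[[lv]])]
    if (!length(v)) {
      message("level_summaries: no pairs in class '", lv, "'; omitted")
      return(NULL)
    }
    data.frame(level = lv, n_pairs = length(v), min = min(v), mean = mean(v),
               max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a per-species barcode-gap summary CSV
#'
#' Columns follow the conventional distance-summary layout; percentages are
#' rounded half-up to two decimals unless `full_precision`, and an absent
#' gap is printed as `"no gap"`.
#'
#' @param summary A [species_summaries()] result.
#' @param path Output CSV path.
#' @param full_precision Keep full precision.
#' @return Invisibly, the data frame written.
#' @export
write_gap_csv <- function(summary, path, full_precision = FALSE) {
  out <- as.data.frame(summary)
  num <- c("mean_intra", "sd_intra", "min_intra", "max_intra", "nn_distance")
  if (!full_precision) out[num] <- lapply(out[num], round_half_up, digits = 2)
  out$barcode_gap <- ifelse(is.na(out$barcode_gap), "no gap",
                            if (full_precision) out$barcode_gap
                            else round_half_up(out$barcode_gap, 2))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(out)
}
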