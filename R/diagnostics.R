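#' Tabulate variable sites and detect species-diagnostic nucleotides
#'
#' Scans every alignment column and records, per species, the consensus
#' state: the shared base when all sequences of the species carry the same
#' unambiguous base there, otherwise missing.  A site is listed when at
#' least two distinct unambiguous consensus states occur across species.
#' A listed site is *diagnostic* for species `s` iff (a) every sequence of
#' `s` carries the same unambiguous base `b` there, and (b) no sequence of
#' any other species carries `b` — nor an IUPAC ambiguity code whose base
#' set contains `b` (conservative rule: an ambiguous read that could be `b`
#' disqualifies the site).  Positions are 1-based on the (primer-trimmed)
#' alignment.
#'
#' @param aln A [bk_alignment].
#' @param species Optional per-record species vector overriding the
#'   alignment's labels.
#' @return Data frame of class `diag_table`: `position`, one column of
#'   consensus states per species (`NA` = no unambiguous fixed state), and
#'   `diagnostic_for` (species name, several joined by `"; "`, or `""`).
#'   Attributes: `species`, `n_species`, `alignment_length`.
#' @examples
#' aln <- bk_alignment(c(m1 = "ACGT", m2 = "ACGT", t1 = "AGGT", t2 = "AGGT"),
#'                     species = rep(c("sp m", "sp t"), each = 2))
#' diagnostic_sites(aln)
#' @export
diagnostic_sites <- function(aln, species = NULL) {
  stopifnot(inherits(aln, "bk_alignment"))
  sp <- if (is.null(species)) aln$species else as.character(species)
  groups <- split(seq_along(sp), sp)
  if (length(groups) < 2L) stop("need at least 2 species")
  if (any(!lengths(groups))) stop("empty species group")
  sp_names <- names(groups)
  L <- aln$length
  bases <- c("A", "C", "G", "T")

  # per-species consensus state at each column (NA unless fixed unambiguous)
  cons <- vapply(groups, function(idx) {
    sub <- aln$seq[idx, , drop = FALSE]
    apply(sub, 2L, function(col) {
      u <- unique(col)
      if (length(u) == 1L && u %in% bases) u else NA_character_
    })
  }, character(L))
  if (L == 1L) cons <- matrix(cons, nrow = 1L, dimnames = list(NULL, sp_names))

  variable <- which(apply(cons, 1L, function(r) length(unique(r[!is.na(r)])) >= 2L))
  diag_for <- character(length(variable))
  for (k in seq_along(variable)) {
    pos <- variable[k]
    hits <- character(0)
    for (s in sp_names) {
      b <- cons[pos, s]
      if (is.na(b)) next
      others <- unlist(lapply(groups[sp_names != s], function(idx) aln$seq[idx, pos]))
      compatible <- vapply(others, function(ch) b %in% BK_IUPAC[[ch]], TRUE)
      if (!any(compatible)) hits <- c(hits, s)
    }
    diag_for[k] <- paste(hits, collapse = "; ")
  }
  out <- data.frame(position = variable, stringsAsFactors = FALSE)
  for (s in sp_names) out[[s]] <- cons[variable, s]
  out$diagnostic_for <- diag_for
  structure(out, species = sp_names, n_species = length(sp_names),
            alignment_length = L, class = c("diag_table", "data.frame"))
}

#' Multi-site combination signature of a species
#'
#' The species' consensus states across all variable sites.  A species
#' without any pure diagnostic site can still be identified when this
#' combination differs from every other species' combination (the
#' fallback that rescues identification when no single site is fixed and
#' exclusive).
#'
#' @param table A [diagnostic_sites()] result.
#' @param species Species name present in the table.
#' @return Character vector of states (named by position) with attribute
#'   `identifiable`: `TRUE` iff the vector differs from every other
#'   species' vector.
#' @export
combination_signature <- function(table, species) {
  stopifnot(inherits(table, "diag_table"))
  all_sp <- attr(table, "species")
  if (!species %in% all_sp) stop("species not in table: ", species)
  sig <- function(s) stats::setNames(as.character(table[[s]]),
                                     table$position)
  mine <- sig(species)
  clash <- vapply(setdiff(all_sp, species),
                  function(s) identical(unname(sig(s)), unname(mine)), TRUE)
  attr(mine, "identifiable") <- !any(clash)
  mine
}

#' Count pure diagnostic sites per species
#'
#' @param table A [diagnostic_sites()] result.
#' @return Named integer vector over all species in the table (zeros
#'   included).
#' @export
count_diagnostics <- function(table) {
  stopifnot(inherits(table, "diag_table"))
  sp <- attr(table, "species")
  counts <- stats::setNames(integer(length(sp)), sp)
  if (nrow(table)) {
    hits <- unlist(strsplit(table$diagnostic_for[nzchar(table$diagnostic_for)],
                            "; ", fixed = TRUE))
    for (h in hits) counts[h] <- counts[h] + 1L
  }
  counts
}

#' Write a diagnostic-site table as CSV
#'
#' @param table A [diagnostic_sites()] result.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_diagnostics_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "",
                   quote = TRUE)
  invisible(table)
}
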