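#' @keywords internal
"_PACKAGE"

# Allowed residue alphabet: the four bases, IUPAC ambiguity codes, gap.
BK_ALPHABET <- c("A", "C", "G", "T",
                 "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# IUPAC code -> set of compatible unambiguous bases
BK_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = character(0)
)

#' Construct an alignment of labelled specimen sequences
#'
#' An alignment couples equal-length DNA sequences with per-specimen
#' metadata (species and marker labels).  It is the substrate for every
#' molecular stage: distance matrices, trees, barcode-gap summaries, OTU
#' clustering and diagnostic-site detection.
#'
#' @param sequences Character vector of equal-length DNA sequences
#'   (IUPAC codes and `-` allowed; case-insensitive), named by specimen id
#'   unless `specimen_id` is given.
#' @param species Character vector of species labels (binomials). Missing or
#'   empty labels are stored as `"unknown"`; such specimens are kept in trees
#'   and clustering but excluded from species-wise statistics.
#' @param specimen_id Character vector of unique specimen identifiers.
#' @param marker Marker name(s), e.g. `"COI"` or `"Rhodopsin"`. Recycled.
#' @return An object of class `bk_alignment`: a list with elements
#'   `specimen_id`, `species`, `marker`, `length`, and `seq` (an
#'   `n x length` character matrix of upper-case residues, one row per
#'   specimen).
#' @examples
#' aln <- bk_alignment(c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC"),
#'                     species = c("Ammodytes marinus", "Ammodytes marinus"))
#' aln$length
#' @export
bk_alignment <- function(sequences, species = NULL, specimen_id = names(sequences),
                         marker = "COI") {
  if (is.null(specimen_id)) {
    stop("specimen ids are required (names of `sequences` or `specimen_id`)")
  }
  specimen_id <- as.character(specimen_id)
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 2L) stop("an alignment needs at least 2 records")
  if (length(specimen_id) != n) stop("one specimen_id per sequence required")
  if (anyDuplicated(specimen_id)) {
    stop("duplicate specimen_id: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "))
  }
  if (any(!nzchar(specimen_id))) stop("specimen_id must be non-empty")
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence for: ",
                            paste(specimen_id[lens == 0L], collapse = ", "))
  if (length(unique(lens)) != 1L) {
    off <- specimen_id[lens != lens[1L]]
    stop("unequal sequence lengths (not an alignment); offending records: ",
         paste(off, collapse = ", "))
  }
  if (is.null(species)) species <- rep("unknown", n)
  species <- as.character(species)
  species[is.na(species) | !nzchar(species)] <- "unknown"
  if (length(species) != n) stop("one species label per sequence required")
  marker <- rep_len(as.character(marker), n)

  seq_mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(seq_mat) <- specimen_id
  bad <- !(seq_mat %in% BK_ALPHABET)
  if (any(bad)) {
    chars <- unique(seq_mat[bad])
    stop("invalid residue characters: ", paste(chars, collapse = " "))
  }
  structure(
    list(specimen_id = specimen_id, species = species, marker = marker,
         length = unname(lens[1L]), seq = seq_mat),
    class = "bk_alignment"
  )
}

#' @export
print.bk_alignment <- function(x, ...) {
  cat(sprintf("<bk_alignment> %d records x %d sites (%s)\n",
              length(x$specimen_id), x$length,
              paste(unique(x$marker), collapse = ", ")))
  tab <- table(x$species)
  cat("species:", paste(sprintf("%s (%d)", names(tab), tab), collapse = "; "),
      "\n")
  invisible(x)
}

#' @export
length.bk_alignment <- function(x) length(x$specimen_id)

#' Subset an alignment by record
#'
#' @param x A `bk_alignment`.
#' @param i Index vector (numeric, logical, or specimen ids).
#' @param ... Unused.
#' @return A `bk_alignment` with the selected records.
#' @export
`[.bk_alignment` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$specimen_id)
  bk_alignment(apply(x$seq[i, , drop = FALSE], 1L, paste, collapse = ""),
               species = x$species[i], specimen_id = x$specimen_id[i],
               marker = x$marker[i])
}

#' Sequences of an alignment as strings
#'
#' @param aln A `bk_alignment`.
#' @return Named character vector of sequences.
#' @export
alignment_strings <- function(aln) {
  stopifnot(inherits(aln, "bk_alignment"))
  stats::setNames(apply(aln$seq, 1L, paste, collapse = ""), aln$specimen_id)
}

#' Read a FASTA alignment together with specimen metadata
#'
#' The FASTA identifier (up to the first whitespace) is the join key into the
#' metadata table, which must have columns `specimen_id`, `species` and
#' `marker` and exactly one row per FASTA record.  Sequences are upper-cased;
#' records keep FASTA order.
#'
#' @param fasta_path Path to a FASTA file of equal-length (aligned) sequences.
#' @param metadata_path Path to a TSV or CSV metadata table with a header row.
#'   The delimiter is taken from the file extension (`.csv` is
#'   comma-separated, anything else tab-separated).
#' @return A [bk_alignment].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGAACGTAC"), fa)
#' md <- tempfile(fileext = ".csv")
#' writeLines(c("specimen_id,species,marker",
#'              "s1,Ammodytes marinus,COI",
#'              "s2,Ammodytes tobianus,COI"), md)
#' aln <- read_fasta_with_metadata(fa, md)
#' @export
read_fasta_with_metadata <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- read_metadata(metadata_path)
  missing <- setdiff(ids, meta$specimen_id)
  if (length(missing)) {
    stop("FASTA ids missing from metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  bk_alignment(as.character(seqs), species = meta$species,
               specimen_id = ids, marker = meta$marker)
}

read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "")
  need <- c("specimen_id", "species", "marker")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta$specimen_id <- as.character(meta$specimen_id)
  if (anyDuplicated(meta$specimen_id)) {
    stop("duplicate specimen_id in metadata: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  }
  meta
}

#' Write an alignment to FASTA and its metadata to TSV
#'
#' @param aln A [bk_alignment].
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output TSV path for the specimen table.
#' @return Invisibly, `aln`.
#' @export
write_fasta_with_metadata <- function(aln, fasta_path, metadata_path = NULL) {
  stopifnot(inherits(aln, "bk_alignment"))
  x <- Biostrings::DNAStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(metadata_path)) {
    utils::write.table(
      data.frame(specimen_id = aln$specimen_id, species = aln$species,
                 marker = aln$marker, stringsAsFactors = FALSE),
      metadata_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(aln)
}

#' Write a tree to Newick, filtering bootstrap labels by support
#'
#' Internal-node bootstrap values are written as node labels only when they
#' reach `min_support`; common practice in barcoding dendrograms is to show
#' only values of at least 50.
#'
#' @param tree An `ape` `phylo` object, optionally with numeric
#'   `node.label` bootstrap percentages (as produced by
#'   [bootstrap_support()]).
#' @param path Output file path.
#' @param min_support Minimum support (percent) for a label to be written.
#'   Use 0 to write all supports.
#' @return Invisibly, the Newick string written.
#' @export
write_newick <- function(tree, path, min_support = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    lab <- ifelse(!is.na(sup) & sup >= min_support,
                  formatC(sup, format = "fg"), "")
    tree$node.label <- lab
  }
  txt <- ape::write.tree(tree)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write tree to ", path)
  invisible(txt)
}
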