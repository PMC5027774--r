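#' Default identification-key configuration for northeast Atlantic sand lances
#'
#' Per-species qualitative states and numeric character ranges for the four
#' species (Ammodytes marinus, A. tobianus, Hyperoplus immaculatus,
#' H. lanceolatus), derived from published per-species character ranges.
#' Genus assignment rests on the protrusibility of the premaxillae (PCP),
#' the presence of the hooked prevomer ends that read as "vomerine teeth"
#' (VTP), the dermal plica count (DP), and pectoral-fin length in %SL (PFL).
#' Within Hyperoplus, the snout spot (DSSS) and the gill-raker/vertebra/fin
#' ray counts separate the species; within Ammodytes, the squamation
#' characters (BSTC, SBCF, SADF) and the plica/ray/vertebra counts.
#'
#' @return A list of class `bk_key` with elements `genus` (per-genus
#'   qualitative states and numeric ranges) and `species` (per-species
#'   qualitative states, numeric ranges and genus membership).
#' @export
sandlance_key <- function() {
  key <- list(
    genus = list(
      Ammodytes = list(
        qualitative = c(PCP = "yes", VTP = "no"),
        ranges = list(DP = c(123, 150), PFL = c(8.6, 11.9))),
      Hyperoplus = list(
        qualitative = c(PCP = "no", VTP = "yes"),
        ranges = list(DP = c(169, 196), PFL = c(6.7, 8.7)))),
    species = list(
      `Ammodytes marinus` = list(
        genus = "Ammodytes",
        qualitative = c(BSTC = "no", SBCF = "no", SADF = "no"),
        ranges = list(DP = c(140, 150), DR = c(56, 62), PV = c(42, 44),
                      TV = c(68, 71))),
      `Ammodytes tobianus` = list(
        genus = "Ammodytes",
        qualitative = c(BSTC = "yes", SBCF = "yes", SADF = "yes"),
        ranges = list(DP = c(123, 135), DR = c(51, 55), PV = c(36, 41),
                      TV = c(60, 66))),
      `Hyperoplus immaculatus` = list(
        genus = "Hyperoplus",
        qualitative = c(DSSS = "no"),
        ranges = list(LR = c(23, 25), GR = c(28, 30), CV = c(29, 30),
                      TV = c(72, 73), DR = c(59, 61), AR = c(31, 32))),
      `Hyperoplus lanceolatus` = list(
        genus = "Hyperoplus",
        qualitative = c(DSSS = "yes"),
        ranges = list(LR = c(20, 22), GR = c(25, 27), CV = c(25, 28),
                      TV = c(65, 68), DR = c(54, 57), AR = c(28, 30))))
  )
  class(key) <- "bk_key"
  key
}

#' Rule-based morphological identification of a specimen
#'
#' Two-stage key: genus first (each available genus character votes for the
#' genus whose expected state or range it matches; a character falling in
#' both genera's ranges abstains), then species within the assigned genus
#' (fraction of matching characters among those available).  Ambiguity —
#' a genus vote tie, a species score tie, or no usable characters — yields
#' `"indeterminate"` with the conflict recorded.  PFL is standardized to
#' %SL internally when `SL_mm` is present.
#'
#' @param specimen A single-row data frame (or list) in the
#'   [read_morph_table()] layout; missing characters are simply skipped.
#' @param key_config Key configuration, default [sandlance_key()].
#' @return A list of class `bk_key_call`: `genus`, `species`, `status`
#'   (`"ok"` or `"indeterminate"`), `confidence` (matched/assessed characters
#'   of the winning species), `evidence` (data frame of characters consulted,
#'   values, and the taxa they support), `conflict` (character vector,
#'   empty when unambiguous).
#' @examples
#' identification_key(list(PCP = "yes", VTP = "no", DP = 130, BSTC = "yes"))
#' identification_key(list(PCP = "no", LR = 24))
#' @export
identification_key <- function(specimen, key_config = sandlance_key()) {
  x <- as.list(specimen)
  for (q in BK_QUALITATIVE) {
    if (!is.null(x[[q]]) && !is.na(x[[q]])) x[[q]] <- tolower(as.character(x[[q]]))
  }
  # PFL must be in %SL for the range comparison
  if (!is.null(x$PFL) && !is.na(x$PFL) && !is.null(x$SL_mm) && !is.na(x$SL_mm)) {
    x$PFL <- standardize_percent_sl(x$PFL, x$SL_mm)
  }
  has <- function(ch) !is.null(x[[ch]]) && !is.na(x[[ch]]) && x[[ch]] != "unknown"
  in_range <- function(v, r) v >= r[1] && v <= r[2]

  evidence <- list()
  note <- function(ch, val, supports) {
    evidence[[length(evidence) + 1L]] <<- data.frame(
      character = ch, value = as.character(val), supports = supports,
      stringsAsFactors = FALSE)
  }

  # ---- genus stage -------------------------------------------------------
  genera <- names(key_config$genus)
  votes <- stats::setNames(numeric(length(genera)), genera)
  all_q <- unique(unlist(lapply(key_config$genus, function(g) names(g$qualitative))))
  for (ch in all_q) {
    if (!has(ch)) next
    for (ge in genera) {
      expect <- key_config$genus[[ge]]$qualitative[[ch]]
      if (!is.null(expect) && x[[ch]] == expect) {
        votes[ge] <- votes[ge] + 1
        note(ch, x[[ch]], ge)
      }
    }
  }
  all_r <- unique(unlist(lapply(key_config$genus, function(g) names(g$ranges))))
  for (ch in all_r) {
    if (!has(ch)) next
    inside <- vapply(genera, function(ge) {
      r <- key_config$genus[[ge]]$ranges[[ch]]
      !is.null(r) && in_range(x[[ch]], r)
    }, TRUE)
    if (sum(inside) == 1L) {  # a value in both ranges is uninformative
      votes[genera[inside]] <- votes[genera[inside]] + 1
      note(ch, x[[ch]], genera[inside])
    }
  }
  ev_df <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(character = character(0), value = character(0),
               supports = character(0), stringsAsFactors = FALSE)

  result <- function(genus, species, status, confidence, conflict) {
    structure(list(genus = genus, species = species, status = status,
                   confidence = confidence, evidence = ev_df,
                   conflict = conflict), class = "bk_key_call")
  }
  if (all(votes == 0)) {
    return(result(NA_character_, NA_character_, "indeterminate", NA_real_,
                  "no usable genus character"))
  }
  top <- genera[votes == max(votes)]
  if (length(top) > 1L) {
    return(result(NA_character_, NA_character_, "indeterminate", NA_real_,
                  paste("genus vote tie:", paste(top, collapse = " vs "))))
  }
  genus <- top

  # ---- species stage -----------------------------------------------------
  cands <- names(Filter(function(s) s$genus == genus, key_config$species))
  scores <- lapply(cands, function(s) {
    cfg <- key_config$species[[s]]
    matched <- 0L
    assessed <- 0L
    for (ch in names(cfg$qualitative)) {
      if (!has(ch)) next
      assessed <- assessed + 1L
      if (x[[ch]] == cfg$qualitative[[ch]]) {
        matched <- matched + 1L
        note(ch, x[[ch]], s)
      }
    }
    for (ch in names(cfg$ranges)) {
      if (!has(ch)) next
      assessed <- assessed + 1L
      if (in_range(x[[ch]], cfg$ranges[[ch]])) {
        matched <- matched + 1L
        note(ch, x[[ch]], s)
      }
    }
    c(matched = matched, assessed = assessed)
  })
  names(scores) <- cands
  ev_df <- do.call(rbind, evidence)
  assessed <- vapply(scores, `[[`, 0L, "assessed")
  matched <- vapply(scores, `[[`, 0L, "matched")
  if (all(assessed == 0L)) {
    return(result(genus, NA_character_, "indeterminate", NA_real_,
                  "no usable species character"))
  }
  frac <- ifelse(assessed > 0, matched / assessed, -Inf)
  best <- cands[frac == max(frac)]
  if (length(best) > 1L) {
    return(result(genus, NA_character_, "indeterminate", NA_real_,
                  paste("species score tie:", paste(best, collapse = " vs "))))
  }
  result(genus, best, "ok", frac[[best]], character(0))
}

#' @export
print.bk_key_call <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("%s (genus %s), %.0f%% of assessed characters in agreement\n",
                x$species, x$genus, 100 * x$confidence))
  } else {
    cat("indeterminate:", paste(x$conflict, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Apply the identification key to every specimen of a morphology table
#'
#' @param t A [read_morph_table()] data frame or CSV path.
#' @param key_config Key configuration, default [sandlance_key()].
#' @return Data frame with `specimen_id`, recorded `species` (if any),
#'   `genus_call`, `species_call`, `status`, `confidence`.
#' @export
identify_specimens <- function(t, key_config = sandlance_key()) {
  t <- read_morph_table(t)
  calls <- lapply(seq_len(nrow(t)), function(i)
    identification_key(t[i, , drop = FALSE], key_config))
  data.frame(
    specimen_id = t$specimen_id,
    species = if ("species" %in% names(t)) t$species else NA_character_,
    genus_call = vapply(calls, function(cl) cl$genus %||% NA_character_, ""),
    species_call = vapply(calls, function(cl) cl$species %||% NA_character_, ""),
    status = vapply(calls, `[[`, "", "status"),
    confidence = vapply(calls, function(cl) cl$confidence %||% NA_real_, 0),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
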