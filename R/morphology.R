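# Character sets of the morphology table, keyed by the field's customary
# abbreviations.
BK_MERISTICS <- c("DP", "DR", "AR", "PR", "CR", "UR", "LR", "GR", "PV", "CV", "TV")
BK_MEASUREMENTS <- c("BDD", "BDA", "BWD", "HL", "SNL", "OD", "IW", "UJL",
                     "CPD", "CPL", "PPL", "PDL", "PAL", "PFL", "DFBL",
                     "AFBL", "CFL", "DFH", "AFH")
BK_QUALITATIVE <- c("MDAS", "BCOP", "PCP", "VTP", "DSSS", "BSTC", "SBCF", "SADF")
# composite counts derived from parts: excluded from multivariate analyses
BK_COMPOSITES <- c(GR = "UR+LR", TV = "PV+CV")

#' Read and validate a specimen morphology table
#'
#' The CSV must have a header row with `specimen_id`, `species`, `SL_mm`
#' (standard length in mm), and any subset of the meristic counts
#' (`DP, DR, AR, PR, CR, UR, LR, GR, PV, CV, TV`), raw measurements in mm
#' (`BDD, BDA, BWD, HL, SNL, OD, IW, UJL, CPD, CPL, PPL, PDL, PAL, PFL,
#' DFBL, AFBL, CFL, DFH, AFH`) and qualitative yes/no characters
#' (`MDAS, BCOP, PCP, VTP, DSSS, BSTC, SBCF, SADF`).  Missing values are
#' allowed.  Part-sum consistency (`GR = UR + LR`, `TV = PV + CV`) is
#' checked wherever all parts are present.
#'
#' @param path CSV path, or a data frame already in this layout.
#' @return The validated data frame of class `morph_table`.
#' @export
read_morph_table <- function(path) {
  t <- if (is.data.frame(path)) {
    as.data.frame(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("specimen_id", "species", "SL_mm")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("morphology table lacks column(s): ",
                         paste(miss, collapse = ", "))
  t$specimen_id <- as.character(t$specimen_id)
  if (anyDuplicated(t$specimen_id)) {
    stop("duplicate specimen_id: ",
         paste(unique(t$specimen_id[duplicated(t$specimen_id)]), collapse = ", "))
  }
  if (any(!is.na(t$SL_mm) & t$SL_mm <= 0)) stop("SL_mm must be positive")
  for (m in intersect(BK_MERISTICS, names(t))) {
    if (any(!is.na(t[[m]]) & t[[m]] < 0)) stop("negative count in ", m)
  }
  if (all(c("GR", "UR", "LR") %in% names(t))) {
    ok <- stats::complete.cases(t[c("GR", "UR", "LR")])
    if (any(t$GR[ok] != t$UR[ok] + t$LR[ok])) {
      warning("GR != UR + LR for: ",
              paste(t$specimen_id[ok][t$GR[ok] != t$UR[ok] + t$LR[ok]],
                    collapse = ", "))
    }
  }
  if (all(c("TV", "PV", "CV") %in% names(t))) {
    ok <- stats::complete.cases(t[c("TV", "PV", "CV")])
    if (any(t$TV[ok] != t$PV[ok] + t$CV[ok])) {
      warning("TV != PV + CV for: ",
              paste(t$specimen_id[ok][t$TV[ok] != t$PV[ok] + t$CV[ok]],
                    collapse = ", "))
    }
  }
  for (q in intersect(BK_QUALITATIVE, names(t))) {
    t[[q]] <- tolower(as.character(t[[q]]))
    bad <- !is.na(t[[q]]) & !t[[q]] %in% c("yes", "no", "unknown")
    if (any(bad)) stop("qualitative column ", q,
                       " must be yes/no/unknown; offending: ",
                       paste(unique(t[[q]][bad]), collapse = ", "))
  }
  class(t) <- c("morph_table", "data.frame")
  t
}

#' Standardize a measurement to percent of standard length
#'
#' Morphometric measurements are expressed as a proportion of standard
#' length so that specimens of different size are comparable:
#' `raw * 100 / SL`.
#'
#' @param raw_mm Measurement in mm (vectorized).
#' @param sl_mm Standard length in mm (vectorized).
#' @return Measurement as %SL.
#' @examples
#' standardize_percent_sl(43.4, 200)  # 21.7
#' @export
standardize_percent_sl <- function(raw_mm, sl_mm) {
  if (any(!is.na(raw_mm) & raw_mm <= 0) || any(!is.na(sl_mm) & sl_mm <= 0)) {
    stop("measurements and standard length must be positive")
  }
  raw_mm * 100 / sl_mm
}

# %SL versions of all measurement columns present
percent_sl_columns <- function(t) {
  out <- t
  for (m in intersect(BK_MEASUREMENTS, names(t))) {
    out[[m]] <- standardize_percent_sl(t[[m]], t$SL_mm)
  }
  out
}

#' Per-species character summaries (range; mean +/- SD; n)
#'
#' For every species and character: the range, the mean with sample standard
#' deviation, and the number of specimens with the character recorded.
#' Measurements are summarized in %SL, standard length in mm, meristics as
#' counts; qualitative characters are summarized by their tally of states.
#'
#' @param t A [read_morph_table()] data frame (measurements in mm).
#' @return Data frame with columns `species`, `character`, `type`, `n`,
#'   `min`, `max`, `mean`, `sd`, and `summary` — the conventional
#'   `"min–max; mean ± sd (n)"` rendering.
#' @export
summarize_characters <- function(t) {
  t <- read_morph_table(t)
  tp <- percent_sl_columns(t)
  num_chars <- c(SL_mm = "SL",
                 stats::setNames(rep("meristic", length(BK_MERISTICS)), BK_MERISTICS),
                 stats::setNames(rep("measurement_pctSL", length(BK_MEASUREMENTS)),
                                 BK_MEASUREMENTS))
  num_chars <- num_chars[names(num_chars) %in% names(tp)]
  rows <- list()
  for (s in sort(unique(t$species))) {
    sub <- tp[tp$species == s, , drop = FALSE]
    for (ch in names(num_chars)) {
      v <- sub[[ch]][!is.na(sub[[ch]])]
      n <- length(v)
      if (!n) next
      m <- mean(v)
      sdv <- if (n > 1L) stats::sd(v) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, character = ch, type = unname(num_chars[ch]), n = n,
        min = min(v), max = max(v), mean = m, sd = sdv,
        summary = format_character_summary(min(v), max(v), m, sdv, n),
        stringsAsFactors = FALSE)
    }
    for (q in intersect(BK_QUALITATIVE, names(sub))) {
      v <- sub[[q]][!is.na(sub[[q]]) & sub[[q]] != "unknown"]
      if (!length(v)) next
      tab <- sort(table(v), decreasing = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, character = q, type = "qualitative", n = length(v),
        min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_,
        summary = paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                        collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

format_character_summary <- function(mn, mx, mean, sd, n) {
  fmt <- function(x) {
    if (isTRUE(all.equal(x, round(x))) && abs(x - round(x)) < 1e-9) {
      sprintf("%d", as.integer(round(x)))
    } else {
      sprintf("%.1f", x)
    }
  }
  range_part <- if (mn == mx) fmt(mn) else sprintf("%s–%s", fmt(mn), fmt(mx))
  if (n == 1L) return(sprintf("%s (1)", range_part))
  sprintf("%s; %.1f ± %.1f (%d)", range_part, mean, sd, n)
}

#' Select variables for a discriminant analysis
#'
#' Mirrors the customary pre-filtering for multi-group discriminant analysis
#' of mixed fish characters: qualitative characters are excluded, composite
#' counts that are sums of other counts (total gill rakers `GR`, total
#' vertebrae `TV`) are excluded, and variables without any variation (e.g. a
#' principal caudal-fin ray count fixed at 15) are excluded.  Meristic mode
#' works on counts; morphometric mode on the %SL measurements.
#'
#' @param t A [read_morph_table()] data frame.
#' @param mode `"meristic"` or `"morphometric"`.
#' @return Character vector of retained column names, with attribute
#'   `dropped` (named reasons for each exclusion).
#' @export
select_dfa_variables <- function(t, mode = c("meristic", "morphometric")) {
  t <- read_morph_table(t)
  mode <- match.arg(mode)
  cand <- if (mode == "meristic") {
    intersect(BK_MERISTICS, names(t))
  } else {
    intersect(BK_MEASUREMENTS, names(t))
  }
  tp <- if (mode == "morphometric") percent_sl_columns(t) else t
  dropped <- character(0)
  keep <- character(0)
  for (v in cand) {
    if (v %in% names(BK_COMPOSITES)) {
      dropped[v] <- paste0("composite (", BK_COMPOSITES[[v]], ")")
      next
    }
    x <- tp[[v]][!is.na(tp[[v]])]
    if (length(x) < 2L || diff(range(x)) <= 1e-9 * max(1, max(abs(x)))) {
      dropped[v] <- "no variation"
      next
    }
    keep <- c(keep, v)
  }
  structure(keep, dropped = dropped)
}
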