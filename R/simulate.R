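#' Configuration for the sequence simulator
#'
#' Describes a star-shaped haplotype structure: a random root sequence, one
#' consensus per species obtained by planting species-specific substitutions
#' into the root, and per-specimen intraspecific mutations added on top.
#' This is the minimal structure under which barcode gaps, diagnostic sites
#' and OTU clustering have a known ground truth.
#'
#' @param species List of per-species specs: each a list with `name`,
#'   `n_specimens`, and optionally `planted`, a data frame with columns
#'   `position` and `base` giving that species' fixed substitutions.
#' @param root_length Alignment length in bp.
#' @param intraspecific_rate Per-site, per-specimen substitution probability
#'   on top of the species consensus (0 = clonal haplotypes).
#' @param protect_planted_sites If `TRUE` (default), intraspecific mutations
#'   never hit any planted column, so planted diagnostics stay clean.
#' @param transition_bias Ratio of transition to transversion probability
#'   for intraspecific mutations (default 2, a typical mitochondrial bias).
#' @param root_states Optional named character vector pinning root bases at
#'   given positions (names = 1-based positions), used to reconstruct
#'   published site patterns exactly.
#' @param marker Marker name recorded in the alignment.
#' @return A validated list of class `seq_sim_config`.
#' @export
seq_sim_config <- function(species, root_length, intraspecific_rate = 0,
                           protect_planted_sites = TRUE, transition_bias = 2,
                           root_states = NULL, marker = "sim") {
  stopifnot(root_length >= 1, intraspecific_rate >= 0, intraspecific_rate <= 1,
            transition_bias > 0)
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("species names must be unique")
  for (s in species) {
    if (is.null(s$n_specimens) || s$n_specimens < 1) {
      stop("each species needs n_specimens >= 1")
    }
    if (!is.null(s$planted) && nrow(s$planted)) {
      if (any(s$planted$position < 1 | s$planted$position > root_length)) {
        stop("planted position outside [1, root_length] for ", s$name)
      }
      if (!all(s$planted$base %in% c("A", "C", "G", "T"))) {
        stop("planted bases must be unambiguous (A/C/G/T)")
      }
    }
  }
  if (!is.null(root_states)) {
    stopifnot(all(as.integer(names(root_states)) >= 1),
              all(as.integer(names(root_states)) <= root_length),
              all(root_states %in% c("A", "C", "G", "T")))
  }
  structure(list(species = species, root_length = as.integer(root_length),
                 intraspecific_rate = intraspecific_rate,
                 protect_planted_sites = isTRUE(protect_planted_sites),
                 transition_bias = transition_bias,
                 root_states = root_states, marker = marker),
            class = "seq_sim_config")
}

#' Simulate an alignment with planted species-specific substitutions
#'
#' Draws a uniform-random root sequence (with any pinned positions applied),
#' derives each species' consensus by planting its substitutions, then adds
#' independent per-site intraspecific mutations to each specimen.  A mutated
#' site becomes the transition base with probability
#' `transition_bias / (transition_bias + 1)`, otherwise one of the two
#' transversion bases uniformly.  Deterministic for a fixed seed.
#'
#' @param cfg A [seq_sim_config()].
#' @param seed Integer seed.
#' @return List with `alignment` (a [bk_alignment]) and `truth`: `root`,
#'   `consensus` (named character vector of species consensus sequences),
#'   and `planted` (per-species data frames of planted sites).
#' @export
simulate_alignment <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "seq_sim_config"))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- cfg$root_length
  root <- sample(bases, L, replace = TRUE)
  if (!is.null(cfg$root_states)) {
    root[as.integer(names(cfg$root_states))] <- cfg$root_states
  }
  planted_cols <- integer(0)
  consensus <- list()
  for (s in cfg$species) {
    cons <- root
    if (!is.null(s$planted) && nrow(s$planted)) {
      clash <- root[s$planted$position] == s$planted$base
      if (any(clash)) {
        stop("planted base equals the root base at position ",
             paste(s$planted$position[clash], collapse = ", "), " for ", s$name)
      }
      cons[s$planted$position] <- s$planted$base
      planted_cols <- union(planted_cols, s$planted$position)
    }
    consensus[[s$name]] <- cons
  }
  mutable <- if (cfg$protect_planted_sites) setdiff(seq_len(L), planted_cols)
             else seq_len(L)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  p_ts <- cfg$transition_bias / (cfg$transition_bias + 1)

  ids <- character(0); sp <- character(0); seqs <- character(0)
  for (s in cfg$species) {
    cons <- consensus[[s$name]]
    tag <- gsub("[^A-Za-z0-9]+", "_", s$name)
    for (i in seq_len(s$n_specimens)) {
      seq_i <- cons
      if (cfg$intraspecific_rate > 0 && length(mutable)) {
        hit <- mutable[stats::runif(length(mutable)) < cfg$intraspecific_rate]
        for (posn in hit) {
          b <- seq_i[posn]
          seq_i[posn] <- if (stats::runif(1) < p_ts) transition[[b]] else
            sample(setdiff(bases, c(b, transition[[b]])), 1L)
        }
      }
      ids <- c(ids, sprintf("%s_%02d", tag, i))
      sp <- c(sp, s$name)
      seqs <- c(seqs, paste(seq_i, collapse = ""))
    }
  }
  aln <- bk_alignment(seqs, species = sp, specimen_id = ids,
                      marker = cfg$marker)
  truth <- list(root = paste(root, collapse = ""),
                consensus = vapply(consensus, paste, "", collapse = ""),
                planted = stats::setNames(
                  lapply(cfg$species, function(s) s$planted),
                  vapply(cfg$species, `[[`, "", "name")))
  list(alignment = aln, truth = truth)
}

#' Rhodopsin-style simulator configuration for the four sand lance species
#'
#' Reconstructs the published nuclear Rhodopsin site pattern: a 464-bp
#' fragment in which A. marinus is fixed for C at site 460, H. lanceolatus
#' for T at site 82, H. immaculatus for A at site 433, and A. tobianus
#' carries the shared states (C, G, A) at those three sites and nothing of
#' its own.  Group sizes 27/7/30/8 match the published comparison (study
#' specimens plus GenBank records).  Intraspecific rate defaults to 0, as
#' the real fragment shows no within-species variation at these sites.
#'
#' @param intraspecific_rate Per-site mutation rate, default 0.
#' @return A [seq_sim_config()].
#' @export
sandlance_rhodopsin_config <- function(intraspecific_rate = 0) {
  seq_sim_config(
    species = list(
      list(name = "Ammodytes marinus", n_specimens = 27,
           planted = data.frame(position = 460, base = "C")),
      list(name = "Ammodytes tobianus", n_specimens = 7, planted = NULL),
      list(name = "Hyperoplus lanceolatus", n_specimens = 30,
           planted = data.frame(position = 82, base = "T")),
      list(name = "Hyperoplus immaculatus", n_specimens = 8,
           planted = data.frame(position = 433, base = "A"))),
    root_length = 464,
    intraspecific_rate = intraspecific_rate,
    root_states = c(`82` = "C", `433` = "G", `460` = "A"),
    marker = "Rhodopsin")
}

#' COI-style simulator configuration for the four sand lance species
#'
#' Emulates the structure of the mitochondrial barcode dataset: A. marinus
#' and H. immaculatus are mutual nearest neighbours around 3.5% apart, each
#' with a clear barcode gap and its own OTU, while A. tobianus and
#' H. lanceolatus differ by a single fixed site each (~0.3%), so they
#' co-cluster at the usual OTU threshold and show no usable gap.  A. marinus
#' carries 30 fixed substitutions relative to the tobianus-like root;
#' H. immaculatus shares 20 of them (a common divergent history) plus 13
#' private ones.  Per-pair substitution counts are a modelling choice — the
#' real per-haplotype differences are not published — set once so that the
#' pairwise distances fall in the observed congeneric/intergeneric ranges.
#' Group sizes 27/6/29/8 match the barcode dataset.
#'
#' @param intraspecific_rate Per-site mutation rate, default 5e-4 (about
#'   0.1–0.3% intraspecific distances on a 652-bp fragment).
#' @param seed_positions Base position offset for the planted blocks.
#' @return A [seq_sim_config()].
#' @export
sandlance_coi_config <- function(intraspecific_rate = 5e-4,
                                 seed_positions = 10L) {
  L <- 652L
  block <- function(start, k, base) {
    data.frame(position = seq(start, by = 3L, length.out = k),
               base = base, stringsAsFactors = FALSE)
  }
  pos <- seed_positions
  # root pinned to A at planted columns so substitutions are guaranteed valid
  planted_am <- block(pos, 30L, "G")
  planted_hi <- rbind(planted_am[seq_len(20L), ],
                      block(pos + 300L, 13L, "C"))
  planted_at <- data.frame(position = pos + 440L, base = "T")
  planted_hl <- data.frame(position = pos + 443L, base = "G")
  all_pos <- c(planted_am$position, planted_hi$position,
               planted_at$position, planted_hl$position)
  seq_sim_config(
    species = list(
      list(name = "Ammodytes marinus", n_specimens = 27, planted = planted_am),
      list(name = "Ammodytes tobianus", n_specimens = 6, planted = planted_at),
      list(name = "Hyperoplus lanceolatus", n_specimens = 29,
           planted = planted_hl),
      list(name = "Hyperoplus immaculatus", n_specimens = 8,
           planted = planted_hi)),
    root_length = L,
    intraspecific_rate = intraspecific_rate,
    root_states = stats::setNames(rep("A", length(all_pos)), all_pos),
    marker = "COI")
}

#' Configuration for the morphology simulator
#'
#' @param species List of per-species specs: each a list with `name`, `n`,
#'   `SL` (c(mean, sd) in mm), `meristics` (named list of `list(mean, sd,
#'   range)`), `measurements` (named list of `c(mean, sd)` in %SL), and
#'   `qualitative` (named character vector of yes/no/unknown states).
#' @return A validated list of class `morph_sim_config`.
#' @export
morph_sim_config <- function(species) {
  for (s in species) {
    stopifnot(!is.null(s$name), s$n >= 1, length(s$SL) == 2, s$SL[2] >= 0)
    for (m in s$meristics) {
      stopifnot(m$sd >= 0, length(m$range) == 2,
                m$mean >= m$range[1], m$mean <= m$range[2])
    }
    for (m in s$measurements) stopifnot(length(m) == 2, m[2] >= 0)
  }
  structure(list(species = species), class = "morph_sim_config")
}

#' Simulate a specimen morphology table
#'
#' Per specimen: standard length is Normal (truncated positive); each
#' measurement is drawn in %SL and back-converted to mm; each meristic count
#' is drawn Normal, rounded to the nearest integer (half away from zero) and
#' clamped to its configured range; the composite counts `GR = UR + LR` and
#' `TV = PV + CV` are derived from their parts; qualitative states are
#' copied from the configuration.  Characters are drawn independently
#' (diagonal covariance): published tables give only marginal moments.
#' Deterministic for a fixed seed.
#'
#' @param cfg A [morph_sim_config()], e.g. [sandlance_morph_config()].
#' @param seed Integer seed.
#' @return List with `table` (a `morph_table` data frame, measurements in
#'   mm) and `truth` (the configuration the rows were drawn from).
#' @export
simulate_morphology <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "morph_sim_config"))
  set.seed(seed)
  rows <- list()
  for (s in cfg$species) {
    tag <- gsub("[^A-Za-z0-9]+", "_", s$name)
    for (i in seq_len(s$n)) {
      sl <- -1
      while (sl <= 0) sl <- stats::rnorm(1, s$SL[1], s$SL[2])
      row <- list(specimen_id = sprintf("%s_m%02d", tag, i), species = s$name,
                  SL_mm = sl)
      for (mn in names(s$meristics)) {
        m <- s$meristics[[mn]]
        v <- round_half_up(stats::rnorm(1, m$mean, m$sd))
        row[[mn]] <- min(max(v, m$range[1]), m$range[2])
      }
      if (all(c("UR", "LR") %in% names(row))) row$GR <- row$UR + row$LR
      if (all(c("PV", "CV") %in% names(row))) row$TV <- row$PV + row$CV
      for (mn in names(s$measurements)) {
        m <- s$measurements[[mn]]
        pct <- -1
        while (pct <= 0) pct <- stats::rnorm(1, m[1], m[2])
        row[[mn]] <- pct * sl / 100  # back to mm
      }
      for (qn in names(s$qualitative)) row[[qn]] <- unname(s$qualitative[[qn]])
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  tab <- do.call(rbind, rows)
  list(table = read_morph_table(tab), truth = cfg)
}

#' Morphology simulator configuration for the four sand lance species
#'
#' Encodes the published per-species means, standard deviations and ranges
#' of the meristic counts, %SL measurements, standard length, and the
#' qualitative character states of Ammodytes marinus, A. tobianus,
#' Hyperoplus immaculatus and H. lanceolatus.  Default group sizes are the
#' study's morphology sample (27/21/8/29); pass `n` to override (e.g. equal
#' groups for simulation experiments).
#'
#' @param n Optional vector of group sizes, recycled over the four species
#'   in the order marinus, tobianus, immaculatus, lanceolatus.
#' @return A [morph_sim_config()].
#' @export
sandlance_morph_config <- function(n = NULL) {
  me <- function(mean, sd, lo, hi) list(mean = mean, sd = sd, range = c(lo, hi))
  sizes <- if (is.null(n)) c(27L, 21L, 8L, 29L) else rep_len(as.integer(n), 4L)
  species <- list(
    list(
      name = "Ammodytes marinus", n = sizes[1], SL = c(136.7, 29.7),
      meristics = list(
        DP = me(143.1, 2.6, 140, 150), DR = me(59.1, 1.4, 56, 62),
        AR = me(29.5, 0.8, 28, 31), PR = me(13.6, 0.6, 12, 15),
        CR = me(15, 0, 15, 15), UR = me(5.0, 0.2, 5, 6),
        LR = me(18.6, 0.8, 18, 20), PV = me(42.9, 0.7, 42, 44),
        CV = me(26.7, 0.5, 26, 28)),
      measurements = list(
        BDD = c(9.1, 1.3), BDA = c(8.1, 1.2), BWD = c(5.3, 0.7),
        HL = c(20.0, 1.1), SNL = c(5.7, 0.3), OD = c(3.2, 0.5),
        IW = c(2.4, 0.3), UJL = c(6.7, 1.0), CPD = c(2.6, 0.2),
        CPL = c(4.1, 0.5), PPL = c(18.6, 1.0), PDL = c(25.3, 1.0),
        PAL = c(64.9, 1.1), PFL = c(9.9, 0.7), DFBL = c(69.8, 1.4),
        AFBL = c(30.5, 1.0), CFL = c(10.1, 0.7), DFH = c(4.7, 0.7),
        AFH = c(4.7, 0.8)),
      qualitative = c(MDAS = "yes", BCOP = "yes", PCP = "yes", VTP = "no",
                      DSSS = "no", BSTC = "no", SBCF = "no", SADF = "no")),
    list(
      name = "Ammodytes tobianus", n = sizes[2], SL = c(134.1, 7.7),
      meristics = list(
        DP = me(128.5, 3.0, 123, 135), DR = me(52.8, 1.1, 51, 55),
        AR = me(27.8, 1.3, 25, 30), PR = me(13.0, 0.2, 12, 13),
        CR = me(15, 0, 15, 15), UR = me(5, 0, 5, 5),
        LR = me(20, 0, 20, 20), PV = me(38.1, 1.4, 36, 41),
        CV = me(25.1, 0.6, 24, 26)),
      measurements = list(
        BDD = c(9.5, 0.8), BDA = c(9.4, 0.8), BWD = c(6.0, 0.9),
        HL = c(19.6, 0.8), SNL = c(5.4, 0.3), OD = c(3.0, 0.3),
        IW = c(2.4, 0.2), UJL = c(6.4, 0.4), CPD = c(3.0, 0.1),
        CPL = c(4.3, 0.5), PPL = c(18.6, 1.1), PDL = c(25.4, 1.0),
        PAL = c(63.7, 1.9), PFL = c(10.4, 0.5), DFBL = c(69.2, 1.1),
        AFBL = c(31.6, 1.9), CFL = c(10.3, 0.7), DFH = c(4.8, 0.6),
        AFH = c(4.8, 0.5)),
      qualitative = c(MDAS = "yes", BCOP = "yes", PCP = "yes", VTP = "no",
                      DSSS = "no", BSTC = "yes", SBCF = "yes", SADF = "yes")),
    list(
      name = "Hyperoplus immaculatus", n = sizes[3], SL = c(251.4, 15.0),
      meristics = list(
        DP = me(187.8, 5.4, 179, 196), DR = me(60.1, 0.6, 59, 61),
        AR = me(31.8, 0.5, 31, 32), PR = me(14.1, 0.6, 13, 15),
        CR = me(15, 0, 15, 15), UR = me(5, 0, 5, 5),
        LR = me(24.3, 0.7, 23, 25), PV = me(42.9, 0.4, 42, 43),
        CV = me(29.5, 0.5, 29, 30)),
      measurements = list(
        BDD = c(6.8, 0.9), BDA = c(7.5, 0.5), BWD = c(6.5, 0.8),
        HL = c(19.4, 0.7), SNL = c(6.1, 0.1), OD = c(2.3, 0.2),
        IW = c(3.2, 0.3), UJL = c(5.3, 0.4), CPD = c(2.7, 0.1),
        CPL = c(4.8, 0.7), PPL = c(18.4, 0.3), PDL = c(26.6, 0.5),
        PAL = c(62.8, 1.4), PFL = c(7.7, 0.4), DFBL = c(69.1, 0.7),
        AFBL = c(32.4, 1.2), CFL = c(8.9, 0.4), DFH = c(4.1, 0.4),
        AFH = c(3.9, 0.7)),
      qualitative = c(MDAS = "yes", BCOP = "yes", PCP = "no", VTP = "yes",
                      DSSS = "no", BSTC = "yes", SBCF = "yes", SADF = "yes")),
    list(
      name = "Hyperoplus lanceolatus", n = sizes[4], SL = c(219.3, 32.7),
      meristics = list(
        DP = me(182.6, 6.4, 169, 194), DR = me(55.9, 0.8, 54, 57),
        AR = me(29.1, 0.8, 28, 30), PR = me(13.5, 0.5, 13, 14),
        CR = me(15, 0, 15, 15), UR = me(5, 0, 5, 5),
        LR = me(20.7, 0.8, 20, 22), PV = me(40.3, 0.8, 38, 42),
        CV = me(26.5, 0.7, 25, 28)),
      measurements = list(
        BDD = c(7.0, 0.9), BDA = c(6.7, 0.6), BWD = c(5.4, 0.8),
        HL = c(21.7, 0.6), SNL = c(7.2, 0.5), OD = c(2.5, 0.5),
        IW = c(3.3, 0.3), UJL = c(7.1, 0.3), CPD = c(2.5, 0.1),
        CPL = c(4.9, 0.4), PPL = c(20.8, 0.7), PDL = c(27.9, 1.0),
        PAL = c(64.9, 4.1), PFL = c(7.7, 0.6), DFBL = c(67.4, 1.1),
        AFBL = c(29.8, 1.0), CFL = c(8.9, 0.7), DFH = c(3.9, 0.6),
        AFH = c(4.1, 0.6)),
      qualitative = c(MDAS = "yes", BCOP = "yes", PCP = "no", VTP = "yes",
                      DSSS = "yes", BSTC = "unknown", SBCF = "yes",
                      SADF = "yes")))
  morph_sim_config(species)
}
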