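#' Run the molecular identification pipeline
#'
#' Distances -> NJ tree with bootstrap -> per-species barcode-gap summary ->
#' single-linkage OTUs with concordance report -> diagnostic sites.  All
#' stages consume each other's in-memory objects; the report bundle is
#' written to `out_dir`: `dist.csv`, `tree.nwk`, `gap_summary.csv`,
#' `otus.csv`, `diagnostics.csv` and `run_log.txt`.  Any stage error aborts
#' the run and removes partial outputs.
#'
#' @param aln A [bk_alignment], or a FASTA path (then `metadata` is
#'   required).
#' @param out_dir Output directory (created if needed).
#' @param metadata Metadata TSV/CSV path when `aln` is a FASTA path.
#' @param model Distance model, `"K2P"` or `"p"`.
#' @param replicates Bootstrap replicates (0 disables bootstrapping).
#' @param seed Integer seed for the bootstrap.
#' @param otu_threshold Single-linkage threshold in percent.
#' @param min_support Minimum bootstrap percentage written to the tree.
#' @param full_precision Write full precision instead of two-decimal
#'   percentages.
#' @return Invisibly, a list with the stage objects (`distances`, `tree`,
#'   `gap_summary`, `otus`, `concordance`, `diagnostics`) and `files`.
#' @export
run_molecular_pipeline <- function(aln, out_dir, metadata = NULL,
                                   model = c("K2P", "p"), replicates = 1000,
                                   seed = 1, otu_threshold = 2.2,
                                   min_support = 50, full_precision = FALSE) {
  model <- match.arg(model)
  if (is.character(aln)) {
    if (is.null(metadata)) stop("[input] metadata path required with a FASTA path")
    aln <- read_fasta_with_metadata(aln, metadata)
  }
  stopifnot(inherits(aln, "bk_alignment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c(dist = "dist.csv", tree = "tree.nwk",
                                gap = "gap_summary.csv", otus = "otus.csv",
                                diag = "diagnostics.csv", log = "run_log.txt"))
  names(files) <- c("dist", "tree", "gap", "otus", "diag", "log")
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)

  log_lines <- c(sprintf("barcodekit molecular pipeline %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("records: %d  alignment length: %d  model: %s",
                         length(aln), aln$length, model),
                 sprintf("replicates: %d  seed: %d  otu_threshold: %.2f",
                         replicates, seed, otu_threshold))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  dm <- stage("distances", distance_matrix(aln, model))
  undef <- attr(dm, "undefined")
  log_lines <- c(log_lines,
                 sprintf("undefined pairs: %d%s", nrow(undef),
                         if (nrow(undef)) paste0(" (", paste(undef$a, undef$b,
                           sep = "~", collapse = ", "), ")") else ""))
  stage("distances", write_distance_csv(dm, files["dist"], full_precision))

  tree <- stage("treebuild", {
    if (replicates > 0) {
      bootstrap_support(aln, model, replicates = replicates, seed = seed)
    } else {
      nj_tree(dm)
    }
  })
  stage("treebuild", write_newick(tree, files["tree"], min_support))
  if (!is.null(attr(tree, "replicates_skipped"))) {
    log_lines <- c(log_lines, sprintf("bootstrap replicates used: %d, skipped: %d",
                                      attr(tree, "replicates_used"),
                                      attr(tree, "replicates_skipped")))
  }

  gaps <- stage("barcode_gap", species_summaries(dm))
  stage("barcode_gap", write_gap_csv(gaps, files["gap"], full_precision))

  otus <- stage("otu_cluster", single_linkage_otus(dm, otu_threshold))
  conc <- stage("otu_cluster", concordance_report(otus))
  stage("otu_cluster", utils::write.csv(
    merge(otus$assignments, conc, by = "otu", sort = TRUE),
    files["otus"], row.names = FALSE, quote = TRUE))

  diag <- stage("diagnostics", diagnostic_sites(aln))
  stage("diagnostics", write_diagnostics_csv(diag, files["diag"]))
  log_lines <- c(log_lines,
                 sprintf("variable sites: %d  otus: %d  species: %d",
                         nrow(diag), length(otus$clusters),
                         length(unique(aln$species[aln$species != "unknown"]))))
  writeLines(log_lines, files["log"])
  ok <- TRUE
  invisible(list(distances = dm, tree = tree, gap_summary = gaps, otus = otus,
                 concordance = conc, diagnostics = diag, files = files))
}

#' Run the morphology identification pipeline
#'
#' Character summaries -> meristic and morphometric discriminant analyses ->
#' per-specimen identification-key calls.  The bundle written to `out_dir`:
#' `morph_summary.csv`, `dfa_<mode>_coefficients.csv`,
#' `dfa_<mode>_scores.csv`, `dfa_<mode>_stats.json` for each mode,
#' `identifications.csv`, and `run_log.txt`.
#'
#' @param t A morphology table (data frame or CSV path) in the
#'   [read_morph_table()] layout.
#' @param out_dir Output directory.
#' @param key_config Identification-key configuration.
#' @return Invisibly, a list with `summary`, `dfa` (per mode), `calls`,
#'   `files`.
#' @export
run_morphology_pipeline <- function(t, out_dir, key_config = sandlance_key()) {
  t <- read_morph_table(t)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(summary = file.path(out_dir, "morph_summary.csv"),
             ident = file.path(out_dir, "identifications.csv"),
             log = file.path(out_dir, "run_log.txt"))
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(c(files, written)), add = TRUE)

  summ <- summarize_characters(t)
  utils::write.csv(summ, files["summary"], row.names = FALSE, quote = TRUE,
                   na = "")
  log_lines <- c(sprintf("barcodekit morphology pipeline %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("specimens: %d  species: %d", nrow(t),
                         length(unique(t$species))))

  dfas <- list()
  for (mode in c("meristic", "morphometric")) {
    vars <- select_dfa_variables(t, mode)
    fit <- tryCatch(discriminant_analysis(t, vars),
                    error = function(e) stop("[dfa_", mode, "] ",
                                             conditionMessage(e), call. = FALSE))
    dfas[[mode]] <- fit
    f_coef <- file.path(out_dir, sprintf("dfa_%s_coefficients.csv", mode))
    f_scores <- file.path(out_dir, sprintf("dfa_%s_scores.csv", mode))
    f_stats <- file.path(out_dir, sprintf("dfa_%s_stats.json", mode))
    written <- c(written, f_coef, f_scores, f_stats)
    coef_tab <- data.frame(variable = rownames(fit$std_coefficients),
                           round(fit$std_coefficients, 3),
                           check.names = FALSE)
    extra <- data.frame(variable = c("Percentage of explained variance",
                                     "Eigenvalue", "Cumulative variance in %"),
                        rbind(round(fit$explained_pct, 3),
                              round(fit$eigenvalues, 3),
                              round(fit$cumulative_pct, 3)),
                        check.names = FALSE)
    utils::write.csv(rbind(coef_tab, extra), f_coef, row.names = FALSE)
    utils::write.csv(data.frame(specimen_id = rownames(fit$scores),
                                species = fit$classification$species,
                                predicted = fit$classification$predicted,
                                fit$scores, check.names = FALSE),
                     f_scores, row.names = FALSE)
    jsonlite::write_json(
      list(mode = mode, n_used = fit$n_used, n_dropped = fit$n_dropped,
           eigenvalues = fit$eigenvalues, explained_pct = fit$explained_pct,
           wilks_lambda = fit$wilks_lambda, bartlett = fit$bartlett,
           boxm = fit$boxm),
      f_stats, auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines,
                   sprintf("%s DFA: %d variables, %d specimens used, %d dropped",
                           mode, length(vars), fit$n_used, fit$n_dropped))
  }

  calls <- identify_specimens(t, key_config)
  utils::write.csv(calls, files["ident"], row.names = FALSE, quote = TRUE,
                   na = "")
  writeLines(log_lines, files["log"])
  ok <- TRUE
  invisible(list(summary = summ, dfa = dfas, calls = calls,
                 files = c(files, written)))
}
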