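# End-to-end orchestration: classify -> matrix prep -> model selection ->
# ML search -> bootstrap -> parametric bootstrap -> origin counting, with
# seeded determinism, stage-tagged diagnostics and standard-format output.

#' Build a run configuration
#'
#' Defaults follow the analysis protocol the pipeline implements: twenty
#' search replicates, one hundred bootstrap replicates with two search
#' replicates each, and one hundred parametric-bootstrap replicates.
#' Either `fasta` + `layout` (real input) or `synthetic` (a preset list
#' passed to [simulate_vssc_dataset()]) must be given.
#'
#' @param fasta Path to an aligned FASTA of Vssc fragments (optional).
#' @param layout A [fragment_layout()] (required with `fasta`).
#' @param synthetic List of arguments for [simulate_vssc_dataset()]
#'   (optional; used when `fasta` is absent).
#' @param matrix `"full"` (all sites) or `"strict"` (ambiguous columns
#'   excluded).
#' @param excluded_sites 1-based columns to exclude under `"strict"` for
#'   FASTA input (synthetic input carries its own mask).
#' @param candidates Model candidate set (default [candidate_models()]).
#' @param search_replicates,bootstrap_replicates,bootstrap_search_reps,sowh_replicates,sowh_search_reps
#'   Replicate counts for the search, bootstrap and parametric-bootstrap
#'   stages (all `>= 1`).
#' @param seed Integer seed; all stages derive their seeds from it.
#' @param outdir Output directory for [write_report()] (optional).
#' @return A list of class `run_config` with all defaults filled in.
#' @export
run_config <- function(fasta = NULL, layout = NULL, synthetic = NULL,
                       matrix = c("full", "strict"),
                       excluded_sites = integer(0),
                       candidates = candidate_models(),
                       search_replicates = 20, bootstrap_replicates = 100,
                       bootstrap_search_reps = 2, sowh_replicates = 100,
                       sowh_search_reps = 2, seed = 1, outdir = NULL) {
  matrix <- match.arg(matrix)
  if (is.null(fasta) && is.null(synthetic))
    stop("config needs either 'fasta' or 'synthetic'")
  if (!is.null(fasta) && is.null(layout))
    stop("FASTA input needs a fragment_layout")
  counts <- c(search_replicates, bootstrap_replicates,
              bootstrap_search_reps, sowh_replicates, sowh_search_reps)
  if (any(counts < 1)) stop("all replicate counts must be >= 1")
  structure(list(fasta = fasta, layout = layout, synthetic = synthetic,
                 matrix = matrix, excluded_sites = excluded_sites,
                 candidates = candidates,
                 search_replicates = search_replicates,
                 bootstrap_replicates = bootstrap_replicates,
                 bootstrap_search_reps = bootstrap_search_reps,
                 sowh_replicates = sowh_replicates,
                 sowh_search_reps = sowh_search_reps,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order and returns a machine-readable report.
#' Re-running with an identical configuration reproduces the report.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress via `message()`.
#' @return An object of class `kdr_report`.
#' @export
run_full_analysis <- function(config, verbose = TRUE) {
  if (!inherits(config, "run_config")) stop("config must come from run_config()")
  say <- function(...) if (verbose) message("[kdrorigins] ", ...)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 8)

  say("stage input")
  inp <- stage("input", {
    if (!is.null(config$fasta)) {
      aln <- read_fasta_alignment(config$fasta)
      list(aln = aln, layout = config$layout, truth = NULL)
    } else {
      sim <- do.call(simulate_vssc_dataset,
                     c(config$synthetic, list(seed = seeds[1])))
      list(aln = sim$aln, layout = sim$layout, truth = sim)
    }
  })

  say("stage classify")
  hap <- stage("classify", classify_sequences(inp$aln, inp$layout))
  catal <- hap$catalog

  say("stage matrix (", config$matrix, ")")
  haln <- stage("matrix", {
    seqs <- setNames(catal$records$sequence, catal$records$name)
    mask <- if (config$matrix == "full") NULL else {
      m <- inp$aln$mask
      if (length(config$excluded_sites)) m[config$excluded_sites] <- FALSE
      m
    }
    alignment(seqs, mask = mask)
  })
  if (n_taxa(haln) < 4)
    stop("stage [matrix]: fewer than 4 distinct haplotypes; ",
         "nothing to analyse")

  say("stage model selection (BIC, ", length(config$candidates),
      " candidates)")
  fit <- stage("model_selection", select_model_bic(haln, config$candidates))

  say("stage ML search (", config$search_replicates, " replicates)")
  best <- stage("ml_search",
                ml_search(haln, fit$model, config$search_replicates,
                          seed = seeds[2]))

  say("stage bootstrap (", config$bootstrap_replicates, " x ",
      config$bootstrap_search_reps, " search reps)")
  boot <- stage("bootstrap",
                bootstrap_support(haln, fit$model, tree = best$tree,
                                  n_boot = config$bootstrap_replicates,
                                  search_reps = config$bootstrap_search_reps,
                                  seed = seeds[3]))

  states <- setNames(catal$records$class, catal$records$name)
  resistant <- catal$records$name[catal$records$class %in% RESISTANT_CLASSES]

  sowh <- NULL
  if (length(resistant) >= 2 && length(resistant) <= n_taxa(haln) - 2) {
    say("stage SOWH (", config$sowh_replicates, " replicates)")
    sowh <- stage("sowh",
                  sowh_test(haln, fit$model, resistant,
                            n_reps = config$sowh_replicates,
                            seed = seeds[4],
                            search_reps = config$search_replicates,
                            rep_search_reps = config$sowh_search_reps))
  } else say("stage SOWH skipped (resistant set size ", length(resistant),
             " leaves no testable constraint)")

  say("stage origins")
  orig <- stage("origins", {
    disp <- midpoint_root(best$tree)
    list(display_tree = disp,
         report = origin_report(disp, states),
         pairs = derive_sequential_pairs(catal))
  })

  structure(list(
    haplotypes = hap, catalog = catal, alignment = haln,
    model_fit = fit, search = best, bootstrap = boot, sowh = sowh,
    origins = orig$report, sequential_pairs = orig$pairs,
    display_tree = orig$display_tree,
    truth = inp$truth,
    provenance = list(config = config[setdiff(names(config), "candidates")],
                      candidate_names = names(config$candidates),
                      stage_seeds = seeds,
                      package_version =
                        as.character(utils::packageVersion("kdrorigins")))),
    class = "kdr_report")
}

#' @export
print.kdr_report <- function(x, ...) {
  cat("kdr-origins analysis report\n")
  cat("  haplotypes:", nrow(x$catalog$records), "distinct (",
      paste(names(table(x$catalog$records$class)),
            table(x$catalog$records$class), sep = "=", collapse = ", "),
      ")\n")
  cat("  intron groups:", length(x$haplotypes$groups$groups), "\n")
  cat("  model:", x$model_fit$name,
      sprintf("(BIC %.2f)\n", x$model_fit$bic))
  cat(sprintf("  best tree lnL: %.6f\n", x$search$loglik))
  if (!is.null(x$sowh)) {
    cat(sprintf("  SOWH delta: %.2f, %s\n", x$sowh$observed_delta,
                x$sowh$p_display))
  }
  cat("  origin counts (midpoint-rooted display tree):\n")
  print(as.data.frame(x$origins), row.names = FALSE)
  invisible(x)
}

report_json <- function(report) {
  x <- list(
    n_haplotypes = nrow(report$catalog$records),
    class_counts = as.list(table(report$catalog$records$class)),
    n_intron_groups = length(report$haplotypes$groups$groups),
    model = report$model_fit$name,
    bic_table = report$model_fit$table,
    best_loglik = report$search$loglik,
    best_tree = ape::write.tree(report$search$tree),
    bootstrap = report$bootstrap$table,
    sowh = if (!is.null(report$sowh)) list(
      observed_delta = report$sowh$observed_delta,
      lnl_best = report$sowh$lnl_best,
      lnl_constrained = report$sowh$lnl_constrained,
      p_value = report$sowh$p_value,
      p_corrected = report$sowh$p_corrected,
      p_display = report$sowh$p_display,
      n_reps = report$sowh$n_reps,
      replicate_deltas = report$sowh$replicate_deltas),
    origins = as.data.frame(report$origins),
    sequential_pairs = report$sequential_pairs,
    provenance = report$provenance[c("candidate_names", "stage_seeds",
                                     "package_version")],
    config = report$provenance$config[
      !vapply(report$provenance$config, is.null, logical(1))])
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null")
}

#' Write a report to standard formats
#'
#' Newick for trees (bootstrap labels above 50% only, matching the usual
#' display convention), FASTA for unique haplotypes, TSV for tables, JSON
#' for the whole machine-readable report.  Output is deterministic given
#' the report.
#'
#' @param report A `kdr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- character(0)
  p <- function(...) file.path(dir, paste0(...))
  ape::write.tree(report$search$tree, p("best_tree.nwk"))
  f <- c(f, p("best_tree.nwk"))
  bt <- report$bootstrap$tree
  if (!is.null(bt$node.label)) {
    v <- suppressWarnings(as.numeric(bt$node.label))
    bt$node.label <- ifelse(!is.na(v) & v > 50, bt$node.label, "")
  }
  ape::write.tree(bt, p("bootstrap_tree.nwk"))
  f <- c(f, p("bootstrap_tree.nwk"))
  write_catalog_tsv(report$catalog, p("catalog.tsv"))
  f <- c(f, p("catalog.tsv"))
  write_fasta(setNames(report$catalog$records$sequence,
                       report$catalog$records$name),
              p("unique_haplotypes.fasta"))
  f <- c(f, p("unique_haplotypes.fasta"))
  write.table(as.data.frame(report$origins), p("origins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  f <- c(f, p("origins.tsv"))
  write.table(report$bootstrap$table, p("bootstrap_support.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  f <- c(f, p("bootstrap_support.tsv"))
  writeLines(report_json(report), p("report.json"))
  f <- c(f, p("report.json"))
  invisible(f)
}
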