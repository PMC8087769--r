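#' Analysis-stage parameters
#'
#' Collects every tunable of the counts-to-calls pipeline with its
#' default, so a run's effective configuration can be recorded next to its
#' outputs.
#'
#' @param alpha,scale fold-change pseudocount and scale
#'   ([guide_log_fold_change()]).
#' @param bandwidth,floor_eps density fit controls ([fit_densities()]).
#' @param boot bootstrap iterations for [gene_bayes_factor()] (default 0;
#'   see the methods vignette on the runtime trade-off).
#' @param aggregate replicate-line aggregation ([genotype_bf()]).
#' @param threshold Z calling threshold ([select_dependencies()]).
#' @param sd_type Z standard-deviation convention ([residual_z_scores()]).
#' @param seed master seed for stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 5, scale = 1e7, bandwidth = "silverman",
                       floor_eps = 1e-12, boot = 0,
                       aggregate = "mean", threshold = 3.5,
                       sd_type = "population", seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the counts-to-calls analysis
#'
#' Executes fold change -> per-line Bayes factors -> genotype aggregation
#' -> knockout-on-wild-type linear model -> residual Z scores ->
#' dependency calls, on in-memory objects.
#'
#' @param counts a [count_matrix()].
#' @param sheet a [sample_sheet()].
#' @param library a [guide_library()].
#' @param refsets a [reference_gene_sets()].
#' @param config a [run_config()].
#' @param validate run [validate_inputs()] first (warnings reported,
#'   fatals abort).
#' @return A `screen_analysis` list: `fc`, `bf_lines`, `bf_genotype`,
#'   `fit`, `z`, `table` (the [select_dependencies()] output), `config`,
#'   `config_hash`.
#' @export
analyze_screen <- function(counts, sheet, library, refsets,
                           config = run_config(), validate = TRUE) {
  if (validate) validate_inputs(library, counts, sheet, refsets)
  plasmid <- samples_of(sheet, "plasmid")
  fc <- guide_log_fold_change(counts, plasmid, alpha = config$alpha,
                              scale = config$scale)
  bf_lines <- list()
  for (gt in c("knockout", "wildtype")) {
    ids <- samples_of(sheet, gt)
    if (length(ids) == 0) {
      stop_iso("no samples of genotype ", gt, " in the sheet",
               class = "isoscreen_validation_error")
    }
    bf_lines[[gt]] <- stats::setNames(lapply(seq_along(ids), function(i) {
      gene_bayes_factor(fc, library, samples = ids[i], refsets = refsets,
                        boot = config$boot, seed = config$seed + i,
                        bandwidth = config$bandwidth,
                        floor_eps = config$floor_eps)
    }), ids)
  }
  gbf <- genotype_bf(bf_lines, aggregate = config$aggregate)
  vec <- function(gt) {
    sub <- gbf[gbf$genotype == gt, ]
    stats::setNames(sub$bf, sub$gene)
  }
  bf_wt <- vec("wildtype")
  bf_ko <- vec("knockout")
  fit <- fit_bf_linear_model(bf_wt, bf_ko)
  z <- residual_z_scores(fit$residuals, sd_type = config$sd_type)
  table <- select_dependencies(z, threshold = config$threshold, fit = fit,
                               bf_wt = bf_wt, bf_ko = bf_ko)
  structure(list(fc = fc, bf_lines = bf_lines, bf_genotype = gbf,
                 fit = fit, z = z, table = table, config = config,
                 config_hash = config_hash(config)),
            class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat(sprintf("screen_analysis: %d genes modelled, %d dependencies at Z > %g\n",
              x$fit$n, sum(x$table$is_dependency),
              attr(x$table, "threshold")))
  invisible(x)
}

#' File-based end-to-end run
#'
#' Reads the inputs, runs [count_screen()] when FASTQ paths are given and
#' counts are not, then [analyze_screen()], and writes `counts.tsv`,
#' `bf.tsv`, `diff.tsv` and a `provenance.tsv` (effective parameters plus
#' their hash) into `out_dir`. Any stage error aborts with the stage name.
#'
#' @param library_path,sheet_path TSV inputs.
#' @param counts_path optional counts TSV (skips quantification).
#' @param fastq_paths optional named FASTQ paths, one per sample.
#' @param essential_path,nonessential_path training gene-set files.
#' @param out_dir output directory (created).
#' @param config a [run_config()].
#' @return The `screen_analysis`, invisibly.
#' @export
run_all <- function(library_path, sheet_path, counts_path = NULL,
                    fastq_paths = NULL, essential_path, nonessential_path,
                    out_dir, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_iso("stage '", name, "' failed: ", conditionMessage(e),
               class = "isoscreen_stage_error")
    })
  }
  library <- stage("read_library", read_library(library_path))
  sheet <- stage("read_sheet", read_sample_sheet(sheet_path))
  refsets <- stage("read_refsets",
                   read_gene_sets(essential_path, nonessential_path))
  counts <- if (!is.null(counts_path)) {
    stage("read_counts", read_counts(counts_path, library = library))
  } else if (!is.null(fastq_paths)) {
    stage("count", count_screen(sheet, fastq_paths, library, quiet = TRUE))
  } else {
    stop_iso("supply counts_path or fastq_paths", class = "isoscreen_format_error")
  }
  res <- stage("analyze", analyze_screen(counts, sheet, library, refsets,
                                         config = config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage("write", {
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    utils::write.table(res$bf_genotype, file.path(out_dir, "bf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(res$table),
                       file.path(out_dir, "diff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- data.frame(
      key = c(names(res$config), "config_hash"),
      value = c(vapply(res$config, function(v) paste(format(v), collapse = ","),
                       character(1)),
                res$config_hash),
      stringsAsFactors = FALSE)
    utils::write.table(prov, file.path(out_dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(res)
}

#' One-command synthetic end-to-end demonstration
#'
#' Simulates a screen, analyzes it, and scores the dependency calls
#' against the planted truth. Deterministic for a given seed and
#' configuration.
#'
#' @param seed integer master seed.
#' @param sim a [sim_config()] (default: desk-scale defaults).
#' @param config a [run_config()] (its seed is taken from `seed`).
#' @param refset_size neutral genes drawn as the non-essential training
#'   set.
#' @param quiet suppress the printed report.
#' @return List: `screen`, `analysis`, `recovery`.
#' @export
demo_screen <- function(seed = 1, sim = sim_config(), config = run_config(),
                        refset_size = 100, quiet = FALSE) {
  config$seed <- seed
  library <- generate_library(sim, seed = seed)
  truth <- generate_truth(library, sim, seed = seed)
  screen <- simulate_screen(library, truth, sim, seed = seed)
  refsets <- reference_sets_from_truth(truth, n_nonessential = refset_size,
                                       seed = seed)
  analysis <- analyze_screen(screen$counts, screen$sheet, library, refsets,
                             config = config)
  recovery <- evaluate_recovery(truth, analysis$table)
  if (!quiet) {
    print(analysis)
    print(recovery)
  }
  invisible(list(screen = screen, analysis = analysis, recovery = recovery))
}
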