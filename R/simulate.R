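with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Synthetic screen configuration
#'
#' Defaults emulate a genome-wide drop-out screen at desk scale: a library
#' of 3-5 guides per gene plus non-targeting controls, infected at 200
#' cells per guide with ~30% transduction efficiency, puromycin-selected at
#' day 2, grown for ~16 cell doublings with at least 500 cells per guide
#' maintained at passaging, and sequenced to a fixed per-sample depth, with
#' three clonal knockout and three wild-type replicate lines plus the
#' plasmid library.
#'
#' @param n_genes number of targeting genes (desk-scale default 2000; the
#'   emulated screen had 18,010).
#' @param guides_per_gene inclusive integer range, default `c(3, 5)`.
#' @param n_control_guides non-targeting controls, default 100.
#' @param coverage infected cells per guide, default 200.
#' @param transduction_fraction default 0.30.
#' @param selection_day day drug selection starts, default 2 (bookkeeping
#'   only; uninfected cells never carry a guide).
#' @param doublings population doublings between selection and harvest,
#'   default 16.
#' @param passage_floor cells per guide maintained at passaging, default
#'   500.
#' @param depth sequencing reads per sample, default 5e6.
#' @param plasmid_sigma log-normal sigma of plasmid guide abundance,
#'   default 0.5.
#' @param efficiency_shape Beta shape parameters of guide knockout
#'   efficiency, default `c(5, 2)` (most guides effective, a tail of poor
#'   ones).
#' @param n_lines clonal replicate lines per genotype, default 3.
#' @param n_core_essential genes lethal in both genotypes, default 100.
#' @param n_ko_specific genes lethal only in the knockout background,
#'   default 50.
#' @param n_wt_specific genes lethal only in wild-type, default 0.
#' @param n_enriched genes whose loss confers a growth advantage in the
#'   knockout background, default 0.
#' @param f_essential,f_ko_specific,f_wt_specific,f_enriched per-doubling
#'   log2 fitness effects of the respective classes (defaults -0.3, -0.2,
#'   -0.2, +0.1).
#' @param deterministic replace all sampling with expectations (counts
#'   become exact real-valued expected reads).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, guides_per_gene = c(3, 5),
                       n_control_guides = 100, coverage = 200,
                       transduction_fraction = 0.30, selection_day = 2,
                       doublings = 16, passage_floor = 500, depth = 5e6,
                       plasmid_sigma = 0.5, efficiency_shape = c(5, 2),
                       n_lines = 3, n_core_essential = 100,
                       n_ko_specific = 50, n_wt_specific = 0,
                       n_enriched = 0, f_essential = -0.3,
                       f_ko_specific = -0.2, f_wt_specific = -0.2,
                       f_enriched = 0.1, deterministic = FALSE) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, length(guides_per_gene) == 2,
            guides_per_gene[1] >= 1,
            guides_per_gene[2] >= guides_per_gene[1],
            coverage > 0, transduction_fraction > 0,
            transduction_fraction <= 1, doublings >= 0,
            passage_floor > 0, depth > 0, plasmid_sigma >= 0,
            n_lines >= 1)
  if (n_core_essential + n_ko_specific + n_wt_specific + n_enriched > n_genes) {
    stop_iso("planted classes exceed n_genes", class = "isoscreen_validation_error")
  }
  structure(cfg, class = "sim_config")
}

random_spacers <- function(n, len = 20) {
  if (n > 4^10) {  # collision management below assumes sparse occupancy
    stop_iso("requested library larger than practical sequence space",
             class = "isoscreen_validation_error")
  }
  seqs <- character(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    new <- vapply(seq_len(need + ceiling(need * 0.05) + 10), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  seqs[seq_len(n)]
}

#' Generate a random guide library
#'
#' Unique random 20-nt spacers; guides per gene drawn uniformly from the
#' configured range; gene symbols `G0001`, ...; controls labelled with the
#' reserved control gene. Deterministic for a given seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A [guide_library()].
#' @export
generate_library <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    range <- config$guides_per_gene[1]:config$guides_per_gene[2]
    npg <- range[sample.int(length(range), config$n_genes, replace = TRUE)]
    gene_col <- rep(genes, npg)
    n_total <- length(gene_col) + config$n_control_guides
    seqs <- random_spacers(n_total)
    df <- data.frame(
      guide_id = c(sprintf("%s_g%d", gene_col,
                           unlist(lapply(npg, seq_len))),
                   sprintf("CTRL_g%d", seq_len(config$n_control_guides))),
      gene = c(gene_col, rep(control_gene_label(), config$n_control_guides)),
      sequence = seqs,
      guide_class = c(rep("targeting", length(gene_col)),
                      rep("control", config$n_control_guides)),
      stringsAsFactors = FALSE)
    guide_library(df)
  })
}

#' Plant ground-truth fitness effects
#'
#' Assigns each targeting gene a class (`neutral`, `core_essential`,
#' `ko_specific`, `wt_specific`, `enriched_on_loss`) with the per-doubling
#' log2 fitness effect `f` of that class in each genotype, and draws a
#' knockout efficiency `e` in \[0, 1\] for every guide. `f <= 0` is a
#' growth deficit; the enriched class has `f > 0` in the knockout
#' background (loss confers advantage). Controls have `e = 0`.
#'
#' @param library a [guide_library()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A `sim_truth` list: `genes` (data frame `gene`, `class`,
#'   `f_knockout`, `f_wildtype`) and `guides` (data frame `guide_id`,
#'   `efficiency`).
#' @export
generate_truth <- function(library, config, seed = 1) {
  stopifnot(inherits(library, "guide_library"), inherits(config, "sim_config"))
  genes <- library_genes(library)
  with_seed(seed + 1L, {
    classes <- rep("neutral", length(genes))
    pool <- sample(seq_along(genes))
    take <- function(n) {
      out <- pool[seq_len(n)]
      if (n > 0) pool <<- pool[-seq_len(n)]
      out
    }
    classes[take(config$n_core_essential)] <- "core_essential"
    classes[take(config$n_ko_specific)] <- "ko_specific"
    classes[take(config$n_wt_specific)] <- "wt_specific"
    classes[take(config$n_enriched)] <- "enriched_on_loss"
    f_ko <- c(neutral = 0, core_essential = config$f_essential,
              ko_specific = config$f_ko_specific, wt_specific = 0,
              enriched_on_loss = config$f_enriched)[classes]
    f_wt <- c(neutral = 0, core_essential = config$f_essential,
              ko_specific = 0, wt_specific = config$f_wt_specific,
              enriched_on_loss = 0)[classes]
    if (any(c(f_ko, f_wt) < -1)) {
      stop_iso("fitness effect f < -1 is not meaningful per doubling; ",
               "model partial dropout via guide efficiency",
               class = "isoscreen_validation_error")
    }
    eff <- stats::rbeta(nrow(library), config$efficiency_shape[1],
                        config$efficiency_shape[2])
    eff[library$guide_class == "control"] <- 0
    structure(list(
      genes = data.frame(gene = genes, class = classes,
                         f_knockout = unname(f_ko), f_wildtype = unname(f_wt),
                         stringsAsFactors = FALSE),
      guides = data.frame(guide_id = library$guide_id,
                          efficiency = eff, stringsAsFactors = FALSE)),
      class = "sim_truth")
  })
}

#' @rdname generate_truth
#' @param truth a `sim_truth`
#' @param path TSV path; `write_truth` stores the gene table and guide
#'   efficiencies side by side for reloading with `read_truth`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$genes, paste0(path, ".genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$guides, paste0(path, ".guides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# expected relative abundance of each guide after d doublings, given
# knockout / non-knockout cell mixtures (2^d common factor divided out)
grown_weights <- function(ko_cells, other_cells, f, doublings) {
  ko_cells * 2^(doublings * f) + other_cells
}

sim_one_sample <- function(library, truth, config, f_by_guide, w) {
  n_guides <- nrow(library)
  infected_total <- round(config$coverage * n_guides)
  e <- truth$guides$efficiency
  if (config$deterministic) {
    n_inf <- infected_total * w / sum(w)
    ko <- n_inf * e
    grown <- grown_weights(ko, n_inf - ko, f_by_guide, config$doublings)
    config$depth * grown / sum(grown)
  } else {
    n_inf <- as.numeric(stats::rmultinom(1, infected_total, w))
    ko <- stats::rbinom(n_guides, n_inf, e)
    grown <- grown_weights(ko, n_inf - ko, f_by_guide, config$doublings)
    # passaging bottleneck: the culture is subsampled to the maintained
    # cell number before sequencing
    pool <- as.numeric(stats::rmultinom(1, round(config$passage_floor * n_guides),
                                        grown))
    as.numeric(stats::rmultinom(1, config$depth, pmax(pool, 0)))
  }
}

#' Simulate a full drop-out screen
#'
#' Generative model: plasmid guide weights are log-normal; each sample's
#' infection draws `coverage * n_guides` infected cells from those weights
#' (drug selection removes uninfected cells, which never carry a guide);
#' within a guide, cells are knockouts with probability equal to the
#' guide's efficiency; knockout cells grow as `2^(d * (1 + f))` against
#' `2^d` for unedited cells over `d` doublings; the culture is passaged
#' through a `passage_floor * n_guides`-cell bottleneck; sequencing draws
#' `depth` reads multinomially. Replicate lines of a genotype differ only
#' by sampling noise. In deterministic mode every draw is replaced by its
#' expectation.
#'
#' @param library a [guide_library()].
#' @param truth a [generate_truth()] result covering all targeting genes.
#' @param config a [sim_config()].
#' @param seed integer seed; the screen is a pure function of
#'   (library, truth, config, seed).
#' @return A `simulated_screen` list: `library`, `truth`, `counts`
#'   ([count_matrix()]; plasmid column plus `n_lines` knockout and
#'   wild-type columns), `sheet` ([sample_sheet()]), `config`.
#' @export
simulate_screen <- function(library, truth, config, seed = 1) {
  stopifnot(inherits(library, "guide_library"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  missing_genes <- setdiff(library_genes(library), truth$genes$gene)
  if (length(missing_genes) > 0) {
    stop_iso("truth does not cover gene(s): ",
             paste(utils::head(missing_genes, 5), collapse = ", "),
             class = "isoscreen_validation_error")
  }
  f_of <- function(col) {
    f <- truth$genes[[col]][match(library$gene, truth$genes$gene)]
    f[is.na(f)] <- 0  # controls
    f
  }
  with_seed(seed + 2L, {
    n_guides <- nrow(library)
    w <- stats::rlnorm(n_guides, 0, config$plasmid_sigma)
    plasmid <- if (config$deterministic) {
      config$depth * w / sum(w)
    } else {
      as.numeric(stats::rmultinom(1, config$depth, w))
    }
    samples <- c("plasmid",
                 sprintf("ko_%d", seq_len(config$n_lines)),
                 sprintf("wt_%d", seq_len(config$n_lines)))
    m <- matrix(0, n_guides, length(samples),
                dimnames = list(library$guide_id, samples))
    m[, "plasmid"] <- plasmid
    for (i in seq_len(config$n_lines)) {
      m[, sprintf("ko_%d", i)] <-
        sim_one_sample(library, truth, config, f_of("f_knockout"), w)
      m[, sprintf("wt_%d", i)] <-
        sim_one_sample(library, truth, config, f_of("f_wildtype"), w)
    }
    counts <- if (config$deterministic) {
      structure(list(counts = m, depth = colSums(m),
                     unmatched = stats::setNames(rep(0, ncol(m)), colnames(m))),
                class = "count_matrix")
    } else {
      count_matrix(m)
    }
    sheet <- sample_sheet(data.frame(
      sample_id = samples,
      genotype = c("plasmid", rep("knockout", config$n_lines),
                   rep("wildtype", config$n_lines)),
      replicate = c("lib", sprintf("clone%d", seq_len(config$n_lines)),
                    sprintf("clone%d", seq_len(config$n_lines))),
      timepoint_days = c(0, rep(21, 2 * config$n_lines)),
      stringsAsFactors = FALSE))
    structure(list(library = library, truth = truth, counts = counts,
                   sheet = sheet, config = config),
              class = "simulated_screen")
  })
}

#' Training gene sets from planted truth
#'
#' Synthetic runs train the essentiality classifier on planted
#' core-essential genes (essential set) and a seeded random draw of
#' neutral genes (non-essential set).
#'
#' @param truth a `sim_truth`.
#' @param n_nonessential size of the neutral draw (default 100).
#' @param seed integer seed.
#' @return A [reference_gene_sets()].
#' @export
reference_sets_from_truth <- function(truth, n_nonessential = 100, seed = 1) {
  ess <- truth$genes$gene[truth$genes$class == "core_essential"]
  neutral <- truth$genes$gene[truth$genes$class == "neutral"]
  with_seed(seed + 3L, {
    reference_gene_sets(ess, sample(neutral, min(n_nonessential,
                                                 length(neutral))))
  })
}

#' Write simulated counts as FASTQ reads
#'
#' Emits, for each requested sample, exactly `count(g, s)` reads of the
#' form `flank5 + spacer + flank3` per guide, plus optional random decoy
#' reads guaranteed to contain no library spacer, shuffled into random
#' order. Quantifying the files recovers the counts exactly (decoys land
#' in the unmatched tally).
#'
#' @param screen a `simulated_screen` (counts must be integer mode).
#' @param dir output directory; files are named `<sample>.fastq` (or
#'   `.fastq.gz` when `gzip = TRUE`).
#' @param samples sample ids to write (default all).
#' @param flank5,flank3 constant flanking sequence around the spacer.
#' @param n_decoys random unmatched reads to spike per sample (default 0).
#' @param gzip write gzip-compressed FASTQ.
#' @param seed integer seed for shuffling and decoys.
#' @return Named vector of file paths.
#' @export
write_fastq <- function(screen, dir, samples = NULL, flank5 = "ACCG",
                        flank3 = "GTTT", n_decoys = 0, gzip = FALSE,
                        seed = 1) {
  counts <- if (inherits(screen, "simulated_screen")) screen$counts else screen
  library <- if (inherits(screen, "simulated_screen")) screen$library else
    attr(screen, "library")
  stopifnot(inherits(counts, "count_matrix"), inherits(library, "guide_library"))
  if (any(abs(counts$counts - round(counts$counts)) > 1e-8)) {
    stop_iso("FASTQ export needs integer counts (not deterministic mode)",
             class = "isoscreen_validation_error")
  }
  samples <- samples %||% colnames(counts$counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  read_len <- nchar(flank5) + max(nchar(library$sequence)) + nchar(flank3)
  paths <- stats::setNames(character(length(samples)), samples)
  with_seed(seed + 4L, {
    for (s in samples) {
      n <- counts$counts[, s]
      reads <- rep(paste0(flank5, library$sequence, flank3), times = n)
      if (n_decoys > 0) {
        decoys <- character(0)
        while (length(decoys) < n_decoys) {
          cand <- vapply(seq_len(n_decoys - length(decoys)), function(i)
            paste(sample(c("A", "C", "G", "T"), read_len, replace = TRUE),
                  collapse = ""), character(1))
          clean <- vapply(cand, function(r) {
            !any(vapply(library$sequence, function(sp)
              grepl(sp, r, fixed = TRUE), logical(1)))
          }, logical(1))
          decoys <- c(decoys, cand[clean])
        }
        reads <- c(reads, decoys)
      }
      if (length(reads) > 0) reads <- sample(reads)
      ext <- if (gzip) ".fastq.gz" else ".fastq"
      path <- file.path(dir, paste0(s, ext))
      con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
      if (length(reads) > 0) {
        rec <- paste0("@", s, ":", seq_along(reads), "\n", reads, "\n+\n",
                      strrep("I", nchar(reads)))
        writeLines(rec, con)
      }
      close(con)
      paths[s] <- path
    }
  })
  paths
}

#' Score dependency calls against planted truth
#'
#' Positives are the genes planted as `ko_specific`; precision and recall
#' of the `is_dependency` calls are computed against that set, with a
#' per-class breakdown of where the calls fell. Undefined ratios (no
#' positives, or no calls) are reported as `NA`, not 0.
#'
#' @param truth a `sim_truth`.
#' @param calls a [select_dependencies()] table.
#' @return A `recovery_report` list: `precision`, `recall`, `n_called`,
#'   `n_planted`, `true_positives`, `by_class` (calls per truth class),
#'   `missed` (planted genes not called).
#' @export
evaluate_recovery <- function(truth, calls) {
  stopifnot(inherits(truth, "sim_truth"))
  unknown <- setdiff(calls$gene, truth$genes$gene)
  if (length(unknown) > 0) {
    stop_iso("calls contain gene(s) outside the simulated universe: ",
             paste(utils::head(unknown, 5), collapse = ", "),
             class = "isoscreen_validation_error")
  }
  planted <- truth$genes$gene[truth$genes$class == "ko_specific"]
  called <- calls$gene[calls$is_dependency]
  tp <- length(intersect(called, planted))
  precision <- if (length(called) == 0) NA_real_ else tp / length(called)
  recall <- if (length(planted) == 0) NA_real_ else tp / length(planted)
  by_class <- table(truth$genes$class[match(called, truth$genes$gene)])
  structure(list(precision = precision, recall = recall,
                 n_called = length(called), n_planted = length(planted),
                 true_positives = tp,
                 by_class = by_class,
                 missed = setdiff(planted, called)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("recovery: precision %s, recall %s (%d called, %d planted, %d TP)\n",
              fmt(x$precision), fmt(x$recall), x$n_called, x$n_planted,
              x$true_positives))
  invisible(x)
}
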