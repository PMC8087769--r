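#' Reserved gene label for control guides
#'
#' Control (non-targeting or safe-harbor) guides are modelled as a guide
#' class, not as pseudo-genes; internally they all carry this reserved gene
#' label so they can never collide with a real targeting gene symbol.
#'
#' @return A length-1 character string.
#' @export
control_gene_label <- function() "__control__"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_iso <- function(..., class) {
  stop(structure(
    class = c(class, "isoscreen_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Construct and validate a guide library
#'
#' A guide library is a data frame with one row per sgRNA and columns
#' `guide_id`, `gene`, `sequence`, `guide_class`. Spacer sequences must be
#' 19-20 nt of A/C/G/T and unique across the whole library (a sequencing
#' read cannot be attributed to two guides), and `guide_id` must be unique.
#' Control guides (`guide_class == "control"`) are relabelled to the
#' reserved control gene so they never mix with targeting genes.
#'
#' @param df data frame with columns `guide_id`, `gene`, `sequence` and
#'   optionally `guide_class` (default `"targeting"`).
#' @return A `guide_library`: the validated data frame, with a
#'   `gene_index` attribute mapping each targeting gene to its guide ids.
#' @export
guide_library <- function(df) {
  required <- c("guide_id", "gene", "sequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_iso("guide library is missing column(s): ",
             paste(missing_cols, collapse = ", "),
             class = "isoscreen_format_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$guide_class)) df$guide_class <- "targeting"
  df$guide_id <- as.character(df$guide_id)
  df$gene <- as.character(df$gene)
  df$sequence <- toupper(as.character(df$sequence))
  df$guide_class <- as.character(df$guide_class)
  df <- df[, c("guide_id", "gene", "sequence", "guide_class")]

  bad_class <- setdiff(unique(df$guide_class), c("targeting", "control"))
  if (length(bad_class) > 0) {
    stop_iso("unknown guide_class value(s): ", paste(bad_class, collapse = ", "),
             class = "isoscreen_validation_error")
  }
  bad_seq <- !grepl("^[ACGT]{19,20}$", df$sequence)
  if (any(bad_seq)) {
    stop_iso("non-ACGT or wrong-length spacer sequence for guide(s): ",
             paste(utils::head(df$guide_id[bad_seq], 5), collapse = ", "),
             class = "isoscreen_validation_error")
  }
  dup_id <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup_id) > 0) {
    stop_iso("duplicate guide_id(s): ", paste(unique(dup_id), collapse = ", "),
             class = "isoscreen_validation_error")
  }
  dup_seq <- unique(df$sequence[duplicated(df$sequence)])
  if (length(dup_seq) > 0) {
    offenders <- df$guide_id[df$sequence %in% dup_seq]
    stop_iso("duplicate spacer sequence(s) shared by guides: ",
             paste(offenders, collapse = ", "),
             class = "isoscreen_validation_error")
  }
  df$gene[df$guide_class == "control"] <- control_gene_label()
  if (any(df$gene == control_gene_label() & df$guide_class == "targeting")) {
    stop_iso("targeting guides may not use the reserved control gene label",
             class = "isoscreen_validation_error")
  }

  targeting <- df[df$guide_class == "targeting", ]
  attr(df, "gene_index") <- split(targeting$guide_id, targeting$gene)
  class(df) <- c("guide_library", "data.frame")
  df
}

#' @export
print.guide_library <- function(x, ...) {
  genes <- library_genes(x)
  cat(sprintf("guide_library: %d guides (%d targeting %d genes, %d control)\n",
              nrow(x), sum(x$guide_class == "targeting"), length(genes),
              sum(x$guide_class == "control")))
  invisible(x)
}

#' Targeting genes of a library
#' @param library a `guide_library`
#' @return Character vector of targeting gene symbols (controls excluded).
#' @export
library_genes <- function(library) {
  sort(unique(library$gene[library$guide_class == "targeting"]))
}

#' Read / write a guide library TSV
#'
#' The interchange format is a tab-separated table with header columns
#' `guide_id`, `gene`, `sequence`, `guide_class` (the last optional on
#' read). Writing then reading reproduces the table byte-identically.
#'
#' @param path file path.
#' @return `read_library` returns a validated [guide_library()];
#'   `write_library` returns `path` invisibly.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) {
    stop_iso("library file not found: ", path, class = "isoscreen_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  guide_library(df)
}

#' @rdname read_library
#' @param library a `guide_library`
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "guide_library"))
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix
#'
#' Integer read counts, guides x samples. Column sums define the per-sample
#' matched depth; an optional `unmatched` vector records reads matching no
#' guide in each sample.
#'
#' @param counts integer matrix with rownames = guide ids and colnames =
#'   sample ids.
#' @param unmatched optional named integer vector of unmatched-read tallies
#'   per sample (default 0).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, unmatched = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_iso("count matrix needs guide ids as rownames and sample ids as colnames",
             class = "isoscreen_validation_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop_iso("counts must be finite non-negative integers",
             class = "isoscreen_validation_error")
  }
  storage.mode(counts) <- "double"  # exact for counts < 2^53, avoids int overflow in sums
  if (is.null(unmatched)) {
    unmatched <- stats::setNames(rep(0, ncol(counts)), colnames(counts))
  }
  unmatched <- unmatched[colnames(counts)]
  structure(list(counts = counts,
                 depth = colSums(counts),
                 unmatched = unmatched),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples; depth %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(format(x$depth, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Read / write a count matrix TSV
#'
#' The table has a `guide_id` column followed by one integer column per
#' sample. When a `library` is supplied on read, guides present in the
#' library but absent from the file are zero-filled and rows are reordered
#' to the library's guide order; guides in the file but not the library are
#' an error (use [validate_inputs()] for a non-fatal report).
#'
#' @param path file path.
#' @param library optional [guide_library()] for reconciliation.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, library = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"guide_id" %in% names(df)) {
    stop_iso("counts file has no guide_id column", class = "isoscreen_format_error")
  }
  ids <- as.character(df$guide_id)
  m <- as.matrix(df[, setdiff(names(df), "guide_id"), drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
      any(abs(m - round(m)) > 1e-8)) {
    stop_iso("counts file contains negative or non-integer entries",
             class = "isoscreen_validation_error")
  }
  rownames(m) <- ids
  if (!is.null(library)) {
    extra <- setdiff(ids, library$guide_id)
    if (length(extra) > 0) {
      stop_iso("counts contain guide(s) absent from library: ",
               paste(utils::head(extra, 5), collapse = ", "),
               class = "isoscreen_validation_error")
    }
    full <- matrix(0, nrow(library), ncol(m),
                   dimnames = list(library$guide_id, colnames(m)))
    full[ids, ] <- m
    m <- full
  }
  count_matrix(m)
}

#' @rdname read_counts
#' @param x a [count_matrix()]
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(guide_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / read a sample sheet
#'
#' One row per sequenced sample: `sample_id`, `genotype` (one of
#' `knockout`, `wildtype`, `plasmid`), `replicate` (clone label) and
#' `timepoint_days`. Exactly one plasmid reference sample is required;
#' replicate labels must be unique within genotype.
#'
#' @param df data frame with the four columns above.
#' @return A `sample_sheet` data frame.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "genotype", "replicate", "timepoint_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_iso("sample sheet is missing column(s): ",
             paste(missing_cols, collapse = ", "),
             class = "isoscreen_format_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$genotype <- as.character(df$genotype)
  df$replicate <- as.character(df$replicate)
  df$timepoint_days <- as.numeric(df$timepoint_days)
  bad_gt <- setdiff(unique(df$genotype), c("knockout", "wildtype", "plasmid"))
  if (length(bad_gt) > 0) {
    stop_iso("unknown genotype value(s): ", paste(bad_gt, collapse = ", "),
             class = "isoscreen_validation_error")
  }
  if (anyDuplicated(df$sample_id)) {
    stop_iso("duplicate sample_id in sample sheet",
             class = "isoscreen_validation_error")
  }
  if (sum(df$genotype == "plasmid") != 1) {
    stop_iso("exactly one plasmid reference sample is required",
             class = "isoscreen_validation_error")
  }
  if (any(df$timepoint_days < 0) || any(!is.finite(df$timepoint_days))) {
    stop_iso("timepoint_days must be non-negative", class = "isoscreen_validation_error")
  }
  for (gt in c("knockout", "wildtype")) {
    reps <- df$replicate[df$genotype == gt]
    if (anyDuplicated(reps)) {
      stop_iso("duplicate replicate label within genotype ", gt,
               class = "isoscreen_validation_error")
    }
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname sample_sheet
#' @param path TSV file path
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.delim(path, header = TRUE, sep = "\t",
                                 colClasses = "character", check.names = FALSE))
}

#' @rdname sample_sheet
#' @param sheet a `sample_sheet`
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample ids of one genotype, in sheet order
#' @param sheet a `sample_sheet`
#' @param genotype `"knockout"`, `"wildtype"` or `"plasmid"`
#' @export
samples_of <- function(sheet, genotype) {
  sheet$sample_id[sheet$genotype == genotype]
}

#' Reference essential / non-essential training gene sets
#'
#' Two disjoint, non-empty gene sets used to train the fold-change density
#' classifier. They are intersected with the library's targeting genes
#' before use ([validate_inputs()] reports the dropped symbols).
#'
#' @param essential,nonessential character vectors of gene symbols.
#' @return A `reference_gene_sets` list with elements `essential` and
#'   `nonessential`.
#' @export
reference_gene_sets <- function(essential, nonessential) {
  essential <- unique(as.character(essential))
  nonessential <- unique(as.character(nonessential))
  if (length(essential) == 0 || length(nonessential) == 0) {
    stop_iso("both reference gene sets must be non-empty",
             class = "isoscreen_validation_error")
  }
  overlap <- intersect(essential, nonessential)
  if (length(overlap) > 0) {
    stop_iso("reference gene sets overlap: ", paste(utils::head(overlap, 5), collapse = ", "),
             class = "isoscreen_validation_error")
  }
  structure(list(essential = essential, nonessential = nonessential),
            class = "reference_gene_sets")
}

#' @rdname reference_gene_sets
#' @param essential_path,nonessential_path plain-text files, one gene per line
#' @export
read_gene_sets <- function(essential_path, nonessential_path) {
  rd <- function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    x[nzchar(x)]
  }
  reference_gene_sets(rd(essential_path), rd(nonessential_path))
}

#' Cross-validate library, counts, sample sheet and reference sets
#'
#' Produces a deterministic, order-independent report of inconsistencies.
#' Fatal issues (guides counted that the library does not contain; counted
#' samples missing from the sample sheet) abort unless `force = TRUE`;
#' warnings (reference genes absent from the library, which are simply
#' dropped from training; sheet samples without counts) are reported only.
#'
#' @param library a [guide_library()]
#' @param counts a [count_matrix()]
#' @param sheet a [sample_sheet()]
#' @param refsets optional [reference_gene_sets()]
#' @param force if `TRUE`, fatal issues are downgraded to messages.
#' @return A data frame with columns `severity`, `category`, `item`
#'   (zero rows when fully consistent), invisibly classed
#'   `validation_report`.
#' @export
validate_inputs <- function(library, counts, sheet, refsets = NULL,
                            force = FALSE) {
  issues <- list()
  add <- function(severity, category, items) {
    if (length(items) > 0) {
      issues[[length(issues) + 1L]] <<- data.frame(
        severity = severity, category = category, item = sort(items),
        stringsAsFactors = FALSE)
    }
  }
  add("fatal", "guide_not_in_library",
      setdiff(rownames(counts$counts), library$guide_id))
  add("warning", "library_guide_uncounted",
      setdiff(library$guide_id, rownames(counts$counts)))
  add("fatal", "sample_not_in_sheet",
      setdiff(colnames(counts$counts), sheet$sample_id))
  add("warning", "sheet_sample_uncounted",
      setdiff(sheet$sample_id, colnames(counts$counts)))
  if (!is.null(refsets)) {
    genes <- library_genes(library)
    add("warning", "refset_gene_not_in_library",
        setdiff(c(refsets$essential, refsets$nonessential), genes))
  }
  report <- if (length(issues) > 0) {
    do.call(rbind, issues)
  } else {
    data.frame(severity = character(0), category = character(0),
               item = character(0), stringsAsFactors = FALSE)
  }
  report <- report[order(report$severity, report$category, report$item), ,
                   drop = FALSE]
  rownames(report) <- NULL
  class(report) <- c("validation_report", "data.frame")
  if (any(report$severity == "fatal") && !force) {
    fat <- report[report$severity == "fatal", ]
    stop_iso("fatal input inconsistencies: ",
             paste(unique(fat$category), collapse = ", "),
             " (", nrow(fat), " item(s)); rerun with force = TRUE to proceed",
             class = "isoscreen_validation_error")
  }
  report
}
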