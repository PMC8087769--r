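#' Read-to-guide matching policy
#'
#' Adapter-trimmed reads are assigned to guides by exact spacer matching.
#' In `scan` mode (the default) every offset of the read is searched for a
#' library spacer and the leftmost hit wins; in `anchored` mode only the
#' substring starting at `anchor_offset` (0-based) is compared. Because the
#' library enforces unique spacers, a read can never be attributed to two
#' different guides at one position; at the same start position a shorter
#' spacer is tried before a longer one.
#'
#' @param mode `"scan"` or `"anchored"`.
#' @param anchor_offset 0-based offset of the spacer within the read
#'   (anchored mode only).
#' @param min_read_length reads shorter than this are discarded and tallied
#'   separately; default `NULL` means the library's longest spacer
#'   (plus `anchor_offset` in anchored mode).
#' @return A `match_policy` list.
#' @export
match_policy <- function(mode = c("scan", "anchored"), anchor_offset = 0L,
                         min_read_length = NULL) {
  mode <- match.arg(mode)
  anchor_offset <- as.integer(anchor_offset)
  if (anchor_offset < 0) {
    stop_iso("anchor_offset must be >= 0", class = "isoscreen_validation_error")
  }
  structure(list(mode = mode, anchor_offset = anchor_offset,
                 min_read_length = min_read_length),
            class = "match_policy")
}

read_fastq_sequences <- function(fastq) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) {
      stop_iso("failed to parse FASTQ ", fastq, ": ", conditionMessage(e),
               class = "isoscreen_format_error")
    })
  as.character(seqs)
}

#' Count one sample's reads against the guide library
#'
#' Each read increments exactly one guide or the unmatched tally, so
#' matched + unmatched + short-discarded always equals the number of input
#' reads. Matching is exact (0 mismatches) per [match_policy()].
#'
#' @param fastq path to a FASTQ or FASTQ.gz file of adapter-trimmed reads,
#'   or a character vector of read sequences.
#' @param library a validated [guide_library()].
#' @param policy a [match_policy()].
#' @return A list with `counts` (named integer vector over all library
#'   guides), `unmatched`, `short` and `total`.
#' @export
count_sample <- function(fastq, library, policy = match_policy()) {
  stopifnot(inherits(library, "guide_library"))
  reads <- if (is.character(fastq) && length(fastq) > 0 &&
               !file.exists(fastq[1]) && length(fastq) > 1) {
    fastq
  } else if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else {
    as.character(fastq)
  }
  reads <- toupper(reads)
  spacer_lens <- sort(unique(nchar(library$sequence)))
  min_len <- policy$min_read_length %||%
    (max(spacer_lens) + if (policy$mode == "anchored") policy$anchor_offset else 0L)

  total <- length(reads)
  keep <- nchar(reads) >= min_len
  short <- total - sum(keep)
  reads <- reads[keep]

  counts <- stats::setNames(rep(0, nrow(library)), library$guide_id)
  if (length(reads) == 0) {
    return(list(counts = counts, unmatched = 0L, short = short, total = total))
  }

  # guide index per read; NA = unassigned so far
  assigned <- rep(NA_integer_, length(reads))
  offsets <- if (policy$mode == "anchored") {
    policy$anchor_offset
  } else {
    0:(max(nchar(reads)) - min(spacer_lens))
  }
  for (off in offsets) {
    for (len in spacer_lens) {
      open <- which(is.na(assigned) & nchar(reads) >= off + len)
      if (length(open) == 0) next
      hit <- match(substr(reads[open], off + 1L, off + len), library$sequence)
      assigned[open[!is.na(hit)]] <- hit[!is.na(hit)]
    }
    if (!anyNA(assigned)) break
  }
  tab <- table(factor(assigned, levels = seq_len(nrow(library))))
  counts[] <- as.vector(tab)
  list(counts = counts, unmatched = sum(is.na(assigned)), short = short,
       total = total)
}

#' Count a whole screen into a count matrix
#'
#' Runs [count_sample()] for every sample in the sheet and assembles the
#' columns in sample-sheet order. Per-sample mapping rates are reported via
#' `message()`; a sample with zero reads yields a zero column with a
#' warning.
#'
#' @param sheet a [sample_sheet()].
#' @param fastq_paths named character vector (or list), one FASTQ path per
#'   `sample_id` in the sheet.
#' @param library a [guide_library()].
#' @param policy a [match_policy()].
#' @param quiet suppress per-sample mapping-rate messages.
#' @return A [count_matrix()] with the unmatched tallies attached.
#' @export
count_screen <- function(sheet, fastq_paths, library,
                         policy = match_policy(), quiet = FALSE) {
  stopifnot(inherits(sheet, "sample_sheet"))
  missing_samples <- setdiff(sheet$sample_id, names(fastq_paths))
  if (length(missing_samples) > 0) {
    stop_iso("no FASTQ supplied for sample(s): ",
             paste(missing_samples, collapse = ", "),
             class = "isoscreen_format_error")
  }
  absent <- !vapply(fastq_paths[sheet$sample_id], file.exists, logical(1))
  if (any(absent)) {
    stop_iso("FASTQ file(s) not found: ",
             paste(unlist(fastq_paths[sheet$sample_id][absent]), collapse = ", "),
             class = "isoscreen_format_error")
  }
  cols <- matrix(0, nrow(library), nrow(sheet),
                 dimnames = list(library$guide_id, sheet$sample_id))
  unmatched <- stats::setNames(rep(0, nrow(sheet)), sheet$sample_id)
  for (s in sheet$sample_id) {
    res <- count_sample(fastq_paths[[s]], library, policy)
    cols[, s] <- res$counts
    unmatched[s] <- res$unmatched
    if (res$total == 0) {
      warning("sample ", s, " has zero reads", call. = FALSE)
    } else if (!quiet) {
      message(sprintf("sample %s: %d reads, %.1f%% mapped, %d short",
                      s, res$total,
                      100 * sum(res$counts) / max(res$total, 1), res$short))
    }
  }
  count_matrix(cols, unmatched = unmatched)
}
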