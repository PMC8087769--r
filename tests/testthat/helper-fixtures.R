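# in-code fixtures shared across test files

# small fixed library: n_genes targeting genes x guides each, plus controls,
# with deterministic distinct spacers (no randomness needed)
tiny_library <- function(n_genes = 2, guides = 2, controls = 1) {
  enc <- c("A", "C", "G", "T")
  spacer <- function(i) {
    # base-4 encode i into a 20-mer so sequences are distinct by construction
    digits <- (i %/% 4^(0:19)) %% 4
    paste(enc[digits + 1], collapse = "")
  }
  n <- n_genes * guides + controls
  df <- data.frame(
    guide_id = c(sprintf("g%d_%d", rep(seq_len(n_genes), each = guides),
                         rep(seq_len(guides), n_genes)),
                 sprintf("ctrl%d", seq_len(controls))),
    gene = c(rep(sprintf("GENE%d", seq_len(n_genes)), each = guides),
             rep("na", controls)),
    sequence = vapply(seq_len(n), spacer, character(1)),
    guide_class = c(rep("targeting", n_genes * guides),
                    rep("control", controls)),
    stringsAsFactors = FALSE)
  guide_library(df)
}

# counts fixture over a library, filled deterministically
tiny_counts <- function(library, samples = c("plasmid", "s1"), base = 100) {
  m <- matrix(base + seq_len(nrow(library) * length(samples)),
              nrow = nrow(library),
              dimnames = list(library$guide_id, samples))
  count_matrix(m)
}

tiny_sheet <- function(samples = c("plasmid", "s1"),
                       genotypes = c("plasmid", "knockout")) {
  sample_sheet(data.frame(
    sample_id = samples, genotype = genotypes,
    replicate = paste0("r", seq_along(samples)),
    timepoint_days = ifelse(genotypes == "plasmid", 0, 21),
    stringsAsFactors = FALSE))
}

# write a FASTQ file from raw read sequences
write_test_fastq <- function(reads, path = tempfile(fileext = ".fastq"),
                             gzip = FALSE) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  if (length(reads) > 0) {
    writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                      strrep("I", nchar(reads))), con)
  }
  close(con)
  path
}

# parametric Gaussian density hook: essential N(-3, 1), non-essential N(0, 1)
gaussian_hook <- function() {
  density_pair(function(x) stats::dnorm(x, -3, 1),
               function(x) stats::dnorm(x, 0, 1))
}

# wrap a named numeric vector as a single-sample fold-change table
as_fc_table <- function(x, sample = "s1") {
  structure(matrix(x, ncol = 1, dimnames = list(names(x), sample)),
            alpha = 0, scale = 1e7, plasmid_sample = "plasmid",
            class = c("fold_change_table", "matrix", "array"))
}

# fast simulation scale for pipeline-level tests
fast_sim <- function(...) {
  sim_config(n_genes = 150, n_control_guides = 10, depth = 2e5,
             coverage = 100, passage_floor = 100,
             n_core_essential = 25, n_ko_specific = 10, ...)
}
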