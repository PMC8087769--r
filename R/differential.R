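#' Linear model of knockout gene BF on wild-type gene BF
#'
#' Ordinary least squares with intercept, wild-type BF as the predictor and
#' knockout BF as the response, one point per gene. The residuals measure
#' how much more (or less) lethal a gene's knockout is in the mutant
#' background than its wild-type essentiality predicts.
#'
#' @param bf_wt,bf_ko named numeric vectors of per-gene Bayes factors
#'   (names = gene symbols). Genes missing from either vector, or with a
#'   non-finite value, are excluded and listed in the result.
#' @return A `bf_model_fit` list: `slope`, `intercept`, `n`, `rss`,
#'   `fitted` and `residuals` (named by gene), `excluded` (gene symbols
#'   dropped).
#' @export
fit_bf_linear_model <- function(bf_wt, bf_ko) {
  genes <- union(names(bf_wt), names(bf_ko))
  common <- intersect(names(bf_wt), names(bf_ko))
  common <- common[is.finite(bf_wt[common]) & is.finite(bf_ko[common])]
  excluded <- setdiff(genes, common)
  if (length(common) < 3) {
    stop_iso("need >= 3 genes with finite BF in both genotypes, got ",
             length(common), class = "isoscreen_validation_error")
  }
  x <- bf_wt[common]
  y <- bf_ko[common]
  if (stats::sd(x) == 0) {
    stop_iso("zero variance in wild-type BF predictor",
             class = "isoscreen_validation_error")
  }
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), y)
  res <- stats::setNames(as.numeric(fit$residuals), common)
  structure(list(slope = unname(fit$coefficients["slope"]),
                 intercept = unname(fit$coefficients["intercept"]),
                 n = length(common),
                 rss = sum(res^2),
                 fitted = stats::setNames(as.numeric(fit$fitted.values), common),
                 residuals = res,
                 excluded = sort(excluded)),
            class = "bf_model_fit")
}

#' @export
print.bf_model_fit <- function(x, ...) {
  cat(sprintf("bf_model_fit: ko_bf = %.4f + %.4f * wt_bf over %d genes (rss %.3g)\n",
              x$intercept, x$slope, x$n, x$rss))
  if (length(x$excluded) > 0) {
    cat(" excluded (missing a genotype):", length(x$excluded), "gene(s)\n")
  }
  invisible(x)
}

#' Standardized residuals (Z scores)
#'
#' `z = (residual - mean(residuals)) / stddev(residuals)`. The default
#' standard-deviation convention is the population form (divide by n),
#' the literal reading of "stddev of all residuals"; the sample (n - 1)
#' form is available. At genome scale the two are indistinguishable.
#'
#' @param residuals named numeric vector.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Named numeric vector of Z scores (mean 0, chosen-convention
#'   sd 1).
#' @export
residual_z_scores <- function(residuals, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(residuals) < 2) {
    stop_iso("need >= 2 residuals to standardize", class = "isoscreen_validation_error")
  }
  m <- mean(residuals)
  s <- stats::sd(residuals)
  if (sd_type == "population") {
    s <- s * sqrt((length(residuals) - 1) / length(residuals))
  }
  if (!is.finite(s) || s == 0) {
    stop_iso("residuals have zero variance; Z scores undefined",
             class = "isoscreen_validation_error")
  }
  (residuals - m) / s
}

#' Call selective dependencies from Z scores
#'
#' A gene is called a dependency when its Z score strictly exceeds the
#' threshold (default 3.5); ties at exactly the threshold are not called.
#' Genes are ranked 1..n by descending Z, ties broken alphabetically.
#'
#' @param z named numeric vector of per-gene Z scores.
#' @param threshold calling threshold (default 3.5).
#' @param fit optional [fit_bf_linear_model()] result used to carry
#'   `bf_wt`/`bf_ko`/`fitted`/`residual` columns into the table.
#' @param bf_wt,bf_ko optional named vectors for the same purpose.
#' @return A `differential_table` data frame sorted by rank, with columns
#'   `gene`, (`bf_wt`, `bf_ko`, `fitted`, `residual` when available), `z`,
#'   `rank`, `is_dependency`.
#' @export
select_dependencies <- function(z, threshold = 3.5, fit = NULL,
                                bf_wt = NULL, bf_ko = NULL) {
  if (length(z) == 0) {
    out <- data.frame(gene = character(0), z = numeric(0),
                      rank = integer(0), is_dependency = logical(0))
    class(out) <- c("differential_table", "data.frame")
    return(out)
  }
  ord <- order(-z, names(z))
  out <- data.frame(gene = names(z)[ord], z = as.numeric(z[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out$is_dependency <- out$z > threshold
  if (!is.null(fit)) {
    out$fitted <- as.numeric(fit$fitted[out$gene])
    out$residual <- as.numeric(fit$residuals[out$gene])
  }
  if (!is.null(bf_wt)) out$bf_wt <- as.numeric(bf_wt[out$gene])
  if (!is.null(bf_ko)) out$bf_ko <- as.numeric(bf_ko[out$gene])
  cols <- intersect(c("gene", "bf_wt", "bf_ko", "fitted", "residual",
                      "z", "rank", "is_dependency"), names(out))
  out <- out[, cols]
  attr(out, "threshold") <- threshold
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Hypergeometric term enrichment of the dependency calls
#'
#' One-sided upper-tail hypergeometric test per annotation term: with
#' universe size N, K genes carrying the term, n selected genes and k
#' selected genes carrying the term, `p = P(X >= k)` for
#' X ~ Hypergeometric(N, K, n), and fold enrichment `(k/n) / (K/N)`.
#' P-values are reported unadjusted (screen-analysis convention for
#' exploratory annotation); a Benjamini-Hochberg column is included for
#' convenience.
#'
#' @param selected character vector of called genes.
#' @param annotation named list: term -> character vector of genes.
#' @param universe character vector of all genes eligible for selection;
#'   must contain `selected`. Annotation sets are intersected with it.
#' @return Data frame `term`, `N`, `K`, `n`, `k`, `fold_enrichment`, `p`,
#'   `p_bh`, sorted by `p`. Terms with K = 0 after restriction are skipped
#'   with a note.
#' @export
enrichment_test <- function(selected, annotation, universe) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) {
    stop_iso("selected genes must be a subset of the universe",
             class = "isoscreen_validation_error")
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(annotation), function(term) {
    members <- intersect(unique(annotation[[term]]), universe)
    K <- length(members)
    if (K == 0) {
      message("term '", term, "' has no genes in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(selected, members))
    p <- if (n == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n == 0) NA_real_ else (k / n) / (K / N)
    data.frame(term = term, N = N, K = K, n = n, k = k,
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      p_bh = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
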