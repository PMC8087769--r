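#' Guide-level log2 fold change against the plasmid library
#'
#' For guide g in sample s with pseudocount `alpha` and scale `S`,
#' `fc(g, s) = log2((c[g,s] + alpha) * S / depth_s) -
#'             log2((c[g,plasmid] + alpha) * S / depth_plasmid)`.
#' The pseudocount keeps fold changes finite at zero counts; the scale
#' cancels in the difference and is retained for interpretable
#' normalized-abundance intermediates (reads per `S`).
#'
#' @param counts a [count_matrix()].
#' @param plasmid_sample sample id of the plasmid reference column.
#' @param alpha pseudocount, > 0 (default 5).
#' @param scale normalization scale S (default 1e7).
#' @param samples sample ids to compute fold changes for; default all
#'   non-plasmid columns.
#' @return A `fold_change_table`: numeric matrix guides x samples of log2
#'   fold changes, with `alpha`, `scale` and `plasmid_sample` attributes.
#' @export
guide_log_fold_change <- function(counts, plasmid_sample, alpha = 5,
                                  scale = 1e7, samples = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!plasmid_sample %in% colnames(counts$counts)) {
    stop_iso("plasmid sample ", plasmid_sample, " not present in counts",
             class = "isoscreen_validation_error")
  }
  if (alpha <= 0) {
    stop_iso("pseudocount alpha must be > 0", class = "isoscreen_validation_error")
  }
  samples <- samples %||% setdiff(colnames(counts$counts), plasmid_sample)
  used <- c(samples, plasmid_sample)
  if (any(counts$depth[used] == 0)) {
    stop_iso("zero sequencing depth in sample(s): ",
             paste(used[counts$depth[used] == 0], collapse = ", "),
             class = "isoscreen_validation_error")
  }
  norm <- function(s) log2((counts$counts[, s] + alpha) * scale / counts$depth[s])
  ref <- norm(plasmid_sample)
  fc <- vapply(samples, function(s) norm(s) - ref,
               numeric(nrow(counts$counts)))
  fc <- matrix(fc, nrow = nrow(counts$counts),
               dimnames = list(rownames(counts$counts), samples))
  structure(fc, alpha = alpha, scale = scale, plasmid_sample = plasmid_sample,
            class = c("fold_change_table", "matrix", "array"))
}

gaussian_kde <- function(train, bandwidth, floor_eps) {
  force(train); force(bandwidth); force(floor_eps)
  function(x) {
    # exact Gaussian kernel mixture, chunked to bound memory
    out <- numeric(length(x))
    step <- max(1L, floor(5e6 / length(train)))
    for (i in seq(1, length(x), by = step)) {
      idx <- i:min(i + step - 1L, length(x))
      z <- outer(x[idx], train, "-") / bandwidth
      out[idx] <- rowMeans(stats::dnorm(z)) / bandwidth
    }
    pmax(out, floor_eps)
  }
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (!is.finite(s) || s == 0) s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 0.1  # degenerate training cloud
  0.9 * s * n^(-1 / 5)
}

#' Essential / non-essential fold-change densities
#'
#' Fits one-dimensional Gaussian kernel density estimates to the fold
#' changes of guides targeting the reference essential and non-essential
#' training genes. Evaluations are floored at `floor_eps` so downstream
#' log likelihood ratios stay finite in the tails.
#'
#' @param fc a [guide_log_fold_change()] table.
#' @param library a [guide_library()].
#' @param refsets a [reference_gene_sets()]; genes absent from the library
#'   are dropped silently (see [validate_inputs()] for reporting).
#' @param samples which fold-change columns feed the training cloud
#'   (default: all).
#' @param bandwidth `"silverman"` or a positive number.
#' @param floor_eps density floor (default 1e-12).
#' @param min_train minimum training guides per class (default 10).
#' @param clamp_eps reliability bound used to derive the evaluation clamp:
#'   fold changes are clamped into `[lo, hi]` where `lo` is the leftmost
#'   point at which the non-essential density still exceeds `clamp_eps`
#'   (default `2^-7`) and `hi` is the position of the minimum log ratio
#'   right of `lo` (so the ratio cannot spuriously rise again in the
#'   right tail). The clamp bounds per-observation likelihood ratios, so
#'   one outlying fold change cannot dominate a gene's score. Set to
#'   `NULL` to disable.
#' @return A `density_pair` with evaluator functions `essential` and
#'   `nonessential`, the training vectors, bandwidths and the `clamp`
#'   interval applied by [log_likelihood_ratio()].
#' @export
fit_densities <- function(fc, library, refsets, samples = colnames(fc),
                          bandwidth = "silverman", floor_eps = 1e-12,
                          min_train = 10, clamp_eps = 2^-7) {
  stopifnot(inherits(fc, "fold_change_table"))
  train_of <- function(genes) {
    ids <- library$guide_id[library$gene %in% genes &
                            library$guide_class == "targeting"]
    as.vector(fc[ids, samples, drop = FALSE])
  }
  ess <- train_of(refsets$essential)
  non <- train_of(refsets$nonessential)
  for (cls in c("essential", "nonessential")) {
    n <- length(if (cls == "essential") ess else non)
    if (n < min_train) {
      stop_iso("under-populated training class '", cls, "': ", n,
               " guide observation(s), need >= ", min_train,
               class = "isoscreen_validation_error")
    }
  }
  bw <- function(x) if (identical(bandwidth, "silverman")) silverman_bw(x) else
    as.numeric(bandwidth)
  bw_ess <- bw(ess); bw_non <- bw(non)
  if (bw_ess <= 0 || bw_non <= 0) {
    stop_iso("bandwidth must be positive", class = "isoscreen_validation_error")
  }
  d_ess <- gaussian_kde(ess, bw_ess, floor_eps)
  d_non <- gaussian_kde(non, bw_non, floor_eps)
  clamp <- NULL
  if (!is.null(clamp_eps)) {
    all_train <- c(ess, non)
    grid <- seq(min(all_train) - 3 * max(bw_ess, bw_non),
                max(all_train) + 3 * max(bw_ess, bw_non), by = 0.01)
    reliable <- grid[d_non(grid) > clamp_eps]
    if (length(reliable) >= 2) {
      lo <- min(reliable)
      sub <- grid[grid >= lo & grid <= max(reliable)]
      lr <- log2(d_ess(sub)) - log2(d_non(sub))
      hi <- sub[which.min(lr)]
      if (hi > lo) clamp <- c(lo = lo, hi = hi)
    }
  }
  density_pair(d_ess, d_non,
               bandwidth = c(essential = bw_ess, nonessential = bw_non),
               train = list(essential = ess, nonessential = non),
               floor_eps = floor_eps, clamp = clamp)
}

#' Build a density pair from arbitrary density functions
#'
#' The Bayes-factor core only needs two evaluable densities; this
#' constructor is also the parametric test hook (e.g. two Gaussians) that
#' lets the scoring path be checked against closed forms.
#'
#' @param essential,nonessential vectorized density functions.
#' @param bandwidth,train,floor_eps,clamp optional metadata (filled by
#'   [fit_densities()]); `clamp = c(lo, hi)` bounds the evaluation range
#'   used by [log_likelihood_ratio()].
#' @return A `density_pair` list.
#' @export
density_pair <- function(essential, nonessential, bandwidth = NULL,
                         train = NULL, floor_eps = 0, clamp = NULL) {
  stopifnot(is.function(essential), is.function(nonessential))
  structure(list(essential = essential, nonessential = nonessential,
                 bandwidth = bandwidth, train = train, floor_eps = floor_eps,
                 clamp = clamp),
            class = "density_pair")
}

#' Per-observation log2 likelihood ratio
#'
#' Fold changes are first clamped into the pair's evaluation bounds when
#' present (see [fit_densities()]), then scored as
#' `log2(p_essential(x) / p_nonessential(x))`.
#'
#' @param densities a [density_pair()]
#' @param x fold-change values
#' @return Log likelihood ratios in bits.
#' @export
log_likelihood_ratio <- function(densities, x) {
  if (!is.null(densities$clamp)) {
    x <- pmin(pmax(x, densities$clamp["lo"]), densities$clamp["hi"])
  }
  log2(densities$essential(x)) - log2(densities$nonessential(x))
}

#' Gene-level Bayes-factor lethality scores
#'
#' For each targeting gene, the Bayes factor is the sum, over the gene's
#' guide x sample fold-change observations, of the log2 likelihood ratio of
#' the essential vs non-essential densities. Positive BF (bits) = the
#' gene's guides drop out like essential-gene guides. Optional
#' bootstrapping refits the densities on training genes resampled with
#' replacement and reports the bootstrap mean and sd.
#'
#' @param fc a [guide_log_fold_change()] table.
#' @param library a [guide_library()].
#' @param densities a [density_pair()], or `NULL` to fit via
#'   [fit_densities()] (then `refsets` is required).
#' @param samples fold-change columns to score (default all); their LRs are
#'   summed per gene.
#' @param refsets training sets, used when `densities` is `NULL` and for
#'   bootstrap refits.
#' @param boot number of bootstrap iterations (0 = plain fit; default 0,
#'   see the methods vignette on runtime).
#' @param min_train minimum training observations per class, passed to
#'   [fit_densities()].
#' @param seed integer seed for the bootstrap resampling.
#' @param bandwidth,floor_eps passed to [fit_densities()].
#' @return A `bayes_factor_table` data frame: `gene`, `bf`, `n_guides`,
#'   `n_obs`, and `boot_mean` / `boot_sd` when `boot > 0` (then `bf` is the
#'   bootstrap mean). Control guides are excluded; genes with zero usable
#'   guides are absent rather than zero.
#' @export
gene_bayes_factor <- function(fc, library, densities = NULL,
                              samples = colnames(fc), refsets = NULL,
                              boot = 0, seed = 1, bandwidth = "silverman",
                              floor_eps = 1e-12, min_train = 10) {
  stopifnot(inherits(fc, "fold_change_table"))
  targeting <- library[library$guide_class == "targeting", ]
  gene_of <- targeting$gene[match(rownames(fc), targeting$guide_id)]
  usable <- !is.na(gene_of)

  score_once <- function(dp) {
    lr <- log_likelihood_ratio(dp, as.vector(fc[usable, samples, drop = FALSE]))
    gene_rep <- rep(gene_of[usable], times = length(samples))
    tapply(lr, gene_rep, sum)
  }

  if (is.null(densities)) {
    if (is.null(refsets)) {
      stop_iso("either densities or refsets must be supplied",
               class = "isoscreen_validation_error")
    }
    densities <- fit_densities(fc, library, refsets, samples = samples,
                               bandwidth = bandwidth, floor_eps = floor_eps,
                               min_train = min_train)
  }
  bf <- score_once(densities)

  boot_mean <- boot_sd <- NULL
  if (boot > 0) {
    if (is.null(refsets)) {
      stop_iso("bootstrapping requires refsets to resample training genes",
               class = "isoscreen_validation_error")
    }
    genes_in_lib <- library_genes(library)
    ess_pool <- intersect(refsets$essential, genes_in_lib)
    non_pool <- intersect(refsets$nonessential, genes_in_lib)
    set.seed(as.integer(seed))
    draws <- matrix(NA_real_, length(bf), boot,
                    dimnames = list(names(bf), NULL))
    for (b in seq_len(boot)) {
      rs <- reference_gene_sets(sample(ess_pool, replace = TRUE),
                                setdiff(sample(non_pool, replace = TRUE),
                                        ess_pool))
      dp_b <- fit_densities(fc, library, rs, samples = samples,
                            bandwidth = bandwidth, floor_eps = floor_eps,
                            min_train = min_train)
      draws[, b] <- score_once(dp_b)[names(bf)]
    }
    boot_mean <- rowMeans(draws)
    boot_sd <- apply(draws, 1, stats::sd)
    bf <- boot_mean
  }

  n_guides <- tapply(rep(1L, sum(usable)), gene_of[usable], sum)
  out <- data.frame(gene = names(bf), bf = as.numeric(bf),
                    n_guides = as.integer(n_guides[names(bf)]),
                    n_obs = as.integer(n_guides[names(bf)]) * length(samples),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(boot_sd)) {
    out$boot_mean <- as.numeric(boot_mean[out$gene])
    out$boot_sd <- as.numeric(boot_sd[out$gene])
  }
  class(out) <- c("bayes_factor_table", "data.frame")
  out
}

#' Aggregate per-replicate-line Bayes factors by genotype
#'
#' Each clonal line of a genotype is scored separately; this combines them
#' into one BF per (gene, genotype), by arithmetic mean by default.
#'
#' @param bf_lines named list of [gene_bayes_factor()] tables, one per
#'   replicate line, grouped as `list(knockout = list(...), wildtype =
#'   list(...))`.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return A data frame `gene`, `genotype`, `bf`, `n_lines`. Genes present
#'   in only one genotype are kept here but flagged and excluded by
#'   [fit_bf_linear_model()].
#' @export
genotype_bf <- function(bf_lines, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  fun <- if (aggregate == "mean") mean else stats::median
  rows <- lapply(names(bf_lines), function(gt) {
    tabs <- bf_lines[[gt]]
    if (length(tabs) == 0) {
      stop_iso("genotype ", gt, " has no replicate lines",
               class = "isoscreen_validation_error")
    }
    long <- do.call(rbind, lapply(tabs, function(t) t[, c("gene", "bf")]))
    agg <- tapply(long$bf, long$gene, fun)
    n <- tapply(long$bf, long$gene, length)
    data.frame(gene = names(agg), genotype = gt, bf = as.numeric(agg),
               n_lines = as.integer(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
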