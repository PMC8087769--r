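test_that("guide log fold change follows the closed form", {
  lib <- tiny_library(n_genes = 1, guides = 2, controls = 0)
  m <- matrix(c(100, 100, 100, 100), 2,
              dimnames = list(lib$guide_id, c("plasmid", "s1")))
  cm <- count_matrix(m)
  fc <- guide_log_fold_change(cm, "plasmid", alpha = 5)
  expect_equal(unname(fc[, "s1"]), c(0, 0))   # identical counts and depths

  m2 <- matrix(c(100, 100, 10, 190), 2,
               dimnames = list(lib$guide_id, c("plasmid", "s1")))
  fc2 <- guide_log_fold_change(count_matrix(m2), "plasmid", alpha = 5)
  # equal depths (200 each): fc = log2(15/105)
  expect_equal(unname(fc2["g1_1", "s1"]), log2(15 / 105), tolerance = 1e-9)
  expect_equal(unname(fc2["g1_1", "s1"]), -2.8074, tolerance = 1e-4)

  # zero count stays finite thanks to the pseudocount
  m3 <- matrix(c(100, 100, 0, 200), 2,
               dimnames = list(lib$guide_id, c("plasmid", "s1")))
  fc3 <- guide_log_fold_change(count_matrix(m3), "plasmid", alpha = 5)
  expect_true(is.finite(fc3["g1_1", "s1"]) && fc3["g1_1", "s1"] < 0)

  expect_error(guide_log_fold_change(cm, "plasmid", alpha = 0),
               class = "isoscreen_validation_error")
  zero <- count_matrix(matrix(0, 2, 2, dimnames = dimnames(m)))
  expect_error(guide_log_fold_change(zero, "plasmid"),
               class = "isoscreen_validation_error")
})

test_that("fold change is depth-scaling consistent", {
  lib <- tiny_library(n_genes = 2, guides = 2, controls = 0)
  set.seed(42)
  base <- matrix(rpois(8, 200) + 1, 4,
                 dimnames = list(lib$guide_id, c("plasmid", "s1")))
  scaled <- base
  scaled[, "s1"] <- scaled[, "s1"] * 10   # depth and counts both x10
  a <- guide_log_fold_change(count_matrix(base), "plasmid", alpha = 1e-9)
  b <- guide_log_fold_change(count_matrix(scaled), "plasmid", alpha = 1e-9)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("KDE evaluation equals a brute-force kernel sum", {
  lib <- tiny_library(n_genes = 4, guides = 3, controls = 0)
  set.seed(7)
  fc <- as_fc_table(stats::setNames(
    c(rnorm(6, -3, 0.5), rnorm(6, 0, 0.5)), lib$guide_id))
  rs <- reference_gene_sets(c("GENE1", "GENE2"), c("GENE3", "GENE4"))
  dp <- fit_densities(fc, lib, rs, min_train = 5)

  xs <- seq(-5, 2, by = 0.37)
  for (cls in c("essential", "nonessential")) {
    train <- dp$train[[cls]]
    bw <- dp$bandwidth[[cls]]
    brute <- vapply(xs, function(x) {
      acc <- 0
      for (t in train) acc <- acc + stats::dnorm((x - t) / bw)
      max(acc / (length(train) * bw), 1e-12)
    }, numeric(1))
    expect_equal(dp[[cls]](xs), brute, tolerance = 1e-9)
  }
})

test_that("density fit behaviour: peaks, symmetry, under-population", {
  lib <- tiny_library(n_genes = 2, guides = 10, controls = 0)
  ids <- lib$guide_id
  fc <- as_fc_table(stats::setNames(
    c(rep(-3, 10), rep(0, 10)), ids))
  rs <- reference_gene_sets("GENE1", "GENE2")
  dp <- fit_densities(fc, lib, rs, bandwidth = 0.1, clamp_eps = NULL)
  # point-mass training at -3 / 0 with a small kernel peaks there
  expect_gt(dp$essential(-3), dp$essential(-2))
  expect_gt(dp$nonessential(0), dp$nonessential(-1))
  # symmetric training sets cross at the midpoint
  expect_equal(dp$essential(-1.5), dp$nonessential(-1.5), tolerance = 1e-12)
  expect_equal(log_likelihood_ratio(dp, -1.5), 0, tolerance = 1e-9)

  err <- tryCatch(fit_densities(fc, lib, rs, min_train = 11),
                  error = identity)
  expect_s3_class(err, "isoscreen_validation_error")
  expect_match(conditionMessage(err), "essential")
})

test_that("densities integrate to one over their support", {
  lib <- tiny_library(n_genes = 2, guides = 10, controls = 0)
  set.seed(11)
  fc <- as_fc_table(stats::setNames(c(rnorm(10, -2), rnorm(10, 0, 0.4)),
                                    lib$guide_id))
  dp <- fit_densities(fc, lib, reference_gene_sets("GENE1", "GENE2"))
  for (cls in c("essential", "nonessential")) {
    ig <- stats::integrate(dp[[cls]], -30, 30, subdivisions = 2000)
    expect_equal(ig$value, 1, tolerance = 1e-3)
  }
})

test_that("parametric hook reproduces the Gaussian closed forms", {
  hook <- gaussian_hook()
  expect_equal(log_likelihood_ratio(hook, -3), 4.5 / log(2), tolerance = 1e-9)
  expect_equal(log_likelihood_ratio(hook, -3), 6.4924, tolerance = 1e-4)
  expect_equal(log_likelihood_ratio(hook, -1.5), 0, tolerance = 1e-12)

  # one gene, three guides all at fc = -3
  lib <- tiny_library(n_genes = 1, guides = 3, controls = 0)
  fc <- as_fc_table(stats::setNames(rep(-3, 3), lib$guide_id))
  bf <- gene_bayes_factor(fc, lib, densities = hook)
  expect_equal(bf$bf, 3 * 4.5 / log(2), tolerance = 1e-9)
  expect_equal(bf$bf, 19.477, tolerance = 1e-3)
  expect_equal(bf$n_guides, 3)
})

test_that("BF matches the analytic Gaussian quadratic form on random input", {
  # with ess N(-3,1), non N(0,1): LR(x) = (-3x - 4.5) / ln 2
  hook <- gaussian_hook()
  lib <- tiny_library(n_genes = 5, guides = 3, controls = 2)
  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::setNames(rnorm(nrow(lib), -1, 2), lib$guide_id)
    fc <- as_fc_table(x)
    bf <- gene_bayes_factor(fc, lib, densities = hook)
    targeting <- lib[lib$guide_class == "targeting", ]
    expected <- tapply((-3 * x[targeting$guide_id] - 4.5) / log(2),
                       targeting$gene, sum)
    expect_equal(stats::setNames(bf$bf, bf$gene),
                 stats::setNames(as.numeric(expected[bf$gene]), bf$gene),
                 tolerance = 1e-9)
  }
  # controls are excluded from gene-level output
  bf <- gene_bayes_factor(as_fc_table(stats::setNames(rnorm(nrow(lib)),
                                                      lib$guide_id)),
                          lib, densities = hook)
  expect_false(control_gene_label() %in% bf$gene)
})

test_that("BF is additive over guide and replicate observations", {
  hook <- gaussian_hook()
  lib <- tiny_library(n_genes = 1, guides = 2, controls = 0)
  fc2 <- structure(matrix(c(-1, -2, -3, 0), 2,
                          dimnames = list(lib$guide_id, c("r1", "r2"))),
                   class = c("fold_change_table", "matrix", "array"))
  bf_both <- gene_bayes_factor(fc2, lib, densities = hook,
                               samples = c("r1", "r2"))
  bf_r1 <- gene_bayes_factor(fc2, lib, densities = hook, samples = "r1")
  bf_r2 <- gene_bayes_factor(fc2, lib, densities = hook, samples = "r2")
  expect_equal(bf_both$bf, bf_r1$bf + bf_r2$bf, tolerance = 1e-12)
})

test_that("KDE path converges to the parametric answer with training size", {
  lib <- tiny_library(n_genes = 2, guides = 10, controls = 0)
  set.seed(99)
  # big synthetic training clouds injected through the density_pair surface
  ess_train <- rnorm(4000, -3, 1)
  non_train <- rnorm(4000, 0, 1)
  mk <- function(train) {
    bw <- 0.9 * min(sd(train), IQR(train) / 1.349) * length(train)^(-1 / 5)
    function(x) vapply(x, function(xi)
      max(mean(stats::dnorm((xi - train) / bw)) / bw, 1e-12), numeric(1))
  }
  dp <- density_pair(mk(ess_train), mk(non_train))
  expect_equal(log_likelihood_ratio(dp, -3), 4.5 / log(2), tolerance = 0.5)
  expect_equal(log_likelihood_ratio(dp, -1.5), 0, tolerance = 0.5)
})

test_that("bootstrap reports mean and sd and is seed-deterministic", {
  lib <- tiny_library(n_genes = 6, guides = 3, controls = 0)
  set.seed(3)
  x <- stats::setNames(c(rnorm(9, -3, 0.4), rnorm(9, 0, 0.4)), lib$guide_id)
  fc <- as_fc_table(x)
  rs <- reference_gene_sets(c("GENE1", "GENE2", "GENE3"),
                            c("GENE4", "GENE5", "GENE6"))
  b1 <- gene_bayes_factor(fc, lib, refsets = rs, boot = 10, seed = 5,
                          bandwidth = 0.3, min_train = 3)
  b2 <- gene_bayes_factor(fc, lib, refsets = rs, boot = 10, seed = 5,
                          bandwidth = 0.3, min_train = 3)
  expect_equal(b1, b2)
  expect_true(all(c("boot_mean", "boot_sd") %in% names(b1)))
  expect_true(all(b1$boot_sd >= 0))
  expect_equal(b1$bf, b1$boot_mean)
})

test_that("genotype aggregation is the arithmetic mean of line BFs", {
  mk <- function(v) data.frame(gene = names(v), bf = as.numeric(v),
                               n_guides = 1L, n_obs = 1L)
  lines <- list(
    knockout = list(l1 = mk(c(A = 1)), l2 = mk(c(A = 2)), l3 = mk(c(A = 3))),
    wildtype = list(l1 = mk(c(A = 5))))
  g <- genotype_bf(lines)
  expect_equal(g$bf[g$genotype == "knockout"], 2)   # mean of 1,2,3
  expect_equal(g$bf[g$genotype == "wildtype"], 5)   # single line = identity

  # arithmetic oracle on random tables
  set.seed(8)
  genes <- paste0("G", 1:20)
  tabs <- lapply(1:3, function(i) mk(stats::setNames(rnorm(20), genes)))
  g2 <- genotype_bf(list(knockout = tabs, wildtype = tabs[1]))
  manual <- rowMeans(vapply(tabs, function(t) t$bf, numeric(20)))
  ko <- g2[g2$genotype == "knockout", ]
  expect_equal(ko$bf[match(genes, ko$gene)], manual, tolerance = 1e-12)

  # median alternative
  g3 <- genotype_bf(list(knockout = lapply(list(1, 2, 10), function(v)
    mk(c(A = v))), wildtype = tabs[1]), aggregate = "median")
  expect_equal(g3$bf[g3$genotype == "knockout" & g3$gene == "A"], 2)
})
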