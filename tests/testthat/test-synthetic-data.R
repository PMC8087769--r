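test_that("generate_library is deterministic and structurally sound", {
  cfg <- sim_config(n_genes = 2, guides_per_gene = c(3, 3),
                    n_control_guides = 1, n_core_essential = 0,
                    n_ko_specific = 0)
  lib <- generate_library(cfg, seed = 1)
  expect_equal(nrow(lib), 7)   # 2 genes x 3 guides + 1 control
  expect_equal(anyDuplicated(lib$sequence), 0)
  expect_equal(length(library_genes(lib)), 2)

  lib2 <- generate_library(cfg, seed = 1)
  expect_identical(as.data.frame(lib), as.data.frame(lib2))
  lib3 <- generate_library(cfg, seed = 2)
  expect_false(identical(lib$sequence, lib3$sequence))
})

test_that("guides-per-gene are uniform over the configured range", {
  cfg <- sim_config(n_genes = 10000, n_control_guides = 0)
  lib <- generate_library(cfg, seed = 1)
  npg <- table(table(lib$gene))
  expect_setequal(names(npg), c("3", "4", "5"))
  # chi-square against uniform not rejected at alpha = 0.01
  p <- stats::chisq.test(as.vector(npg), p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.01)
})

test_that("truth planting covers classes and rejects f < -1", {
  cfg <- fast_sim()
  lib <- generate_library(cfg, seed = 1)
  truth <- generate_truth(lib, cfg, seed = 1)
  expect_equal(sum(truth$genes$class == "core_essential"), 25)
  expect_equal(sum(truth$genes$class == "ko_specific"), 10)
  # class determines which genotype's f is nonzero
  ko_spec <- truth$genes[truth$genes$class == "ko_specific", ]
  expect_true(all(ko_spec$f_knockout < 0) && all(ko_spec$f_wildtype == 0))
  neutral <- truth$genes[truth$genes$class == "neutral", ]
  expect_true(all(neutral$f_knockout == 0) && all(neutral$f_wildtype == 0))
  expect_true(all(truth$guides$efficiency >= 0 & truth$guides$efficiency <= 1))
  # controls carry zero efficiency
  ctrl <- lib$guide_id[lib$guide_class == "control"]
  expect_true(all(truth$guides$efficiency[truth$guides$guide_id %in% ctrl] == 0))

  expect_error(generate_truth(lib, fast_sim(f_essential = -1.5), seed = 1),
               class = "isoscreen_validation_error")
})

test_that("simulate_screen is seed-deterministic and conserves depth", {
  cfg <- fast_sim()
  lib <- generate_library(cfg, seed = 3)
  truth <- generate_truth(lib, cfg, seed = 3)
  s1 <- simulate_screen(lib, truth, cfg, seed = 3)
  s2 <- simulate_screen(lib, truth, cfg, seed = 3)
  expect_identical(s1$counts$counts, s2$counts$counts)
  # multinomial column sums equal configured depth exactly
  expect_true(all(s1$counts$depth == cfg$depth))
  expect_equal(ncol(s1$counts$counts), 1 + 2 * cfg$n_lines)
  expect_s3_class(s1$sheet, "sample_sheet")
})

test_that("deterministic mode reproduces the closed-form fold changes", {
  # all genes neutral: every fold change is exactly 0
  cfg <- sim_config(n_genes = 50, guides_per_gene = c(3, 3),
                    n_control_guides = 0, depth = 1e7,
                    n_core_essential = 0, n_ko_specific = 0,
                    deterministic = TRUE)
  lib <- generate_library(cfg, seed = 5)
  truth <- generate_truth(lib, cfg, seed = 5)
  scr <- simulate_screen(lib, truth, cfg, seed = 5)
  fc <- guide_log_fold_change(scr$counts, "plasmid", alpha = 1e-9)
  expect_equal(max(abs(fc)), 0, tolerance = 1e-6)

  # one affected gene among many neutral ones: fc = log2(e * 2^(d f) + 1 - e)
  cfg2 <- sim_config(n_genes = 2000, guides_per_gene = c(3, 3),
                     n_control_guides = 0, depth = 1e7,
                     n_core_essential = 0, n_ko_specific = 1,
                     f_ko_specific = -0.2, deterministic = TRUE)
  lib2 <- generate_library(cfg2, seed = 6)
  truth2 <- generate_truth(lib2, cfg2, seed = 6)
  # force full efficiency so the closed form is exact
  truth2$guides$efficiency[] <- 1
  scr2 <- simulate_screen(lib2, truth2, cfg2, seed = 6)
  fc2 <- guide_log_fold_change(scr2$counts, "plasmid", alpha = 1e-9)
  hit <- truth2$genes$gene[truth2$genes$class == "ko_specific"]
  hit_guides <- lib2$guide_id[lib2$gene == hit]
  # e = 1, f = -0.2, d = 16 -> -3.2, up to renormalization <= 0.01
  expect_equal(unname(fc2[hit_guides, "ko_1"]), rep(16 * -0.2, 3),
               tolerance = 0.01 / 3.2)
  expect_equal(max(abs(fc2[hit_guides, "wt_1"])), 0, tolerance = 0.01)

  # partial efficiency: e = 0.5, f = -1 -> log2(0.5 * 2^-16 + 0.5)
  truth2$guides$efficiency[] <- 0.5
  truth2$genes$f_knockout[truth2$genes$gene == hit] <- -1
  scr3 <- simulate_screen(lib2, truth2, cfg2, seed = 6)
  fc3 <- guide_log_fold_change(scr3$counts, "plasmid", alpha = 1e-9)
  expected <- log2(0.5 * 2^-16 + 0.5)
  expect_equal(unname(fc3[hit_guides, "ko_1"]), rep(expected, 3),
               tolerance = 0.01)
  expect_equal(expected, -0.99998, tolerance = 1e-5)
})

test_that("expected depletion is monotone in effect size and efficiency", {
  d <- 16
  depl <- function(e, f) log2(e * 2^(d * f) + (1 - e))
  fs <- seq(0, -1, by = -0.1)
  expect_true(all(diff(depl(0.8, fs)) <= 0))      # larger |f| -> more depletion
  es <- seq(0, 1, by = 0.1)
  expect_true(all(diff(depl(es, -0.5)) <= 0))     # larger e -> more depletion
  # and the simulator's expected weights honour it
  w1 <- isoscreen:::grown_weights(80, 20, -0.2, d)
  w2 <- isoscreen:::grown_weights(80, 20, -0.4, d)
  expect_gt(w1, w2)
})

test_that("write_fastq round-trips counts exactly, with and without decoys", {
  cfg <- sim_config(n_genes = 10, guides_per_gene = c(2, 3),
                    n_control_guides = 2, depth = 400, coverage = 50,
                    passage_floor = 50, n_core_essential = 2,
                    n_ko_specific = 1, n_lines = 1)
  lib <- generate_library(cfg, seed = 7)
  truth <- generate_truth(lib, cfg, seed = 7)
  scr <- simulate_screen(lib, truth, cfg, seed = 7)

  dir <- tempfile()
  paths <- write_fastq(scr, dir, samples = c("plasmid", "ko_1"), seed = 7)
  for (s in names(paths)) {
    res <- count_sample(paths[[s]], lib, match_policy("scan"))
    expect_equal(unname(res$counts), unname(scr$counts$counts[, s]))
    expect_equal(res$unmatched, 0)
  }

  # spiked decoys change nothing but the unmatched tally
  paths2 <- write_fastq(scr, tempfile(), samples = "ko_1", n_decoys = 37,
                        seed = 8)
  res2 <- count_sample(paths2[["ko_1"]], lib, match_policy("scan"))
  expect_equal(unname(res2$counts), unname(scr$counts$counts[, "ko_1"]))
  expect_equal(res2$unmatched, 37)

  # gzip output quantifies identically
  paths3 <- write_fastq(scr, tempfile(), samples = "ko_1", gzip = TRUE,
                        seed = 7)
  res3 <- count_sample(paths3[["ko_1"]], lib, match_policy("scan"))
  expect_equal(unname(res3$counts), unname(scr$counts$counts[, "ko_1"]))

  # zero counts -> empty FASTQ
  zero <- scr
  zero$counts$counts[, "ko_1"] <- 0
  p0 <- write_fastq(zero, tempfile(), samples = "ko_1", seed = 7)
  expect_equal(length(readLines(p0[["ko_1"]])), 0)
})

test_that("recovery scoring implements the confusion-matrix arithmetic", {
  truth <- structure(list(
    genes = data.frame(gene = paste0("G", 1:20),
                       class = c(rep("ko_specific", 10), rep("neutral", 10)),
                       f_knockout = c(rep(-0.2, 10), rep(0, 10)),
                       f_wildtype = 0, stringsAsFactors = FALSE),
    guides = data.frame(guide_id = character(0), efficiency = numeric(0))),
    class = "sim_truth")

  perfect <- select_dependencies(
    stats::setNames(c(rep(5, 10), rep(0, 10)), paste0("G", 1:20)))
  r <- evaluate_recovery(truth, perfect)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)

  # 8 of 10 planted found plus 2 false calls -> 0.8 / 0.8
  z <- stats::setNames(c(rep(5, 8), rep(0, 2), rep(5, 2), rep(0, 8)),
                       paste0("G", 1:20))
  r2 <- evaluate_recovery(truth, select_dependencies(z))
  expect_equal(r2$precision, 0.8)
  expect_equal(r2$recall, 0.8)
  expect_equal(sort(r2$missed), c("G10", "G9"))

  # degenerate: no positives and no calls -> both NA, not 0
  truth0 <- truth
  truth0$genes$class <- "neutral"
  r3 <- evaluate_recovery(truth0, select_dependencies(
    stats::setNames(rep(0, 20), paste0("G", 1:20))))
  expect_true(is.na(r3$precision) && is.na(r3$recall))

  expect_error(evaluate_recovery(truth, select_dependencies(c(OTHER = 9))),
               class = "isoscreen_validation_error")
})

test_that("reference sets derive from planted truth and stay disjoint", {
  cfg <- fast_sim()
  lib <- generate_library(cfg, seed = 9)
  truth <- generate_truth(lib, cfg, seed = 9)
  rs <- reference_sets_from_truth(truth, n_nonessential = 30, seed = 9)
  expect_setequal(rs$essential,
                  truth$genes$gene[truth$genes$class == "core_essential"])
  expect_equal(length(rs$nonessential), 30)
  expect_length(intersect(rs$essential, rs$nonessential), 0)
  rs2 <- reference_sets_from_truth(truth, n_nonessential = 30, seed = 9)
  expect_identical(rs, rs2)
})
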