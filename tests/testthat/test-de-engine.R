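# Small dense fixture used by several blocks: 3 genes, 4 cells.
tiny_counts <- function() {
  matrix(c(0, 5,    0, 4,
           5, 9995, 0, 3,
           8, 0,    8, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("gA", "gB", "gC"),
                         c("c1", "c2", "c3", "c4")))
}

test_that("log normalization matches the closed form", {
  m <- tiny_counts()
  norm <- log_normalize(m, scale_factor = 1e4)
  # zero count maps to zero
  expect_equal(norm["gA", "c1"], 0)
  # a cell expressing a single gene with count = total: ln(10001)
  expect_equal(norm["gC", "c3"], log(10001), tolerance = 1e-10)
  # count 5 in a cell with total 10000: ln(6)
  expect_equal(norm["gA", "c2"], log(6), tolerance = 1e-10)
  expect_equal(norm["gA", "c2"], 1.7918, tolerance = 1e-4)
  # generic entry follows ln(count / total * sf + 1)
  expect_equal(norm["gB", "c4"], log(3 / 7 * 1e4 + 1), tolerance = 1e-10)
})

test_that("a zero-total cell is rejected by name", {
  m <- tiny_counts()
  m[, "c4"] <- 0
  expect_error(log_normalize(m), "c4")
})

test_that("average log fold change is antisymmetric and matches hand values", {
  a <- matrix(log(c(2, 4) + 1), nrow = 1)   # back-transformed values 2, 4
  b <- matrix(log(c(1, 1) + 1), nrow = 1)
  expect_equal(average_log_fold_change(a, a), 0)
  expect_equal(average_log_fold_change(a, b),
               -average_log_fold_change(b, a))
  # back-transformed group means 3.0 and 1.0: ln(4) - ln(2) = ln 2
  expect_equal(average_log_fold_change(a, b), log(2), tolerance = 1e-10)
  expect_error(average_log_fold_change(a, matrix(numeric(0), nrow = 1)))
  # log base is configurable
  expect_equal(average_log_fold_change(a, b, log_base = 2), 1)
})

test_that("rank-sum p-values track the exact permutation oracle", {
  # identical multisets: no separation
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2)), 1,
               tolerance = 0.05)
  # both groups constant and equal
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2)), 1)
  # fully separated small groups: exact two-sided p = 0.1
  expect_equal(exact_rank_sum_p(1:3, 4:6), 0.1, tolerance = 1e-12)
  expect_lt(abs(wilcoxon_rank_sum(1:3, 4:6) - 0.1), 0.05)
  # random small samples with ties, significance-relevant regime
  set.seed(2024)
  for (i in 1:60) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- sample(0:5, n1, replace = TRUE)
    b <- sample(0:5, n2, replace = TRUE) + sample(0:3, 1)
    if (length(unique(c(a, b))) == 1) next
    pe <- exact_rank_sum_p(a, b)
    pa <- wilcoxon_rank_sum(a, b)
    if (pe <= 0.2) expect_lt(abs(pa - pe), 0.1)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1))
})

test_that("the comparison plan enumerates 25 ordered tests", {
  sim <- null_sim()
  plan <- build_comparison_plan(sim$dataset)
  expect_equal(nrow(plan), 25L)
  expect_equal(sum(plan$kind == "within_region"), 18L)
  expect_equal(sum(plan$kind == "cross_region"), 7L)
  # analogous ALM/VISp specs carry identical class ordering
  within <- plan[plan$kind == "within_region", ]
  alm <- within[within$region == "ALM", c("group", "pair")]
  visp <- within[within$region == "VISp", c("group", "pair")]
  expect_equal(alm$pair[order(alm$pair)], visp$pair[order(visp$pair)])
  # GABAergic ordering follows VIP < SST < PV
  expect_true("VIP vs PV" %in% within$pair)
  expect_true("SST vs PV" %in% within$pair)
  expect_false("PV vs SST" %in% within$pair)
  # cross-region comparisons are ALM-first by construction
  expect_true(all(grepl("ALM vs VISp", plan$comparison_id[
    plan$kind == "cross_region"])))
})

test_that("a glutamatergic-only dataset yields 16 comparisons", {
  sim <- null_sim()
  glut <- subset_cells(sim$dataset, group = "glutamatergic")
  plan <- build_comparison_plan(glut)
  expect_equal(nrow(plan), 16L)
  expect_equal(sum(plan$kind == "within_region"), 12L)
})

test_that("a missing class/region combination aborts the plan", {
  sim <- null_sim()
  ds <- sim$dataset
  drop <- !(ds$cells$region == "ALM" & ds$cells$class == "VIP")
  broken <- expression_dataset(ds$counts[, drop], ds$cells[drop, ])
  expect_error(build_comparison_plan(broken), "VIP missing from region ALM")
})

test_that("a planted gene is detected and the filters behave", {
  planted <- data.frame(category = "conserved", class = "VIP",
                        class_b = NA, direction = "up", region = NA,
                        group = NA)
  sim <- generate_counts(synth_config(n_cells_per_group = 60, n_genes = 50,
                                      planted = planted, seed = 21))
  plan <- build_comparison_plan(sim$dataset)
  spec <- plan[plan$comparison_id == "GABAergic ALM VIP vs PV", ]
  de <- run_de_test(sim$dataset, spec)
  expect_true("g0001" %in% de$gene)
  expect_gt(de$avg_logFC[de$gene == "g0001"], 0)
  # Bonferroni over the full gene universe, capped at 1
  expect_equal(de$p_adj, pmin(1, de$p_raw * 50))
  expect_true(all(de$p_adj < 0.05))
  expect_true(all(abs(de$avg_logFC) >= 0.25))
  expect_true(all(pmax(de$pct_a, de$pct_b) >= 0.1))

  # sign convention: swapping the group order negates the fold change
  swapped <- spec
  swapped$class_a <- spec$class_b
  swapped$class_b <- spec$class_a
  swapped$pair <- paste(swapped$class_a, "vs", swapped$class_b)
  de_sw <- run_de_test(sim$dataset, swapped)
  both <- intersect(de$gene, de_sw$gene)
  expect_true(length(both) > 0)
  expect_equal(de$avg_logFC[match(both, de$gene)],
               -de_sw$avg_logFC[match(both, de_sw$gene)])
  expect_equal(de$p_raw[match(both, de$gene)],
               de_sw$p_raw[match(both, de_sw$gene)])

  # filter monotonicity: stricter thresholds never add rows
  strict <- run_de_test(sim$dataset, spec,
                        de_test_config(logfc_threshold = 0.5,
                                       alpha = 0.01))
  expect_true(all(paste(strict$gene) %in% paste(de$gene)))
})

test_that("DE tables round-trip through CSV", {
  fx <- seven_gene_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_de_csv(fx, path)
  back <- read_de_csv(path)
  expect_equal(back[order(back$comparison_id, back$gene),
                    c("comparison_id", "gene", "avg_logFC", "pair")],
               fx[order(fx$comparison_id, fx$gene),
                  c("comparison_id", "gene", "avg_logFC", "pair")],
               ignore_attr = TRUE)
})
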