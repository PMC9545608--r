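test_that("the interneuron truth table matches over all 27 sign patterns", {
  comps <- c("VIP vs PV", "VIP vs SST", "SST vs PV")
  grid <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  for (i in seq_len(nrow(grid))) {
    pattern <- stats::setNames(as.numeric(grid[i, ]), comps)
    want <- oracle_class_calls_gaba(pattern)
    got <- identify_class_relevant(pattern_to_records(pattern), "conserved")
    expect_equal(nrow(got), nrow(want), label = paste(pattern, collapse = ","))
    expect_setequal(paste(got$class, got$direction),
                    paste(want$class, want$direction))
  }
})

test_that("the projection-neuron truth table matches over all 729 patterns", {
  comps <- c("L2/3 IT vs L5 IT", "L2/3 IT vs L5 PT", "L2/3 IT vs L6 CT",
             "L5 IT vs L5 PT", "L5 IT vs L6 CT", "L5 PT vs L6 CT")
  grid <- as.matrix(expand.grid(rep(list(-1:1), 6)))
  for (i in seq_len(nrow(grid))) {
    pattern <- stats::setNames(as.numeric(grid[i, ]), comps)
    want <- oracle_class_calls_glut(pattern)
    got <- identify_class_relevant(
      pattern_to_records(pattern, group = "glutamatergic"), "conserved")
    expect_setequal(paste(got$class, got$direction),
                    paste(want$class, want$direction))
  }
})

test_that("direction soundness: emitted records sit on one side everywhere", {
  sets <- class_set_table()
  set.seed(77)
  for (i in 1:50) {
    comps <- class_pairs("glutamatergic")$pair
    pattern <- stats::setNames(sample(-1:1, 6, replace = TRUE), comps)
    recs <- pattern_to_records(pattern, group = "glutamatergic")
    out <- identify_class_relevant(recs, "ALM")
    for (j in seq_len(nrow(out))) {
      cs <- sets[[out$class[j]]]
      for (p in cs) {
        s <- pattern[[p]]
        parts <- strsplit(p, " vs ", fixed = TRUE)[[1]]
        on_first <- if (out$class[j] == "IT")
          parts[1] %in% c("L2/3 IT", "L5 IT") else parts[1] == out$class[j]
        higher <- (s > 0 && on_first) || (s < 0 && !on_first)
        expect_equal(higher, out$direction[j] == "up")
      }
    }
  }
})

test_that("a single significant comparison never satisfies a class set", {
  recs <- data.frame(gene = "g", pair = "VIP vs PV", group = "GABAergic",
                     avg_logFC = 0.5)
  expect_equal(nrow(identify_class_relevant(recs)), 0L)
})

test_that("a PV-enriched gene yields linked dual records (diamond)", {
  # higher in PV than VIP and SST; SST lower than both VIP and PV
  recs <- data.frame(gene = "erbb4",
                     pair = c("VIP vs PV", "SST vs PV", "VIP vs SST"),
                     group = "GABAergic",
                     avg_logFC = c(-0.5, -0.5, 0.5))
  out <- identify_class_relevant(recs)
  expect_setequal(paste(out$class, out$direction),
                  c("PV up", "SST down"))
  expect_equal(out$dual_partner[out$class == "PV"], "SST")
  expect_equal(out$dual_partner[out$class == "SST"], "PV")
})

test_that("the IT composite emits alone when only its set is satisfied", {
  recs <- data.frame(gene = "g",
                     pair = c("L2/3 IT vs L5 PT", "L2/3 IT vs L6 CT",
                              "L5 IT vs L5 PT", "L5 IT vs L6 CT"),
                     group = "glutamatergic",
                     avg_logFC = 0.5)
  out <- identify_class_relevant(recs)
  expect_equal(out$class, "IT")
  expect_equal(out$direction, "up")
})

test_that("unknown comparison names are rejected", {
  recs <- data.frame(gene = "g", pair = "VIP vs L5 PT",
                     group = "GABAergic", avg_logFC = 0.5)
  expect_error(identify_class_relevant(recs), "vocabulary")
})

test_that("divergent results never contribute to class relevance", {
  de <- generate_de_table(data.frame(
    gene = "g", region = c("ALM", "VISp", "ALM", "VISp", "ALM", "VISp"),
    pair = rep(c("VIP vs PV", "VIP vs SST", "SST vs PV"), each = 2),
    sign = c(1, -1, 1, -1, 1, -1)))
  col <- collapse_de(de)
  expect_true(all(col$category == "divergent"))
  rel <- class_relevance(col)
  expect_equal(nrow(rel$conserved) + nrow(rel$alm) + nrow(rel$visp), 0L)
})

test_that("cross-region reconciliation dedupes, stars, and is idempotent", {
  col <- collapse_de(egr1_fixture())
  rel <- class_relevance(col)
  # identical (class, direction) removed from the region set
  expect_false(any(paste(rel$alm$class, rel$alm$direction) == "PV down"))
  # different class labels across regionalities star both records
  expect_equal(rel$alm$class, "VIP")
  expect_true(all(rel$alm$asterisk))
  expect_true(all(rel$conserved$asterisk))
  # a gene relevant only in one region is kept unstarred
  fx <- class_relevance(collapse_de(seven_gene_fixture()))
  expect_false(any(fx$visp$asterisk[fx$visp$gene == "pten"]))
  # idempotence
  twice <- reconcile_regional(rel$conserved, rel$alm, rel$visp)
  expect_equal(twice$conserved, rel$conserved)
  expect_equal(twice$alm, rel$alm)
  expect_equal(twice$visp, rel$visp)
})

test_that("region-bias queries follow their definitions", {
  # positive and significant in all 4 excitatory cross-region tests -> ALM
  cross <- generate_de_table(data.frame(
    gene = "lmo4", class = c("L2/3 IT", "L5 IT", "L5 PT", "L6 CT"),
    sign = 1))
  out <- region_biased_genes(cross, "glutamatergic")
  expect_equal(out$gene, "lmo4")
  expect_equal(out$biased_to, "ALM")
  expect_equal(out$scope, "all-classes")
  # 3 of 4 is not enough
  expect_equal(nrow(region_biased_genes(cross[-1, ], "glutamatergic")), 0L)
  # mixed signs are not uniform bias
  mixed <- cross
  mixed$avg_logFC[1] <- -0.5
  expect_equal(nrow(region_biased_genes(mixed, "glutamatergic")), 0L)
  # all negative means biased to VISp
  neg <- cross
  neg$avg_logFC <- -neg$avg_logFC
  expect_equal(region_biased_genes(neg, "glutamatergic")$biased_to, "VISp")
  # missing planned cross-region test is an error
  sim <- null_sim()
  plan <- build_comparison_plan(sim$dataset)
  broken <- plan[!(plan$kind == "cross_region" & plan$class_a == "L5 IT"), ]
  expect_error(region_biased_genes(cross, "glutamatergic", broken),
               "L5 IT")
})

test_that("origin-specific queries split VIP from PV/SST", {
  cross <- generate_de_table(data.frame(
    gene = c("igf1", "both", "both", "mge", "mge"),
    class = c("VIP", "VIP", "PV", "PV", "SST"),
    sign = c(-1, 1, 1, 1, 1)))
  out <- origin_specific_genes(cross)
  # significant in VIP only
  vip <- out[out$scope == "VIP-only", ]
  expect_equal(vip$gene, "igf1")
  expect_equal(vip$biased_to, "VISp")
  # significant in VIP and PV qualifies for neither scope
  expect_false("both" %in% out$gene)
  # PV & SST uniform, VIP silent
  mge <- out[out$scope == "PV&SST-only", ]
  expect_equal(mge$gene, "mge")
  expect_equal(mge$biased_to, "ALM")
})
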