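# Synthetic class-labeled count data with planted effects, plus encoded
# worked-example fixtures, so every downstream stage is testable without the
# external atlas data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic count generator
#'
#' Counts follow a negative-binomial model with per-cell log-normal size
#' factors: gene g in cell c of group (region r, class k) has mean
#' `baseline_mean * sizefactor(c) * fold(g, r, k)`, where the fold encodes
#' the planted category of the gene (1 for null genes).
#'
#' @param n_cells_per_group cells per (region, class) group (>= 2).
#' @param n_genes total genes, planted plus null (must be at least the
#'   number of planted genes).
#' @param baseline_mean expected count of a null gene (default 2).
#' @param dispersion negative-binomial overdispersion phi, variance
#'   `mu + phi * mu^2` (default 0.5).
#' @param library_size_cv coefficient of variation of the per-cell size
#'   factors (default 0.2).
#' @param effect_fold multiplicative expression effect of planted genes
#'   (> 1; "down" effects use its reciprocal; default 4).
#' @param seed integer RNG seed.
#' @param planted data.frame describing the planted genes (see
#'   [default_planted()]); zero rows means an all-null dataset.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cells_per_group = 200, n_genes = 300,
                         baseline_mean = 2, dispersion = 0.5,
                         library_size_cv = 0.2, effect_fold = 4,
                         seed = 1, planted = default_planted()) {
  stopifnot(n_cells_per_group >= 2, baseline_mean > 0, dispersion > 0,
            library_size_cv >= 0, effect_fold > 0)
  planted <- as.data.frame(planted)
  if (nrow(planted) && effect_fold == 1)
    stop("effect_fold must differ from 1 when genes are planted")
  if (n_genes < nrow(planted))
    stop("n_genes (", n_genes, ") is smaller than the number of planted ",
         "genes (", nrow(planted), ")")
  structure(list(n_cells_per_group = n_cells_per_group, n_genes = n_genes,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 library_size_cv = library_size_cv,
                 effect_fold = effect_fold, seed = seed, planted = planted),
            class = "synth_config")
}

#' Default planted-gene specification
#'
#' Exercises every truth category at least once: conserved class-relevant
#' genes (up and down, both neurotransmitter groups), ALM- and
#' VISp-specific class-relevant genes, divergent genes, region-biased
#' genes, origin-specific interneuron genes, and inconsistent decoys (genes
#' elevated in two non-adjacent glutamatergic classes so that no class set
#' is satisfied).
#'
#' @return data.frame with columns `category`, `class`, `class_b`,
#'   `direction`, `region`, `group`.
#' @export
default_planted <- function() {
  p <- function(category, class = NA, class_b = NA, direction = NA,
                region = NA, group = NA)
    data.frame(category = category, class = class, class_b = class_b,
               direction = direction, region = region, group = group,
               stringsAsFactors = FALSE)
  rbind(
    p("conserved", class = "VIP",     direction = "up"),
    p("conserved", class = "VIP",     direction = "down"),
    p("conserved", class = "SST",     direction = "up"),
    p("conserved", class = "PV",      direction = "up"),
    p("conserved", class = "L2/3 IT", direction = "up"),
    p("conserved", class = "L5 PT",   direction = "up"),
    p("conserved", class = "L6 CT",   direction = "down"),
    p("ALM-specific",  class = "VIP",   direction = "up"),
    p("ALM-specific",  class = "L5 PT", direction = "up"),
    p("VISp-specific", class = "SST",   direction = "up"),
    p("VISp-specific", class = "L6 CT", direction = "down"),
    p("divergent", class = "L5 IT", class_b = "L5 PT"),
    p("divergent", class = "VIP",   class_b = "PV"),
    p("region-biased", group = "glutamatergic", region = "ALM"),
    p("region-biased", group = "GABAergic",     region = "VISp"),
    p("origin-specific", class = "VIP",    region = "ALM"),
    p("origin-specific", class = "PV&SST", region = "VISp"),
    p("inconsistent-decoy", group = "glutamatergic"),
    p("inconsistent-decoy", group = "glutamatergic")
  )
}

# fold matrix: genes x (region, class) groups, default 1
planted_fold_matrix <- function(planted, genes, effect_fold) {
  regions <- cortical_regions()
  classes <- names(cortical_classes())
  grp_names <- as.vector(outer(regions, classes, paste, sep = "|"))
  fold <- matrix(1, length(genes), length(grp_names),
                 dimnames = list(genes, grp_names))
  col_of <- function(region, class) paste(region, class, sep = "|")
  for (i in seq_len(nrow(planted))) {
    pl <- planted[i, ]
    g <- genes[i]
    f <- if (identical(pl$direction, "down")) 1 / effect_fold
         else effect_fold
    switch(pl$category,
      "conserved" = {
        fold[g, col_of(regions, pl$class)] <- f
      },
      "ALM-specific" = {
        fold[g, col_of("ALM", pl$class)] <- f
      },
      "VISp-specific" = {
        fold[g, col_of("VISp", pl$class)] <- f
      },
      "divergent" = {
        fold[g, col_of("ALM", pl$class)] <- effect_fold
        fold[g, col_of("VISp", pl$class_b)] <- effect_fold
      },
      "region-biased" = {
        fold[g, col_of(pl$region, classes_of_group(pl$group))] <- effect_fold
      },
      "origin-specific" = {
        cls <- if (pl$class == "PV&SST") c("PV", "SST") else "VIP"
        fold[g, col_of(pl$region, cls)] <- effect_fold
      },
      "inconsistent-decoy" = {
        # elevated in two non-adjacent classes of the group in both regions:
        # several comparisons are significant but no class set is satisfied
        fold[g, col_of(regions, "L2/3 IT")] <- effect_fold
        fold[g, col_of(regions, "L5 PT")] <- effect_fold
      },
      stop("unknown planted category: ", pl$category)
    )
  }
  fold
}

#' Generate a synthetic class-labeled count dataset with planted effects
#'
#' Draws negative-binomial counts for all 7 classes x 2 regions under the
#' model described in [synth_config()] and returns both the dataset and the
#' truth table of planted gene categories. Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @return list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (data.frame: `gene`, `category`, `class`, `class_b`,
#'   `direction`, `region`, `group`; unplanted genes are category "null").
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  planted <- config$planted
  truth <- data.frame(gene = genes, category = "null",
                      class = NA_character_, class_b = NA_character_,
                      direction = NA_character_, region = NA_character_,
                      group = NA_character_, stringsAsFactors = FALSE)
  if (nrow(planted)) {
    truth$category[seq_len(nrow(planted))] <- planted$category
    truth$class[seq_len(nrow(planted))] <- planted$class
    truth$class_b[seq_len(nrow(planted))] <- planted$class_b
    truth$direction[seq_len(nrow(planted))] <- planted$direction
    truth$region[seq_len(nrow(planted))] <- planted$region
    truth$group[seq_len(nrow(planted))] <- planted$group
  }
  fold <- planted_fold_matrix(planted, genes, config$effect_fold)

  regions <- cortical_regions()
  classes <- names(cortical_classes())
  n <- config$n_cells_per_group
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  size <- 1 / config$dispersion

  with_seed(config$seed, {
    blocks <- list()
    meta <- list()
    for (r in regions) for (k in classes) {
      sf <- if (config$library_size_cv > 0)
        stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, n)
      mu <- config$baseline_mean *
        outer(fold[, paste(r, k, sep = "|")], sf)
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                    nrow = config$n_genes)
      blocks[[length(blocks) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <- data.frame(
        cell_id = sprintf("%s_%s_%03d", r, gsub("[ /]", "", k), seq_len(n)),
        region = r, class = k, stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, blocks)
    cells <- do.call(rbind, meta)
    rownames(counts) <- genes
    colnames(counts) <- cells$cell_id
    list(dataset = expression_dataset(counts, cells), truth = truth)
  })
}

#' Build a differential-expression table directly from a pattern
#'
#' Lets the collapse and class-relevance stages be unit-tested without
#' running the DE engine. One output row per pattern entry flagged
#' significant, with `avg_logFC = sign * magnitude` and an adjusted p-value
#' below 0.05; non-significant entries are omitted.
#'
#' @param pattern data.frame with columns `gene`, `sign` (+1/-1) and either
#'   `region` + `pair` (within-region entries, e.g. pair "VIP vs PV") or
#'   `class` with `region = NA` (cross-region entries). Optional columns:
#'   `magnitude` (default 0.5 natural-log units) and `significant`
#'   (default TRUE).
#' @return data.frame in the [run_de_test()] layout.
#' @export
generate_de_table <- function(pattern) {
  pattern <- as.data.frame(pattern)
  if (!nrow(pattern)) return(empty_de_table())
  if (is.null(pattern$magnitude)) pattern$magnitude <- 0.5
  if (is.null(pattern$significant)) pattern$significant <- TRUE
  if (is.null(pattern$class)) pattern$class <- NA_character_
  if (is.null(pattern$region)) pattern$region <- NA_character_
  if (is.null(pattern$pair)) pattern$pair <- NA_character_
  if (any(!pattern$sign %in% c(-1, 1)))
    stop("sign must be +1 or -1")
  pattern <- pattern[pattern$significant, , drop = FALSE]
  if (!nrow(pattern)) return(empty_de_table())

  rows <- lapply(seq_len(nrow(pattern)), function(i) {
    p <- pattern[i, ]
    if (!is.na(p$pair)) {
      if (!p$region %in% cortical_regions())
        stop("within-region entry needs a valid region (row ", i, ")")
      cls <- split_pair(p$pair)[[1]]
      grp <- unique(group_of_class(cls))
      if (length(grp) != 1L)
        stop("pair '", p$pair, "' mixes neurotransmitter groups")
      valid <- class_pairs(grp)$pair
      if (!p$pair %in% valid)
        stop("'", p$pair, "' is not a canonically ordered class pair")
      data.frame(comparison_id = within_comparison_id(grp, p$region, p$pair),
                 kind = "within_region", group = grp, region = p$region,
                 class_a = cls[1L], class_b = cls[2L], pair = p$pair,
                 gene = p$gene, avg_logFC = p$sign * p$magnitude,
                 p_raw = 1e-10, p_adj = 1e-6, pct_a = 0.8, pct_b = 0.4,
                 row.names = NULL)
    } else {
      grp <- group_of_class(p$class)
      data.frame(comparison_id = cross_comparison_id(grp, p$class),
                 kind = "cross_region", group = grp, region = NA_character_,
                 class_a = p$class, class_b = p$class, pair = "ALM vs VISp",
                 gene = p$gene, avg_logFC = p$sign * p$magnitude,
                 p_raw = 1e-10, p_adj = 1e-6, pct_a = 0.8, pct_b = 0.4,
                 row.names = NULL)
    }
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(paste(out$comparison_id, out$gene)))
    stop("duplicate (comparison, gene) entries in pattern")
  rownames(out) <- NULL
  out
}

#' The seven-gene interneuron worked example
#'
#' Encodes the published pattern of significant differential expression for
#' seven circuit-related genes across the three interneuron comparisons:
#' cyfip1 (VIP > PV, ALM only), dlg2 (VIP > PV, both regions), kctd13
#' (VIP > PV, VISp only) — each with no other significant test — and
#' nrxn1/snap25 (consistent VIP pattern in both regions), socs5 (ALM only),
#' pten (VISp only), each significant in all three interneuron tests. The
#' SST-vs-PV direction for the latter four is encoded as SST > PV (the
#' source reports significance but not the direction); magnitudes are fixed
#' at 0.5 natural-log units since the categorization depends only on
#' significance and sign.
#'
#' @return data.frame of 22 significant within-region results.
#' @export
seven_gene_fixture <- function() {
  vip_block <- function(gene, region) data.frame(
    gene = gene, region = region,
    pair = c("VIP vs PV", "VIP vs SST", "SST vs PV"), sign = 1)
  generate_de_table(rbind(
    data.frame(gene = "cyfip1", region = "ALM",  pair = "VIP vs PV", sign = 1),
    data.frame(gene = "dlg2",   region = "ALM",  pair = "VIP vs PV", sign = 1),
    data.frame(gene = "dlg2",   region = "VISp", pair = "VIP vs PV", sign = 1),
    data.frame(gene = "kctd13", region = "VISp", pair = "VIP vs PV", sign = 1),
    vip_block("nrxn1", "ALM"),  vip_block("nrxn1", "VISp"),
    vip_block("snap25", "ALM"), vip_block("snap25", "VISp"),
    vip_block("socs5", "ALM"),
    vip_block("pten", "VISp")
  ))
}

#' The egr1 cross-region reconciliation worked example
#'
#' egr1 is significant in all three interneuron tests in ALM (VIP > PV,
#' VIP > SST, SST > PV) but only two in VISp (VIP > PV, SST > PV): in ALM it
#' is class-relevant to VIP (up), while the conserved subset makes it
#' class-relevant to PV (down) — the prototypical asterisk gene.
#'
#' @return data.frame of 5 significant within-region results.
#' @export
egr1_fixture <- function() {
  generate_de_table(data.frame(
    gene = "egr1",
    region = c("ALM", "ALM", "ALM", "VISp", "VISp"),
    pair = c("VIP vs PV", "VIP vs SST", "SST vs PV",
             "VIP vs PV", "SST vs PV"),
    sign = 1))
}
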