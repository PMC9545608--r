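# Independent brute-force oracles. These are deliberately written as
# literal, unoptimized restatements of the definitions, separate from the
# package implementations they check.

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations to the first group (midranks for ties).
exact_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  combos <- combn(length(pooled), n1)
  stats <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Literal categorization of one analogous comparison pair for one gene.
# alm / visp each in c("absent", "+", "-").
oracle_collapse_category <- function(alm, visp) {
  if (alm == "absent" && visp == "absent") return(NA_character_)
  if (alm == "absent") return("VISp-specific")
  if (visp == "absent") return("ALM-specific")
  if (alm == visp) "conserved" else "divergent"
}

# Literal class-relevance truth for the GABAergic group. `pattern` is a
# named vector over the three comparisons with values in {0, +1, -1}
# (0 = not significant). Returns data.frame(class, direction).
# Positions and class sets are hardcoded here, independent of the package.
oracle_class_calls_gaba <- function(pattern) {
  comps <- c("VIP vs PV", "VIP vs SST", "SST vs PV")
  stopifnot(setequal(names(pattern), comps))
  # which side each class occupies in each comparison it takes part in
  membership <- list(
    VIP = c("VIP vs PV" = "first", "VIP vs SST" = "first"),
    SST = c("SST vs PV" = "first", "VIP vs SST" = "second"),
    PV  = c("SST vs PV" = "second", "VIP vs PV" = "second"))
  out <- list()
  for (cls in names(membership)) {
    mem <- membership[[cls]]
    if (any(pattern[names(mem)] == 0)) next  # class set not fully significant
    higher <- logical(length(mem))
    for (j in seq_along(mem)) {
      s <- pattern[[names(mem)[j]]]
      higher[j] <- (s > 0 && mem[[j]] == "first") ||
        (s < 0 && mem[[j]] == "second")
    }
    if (all(higher))
      out[[length(out) + 1L]] <- data.frame(class = cls, direction = "up")
    else if (all(!higher))
      out[[length(out) + 1L]] <- data.frame(class = cls, direction = "down")
  }
  if (!length(out)) return(data.frame(class = character(),
                                      direction = character()))
  do.call(rbind, out)
}

# Same idea for the glutamatergic group, including the IT composite and
# the rule that IT supersedes its constituents only when all three emit.
oracle_class_calls_glut <- function(pattern) {
  comps <- c("L2/3 IT vs L5 IT", "L2/3 IT vs L5 PT", "L2/3 IT vs L6 CT",
             "L5 IT vs L5 PT", "L5 IT vs L6 CT", "L5 PT vs L6 CT")
  stopifnot(setequal(names(pattern), comps))
  membership <- list(
    "L2/3 IT" = c("L2/3 IT vs L5 IT" = "first",
                  "L2/3 IT vs L6 CT" = "first",
                  "L2/3 IT vs L5 PT" = "first"),
    "L5 IT" = c("L2/3 IT vs L5 IT" = "second",
                "L5 IT vs L5 PT" = "first",
                "L5 IT vs L6 CT" = "first"),
    "IT" = c("L2/3 IT vs L5 PT" = "first", "L2/3 IT vs L6 CT" = "first",
             "L5 IT vs L5 PT" = "first", "L5 IT vs L6 CT" = "first"),
    "L5 PT" = c("L2/3 IT vs L5 PT" = "second", "L5 IT vs L5 PT" = "second",
                "L5 PT vs L6 CT" = "first"),
    "L6 CT" = c("L2/3 IT vs L6 CT" = "second", "L5 IT vs L6 CT" = "second",
                "L5 PT vs L6 CT" = "second"))
  out <- list()
  for (cls in names(membership)) {
    mem <- membership[[cls]]
    # the IT composite is only a candidate when both constituents appear
    # among the significant comparisons' classes
    if (cls == "IT") {
      sig <- names(pattern)[pattern != 0]
      cls_seen <- unique(unlist(strsplit(sig, " vs ", fixed = TRUE)))
      if (!all(c("L2/3 IT", "L5 IT") %in% cls_seen)) next
    }
    if (any(pattern[names(mem)] == 0)) next
    higher <- logical(length(mem))
    for (j in seq_along(mem)) {
      s <- pattern[[names(mem)[j]]]
      higher[j] <- (s > 0 && mem[[j]] == "first") ||
        (s < 0 && mem[[j]] == "second")
    }
    if (all(higher))
      out[[length(out) + 1L]] <- data.frame(class = cls, direction = "up")
    else if (all(!higher))
      out[[length(out) + 1L]] <- data.frame(class = cls, direction = "down")
  }
  if (!length(out)) return(data.frame(class = character(),
                                      direction = character()))
  res <- do.call(rbind, out)
  if (all(c("IT", "L2/3 IT", "L5 IT") %in% res$class))
    res <- res[!res$class %in% c("L2/3 IT", "L5 IT"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Build a one-regionality class-relevance input from a sign pattern.
pattern_to_records <- function(pattern, gene = "gX",
                               group = "GABAergic") {
  sig <- pattern[pattern != 0]
  if (!length(sig))
    return(data.frame(gene = character(), pair = character(),
                      group = character(), avg_logFC = numeric()))
  data.frame(gene = gene, pair = names(sig), group = group,
             avg_logFC = 0.5 * unname(sig))
}
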