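# Fixed cortical cell-type vocabulary shared by every stage of the pipeline.

#' Neuronal class and region vocabulary
#'
#' The analysis covers seven major neuronal classes shared between two
#' neocortical regions, the anterior lateral motor cortex (ALM) and the
#' primary visual cortex (VISp). Four classes are glutamatergic projection
#' neurons (L2/3 IT, L5 IT, L5 PT, L6 CT) and three are GABAergic
#' interneurons (VIP, SST, PV). The class order is the canonical comparison
#' order: within each group, pairwise comparisons always list the
#' earlier class first, so the sign of a fold change is directly comparable
#' between analogous ALM and VISp tests.
#'
#' @return `cortical_classes()` returns a named character vector mapping the
#'   seven class labels to their neurotransmitter group; `cortical_regions()`
#'   returns `c("ALM", "VISp")`.
#' @export
cortical_classes <- function() {
  c("L2/3 IT" = "glutamatergic",
    "L5 IT"   = "glutamatergic",
    "L5 PT"   = "glutamatergic",
    "L6 CT"   = "glutamatergic",
    "VIP"     = "GABAergic",
    "SST"     = "GABAergic",
    "PV"      = "GABAergic")
}

#' @rdname cortical_classes
#' @export
cortical_regions <- function() c("ALM", "VISp")

#' @param group `"glutamatergic"` or `"GABAergic"`.
#' @rdname cortical_classes
#' @export
classes_of_group <- function(group) {
  group <- match.arg(group, c("glutamatergic", "GABAergic"))
  cls <- cortical_classes()
  names(cls)[cls == group]
}

#' Group membership of a class label
#'
#' @param class character vector of class labels.
#' @return character vector of neurotransmitter groups.
#' @export
group_of_class <- function(class) {
  cls <- cortical_classes()
  bad <- setdiff(class, names(cls))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  unname(cls[class])
}

# "A vs B" pair label helpers ------------------------------------------------

pair_label <- function(class_a, class_b) paste(class_a, "vs", class_b)

split_pair <- function(pair) {
  parts <- strsplit(pair, " vs ", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed class pair label(s): ", paste(pair[bad], collapse = ", "))
  parts
}

#' Canonical within-group class pairs
#'
#' All unordered class pairs within a neurotransmitter group, each in the
#' canonical order (glutamatergic: L2/3 IT, L5 IT, L5 PT, L6 CT; GABAergic:
#' VIP, SST, PV).
#'
#' @inheritParams classes_of_group
#' @return data.frame with columns `class_a`, `class_b`, `pair`, `group`.
#' @export
class_pairs <- function(group) {
  cls <- classes_of_group(group)
  idx <- utils::combn(length(cls), 2L)
  data.frame(class_a = cls[idx[1L, ]],
             class_b = cls[idx[2L, ]],
             pair    = pair_label(cls[idx[1L, ]], cls[idx[2L, ]]),
             group   = group,
             row.names = NULL)
}

#' The fixed class sets used to call class-relevant genes
#'
#' A gene is relevant to a class only when its differential-expression
#' results are jointly consistent across every comparison in that class's
#' set. The composite class `"IT"` covers genes relevant to both L2/3 IT and
#' L5 IT; its set deliberately excludes the "L2/3 IT vs L5 IT" comparison.
#'
#' @return named list: class label -> character vector of comparison (pair)
#'   labels.
#' @export
class_set_table <- function() {
  list(
    "L2/3 IT" = c("L2/3 IT vs L5 IT", "L2/3 IT vs L6 CT", "L2/3 IT vs L5 PT"),
    "L5 IT"   = c("L2/3 IT vs L5 IT", "L5 IT vs L5 PT",   "L5 IT vs L6 CT"),
    "IT"      = c("L2/3 IT vs L5 PT", "L2/3 IT vs L6 CT",
                  "L5 IT vs L5 PT",   "L5 IT vs L6 CT"),
    "L5 PT"   = c("L2/3 IT vs L5 PT", "L5 IT vs L5 PT",   "L5 PT vs L6 CT"),
    "L6 CT"   = c("L2/3 IT vs L6 CT", "L5 IT vs L6 CT",   "L5 PT vs L6 CT"),
    "VIP"     = c("VIP vs PV", "VIP vs SST"),
    "SST"     = c("SST vs PV", "VIP vs SST"),
    "PV"      = c("SST vs PV", "VIP vs PV")
  )
}

# Which side of a pair a (possibly composite) class sits on: "first",
# "second", or NA if it does not participate. The IT composite matches
# whichever of its constituents appears; in the IT class set the constituent
# is always the first class.
class_side <- function(class, pair) {
  parts <- split_pair(pair)
  vapply(seq_along(pair), function(i) {
    a <- parts[[i]][1L]; b <- parts[[i]][2L]
    if (class == "IT") {
      if (a %in% c("L2/3 IT", "L5 IT")) "first"
      else if (b %in% c("L2/3 IT", "L5 IT")) "second"
      else NA_character_
    } else if (class == a) "first"
    else if (class == b) "second"
    else NA_character_
  }, character(1L))
}

# Comparison-id builders used across modules so labels stay byte-identical.
within_comparison_id <- function(group, region, pair)
  paste(group, region, pair)

cross_comparison_id <- function(group, class)
  paste(group, "ALM vs VISp", class)
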