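# Attaching feature tables to trees, branch-support classification and
# per-clade feature summaries.

#' Branch-support star thresholds
#'
#' The display convention used on the family tree: one star for support
#' above `one_star` percent, two stars for support reaching `two_star`
#' percent (defaults 75 and 100).
#'
#' @param one_star single-star threshold, percent.
#' @param two_star double-star threshold, percent.
#' @return A list of class `support_thresholds`.
#' @export
support_thresholds <- function(one_star = 75, two_star = 100) {
  if (!(one_star > 0 && one_star < two_star && two_star <= 100)) {
    stop("require 0 < one_star < two_star <= 100", call. = FALSE)
  }
  structure(list(one_star = one_star, two_star = two_star),
            class = "support_thresholds")
}

#' Classify branch support into star classes
#'
#' Returns 2 when support reaches the two-star threshold, 1 when it
#' strictly exceeds the one-star threshold (but not the two-star one),
#' otherwise 0. Missing supports give `NA` ("unscored").
#'
#' @param support numeric vector of support percents (typically ultrafast
#'   bootstrap values).
#' @param thresholds a [support_thresholds()].
#' @return Integer vector of 0, 1, 2 or `NA`.
#' @export
support_class <- function(support, thresholds = support_thresholds()) {
  stopifnot(inherits(thresholds, "support_thresholds"))
  out <- ifelse(is.na(support), NA_integer_,
         ifelse(support >= thresholds$two_star, 2L,
         ifelse(support > thresholds$one_star, 1L, 0L)))
  as.integer(out)
}

#' Star classes for every internal node of a support tree
#'
#' Keys on the ultrafast-bootstrap value when dual supports are present;
#' the SH-aLRT values remain available on the tree for reporting.
#'
#' @param tree a tree from [read_newick()].
#' @param thresholds a [support_thresholds()].
#' @return Integer vector, one class per internal node.
#' @export
tree_support_classes <- function(tree, thresholds = support_thresholds()) {
  if (is.null(tree$ufboot)) stop("tree carries no support values", call. = FALSE)
  support_class(tree$ufboot, thresholds)
}

#' Attach a feature table to the tips of a tree
#'
#' Tip ids are matched against the table's `id` column after applying
#' `id_normalize` to both sides. The tree itself is never modified.
#'
#' @param tree a `phylo` (or [read_newick()] tree).
#' @param table a feature table with an `id` column.
#' @param id_normalize function applied to ids before matching
#'   (default: identity).
#' @return A list of class `annotated_tree`: `tree` (unchanged),
#'   `features` (table rows reordered to tip order, NA-rows for unmatched
#'   tips) and `unmatched` (tip labels without a table row).
#' @export
annotate_tips <- function(tree, table, id_normalize = identity) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(table))
  tip_key <- id_normalize(tree$tip.label)
  tab_key <- id_normalize(table$id)
  idx <- match(tip_key, tab_key)
  if (all(is.na(idx))) {
    stop("no tree tip matches any feature-table id; check id schemes",
         call. = FALSE)
  }
  feats <- table[idx, , drop = FALSE]
  feats$id <- tree$tip.label
  rownames(feats) <- NULL
  unmatched <- tree$tip.label[is.na(idx)]
  structure(list(tree = tree, features = feats, unmatched = unmatched),
            class = "annotated_tree")
}

#' Per-clade feature summary
#'
#' The machine-readable twin of a clade-annotated feature figure: for
#' every clade in the map, the member count, a monophyly check (is the
#' smallest subtree containing the clade's tips tip-pure?), per-length
#' feature min/median/max and the fraction exceeding a threshold, and
#' per-boolean feature the fraction true (NA values excluded).
#'
#' @param tree a `phylo` whose tips the clade map addresses.
#' @param clade_map `data.frame` with columns `id` and `clade`; every
#'   mapped id must be a tip of `tree`.
#' @param table feature table with an `id` column.
#' @param length_thresholds optional named numeric vector; for a length
#'   column `L` present in its names, the fraction of members with
#'   `L > length_thresholds[L]` is reported.
#' @return A `data.frame` with one row per clade and feature statistic
#'   columns; empty clades yield a row with `n = 0`.
#' @export
clade_summary <- function(tree, clade_map, table, length_thresholds = NULL) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(clade_map), is.data.frame(table))
  missing_tips <- setdiff(clade_map$id, tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("clade map refers to tips absent from the tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  len_cols <- grep("_len$", names(table), value = TRUE)
  bool_cols <- names(table)[vapply(table, is.logical, logical(1))]
  clades <- unique(clade_map$clade)
  rows <- vector("list", length(clades))
  for (ci in seq_along(clades)) {
    cl <- clades[ci]
    tips <- clade_map$id[clade_map$clade == cl]
    members <- table[table$id %in% tips, , drop = FALSE]
    row <- list(clade = cl, n = nrow(members))
    row$monophyletic <- if (length(tips) == 0) NA else {
      if (length(tips) <= 1 || length(tips) == length(tree$tip.label)) TRUE
      else ape::is.monophyletic(tree, tips)
    }
    for (lc in len_cols) {
      v <- members[[lc]]
      v <- v[!is.na(v)]
      row[[paste0(lc, "_min")]] <- if (length(v)) min(v) else NA_real_
      row[[paste0(lc, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
      row[[paste0(lc, "_max")]] <- if (length(v)) max(v) else NA_real_
      if (!is.null(length_thresholds) && lc %in% names(length_thresholds)) {
        row[[paste0(lc, "_frac_over")]] <-
          if (length(v)) mean(v > length_thresholds[[lc]]) else NA_real_
      }
    }
    for (bc in bool_cols) {
      v <- members[[bc]]
      v <- v[!is.na(v)]
      row[[paste0(bc, "_frac")]] <- if (length(v)) mean(v) else NA_real_
    }
    rows[[ci]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Re-root a tree on a named outgroup
#'
#' @param tree a `phylo`.
#' @param outgroup_tips character vector of tip labels forming the
#'   outgroup (e.g. the non-metazoan homologs).
#' @return The re-rooted tree.
#' @export
root_on_outgroup <- function(tree, outgroup_tips) {
  missing <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing) > 0) {
    stop("outgroup tips absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE)
}
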