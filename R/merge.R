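# Marker-overlap cluster merging.
#
# Clusters are labeled high/low quality by thresholding their marker F scores
# at t_C; pairs whose marker sets overlap by at least a fraction t_G (in
# either direction) become merge candidates; only pairs containing at least
# one low-quality cluster are merged, transitively via union-find. Merging is
# a pure relabeling: per-cell order and all upstream results are untouched.

#' Label clusters high/low quality
#'
#' @param S named per-cluster scores in \[0, 1\].
#' @param t_C quality threshold; high iff `S_i >= t_C` (boundary counts as
#'   high).
#' @return named character vector of `"high"` / `"low"`.
#' @export
label_quality <- function(S, t_C) {
  stopifnot(all(S >= 0 & S <= 1))
  stats::setNames(ifelse(S >= t_C, "high", "low"), names(S))
}

#' Candidate merge pairs by marker overlap
#'
#' For each ordered pair, the overlap fraction is
#' `|G_i intersect G_j| / |G_i|`; the unordered pair is a candidate when the
#' fraction reaches `t_G` in either direction (or in the forward direction
#' only, with `direction = "forward"`). Empty marker sets are skipped with a
#' warning.
#'
#' @param marker_sets named list of per-cluster marker gene vectors (or a
#'   `MarkerSet`).
#' @param t_G overlap threshold in \[0, 1\]; default 1 (identical sets).
#' @param direction `"both"` (default) or `"forward"`.
#' @return data.frame with columns `i`, `j` (cluster names), `overlap_i`,
#'   `overlap_j` (the two directed fractions).
#' @export
candidate_pairs <- function(marker_sets, t_G = 1, direction = c("both", "forward")) {
  direction <- match.arg(direction)
  if (inherits(marker_sets, "MarkerSet")) marker_sets <- marker_genes(marker_sets)
  if (t_G < 0 || t_G > 1) stop("t_G must be in [0, 1]")
  ids <- names(marker_sets)
  empty <- vapply(marker_sets, length, integer(1)) == 0
  if (any(empty)) {
    warning("skipping cluster(s) with empty marker sets: ",
            paste(ids[empty], collapse = ", "))
  }
  out <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a || empty[a] || empty[b]) next
      Gi <- marker_sets[[a]]; Gj <- marker_sets[[b]]
      f_ij <- length(intersect(Gi, Gj)) / length(Gi)
      f_ji <- length(intersect(Gj, Gi)) / length(Gj)
      hit <- if (direction == "both") max(f_ij, f_ji) >= t_G else f_ij >= t_G
      if (hit) out[[length(out) + 1]] <- data.frame(
        i = ids[a], j = ids[b], overlap_i = f_ij, overlap_j = f_ji,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    data.frame(i = character(0), j = character(0),
               overlap_i = numeric(0), overlap_j = numeric(0))
  } else {
    do.call(rbind, out)
  }
}

#' Build a merge plan from candidate pairs and quality labels
#'
#' Pairs where both members are high quality are dropped; the remaining pairs
#' are closed transitively with union-find, and each merged component is
#' relabeled to the id of its largest member cluster (by cell count).
#'
#' @param pairs a [candidate_pairs()] data.frame.
#' @param quality named high/low labels from [label_quality()].
#' @param sizes named per-cluster cell counts (used to pick each component's
#'   representative id).
#' @return an object of class `MergePlan`: `relabeling` (named old -> merged
#'   id map over all clusters), `components` (list), `quality`, `pairs`.
#' @export
build_merge_plan <- function(pairs, quality, sizes) {
  ids <- names(quality)
  stopifnot(!is.null(ids), all(names(sizes) %in% ids), all(ids %in% names(sizes)))
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  mergeable <- pairs[quality[pairs$i] == "low" | quality[pairs$j] == "low", ,
                     drop = FALSE]
  for (r in seq_len(nrow(mergeable))) {
    ra <- find(match(mergeable$i[r], ids))
    rb <- find(match(mergeable$j[r], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  relabeling <- stats::setNames(character(length(ids)), ids)
  components <- list()
  for (r in unique(roots)) {
    members <- ids[roots == r]
    rep_id <- members[which.max(sizes[members])]
    relabeling[members] <- rep_id
    components[[rep_id]] <- members
  }
  structure(list(relabeling = relabeling, components = components,
                 quality = quality, pairs = mergeable),
            class = "MergePlan")
}

#' Apply a merge plan to per-cell labels
#'
#' Pure relabeling: cell order is untouched and the number of distinct output
#' labels equals the number of merge components. Idempotent (component
#' representatives map to themselves).
#'
#' @param labels per-cell cluster ids drawn from the plan's domain.
#' @param plan a `MergePlan`.
#' @return per-cell merged ids (character).
#' @export
apply_merge <- function(labels, plan) {
  lab <- as.character(labels)
  unknown <- setdiff(unique(lab), names(plan$relabeling))
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  unname(plan$relabeling[lab])
}

#' End-to-end cluster merging
#'
#' Convenience wrapper: quality labeling at `t_C`, candidate pairs at `t_G`,
#' union-find plan, relabeled cells.
#'
#' @param labels per-cell cluster labels.
#' @param marker_set a `MarkerSet` from [find_markers()].
#' @param t_C quality threshold on S_i (default 0.5).
#' @param t_G overlap threshold (default 1: only identical marker sets merge).
#' @param direction see [candidate_pairs()].
#' @return list with `labels` (merged per-cell ids) and `plan`.
#' @export
merge_clusters <- function(labels, marker_set, t_C = 0.5, t_G = 1,
                           direction = "both") {
  quality <- label_quality(marker_set$S, t_C)
  pairs <- candidate_pairs(marker_set, t_G = t_G, direction = direction)
  sizes <- table(as.character(labels))
  sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  missing <- setdiff(names(quality), names(sizes))
  sizes[missing] <- 0
  plan <- build_merge_plan(pairs, quality, sizes)
  list(labels = apply_merge(labels, plan), plan = plan)
}
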