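## Per-patient clonal phylogenies from biopsy presence patterns. Each distinct
## nonempty presence bitmask becomes a candidate edge whose length is its
## mutation count; pairwise-compatible (nested or disjoint) patterns form a
## perfect phylogeny, rendered as the Hasse diagram of bitmask containment
## rooted at the full mask (the trunk, carrying clonal mutations).

.mask_from_logical <- function(presence) {
  sum(2^(which(presence) - 1L))
}

.mask_bits <- function(mask, n) {
  bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
}

#' Group a patient's variants into presence patterns
#'
#' One pattern per distinct nonempty presence bitmask, with the number of
#' merged variants showing exactly that pattern. NONE-labelled variants
#' (empty presence) are excluded.
#'
#' @param merged Classified merged variants for one patient (needs the
#'   \code{presence} list-column).
#' @return Data.frame with columns \code{mask} (integer bitmask over the
#'   biopsy order, bit 1 = first biopsy) and \code{count}; counts sum to the
#'   number of included variants.
#' @export
build_presence_patterns <- function(merged) {
  if (nrow(merged) == 0L) {
    return(data.frame(mask = integer(0), count = integer(0)))
  }
  masks <- vapply(merged$presence, .mask_from_logical, numeric(1))
  masks <- masks[masks > 0]
  if (length(masks) == 0L) {
    return(data.frame(mask = integer(0), count = integer(0)))
  }
  tab <- table(masks)
  data.frame(mask = as.integer(names(tab)), count = as.integer(tab))
}

.compatible <- function(a, b) {
  inter <- bitwAnd(a, b)
  inter == 0L || inter == a || inter == b
}

#' Greedy resolution of incompatible presence patterns
#'
#' Patterns are sorted by descending mutation count (ties broken by smaller
#' bitmask integer value first) and accepted greedily when compatible (nested
#' or disjoint) with everything accepted so far. Dropped patterns are
#' returned, never silently discarded.
#'
#' @param patterns Data.frame from \code{\link{build_presence_patterns}}.
#' @return List with \code{kept} and \code{dropped} pattern data.frames.
#' @export
resolve_conflicts <- function(patterns) {
  if (nrow(patterns) == 0L) {
    return(list(kept = patterns, dropped = patterns))
  }
  ord <- order(-patterns$count, patterns$mask)
  p <- patterns[ord, , drop = FALSE]
  keep <- logical(nrow(p))
  accepted <- integer(0)
  for (i in seq_len(nrow(p))) {
    if (all(vapply(accepted, .compatible, logical(1), b = p$mask[i]))) {
      keep[i] <- TRUE
      accepted <- c(accepted, p$mask[i])
    }
  }
  list(kept = p[keep, , drop = FALSE], dropped = p[!keep, , drop = FALSE])
}

#' Build a clonal tree from compatible presence patterns
#'
#' Constructs the Hasse diagram of bitmask containment, rooted at the
#' full-presence mask (the trunk; inserted with length 0 when no clonal
#' mutations exist). Singleton masks attach as leaf edges; biopsies lacking
#' private mutations get leaf edges of length 0. Edge length = mutation count
#' of the pattern.
#'
#' @param patterns Pairwise-compatible pattern data.frame (see
#'   \code{\link{resolve_conflicts}}).
#' @param biopsy_order Character vector of biopsy ids; bit i of a mask refers
#'   to \code{biopsy_order[i]}.
#' @return A \code{clonal_tree}: list with \code{edges} (data.frame
#'   \code{mask, parent, length}), \code{biopsy_order}, \code{root_mask}.
#' @export
build_tree <- function(patterns, biopsy_order) {
  n <- length(biopsy_order)
  stopifnot(n >= 1)
  if (anyDuplicated(biopsy_order)) {
    stop_parse("build_tree: duplicate biopsy ids")
  }
  masks <- patterns$mask
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (!.compatible(masks[i], masks[j])) {
        stop_parse("build_tree: incompatible patterns %d and %d (resolve first)",
                   masks[i], masks[j])
      }
    }
  }
  full <- sum(2^(seq_len(n) - 1L))
  counts <- stats::setNames(patterns$count, patterns$mask)
  all_masks <- unique(c(full, masks, 2^(seq_len(n) - 1L)))
  len <- vapply(as.character(all_masks),
                function(m) unname(counts[m]) %na0% 0L, numeric(1))
  # parent = smallest strict superset among the node masks (containment chain)
  parent <- vapply(all_masks, function(m) {
    sup <- all_masks[all_masks != m & bitwAnd(all_masks, m) == m]
    if (length(sup) == 0L) return(NA_integer_)
    sup[which.min(vapply(sup, function(s) sum(.mask_bits(s, n)), numeric(1)))]
  }, numeric(1))
  edges <- data.frame(mask = all_masks, parent = parent, length = unname(len))
  structure(list(edges = edges, biopsy_order = biopsy_order,
                 root_mask = full),
            class = "clonal_tree")
}

`%na0%` <- function(a, b) if (is.na(a)) b else a

#' Total branch length of a clonal tree
#' @param tree A \code{clonal_tree}.
#' @return Sum of all edge lengths (= mutations retained).
#' @export
tree_total_length <- function(tree) sum(tree$edges$length)

#' Newick string for a clonal tree
#'
#' Leaves are biopsy ids, branch lengths are mutation counts, the trunk is the
#' root branch length. Errors on duplicate leaf names.
#'
#' @param tree A \code{clonal_tree}.
#' @return Newick string terminated by \code{";"}.
#' @export
format_newick <- function(tree) {
  n <- length(tree$biopsy_order)
  if (anyDuplicated(tree$biopsy_order)) {
    stop_parse("format_newick: duplicate leaf names")
  }
  edges <- tree$edges
  render <- function(mask) {
    len <- edges$length[edges$mask == mask]
    kids <- edges$mask[!is.na(edges$parent) & edges$parent == mask]
    is_leaf_mask <- sum(.mask_bits(mask, n)) == 1L
    if (is_leaf_mask && length(kids) == 0L) {
      leaf <- tree$biopsy_order[which(.mask_bits(mask, n))]
      return(sprintf("%s:%s", leaf, format(len, scientific = FALSE)))
    }
    if (length(kids) == 0L) {
      # internal mask with no children can only be the degenerate full mask
      leaf <- tree$biopsy_order[which(.mask_bits(mask, n))]
      return(sprintf("(%s)", paste0(leaf, ":0")))
    }
    inner <- paste(vapply(sort(kids), render, character(1)), collapse = ",")
    sprintf("(%s):%s", inner, format(len, scientific = FALSE))
  }
  root <- tree$root_mask
  kids <- edges$mask[!is.na(edges$parent) & edges$parent == root]
  root_len <- edges$length[edges$mask == root]
  if (length(kids) == 0L) {
    # single-biopsy patient: root mask is itself the singleton
    leaf <- tree$biopsy_order[which(.mask_bits(root, n))]
    return(sprintf("(%s:0):%s;", leaf, format(root_len, scientific = FALSE)))
  }
  inner <- paste(vapply(sort(kids), render, character(1)), collapse = ",")
  sprintf("(%s):%s;", inner, format(root_len, scientific = FALSE))
}

#' Exhaustive maximum-count compatible pattern subset (test oracle)
#'
#' Brute-force search over all subsets of patterns for the pairwise-compatible
#' subset with maximal total mutation count. Exponential; intended for
#' small instances (<= 20 patterns) as an oracle for
#' \code{\link{resolve_conflicts}}.
#'
#' @param patterns Pattern data.frame.
#' @return List with \code{best_count} and \code{kept} (one optimal subset).
#' @export
best_compatible_subset <- function(patterns) {
  m <- nrow(patterns)
  stopifnot(m <= 20)
  if (m == 0L) return(list(best_count = 0, kept = patterns))
  best <- 0
  best_idx <- integer(0)
  for (s in 0:(2^m - 1)) {
    idx <- which(bitwAnd(s, 2^(seq_len(m) - 1L)) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (i in seq_along(idx)) {
        for (j in seq_len(i - 1L)) {
          if (!.compatible(patterns$mask[idx[i]], patterns$mask[idx[j]])) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) {
      tot <- sum(patterns$count[idx])
      if (tot > best) {
        best <- tot
        best_idx <- idx
      }
    }
  }
  list(best_count = best, kept = patterns[best_idx, , drop = FALSE])
}
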