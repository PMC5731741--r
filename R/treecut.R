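#' Tree-cut parameters
#'
#' @param maxTreeHeight Merges above this dendrogram height never join two
#'   clusters (default 1, the maximum of a Jaccard or correlation
#'   dissimilarity).
#' @param deepSplit Aggressive sub-cluster decomposition (default TRUE). See
#'   \code{\link{dynamic_tree_cut}} for the operational meaning.
#' @param minModuleSize Minimum cluster size (default 50); smaller fragments
#'   are left unassigned.
#' @return An object of class \code{tree_cut_params}.
#' @export
tree_cut_params <- function(maxTreeHeight = 1, deepSplit = TRUE,
                            minModuleSize = 50L) {
  if (minModuleSize < 1L) stop("minModuleSize must be >= 1", call. = FALSE)
  structure(list(maxTreeHeight = maxTreeHeight,
                 deepSplit = isTRUE(deepSplit),
                 minModuleSize = as.integer(minModuleSize)),
            class = "tree_cut_params")
}

#' Adaptive dynamic cut of a dendrogram
#'
#' Extracts clusters from an agglomerative tree without a single fixed cut
#' height. The tree is first cut statically at \code{maxTreeHeight} (merges
#' above it never join clusters). Each resulting branch of at least
#' \code{minModuleSize} leaves is then cut adaptively: every internal merge
#' height is a candidate cut, a candidate is admissible only when the next
#' merge above it is separated by a clear height gap (so homogeneous branches
#' are not shattered at arbitrary heights), and among admissible candidates
#' the cut producing the most clusters of size >= \code{minModuleSize} is
#' chosen (ties broken by the number of leaves assigned, then by the lower
#' cut). Leaves falling in fragments below \code{minModuleSize} at the chosen
#' cut get label 0 (unassigned), which makes the procedure robust to outlying
#' leaves. \code{deepSplit} sets the required gap as a fraction of the
#' dissimilarity scale (the height cap, or the tree top if lower):
#' \code{TRUE} demands only 5\% (aggressive decomposition), \code{FALSE}
#' 25\% (coarse clusters).
#'
#' Clusters are numbered 1, 2, ... in decreasing size (ties by lowest leaf
#' index); the partition does not depend on the input item order.
#'
#' @param h An \code{\link[stats]{hclust}} object (or something
#'   \code{as.hclust} can coerce).
#' @param params A \code{\link{tree_cut_params}} object.
#' @return Integer vector of cluster labels (0 = unassigned), named by the
#'   tree's leaf labels, in the original item order.
#' @export
dynamic_tree_cut <- function(h, params = tree_cut_params()) {
  stopifnot(inherits(params, "tree_cut_params"))
  h <- stats::as.hclust(h)
  n <- length(h$order)
  labs <- if (!is.null(h$labels)) h$labels else as.character(seq_len(n))
  out <- stats::setNames(integer(n), labs)
  if (params$minModuleSize > n) {
    warning("minModuleSize (", params$minModuleSize,
            ") exceeds the item count (", n, "); all items unassigned")
    return(out)
  }
  if (n == 1L) {
    out[] <- if (params$minModuleSize <= 1L) 1L else 0L
    return(out)
  }

  static <- stats::cutree(h, h = params$maxTreeHeight)
  # each merge applied at <= maxTreeHeight lies inside exactly one static
  # cluster; find a representative leaf for every merge
  rep_leaf <- integer(length(h$height))
  for (i in seq_along(h$height)) {
    child <- h$merge[i, 1L]
    rep_leaf[i] <- if (child < 0L) -child else rep_leaf[child]
  }
  merge_cluster <- ifelse(h$height <= params$maxTreeHeight,
                          static[rep_leaf], NA_integer_)

  # admissible cuts must be separated from the next merge by a fixed fraction
  # of the dissimilarity scale (the height cap, or the tree top if lower), so
  # jitter-level height differences inside a homogeneous branch never count
  # as structure
  gap_frac <- if (params$deepSplit) 0.05 else 0.25
  scale <- min(params$maxTreeHeight, max(h$height))
  gap_needed <- gap_frac * max(scale, .Machine$double.eps)
  clusters <- list()   # list of integer leaf-index vectors

  for (cl in sort(unique(static))) {
    leaves <- which(static == cl)
    if (length(leaves) < params$minModuleSize) next
    internal_h <- h$height[!is.na(merge_cluster) & merge_cluster == cl]
    cand <- sort(unique(internal_h))
    if (!length(cand)) {  # single-leaf static cluster (minModuleSize = 1)
      clusters <- c(clusters, list(leaves))
      next
    }
    hrange <- max(cand)
    best <- NULL
    for (hc in cand) {
      above <- cand[cand > hc]
      sep <- if (length(above)) min(above) - hc else Inf
      if (hc < hrange && sep < gap_needed) next  # no clear separation
      glab <- stats::cutree(h, h = hc)[leaves]
      sizes <- table(glab)
      valid <- sizes >= params$minModuleSize
      score <- c(sum(valid), sum(sizes[valid]), -hc)
      if (is.null(best) ||
          score[1L] > best$score[1L] ||
          (score[1L] == best$score[1L] && score[2L] > best$score[2L]) ||
          (score[1L] == best$score[1L] && score[2L] == best$score[2L] &&
           score[3L] > best$score[3L])) {
        comps <- split(leaves, glab)
        best <- list(score = score,
                     comps = comps[names(sizes)[valid]])
      }
    }
    clusters <- c(clusters, best$comps)
  }

  if (length(clusters)) {
    ord <- order(-lengths(clusters),
                 vapply(clusters, min, integer(1L)))
    clusters <- clusters[ord]
    for (i in seq_along(clusters))
      out[clusters[[i]]] <- i
  }
  out
}
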