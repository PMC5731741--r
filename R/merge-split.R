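#' Jaccard overlap ratio between two modules
#'
#' @param m1,m2 Non-empty character vectors of gene ids.
#' @return \eqn{|m1 \cap m2| / |m1 \cup m2|} in [0, 1].
#' @export
overlap_ratio <- function(m1, m2) {
  if (!length(m1) || !length(m2))
    stop("overlap ratio of an empty module is undefined", call. = FALSE)
  length(intersect(m1, m2)) / length(union(m1, m2))
}

#' Pairwise overlap-ratio matrix of a module set
#'
#' Computed via a membership indicator matrix so large collections stay fast:
#' intersections are a single cross-product, unions follow from the sizes.
#'
#' @param ms A \code{module_set} with at least 2 modules.
#' @return Symmetric matrix of Jaccard indices with unit diagonal.
#' @export
overlap_matrix <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  mods <- ms$modules
  if (length(mods) < 2L) stop("need at least 2 modules", call. = FALSE)
  if (any(lengths(mods) == 0L)) stop("empty module in set", call. = FALSE)
  genes <- sort(unique(unlist(mods)))
  B <- matrix(0, nrow = length(mods), ncol = length(genes),
              dimnames = list(names(mods), genes))
  for (i in seq_along(mods))
    B[i, mods[[i]]] <- 1
  inter <- B %*% t(B)
  sizes <- lengths(mods)
  uni <- outer(sizes, sizes, `+`) - inter
  ov <- inter / uni
  diag(ov) <- 1
  ov
}

#' Merge highly overlapping SPE modules into large modules (Step 3)
#'
#' SPE modules grown from seed pairs inside the same co-expression structure
#' are nearly identical; this step groups them by hierarchical clustering on
#' the dissimilarity (1 - overlap ratio) followed by
#' \code{\link{dynamic_tree_cut}}, and unions the gene sets within each
#' cluster into one "large" module. SPE modules the cut leaves unassigned are
#' passed through as singleton large modules (flagged in the provenance)
#' rather than discarded.
#'
#' @param spe A non-empty \code{module_set} of stage \code{"SPE"}.
#' @param params A \code{\link{tree_cut_params}} object.
#' @param linkage Agglomeration method for \code{\link[stats]{hclust}}.
#' @return A \code{module_set} of stage \code{"large"}; provenance records
#'   the member SPE modules of each cluster.
#' @export
merge_similar_modules <- function(spe, params = tree_cut_params(),
                                  linkage = c("average", "complete",
                                              "single")) {
  stopifnot(inherits(spe, "module_set"))
  linkage <- match.arg(linkage)
  mods <- spe$modules
  if (!length(mods)) stop("empty SPE module set", call. = FALSE)
  if (length(mods) == 1L)
    return(module_set(stats::setNames(mods, "large_1"), stage = "large",
                      provenance = names(spe$modules)))
  ov <- overlap_matrix(spe)
  d <- stats::as.dist(1 - ov)
  tree <- stats::hclust(d, method = linkage)
  labels <- dynamic_tree_cut(tree, params)

  large <- list()
  prov <- character(0L)
  for (cl in sort(unique(labels[labels > 0L]))) {
    member_mods <- names(labels)[labels == cl]
    large <- c(large, list(sort(unique(unlist(mods[member_mods])))))
    prov <- c(prov, paste(member_mods, collapse = ","))
  }
  for (nm in names(labels)[labels == 0L]) {
    large <- c(large, list(mods[[nm]]))
    prov <- c(prov, paste0("unassigned:", nm))
  }
  names(large) <- sprintf("large_%d", seq_along(large))
  module_set(large, stage = "large", provenance = prov)
}

#' Split a large module into final modules (Step 4)
#'
#' Genes of one large module are clustered hierarchically with dissimilarity
#' \eqn{1 - a_{ij}} (one minus absolute correlation; set
#' \code{use_abs = FALSE} for signed \eqn{1 - r_{ij}}) and cut with
#' \code{\link{dynamic_tree_cut}}. Each cluster becomes a final module; genes
#' the cut leaves unassigned are dropped, so the final modules from one large
#' module are pairwise disjoint. A large module smaller than
#' \code{minModuleSize} is returned unsplit as a single module flagged in its
#' provenance.
#'
#' @param large Character vector, the large module's members (>= 2).
#' @param a Absolute correlation matrix covering the members.
#' @param params A \code{\link{tree_cut_params}} object.
#' @param linkage Agglomeration method.
#' @param name_prefix Prefix for the resulting module names.
#' @return A \code{module_set} of stage \code{"FGMD"}.
#' @export
split_large_module <- function(large, a, params = tree_cut_params(),
                               linkage = c("average", "complete", "single"),
                               name_prefix = "FGMD") {
  linkage <- match.arg(linkage)
  check_cor_matrix(a)
  large <- sort(unique(as.character(large)))
  if (length(large) < 2L)
    stop("a large module needs at least 2 members", call. = FALSE)
  if (!all(large %in% rownames(a)))
    stop("large-module genes missing from the correlation matrix",
         call. = FALSE)
  if (length(large) < params$minModuleSize) {
    return(module_set(stats::setNames(list(large),
                                      paste0(name_prefix, "_1")),
                      stage = "FGMD", provenance = "unsplit:below-min-size"))
  }
  d <- stats::as.dist(1 - a[large, large])
  tree <- stats::hclust(d, method = linkage)
  labels <- dynamic_tree_cut(tree, params)
  cl_ids <- sort(unique(labels[labels > 0L]))
  if (!length(cl_ids)) {
    # the cut found no valid sub-cluster; keep the module whole
    return(module_set(stats::setNames(list(large),
                                      paste0(name_prefix, "_1")),
                      stage = "FGMD", provenance = "unsplit:no-valid-cut"))
  }
  mods <- lapply(cl_ids, function(cl) sort(names(labels)[labels == cl]))
  names(mods) <- sprintf("%s_%d", name_prefix, seq_along(mods))
  module_set(mods, stage = "FGMD",
             provenance = rep("split", length(mods)))
}

#' Split every large module (Step 4, whole set)
#'
#' @param large_ms A \code{module_set} of stage \code{"large"}.
#' @param a Absolute correlation matrix.
#' @param params,linkage Passed to \code{\link{split_large_module}}.
#' @return A \code{module_set} of stage \code{"FGMD"}; provenance names each
#'   module's parent large module.
#' @export
split_all_large_modules <- function(large_ms, a, params = tree_cut_params(),
                                    linkage = "average") {
  stopifnot(inherits(large_ms, "module_set"))
  mods <- list()
  prov <- character(0L)
  for (nm in names(large_ms$modules)) {
    sub <- split_large_module(large_ms$modules[[nm]], a, params, linkage,
                              name_prefix = nm)
    mods <- c(mods, sub$modules)
    prov <- c(prov, rep(nm, length(sub$modules)))
  }
  names(mods) <- sprintf("FGMD_%d", seq_along(mods))
  module_set(mods, stage = "FGMD", provenance = prov)
}

#' Extend small modules with overlapping genes from their parent
#'
#' Within one large module, the tree-cut split yields disjoint final modules.
#' This variant re-introduces overlap: for each final module, the parent gene
#' with the highest mean absolute correlation to the current members is added,
#' repeatedly, as long as adding it improves the module's mean in-module
#' absolute correlation. Modules from the same parent can then share genes.
#'
#' @param fgmd_ms A \code{module_set} whose modules are all subsets of
#'   \code{parent}.
#' @param parent Character vector, the parent large module's members.
#' @param a Absolute correlation matrix.
#' @return The extended \code{module_set} (same names and stage).
#' @export
extend_small_modules_with_overlap <- function(fgmd_ms, parent, a) {
  stopifnot(inherits(fgmd_ms, "module_set"))
  check_cor_matrix(a)
  parent <- unique(as.character(parent))
  mods <- fgmd_ms$modules
  if (!all(unlist(mods) %in% parent))
    stop("every module must be a subset of the parent module", call. = FALSE)
  for (nm in names(mods)) {
    members <- mods[[nm]]
    if (length(members) < 2L) next
    sub <- a[members, members]
    pair_sum <- (sum(sub) - length(members)) / 2
    n_pairs <- length(members) * (length(members) - 1L) / 2
    repeat {
      cand <- sort(setdiff(parent, members))
      if (!length(cand)) break
      cand_mean <- if (length(cand) == 1L)
        stats::setNames(mean(a[cand, members]), cand)
      else
        rowMeans(a[cand, members, drop = FALSE])
      best <- names(which.max(cand_mean))
      new_sum <- pair_sum + sum(a[best, members])
      new_pairs <- n_pairs + length(members)
      if (new_sum / new_pairs <= pair_sum / n_pairs) break
      members <- c(members, best)
      pair_sum <- new_sum
      n_pairs <- new_pairs
    }
    mods[[nm]] <- sort(members)
  }
  module_set(mods, stage = fgmd_ms$stage, provenance = fgmd_ms$provenance)
}

#' Filter modules by size
#'
#' Keeps modules with \code{min_size <= size <= max_size}. The published
#' bounds are 10-300 for gene modules and 10-500 for isoform modules.
#'
#' @param ms A \code{module_set}.
#' @param min_size,max_size Inclusive bounds.
#' @return The filtered \code{module_set}.
#' @export
filter_module_sizes <- function(ms, min_size = 10L, max_size = 300L) {
  stopifnot(inherits(ms, "module_set"))
  if (min_size > max_size) stop("min_size must be <= max_size", call. = FALSE)
  keep <- lengths(ms$modules) >= min_size & lengths(ms$modules) <= max_size
  module_set(ms$modules[keep], stage = ms$stage,
             provenance = if (is.null(ms$provenance)) NULL
                          else ms$provenance[keep])
}
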