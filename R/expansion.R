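#' Expansion parameters for seed-pair growth (Step 2)
#'
#' Bundles the module threshold \code{M} (an absolute-correlation value,
#' conventionally the top-1\% pair quantile of the correlation matrix), the
#' batch size \code{k} of genes admitted per iteration, and the degree-capped
#' exclusion set. The cap interprets the "degree constraint" on candidates as
#' an upper bound only: a gene whose degree in the M-thresholded correlation
#' graph (edges where \eqn{a_{ij} \ge M}) exceeds the degree found at the
#' top-\code{degree_cap_percent} rank is never admitted to any module, which
#' limits redundancy among modules driven by promiscuous hub genes.
#'
#' @param a Absolute correlation matrix.
#' @param M Module threshold value; if \code{NULL}, computed as
#'   \code{top_quantile_threshold(a, M_percent)}.
#' @param M_percent Quantile (percent units) used when \code{M} is NULL.
#' @param k Genes added per iteration (default 10).
#' @param degree_cap_percent Rank position (percent of genes with non-zero
#'   degree in the M-graph) whose degree becomes the cap; \code{NULL} disables
#'   the cap.
#' @param max_iter Iteration ceiling guarding against non-termination.
#' @return An object of class \code{expansion_params}.
#' @export
expansion_params <- function(a, M = NULL, M_percent = 1, k = 10L,
                             degree_cap_percent = 0.1, max_iter = 1000L) {
  check_cor_matrix(a)
  if (is.null(M)) M <- top_quantile_threshold(a, M_percent)
  if (M < 0 || M > 1) stop("M must lie in [0, 1]", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  excluded <- character(0L)
  degree_cap <- Inf
  if (!is.null(degree_cap_percent)) {
    deg_m <- rowSums(a >= M) - 1L   # degree in the M-thresholded graph
    pos <- deg_m[deg_m > 0L]
    if (length(pos)) {
      rank_pos <- max(1L, ceiling(length(pos) * degree_cap_percent / 100))
      degree_cap <- unname(sort(pos, decreasing = TRUE)[rank_pos])
      excluded <- names(deg_m)[deg_m > degree_cap]
    }
  }
  structure(list(M = M, k = as.integer(k), excluded = excluded,
                 degree_cap = degree_cap, max_iter = as.integer(max_iter)),
            class = "expansion_params")
}

#' Minimum correlation of a candidate gene to a module
#'
#' The similarity of a candidate to a module is its weakest link: the minimum
#' absolute correlation between the candidate and any current member.
#'
#' @param a Absolute correlation matrix.
#' @param members Character vector of current module members.
#' @param gene A candidate gene id, not already a member.
#' @return The minimum \eqn{a_{gene, m}} over members \eqn{m}.
#' @export
candidate_pmin <- function(a, members, gene) {
  if (gene %in% members)
    stop("gene '", gene, "' is already a module member", call. = FALSE)
  if (!gene %in% rownames(a) || !all(members %in% rownames(a)))
    stop("gene or members missing from the correlation universe",
         call. = FALSE)
  min(a[gene, members])
}

#' Grow a seed pair into an SPE module (Step 2)
#'
#' Greedy expansion: starting from the two seed genes, each iteration computes
#' every non-member, non-excluded gene's minimum correlation to the current
#' members (\code{P_min}); genes with \code{P_min} strictly above the module
#' threshold \code{M} are eligible, and the \code{k} with the largest
#' \code{P_min} are all admitted simultaneously (genes tied with the k-th
#' value are also admitted, for order-independence). Iteration stops when no
#' gene is eligible. A pair with no eligible neighbours yields a two-member
#' module.
#'
#' @param pair Character vector of two gene ids.
#' @param a Absolute correlation matrix.
#' @param params An \code{\link{expansion_params}} object.
#' @return Character vector of module members, seed genes first and admitted
#'   genes in admission order (ties by id).
#' @export
expand_seed_pair <- function(pair, a, params) {
  stopifnot(inherits(params, "expansion_params"))
  if (length(pair) != 2L || !all(pair %in% rownames(a)))
    stop("pair must be two gene ids present in the correlation matrix",
         call. = FALSE)
  genes <- rownames(a)
  members <- as.character(pair)
  pool <- setdiff(genes, c(members, params$excluded))
  if (!length(pool)) return(members)
  # running minimum over members, updated incrementally as genes join
  pmin_vec <- pmin(a[members[1L], pool], a[members[2L], pool])
  names(pmin_vec) <- pool
  for (it in seq_len(params$max_iter)) {
    eligible <- pmin_vec[pmin_vec > params$M]
    if (!length(eligible)) return(members)
    ord <- order(-eligible, names(eligible))
    eligible <- eligible[ord]
    if (length(eligible) > params$k) {
      kth <- eligible[params$k]
      admit <- names(eligible)[eligible >= kth]
    } else {
      admit <- names(eligible)
    }
    members <- c(members, admit)
    pool <- setdiff(names(pmin_vec), admit)
    if (!length(pool)) return(members)
    pmin_vec <- pmin_vec[pool]
    for (g in admit)
      pmin_vec <- pmin(pmin_vec, a[g, pool])
  }
  stop("expansion did not terminate within ", params$max_iter, " iterations",
       call. = FALSE)
}

#' Expand every seed pair into an SPE module
#'
#' Runs \code{\link{expand_seed_pair}} independently for each seed pair; the
#' operation is pure per pair, so the result equals sequential execution
#' regardless of order. Duplicate member sets are retained (each seed pair
#' yields one module, as in the published pipeline).
#'
#' @param sn A \code{seed_network}.
#' @param a Absolute correlation matrix.
#' @param params An \code{\link{expansion_params}} object.
#' @return A \code{module_set} of stage \code{"SPE"}; module names are
#'   \code{SPE_<i>} with provenance recording the seed pair.
#' @export
expand_all_seeds <- function(sn, a, params) {
  stopifnot(inherits(sn, "seed_network"))
  n <- nrow(sn$pairs)
  mods <- vector("list", n)
  for (i in seq_len(n))
    mods[[i]] <- expand_seed_pair(sn$pairs[i, ], a, params)
  names(mods) <- sprintf("SPE_%d", seq_len(n))
  prov <- apply(sn$pairs, 1L, paste, collapse = "|")
  module_set(mods, stage = "SPE", provenance = prov)
}
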