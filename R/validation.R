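#' Mean in-module absolute correlation
#'
#' The coherence statistic of a module: the mean of \eqn{a_{ij}} over all
#' unordered member pairs, diagonal excluded.
#'
#' @param members Character vector of >= 2 gene ids.
#' @param a Absolute correlation matrix.
#' @return A number in [0, 1].
#' @export
in_module_mean_pcc <- function(members, a) {
  members <- unique(as.character(members))
  if (length(members) < 2L)
    stop("in-module mean needs at least 2 members", call. = FALSE)
  if (!all(members %in% rownames(a)))
    stop("module members missing from the correlation matrix", call. = FALSE)
  sub <- a[members, members]
  mean(sub[upper.tri(sub)])
}

#' Permutation test of module coherence
#'
#' Tests the null hypothesis that a module's mean in-module correlation is no
#' higher than that of a random gene set of the same size: \code{N} modules
#' are drawn uniformly from the correlation universe (without replacement
#' within a draw, independently across draws) and
#' \deqn{p = \#\{i : module_{avg} < random_{avg(i)}\} / N.}
#'
#' @param members Module members (>= 2, fewer than the universe size).
#' @param a Absolute correlation matrix.
#' @param N Number of random modules (default 1000).
#' @param seed Integer seed for the draws; required for reproducibility.
#' @return List with \code{module_avg}, \code{p}, \code{N} and \code{n_genes}.
#' @seealso \code{\link{permutation_test_set}} for testing a whole module set
#'   with Bonferroni correction.
#' @export
permutation_test <- function(members, a, N = 1000L, seed) {
  check_cor_matrix(a)
  members <- unique(as.character(members))
  n <- length(members)
  universe <- rownames(a)
  if (n >= length(universe))
    stop("module must be smaller than the correlation universe", call. = FALSE)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (!missing(seed)) set.seed(seed)
  module_avg <- in_module_mean_pcc(members, a)
  ut <- upper.tri(matrix(0, n, n))
  random_avg <- vapply(seq_len(N), function(i) {
    idx <- sample.int(length(universe), n)
    sub <- a[idx, idx]
    mean(sub[ut])
  }, numeric(1L))
  list(module_avg = module_avg,
       p = sum(module_avg < random_avg) / N,
       N = as.integer(N),
       n_genes = n)
}

#' Permutation coherence test for a module set
#'
#' Applies \code{\link{permutation_test}} to every module and corrects the
#' p-values across the tested modules with Bonferroni
#' (\eqn{q = min(1, p m)}).
#'
#' @param ms A \code{module_set}.
#' @param a Absolute correlation matrix.
#' @param N Random modules per test.
#' @param seed Integer seed.
#' @return data.frame with \code{module}, \code{n_genes}, \code{module_avg},
#'   \code{p} and \code{q}.
#' @export
permutation_test_set <- function(ms, a, N = 1000L, seed) {
  stopifnot(inherits(ms, "module_set"))
  if (!missing(seed)) set.seed(seed)
  rows <- lapply(names(ms$modules), function(nm) {
    r <- permutation_test(ms$modules[[nm]], a, N = N)
    data.frame(module = nm, n_genes = r$n_genes,
               module_avg = r$module_avg, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- pmin(1, out$p * nrow(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control,
#' \eqn{q_{(i)} = \min_{j \ge i} (p_{(j)} m / j)} capped at 1, returned in
#' input order. Thin validated wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0) || any(pvals > 1))
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric gene-set enrichment of modules
#'
#' For every module x term pair, computes the upper-tail hypergeometric
#' probability \eqn{P(X \ge overlap)} of drawing at least the observed number
#' of term genes when \code{module size} genes are drawn from a universe of
#' \code{universe_size} genes containing \code{term size} successes. Term
#' members are first restricted to the analysis universe. q-values are BH
#' adjusted per module across the terms of the collection.
#'
#' @param ms A \code{module_set}.
#' @param sets Named list of character vectors (one gene-set collection, e.g.
#'   from \code{\link{read_gmt}}).
#' @param universe Character vector of gene ids defining the background; its
#'   length is the hypergeometric population size.
#' @param global_adjust Adjust across all module x term tests at once instead
#'   of per module.
#' @return data.frame with \code{module}, \code{term}, \code{overlap},
#'   \code{module_size}, \code{term_size}, \code{universe_size}, \code{p},
#'   \code{q}, ordered by module then p.
#' @export
hypergeom_enrichment <- function(ms, sets, universe, global_adjust = FALSE) {
  stopifnot(inherits(ms, "module_set"))
  universe <- unique(as.character(universe))
  N <- length(universe)
  sets <- lapply(sets, intersect, y = universe)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) return(data.frame())
  rows <- list()
  for (nm in names(ms$modules)) {
    mod <- intersect(ms$modules[[nm]], universe)
    k <- length(mod)
    if (k == 0L) next
    if (k > N) stop("module larger than the universe", call. = FALSE)
    for (tn in names(sets)) {
      K <- length(sets[[tn]])
      ov <- length(intersect(mod, sets[[tn]]))
      p <- stats::phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(module = nm, term = tn, overlap = ov, module_size = k,
                   term_size = K, universe_size = N, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (global_adjust) {
    out$q <- bh_adjust(out$p)
  } else {
    out$q <- NA_real_
    for (nm in unique(out$module)) {
      sel <- out$module == nm
      out$q[sel] <- bh_adjust(out$p[sel])
    }
  }
  out[order(out$module, out$p), , drop = FALSE]
}

#' Ratio of a gene list captured by a module set
#'
#' \code{pooled}: total list hits over total module membership, counting a
#' gene once per module it occurs in. \code{unique}: hits among the distinct
#' genes of the set over the number of distinct genes.
#'
#' @param ms A non-empty \code{module_set}.
#' @param gene_list Non-empty character vector (e.g. known cancer genes).
#' @param mode \code{"pooled"} or \code{"unique"}.
#' @return A single ratio in [0, 1].
#' @export
gene_list_ratio <- function(ms, gene_list, mode = c("pooled", "unique")) {
  stopifnot(inherits(ms, "module_set"))
  mode <- match.arg(mode)
  if (!length(ms$modules)) stop("empty module set", call. = FALSE)
  if (!length(gene_list)) stop("empty gene list", call. = FALSE)
  gene_list <- unique(as.character(gene_list))
  if (mode == "pooled") {
    hits <- sum(vapply(ms$modules,
                       function(m) length(intersect(m, gene_list)),
                       integer(1L)))
    hits / sum(lengths(ms$modules))
  } else {
    uni <- unique(unlist(ms$modules))
    length(intersect(uni, gene_list)) / length(uni)
  }
}

#' Summary statistics of a module set
#'
#' Mirrors the standard module-statistics table: module count, mean size,
#' unique gene count, average occurrence of genes (total membership over
#' unique genes), mean in-module absolute correlation averaged over modules,
#' and the ratio of module duplication, defined here as (module count -
#' distinct member-set count) / module count.
#'
#' @param ms A non-empty \code{module_set}.
#' @param a Absolute correlation matrix (NULL skips the coherence column).
#' @return One-row data.frame.
#' @export
module_summary <- function(ms, a = NULL) {
  stopifnot(inherits(ms, "module_set"))
  mods <- ms$modules
  if (!length(mods)) stop("empty module set", call. = FALSE)
  sizes <- lengths(mods)
  uniq <- length(unique(unlist(mods)))
  distinct_sets <- length(unique(vapply(
    mods, function(m) paste(m, collapse = "\r"), character(1L))))
  mean_pcc <- if (is.null(a)) NA_real_ else
    mean(vapply(mods[sizes >= 2L], in_module_mean_pcc, numeric(1L), a = a))
  data.frame(n_modules = length(mods),
             mean_size = mean(sizes),
             unique_genes = uniq,
             duplication_ratio = (length(mods) - distinct_sets) / length(mods),
             mean_occurrence = sum(sizes) / uniq,
             mean_in_module_pcc = mean_pcc)
}
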