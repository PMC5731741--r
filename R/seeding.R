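#' Extract seed gene pairs (Step 1)
#'
#' Selects the top \code{S}\% of absolute-correlation gene pairs as candidate
#' seed pairs, then filters genes by their degree in the resulting seed-pair
#' network: genes connected to too few partners produce undersized modules,
#' genes connected to too many produce redundant ones. The upper bound
#' \code{D_max} is the degree of the gene at the top-\code{D_max_percent}
#' rank when genes are ordered by decreasing degree (ties with that degree are
#' kept). The filter runs in a single pass on the degrees of the unfiltered
#' candidate network, so a gene whose partner is removed survives if its own
#' original degree satisfied the bounds; set \code{iterate = TRUE} to instead
#' re-evaluate degrees after each removal round until stable.
#'
#' @param a Absolute correlation matrix.
#' @param S Seed quantile in percent units (default 0.005 = top 0.005\%).
#' @param D_min Minimum degree (default 5).
#' @param D_max_percent Rank position defining \code{D_max}, as a percent of
#'   genes with non-zero candidate degree (default 0.1). Use
#'   \code{rank_over_all = TRUE} to rank over the full gene universe instead.
#' @param iterate Re-apply the degree filter until a fixed point.
#' @param rank_over_all Rank the \code{D_max} position over all genes.
#' @return An object of class \code{seed_network}: list with \code{pairs}
#'   (two-column character matrix, lexicographically ordered within and across
#'   rows), \code{degrees} (over retained pairs), \code{seed_threshold},
#'   \code{D_max} and \code{params}.
#' @export
extract_seed_pairs <- function(a, S = 0.005, D_min = 5L, D_max_percent = 0.1,
                               iterate = FALSE, rank_over_all = FALSE) {
  check_cor_matrix(a)
  thr <- top_quantile_threshold(a, S)
  idx <- which(upper.tri(a) & a >= thr, arr.ind = TRUE)
  genes <- rownames(a)
  pairs <- cbind(genes[idx[, 1L]], genes[idx[, 2L]])
  # canonical order: smaller id first within a pair, pairs sorted
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, 2:1]
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]

  cand_deg <- table(factor(c(pairs[, 1L], pairs[, 2L]), levels = genes))
  cand_deg <- as.integer(cand_deg)
  names(cand_deg) <- genes

  pos_deg <- cand_deg[cand_deg > 0L]
  n_rank <- if (rank_over_all) length(genes) else length(pos_deg)
  rank_pos <- max(1L, ceiling(n_rank * D_max_percent / 100))
  sorted_deg <- sort(pos_deg, decreasing = TRUE)
  D_max <- if (rank_pos <= length(sorted_deg))
    unname(sorted_deg[rank_pos]) else 0L

  keep_gene <- function(deg) deg >= D_min & deg <= D_max
  deg <- cand_deg
  repeat {
    alive <- keep_gene(deg[pairs[, 1L]]) & keep_gene(deg[pairs[, 2L]])
    kept <- pairs[alive, , drop = FALSE]
    if (!iterate || nrow(kept) == nrow(pairs)) {
      pairs <- kept
      break
    }
    pairs <- kept
    deg <- table(factor(c(pairs[, 1L], pairs[, 2L]), levels = genes))
    deg <- stats::setNames(as.integer(deg), genes)
  }

  final_deg <- table(factor(c(pairs[, 1L], pairs[, 2L]), levels = genes))
  final_deg <- stats::setNames(as.integer(final_deg), genes)
  final_deg <- final_deg[final_deg > 0L]
  if (nrow(pairs) == 0L)
    warning("no seed pairs survive the degree filter")
  structure(list(pairs = unname(pairs),
                 degrees = final_deg,
                 seed_threshold = thr,
                 D_max = D_max,
                 params = list(S = S, D_min = D_min,
                               D_max_percent = D_max_percent,
                               iterate = iterate,
                               rank_over_all = rank_over_all)),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat("Seed gene-pair network\n")
  cat("  pairs:         ", nrow(x$pairs), "\n")
  cat("  genes:         ", length(x$degrees), "\n")
  cat(sprintf("  seed threshold: %.4f (top %g%% of |PCC|)\n",
              x$seed_threshold, x$params$S))
  cat("  degree bounds:  [", x$params$D_min, ", ", x$D_max, "]\n", sep = "")
  invisible(x)
}

#' Export seed pairs as TSV
#'
#' Writes one pair per line (\code{gene_a}, \code{gene_b}, \code{abs_pcc});
#' a leading \code{#} comment records the realized thresholds.
#'
#' @param sn A \code{seed_network}.
#' @param a The correlation matrix the network was built from.
#' @param path Output path.
#' @export
write_seed_pairs_tsv <- function(sn, a, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# seed pairs: S=%g%% threshold=%.6f D_min=%d D_max=%d",
    sn$params$S, sn$seed_threshold, as.integer(sn$params$D_min),
    as.integer(sn$D_max)), con)
  writeLines("gene_a\tgene_b\tabs_pcc", con)
  if (nrow(sn$pairs)) {
    vals <- a[cbind(sn$pairs[, 1L], sn$pairs[, 2L])]
    writeLines(sprintf("%s\t%s\t%.6f", sn$pairs[, 1L], sn$pairs[, 2L], vals),
               con)
  }
  invisible(path)
}
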