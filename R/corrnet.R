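# Internal: validate an absolute-correlation matrix (symmetric, unit diagonal,
# entries in [0, 1], named).
check_cor_matrix <- function(a) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a))
    stop("correlation input must be a square numeric matrix", call. = FALSE)
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    stop("correlation matrix must have identical row and column names",
         call. = FALSE)
  if (max(abs(a - t(a))) > 1e-12)
    stop("correlation matrix is not symmetric", call. = FALSE)
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("absolute correlations must lie in [0, 1]", call. = FALSE)
  invisible(a)
}

#' Absolute Pearson correlation matrix
#'
#' Computes \eqn{a_{ij} = |corr(x_i, x_j)|}, the connection strength between
#' every pair of features, with a unit diagonal. Features with zero variance
#' have no defined correlation; they are an error in strict mode and are
#' dropped (with a warning) otherwise.
#'
#' @param m Expression matrix (features x samples, >= 3 samples).
#' @param strict Error on constant rows instead of dropping them.
#' @return Symmetric matrix of absolute correlations with feature dimnames.
#' @export
abs_pcc_matrix <- function(m, strict = TRUE) {
  check_expression_matrix(m)
  if (ncol(m) < 3L)
    stop("need at least 3 samples to correlate", call. = FALSE)
  if (nrow(m) < 2L)
    stop("need at least 2 features to correlate", call. = FALSE)
  vars <- apply(m, 1L, stats::var)
  if (any(vars == 0)) {
    bad <- rownames(m)[vars == 0]
    if (strict)
      stop("constant feature(s) with zero variance: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    warning("dropping ", length(bad), " constant feature(s)")
    m <- m[vars > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(m)))
  a[a > 1] <- 1   # guard tiny fp overshoot
  diag(a) <- 1
  a
}

#' Threshold at the top quantile of pairwise correlations
#'
#' Returns the value \eqn{t} such that the \code{ceiling(P * top_percent /
#' 100)} largest off-diagonal pair values are \code{>= t}, where \eqn{P = n(n -
#' 1)/2} counts each unordered pair once. \code{top_percent} is in percent
#' units: 0.005 means the top 0.005\% of pairs, 1 the top 1\%.
#'
#' @param a Absolute correlation matrix.
#' @param top_percent Fraction of pairs to admit, in (0, 100].
#' @return The threshold value.
#' @export
top_quantile_threshold <- function(a, top_percent) {
  check_cor_matrix(a)
  if (!is.numeric(top_percent) || length(top_percent) != 1L ||
      top_percent <= 0 || top_percent > 100)
    stop("top_percent must lie in (0, 100]", call. = FALSE)
  vals <- a[upper.tri(a)]
  if (!length(vals)) stop("correlation matrix has no off-diagonal pairs",
                          call. = FALSE)
  k <- ceiling(length(vals) * top_percent / 100)
  k <- max(1L, min(length(vals), k))
  sort(vals, decreasing = TRUE)[k]
}

#' Weighted-network summary statistics
#'
#' Per-feature connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}} and coefficient
#' of variation of each feature's connection strengths, plus the scalar
#' statistics of the weighted co-expression network:
#' \deqn{Density = \sum_{i \ne j} a_{ij} / (n(n-1))}
#' \deqn{Centralization = max(k)/n - Density}
#' \deqn{Heterogeneity = \sqrt{variance(k)} / mean(k)}
#' The density sum excludes the diagonal; centralization follows the
#' unnormalised form above and may be negative (set \code{normalized = TRUE}
#' for the (n/(n-2)) * (max(k)/(n-1) - Density) variant); variance is the
#' population (divide-by-n) form.
#'
#' @param a Absolute correlation matrix over n >= 2 features.
#' @param normalized Use the normalised centralization variant.
#' @return A list with \code{connectivity}, \code{cv}, \code{density},
#'   \code{centralization}, \code{heterogeneity} and \code{n}.
#' @export
network_stats <- function(a, normalized = FALSE) {
  check_cor_matrix(a)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 features", call. = FALSE)
  k <- rowSums(a) - diag(a)
  density <- sum(k) / (n * (n - 1))
  centralization <- if (normalized)
    (n / (n - 2)) * (max(k) / (n - 1) - density)
  else
    max(k) / n - density
  pop_var <- function(x) mean((x - mean(x))^2)
  heterogeneity <- sqrt(pop_var(k)) / mean(k)
  off <- a
  diag(off) <- NA
  row_mean <- rowMeans(off, na.rm = TRUE)
  row_sd <- apply(off, 1L, function(x) sqrt(pop_var(x[!is.na(x)])))
  list(connectivity = k,
       cv = row_sd / row_mean,
       density = density,
       centralization = centralization,
       heterogeneity = heterogeneity,
       n = n)
}

#' Per-pair differences between two correlation matrices
#'
#' For the gene pairs shared by two platforms (e.g. microarray vs RNA-Seq),
#' summarises \eqn{|a^{(1)}_{ij} - a^{(2)}_{ij}|}: the mean absolute
#' difference, the count of pairs exceeding \code{cutoff}, and a histogram of
#' the differences.
#'
#' @param a1,a2 Absolute correlation matrices; universes are intersected (an
#'   empty intersection is an error).
#' @param cutoff Difference level defining a "large" discrepancy.
#' @param breaks Histogram breaks over [0, 1].
#' @return List with \code{mean_difference}, \code{n_pairs},
#'   \code{count_above_cutoff}, \code{cutoff} and \code{histogram}.
#' @export
paired_pcc_differences <- function(a1, a2, cutoff = 0.5,
                                   breaks = seq(0, 1, by = 0.1)) {
  check_cor_matrix(a1)
  check_cor_matrix(a2)
  shared <- intersect(rownames(a1), rownames(a2))
  if (length(shared) < 2L)
    stop("correlation matrices share fewer than 2 features", call. = FALSE)
  d1 <- a1[shared, shared]
  d2 <- a2[shared, shared]
  diffs <- abs(d1 - d2)[upper.tri(d1)]
  list(mean_difference = mean(diffs),
       n_pairs = length(diffs),
       count_above_cutoff = sum(diffs > cutoff),
       cutoff = cutoff,
       histogram = graphics::hist(diffs, breaks = breaks, plot = FALSE))
}

#' Maximum isoform-level correlation for gene pairs
#'
#' For each gene pair (typically a validated gene-gene interaction), takes the
#' maximum absolute Pearson correlation over all combinations of the two
#' genes' isoforms. Pairs where a gene has no surviving isoform in the
#' expression matrix are skipped and reported.
#'
#' @param gene_pairs Two-column character matrix or data.frame of gene pairs.
#' @param iso_map Named list: gene id -> character vector of isoform ids.
#' @param iso_expr Isoform expression matrix (isoforms x samples).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{max_abs_pcc} (NA for skipped pairs) and \code{skipped}.
#' @export
ggi_max_isoform_pcc <- function(gene_pairs, iso_map, iso_expr) {
  check_expression_matrix(iso_expr)
  gene_pairs <- as.matrix(gene_pairs)
  if (ncol(gene_pairs) != 2L)
    stop("gene_pairs must have two columns", call. = FALSE)
  res <- data.frame(gene_a = gene_pairs[, 1L], gene_b = gene_pairs[, 2L],
                    max_abs_pcc = NA_real_, skipped = FALSE,
                    stringsAsFactors = FALSE)
  et <- t(iso_expr)
  for (i in seq_len(nrow(gene_pairs))) {
    iso_a <- intersect(iso_map[[gene_pairs[i, 1L]]], rownames(iso_expr))
    iso_b <- intersect(iso_map[[gene_pairs[i, 2L]]], rownames(iso_expr))
    if (!length(iso_a) || !length(iso_b)) {
      res$skipped[i] <- TRUE
      warning("pair (", gene_pairs[i, 1L], ", ", gene_pairs[i, 2L],
              ") skipped: gene with no surviving isoform")
      next
    }
    cc <- abs(stats::cor(et[, iso_a, drop = FALSE], et[, iso_b, drop = FALSE]))
    res$max_abs_pcc[i] <- max(cc)
  }
  res
}

#' Export per-feature connectivity as TSV
#'
#' @param stats Result of \code{\link{network_stats}}.
#' @param path Output path.
#' @export
write_connectivity_tsv <- function(stats, path) {
  df <- data.frame(feature = names(stats$connectivity),
                   connectivity = unname(stats$connectivity),
                   cv = unname(stats$cv))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
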