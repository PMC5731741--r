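#' Describe a planted correlated block
#'
#' @param id Block identifier.
#' @param genes Character vector of >= 2 member gene ids; blocks may share
#'   genes.
#' @param r Target within-block correlation in (0, 1).
#' @param noise_sd Standard deviation of the gene-specific noise before row
#'   normalisation (default 1).
#' @return An object of class \code{block_spec}.
#' @export
block_spec <- function(id, genes, r, noise_sd = 1) {
  if (length(genes) < 2L) stop("a block needs >= 2 genes", call. = FALSE)
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)", call. = FALSE)
  structure(list(id = id, genes = as.character(genes), r = r,
                 noise_sd = noise_sd),
            class = "block_spec")
}

#' Standard planted-block layout
#'
#' The package's reference simulation scenario: \code{n_blocks} blocks of
#' \code{block_size} genes with target within-block correlation \code{r} on a
#' background of independent noise genes, with the last two blocks sharing
#' \code{n_shared} genes (emulating genes that participate in two biological
#' functions). Defaults give 5 blocks of 40 genes at r = 0.8, two of them
#' sharing 10 genes, inside a 600-gene universe.
#'
#' @param n_genes Total genes in the universe.
#' @param n_blocks,block_size,r,n_shared Layout parameters.
#' @return List of \code{\link{block_spec}} objects; gene ids are
#'   \code{g0001, g0002, ...}.
#' @export
default_planted_blocks <- function(n_genes = 600L, n_blocks = 5L,
                                   block_size = 40L, r = 0.8,
                                   n_shared = 10L) {
  if (n_blocks * block_size - n_shared > n_genes)
    stop("blocks need ", n_blocks * block_size - n_shared,
         " distinct genes but the universe has only ", n_genes, call. = FALSE)
  ids <- sprintf("g%04d", seq_len(n_genes))
  blocks <- vector("list", n_blocks)
  at <- 1L
  for (b in seq_len(n_blocks)) {
    take <- ids[at:(at + block_size - 1L)]
    if (b == n_blocks && n_shared > 0L && n_blocks >= 2L) {
      prev <- blocks[[b - 1L]]$genes
      take <- c(utils::tail(prev, n_shared),
                ids[at:(at + block_size - n_shared - 1L)])
      at <- at + block_size - n_shared
    } else {
      at <- at + block_size
    }
    blocks[[b]] <- block_spec(sprintf("block_%d", b), take, r = r)
  }
  blocks
}

#' Generate an expression matrix with planted correlated blocks
#'
#' Each block gets a latent Gaussian sample factor; a member gene is
#' \eqn{\sqrt{r} f_b + \sqrt{1-r}\,\epsilon}. A gene in several blocks sums
#' the \eqn{\sqrt{r_b} f_b} loadings of its blocks, and every row is
#' renormalised to unit generative variance. Genes outside every block are
#' independent standard Gaussian noise. Fully reproducible from \code{seed}.
#'
#' @param n_genes Number of genes (ids \code{g0001, ...}; block members must
#'   be among them).
#' @param n_samples Number of samples, >= 3.
#' @param blocks List of \code{\link{block_spec}} objects (may be empty).
#' @param seed Integer seed.
#' @return A raw-kind expression matrix of size n_genes x n_samples.
#' @export
generate_block_expression <- function(n_genes, n_samples, blocks = list(),
                                      seed) {
  if (n_samples < 3L) stop("need at least 3 samples", call. = FALSE)
  ids <- sprintf("g%04d", seq_len(n_genes))
  for (b in blocks)
    if (!all(b$genes %in% ids))
      stop("block '", b$id, "' names genes outside the universe",
           call. = FALSE)
  set.seed(seed)
  factors <- matrix(stats::rnorm(length(blocks) * n_samples),
                    nrow = length(blocks))
  m <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(ids, sprintf("s%03d", seq_len(n_samples))))
  if (length(blocks)) {
    loading <- matrix(0, nrow = n_genes, ncol = length(blocks))
    noise_sd <- rep(1, n_genes)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      gi <- match(b$genes, ids)
      loading[gi, bi] <- sqrt(b$r)
      noise_sd[gi] <- b$noise_sd
    }
    sig_var <- rowSums(loading^2)
    in_block <- sig_var > 0
    eps_sd <- noise_sd * sqrt(pmax(1 - sig_var, 0))
    eps_sd[in_block & eps_sd == 0] <- 0.01 * noise_sd[in_block & eps_sd == 0]
    signal <- loading %*% factors
    tot_sd <- sqrt(sig_var + eps_sd^2)
    m[in_block, ] <- (signal[in_block, , drop = FALSE] +
                        eps_sd[in_block] * m[in_block, , drop = FALSE]) /
      tot_sd[in_block]
  }
  expression_matrix(m, value_kind = "raw")
}

#' Best-match recovery of planted blocks
#'
#' For every true block, the maximum Jaccard index between its gene set and
#' any found module.
#'
#' @param found A non-empty \code{module_set}.
#' @param truth Non-empty list of \code{\link{block_spec}} objects.
#' @return Named numeric vector, one best Jaccard per block.
#' @export
planted_recovery_score <- function(found, truth) {
  stopifnot(inherits(found, "module_set"))
  if (!length(found$modules) || !length(truth))
    stop("found modules and truth blocks must be non-empty", call. = FALSE)
  scores <- vapply(truth, function(b) {
    max(vapply(found$modules, overlap_ratio, numeric(1L), m2 = b$genes))
  }, numeric(1L), USE.NAMES = FALSE)
  stats::setNames(scores, vapply(truth, `[[`, character(1L), "id"))
}

#' Write planted-block truth as TSV
#'
#' Two columns (\code{block}, \code{gene}), one row per membership.
#'
#' @param blocks List of \code{\link{block_spec}} objects.
#' @param path Output path.
#' @export
write_truth_tsv <- function(blocks, path) {
  df <- do.call(rbind, lapply(blocks, function(b)
    data.frame(block = b$id, gene = b$genes, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write planted blocks as a toy GMT collection
#'
#' Each block becomes a gene set, making enrichment testable end-to-end on
#' synthetic data.
#'
#' @param blocks List of \code{\link{block_spec}} objects.
#' @param path Output path.
#' @export
write_blocks_gmt <- function(blocks, path) {
  lines <- vapply(blocks, function(b)
    paste(c(b$id, "planted block", b$genes), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
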