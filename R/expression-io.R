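# Internal: validate a genes/isoforms x samples expression matrix.
# Plain numeric matrices with unique dimnames are the package's working
# representation; `value_kind` ("raw" or "log2_ratio") travels as an attribute.
check_expression_matrix <- function(m, require_finite = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have row (feature) and column (sample) names",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  if (require_finite && !all(is.finite(m)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(m)
}

#' Construct an expression matrix
#'
#' Wraps a numeric matrix of expression values (features in rows, samples in
#' columns) after validating that row and column identifiers are present and
#' unique and that all values are finite.
#'
#' @param values Numeric matrix with feature row names and sample column names.
#' @param value_kind Either \code{"raw"} (non-negative abundances) or
#'   \code{"log2_ratio"} (log2 tumor/normal ratios).
#' @return The validated matrix with a \code{value_kind} attribute.
#' @export
expression_matrix <- function(values, value_kind = c("raw", "log2_ratio")) {
  value_kind <- match.arg(value_kind)
  check_expression_matrix(values)
  attr(values, "value_kind") <- value_kind
  values
}

#' Read an expression matrix from tab-separated text
#'
#' The first line is a header of sample identifiers; every following line is a
#' feature identifier followed by one numeric value per sample. Ragged rows,
#' non-numeric cells and duplicated feature identifiers are parse errors that
#' name the offending line.
#'
#' @param path Path to the TSV file.
#' @param value_kind Passed to \code{\link{expression_matrix}}.
#' @return A numeric matrix with feature row names and sample column names.
#' @export
read_expression_tsv <- function(path, value_kind = "raw") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file needs a header line and at least one feature row",
         call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  # tolerate an optional leading corner label in the header
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n_fields <- lengths(body)
  n_samples <- n_fields[1L] - 1L
  samples <- if (length(header) == n_samples) header else header[-1L]
  if (length(samples) != n_samples)
    stop("header has ", length(samples), " sample ids but line 2 has ",
         n_samples, " values", call. = FALSE)
  bad <- which(n_fields != n_samples + 1L)
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, ": expected ",
         n_samples + 1L, " fields, found ", n_fields[bad[1L]], call. = FALSE)
  ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate feature id '", ids[dup[1L]], "' at line ", dup[1L] + 1L,
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_samples))
  )
  vals <- if (n_samples == 1L) matrix(vals, nrow = 1L) else vals
  m <- t(vals)
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1L, any))[1L]
    stop("non-numeric cell at line ", bad_row + 1L, " (feature '",
         ids[bad_row], "')", call. = FALSE)
  }
  dimnames(m) <- list(ids, samples)
  expression_matrix(m, value_kind = value_kind)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of \code{\link{read_expression_tsv}}: a header of sample ids, then
#' one line per feature. Values are written with \code{format(..., digits = 15)}
#' so finite decimals round-trip exactly.
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  check_expression_matrix(m)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            format(m[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Replace exact zeros with the minimum non-zero value
#'
#' RNA-Seq abundance tables contain many exact zeros that break log-ratio
#' normalisation. Every zero cell is replaced by the smallest strictly positive
#' value observed, by default over the whole matrix; \code{per_row = TRUE}
#' uses each row's own minimum positive value instead.
#'
#' @param m Expression matrix of raw (non-negative) values.
#' @param per_row Use per-feature rather than global minima.
#' @return The matrix with zeros replaced; idempotent.
#' @export
replace_zeros_with_min_nonzero <- function(m, per_row = FALSE) {
  check_expression_matrix(m)
  if (any(m < 0))
    stop("zero replacement expects raw non-negative values", call. = FALSE)
  if (per_row) {
    for (i in seq_len(nrow(m))) {
      z <- m[i, ] == 0
      if (!any(z)) next
      pos <- m[i, ][m[i, ] > 0]
      if (!length(pos))
        stop("row '", rownames(m)[i], "' is all zero; no replacement value",
             call. = FALSE)
      m[i, z] <- min(pos)
    }
    return(m)
  }
  z <- m == 0
  if (!any(z)) return(m)
  pos <- m[m > 0]
  if (!length(pos))
    stop("all-zero matrix: no non-zero replacement value exists", call. = FALSE)
  m[z] <- min(pos)
  m
}

#' Log2 ratio of tumor samples over the mean of normal samples
#'
#' Normalises tumor abundances to relative values: each cell becomes
#' \code{log2(tumor[i, s] / mean(normal[i, ]))}, with the unmatched normal
#' samples averaged unweighted. Both matrices must be strictly positive (apply
#' \code{\link{replace_zeros_with_min_nonzero}} first) and share identical
#' feature identifiers; a mismatch is an error rather than a silent drop.
#'
#' @param tumor,normal Raw expression matrices over the same features.
#' @return A \code{log2_ratio} expression matrix shaped like \code{tumor}.
#' @export
log2_tumor_over_mean_normal <- function(tumor, normal) {
  check_expression_matrix(tumor)
  check_expression_matrix(normal)
  if (!identical(rownames(tumor), rownames(normal)))
    stop("tumor and normal matrices must share identical feature ids",
         call. = FALSE)
  if (any(tumor <= 0) || any(normal <= 0))
    stop("all values must be strictly positive; replace zeros first",
         call. = FALSE)
  ratio <- log2(tumor / rowMeans(normal))
  expression_matrix(ratio, value_kind = "log2_ratio")
}

#' Drop lowly expressed features
#'
#' Two-stage filter: (a) remove the \code{drop_fraction} of rows with the
#' lowest mean expression (ties at the boundary broken by keeping the
#' lexicographically smaller id), then (b) remove any remaining row whose value
#' is zero in strictly more than half of the samples. Surviving rows keep their
#' original order.
#'
#' @param m Raw expression matrix.
#' @param drop_fraction Fraction in \code{[0, 1)} of rows to drop by mean.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(m, drop_fraction = 0.25) {
  check_expression_matrix(m)
  if (!is.numeric(drop_fraction) || length(drop_fraction) != 1L ||
      drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)", call. = FALSE)
  n_drop <- floor(nrow(m) * drop_fraction)
  if (n_drop > 0L) {
    means <- rowMeans(m)
    # lowest means dropped first; at a tied boundary the lexicographically
    # larger id goes first, so the smaller id is kept
    ord <- order(means, rev(rank(rownames(m))))
    drop_ids <- rownames(m)[ord[seq_len(n_drop)]]
    m <- m[!(rownames(m) %in% drop_ids), , drop = FALSE]
  }
  zero_frac_bad <- rowSums(m == 0) > ncol(m) / 2
  m[!zero_frac_bad, , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Members are intersected with \code{universe}; sets whose surviving
#' membership is below \code{min_size} or above \code{max_size} are dropped
#' (overly specific or overly general terms).
#'
#' @param path GMT file path.
#' @param universe Character vector of gene ids defining the analysis universe,
#'   or \code{NULL} to keep all members.
#' @param min_size,max_size Inclusive size bounds after intersection.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path, universe = NULL, min_size = 3L, max_size = 300L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 fields", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  if (!is.null(universe))
    sets <- lapply(sets, intersect, y = universe)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets[keep]
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}
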