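# Shared fixtures and independent oracles for the test suite.

# Build a correlation-matrix-like object directly from upper-triangle values
# (row-major over pairs (1,2), (1,3), ..., (n-1,n)).
cor_from_pairs <- function(n, pair_values, ids = sprintf("G%02d", seq_len(n))) {
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  a[upper.tri(a)] <- 0
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a[i, j] <- a[j, i] <- pair_values[k]
      k <- k + 1L
    }
  }
  diag(a) <- 1
  a
}

# Random small expression matrix (iid Gaussian noise).
random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Two-pass covariance Pearson correlation, written independently of
# stats::cor, as an oracle for abs_pcc_matrix.
pearson_two_pass <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Brute-force greedy expansion reference: re-scans every candidate gene from
# scratch at each iteration (no incremental state), mirroring the published
# procedure literally.
reference_expand <- function(pair, a, M, k, excluded = character(0)) {
  members <- as.character(pair)
  genes <- rownames(a)
  repeat {
    cand <- setdiff(genes, c(members, excluded))
    if (!length(cand)) return(members)
    pmins <- vapply(cand, function(g) min(a[g, members]), numeric(1))
    eligible <- pmins[pmins > M]
    if (!length(eligible)) return(members)
    ord <- order(-eligible, names(eligible))
    eligible <- eligible[ord]
    admit <- if (length(eligible) > k) {
      kth <- eligible[k]
      names(eligible)[eligible >= kth]
    } else names(eligible)
    members <- c(members, admit)
  }
}

# Connected components of the graph with edges where dissimilarity <= thr;
# breadth-first search, independent of hclust/cutree.
components_at_threshold <- function(d, thr) {
  n <- nrow(d)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(d[v, ] <= thr & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Dissimilarity matrix with planted groups: within-group values near `within`,
# between-group near `between`, jittered for realism.
grouped_dissimilarity <- function(sizes, within = 0.1, between = 0.9,
                                  jitter = 0.03, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n, dimnames = list(sprintf("i%03d", 1:n),
                                       sprintf("i%03d", 1:n)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      base <- if (grp[i] == grp[j]) within else between
      v <- min(max(base + runif(1, -jitter, jitter), 0), 1)
      d[i, j] <- d[j, i] <- v
    }
  }
  list(d = d, groups = grp)
}

# Exhaustive hypergeometric upper tail by summing exact point probabilities
# (factorial form), independent of phyper/dhyper.
hyper_upper_tail_enum <- function(ov, term_size, universe_size, module_size) {
  xs <- seq(ov, min(term_size, module_size))
  if (!length(xs)) return(0)
  sum(vapply(xs, function(x)
    choose(term_size, x) * choose(universe_size - term_size, module_size - x) /
      choose(universe_size, module_size), numeric(1)))
}

# Partition equality up to label renaming.
same_partition <- function(lab1, lab2) {
  lab1 <- unname(lab1)
  lab2 <- unname(lab2)
  u1 <- lab1 != 0
  if (!identical(u1, lab2 != 0)) return(FALSE)
  tab <- table(lab1[u1], lab2[u1])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
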