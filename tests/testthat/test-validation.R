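test_that("in-module mean correlation averages unordered pairs", {
  a <- cor_from_pairs(3, c(0.2, 0.4, 0.6))
  expect_equal(in_module_mean_pcc(rownames(a), a), 0.4)
  expect_equal(in_module_mean_pcc(rownames(a)[1:2], a), 0.2)
  expect_error(in_module_mean_pcc(rownames(a)[1], a), "at least 2")

  base <- seq_len(20)
  m <- rbind(g1 = base, g2 = base * 2, g3 = base + 5)
  colnames(m) <- paste0("s", 1:20)
  expect_equal(in_module_mean_pcc(rownames(m), abs_pcc_matrix(m)), 1)
})

test_that("the permutation test pins down degenerate cases", {
  # planted perfectly coherent module inside noise: no random module wins
  blocks <- list(block_spec("b", sprintf("g%04d", 1:10), r = 0.95))
  m <- generate_block_expression(80, 100, blocks, seed = 6)
  a <- abs_pcc_matrix(m)
  res <- permutation_test(blocks[[1]]$genes, a, N = 500, seed = 1)
  expect_equal(res$p, 0)
  expect_gt(res$module_avg, 0.9)

  # incoherent pair in a coherent universe: any random pair not equal to the
  # module itself has a strictly higher mean correlation, so p = 1 whenever
  # the module is not redrawn (checked at this fixed seed)
  set.seed(4)
  a2 <- cor_from_pairs(80, runif(80 * 79 / 2, 0.2, 0.9))
  a2[1, 2] <- a2[2, 1] <- 0.01
  res2 <- permutation_test(rownames(a2)[1:2], a2, N = 200, seed = 2)
  expect_equal(res2$p, 1)
})

test_that("null modules give roughly uniform permutation p-values", {
  m <- random_expression(60, 25, seed = 99)
  a <- abs_pcc_matrix(m)
  set.seed(17)
  ps <- vapply(1:60, function(i) {
    mod <- sample(rownames(a), 8)
    permutation_test(mod, a, N = 100)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("Bonferroni correction across a module set bounds raw p", {
  blocks <- list(block_spec("b", sprintf("g%04d", 1:8), r = 0.9))
  m <- generate_block_expression(40, 60, blocks, seed = 10)
  a <- abs_pcc_matrix(m)
  ms <- module_set(list(planted = blocks[[1]]$genes,
                        random1 = sprintf("g%04d", 11:18),
                        random2 = sprintf("g%04d", 21:28)), stage = "FGMD")
  res <- permutation_test_set(ms, a, N = 200, seed = 3)
  expect_equal(res$q, pmin(1, res$p * nrow(res)))
  expect_true(all(res$q >= res$p))
  expect_equal(res$p[res$module == "planted"], 0)
})

test_that("hypergeometric p-values match closed forms and enumeration", {
  universe <- sprintf("u%03d", 1:100)
  term <- universe[1:5]
  ms <- module_set(list(hit = universe[1:5]), stage = "FGMD")
  res <- hypergeom_enrichment(ms, list(t = term), universe)
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)

  # zero overlap is certain: p = 1
  ms0 <- module_set(list(miss = universe[50:60]), stage = "FGMD")
  res0 <- hypergeom_enrichment(ms0, list(t = term), universe)
  expect_equal(res0$p, 1)

  # module = universe: overlap = term size with certainty
  msu <- module_set(list(all = universe), stage = "FGMD")
  resu <- hypergeom_enrichment(msu, list(t = term), universe)
  expect_equal(resu$p, 1)

  # enumeration oracle over small universes
  set.seed(20)
  for (trial in 1:20) {
    N <- sample(8:30, 1)
    uni <- sprintf("v%02d", 1:N)
    K <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    term <- sample(uni, K)
    mod <- sample(uni, k)
    ov <- length(intersect(term, mod))
    res <- hypergeom_enrichment(module_set(list(m = mod), stage = "FGMD"),
                                list(t = term), uni)
    expect_equal(res$p, hyper_upper_tail_enum(ov, K, N, k),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # step-up by hand: q_(i) = min_{j>=i} p_(j) m / j, input order preserved
  p <- c(0.3, 0.001, 0.02, 0.9)
  expect_equal(bh_adjust(p), c(0.4, 0.004, 0.04, 0.9))
  # monotone after sorting; idempotent-capped on adjusted values
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment q-values are BH per module by default", {
  universe <- sprintf("u%03d", 1:60)
  sets <- list(t1 = universe[1:10], t2 = universe[11:20], t3 = universe[21:30])
  ms <- module_set(list(m1 = universe[1:10], m2 = universe[25:34]),
                   stage = "FGMD")
  res <- hypergeom_enrichment(ms, sets, universe)
  for (nm in c("m1", "m2")) {
    sel <- res$module == nm
    expect_equal(res$q[sel], bh_adjust(res$p[sel]))
  }
  expect_true(all(res$overlap <= pmin(res$module_size, res$term_size)))
})

test_that("gene-list ratios distinguish pooled and unique modes", {
  ms <- module_set(list(m1 = c("A", "B"), m2 = c("B", "C")), stage = "FGMD")
  expect_equal(gene_list_ratio(ms, "B", "pooled"), 0.5)
  expect_equal(gene_list_ratio(ms, "B", "unique"), 1 / 3)
  expect_equal(gene_list_ratio(ms, c("A", "B", "C"), "pooled"), 1)
  expect_equal(gene_list_ratio(ms, c("A", "B", "C"), "unique"), 1)
  expect_equal(gene_list_ratio(ms, c("X", "Y"), "pooled"), 0)
  expect_error(gene_list_ratio(module_set(list(), stage = "FGMD"), "A"),
               "empty module set")
})

test_that("module summaries count occurrence and duplication", {
  ms <- module_set(list(m1 = c("A", "B"), m2 = c("B", "C")), stage = "FGMD")
  s <- module_summary(ms)
  expect_equal(s$unique_genes, 3)
  expect_equal(s$mean_occurrence, 4 / 3)
  expect_equal(s$duplication_ratio, 0)

  single <- module_summary(module_set(list(m = c("A", "B")), stage = "FGMD"))
  expect_equal(single$mean_occurrence, 1)
  expect_equal(single$duplication_ratio, 0)

  trip <- module_set(list(a = c("X", "Y"), b = c("X", "Y"), c = c("X", "Y")))
  expect_equal(module_summary(trip)$duplication_ratio, 2 / 3)
})
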