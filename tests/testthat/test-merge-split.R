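test_that("overlap ratio is the Jaccard index", {
  expect_equal(overlap_ratio(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(overlap_ratio(c("A", "B"), c("A", "B")), 1)
  expect_equal(overlap_ratio(c("A", "B"), c("X", "Y")), 0)
  expect_error(overlap_ratio(character(0), "A"), "empty")
})

test_that("overlap matrices enumerate pairwise Jaccard values", {
  ms <- module_set(list(m1 = c("A", "B", "C"), m2 = c("B", "C", "D"),
                        m3 = c("X", "Y"), m4 = c("A", "X", "Y", "Z")))
  ov <- overlap_matrix(ms)
  expect_equal(diag(ov), c(m1 = 1, m2 = 1, m3 = 1, m4 = 1))
  expect_equal(ov["m1", "m2"], 0.5)
  expect_equal(ov["m1", "m3"], 0)
  expect_equal(ov["m3", "m4"], 0.5)
  expect_equal(ov["m1", "m4"], 1 / 6)
  expect_equal(ov, t(ov))

  dup <- module_set(list(a = c("P", "Q"), b = c("P", "Q"), c = c("P", "Q")))
  expect_true(all(overlap_matrix(dup) == 1))
  # 1 - overlap is a valid dissimilarity: zero iff identical sets
  expect_true(all((1 - ov >= 0)))
})

test_that("identical SPE modules merge into one large module", {
  ms <- module_set(rep(list(c("A", "B", "C")), 5), stage = "SPE")
  large <- merge_similar_modules(ms, tree_cut_params(minModuleSize = 2))
  expect_equal(length(large), 1)
  expect_setequal(large$modules[[1]], c("A", "B", "C"))
})

test_that("two families of SPE modules merge into their unions", {
  set.seed(14)
  fam <- function(core, n) {
    lapply(seq_len(n), function(i)
      c(core, sample(core, 2)))  # ~identical modules within a family
  }
  core1 <- sprintf("a%02d", 1:30)
  core2 <- sprintf("b%02d", 1:25)
  mods <- c(fam(core1, 60), fam(core2, 60))
  ms <- module_set(mods, stage = "SPE")
  large <- merge_similar_modules(ms, tree_cut_params(minModuleSize = 20))
  expect_equal(length(large), 2)
  sets <- lapply(large$modules, sort)
  expect_true(any(vapply(sets, identical, logical(1), sort(core1))))
  expect_true(any(vapply(sets, identical, logical(1), sort(core2))))
  # no gene invented, none lost
  expect_setequal(unique(unlist(large$modules)), unique(unlist(mods)))
})

test_that("a single SPE module passes through as one large module", {
  ms <- module_set(list(only = c("A", "B", "C")), stage = "SPE")
  large <- merge_similar_modules(ms, tree_cut_params())
  expect_equal(length(large), 1)
  expect_setequal(large$modules[[1]], c("A", "B", "C"))
})

test_that("splitting a two-block large module recovers the blocks", {
  blocks <- list(block_spec("b1", sprintf("g%04d", 1:25), r = 0.9),
                 block_spec("b2", sprintf("g%04d", 26:50), r = 0.9))
  m <- generate_block_expression(50, 150, blocks, seed = 8)
  a <- abs_pcc_matrix(m)
  large <- rownames(a)
  out <- split_large_module(large, a, tree_cut_params(minModuleSize = 10))
  expect_equal(length(out), 2)
  score <- planted_recovery_score(out, blocks)
  expect_true(all(score >= 0.9))
  # pairwise disjoint within one large module
  expect_equal(length(intersect(out$modules[[1]], out$modules[[2]])), 0)
})

test_that("degenerate large modules are returned whole", {
  # perfectly correlated genes: one module containing the whole set
  base <- sin(seq_len(30))
  m <- t(vapply(seq_len(12), function(i) base * i + i, numeric(30)))
  dimnames(m) <- list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:30))
  a <- abs_pcc_matrix(m)
  out <- split_large_module(rownames(a), a, tree_cut_params(minModuleSize = 5))
  expect_equal(length(out), 1)
  expect_setequal(out$modules[[1]], rownames(a))

  # fewer members than minModuleSize: unsplit and flagged
  out2 <- split_large_module(rownames(a)[1:4], a,
                             tree_cut_params(minModuleSize = 10))
  expect_equal(length(out2), 1)
  expect_match(out2$provenance, "unsplit")
})

test_that("overlap extension adds genes only while coherence improves", {
  ids <- c("m1", "m2", "m3", "m4", "m5", "good", "bad")
  a <- cor_from_pairs(7, rep(0.9, 21), ids = ids)
  mem <- ids[1:5]
  a["good", mem] <- a[mem, "good"] <- 0.95
  a["bad", mem] <- a[mem, "bad"] <- 0.3
  a["good", "bad"] <- a["bad", "good"] <- 0.3
  ms <- module_set(list(small = mem), stage = "FGMD")
  ext <- extend_small_modules_with_overlap(ms, ids, a)
  expect_setequal(ext$modules$small, c(mem, "good"))   # exactly one added

  # candidate perfectly correlated with every member is always added
  a2 <- cor_from_pairs(4, rep(0.8, 6), ids = c("x1", "x2", "x3", "p"))
  a2["p", c("x1", "x2", "x3")] <- a2[c("x1", "x2", "x3"), "p"] <- 1
  ms2 <- module_set(list(s = c("x1", "x2", "x3")), stage = "FGMD")
  ext2 <- extend_small_modules_with_overlap(ms2, rownames(a2), a2)
  expect_true("p" %in% ext2$modules$s)

  # all candidates uncorrelated: nothing added
  a3 <- cor_from_pairs(5, rep(0.9, 10),
                       ids = c("y1", "y2", "y3", "n1", "n2"))
  a3[c("n1", "n2"), c("y1", "y2", "y3")] <- 0.01
  a3[c("y1", "y2", "y3"), c("n1", "n2")] <- 0.01
  ms3 <- module_set(list(s = c("y1", "y2", "y3")), stage = "FGMD")
  ext3 <- extend_small_modules_with_overlap(ms3, rownames(a3), a3)
  expect_setequal(ext3$modules$s, c("y1", "y2", "y3"))
})

test_that("extension never decreases mean in-module correlation", {
  m <- random_expression(30, 20, seed = 55)
  a <- abs_pcc_matrix(m)
  parent <- rownames(a)
  for (s in 1:5) {
    set.seed(s)
    mem <- sample(parent, 6)
    before <- in_module_mean_pcc(mem, a)
    ext <- extend_small_modules_with_overlap(
      module_set(list(x = mem), stage = "FGMD"), parent, a)
    after <- in_module_mean_pcc(ext$modules$x, a)
    expect_gte(after, before)
    expect_lte(length(ext$modules$x), length(parent))
  }
})

test_that("module size filtering is boundary-inclusive", {
  mk <- function(n, tag) sprintf("%s%03d", tag, seq_len(n))
  ms <- module_set(list(s5 = mk(5, "a"), s10 = mk(10, "b"),
                        s300 = mk(300, "c"), s301 = mk(301, "d")),
                   stage = "FGMD")
  out <- filter_module_sizes(ms, 10, 300)
  expect_named(out$modules, c("s10", "s300"))

  empty <- module_set(list(), stage = "FGMD")
  expect_equal(length(filter_module_sizes(empty, 10, 300)), 0)
  expect_named(filter_module_sizes(ms, 1, 1000)$modules,
               names(ms$modules))
  expect_error(filter_module_sizes(ms, 10, 5), "min_size")
})
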