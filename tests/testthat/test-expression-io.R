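make_small <- function() {
  m <- matrix(c(1, 2.5, 3, 4, 0.125, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("TP53", "BRCA1"), c("s1", "s2", "s3")))
  expression_matrix(m)
}

test_that("TSV round-trip preserves ids, ordering and values exactly", {
  m <- make_small()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(m, path)
  back <- read_expression_tsv(path)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(unclass(back)[, ], m[, ], ignore_attr = TRUE)

  # larger matrix with awkward decimals still round-trips bit-for-bit
  m2 <- random_expression(20, 5, seed = 3)
  m2 <- round(m2, 6)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(expression_matrix(m2), p2)
  expect_equal(read_expression_tsv(p2)[, ], m2, ignore_attr = TRUE)
})

test_that("malformed expression files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\ts2", "TP53\t1\t2", "TP53\t3\t4"), path)
  expect_error(read_expression_tsv(path), "duplicate feature id 'TP53'.*line 3")

  writeLines(c("s1\ts2", "A\t1\t2", "B\t3"), path)
  expect_error(read_expression_tsv(path), "ragged row at line 3")

  writeLines(c("s1\ts2", "A\t1\t2", "B\t3\tx"), path)
  expect_error(read_expression_tsv(path), "non-numeric cell at line 3")
})

test_that("zero replacement uses the global minimum positive value", {
  m <- expression_matrix(matrix(c(0, 0.5, 2, 4), 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))))
  out <- replace_zeros_with_min_nonzero(m)
  expect_equal(sort(as.vector(out)), c(0.5, 0.5, 2, 4))

  m2 <- expression_matrix(matrix(c(0, 6, 3, 0), 2, 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))))
  out2 <- replace_zeros_with_min_nonzero(m2)
  expect_equal(out2[, ], matrix(c(3, 6, 3, 3), 2, 2,
                                dimnames = dimnames(m2)))

  # no zeros -> identity; idempotence in general
  m3 <- make_small()
  expect_equal(replace_zeros_with_min_nonzero(m3)[, ], m3[, ])
  expect_equal(replace_zeros_with_min_nonzero(out)[, ], out[, ])

  allz <- expression_matrix(matrix(0, 2, 3, dimnames = list(c("a", "b"),
                                                            c("x", "y", "z"))))
  expect_error(replace_zeros_with_min_nonzero(allz), "all-zero")
})

test_that("log2 tumor/normal ratio matches hand values", {
  tum <- expression_matrix(matrix(c(8, 8, 1, 2), 2, 2, byrow = TRUE,
                                  dimnames = list(c("a", "b"),
                                                  c("t1", "t2"))))
  nor <- expression_matrix(matrix(c(1, 3, 4, 4), 2, 2, byrow = TRUE,
                                  dimnames = list(c("a", "b"),
                                                  c("n1", "n2"))))
  out <- log2_tumor_over_mean_normal(tum, nor)
  expect_equal(out["a", "t1"], 2)            # log2(8/2)
  expect_equal(out["b", "t1"], -2)           # log2(1/4)
  expect_equal(attr(out, "value_kind"), "log2_ratio")

  # tumor equal to the normal mean everywhere -> all zeros
  tum2 <- expression_matrix(matrix(2, 2, 2, dimnames = dimnames(tum)))
  nor2 <- expression_matrix(matrix(2, 2, 2, dimnames = dimnames(nor)))
  expect_true(all(log2_tumor_over_mean_normal(tum2, nor2) == 0))

  rownames(nor) <- c("a", "c")
  expect_error(log2_tumor_over_mean_normal(tum, nor), "identical feature ids")
})

test_that("low-expression filter applies the mean cut then the zero rule", {
  m <- matrix(c(0, 0, 0, 0,
                1, 1, 1, 1,
                2, 2, 2, 2,
                3, 3, 3, 3), 4, 4, byrow = TRUE,
              dimnames = list(c("w", "x", "y", "z"), paste0("s", 1:4)))
  out <- filter_low_expression(expression_matrix(m), 0.25)
  expect_identical(rownames(out), c("x", "y", "z"))

  mz <- matrix(c(0, 0, 0, 5,
                 1, 2, 3, 4), 2, 4, byrow = TRUE,
               dimnames = list(c("mostly0", "ok"), paste0("s", 1:4)))
  out2 <- filter_low_expression(expression_matrix(mz), 0)
  expect_identical(rownames(out2), "ok")

  m8 <- random_expression(8, 4, seed = 1)^2 + 1   # strictly positive
  out3 <- filter_low_expression(expression_matrix(m8), 0.5)
  expect_equal(nrow(out3), 4)
  expect_true(all(rownames(out3) %in% rownames(m8)))

  # idempotence at drop_fraction 0 and subset property
  once <- filter_low_expression(expression_matrix(mz), 0)
  twice <- filter_low_expression(expression_matrix(once), 0)
  expect_identical(once[, ], twice[, ])
  expect_error(filter_low_expression(expression_matrix(m8), 1), "\\[0, 1\\)")
})

test_that("GMT parsing intersects with the universe and filters set sizes", {
  path <- withr::local_tempfile(fileext = ".gmt")
  big <- paste0("u", 1:301)
  writeLines(c(
    paste(c("tiny", "desc", "g1", "g2"), collapse = "\t"),
    paste(c("ok", "desc", "g1", "g2", "g3", "zzz", "yyy"), collapse = "\t"),
    paste(c("huge", "desc", big), collapse = "\t")
  ), path)
  universe <- c("g1", "g2", "g3", big)
  sets <- read_gmt(path, universe = universe)
  expect_named(sets, "ok")
  expect_setequal(sets$ok, c("g1", "g2", "g3"))

  writeLines("broken\tonly-two-fields", path)
  expect_error(read_gmt(path, universe = universe), "malformed GMT line 1")
})

test_that("gene lists skip comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cancer genes", "TP53", "", "BRCA1", "TP53"), path)
  expect_identical(read_gene_list(path), c("TP53", "BRCA1"))
})
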