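test_that("expression TSV round-trips and rejects malformed input", {
  m <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  m2 <- read_expression_table(path)
  expect_equal(dim(m2), c(3L, 2L))
  expect_equal(m2$values, m$values)
  expect_identical(m2$scale_tag, "raw_log2")

  # duplicated sample id in header
  writeLines(c("gene_id\tS1\tS1", "G1\t1\t2"), path)
  expect_error(read_expression_table(path), "S1")
  # non-numeric cell names the location
  writeLines(c("gene_id\tS1\tS2", "G1\t1\txx"), path)
  expect_error(read_expression_table(path), "G1.*S2")
  # missing header entirely
  writeLines("G1\t1", path)
  expect_error(read_expression_table(path))
})

test_that("duplicate gene rows collapse to the max-mean row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2",
               "G1\t0.5\t1.5",   # mean 1.0
               "G1\t1.5\t2.5",   # mean 2.0 -> retained
               "G2\t0\t0"), path)
  m <- read_expression_table(path)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m$values["G1", ]), c(1.5, 2.5))
  expect_error(read_expression_table(path, collapse = "error"), "G1")
})

test_that("quantile normalization matches hand-computed rank means and is idempotent", {
  m <- make_expr(cbind(c(1, 2, 3), c(4, 5, 6)))
  q <- quantile_normalize(m)
  expect_equal(unname(q$values), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  expect_identical(q$scale_tag, "quantile_normalized")

  # identical columns are a fixed point
  m2 <- make_expr(cbind(c(2, 0, 5), c(2, 0, 5)))
  expect_equal(quantile_normalize(m2)$values, m2$values)

  # tie rule: tied values receive the mean of the reference values across
  # the ranks they span (hand-derived 3 x 2 example)
  mt <- make_expr(cbind(c(1, 1, 3), c(2, 4, 6)))
  qt <- quantile_normalize(mt)
  # reference quantiles: (1.5, 2.5, 4.5); column 1 ties span ranks 1-2
  expect_equal(unname(qt$values), cbind(c(2, 2, 4.5), c(1.5, 2.5, 4.5)))

  # defining property + idempotence on tie-free random input (with ties
  # the tie rule above intentionally breaks the shared-multiset property)
  set.seed(7)
  m3 <- make_expr(matrix(rnorm(60), 12, 5))
  q3 <- quantile_normalize(m3)
  sorted <- apply(q3$values, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(quantile_normalize(q3)$values, q3$values, tolerance = 1e-12)

  expect_error(quantile_normalize(make_expr(matrix(1:3, 3, 1))), "two samples")
})

test_that("gene standardization yields exact z-scores and drops constant rows", {
  m <- make_expr(matrix(c(1, 2, 3), 1, 3))
  z <- standardize_genes(m)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_identical(z$scale_tag, "gene_standardized")

  set.seed(11)
  r <- standardize_genes(make_expr(matrix(rnorm(200, 5, 3), 20, 10)))
  expect_equal(unname(rowMeans(r$values)), rep(0, 20), tolerance = 1e-9)
  expect_equal(unname(apply(r$values, 1, sd)), rep(1, 20), tolerance = 1e-9)

  const <- make_expr(rbind(c(5, 5, 5), c(1, 2, 3)))
  expect_warning(z2 <- standardize_genes(const), "constant")
  expect_equal(nrow(z2$values), 1L)
  expect_error(standardize_genes(make_expr(matrix(1, 2, 1))), "two samples")
})

test_that("differential expression reproduces the hand-derived Welch contrast", {
  v <- rbind(c(0.9, 1.0, 1.1, 1.9, 2.0, 2.1),
             c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0) + rep(c(0, 1e-3), 3))
  m <- make_expr(v)
  ann <- make_ann(rep(c("primary", "metastatic"), each = 3))
  deg <- differential_expression(m, ann, "primary", "metastatic")
  # t = 1.0 / sqrt(0.01/3 + 0.01/3) = 12.2474
  expect_equal(deg$log2fc[1], 1.0, tolerance = 1e-12)
  expect_equal(deg$log2fc[1] / sqrt(var(v[1, 1:3]) / 3 + var(v[1, 4:6]) / 3),
               12.2474487, tolerance = 1e-6)
  expect_lt(deg$p_value[1], 1e-3)
  expect_identical(deg$direction[1], "up")
})

test_that("differential expression is antisymmetric and handles degenerate genes", {
  co <- make_two_class_cohort(n_a = 8, n_b = 6, seed = 3)
  d1 <- differential_expression(co$expr, co$ann, "primary", "metastatic")
  d2 <- differential_expression(co$expr, co$ann, "metastatic", "primary")
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p_value, d2$p_value)

  # zero within-group variance on both sides: fc reported, p missing
  v <- rbind(c(1, 1, 2, 2), c(1, 2, 3, 4))
  deg <- differential_expression(make_expr(v),
                                 make_ann(rep(c("primary", "metastatic"), each = 2)),
                                 "primary", "metastatic")
  expect_equal(deg$log2fc[1], 1)
  expect_equal(deg$p_value[1], 0)   # separated means, zero variance

  v2 <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4))
  deg2 <- differential_expression(make_expr(v2),
                                  make_ann(rep(c("primary", "metastatic"), each = 2)),
                                  "primary", "metastatic")
  expect_true(is.na(deg2$p_value[1]))

  expect_error(differential_expression(co$expr, co$ann, "primary", "normal"),
               "at least 2")
})

test_that("annotation validation enforces the survival-column contract", {
  ann <- make_ann(c("primary", "metastatic"))
  expect_silent(validate_annotation(ann))
  ann$os_event <- c(1, 0)
  expect_error(validate_annotation(ann), "os_time")
  ann$os_time <- c(5, NA); ann$os_event <- c(1, 1)
  expect_error(validate_annotation(ann), "event flag without time")
  ann$os_time <- c(5, -1); ann$os_event <- c(1, 1)
  expect_error(validate_annotation(ann), "non-negative")
  bad <- make_ann(c("primary", "tumour"))
  expect_error(validate_annotation(bad), "disease_class")

  path <- withr::local_tempfile(fileext = ".tsv")
  good <- make_ann(c("primary", "metastatic"), os_time = c(10, NA),
                   os_event = c(1, NA))
  write_annotation(good, path)
  expect_equal(read_annotation(path), good)
})
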