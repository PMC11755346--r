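# Encoders, the pair dataset and the stratified split.

test_that("phenotype one-hot encoding follows the declared vocabularies", {
  ph <- tibble::tibble(sample_id = paste0("s", 1:4),
                       age = c(63, 25, 41, NA),
                       sex = c("M", "F", "F", "M"),
                       cancer_type = c("LUAD", "PAAD", "LUAD", "SKCM"))
  enc <- suppressWarnings(encode_phenotype(ph))
  m <- enc$matrix
  expect_equal(unname(m[1, c("sex_M", "sex_F")]), c(1, 0))
  expect_equal(unname(m[1, "age_60_70"]), 1)
  expect_equal(sum(m[1, grep("^age_", colnames(m))]), 1)
  # missing age goes to the training-median bin (median of 25, 41, 63 = 41)
  expect_equal(unname(m[4, "age_40_50"]), 1)

  twelve <- tibble::tibble(sample_id = paste0("s", 1:12), age = 50, sex = "F",
                           cancer_type = sprintf("CT%02d", 1:12))
  m12 <- encode_phenotype(twelve)$matrix
  expect_equal(sum(grepl("^cancer_", colnames(m12))), 12L)

  # transform mode: fitted schema applied, unseen categories refused
  schema <- small_features()$schema
  bad <- tibble::tibble(sample_id = "x", age = 50, sex = "F",
                        cancer_type = "NOT_A_TYPE")
  expect_error(encode_phenotype(bad, schema = schema), "NOT_A_TYPE")
})

test_that("SNV encoding is 1 iff a non-silent variant hits the panel gene", {
  mut <- tibble::tibble(
    sample_id = c("s1", "s2", "s1"),
    gene = c("TP53", "KRAS", "TP53"),
    variant_class = c("missense", "silent", "nonsense"))
  m <- encode_snv(mut, gene_list = c("TP53", "KRAS"), sample_ids = c("s1", "s2", "s3"))
  expect_equal(unname(m["s1", "TP53"]), 1L)
  expect_equal(unname(m["s2", "KRAS"]), 0L)   # silent never counts
  expect_equal(unname(m["s3", ]), c(0L, 0L))  # no rows -> all-zero row
  expect_error(encode_snv(dplyr::mutate(mut, variant_class = "funky"),
                          c("TP53"), "s1"), "vocabulary")
})

test_that("response transforms match their closed forms", {
  expect_equal(transform_response(1, "IC50"), 0)
  expect_equal(transform_response(exp(1), "IC50"), 1)
  expect_error(transform_response(-2, "IC50"), "positive")
  expect_equal(transform_response(c(-1.3, 0.2), "MFI"), c(-1.3, 0.2))
  expect_equal(transform_response(c("PD", "SD", "PR"), "BOR"), c(1, 0, 0))
  expect_equal(transform_response(c("CR", "non-PD"), "BOR"), c(0, 0))
  expect_error(transform_response("huh", "BOR"), "huh")
})

test_that("pair construction is one row per measured response, sample-major", {
  sids <- c("s1", "s2")
  dids <- c("d1", "d2", "d3")
  Xs <- matrix(1:4, 2, 2, dimnames = list(sids, c("a", "b")))
  Xd <- matrix(1:6, 3, 2, dimnames = list(dids, c("u", "v")))
  resp <- tibble::tibble(
    sample_id = c("s2", "s1", "s1", "s2", "s1"),
    drug_id = c("d3", "d1", "d2", "d1", "d3"),
    value = exp(c(5, 1, 2, 4, 3)), endpoint = "IC50")
  # one pair (s2, d2) unmeasured -> 5 rows
  pairs <- build_pairs(Xs, Xd, resp)
  expect_equal(n_pairs(pairs), 5L)
  expect_equal(pairs$index$sample_id, c("s1", "s1", "s1", "s2", "s2"))
  expect_equal(pairs$index$drug_id, c("d1", "d2", "d3", "d1", "d3"))
  expect_equal(pairs$y, c(1, 2, 3, 4, 5))
  # X_sample rows duplicate the sample feature vector across its drugs
  expect_equal(pairs$X_sample[1, ], pairs$X_sample[3, ])
  expect_equal(unname(pairs$X_sample[4, ]), c(2, 4))

  resp_bad <- resp
  resp_bad$sample_id[1] <- "nope"
  expect_error(build_pairs(Xs, Xd, resp_bad), "unknown sample")
  expect_error(
    build_pairs(Xs, Xd, dplyr::mutate(resp, endpoint = c("IC50", "MFI")[c(1, 2, 1, 1, 1)])),
    "single endpoint")
})

test_that("pair count equals response rows after omission on the small cohort", {
  co <- small_cohort()
  pairs <- small_pairs()
  expect_equal(n_pairs(pairs), nrow(co$response))
  expect_equal(n_pairs(pairs), 60 * 6)
  expect_false(anyDuplicated(paste(pairs$index$sample_id, pairs$index$drug_id)) > 0)
})

test_that("the stratified split is sample-wise, exact, and seeded", {
  pairs <- toy_pairs(542, 2, cancer_types = sprintf("CT%02d", 1:12))
  sp <- stratified_split(pairs, 0.75, seed = 7)
  tr <- unique(sp$train$index$sample_id)
  te <- unique(sp$test$index$sample_id)
  expect_equal(length(tr), 407L)
  expect_equal(length(te), 135L)
  expect_length(intersect(tr, te), 0)
  expect_equal(n_pairs(sp$train) + n_pairs(sp$test), n_pairs(pairs))

  again <- stratified_split(pairs, 0.75, seed = 7)
  expect_identical(sort(unique(again$train$index$sample_id)), sort(tr))
  other <- stratified_split(pairs, 0.75, seed = 8)
  expect_false(identical(sort(unique(other$train$index$sample_id)), sort(tr)))
})

test_that("split rounding and degenerate strata behave as documented", {
  pairs4 <- toy_pairs(4, 2, cancer_types = "ONLY")
  sp4 <- stratified_split(pairs4, 0.75, seed = 1)
  expect_equal(length(unique(sp4$train$index$sample_id)), 3L)
  expect_equal(length(unique(sp4$test$index$sample_id)), 1L)

  # a singleton stratum goes to train, with a warning
  lop <- toy_pairs(9, 1, cancer_types = c(rep("BIG", 8), "TINY"))
  expect_warning(sp <- stratified_split(lop, 0.75, seed = 2), "stratum")
  tiny <- lop$index$sample_id[lop$index$cancer_type == "TINY"]
  expect_true(all(tiny %in% sp$train$index$sample_id))
})

test_that("a fitted schema makes encoding idempotent and order-invariant", {
  co <- small_cohort()
  fs <- small_features()
  # permute expression columns and mutation rows: identical feature matrix
  perm_expr <- co$expression[, sample(ncol(co$expression))]
  fs2 <- featurize_cohort(co$phenotype, co$mutations[sample(nrow(co$mutations)), ],
                          perm_expr, co$drugs, schema = fs$schema)
  expect_identical(fs2$sample_features, fs$sample_features)
  expect_identical(fs2$drug_features, fs$drug_features)
  # and transform mode twice is the same as once
  fs3 <- featurize_cohort(co$phenotype, co$mutations, co$expression, co$drugs,
                          schema = fs$schema)
  expect_identical(fs3$sample_features, fs$sample_features)
})
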