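# Readers, validators and the model archive round trip.

write_tmp <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  write_cohort_table(df, path)
  path
}

test_that("phenotype files parse, validate, and round-trip unchanged", {
  ph <- tibble::tibble(sample_id = c("a", "b", "c"), age = c(50, 63, NA),
                       sex = c("M", "F", "M"),
                       cancer_type = c("LUAD", "PAAD", "LUAD"))
  path <- write_tmp(ph)
  got <- suppressWarnings(suppressMessages(read_cohort_table(path, "phenotype")))
  expect_equal(nrow(got), 3)
  expect_equal(got$sample_id, ph$sample_id)
  expect_equal(got$age, ph$age)

  # validation is a pass-through for valid tables, an error otherwise
  expect_identical(suppressWarnings(validate_phenotype(ph)), ph)
  expect_error(validate_phenotype(dplyr::bind_rows(ph, ph[1, ])), "duplicated")
  expect_error(validate_phenotype(dplyr::mutate(ph, age = c(-1, 2, 3))), "age")
  expect_error(suppressWarnings(validate_phenotype(ph, cancer_vocab = "LUAD")), "PAAD")
  expect_error(suppressWarnings(validate_phenotype(ph[, 1:3])), "cancer_type")
})

test_that("response validation enforces uniqueness and the IC50 domain", {
  ok <- tibble::tibble(sample_id = c("a", "a", "b"), drug_id = c("d1", "d2", "d1"),
                       value = c(1.5, 2, 0.3), endpoint = "IC50")
  expect_identical(validate_response(ok), ok)
  dup <- dplyr::bind_rows(ok, ok[1, ])
  expect_error(validate_response(dup), "duplicated")
  neg <- dplyr::mutate(ok, value = c(-1, 2, 3))
  expect_error(validate_response(neg), "strictly positive")
  # the same value is fine for MFI (log fold changes may be negative)
  expect_silent(validate_response(dplyr::mutate(neg, endpoint = "MFI")))
  expect_error(validate_response(dplyr::mutate(ok, endpoint = "AUC")), "endpoint")
  bor <- tibble::tibble(sample_id = "a", drug_id = "d", value = "XX",
                        endpoint = "BOR")
  expect_error(validate_response(bor), "BOR")
})

test_that("expression matrices round-trip through disk within 1e-12", {
  m <- matrix(abs(rnorm(12)) * 100, 3, 4,
              dimnames = list(c("s1", "s2", "s3"), paste0("g", 1:4)))
  path <- write_tmp(m)
  got <- suppressMessages(read_cohort_table(path, "expression"))
  expect_equal(dimnames(got), dimnames(m))
  expect_lt(max(abs(got - m) / pmax(abs(m), 1)), 1e-12)
  bad <- m
  bad[2, 2] <- -5
  expect_error(validate_expression(bad), "negative")
})

test_that("survival and mutation validators catch malformed rows", {
  sv <- tibble::tibble(patient_id = c("p1", "p2"), time = c(3, 0), event = c(1L, 0L))
  expect_identical(validate_survival(sv), sv)
  expect_error(validate_survival(dplyr::mutate(sv, time = c(-1, 2))), "non-negative")
  expect_error(validate_survival(dplyr::mutate(sv, event = c(2L, 0L))), "event")

  mut <- tibble::tibble(sample_id = "s", gene = "TP53", variant_class = "missense")
  expect_identical(validate_mutation(mut), mut)
  expect_error(validate_mutation(dplyr::mutate(mut, variant_class = "weird")),
               "vocabulary")
  expect_error(suppressMessages(read_cohort_table(write_tmp(mut[, 1:2]), "mutation")),
               "variant_class")
})

test_that("model archives round-trip bit-exactly and realign columns by name", {
  model <- small_model()
  pairs <- small_pairs()
  sub <- ttrec:::pairs_subset(pairs, 1:10)
  before <- predict(model, sub)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(predict(loaded, sub), before)

  # column shuffle: identical predictions via schema realignment
  shuf <- sub
  perm_s <- sample(ncol(shuf$X_sample))
  perm_d <- sample(ncol(shuf$X_drug))
  shuf$X_sample <- shuf$X_sample[, perm_s]
  shuf$X_drug <- shuf$X_drug[, perm_d]
  expect_identical(predict(loaded, shuf), before)

  # dropping a column is a contract error, never silent reordering
  broken <- sub
  broken$X_sample <- broken$X_sample[, -1]
  expect_error(predict(loaded, broken), "schema")
})

test_that("corrupt model archives fail integrity checks", {
  model <- small_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  p <- jsonlite::read_json(path)
  p$weights$sample[[1]]$W <- NULL  # delete one weight array
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(p, path2, auto_unbox = TRUE, null = "null")
  expect_error(load_model(path2), "corrupt")
  expect_error(load_model(withr::local_tempfile(fileext = ".json")), "not found")
})
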