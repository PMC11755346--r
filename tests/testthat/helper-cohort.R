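# Shared fixtures, built in code and memoized for the test run.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# A small but complete cohort: 60 samples x 6 drugs x 40 genes.
small_cohort <- function() {
  memo("small_cohort",
       simulate_cohort(sim_config(n_samples = 60, n_drugs = 6, n_genes = 40,
                                  seed = 42)))
}

small_features <- function() {
  memo("small_features", {
    co <- small_cohort()
    suppressWarnings(
      featurize_cohort(co$phenotype, co$mutations, co$expression, co$drugs))
  })
}

small_pairs <- function() {
  memo("small_pairs", {
    co <- small_cohort()
    fs <- small_features()
    build_pairs(fs$sample_features, fs$drug_features, co$response,
                phenotypes = co$phenotype, schema = fs$schema)
  })
}

# A quick trained model on the small cohort (tiny towers, few epochs).
small_model <- function() {
  memo("small_model", {
    cfg <- model_config(architecture = "concat", sample_hidden = c(32),
                        drug_hidden = c(16), sample_out = 8, drug_out = 8,
                        post_hidden = 8, epochs = 5, batch_size = 64, seed = 9)
    train_recommender(small_pairs(), cfg)
  })
}

# Hand-rolled pair dataset with arbitrary dimensions (for split tests etc.).
toy_pairs <- function(n_samples, n_drugs, cancer_types, seed = 1) {
  withr::with_seed(seed, {
    sids <- sprintf("S%03d", seq_len(n_samples))
    dids <- sprintf("D%02d", seq_len(n_drugs))
    Xs <- matrix(rnorm(n_samples * 3), n_samples, 3,
                 dimnames = list(sids, c("f1", "f2", "f3")))
    Xd <- matrix(rnorm(n_drugs * 2), n_drugs, 2,
                 dimnames = list(dids, c("g1", "g2")))
    resp <- tibble::tibble(sample_id = rep(sids, each = n_drugs),
                           drug_id = rep(dids, times = n_samples),
                           value = exp(rnorm(n_samples * n_drugs)),
                           endpoint = "IC50")
    pheno <- tibble::tibble(sample_id = sids, age = 60, sex = "F",
                            cancer_type = rep_len(cancer_types, n_samples))
    build_pairs(Xs, Xd, resp, phenotypes = pheno)
  })
}
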