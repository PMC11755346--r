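# The two-tower models: configuration, gradients, training, prediction.

tiny_schema <- function(ds = 5, dd = 4) {
  list(sample_features = paste0("s", seq_len(ds)),
       drug_features = paste0("d", seq_len(dd)))
}

tiny_data <- function(n = 40, ds = 5, dd = 4, seed = 3) {
  withr::with_seed(seed, {
    list(Xs = matrix(rnorm(n * ds), n, ds, dimnames = list(NULL, paste0("s", 1:ds))),
         Xd = matrix(rnorm(n * dd), n, dd, dimnames = list(NULL, paste0("d", 1:dd))),
         y = rnorm(n))
  })
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(architecture = "dot", sample_out = 8, drug_out = 16),
               "equal tower output widths")
  expect_error(model_config(l2_alpha = -1), "l2_alpha")
  expect_error(model_config(sample_hidden = c(0, 4)), "positive")
  expect_s3_class(model_config(architecture = "dot"), "ttrec_config")
})

test_that("a dot model with all-zero weights predicts exactly zero", {
  cfg <- model_config(architecture = "dot", sample_hidden = c(4), drug_hidden = c(4),
                      sample_out = 3, drug_out = 3, seed = 1)
  m <- build_recommender(cfg, tiny_schema())
  m$weights <- rapply(m$weights, function(x) x * 0, how = "replace")
  d <- tiny_data()
  pairs <- structure(list(X_sample = d$Xs, X_drug = d$Xd, y = d$y,
                          index = NULL, endpoint = "IC50"),
                     class = "pair_dataset")
  expect_equal(predict(m, pairs), rep(0, 40))
})

test_that("parameter counts match the closed form sum (in+1)*out", {
  cfg <- model_config(architecture = "concat", sample_hidden = c(7, 5),
                      drug_hidden = c(6), sample_out = 3, drug_out = 4,
                      post_hidden = 5)
  m <- build_recommender(cfg, tiny_schema(ds = 9, dd = 8))
  dims_s <- c(9, 7, 5, 3)
  dims_d <- c(8, 6, 4)
  dims_p <- c(7, 5, 1)
  closed <- sum((dims_s[-length(dims_s)] + 1) * dims_s[-1]) +
    sum((dims_d[-length(dims_d)] + 1) * dims_d[-1]) +
    sum((dims_p[-length(dims_p)] + 1) * dims_p[-1])
  expect_equal(n_params(m), closed)
})

test_that("analytic gradients agree with numerical differentiation", {
  d <- tiny_data(n = 12)
  for (arch in c("dot", "concat")) {
    cfg <- model_config(architecture = arch, sample_hidden = c(4),
                        drug_hidden = c(3), sample_out = 2, drug_out = 2,
                        post_hidden = 3, l2_alpha = 0.01, seed = 5)
    m <- build_recommender(cfg, tiny_schema())
    g <- ttrec:::mlp_loss_grad_cpp(d$Xs, d$Xd, d$y, m$weights$sample,
                                   m$weights$drug, m$weights$post,
                                   arch == "dot", 0.01)
    loss_at <- function(w) {
      ttrec:::mlp_loss_grad_cpp(d$Xs, d$Xd, d$y, w$sample, w$drug, w$post,
                                arch == "dot", 0.01)$loss
    }
    # central differences on the (float) loss; a probe stepping across a ReLU
    # kink makes the numeric estimate meaningless, so keep h small and allow
    # a small absolute slack on top of the relative one
    h <- 2e-3
    withr::with_seed(71, {
      for (tower in c("sample", "drug", if (arch == "concat") "post")) {
        for (l in seq_along(m$weights[[tower]])) {
          for (probe in 1:3) {
            W <- m$weights[[tower]][[l]]$W
            ij <- c(sample(nrow(W), 1), sample(ncol(W), 1))
            wp <- m$weights
            wp[[tower]][[l]]$W[ij[1], ij[2]] <- W[ij[1], ij[2]] + h
            wm <- m$weights
            wm[[tower]][[l]]$W[ij[1], ij[2]] <- W[ij[1], ij[2]] - h
            num <- (loss_at(wp) - loss_at(wm)) / (2 * h)
            ana <- g[[tower]][[l]]$W[ij[1], ij[2]]
            expect_lt(abs(ana - num), 2e-3 + 0.02 * abs(num))
          }
        }
      }
    })
  }
})

test_that("an exactly realizable linear target trains to near-zero MSE", {
  withr::with_seed(11, {
    n <- 500
    Xs <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("s", 1:6)))
    Xd <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("d", 1:4)))
    y <- as.numeric(Xs %*% rnorm(6) + Xd %*% rnorm(4))
  })
  pairs <- structure(list(X_sample = Xs, X_drug = Xd, y = y, index = NULL,
                          endpoint = "MFI"), class = "pair_dataset")
  cfg <- model_config(architecture = "concat", sample_hidden = c(16),
                      drug_hidden = c(8), sample_out = 8, drug_out = 8,
                      post_hidden = 8, l2_alpha = 0, learning_rate = 3e-3,
                      epochs = 300, batch_size = 64, seed = 2)
  fit <- train_recommender(pairs, cfg)
  final <- utils::tail(fit$history$train_mse, 1)
  expect_lt(final, 1e-3)
  expect_lt(mean((predict(fit, pairs) - y)^2), 1e-3)
})

test_that("with identity towers the dot model recovers a bilinear factorization", {
  # noiseless y = <U, V>, features linearly exposing the latents
  withr::with_seed(21, {
    k <- 3
    n_s <- 80
    n_d <- 10
    U <- matrix(rnorm(n_s * k), n_s, k)
    V <- matrix(rnorm(n_d * k), n_d, k)
    As <- matrix(rnorm(k * 6), k, 6)
    Ad <- matrix(rnorm(k * 5), k, 5)
    Xs_u <- U %*% As   # n_s x 6, invertible exposure (6 >= k)
    Xd_u <- V %*% Ad
    idx_s <- rep(seq_len(n_s), each = n_d)
    idx_d <- rep(seq_len(n_d), times = n_s)
    pairs <- structure(list(
      X_sample = `dimnames<-`(Xs_u[idx_s, ], list(NULL, paste0("s", 1:6))),
      X_drug = `dimnames<-`(Xd_u[idx_d, ], list(NULL, paste0("d", 1:5))),
      y = rowSums(U[idx_s, ] * V[idx_d, ]), index = NULL, endpoint = "MFI"),
      class = "pair_dataset")
    test_rows <- idx_s > 60
  })
  cfg <- model_config(architecture = "dot", sample_hidden = integer(0),
                      drug_hidden = integer(0), sample_out = 3, drug_out = 3,
                      l2_alpha = 0, learning_rate = 5e-3, epochs = 150,
                      batch_size = 64, seed = 4)
  fit <- train_recommender(ttrec:::pairs_subset(pairs, which(!test_rows)), cfg)
  held <- ttrec:::pairs_subset(pairs, which(test_rows))
  r <- pearson_r(predict(fit, held), held$y)$r
  expect_gte(r, 0.95)
})

test_that("heavy regularization crushes the weights (and monotonically so)", {
  pairs <- small_pairs()
  base <- model_config(architecture = "concat", sample_hidden = c(16),
                       drug_hidden = c(8), sample_out = 4, drug_out = 4,
                       post_hidden = 4, epochs = 100, learning_rate = 1e-2,
                       batch_size = 64, seed = 6)
  fits <- lapply(c(0, 1e-5, 1e3), function(a) {
    cfg <- base
    cfg$l2_alpha <- a
    train_recommender(pairs, cfg)
  })
  ssq <- vapply(fits, ttrec:::sum_sq_weights, numeric(1))
  expect_lt(ssq[3], 0.01 * ssq[1])   # alpha = 1e3 vs alpha = 0
  expect_lte(ssq[3], ssq[2])         # non-increasing at the grid endpoints
})

test_that("training is reproducible under a fixed seed", {
  pairs <- small_pairs()
  cfg <- model_config(architecture = "dot", sample_hidden = c(16),
                      drug_hidden = c(8), sample_out = 4, drug_out = 4,
                      epochs = 2, batch_size = 64, seed = 31)
  f1 <- train_recommender(pairs, cfg)
  f2 <- train_recommender(pairs, cfg)
  expect_equal(f1$history$train_mse[1], f2$history$train_mse[1], tolerance = 1e-6)
  expect_identical(predict(f1, pairs), predict(f2, pairs))
})

test_that("prediction honors the schema contract", {
  model <- small_model()
  pairs <- small_pairs()
  sub <- ttrec:::pairs_subset(pairs, 1:6)
  p <- predict(model, sub)
  expect_length(p, 6)
  expect_true(all(is.finite(p)))

  # duplicated input row -> duplicated identical score
  dup <- ttrec:::pairs_subset(pairs, c(1, 1))
  expect_equal(predict(model, dup)[1], predict(model, dup)[2])

  # empty pair set -> empty score vector
  empty <- ttrec:::pairs_subset(pairs, integer(0))
  expect_length(predict(model, empty), 0)

  # permuted feature columns -> identical scores
  shuf <- sub
  shuf$X_sample <- shuf$X_sample[, rev(seq_len(ncol(shuf$X_sample)))]
  expect_identical(predict(model, shuf), p)
})

test_that("cross-validation partitions samples and prefers stronger ties", {
  pairs <- toy_pairs(50, 3, cancer_types = c("A", "B", "C", "D", "E"))
  cfg <- model_config(architecture = "concat", sample_hidden = c(8),
                      drug_hidden = c(4), sample_out = 4, drug_out = 4,
                      post_hidden = 4, epochs = 2, batch_size = 64, seed = 12)
  cv <- cv_tune_alpha(pairs, alpha_grid = c(1e-2, 1e-4), k = 5, config = cfg)
  expect_equal(nrow(cv$folds), 50L)
  expect_equal(sort(unique(cv$folds$fold)), 1:5)
  # every sample in exactly one validation fold
  expect_equal(anyDuplicated(cv$folds$sample_id), 0L)
  expect_true(cv$best_alpha %in% cv$alpha_grid)
  expect_equal(dim(cv$mse), c(5L, 2L))
  expect_error(cv_tune_alpha(pairs, alpha_grid = numeric(0), k = 5, config = cfg),
               "non-empty")
})
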