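# The two-tower content-based filtering models.
#
# Both architectures push the sample features and the drug fingerprint
# through separate dense (MLP) towers -- ReLU hidden layers, linear tower
# output -- and fuse the two tower outputs either by inner product ("dot")
# or by concatenation followed by one more dense block ("concat") ending in
# a linear scalar: the predicted response for the pair (ln IC50 scale when
# trained on IC50; lower = more sensitive). Training minimizes
# MSE + alpha * sum(W^2) (weights only, uniformly over all layers) with Adam.
# Tower outputs are linear, not ReLU, because a non-negative dot product
# could never represent negative log-IC50 values.

#' Model configuration
#'
#' @param architecture `"concat"` (default, concatenation fusion) or `"dot"`
#'   (inner-product fusion; both towers must then emit the same width).
#' @param sample_hidden,drug_hidden Integer vectors of hidden-layer widths
#'   for the two towers (may be `integer(0)` for a purely linear tower).
#' @param sample_out,drug_out Tower output widths; must be equal for
#'   `"dot"`.
#' @param post_hidden Hidden widths of the post-concatenation block
#'   (concat only).
#' @param l2_alpha Uniform L2 regularization coefficient (>= 0) applied to
#'   all weight matrices, never biases.
#' @param learning_rate,epochs,batch_size Adam step size, epoch count and
#'   minibatch size.
#' @param seed Integer seed controlling weight initialization and batch
#'   order; training is reproducible for a fixed seed.
#' @return A `ttrec_config` list.
#' @export
model_config <- function(architecture = c("concat", "dot"),
                         sample_hidden = c(256, 64), drug_hidden = c(128, 64),
                         sample_out = 32, drug_out = 32, post_hidden = 32,
                         l2_alpha = 1e-3, learning_rate = 1e-3, epochs = 100,
                         batch_size = 128, seed = 1L) {
  architecture <- match.arg(architecture)
  sizes <- c(sample_hidden, drug_hidden, sample_out, drug_out, post_hidden,
             batch_size, epochs)
  if (any(sizes < 1) || any(sizes != floor(sizes))) {
    abort("all layer sizes, epochs and batch_size must be positive integers")
  }
  stopifnot_scalar_number(l2_alpha, "l2_alpha", min = 0)
  stopifnot_scalar_number(learning_rate, "learning_rate", min = 0)
  if (architecture == "dot" && sample_out != drug_out) {
    abort(sprintf(
      "dot fusion requires equal tower output widths (sample_out %d != drug_out %d)",
      sample_out, drug_out))
  }
  structure(list(architecture = architecture,
                 sample_hidden = as.integer(sample_hidden),
                 drug_hidden = as.integer(drug_hidden),
                 sample_out = as.integer(sample_out),
                 drug_out = as.integer(drug_out),
                 post_hidden = as.integer(post_hidden),
                 l2_alpha = l2_alpha, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ttrec_config")
}

# Glorot-uniform initialization for one tower given its layer dimensions.
init_tower <- function(dims) {
  lapply(seq_len(length(dims) - 1), function(l) {
    fan_in <- dims[l]
    fan_out <- dims[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

model_schema <- function(schema, pairs = NULL) {
  if (inherits(schema, "ttrec_schema")) return(schema)
  if (!is.null(pairs)) {
    return(list(sample_features = colnames(pairs$X_sample),
                drug_features = colnames(pairs$X_drug)))
  }
  schema
}

#' Build an untrained two-tower model
#'
#' Initializes all weight arrays (Glorot uniform, biases zero) under the
#' config seed. The result predicts (from its random weights) and can be
#' passed to [train_recommender()].
#'
#' @param config A [model_config()].
#' @param schema A fitted `ttrec_schema`, or any list with
#'   `sample_features` / `drug_features` character vectors fixing the input
#'   columns.
#' @return A `ttrec_model`.
#' @export
build_recommender <- function(config, schema) {
  stopifnot(inherits(config, "ttrec_config"))
  d_s <- length(schema$sample_features)
  d_d <- length(schema$drug_features)
  if (d_s < 1 || d_d < 1) abort("schema must declare sample and drug features")
  weights <- with_seed(derive_seed(config$seed, 11L), {
    w <- list(
      sample = init_tower(c(d_s, config$sample_hidden, config$sample_out)),
      drug = init_tower(c(d_d, config$drug_hidden, config$drug_out))
    )
    w$post <- if (config$architecture == "concat") {
      init_tower(c(config$sample_out + config$drug_out, config$post_hidden, 1L))
    } else {
      list()
    }
    w
  })
  structure(list(config = config, schema = schema, weights = weights,
                 history = tibble::tibble(epoch = integer(), train_mse = double(),
                                          val_mse = double()),
                 trained = FALSE),
            class = "ttrec_model")
}

#' Train a two-tower recommender
#'
#' Minimizes `MSE + l2_alpha * sum(W^2)` with Adam under the config seed
#' (initialization and minibatch order both derive from it); per-epoch
#' training MSE -- and validation MSE when `validation` is supplied -- is
#' recorded in the model history.
#'
#' @param pairs Training `pair_dataset`.
#' @param config A [model_config()]; ignored when `model` is given.
#' @param validation Optional held-out `pair_dataset` scored every epoch.
#' @param model Optionally continue from an existing [build_recommender()]
#'   model (its config and weights are used).
#' @param schema Optional full `ttrec_schema` to embed in the model for
#'   cross-dataset prediction; defaults to the pair dataset's column names.
#' @return A trained `ttrec_model`.
#' @export
train_recommender <- function(pairs, config = model_config(), validation = NULL,
                              model = NULL, schema = NULL) {
  stopifnot(inherits(pairs, "pair_dataset"))
  if (n_pairs(pairs) == 0) abort("cannot train on an empty pair dataset")
  if (any(!is.finite(pairs$y))) abort("training responses must be finite")
  if (is.null(model)) {
    model <- build_recommender(config, schema %||% model_schema(NULL, pairs))
  }
  config <- model$config
  Xs <- align_columns(pairs$X_sample, model$schema$sample_features, "sample feature")
  Xd <- align_columns(pairs$X_drug, model$schema$drug_features, "drug feature")
  n <- nrow(Xs)
  order_mat <- with_seed(derive_seed(config$seed, 23L), {
    vapply(seq_len(config$epochs), function(e) sample.int(n) - 1L, integer(n))
  })
  if (!is.matrix(order_mat)) order_mat <- matrix(order_mat, nrow = n)

  has_val <- !is.null(validation)
  Xs_val <- if (has_val) {
    align_columns(validation$X_sample, model$schema$sample_features, "sample feature")
  } else matrix(0, 0, 0)
  Xd_val <- if (has_val) {
    align_columns(validation$X_drug, model$schema$drug_features, "drug feature")
  } else matrix(0, 0, 0)
  y_val <- if (has_val) validation$y else numeric(0)

  fit <- mlp_train_cpp(Xs, Xd, pairs$y,
                       model$weights$sample, model$weights$drug, model$weights$post,
                       dot = config$architecture == "dot",
                       alpha = config$l2_alpha, lr = config$learning_rate,
                       epochs = config$epochs, batch_size = config$batch_size,
                       order = order_mat, Xs_val = Xs_val, Xd_val = Xd_val,
                       y_val = y_val)
  model$weights <- fit[c("sample", "drug", "post")]
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  train_mse = fit$history[, 1],
                                  val_mse = fit$history[, 2])
  model$trained <- TRUE
  model
}

#' @export
print.ttrec_model <- function(x, ...) {
  cat(sprintf("<ttrec_model> %s fusion, %s, %s parameters\n",
              x$config$architecture,
              if (x$trained) "trained" else "untrained",
              format(n_params(x), big.mark = ",")))
  cat(sprintf("  sample tower: %s -> [%s] -> %d\n", length(x$schema$sample_features),
              paste(x$config$sample_hidden, collapse = ", "), x$config$sample_out))
  cat(sprintf("  drug tower:   %s -> [%s] -> %d\n", length(x$schema$drug_features),
              paste(x$config$drug_hidden, collapse = ", "), x$config$drug_out))
  if (x$trained) {
    cat(sprintf("  final training MSE: %.4g\n", utils::tail(x$history$train_mse, 1)))
  }
  invisible(x)
}

#' Total parameter count of a model
#'
#' Sums `(fan_in + 1) * fan_out` over every dense layer of the three towers.
#'
#' @param model A `ttrec_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(unlist(model$weights, recursive = FALSE),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Predict pair scores
#'
#' Feature columns are realigned to the model schema by name, so a column
#' permutation of the inputs yields identical predictions; missing or
#' unknown columns are a contract error, never silently reordered.
#'
#' @param object A `ttrec_model`.
#' @param pairs A `pair_dataset` conforming to the model schema.
#' @param ... Unused.
#' @return Numeric score vector, one finite value per pair (lower score =
#'   higher predicted sensitivity).
#' @export
predict.ttrec_model <- function(object, pairs, ...) {
  stopifnot(inherits(pairs, "pair_dataset"))
  if (n_pairs(pairs) == 0) return(numeric(0))
  Xs <- align_columns(pairs$X_sample, object$schema$sample_features, "sample feature")
  Xd <- align_columns(pairs$X_drug, object$schema$drug_features, "drug feature")
  as.numeric(mlp_predict_cpp(Xs, Xd, object$weights$sample, object$weights$drug,
                             object$weights$post,
                             dot = object$config$architecture == "dot"))
}

#' Score pairs into a tidy table
#'
#' @inheritParams predict.ttrec_model
#' @param model A `ttrec_model`.
#' @return Tibble with `sample_id`, `drug_id`, `score` (and `y` when the
#'   pair dataset carries responses).
#' @export
score_pairs <- function(model, pairs) {
  out <- dplyr::mutate(pairs$index, score = predict(model, pairs))
  if (!is.null(pairs$y)) out$y <- pairs$y
  out
}

sum_sq_weights <- function(model) {
  sum(vapply(unlist(model$weights, recursive = FALSE),
             function(l) sum(l$W^2), numeric(1)))
}
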