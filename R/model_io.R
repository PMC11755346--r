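# Trained-model serialization.
#
# One self-describing JSON file: a manifest (package version, config, feature
# schema in fixed order, per-array shapes) plus every weight array base64-
# encoded from its raw IEEE-754 doubles. Base64 of the binary payload -- not
# decimal printing -- is what makes the round trip bit-exact.

encode_array <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

decode_array <- function(txt, n) {
  readBin(jsonlite::base64_dec(txt), what = "numeric", n = n, size = 8,
          endian = "little")
}

#' Save a trained model
#'
#' Writes a single JSON archive holding the config, the ordered feature
#' schema and all weight arrays (base64-encoded doubles). The round trip is
#' bit-exact: a loaded model reproduces predictions identically.
#'
#' @param model A `ttrec_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ttrec_model"))
  ser_tower <- function(tw) {
    lapply(tw, function(l) list(
      dim = dim(l$W),
      W = encode_array(l$W),
      b = encode_array(l$b)
    ))
  }
  payload <- list(
    format = "ttrec_model",
    version = 1L,
    package_version = as.character(utils::packageVersion("ttrec")),
    config = unclass(model$config),
    schema = list(
      sample_features = model$schema$sample_features,
      drug_features = model$schema$drug_features,
      full = if (inherits(model$schema, "ttrec_schema")) {
        s <- unclass(model$schema)
        s[!vapply(s, is.null, logical(1))]
      }
    ),
    trained = model$trained,
    history = as.list(model$history),
    weights = lapply(model$weights, ser_tower)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a trained model
#'
#' @param path Path written by [save_model()].
#' @return A `ttrec_model`; integrity failures (missing arrays, shape
#'   mismatches) are an error, never silently patched.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(p$format, "ttrec_model")) abort("not a ttrec model archive")
  cfg <- p$config
  config <- model_config(architecture = cfg$architecture,
                         sample_hidden = as.integer(unlist(cfg$sample_hidden)),
                         drug_hidden = as.integer(unlist(cfg$drug_hidden)),
                         sample_out = cfg$sample_out, drug_out = cfg$drug_out,
                         post_hidden = as.integer(unlist(cfg$post_hidden)),
                         l2_alpha = cfg$l2_alpha, learning_rate = cfg$learning_rate,
                         epochs = cfg$epochs, batch_size = cfg$batch_size,
                         seed = cfg$seed)
  de_tower <- function(tw, name) {
    lapply(seq_along(tw), function(i) {
      l <- tw[[i]]
      if (is.null(l$W) || is.null(l$b) || is.null(l$dim)) {
        abort(sprintf("model archive corrupt: %s tower layer %d incomplete", name, i))
      }
      d <- as.integer(unlist(l$dim))
      W <- decode_array(l$W, prod(d))
      if (length(W) != prod(d)) {
        abort(sprintf("model archive corrupt: %s tower layer %d truncated", name, i))
      }
      b <- decode_array(l$b, d[2])
      if (length(b) != d[2]) {
        abort(sprintf("model archive corrupt: %s tower layer %d bias truncated", name, i))
      }
      list(W = matrix(W, d[1], d[2]), b = b)
    })
  }
  weights <- list(sample = de_tower(p$weights$sample, "sample"),
                  drug = de_tower(p$weights$drug, "drug"),
                  post = if (length(p$weights$post) > 0) {
                    de_tower(p$weights$post, "post")
                  } else list())
  expect_layers <- function(tw, dims, name) {
    if (length(tw) != length(dims) - 1) {
      abort(sprintf("model archive corrupt: %s tower has %d layers, config implies %d",
                    name, length(tw), length(dims) - 1))
    }
    for (i in seq_along(tw)) {
      if (!identical(dim(tw[[i]]$W), c(dims[i], dims[i + 1]))) {
        abort(sprintf("model archive corrupt: %s tower layer %d shape mismatch", name, i))
      }
    }
  }
  schema <- if (!is.null(p$schema$full)) {
    do.call(new_schema, p$schema$full)
  } else {
    list(sample_features = unlist(p$schema$sample_features),
         drug_features = unlist(p$schema$drug_features))
  }
  d_s <- length(schema$sample_features)
  d_d <- length(schema$drug_features)
  expect_layers(weights$sample, c(d_s, config$sample_hidden, config$sample_out), "sample")
  expect_layers(weights$drug, c(d_d, config$drug_hidden, config$drug_out), "drug")
  if (config$architecture == "concat") {
    expect_layers(weights$post,
                  c(config$sample_out + config$drug_out, config$post_hidden, 1L),
                  "post")
  }
  history <- tibble::tibble(epoch = as.integer(unlist(p$history$epoch)),
                            train_mse = as.numeric(unlist(p$history$train_mse)),
                            val_mse = {
                              v <- p$history$val_mse
                              if (is.null(v) || length(v) == 0) {
                                rep(NA_real_, length(unlist(p$history$epoch)))
                              } else as.numeric(unlist(v))
                            })
  structure(list(config = config, schema = schema, weights = weights,
                 history = history, trained = isTRUE(p$trained)),
            class = "ttrec_model")
}
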