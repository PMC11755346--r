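# Feature encoding and pair construction.
#
# Sample-side features follow the TME encoding: phenotype one-hots (sex,
# decade-binned age, cancer type), binary non-silent mutation status per
# panel gene, and TPM expression of the panel genes. Drug-side features are
# hashed Morgan fingerprint bits. A fitted `ttrec_schema` freezes the column
# order so a trained model can realign any conforming input by name.

new_schema <- function(...) {
  structure(list(...), class = "ttrec_schema")
}

#' @export
print.ttrec_schema <- function(x, ...) {
  cat("<ttrec_schema>\n")
  cat(sprintf("  sample features: %d (%d phenotype, %d SNV, %d GEP)\n",
              length(x$sample_features),
              length(x$sample_features) - length(x$snv_genes) - length(x$gep_genes),
              length(x$snv_genes), length(x$gep_genes)))
  cat(sprintf("  drug features:   %d fingerprint bits (radius %d)\n",
              length(x$drug_features), x$radius))
  invisible(x)
}

.default_age_breaks <- c(seq(0, 90, by = 10), Inf)

age_bin_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  out <- sprintf("age_%d_plus", as.integer(lo))
  fin <- is.finite(hi)
  out[fin] <- sprintf("age_%d_%d", as.integer(lo[fin]), as.integer(hi[fin]))
  out
}

#' One-hot encode phenotype features
#'
#' Sex and cancer type become indicator columns; age is binned by decade and
#' then one-hot encoded (a continuous value has no dummy encoding). In
#' fitting mode (`schema = NULL`) the category vocabularies and the
#' training-median age bin (used to impute missing ages, with a warning) are
#' learned; in transform mode the stored schema is applied and unseen
#' categories are an error.
#'
#' @param phenotypes Phenotype table (`sample_id`, `age`, `sex`,
#'   `cancer_type`).
#' @param schema A fitted `ttrec_schema`, or `NULL` to fit.
#' @param age_breaks Ascending bin edges for age, last edge may be `Inf`.
#' @return List with `matrix` (samples x dummies, row names = sample ids) and
#'   the phenotype `encoder` (vocabularies + age handling).
#' @export
encode_phenotype <- function(phenotypes, schema = NULL,
                             age_breaks = .default_age_breaks) {
  phenotypes <- validate_phenotype(phenotypes)
  if (is.null(schema)) {
    enc <- list(
      sex_levels = sort(unique(as.character(phenotypes$sex))),
      cancer_levels = sort(unique(as.character(phenotypes$cancer_type))),
      age_breaks = age_breaks
    )
    med <- stats::median(phenotypes$age, na.rm = TRUE)
    if (is.na(med)) med <- 60  # all ages missing at fit time; neutral default
    enc$age_impute_bin <- as.integer(cut(med, breaks = enc$age_breaks, right = FALSE))
  } else {
    enc <- schema[c("sex_levels", "cancer_levels", "age_breaks", "age_impute_bin")]
    for (col in c("sex", "cancer_type")) {
      lv <- if (col == "sex") enc$sex_levels else enc$cancer_levels
      bad <- setdiff(unique(as.character(phenotypes[[col]])), lv)
      if (length(bad) > 0) {
        abort(sprintf("unseen %s category '%s' not in the fitted vocabulary {%s}",
                      col, bad[1], paste(lv, collapse = ", ")))
      }
    }
  }

  one_hot <- function(x, levels, prefix) {
    m <- matrix(0, nrow = length(x), ncol = length(levels),
                dimnames = list(NULL, paste0(prefix, levels)))
    m[cbind(seq_along(x), match(x, levels))] <- 1
    m
  }
  age <- phenotypes$age
  bins <- as.integer(cut(age, breaks = enc$age_breaks, right = FALSE))
  if (anyNA(bins[!is.na(age)])) {
    abort("age outside the configured bin range")
  }
  if (anyNA(bins)) {
    warn(sprintf("imputing %d missing age(s) to the training-median age bin",
                 sum(is.na(bins))))
    bins[is.na(bins)] <- enc$age_impute_bin
  }
  labels <- age_bin_labels(enc$age_breaks)
  age_m <- matrix(0, nrow = length(bins), ncol = length(labels),
                  dimnames = list(NULL, labels))
  age_m[cbind(seq_along(bins), bins)] <- 1

  m <- cbind(one_hot(as.character(phenotypes$sex), enc$sex_levels, "sex_"),
             age_m,
             one_hot(as.character(phenotypes$cancer_type), enc$cancer_levels, "cancer_"))
  rownames(m) <- phenotypes$sample_id
  list(matrix = m, encoder = enc)
}

#' Binary non-silent mutation status
#'
#' Entry (sample, gene) is 1 when the sample carries at least one variant of a
#' non-silent class in that gene, 0 otherwise (silent variants never count).
#'
#' @param mutations Long-format mutation table (`sample_id`, `gene`,
#'   `variant_class`).
#' @param gene_list The driver-gene panel (fixed column set and order).
#' @param sample_ids Samples to encode (rows); samples with no mutation rows
#'   get an all-zero row.
#' @param nonsilent Variant classes that count as non-silent.
#' @param variant_vocab Full declared vocabulary (including silent classes);
#'   anything outside it is an error.
#' @return Binary integer matrix `length(sample_ids) x length(gene_list)`.
#' @export
encode_snv <- function(mutations, gene_list, sample_ids,
                       nonsilent = nonsilent_classes(),
                       variant_vocab = union(nonsilent, "silent")) {
  mutations <- validate_mutation(mutations, variant_vocab = variant_vocab)
  m <- matrix(0L, nrow = length(sample_ids), ncol = length(gene_list),
              dimnames = list(sample_ids, gene_list))
  hit <- mutations$variant_class %in% nonsilent &
    mutations$sample_id %in% sample_ids &
    mutations$gene %in% gene_list
  if (any(hit)) {
    m[cbind(match(mutations$sample_id[hit], sample_ids),
            match(mutations$gene[hit], gene_list))] <- 1L
  }
  m
}

# Align an expression matrix to the fitted gene panel; genes absent from the
# input are zero-filled with a warning (cross-dataset transfer rule).
encode_gep <- function(expression, gene_list, standardize = FALSE,
                       center = NULL, scale = NULL) {
  expression <- validate_expression(expression)
  missing <- setdiff(gene_list, colnames(expression))
  if (length(missing) > 0) {
    warn(sprintf("expression: %d panel gene(s) absent from input; zero-filled (e.g. %s)",
                 length(missing), paste(utils::head(missing, 3), collapse = ", ")))
    fill <- matrix(0, nrow = nrow(expression), ncol = length(missing),
                   dimnames = list(rownames(expression), missing))
    expression <- cbind(expression, fill)
  }
  m <- expression[, gene_list, drop = FALSE]
  if (standardize) {
    if (is.null(center)) {
      center <- colMeans(m)
      scale <- apply(m, 2, stats::sd)
      scale[scale == 0] <- 1
    }
    m <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  }
  list(matrix = m, center = center, scale = scale)
}

#' Transform raw response values to the modeling scale
#'
#' IC50 is natural-log transformed (values must be strictly positive), MFI
#' log-fold-change passes through unchanged, and BOR collapses to PD = 1
#' versus non-PD = 0 (RECIST labels SD/PR/CR and the literal "non-PD" all map
#' to 0; numeric 0/1 passes through).
#'
#' @param values Numeric values (IC50, MFI) or labels/0-1 (BOR).
#' @param endpoint One of `"IC50"`, `"MFI"`, `"BOR"`.
#' @return Numeric vector on the modeling scale.
#' @export
transform_response <- function(values, endpoint = c("IC50", "MFI", "BOR")) {
  endpoint <- match.arg(endpoint)
  switch(endpoint,
    IC50 = {
      v <- as.numeric(values)
      if (any(!is.na(v) & v <= 0)) {
        abort("IC50 values must be strictly positive for the ln transform")
      }
      log(v)
    },
    MFI = as.numeric(values),
    BOR = {
      if (is.numeric(values)) {
        if (!all(values %in% c(0, 1))) abort("numeric BOR values must be 0/1")
        as.numeric(values)
      } else {
        v <- as.character(values)
        bad <- setdiff(unique(v), .bor_labels)
        if (length(bad) > 0) {
          abort(sprintf("unknown BOR label '%s'", bad[1]))
        }
        as.numeric(v == "PD")
      }
    }
  )
}

#' Featurize a cohort against a new or fitted schema
#'
#' Builds the full sample-feature matrix (phenotype dummies + `snv_` mutation
#' bits + `gep_` TPM columns) and the drug fingerprint matrix, fitting a
#' [new]{ttrec_schema} or applying a stored one (transform mode realigns all
#' blocks by name; the resulting column order is identical to the fit).
#'
#' @param phenotypes,mutations,expression,drugs The four input tables (see
#'   [read_cohort_table()]).
#' @param schema Fitted schema, or `NULL` to fit one.
#' @param gene_panel Driver-gene panel for the SNV block; default: all genes
#'   of the expression matrix.
#' @param gep_panel Gene panel for the expression block; defaults to
#'   `gene_panel` (one shared panel).
#' @param n_bits,radius Fingerprint parameters.
#' @param gep_standardize Optionally z-score each expression column using
#'   fit-time statistics; off by default (TPM is used as-is).
#' @param age_breaks Age bin edges (see [encode_phenotype()]).
#' @return List with `sample_features`, `drug_features` (matrices) and
#'   `schema`.
#' @export
featurize_cohort <- function(phenotypes, mutations, expression, drugs,
                             schema = NULL, gene_panel = NULL, gep_panel = NULL,
                             n_bits = 512, radius = 2, gep_standardize = FALSE,
                             age_breaks = .default_age_breaks) {
  phenotypes <- validate_phenotype(phenotypes)
  expression <- validate_expression(expression)
  if (!setequal(phenotypes$sample_id, rownames(expression))) {
    abort("phenotype and expression tables must cover the same samples")
  }
  expression <- expression[phenotypes$sample_id, , drop = FALSE]

  fitting <- is.null(schema)
  if (fitting) {
    gene_panel <- gene_panel %||% sort(colnames(expression))
    gep_panel <- gep_panel %||% gene_panel
  } else {
    gene_panel <- schema$snv_genes
    gep_panel <- schema$gep_genes
    n_bits <- schema$n_bits
    radius <- schema$radius
    gep_standardize <- schema$gep_standardize
    age_breaks <- schema$age_breaks
  }

  ph <- encode_phenotype(phenotypes, schema = schema, age_breaks = age_breaks)
  snv <- encode_snv(mutations, gene_panel, phenotypes$sample_id)
  colnames(snv) <- paste0("snv_", gene_panel)
  gep <- encode_gep(expression, gep_panel, standardize = gep_standardize,
                    center = if (fitting) NULL else schema$gep_center,
                    scale = if (fitting) NULL else schema$gep_scale)
  gep_m <- gep$matrix
  colnames(gep_m) <- paste0("gep_", gep_panel)

  X <- cbind(ph$matrix, snv, gep_m)
  storage.mode(X) <- "double"
  fp <- fingerprint_drugs(drugs, n_bits = n_bits, radius = radius)
  fp_d <- fp
  storage.mode(fp_d) <- "double"

  if (fitting) {
    schema <- new_schema(
      sex_levels = ph$encoder$sex_levels,
      cancer_levels = ph$encoder$cancer_levels,
      age_breaks = ph$encoder$age_breaks,
      age_impute_bin = ph$encoder$age_impute_bin,
      snv_genes = gene_panel,
      gep_genes = gep_panel,
      n_bits = n_bits,
      radius = radius,
      gep_standardize = gep_standardize,
      gep_center = gep$center,
      gep_scale = gep$scale,
      sample_features = colnames(X),
      drug_features = colnames(fp_d)
    )
  } else {
    X <- align_columns(X, schema$sample_features, "sample feature")
    fp_d <- align_columns(fp_d, schema$drug_features, "drug feature")
  }
  list(sample_features = X, drug_features = fp_d, schema = schema)
}

#' Assemble the flattened pair dataset
#'
#' One row per measured (sample, drug) response, ordered row-major by sample
#' then drug (sample order = row order of `sample_features`, drug order = row
#' order of `drug_features`). Pairs without a measured response are omitted;
#' responses referencing unknown samples or drugs are an error. The response
#' values are moved to the modeling scale with [transform_response()].
#'
#' @param sample_features Sample feature matrix (rows named by sample id).
#' @param drug_features Drug fingerprint matrix (rows named by drug id).
#' @param responses Response table with a single endpoint.
#' @param phenotypes Optional phenotype table supplying per-sample
#'   `cancer_type` group labels (needed for stratified splitting and grouped
#'   evaluation).
#' @param schema Optional fitted schema; when supplied both feature blocks
#'   are realigned to it by column name.
#' @return A `pair_dataset`: list with matrices `X_sample`, `X_drug`, vector
#'   `y`, tibble `index` (`sample_id`, `drug_id`, `cancer_type`) and the
#'   `endpoint`.
#' @export
build_pairs <- function(sample_features, drug_features, responses,
                        phenotypes = NULL, schema = NULL) {
  responses <- validate_response(responses)
  ep <- unique(responses$endpoint)
  if (length(ep) != 1) {
    abort(sprintf("build_pairs needs a single endpoint; got {%s}",
                  paste(ep, collapse = ", ")))
  }
  if (!is.null(schema)) {
    sample_features <- align_columns(sample_features, schema$sample_features,
                                     "sample feature")
    drug_features <- align_columns(drug_features, schema$drug_features,
                                   "drug feature")
  }
  sids <- rownames(sample_features)
  dids <- rownames(drug_features)
  if (is.null(sids) || is.null(dids)) {
    abort("feature matrices must have row names (sample/drug ids)")
  }
  unknown_s <- setdiff(responses$sample_id, sids)
  if (length(unknown_s) > 0) {
    abort(sprintf("response references unknown sample '%s'", unknown_s[1]))
  }
  unknown_d <- setdiff(responses$drug_id, dids)
  if (length(unknown_d) > 0) {
    abort(sprintf("response references unknown drug '%s'", unknown_d[1]))
  }

  si <- match(responses$sample_id, sids)
  di <- match(responses$drug_id, dids)
  ord <- order(si, di)
  responses <- responses[ord, ]
  si <- si[ord]
  di <- di[ord]

  cancer <- rep(NA_character_, nrow(responses))
  if (!is.null(phenotypes)) {
    phenotypes <- validate_phenotype(phenotypes)
    cancer <- as.character(phenotypes$cancer_type)[
      match(responses$sample_id, phenotypes$sample_id)]
  }
  structure(list(
    X_sample = sample_features[si, , drop = FALSE],
    X_drug = drug_features[di, , drop = FALSE],
    y = transform_response(responses$value, ep),
    index = tibble::tibble(sample_id = responses$sample_id,
                           drug_id = responses$drug_id,
                           cancer_type = cancer),
    endpoint = ep
  ), class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d pairs (%d samples x %d drugs measured), endpoint %s\n",
              length(x$y), dplyr::n_distinct(x$index$sample_id),
              dplyr::n_distinct(x$index$drug_id), x$endpoint))
  cat(sprintf("  sample features: %d, drug features: %d\n",
              ncol(x$X_sample), ncol(x$X_drug)))
  invisible(x)
}

#' Number of pairs in a pair dataset
#' @param pairs A `pair_dataset`.
#' @return Integer pair count.
#' @export
n_pairs <- function(pairs) length(pairs$y)

# Row subset of a pair dataset (internal).
pairs_subset <- function(pairs, rows) {
  structure(list(
    X_sample = pairs$X_sample[rows, , drop = FALSE],
    X_drug = pairs$X_drug[rows, , drop = FALSE],
    y = pairs$y[rows],
    index = pairs$index[rows, ],
    endpoint = pairs$endpoint
  ), class = "pair_dataset")
}

#' Sample-level stratified train/test split
#'
#' Splits at the sample level (all pairs of a sample travel together) with
#' strata defined by cancer type. Per-stratum training counts follow a
#' largest-remainder allocation whose total is exactly
#' `floor(train_frac * n_samples + 0.5)`, so 542 samples at 75:25 give
#' 407/135. Strata with a single sample go to the training set with a
#' warning. Seeded and reproducible.
#'
#' @param pairs A `pair_dataset` whose index carries `cancer_type`.
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed controlling the within-stratum draw.
#' @return List with `train` and `test` pair datasets.
#' @export
stratified_split <- function(pairs, train_frac = 0.75, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0, 1)")
  samples <- dplyr::distinct(pairs$index, .data$sample_id, .data$cancer_type)
  if (anyNA(samples$cancer_type)) {
    abort("stratified_split needs a cancer_type label for every sample")
  }
  n <- nrow(samples)
  total_train <- floor(train_frac * n + 0.5)

  strata <- dplyr::count(samples, .data$cancer_type)
  single <- strata$n < 2
  if (any(single)) {
    warn(sprintf("%d stratum(s) with < 2 samples assigned wholly to the training set",
                 sum(single)))
  }
  quota <- train_frac * strata$n
  base <- pmin(floor(quota), strata$n)
  base[single] <- strata$n[single]
  left <- total_train - sum(base)
  if (left > 0) {
    frac <- quota - floor(quota)
    frac[single] <- -Inf
    room <- strata$n - base
    ord <- order(-frac, -strata$n, strata$cancer_type)
    for (i in ord) {
      if (left == 0) break
      take <- min(room[i], 1L)
      base[i] <- base[i] + take
      left <- left - take
    }
    while (left > 0 && any(base < strata$n & !single)) {
      i <- which(base < strata$n & !single)[1]
      base[i] <- base[i] + 1L
      left <- left - 1L
    }
  } else if (left < 0) {
    # single-sample strata forced more into train than the global share
    ord <- order(strata$n, decreasing = TRUE)
    for (i in ord) {
      if (left == 0) break
      if (!single[i] && base[i] > 0) {
        base[i] <- base[i] - 1L
        left <- left + 1L
      }
    }
  }

  train_ids <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(strata)), function(i) {
      ids <- samples$sample_id[samples$cancer_type == strata$cancer_type[i]]
      sample(ids, size = base[i])
    }), use.names = FALSE)
  })
  in_train <- pairs$index$sample_id %in% train_ids
  list(train = pairs_subset(pairs, which(in_train)),
       test = pairs_subset(pairs, which(!in_train)))
}
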