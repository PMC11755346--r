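# Reading, validating and writing the five tabular input kinds.
#
# All readers return tibbles (the expression kind returns a numeric matrix,
# the field's natural container for samples x genes TPM) and run the matching
# validator, so invalid files fail at the door with the offending row named.

.table_kinds <- c("phenotype", "mutation", "expression", "drug", "response", "survival")

.default_variant_vocab <- c(
  "missense", "nonsense", "frameshift", "splice_site", "in_frame_indel",
  "nonstop", "silent"
)

#' Non-silent variant classes
#'
#' The default vocabulary of somatic variant classes that count as
#' "non-silent" when binarizing mutation status. Configurable wherever it is
#' used; `silent` rows are accepted in mutation tables but never set a bit.
#'
#' @return Character vector of variant-class labels.
#' @export
nonsilent_classes <- function() {
  setdiff(.default_variant_vocab, "silent")
}

#' Read and validate a cohort table
#'
#' Reads one of the six tabular inputs (TSV by default, CSV accepted; the
#' delimiter is taken from the file extension unless `delim` is given),
#' validates it against the invariants of its kind, and returns it unchanged.
#' A short schema report (rows, missing values) is emitted as a message.
#'
#' @param path Path to a delimited text file with a header row.
#' @param kind One of `"phenotype"`, `"mutation"`, `"expression"`, `"drug"`,
#'   `"response"`, `"survival"`.
#' @param delim Optional delimiter override (`"\t"` or `","`).
#' @param cancer_vocab Optional declared cancer-type vocabulary for phenotype
#'   validation; unseen types then raise an error.
#' @param variant_vocab Variant-class vocabulary for mutation validation.
#' @param verbose Emit the schema report message.
#' @return A validated tibble; for `kind = "expression"` a numeric matrix
#'   (samples in rows, genes in columns).
#' @export
read_cohort_table <- function(path, kind, delim = NULL, cancer_vocab = NULL,
                              variant_vocab = .default_variant_vocab,
                              verbose = TRUE) {
  kind <- match.arg(kind, .table_kinds)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols())
  out <- switch(kind,
    phenotype  = validate_phenotype(df, cancer_vocab = cancer_vocab),
    mutation   = validate_mutation(df, variant_vocab = variant_vocab),
    drug       = validate_drug(df),
    response   = validate_response(df),
    survival   = validate_survival(df),
    expression = {
      if (!"sample_id" %in% names(df)) {
        abort("expression table must have a `sample_id` first column")
      }
      m <- as.matrix(df[setdiff(names(df), "sample_id")])
      storage.mode(m) <- "double"
      rownames(m) <- as.character(df$sample_id)
      validate_expression(m)
    }
  )
  if (verbose) {
    n_miss <- if (is.matrix(out)) sum(is.na(out)) else sum(is.na(out))
    message(sprintf("[ttrec] read %s table: %d rows, %d missing values",
                    kind, NROW(out), n_miss))
  }
  out
}

#' Write a cohort table
#'
#' Inverse of [read_cohort_table()]: TSV unless the path ends in `.csv`.
#' Matrices (expression) gain a `sample_id` first column.
#'
#' @param x Table or expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)),
                          tibble::as_tibble(x))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}

.require_columns <- function(df, cols, kind) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing required column(s): %s",
                  kind, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' @rdname read_cohort_table
#' @param df Data frame to validate.
#' @export
validate_phenotype <- function(df, cancer_vocab = NULL) {
  .require_columns(df, c("sample_id", "age", "sex", "cancer_type"), "phenotype")
  df <- tibble::as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    abort(sprintf("phenotype: duplicated sample_id at row %d (%s)",
                  which(dup)[1], df$sample_id[which(dup)[1]]))
  }
  df$age <- suppressWarnings(as.numeric(df$age))
  bad_age <- which(!is.na(df$age) & df$age < 0)
  if (length(bad_age) > 0) {
    abort(sprintf("phenotype: negative age at row %d", bad_age[1]))
  }
  if (anyNA(df$age)) {
    warn(sprintf("phenotype: %d sample(s) with missing age (will be imputed at encoding time)",
                 sum(is.na(df$age))))
  }
  if (!is.null(cancer_vocab)) {
    bad <- which(!df$cancer_type %in% cancer_vocab)
    if (length(bad) > 0) {
      abort(sprintf("phenotype: cancer_type '%s' at row %d not in declared vocabulary",
                    df$cancer_type[bad[1]], bad[1]))
    }
  }
  df
}

#' @rdname read_cohort_table
#' @export
validate_mutation <- function(df, variant_vocab = .default_variant_vocab) {
  .require_columns(df, c("sample_id", "gene", "variant_class"), "mutation")
  df <- tibble::as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  df$gene <- as.character(df$gene)
  bad <- which(!df$variant_class %in% variant_vocab)
  if (length(bad) > 0) {
    abort(sprintf("mutation: variant_class '%s' at row %d outside vocabulary {%s}",
                  df$variant_class[bad[1]], bad[1],
                  paste(variant_vocab, collapse = ", ")))
  }
  df
}

#' @rdname read_cohort_table
#' @param mat Expression matrix (samples x genes, TPM).
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) abort("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    abort("expression: row (sample) ids must be present and unique")
  }
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat))) {
    abort("expression: column (gene) ids must be present and unique")
  }
  neg <- which(mat < 0)
  if (length(neg) > 0) {
    abort(sprintf("expression: negative TPM value at entry [%d] (TPM must be >= 0)", neg[1]))
  }
  mat
}

#' @rdname read_cohort_table
#' @export
validate_drug <- function(df) {
  .require_columns(df, c("drug_id", "smiles"), "drug")
  df <- tibble::as_tibble(df)
  df$drug_id <- as.character(df$drug_id)
  dup <- duplicated(df$drug_id)
  if (any(dup)) {
    abort(sprintf("drug: duplicated drug_id at row %d (%s)",
                  which(dup)[1], df$drug_id[which(dup)[1]]))
  }
  blank <- which(is.na(df$smiles) | !nzchar(trimws(df$smiles)))
  if (length(blank) > 0) {
    abort(sprintf("drug: empty SMILES at row %d", blank[1]))
  }
  df
}

.bor_labels <- c("PD", "SD", "PR", "CR", "non-PD")

#' @rdname read_cohort_table
#' @export
validate_response <- function(df) {
  .require_columns(df, c("sample_id", "drug_id", "value", "endpoint"), "response")
  df <- tibble::as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  df$drug_id <- as.character(df$drug_id)
  bad_ep <- which(!df$endpoint %in% c("IC50", "MFI", "BOR"))
  if (length(bad_ep) > 0) {
    abort(sprintf("response: endpoint '%s' at row %d (must be IC50, MFI or BOR)",
                  df$endpoint[bad_ep[1]], bad_ep[1]))
  }
  key <- paste(df$sample_id, df$drug_id, df$endpoint, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf("response: duplicated (sample_id, drug_id, endpoint) at row %d (%s, %s, %s)",
                  which(dup)[1], df$sample_id[which(dup)[1]],
                  df$drug_id[which(dup)[1]], df$endpoint[which(dup)[1]]))
  }
  num <- df$endpoint %in% c("IC50", "MFI")
  if (any(num)) {
    v <- suppressWarnings(as.numeric(df$value[num]))
    bad <- which(is.na(v) & !is.na(df$value[num]))
    if (length(bad) > 0) {
      abort(sprintf("response: non-numeric %s value at row %d",
                    df$endpoint[num][bad[1]], which(num)[bad[1]]))
    }
    nonpos <- which(df$endpoint[num] == "IC50" & v <= 0)
    if (length(nonpos) > 0) {
      abort(sprintf(
        "response: IC50 value %s at row %d must be strictly positive (ln transform)",
        format(v[nonpos[1]]), which(num)[nonpos[1]]))
    }
  }
  bor <- df$endpoint == "BOR"
  if (any(bor)) {
    ok <- df$value[bor] %in% .bor_labels | df$value[bor] %in% c("0", "1", 0, 1)
    if (!all(ok)) {
      abort(sprintf("response: BOR value '%s' at row %d (expected RECIST label or PD/non-PD)",
                    df$value[bor][!ok][1], which(bor)[which(!ok)[1]]))
    }
  }
  df
}

#' @rdname read_cohort_table
#' @export
validate_survival <- function(df) {
  .require_columns(df, c("patient_id", "time", "event"), "survival")
  df <- tibble::as_tibble(df)
  df$patient_id <- as.character(df$patient_id)
  df$time <- suppressWarnings(as.numeric(df$time))
  bad_t <- which(is.na(df$time) | df$time < 0)
  if (length(bad_t) > 0) {
    abort(sprintf("survival: time at row %d must be a non-negative number", bad_t[1]))
  }
  if (!all(df$event %in% c(0, 1))) {
    bad <- which(!df$event %in% c(0, 1))
    abort(sprintf("survival: event at row %d must be 0 (censored) or 1 (event)", bad[1]))
  }
  df$event <- as.integer(df$event)
  df
}
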