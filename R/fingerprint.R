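# Morgan (ECFP) fingerprints via RDKit.
#
# There is no cheminformatics toolkit on CRAN/Bioconductor in this stack, and
# hashed circular fingerprints are a standard primitive that should not be
# reimplemented, so the package drives the system `python` + RDKit through a
# small bundled helper script. Results are cached per session keyed on
# (smiles, radius, n_bits), so repeated featurization of the same drug panel
# costs one interpreter start-up.

.fp_cache <- new.env(parent = emptyenv())

find_python <- function() {
  py <- Sys.getenv("TTREC_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) abort("no `python` interpreter with RDKit found on PATH")
  py
}

#' Hashed Morgan fingerprints for SMILES strings
#'
#' Computes deterministic circular (Morgan / ECFP) fingerprints folded to
#' `n_bits` bits. Radius 2 with 512 bits (the defaults) corresponds to the
#' common ECFP4-at-512 setting.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Folded fingerprint length (default 512).
#' @param radius Morgan radius (default 2, i.e. ECFP4-equivalent).
#' @return Integer matrix `length(smiles) x n_bits` with entries in \{0, 1\}
#'   and column names `fp_001 ...`; row names are the names of `smiles` when
#'   present.
#' @examples
#' \dontrun{
#' fp <- morgan_fingerprints("CC(=O)Oc1ccccc1C(=O)O") # aspirin
#' sum(fp)
#' }
#' @export
morgan_fingerprints <- function(smiles, n_bits = 512, radius = 2) {
  stopifnot_scalar_number(n_bits, "n_bits", min = 1)
  stopifnot_scalar_number(radius, "radius", min = 0)
  if (length(smiles) == 0) {
    out <- matrix(integer(0), nrow = 0, ncol = n_bits)
    colnames(out) <- fp_bit_names(n_bits)
    return(out)
  }
  if (anyNA(smiles) || !all(nzchar(smiles))) abort("SMILES must be non-empty strings")

  keys <- sprintf("r%d_b%d_%s", radius, n_bits, smiles)
  todo <- !vapply(keys, exists, logical(1), envir = .fp_cache)
  if (any(todo)) {
    uniq <- unique(smiles[todo])
    hits <- fp_python_batch(uniq, n_bits = n_bits, radius = radius)
    for (i in seq_along(uniq)) {
      assign(sprintf("r%d_b%d_%s", radius, n_bits, uniq[i]), hits[[i]],
             envir = .fp_cache)
    }
  }
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits,
                dimnames = list(names(smiles), fp_bit_names(n_bits)))
  for (i in seq_along(smiles)) {
    out[i, get(keys[i], envir = .fp_cache) + 1L] <- 1L
  }
  out
}

fp_bit_names <- function(n_bits) {
  sprintf("fp_%0*d", nchar(as.character(n_bits)), seq_len(n_bits))
}

# One python call for a batch of unique SMILES; returns a list of 0-based
# on-bit index vectors, erroring with the offending string on parse failure.
fp_python_batch <- function(smiles, n_bits, radius) {
  script <- system.file("python", "morgan_fp.py", package = "ttrec")
  if (!nzchar(script)) abort("bundled morgan_fp.py not found; reinstall ttrec")
  src <- tempfile(fileext = ".tsv")
  dst <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(src, dst)), add = TRUE)
  writeLines(sprintf("%d\t%s", seq_along(smiles), smiles), src)
  status <- system2(find_python(), c(shQuote(script), shQuote(src), shQuote(dst),
                                     as.character(radius), as.character(n_bits)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(dst)) {
    abort(c("RDKit fingerprint helper failed", paste(status, collapse = "\n")))
  }
  lines <- readLines(dst)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  err <- vapply(parts, function(p) p[2] == "ERR", logical(1))
  if (any(err)) {
    abort(sprintf("fingerprint error: %s", parts[[which(err)[1]]][3]))
  }
  lapply(parts, function(p) {
    if (length(p) < 3 || !nzchar(p[3])) integer(0)
    else as.integer(strsplit(p[3], ",", fixed = TRUE)[[1]])
  })
}

#' Fingerprint a drug table
#'
#' @param drugs Drug table with `drug_id` and `smiles` columns
#'   (see [read_cohort_table()]).
#' @inheritParams morgan_fingerprints
#' @return Integer bit matrix with one row per drug (row names `drug_id`).
#' @export
fingerprint_drugs <- function(drugs, n_bits = 512, radius = 2) {
  drugs <- validate_drug(drugs)
  smi <- rlang::set_names(drugs$smiles, drugs$drug_id)
  morgan_fingerprints(smi, n_bits = n_bits, radius = radius)
}

#' Bundled oncology drug panel
#'
#' Eighteen well-known oncology agents with PubChem-style SMILES, shipped so
#' that synthetic cohorts carry realistic drug structures. The panel is
#' illustrative: it is not the drug list of any particular screen.
#'
#' @return Tibble with `drug_id` and `smiles`.
#' @export
oncology_drugs <- function() {
  path <- system.file("extdata", "oncology_drugs.csv", package = "ttrec")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
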