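# Synthetic cohort generator.
#
# The stated world: a bilinear sample x drug response surface. Sample latents
# U ~ N(0, I_k); drug latents V are a fixed random projection of the drug's
# Morgan fingerprint (so the drug-side signal is recoverable from the
# fingerprint by construction), standardized across the panel and scaled by
# 1/sqrt(k) so the noiseless pair signal has unit variance. The response
# adds a per-cancer-type offset and Gaussian noise. GEP exposes U through a
# linear map observed on a log scale and exponentiated to TPM-like positive
# values; SNV bits are Bernoulli with logits tied to U and an intercept
# calibrated (by numerical integration) to the target sparsity. BOR labels
# and exponential survival times hang off the same response surface, with
# uniform censoring calibrated to the configured rate.

#' Simulation configuration
#'
#' Defaults mirror the desk-scale shape of a large cell-line screen: 542
#' samples x 18 drugs x 776 panel genes, latent dimension 4.
#'
#' @param n_samples,n_drugs,n_genes Cohort dimensions.
#' @param latent_dim Latent dimension k of the bilinear signal.
#' @param noise_sd Response noise sd, same units as y (the noiseless signal
#'   has sd ~ 1 by construction, so 0.25 is a 4:1 signal-to-noise setting).
#' @param gep_noise_sd Noise sd on the log-latent expression scale.
#' @param gep_mu,gep_sigma Location/scale of log TPM: TPM =
#'   `exp(gep_mu + gep_sigma * (latent + noise))`, giving a median around
#'   `exp(gep_mu)` ~ 10 TPM for expressed driver genes.
#' @param snv_sparsity Target mean mutation frequency per gene.
#' @param snv_slope Latent-to-logit slope for mutation bits.
#' @param cancer_types Cancer-type vocabulary (default: 12 TCGA codes).
#' @param cancer_effect_sd sd of the per-cancer-type response offsets.
#' @param sex_prob Probability of "M".
#' @param age_mean,age_sd Age distribution (years), truncated to [18, 90].
#' @param silent_rate Expected silent-mutation rows per sample-gene, added so
#'   the non-silent filter is exercised.
#' @param bor_threshold,bor_noise_scale PD iff `y + logistic(0, scale) >
#'   threshold` for the treated pair.
#' @param base_hazard Baseline event rate per month (0.058 ~ 12-month median
#'   survival).
#' @param hazard_coef Log-hazard increase per unit predicted response.
#' @param censoring_rate Target fraction censored (uniform censoring
#'   calibrated to hit it in expectation).
#' @param seed Master seed; every table derives from it.
#' @return A `ttrec_sim_config` list.
#' @export
sim_config <- function(n_samples = 542, n_drugs = 18, n_genes = 776,
                       latent_dim = 4, noise_sd = 0.25, gep_noise_sd = 0.3,
                       gep_mu = log(10), gep_sigma = 0.5, snv_sparsity = 0.1,
                       snv_slope = 1, cancer_types = NULL,
                       cancer_effect_sd = 0.3, sex_prob = 0.55,
                       age_mean = 60, age_sd = 12, silent_rate = 0.02,
                       bor_threshold = 0.5, bor_noise_scale = 0.5,
                       base_hazard = 0.058, hazard_coef = 0.7,
                       censoring_rate = 0.3, seed = 1L) {
  cancer_types <- cancer_types %||% c("BRCA", "COAD", "ESCA", "GBM", "HNSC",
                                      "KIRC", "LUAD", "OV", "PAAD", "SARC",
                                      "SCLC", "SKCM")
  dims <- c(n_samples, n_drugs, n_genes, latent_dim)
  if (any(dims < 1) || any(dims != floor(dims))) {
    abort("all dimensions must be positive integers")
  }
  for (nm in c("noise_sd", "gep_noise_sd", "gep_sigma", "snv_slope",
               "cancer_effect_sd", "base_hazard", "hazard_coef")) {
    stopifnot_scalar_number(get(nm), nm, min = 0)
  }
  if (snv_sparsity <= 0 || snv_sparsity >= 1) abort("snv_sparsity must be in (0, 1)")
  if (censoring_rate < 0 || censoring_rate >= 1) abort("censoring_rate must be in [0, 1)")
  structure(as.list(environment()), class = "ttrec_sim_config")
}

# Intercept c such that E[plogis(c + slope * Z)] = target for Z ~ N(0, 1),
# by Gauss-Hermite-free quadrature on a fine grid.
calibrate_logit_intercept <- function(target, slope) {
  z <- seq(-6, 6, length.out = 2001)
  wz <- stats::dnorm(z)
  wz <- wz / sum(wz)
  f <- function(c) sum(stats::plogis(c + slope * z) * wz) - target
  stats::uniroot(f, c(-30, 30))$root
}

# Uniform censoring horizon m with mean censoring probability `target`
# given per-subject exponential rates.
calibrate_censoring_horizon <- function(rates, target) {
  p_cens <- function(m) mean((1 - exp(-rates * m)) / (rates * m))
  stats::uniroot(function(m) p_cens(m) - target, c(1e-6, 1e6),
                 extendInt = "downX")$root
}

#' Simulate a full synthetic cohort
#'
#' Generates the six tables of the pipeline (phenotype, mutations,
#' expression, drugs, IC50 responses, survival) plus a BOR table for the
#' one treated drug per sample, and the hidden `truth` used by recovery
#' tests. IC50 values are `exp(y)` so the ln transform recovers the modeled
#' response exactly. Fully deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return List with `phenotype`, `mutations`, `expression`, `drugs`,
#'   `response` (IC50, all pairs), `bor` (one treated pair per sample),
#'   `survival`, and `truth` (a `ttrec_truth`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "ttrec_sim_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, 101L), {
    n <- cfg$n_samples
    k <- cfg$latent_dim
    sample_ids <- sprintf("S%04d", seq_len(n))
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))

    # drugs: packaged panel first, random fingerprints past the fixture
    panel <- oncology_drugs()
    if (cfg$n_drugs <= nrow(panel)) {
      drugs <- panel[seq_len(cfg$n_drugs), ]
      fp <- fingerprint_drugs(drugs)
    } else {
      drugs <- panel
      extra_n <- cfg$n_drugs - nrow(panel)
      fp <- fingerprint_drugs(drugs)
      extra <- matrix(stats::rbinom(extra_n * ncol(fp), 1, 0.08),
                      nrow = extra_n,
                      dimnames = list(sprintf("SYND%02d", seq_len(extra_n)),
                                      colnames(fp)))
      fp <- rbind(fp, extra)
      drugs <- dplyr::bind_rows(
        drugs, tibble::tibble(drug_id = rownames(extra), smiles = NA_character_))
      warn("n_drugs exceeds the packaged panel; extra drugs use random fingerprints")
    }

    # latents
    U <- matrix(stats::rnorm(n * k), n, k, dimnames = list(sample_ids, NULL))
    P <- matrix(stats::rnorm(k * ncol(fp), sd = 1 / sqrt(mean(rowSums(fp)))),
                k, ncol(fp))
    V <- fp %*% t(P)                       # n_drugs x k, affine in the fingerprint
    V <- scale(V)                          # unit-variance drug latents
    attr(V, "scaled:center") <- NULL
    attr(V, "scaled:scale") <- NULL
    if (any(!is.finite(V))) V[!is.finite(V)] <- 0

    # phenotype
    age <- round(pmin(90, pmax(18, stats::rnorm(n, cfg$age_mean, cfg$age_sd))))
    sex <- ifelse(stats::runif(n) < cfg$sex_prob, "M", "F")
    cancer <- sample(cfg$cancer_types, n, replace = TRUE)
    phenotype <- tibble::tibble(sample_id = sample_ids, age = age, sex = sex,
                                cancer_type = cancer)
    offsets <- stats::rnorm(length(cfg$cancer_types), 0, cfg$cancer_effect_sd)
    names(offsets) <- cfg$cancer_types

    # noiseless response surface (ln IC50 scale)
    signal <- (U %*% t(V)) / sqrt(k) + offsets[cancer]
    colnames(signal) <- rownames(fp)
    y <- signal + stats::rnorm(length(signal), 0, cfg$noise_sd)

    # expression: latent exposure on log scale, exponentiated to TPM
    W <- matrix(stats::rnorm(cfg$n_genes * k, sd = 1 / sqrt(k)), cfg$n_genes, k,
                dimnames = list(genes, NULL))
    logexpr <- U %*% t(W) +
      matrix(stats::rnorm(n * cfg$n_genes, 0, cfg$gep_noise_sd), n, cfg$n_genes)
    expression <- exp(cfg$gep_mu + cfg$gep_sigma * logexpr)
    dimnames(expression) <- list(sample_ids, genes)

    # mutations: logits tied to U through a second projection
    Z <- matrix(stats::rnorm(cfg$n_genes * k, sd = 1 / sqrt(k)), cfg$n_genes, k)
    icp <- calibrate_logit_intercept(cfg$snv_sparsity, cfg$snv_slope)
    pmat <- stats::plogis(icp + cfg$snv_slope * (U %*% t(Z)))
    bits <- matrix(stats::rbinom(length(pmat), 1, pmat), n, cfg$n_genes)
    hit <- which(bits == 1, arr.ind = TRUE)
    mut_rows <- tibble::tibble(
      sample_id = sample_ids[hit[, 1]],
      gene = genes[hit[, 2]],
      variant_class = sample(nonsilent_classes(), nrow(hit), replace = TRUE,
                             prob = c(0.6, 0.1, 0.12, 0.08, 0.06, 0.04))
    )
    n_silent <- stats::rpois(1, cfg$silent_rate * n * cfg$n_genes)
    silent_rows <- tibble::tibble(
      sample_id = sample(sample_ids, n_silent, replace = TRUE),
      gene = sample(genes, n_silent, replace = TRUE),
      variant_class = "silent"
    )
    mutations <- dplyr::arrange(dplyr::bind_rows(mut_rows, silent_rows),
                                .data$sample_id, .data$gene)

    # responses: IC50 = exp(y) over the full grid
    response <- tibble::tibble(
      sample_id = rep(sample_ids, each = cfg$n_drugs),
      drug_id = rep(rownames(fp), times = n),
      value = exp(as.numeric(t(y))),
      endpoint = "IC50"
    )

    # one treated drug per sample: BOR label and survival time off its y
    treated <- sample.int(cfg$n_drugs, n, replace = TRUE)
    y_treated <- y[cbind(seq_len(n), treated)]
    pd <- (y_treated + stats::rlogis(n, 0, cfg$bor_noise_scale)) > cfg$bor_threshold
    bor <- tibble::tibble(sample_id = sample_ids,
                          drug_id = rownames(fp)[treated],
                          value = ifelse(pd, "PD", "non-PD"),
                          endpoint = "BOR")
    log_hazard <- log(cfg$base_hazard) + cfg$hazard_coef * y_treated
    rate <- exp(log_hazard)
    t_event <- stats::rexp(n, rate)
    if (cfg$censoring_rate > 0) {
      m <- calibrate_censoring_horizon(rate, cfg$censoring_rate)
      t_cens <- stats::runif(n, 0, m)
    } else {
      t_cens <- rep(Inf, n)
    }
    survival <- tibble::tibble(
      patient_id = sample_ids,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      score = y_treated,
      drug_id = rownames(fp)[treated]
    )

    truth <- structure(list(U = U, V = V, W = W, Z = Z, P = P,
                            offsets = offsets, signal = signal,
                            log_hazard = log_hazard, treated = treated,
                            config = cfg),
                       class = "ttrec_truth")
    list(phenotype = phenotype, mutations = mutations, expression = expression,
         drugs = drugs, response = response, bor = bor, survival = survival,
         truth = truth)
  })
}

#' Noiseless generative score for a pair
#'
#' The oracle against which trained models are compared: the cohort's
#' hidden `U . V / sqrt(k)` plus the cancer-type offset for the sample.
#'
#' @param truth The `truth` component of [simulate_cohort()].
#' @param sample_id,drug_id Pair identifiers (vectorized, recycled).
#' @return Numeric noiseless response.
#' @export
truth_score <- function(truth, sample_id, drug_id) {
  stopifnot(inherits(truth, "ttrec_truth"))
  si <- match(sample_id, rownames(truth$U))
  di <- match(drug_id, colnames(truth$signal))
  if (anyNA(si)) abort(sprintf("unknown sample_id '%s'", sample_id[which(is.na(si))[1]]))
  if (anyNA(di)) abort(sprintf("unknown drug_id '%s'", drug_id[which(is.na(di))[1]]))
  truth$signal[cbind(si, di)]
}
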