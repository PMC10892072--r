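#' Bundled valid SMILES strings
#'
#' 150 syntactically valid SMILES spanning simple homologous series
#' (alkanes, alcohols, amines, acids, esters, aldehydes, ketones,
#' chlorides, nitriles, ethers) and benzene derivatives. They give the
#' synthetic generator chemically plausible text input for the
#' embedding pipeline without any chemistry dependency; no claim of
#' toxicological realism is attached to them.
#'
#' @return Character vector of 150 SMILES.
#' @export
smiles_bank <- function() {
  bank <- c(
    strrep("C", 1:20),                       # alkanes
    paste0(strrep("C", 1:20), "O"),          # alcohols
    paste0(strrep("C", 1:15), "N"),          # amines
    paste0(strrep("C", 1:15), "C(=O)O"),     # carboxylic acids
    paste0("CC(=O)O", strrep("C", 1:10)),    # acetate esters
    paste0(strrep("C", 1:10), "C=O"),        # aldehydes
    paste0("CC(=O)", strrep("C", 1:10)),     # methyl ketones
    paste0(strrep("C", 1:10), "Cl"),         # alkyl chlorides
    paste0(strrep("C", 1:10), "C#N"),        # nitriles
    paste0(strrep("C", 1:10), "OC"),         # methyl ethers
    paste0(strrep("C", 0:14), "c1ccccc1"),   # alkylbenzenes
    paste0("Oc1ccccc1", strrep("C", 0:4))    # phenols
  )
  bank[1:150]
}

#' Configuration of the synthetic substance generator
#'
#' Fixes the study conditions the generator emulates: an imbalanced
#' 6-category potency distribution matching the composition reported
#' for the emulated dataset's test set (collapsed 1A:1B:NC =
#' 0.2:0.48:0.32), assay readouts monotonically related to potency,
#' EC1.5 right-censored at 2000, correlated descriptor blocks and a
#' weak embedding-scalar signal.
#'
#' @param n Substance count; default 122 (the emulated dataset scale).
#' @param category_probs Probabilities over potency categories 1..6;
#'   must sum to 1. Default `c(0.10, 0.10, 0.24, 0.24, 0.16, 0.16)`.
#' @param effect Global effect-size multiplier (beta) coupling every
#'   readout to the latent potency score; 0 = pure noise. Default 2,
#'   a strong-signal regime in which the pipeline should recover the
#'   labels.
#' @param noise_sd Standard deviation of the latent-score noise;
#'   default 0.05 (small relative to the 1/6 gap between adjacent
#'   categories, so the strong-effect regime is clearly learnable:
#'   adjacent-category confusion at the hazard boundary is about 5%).
#' @param assay_noise_sd Noise on the assay-response scales; default 0.5.
#' @param missing_rate Per-assay probability of masking a readout in
#'   [inject_missing()]; default 0 (generation is complete; missingness
#'   is injected explicitly).
#' @param n_descriptors Number of descriptor columns; default 30.
#' @param n_corr_blocks Number of correlated descriptor blocks;
#'   default 3.
#' @param block_r Within-block correlation; default 0.85.
#' @param seed Integer seed (required at generation time).
#' @return A list of class `sens_synth_config`.
#' @export
synthetic_config <- function(n = 122,
                             category_probs = c(0.10, 0.10, 0.24, 0.24, 0.16, 0.16),
                             effect = 2,
                             noise_sd = 0.05,
                             assay_noise_sd = 0.5,
                             missing_rate = 0,
                             n_descriptors = 30,
                             n_corr_blocks = 3,
                             block_r = 0.85,
                             seed = NULL) {
  if (n < 1) abort("n must be positive", class = "skinsens_domain_error")
  if (length(category_probs) != 6 ||
      abs(sum(category_probs) - 1) > 1e-8 || any(category_probs < 0)) {
    abort("category_probs must be 6 non-negative values summing to 1",
          class = "skinsens_domain_error")
  }
  if (effect < 0) abort("effect must be >= 0", class = "skinsens_domain_error")
  if (missing_rate < 0 || missing_rate > 1) {
    abort("missing_rate must be in [0, 1]", class = "skinsens_domain_error")
  }
  if (block_r < 0 || block_r >= 1) {
    abort("block_r must be in [0, 1)", class = "skinsens_domain_error")
  }
  if (n_corr_blocks < 1 || n_descriptors < n_corr_blocks) {
    abort("need at least one descriptor per block", class = "skinsens_domain_error")
  }
  structure(list(
    n = as.integer(n), category_probs = category_probs, effect = effect,
    noise_sd = noise_sd, assay_noise_sd = assay_noise_sd,
    missing_rate = missing_rate, n_descriptors = as.integer(n_descriptors),
    n_corr_blocks = as.integer(n_corr_blocks), block_r = block_r, seed = seed
  ), class = "sens_synth_config")
}

#' Generate a synthetic substance table
#'
#' Draws `n` substances from a fixed generative model: a latent potency
#' score `u = (7 - category)/6 + N(0, noise_sd)` drives every readout
#' monotonically - EC1.5 falls with `u` (and is censored at 2000),
#' peptide depletions, the h-CLAT positive rate and the SENS-IS class
#' rise with `u`, the first descriptor block is shifted by `effect * u`,
#' and the embedding scalar carries a weak positive signal
#' `0.5 * effect * u + N(0, 1)`. SMILES strings are drawn from
#' [smiles_bank()]. Fully reproducible under the config seed.
#'
#' @param config A [synthetic_config()] with a non-`NULL` seed.
#' @return A substance tibble in the canonical schema (including a
#'   precomputed `roberta_embedding_mean` column and descriptor columns
#'   `phys01`, `phys02`, ...).
#' @export
#' @examples
#' d <- simulate_substances(synthetic_config(n = 10, seed = 1))
#' dplyr::glimpse(d)
simulate_substances <- function(config = synthetic_config(seed = 1)) {
  stopifnot(inherits(config, "sens_synth_config"))
  if (is.null(config$seed)) {
    abort("config$seed must be set for reproducible generation",
          class = "skinsens_domain_error")
  }
  set.seed(config$seed)
  n <- config$n
  beta <- config$effect

  category <- sample(1:6, n, replace = TRUE, prob = config$category_probs)
  u <- (7 - category) / 6 + rnorm(n, 0, config$noise_sd)

  ec15 <- pmin(2000, exp(8 - 4 * beta * u + rnorm(n, 0, config$assay_noise_sd)))
  dep_c <- 100 * stats::plogis(-3 + 6 * beta * u + rnorm(n, 0, config$assay_noise_sd))
  dep_k <- 100 * stats::plogis(-3 + 6 * beta * u + rnorm(n, 0, config$assay_noise_sd))
  hclat <- rbinom(n, 1, stats::plogis(-1 + 3 * beta * u))
  # SENS-IS latent: centered on the expected potency score so the class
  # carries label signal only through the effect multiplier (beta = 1
  # recovers plain u + noise); cut points straddle the center
  u_bar <- sum((7 - (1:6)) / 6 * config$category_probs)
  v <- u_bar + beta * (u - u_bar) + rnorm(n, 0, config$noise_sd)
  sensis <- cut(v, breaks = c(-Inf, 0.35, 0.55, 0.75, 0.90, Inf),
                labels = c("negative", "weak", "moderate", "strong", "extreme"))
  embedding <- 0.5 * beta * u + rnorm(n, 0, 1)

  out <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    name = sprintf("substance_%04d", seq_len(n)),
    smiles = sample(smiles_bank(), n, replace = TRUE),
    potency_category = as.integer(category),
    dpra_c_depletion = dep_c,
    dpra_k_depletion = dep_k,
    keratinosens_ec15 = ec15,
    hclat_positive = as.numeric(hclat),
    sensis_class = as.character(sensis),
    roberta_embedding_mean = embedding
  )

  # descriptor blocks: shared factor per block gives within-block
  # correlation block_r; only the first block carries label signal
  sizes <- diff(floor(seq(0, config$n_descriptors, length.out = config$n_corr_blocks + 1)))
  idx <- 0L
  for (b in seq_len(config$n_corr_blocks)) {
    f <- rnorm(n)
    for (j in seq_len(sizes[b])) {
      idx <- idx + 1L
      col <- sqrt(config$block_r) * f +
        sqrt(1 - config$block_r) * rnorm(n)
      if (b == 1) col <- col + beta * u
      out[[sprintf("phys%02d", idx)]] <- col
    }
  }
  if (config$missing_rate > 0) {
    out <- inject_missing(out, rates = config$missing_rate,
                          seed = config$seed + 555L)
  }
  validate_substances(out)
  out
}

#' Mask assay readouts at random
#'
#' Emulates sporadically missing in vitro results: each assay column is
#' masked independently per substance with its own Bernoulli rate. Ids
#' and all other columns are untouched.
#'
#' @param data Substance tibble.
#' @param rates Either a single rate applied to all assay columns or a
#'   named vector over any of `dpra_c_depletion`, `dpra_k_depletion`,
#'   `keratinosens_ec15`, `hclat_positive`, `sensis_class`.
#' @param seed Integer seed.
#' @return The masked tibble.
#' @export
inject_missing <- function(data, rates, seed) {
  assay_cols <- c("dpra_c_depletion", "dpra_k_depletion", "keratinosens_ec15",
                  "hclat_positive", "sensis_class")
  if (is.null(names(rates))) {
    if (length(rates) != 1) {
      abort("unnamed rates must be a single value", class = "skinsens_domain_error")
    }
    rates <- setNames(rep(rates, length(assay_cols)), assay_cols)
  }
  stray <- setdiff(names(rates), assay_cols)
  if (length(stray) > 0) {
    abort(paste0("unknown assay column(s): ", paste(stray, collapse = ", ")),
          class = "skinsens_schema_error")
  }
  if (any(rates < 0 | rates > 1)) {
    abort("rates must be in [0, 1]", class = "skinsens_domain_error")
  }
  set.seed(seed)
  for (col in names(rates)) {
    if (!col %in% names(data)) next
    mask <- runif(nrow(data)) < rates[[col]]
    data[[col]][mask] <- if (is.character(data[[col]])) NA_character_ else NA_real_
  }
  data
}
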