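#' Deterministic fallback embedding provider
#'
#' Stand-in for a pretrained chemical language model: each SMILES
#' string is split into overlapping character trigrams (one token per
#' trigram), and every token is mapped to a `dim`-dimensional row of
#' unit-interval reals through a fixed integer hash scrambled by two
#' Lehmer rounds. The output is bit-identical across platforms for a
#' given `seed_salt` (all arithmetic stays below 2^53, exact in
#' doubles), requires no network access, and is not a chemical model.
#'
#' @param dim Hidden dimension of each token row; default 768 to match
#'   the pretrained backend's geometry.
#' @param seed_salt Integer mixed into the hash so alternative feature
#'   universes can be generated.
#' @return A provider: `function(smiles) -> tokens x dim matrix`.
#' @export
#' @examples
#' p <- fallback_provider(dim = 8)
#' dim(p("CCO"))  # 1 trigram token x 8
fallback_provider <- function(dim = 768, seed_salt = 0L) {
  if (dim < 1) abort("dim must be >= 1", class = "skinsens_domain_error")
  force(seed_salt)
  f <- function(smiles) {
    if (length(smiles) != 1 || is.na(smiles) || nchar(smiles) == 0) {
      abort("SMILES must be a non-empty string", class = "skinsens_domain_error")
    }
    tokens <- smiles_trigrams(smiles)
    M <- 2147483647  # 2^31 - 1
    out <- matrix(0, nrow = length(tokens), ncol = dim)
    for (t in seq_along(tokens)) {
      bytes <- utf8ToInt(tokens[t])
      h <- 17
      for (b in bytes) h <- (h * 31 + b) %% M
      for (j in seq_len(dim)) {
        x <- (h + j * 2654435 + (seed_salt %% M) * 97) %% M
        x <- (x * 48271) %% M  # Lehmer round 1
        x <- (x * 48271) %% M  # Lehmer round 2
        out[t, j] <- x / M
      }
    }
    out
  }
  structure(f, backend = paste0("trigram_hash_fallback/dim=", dim,
                                "/salt=", seed_salt))
}

smiles_trigrams <- function(smiles) {
  n <- nchar(smiles)
  if (n < 3) return(smiles)
  vapply(seq_len(n - 2L), function(i) substr(smiles, i, i + 2L), character(1))
}

#' Provider slot for a pretrained chemical language model
#'
#' The package consumes token-level embeddings through a provider
#' contract (`function(smiles) -> tokens x hidden matrix`). A
#' pretrained transformer backend (tokenizer and checkpoint pinned by
#' the caller) can be plugged in here, e.g. via reticulate; embeddings
#' are checkpoint-dependent, so `backend_id` is recorded with every
#' feature table. When no embed function is supplied the provider
#' fails loudly rather than silently falling back.
#'
#' @param embed_fn Function taking one SMILES string and returning the
#'   last-hidden-layer matrix (tokens x hidden), or `NULL`.
#' @param backend_id Identifier (e.g. checkpoint name) recorded as the
#'   provider's provenance.
#' @return A provider function with a `backend` attribute.
#' @export
chem_lm_provider <- function(embed_fn = NULL, backend_id = "pretrained_chem_lm") {
  f <- function(smiles) {
    if (is.null(embed_fn)) {
      abort(paste0("pretrained backend '", backend_id,
                   "' not resolvable: supply embed_fn"),
            class = "skinsens_backend_error")
    }
    out <- embed_fn(smiles)
    if (!is.matrix(out) || nrow(out) < 1 || !all(is.finite(out))) {
      abort(paste0("backend '", backend_id,
                   "' returned an invalid embedding matrix"),
            class = "skinsens_backend_error")
    }
    out
  }
  structure(f, backend = backend_id)
}

#' Scalar SMILES feature by mean pooling
#'
#' Runs the provider on one SMILES and returns the grand mean over all
#' token positions and hidden dimensions of the last-hidden-layer
#' matrix (mean over tokens, then over dimensions - identical to the
#' grand mean). This single scalar is the `roberta_embedding_mean`
#' feature used downstream.
#'
#' @param smiles A non-empty SMILES string.
#' @param provider An embedding provider, e.g. [fallback_provider()].
#' @return A single numeric value.
#' @export
#' @examples
#' smiles_scalar_feature("CCO", fallback_provider(dim = 16))
smiles_scalar_feature <- function(smiles, provider = fallback_provider()) {
  if (length(smiles) != 1 || is.na(smiles) || nchar(smiles) == 0) {
    abort("SMILES must be a non-empty string", class = "skinsens_domain_error")
  }
  emb <- provider(smiles)
  if (!is.matrix(emb) || nrow(emb) < 1) {
    abort("provider must return a matrix with at least one token row",
          class = "skinsens_backend_error")
  }
  if (!all(is.finite(emb))) {
    abort("provider returned non-finite embedding values",
          class = "skinsens_backend_error")
  }
  mean(emb)
}

#' Embed every substance and cache the scalars
#'
#' Computes the embedding scalar for each SMILES and returns a feature
#' cache recording the backend identity, so downstream stages never
#' re-embed. Optionally writes the cache as CSV.
#'
#' @param data Substance tibble.
#' @param provider Embedding provider.
#' @param cache_path Optional CSV path for the cache.
#' @return Tibble: `id`, `smiles`, `backend`, `roberta_embedding_mean`.
#' @export
embed_substances <- function(data, provider = fallback_provider(),
                             cache_path = NULL) {
  backend <- attr(provider, "backend") %||% "custom"
  out <- tibble::tibble(
    id = data$id,
    smiles = data$smiles,
    backend = backend,
    roberta_embedding_mean = vapply(data$smiles, smiles_scalar_feature,
                                    numeric(1), provider = provider,
                                    USE.NAMES = FALSE)
  )
  if (!is.null(cache_path)) readr::write_csv(out, cache_path, progress = FALSE)
  out
}
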