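#' Deterministic character-trigram name embedder
#'
#' Embeds a name as an L2-normalized bag of hashed character trigrams of its
#' normalized form (padded with boundary markers). Fully deterministic, needs
#' no model weights, and satisfies the name-embedder contract: identical input
#' gives an identical vector, and the cosine similarity of a name with itself
#' is 1. A pretrained clinical language model can be plugged in through the
#' same interface (any object with an [embed_names()] method).
#'
#' @param dim Embedding dimension (number of hash buckets); default 512.
#' @return An object of class `c("trigram_embedder", "name_embedder")`.
#' @export
#' @examples
#' e <- trigram_embedder()
#' emb <- embed_names(e, c("asthma", "asthma", "psoriasis"))
#' sum(emb[1, ] * emb[2, ]) # 1: identical names
trigram_embedder <- function(dim = 512) {
  structure(
    list(dim = as.integer(dim), model_tag = paste0("trigram-hash-", dim)),
    class = c("trigram_embedder", "name_embedder")
  )
}

#' Embed names with a name embedder
#'
#' @param embedder A name embedder, e.g. [trigram_embedder()].
#' @param names Character vector of names.
#' @return A numeric matrix with one L2-normalized row per name.
#' @export
embed_names <- function(embedder, names) {
  UseMethod("embed_names")
}

#' @export
embed_names.trigram_embedder <- function(embedder, names) {
  dim <- embedder$dim
  out <- matrix(0, nrow = length(names), ncol = dim)
  for (i in seq_along(names)) {
    s <- paste0("^", normalize_name(names[i]), "$")
    codes <- utf8ToInt(s)
    n <- length(codes)
    if (n < 3) {
      tri_hash <- (sum(codes * c(31L, 7L, 1L)[seq_len(n)])) %% dim
      out[i, tri_hash + 1] <- 1
    } else {
      v <- numeric(dim)
      for (k in seq_len(n - 2)) {
        h <- ((codes[k] * 31L + codes[k + 1]) * 31L + codes[k + 2]) %% dim
        v[h + 1] <- v[h + 1] + 1
      }
      nrm <- sqrt(sum(v^2))
      out[i, ] <- v / nrm
    }
  }
  out
}

#' @export
print.name_embedder <- function(x, ...) {
  cat("<name embedder>", x$model_tag, "\n")
  invisible(x)
}
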