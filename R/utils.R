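#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard amino acids, in lexicographic order.
#' Together with the edge symbol \code{"#"} these define the k-mer pattern
#' alphabet.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Edge (boundary) symbol used for k-mer padding
#' @export
EDGE_SYMBOL <- "#"

#' Derive a reproducible child seed from a master seed and context labels
#'
#' Deterministic polynomial string hash, used so that every learning trial,
#' augmentation pass and subsample gets an independent but reproducible
#' random stream from one master seed.
#'
#' @param master integer master seed.
#' @param ... context values (coerced to character), e.g. method name,
#'   training size, trial index.
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "|")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% m
  as.integer(h %% (m - 1L)) + 1L
}

## Evaluate `code` under a temporary RNG seed, restoring the caller's
## RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
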