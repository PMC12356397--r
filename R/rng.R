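#' Derive a reproducible substream seed
#'
#' All randomness in the pipeline flows from a single root seed via named
#' substreams (per participant, per block), so that e.g. changing the cohort
#' size does not reshuffle earlier participants.  Components may be numbers
#' or strings; the result is a deterministic integer in `[1, 2^31 - 2]`.
#'
#' @param root integer root seed.
#' @param ... stream components (numbers or strings).
#' @return Integer seed.
#' @export
substream_seed <- function(root, ...) {
  s <- as.double(root) %% 2147483647
  for (part in list(...)) {
    if (is.character(part)) {
      h <- 0
      for (ch in utf8ToInt(paste(part, collapse = "/"))) {
        h <- (h * 131 + ch) %% 1000003
      }
      part <- h
    }
    s <- (s * 69069 + as.double(part) + 1) %% 2147483647
  }
  as.integer(s + 1)
}
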