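#' Construct the external-noise ladder
#'
#' The experiment's independent variable is the standard deviation sigma of
#' zero-mean Gaussian pixel noise (grey-level units on a 0-255 scale).  The
#' ladder is a leading zero level followed by `n_nonzero` geometrically
#' spaced levels from `sigma_min` to `sigma_max` inclusive (equal spacing in
#' log space).
#'
#' @param sigma_min smallest nonzero sigma (> 0).
#' @param sigma_max largest sigma (> `sigma_min`).
#' @param n_nonzero number of nonzero levels (integer >= 2).
#' @return Numeric vector `c(0, sigma_min, ..., sigma_max)` of length
#'   `n_nonzero + 1`.
#' @examples
#' round(make_noise_ladder(0.25, 64, 6), 2)  # 0 0.25 0.76 2.30 6.96 21.11 64
#' @export
make_noise_ladder <- function(sigma_min = 0.25, sigma_max = 64,
                              n_nonzero = 6L) {
  if (!is.numeric(sigma_min) || length(sigma_min) != 1L || sigma_min <= 0) {
    stop("'sigma_min' must be a single positive number")
  }
  if (!is.numeric(sigma_max) || length(sigma_max) != 1L ||
      sigma_max <= sigma_min) {
    stop("'sigma_max' must be a single number > sigma_min")
  }
  n_nonzero <- as.integer(n_nonzero)
  if (is.na(n_nonzero) || n_nonzero < 2L) {
    stop("'n_nonzero' must be an integer >= 2")
  }
  c(0, exp(seq(log(sigma_min), log(sigma_max), length.out = n_nonzero)))
}

#' Generate a Gaussian pixel-noise field
#'
#' Independent zero-mean Gaussian deviates with standard deviation `sigma`
#' at every pixel.  `sigma = 0` returns an all-zero field.
#'
#' @param sigma noise standard deviation (grey-level units, >= 0).
#' @param shape integer vector `c(rows, cols)`.
#' @param seed optional integer; when supplied the global RNG is seeded so
#'   the field is reproducible.
#' @return Numeric `rows x cols` matrix.
#' @export
generate_noise_field <- function(sigma, shape = c(100L, 100L), seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("'sigma' must be a single non-negative number")
  }
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (sigma == 0) {
    return(matrix(0, shape[1L], shape[2L]))
  }
  matrix(stats::rnorm(prod(shape), mean = 0, sd = sigma),
         shape[1L], shape[2L])
}

#' Compose the noisy frames of one stimulus presentation
#'
#' Each frame is `clip(background + increment * mask + noise, 0, 255)` with a
#' fresh noise field per frame (the display refreshes the noise at 60 Hz, so
#' a 1 s presentation is 60 frames).  With `sigma = 0` all frames are
#' identical.
#'
#' @param template a `letter_template` (tight or field-embedded mask).
#' @param letter_increment letter luminance increment above background
#'   (grey-level units); `background + letter_increment` must lie in
#'   `[0, 255]`.
#' @param sigma noise standard deviation (>= 0).
#' @param n_frames number of frames (>= 1; default 60, i.e. 1 s at 60 Hz).
#' @param background background grey level (default 127).
#' @param field edge length of the square stimulus field the mask is
#'   embedded in (default 100).
#' @param seed optional integer RNG seed for reproducible noise.
#' @return Object of class `stimulus_frames`: list with `frames`
#'   (`field x field x n_frames` array clipped to `[0, 255]`), `background`,
#'   `increment`, `sigma` and `mask` (the embedded letter mask).
#' @export
compose_trial_frames <- function(template, letter_increment, sigma,
                                 n_frames = 60L, background = 127,
                                 field = 100L, seed = NULL) {
  stopifnot(inherits(template, "letter_template"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("'n_frames' must be >= 1")
  if (!is.numeric(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  lum <- background + letter_increment
  if (lum < 0 || lum > 255) {
    stop("background + letter_increment must lie in [0, 255], got ", lum)
  }
  mask <- template$mask
  if (!all(dim(mask) == c(field, field))) mask <- embed_mask(mask, field)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sig <- background + letter_increment * mask
  frames <- array(0, dim = c(field, field, n_frames))
  for (k in seq_len(n_frames)) {
    fr <- if (sigma > 0) sig + generate_noise_field(sigma, c(field, field))
          else sig
    frames[, , k] <- pmin(pmax(fr, 0), 255)
  }
  structure(
    list(frames = frames, background = background,
         increment = letter_increment, sigma = sigma, mask = mask),
    class = "stimulus_frames"
  )
}

#' @export
print.stimulus_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<stimulus_frames %dx%d, %d frame(s), sigma=%.3g, increment=%.3g>\n",
    d[1L], d[2L], d[3L], x$sigma, x$increment))
  invisible(x)
}
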