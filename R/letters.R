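#' The six-letter stimulus set
#'
#' The paradigm uses three consonants (C, B, H) and three vowels (O, E, U),
#' chosen so that each letter's most confusable neighbour lies in the
#' opposite category (C with O, B with E, H with U).  `letter_set()` returns
#' the letters in canonical order; `letter_category()` maps letters to their
#' category.
#'
#' @return `letter_set()`: character vector of the six letters.
#' @export
letter_set <- function() c("C", "B", "H", "O", "E", "U")

.letter_categories <- c(
  C = "consonant", B = "consonant", H = "consonant",
  O = "vowel", E = "vowel", U = "vowel"
)

#' @rdname letter_set
#' @param letter character vector of letters from the stimulus set.
#' @return `letter_category()`: character vector, `"consonant"` or `"vowel"`.
#' @export
letter_category <- function(letter) {
  bad <- setdiff(unique(letter), names(.letter_categories))
  if (length(bad) > 0L) {
    stop("unknown letter(s): ", paste(bad, collapse = ", "),
         "; stimulus set is ", paste(letter_set(), collapse = ", "))
  }
  unname(.letter_categories[letter])
}

# Block-stroke glyphs on a 5x5 grid, in the style of the 5x5 stroke lattice
# used by acuity optotypes.  Strokes are placed so that each letter's nearest
# neighbour by pixel overlap (Jaccard) is its cross-category confusion
# partner: C-O, B-E, H-U.
.glyphs5 <- list(
  C = c("01110",
        "10000",
        "10000",
        "10000",
        "01110"),
  B = c("11100",
        "10010",
        "11100",
        "10010",
        "11100"),
  H = c("10001",
        "10001",
        "11111",
        "10001",
        "10001"),
  O = c("01110",
        "10001",
        "10001",
        "10001",
        "01110"),
  E = c("11110",
        "10000",
        "11100",
        "10000",
        "11110"),
  U = c("10001",
        "10001",
        "10001",
        "10001",
        "11111")
)

.glyph_matrix <- function(letter) {
  rows <- .glyphs5[[letter]]
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
}

#' Render a deterministic bitmap letter template
#'
#' Scales the 5x5 stroke glyph of `letter` up to a square bitmap whose tight
#' bounding box is `glyph_height_px` pixels tall.  Templates are fully
#' deterministic; the same letter and height always produce the same mask.
#'
#' @param letter one of C, B, H, O, E, U.
#' @param glyph_height_px integer target glyph height in pixels (>= 8).
#' @return An object of class `letter_template`: a list with elements
#'   `letter`, `category`, `mask` (binary integer matrix, row-major, origin
#'   top-left) and `glyph_height_px`.
#' @examples
#' tpl <- render_letter_template("O", 85)
#' dim(tpl$mask)
#' @export
render_letter_template <- function(letter, glyph_height_px = 85L) {
  if (length(letter) != 1L || !letter %in% letter_set()) {
    stop("'letter' must be one of ", paste(letter_set(), collapse = ", "))
  }
  glyph_height_px <- as.integer(glyph_height_px)
  if (is.na(glyph_height_px) || glyph_height_px < 8L) {
    stop("'glyph_height_px' must be an integer >= 8")
  }
  m5 <- .glyph_matrix(letter)
  # split the target height into 5 near-equal stroke bands
  cuts <- round(seq(0, glyph_height_px, length.out = 6L))
  reps <- diff(cuts)
  mask <- m5[rep(seq_len(5L), reps), rep(seq_len(5L), reps), drop = FALSE]
  structure(
    list(letter = letter,
         category = letter_category(letter),
         mask = mask,
         glyph_height_px = glyph_height_px),
    class = "letter_template"
  )
}

#' @export
print.letter_template <- function(x, ...) {
  cat(sprintf("<letter_template '%s' (%s), %dx%d mask, %d ink pixels>\n",
              x$letter, x$category, nrow(x$mask), ncol(x$mask),
              sum(x$mask)))
  invisible(x)
}

#' Jaccard pixel overlap of two letter templates
#'
#' @param a,b `letter_template` objects of equal mask size.
#' @return Overlap in `[0, 1]`: intersection over union of ink pixels.
#' @export
template_overlap <- function(a, b) {
  stopifnot(inherits(a, "letter_template"), inherits(b, "letter_template"),
            all(dim(a$mask) == dim(b$mask)))
  sum(a$mask & b$mask) / sum(a$mask | b$mask)
}

#' Embed a glyph mask centred in a square stimulus field
#'
#' @param mask binary matrix (glyph bounding box).
#' @param field integer edge length of the square field (default 100).
#' @return Binary integer matrix `field x field`.
#' @export
embed_mask <- function(mask, field = 100L) {
  field <- as.integer(field)
  if (nrow(mask) > field || ncol(mask) > field) {
    stop("mask does not fit in a ", field, "x", field, " field")
  }
  out <- matrix(0L, field, field)
  r0 <- (field - nrow(mask)) %/% 2L
  c0 <- (field - ncol(mask)) %/% 2L
  out[r0 + seq_len(nrow(mask)), c0 + seq_len(ncol(mask))] <- mask
  out
}

#' All six letter templates embedded in the stimulus field
#'
#' Convenience constructor used by the synthetic observer: renders every
#' letter at the same glyph height and embeds each mask centred in the
#' `field x field` stimulus square.
#'
#' @inheritParams render_letter_template
#' @inheritParams embed_mask
#' @return Named list of `letter_template` objects (masks are field-sized).
#' @export
letter_templates <- function(glyph_height_px = 85L, field = 100L) {
  out <- lapply(letter_set(), function(l) {
    tpl <- render_letter_template(l, glyph_height_px)
    tpl$mask <- embed_mask(tpl$mask, field)
    tpl
  })
  names(out) <- letter_set()
  out
}

#' Template pixel matrix for evidence computation
#'
#' Stacks the six embedded letter masks as columns of a
#' `field^2 x 6` matrix (canonical letter order), the form consumed by
#' [letter_evidence()].
#'
#' @param templates list returned by [letter_templates()].
#' @return Numeric matrix with one column per letter.
#' @export
template_matrix <- function(templates = letter_templates()) {
  m <- vapply(templates[letter_set()], function(t) as.numeric(t$mask),
              numeric(length(templates[[1L]]$mask)))
  colnames(m) <- letter_set()
  m
}
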