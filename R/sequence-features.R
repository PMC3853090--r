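#' Build a positional weighted matrix from sequence windows
#'
#' The PWM records, for each window column, the relative frequency of each
#' of the 21 alphabet letters (20 amino acids plus the terminal symbol).
#' It is conventionally estimated from the positive (substrate-site)
#' windows only and then used to encode both classes.
#'
#' @param windows Character vector of equal-width window strings.
#' @param pseudocount Added to every cell count before normalisation
#'   (default 0); each column then sums to 1 exactly.
#' @return Object of class `pwm`: a 21 x w numeric matrix of column-wise
#'   relative frequencies, rows named by [ALPHABET21].
#' @export
build_pwm <- function(windows, pseudocount = 0) {
  if (!length(windows)) stop("cannot build a PWM from zero windows",
                             call. = FALSE)
  widths <- nchar(windows)
  if (length(unique(widths)) != 1L) {
    stop("all windows must have the same width", call. = FALSE)
  }
  w <- widths[1]
  n <- length(windows)
  mat <- matrix(pseudocount, nrow = length(ALPHABET21), ncol = w,
                dimnames = list(ALPHABET21, NULL))
  for (j in seq_len(w)) {
    col <- substring(windows, j, j)
    bad <- setdiff(unique(col), ALPHABET21)
    if (length(bad)) {
      stop("letter(s) outside the 21-letter alphabet in column ", j, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab <- table(factor(col, levels = ALPHABET21))
    mat[, j] <- mat[, j] + as.numeric(tab)
  }
  freq <- mat / (n + length(ALPHABET21) * pseudocount)
  class(freq) <- c("pwm", class(freq))
  freq
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d x %d positional frequency matrix\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Encode a window with a positional weighted matrix
#'
#' Each window letter is replaced by its positional relative frequency in
#' the PWM, giving a length-w numeric vector.
#'
#' @param window Window string, same width as the PWM.
#' @param pwm A [build_pwm()] matrix.
#' @return Numeric vector of length `ncol(pwm)`.
#' @export
encode_window_pwm <- function(window, pwm) {
  wl <- seq_chars(window)
  if (length(wl) != ncol(pwm)) {
    stop("window width ", length(wl), " does not match PWM width ",
         ncol(pwm), call. = FALSE)
  }
  idx <- match(wl, rownames(pwm))
  if (anyNA(idx)) {
    stop("window letter(s) outside the PWM alphabet: ",
         paste(unique(wl[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  pwm[cbind(idx, seq_along(wl))]
}

#' Amino acid composition of a window
#'
#' Relative frequency of each of the 20 amino acid types among the window's
#' non-terminal letters; sums to 1.
#'
#' @param window Window string over the 21-letter alphabet.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(window) {
  wl <- seq_chars(window)
  wl <- wl[wl != TERMINAL_SYMBOL]
  if (!length(wl)) stop("window contains only terminal symbols",
                        call. = FALSE)
  bad <- setdiff(unique(wl), AA20)
  if (length(bad)) stop("illegal letter(s) in window: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- as.numeric(table(factor(wl, levels = AA20))) / length(wl)
  names(out) <- AA20
  out
}

# Look up per-position annotation values around a site. `annotations` is the
# per-protein slice of an annotation table (columns position, asa_rel, ss3).
annotation_at <- function(annotations, positions, column) {
  idx <- match(positions, annotations$position)
  annotations[[column]][idx]
}

#' Encode the relative solvent accessibility window around a site
#'
#' @param annotations Annotation rows for the site's protein (columns
#'   `position`, `asa_rel`, `ss3`).
#' @param position 1-based site position.
#' @param flank Window flank (default 6).
#' @return Numeric vector of length `2 * flank + 1`; offsets outside the
#'   protein (or without an annotation) encode as 0.
#' @export
encode_asa_window <- function(annotations, position, flank = 6L) {
  offsets <- (position - flank):(position + flank)
  vals <- annotation_at(annotations, offsets, "asa_rel")
  vals[is.na(vals)] <- 0
  vals
}

#' Encode the secondary structure window around a site
#'
#' One-hot triplet (H, E, C order) per window offset.
#'
#' @inheritParams encode_asa_window
#' @return Numeric vector of length `3 * (2 * flank + 1)`; out-of-range
#'   offsets give an all-zero triplet.
#' @export
encode_ss_window <- function(annotations, position, flank = 6L) {
  offsets <- (position - flank):(position + flank)
  ss <- annotation_at(annotations, offsets, "ss3")
  out <- numeric(3L * length(offsets))
  states <- c("H", "E", "C")
  for (k in seq_along(offsets)) {
    hit <- match(ss[k], states)
    if (!is.na(hit)) out[3L * (k - 1L) + hit] <- 1
  }
  out
}

#' Feature-set presets
#'
#' Block composition of the three model flavours: sequence information only,
#' structural information only, or their combination.
#'
#' @param preset One of `"sequence_only"`, `"structure_only"`, `"combined"`.
#' @return Character vector of block names in canonical order.
#' @export
preset_blocks <- function(preset = c("sequence_only", "structure_only",
                                     "combined")) {
  preset <- match.arg(preset)
  switch(preset,
         sequence_only = c("pwm", "aac", "asa", "ss"),
         structure_only = "spatial",
         combined = c("pwm", "aac", "asa", "ss", "spatial"))
}

#' Assemble named feature blocks into a single feature vector
#'
#' Blocks are concatenated in the canonical order pwm, aac, asa, ss,
#' spatial; the block layout is recorded in the `"blocks"` attribute so
#' downstream models can verify schemas.
#'
#' @param blocks Named list of numeric vectors (a subset of the canonical
#'   block names).
#' @param preset Optional preset name; when given, exactly the preset's
#'   blocks must be present.
#' @return Named numeric vector with a `"blocks"` attribute (named integer
#'   vector of block lengths).
#' @export
assemble_features <- function(blocks, preset = NULL) {
  canonical <- c("pwm", "aac", "asa", "ss", "spatial")
  unknown <- setdiff(names(blocks), canonical)
  if (length(unknown)) stop("unknown feature block(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(preset)) {
    need <- preset_blocks(preset)
    missing <- setdiff(need, names(blocks))
    if (length(missing)) {
      stop("preset '", preset, "' requires missing block(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    blocks <- blocks[need]
  } else {
    blocks <- blocks[intersect(canonical, names(blocks))]
  }
  lens <- vapply(blocks, length, 0L)
  out <- unlist(blocks, use.names = FALSE)
  if (!all(is.finite(out))) stop("non-finite feature values", call. = FALSE)
  names(out) <- unlist(lapply(names(blocks), function(b) {
    paste0(b, ".", seq_len(lens[[b]]))
  }))
  attr(out, "blocks") <- lens
  out
}
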