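#' Amino acid alphabets and the maximum accessible surface area table
#'
#' `AA20` is the 20 standard one-letter amino acid codes (alphabetical).
#' `ALPHABET21` appends the terminal symbol `"-"` used to pad sequence
#' windows that run past a protein end. `MAX_ASA` is the per-residue
#' theoretical maximum accessible surface area in squared Angstroms
#' (Tien et al. 2013), used to normalise absolute ASA to relative ASA
#' in `[0, 1]`.
#'
#' @format `AA20`: character vector of length 20. `ALPHABET21`: character
#'   vector of length 21. `MAX_ASA`: named numeric vector of length 20.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname alphabets
#' @export
TERMINAL_SYMBOL <- "-"

#' @rdname alphabets
#' @export
ALPHABET21 <- c(AA20, TERMINAL_SYMBOL)

#' @rdname alphabets
#' @export
MAX_ASA <- c(
  A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224,
  I = 197, K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225,
  R = 274, S = 155, T = 172, V = 174, W = 285, Y = 263
)

#' Default radial distances for spatial amino acid composition
#'
#' Integer radii from 3 to 12 Angstroms around the phosphoacceptor.
#' @export
DEFAULT_RADII <- 3:12

# Split a sequence string into single letters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Validate a protein sequence against the 20-letter alphabet.
check_aa_sequence <- function(sequence, id = "<protein>") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("protein '", id, "': sequence must be a non-empty string", call. = FALSE)
  }
  letters <- seq_chars(sequence)
  bad <- which(!letters %in% AA20)
  if (length(bad)) {
    stop("protein '", id, "': illegal residue code(s) ",
         paste0("'", unique(letters[bad]), "'", collapse = ", "),
         " at position(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
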