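#' @keywords internal
#' @importFrom stats qchisq runif sd setNames
#' @importFrom utils head read.table write.table
"_PACKAGE"

# Standard 20-letter amino-acid alphabet, fixed order used throughout.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

# Pad character for windows overhanging protein termini.
PAD_CHAR <- "X"

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' library functions do not perturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Split windows into a character matrix
#'
#' @param windows character vector of equal-length window strings.
#' @return matrix of single characters, one row per window.
#' @keywords internal
window_matrix <- function(windows) {
  if (length(windows) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  len <- unique(nchar(windows))
  if (length(len) != 1L) {
    stop("all windows must have the same length")
  }
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = len, byrow = TRUE)
}

# Flank coordinates -w..+w for a window of length 2w+1 (0 = site).
flank_coords <- function(w) seq.int(-w, w)

# Column index inside a window for flank coordinate p.
flank_col <- function(p, w) p + w + 1L

# Half-window from a window length, erroring on even lengths.
half_window <- function(window_length) {
  if (window_length %% 2L == 0L) stop("window length must be odd")
  (window_length - 1L) %/% 2L
}

#' An empty fragment table
#' @keywords internal
empty_fragments <- function() {
  data.frame(protein_id = character(0), position = integer(0),
             residue = character(0), window = character(0),
             label = character(0), stringsAsFactors = FALSE)
}
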