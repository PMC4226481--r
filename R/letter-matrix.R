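#' The 6 x 6 speller letter matrix
#'
#' Builds the standard 36-symbol speller matrix: the letters A--Z, the digits
#' 1--9 and the underscore, filled row-major into a 6 x 6 grid. Rows and
#' columns are 0-based.
#'
#' @return A tibble with columns `symbol`, `row`, `col` (one row per cell,
#'   in row-major order).
#' @examples
#' letter_matrix()
#' @export
letter_matrix <- function() {
  symbols <- c(LETTERS, as.character(1:9), "_")
  tibble::tibble(
    symbol = symbols,
    row = rep(0:5, each = 6),
    col = rep(0:5, times = 6)
  )
}

#' Look up symbol positions in a letter matrix
#'
#' @param matrix A letter matrix as returned by [letter_matrix()].
#' @param symbols Character vector of symbols to look up.
#' @return A tibble with columns `symbol`, `row`, `col`, one row per element
#'   of `symbols`, in their order.
#' @export
symbol_positions <- function(matrix, symbols) {
  idx <- match(symbols, matrix$symbol)
  if (anyNA(idx)) {
    stop("symbol(s) not in matrix: ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  matrix[idx, , drop = FALSE]
}

assert_letter_matrix <- function(matrix) {
  stopifnot(is.data.frame(matrix),
            all(c("symbol", "row", "col") %in% names(matrix)))
  if (nrow(matrix) != 36L || anyDuplicated(matrix$symbol) > 0L) {
    stop("letter matrix must contain 36 unique symbols")
  }
  cells <- paste(matrix$row, matrix$col)
  if (anyDuplicated(cells) > 0L || !all(matrix$row %in% 0:5) ||
      !all(matrix$col %in% 0:5)) {
    stop("letter matrix must be a bijection onto the 6 x 6 grid")
  }
  invisible(matrix)
}
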