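#' @keywords internal
"_PACKAGE"

# Round half away from zero (the rendering used in the printed tables, where
# e.g. 79.56 -> 79.6), as opposed to base round()'s round-half-even.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("'%s' must be TRUE or FALSE", nm)
  x
}

check_count <- function(x, nm, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stopf("'%s' must be a single integer >= %d", nm, min)
  }
  as.integer(x)
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("'%s' must be a probability in [0, 1]", nm)
  }
  as.numeric(x)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Convert a 0-based (row, col) well to a plate label such as "A01"
#'
#' Rows map to letters (row 0 = "A") and columns to zero-padded 1-based
#' numbers, the usual microtitre-plate convention.
#'
#' @param row,col integer vectors, 0-based.
#' @return character vector of well labels.
#' @export
well_label <- function(row, col) {
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

#' Parse plate well labels such as "A01" back to 0-based (row, col)
#'
#' @param label character vector of well labels.
#' @return data.frame with integer columns `row` and `col` (0-based).
#' @export
parse_well <- function(label) {
  ok <- grepl("^[A-Z][0-9]{1,2}$", label)
  if (!all(ok)) stopf("malformed well label(s): %s", paste(label[!ok], collapse = ", "))
  data.frame(
    row = match(substr(label, 1L, 1L), LETTERS) - 1L,
    col = as.integer(substr(label, 2L, nchar(label))) - 1L
  )
}
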