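#' Compile a position-wise residue-class pattern
#'
#' Patterns use the compact bracket syntax of the SDP table: a bare uppercase
#' letter is a singleton class, a square-bracket group (e.g. `[AGI]`) is the
#' class of its letters. `"[AGI][ISV][GA]R"` compiles to four classes of
#' sizes 3, 3, 2, 1.
#'
#' @param pattern_string Pattern string of uppercase residues and bracket
#'   groups.
#' @return A list of character vectors, one residue class per position.
#' @export
compile_pattern <- function(pattern_string) {
  if (!is.character(pattern_string) || length(pattern_string) != 1 ||
      is.na(pattern_string) || !nzchar(pattern_string)) {
    abort("Pattern must be a non-empty string.", class = "aqpkit_syntax_error")
  }
  chars <- seq_chars(pattern_string)
  classes <- list()
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      group <- character(0)
      while (j <= n && chars[j] != "]") {
        group <- c(group, chars[j])
        j <- j + 1
      }
      if (j > n) {
        abort(sprintf("Unbalanced '[' in pattern '%s'.", pattern_string),
              class = "aqpkit_syntax_error")
      }
      if (length(group) == 0) {
        abort(sprintf("Empty residue class in pattern '%s'.", pattern_string),
              class = "aqpkit_syntax_error")
      }
      classes[[length(classes) + 1]] <- group
      i <- j + 1
    } else if (ch == "]") {
      abort(sprintf("Unbalanced ']' in pattern '%s'.", pattern_string),
            class = "aqpkit_syntax_error")
    } else {
      classes[[length(classes) + 1]] <- ch
      i <- i + 1
    }
  }
  bad <- setdiff(unlist(classes), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("Invalid residue(s) %s in pattern '%s'.",
                  paste0("'", bad, "'", collapse = ", "), pattern_string),
          class = "aqpkit_syntax_error")
  }
  classes
}

#' Match a residue string against compiled residue classes
#'
#' @param residues Residue string, same length as `classes`.
#' @param classes Compiled pattern, as from [compile_pattern()].
#' @return A list with `match` (logical) and `first_fail` (1-based index of
#'   the first failing position, `NA` on a match).
#' @export
match_component <- function(residues, classes) {
  chars <- seq_chars(residues)
  if (length(chars) != length(classes)) {
    abort(sprintf("Residue string length %d does not match pattern length %d.",
                  length(chars), length(classes)),
          class = "aqpkit_input_error")
  }
  ok <- purrr::map2_lgl(chars, classes, ~ .x %in% .y)
  if (all(ok)) {
    list(match = TRUE, first_fail = NA_integer_)
  } else {
    list(match = FALSE, first_fail = which(!ok)[1])
  }
}
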