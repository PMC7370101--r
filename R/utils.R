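# Shared constants and small helpers.

# 20-letter amino-acid alphabet; X is tolerated in input sequences but never
# generated, and flags approximate physicochemical values downstream.
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0
)

AQP_SUBFAMILIES <- c("PIP", "TIP", "NIP", "SIP", "XIP")

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

assert_aa_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0) {
    abort(sprintf("Record '%s': sequence must be a non-empty string.", id),
          class = "aqpkit_domain_error")
  }
  bad <- setdiff(unique(seq_chars(sequence)), c(AA_ALPHABET, "X"))
  if (length(bad) > 0) {
    abort(sprintf(
      "Record '%s': invalid residue(s) %s (allowed: 20-letter alphabet plus X).",
      id, paste0("'", bad, "'", collapse = ", ")
    ), class = "aqpkit_domain_error")
  }
  invisible(TRUE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Stable small integer hash of a string, for deriving per-template seeds.
string_seed <- function(x, base = 0) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147480009
  as.integer((h + as.numeric(base)) %% 2147480009)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "aqpkit", mustWork = FALSE)
  if (!nzchar(path)) {
    abort(sprintf("Bundled data file '%s' not found.", file),
          class = "aqpkit_data_error")
  }
  path
}
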