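# Shared validation helpers and the amino-acid alphabet.

# 20 canonical residues plus X (unknown), in alphabetical order.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
  "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y"
)
GAP_CHAR <- "-"

aa_code <- function(chars) match(chars, AA_ALPHABET)

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "gainscan_format_error")
}

stop_domain <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "gainscan_domain_error")
}

check_residues <- function(x, what = "sequence", allow_gap = FALSE) {
  allowed <- AA_ALPHABET
  if (allow_gap) allowed <- c(allowed, GAP_CHAR)
  chars <- strsplit(x, "", fixed = TRUE)
  bad <- purrr::imap(chars, function(cc, i) {
    j <- which(!cc %in% allowed)
    if (length(j)) sprintf("%s %s: illegal character '%s' at position %d",
                           what, i, cc[j[1]], j[1])
  })
  bad <- purrr::compact(bad)
  if (length(bad)) stop_format("%s", bad[[1]])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label, so
# generators composing several random components stay independent and stable.
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  s <- as.double(seed %% 2147483647L)
  for (k in codes) s <- (s * 69069 + k) %% 2147483647
  as.integer(s)
}

local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
}
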