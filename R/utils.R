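## Internal helpers shared across modules.

# Shift a matrix by (dr, dc) with replicate (clamped-index) padding.
shiftClamped <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Run expr with a locally seeded RNG, restoring any pre-existing global
# state afterwards; no stage leaks entropy into the session.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to
# fingerprint configurations; stability matters, cryptography does not.
# Arithmetic is done in doubles, split to stay within exact integer range.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches low byte only
    hl <- h %% 65536
    hh <- (h - hl) / 65536
    h <- (hl * prime + ((hh * prime) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Canonical string form of a nested list: names sorted recursively, numbers
# formatted at full precision, so the hash ignores field order.
canonicalString <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      inner <- vapply(x, canonicalString, character(1))
      paste0("[", paste(inner, collapse = ","), "]")
    } else {
      o <- order(nm)
      inner <- vapply(o, function(i)
        paste0(nm[i], ":", canonicalString(x[[i]])), character(1))
      paste0("{", paste(inner, collapse = ","), "}")
    }
  } else if (is.numeric(x)) {
    paste(formatC(x, digits = 17, format = "g"), collapse = ",")
  } else {
    paste(as.character(x), collapse = ",")
  }
}
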