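# Sequence input grammars.
#
# Peptides: standard single-letter codes, nonstandard residues in parentheses,
# e.g. "AC(pS)G".  Peptoids: dash-separated multi-letter codes with nested
# repeat groups, e.g. "(Nme-Npe)3".  Both parse to a polymer_seq whose termini
# are supplied out-of-band (the sequence string never carries end groups).

MAX_RESIDUES <- 150L

new_polymer_seq <- function(codes, polymer_class, n_term, c_term) {
  structure(list(codes = codes, polymer_class = polymer_class,
                 n_term = n_term, c_term = c_term),
            class = "polymer_seq")
}

#' @export
length.polymer_seq <- function(x) length(x$codes)

#' @export
print.polymer_seq <- function(x, ...) {
  cat(sprintf("<polymer_seq: %s, %d residues>\n", x$polymer_class, length(x)))
  cat("  sequence:", canonical_string(x), "\n")
  cat("  N-terminus:", x$n_term$name, " C-terminus:", x$c_term$name, "\n")
  invisible(x)
}

seq_error <- function(pos, text, msg) {
  stop(sprintf("sequence parse error at position %d of '%s': %s",
               pos, text, msg), call. = FALSE)
}

check_length_cap <- function(n, text) {
  if (n > MAX_RESIDUES) {
    stop(sprintf("sequence '%s' has %d residues; the maximum is %d",
                 abbreviate_seq(text), n, MAX_RESIDUES), call. = FALSE)
  }
}

abbreviate_seq <- function(text) {
  if (nchar(text) > 40) paste0(substr(text, 1, 37), "...") else text
}

strip_outer_ws <- function(text) sub("^[[:space:]]+", "", sub("[[:space:]]+$", "", text))

#' Parse a peptide sequence string
#'
#' Single letters outside parentheses are canonical amino acids; parenthesized
#' tokens are nonstandard residue codes (case-sensitive), e.g. `"AC(pS)G"`.
#' Leading/trailing whitespace is ignored; whitespace inside the sequence is
#' an error.  The expanded chain may hold at most 150 residues.
#'
#' @param text sequence string.
#' @param n_term,c_term terminus name or custom formula string
#'   (see [resolve_terminus()]).
#' @return A `polymer_seq`.
#' @examples
#' parse_peptide("AC(pS)G")
#' @export
parse_peptide <- function(text, n_term = "unmodified", c_term = "acid") {
  stopifnot(is.character(text), length(text) == 1)
  text <- strip_outer_ws(text)
  if (!nzchar(text)) stop("empty peptide sequence", call. = FALSE)
  codes <- character(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (ch == "(") {
      close <- regexpr(")", substr(text, pos + 1L, n), fixed = TRUE)
      if (close == -1L) seq_error(pos, text, "unbalanced parenthesis")
      tok <- substr(text, pos + 1L, pos + close - 1L)
      if (!nzchar(tok)) seq_error(pos, text, "empty parentheses")
      if (grepl("[[:space:]]", tok)) seq_error(pos, text, "whitespace inside residue code")
      lookup_or_error(tok, "peptide", pos, text)
      codes <- c(codes, tok)
      pos <- pos + close + 1L
    } else if (ch == ")") {
      seq_error(pos, text, "unbalanced parenthesis")
    } else if (grepl("[[:space:]]", ch)) {
      seq_error(pos, text, "embedded whitespace")
    } else {
      lookup_or_error(ch, "peptide", pos, text)
      codes <- c(codes, ch)
      pos <- pos + 1L
    }
  }
  check_length_cap(length(codes), text)
  new_polymer_seq(codes, "peptide",
                  resolve_terminus(n_term, "N"), resolve_terminus(c_term, "C"))
}

lookup_or_error <- function(code, polymer_class, pos, text) {
  tryCatch(lookup_residue(code, polymer_class), error = function(e) {
    seq_error(pos, text, conditionMessage(e))
  })
}

#' Parse a peptoid sequence string
#'
#' Dash-separated residue codes with optional repeat groups:
#' `"(" subsequence ")" k` repeats the group `k` times, and groups nest, e.g.
#' `"((Nme)2-Npe)2"`.  A missing multiplier defaults to 1.  Repeats are fully
#' expanded before the 150-residue cap is enforced.
#'
#' @inheritParams parse_peptide
#' @return A `polymer_seq`.
#' @examples
#' parse_peptoid("(Nme-Npe)2")
#' @export
parse_peptoid <- function(text, n_term = "unmodified", c_term = "acid") {
  stopifnot(is.character(text), length(text) == 1)
  raw <- strip_outer_ws(text)
  if (!nzchar(raw)) stop("empty peptoid sequence", call. = FALSE)
  if (grepl("[[:space:]]", raw)) {
    seq_error(regexpr("[[:space:]]", raw), raw, "embedded whitespace")
  }
  res <- peptoid_parse_group(raw, 1L, raw, depth = 0L)
  if (res$pos <= nchar(raw)) {
    seq_error(res$pos, raw, "unbalanced parenthesis")
  }
  if (length(res$codes) == 0) seq_error(1L, raw, "no residue codes")
  check_length_cap(length(res$codes), raw)
  for (code in unique(res$codes)) lookup_or_error(code, "peptoid", 1L, raw)
  new_polymer_seq(res$codes, "peptoid",
                  resolve_terminus(n_term, "N"), resolve_terminus(c_term, "C"))
}

# recursive-descent parser for dash-separated items; returns codes + next pos.
# stops at a ')' (letting the caller consume it) or at end of input.
peptoid_parse_group <- function(text, pos, full, depth) {
  codes <- character(0)
  n <- nchar(text)
  expect_item <- TRUE
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (ch == ")") {
      if (depth == 0L) seq_error(pos, full, "unbalanced parenthesis")
      break
    } else if (ch == "(") {
      inner <- peptoid_parse_group(text, pos + 1L, full, depth + 1L)
      pos <- inner$pos
      if (pos > n || substr(text, pos, pos) != ")") {
        seq_error(pos, full, "unbalanced parenthesis")
      }
      pos <- pos + 1L
      mult_m <- regmatches(substr(text, pos, n),
                           regexec("^([0-9]+)", substr(text, pos, n)))[[1]]
      mult <- 1L
      if (length(mult_m) > 0 && nzchar(mult_m[1])) {
        mult <- suppressWarnings(as.integer(mult_m[1]))
        if (is.na(mult) || mult < 1L) {
          seq_error(pos, full, "repeat multiplier must be a positive integer")
        }
        pos <- pos + nchar(mult_m[1])
      }
      if (length(inner$codes) == 0) seq_error(pos, full, "empty repeat group")
      expanded <- rep(inner$codes, times = mult)
      check_length_cap(length(codes) + length(expanded), full)
      codes <- c(codes, expanded)
      expect_item <- FALSE
    } else if (ch == "-") {
      if (expect_item) seq_error(pos, full, "unexpected dash")
      pos <- pos + 1L
      expect_item <- TRUE
    } else {
      m <- regmatches(substr(text, pos, n),
                      regexec("^([^()-]+)", substr(text, pos, n)))[[1]]
      tok <- m[1]
      codes <- c(codes, tok)
      check_length_cap(length(codes), full)
      pos <- pos + nchar(tok)
      expect_item <- FALSE
    }
  }
  if (expect_item && length(codes) > 0) {
    seq_error(pos, full, "trailing dash")
  }
  list(codes = codes, pos = pos)
}

#' Canonical string form of a sequence
#'
#' Serializes a `polymer_seq` so that reparsing reproduces the identical
#' residue list.  Peptoid repeats are not re-compressed: the canonical form is
#' the fully expanded dash-separated string.
#'
#' @param seq a `polymer_seq`.
#' @return A single string.
#' @export
canonical_string <- function(seq) {
  stopifnot(inherits(seq, "polymer_seq"))
  if (seq$polymer_class == "peptide") {
    paste(vapply(seq$codes, function(code) {
      r <- lookup_residue(code, "peptide")
      if (r$canonical) code else paste0("(", code, ")")
    }, character(1)), collapse = "")
  } else {
    paste(seq$codes, collapse = "-")
  }
}

seq_residues <- function(seq) {
  lapply(seq$codes, lookup_residue, polymer_class = seq$polymer_class)
}
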