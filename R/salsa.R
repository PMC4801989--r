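# Beta-strand contiguity profiles by the sliding-average (SALSA) procedure:
# every window of 4..20 residues is scored as
#   sum(P_beta) / (0.5 * (sum(P_alpha) + sum(P_turn)))
# from Chou-Fasman propensities; windows scoring below the cutoff (1.2) are
# discarded and each residue accumulates the scores of the retained windows
# that cover it.

#' Chou-Fasman propensity table
#'
#' Per-residue helix / strand / reverse-turn propensities for the 20 canonical
#' amino acids, loaded from the versioned data file.
#'
#' @return Data frame with columns `code`, `p_alpha`, `p_beta`, `p_turn`.
#' @export
chou_fasman <- function() the$chou_fasman_default

#' Score one sequence window
#'
#' Ratio of the summed strand propensity to the mean of the summed helix and
#' turn propensities over the fragment.  Fragments containing a residue
#' without Chou-Fasman parameters (any non-canonical residue) are unscorable
#' and return `NA`.
#'
#' @param codes character vector of residue codes (the fragment).
#' @param table propensity table, defaults to [chou_fasman()].
#' @return The fragment score, or `NA_real_` if unscorable.
#' @export
window_score <- function(codes, table = chou_fasman()) {
  idx <- match(codes, table$code)
  if (anyNA(idx)) return(NA_real_)
  sum(table$p_beta[idx]) / (0.5 * (sum(table$p_alpha[idx]) + sum(table$p_turn[idx])))
}

#' Beta-strand contiguity profile
#'
#' Scans windows of every size from `w_min` to `min(w_max, length)` across the
#' sequence, discards windows scoring below `cutoff`, and reports, for each
#' residue, the sum of the retained window scores covering it.  Windows that
#' contain a non-canonical residue are skipped entirely.  Sequences shorter
#' than 10 residues have no profile: the result carries `available = FALSE`.
#'
#' @param seq a peptide `polymer_seq`.
#' @param w_min,w_max smallest and largest window size, in residues.
#' @param cutoff minimum retained window score.
#' @param table propensity table, defaults to [chou_fasman()].
#' @return An object of class `salsa_profile`: list with `available`, and when
#'   available, `values` (numeric, one per residue), `codes`, and the
#'   parameters used.
#' @export
contiguity_profile <- function(seq, w_min = 4L, w_max = 20L, cutoff = 1.2,
                               table = chou_fasman()) {
  stopifnot(inherits(seq, "polymer_seq"))
  if (seq$polymer_class != "peptide") {
    stop("contiguity profiles are only defined for peptides", call. = FALSE)
  }
  stopifnot(w_min >= 2L, w_max >= w_min, cutoff >= 0)
  n <- length(seq$codes)
  if (n < 10L) {
    return(structure(list(available = FALSE,
                          reason = sprintf(
                            "profile unavailable: %d residues (requires 10 or more)", n)),
                     class = "salsa_profile"))
  }
  values <- numeric(n)
  for (k in seq.int(w_min, min(w_max, n))) {
    for (start in seq_len(n - k + 1L)) {
      idx <- start:(start + k - 1L)
      s <- window_score(seq$codes[idx], table)
      if (!is.na(s) && s >= cutoff) {
        values[idx] <- values[idx] + s
      }
    }
  }
  structure(list(available = TRUE, values = values, codes = seq$codes,
                 w_min = w_min, w_max = w_max, cutoff = cutoff),
            class = "salsa_profile")
}

#' @export
print.salsa_profile <- function(x, ...) {
  if (!x$available) {
    cat("<salsa_profile> ", x$reason, "\n", sep = "")
  } else {
    cat(sprintf("<salsa_profile> %d residues, windows %d..%d, cutoff %.2f\n",
                length(x$values), x$w_min, x$w_max, x$cutoff))
    print(round(stats::setNames(x$values, x$codes), 3))
  }
  invisible(x)
}

#' @export
as.data.frame.salsa_profile <- function(x, ...) {
  if (!x$available) stop(x$reason, call. = FALSE)
  data.frame(position = seq_along(x$values), residue = x$codes,
             propensity = x$values)
}

#' Write a contiguity profile as TSV
#'
#' Columns: 1-based position, residue code, propensity (3 decimals).
#'
#' @param x a `salsa_profile`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df$propensity <- sprintf("%.3f", df$propensity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
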