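# Assignment of singly-charged m/z peaks from synthesis mass spectra to
# residue-deletion sequences, metal adducts and unremoved protecting groups.
#
# The engine deepens iteratively: iteration N considers every combination of
# at most N residue deletions with at most N modifications (including the
# null entries), computes the neutral species mass for each combination, and
# assigns any still-unassigned peak lying within the tolerance of a candidate
# mass.  Peaks assigned at iteration N are not re-examined later.  The number
# of iterations is capped by sequence length (5 up to 30 residues, 4 up to
# 60, 3 up to 150).  Deletions are compositional -- tracked by residue code,
# not position -- because positional variants are mass-identical.

#' Iteration cap for a sequence length
#'
#' @param n sequence length in residues (1..150).
#' @return Maximum number of assignment iterations: 5 for lengths up to 30,
#'   4 up to 60, 3 up to 150.
#' @export
iteration_cap <- function(n) {
  stopifnot(n >= 1, n <= MAX_RESIDUES)
  if (n <= 30) 5L else if (n <= 60) 4L else 3L
}

# multisets (named integer vectors) of size <= n drawn from `avail`
# (named integer capacity vector); always includes the empty multiset.
enumerate_multisets <- function(avail, n) {
  avail <- avail[avail > 0L]
  out <- list(stats::setNames(integer(0), character(0)))
  if (n < 1L || length(avail) == 0) return(out)
  keys <- names(avail)
  recurse <- function(i, remaining, current) {
    if (i > length(keys)) return()
    for (take in 0:min(avail[[i]], remaining)) {
      nxt <- current
      if (take > 0L) nxt[keys[i]] <- take
      if (take > 0L) out[[length(out) + 1L]] <<- nxt
      if (remaining - take > 0L) recurse(i + 1L, remaining - take, nxt)
    }
  }
  # the loop above emits each multiset once because element order is fixed
  recurse(1L, as.integer(n), stats::setNames(integer(0), character(0)))
  out
}

#' Enumerate residue-deletion multisets
#'
#' All compositional multisets of at most `n` deletions, each residue's
#' multiplicity bounded by its count in the sequence.  The empty multiset
#' (no deletion) is always included.
#'
#' @param seq a `polymer_seq`.
#' @param n maximum number of deletions.
#' @return List of named integer vectors (residue code -> multiplicity).
#' @export
enumerate_deletions <- function(seq, n) {
  stopifnot(inherits(seq, "polymer_seq"), n >= 0)
  counts <- table(seq$codes)
  avail <- stats::setNames(as.integer(counts), names(counts))
  enumerate_multisets(avail, n)
}

# how many of each modification the sequence licenses.  metals (empty site
# list) are unrestricted; a protecting group is bounded by the number of
# licensing residues present (plus one for an Nterm license when the
# N-terminus is unmodified).
modification_capacity <- function(seq, mods = modification_table()) {
  vapply(mods, function(m) {
    if (length(m$sites) == 0) return(NA_integer_)  # unrestricted
    n_sites <- sum(seq$codes %in% setdiff(m$sites, "Nterm"))
    if ("Nterm" %in% m$sites && seq$n_term$name == "unmodified") {
      n_sites <- n_sites + 1L
    }
    as.integer(n_sites * m$max_per_site)
  }, integer(1))
}

#' Enumerate modification multisets
#'
#' All multisets of at most `n` modifications drawn from `mods`.  Metal
#' adducts are unrestricted (up to `n` each); a protecting group's
#' multiplicity is bounded by the number of residues (or terminus) in the
#' sequence that license it.  The empty multiset is always included.
#'
#' @inheritParams enumerate_deletions
#' @param mods modification records, defaults to the full
#'   [modification_table()].
#' @return List of named integer vectors (modification name -> multiplicity).
#' @export
enumerate_modifications <- function(seq, n, mods = modification_table()) {
  stopifnot(inherits(seq, "polymer_seq"), n >= 0)
  cap <- modification_capacity(seq, mods)
  cap[is.na(cap)] <- as.integer(n)
  enumerate_multisets(cap, n)
}

normalize_multiset <- function(x) {
  if (is.character(x)) {
    counts <- table(x)
    x <- stats::setNames(as.integer(counts), names(counts))
  }
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  stopifnot(!is.null(names(x)), all(x >= 1))
  stats::setNames(as.integer(x), names(x))
}

#' Mass of a deletion / modification candidate
#'
#' Molecular weight of the sequence minus the masses of the deleted residues
#' plus the signed mass deltas of the modifications.
#'
#' @inheritParams enumerate_deletions
#' @param deletions residue codes to delete: a character vector (with
#'   repeats) or a named multiplicity vector.  Must not exceed the sequence
#'   composition.
#' @param modifications modification names, same conventions.
#' @param mods modification records used to resolve `modifications`.
#' @return The candidate's neutral species mass in u.
#' @export
candidate_mass <- function(seq, deletions = character(0),
                           modifications = character(0),
                           mods = modification_table()) {
  stopifnot(inherits(seq, "polymer_seq"))
  del <- normalize_multiset(deletions)
  mod <- normalize_multiset(modifications)
  counts <- table(seq$codes)
  for (code in names(del)) {
    have <- if (code %in% names(counts)) counts[[code]] else 0L
    if (del[[code]] > have) {
      stop(sprintf("cannot delete %d x '%s': sequence contains %d",
                   del[[code]], code, have), call. = FALSE)
    }
  }
  m <- molecular_weight(seq)
  for (code in names(del)) {
    m <- m - del[[code]] * formula_mass(lookup_residue(code, seq$polymer_class)$formula)
  }
  missing_mods <- setdiff(names(mod), names(mods))
  if (length(missing_mods)) {
    stop("unknown modification(s): ", paste(missing_mods, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(mod)) {
    m <- m + mod[[nm]] * modification_delta_mass(mods[[nm]])
  }
  m
}

multiset_label <- function(x) {
  if (length(x) == 0) return("-")
  paste(rep(names(x), times = x), collapse = ", ")
}

#' Assign mass spectral peaks to deletion / modification candidates
#'
#' Runs the iterative-deepening assignment described above.  A peak is
#' assigned at the first iteration in which at least one candidate mass lies
#' within `tolerance` of its m/z; *all* candidates matching at that iteration
#' are reported, ordered by total deletion + modification count and then by
#' mass error.  The calculated neutral species mass is compared directly
#' against the entered m/z; the tolerance absorbs the ionizing proton.
#'
#' @inheritParams enumerate_deletions
#' @param peaks numeric vector of singly-charged m/z values (all > 0).
#' @param tolerance assignment tolerance in u (inclusive), default 1.0.
#' @param mods modification records to consider.
#' @param max_iterations override of the length-based [iteration_cap()].
#' @param budget maximum number of deletion x modification combinations
#'   examined per iteration; past it the run aborts with an error rather than
#'   exhausting memory.
#' @return An `assignment_report`: per input peak, the assignment status,
#'   the iteration of first assignment, and the candidate list.
#' @export
assign_peaks <- function(seq, peaks, tolerance = 1.0,
                         mods = modification_table(),
                         max_iterations = NULL, budget = 5e6) {
  stopifnot(inherits(seq, "polymer_seq"))
  if (length(peaks) == 0) stop("at least one peak is required", call. = FALSE)
  if (!is.numeric(peaks) || any(!is.finite(peaks)) || any(peaks <= 0)) {
    stop("peaks must be positive finite m/z values", call. = FALSE)
  }
  stopifnot(tolerance > 0)
  cap <- if (is.null(max_iterations)) iteration_cap(length(seq)) else
    as.integer(max_iterations)

  entries <- lapply(peaks, function(p) {
    list(mz = p, assigned = FALSE, iteration = NA_integer_, candidates = list())
  })
  base_mw <- molecular_weight(seq)

  for (iter in seq_len(cap)) {
    open <- which(!vapply(entries, `[[`, logical(1), "assigned"))
    if (length(open) == 0) break
    dels <- enumerate_deletions(seq, iter)
    modsets <- enumerate_modifications(seq, iter, mods)
    n_combo <- length(dels) * length(modsets)
    if (n_combo > budget) {
      stop(sprintf(paste0("candidate budget exceeded at iteration %d: %g ",
                          "combinations (budget %g); raise `budget` or reduce ",
                          "the modification set"), iter, n_combo, budget),
           call. = FALSE)
    }
    del_mass <- vapply(dels, function(d) {
      if (length(d) == 0) return(0)
      sum(vapply(names(d), function(code) {
        d[[code]] * formula_mass(lookup_residue(code, seq$polymer_class)$formula)
      }, numeric(1)))
    }, numeric(1))
    mod_delta <- vapply(modsets, function(m) {
      if (length(m) == 0) return(0)
      sum(vapply(names(m), function(nm) {
        m[[nm]] * modification_delta_mass(mods[[nm]])
      }, numeric(1)))
    }, numeric(1))
    # candidate mass matrix: rows = deletion sets, cols = modification sets
    cand_mass <- outer(base_mw - del_mass, mod_delta, `+`)

    for (i in open) {
      hit <- which(abs(cand_mass - entries[[i]]$mz) <= tolerance,
                   arr.ind = TRUE)
      if (nrow(hit) == 0) next
      cands <- lapply(seq_len(nrow(hit)), function(h) {
        d <- dels[[hit[h, 1]]]
        m <- modsets[[hit[h, 2]]]
        mass <- cand_mass[hit[h, 1], hit[h, 2]]
        list(deletions = d, modifications = m, mass = mass,
             delta = abs(mass - entries[[i]]$mz))
      })
      ord <- order(vapply(cands, function(x) sum(x$deletions) + sum(x$modifications),
                          numeric(1)),
                   vapply(cands, `[[`, numeric(1), "delta"),
                   vapply(cands, function(x)
                     paste(multiset_label(x$deletions),
                           multiset_label(x$modifications)), character(1)))
      entries[[i]]$assigned <- TRUE
      entries[[i]]$iteration <- iter
      entries[[i]]$candidates <- cands[ord]
    }
  }

  structure(list(sequence = canonical_string(seq),
                 polymer_class = seq$polymer_class,
                 n_term = seq$n_term$name, c_term = seq$c_term$name,
                 full_mass = base_mw, tolerance = tolerance,
                 iterations_run = min(cap, iter), iteration_cap = cap,
                 peaks = entries),
            class = "assignment_report")
}

#' @export
as.data.frame.assignment_report <- function(x, ...) {
  rows <- list()
  for (e in x$peaks) {
    if (!e$assigned) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_mz = e$mz, deletions = NA_character_, adducts = NA_character_,
        calculated_mass = NA_real_, delta = NA_real_, iteration = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    for (cand in e$candidates) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_mz = e$mz,
        deletions = multiset_label(cand$deletions),
        adducts = multiset_label(cand$modifications),
        calculated_mass = cand$mass, delta = cand$delta,
        iteration = e$iteration, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("<assignment_report> %s (%s), full mass %.4f u, tolerance %.2f u\n",
              x$sequence, x$polymer_class, x$full_mass, x$tolerance))
  df <- as.data.frame(x)
  df$calculated_mass <- ifelse(is.na(df$calculated_mass), "",
                               sprintf("%.4f", df$calculated_mass))
  df$delta <- ifelse(is.na(df$delta), "", sprintf("%.4f", df$delta))
  df$deletions[is.na(df$deletions)] <- "(unassigned)"
  df$adducts[is.na(df$adducts)] <- ""
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an assignment report as TSV
#'
#' One row per candidate (unassigned peaks get a single row with empty
#' fields), mirroring the peak / deletions / adducts / calculated-mass table
#' layout, plus the mass error and assigning iteration.
#'
#' @param x an `assignment_report`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_assignment_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df$calculated_mass <- ifelse(is.na(df$calculated_mass), "",
                               sprintf("%.4f", df$calculated_mass))
  df$delta <- ifelse(is.na(df$delta), "", sprintf("%.4f", df$delta))
  df$deletions[is.na(df$deletions)] <- ""
  df$adducts[is.na(df$adducts)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
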