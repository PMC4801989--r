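# Independent oracles and random-input generators for property tests.
# These deliberately re-derive results by brute force, along code paths that
# share nothing with the implementation's algorithms.

CANONICAL20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide_string <- function(len, nonstandard_p = 0) {
  codes <- sample(CANONICAL20, len, replace = TRUE)
  if (nonstandard_p > 0) {
    swap <- runif(len) < nonstandard_p
    ns <- c("pS", "pT", "pY", "Nle", "Orn", "Cit")
    codes[swap] <- sample(ns, sum(swap), replace = TRUE)
  }
  paste(ifelse(nchar(codes) > 1, paste0("(", codes, ")"), codes), collapse = "")
}

PEPTOID_CODES <- c("Nme", "Net", "Npr", "Nbu", "Npm", "Npe", "Nspe",
                   "Nae", "Nab", "Nce", "Nhe")

# --- peptoid repeat grammar: independent string-rewriting expander ------------
# repeatedly rewrites the innermost "(...)k" group into its literal expansion,
# then splits the flat string on dashes.
rewrite_expand_peptoid <- function(text) {
  repeat {
    m <- regexpr("\\(([^()]*)\\)([0-9]*)", text)
    if (m == -1) break
    whole <- regmatches(text, m)
    inner <- sub("\\(([^()]*)\\)([0-9]*)", "\\1", whole)
    mult <- sub("\\(([^()]*)\\)([0-9]*)", "\\2", whole)
    mult <- if (nzchar(mult)) as.integer(mult) else 1L
    expansion <- paste(rep(inner, mult), collapse = "-")
    regmatches(text, m) <- expansion
  }
  strsplit(text, "-", fixed = TRUE)[[1]]
}

# random nested repeat pattern over the peptoid codes; returns the string
random_peptoid_pattern <- function(depth = 0) {
  n_items <- sample(1:3, 1)
  items <- vapply(seq_len(n_items), function(i) {
    if (depth < 2 && runif(1) < 0.35) {
      paste0("(", random_peptoid_pattern(depth + 1), ")", sample(1:3, 1))
    } else {
      sample(PEPTOID_CODES, 1)
    }
  }, character(1))
  paste(items, collapse = "-")
}

# --- pI: grid-scan oracle -----------------------------------------------------
# locates the sign change of the net charge on a 0.0001-step grid (coarse
# bracket first, then the fine grid inside the bracket).
grid_scan_pi <- function(seq) {
  coarse <- seq(0, 14, by = 0.01)
  ch <- net_charge(seq, coarse)
  i <- which(ch < 0)[1]
  stopifnot(!is.na(i), i > 1)
  fine <- seq(coarse[i - 1], coarse[i], by = 0.0001)
  chf <- net_charge(seq, fine)
  j <- which(chf < 0)[1]
  # root lies between fine[j-1] and fine[j]; report the midpoint
  (fine[j - 1] + fine[j]) / 2
}

# --- SALSA: exhaustive per-position oracle ------------------------------------
# for each residue, loops over every window of every size and adds the scores
# of retained windows that cover that residue.
salsa_oracle <- function(codes, w_min = 4, w_max = 20, cutoff = 1.2,
                         table = chou_fasman()) {
  n <- length(codes)
  vapply(seq_len(n), function(pos) {
    total <- 0
    for (k in w_min:min(w_max, n)) {
      for (start in 1:(n - k + 1)) {
        if (pos < start || pos > start + k - 1) next
        idx <- match(codes[start:(start + k - 1)], table$code)
        if (anyNA(idx)) next
        s <- sum(table$p_beta[idx]) /
          (0.5 * (sum(table$p_alpha[idx]) + sum(table$p_turn[idx])))
        if (s >= cutoff) total <- total + s
      }
    }
    total
  }, numeric(1))
}

# --- assignment: flat exhaustive oracle ---------------------------------------
# enumerates every deletion multiset (expand.grid over per-code multiplicity)
# and modification multiset up to the iteration cap in one flat pass, then
# replays the iterative-deepening schedule peak by peak.
oracle_deletion_sets <- function(seq, n_max) {
  counts <- table(seq$codes)
  grids <- lapply(as.integer(counts), function(k) 0:min(k, n_max))
  names(grids) <- names(counts)
  g <- expand.grid(grids)
  g <- g[rowSums(g) <= n_max, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) {
    row <- unlist(g[i, , drop = TRUE])
    row <- row[row > 0]
    setNames(as.integer(row), names(row))
  })
}

oracle_mod_sets <- function(seq, n_max, mods = modification_table()) {
  caps <- vapply(mods, function(m) {
    if (length(m$sites) == 0) return(n_max)
    n_sites <- sum(seq$codes %in% setdiff(m$sites, "Nterm"))
    if ("Nterm" %in% m$sites && seq$n_term$name == "unmodified") {
      n_sites <- n_sites + 1L
    }
    min(n_max, n_sites * m$max_per_site)
  }, numeric(1))
  g <- expand.grid(lapply(caps, function(k) 0:k))
  g <- g[rowSums(g) <= n_max, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) {
    row <- unlist(g[i, , drop = TRUE])
    row <- row[row > 0]
    setNames(as.integer(row), names(row))
  })
}

# candidate label used to compare engine and oracle candidate sets
cand_key <- function(del, mod) {
  d <- if (length(del)) paste(sort(rep(names(del), del)), collapse = "+") else ""
  m <- if (length(mod)) paste(sort(rep(names(mod), mod)), collapse = "+") else ""
  paste(d, m, sep = "|")
}

oracle_assign <- function(seq, peaks, tolerance = 1.0) {
  cap <- iteration_cap(length(seq))
  dels <- oracle_deletion_sets(seq, cap)
  modsets <- oracle_mod_sets(seq, cap)
  res_mass <- vapply(unique(seq$codes), function(code)
    formula_mass(lookup_residue(code, seq$polymer_class)$formula), numeric(1))
  mod_delta <- vapply(modification_table(), function(m)
    formula_mass(m$plus) - formula_mass(m$minus), numeric(1))
  mw <- molecular_weight(seq)
  combos <- list()
  for (d in dels) for (m in modsets) {
    combos[[length(combos) + 1L]] <- list(
      del = d, mod = m,
      iter = max(1L, max(sum(d), sum(m))),  # first iteration that includes it
      mass = mw - sum(res_mass[names(d)] * d) + sum(mod_delta[names(m)] * m))
  }
  iters <- vapply(combos, `[[`, numeric(1), "iter")
  masses <- vapply(combos, `[[`, numeric(1), "mass")
  lapply(peaks, function(p) {
    match_at <- which(abs(masses - p) <= tolerance)
    if (length(match_at) == 0) {
      return(list(assigned = FALSE, iteration = NA, keys = character(0)))
    }
    first <- min(iters[match_at])
    keep <- match_at[iters[match_at] <= first]
    list(assigned = TRUE, iteration = first,
         keys = sort(vapply(keep, function(i)
           cand_key(combos[[i]]$del, combos[[i]]$mod), character(1))))
  })
}

report_keys <- function(report_entry) {
  sort(vapply(report_entry$candidates, function(cand)
    cand_key(cand$deletions, cand$modifications), character(1)))
}
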