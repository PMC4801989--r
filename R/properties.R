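# Whole-sequence calculators: molecular formula/weight, 280 nm extinction
# coefficients, residue charge summary, Henderson-Hasselbalch net charge and
# the bisection isoelectric point.

#' Molecular formula of a sequence
#'
#' Sum of the chain-incorporated residue compositions plus both terminus
#' deltas.  With the default unmodified/acid termini this is the free
#' (hydrated) species.
#'
#' @param seq a `polymer_seq` from [parse_peptide()] or [parse_peptoid()].
#' @return A [chem_formula()].
#' @export
molecular_formula <- function(seq) {
  stopifnot(inherits(seq, "polymer_seq"))
  Reduce(`+.chem_formula`,
         lapply(seq_residues(seq), `[[`, "formula"),
         chem_formula()) + seq$n_term$delta + seq$c_term$delta
}

#' Molecular weight of a sequence
#'
#' Most-abundant-isotope (monoisotopic) mass of [molecular_formula()], in u.
#'
#' @inheritParams molecular_formula
#' @param masses element mass table override.
#' @return Mass in u.
#' @export
molecular_weight <- function(seq, masses = element_masses()) {
  formula_mass(molecular_formula(seq), masses)
}

#' Molar extinction coefficient at 280 nm
#'
#' Pace-style estimate from chromophore counts:
#' `5500 n_Trp + 1490 n_Tyr + 125 n_cystine` (in M^-1 cm^-1).  Two values are
#' returned: fully oxidized (`n_cystine = floor(n_Cys / 2)`, the maximum
#' number of disulfides) and fully reduced (`n_cystine = 0`).  Peptide-only.
#'
#' @inheritParams molecular_formula
#' @return List with `n_trp`, `n_tyr`, `n_cys`, `n_cystine_max`,
#'   `epsilon_oxidized`, `epsilon_reduced`.
#' @export
extinction_280 <- function(seq) {
  stopifnot(inherits(seq, "polymer_seq"))
  if (seq$polymer_class != "peptide") {
    stop("extinction coefficients at 280 nm are only defined for peptides",
         call. = FALSE)
  }
  chromo <- vapply(seq_residues(seq),
                   function(r) if (is.null(r$chromophore)) "" else r$chromophore,
                   character(1))
  n_trp <- sum(chromo == "Trp")
  n_tyr <- sum(chromo == "Tyr")
  n_cys <- sum(chromo == "Cys")
  n_cystine <- n_cys %/% 2L
  list(n_trp = n_trp, n_tyr = n_tyr, n_cys = n_cys, n_cystine_max = n_cystine,
       epsilon_oxidized = 5500 * n_trp + 1490 * n_tyr + 125 * n_cystine,
       epsilon_reduced = 5500 * n_trp + 1490 * n_tyr)
}

CHARGE_ACIDIC <- c("D", "E", "C", "Y")
CHARGE_BASIC <- c("R", "H", "K")

#' Residue charge summary
#'
#' Counts and fractions of acidic (Asp, Glu, Cys, Tyr), basic (Arg, His, Lys)
#' and other residues.  Every residue without an ionizable side chain in the
#' pKa set -- including all nonstandard residues -- is counted as "other".
#'
#' @inheritParams molecular_formula
#' @return List with `counts` and `fractions` (acidic, basic, other).
#' @export
charge_summary <- function(seq) {
  stopifnot(inherits(seq, "polymer_seq"))
  if (seq$polymer_class != "peptide") {
    stop("the charge summary is only defined for peptides", call. = FALSE)
  }
  n_acidic <- sum(seq$codes %in% CHARGE_ACIDIC)
  n_basic <- sum(seq$codes %in% CHARGE_BASIC)
  n_other <- length(seq$codes) - n_acidic - n_basic
  counts <- c(acidic = n_acidic, basic = n_basic, other = n_other)
  list(counts = counts, fractions = counts / length(seq$codes))
}

#' Default pKa set
#'
#' The shipped side-chain and terminus pKa table (IPC_peptide values).  Rows:
#' group id, pKa, and sign (-1 acidic, +1 basic).
#'
#' @return A data frame with columns `group`, `pka`, `sign`.
#' @export
default_pka <- function() the$pka_default

# assemble the ionizable groups of a sequence as a data.frame(pka, sign).
# terminal groups enter only for the unmodified N-terminus / acid C-terminus.
ionizable_groups <- function(seq, pka = default_pka()) {
  stopifnot(inherits(seq, "polymer_seq"))
  if (seq$polymer_class != "peptide") {
    stop("net charge and pI are only defined for peptides", call. = FALSE)
  }
  gid <- unlist(lapply(seq_residues(seq), `[[`, "ionizable"))
  if (seq$n_term$name == "unmodified") gid <- c(gid, "Nterm")
  if (seq$c_term$name == "acid") gid <- c(gid, "Cterm")
  if (length(gid) == 0) {
    return(data.frame(pka = numeric(0), sign = numeric(0)))
  }
  idx <- match(gid, pka$group)
  if (anyNA(idx)) {
    stop("pKa set lacks group(s): ", paste(unique(gid[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(pka = pka$pka[idx], sign = pka$sign[idx])
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch net charge: acidic groups contribute
#' `-1 / (1 + 10^(pKa - pH))` and basic groups `+1 / (1 + 10^(pH - pKa))`.
#' Side chains of Arg, Asp, Cys, Glu, His, Lys and Tyr contribute; the
#' N-terminal amine and C-terminal carboxyl contribute only when the termini
#' are "unmodified" and "acid" respectively.  Vectorized over `pH`.
#'
#' @inheritParams molecular_formula
#' @param pH numeric vector of pH values.
#' @param pka pKa set, defaults to [default_pka()].
#' @return Net charge in elementary charges, one value per pH.
#' @export
net_charge <- function(seq, pH, pka = default_pka()) {
  groups <- ionizable_groups(seq, pka)
  vapply(pH, function(p) {
    if (nrow(groups) == 0) return(0)
    acid <- groups$sign < 0
    sum(-1 / (1 + 10^(groups$pka[acid] - p))) +
      sum(1 / (1 + 10^(p - groups$pka[!acid])))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in (0, 14) at which [net_charge()] is zero, by bisection.
#' Requires at least one acidic and one basic group (otherwise the charge
#' never crosses zero and the pI is undefined).
#'
#' @inheritParams net_charge
#' @param tol_ph stop when the bracketing interval is narrower than this
#'   (pH units).
#' @param tol_charge stop early when the midpoint net charge is this close to
#'   zero.
#' @return The pI, in pH units.
#' @export
isoelectric_point <- function(seq, pka = default_pka(),
                              tol_ph = 1e-4, tol_charge = 1e-9) {
  groups <- ionizable_groups(seq, pka)
  if (nrow(groups) == 0 || !any(groups$sign < 0) || !any(groups$sign > 0)) {
    stop("pI undefined: the sequence needs at least one acidic and one basic group",
         call. = FALSE)
  }
  f <- function(p) net_charge(seq, p, pka)
  lo <- 0; hi <- 14
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop("pI undefined: net charge does not change sign on [0, 14]",
         call. = FALSE)
  }
  # net charge is strictly decreasing, so f(lo) > 0 > f(hi)
  while (hi - lo > tol_ph) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(f_mid) < tol_charge) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' pH / net-charge curve
#'
#' Tabulates [net_charge()] over a pH grid (default 0 to 14 in 0.1 steps),
#' e.g. for titration-curve plotting.
#'
#' @inheritParams net_charge
#' @param step pH grid step.
#' @return Data frame with columns `pH` and `charge`.
#' @export
charge_curve <- function(seq, step = 0.1, pka = default_pka()) {
  grid <- seq.int(0L, 14 / step) * step
  data.frame(pH = grid, charge = net_charge(seq, grid, pka))
}
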