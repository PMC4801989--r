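---
title: "pepkit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepkit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepkit)
```

`pepkit` computes physicochemical properties of synthetic peptides and
peptoids and assigns mass-spectral peaks from crude synthesis products to
deletion sequences and adducts.  This vignette records the models behind
each calculator, the conventions and tunable parameters, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## Mass convention and the formula model

All masses are *most-abundant-isotope* (monoisotopic) masses: each element
contributes the mass of its single most abundant isotope, so `mass(C)` is
exactly 12 u.  This matches how singly-charged peaks of small peptides are
read off a well-resolved spectrum.  Average (abundance-weighted) masses are
deliberately out of scope.

Residue compositions are stored *chain-incorporated* (dehydrated): glycine
is `C2H3NO`, not `C2H5NO2`.  A chain's formula is then a pure sum, and the
two termini add their end groups — the default pair, unmodified N (+H) and
acid C (+OH), reconstitutes the free peptide (chain + H₂O).  Custom termini
are entered as the formula *added* to the bare chain end, e.g. `"C2H3O"`
for acetyl.  This additive convention is what makes deletion arithmetic in
the assignment engine a one-liner: removing a residue subtracts exactly its
residue formula, with no end-group bookkeeping.

Element masses, residues (20 canonical amino acids, 6 nonstandard residues
including the phospho-series, 11 peptoid building blocks), termini,
modifications, pKa values and Chou–Fasman propensities all ship as
versioned plain-text TSV files under `inst/extdata/`, so their provenance
is auditable and tests can pin them.  The hosted databases this package's
seed set reconstructs are much larger and grow on request; here,
`register_residue()` plays that role programmatically.

## Net charge and isoelectric point

Net charge at a given pH is the Henderson–Hasselbalch sum over ionizable
groups; acidic groups (Asp, Glu, Cys, Tyr side chains, C-terminal
carboxyl) contribute $-1/(1+10^{pK_a-pH})$ and basic groups (Arg, His, Lys
side chains, N-terminal amine) contribute $+1/(1+10^{pH-pK_a})$.  Terminal
groups are included only when the termini are actually ionizable — the
predefined "unmodified" N-terminus and "acid" C-terminus.  Every other
residue, including all nonstandard residues (even phosphoserine, which in
reality titrates), contributes nothing; this keeps the calculator's claims
honest about what its pKa table covers, and those residues are bucketed as
"other" in the charge summary.

The shipped pKa set is the IPC_peptide table (Kozlowski 2016), chosen
because it was fitted specifically for short peptides rather than folded
proteins and its values are published to three decimals.  It can be
swapped wholesale via the `pka` argument (a `group`/`pka`/`sign` data
frame).

The pI is the unique root of the strictly decreasing charge function on
(0, 14), found by bisection.  Defaults: halve until the bracket is narrower
than `tol_ph = 1e-4`, with an early exit when `|charge| < tol_charge =
1e-9`.  Both are deliberately tighter than the "0.001 pH" accuracy the
package promises: on sequences whose ionizable groups are all far from the
pI (e.g. only a carboxyl near 2.4 and an amine near 9.6), the charge
plateaus at ~10⁻⁵ e over a wide pH range, and a looser charge threshold
(say 10⁻⁶) can trigger several millipH units from the true root — the
tight defaults make the bisection agree with a 10⁻⁴-step grid scan to
better than 0.001 pH in all 500 randomized test cases.  A sequence with no
acidic or no basic group has no root, and `isoelectric_point()` says so
("pI undefined") rather than returning a boundary value.

Cysteine is counted in the *acidic* bucket of the charge summary because it
carries an acidic pKa in the charge model; a thiol purist may disagree for
neutral pH, but consistency between the pie-chart buckets and the pI model
seemed more useful than a third convention.

## Extinction coefficients at 280 nm

The Pace composition formula: $\varepsilon_{280} = 5500\,n_{Trp} +
1490\,n_{Tyr} + 125\,n_{cystine}$ (M⁻¹cm⁻¹).  Two values are always
reported: "oxidized" assumes the maximum possible number of disulfides
($n_{cystine} = \lfloor n_{Cys}/2 \rfloor$), "reduced" assumes none.  The
true value for a partly oxidized sample lies between them.  Peptoids get an
explicit unsupported-operation error — their backbone lacks these
chromophores and silently returning 0 would invite misuse.

## β-strand contiguity (SALSA)

The profile uses the simple algorithm for sliding averages (SALSA; Zibaee
et al. 2007) over Chou–Fasman propensities: every window of length 4 up to
`min(20, length)` — every integer size, every offset — is scored
$\sum P_\beta \,/\, \tfrac12(\sum P_\alpha + \sum P_t)$; windows scoring
below 1.2 are discarded; each residue reports the sum of retained-window
scores covering it.  High plateaus flag contiguous β-prone stretches,
which for synthesis purposes correlate with aggregation-prone, "difficult"
sequences.  Window bounds and the cutoff are arguments with these defaults.

Two conventions needed fixing:

* **Short sequences.** Profiles are only defined for 10 residues or more;
  below that the result object carries `available = FALSE` with a reason,
  not an error — a report for a 9-mer is still a valid report.
* **Non-canonical residues.** Chou–Fasman parameters exist only for the 20
  canonical amino acids.  Any window containing an unparameterized residue
  is skipped *entirely* rather than partially summed: a partial ratio would
  silently bias the score, whereas a skipped window only lowers coverage
  around the exotic residue, which is the honest statement of ignorance.

The profile "is a guide, not a predictor": single-parameter ab initio
scores misfire on real structures often enough that no aggregation claim
beyond the computed numbers is made.

## Peak assignment

The engine explains each user-entered singly-charged m/z value as the
target sequence minus a multiset of residue *deletions* plus a multiset of
*modifications* (metal adducts; unremoved protecting groups).  Key
conventions:

* **Compositional deletions.** Deletions are tracked by residue code, not
  position: positional variants are mass-identical and would only duplicate
  report rows.
* **Metal adducts are salt-form:** +metal −H (so Na is +21.982 u, K is
  +37.956 u), the usual convention for acids picking up Na⁺/K⁺ during
  ionization.  The internal mass differences of the worked example only
  balance under this convention.
* **Protecting-group licensing.** A protecting group may appear only as
  often as the sequence contains residues that carry it: Pbf→Arg; Boc→Lys,
  Trp, free N-terminus; tBu→Ser, Thr, Tyr, Asp, Glu; Trt→Cys, His, Asn,
  Gln.  The licensing table is an editable data file, since resin/chemistry
  choices vary.  Licensing is computed against the *full* sequence — a
  species can simultaneously lack an Arg and carry a stray Pbf (now on a
  neighbouring functionality), and such combinations do occur in real
  crudes.
* **Pbf mass.** The shipped Pbf increment is the chemically standard
  sulfonyl substitution, C13H16O3S = +252.082 u.  Some published assignment
  tables imply +253.00 u for Pbf by internal differencing; that convention
  is not reproducible from the group's composition, so the standard value
  ships and the discrepancy is documented rather than reverse-engineered.
* **Iterative deepening.** Iteration *N* considers every combination of at
  most *N* deletions with at most *N* modifications (null entries
  included), so the first iteration covers "single deletion and/or single
  modification".  A peak is assigned at the first iteration that matches it
  within the tolerance (default ±1.0 u, inclusive), and *all* candidates
  matching at that iteration are reported, ordered by total edit count then
  mass error.  Assigned peaks are not re-examined.  The calculated neutral
  mass is compared directly with the entered m/z; the tolerance absorbs
  the ionizing proton.  Iterations cap at 5 (≤ 30 residues), 4 (≤ 60) or 3
  (≤ 150) to bound the combinatorics.
* **Guardrail.** The deletion × modification product is counted before the
  mass matrix is built; past `budget` (default 5×10⁶ combinations per
  iteration) the run aborts with instructions, rather than exhausting
  memory.

The test suite checks the engine against an independently coded flat
enumeration (all combinations up to the cap in one pass, then the deepening
schedule replayed per peak) on 100 random sequences, so the schedule
semantics above are pinned, not just described.

## The synthetic-spectrum generator

`generate_fixture()` emulates the one thing the assignment engine needs
from a real crude spectrum: peaks at the masses of deletion/adduct variants
of a known sequence, observed with sub-u inaccuracy.  For each spectrum it
draws a random sequence (canonical residues for peptides, the shipped
building blocks for peptoids), then for each peak a random combination of
up to 2 deletions (from the sequence's own composition) and up to 2
licensed modifications, and reports m/z = true mass + U(−0.5, 0.5) u.

One construction rule matters: if a planted combination first enters at
iteration *k* but some *smaller*-iteration candidate also lies within the
assignment tolerance of the jittered peak, the engine would (correctly)
assign the peak at the earlier iteration and never report the planted
truth — e.g. a planted double-Gly deletion (−114.043 u) is
indistinguishable from a single Asn deletion (−114.043 u).  The generator
redraws such peaks, so 100% ground-truth recovery is guaranteed *by
construction*, and the recovery test verifies the engine, not the luck of
the draw.  Consequently a green recovery suite establishes that the engine
finds what is findable; it says nothing about genuinely ambiguous peaks
(which the engine reports as multi-candidate lists) or about real-spectrum
artefacts the generator does not model: multiply-charged species, isotope
envelopes, intensity information, chemical noise.

## Structure export (CDXML)

Every residue carries an all-atom heavy-atom template with two backbone
attachment points; chains are joined by amide bonds (side chains on the
α-carbon for peptides, on the backbone nitrogen for peptoids — the
N-substituted glycine connectivity, which makes every internal peptoid
amide tertiary) and the termini are capped from their own templates.
Hydrogens are implicit, reconciled from standard valences (C 4, N 3, O 2,
S 2, P 5), and the invariant *heavy atoms + implicit H = molecular formula*
is enforced by tests for every shipped residue and terminus, and verified
externally by re-importing exported files with RDKit.

Layout is functional, not aesthetic: fixed bond length, zig-zag backbone,
side chains grown perpendicular, alternating above/below the axis.
Stereocenters are drawn flat (no wedge/hash).  Node ids follow traversal
order and coordinates are fixed-precision, so output is byte-identical
across runs — golden files diff cleanly.  Custom formula-only termini have
no template, and structure export for them fails with a clear message
instead of inventing a connectivity.

## Numeric report conventions

Masses print with 4 decimals, pI with 2, extinction coefficients as
integers, profile values with 3 decimals.  These are formatting choices for
report stability (golden-file tests), not statements of accuracy.

## Known limitations

* pKa values are context-free constants; no charge-state coupling,
  temperature or ionic-strength corrections.
* Nonstandard residues are chargeless in the pI model and invisible to the
  contiguity profile.
* The assignment engine assumes singly-charged species and ignores
  intensities and isotope patterns.
* The seed residue database is a small documented subset of what a hosted
  service accumulates; extend it via the TSV files or
  `register_residue()`.
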