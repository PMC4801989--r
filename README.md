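# pepkit

Property calculators and mass-spectral peak assignment for synthetic
peptides and peptoids, as an offline R library with a command-line front
end.

Peptide chemists routinely need, for a sequence they are about to make or
have just made: its molecular formula and monoisotopic mass, an estimated
isoelectric point, molar extinction coefficients at 280 nm, and — after the
synthesis — an explanation for every extra peak in the crude mass spectrum.
Those peaks are usually *deletion sequences* (chains missing one or more
residues after incomplete couplings), metal adducts (Na⁺/K⁺ replacing an
acidic proton), or unremoved protecting groups such as Pbf on arginine.
Matching dozens of candidate compositions against a peak list by hand is
slow and error-prone; `pepkit` automates it, for peptides and for peptoids
(poly-N-substituted glycines, whose building blocks have no single-letter
code and whose sequences are written `Nme-Npe-...` with repeat groups like
`(Nme-Npe)3`).

## What it computes

* **Formula / molecular weight** — residues are stored as chain-incorporated
  (dehydrated) compositions; termini add their end groups; masses use the
  most abundant isotope of each element (`mass(C) = 12` exactly).
* **Net charge and pI** — Henderson–Hasselbalch summation over ionizable
  groups,

  `charge(pH) = Σ_acidic −1/(1+10^(pKa−pH)) + Σ_basic 1/(1+10^(pH−pKa))`,

  with side-chain contributions from Arg, Asp, Cys, Glu, His, Lys, Tyr and
  the terminal amine/carboxyl (only when the termini are unmodified/acid).
  The pI is the root of this equation on (0, 14), found by bisection.
* **ε₂₈₀** — the Pace estimate `5500·n_Trp + 1490·n_Tyr + 125·n_cystine`,
  reported both fully oxidized (`n_cystine = ⌊n_Cys/2⌋`) and fully reduced.
* **β-strand contiguity profile** — the SALSA sliding-average score
  `ΣP_β / (½(ΣP_α + ΣP_t))` over all windows of 4–20 residues
  (Chou–Fasman propensities); windows under 1.2 are discarded and each
  residue sums the retained windows covering it. Requires ≥ 10 residues.
* **Peak assignment** — iterative deepening: iteration *N* tests every
  combination of ≤ *N* compositional deletions with ≤ *N* modifications
  (metal adducts, licensed protecting groups), assigning a peak when a
  candidate's neutral mass falls within ±1.0 u of the entered singly-charged
  m/z. Iterations are capped at 5/4/3 for sequences of ≤ 30/≤ 60/≤ 150
  residues.
* **CDXML export** — an all-atom ChemDraw XML structure for any sequence
  whose residues have templates (the full shipped database does).

## Worked example

The test suite's worked assignment example is an 11-mer thioester peptide
(`STPLTRPSTPL` with the predefined ethyl 3-mercaptopropionate thioester
C-terminus, full species mass 1284.67 u) and five observed peaks:

```r
library(pepkit)
s <- parse_peptide("STPLTRPSTPL",
                   c_term = "ethyl 3-mercaptopropionate thioester")
assign_peaks(s, c(1063.7, 1197.8, 1315.9, 1450.0, 1537.0))
#> <assignment_report> STPLTRPSTPL (peptide), full mass 1284.6748 u, tolerance 1.00 u
#>  peak_mz deletions adducts calculated_mass  delta iteration
#>   1063.7      R, S      Na       1063.5236 0.1764         2
#>   1197.8         S       -       1197.6427 0.1573         1
#>   1315.9      R, S Na, Pbf       1315.6056 0.2944         2
#>   1450.0         S     Pbf       1449.7248 0.2752         1
#>   1537.0         -     Pbf       1536.7568 0.2432         1
```

Reading: peak 1197.8 is the chain missing one serine (calculated 1197.64,
0.16 u from the observation, found on the first iteration); 1063.7 needs
two deletions (Arg and Ser) plus a sodium adduct, found on the second.
Peaks at higher mass than the product carry unremoved Pbf (+252.08 u,
licensed only because the sequence contains arginine).

A property report for a peptide:

```r
property_report(parse_peptide("ACDEFWKRTG"))
```

returns formula `C53H77N15O16S`, molecular weight 1211.5393 u, pI 6.37,
ε₂₈₀ 5500 M⁻¹cm⁻¹ (one Trp, no cystine), and a charge summary of 3 acidic /
2 basic / 5 other residues.

## Command line

```sh
inst/cli/pepkit peptide --seq "AC(pS)G" --out report.json --cdxml mol.cdxml
inst/cli/pepkit peptoid --seq "(Nme-Npe)3" --peaks "520.3, 803.5"
inst/cli/pepkit fixtures --seed 7 --n-spectra 20
```

Formats: JSON (default) or `--format tsv` (key/value table plus
`*_assignment.tsv` / `*_profile.tsv`). Errors exit nonzero with a single
diagnostic line on standard error.

## Extending the database

Residue, terminus, modification, pKa and Chou–Fasman tables ship as
versioned TSV files under `inst/extdata/`. New residues can also be added
at run time:

```r
register_residue("Nxx", "peptoid", "C7H13NO")
parse_peptoid("Nme-Nxx")   # immediately usable
```

See the methods vignette (`vignettes/pepkit-methods.Rmd`) for the models,
conventions, parameter choices and limitations.
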