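---
title: "Lead selection by descriptor panels, an elimination cascade, and docking post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lead selection by descriptor panels, an elimination cascade, and docking post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadsieve)
```

## The procedure

`leadsieve` implements the in-silico triage that turns a designed compound
library into a short list of lead candidates. The pipeline has three legs:

1. **Descriptors and rule panels.** Each structure gets a physicochemical
   panel -- molecular weight, atom counts, ring count, fraction Csp3,
   rotatable bonds, H-bond donor/acceptor counts, Ertl topological polar
   surface area, Wildman--Crippen WlogP and molar refractivity, and
   Moriguchi MlogP -- which feeds the five standard drug-likeness rule sets
   (Lipinski, Ghose, Veber, Egan, Muegge) plus the six-component CNS MPO
   desirability score.
2. **The elimination cascade.** Ten ordered steps remove compounds that are
   toxic, reactive, or pharmacokinetically unpromising, combining the rule
   verdicts with server-derived annotations (Cramer class, toxicity alert
   flags, solubility and absorption classes, CYP/P-gp interactions,
   drug-likeness and synthetic-accessibility scores). A compound falls at
   the *first* step whose predicate holds; every elimination carries an
   audit record of the clauses that fired.
3. **Docking post-processing.** Given docking outputs -- cluster element
   energies and pose coordinates -- the package computes FullFitness (mean
   of the most favourable 30% of element energies), the inhibition constant
   `Ki = base^((dG*1000)/(R*T))`, symmetry-corrected RMSD bounds between
   poses, lowest-energy binding-site selection, polar contacts in the
   1.49--2.81 Angstrom window, and active-torsion counts.

The package treats external predictive engines (toxicity, solubility,
CYP models, docking searches) as *annotation inputs*, not as things to
re-derive: its own contributions are the descriptor panel, the rule
algebra, the cascade semantics, and the docking arithmetic.

## Assumptions of the cascade

* Steps run in their printed order and a compound is eliminated exactly
  once (first match). Re-running on identical inputs is bit-identical; the
  cascade itself has no randomness.
* "Does not follow rule X" means violation count >= 1 for that rule; the
  violation counts themselves are carried so stricter readings can be
  configured.
* A predicate clause that references a missing annotation field evaluates
  to *not triggered* and the compound is tagged with a warning. The
  rationale: never eliminate on absent evidence.
* Step 3's "does not exceed 0.90" is read inclusively (<= 0.90).
* Step 2's narrative mixes conjunctions and disjunctions; the default is
  the disjunction of the rule-based clause (Lipinski and Veber broken and
  CNS MPO < 4) with each annotation clause (poor solubility, any CYP
  isoform inhibited, P-gp interaction). `step2_strict_and = TRUE` conjoins
  everything instead.
* Step 4's "or overlap with at least one Muegge violation" attaches to the
  Cramer clause by default; `step4_muegge_with_ghose = TRUE` attaches it to
  the Ghose clause.
* Step 7 deliberately subsumes Step 6 (same conditions, no SA floor); the
  redundancy is preserved so audits align with the narrative step numbers.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tox_classes_step1` | 2 | count | flags needed for outright elimination |
| `cnsmpo_min` | 4 | score (0--6) | CNS MPO cut-off in Step 2 |
| `druglikeness_step3` | 0.90 | score | Step 3 rescue threshold |
| `sa_step6`, `sa_step9`, `sa_step10` | 2, 4, 3 | SA score (1 easy -- 10 hard) | synthetic-accessibility floors |
| `druglikeness_step10` | 0.5 | score | Step 10 alternative trigger |
| Ki constants | R = 1.98719 cal/(mol K), T = 298.15 K, base = 2.7182 | | conventional printed values; `e_base = exp(1)` differs by ~3e-5 per exponent unit (about 0.04% at dG = -8.1, under 0.15% anywhere in |dG| <= 20) |
| FullFitness fraction | 0.30 | | most favourable share averaged; element count rounds half-up with a floor of 1 |
| polar-contact window | 1.49--2.81 | Angstrom | inclusive hydrogen-bond contact range |
| oral LD50 bands | 5, 50, 300, 2000, 5000 | mg/kg | GHS/OECD acute oral categories, upper bounds inclusive; above 5000 is "Non-Toxic" |

All rule bounds are inclusive on the printed value; the only strict
comparisons are the two Muegge counts printed with `>` (carbons > 4,
heteroatoms > 1) and the bioactivity interpreter's "more than 0.0".

## Descriptor provenance and numerical choices

* Structure parsing, aromaticity perception, Ertl TPSA, average-mass MW and
  pharmacophore donor/acceptor counts come from OpenBabel (via
  ChemmineR/ChemmineOB). Implicit hydrogens are materialised before any
  counting.
* **WlogP and molar refractivity** are computed in-package from the
  published Wildman--Crippen atom-contribution table. Each atom receives
  the first type in table order whose SMARTS matches rooted at that atom;
  rooted matching is done by wrapping each pattern in a recursive-SMARTS
  environment, which also sidesteps OpenBabel's deduplication of
  automorphic matches on symmetric molecules. On a 20-molecule fixture the
  panel agrees with an independent implementation of the same published
  tables to well under 0.01.
* **MlogP** is the Moriguchi 13-parameter regression, implemented from the
  published descriptor definitions. Where those definitions leave structure
  perception open, this package's reading is: proximity (PRX) counts N/O
  pairs at topological distance 1 (weight 2) and 2 (weight 1) with amide
  N-C(=O) promoted to 2; unsaturation excludes nitro N=O; the
  ring dummy (RNG) fires for any ring system other than pure benzenoid
  carbocycles; the amphoteric dummy recognises alpha-amino acids (1.0) and
  aromatic amino-/pyridine-carboxylic acids (0.5); the intramolecular
  H-bond dummy is a conservative ortho-aromatic donor/acceptor pattern.
* **XlogP** is not computed structurally; it defaults to WlogP with an
  `xlogp_proxied` flag, and an `xlogp` column on the input overrides the
  proxy. The Muegge window (-2..5) is wide enough that the proxy rarely
  flips a verdict; the flag keeps it auditable.
* TPSA follows OpenBabel's extended Ertl parameterisation, which includes
  sulfur/phosphorus contributions; for S/P-free molecules it coincides
  with the original fragment table.
* The Ghose "atoms" bound (20--70) counts *all* atoms including hydrogens,
  matching the original definition; ring count is the smallest set of
  smallest rings (cyclomatic number).
* Percentages and the FullFitness element count round half away from zero
  (`round_half_up()`), so 9/123 prints as 7.3%.
* RMSD bounds: the lower bound is the symmetry-corrected
  `max(RMSD'(a,b), RMSD'(b,a))` with a per-atom, element-restricted
  minimum -- deliberately *not* a bijective assignment, matching the
  symmetry-corrected docking convention; the upper bound is the
  identity-correspondence RMSD. Hydrogens are excluded from RMSD but polar
  hydrogens participate in contact detection. No superposition is applied:
  docking poses share the receptor frame.
* Binding-site ties (equal dG) break to the lowest cluster id and are
  logged.

## The synthetic-data generator

`gen_library()` emulates the screening study's *statistical shape*: 123
taxonomy-coded compounds (ids like `1Aa1`, `4Db6`), 9 of which survive the
default cascade (7.3%), generated deterministically from seed 42.
Per-step elimination quotas default to 30, 25, 12, 8, 7, 5, 8, 6, 8, 5 for
steps 1--10: a front-loaded attrition profile, chosen once as plausible for
a campaign where whole structural classes fall to early toxicity alerts.

Construction is deterministic-assignment-first, noise-second: each
compound gets a target outcome, then a template structure whose
rule-violation profile fits that target (templates are ordinary reference
molecules spanning the rule boundaries -- small polar fragments violate all
four Ghose criteria, long alkylbenzenes violate Ghose/Muegge lipophilicity
bounds, clean drug-like acids violate nothing), then annotations that make
exactly the targeted step fire first. Random noise only touches fields
that cannot flip the outcome. Template profiles are re-derived from the
package's own descriptor panel at generation time, and the generated
library is verified by running the cascade, so infeasibility aborts
generation instead of silently missing quotas.

What the fixtures do **not** emulate: real glutamic-acid-derivative
chemistry, correlated annotation structure (e.g. solubility tracking
lipophilicity), or 3-D conformers beyond jittered skeletons. Passing tests
demonstrate the pipeline's algebra and bookkeeping, not predictions about
any real compound series. Docking fixtures draw element energies from a
normal distribution per cluster (defaults mirror a three-cluster system at
-8.1/-7.6/-6.8 kcal/mol), define the cluster dG as its most favourable
element energy, and jitter a fixed heavy-atom skeleton for poses, with a
permuted-atom-order duplicate for RMSD symmetry checks.

## Problem sizes

The test suite runs the full 123-compound worked example once through the
command-line interface, 50 smaller random fixtures (15--60 compounds) for
cascade conservation, 200 random small poses (up to 6 heavy atoms) against
a brute-force RMSD oracle, and exhaustive FullFitness checks to 12
elements. These sizes give each property dozens-to-hundreds of independent
cases while keeping a full run to tens of seconds.

## Known limitations

* MlogP perception choices above are one defensible reading of the
  published descriptor definitions; molecules dominated by PRX/POL/HB
  corrections may differ from other implementations by a few tenths of a
  log unit. The Lipinski bound (4.15) is rarely near that margin for
  drug-like inputs.
* OpenBabel and other toolkits can disagree on aromatic-NH perception in
  azoles, shifting WlogP by up to ~0.5 for those heterocycles.
* Only the oral route ships a default LD50 band table; other routes need a
  user-supplied table (the route-specific schemes are not standardised in
  a citable form) and otherwise return "Unclassified" with a warning.
* The bijective (assignment-problem) RMSD variant is out of scope; the
  per-atom minimum can undershoot it on degenerate geometries, which is
  why it is reported as a lower bound alongside the identity upper bound.
* The CNS MPO component desirabilities are the conventional six-parameter
  scheme held in a configuration table; alternative breakpoint sets can be
  swapped in without code changes.
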