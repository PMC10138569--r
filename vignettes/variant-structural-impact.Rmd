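---
title: "Assessing the structural impact of missense variants with structvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the structural impact of missense variants with structvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structvar)
```

## The problem

Roughly half of the missense variants reported in clinically important genes
are variants of uncertain significance (VUS): they cannot be classified from
clinical evidence alone, and functional assays do not scale to thousands of
variants.  For a protein with a known or confidently predicted structure, a
substantial part of the missing evidence can be read off the structure itself:
does the substitution sterically fit, which interactions does it break or
create, does it bury a charge or expose a hydrophobic core, does it remove a
glycosylation site or kink a transmembrane helix?

`structvar` implements this workflow as a composable pipeline: in-silico
mutagenesis with a rotamer library, geometric feature extraction, rigid-body
superposition scoring (RMSD and TM-score), stability (ddG) classification,
binarization and consensus of informatics predictors, allele-frequency
evidence, and assembly into the ACMG/AMP computational-evidence codes PP3,
BP4 and PM2.  It ships a curated 30-variant cohort for the retina-specific
ABC transporter ABCA4 (10 ClinVar-benign, 10 pathogenic, 10 VUS) as a
validation fixture, together with synthetic structure generators that plant
each geometric feature in a miniature structure where it can be verified
against brute-force oracles.

## The decision model

Each variant is evaluated along independent axes that are combined only at
the end:

1. **Structural category** (`structural_category()`): a variant is
   *deleterious* (`Del`) if any of the following hold — every rotamer of the
   replacement side chain clashes sterically with the rigid environment; a
   polar contact to a ligand (ATP, Mg, the retinoid substrate), a disulfide,
   or an interdomain/interchain contact is lost; an N-X-S/T glycosylation
   sequon is destroyed; a proline lands in a helix interior; a buried glycine
   is replaced or a buried site changes hydrophobicity class; or the site
   flips between buried and exposed.  It is *mild* (`Mild`) if none of those
   hold but new contacts are gained, and *neutral* (`Neu`) otherwise.  This
   rule set is the complete enumeration of the structural verdicts reported
   for the reference cohort, and it is deliberately conservative: any single
   deleterious finding dominates.
2. **Stability class** (`classify_stability()`): ddG values (kcal/mol,
   computed externally by an energy function such as FoldX and consumed as
   input) are *neutral* in the inclusive band [-0.5, +0.5], *stabilizing*
   below, *destabilizing* above.  The band boundaries are inclusive because
   the reference cohort's own calls require it (+0.48 and +0.15 are called
   neutral, +0.71 destabilizing).
3. **Predictor consensus** (`binarize_predictors()`, `consensus_call()`):
   CADD PHRED >= 20, PolyPhen-2 possibly/probably damaging, REVEL >= 0.5 and
   MutPred-2 >= 0.5 each count as a pathogenic call; a 3-of-4 majority gives
   the collective prediction, anything less is *conflicting*.  Missing tools
   drop out of the denominator; below three available calls no consensus is
   attempted.
4. **Population absence** (`pm2_check()`): PM2 requires absence from gnomAD,
   ExAC and 1000 Genomes simultaneously.
5. **Evidence assembly** (`assemble_evidence()`): PP3 requires consensus
   pathogenic *and* a deleterious (or loss-of-function) structure; BP4
   requires consensus benign *and* a neutral structure; a predicted complete
   loss of function (e.g. a splice-disruption truncation) overrides the
   categorical axes and forces pathogenic support.  Structure/predictor
   disagreement is reported as *conflicting*, never silently resolved.

Conservation grades are carried as annotation only; they corroborate but do
not enter the final call, because no quantitative decision rule for them is
part of the validated workflow.

## Geometric criteria and their defaults

All criteria are heavy-atom and distance-based (the inputs — cryo-EM models
and predicted structures — carry no hydrogens):

| criterion | default | unit |
|---|---|---|
| severe clash (vdW overlap) | >= 0.4 | A |
| hydrogen bond (N/O/S donor-acceptor) | <= 3.5 | A |
| salt bridge (charged N to charged O) | <= 4.0 | A |
| disulfide (SG-SG) | 1.8-2.5 | A |
| buried residue | RSA < 0.25 | fraction |
| pLDDT low confidence | <= 50 (inclusive) | — |

1-2 and 1-3 bonded pairs are excluded from clash counting and 1-4 pairs are
reported separately, following the usual severe-clash convention.  Histidine
is treated as potentially charged in salt-bridge detection but classed as
polar for the buried-polarity rule.  All thresholds are config-overridable
(`pipeline_config()`); the defaults are standard conventions, since the
interactive tools used for the original analyses do not expose their exact
cutoffs.

Solvent accessibility is computed by Shrake-Rupley point sampling (480
golden-spiral points per atom by default; doubling the sampling moves atomic
ASA fractions by under 1%).  RSA normalizes by the Miller extended
Gly-X-Gly standard-state areas, chosen over "theoretical maximum"
normalizations because an honestly computed extended tripeptide then scores
RSA close to 1, which is the property the burial cutoff is calibrated
against.

## Mutagenesis model

Side chains are rebuilt from ideal internal-coordinate templates
(Engh & Huber-style bond lengths and angles, L-configuration calibrated
against experimental structures) at the chi angles of a compact
backbone-independent rotamer library (1-5 rotamers per amino acid with
probabilities, shipped as `inst/extdata/rotamers.tsv`).  The backbone and
every other residue are held rigid — no repacking, no minimization — which
mirrors interactive mutagenesis tools and makes the all-rotamer clash verdict
well defined: a substitution is sterically impossible at a site exactly when
*every* library rotamer produces at least one severe clash.  Placements are
ordered by descending library probability with ties broken by ascending chi1,
so results are deterministic.  One consequence worth knowing: in a helix
interior, gauche side-chain rotamers genuinely overlap the preceding
carbonyl oxygen (~1 A overlap), so "all rotamers clash-free" outcomes are
realized in open environments (surface sites, helix termini), not in packed
interiors — that is physics, not an artifact.

## Superposition scoring

`kabsch_superpose()` computes the least-squares rigid superposition by SVD
with reflection correction; `tm_score()` maximizes the standard
length-normalized similarity `TM = (1/L) sum 1/(1 + (d_i/d0)^2)` with
`d0 = 1.24 (L-15)^(1/3) - 1.8`, seeding from the full residue set and sliding
fragments and iteratively re-superposing on residues below a shrinking
distance cutoff (d0 down to d0/2, at most 20 iterations).  On instances of
up to 30 residues every sliding fragment is used as a seed, so small-instance
results coincide with exhaustive fragment-seeded search; larger instances use
the usual L, L/2, L/4 schedule.  Model comparison is Calpha-based with
identity correspondence and **no outlier rejection** — deterministic, and
deliberately different from interactive `align`-style commands that trim
atoms.  TM is normalized by the WT chain length.  Because both scores depend
on the specific predicted models, the cohort fixture carries them as recorded
inputs; the package recomputes scores only for structures it is given.

## The splice-consequence model

One cohort variant (c.5584G>A) is annotated as missense (p.G1862S) but
disrupts the donor site at the last base of its exon.  The package models the
consequence as *full retention of the downstream intron*: the mRNA is rebuilt
with the intron kept and the donor -1 substitution applied, translated to the
first stop, and the truncation is accounted against the domain map
(`translate_and_diff()`), reporting the last preserved residue, the novel
residues, and fully/partially lost domains.  Retention is an interpretation
(exon skipping is not modeled), and splice-site strength scoring is out of
scope — the disruption itself is an input assertion.  `toy_transcript()`
builds a miniature gene with a configurable novel-residue run (donor -1 G>A,
junction phenylalanine) that mirrors the cohort case at desk scale, including
a degenerate non-stop configuration.

## The packaged cohort and what validation shows

`table1_fixture()` returns the 30-variant ABCA4 cohort: HGVS identities,
ddG values, RMSD/TM scores, gnomAD frequencies, per-tool predictor calls
(including the three 3-vs-1 conflicting panels), and *encoded* structural
findings — an explicit transcription of the reported per-variant analyses
(lost/gained contacts with their domain relations, clash verdicts, burial
flags), not geometry recomputed by this package, because the underlying
full-length predicted models are not redistributable.  The fixture metadata
states this.  Domain boundaries in `inst/extdata/abca4_domains.json` are
approximate (the exact residue ranges are not published); fixture contacts
therefore carry their domain relation directly, so no cohort-level result
depends on the approximate map.

Replaying the cohort through the decision layer reproduces, by computation:
6 neutral / 3 stabilizing / 1 destabilizing among the ten benign-group ddG
values; 8 neutral + 2 mild structural categories for the benign group and 10
deleterious for the pathogenic group; 7 of the 9 missense VUS
consensus-pathogenic, 5 VUS absent from all population databases (PM2), and
final calls of pathogenic support for 8 VUS and benign support for 1
(p.V1211I), with the structurally deleterious but predictor-benign p.N98K
reported as conflicting.  `scripts/acceptance.R` recomputes the four
headline counts from the installed package.

The synthetic generators validate the geometry the encoded findings assume:
each `build_toy_structure()` kind plants exactly one feature (a 3.9 A salt
bridge, a 2.05 A disulfide, a 2.9 A ligand contact with a clash trap for
proline, an all-rotamer clash cage, an ideal helix, an extended tripeptide)
and the corresponding detector — and only it — recovers the plant.  What
passing these tests shows is that the *rules* and *detectors* behave as
specified on unambiguous geometry; they do not show that any particular
predicted model of a real protein is accurate, and they cannot, since model
quality is an input (tracked per residue via pLDDT flags, with two cohort
positions marked low-confidence).

## Problem sizes and numerical choices

The test suite and the acceptance script run on miniature inputs by design:
toy structures of 1-60 residues, sphere sampling at 480-960 points,
superposition instances of 25-60 residues, and the 30-record cohort — the
whole suite completes in well under a minute.  Degenerate inputs are handled
explicitly: inverted trim ranges, identity substitutions, sub-3-point
superpositions, TM normalization below 22 residues (where d0 is undefined),
glycine side chains, missing intron sequences and non-stop translations all
raise informative errors or flags rather than propagating nonsense.  Boundary
conventions are inclusive throughout (clash overlap >= 0.4, ddG band
[-0.5, +0.5], pLDDT <= 50, REVEL/MutPred-2 >= 0.5) because the cohort's own
printed calls pin them.

## Known limitations

* The environment is rigid during mutagenesis: no repacking of neighbours, no
  backbone relaxation.  Clash verdicts are therefore conservative upper
  bounds on steric strain.
* Contact criteria are distance-only (no angular terms), as the inputs carry
  no hydrogens.
* The structural category is a rule set, not a trained model; it reproduces
  the reference cohort by construction of its rules and should be re-examined
  before transfer to proteins with very different architecture.
* Electrostatic surface potentials, conformational dynamics and splice-site
  strength scoring are out of scope; ddG and predictor scores are consumed,
  never computed.
* The pipeline is exposed as R functions (`run_pipeline()` and the module
  functions documented here); there is no shell entry point, as the intended
  users drive it from R scripts.
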