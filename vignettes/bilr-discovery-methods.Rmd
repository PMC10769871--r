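---
title: "Discovering and profiling bacterial bilirubin reductase in silico"
author: "bilRscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and profiling bacterial bilirubin reductase in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilRscreen)
```

## The problem

Gut bacteria reduce bilirubin, the terminal haem-degradation pigment, to
urobilinogen; the enzyme responsible, bilirubin reductase (BilR), is an
Old Yellow Enzyme–family flavin-dependent oxidoreductase. Identifying the
gene behind this phenotype and mapping its distribution across human gut
metagenomes involves four computational stages, each of which this
package implements as a tested, reusable component:

1. **Assay calling** — turning replicate urobilin-fluorescence
   measurements into reducer / non-reducer strain phenotypes.
2. **Comparative screening** — clustering proteomes of reducer and
   non-reducer strains into orthogroups and nominating candidates whose
   presence/absence pattern tracks the phenotype and whose members are
   annotated as oxidoreductases (EC class 1).
3. **Profile-HMM classification** — modelling the BilR TIM-barrel region
   (the first 373 residues of the reference protein) as a profile hidden
   Markov model, scanning protein databases, and applying a four-part
   quality control: E-value strictly below $10^{-100}$, target at least
   50% of the reference protein length, the conserved His-Gly-Asp-Arg
   (HGDR) motif at its homologous alignment columns, and exactly the
   expected Pfam domain architecture (PF00724 for short BilR; PF07992 +
   PF00724 for the long form).
4. **Metagenome profiling** — counting reads that map to a *bilR* gene
   reference set per stool metagenome, normalizing to counts per million
   (CPM), calling presence at CPM > 5 (strictly), and comparing cohort
   prevalence with a two-proportion chi-square test.

Every stage is driven from a single configuration object
(`bilrConfig()`) so that no decision threshold is duplicated in stage
code.

## Synthetic data as the test bed

The real study inputs are large external resources (reference genome
databases, thousands of SRA metagenomes). The package therefore ships
generators that emulate each input *with recorded ground truth*, and the
test suite and acceptance script measure the pipeline against that
truth. What the generators emulate, and deliberately do not:

* `generatePangenome()` builds reducer/non-reducer strain proteomes.
  Each orthogroup descends from a random ancestral protein by i.i.d.
  substitutions (`noise`, default 0.05, plus occasional short indels in
  background families); background groups are present in each strain
  independently with probability $p = 0.7$, so a background group
  matches a 5-vs-5 phenotype split by accident with probability
  $p^5 (1-p)^5 \approx 4.1 \times 10^{-4}$ — about 0.08 expected false
  patterns per 200-group fixture. Six percent of background families
  carry EC class-1 annotations (roughly the oxidoreductase share of
  annotated orthogroups in real bacterial pangenomes, where a few
  hundred of several thousand orthogroups are class 1), 45% carry other
  EC classes, and the rest are unannotated. The planted causal group
  tracks the phenotype exactly and is class-1 annotated. This is not a
  phylogenetically realistic simulation — there is no shared gene tree,
  no rate variation — which is fine for its purpose: exercising
  presence/absence logic, not ancestral reconstruction.
* `generateBilrFamily()` builds a clade of short (TIM-barrel only,
  380 aa) and long (+160 aa NAD(P)H-binding extension) BilR-like
  proteins around a common core with HGDR at reference positions
  164–167, together with the clade alignment and a Pfam-style domain
  table. Decoys each violate exactly one classification filter (motif
  mutated to HGAA — the D$\to$A, R$\to$A double mutant —, truncation
  below half the reference length, an extra PF01266 domain, or no
  homology at all), so the classifier's audit trail can be checked
  filter by filter.
* `generateMetagenome()` draws reads from three origins — a *bilR* gene
  reference set, a host "contaminant" reference, and a random background
  genome — at recorded per-sample fractions, with per-base substitution
  errors and constant Phred-40 qualities (no stage consumes quality).
  Per-origin counts are deterministic rounds of fraction × reads rather
  than multinomial draws: a sample's true CPM is then exactly
  `fraction * 1e6`, so presence truth remains recoverable even when the
  expected gene-read count is a single read in 50,000 — the regime the
  infant-gut analysis lives in. Read positions, strands and error
  positions stay random.
* `generateFluorescence()` plants reducer strains at `foldChange` times
  the abiotic-control mean with lognormal replicate noise of a given
  coefficient of variation.

Because the fixtures are synthetic, passing tests demonstrate that the
*pipeline logic* is correct under known truth; they do not validate the
biological thresholds themselves against real data.

## Statistical and numerical choices

**Reducer calls.** The fluorescence ratio is the mean of strain
replicates over the mean of abiotic-control replicates (medians are
available behind `center = "median"`). The call is strictly
above-threshold: a ratio of exactly 5 is a non-reducer. Supporting
t-tests are computed on log2-transformed raw fluorescence, not on
ratios. The two-sample test defaults to Welch (unequal variances) —
the safer choice when replicate counts are 3–4 — with pooled variance
available via `varEqual = TRUE`; the degenerate zero-variance case
(identical groups) returns $t = 0$ and one-sided $p = 0.5$ rather than
erroring.

**Orthogroup clustering.** Dedicated orthology tools are out of scope;
`clusterOrthogroups()` is a transparent reciprocal-best-hit stand-in
with the same output contract. Scores are Smith–Waterman local
alignments (BLOSUM62, gap open 11, extend 1); a hit requires at least
`minScoreRatio` (0.3) of the query's self-score; best-hit ties break by
lexicographic protein id so the partition is deterministic and
order-invariant. A shared-5-mer prefilter keeps the number of computed
alignments proportional to the number of genuinely homologous pairs.

**The oxidoreductase filter.** "Groups containing only more than 2
proteins assigned to EC 1.-.-.-" is genuinely ambiguous. The default
reading keeps groups with **at least 3 class-1-annotated members**;
the alternative ("more than 2 members, all class-1") is available via
`ecAllMembers = TRUE`. EC matching is by class prefix; malformed EC
strings warn and count as unannotated. The candidate screen composes
this filter with the strict phenotype pattern match (present in every
reducer, absent from every non-reducer); the two filters are pure and
commute. Note that with 200 background groups the pattern filter alone
admits an accidental candidate in roughly 8% of fixtures — it is the
composition with the EC filter, as in the discovery workflow, that
makes recovery of exactly the planted gene the overwhelmingly likely
outcome.

**Profile HMM.** The profile is Plan-7-like: match columns are the
alignment columns where the reference has a residue inside the modelled
span, demoted to insert columns when more than 50% gapped
(configurable); emissions are Laplace (+1) estimates over the
20-residue alphabet; transitions are counted from the alignment's gap
structure with add-one pseudocounts. The search is a local Viterbi with
free entry/exit at any match column (Smith–Waterman style), inserts
emitting at background, scores in bits. This reproduces the "scanner
with a hard E-value cut" usage of a full HMM search tool at desk scale;
it does not reproduce full forward/posterior machinery, bit-score
semantics, or domain envelopes, which the pipeline does not need.
E-values come from a Gumbel null fitted by maximum likelihood (moment
start, BFGS refinement) to Viterbi scores of i.i.d. background
sequences; $E(s) = N(1 - \exp(-e^{-\lambda (s - \mu)}))$. The
E-value comparison is strict (< $10^{-100}$) and applies to the
full-sequence score. The reference length used by the 50% filter is an
explicit profile field (default: the full degapped reference protein),
never a hard-coded constant, because which reference protein defines
"the length" is a modelling decision.

**Motif detection** is by column homology: the residues aligned to the
four motif match columns must spell HGDR with no deletions. A
substring search (`motifMode = "regex"`) is provided as a fallback but
the column-anchored mode is the default precisely because it rejects
spurious HGDR substrings outside the conserved site (the test suite
plants one to prove it). Domain architecture uses set semantics:
duplicate accessions collapse; any unexpected accession fails;
missing annotation fails with reason `"unannotated"` rather than
erroring.

**Read processing.** Host subtraction removes reads whose canonical
k-mer (k = 31) sharing with the host reference reaches 50%. Mapping is
an exact-k-mer (k = 21) seed with ungapped diagonal extension at ≥ 90%
identity over the read, both strands, each read counted once — a
deterministic, testable presence counter standing in for a full
aligner. The CPM denominator is the post-host-removal read count (the
count available at the alignment step); `cpmDenominator = "raw"`
exposes the pre-removal reading since the wording "total number of
reads in the sample" is ambiguous. Sample QC keeps samples with at
least one million reads (inclusive boundary; scale `minReads` down for
fixtures). Age bins are half-open $[30i, 30(i+1))$ days over the first
year; samples without age metadata are excluded from binning. Healthy
adult cohorts exclude samples below 3 years of age; IBD samples split
into Crohn's disease and ulcerative colitis groups. Prevalence
comparisons use `stats::prop.test` semantics (chi-square test of equal
proportions, 1 df), with the Yates continuity correction on by default
to match that function's default.

## Problem sizes

The test suite and the acceptance script run at fixture scale, chosen
as the smallest sizes at which each statistical property is
informative: 100 seeds of 200-group pangenomes for screen recovery;
20-protein families for classification; metagenome collections of 20
samples × 50,000 reads, with true CPM 20 corresponding to a single
expected gene read per positive sample; 2,000–5,000 draws for Gumbel
calibration checks. The Viterbi implementation is verified exactly
against exhaustive path enumeration on profiles of up to 5 match
states and targets up to 6 residues, where enumeration is feasible.

## Known limitations

* The clustering stand-in does not reproduce any particular orthology
  tool's groupings, only the output contract the screen needs.
* EC labels and Pfam domains are consumed as input tables; the package
  does not predict either (a lightweight stand-in annotation path would
  hide that substitution rather than flag it).
* Gumbel calibration assumes the null score distribution is
  Gumbel-shaped, which holds for local ungapped-ish alignment scores;
  extreme tail extrapolation (far below the calibration sample) relies
  on that parametric form.
* The generators do not simulate phylogeny, quality-score error
  profiles, or adaptor contamination; conclusions about real-data
  robustness to those features need real data.
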