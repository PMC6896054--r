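---
title: "The neoantigen fitness-cost model in neofit"
author: "neofit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neoantigen fitness-cost model in neofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofit)
```

## The scientific question

Actinic keratoses (AK) are UV-induced precursor lesions, a small fraction
of which progress to invasive cutaneous squamous cell carcinoma (cuSCC).
Under the immunoediting model, lesions the immune system can see are
eliminated or held in equilibrium; invasive carcinomas have escaped. The
analysis implemented here asks which property of a lesion's neoantigen
repertoire — the number of mutations, the number of MHC-binding
neoepitopes, their predicted TCR recognition, their combined fitness cost,
or the expression-weighted version of that cost — distinguishes the two
lesion classes in a small two-group cohort.

## The model

**Candidate neoepitopes.** For each non-synonymous SNV the surrounding
21-residue window of the protein is taken (10 residues per flank, truncated
at the termini), the mutant window is the wild-type window with the
alternate residue substituted, and every contiguous 9-mer of the pair is a
candidate (a full-length 21-mer yields 13 windows; a window of length $L$
yields $L-8$). All windows are enumerated and counted whether or not they
contain the mutated residue; a `contains_mutation` flag records which do.
SNVs within 1 bp of an indel call are removed first, as likely alignment
artifacts. Indels themselves are retained in mutation counts but generate
no peptides, because single-residue substitution is the only change the
peptide model describes.

**MHC binding.** Each 9-mer receives the minimum predicted dissociation
constant over the sample's (up to six) HLA class I alleles, selected
independently for the mutant and its wild-type counterpart. A mutant 9-mer
with $K_d^{MT} < 500$ nM (strict inequality; the threshold is
configurable) is a *binding* neoantigen. The amplitude

$$A = \frac{K_d^{WT}}{K_d^{MT}}$$

rewards mutants that bind well while their wild-type counterpart does not —
the counterpart's binding matters because T cells recognizing well-presented
self peptides are deleted during thymic selection. An optional cap on
$K_d^{WT}$ (`wtKdCap`, default off) is provided as a monotone hook for
predictors whose affinity estimates saturate far above their training
range; no specific functional form is imposed.

**TCR recognition.** The similarity $|s,e|$ between a candidate $s$ and a
known T-cell epitope $e$ is the maximal-scoring ungapped local alignment
under BLOSUM62 — the maximum, over all equal-length contiguous substring
pairs of length $\ge 1$, of the summed substitution scores. The package
embeds the canonical NCBI integer matrix as a constant (cross-checked in a
test against the copy shipped with Biostrings) so scores cannot drift with
an external dependency. The recognition potential is a two-state partition
function over the unbound state and all bound epitope states,

$$R \;=\; Z(k)^{-1}\sum_{e}\exp\!\big[-k\,(a-|s,e|)\big],\qquad
Z(k) \;=\; 1+\sum_{e}\exp\!\big[-k\,(a-|s,e|)\big],$$

with $a = 26$ (horizontal displacement of the binding curve, in
alignment-score units) and $k = 4.87$ (steepness). Since
$k\,(a-|s,e|)$ spans roughly $-100$ to $+150$, the sum is evaluated by
log-sum-exp and $R = S/(1+S)$ as `plogis(log S)`; $R$ is mathematically in
$[0,1)$, although when the best similarity reaches about 33 the quantity
$1-R$ underflows double precision and $R$ prints as 1. $R$ is computed for
records passing the binding filter (only those enter any downstream
quantity; a `computeAllR` switch scores every window when wanted).

**Fitness cost and expression adjustment.** The fitness cost is
$F = A \times R$, kept positive: a larger $F$ predicts more immune-mediated
destruction. Within each sample, every record with $F>0$ receives an
expression fraction $\mathrm{RPKM}_i / \sum_j \mathrm{RPKM}_j$ (the sum
over that sample's $F>0$ records; RPKM is used for both numerator and
denominator since the expression input is RPKM-normalized), and the
adjusted fitness cost is $F$ times that fraction. Records on transcripts
absent from the expression table get RPKM 0; a sample whose $F>0$ records
carry zero total RPKM has an undefined adjustment and is flagged.

**Per-sample summaries and eligibility.** *Immunogenic* means binding with
$R > 0$ (exactly zero only when the bound-state sum is zero); *stringent*
means binding with $R \ge 0.01$. Per-sample means of $K_d^{MT}$, $A$, $R$
and $F$ are taken over the immunogenic records by default (configurable to
the binding set); the averaging population feeds the fitness comparison,
which is restricted to samples defined by their immunogenic neoantigens.
The maximum fitness cost is taken over immunogenic records, and the
adjusted mean/maximum over records with a defined adjustment. A sample
enters the between-group comparison when it has more than one immunogenic
neoantigen (configurable). The magnitude-outlier exclusion — dropping a
sample whose maximum fitness cost sits two orders of magnitude below the
cohort mean — is implemented as an explicit, off-by-default rule rather
than a hard-coded case, since it encodes a judgment about one sample.

## Statistics

Count metrics (somatic mutations, binding and immunogenic counts) are
compared over all samples; fitness metrics over eligible samples only.
`wilcoxonRankSum()` offers three modes. *Exact* enumerates all
$\binom{n_x+n_y}{n_x}$ assignments of the observed (mid-)ranks and doubles
the smaller tail (capped at 1); on tie-free data this equals the
probability of a rank sum at least as far from its null mean as observed,
and is verified against that independent formulation and against
`wilcox.test`. *Normal* is the tie-corrected large-sample $z$ test without
continuity correction — the behaviour of mainstream statistics packages'
rank-sum command. `compareGroups()` defaults to the normal mode: at the
3-vs-4 design the smallest attainable exact two-sided p is
$2/\binom{7}{3} = 0.057$, so an exact test can never reach the
conventional 0.05 level there, whereas the normal approximation assigns
the fully separated arrangement $z = 2.12$, $p = 0.034$. This choice is a
property of the test, not of the data; the exact mode remains available
and is what `auto` picks at small tie-free sizes.

Spearman's rho is the Pearson correlation of mid-ranks via `cor()`;
least-squares slopes and $t$-based 95% CIs come from `lm()`; Bonferroni
correction is `p.adjust()` behind a domain check. The HLA checks flag
variants inside annotated HLA-A/B/C exons (user-supplied BED, 0-based
half-open on disk, converted on import) and inside exons 2–3, which encode
the peptide-binding groove; the expression check asks whether a mutated
gene's expression lies within two sample standard deviations
($n-1$ denominator, appropriate at cohort sizes under ten) of the cohort
mean.

## The synthetic cohort generator

The study's exome data are not public, so `generateCohort()` produces
complete, seeded input bundles with the statistical structure the analysis
assumes. What it emulates, and the choices behind the defaults:

* **Design**: 3 group-A plus 4 group-B samples — the eligible-sample
  configuration of the motivating study (`nSamples = c(3, 4)`).
* **Burden**: per-sample somatic mutation counts uniform on 50–5000,
  emulating the two-orders-of-magnitude spread seen in such cohorts. Half
  of SNVs are non-synonymous; 3% of calls are indels, and 20% of indels
  get a planted SNV 1 bp away so the proximity filter has ground truth to
  remove (the manifest lists these).
* **Proteome**: 60 random proteins of 300–600 residues drawn with natural
  (Swiss-Prot average) residue frequencies. Composition matters: under a
  uniform alphabet the heavy BLOSUM62 diagonal (W = 11, minimum diagonal 4)
  makes random 9-mer pairs reach similarity $\ge a$ at about $10^{-4}$ per
  pair, flooding the cohort with spurious high-$R$ records; natural
  frequencies put that tail orders of magnitude lower, as in real
  proteomes.
* **Dissociation constants**: a pure hash-based lognormal model
  (`syntheticKdPredictor`). Each (allele, position, residue) combination
  maps through a stable multiplicative string hash to a standard-normal
  effect; a peptide's log-$K_d$ is the scaled sum of its nine positional
  effects, so the model is deterministic, allele-specific, and gives
  single-residue neighbours (mutant vs wild type) correlation 8/9. The
  lognormal sd is 2 ("lognormal-range" affinities); the mean is calibrated
  as `log(500) - 2*qnorm(target)` with a marginal per-(peptide, allele)
  binding target of 0.005, chosen so that after best-of-six-allele
  selection about 3% of 9-mer windows bind — the binding:possible ratio
  the published per-sample count table shows.
* **Epitope reference and drivers**: each sample carries one planted
  immunodominant driver mutation. A driver site converts its wild-type
  9-mer into the epitope entered into the reference set, so its
  recognition potential is essentially 1; candidate sites are accepted
  only when a mutant window close to the epitope binds one of the sample's
  alleles below 500 nM *with amplitude at least 2*, making the planted
  neoantigen both presented and novel to the repertoire — and guaranteeing
  it heads the sample's fitness ranking. Background mutations avoid driver
  neighbourhoods so planted structure stays identifiable. The reference is
  completed with 15 random decoy sequences (9–13 residues, natural
  frequencies).
* **Expression and the group effect**: RPKM is lognormal(meanlog 1,
  sdlog 0.5) per transcript and sample — a modest between-sample
  dispersion chosen, before any end-to-end runs, from an abstract design
  calculation of the adjusted-maximum comparison's noise budget. In
  group-B samples the top `suppressionTopK = 3` distinct transcripts by
  fitness cost are multiplied by `suppressionEffect = 0.05` (20-fold
  down). "Top-k" counts distinct transcripts in descending-fitness record
  order, so the planted driver is always covered and up to two further
  transcripts — including any background record that happens to resemble
  an epitope — are suppressed with it. One driver per sample rather than
  several is deliberate: it leaves those two spare suppression slots, which
  is what makes the planted effect reliably expressible.

Everything derives from one integer seed (`simConfig(seed = )`); the
generator reuses its internal scoring pass to place the expression effect,
and the bundle plus manifest are byte-reproducible.

What the generator does **not** emulate: clonal architecture and variant
allele frequencies, phased multi-mutation peptides, real HLA binding
motifs (the hash model has no anchor positions), curated epitope-database
content, transcript-level expression correlation structure, and the exact
zero-$R$ records real pipelines produce by numeric underflow at coarser
precision — in the synthetic cohorts every binding record has $R > 0$, so
immunogenic and binding counts coincide. Passing tests therefore show that
the pipeline's arithmetic, filters and statistics behave as specified and
that the expression-suppression signature is recoverable under realistic
noise — not that the affinity or recognition predictions themselves are
biologically accurate.

## Numerical and design notes

* Coordinates are 1-based and closed everywhere internally; VCF and TSV
  protein positions are 1-based, BED is converted on import.
* Result TSVs print doubles with 6 significant digits for diffability;
  data TSVs (variants, expression, Kd) print with `%.17g` and round-trip
  bit-identically.
* Two-sided p-values throughout; doubling convention for the exact test.
* Duplicate 9-mers from overlapping windows or recurrent mutations are
  kept as separate records keyed by (sample, variant, window): the
  published per-sample counts are window counts.
* Multiple variants falling in one 21-mer window each generate their own
  pair against the reference protein; no phasing is attempted.
* Ungapped alignment allows overlaps of length 1 and up; no minimum
  overlap is imposed (configurable only through the substitution matrix).
* The per-test problem sizes (cohort sizes in unit tests, 100 seeds for
  the recovery simulations, 1000 alignment-oracle pairs) are chosen to
  give stable pass/fail behaviour at interactive runtimes.

## Limitations

The fitness model inherits the assumptions of its components: affinity
predictions stand in for presentation, sequence similarity to known
epitopes stands in for TCR recognition, and RPKM fractions stand in for
antigen abundance. The 3-vs-4 design has essentially one informative
arrangement, so significance there means complete group separation — the
package reports this honestly rather than smoothing over it. Indel- and
fusion-derived neoantigens, MHC class II, and clonality weighting are out
of scope.
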