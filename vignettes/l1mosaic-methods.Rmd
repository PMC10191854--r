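---
title: "Models and methods behind l1mosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind l1mosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1mosaic)
```

# Scope

`l1mosaic` analyses somatic LINE-1 retrotransposition (soL1R) in panels of
single-cell-derived clones: it validates and classifies mobile-element
insertion calls, reconstructs the early developmental phylogeny of the
clones from shared postzygotic mutations, assigns developmental stages to
branches, estimates mutation-normalized retrotransposition rates, traces 3'
transductions back to their source elements, scores L1 promoter methylation,
and measures genomic-feature enrichment of insertion sites. Because the
single-cell whole-genome data this kind of study rests on are controlled
access, the package ships a synthetic-data generator that reproduces the
*statistical structure* of such data, so the full pipeline is exercisable
and its estimators can be calibrated end to end.

# Insertion calls

## Validation and VAF

A candidate insertion passes validation when it shows the two hallmarks of
target-primed reverse transcription -- a poly-A tail and a target-site
duplication (TSD) -- and when insertion-supporting read pairs are at least
10% of all read pairs at the site. Blunt (TSD-less) insertions do occur, so
`validate_insertion(allow_tsd_absent = TRUE)` can let them through with an
explicit exception flag; the default is strict.

The insertion VAF is defined on spanning ("informative") read pairs, with
reference pairs counted twice because an insertion presents two junctions:

$$\mathrm{VAF} = \frac{s}{s + 2r}$$

where $s$ and $r$ are insertion- and reference-supporting pair counts. A
fully clonal heterozygous insertion therefore sits near 0.5, and cell
fraction is `2 * VAF` capped at 1 (`call_clonal_in_cancer()`; sex-chromosome
ploidy is a parameter). The clonality cutoff for cancer samples is anchored
on the minimum cell fraction of insertions shared by multiple normal clones,
which are necessarily true events.

## Classification and fingerprinting

Classes follow what the inserted segment maps to: only L1 consensus
(`solo`), L1 plus unique downstream sequence (`partnered`), unique sequence
only (`orphan`). A unique transduced segment is attributed to the source
element whose 3' end lies within 15 kb upstream of it, *in the source-strand
sense*: transduced sequence lies 3' of the source, so on a minus-strand
source the window extends to lower coordinates. Distance is the gap between
the source 3' end and the segment (a segment starting immediately after the
3' end has distance 0). When two sources fall in the window the nearer one
wins and the call is flagged ambiguous rather than silently resolved.

Mechanism flags are inferred from breakpoint anatomy: `twin_priming` when
the two insert ends map to the L1 consensus on opposite strands (an
internal inversion of the retrotransposed body); `foldback` when the 5'-most
inserted sequence maps back near the breakpoint on the opposite strand (an
inverted duplication of the target flank); and `extra_synthesis_len`, the
inserted bases accounted for by neither mapped segments, poly-A, nor flank
duplication. Twin priming in a partnered event whose 3' end is the unique
segment is not detectable by this two-end rule; the generator therefore
draws twin priming for solo and partnered events but only solo events are
flagged at detection, a deliberate asymmetry between truth and observation.

# Phylogeny reconstruction

Reconstruction follows the genotype-matrix procedure exactly: candidate
mutations need depth >= 5 in every sample and VAF >= 0.25 in at least one
sample; the binary genotype is VAF > 0.1 (strict); all-ones rows are
germline and dropped. Mutations are grouped by the exact set of carrying
samples, and nested groups define the rooted tree, with branch length the
group's mutation count.

The grouping rule does not say how to resolve *conflicting* groups
(overlapping, non-nested sample sets, which arise from genotyping noise).
We resolve greedily: groups are accepted in decreasing size (ties broken
lexicographically by sample-set key), and a group incompatible with the
accepted laminar family has its mutations discarded from the tree and
logged in `tree$discarded`. This mirrors standard perfect-phylogeny
practice, is deterministic, and keeps the accepted rules intact; on
conflict-free input it is exact, which the tests verify against an
independent shared-mutation oracle (in a perfect phylogeny, the molecular
time of a pair's MRCA equals the number of mutations the two samples
co-carry).

# Staging, EPMs and rates

Branches are staged by two observables: shared branches whose mutations are
detectable in bulk blood are pregastrulational (blood is mesodermal,
colorectal epithelium endodermal, so cross-germ-layer detection predates
germ-layer separation); shared branches absent from blood are
postgastrulational; terminal branches of normal clones are ageing; the
clonal branch of a matched cancer is tumourigenesis. Missing blood data
defaults shared branches to postgastrulation, with a warning.

The molecular clock for rates is the endogenous point mutation (EPM) count:
SNVs attributed to SBS1 and SBS5/40 plus indels attributed to ID1 and ID2.
Attribution is by non-negative least-squares refitting of the stage's
mutation spectrum against a reference signature matrix
(`fit_signature_exposures()`), not per-mutation probabilistic assignment --
refitting is deterministic and testable, and de novo signature extraction is
out of scope. Exposures stay real-valued internally and are rounded only
where a count is needed.

Rates are events per 1,000 EPMs with the exact Poisson (chi-square
quantile) interval; two rates are compared with the exact conditional
binomial test (conditional on the total event count, the split is binomial
with probability proportional to exposure). Molecular time converts to cell
generations with the stage-specific per-division rates 2.4--3.8 pcpcd for
the first two divisions and 0.7--1.2 pcpcd after; for a rate pair
$(r_1, r_2)$, $g = m/r_1$ if $m \le 2r_1$, else $g = 2 + (m - 2r_1)/r_2$,
and the fast/slow pairs give the earliest/latest consistent generation.
Other inversion conventions (e.g. applying each rate bound to both epochs
asymmetrically) yield different outer ranges; we document ours and do not
attempt to reverse-engineer alternatives.

# Source activity and population frequency

Per-source activity is TPAM: transductions per L1 allele per million EPMs of
molecular time, over the individuals carrying the source. Whether to pool
exposures across carriers or average per-carrier rates is an open choice; we
pool (ratio of sums), because under Poisson counts the pooled estimator is
the maximum-likelihood rate and is unbiased, whereas the mean of per-carrier
ratios is dominated by low-exposure carriers. Postzygotic sources count one
allele in carrier lineages only.

Population allele frequency (PAF) is the percentage of panel individuals
with presence evidence >= 15% (L1-supporting reads for non-reference
sources, short-insert deletion-opposing reads for reference sources).
Truncation status is "truncated" only when every informative allele carries
a stop or frameshift inside an ORF; ORF intervals are configuration, with a
shipped L1HS consensus annotation (`l1_orf_annotation()`) as default.

# Promoter methylation

In a clonal genome a CpG's methylated fraction is effectively a diploid
genotype: below 25% homozygous demethylated (score 0), at least 75%
homozygous methylated (score 10), otherwise heterozygous (score 5). The
promoter score is the mean CpG score over the +1..+250 window downstream of
the L1 transcription start site; zero-coverage CpGs are excluded, never
imputed, and counted in a coverage report. Categorical epigenotypes cut the
0--10 score at 2.5 and 7.5 -- the midpoints between the pure score levels;
the categories themselves are standard but these numeric cutoffs are this
package's choice.

`concordance_vs_branching()` asks when the epigenotype was fixed in
development: clone pairs are stratified by the molecular time of their MRCA
(default strata split at 17 and 65 mutations, the window from near
gastrulation to organogenesis, inclusive on both ends), and pairs that
diverged after the fixing window should agree more often than pairs that
diverged before it. The two-sample Kolmogorov-Smirnov statistic compares
score-difference distributions between the earliest and latest populated
strata. Selecting the "most variable" sources is done by promoter-score
variance across clones (`top_k`), the selection statistic being otherwise
unspecified.

# Enrichment

Feature tracks are divided into four bins. "Equal-sized" bins are equal
*genomic base pairs*, not equal interval counts, because bin sizes are rate
denominators. Fold enrichment of bin $k$ against bin 0 is
$(c_k/s_k)/(c_0/s_0)$ with the exact conditional-binomial rate-ratio
interval. For the L1 endonuclease motif (TTTT|R, or Y|AAAA on the other
strand), positions are scored by minimum Hamming mismatches to either
orientation; the usual bin phrasing ("more than four" and "fewer than one"
mismatches for the extreme bins) leaves counts of exactly 4 and exactly 1
unassigned, and we close the gap inclusively (>= 4 to bin 0, <= 1 to
bin 3). Ambiguous bases count as mismatches. Sliding-window
insertion rates use half-open 10 Mb windows at 5 Mb steps.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and are not tuned per analysis:

* **Lineage**: a rooted binary tree over `n_clones` (default 20) by
  uniformly random splits -- real developmental trees are irregular, so the
  topology is a free simulation parameter. Branches in generations 1--2
  span one division at a rate drawn from 2.4--3.8 pcpcd; deeper embryonic
  branches span 10 divisions (configurable) at 0.7--1.2 pcpcd; terminal
  branches carry Poisson(2,500) lifetime mutations, a typical somatic
  burden for an adult colorectal clone. Branch counts are Poisson with mean
  = generations x rate.
* **Mutation composition**: 90% SNVs; 80% of SNVs endogenous (SBS1 and
  SBS5/40) and 90% of indels ID1/ID2, reflecting the dominance of
  endogenous processes in normal colon; each mutation draws an observable
  spectrum channel from deterministic synthetic reference signatures
  (`synthetic_signatures()`), so EPM refitting is genuinely exercised.
* **soL1R occurrence**: per branch Poisson(stage rate x EPM / 1000) with
  default stage rates 1.06 / 4.52 / 1.2 per 1,000 EPMs for
  pregastrulation / postgastrulation / ageing; class weights 89:1:10;
  twin-priming fraction 29.5%; foldback 0.3% with 52--220 bp extra
  synthesis. Sources come from a registry whose activity is inversely
  related to population frequency except for a few "prevalent-active"
  escapees, and an event can only arise from a source the individual
  carries whose promoter is not closed in that lineage.
* **Epigenotype fixing**: per source, a fixation time is drawn uniformly in
  the 17--65 mutation window; lineages are open (globally demethylated)
  before it, and the first branch to cross it draws the state once, after
  which descendants inherit. This is what makes late-diverging clone pairs
  concordant.
* **Observations**: depth ~ Poisson(17), variant reads ~ Binomial(depth,
  0.5) for carriers; insertion support $s \sim \mathrm{Pois}(fd)$ and
  reference $r \sim \mathrm{Pois}((1-f/2)d)$ so that $s/(s+2r)$ centres on
  $f/2$; CpG coverage ~ Poisson(20) with methylated reads Binomial at
  0.05 / 0.5 / 0.95 for open / heterozygous / closed; panel evidence
  fractions Beta-distributed near 0.5 for carriers and near 0.03 otherwise.
  Zero-depth rows are emitted, never silently dropped. Truth and
  observation are serialized separately so recovery tests cannot leak
  truth.

What the generator does **not** model: sequencing error reads in
non-carriers, alignment artefacts, culture-associated mutations, copy
number, or read-level sequence (FASTQ). Passing tests therefore demonstrate
estimator correctness under clean clonal structure with read-sampling
noise, not robustness to mapping artefacts or contamination.

# Numerical choices and degenerate inputs

* Boundary conventions are tested explicitly: genotype 1 requires VAF
  strictly above 0.1; panel removal at >= 1%; clipping removal strictly
  above 70%; CpG class boundaries inclusive at 0.25 and 0.75; presence
  inclusive at 15%.
* `insertion_vaf(0, 0)` is `NA` (undefined), distinct from an observed 0.
  A zero-EPM rate is an error, not a zero. An empty genotype matrix after
  filtering is an empty result, not an exception.
* Equal-size group ties in tree building are broken lexicographically;
  equal-distance source ties take the first, flagged ambiguous.
* Zero-count rates use the closed-form exact bound
  $\chi^2_{0.975,2}/2 = -\log(0.025) \approx 3.689$ on the count scale.

# Problem sizes used in validation

The shipped tests run the phylogeny oracle on matrices of up to 8 samples,
interval coverage at 600 replicates, enrichment calibration at 10,000
uniform insertions, and class recovery on >100 simulated events; the
acceptance script simulates a cohort of 40 individuals x 15 clones at 2,000
mutations per terminal branch. These sizes give Monte-Carlo errors well
inside the tolerances asserted and keep a full run in minutes on one core.

# Known limitations

Conflict resolution is greedy, not globally optimal; heavily conflicted
matrices (far from the clean-clone setting) may discard more mutations than
an exact maximum-compatibility solver would. EPM refitting assumes the
reference signatures span the spectrum; an unmodelled exogenous process
inflates the residual rather than corrupting EPMs, but is not detected
automatically. The mechanism annotator sees only two insert-end mappings
and one flank mapping, so composite events (twin priming plus transduction)
are only partially flagged.
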