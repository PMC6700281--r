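---
title: "Models and methods behind cagtract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cagtract}
  %\VignetteEncoding{UTF-8}
---

`cagtract` analyses the *HTT* exon-1 repeat region in Huntington's disease
(HD) genetics. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical choices made where a
design was genuinely open, and what its synthetic-data tests do and do not
establish about real data.

## 1. The repeat-structure model

The polymorphic tract is modelled as an ordered list of trinucleotide runs
(`repeat_structure`), serialized in run notation such as
`CAG_42 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2`. Run notation is the canonical
text form; DNA constructors (`structure_from_dna()`) normalize to runs, and
adjacent equal-codon runs are always merged, so classification cannot
depend on how a caller split runs. The glutamine-coding segment is the
maximal contiguous block of CAG/CAA runs starting at the leading CAG run;
three allele classes are distinguished by its shape:

| class            | glutamine segment             | polyQ − CAG | assay bias |
|------------------|-------------------------------|-------------|------------|
| canonical        | `CAG_n CAA_1 CAG_1`           | +2          | 0          |
| CAA-loss         | `CAG_n`                       | 0           | −2         |
| CAACAG-dup       | `CAG_n (CAA_1 CAG_1) × 2`     | +4          | +2 or +1   |

Everything else is `other`: such structures parse and classify, but the
fragment-assay model refuses them — there is no defensible estimation rule
for arbitrary rare arrangements, and silently treating them as canonical
would reintroduce exactly the mis-estimation bias the package exists to
correct. The +1 case on duplication alleles arises from PCR primer
mis-priming on the duplicated interruption; which duplication chromosomes
mis-prime is not predictable from the run structure alone, so mis-priming
is an explicit boolean input (and a Bernoulli draw, default probability
0.5, in simulation) rather than something inferred.

`fragment_assay_estimate()` and `correct_estimated_cag()` are exact
inverses by construction, and the test suite checks this exhaustively over
CAG 36–60 for every class/mis-priming combination.

## 2. Read profiling

Two complementary scanners recover structures from reads.

**Forward (amplicon paired-end).** `profile_forward()` anchors at the
first occurrence of the `CAGCAGCAG` 9-mer, which fixes the reading frame;
successive in-frame triplets are consumed into runs until the nine bases
ahead equal the `CAGCTTCCT` tract terminator (terminator found) or the
read ends (not found). Anchor and terminator matching is exact — no
mismatch tolerance — and base qualities are ignored; error control comes
instead from the pair-agreement rule: the antisense mate is
reverse-complemented and profiled identically, and the pair is kept only
when both run lists agree. A non-ACGT base inside the profiled window
voids the profile. Overlapping anchor matches resolve leftmost-first.

**Genotype calling.** The histogram of retained structures is projected
onto uninterrupted CAG length using only *CAG-complete* profiles — those
whose leading CAG run demonstrably ended inside the read (a following run
or the terminator). A lone CAG run without terminator is only a lower
bound on the allele length; admitting such profiles would bias peaks
toward truncation artifacts, so they are excluded from peak formation.
The two most frequent CAG lengths become the genotype (one for a
homozygote); equally frequent peaks are broken deterministically in
favour of the longer CAG and flagged. Each called peak is then assigned
the highest-count terminator-complete structure carrying that length;
a peak with no such structure flags the genotype incomplete.

**Reverse (whole-genome reads).** `profile_reverse_wgs()` searches each
read for `CAGCTTCCT`, then walks 3'→5' in the terminator's frame until an
in-frame `CAGCAGCAG` is met. The recovered fragment therefore carries a
three-CAG head regardless of the allele's true run length — this path
genotypes the *adjacent structure*, not the CAG length. Complete fragments
are aggregated; those representing **14% or less** of aggregated complete
reads are dropped (the boundary itself is dropped: "or less"). The filter
denominator is the count of complete sequences: only complete sequences
survive aggregation in the preceding step, so no other denominator is
available without changing the algorithm. One survivor is a homozygote,
two a heterozygote, zero a no-call, more than two an ambiguity flag.

## 3. The somatic-expansion index

Fragment-analysis peak tables (sample, plate, called main CAG, size in bp,
height in RFU, area, scan) are scored in this order: size/height
filtering, per-plate calibration, CAG assignment, collision resolution,
summation.

* **Filters:** size ≤ 500 bp, height ≥ 50 RFU, both boundaries inclusive
  on the keep side as printed.
* **Calibration:** ordinary least squares of the called main CAG on the
  main peak's size, per plate, via `stats::lm`; it needs at least two
  distinct main-peak sizes and a positive slope.
* **Assignment:** `round(b0 + b1 · size)` to the nearest integer, half
  away from zero (the choice is unstated upstream; half-away-from-zero
  avoids the even-length bias of banker's rounding on a grid of repeat
  lengths). Within a sample, peaks colliding on a CAG length keep the
  taller record.
* **Peak proportional sum:** heights of peaks assigned a CAG strictly
  greater than the main allele, each divided by the main peak height,
  summed. Peaks at or left of the main are PCR stutter and contribute
  nothing. Height, not area, is the proportion basis; area is retained in
  the record for alternate analyses.

Filtering before assignment (rather than after) can only change which
record wins a collision, never the set of surviving CAG lengths; the
chosen order is applied consistently and documented here.

`rank_top_quartile()` sorts descending and puts exactly `floor(n/4)`
samples in the top quartile, distributing the remainder to the lower
quartiles; 7,013 samples yield a 1,753-sample top quartile. Boundary ties
break by sample id. The top-quartile HWE report supports both a pooled
ranking (default — it reproduces the 1,753) and a per-CAG-length
stratified mode.

## 4. Residual age-at-onset phenotype

Expected onset is a pluggable, strictly decreasing function of the
expanded allele's uninterrupted CAG length. Two forms ship: log-linear
`E[AO] = exp(a + b·CAG)` and shifted-exponential
`E[AO] = c + exp(a + b·CAG)`. The residual is observed minus expected, in
natural-scale years (+5 = five years later than expected). The published
coefficient sets for such models belong to their own studies, so the
package does not hard-code any: `default_onset_model()` fits the
log-linear form to a small synthetic reference cohort shipped as a
plain-text fixture (`inst/extdata/synthetic_reference_cohort.tsv`,
generated by this package's own simulator at seed 1234 from a log-linear
truth with a = 6.5, b = −0.063 — chosen to give plausible expectations,
about 53 years at 40 CAGs and 21 at 55), and any real analysis should
substitute a model fit to its own cohort.

Non-canonical alleles distort this phenotype: a CAA-loss allele estimated
two CAGs short makes the expected onset too late and the residual
artificially negative, i.e. a spurious early-onset signal at any SNP
tagging the structure. `recompute_with_true_cag()` recomputes residuals
from the corrected length (keeping the estimated-CAG residual for
comparison) and is idempotent. The cohort filter keeps 40–55 CAGs, true
length taking precedence where known; subjects carrying two expanded
alleles should be entered with the longer one. Dichotomization takes the
top and bottom `floor(0.30 · n)` residuals as late/early groups (9,064
subjects give 2,719 per group), ties broken by subject id.

## 5. Modifier statistics

* **HWE enrichment:** expected counts `n(1−q)², 2nq(1−q), nq²` at an
  externally fixed minor allele frequency q, chi-square `Σ(O−E)²/E` with
  the upper tail on **2 degrees of freedom** — the conventional df = 1
  subtracts an allele frequency estimated from the observed table, but
  here q is fixed from the full cohort, so no parameter is consumed.
* **Association:** fixed-effects least squares of the residual phenotype
  on minor-allele dosage plus covariates; conditional analysis adds
  conditioning-SNP dosages as covariates, with aliased designs rejected
  loudly. A kinship-corrected mixed model is out of scope — the synthetic
  cohorts are unrelated, for which ordinary least squares is the correct
  likelihood; users with related samples need an external mixed-model
  fit. A plain logistic fit for the dichotomous phenotype is included as
  plumbing without calibration claims.
* **Tag-SNP rules:** the 5AM1–3, 15AM1–4, 19AM1–3 modifier-haplotype
  definitions ship as a YAML fixture evaluated in declared order,
  first match wins, all comparisons strict except the 20–35% frequency
  window of 5AM3, which is stated as a range rather than an inequality
  and is implemented inclusively. The 15AM3 wording "conditional analyses
  with either marker" is implemented as *below threshold in both*
  conditional analyses — a signal that survives conditioning on either
  FAN1 marker — and 15AM4 carries no direction constraint because none is
  stated. A SNP missing a conditional p-value that a candidate rule needs
  is skipped with a warning rather than silently failed.

## 6. The synthetic-data generators

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes. Defaults are fixed once, as
the study conditions the package is exercised under:

* disease-allele CAG 40–55 with geometrically decaying weights (longer
  alleles rarer), normal alleles 15–25;
* class mix 96% canonical / 2.5% CAA-loss / 1.5% duplication — canonical
  well above 95%, the non-canonical classes rare, as on European HD
  chromosomes;
* onset = expected(true CAG) + additive SNP effects + Gaussian residual,
  SD 8 years in natural scale (the residual distribution of such cohorts
  is close to normal; natural-scale noise keeps the residual SD
  interpretable in years);
* 2×300 bp pairs, 100 per allele, 0.5% per-base substitution error;
* traces: three left stutter peaks at 35% of the main height decaying by
  half, and an expansion tail whose total height fraction equals a
  per-subject Beta(μφ, (1−μ)φ) propensity with φ = 50 and mean
  μ = 0.05 + 0.012·(CAG − 40), optionally shifted by a designated SNP's
  dosage. The Beta form and its coefficients are this package's choice:
  only the qualitative pattern — per-individual expansion proportion
  rising with inherited CAG length — is established upstream. Expansion
  mass is split equally over up to four peaks so that every generated
  peak clears the 50 RFU detection filter; propensities whose total mass
  falls below one detectable peak are reported as zero, mirroring the
  real assay's detection floor.

Sub-seeds are derived per generator (seed + 1 … + 4) so each top-level
call is reproducible in isolation; all randomness flows through R's RNG.

**What passing tests show — and don't.** The simulators emulate read
errors as independent substitutions (no indels, no quality decay along the
read, no PCR chimeras), traces as clean geometric stutter (no baseline
noise, no off-grid peak sizes beyond small jitter), and cohorts as
unrelated individuals with exactly additive, exactly HWE modifier SNPs.
Parameter-recovery results on these inputs validate the *arithmetic* of
the pipeline, not its robustness to the messier failure modes of real
instruments and pedigrees.

## 7. Problem sizes and numerical checks

The shipped tests run at deliberately desk-scale sizes: 30-structure
profiling libraries at 200 error-free pairs each, 200 noisy genotype
replicates at 100 pairs/allele, 1,000-replicate null calibration at
n = 300, effect recovery at n = 5,000, and a 4,000-subject cohort for the
mis-estimation artifact study — large enough for the stated tolerances
(type-I error within ±0.02, effect recovery within ±0.5 years, expansion
fractions within 0.01), small enough to run routinely. Degenerate inputs
are rejected rather than guessed at: single-point plate calibrations,
zero-variance dosages, aliased conditional designs, structures without a
leading CAG run, and assay corrections on `other`-class alleles all raise
errors.

## 8. Known limitations

* The forward profiler requires reads spanning the full tract; very long
  alleles on short reads yield lower bounds only (flagged, not called).
* The reverse (WGS) path cannot measure CAG length, only the adjacent
  structure — by design of its anchoring rule.
* The expansion index has the bulk assay's floor: expansion products
  below the stutter/detection threshold are invisible, so small indices
  are censored at zero.
* The tag-rule engine evaluates printed thresholds literally; it does not
  attempt LD-aware haplotype inference.
* No imputation, meta-analysis, mixed models, TWAS, or pathway methods:
  those are external tools in the analyses this package accompanies.
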