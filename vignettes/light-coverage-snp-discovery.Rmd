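---
title: "Light-coverage SNP discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-coverage SNP discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a genome is sequenced at only a few-fold redundancy across several
individuals, most polymorphic sites are seen in one or two reads, so SNP
discovery cannot rely on genotype likelihoods or allele-balance statistics.
What it can rely on is *base-level* evidence quality: a discrepant base is
believed only when the base itself and its local neighborhood are
well-determined. `lightsnp` implements this style of discovery — the
Neighborhood Quality Standard (NQS) with a pileup-depth cap — together with
the downstream resource statistics a SNP-map project needs (per-individual
SNP rates, discoverer-category partitions, windowed densities, occupancy
curves, genotyping-panel design, and empirical validation arithmetic), and a
synthetic population/read generator that emulates an eight-cat
light-coverage survey so the entire pipeline is testable end to end without
any external data.

# The NQS calling model

A read base at read offset $i$ qualifies when, with flank half-width $w = 5$:

* its own PHRED quality is at least `center_min_q` (default 23, i.e. an
  error probability of $5\times10^{-3}$ or less);
* all $2w$ flanking bases have quality at least `flank_min_q` (default 15);
* at least `min_flank_matches` (default 9) of the $2w$ flanking bases match
  the consensus;
* the full neighborhood lies inside the read and no alignment gap crosses it.

A qualified base that differs from the consensus becomes a per-read SNP
record; an insertion or deletion of at most `max_dip_length` (default 10)
bases becomes a DIP record when *both* bases immediately flanking the gap
qualify, with the gap itself spliced out of their neighborhoods. Columns
whose read depth exceeds `max_depth` emit nothing — under light coverage a
deep column is more likely a collapsed repeat than a well-sampled locus —
and columns at or within `flank_width` of a reference N run are excluded.

Choices the rule definition leaves open, fixed here:

* **Read ends.** Bases whose neighborhood is incomplete never qualify; they
  also never count toward the NQS-base denominator.
* **Gaps.** Any alignment gap intersecting an 11-base neighborhood
  disqualifies the center base (except the candidate gap itself in DIP
  flank evaluation).
* **Coverage cap.** The cap applies to DIP records as well as SNP records;
  the cap's motivation (repeat pileups) is the same for both. The default
  `max_depth = 8` is roughly 2.5 times a ~3-fold survey's mean redundancy,
  so true columns are essentially never suppressed (a Poisson(3) column
  exceeds 8 with probability 0.004) while collapsed two-copy repeats
  (Poisson(6) and up) start to be.
* **Site identity.** Merging is alt-allele-resolved: one non-redundant site
  per (chromosome, position, type, alternate allele), so a tri-allelic
  position yields two sites, each with its own discoverer set.
* **SNP-rate denominator.** "One SNP per $x$ bases" divides the number of
  NQS-qualified bases across an individual's reads (each read base counted
  once per read, i.e. depth counted multiply) by that individual's SNP
  record count, rounded half-up. A zero SNP count is an error, not a rate.

`call_variants()` scans each read once with vectorized window sums rather
than materializing a per-base pileup table; `build_pileup()` exists for
inspection and is the brute-force cross-check in the tests. Depth is
computed from reference-span coverage (deletions covered by a read count
toward depth).

# The synthetic population generator

The generator emulates the structure of the survey it models, at desk scale:

* **Eight individuals**: six outbred domestic breed cats, one wildcat
  (Nancy), one deeply sequenced inbred individual (Cinnamon). Two of the
  domestic cats are male, so chromosome X is hemizygous in them.
* **Shared domestic polymorphism.** Sites are laid down as a Poisson process
  on non-N sequence with population allele frequencies drawn from a
  symmetric Beta(0.5, 0.5) discretized to the attainable grid $k/16$; each
  individual's two haplotypes carry the alternate allele independently with
  probability $f$. The site density is `domestic_het_rate / E[2f(1-f)]`, so
  a domestic cat's expected heterozygosity is exactly the configured
  `domestic_het_rate` (default 1/600 per base). The U-shaped spectrum
  produces both singletons and common alleles, which gives the
  informative-fraction estimator signal; the real spectrum is unknown here.
* **Wildcat divergence.** Nancy carries the shared sites plus private sites
  fixed in her (default `wildcat_extra_rate` 1/720 per base), emulating
  subspecies divergence. Her *observed* discovery rate also depends on
  assembly composition, so the generator makes no promise that it matches
  any particular printed rate without calibration.
* **Inbred mosaic.** Cinnamon is the founder of the reference; her only
  variation is private heterozygous sites confined to the heterozygous
  tracts of a two-state alternating-exponential process with stationary
  homozygous probability 0.60 and mean homozygous tract length
  `inbred_tract_mean_length`. The default is 50 kb: on a 5–10 Mb desk
  genome this yields 60–120 tract cycles, so the realized genome fraction
  concentrates near 0.60 (renewal-theory SD
  $\approx \sqrt{f^2(1-f)^2 \cdot 2 / n_{\text{cycles}}} \approx 0.03$).
  A 500 kb tract mean — closer to the megabase tracts of a real 2.5 Gb
  genome — would leave only ~6 cycles on 5 Mb and a realized fraction
  anywhere between 0.4 and 0.8; tract length must scale with genome length
  for the fraction to be meaningful at desk scale.
* **DIPs** are a configurable fraction of sites (default 0.18, the
  genome-wide DIP:SNP balance of the survey), short (geometric, capped at 5
  bases), isolated from neighboring sites, and stored anchored on the last
  matching reference base — the same convention VCF uses, so positions are
  directly comparable across the pipeline.
* **Reads** are fosmid paired ends: ~37 kb inserts with CV < 0.10 (default
  0.08), one ~Normal(700, 50) read from each end on opposite strands, drawn
  from a uniformly chosen haplotype. Substitution errors are injected at
  exactly $10^{-q/10}$ per base from the emitted quality string, and every
  injected error is recorded, so reads reconstruct exactly from
  reference + truth variants + error log (a tested invariant).
* **`consensus_from`**: optionally one individual's first haplotype is
  substituted as the consensus, emulating an assembly dominated by that
  animal's reads (their reads then mostly match "their own" haploid and
  their apparent SNP rate collapses). To keep coordinates stable the donor's
  first haplotype absorbs only SNPs, never indels.

A single pipeline seed fans out to per-stage, per-individual child seeds via
a stable string hash, so adding an individual never changes another
individual's genotypes or reads, and identical configurations give
byte-identical output files (no timestamps are embedded in any artifact).

## Quality profile and caller specificity

The quality profile is a q≈40 plateau with logistic decay to q≈10 at the
read ends. The ramps are deliberately steep (rise over ~20 bases, fall over
the final ~60), emulating quality-trimmed traces. This matters more than it
looks: with gentle ramps, a long q 20–35 shoulder passes the NQS flank rule
while carrying calibrated error rates of $10^{-3.5}$–$10^{-2.3}$, and
20–30% of all called sites are sequencing errors. Even with steep ramps the
plateau sets a specificity floor: at q40 the qualified-base error rate is
$10^{-4}$, against a domestic true-discovery rate of roughly $2\times
10^{-3}$ per read base, so about 5% of domestic-discovered sites are
error-driven and the synthetic validation rate settles near 92–95% rather
than 99%. Reproducing a 99% empirical validation rate with calibrated
qualities would require plateau qualities near q47 or higher; the package
keeps the q40 default and reports what it implies. For the deeply sequenced
inbred individual — whose true rate is ~10-fold lower — error calls are
proportionally much more prominent, which is why the pipeline's validation
stage samples candidates among sites discovered in the *domestic*
individuals, as the original validation experiment did.

With `error_model = "none"` the caller is exact: every called site
coincides with a truth site (zero false positives, a tested acceptance
property), and recall rises with coverage.

# Resource statistics

* **Categories.** A site is in category C always; in B unless discovered
  only in the inbred individual; in A only if discovered in at least one
  ordinary domestic individual. Hence $A \subseteq B \subseteq C$ by
  construction, and per-chromosome category counts sum to the genome totals.
* **Spacing cells.** Bases-per-SNP cells are non-N bases divided by the
  count, rounded half-up; all 66 printed cells of the survey's
  per-chromosome table reproduce under this rule from the printed count
  pairs (a tested acceptance property).
* **Windows.** Density windows tile each chromosome half-open; the final
  partial window is kept (shorter). Windows with no non-N base are flagged
  undetermined and excluded from occupancy denominators by default
  (`include_unmapped = TRUE` restores them).
* **Informative fraction.** With only a handful of genotyped animals, MAF
  ≥ 5% cannot be estimated; the proxy is singleton (alternate allele in one
  cat) versus multi-cat. The extrapolated informative count multiplies the
  multi-cat percentage *rounded to a whole percent* by the resource size —
  deliberately copying how such extrapolations are quoted (88% of 964,285
  → "849 k"), rather than the unrounded ratio.
* **Validation rates.** SNP mode excludes low-quality amplimers from the
  denominator (confirmed / assayable); DIP mode keeps every record in the
  amplicons, including untested ones. The two conventions intentionally
  differ because that is how such experiments are conventionally reported;
  harmonizing them would change the printed rates.
* **Gap distance.** A validation candidate must be at least 750 bases from
  the nearest N character or contig end, boundary-inclusive, with distance 1
  meaning immediately adjacent; positions just past the contig ends behave
  like flanking Ns.
* **Tract fraction.** `tract_homozygosity()` merges an individual's
  discovered sites within `max_gap` (default 6 kb) into heterozygous
  segments, extends each segment by `max_gap`/2 per side, and reports the
  genome fraction outside them. All-or-nothing binning was measured to
  underestimate the fraction by 0.06–0.08 at 1× coverage (boundary bins
  holding a single call score fully heterozygous); segment merging is
  unbiased to within ~0.01 under the same conditions.

# Panel design

"A SNP every 15 kb" is implemented as one site per 15 kb window — the
category-A site nearest the window midpoint, ties to the smaller coordinate
— because the target assay count then equals the A-occupancy figure at the
same window size exactly (a tested equivalence). Backfill fills A-less
windows from B, then C, without counting toward the covered fraction, which
is defined as A-covered windows over determined windows. Two consequences
are documented rather than "fixed": adjacent-window selections can be closer
than the spacing (windowed, not greedy, selection — a greedy variant is
available via `method = "greedy"`), and at desk scale only the construction,
not any genome-scale assay count, is reproduced. No assay-design filters
(GC, flanking uniqueness) are applied at this stage.

# Problem sizes and numerical choices

Default study conditions are desk-scale: a 5 Mb genome (90% autosome, 10%
X), eight individuals sharing 2.8× total coverage split by the survey's
per-cat read shares (the inbred reference animal carries ~72% of reads),
~37 kb inserts. The acceptance checks run the recovery analysis on a 5 Mb
single-chromosome population with three individuals (one per class) at 3×
total coverage with error-free reads, and the statistical examples at sizes
where binomial/Poisson expectations are sharp (for example, 600,000 bases at
1/600 gives a heterozygous-site count of 1000 ± 32, tested at four standard
deviations). Internally all coordinates are 0-based half-open; SAM and VCF
are written 1-based, BED 0-based half-open, and each boundary convention is
covered by a test. Rounding of printed-style integers is half-up via
`trunc(x + 0.5)`, never banker's rounding.

# What passing tests do and do not show

The generator emulates diversity structure, coverage structure, insert
geometry, quality decay and calibrated substitution errors. It does not
emulate: chromatogram-level artifacts or miscalibrated quality strings,
fosmid cloning bias, assembly errors (reads are aligned to the true
reference by construction — no aligner or assembler runs), alignment
ambiguity in repeats, or contamination. Consequently, passing the zero
false-positive property says the *rule* is implemented exactly, not that
real Sanger data would validate at 100%; the specificity arithmetic above is
the more honest statement about real data. Similarly, the wildcat's
configured divergence controls truth density, while observed printed rates
in a real survey also reflect assembly composition, which is only emulated
via `consensus_from`.

# Known limitations

* Genotype likelihoods, realignment and base-quality recalibration are out
  of scope by design; the package implements discovery, not genotyping.
* `read_sam()` accepts only M/I/D CIGARs (strict by default; `lenient`
  drops offending records), and plain-text SAM only.
* The informative-fraction proxy ignores linkage and population structure.
* Multi-allelic DIP representation follows the anchored convention; complex
  substitution events are not modeled or called.
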