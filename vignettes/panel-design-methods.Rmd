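---
title: "Designing and evaluating a targeted SNP capture panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a targeted SNP capture panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsmith)
```

`panelsmith` builds solution-phase capture ("liquid chip") SNP panels from
population variant data and implements the downstream analyses such panels
serve: population-genetic summaries, cultivar fingerprinting with
identity-by-descent kinship, and recombination bin maps for outcrossing F1
populations. This vignette explains the models and procedures, the
parameters that matter, the choices made where the design was genuinely
open, and what the simulation-based tests do and do not establish.

## The design procedure

A candidate SNP survives three stages.

**1. Site quality and informativeness.** With alternate-allele frequency
$p$ ($q = 1-p$) computed from called genotypes (a heterozygote contributes
one alternate allele; missing genotypes are excluded, never imputed), a
site passes iff

* missing rate $< 0.1$,
* minor allele frequency $\min(p, q) > 0.35$, and
* observed heterozygosity (fraction of called genotypes that are het)
  $< 0.5$.

All three inequalities are strict, and `qc_filter()` guards the
comparisons with a $10^{-9}$ tolerance so that a value equal to a
threshold up to floating-point rounding fails deterministically. The
heterozygosity cap matters in clonally propagated, highly heterozygous
crops: sites that are heterozygous in more than half the cohort are
enriched for paralog collapse and other artifacts.

*On PIC.* The classical biallelic polymorphic information content
$1 - p^2 - q^2 - 2p^2q^2$ cannot exceed 0.375, yet high-MAF chip designs
are routinely described with PIC ranges reaching 0.5. That range is only
attainable if "PIC" denotes expected heterozygosity $H_e = 2pq$. The
package therefore reports `pic_chip` $= H_e$ (the score used for ranking
and the one whose attainable band under the MAF filter is
$(2 \cdot 0.35 \cdot 0.65,\ 0.5] = (0.455,\ 0.5]$) and `pic_classic` for
transparency. This is a documented reading, not an assertion about any
particular published design's intent.

**2. Probe screening.** Capture baits tile both sides of a target, so the
unit of evaluation is the pair of 110-bp flanks (left: positions
$[\mathrm{pos}-110, \mathrm{pos}-1]$; right:
$[\mathrm{pos}+1, \mathrm{pos}+110]$). An alternative single-window
reading (one 110-bp window containing the SNP) is available via
`evaluate_probe(mode = "centered")`. Both flanks must have GC content
inside the *closed* band $[0.3, 0.7]$ (N bases count in the denominator
only), and pooled over both flanks there must be strictly fewer than 5
homologous regions elsewhere in the genome. A homologous region is an
ungapped alignment, on either strand, satisfying at least one of

* more than 40 bp of identical sequence (so an exact 41-mer triggers, an
  exact 40-mer does not),
* more than 85% identity over an 80-bp window (69/80 matches trigger,
  68/80 do not), or
* more than 95% identity over a 70-bp window (67/70 trigger, 66/70 do
  not).

"Similarity over $N$ bp" is read as ungapped $N$-bp window identity
(Hamming); the scan in `src/homology.cpp` sweeps every diagonal (every
ungapped probe/genome offset) of every chromosome on both strands, so no
seeding heuristic is involved and the semantics are exactly the exhaustive
definition. Qualifying windows are unioned per diagonal, hits closer than
10 bp are merged into one *region* (the criterion counts regions, not
alignments), and regions overlapping the probe's own span
($\mathrm{pos} \pm 110$) are excluded — the slightly generous self-span
prevents one flank from "hitting" the other. Truncated flanks at contig
ends fail automatically. The test suite validates the scanner against an
independent exhaustive oracle built from `Biostrings::matchPattern` with
the per-rule mismatch budgets, including planted repeats on both strands
and the strict boundary cases above.

**3. Uniform spacing.** Each chromosome is partitioned into fixed,
non-overlapping 100-kb windows anchored at position 0 (the anchoring is a
package choice; nothing in the criterion fixes it). Per window the
candidate with the highest `pic_chip` is selected; ties break by proximity
to the window center, then lowest position, making re-runs bit-identical.
One-per-window is the recorded default where a published procedure might
have allowed more in sparse regions; it yields the cleanest density
guarantee (≤ 1 site per 100 kb).

## Evaluation statistics

**Nucleotide diversity.** Per site, with allele counts $c_r, c_a$ and
$n = c_r + c_a$, $\pi = c_r c_a / \binom{n}{2}$ — the mean pairwise
difference, phase-free. Windowed $\pi$ sums site values over a 100-kb
window sliding by 10 kb and divides by the window span in bp (empty
windows report 0 but are excluded from concordance correlations);
`fragment_pi()` applies the same estimator to captured fragments. Panels
filtered to MAF > 0.35 *must* show inflated per-fragment diversity
relative to the genome-wide value — the tests assert the direction of this
inflation on simulated data, not any particular magnitude, because the
magnitude depends on the cohort's frequency spectrum.

**Fst.** Weir & Cockerham's (1984) variance components $a$ (among
populations), $b$, $c$ are computed per site from per-population sample
sizes, allele frequencies and heterozygote fractions; windowed and
genome-wide estimates are ratio-of-sums $\sum a / \sum(a+b+c)$. Negative
window estimates are reported, not clipped. Sites contribute when every
population has at least one called genotype and the variance components
are defined ($\bar n > 1$, $n_c > 0$). An independently transcribed
formula oracle in the tests checks $a, b, c$ per site, and
Balding–Nichols simulations check that the genome-wide estimate recovers
the divergence parameter $F$.

**Tajima's D.** $D = (\theta_\pi - S/a_1)/\widehat{\mathrm{SE}}$ with the
standard $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ constants. Each diploid
contributes two alleles; missing calls reduce the per-site allele count
and the region-level $n$ is the *minimum* across sites — a conservative
choice that slightly understates $|D|$ when missingness varies. Regions
with $S = 0$ return NaN with an explicit flag.

## Fingerprinting and kinship

**Locus distillation.** The panel is reduced to $k = 384$ loci by
allocating counts to chromosomes proportionally to length
(largest-remainder rounding), then greedily taking the highest-`pic_chip`
loci subject to a minimum spacing (default 100 kb). Unfillable quotas are
redistributed; an infeasible spacing yields a best-effort set with a
warning. The published procedures this emulates rarely state their
refinement rule; greedy informativeness-under-spacing is the package's
recorded default and is isolated behind `select_fingerprint()` so other
strategies can replace it.

**QR profiles.** Genotypes are 2-bit codes (00 hom-ref, 01 het, 10
hom-alt, 11 missing) laid row-major into a 32-column binary grid plus one
column-parity checksum row; the scheme is versioned (`qr1`) in each
profile. Decoding verifies parity first, so any single flipped cell is
detected — the tests flip every cell of a profile exhaustively. This
encoding is original to the package; published "QR-code-like" profiles
describe the concept without an encoding.

**IBD.** The method-of-moments estimator observes identity-by-state
counts for a pair and solves for IBD-state probabilities $Z_0, Z_1, Z_2$
using expected IBS-given-IBD probabilities that are functions of cohort
allele frequencies with PLINK-style small-sample correction factors
($A/(A-1)$ etc., where $A$ is the cohort allele count). The solution is
sequential ($Z_0$ from IBS0, then $Z_1$, then $Z_2$), and bounding follows
the same sequential logic: an overshooting $Z_0$ collapses the remaining
states before the triple is clamped to $[0,1]$ and renormalized. This
matters for unrelated pairs: with symmetric clamping alone, positive noise
in $Z_1, Z_2$ cannot cancel and $\hat\pi = Z_2 + Z_1/2$ acquires a visible
upward bias. Loci with cohort MAF < 0.01 or missing in either sample are
skipped; pairs with fewer than 50 informative loci carry a low-confidence
flag. Relationship classes are monotone in $\hat\pi$ — clone/bud-sport at
$\hat\pi \ge 0.9$, parent–offspring at $\hat\pi \in [0.4, 0.6]$ with
$Z_0 \le 0.05$, other first degree at the same $\hat\pi$ band with
$Z_0 > 0.05$, related for $\hat\pi \in [0.15, 0.4)$ and also for the
otherwise-unnamed $(0.6, 0.9)$ band (keeping the mapping monotone),
unrelated below 0.15; all thresholds are arguments. Clone groups are
connected components of clone-class edges — transitive closure, matching
how synonym groups are reported in practice.

## F1 bin maps

Markers heterozygous in exactly one parent (the pseudo-testcross
configurations, e.g. 0/0 × 0/1 and its allele-relabeled mirrors) identify
which allele the heterozygous parent transmitted. Which *haplotype*
carried it is a separate question: the linkage phase of a parent's markers
is arbitrary per marker. `recode_origin()` therefore orients each marker
against its predecessors on the chromosome by progeny majority vote —
adjacent informative markers recombine in well under half the progeny at
realistic densities, so the vote is effectively unambiguous; at the
package's default simulated density (~20 kb spacing, ~22 cM/Mb) adjacent
markers recombine in ~0.5% of gametes. Markers heterozygous in both
parents are phase-ambiguous in the progeny and are used only for
segregation tests (the pseudo-testcross convention).

Bins then merge consecutive markers whose progeny origin vectors are
compatible (equal wherever both are non-missing; an all-missing marker is
absorbed), splitting exactly between the first conflicting pair. This is
deliberately map-free: marker order comes from the physical map, justified
when linkage and physical maps are collinear, and reproduces
recombination-defined bins without reimplementing linkage-map ordering.
On error-free simulated crosses this recovers every breakpoint interval
exactly and gives bins-per-chromosome = distinct breakpoints + 1, which
the tests assert at 500 progeny × 1000 markers.

Per-parent recombination maps count origin transitions between adjacent
bins per progeny. An isolated bin whose call differs from two agreeing
neighbours is a double transition within a 3-bin span — overwhelmingly a
genotyping error at realistic error rates — and is smoothed by default
(`smooth = FALSE` keeps and flags such spans). Segregation scans use
Pearson chi-square against 1:1 (testcross, df 1) or 1:2:1 (intercross,
df 2) with impossible progeny genotypes excluded and a 20-progeny floor;
distortion regions are runs of ≥ 3 consecutive markers significant at the
Bonferroni-corrected level $\alpha/n$ (the correction procedure is a
package choice).

## The simulators: what they emulate, and what they do not

`simulate_genome()` draws iid bases at a target GC and plants repeat
copies with exact mismatch counts (optionally reverse-complemented),
recording a truth table — precisely the structure the homology rules need
to be exercised, with none of the long-range repeat families of a real
plant genome.

`simulate_population()` is a Balding–Nichols island model: ancestral
frequency uniform on $[\mathrm{floor}, 1-\mathrm{floor}]$, per-population
frequencies Beta-distributed around it with divergence $F$, genotypes in
Hardy–Weinberg within populations. $F$ equals the expected Fst, which is
what makes estimator-recovery tests analytic. It has no linkage
disequilibrium, no inbreeding and no frequency-spectrum realism, so tests
on it validate estimator algebra and calibration, not robustness to real
cohort structure.

`simulate_f1()` emulates a published litchi biparental design in its
defaults: 264 progeny; 53.6% of informative markers heterozygous only in
the second parent (the one published figure), with the remainder split
evenly between the other two configurations as the package's choice; and
per-chromosome map lengths of 90 cM (female) / 70 cM (male) — the mean
matches the ~80 cM per chromosome implied by a ~1206-cM, 15-chromosome
map, and the asymmetry follows the published direction (female higher),
its magnitude being a package choice. Crossovers are Poisson with uniform
positions (no interference), adequate for breakpoint-recovery testing but
not for interference-sensitive statistics.

All generators are bit-reproducible from (seed, arguments).

## Numerical and scale choices

* Coordinates are 1-based internally (VCF convention); BED export and
  window coordinates are 0-based half-open. Multiallelic and indel
  records are excluded at ingest; phase is collapsed everywhere.
* The homology scanner encodes A/C/G/T as 1–4 and anything else as 0,
  which never matches (including N against N).
* Test problem sizes: the oracle-equivalence comparison runs on a 100-kb
  two-chromosome genome with planted repeats; Fst recovery uses 6
  replicates of 2 × 50 samples × 2000 SNPs per divergence value; IBD
  recovery uses 200 pairs per relationship class at 384 loci; bin-map
  exactness uses 500 progeny × 1000 markers over 5 chromosomes; the
  segregation-test calibration uses 2000 null markers × 100 progeny.
  These sizes make the Monte-Carlo error small relative to the asserted
  tolerances while keeping the default suite fast.

## Known limitations

* The homology rules are ungapped; a gapped aligner would count some
  indel-containing paralogs that the window rules miss.
* Method-of-moments IBD assumes unlinked loci and cohort-representative
  allele frequencies; at 384 loci the unrelated-pair $\hat\pi$
  distribution has a long right tail (its mean is ~0.04), so
  classification thresholds, not point estimates, carry the inference.
* Majority-vote phase orientation can fail across very large gaps
  (adjacent-marker recombination approaching 50%) or in tiny families;
  bins then split spuriously at the misoriented marker.
* Windowed estimators use the VCFtools convention of dividing by window
  span, which understates diversity in windows with poor callability
  (no callability mask is modeled).
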