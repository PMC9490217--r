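---
title: "Detecting strain-level gut microbiome transmission from SNV profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting strain-level gut microbiome transmission from SNV profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When animals share a pen, their gut microbes can move between hosts; within
a ruminant, microbes can also move between the foregut (rumen) and hindgut
(cecum). Species-level composition is too coarse to see this: two hosts can
carry the "same" species without any transfer having occurred. Strain-level
evidence comes from single-nucleotide variants (SNVs): if two samples carry
the same alleles at many polymorphic positions of a strain's genome, and
those alleles are rare enough that chance agreement is unlikely, the strain
was plausibly shared.

`strainshare` implements that inference as a pipeline over tabular inputs
(coverage summaries, pileup-like allele counts, sample metadata), together
with the genome-catalog computations that surround it in a typical
metagenome-assembled-genome (MAG) study, and a synthetic-study generator
that plants known transmission events so every stage can be validated
end to end.

## The transmission score

For one strain, the screening samples are those passing the presence filter
(breadth ≥ 10% of positions covered, mean depth ≥ 0.15×). An allele is
called in a sample when at least two reads with base quality Phred ≥ 15
support it; a position is evaluable when its qualifying depth reaches the
same bound. Across screening samples, each variant allele *i* gets an
incidence

> f(i) = (number of screening samples carrying *i*) /
>        (number of screening samples whose evaluable positions include *i*'s position).

The coverage-aware denominator avoids counting non-coverage as absence; a
configuration flag (`coverage_aware = FALSE`) restores the naive global
denominator. Incidences are clamped to
[1/(2n), 1 − 1/(2n)] (n = screening samples) before any logarithm, the
add-half pseudocount convention.

For a pair of samples, each evaluable allele falls in one of four agreement
classes — present in both (1,1), absent in both (0,0), present in exactly
one (1,0)/(0,1) — with probabilities taken as independence products of the
single strain-level incidence:

> p11 = f², p00 = (1 − f)², p10 = p01 = f(1 − f).

These sum to one per allele. (The difference forms `f1 − f2` etc. are
retained as `pair_probabilities(method = "literal")` for comparison; they
can be negative and do not form a probability distribution, so the product
reading is the one the pipeline uses.)

The observed-overlap log-likelihood rewards agreement and penalizes
disagreement,

> L_obs = [Σ₍₁,₁₎ ln p11 + Σ₍₀,₀₎ ln p00] − [Σ₍₁,₀₎ ln p10 + Σ₍₀,₁₎ ln p01],

and is normalized by the least likely all-agreement case,
L_min = Σᵢ min(ln p11, ln p00), giving P_raw = L_obs / L_min. P_raw is 1
when every allele agrees in its least likely class, near 0 for unrelated
samples (agreement and disagreement terms cancel in expectation), and can
be negative when disagreement dominates. Finally, per strain, P_raw is
z-standardized over all of the strain's evaluated pairs:

> S_T = (P_raw − μ_raw) / σ_raw,  σ_raw with the n−1 denominator.

All unordered pairs of screening samples are evaluated (excluding the same
gut site of the same host), so the many control-group cross-host pairs act
as the null reference distribution of the standardization. This matters for
detection: true sharing events inflate σ_raw slightly, but because they sit
far in the tail, background pairs rarely reach the default threshold
S_T ≥ 2 (≈ 97.7th percentile under normality; the cutoff is configurable
since no canonical value exists).

Events are called only on *eligible* pairs: same-gut-site pairs between two
different cohoused hosts, and rumen–cecum pairs within a host. Cross-host
pairs of *different* gut sites are scored (they enrich the background) but
not callable — sharing there cannot be attributed to exactly one of the
three event types (intra-species, inter-species, foregut–hindgut), and
pen-level transfer is observed site-matched. Event types follow the sample
metadata alone: same host, rumen vs cecum → foregut–hindgut; different
hosts, same species → intra-species; different species → inter-species.

### Gates and degenerate cases

* `min_alleles = 20`: pairs with fewer evaluable variant alleles are
  skipped; P_raw over a handful of alleles is too noisy to standardize.
* `min_pairs = 3`: a strain with fewer evaluated pairs gets no S_T; a
  z-score over two points is meaningless.
* σ_raw = 0 (all P_raw identical) leaves S_T undefined (`NA`) for the
  strain rather than forcing a value.
* L_min < 0 is guaranteed by the incidence clamping; `raw_score()` refuses
  L_min = 0.

## Catalog computations

* **MAG quality**: quality = completeness − 5 × contamination + log(N50),
  retention at quality ≥ 50, contamination ≤ 10, completeness ≥ 50 (all
  inclusive). The log is natural by default; base 10 is exposed
  (`log_base`) because the source convention is ambiguous and the choice
  only rescales the N50 term.
* **Tiers**: high (completeness ≥ 90, contamination ≤ 5), else medium
  (≥ 70, ≤ 10), else low, with high → medium → low precedence so the three
  tiers partition the retained set — as-printed tier rules overlap and
  leave gaps, while published tier counts sum exactly to catalog totals,
  implying a partition.
* **Dereplication**: greedy best-genome-wins centroid clustering on a
  pairwise ANI table (99% strain level, 95% species level), priority
  defaulting to the quality score. This reproduces the semantics of dRep's
  representative choice while consuming ANI tables rather than sequences.
* **Novelty**: best reference hit among those with aligned fraction ≥ 65%;
  ANI ≥ 99 known, ≥ 95 novel strain, otherwise (or no qualifying hit) novel
  species. The alignment gate is applied to both boundaries (configurable
  via `best_reference_hit(min_af=)`), since the printed rules state it only
  for the species call.
* **Abundance**: contig counts → CPM (per-sample sum 10⁶), MAG abundance as
  the median of its contigs' CPM (midpoint for even counts), phylum
  fractions renormalized per sample, Firmicutes*/Bacteroidota ratio,
  Shannon (natural log) and richness.
* **Community statistics**: Bray–Curtis (`vegan::vegdist`), sequential
  PERMANOVA (`vegan::adonis2`, 999 unrestricted permutations, Monte Carlo
  p = (1 + k)/(1 + n_perm)), Wilcoxon rank-sum (exact for tie-free groups
  of ≤ 8, else corrected normal approximation), Spearman correlation, and a
  one-dimensional "community composition" summary taken as the first
  principal-coordinate axis of Bray–Curtis — a documented stand-in, since
  no canonical definition exists for that quantity.

## The synthetic study generator

`sim_config()` defaults encode the cohousing design the pipeline targets:
15 goats and 15 pigs, six of each cohoused after weaning, goats sampled at
rumen and cecum, pigs at cecum, one sampling timepoint (the generator
supports several). Strains (50 by default) carry phylum labels drawn with
frequencies resembling a gut catalog (Firmicutes_A and Bacteroidota
dominant). Each strain occupies each of the three habitats (goat rumen,
goat cecum, pig cecum) with probability 0.6 and gets an independent
log-normal abundance profile per habitat; cohoused sample compositions are
linearly mixed toward the cohoused-pen mean with coefficient 0.3,
emulating the homogenization that cohousing produces.

Haplotypes are biallelic over 200 polymorphic positions with population
alt-allele frequencies uniform on [0.2, 0.8] (keeping incidences
informative); each (strain, host, gut site) draws its own haplotype. Reads
are Poisson per position with mean 10× scaled by the strain's relative
abundance, carry sequencing errors at rate 0.002 and Phred qualities
rounded from Normal(30, 3) truncated to [2, 41]; breadth is drawn from
[0.7, 0.95].

Planting: per goat and strain carried at both sites, a foregut–hindgut
event copies the rumen haplotype to the cecum with per-position flip rate
0.005 (probability 0.3). Cohoused events are planted on same-gut-site
cross-host pairs under a per-strain host matching — each host joins at most
one planted pair per strain — because unrestricted planting makes shared
haplotypes transitive (A–B and B–C copies silently make A–C a true sharer
that the truth table would wrongly call a false positive). When a copy
lands on a goat site that has a planted foregut–hindgut link, it is
propagated to the goat's other site so both planted events remain true.
Eligibility requires genuine habitat occupancy in both hosts: a strain
present in a cohoused sample only through trace mixing mass has essentially
no reads there, and a planted event on such a pair would be unobservable by
construction. The eligibility Bernoulli draws run on a dedicated seeded
stream, separate from the haplotype-copy draws, so the planting decisions
can be replayed independently for validation.

Where no source value exists, rates are calibration choices: the planting
rate 0.3 is the validation operating point (it yields a few planted pairs
per strain against a large scored background), not an estimate of any real
transmission frequency.

### What the generator does and does not emulate

It reproduces the features the score depends on — habitat-structured
abundances, presence/absence through coverage, allele incidence spectra,
depth- and quality-limited allele calls, planted sharing with mutational
divergence — and is deterministic given the seed. It does not simulate
reads or assembly, phylogenetic correlation among strains, strain mixtures
within a sample (each strain is one haplotype per sample), directional
transfer, or time dynamics (haplotypes are constant across timepoints).
Two visible simplifications: composition mixing gives cohoused samples
near-complete strain rosters, so cohoused richness is inflated relative to
controls (real data show no such alpha-diversity shift); and at the default
planting rate most strains end up with at least one event, so the
transmitted-abundance fraction saturates near 1 — correlation analyses on
synthetic data are therefore illustrative, not calibrated. Passing
recovery tests shows the score separates planted sharing from background
under these conditions; it does not certify performance on real data with
strain mixtures or reference bias.

## Numerical and design choices

* Natural logs everywhere a base is unstated (quality score, Shannon,
  likelihoods).
* Boundary conventions are inclusive exactly as printed: breadth ≥ 0.10,
  depth ≥ 0.15, two reads at Phred ≥ 15, completeness ≥ 50, quality ≥ 50;
  novelty uses strict `<` at 95 and 99.
* Ties in greedy clustering break lexicographically by genome id, making
  dereplication deterministic for equal priorities.
* PERMANOVA canonicalizes samples to sorted-id order before permuting, so
  results are invariant to input row order at a fixed seed; the
  calibration check uses two groups of 10 null samples because with
  smaller groups the chance that a random permutation ties the observed
  partition biases the Monte Carlo p upward, and the planted-effect check
  uses two groups of 6, the smallest size whose attainable p reaches 0.01.
* Problem sizes in tests and validation runs (50-strain studies, 500-run
  PERMANOVA calibration at 199 permutations) are chosen so a full
  validation completes in minutes on a laptop while keeping Monte Carlo
  error well inside the asserted margins.

## Known limitations

The score is symmetric: it detects sharing, not direction. Per-sample
incidences are approximated by one strain-level incidence table, which is
what makes the independence-product probabilities well defined but ignores
sample-specific allele frequency shifts. Strains are haploid-like single
haplotypes; real strain mixtures within a sample would dilute agreement
classes in ways the generator does not model. The 231-of-3262 scale of a
real catalog is far beyond desk-scale simulation; dataset-level headline
numbers are reproduced as arithmetic over their printed components, not
re-derived from reads.
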