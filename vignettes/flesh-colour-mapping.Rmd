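---
title: "Mapping the two-locus control of canary yellow watermelon flesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the two-locus control of canary yellow watermelon flesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleshmap)
```

## The genetic question

Canary yellow (CY) flesh in watermelon requires a dominant allele at the
*C* locus, the *LCYB* lycopene β-cyclase gene; its recessive homozygote
*cc* gives red flesh. Some lines carrying dominant *C* alleles still show
red mixed into the yellow background — incomplete canary yellow (ICY).
`fleshmap` implements the analysis chain that treats ICY as a Mendelian
trait in its own right: contrast resequenced ICY and CY inbred groups to
find a group-diagnostic genomic region, convert region SNPs into CAPS
markers, map the controlling locus (*C2*) in an F2, and validate a
two-locus epistasis model on a germplasm panel.

The model at the end is simple and fully enumerable: phenotype is R if the
*C* locus is *cc* (the *C2* genotype is masked), else CY if the *C2* locus
carries a dominant allele, else ICY. Both dominant alleles are required
for full canary yellow.

## Genotype classification and the integrated matrix

Per-sample calls at a biallelic SNP are classified from the alt-supporting
read fraction: homozygous-alt at ≥ 0.90, heterozygous in the inclusive
0.40–0.60 band, and "etc" (undistinguishable) in between; an absent rate
is missing. The ≤ 0.10 homozygous-reference band mirrors the alt band by
symmetry — the classification is defined on the alt-allele fraction, a
choice this package documents rather than inherits, since a read rate can
equally be defined against the consensus. The five classes partition
[0, 1] ∪ {absent}, which the tests assert directly.

The matrix is the union of per-line variant positions; a line without a
record at a union site is missing until imputation fills it from that
line's consensus base: consensus = ref → hom_ref, = alt → hom_alt,
anything else (N, third allele) → "etc", because such a call cannot be
distinguished as homozygous or heterozygous. Imputation is idempotent and
never touches non-missing calls. Multi-allelic records are dropped at
ingestion with a logged count; the downstream cascade is defined over
biallelic homozygous contrasts, so nothing later would consume them.

## The filtering cascade

The contrast uses three groups: two severely reddish ICY lines (ICY-H),
one slightly reddish line (ICY-L), and three CY lines. Steps:

1. sites monomorphic within ICY-H and within CY — every sample of the
   group shares the same *homozygous* class; het/etc/missing break
   monomorphism (strict homozygosity);
2. the comparable intersection, then the subset whose shared classes
   differ between the groups;
3. arbitration with ICY-L: the polymorphic set splits into sites where
   ICY-L matches the ICY-H class, sites where it matches the CY class,
   and an unassigned remainder.

The final diagnostic set is the ICY-L-agrees-with-ICY-H subset — the only
partition member in which all three ICY lines share one homozygous allele
and all three CY lines the other, i.e. the sites specific to the ICY/CY
contrast. The report retains every intermediate set and count so the other
readings can be audited. A brute-force oracle (direct evaluation of the
set definition on the matrix) is compared against the cascade on random
matrices in the tests.

## Candidate regions and effect annotation

Diagnostic SNPs are counted in non-overlapping 4-Mb tiles
[k·w+1, (k+1)·w]. Density clusters are maximal runs of adjacent tiles
with at least `min_snps` SNPs (default 3, the smallest cluster size of
interest), refined to the min/max SNP position inside the run. Counts are
conserved per chromosome by construction.

Effect annotation walks gene models: intergenic outside all gene spans,
intron inside a gene but outside exons, exon otherwise; for CDS exons the
reference and alternate codons are compared after splicing, with
minus-strand genes reverse-complemented, under the standard genetic code.
A CDS whose joined length is not divisible by 3 is an error naming the
gene; a reference-allele mismatch against the genome is a data error.
Indels get context only. The test oracle rebuilds the whole CDS,
substitutes the allele, translates both proteins with Biostrings and
diffs them — a deliberately different route from the codon arithmetic in
the implementation.

## CAPS and dCAPS design

Flanks are 300 bp on each side of the SNP; the allele sequences are
300 + 1 + 300 = 601 bp because the SNP base itself must be included.
Restriction-site scanning expands IUPAC degeneracy and searches both
strands (forward pattern plus its reverse complement; palindromes counted
once per position), via `Biostrings::matchPattern(fixed = FALSE)`; the
test oracle is a naive every-offset bitmask scanner. An enzyme is
*differential* when its match set differs between the allele sequences,
and only matches whose footprint covers the SNP are causal and returned.

Fragment prediction cuts at `cut_offset` bases after each match start;
lengths always sum to the amplicon length. For Type IIS enzymes (FokI,
MnlI) the offset encodes the downstream top-strand cleavage point
(GGATG(9), CCTC(7)); for matches in reverse orientation the same offset
from the match start is used, a simplification that preserves fragment
conservation and differentiality, which is what gel-based genotyping
needs, at the cost of a few bp of accuracy in the printed sizes.

Primers come from a deliberately simple picker: lengths 18–25, Tm by
64.9 + 41·(GC − 16.4)/N in 55–62 °C by default, no primer may overlap the
SNP, product must contain the SNP within the allowed size range.
Tie-breaking is leftmost start, then shortest, then smallest Tm distance
to the range midpoint — fully deterministic. Thermodynamic design
(hairpins, dimers, salt correction) is out of scope.

dCAPS is the fallback when no natural differential enzyme exists (calling
it otherwise is an error): the search enumerates single-base
substitutions within a window (default 12 bp) on either side of the SNP,
in deterministic order (distance, upstream first, base A<C<G<T, enzyme
table order), keeping substitutions for which the modified template plus
exactly one allele contains a SNP-covering recognition site. The mismatch
is carried by the primer whose 3' end abuts the SNP, and every returned
assay is validated in silico: the two allele amplicons must digest to
different fragment multisets.

## Segregation and linkage

The χ² ratio test uses expected counts proportional to the Mendelian
ratio, df = classes − 1, upper-tail p; for the observed 94 CY : 41 ICY F2
this gives χ² = 2.076, p = 0.149, consistent with 3:1.

Two-point recombination fractions are maximum-likelihood under the F2
two-locus class probabilities in coupling with no interference. With
parental gametes at (1−r)/2 and recombinants at r/2, the 3×3
(a/h/b × a/h/b) probabilities follow from gamete products; the double
heterozygote is the phase mixture (2p² + 2q²). The dominant-trait
estimator collapses the trait columns (h + b) because phenotype cannot
separate the heterozygote from the dominant homozygote. Likelihoods are
maximised by a grid at 10⁻³ with local refinement by `optimize`, with the
endpoints {0, 0.5} always compared explicitly so perfect cosegregation
returns exactly 0 — a grid-vs-likelihood oracle in the tests checks the
maximiser. LOD is log₁₀ L(r̂) − log₁₀ L(0.5), with 2.0 as the linkage
threshold.

Map distances use Kosambi, d = 25·ln((1+2r)/(1−2r)) cM, and the analytic
inverse r = tanh(d/50)/2; the round trip is exact to 10⁻¹⁰ over the
tested grid. Maps are assembled along the externally fixed physical
order — multipoint ordering is deliberately replaced by two-point
estimates because the markers map in physical order anyway — accumulating
adjacent-pair Kosambi distances, so cosegregating loci share a position.
Missing calls are dropped pairwise, never imputed.

"Definite recombinant" counting under dominance is conservative: with the
recessive phenotype any dominant-parent marker allele is impossible
without recombination (marker b counts two gametes, h one), whereas a
recessive-class marker with the dominant phenotype is ambiguous and not
counted. This operational rule is a documented choice; phenotype alone
cannot resolve the ambiguous class.

## What the generator emulates — and what it does not

`gen_resequencing_panel` plants a 272-SNP diagnostic region at
27.60–27.88 Mb on a 36-Mb chromosome 2, plus 3- and 8-SNP clusters on
chromosomes 5 and 9, over background variation at 10⁻⁵ sites/bp across
108 Mb. Inside planted regions all ICY lines are homozygous for one
allele and all CY lines for the other; background sites are either shared
by all six lines (cultivar-vs-reference differences, the dominant class
in real panels of related inbreds) or private to one line. Neither
background class can form a perfect three-vs-three group split, so with
no missingness the cascade recovers the planted set exactly — the
planted-truth recoverability the tests rely on, and consistent with a
contrast in which the diagnostic SNPs concentrate in the causal region.

Read rates come from a depth model: depth ~ Poisson(30), alt reads ~
Binomial(depth, p) with p = 0.998/0.002 for homozygous truth; 2% of calls
are missing (no reads) with the line's true base retained as the
consensus for imputation. At 30× a true heterozygote would fall outside
the 0.40–0.60 band about a fifth of the time, which is how a large "etc"
class arises in real panels; since simulated inbreds are fully
homozygous, an explicit `ambiguous_frac` dial (default 0) forces rates
into 0.6–0.9 to exercise that class. The generator does not model
alignment artifacts, paralogy, indel-proximal miscalls, base-quality
variation, or linkage disequilibrium between background sites — so
passing recovery tests demonstrates the logic of the cascade, not its
robustness to real-data pathologies upstream of the variant matrix.

The F2 generator forms each gamete locus-by-locus with recombination
probabilities from Kosambi-inverted cM gaps, independently per interval
(no interference) — the simplest model consistent with the two-point
estimators downstream, and the same transform used in mapping, so
parameter-recovery tests are calibrated end to end. Defaults are 135
plants with nine markers at their published map positions and the trait
cosegregating at 8.7 cM. The genome fixture builds two-exon genes on
alternating strands with planted codon pairs (GGA>GGG and CTG>CTA
synonymous; GGG>GCG and ATG>ACG non-synonymous), intronic, intergenic and
5'UTR SNPs, all with truth labels.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere internally (VCF/GFF3
  convention); BED output converts to 0-based half-open in one place
  (`to_bed`), and no other module performs 0/1-based arithmetic.
* All generators take an integer seed and are deterministic given it;
  panel VCF output is byte-identical across runs with the same seed.
* VCF calls are classified from AD-derived rates when AD is present
  (matching how the matrix is defined), falling back to GT otherwise.
* The r̂ grid (10⁻³, refined to ~10⁻⁹) trades negligible bias for exact
  reproducibility; estimates are clamped to [0, 0.5].
* Problem sizes in the tests — 100 panels of ~1,300 sites, 200 F2
  replicates of n = 500, 1,000 random 600-bp sequences × 8 enzymes —
  were chosen as the smallest sizes at which recovery statistics are
  stable; the whole suite runs in under two minutes.

## Known limitations

The resequencing-scale SNP counts of a real panel (hundreds of thousands
of raw SNPs per line) are not reproduced at this scale; the cascade's
correctness is established by oracle equivalence instead. The two-locus
model collapses the two *C*-locus markers into one genotype and treats
marker genotype as locus genotype (the markers cosegregate in the mapping
population); marker/locus recombinants in unrelated germplasm would
violate that assumption and are reported as mismatches, not resolved.
dCAPS reconstruction is a documented method, not a reproduction of any
particular published assay's design path.
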