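---
title: "Detecting, validating and dating horizontal nuclear DNA transfer in transmissible cancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, validating and dating horizontal nuclear DNA transfer in transmissible cancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hgtscreen)
```

## The problem

Transmissible cancers — the canine transmissible venereal tumor (CTVT) and
the two Tasmanian devil facial tumor clones — are malignant cell lineages
passed between animals as allografts. Every tumor of such a lineage carries
the germline genome of the single founder animal in which the cancer arose,
clonally propagated for centuries to millennia. This makes them uniquely
suited to detecting host-to-tumor *horizontal transfer* of nuclear DNA: any
germline polymorphism among tumors of one clone that cannot be explained by
somatic mutation hints at DNA acquired from a transient host.

`hgtscreen` implements the computational machinery of such a screen as a
reusable, fully testable pipeline: purity-aware genotyping, the
flipping-SNP screen, three hallmark validations, breakpoint-chain assembly
of the transferred element, CpG molecular-clock dating, donor-haplotype
inference, and allelic expression deconvolution — together with a
synthetic-cohort generator that provides ground truth for every stage.

## The read-count model and genotyping

A bulk tumor biopsy with purity $p$ mixes cancer cells with diploid host
cells. At a biallelic site where the cancer cell carries $k$ alternate
copies of $c_t$ total and the matched host carries $h \in \{0,1,2\}$
alternate copies, the expected alternate read fraction is

$$ \pi(k) = \frac{p\,k + (1-p)\,h}{p\,c_t + 2(1-p)}. $$

`correct_vaf()` inverts this mixture to report VAFs on the cancer-cell
scale, and `classify_genotype()` picks the $k$ maximizing the binomial
likelihood of the observed alternate reads at
$\pi'(k) = e + (1-2e)\,\pi(k)$, where $e$ is a per-base sequencing error
rate (default 0.005) that lets homozygous states absorb occasional stray
reads. We chose a likelihood rule over fixed VAF cutoffs because it
generalizes across copy number and purity without re-tuning. The host
dosage is taken from the matched host's own genotype call; when the host
column is absent it is estimated as twice the host VAF rounded to
$\{0, \tfrac12, 1\}$. Calls need depth $\ge 15$ (configurable) and copy
number $\ge 2$; the lineage consensus per site is a strict majority of
non-missing homozygous versus heterozygous calls, requiring calls in at
least 80% of tumors.

## The flipping-SNP screen

A *flipping SNP* is a site whose genotype in one tumor conflicts with the
lineage consensus. The screen counts hom→het flips in non-overlapping
100-kb windows and flags windows that are outliers by two joint criteria:

* a robust z score $0.6745\,(x - \mathrm{median})/\mathrm{MAD} > 3.5$ over
  the tumor's own genome-wide window counts; and
* Cook's distance above $4/n_\mathrm{windows}$ from an ordinary
  least-squares regression of the tumor's window counts on the
  cohort-median window profile. The regression model behind the published
  Cook's-distance filter is not fully specified anywhere we could follow,
  so this choice — which isolates tumor-specific excess from any structure
  shared across the cohort — is our own and is recorded in the output
  metadata.

When flipping is so rare that the MAD is zero, the z criterion falls back
to a Poisson upper tail test with a robust rate $\max(\mathrm{median},
0.1)$ at tail probability $10^{-3}$. Flagged windows within 500 kb of each
other are clustered; a cluster becomes a candidate region when it contains
at least three consecutive flagged windows. Only hom→het flips seed
regions (the signature of an introduced haplotype); het→hom flips are
recorded but never trigger detection. Sites must also lie in regions that
retain both parental homologues — operationalized as 1-Mb eligibility
windows in which at least 10% of consensus-determined sites are
heterozygous — because a transfer into a region that lost one homologue is
indistinguishable from simple loss of heterozygosity and is undetectable
by design.

## Hallmark validation

Three independent lines of evidence distinguish a horizontally transferred
haplotype from mundane copy-number gain:

1. **Integer copy-number step** (`copy_number_step()`): the modal integer
   state in carriers must exceed the non-carrier modal state by exactly +1
   in every copy-number interval intersecting the region. Modal ties mark
   an interval indeterminate and fail the hallmark.
2. **Somatic VAF dosage pattern** (`vaf_pattern_test()`): in carrier
   regions of copy number 3, pre-existing somatic mutations sit on one of
   three copies (dosage 1/3). A recent duplication of a parental
   chromosome would instead show pre-duplication mutations at dosage 2/3.
   Per mutation, the two dosages' binomial log-likelihoods are compared
   (summed over the carriers observing it); the hallmark passes when fewer
   than 5% of mutations favor 2/3. Ten mutations are required for a
   determination.
3. **Per-copy mutation-density deficit** (`mutation_density_contrast()`):
   mutation counts in 10-kb windows, normalized by total copy number, are
   compared between the footprint and an equal number of immediately
   flanking windows (split half per side, truncated at chromosome ends —
   window-count matching was chosen where length- versus count-matching
   was ambiguous) with a two-sided Welch t test, which we prefer over the
   pooled-variance t test since nothing guarantees equal variances.

A duplication decoy as old as the transfer produces the *same* per-copy
density deficit as a genuine transfer — density alone cannot separate the
two — which is exactly why the dosage pattern of hallmark 2 matters; the
generator's `decoy_duplication` mode exists to exercise this distinction.

## Chain assembly

`assemble_chain()` walks the derivative structure of the element as a
simple chain: starting from a seed terminus, it alternates between
traversing a copy-number step segment and hopping across the junction
matched to the segment's exit end. Breakends match segment ends within a
tolerance of ±5 kb, since copy-number breakpoints are window-resolution.
Blocks entered through their right end are reported on the `-` strand; the
BEDPE strand columns encode breakend sides. A breakend matched by two or
more junctions violates the simple-chain assumption and raises an error
naming the breakends; a walk that returns to its start is reported as a
circular element, not an error. Junctions need three supporting reads by
default. The packaged fixture under `inst/extdata/` reproduces the
published summary topology of the CTVT element (11 blocks from six
chromosomes, 15 Mb, centromeric tip to centromeric tip); its coordinates
are synthetic, as marked in the file names, because the real junction
table is not redistributed here.

## Molecular-clock dating

C>T mutations at CpG dinucleotides accumulate at an approximately constant
rate and serve as a clock. In segments where the non-carrier modal copy
number is 0–2 and the carrier modal state is exactly one higher, the
single extra carrier copy is attributed wholly to the transferred
haplotype. Per 1-kb bin, the parental per-copy density is the non-carrier
mean of $\mathrm{count}/(\mathrm{CpG\ sites} \times \mathrm{copies})$;
subtracting the expected parental count from each carrier's bins leaves
the residual attributed to the transferred copy. The point estimate is the
mean over carriers of per-carrier densities; its SE is taken **across
carrier tumors**, not across bins, because the per-tumor densities are the
independent observations (bins within a tumor share the tumor's history).
Negative residuals are retained in the raw estimate and only the reported
value is clamped at zero. With a diploid rate $\mu$ (default
$6.87\times10^{-7}$ mutations/site/year), the per-copy rate is $\mu/2$ and
the age is $d_h/(\mu/2)$, with a 95% CI from $d_h \pm 1.96\,\mathrm{SE}$;
years are rounded for reporting and the raw value kept. Age is linear in
the density and inversely linear in the rate, which the tests assert
exactly.

## Haplotype inference and expression deconvolution

At biallelic sites inside step segments, the parental alternate dosage
$a_p$ comes from the non-carrier consensus scaled to the parental copy
number; each carrier's reads are scored under dosages $a_p$ versus
$a_p + 1$ of $c_p + 1$ copies through its purity mixture, log-likelihood
differences are summed across carriers, and the transferred allele is
called when the sum clears ±3 (a conventional strong-evidence threshold;
the published procedure subtracts allele counts but does not state its
decision rule, and the likelihood form is more robust to sampling noise).
Sites are restricted to transversions by default, the class least affected
by recurrent mutation; the generator labels sites transition/transversion
at the canonical 2:1 ratio.

For expression, an allele is *informative* when exactly one of the three
DNA sources in a biopsy — transferred element, cancer parental
chromosomes, infiltrating host cells — carries it. Informative-allele read
counts are normalized by median-of-ratios size factors computed in-module
(re-implemented rather than delegated so the pipeline stays
dependency-free and the computation testable; an installed reference
implementation is used as an independent cross-check in the test suite),
then divided by the allele's copy number in its source, and pooled per
(gene, source) across tumors with SEM-based 95% CIs. Size factors are
computed from genes off the element only: the element's extra copy shifts
its genes' counts in carriers, and median-of-ratios is only robust while a
minority of reference genes move (in the real transcriptome the element is
a negligible fraction; in the simulation it is not, so the control-gene
restriction matters). CIs use the Student-t quantile on the SEM so that
records pooled from two or three tumors get honestly wide intervals; a
single-tumor record has an undefined CI. Genes need five informative reads
to be reported. Source comparisons are ordinary least-squares fits with
Pearson correlation (`cor.test`).

## The synthetic cohort generator

`simulate_cohort()` generates everything the pipeline consumes, with known
truth:

* **Cohort structure.** 47 tumors in two clades (7 carriers, 40
  non-carriers), one diploid matched host each; per-tumor purity uniform
  on [0.8, 0.95]; Poisson depth with mean 77, the cohort median depth of
  the study design it emulates.
* **Transmission tree.** A trunk from lineage origin to the clade split,
  an optional shared carrier-clade branch down to the element acquisition,
  and private branches to each tumor (a two-clade star within clades —
  the screen needs clade structure, not full topology). Defaults: lineage
  age 6,434 y, split and acquisition both 2,006 y. These are chosen so
  that, at the per-copy rate $3.435\times10^{-7}$/site/year, parental
  copies carry a per-CpG-site density of $2.21\times10^{-3}$ and the
  transferred copy $6.89\times10^{-4}$ — the regime the clock estimators
  are designed for. The acquisition is placed at the split because the
  constraint "acquired no earlier than the split" and the near-equality
  of the two dates leave no room between them.
* **Genome.** Four chromosomes at realistic dog lengths (~339 Mb total)
  carrying a three-block planted chain (5.5 + 1.5 + 1.0 Mb). The genome
  is scaled down ~7× from a full genome, but the element is *not* scaled
  with it: the planted blocks occupy under 3% of the screening windows,
  preserving the sparsity regime that genome-wide outlier statistics
  (MAD, Cook's distance at the 4/n threshold) assume. An earlier,
  smaller prototype genome in which the element covered a third of all
  windows made the element mask itself in the regression — a scaled-down
  genome must preserve the signal-to-genome ratio, not just shrink.
* **Panel.** 160,000 uniformly placed biallelic SNPs (~0.5/kb). Founder
  heterozygosity 0.3 per site; host genotypes at per-site population
  frequencies; the donor haplotype is a copy of one founder haplotype
  redrawn uniformly at a site with probability `donor_divergence`
  (default 0.3, in the range of allele-sharing distances between
  unrelated dogs at common biallelic SNPs; the screen only needs allelic
  difference, not a donor population model).
* **Somatic mutations.** Poisson along the tree at
  `somatic_rate_per_copy` per site per year per copy, with a CpG-context
  flag drawn Bernoulli(`cpg_fraction`, default 0.01) rather than from
  sequence — this avoids any reference-genome dependency and makes the
  expected CpG-site count per kilobase (`1000 * cpg_fraction`) exactly
  consistent with the thinned mutation rate. Mutations are simulated only
  inside `somatic_regions` (blocks ± 5 Mb by default), the only
  intervals any downstream stage reads mutations from; simulating them
  genome-wide would cost tens of millions of rows for no analysis gain.
* **RNA.** Gene expression follows a log-normal cancer program shared by
  the parental copies and the transferred copy, and an independent host
  program expressed by the infiltrating fraction; counts are Poisson with
  per-sample library size factors. 30% of genes are placed on the element
  (kept below one half deliberately — see the size-factor discussion
  above).
* **Decoys.** `decoy_duplication = TRUE` replaces the transferred
  haplotype with a duplication of a parental copy of configurable age:
  the copy-number step is identical, flipping SNPs are absent, pre-
  duplication mutations ride 2 of 3 copies, and the clock attributes the
  duplicate's own age to the "extra" copy.

What the generator does **not** emulate: sequence-level reads, real SNP
spatial clustering and linkage, aneuploid karyotypes beyond the planted
step, sub-clonal copy number, multi-allelic sites, mutational-signature
composition (only a CpG flag), sequencing error in the emitted counts, or
within-clade phylogenetic structure. Tests passing on these simulations
therefore demonstrate that the estimators recover what the model plants
under realistic sampling noise — not that every complication of real
tumor genomes is handled.

## Numerical choices and degenerate inputs

* Genotype scores drop the $k$-independent binomial coefficient; all
  comparisons and confidences are unchanged, and computation is grouped
  by the handful of distinct (copy number, host dosage) success
  probabilities per tumor.
* Modal copy numbers resolve ties to "indeterminate" rather than picking
  a side.
* `ht_density` keeps negative residual bins; only the reported density is
  clamped at zero.
* Regions shorter than one window, zero-CpG bins, zero-variance
  correlation inputs, zero size factors, and missing upstream pipeline
  outputs all have explicit, tested behaviours (error, exclusion or `NA`
  with a reason).
* Problem sizes in the test suite: module tests run a 24-tumor, 80-Mb,
  40,000-site reduction of the default configuration (~1 s per cohort);
  the cohort-scale screen-recovery check runs the full 47-tumor default
  across 50 seeds; clock recovery uses 2×10^5 to 4×10^6 CpG sites. These
  sizes were chosen to make every stochastic claim testable in minutes on
  a single core.

## Known limitations

* The screen cannot see transfers that replace a haplotype without a
  copy-number change in regions lacking retained heterozygosity — a
  design limitation inherited from the biology, not an implementation
  gap.
* The Cook's-distance gate assumes the transferred element is sparse
  relative to the genome; cohorts where a putative element spans more
  than roughly a tenth of all windows would mask themselves and need a
  larger screened genome or an external candidate list.
* Dating assumes the clock rate is constant and shared between parental
  and transferred DNA after acquisition, and that the carrier modal copy
  number attributes exactly one copy to the element.
* Haplotype inference assumes a consistent carrier copy number across
  tumors at each site and reports "undetermined" where that fails.
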