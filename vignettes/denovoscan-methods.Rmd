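---
title: "Calling and characterizing de novo genes with denovoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing de novo genes with denovoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A *de novo* gene is a protein-coding gene born from previously noncoding
DNA, rather than by duplication, fusion, or horizontal transfer. Detecting
one requires showing two things about a focal-genome gene: (i) it has no
protein-level homolog in close relatives, and (ii) the orthologous locus in
those relatives is demonstrably *noncoding* — not merely unannotated. The
classic design compares the focal genome against a panel of close relatives
split into an **in-group** (very close, e.g. conspecific cultivars and
sibling species) and an **out-group** (slightly more distant species):
requiring noncoding ancestry in at least one genome of *each* group places
the gene's birth on the focal lineage rather than explaining it by loss.

`denovoscan` implements that design end to end for desk-scale data, plus
the standard downstream characterizations: gene-structure and codon-usage
features, an intrinsic-disorder proxy, expression level and breadth,
promoter cis-regulatory binding sites (CRBS), GO enrichment of flanking
genes, weighted co-expression modules, and QTL overlap. A seeded synthetic
genome generator plants every gene class with a truth table, so the whole
pipeline is testable without any external download.

## The calling procedure

1. **Homology filter.** Every focal protein is locally aligned
   (Smith–Waterman, BLOSUM62, affine gaps 11/1) against every relative
   proteome. Significance uses the Karlin–Altschul expectation
   $E = K\,m\,n\,e^{-\lambda S}$ with the published gapped-BLOSUM62
   constants $\lambda = 0.267$, $K = 0.041$ and no edge correction. A gene
   with no hit at $E \le 10^{-5}$ in *any* relative is a **candidate**.
   Conversely, a gene with a unique reciprocal best hit at $E \le 10^{-5}$
   in *every* relative is a **conserved** one-to-one ortholog; these two
   sets are disjoint by construction. Because exact reproduction of an
   external search engine's E-values is impossible, the contract here is
   the threshold behavior on well-separated data, and an adapter accepts
   precomputed tabular hits.

2. **DNA mapping.** Each candidate CDS is mapped onto both strands of every
   relative chromosome by exact 12-mer seeding followed by full local
   alignment of the seeded window (match +1, mismatch −2, gap open 5 /
   extend 2). Co-linear alignments on one chromosome and strand within 5 kb
   are chained. Two gates apply: a per-segment score floor
   (`min_score = 25`) that removes the short chance alignments any seeded
   whole-genome scan produces (noise scores ~15–20 here, true locus
   alignments ≥ 35), and an identity floor (`min_identity = 0.7`).

3. **Region class.** A hit is `coding` when more than `tau_nc = 0.05` of
   its aligned target bases fall in annotated protein-coding exons, `te`
   when the same holds for transposable-element annotation, else
   `noncoding`. The tolerance absorbs annotation edge noise; it is
   configurable.

4. **ORF-trap screen.** A "noncoding" locus may simply be an unannotated
   gene. For every supporting noncoding hit the aligned span ±300 nt is
   scanned in six frames; if an ATG→stop ORF encodes a peptide that locally
   aligns to the candidate protein covering ≥ 80% of it at ≥ 60% identity,
   the hit is a trap and cannot support the call. The window and both
   thresholds are configurable; the defaults describe "an intact hidden
   homolog of essentially the whole protein".

5. **The call rule.** A candidate is **putative** iff, after trap removal,
   noncoding hits with chained query coverage ≥ 0.5 remain in at least one
   in-group *and* one out-group genome. Candidates that would have passed
   only with trapped hits are recorded `excluded_orf_trap`; the rest
   `excluded_no_support`. Support uses presence semantics: one qualifying
   hit per genome suffices even if other hits are coding.

6. **Origin classes.** Over all relatives, the fractions of the candidate
   CDS covered by alignments onto annotated gene exons ($f_{gene}$) and TE
   bases ($f_{te}$) are computed as union coverage. Type I:
   $f_{gene} = f_{te} = 0$ (entirely noncoding ancestry). Type II:
   $f_{gene} > 0$ and $f_{gene} + f_{te} \le \theta$ (chimera with a minor
   portion of a pre-existing gene). Type III: $f_{gene} = 0 <
   f_{te} \le \theta$ (TE-only chimera). When $f_{gene} + f_{te} > \theta$
   the sequence is majority ancestral-coding and the call is demoted. The
   literature describes the TE-containing class inconsistently, so
   `te_class = "type2"` folds TE chimeras into Type II instead; $\theta$
   defaults to 0.5 ("minor portion" is not quantified anywhere, half is
   the natural reading).

   Sub-coverage hits (e.g. a donor fragment covering 20% of a chimera)
   never count as support but *are* kept as evidence: they are the only
   observable trace of chimeric origin, and dropping them would turn every
   Type II gene into an apparent Type I.

7. **Expression confirmation.** A transcript is *not expressed* only when
   its FPKM is zero across all replicates of every tissue; putative calls
   expressed in ≥ 1 tissue become `confirmed_expressed`. Expression level
   is $\log_2(\text{mean FPKM} + 1)$ over all samples (the aggregation is
   configurable in spirit — the transform is standard, the mean is our
   choice) and breadth is the count of expressed tissues.

## Downstream characterizations

**Features.** Gene/CDS/intron/exon lengths come from the gene models
(intron total = span − exon total; single-exon genes have 0). GC and
GC1/GC2/GC3 are computed on codon-clean CDS, where GC =
(GC1+GC2+GC3)/3 exactly. Fop is the fraction of degenerate-family codons
that are their family's optimal codon; the optimal table is inferred as the
most frequent codon per family in the top 10% of genes by expression
(alphabetical tie-break), replacing correspondence-analysis-based detection
with a transparent, testable rule — a user-supplied table is accepted. The
disorder score is a FoldIndex-style sliding-window proxy
($2.785\langle H\rangle - |\langle R\rangle| - 1.151$, window 51,
Kyte–Doolittle hydropathy normalized to [0,1], K/R = +1, D/E = −1; ISD =
fraction of residues with negative window score). It is *not* a
re-implementation of any machine-learned predictor; externally computed
scores can be injected via `isd_override`. Class comparisons use two-sided
Mann–Whitney tests (normal approximation, tie-corrected) and Spearman
correlation of GC with ISD within class.

**CRBS.** Promoters are the 2 kb upstream of the start codon,
strand-aware, truncated at chromosome edges with a warning. Motifs are
IUPAC consensi scanned exactly on both strands (overlaps counted,
palindromes counted once per strand). Significance follows a
CI-exceedance rule: the expected count is
$E = 2\,(L - w + 1)\prod_i p(\text{allowed}_i)$ under the promoter's own
base composition with positional independence, the 95% bound is
$E + 1.96\sqrt{E}$ (normal approximation to a Poisson count; exact Poisson
quantile behind `ci_method = "poisson"`), and a count is significant iff it
exceeds the bound *and* $E \le 5$ (the expected-count cap keeps
promiscuous, high-expectation motifs out). The null model is the package's
explicit choice — the source procedure names the criterion but not the
model — and its false-positive rate is Monte-Carlo checked by
`crbs_calibration`. The bundled ~40-motif library is a labeled stand-in
for real binding-site databases, not a reproduction of one.

**Enrichment.** Genes whose bodies overlap the 10-kb flanks of de novo
loci are collected either around the ancestral noncoding loci in the
relatives (`flank_mode = "ancestral"`, the default) or around the gene in
the focal genome (`"focal"`); both readings appear in the field and both
are implemented. One-sided Fisher (hypergeometric upper tail) per GO term
at raw $p < 0.05$; BH q-values are reported alongside but deliberately not
used for the cutoff, matching common practice in this literature. The GO
map is taken as-is (no DAG propagation).

**Network.** On $\log_2(\text{FPKM}+1)$: signed similarity
$s = (1 + r)/2$, soft power $\beta$ = smallest integer with scale-free fit
$R^2 \ge 0.8$ (fallback 6), topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$, average-linkage clustering of $1-\mathrm{TOM}$, and a *static*
cut — dynamic tree cut is intentionally out of scope. The default cut
height is 0.9: TOM arithmetic puts within-block heights near 0.3–0.4 even
for strongly correlated blocks and between-block heights near 0.97, so a
cut must sit between those plateaus; the familiar 0.25 is an *eigengene
merge* threshold and would shatter every module if used as a dendrogram
cut. Clusters ≥ 30 genes get size-ranked color labels, the rest pool as
"unassigned". A known coarseness of the static cut is that weakly
correlated background genes can be absorbed into a module rather than left
unassigned. Module significance is the mean |cor| of members with a trait;
default traits are one-hot tissue indicators. Modules with more than 10 de
novo members are flagged de novo-rich.

**QTL.** Intervals arrive in focal coordinates (1-based inclusive TSV,
converted once); a gene hits an interval iff its body overlaps ≥ 1 base
(half-open arithmetic: abutting is not overlap), and ≥ 2 hits flag a
pleiotropy candidate. Cross-genome lift-over is out of scope.

## The synthetic study generator

`simulate_genomes(sim_config(seed))` builds the focal genome as the common
ancestor and derives each relative by substitutions (default 10% per site)
plus short indels confined to intergenic spacers. Genes occupy 5-kb slots,
20 per ~100-kb chromosome, so 2-kb promoters never collide and the 10-kb
flank of any locus spans exactly the neighbors within two slots. Classes:

* **conserved** (100): ancestral CDS annotated everywhere, ORF preserved
  under mutation — a guaranteed one-to-one ortholog. Conserved genes carry
  a planted codon-usage bias (90% optimal codons) and broad log-normal
  expression (meanlog 3, sdlog 1, all 19 tissues × 3 replicates).
* **denovo_type1** (20): focal ORF whose relative loci are the ancestral
  sequence with ≥ 3 planted in-frame stops, verified in all six frames to
  contain no ORF ≥ 75% of the gene, and unannotated.

Two construction checks keep the truth table true by construction rather
than in expectation. First, the relatives' annotated ortholog CDS are
drawn before assembly, and every candidate-class protein (Type I/II, trap)
is locally aligned against the full annotated proteome — focal and all
relative copies — and resampled if any chance alignment comes within an
order of magnitude of the homology filter's E-value bar (E ≤ 1e-4 vs the
1e-5 filter). Without this, roughly one random ~100-aa protein in ten
thousand pairs grazes E ≤ 1e-5 and a planted de novo gene silently fails
the candidate filter on some seeds. Second, the Type II construction
verifies the chimera's peptide has no homology to its donor protein (the
frameshifted copy makes this true almost surely; failures resample).
* **denovo_type2** (10): chimera whose first 10–40% is copied +1
  frame-shifted from a conserved donor's first exon (DNA-detectable,
  protein-invisible; the homology-freeness of the encoded peptide against
  the donor is checked and resampled). The remainder's ancestral state is
  disrupted noncoding sequence. Fragments are floored at 60 nt so the
  12-mer seeded scan finds them reliably.
* **decoy_partial_ortholog** (10): intact annotated ortholog in exactly
  one in-group genome — caught by the homology filter, never called.
* **orf_trap** (5): relative loci unannotated but containing an intact,
  synonymously diverged ORF — caught by the trap screen.

De novo-like genes get low, narrow expression (meanlog 0.5, 1–4 random
tissues, zero elsewhere). Promoters receive Poisson(2) planted motif
instances recorded in the truth table; a plastid-organization GO term is
planted at 0.8 probability on genes within two slots of a de novo locus
(0.1 elsewhere); QTL intervals cover a recorded subset of de novo genes,
four of them twice. `simulate_coexpression` separately plants latent-factor
blocks (within-correlation 0.9, two blocks of 50 over 100 background
genes) for module-detection tests.

What the generator does **not** emulate: genome rearrangement and synteny
breaks, TE dynamics, coalescent population structure, sequencing noise in
FPKM, multi-isoform genes, and annotation error beyond the planted decoys.
Passing tests therefore demonstrate the pipeline's logic under clean,
well-separated conditions — not its robustness to assembly or annotation
artifacts in real data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 and QTL TSV are
  1-based inclusive only at the file boundary (one conversion site).
* CDS not divisible by 3, or containing N, is kept but excluded from codon
  statistics and translation-based steps.
* Ties: best-hit ties disqualify a reciprocal best hit; optimal-codon ties
  break alphabetically; `which.max` order resolves module label ties.
* Empty degenerate families in the Fop reference set fall back to
  genome-wide frequencies with a warning; genes with no eligible codon get
  NA.
* Promoters shorter than a motif score 0 matches and expectation 0;
  observed 0 is never significant.
* Problem sizes throughout the test-suite (145 focal genes, 4 relatives,
  ~100-aa proteins, ~100-kb chromosomes, 57 samples) were chosen as the
  smallest sizes at which every class recipe is unambiguous — e.g. protein
  E-values of true orthologs sit ~40 orders of magnitude below the 1e-5
  bar, and seed-and-extend mapping has negligible miss probability.

## Known limitations

* The E-value constants are fixed for BLOSUM62(11,1); other matrices would
  need their own $(\lambda, K)$.
* `map_dna` reports one best local alignment per seeded window; heavily
  repetitive targets would need multi-HSP reporting.
* The static dendrogram cut can absorb weak background genes into modules
  (see above) and has no analog of dynamic-tree-cut's adaptive depth.
* Fisher enrichment treats GO terms independently and unpropagated.
* The CRBS null assumes positional independence within the promoter;
  dinucleotide structure in real promoters makes the test slightly
  conservative or liberal depending on the motif.
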