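---
title: "Detecting horizontally transferred hAT transposase genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontally transferred hAT transposase genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtscreen)
```

## The problem

Parasitic plants draw water, nutrients and macromolecules from their hosts
through haustoria, and this intimate connection occasionally moves DNA across
the graft: host genes turn up integrated in parasite genomes. Detecting such
horizontal gene transfer (HGT) from transcriptome data is a screening problem
with three characteristic failure modes:

1. **Host contamination.** A parasite attached to its host inevitably
   co-samples host mRNA, which looks exactly like a recent transfer.
2. **Spurious short ORFs.** Weak similarity of short translated fragments
   produces unstable taxonomic signals.
3. **Ancestral similarity.** A native gene conserved since the common
   ancestor of the parasite and a distant lineage can superficially resemble
   a transfer.

`hgtscreen` implements the screen used to find two foreign hAT-superfamily
DNA-transposase genes in broomrape transcriptomes, together with the
annotation analyses that characterise such candidates: transposon border
structure search, pseudogene calling, flanking-gene synteny, and expression
summarisation. Every stage is exercised end-to-end on synthetic data with a
known ground-truth manifest.

## The screen

For each transcript, in this fixed order:

1. **Stage filter.** Only transcripts expressed (abundance > `min_abundance`,
   default 0) in at least one *pre-attachment* stage (defaults `0G`, `2G`:
   imbibed seeds and seedlings not yet attached to a host) survive. A
   transcript seen only after attachment is treated as possible host
   contamination. The default threshold of 0 means any positive abundance
   counts as "expressed"; there is no principled universal threshold, and raising it only
   makes the filter stricter.
2. **ORF length filter.** The transcript must contain a stop-free translated
   stretch strictly longer than `min_aa` = 100 amino acids in one of the six
   frames. We deliberately define an ORF as a maximal stop-to-stop stretch
   with no start-codon requirement: the screen targets homology, not gene
   models, and candidate transcripts are frequently fragments. The threshold
   is strict — 101 aa passes, 100 aa does not.
3. **Alien score ratio.** Hit evidence (protein level) is partitioned into
   *self* (the screened species; never scored), *ingroup* (relatives of the
   recipient — for a broomrape, the Lamiales) and *outgroup* (potential
   donors). The statistic is the ratio of the best outgroup bitscore to the
   best ingroup bitscore; a transcript is a candidate when the ratio is
   strictly greater than 1.2. "Best" is the highest bitscore with ties broken
   by lower e-value and then subject id, making the verdict invariant to hit
   order. Bitscores are used because the ratio is then scale-free: multiplying
   all scores by a positive constant changes nothing, so the choice of raw
   versus bit score is low-risk and is logged with the output. A query with
   outgroup hits but no ingroup hit at all is a *flagged* candidate
   (ratio `Inf`, flag `no_ingroup_hit`): complete absence of ingroup homology
   is stronger evidence than any finite ratio. No e-value cutoff is applied
   before the ratio by default.
4. **Nucleotide-level relative filter.** A candidate whose best
   nucleotide-level hit over all taxa is the designated closest ingroup
   relative (default *Mimulus guttatus*) is removed: strong nucleotide
   similarity to the nearest relative indicates shared ancestry, not
   transfer. Queries with no nucleotide similarity at all pass — that is the
   expected signature of a diverged foreign gene.

Every transcript receives a verdict row with the first failing stage flagged,
so the output table is auditable; the putative donor is the taxon of the best
outgroup hit.

## The built-in aligner

Hit evidence normally arrives as 12-column BLAST-style tabular files. For
self-contained testing the package also computes local alignments with a full
affine-gap dynamic-programming aligner (Rcpp): no heuristic seeding, intended
for test-scale inputs. Conventions, all of which matter for reproducibility:

* a gap of length $L$ costs `gap_open` $+ (L-1) \cdot$ `gap_extend` (the
  first gapped position is charged `gap_open`); both penalties are
  non-positive;
* percent identity is identical columns divided by all alignment columns,
  gaps included (the BLAST convention);
* raw scores convert to bits as $S' = (\lambda S - \ln K)/\ln 2$, with
  defaults $\lambda = 0.267$, $K = 0.041$ (standard gapped-protein values)
  and BLOSUM62 in protein mode, match $+1$ / mismatch $-2$ in nucleotide
  mode. All of these are configurable; the scale-freeness of the ratio makes
  the screen insensitive to them.

The aligner is verified in three independent ways: against a brute-force
recursive enumeration of all alignments on short pairs, against
`Biostrings::pairwiseAlignment` under a matched gap model, and against
hand-computed examples.

## TSD–TIR border structure search

An autonomously transposing hAT element sits between two copies of an 8-bp
target-site duplication (TSD) created at insertion, with terminal inverted
repeats (TIRs) immediately inside them:
TSD – TIR – transposase – revcomp(TIR) – TSD. `find_tsd_tir()` searches
windows (by default the 5000 bp on each side of a gene, plus intergenic
segments between tandem genes) for every such structure with:

* exact 8-bp TSD copies (duplications are created identical at insertion, so
  no tolerance is given here, unlike for TIRs);
* TIR length 8–23 bp, the two TIRs reverse complements of each other with at
  most one tolerated mismatch, and only at the outermost TIR base (the base
  adjacent to the TSD), flagged `imperfect_first_base`;
* at least three distinct nucleotides in the TIR — two-letter TIRs are simple
  repeats, not credible termini;
* `N` never matches anything, including `N`;
* all overlapping and nested structures reported, with no maximality pruning.

Each structure is annotated (never filtered) with whether the degenerate hAT
consensus `(T/C)A(A/G)NG` occurs in its TSD; since the 5-nt pattern cannot
anchor an 8-nt TSD uniquely, it is scanned at all four offsets.

The finder indexes exact 8-mers and tests TSD pairs; a separately written
brute-force oracle (`tsd_tir_oracle()`) enumerates all
(left TSD start, TIR length, right TIR start) tuples directly, and the two
are required to agree exactly on hundreds of seeded random windows and on all
constructed fixtures. Planted structures (via `plant_te()`) must be recovered
at exact coordinates; a single mutated TSD base must make the structure
undetectable.

## Pseudogene calling

Candidates are aligned to an in-frame reference CDS with an overlap
(free-end-gap) affine alignment, and two lesion kinds are called:

* **frameshift indels** — each contiguous internal gap whose length is not a
  multiple of 3. Gaps are judged per run, not summed over the gene: a 1-nt
  and a 2-nt gap 100 codons apart restore the global frame, but each
  disrupts local coding and both are reported. Clean in-frame indels are not
  lesions.
* **premature stops** — a stop codon aligned to a reference codon strictly
  before the reference's final codon (a stop aligned to the reference's own
  terminator is fine).

A candidate covering less than half the reference (configurable) is
`undetermined` rather than forced into a call. Status is invariant to
synonymous substitutions.

One numerical subtlety: when an indel falls inside a tandem repeat, several
gap placements score identically and "the" lesion position is not
well-defined. The lesion generator (`plant_coding_lesions()`) therefore
plants indels only at sites where no alternative placement within ±6 nt
yields the same candidate string (checked by direct string comparison), and
recovery tests require exact lesion counts and kinds, exact stop codon
indices, and indel positions within ±3 nt of the planted site.

## Synteny

Collinearity of the genes flanking a transposase tandem is evidence against
historical transposition. `compare_to_reference()` scores a species
gene-order table against the reference arrangement of six anchors (two
upstream, four downstream of the transposase genes):

* anchor losses do not break order conservation — order is judged on the
  anchors present, matching how partial assemblies are read;
* a full block reversal counts as conserved (flagged), and strand
  comparisons are normalised for it;
* the report is invariant to insertion of non-anchor loci;
* the tandem test asks whether all transposase-labelled genes lie between
  anchors *b* and *1* with no anchor interleaved.

Anchor assignment from similarity evidence is best-hit (not
reciprocal-best), with a 50-bit default floor and one locus per anchor
(higher bitscore wins; conflicts are logged).

## Expression

FPKM is computed in closed form
($\mathrm{fragments} \times 10^9 / (\mathrm{length} \times \mathrm{library})$),
with effective length defaulting to the annotated transcript length (no
fragment-length correction). Because reference genes such as actin assemble
into multiple isoforms of which only some contain the qPCR primer sites, the
reference level is the *sum* of the usable isoforms' FPKM values. qPCR data
use the comparative CT method, $2^{-(Ct_{target} - Ct_{ref})}$ within a
condition; no calibrator condition is baked in, so cross-condition ratios are
formed by dividing within-condition values.

```{r ct}
# within-flower level of the first transposase gene vs actin
comparative_ct(23.6, 24.2)
# stems-vs-flowers ratio for the second gene
comparative_ct(24.5, 25.2) / comparative_ct(25.0, 24.2)
```

## The synthetic-data generator

`make_screen_dataset()` emulates the statistical structure the screen
assumes, with all randomness seeded and byte-identical outputs under a fixed
seed:

* **native** transcripts descend from ancestors shared recently with the
  closest ingroup relative (default per-site substitution divergence 0.05)
  and distantly with the outgroup (0.35);
* **foreign** transcripts descend from donor-taxon genes (0.05 from the
  donor copy, 0.35 from any ingroup homolog) — the mirror image;
* **contaminants** are host-like transcripts with zero abundance in all
  pre-attachment stages;
* hit tables are computed with the built-in aligner (protein evidence is the
  best alignment over all ORF translations of 30 aa or more, mirroring a
  translated search), so no external search tool is ever needed;
* gene lengths are drawn from 150–400 codons; transcripts are re-mutated
  under a deterministic retry schedule if mutation happens to destroy every
  long ORF, since the screen presumes expressed coding transcripts.

The substitution model is uniform with no transition/transversion bias and
(by default) no indels — deliberately non-biological, but sufficient for the
separability the recovery tests measure. Consequently, passing recovery
tests show that the pipeline's decision rules are implemented correctly and
are well-separated at these divergences; they do not show robustness to
codon bias, heterogeneous rates, alignment-free contamination, or assembly
artefacts in real data.

Default problem sizes used throughout the tests and the acceptance script —
28 transcripts (20 native / 5 foreign / 3 contaminant), 200 oracle windows
of 200–300 nt, 50 planted elements, 100 pseudogene candidates — were chosen
as the smallest sets at which every decision boundary of the pipeline
(both filter directions, all TIR-length extremes, both lesion kinds) is
exercised multiple times.

## Known limitations

* The ratio statistic assumes the hit tables are taxonomically labelled and
  reasonably complete; a missing ingroup database inflates candidates (they
  surface flagged, not silently).
* "First hit" is operationalised as best bitscore; tools that rank by
  e-value can disagree on ties.
* The TSD–TIR search reports all structures; in highly repetitive windows
  the output can be large since no maximality pruning is applied.
* Pseudogene calling is splice-unaware and does not model relaxed selection
  (no dN/dS); it sees only what an alignment to one intact reference shows.
* The built-in aligner is quadratic and meant for test-scale sequences, not
  genome-wide search.
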