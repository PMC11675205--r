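---
title: "Quantifying minigene splice assays from long-read amplicon alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying minigene splice assays from long-read amplicon alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisplice)
```

## The assay and the analysis problem

A minigene splice assay clones a genomic fragment of interest — here 6944 bp
of *ABCA4* intron 11 (chr1:94531516–94538459 on hg19, minus strand; span
c.1554+4787..c.1555-2643) — between two backbone exons of an expression
plasmid. After transfection, the construct's transcripts are amplified with
primers anchored in the backbone exons and read out by long-read (nanopore)
cDNA sequencing. Each read reveals, through the splice junctions of its
alignment, which exons and pseudoexons were joined: the backbone-only
transcript (T1, 119 bp), or transcripts additionally carrying pseudoexon 11a
(c.1554+6710..c.1554+6836, 127 bp), pseudoexon 11b (between the cryptic
acceptor c.1555-5923 and donor c.1555-5750, 174 bp), or both — spliced
lengths 246, 293 and 420 bp.

The analysis problem is to turn a BAM of noisy spliced alignments into a
table of relative transcript abundances that can be compared between
conditions (reference vs variant minigene; untreated vs antisense
oligonucleotide-treated), and to corroborate low-abundance pseudoexons with
orthogonal short-read split-read counts. `minisplice` implements this as a
chain of small, testable stages; a synthetic-data module generates every
input, so the full pipeline is exercised without any external data.

## Coordinate algebra

All positions flow through three coordinate systems:

* **HGVS-style c. positions** with intronic offsets (`c.1555-5882` = 5882
  bases before the exon starting at coding position 1555);
* **genomic coordinates** on a stranded reference (1-based inclusive);
* **construct coordinates**: 1-based transcript-sense positions on the
  insert and on the construct pre-mRNA.

Internally every intronic position is reduced to its transcript-sense index
within the intron (`+k` is index *k*; `-k` is index *N − k + 1* for an
intron of length *N*). One anchor pair plus the intron length then fixes
every conversion, and all round trips are identities — property-tested over
random positions. The intron length (14372 bp for the bundled fixture) is
derived from the requirement that the insert's c. span and its genomic
interval describe the same 6944 bases; on the minus strand, transcript
direction corresponds to decreasing genomic coordinate:

```{r coords}
am <- anchor_map(parse_cnomen("c.1555-2643"), 94531516, "-", 14372)
cnomen_to_genomic(parse_cnomen("c.1555-5882"), am)
fx <- build_fixture_construct()
construct_position(parse_cnomen("c.1555-5923"), fx$construct)
```

Coordinates are 1-based inclusive at every interface; BED export converts
to 0-based half-open on write only.

## Splice-site scoring and the site registry

Candidate cryptic sites are scored with position-frequency matrices: the raw
score of a window is the sum of per-position base frequencies
(Shapiro–Senapathy style) and is min–max normalised to a percent,
`100 (raw − min) / (max − min)`, so 100 is the per-position consensus and 0
the anti-consensus. Frequencies rather than log-odds are the default
precisely because they give this bounded "transformed" percent semantics;
log-odds raw scores are available behind a switch. Default windows are
9 nt for donors (3 exonic + 6 intronic) and 16 nt for acceptors
(14 intronic + 2 exonic), classic PWM conventions; both are configurable,
and the packaged matrices are generic human-like frequencies, not a
reproduction of any proprietary predictor.

The **site registry** collects the construct's annotated backbone exon
boundaries plus predicted or user-supplied cryptic sites, each at the
junction-edge convention (donor = last exonic base, acceptor = first exonic
base). It is the sole reference for junction correction.

## Junction extraction, correction, classification

Junction chains are extracted by walking each alignment's
reference-consuming CIGAR operations: skips (`N`) of at least `min_skip`
(default 30 bp) become junctions, and deletions of at least
`promote_deletion_ge` (default 30 bp) are promoted to junctions, because
long-read aligners sometimes encode short skips as deletions. The defaults
make the assay's kb-scale events unambiguous while ignoring sequencing
indels. Reads must be mapped and primary; QC additionally requires mapping
quality ≥ 10 and ≥ 20 bp aligned coverage of both terminal backbone exons
(full-length amplicons).

Nanopore junction coordinates wobble by a few bases, so each endpoint is
snapped to the nearest registry site of the matching kind within a window
(default ±10 bp — comfortably above typical wobble, comfortably below the
98 bp distance separating the two variants of the complex allele).
Candidate sites are ranked by catalog-junction membership, then smaller
shift, then higher site score, then the more upstream position. The shift
is deliberately ranked above the score: with the score first, an endpoint
sitting exactly on a lower-scoring site could be dragged to a stronger site
nearby, and correction would not be idempotent; with the shift first,
correcting an already-corrected chain is provably the identity. A chain
with any endpoint beyond the window is *uncorrectable* — a value, not an
error.

Classification is exact equality of the corrected chain against the
catalog's canonical chains; everything else is `"other"`. Relative
abundance is the percentage of **all QC-passing reads**, so unclassified
reads stay in the denominator. This convention is what makes published
per-transcript percentages sum to slightly less than 100 — the remainder is
the "others" share — and every comparison and grouped sum in the package
relies on it.

Condition comparison is plain column arithmetic (`delta = B − A` per
transcript), and grouped abundances sum transcripts by event tag (e.g. all
transcripts containing pseudoexon 11b). Antisense-oligonucleotide-treated
samples are ordinary conditions; no AON-specific mathematics exists
anywhere in the quantification path.

## Short-read split-read inclusion

The 9-column splice-junction count dialect of short-read aligners is parsed
with exact column semantics. For a pseudoexon flanked by two exons, three
junction counts matter: upstream-exon→pseudoexon (`j_in_5`),
pseudoexon→downstream-exon (`j_in_3`) and the skipping junction (`j_skip`).
The inclusion range is

$$\mathrm{low} = 100\,\frac{\min(j_{5}, j_{3})}{j_{skip} + \max(j_{5}, j_{3})},
\qquad
\mathrm{high} = 100\,\frac{\max(j_{5}, j_{3})}{j_{skip} + \max(j_{5}, j_{3})}.$$

The denominator convention — skip reads plus the *larger* inclusion count —
deserves emphasis, since PSI-style estimators differ: both inclusion
junctions evidence the same molecules, so the larger count is the better
lower bound on how many included molecules were sampled, and counts of
5, 12 and 993 give 5/1005 and 12/1005, i.e. 0.5–1.2%. A PSI-style point
estimator (mean of the two inclusion counts) is available behind the
`estimator` flag. Only unique-mapper counts feed estimates; multimappers
are parsed and reported but never used. Default filters are permissive
(`min_unique = 1`, `min_overhang = 0`): overhangs are descriptive here, not
a filter.

```{r sj}
pseudoexon_inclusion(5, 12, 993)
```

## AON evaluation

Antisense oligonucleotide candidates are evaluated for length, GC content
(`100 (G+C) / length`, one decimal), melting temperature, exact antisense
complementarity to their target window, and overlap with variant positions
and registry splice sites. Tm is method-parameterised (Wallace rule, basic
GC formula, or unified nearest-neighbour thermodynamics with entropic salt
correction at 50 mM Na+ and 25 nM strands) because no single standard
formula reproduces every published oligo datasheet value; the method used
is always recorded in the report. Chemistry labels (e.g. 2'-MOE-PTO) are
metadata only — no thermodynamic correction for backbone chemistry is
attempted. Guideline flags encode common design ranges (length 18–25 nt,
GC 40–60%).

## What the simulator emulates — and what it does not

The synthetic-data module generates the complete study: the fixture
construct above (with seeded-random DNA carrying consensus splice motifs
planted at every site edge, and the reference bases of the complex allele
c.[1555-5882C>A;1555-5784C>G] planted inside pseudoexon 11b), plus
multi-isoform amplicon reads at chosen proportions with:

* **junction jitter**: independent discretised normal noise (sd 2 bp by
  default) on each junction edge, hard-clipped at ±8 bp — strictly inside
  the ±10 bp correction window, which makes 100% chain recovery provable
  rather than merely likely;
* **indels and substitutions** at per-base rates (defaults 1%/1%/3%),
  with indels kept short (1–3 bp, far below the 30 bp promotion
  threshold);
* **truncations**: with probability 2% per read end, a geometric number of
  bases (mean 30) is clipped, exercising the terminal-coverage QC;
* **"other" reads**: novel internal pseudoexons whose edges are ≥ 25 bp
  from every registry site, so that even maximal jitter (8 bp) cannot
  bring them within the snap window — they are guaranteed to classify as
  `"other"`.

Everything is deterministic under a fixed seed. What the simulator does
*not* model: realistic nanopore error profiles (no basecaller or signal
emulation), PCR chimeras and amplification bias, reverse-transcription
artefacts, or alignment ambiguity (reads are emitted pre-aligned with
self-consistent CIGARs, and separately as FASTQ). Passing tests therefore
demonstrate the correctness of the analysis given spliced alignments, not
the behaviour of any particular aligner on raw nanopore signal.

Short-read counts are generated binomially: included molecules
Binomial(depth, rate), each inclusion junction captured independently, the
remainder supporting the skip junction.

## Numerical and design choices

* Tie-breaks in correction are fully deterministic (see above); ties in
  distance are resolved by score, then upstream position.
* Abundances are stored at full precision; rounding (2 decimals for
  tables, 1 for inclusion estimates) happens only in reports.
* Degenerate inputs are values, not crashes: zero reads is an explicit
  error, an uncorrectable chain is a category, an undetected pseudoexon is
  a (0, 0) estimate with `detected = FALSE`, a primer pair spanning a
  segment a transcript lacks yields "no product".
* The backbone exon split (60 + 59 bp) is configurable; only the 119 bp
  spliced sum is geometrically constrained.
* Complex alleles are applied jointly (both substitutions before any
  scanning), treating the allele as a single unit; motif deltas are
  confined to windows overlapping variant bases and are reported, never
  interpreted as pathogenicity calls.

The verification suite runs the full pipeline on 10,000 simulated reads at
the variant-minigene proportions (plus smaller property-test scenarios);
the acceptance script averages ten such replicates. At these sizes the
recovered T1 abundance is within three binomial standard errors
(±1.5 percentage points) of the generating proportion.

## Known limitations

* Classification requires exact chain equality; partial/fuzzy matching
  (e.g. intron retention subsets) lands in `"other"`.
* Statistical testing between conditions is out of scope — the assay's
  published outputs are descriptive percentages, and so are ours.
* Proprietary splice predictors and published motif resources are not
  reproduced or redistributed; the packaged matrices and hexamer sets are
  generic/synthetic, with loaders accepting the published formats.
* Each alignment file is treated as one sample; deduplication and
  replicate merging are upstream concerns.
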