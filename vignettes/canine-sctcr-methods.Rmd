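---
title: "Models and methods: canine single-cell TCR repertoire analysis"
author: "scTCRdog authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: canine single-cell TCR repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTCRdog)
```

# Scope and data model

`scTCRdog` models the analysis stages of a canine 10x-style single-cell
TCR sequencing experiment, from an annotated TRA/TRB segment reference
through contig annotation, clonotype analytics, pseudogene-rescue
sequence analysis and expanded-vs-non-expanded marker testing. Upstream
wet-lab and assembly steps (cell preparation, PCR, sequencing, de novo
contig assembly, UMI collapsing, expression quantification, cell typing)
are out of scope; their outputs are this package's inputs.

Conventions used throughout: coordinates are 0-based and half-open; all
sequences are stored 5'→3' in transcript (mRNA) orientation, so the
genomic negative-strand placement of the canine TRB locus is purely a
loader concern; V sequences are in-frame V-REGION coding sequence
without leader; J sequences are J-REGION coding sequence with a declared
reading frame (an optional FASTA header field, default 0).

# The segment reference

A `TCRReferenceSet` holds V, D, J and C gene segments with the IMGT
functional taxonomy: *functional* (open reading frame, intact signals),
*ORF* (open reading frame but defective splicing/recombination/
regulatory signals or non-conserved motifs), and *pseudogene* (stop
codons and/or frameshifts in the coding region). Recorded defects carry
a kind (`in_frame_stop`, `frameshift`, `noncanonical_RSS`,
`nonconserved_motif`), a region label and a 0-based position.

**CDR3 anchors.** The CDR3 is delimited by the conserved V cysteine and
the J-region `[FW]GXG` motif. Because IMGT unique numbering is not
carried by plain sequence input, anchors are discovered by deterministic
surrogate rules: the V anchor is the 3'-most codon-aligned `TGT`/`TGC`
within the final 15 codons; the J anchor is the *last* `[FW]GXG`
occurrence in the declared-frame translation. Segments lacking a motif
are flagged `nonconserved_motif` rather than rejected, mirroring the
observation that some expressed ORF segments carry non-conserved
`FGXG` sequences. Scanning only the declared J frame is deliberate: a
chance cross-frame motif downstream of the true one would silently
corrupt the anchor if all frames were searched.

**Template construct.** `buildTemplate()` reproduces the in-silico cDNA
used for enrichment primer design: 5'→3', the Illumina R1 adapter, a
16×N cell-barcode placeholder, a 10×N UMI placeholder, a 13-nt template
switch oligo, then the complete V, (D,) J and C segments, with component
offsets recorded so primer windows can target the C region.

**The bundled synthetic reference.** No database fetch is in scope, so
`syntheticReference()` generates a deterministic, fully synthetic
reference: per chain, 8 functional V (100 codons, Cys four codons from
the 3' end), 6 functional J (20 codons, motif at codon 6), one C (no
stop codon in any frame), plus one D for TRB — and three defective
segments that reproduce, at the geometry level, the three canine
pseudogene-rescue situations reported in dogs:

* `TRBV19*01` — in-frame `TAG` (codon 104) two codons 5' of the Cys; a
  single germline T→C converts it to `CAG` (Q). The stop is too far
  from the segment end for trimming to remove it without destroying the
  anchor, so only carrier donors can use the segment productively.
* `TRAV9-2*01` — in-frame `TGA` at codon 45 plus a 1-nt frameshift at
  codon 57; the donor consensus differs by 8 SNVs and one C insertion
  that restore an open reading frame.
* `TRBJ1-3*01` — `TAG` in codon 2, removable by junctional trimming
  (≥ 6 nt off the J 5' end) while the `[FW]GXG` anchor at codon 6
  survives.

The corrective edit sets ship with the reference
(`syntheticRescueEdits()`).

# The repertoire generator

`simulateRepertoire()` is clone-first. A clonality profile fixes clone
masses:

* *polyclonal* (healthy): `n_cells` equal-mass clones, so most realized
  clones are singletons;
* *oligoclonal* (melanoma-like): expanded clones at fractions
  (0.10, 0.05, 0.03) — the default mirrors a top clonotype around 9 % of
  cells — over a polyclonal background;
* *monoclonal* (T-cell-lymphoma-like): one dominant clone at 0.88 of
  cells over a 400-clone background, matching a dominant clonotype of
  88 % and a few hundred residual clonotypes.

Each clone receives one TRA and one TRB rearrangement: V and J (and a D
for TRB) drawn by usage weights (uniform over functional segments by
default), per-end trimming from a truncated geometric distribution
(p = 0.25, max 8 nt; D ends max 4 nt), and nontemplated insertions with
truncated-geometric length (p = 0.25, max 12 nt) and uniform ACGT
composition. No generative model of canine junctional editing has been
published, so these defaults are declared assumptions chosen once to
span the observed CDR3 length range (about 5–24 aa); they are surfaced
in `simulationConfig()` and never adjusted per analysis.

**Productivity bookkeeping.** Truth fields are computed by definitional
arithmetic, independent of the annotator: the junction is in frame iff
the J-anchor offset in the contig is a multiple of 3 (the V is in frame
0 by construction); the transcript must translate without stop codons
from the V start through the end of the J (the codon straddling the J/C
boundary is completed with C-region bases — annotator and generator
share this boundary rule so their agreement is exact); and both anchors
must survive trimming. By default clone rearrangements are redrawn until
productive (a repertoire of reportable clonotypes); `productive_only =
FALSE` emits unselected rearrangements for annotator stress-testing.
Rejection sampling is also what makes defective segments behave
realistically: a junctionally rescuable J simply succeeds only in draws
that trim past its stop, and a stop deep inside a V succeeds only in
donors whose germline corrects it.

**Pairing noise.** Each cell starts with one TRA and one TRB; an i.i.d.
category per cell then drops or duplicates chains: `single_pair`,
`tra_only`, `trb_only`, `extra_tra`, `extra_trb`, `extra_both`. The v2
preset (0.698, 0.025, 0.157, 0.066, 0.033, 0.021) and v1 preset (0.309,
0.202, 0.409, 0.023, 0.054, 0.003) match the published per-clonotype
pairing statistics for the two 10x 5' kit generations; the v1 extra-both
value is the residual needed to close the distribution, which the source
tables do not print. Extra chains get independently re-drawn junctions,
so cells of one clone with extras split into distinct clonotypes — as
dual-TCR cells do in real data.

**Other knobs.** Per-chain UMI counts are shifted Poisson
(1 + Pois(λ), λ = 6.6/12.5 for TRA/TRB, matching median UMIs per cell
near 7.6 and 13.5) and are bookkeeping only. Barcodes are sequential
distinct 16-mers, not a 10x whitelist — barcode correction is out of
scope. An optional per-base substitution `error_rate` perturbs emitted
contig sequences while truth fields stay error-free, for
robustness-degradation tests; with nonzero error the reassembly
invariant intentionally no longer holds.

# Contig annotation

`annotateContigs()` assigns segments by local (Smith–Waterman)
alignment with match +2, mismatch −2, gap open −4, gap extend −1 and a
score floor of 40 — values chosen once to separate segments at realistic
within-locus divergence. For speed, candidates are prescreened by
shared 12-mer counts (`vcountPDict`), keeping every candidate within two
shared k-mers of the best so that genuine ties are preserved; only the
top candidates are aligned, and traceback is computed for the winner
(plus exact score ties, which are resolved by higher identity, then
lexicographically smaller key, and flagged). Chain is inferred from the
best V hit; J candidates come from that chain; D segments are not
assigned (their short, heavily edited remnants do not support reliable
calls).

The CDR3 spans the mapped Cys codon through the mapped `[FW]` codon,
both inclusive (so reported CDR3s read `C...F/W`). A contig is
productive iff a CDR3 is present, its length is a multiple of 3, the
translation from the V origin through the end of the J region is
stop-free, and the anchors are canonical; failures carry
machine-readable reasons (`out_of_frame`, `stop_codon`,
`anchor_unmapped`, ...). Contigs shorter than 100 nt are flagged
`too_short` rather than annotated.

On error-free simulated repertoires the annotator reproduces the truth
table exactly (v/j calls, CDR3 nucleotide sequence, productivity) — this
oracle equivalence is an acceptance-tested contract, and agreement
degrades monotonically as substitution error is added.

# Clonotypes, pairing and diversity

A clonotype is the exact sorted multiset of productive (chain, CDR3
nucleotide) sequences carried by a cell — one or more TRA and/or TRB
chains expressed in one or more cells; nucleotide-level identity is
deliberate, so silent variants are distinct clonotypes. Cells with no
productive chain are excluded and counted. Pairing categories derive
from the clonotype's chain counts, with anything beyond two of either
chain reported as `gt2_chains` (duplicate-suggestive).

Diversity is the Inverse Simpson index `1 / Σ p_i²` of clonotype
frequencies. It is computed over all clonotyped cells by default; since
the corresponding summary metric is conventionally named *paired*
clonotype diversity and the convention's treatment of unpaired
clonotypes is not documented, `clonotypeDiversity(pairedOnly = TRUE)`
provides the restricted mode.

Rank-bin distributions use bins {1}, {2–5}, {6–10}, {11–100},
{101–1000}, {>1000}; only the first two are fixed by the source figure
convention, the rest are a declared choice. Ranking ties break by
clonotype key.

**Permutation downsampling.** To compare samples of unequal depth,
`downsampleDiversity()` draws `nTarget` cells (default 1,850, the
smallest clonotyped sample in the motivating study) with replacement,
100 times by default. Per-clonotype cell proportions are averaged
across permutations and then ranked and binned, so a clonotype keeps
its identity across permutations; the averaged proportions are unbiased
estimates of the full-sample proportions, which is what makes the
downsampled rank-bin profile concordant with the full-sample profile
(within 0.02 absolute in the acceptance check). Re-ranking within each
permutation instead systematically redistributes the long singleton
tail across rank bins and is not concordant for any clonality profile;
that reading was measured and rejected. The Inverse Simpson index is
averaged over per-permutation values, since it is a per-sample depth-
dependent quantity.

# Pseudogene rescue analysis

For a defective segment, clonotype consensus sequences (one per
distinct junction, per donor) are globally aligned over the segment
span (`global-local`, same scoring as the annotator; alignments under
60 % identity are `not_covered`). Differences are emitted as SNVs,
insertions and deletions on segment coordinates, with indels
left-normalised so the same variant yields the same record in every
clonotype. The junction window — V 3'-terminal 12 nt / J 5'-terminal
12 nt, configurable — approximates "closely flanking the joining
boundary"; no published width exists.

A difference is *donor-shared* (germline) when present in at least 90 %
of a donor's clonotypes using the segment (≥ 2 clonotypes required) and
outside the junction window; the 90 % threshold tolerates rare
sequencing/assembly noise and is a declared surrogate for how
donor-reference inference behaves in practice, not a reconstruction of
any particular tool.

Per defect: an in-frame stop is *corrected* in a clonotype when its
codon is altered to a non-stop or removed entirely (junctional
trimming); a frameshift is corrected when the non-junctional part of
the observed segment translates stop-free (the frame having been
restored by an indel). A defect's status is `corrected` when the
majority (> 50 %) of examined clonotypes show the correction — majority
rather than unanimity because alignment jitter at trimmed junctions can
occasionally mis-localise a boundary — and `retained`/`not_covered`
otherwise. The mechanism is `germline_shared` when every corrected
clonotype's correcting differences are donor-shared; `junctional` when
they sit in the junction window and vary across clonotypes; otherwise
`unresolved`.

`proposeReannotation()` encodes a declared policy inspired by the
frequency-of-expression argument: recommend re-annotation as functional
when all defects are corrected in ≥ 2 donors and the segment appears in
≥ 100 productive cells or ≥ 50 unique clonotypes; a donor-specific note
when corrected in exactly one donor (more dogs would be required);
otherwise no change.

# Expansion phenotype

Cells are *expanded* when their clonotype exceeds 1 % of all cells
(strict inequality; a clonotype at exactly 1 % is not expanded), with
proportions computed over all cells. `testMarkers()` runs a two-sided
Wilcoxon rank-sum test per marker on log-normalized expression values
and Bonferroni-corrects over the number of markers actually tested in
the run — 16 for the default activation {CD38, GZMA, GZMK, MKI67} +
exhaustion {CTLA4, HAVCR2, NFATC1, NR4A1, NR4A2, NR4A3, PDCD1, PRDM1,
TCF7, TIGIT, TOX, TOX2} panels — rather than over the cross-panel
union. Direction is reported only at adjusted p < 0.05. Whether such
tests should run on normalized or additionally scaled values is not
standardised; the package tests normalized (unscaled) values and leaves
scaling to display code. The bundled expression simulator is Gaussian
around a baseline with plantable location shifts — sufficient for
calibration (family-wise error ≤ 0.05 under label permutation) and
power (a 1-log shift at 500 cells per group is detected), but it does
not emulate single-cell dropout or count overdispersion, so passing
tests certify the testing machinery, not distributional realism.

# What the simulator does and does not emulate

The generator reproduces: segment choice with usage weights, junctional
trimming and insertion, donor germline variation including corrective
variants, clonal-expansion profiles, chain dropout/duplication at
published v1/v2 rates, and UMI-count bookkeeping. It does not emulate:
read-level errors and FASTQ structure, UMI collapsing, barcode
whitelists, assembly chimeras, 5' UTR or C-region carry-through
(observed contigs are V..C only, so real contigs are longer than
simulated ones), doublets, or expression-based cell typing. Passing
recovery tests therefore demonstrates the correctness of the analytic
layer under its stated model, not robustness to every artefact of real
10x data.

# Numerical and size choices

Alignment scoring and the score floor are fixed package constants (see
above). Tolerances: pairing probabilities must sum to 1 within 1e-9;
proportion vectors likewise; normalisation identities in tests are
checked at 1e-12. Tie-breaks are deterministic everywhere (lexicographic
keys). Degenerate inputs: empty contig sets annotate to empty tables;
empty clonotype sets are an error for summaries that divide by totals;
`n_cells = 1` yields one cell and one clone.

Test problem sizes were chosen to exercise the asymptotics the claims
need while keeping the default suite quick: oracle equivalence at 2,000
cells, pairing recovery at 10,000 cells, clonality ordering at 100 runs
of 5,000 cells per profile, downsampling at 6,000 cells, rescue
recovery at 20 seeds of 300–600 cells across 2–3 donors, and marker
calibration over 200 permutation nulls at 100 cells per group.

# Known limitations

* The annotator cannot anchor a CDR3 through a frameshifted universal
  V reference (the TRAV9-2-like case): as with real pipelines, that
  requires donor-reference inference, which lives in the rescue module
  rather than the annotator.
* Clonotype merging across samples and germline-aware cross-donor
  repertoire comparison are out of scope.
* Recombination-signal-sequence defects cannot be assessed from
  transcript data at all — the signals are excised during
  recombination; genomic DNA would be required.
* The synthetic reference carries one allele per segment; multi-allele
  references are accepted by the loader but not exercised by the
  bundled generator defaults.
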