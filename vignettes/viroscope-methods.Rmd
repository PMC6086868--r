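---
title: "How viroscope reconstructs and classifies viral genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How viroscope reconstructs and classifies viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscope)
library(dplyr)
```

viroscope recovers viral genomes from metagenomic reads and assigns them
taxonomy. Its central difficulty is the one every viral metagenomics tool
faces: viruses in real samples are often at low coverage and far from their
nearest database relative, while the sample is dominated by host and
bacterial background. The package answers this with two linked ideas: a
*mapping* reconstruction that pools nucleotide **and** protein alignment
evidence into per-genome super-scaffolds (protein sequence is conserved far
beyond nucleotide sequence, so translated hits rescue diverged genomes), and
a *two-pass bits-per-base classifier* that scores whole contigs against a
comprehensive taxonomy-labelled database instead of trusting any single
best hit.

This vignette explains the model, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the procedure was genuinely open.

## Stage 1 — read recruitment

Reads are first dereplicated (`dereplicate()`), exact duplicates collapsing
to one representative with a multiplicity that is re-expanded during
abundance accounting. An optional median k-mer digital normalizer
(`normalize_reads()`, off by default) can thin over-covered piles: a read is
discarded when the median running-sketch count of its 21-mers already
exceeds the target depth (40). Both steps only reduce data volume; nothing
downstream requires them.

Alignments of reads against the viral database — nucleotide records against
genomes, translated records against proteins, both carried in a tabular
9-column dialect (`read_alignments()`) with subject taxids inline — are
thinned by a **score-radius rule** (`filter_alignments()`): a record is
reported iff its bit score is within a margin *d* of the best score among
records sharing its subject **and** within a margin of the best sharing its
query,

$$\mathrm{bits}(r) \ge (1-d_\mathrm{subject})\cdot \max_{\text{same subject}} \quad\wedge\quad \mathrm{bits}(r) \ge (1-d_\mathrm{query})\cdot \max_{\text{same query}}.$$

Defaults are $d_\mathrm{subject}=0.20$, $d_\mathrm{query}=0.08$ for
translated records and $0.90$, $0.05$ for nucleotide records: per query the
nucleotide rule is strict (within 5% of the best), per subject it is
permissive. The four margins are deliberately configuration
(`recruit_params()`) because the binding constraint differs between
amplicon-like and shotgun data.

Each read then joins the read set of every genome any surviving record
points to (`assign_reads()`; protein subjects resolve to their genome
through the CDS table). Because near-identical database genomes recruit
near-identical read sets, sets are de-duplicated greedily by **Jaccard
distance** (`jaccard_filter()`): visiting sets largest-first, a set is
dropped when its distance $1-|A\cap B|/|A\cup B|$ to an already-retained
set is at most `jaccard_tau` (default 0.05, i.e. ≥95% similar). The
largest set is never dropped and ties break lexicographically, making the
stage deterministic.

## Stage 2 — super-scaffold construction

Every retained genome entry is rebuilt by **naive pileup assembly**
(`pileup_assemble()`): reads are laid at their aligned subject coordinates
and each position takes the strict-plurality base. Two mask states are kept
distinct on purpose: `N` marks a position with *conflicting* evidence (tie
among top bases), `-` marks *no* evidence. Downstream length and coverage
accounting ignores gaps but keeps masks, because a mask still asserts that
the position exists. A deletion call (`-` inside a placed read) wins only
when it strictly outnumbers every base — conservative behaviour at deletion
edges. Insertions relative to the reference frame are dropped; the de novo
arm (external contigs passed to `run_pipeline()`) is the intended answer to
genuinely novel insertions.

Protein entries are piled up the same way in amino-acid space, and each
confidently reconstructed amino acid flags its three genome positions —
located through the annotated CDS coordinates, strand respected — as
aa-supported (`back_translate_tile()`). Back-translation is degenerate, so
the protein layer never *invents* nucleotides: base calls enter the aa
evidence layer only where the aa-supporting reads themselves provide
nucleotide-level calls, decoded codon-wise through the CDS. This is a
documented interpretation: the alternative (synthesizing codons from amino
acids) would corrupt nucleotide-space classification downstream.

`build_superscaffold()` then layers everything: the nucleotide call wins
wherever present (including its masks), aa layers fill nucleotide gaps,
disagreements *between* aa layers are masked `N`, and positions with no
evidence stay `-`. Maximal gap-free runs of at least `min_contig_len`
(default 100 bp) become contigs (`split_on_gaps()`).

## Stage 3 — iterative improvement

`improve()` cycles merge → map → pile up → reassemble until the contig set
reaches a fixed point (identical sequence multiset) or `max_rounds`
(default 10) is hit. Overlap detection (`find_overlaps()`) is k-mer
anchored (k = 31) ungapped dovetail matching; an overlap is accepted at
≥100 bp and ≥98% identity, merging is greedy largest-overlap-first with
deterministic tie-breaks, and disagreeing positions inside a merged overlap
are masked `N`. The merge engine assumes a **linear genome**: a contig
whose own ends overlap (the signature of a circular genome) is detected and
reported but never self-joined.

Two deliberate choices here:

* **Reassembly is a polish, not a rebuild.** After reads are mapped back
  (internal exact-seed ungapped mapper, `map_reads()`; an external SAM can
  be supplied instead), the pileup consensus replaces each contig, but a
  position no read covers keeps its previous call. Pure pileup semantics
  would erode contig spans whenever a subsampled read set leaves them
  uncovered, and the fixed point that defines convergence would not exist.
* **Canonical ordering each round** (length-descending, then sequence)
  plus deterministic merge tie-breaks make the final set independent of
  input contig order — a property the tests assert directly.

After convergence, `abundance()` maps the dereplicated reads once more,
assigns each read to its best-scoring contig (ties: longer contig, then
lexicographically smaller id) and re-expands multiplicities.

## Stage 4 — two-pass classification

All alignments of a finished contig against the *comprehensive* database
(viral and non-viral, nucleotide and translated; translated query
coordinates are expressed in nucleotide space so the two kinds overlay) are
reduced to per-base scores $s = \mathrm{bits}/\mathrm{aligned\ length}$.

**Pass 1** (`pass1()`) records, per position and per subject taxon, the
maximum $s$ achieved, and per taxon the sum of those per-position tops —
the taxon's best potential alignment, independent of how fragmented its
database entries are. The per-position maximum over all taxa is the
*global top*.

**Pass 2** (`pass2()`) weighs every record against the global top: at each
covered position the record contributes $s \cdot w(s/g_p)$, where $g_p$ is
the global top there and the damping is

$$w_\mathrm{nt}(r) = r^{p}, \qquad w_\mathrm{aa}(r) = r^{p^p}, \qquad p = 3.$$

Summed over positions and over *all* entries of a taxon this yields the
taxon's **volume** — an aggregate relative accuracy of everything the
database knows about the taxon. A lone mislabelled entry that happens to
edge out the true taxon in pass 1 contributes little volume, because its
taxonomic neighbours do not corroborate it. The functional family of the
weights is an artifact decision (the qualitative requirements are:
$w(1)=1$, monotone increasing, and the translated weight far harsher than
the nucleotide one, since a mismatch in conserved protein sequence is much
stronger evidence against a taxon); the exponent is exposed in
`classifier_params()`. The contribution is $s\cdot w(s/g)$ rather than
$g\cdot w(s/g)$ so that a taxon holding the global top everywhere has
volume exactly equal to its pass-1 score — an exact fixed point the tests
pin down.

Contigs are gated before any taxonomy is assigned:

* **Viral filter** (`viral_filter()`): the top pass-1 taxon must lie in the
  viral superkingdom, and at most 50% of the aligned positions may have
  their global top achieved *only* by non-viral taxa. Position ties count
  as viral, and an exact tie for the top taxon resolves in favour of the
  viral candidate (the same tie convention, extended to the argmax).
* **Information filter**: contigs whose best pass-1 score is below
  `min_contig_bits` (300 bits) are set aside as low-information — short or
  weak alignments are the dominant source of false positives.

Candidates for the LCA are all taxa within a **dynamic radius** of the best
pass-1 score (`candidate_set()`): with quality
$q = \mathrm{pass1\ best} / (L \cdot b_\mathrm{max})$ relative to a
hypothetical perfect self-alignment ($b_\mathrm{max} = 2$ bits/base for
nucleotide), the radius interpolates linearly from `radius_min` (0.02) at
$q=1$ to `radius_max` (0.25) at $q=0$ — a near-perfect hit keeps the
candidate set essentially exclusive, a weak distant hit lets many relatives
in. Only viral candidates proceed.

The **volume-weighted rank-wise LCA** (`lca_classify()`) walks the rank
ladder species → superkingdom ("no rank" clades are transparent). At each
rank, candidate volumes project onto their ancestors; the first projected
taxon holding more than the **dynamic majority**

$$m(V) = 0.5 + \frac{0.45}{1 + V/V_0}, \qquad V_0 = 2000 \text{ bits, capped at } 0.95$$

of the total candidate volume $V$ wins at that rank. The shape encodes the
stated qualitative behaviour — strictly decreasing in $V$, bounded in
$(0.5, 0.95]$: a taxon poorly represented in the database must command a
near-unanimous majority, a richly represented one needs only a slight one.
The hyperbolic form and $V_0$ are artifact decisions, config-exposed, and
the monotonicity/boundedness invariants are tested rather than assumed. If
no rank below the superkingdom produces a majority, the contig falls back
to the maximal-volume candidate (never the superkingdom node itself); all
ties break to the numerically smaller taxid.

Finally `aggregate_report()` groups classified contigs by taxon, sums
pass-1 bits and reads, suppresses taxa under `min_taxon_bits` (1000 bits of
aggregate alignment information), and lists filtered or unclassifiable
contigs of ≥500 bp in a separate section instead of dropping them silently
— they are exactly the contigs a user doing post hoc analysis wants to see.

## The synthetic world

`make_world()` builds a self-consistent test world from one seed: a mini
taxonomy (viral superkingdom containing families, genera, species and one
unranked intermediate clade; a bacterial host lineage), random viral
reference genomes with one plus- and one minus-strand CDS each, protein
translations, *sample* viruses diverged from their references by a
configurable substitution fraction, and substitution-error reads from
sample viruses plus host. The default configuration — four viruses of
2–3 kb at 5–15% divergence, 20× coverage, 150 b reads at 1% error, 30%
host reads — emulates a small purified mock community of RNA-virus-sized
genomes with realistic divergence from the nearest database entry.

The bundled aligner (`score_alignment()` / `align_all()`) is an
exhaustive-seed, ungapped local aligner (match +1 / mismatch −1 for
nucleotide with the scale fixed so a perfect alignment yields exactly 2.0
bits per base; BLOSUM62 with the standard gapless scale for six-frame
translated searches). Honesty of the bit scores — monotone in identity,
calibrated ceiling — matters more here than sensitivity.

What the generator does **not** emulate, and what passing tests therefore
do not show: insertions/deletions (reads and divergence are
substitution-only, so the pipeline's indel handling is exercised only
through the SAM/CIGAR path), quality-score error profiles, chimeric reads,
uneven library coverage, circular genomes, and databases whose entries are
mislabelled or share homologous segments across taxa. Real-data behaviour
on those axes must be established with real aligners (the pipeline accepts
their tabular output and SAM directly).

## Problem sizes and runtimes

The shipped tests and the acceptance script run entirely at desk scale,
chosen so the full suite completes in minutes on one core: scoring-oracle
equivalence on 1000 random instances (≤5 taxa, ≤20 records, contig length
≤50), a 4-virus world of ~2000 reads for the end-to-end benchmark, and ten
10%-subsampled replicates of that world for the robustness check. Genuine
metagenomes are orders of magnitude larger; at that scale the internal
aligner and mapper are replaced by external tools whose outputs enter
through the standard formats.

## Known limitations

* The merge engine never joins across a circularity (reported, not
  performed), so circular genomes remain linearized with redundant ends.
* The internal mapper and stand-in aligner are ungapped; indels inside
  reads survive only through externally supplied SAM placements.
* Jaccard filtering compares read sets per *genome*; with databases of
  many near-identical entries per genome the per-entry granularity might
  behave differently.
* The exact functional forms of the pass-2 weights, the dynamic radius and
  the dynamic majority are qualitative commitments, not fitted quantities;
  all are exposed in `classifier_params()` for sensitivity analysis.
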