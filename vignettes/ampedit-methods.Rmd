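---
title: "Methods: edit calling in a multi-copy gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edit calling in a multi-copy gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The analytical problem

Wheat α-gliadins form a tandem gene family whose members differ mainly in
the epitope content of one repetitive, proline/glutamine-rich region. A
paired-guide CRISPR design cuts on both sides of this region so that the
intervening fragment — for the complete 33-mer, 129 bp — is excised, and
optionally replaced by a short dsODN. Calling these edits from amplicon
sequencing requires (i) assigning each read to the right family member
among many near-identical references, (ii) calling indels that may be
larger than a third of the amplicon, (iii) placing indels consistently in
highly repetitive sequence, and (iv) weighting every statistic by amplicon
abundance. This vignette records the models, parameter choices and
numerical conventions behind each stage, and what the simulation-based
tests do and do not demonstrate.

## Amp construction and the family screen

Merged reads are dereplicated exactly; each unique sequence ("Amp")
carries its read count. Denoising is deliberately not modelled: its role —
dropping low-abundance error sequences — is approximated by the
`min_count` filter (default 2; the value is a pragmatic floor, not a
calibrated error model, and analyses that must count singletons, such as
the planted-truth recovery runs, set it to 1).

The off-target screen asks what fraction of an Amp's k-mers occur anywhere
in the reference panel and keeps the Amp when that fraction reaches
`min_shared_frac`. Defaults `k = 12`, `min_shared_frac = 0.5` were chosen
so that a family member carrying a full 129-bp excision (which removes
roughly a third of its k-mers, plus the k-mers broken at the junction)
passes comfortably, while unrelated sequences — sharing k-mers only by
chance, at a rate of about `L/4^12` per k-mer — essentially never do.
Both are configurable.

## Guide sites and cut windows

A primary site requires the PAM (IUPAC-matched; NGG 3′ for Cas9, TTTV 5′
for Cas12a) and the PAM-proximal 12-nt seed to match exactly; mismatches
over the remaining protospacer are counted but not limited, because a
guide designed on one family member is expected to sit on the others with
PAM-distal polymorphisms. Degenerate sites instead allow up to three
mismatches anywhere, seed included, and are flagged by `seed_perfect`.
Per-guide efficiency denominators use perfect-seed sites only; degenerate
sites contribute windows for event assignment (and hence to overall
editing) but never to a guide's designed-target denominator.

The cut model places the Cas9 blunt cut 3 nt 5′ of the PAM with one
nucleotide of uncertainty toward the PAM-distal side (there is evidence of
occasional 1-nt 5′ overhangs), and the Cas12a staggered cuts 18 nt
(non-target strand) and 23 nt (target strand) 3′ of the PAM, the window
spanning both. Windows are padded by `pad = 5` nt on either side: enough
to absorb placement ambiguity of small indels in repeats, small enough
that the two windows of a 129-bp guide pair stay well separated.

## Alignment

Both aligners are one affine-gap Gotoh kernel (gap of length L costs
`open + L * extend`) with a deterministic traceback — diagonal preferred
over deletion over insertion, gap runs extended greedily on score ties —
so identical inputs give identical single paths on every platform.

* **Local** (Smith–Waterman), scoring +2/−3, open 6, extend 1: the
  workhorse for reference choice; divergent ends are clipped.
* **Semi-global** with free end gaps, same scores but extend 0.1: end
  gaps on *both* sequences are free and reported as offsets, never as
  indel events. The near-free extension makes one long deletion cheaper
  than fragmentary mismatch runs, so inter-guide excisions survive as a
  single D operation. Free end gaps are symmetric (rather than
  query-only) because reference and read are both full amplicons and
  either may overhang after a large edit; symmetry also gives a clean
  independent cross-check against `Biostrings::pairwiseAlignment(type =
  "overlap")`.

Reference choice preselects the `top_c = 8` references sharing the most
k-mers with the Amp, takes the best local alignment (ties: higher score,
then higher baseline abundance, then lexicographically smaller id), and
escalates when more than `clip_frac = 0.15` of the read was clipped: the
semi-global alignment of the same candidates is adopted if its identity
(matches / read length) is higher. The threshold reflects the scoring
arithmetic: local alignment abandons an anchor shorter than about 75 nt
rather than pay for a ≥ 129-bp gap, and an anchor that long is well above
15% of any plausible amplicon. Reads equal (or equal-length and ≥ 98%
identical) to a reference bypass the DP entirely; this fast path is exact
for substitution-only reads and is what keeps error-bearing samples
tractable.

## Indel placement in repeats

A deletion or insertion inside a repeat has many placements that yield the
same edited sequence. Events are normalized within this equivalence
class: enumerate every placement (left-shift and right-shift while the
flanking base rule holds, rotating inserted strings), score each by its
total overlap with the cut windows, and keep the maximum, ties going to
the leftmost placement. Normalization is idempotent and never changes the
reconstructed haplotype; both properties are asserted against a
brute-force enumeration oracle. Events abutting another event on the same
Amp (as in a replacement, where the insertion sits exactly at the
deletion junction) are left in place, since shifting one member of a
complex through the other's span is not haplotype-preserving.

Free alignment has a second failure mode on replacements: scoring favours
fragmenting the inserted oligo against the excised span into several
small, spurious indels. Each Amp is therefore first compared against the
canonical edit haplotypes implied by its reference's cut sites — the
inter-cut excision, the excision with the dsODN (either orientation) at
the junction, and single-cut captures — and a near-exact match (Hamming
distance ≤ 2% over equal length) takes the canonical event representation
directly. This targeted realignment is the package's answer to the
repetitive-sequence refinement problem; the 2% tolerance admits
sequencing errors at realistic rates while remaining far below the
divergence between any two templates.

## Classification and statistics

An Amp is a **multi-guide excision** when ONE deletion contains at least
two distinct guides' expected cut positions (two adjacent single-guide
deletions do not qualify); a **dsODN target** when an insertion in a cut
window matches the dsODN at identity ≥ 0.9 over ≥ 0.8 of its length
(thresholds are choices, not literature values — junctions are often
imperfect); a **single-guide indel** when any event overlaps any cut
window; otherwise its events are **unassigned** and excluded from editing
percentages (they are most plausibly PCR or sequencing artifacts). Frame
status uses the net signed length of all events on the Amp modulo 3.

Editing, deletion and insertion percentages are abundance shares of Amps
carrying at least one assigned event (of the respective kind); an Amp
with both a deletion and an insertion counts once in editing and once in
each kind, so `max(del, ins) <= editing <= del + ins`. The indel spectrum
weights each assigned event by its Amp's count and sums to 100% before
the 0.5% display threshold, which is applied only at the formatting and
plotting layer. Per-type excision frequencies divide excised abundance
(span covering the type's annotated epitope interval, where the panel
provides one) by the type's total abundance. The editing denominator
includes family Amps whose reference carries no guide site; this matches
a family-wide definition of editing and is configurable only through the
panel itself.

Relative epitope loss for motif $e$ is
$100 \sum_r h_e(r)\, a_r\, d_e(r) / \sum_{r: h_e(r) \ge 1} a_r$, where
$h_e(r)$ counts overlapping occurrences in reference $r$'s translation,
$a_r$ is baseline abundance and $d_e(r)$ the abundance fraction of $r$'s
Amps whose re-scanned translation lost at least one occurrence.
Re-scanning translations (instead of coordinate bookkeeping) means
substitutions and frameshifts that break a motif also register. Because
$h_e$ multiplies the numerator while carriers are counted once in the
denominator, a motif present in multiple copies can lose more than 100%,
and the combined loss (sum over motifs, plus the separately tracked
p31-43 peptide when configured) routinely exceeds 100% — deliberately, as
a cumulative burden measure. The p31-43 motif defaults to off because no
canonical sequence is hard-coded; it is a configuration slot.

## The simulator

The generator builds archetypes Alpha0–Alpha7 whose epitope blocks carry
exactly N total DQ2.5 hits: Alpha7 is the canonical 33-mer plus the α3
motif (42 aa, 126 nt), Alpha6 the 33-mer alone, Alpha1–5 use N spaced α3
copies, Alpha0 an epitope-free spacer. Blocks are codon-randomized
back-translations, so DNA-level diversity exists without changing protein
content; boundary codons are pinned so that both guide sites are
perfect-seed on every archetype and the Alpha7 inter-cut distance is
exactly 129 bp. Flanks are shared except for per-reference synonymous
"wobble" in regions free of PAMs and seeds, emulating family
polymorphism and — importantly — keeping fully excised reads assignable
to their source reference. Baseline abundances are Dirichlet draws with
concentration decreasing from Alpha0 (8) to Alpha7 (1), giving the
qualitative skew of real panels (the common types dominate; the
complete-33-mer type is rare). Amplicons run 267–393 nt, so even the
largest planted deletions leave alignable anchors.

Planted edits: per-guide indels at the cuts with lengths from a
distribution peaked at −36 bp over −141..+49 (85% deletions, exponential
decay scales 15/6 — chosen to resemble observed spectra, not fitted);
cut-to-cut excisions per type; dsODN capture in either orientation,
single-cut or replacement; substitution errors last. The truth table
records each read's events *after* the same left-align/window
normalization the caller uses (placement in a repeat is a convention, and
truth must speak the caller's convention to be comparable), and the
category its coordinates imply — including the case where a planted
"single-guide" deletion is long enough to span both cuts and therefore
*is* an excision. Planted events keep a 15-nt separation: closer pairs in
this repeat-rich sequence admit several equal-cost decompositions, which
would make the planted representation, and hence exact recovery,
ill-defined.

What passing the planted-truth suite shows: the calling chain is exact on
substitution-free data and stable under 0.2% substitution error, at the
study's read depth (10,000 reads; chosen to keep a full run in tens of
seconds). What it does not show: robustness to chimeric PCR products,
quality-correlated errors, homopolymer artifacts, or reference panels
with members absent from the database — none of which the generator
emulates.

## Degenerate inputs and edge rules

Empty read sets dereplicate to an empty Amp set (not an error); Amps
shorter than k are discarded with a warning; Amps sharing no k-mer with
any reference are excluded from all denominators and logged. A sample
with zero family abundance reports `NA` throughout. Insertions at a
window's half-open end (`pos == window_end`) are outside it; deletions
touching a cut only at their boundary (`start <= cut <= end`) count as
covering it, so a cut-to-cut excision covers both of its cuts.

## Known limitations

* Large insertions (longer than the dsODN) and inversions are outside the
  event model.
* The dsODN end-chemistry annotation (blunt/overhang) does not influence
  detection; orientation biases must be read from the calls themselves.
* Per-guide efficiencies attribute an event to every guide whose window
  it overlaps; a deletion bridging both windows credits both guides.
* The epitope-loss formula weights a reference's loss by its full hit
  count as soon as one occurrence is lost; partial per-copy accounting
  would need coordinate-level tracking that re-scanning avoids.
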