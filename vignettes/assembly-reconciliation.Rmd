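---
title: "Consensus reconciliation of genome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus reconciliation of genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmrec)
```

## The problem

Hi-C scaffolding turns long-read contigs into chromosome-scale scaffolds by
joining contigs across N-gaps, but the joining step occasionally places
sequence from different chromosomal loci on one scaffold (a *misjoin*), or
flips a fragment. Because different assemblers fragment a genome differently,
a region that is broken in one assembly is often contiguous in another:
independent *alternate assemblies* of the same reads therefore carry exactly
the evidence needed to audit a scaffolded *base assembly*. `asmrec`
implements that audit and the repairs it licenses:

1. **Misjoin detection.** Each alternate assembly is aligned to the base.
   Wherever an alternate contig's alignment breaks against the base —
   the same contig continuing somewhere else, re-ordered, or strand-flipped
   — a candidate breakpoint is recorded. A two-part check makes a candidate
   *actionable*: (A) a gap tract lies near the junction (scaffolding joins
   happen at gaps, so a scaffolding error should sit at one), and (B) at
   least two alternates are discrepant with the base *and* mutually
   consistent, i.e. their local contig arrangements agree after mapping
   through base coordinates.
2. **Block replacement.** Rather than re-ordering scaffolds, the offending
   base region — from the last shared anchor upstream to the first shared
   anchor downstream of the junction cluster — is replaced by the
   corresponding interval of one agreeing alternate (chosen by seeded RNG
   among the agreeing set; the draw is recorded), reverse-complemented for
   minus-strand donors. The result is a *hybrid assembly*.
3. **Gap filling.** A gap whose flanks align, with at least `flank` bp of
   support on both sides, inside a single gap-free block of some alternate
   is replaced (innermost flanking anchor to innermost flanking anchor) by
   the donor interval; the donor is again a seeded random choice among the
   eligible alternates.
4. **Scaffold merging.** Two long scaffolds are merged into one
   pseudo-chromosome when at least two alternates each bridge their termini
   with a single collinear contig; orientations come from block strands and
   the halves are joined by a run of N.
5. **Validation.** Large-insert (BAC-end style) read pairs are classified as
   concordant (both ends mapped, same scaffold, inward-facing FR, insert
   within bounds), discordant, single-end or unaligned; comparing counts
   before and after reconciliation gives a directional quality signal —
   corrections should convert junction-straddling discordant pairs into
   concordant ones and never the reverse.

## Alignment model

The package carries its own aligner so the consensus logic is testable
without external binaries, and ingests PAF for production-scale use.
Anchors are exact matches of canonical minimizers (`k = 15`, window
`w = 10`, repetitive k-mers with more than `max_occ = 50` hits dropped).
Anchors sharing a (base scaffold, alternate contig, strand) triple are
chained by sparse dynamic programming: both coordinates must strictly
advance, each axis may jump at most `gap_limit = 10` kb, and each link must
stay within `diag_limit = 2` kb of the diagonal. The diagonal bound is what
lets a chain bridge plain N-gaps and repeat deserts (where base and
alternate advance together) while refusing to bridge inversions or
misjoins — there the two axes disagree, and without the bound a single
coincidental k-mer hit inside a rearranged segment can stitch two flanks
into one spurious chain. A second guard handles the rarer stray hit that
happens to fall on-diagonal: a chain-end segment separated from the chain
body by more than `stray_gap = 2.5` kb per axis must itself carry at least
`min_end_score = 100` matched bases, or it is trimmed — shared 15-mers
between unrelated megabase-scale sequences are expected by the birthday
bound, but a genuine continuation always brings dense anchors with it.
Chain score is the number of matched bases
(`min(k, dx, dy)` per link) minus a small off-diagonal drift cost
(`diag_penalty = 0.01` per bp of `|dx - dy|`): inside a tandem repeat an
exact k-mer matches every copy, and the drift cost makes the chain prefer
the copy on the flanks' diagonal, so edit boundaries never contract or
expand a repeat. Chains scoring under `min_block_len = 500`
are dropped, and blocks overlapping on the base are resolved
highest-score-first by trimming the weaker block to its anchors outside the
overlap. There is no base-level alignment: the reconciliation unit is the
block, and every edit boundary snaps to an exact-match anchor, so spliced
sequence is never chimeric at the cut points. PAF-derived blocks carry no
anchors; edits then snap to block edges, trading boundary exactness for
aligner freedom.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `k`, `window` | 15, 10 | anchor length / minimizer sampling density |
| `gap_limit` | 10 kb | max per-axis chain jump (bridges gaps, repeats) |
| `diag_limit` | 2 kb | max off-diagonal drift per link (blocks rearrangement bridging) |
| `stray_gap`, `min_end_score` | 2.5 kb, 100 bp | minimum support for a chain end beyond a large anchor gap |
| `min_block_len` | 500 bp | minimum matched bases per alignment block |
| `gap_window` | 20 kb | check A: max gap-to-junction distance |
| `merge_window` | 20 kb | candidate clustering and agreement distance |
| `min_agree` | 2 | check B: discrepant-and-agreeing alternates required |
| `flank` | 5 kb | aligned support required on each side of a filled gap |
| `min_merge_len` | 10 Mb | scaffolds considered for merging |
| `min_merge_evidence` | 2 | alternates that must bridge a merge |
| `join_gap_len` | 100 | N inserted between merged scaffolds |

`gap_window` absorbs alignment-boundary slack around a junction; it is
deliberately generous because the base coordinates of a break are only known
to within the anchor sampling density. `min_agree = 2` is the consensus
floor: one discrepant alternate could itself be misassembled; two
independent assemblies agreeing against the base is strong evidence because
their fragmentations are (approximately) independent.

## What the simulator emulates

Synthetic scenarios make every claim checkable against a known truth:

* a truth genome of i.i.d. bases at 41% GC (primate-like) with ~5% exact
  tandem repeats (unit 20 bp, tracts 0.5–2 kb) to exercise the repetitive
  k-mer filter;
* a base assembly built by cutting each chromosome into fragments and
  rejoining them with junction gaps. Each gap *deletes* 100–900 bp of truth
  (mean ~500 bp, the scale of real scaffold gaps) and inserts that many N —
  mimicking a scaffolder's estimate of missing sequence;
* misjoins as misplaced interior fragments: `n_misjoins` dedicated 10–20 kb
  fragments are excised and their contents rotated across chromosomes, so
  each sits at a locus belonging to other truth sequence, flanked by gaps
  (the premise of check A). One misplaced fragment cannot exist alone while
  conserving content, so `n_misjoins` is 0 or at least 2. Inversions
  strand-flip dedicated fragments in place;
* alternates as independent random fragmentations of the truth into
  gap-free contigs — capturing exactly the property the method exploits
  (different contiguity, shared sequence) without simulating assemblers;
* BAC-end pairs drawn from the truth with Normal(150 kb, 20 kb) inserts and
  500 bp inward-facing FR ends, projected onto any assembly exactly through
  recorded liftover segments rather than by alignment.

The reference conditions (`standard_scenario_config()`) are 3 chromosomes
of 1 Mb, 8 regular fragments each (~31 junction gaps in total), 5 misjoins,
and 3 alternates of 3 contigs per chromosome. Sizes were chosen so that a
full audit-and-repair runs in tens of seconds on one CPU while leaving every
structural signal (misjoin slots, flanks, BAC straddles) orders of magnitude
larger than the anchor sampling noise.

What passing on this simulator does **not** show: robustness to per-base
divergence between assemblies (alternates are exact truth slices by default;
`alt_error_rate` exists to stress that), to segmental duplications larger
than the repeat model, or to misassembled alternates (alternates are clean
by construction, matching the assumption behind the consensus rule). Real
assemblies also need a production aligner — the PAF path — above a few tens
of Mb.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; AGP output is
  1-based inclusive per the standard. Lowercase input is uppercased (the
  method is mask-agnostic); `U` becomes `T`; non-N ambiguity codes are kept
  and flagged.
* NX uses the ceiling convention (the sequence reaching the X% boundary is
  included), matching common N50 calculators; gap tracts are counted at
  every length by default (`min_gap_len = 1`) with an NCBI-style minimum
  available by flag.
* "Mutually consistent" discrepant alternates are those whose continuation
  loci — where each broken contig's remainder lands on the base — agree in
  place within `merge_window`. This operationalises what a dot-plot
  inspection evaluates (local order and orientation agreement).
* Replacement boundaries cut at shared anchors, not at block edges, to keep
  the hybrid sequence locally identical to both base and donor at the seam.
  If no agreeing donor re-anchors downstream within `max_span`, the call is
  skipped with a warning rather than truncating the scaffold: a conservative
  failure mode that leaves the misjoin in place but never destroys sequence.
* Edits within one stage are applied right-to-left per scaffold so pre-edit
  coordinates remain valid; replacements run before gap fills and consume
  the gaps they span; overlapping actionable calls are processed
  largest-evidence-first, ties leftmost, later overlapping calls skipped.
* All randomness (donor draws) flows from one seed; each draw is recorded in
  its EditRecord, so a run is reproducible from its manifest.
* Degenerate inputs: all-N scaffolds split to nothing (warning); empty
  anchor sets yield empty block lists; a reconciliation with alternates
  identical to the base is a byte-exact no-op.

## Known limitations

* Replacement requires a single donor contig anchored on both flanks; a
  misjoin whose repair would need stitching two donors is detected but not
  repaired (counted and logged).
* Exact liftover projection declares a read end unmapped when it spans a
  segment seam, so a handful of pairs near edit boundaries classify as
  single-end rather than concordant; an aligner-based validation would
  recover them.
* The merge step only joins simple paths of pairwise-supported termini;
  conflicting evidence cancels all merges touching the conflicted terminus.
* The hybrid is emitted unpolished; donor-derived intervals are recorded in
  the AGP precisely so a downstream polisher can target them.
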