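# asmrec — consensus-based genome assembly reconciliation

`asmrec` audits and repairs a scaffolded genome assembly using independent
*de novo* assemblies of the same genome as evidence. Hi-C scaffolding joins
long-read contigs across N-gaps into chromosome-scale scaffolds, but
occasionally joins sequence from different chromosomal loci (misjoins) or
flips fragments. Because different assemblers fragment a genome differently,
a locus broken in the base assembly is often contiguous in an alternate
assembly — so alternates can vote on the base's structure. The package is
aimed at assembly builders and curators who have one scaffolded "base"
assembly plus two or more alternate contig sets.

The core procedure, per junction between adjacent alignment blocks:

* **check A** — is a gap tract near the junction? (scaffolding joins happen
  at gaps);
* **check B** — are at least two alternate assemblies discrepant with the
  base there *and* mutually consistent with each other?

If both hold, the region between the last shared anchor upstream and the
first shared anchor downstream is replaced by the corresponding interval of
one randomly chosen agreeing alternate (a *hybrid assembly*). The same
block machinery then fills N-gaps whose flanks align inside a gap-free
alternate block, and merges scaffolds whose termini at least two alternates
bridge collinearly. Quality is scored with contiguity statistics
(N50 / N(X) curves, where N(X) is the length of the shortest sequence in
the minimal set of longest sequences covering X% of the assembly) and with
large-insert (BAC-end) read-pair concordance: a pair is concordant iff both
ends map to one scaffold, inward-facing FR, with outer insert inside
configured bounds.

Everything tabular flows as tibbles (blocks, breakpoint calls, edit
records, pair classes), fitted results have `tidy()` / `glance()` methods,
and each result type has a plot (`autoplot()` for N(X) curves,
`plot_dotplot()` for alignments). A seeded simulator generates truth
genomes, corrupted bases, alternates, and BAC pairs with machine-readable
truth records, so every claim the package makes about itself is checkable.

## Worked example

```r
library(asmrec)

scn <- simulate_scenario(standard_scenario_config(seed = 7))
find_gaps(scn$base)            # 31 N tracts, 16,076 bp of N
rec <- reconcile_assemblies(scn$base, scn$alternates, seed = 1)
glance(rec)
```

```
#>   n_breakpoints_called n_actionable n_blocks_replaced n_replacements_skipped
#> 1                    5            5                 5                      0
#>   n_gaps_filled filled_gap_total_length n_gaps_unfilled n_merges
#> 1            21                   10585               0        0
```

All five injected misjoins produced actionable calls (5 breakpoints, each
supported by all three alternates) and were replaced with alternate
sequence; the 21 gaps not consumed by replacements were filled, removing
10,585 bp of N — the hybrid assembly ends gap-free and, checked against the
simulator's truth records, every corrected locus matches the truth genome
exactly. `tidy(rec)` lists each edit with full donor provenance and the
recorded random draw; `write_agp(rec, ...)`, `write_report(rec, ...)` and
`write_breakpoints_bed(rec, ...)` export the provenance, and
`compose_liftover()` / `project_pairs()` + `classify_pairs()` quantify the
BAC-end concordance gain.

A thin command-line wrapper ships in `inst/cli/asmrec.R`
(`stats | align | reconcile | fill-gaps | merge | validate-pairs |
simulate`).

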