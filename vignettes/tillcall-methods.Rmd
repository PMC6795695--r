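---
title: "Methods: population-scale EMS mutation discovery with tillcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale EMS mutation discovery with tillcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

TILLING (Targeting Induced Local Lesions in Genomes) pairs chemical
mutagenesis with sequencing-based mutation detection: a population of plants
is treated with EMS (ethyl methanesulfonate), selfed once, and the M2
individuals are exome-captured and sequenced at modest depth alongside one
deeply sequenced unmutagenized control. The analytical task is to find, for
every line, the handful of induced point mutations hiding among sequencing
errors, varietal polymorphisms against the reference accession, and — in
polyploids such as durum wheat — homeologous reads collapsed onto one
reference contig. EMS leaves a strong fingerprint: the vast majority of true
induced changes are C→T or G→A transitions, and in M2 material an induced
mutation is expected heterozygous twice as often as homozygous. Both
expectations double as quality controls on any call set.

`tillcall` implements the full stack between read alignment (upstream, out
of scope) and a browsable mutation table: coverage-driven exome-reference
construction, PCR-duplicate removal, a population-scale caller with zygosity
prediction, spectrum reporting, flanking-sequence extraction and CSV/SQLite
export, plus a synthetic M2-population generator that makes every stage
testable without any external data.

## Exome-reference construction

Annotation-free coding-region retrieval uses the control sample's coverage
as the signal: exome capture piles reads on exons (and, usefully, their
intron margins), so high-coverage intervals mark the capture space.

1. `call_core_regions()` marks maximal runs of positions with depth ≥
   `min_depth` (default **17 reads**, inclusive).
2. `flank_and_merge()` extends each run by `flank` bases (default **500**)
   on both sides — coverage does not drop abruptly at intron–exon
   boundaries, so the flanks keep the mappable shoulders — and merges
   flank-extended regions whose gap is **strictly less than** `merge_gap`
   (default **301**; a 300-bp gap merges, a 301-bp gap does not). Merging
   *after* flanking is a deliberate choice: it guarantees the excised
   contigs can never overlap (two cores 900 bp apart would otherwise each
   carry a 500-bp flank into the other), and gaps are therefore measured
   between extended coordinates. Adjacent or overlapping extended regions
   always merge; flanks are clipped silently at chromosome ends.
3. `excise_contigs()` cuts the region sequences out of the source assembly,
   assigning sequential `ctgNNNNNN` identifiers in `(chromosome, start)`
   order and recording provenance (source assembly, chromosome, 1-based
   inclusive span) in the FASTA headers.

`build_reference()` iterates this over up to two assemblies in priority
order — the second track is expected to come from reads that failed to map
to the first assembly; that read partition happens upstream — and appends
externally assembled de-novo contigs, keeping only those of **≥ 500 bp**.
Contig ids continue across sources so the combined reference has one flat
namespace.

Coordinates are 1-based inclusive everywhere inside the package (the pileup
and mutation-table convention); only `write_bed()` converts to BED's
0-based half-open form, at the I/O boundary. A single internal convention is
the cheapest defence against off-by-one drift.

## PCR-duplicate removal

Duplicates are defined by the standard coordinate criterion: two pairs are
copies when they share contig, both mates' leftmost positions, and
orientation. Within each group `mark_duplicates()` keeps the pair with the
highest summed base quality, breaking ties by lexicographically smallest
read name, so the kept set is reproducible. Running the procedure on its own
kept output flags nothing (idempotence), and the number kept always equals
the number of distinct keys. Optical duplicates and UMIs are out of scope.

## The mutation caller

`call_population()` applies three criteria to every non-reference allele
(including the deletion allele `DEL`; insertions are consumed by the parser
but never called) at every pileup column:

1. **Control concordance and uniqueness.** The control's majority allele
   must equal the reference base with a minor-allele fraction ≤
   `control_max_minor_fraction` (default 0.1 — a ~30× control will show
   stray error reads, so exact unanimity would be too brittle). Columns
   failing this are varietal SNPs between the study line and the reference
   accession, not induced mutations. The candidate allele must then be
   *present* — supported by ≥ `presence_min_reads` reads (default 2) — in
   **exactly one** mutant line: the probability of the same induced change
   arising in two independent plants is negligible.
2. **Support.** The carrier must show ≥ `min_mut_support` reads of the
   allele (default 3; stringent analyses typically use 10).
3. **Population coverage.** Absence elsewhere is only evidence when the rest
   of the population covers the site: at least `min_informative_samples`
   *other* mutant lines (default 50; scale to the population) must each
   show ≥ `min_other_depth` reads (default 3) of the control allele.

Zygosity comes from the mutant-allele fraction `f = support / depth`:
homozygous at `f ≥ 0.85`, heterozygous at `0.15 ≤ f < 0.85`, no call below.
The bands sit around the M2 expectations (`f ≈ 1` and `f ≈ 0.5`) with room
for binomial sampling noise at ~10–30× depth; they are configuration, not
constants, because the right minor-allele ratio is a per-study decision.
Every rejected candidate can be audited: `call_position()` (and
`call_population(verdicts = TRUE)`) emits a verdict row naming the failed
criterion.

Two properties of this rule set are worth knowing. First, the call count is
monotone non-increasing in `min_mut_support` and in
`min_informative_samples`, which is what makes the stringency sweep
(`coverage_sweep()`) interpretable. Second, `presence_min_reads` is **not**
a pure stringency knob: it gates the uniqueness test on both sides, so
raising it can *admit* calls (a second line with exactly two reads of the
allele vetoes the call at threshold 2 but not at 3). The test suite pins
down this counterexample rather than asserting a monotonicity the rule set
does not have.

The vectorised caller operates on the in-memory count-matrix container; the
text-pileup file path (`read_pileup()`) fills the same container, and
lossless round-trip tests (`write_pileup()` → `read_pileup()`) make the two
entry points equivalent. Column-by-column (`call_position()`) and
brute-force enumeration implementations are kept equal to the vectorised
path by property tests over random pileups.

## Reporting and export

`summarize_calls()` produces the per-type spectrum, the CG→TA fraction
(reported as a plain fraction; summaries round to integer percent), het/hom
totals and their ratio (`NA` when no homozygous calls exist), and the
mutation rate as calls per Mbp of *callable space* — the summed count of
(mutant sample, position) pairs covered by at least the support threshold,
as returned by `call_population()`. That denominator choice matches the
definition of a rate "per position that could have yielded a call" and makes
rates comparable across samples of very different depth.

`extract_flanks()` returns up to 200 reference bases per side (50 is the
warning floor for primer design) with the site rendered `[control/mutant]`,
e.g. `[G/A]` or `[G/-]` for a deletion; stripping the marker and restoring
the control base always reproduces an exact reference substring.
`as_mutation_records()` + `export_mutation_csv()` + `export_sqlite()`
produce the database table (indexed on mutant id and contig id — the two
query modes of a TILLING browser), with `chromosome_location = "unplaced"`
for de-novo or simulated contigs.

## The synthetic M2 population

`simulate_dataset()` generates reference, truth table, multi-sample pileup
and (optionally) duplicated read pairs. Defaults are the study conditions
the package is calibrated to emulate: 40 mutant lines over 200 × 2-kb
contigs (0.4 Mbp — large enough for several hundred truth mutations, small
enough for fast test cycles), a 29.5× control, per-line mean depths drawn
from 1.2–11.3 (or fixed, e.g. 30, for power analyses), 20 induced
mutations/Mbp per line, 98% canonical EMS transitions, `p_het = 2/3`
(the 2:1 M2 expectation), 0.1% deletions, 0.2% per-read sequencing error,
50 shared varietal SNPs per Mbp, and 5% PCR duplicates.

Model details that matter for interpreting test results:

* Depth is position-independent Poisson per sample. Capture-efficiency and
  GC bias along contigs are deliberately not modelled — they affect which
  positions are callable, not whether the caller's logic is correct.
* A sequencing-error read is misassigned uniformly over the three other
  *bases*; the deletion allele arises only from truth records. Spreading
  error into `*` symbols would conflate two error processes (miscalls and
  alignment artefacts) that the caller treats identically anyway.
* Canonical events are placed on C/G sites (C→T, G→A); non-canonical
  substitutions pick a uniform site and a uniform non-reference base, so
  the expected canonical fraction among mutations is
  `(1 - p_deletion) (p_can + (1 - p_can) · gc/3)` (`expected_cg_ta()`), a
  touch above `p_can`.
* Varietal SNPs are placed once and applied homozygously to the control and
  every line — exactly the signature the control-concordance criterion
  exists to remove.
* Homeolog collapse — two subgenome copies mapping to one contig, the main
  false-positive mechanism in real polyploid data — is *not* simulated.
  Passing recovery tests therefore demonstrates correctness of the calling
  logic under the stated noise model, not robustness to reference
  deficiencies.
* Everything is deterministic under `cfg$seed`: `simulate_dataset()` seeds
  once and runs reference → truth → pileup → reads, so identical
  configurations reproduce byte-identical outputs.

```{r example}
library(tillcall)
cfg <- sim_config(mutant_depth_mean = 30, seed = 42)
ds <- simulate_dataset(cfg)
res <- call_population(ds$pileup,
                       caller_config(min_mut_support = 10,
                                     min_informative_samples = 20),
                       control_id = "control")
score_calls(res$calls, ds$truth, min_support = 10, pileup = ds$pileup)
summarize_calls(res$calls, res$callable$total)
```

## Numerical and design choices

* **Pileup dialect.** The parser consumes read-start (`^` plus mapping
  quality character), read-end (`$`) and indel-length tokens, collapses
  strand case (calling is strand-agnostic), counts `*` as the deletion
  allele and `N`/`<`/`>` as non-callable `N` (excluded from depth). A
  parsed column whose symbol count disagrees with the stated depth is a
  hard error naming the line. Base qualities are parsed but unused: support
  is counted in reads.
* **Reference-N columns** are parseable but never callable.
* **Ties.** A control column whose reference count merely ties the maximum
  still passes the majority test only if the minor fraction is within the
  cap (a 50/50 tie always fails it). Duplicate selection breaks quality
  ties by read name. Gap-rule boundaries are strict as stated above.
* **Degenerate inputs.** Empty pileups, empty call sets, zero-coverage
  tracks, empty region lists and header-only CSVs all round-trip as empty
  objects rather than errors.
* **Problem sizes.** Property tests run 10,000 random pileup columns
  against an independent encoder, 1,000 random coverage tracks against a
  dilate-and-union oracle, 500 random 200-column × 8-sample pileups against
  a literal enumerate-everything caller, and one full 40-line × 0.4-Mbp
  recovery simulation — sizes chosen to exercise every code path at
  high statistical power while keeping the default suite fast on one core.

## Known limitations

* The caller assumes one control and treats samples independently;
  library-pool-aware duplicate handling is not implemented.
* No functional-effect annotation (missense/nonsense) is attempted.
* The flanking-sequence range (50–200 bp) is implemented as "always 200,
  truncated at contig ends, warn below 50"; the choice of when a shorter
  flank suffices is left to the consumer.
* Real-data headline figures (reference size in the hundreds of Mbp,
  tens of thousands of mutations across ~80 lines) require the original
  sequencing archives and full assemblies; the package reproduces the
  *method* and validates it on simulation plus the published spectrum
  table, not the raw-data scale.
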