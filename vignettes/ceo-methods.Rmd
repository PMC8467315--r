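---
title: "Methods: simulating and quantifying Cas12a-based target enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying Cas12a-based target enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long, GC-rich, highly repetitive genes — the silkworm fibroin heavy-chain
gene *FibH* is the motivating case — resist PCR amplification and
short-read assembly. Cas12a (Cpf1) negative-selection enrichment solves the
access problem: genomic DNA is dephosphorylated so that no pre-existing 5'
end can accept a sequencing adapter, Cas12a/crRNA complexes then cut at
guide sites flanking the locus of interest, and only the freshly cut ends
are adapter-ligated and nanopore-sequenced. Reads therefore start
preferentially at the cut sites and run into the excised target.

`ceoseq` implements this workflow twice over: once as a set of analysis
operations applied to real artifacts (guide tables, alignments, methylation
calls), and once as a generative model — an in-silico twin of the protocol
over a synthetic *FibH*-like locus — whose ground truth makes every
analysis operation testable end to end.

# Guide model

A Cas12a guide is a TTTV PAM (IUPAC-configurable) followed 3' by a 20–21 nt
protospacer. Guide records carry the printed-table coordinate convention:
1-based inclusive positions spanning PAM **plus** protospacer, with `start`
the PAM-side terminus, so reverse-strand guides have descending
coordinates.

The off-target census (`count_offtargets()`) counts PAM-anchored sites
only: the PAM must match the pattern exactly (a `degenerate_pam` flag
relaxes it), and mismatches are Hamming distances within the protospacer
alone — the convention of the CRISPR design tools this mirrors. The
guide's own locus is excluded, so a genome-unique guide reports MM0 = 0.
Bulge-tolerant (indel) off-target search is out of scope.

Two guide pairs imply three enrichment regions
(`define_enrichment_regions()`). The boundary contributed by each guide
site is its 5'-most genomic coordinate — `min(start, end)` of the
PAM-inclusive site. Whether the "true" boundary is the PAM-proximal base or
the predicted cut site is not observable from a region table alone; this
convention is the one that makes the published guide table reproduce the
published region table exactly, and it is applied uniformly. The three
regions tile the interval between the outer guides: target between the
inner guides, upstream/downstream between the members of each pair.

# The synthetic locus

`locus_spec()` describes a two-exon gene (57-bp exon 1, 971-bp intron,
16,845 bp in total) whose second exon carries a repetitive core: 12
repetitive domains separated by 11 amorphous spacers. The core is built
from a catalogue of ten literal 11-mer motifs (354 copies in total, from
145 copies of motif-1 down to 3 of motif-10), each containing exactly one
CpG. Copies of each motif are spread as evenly as possible across the
domains and joined by 2–8 bp random linkers; amorphous spacers are 250 bp
of motif-free random sequence. The gene is embedded centrally in a 500-kb
random background chromosome (GC 0.38, the genome-wide GC of the silkworm),
with the four published guide sites planted around it at the published
geometry (inner boundaries 17,962 bp apart; pair spacings 738 and 394 bp).

Numerical choices worth stating:

* **Core GC.** The motif catalogue alone has GC 0.613. The GC of linkers
  and spacers is solved so the expected core GC equals the 0.59 observed
  for the real repetitive exon.
* **Core size.** The catalogue fixes 354 motif copies, so the repetitive
  core is ~8.4 kb; the remaining gene length is unique N-/C-terminal
  sequence. The real exon 2 is more repeat-dense (its degenerate copies are
  not in the ten-motif catalogue), so the synthetic gene is repeat-sparser
  than *FibH* itself while preserving every quantity the census and
  methylation modules measure.
* **No junction CpGs.** Most motifs end in C, so a G-leading linker would
  mint a CpG inside the preceding instance's 11-bp span and pollute the
  per-motif methylation sum. Fillers never start with G.
* **Exact ground truth.** Accidental motif occurrences arising in random
  sequence are removed by point mutation. Several motifs differ by a
  single base, so the replacement base is chosen so the mutated window
  matches *no* catalogue motif (and never creates a CpG); the annotation
  emitted is therefore exact, and the census round-trips it.
* **Amorphous length (250 bp)** exceeds the segmentation window (200 bp) so
  the planted layout is recoverable by the default segmentation; this is a
  property of the blueprint, not a tuned constant.

# The protocol model

`simulate_protocol()` draws `n_molecules` genome copies and, per molecule:

1. **Fragmentation.** Pre-existing fragments have iid uniform lengths
   (default 23–200 kb, the high-molecular-weight range of the extraction
   this emulates).
2. **Dephosphorylation.** Each pre-existing end is ligatable with
   probability $(1-d) + d\,b$, where $d$ is `dephos_efficiency` and $b$
   `background_end_rate`. The real protocol's residual genome-wide
   background has no stated mechanism; these two free parameters are the
   model's stand-in, not a mechanistic claim.
3. **Cleavage.** Each guide site on a fragment is cut independently with
   its per-guide efficiency (defaults 1.00, 1.00, 1.00, 0.98 — the
   gel-estimated activities of the four published guides). The staggered
   cut sits 18/23 nt 3' of the PAM (canonical Cas12a geometry, leaving a
   5-nt 5' overhang); after fill-in the two daughter fragments retain the
   overhang-outer coordinates. Both cut ends are ligatable.
4. **Sequencing.** Each ligatable end seeds a read with probability
   `reads_per_ligatable_end`; the read runs inward for a
   log-normal length (`meanlog` 8.5, `sdlog` 0.55, ~5.8 kb mean, floored
   at 200 bp), truncated at the fragment's far end. Bases are error-free
   copies of the reference: the quantities of interest here are
   coordinates and CpG states, not basecall realism (an error channel
   would only blur the truth alignment the quantification consumes).
   Per-read mean quality is drawn from a two-component Gaussian mixture
   (90% at Q12, 10% at Q5) so the standard Q ≥ 7 pass filter does real
   work.
5. **Methylation calls.** Every CpG wholly inside a read's truth interval
   receives a Bernoulli state from its site's methylation probability
   (motif CpGs inherit their motif's per-instance probability, defaults
   equal to the published per-motif total frequency divided by copy
   number; background CpGs default to 0.01), flipped with
   `meth_caller_error` (default 0.02).

Identical `(spec, params, seed)` give byte-identical outputs; all
randomness flows through the single seed.

# Closed-form expected enrichment fold

`expected_enrichment_fold()` evaluates the model's expected depth
deterministically. A source at distance $u$ from position $x$ covers $x$
with probability

$$ S_L(u)\; S_F(u) \prod_{j:\,c_j \in (x,u)} (1 - e_j), $$

where $S_L$ is the read-length survival, $S_F$ the probability that no
pre-existing breakpoint intervenes (the plain uniform fragment survival for
reads launched at a breakpoint; the forward-recurrence survival
$E[(F-u)_+]/\mu_F$ for reads launched at an interior cut), and each
intervening guide cut blocks passage with its efficiency $e_j$. Sources are
(i) a continuum of breakpoints at density $1/\mu_F$ per bp, ligatable with
the residual-end probability, (ii) the two molecule ends, and (iii) the
discrete cut ends, weighted by $e_j$. The expected fold is the ratio of
the mean expected depth over the target region to the mean over the
genome. Genome-edge effects beyond the explicit end sources, and the small
transient excess of the renewal process over its asymptotic rate, are
ignored; across replicate simulations the expectation sits well within
Monte-Carlo error of the empirical fold.

One regime choice matters for testing: with near-total dephosphorylation
background coverage is negligible, cut-end reads dominate both the target
and the genome-wide mean, and the fold becomes almost invariant to
cleavage efficiency (both numerator and denominator scale with it). The
monotonicity and model-agreement checks therefore run in a
background-visible regime — dephosphorylation 0.9 and 5–20 kb fragments —
where the fold responds identifiably to both knobs. That regime also
produces folds of the same order as real genome-scale experiments, which
the desk-scale default (a 500-kb background with only a handful of
fragment ends per molecule) cannot: at genome scale the background ends
outnumber cut ends millions to one; at 500 kb they do not.

# Quantification, census, methylation

* **Depth** is difference-array accumulation of 0-based half-open truth
  intervals; *average depth* is the mean per-base coverage over the
  1-based inclusive printed region (a median is available behind a flag —
  the published prose once says "median coverage" where its table
  arithmetic is a mean, and the mean reproduces that arithmetic). Folds
  and depths are reported to two decimals, rounding half away from zero as
  the tables print. Reads count toward a region on any overlap (≥ 1 bp).
  Both the filtered and unfiltered genome-wide means are computed, since
  whether the published genome mean preceded the quality filter is
  unstated.
* **Census** is an exhaustive exact-match scan (forward strand — motifs
  are defined on the coding strand); overlapping occurrences count, though
  the catalogue 11-mers cannot self-overlap. A Hamming-tolerance flag
  (default 0) anticipates degenerate copies but is off so the literal
  catalogue semantics hold.
* **Segmentation** slides a 200-bp centered window over per-base motif
  coverage; windows at density ≥ 0.5 seed repetitive segments,
  sub-threshold gaps < 50 bp are absorbed, each segment snaps to the motif
  instances it contains (runs are first expanded by half a window, since a
  centered window depresses density right at domain edges), and the
  remainder is labeled amorphous or N-/C-terminal. The published figure
  shows the resulting architecture without an algorithm; this
  density-window method was chosen for transparency, and all three
  constants are configuration keys. Output tiles the locus exactly.
* **Methylation.** Site frequency is `called_sites_methylated /
  called_sites`. The per-motif statistic is the **sum** of its instances'
  site frequencies — forced by the published table's internal consistency
  (a 3-copy motif reports total 0.438 with one site alone at 0.206, which
  no mean-per-site bounded by 1 could produce); a `per_copy` flag reports
  the mean. A "methylated site" defaults to any site with at least one
  methylated call, with a `min_frequency` override — the threshold behind
  the published methylated-site tally is unknown, so that tally is treated
  as descriptive, not reproducible. A CpG belongs to a motif instance iff
  its start lies within the instance's 11-bp span; call strand is
  collapsed (CpG is symmetric).

# What passing tests do and do not show

The generator reproduces the architecture, guide geometry, GC composition,
and methylation bookkeeping of a *FibH*-like locus, so green tests show
the *operations* are correct and the *model* is self-consistent. They do
not show basecall-level realism (reads are error-free), assembly behavior
(no assembler is run), degenerate-repeat structure (the catalogue is
literal), or the mechanism of genome-wide background (two free
parameters). Published sequencing-scale quantities — read totals,
consensus length, the 306-of-506 methylated-site tally — depend on the
original raw reads and are out of reach by construction; what is
reproduced exactly is the published in-paper arithmetic (guide GC,
region boundaries, enrichment folds, one CpG per motif).

# Problem sizes

The default blueprint (500-kb background) builds in a few seconds. The
test suite and the acceptance script use: the default locus for round-trip
and enrichment checks; a 60-kb-background locus for fast protocol unit
tests; 120–250 molecules per simulation; 5–6 replicate simulations per
parameter setting for Monte-Carlo comparisons; and a spanning-read
(`meanlog` 9.9), error-free regime for methylation recovery, which yields
≥ 50 calls at every locus CpG. Binomial recovery checks use 99% intervals.

# Known limitations

* The closed-form expectation ignores renewal-transient and genome-edge
  corrections of order a few percent; it is an expectation for comparing
  simulations, not an estimator for real data.
* Per-read CpG states are drawn independently per read and per site; real
  molecules share haplotype- and molecule-level methylation correlation.
* The segmentation labels only alternate R/A within one contiguous core;
  loci with multiple separated repeat cores would segment per core but the
  N-/C-terminal labels would span the inter-core gaps.
* PAF output carries truth alignments; the package does not run or model a
  mapper.
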