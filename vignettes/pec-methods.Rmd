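---
title: "Barcode-free PCR error correction: models, defaults and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-free PCR error correction: models, defaults and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecr)
```

## The problem and the method

Libraries built from circulating-free DNA (cfDNA) or single cells are
amplified through many PCR cycles, so most aligned read pairs are PCR
copies of a much smaller set of original fragments. Polymerase errors
introduced during amplification look like high-confidence base calls:
quality-based filtering cannot remove them, and the conventional
de-duplication strategy — keep the highest-quality read per duplicate
group — passes them straight to the variant caller.

`pecr` exploits the redundancy those PCR copies provide. Read pairs that
share unclipped 5′ coordinates on both ends (and an orientation class) are
treated as copies of one fragment: a *duplicate family*, whose size is the
*duplicate depth* d. Families with d ≥ 5 are collapsed to a per-column
consensus, correcting any error carried by a minority of copies. Families
too shallow for a reliable consensus keep their best member, but the
errors corrected in the deep families leave a fingerprint: k-mers that were
contradicted by a consensus somewhere and confirmed nowhere (the
*error-k-mer* catalogue) mark recurrent, dataset-intrinsic error patterns.
Shallow reads containing such k-mers have the implicated base's quality
downgraded to Phred 5 — *intrinsic polishing* — so downstream tools skip it
without the base itself being altered. Everything is finally realigned
(Smith-Waterman) and written back to BAM.

The crucial property of this design is that the error model is learnt from
the dataset being corrected, not from an external panel of control samples,
and it needs no molecular barcodes.

## When is coordinate-based grouping safe?

Merging all pairs with identical endpoints is only valid if two *distinct*
fragments rarely share both endpoints (a *collision*). For fragments of
fixed length L overlapping a locus there are L possible start offsets, so
with an expected count \(M_L = D\,N(L\mid\mu,\sigma)\) of such fragments
(cfDNA depth \(D\); fragment lengths modelled as normal with mean
\(\mu\) and SD \(\sigma\)), the birthday problem gives

\[
C_L = 1 - \frac{L!}{(L-M_L)!\,L^{M_L}},
\qquad
p = \sum_L C_L \, N(L\mid\mu,\sigma),
\]

summing over integer lengths within \(\mu \pm 6\sigma\) (truncation error
below \(10^{-9}\) of the mass). \(M_L\) is real-valued, so the factorial
ratio is evaluated as a log-gamma continuous extension rather than by
rounding — smooth in \(D\) and \(\sigma\) — with clamps \(C_L = 0\) for
\(M_L \le 1\) and \(C_L = 1\) for \(M_L \ge L\).

```{r collision}
depth_threshold_scan(177, 20, c(100, 300, 500))
```

At typical cfDNA parameters (300-fold molecular depth, 177 ± 20 bp
fragments) about 4.6% of loci are affected; beyond roughly 500× collisions
become prohibitive and coordinate-only grouping should not be trusted. The
test suite validates the analytic model against a mechanical Monte-Carlo
(drawing integer fragment counts and placing them uniformly over start
offsets) across a grid of depths and spreads.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `min_dup_depth` | 5 | smallest family collapsed to a consensus; below it a majority vote over so few copies is unreliable and the representative path is used |
| `min_base_qual` | 20 (Phred) | bases below this neither vote in the consensus nor count as PCR errors — the base caller has already marked them, and downstream tools handle them via the quality string |
| `k` | 21 | error-catalogue k-mer length; odd (no self-reverse-complement ambiguity) and standard in k-mer error correction; long enough that 21-mer coincidences across an 8 kb–3 Gb reference are negligible |
| `flag_qual` | 5 (Phred) | quality assigned to polished bases; low enough that every common caller ignores them, configurable because cutoffs differ |
| SW scoring | +2/−2, open −3, extend −1 | affine-gap local alignment defaults; a gap of length g costs open + g·extend |
| `window_margin` | 50 bp | reference context added around the original mapping for realignment |

Reads are kept in reference-forward orientation (as BAM stores them), and
k-mers are compared in that single convention without canonicalisation:
families are coordinate-defined, so one convention makes trusted/untrusted
comparisons exact.

## Numerical and procedural choices

* **Consensus = positional majority vote.** For equal-length reads sharing
  a 5′ end, a per-column vote and a de Bruijn-style assembly coincide on
  substitutions; the positional form is exactly testable. Members whose
  mate length or CIGAR indel profile differs from the family plurality
  cannot be placed into columns and do not vote (they are counted and
  logged); a family with no strict plurality length is routed to the
  representative path. Indel errors inside columns are out of scope.
* **Ties.** At a consensus column, ties break by larger summed Phred among
  supporters, then lexicographically smallest base. Representative
  selection breaks exact quality ties by smallest read name. The
  Smith-Waterman traceback prefers diagonal over up over left, gap openings
  over extensions, and starts from the maximal cell with smallest query
  then target index. Every tie-break is deterministic, so reruns are
  byte-identical and input order never matters.
* **Consensus qualities.** The paired-end format needs a quality per
  consensus base; we assign the maximum Phred among voting-eligible members
  agreeing with the consensus (capped at 93). A column with no eligible
  voter falls back to a plain majority over all bases and the best
  available quality.
* **Polishing localisation.** Each maximal run of consecutive read k-mers
  found in the error catalogue localises the error to the intersection of
  the windows' spans: a full run of k windows pins exactly one base;
  shorter runs near read ends give a small multi-base span (conservative);
  runs longer than k (several nearby errors merged) flag the span between
  the crossed interval endpoints, which contains every contributing error.
  Qualities already below `flag_qual` are never raised.
* **Degenerate inputs.** `N` bases never vote, never count as errors and
  never enter k-mer sets. Orphaned mates (mate unmapped or on another
  contig) have no duplicate key; they pass through unmodified and are
  counted. Reads shorter than k cannot be polished and are returned
  unchanged with a warning. Empty inputs yield empty outputs with the
  header preserved.

## What the simulator emulates

`sim_config()` defaults describe a targeted cfDNA panel: an 8 kb target,
10^4 original fragments (~220× fragment coverage), lengths
Normal(177, 20) truncated below at the 100 bp read length, and duplicate
depths 1 + NegBinom(size 0.5, mean 5) — mean 6 but strongly overdispersed,
as PCR jackpotting yields many singletons alongside a few very deep
families. Random PCR errors hit each duplicate independently (10⁻³ per
base, Phred 30–40, spectrum enriched for G>T and C>T); sequencer miscalls
(2×10⁻³) always carry Phred < 20, exercising the low-quality exemption.

Hotspot loci model context-driven systematic errors: the same substitution
recurring independently across duplicates at five reference positions. The
default per-duplicate recurrence of 0.01 reflects the physically plausible
regime (late-cycle, context-specific polymerase errors): low enough that a
family consensus essentially never adopts the error — if it did, the
pattern would be "trusted" once and, by the strict never-trusted rule,
drop out of the catalogue — yet recurrent enough at ~220× coverage to be
learnt from dozens of deep families and then flagged in singletons. At
recurrence rates above ~0.1 the strict rule defeats itself at any realistic
coverage, which is worth knowing when reasoning about real data: the
catalogue captures errors that are frequent across families but rare
within them.

Distinct fragments that collide (identical start and end) are assigned one
truth family, since no barcode-free method can separate them; at the
default coverage a few such collisions per dataset are expected, exactly as
the collision model predicts.

The simulator does **not** model indel errors, duplex strands, optical
duplicates, quality-profile realism along the read, or alignment ambiguity
(reads are placed at their true coordinates). Passing tests therefore
demonstrate the algorithm's behaviour under its own assumptions, not
performance on real instrument data.

## Scales used in the tests

Unit tests run on constructed families and small simulations (60–1500
fragments). The end-to-end validation uses the default fixture above
(10^4 fragments, ~6×10^4 read pairs); the Monte-Carlo collision check uses
10^5 loci per grid point; Smith-Waterman is compared against an
independent dynamic-programming oracle on 500 random instances, plus the
paired-fixture cases. Determinism (byte-identical reruns, order
invariance) is exercised on a 1500-fragment fixture so two full pipeline
runs stay quick.

The pipeline is a single in-memory pass over a whole dataset. At the
panel scales this package targets that is the simplest correct form; a
streaming or two-pass layout would only change memory behaviour, and the
order-independence property the tests enforce guarantees any such
re-organisation must produce identical output.

## Known limitations

* Collisions merge distinct molecules; at high molecular depth (>500×)
  this corrupts consensus families, and the model above should be
  consulted before trusting coordinate-only grouping.
* A systematic error present in most copies of most families (e.g. severe
  pre-amplification damage) is indistinguishable from a variant to any
  intrinsic method; an external background panel is the only remedy.
* Consensus columns ignore members with discordant indels; indel error
  correction is not attempted.
* The k-mer store is exact (hash set). This is the right choice at panel
  scale; a probabilistic backend would be needed for whole-genome runs.
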