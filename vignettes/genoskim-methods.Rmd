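---
title: "Assembling plastomes and rDNA from genome skims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling plastomes and rDNA from genome skims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoskim)
```

# The model

A genome skim covers the nuclear genome at well under 1×, the plastome
at tens to hundreds of ×, and the tandem nrDNA array somewhere in
between. genoskim exploits that separation: a canonical k-mer count
index of the filtered reads concentrates the organelle signal into a
high-count band, and a coverage threshold anchored on seed k-mers (which
by construction lie on the organelle) carves the organelle subgraph out
of the De Bruijn graph without any reference assembly.

Two structural facts drive the unfolding step.

* The plastome's two inverted repeats (IRa = reverse complement of IRb)
  collapse onto a single unitig whose k-mer coverage is ~2× that of the
  single-copy regions; the collapsed graph of a clean quadripartite
  plastome has exactly three unitigs (LSC, SSC, IR) and four links, and
  the only closed walk through them uses the IR twice, once per
  orientation. Detecting that walk *is* the circularisation.
* A tandem rDNA array collapses onto a one-unit cycle: a unit-path
  unitig plus a short bridge unitig spanning the copy–copy junction
  (whose k-mers occur `copies - 1` times and therefore break the cycle
  at the junction). Traversing the cycle exactly once between the
  unique flanking spacers reports one unit regardless of copy number.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `quality_threshold` | 20 | Phred | end-trimming cut-off of the standard Illumina-era filter |
| `min_length` | 30 | nt | reads shorter than this after trimming are discarded |
| `k` | 31 | nt | long enough to be specific in a ~150 kb plastome, short enough for 101 nt reads (71 windows per read); must be odd so no k-mer is its own reverse complement |
| `retain_fraction` | 0.90 | — | the variable length cut-off keeps 90 % of reads and truncates the rest to a uniform length |
| `min_count` | auto | counts | `max(2, mode of seed-k-mer counts / 4)`; the mode is taken above the error band (counts ≥ 3) so singleton error k-mers harvested by protein seeding cannot drag it down |
| `max_gap_iterations` | 30 | rounds | gap filling rounds; the threshold is relaxed by `gap_relax_factor` (0.5) per round |
| `max_gap_depth` | 500 | nodes | bound on the reconnection search, i.e. the longest coverage hole that can be bridged |
| `tip_max_len` | 2k | nt | dead-end branches shorter than this are pruned as artefacts |
| `seed_word_aa` | 7 | aa | amino-acid word length for six-frame protein seeding |
| `gap_open`, `gap_extend` | −11, −1 | score | BLOSUM62 affine gaps; a gap of length L costs `gap_open + (L−1)·gap_extend` |
| `min_identity`, `min_coverage_of_ref` | 0.5, 0.7 | fraction | acceptance thresholds for a marker hit; deliberately permissive — the score ranking picks the hit, the thresholds only reject junk |

# The simulator: what it emulates, and what it does not

The generator builds three compartments with fixed relative copy
numbers — plastome 100, rDNA array 50, nuclear background 1 — chosen to
reproduce the high-copy regime that makes skimming work (real
plastid:nuclear ratios vary by tissue and are not published per library;
these are stand-ins, flagged here and in the configuration). Reads are
101 nt pairs; fragment lengths are Normal, truncated below at the read
length, with sd = 0.1 × mean (published material reports means only; a
Normal is the simplest choice consistent with sonication). Preservation
presets set the insert mean (silica 350 bp, herbarium 250 bp) and scale
the organelle share of a herbarium library down by the depth ratios
observed between preservation types in the large campaigns (plastid
1/1.7, rDNA 1/1.5). Qualities decay linearly from Q37 to Q28 along the
read (an invented but plausible profile; tests that need the trimming
rules to fire construct lower-quality reads explicitly). Circular
genomes are sampled on a doubled sequence with coordinates reported
modulo length. The PhiX decoy is a 5,386 bp synthetic stand-in
generated from a fixed seed — the screen needs a stable decoy, not the
real PhiX.

What the simulator does **not** model: indel errors, PCR duplicates,
ancient-DNA damage, chimeras, heteroplasmy, and — importantly — a
realistically sized nuclear genome. The background compartment is tens
of kilobases, so at equal read counts the preset contrast in organelle
depth has the right direction but a compressed magnitude compared with
real libraries, where the nuclear compartment absorbs most of the
sequencing. Passing tests on this synthetic data therefore demonstrate
the correctness of the algorithms under their structural assumptions
(single IR-sized repeat, clean tandem array), not performance on real
skims of repeat-rich plastomes (the families that are hard in practice
are hard precisely because they violate those assumptions).

# Numerical and design choices

* **Rule order in trimming.** N-truncation is applied before quality
  trimming; the published description lists them in the other order,
  but the two orders differ only in edge cases and Ns usually carry low
  quality anyway. The second N itself is removed, so a surviving read
  carries at most one N — simpler for k-mer handling downstream.
* **PhiX "mapping".** Replaced by a canonical k-mer containment screen
  (k = 21, flag at ≥ 80 % shared); this avoids bundling an aligner and
  the threshold is exposed. The screen early-exits once the decision is
  provable, which is what makes it cheap.
* **Length cut-off semantics.** Reads above the cut-off are truncated
  to it (not kept whole), so the index is built from uniform-length
  sequences and coverage statistics are length-homogeneous.
* **Gap filling.** Implemented as per-round threshold relaxation with a
  bounded breadth-first reconnection search from each dangling path
  end; only nodes on a path that actually reconnects to the admitted
  graph are kept. This is this package's explicit construction — the
  original assembler's internals are not described publicly.
* **Tie-breaking and determinism.** All node iteration is in
  lexicographic canonical-k-mer order; identical inputs give identical
  outputs, byte for byte.
* **Bubbles and tips.** Parallel unitigs with identical link partners
  and near-equal length collapse to the higher-coverage branch; short
  dead-ends are pruned. With the error-band-aware threshold these
  cleanups rarely fire below ~1 % substitution error.
* **Canonical form of a circular assembly.** A circle is only defined
  up to rotation, strand and (with an IR) the SSC-orientation isomer.
  IR-less circles are reported at the lexicographically minimal
  rotation over both strands (Booth's algorithm). Quadripartite circles
  are instead anchored at the LSC start so that the reported LSC / IRb /
  SSC / IRa layout tiles the sequence; within that anchoring the SSC
  isomer with the lexicographically smaller SSC and then the smaller of
  the two strand readings are chosen. (A purely lexicographic rotation
  would destroy the layout's tiling property, which downstream
  annotation needs.)
* **Depth proxy.** Reported depth is total index count of the
  assembly's k-mer positions divided by the number of positions, times
  `L / (L − k + 1)` to undo the read-edge deficit; k-mers occurring
  twice in the assembly (the IR) contribute both positions, keeping the
  estimate per-locus. On 90× simulations this lands within a few
  percent of 90.
* **Exon model.** In-frame stops split a translated hit into intervals;
  that is adequate for the intronless *matK*/*rbcL* and is a documented
  limitation for spliced genes (no exonerate-style spliced alignment).
* **Reference choice.** Selecting the taxonomically closest reference
  is out of scope; the caller supplies the reference set and the
  best-scoring reference wins.
* **Statistics.** Fisher's exact p is an explicit hypergeometric
  enumeration (via `dhyper`), cross-checked in the tests against
  `stats::fisher.test`; the rank-sum comparison reports the
  Mann–Whitney U of group 1 with an exact p when both groups have ≤ 10
  untied values and the tie-corrected normal approximation otherwise.
  Published summaries mix library and specimen denominators for
  success rates, so both are supported and the choice is explicit in
  the API rather than silently resolved.
* **Pairing information** is not used during graph construction (counts
  only); pairs are used post hoc for insert-size estimation by
  exact-match placement of a subsample on the assembly.

# Problem sizes used in the checks

The shipped tests exercise the full pipeline on plastomes of 18–38 kb
(IR 1–3 kb) with a two-copy ~5.8 kb rDNA unit and 50 kb of nuclear
background at 90× plastome depth — a deliberate scale-down of a real
110–160 kb plastome that preserves every structural feature the
algorithms rely on (quadripartite layout, IR coverage doubling, tandem
cycle, multi-compartment mixture). The acceptance script uses eight such
draws plus an equal-size preset contrast; the test suite runs twenty.

# Known limitations

* One IR-sized repeat is assumed; additional long repeats fragment the
  walk and the assembly is honestly reported `partial` (mirroring the
  real difficulty of repeat-rich families).
* Mitochondrial assembly, scaffolding with mate pairs, structural
  annotation beyond the quadripartite layout, and taxonomy-driven
  reference selection are out of scope.
* The k-mer index stores counts only (no read positions); operations
  that need positions re-stream the reads.
* Counts saturate at the 32-bit limit rather than wrapping; the
  saturation is invisible at skim scale.
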