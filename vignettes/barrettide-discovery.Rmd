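---
title: "Mining sequencing data for cysteine-framework peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining sequencing data for cysteine-framework peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrettideR)
```

## Scope and model

`barrettideR` finds members of a cysteine-framework peptide family in
nucleotide assemblies and corroborates them with mass spectrometry. The
family model has three layers:

1. **The mature peptide.** A short disulfide-rich peptide characterized by
   its cysteine framework — the spacing pattern of its cysteines. For
   barrettides: 31 residues, Cys at positions 5, 7, 18, 23 (framework
   C-x1-C-x10-C-x4-C), disulfides Cys5–Cys23 and Cys7–Cys18 (I–IV,
   II–III). The framework, not overall identity, is the retention
   criterion for candidate hits, because it is the family's most conserved
   feature.

2. **The precursor.** The peptide is ribosomally encoded as part of a
   larger precursor with RiPP-like architecture: a 19-residue signal
   peptide (two observed variants, consensus `MA[TI]KVALL[VA]VSALIAVAAA`),
   a leader segment of 19, 105 or 112 residues whose last residue is Ala,
   then the core peptide, immediately followed by a TGA stop codon and a
   conserved ~33-nt 3′UTR. The package *annotates* these expectations as
   flags (`junction_is_Ala`, `stop_is_TGA`, `leader_len_known`,
   `signal_motif`) rather than filtering on them: they were observed
   regularities, not definitional criteria, and a candidate violating one
   is interesting rather than invalid.

3. **Evidence integration.** A peptide can be supported by sequence
   (transcriptome hit, genome hit) and/or by MS (its theoretical m/z
   observed in a sample's peak list). The presence matrix keeps these
   evidence channels separate per sample, because they genuinely disagree
   in practice: transcripts without detectable peptide (no expression at
   sampling time, MS sensitivity) and peptide without transcript
   (storage of previously produced peptide, assembly dropout) both occur.

## Translated search

The search aligns the mature query against all six reading frames of each
record with Smith–Waterman and affine gaps — an exhaustive, deterministic
equivalent of tblastn at desk scale. Choices:

* **BLOSUM62, gap open 11, extend 1** — the tblastn defaults, since the
  family model prescribes no alignment parameters. A gap of length $k$
  costs $11 + k$ (NCBI convention: the first gap position pays
  open + extend).
* **Raw score threshold 50, no E-values.** Databases here are desk-scale
  (hundreds of records), where E-value machinery adds statistical
  assumptions without changing decisions; a raw threshold is exactly
  reproducible. It is configurable, and at the default the empirical null
  (100 random decoys) yields zero hits while an exact 31-mer coding copy
  scores ≈ 170.
* **Stops score −4 against everything** so alignments do not extend
  through a translated stop, but near-stop hits remain findable. `N`
  codons translate to `X`, which scores as BLOSUM62's `X` column (never
  positive against a standard residue).
* **Deterministic traceback**: ties prefer diagonal, then up, then left;
  among equal-scoring end cells the smallest subject start, then smallest
  query start, wins. Determinism is load-bearing: the pipeline promises
  byte-identical reruns.

The DP kernel is C++ (Rcpp), the convention in this field's R packages
for alignment inner loops. The test suite checks it two independent ways:
a memoised recursive enumeration of all affine-gap local alignments
(exhaustive for short strings) and Biostrings `pairwiseAlignment` on
random peptide pairs.

## Framework matching and core location

`matches_framework()` demands *exact* spacing equality at some offset
(extra cysteines elsewhere are allowed). Exactness is the strictest
defensible reading of "fitting the framework", and the default; a per-gap
`slack` parameter widens it for exploratory use. The core span inside an
ORF is anchored by the best local alignment of the query and then
adjusted by up to ±5 residues so the spanned substring carries cysteines
at exactly the query's positions — this absorbs alignment end-effects
when the candidate's termini diverge from the query.

## Masses and m/z

Neutral monoisotopic mass is the residue-mass sum plus one water, minus
two hydrogens per disulfide. Constants: proton 1.007276466 Da, hydrogen
1.0078250319 Da, water 18.0105646863 Da, standard monoisotopic residue
table (all in `constants.R`). With the printed barrettide C sequence and
2 disulfides these reproduce the published charge-state values
3238.3544 / 1619.6808 / 1080.1230 / 810.3441 to all four printed decimals
(`round()`'s half-to-even at 4 decimals is used for table rendering;
internal arithmetic is full double precision). Leu/Ile have identical
elemental composition, so `isobaric_key()` canonicalizes I→L; peptides
differing only by such swaps produce identical ions at every charge and
are flagged mutually ambiguous in presence calls — they cannot be told
apart by m/z alone.

## MS presence calling

* **Tolerance 0.05 Da absolute** by default (Q-Tof-class accuracy; the
  source study states none); a ppm mode is provided. Matching is
  symmetric (|theoretical − observed| ≤ tol) and each theoretical ion
  takes the *nearest* in-tolerance peak, equidistant ties resolved toward
  lower m/z.
* **`min_charges = 1`**: one matching charge state suffices for a
  presence call, mirroring single-ion presence reasoning; stricter
  settings are available and reduce false positives roughly
  geometrically in the noise density.
* Intensity is carried through but never used in calling.

## Origin heuristics

* **Poly-A**: only a *terminal* run counts, minimum 8 nt (shared
  constant with the 3′UTR boundary in precursor annotation).
* **Introns**: transcript and genomic copy are compared by unique 21-mer
  anchor blocks chained co-linearly; a genomic gap ≥ 50 nt with a
  transcript gap ≤ 5 nt is an intron. Length bands: < 500 nt
  "short_spliceosomal_like", 500–800 nt inclusive "group_II_candidate"
  (the typical prokaryotic group II intron size), > 800 nt "long". Both
  band edges are inclusive in the group II band because the canonical
  500–800 bp range is a closed interval. Splice dinucleotides are
  recorded but never filtered on.
* **GC bimodality**: per-record GC fractions are split by the exhaustive
  1-D threshold minimizing within-cluster variance. The flag requires
  (i) cluster-mean separation ≥ 2× the pooled within-cluster sd,
  (ii) each mode ≥ 10% of records, and (iii) a density valley: ≤ 10% of
  records within the quarter-band around the split. Condition (iii) is a
  deliberate addition: the optimal variance split of a *single* Gaussian
  already yields separation ≈ 2.65× the within-cluster sd, so criterion
  (i) alone would flag any unimodal Gaussian sample as bimodal. A real
  two-mode mixture has a sparse valley at the split; a unimodal sample
  does not. This is a per-assembled-record substitute for read-level GC
  plots, which need raw reads that are out of scope.

## The simulator: what it states and what it omits

`sim_config()` defaults are the stated world of the family model:

| parameter | default | rationale |
|---|---|---|
| `n_precursors` | 5 | a family of five discoverable members |
| `core_template` | barrettide C | the only member printed verbatim |
| `leader_mode` | mixed 19/105/112 | the three observed leader lengths |
| signal | 2 printed motifs | sampled uniformly |
| stop / 3′UTR | TGA / fixed 33 nt | conserved in all observed precursors |
| `polya_geometric_mean` | 12 nt over an 8-nt floor | "short" poly-A tails |
| `intron_lengths` | 300 nt | inside the observed <100–400 nt range |
| `n_decoys`, GC modes | 100; 0.38/0.62 at 50:50 | exercises the bimodality detector |
| `peak_noise_count` | 200 | uniform over the 50–1500 scan range |
| `mz_jitter_sd` | 0.01 Th | well inside the 0.05 Da tolerance |
| codon usage | uniform over synonymous codons | no organism table stated |

All randomness derives from one seed via fixed per-stage substreams
(precursors, codons, decoys, genomic, peaks), so identical configs are
byte-identical and stages can be regenerated independently. Planted ions
are emitted at whatever charges the config requests even when a z = 1 or
z = 2 ion of a ~3.2 kDa peptide falls outside the nominal 50–1500 scan
range — the scan range constrains *noise* peaks; the truth manifest, not
instrument realism, is what the tests score against. Two simulator
details exist purely to make ground truth exact: intron insertion points
reject flanking exon `G` bases (which would make a GT..AG junction
ambiguous under a 1-nt shift), and leaders avoid Cys so the core's
framework match is unique.

The simulator does **not** emulate: read-level errors or coverage,
assembly artifacts (chimeras, fragmentation), isotope envelopes or MS2
fragmentation, retention time, organism-specific codon bias, or
paralogous gene families. A green end-to-end test therefore establishes
the *pipeline's* correctness on data obeying the stated architecture, not
robustness to assembly pathology.

## Degenerate inputs and tie-breaks

* FASTA headers without sequence raise a parse error naming the line;
  `U` is normalized to `T`; characters outside `A,C,G,T,N` are errors.
* Sequences < 3 nt translate to six empty frames with a warning; ORFs may
  run off the transcript end (empty `stop_codon`), in which case the
  appended-tail invariance of ORF extraction does not apply to them.
* Overlapping ORF starts sharing a stop: the longest (leftmost M) is
  reported by default, all starts on request — an implementation
  decision; there is no family-level reason to prefer one convention.
* Candidates with identical core sequence collapse to one entry
  (isoforms); names are assigned in first-seen order (`cand1`, ...).
* `gc_bimodality` requires ≥ 10 records; constant input returns a FALSE
  flag rather than an error.
* `find_introns` returns `NULL` (distinct from an empty intron table)
  when no co-linear chain covers ≥ 50% of the transcript in either
  orientation.

## Known limitations

* Signal peptides are fixed-length (19) with an optional motif check; no
  general signal-peptide predictor is called, by design (reproducibility
  without web services). Families with variable signal lengths need the
  `signal_len` parameter adjusted.
* The raw-score search threshold is not length- or database-normalized;
  screening very large assemblies would warrant E-values.
* Intron detection assumes desk-scale, mostly-unique sequence; repetitive
  genomic context would fragment the anchor chain.
* MS presence is m/z-only; isobaric ambiguity is flagged but can only be
  resolved by orthogonal data (MS2, amino acid analysis, NMR), which is
  out of scope.
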