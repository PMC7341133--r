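---
title: "mitoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some lineages carry amino-acid substitutions in mitochondria-encoded
proteins that are essentially universal within the lineage and essentially
absent outside it. Finding such sites from public sequence collections takes
four bookkeeping steps that are conceptually simple but easy to get subtly
wrong: (i) reconstruct ancestral residues at the internal nodes of a rooted
phylogeny; (ii) tabulate, per tree edge and per alignment column, whether
the ancestral and descendant states differ; (iii) translate alignment
columns into the residue numbering of a structurally characterised reference
species so positions can be discussed against a structure; and (iv) survey
large panels of partially covering DNA-barcode fragments (typically COI) to
ask whether a candidate residue is fixed within a clade. `mitoscan`
implements these steps as a tested pipeline with a synthetic-data generator
that provides exact ground truth for every stage.

## Ancestral reconstruction

States are reconstructed by small parsimony. For a column with leaf states
$x_\ell$ on a rooted tree, the bottom-up pass computes at every internal
node $v$ with children $c_1,\dots,c_k$ the count
$n_v(s) = \#\{i : s \in S_{c_i}\}$ of children whose candidate set contains
state $s$, takes $m_v = \max_s n_v(s)$, sets
$S_v = \{s : n_v(s) = m_v\}$, and adds $k - m_v$ to the column score. This
is Hartigan's algorithm; on binary trees it reduces to the familiar Fitch
intersection/union rule with the score equal to the number of union events.
We chose Hartigan over a literal fold of the binary rule across children
because only the majority rule is guaranteed minimal on multifurcating
trees (children with sets $\{A\},\{B\},\{C\}$ cost 2, not 1), and the test
suite holds the implementation to brute-force enumeration minima on all
small trees, polytomies included.

The reference pipeline this package re-implements used a likelihood,
indel-aware reconstruction (PAGAN). Parsimony was substituted deliberately:
it is fully specified, its optimum can be checked against exhaustive
enumeration, and it supports every downstream bookkeeping step. Edge counts
on real data will deviate from a likelihood reconstruction, most visibly on
long edges; this is a known and accepted trade-off, and no output of this
package should be read as reproducing PAGAN's counts.

Deterministic choices, in one place:

* **Missing data** (`-`, `.`, `X`, `?`, `*`) at a leaf becomes the full
  state set in the bottom-up pass — it never constrains the reconstruction
  and never contributes to the score. An internal node whose descendant
  leaves are all missing in a column is reported as `X`, and transitions
  touching `X` are never counted as substitutions.
* **Top-down tie-break:** a node inherits its parent's state when that
  state is among its candidates, otherwise (and at the root) it takes the
  alphabetically smallest candidate. This makes reconstructions reproducible
  to the byte without randomness.
* **Branch lengths are ignored**; only topology matters.

## Edge tables and candidate selection

`build_edge_table()` turns a reconstruction into the binary indicator
matrix (edge × column), from which everything else is marginal sums: edge
totals (which lineage changed most), per-column counts (how often a
position changed tree-wide), and the focal-edge report (ancestral →
descendant residue per changed column on one edge). The selection rule for
candidate sites is `rank_focal_columns()`: among columns changed on the
focal edge, rank by tree-wide change count ascending — the top hit is the
most conserved position altered on that lineage. The double-counting
identity $\sum_{\text{edges}}$ = $\sum_{\text{columns}}$ is asserted on
every table build.

Edge totals exclude terminal edges by default. Terminal edges accumulate
private polymorphism and sequencing artefacts and would swamp a ranking
meant to find lineage-defining internal edges; they remain available via
`include_terminal = TRUE`.

## Reference numbering

`build_reference_map()` implements the numbering convention used when
discussing residues against a structure (e.g. "position 153" in the
ungapped numbering of the bovine COI sequence): the $k$-th non-gap column
of the reference row is reference position $k$. The map is partial (columns
where the reference is gapped are reported as unmapped), strictly
increasing, and composes with the per-gene offset table of
`concatenate_proteomes()` so positions in a concatenated alignment report
as (gene, within-gene position). Everything is 1-based, matching structural
convention.

## Barcode fixation surveys

`survey_position()` answers: at reference position $p$, what residues do
the members of each clade carry? Barcode fragments arrive as unaligned
nucleotides with unknown reading frame and partial coverage, so the survey:

1. translates each fragment under the chosen mitochondrial code, picking
   the frame with the fewest internal stop codons (ties to the lowest
   frame);
2. places the translation on the reference protein with a local affine-gap
   pairwise alignment (BLOSUM62, gap opening 10, gap extension 0.5 — the
   only alignment computed in the package); and
3. reads off the residue aligned to position $p$.

A sample is **informative** when that residue is one of the 20 standard
amino acids; truncated fragments, gaps, ambiguous `X` and stops stay in
`n_total` but not in `n_informative`. The source study never defines its
informativeness rule; this one is explicit and configurable consumers can
tighten. Fixation is classified against a threshold on the majority-residue
fraction among informative samples; the default 1.0 encodes the strict
"universal within the clade" reading, and `classify_fixation()` is monotone
in the threshold by construction (tested over random spectra). Known
mis-annotated samples are handled by an explicit exclusion list, not
re-identification.

## Structural context

`min_residue_distance()` uses the minimum heavy-atom inter-residue
distance. Published "within X Å" statements rarely say which atoms they
mean; the minimum over heavy-atom pairs is the only convention under which
such statements are testable as upper bounds (any atom-pair convention
gives a larger or equal number). Hydrogens are excluded by default, altlocs
resolve to the highest-occupancy conformer (ties to `A`), and both PDB and
mmCIF inputs are accepted. The bundled
`synthetic_cox_dchannel.pdb` fixture is a **synthetic stand-in** — a
hand-placed neighbourhood of the D-channel landmark residues with realistic
pairwise geometry — because the experimental structure cannot be bundled or
fetched offline. Tests that pass against it validate the distance
machinery and the stated bounds, not the crystal structure.

## The synthetic world

The generator emulates the shape of the real inputs — a clade-structured
bird-like phylogeny with an outgroup, a concatenated mitochondrial protein
alignment, and partially covering barcode panels — under the simplest
process that makes ground truth exact:

* **Tree:** uniform random recursive splits; clades are guaranteed
  monophyletic and their ancestors carry the clade name as a node label.
  Defaults mirror the real scale loosely (the study tree had 645 leaves
  with a 15-leaf focal family; tests default to ≤32 leaves and ≤300
  columns purely for speed, which changes nothing structural).
* **Sequences:** uniform root sequence over 20 residues; per edge and
  column a Poisson($\lambda$) number of substitutions with a uniform
  target among the other 19 (a Jukes–Cantor-style uniform-exchange
  process). Default $\lambda = 0.01$ per column per edge keeps parsimony
  essentially exact while still producing a realistic scatter of background
  events. No rate heterogeneity, no indels, no codon structure — the
  generator makes no claim of evolutionary realism, so a green recovery
  test establishes correctness of the bookkeeping, not robustness to model
  violation.
* **Identifiability in homoplasy-free mode:** background events are
  rejected if they would reuse a column, touch a planted column, land on an
  edge carrying planted events, or land on either edge incident to the
  root. The last rule deserves a word: a single change on a root-incident
  edge can be placed on either side of the root with equal parsimony (and
  equal likelihood), so no method can recover it; excluding it is what
  makes "the pipeline recovers the planted event list exactly" a fair
  claim. Similarly, `simulate_scan_bundle()` never pairs a planted column
  with the focal clade's sister leaf, where placement would be ambiguous.
* **Barcodes:** per-clade residue spectra are planted at the focal
  position, fragments are back-translated with random synonymous codons
  (so translation inverts them exactly), and a configurable fraction is
  truncated upstream of the focal position to emulate partial coverage.

All generators take a mandatory seed and restore the caller's RNG state;
identical seeds give byte-identical outputs.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| fixation `threshold` | 1.0 | strict "universal in clade" reading; 0.99 tolerates one stray sample per ~100 |
| genetic code | vertebrate mitochondrial (NCBI table 2) | the organellar code of the motivating system; tables 1 and 5 included |
| gap opening / extension | 10 / 0.5 | Biostrings defaults for protein local alignment; fragments are near-identical to the reference so placement is insensitive within reason |
| `background_rate` | 0.01 /column/edge | low enough for exact parsimony, high enough to scatter events |
| `include_terminal` | FALSE | rankings target lineage-defining internal edges |

## Limitations

* Parsimony underestimates changes on long edges and cannot resolve
  root-incident placements; counts are bookkeeping over a reconstruction,
  not substitution-rate estimates.
* The placement aligner assumes fragments really derive from the reference
  region; heavily diverged or chimeric barcodes should be pre-filtered.
* The survey does no taxonomy resolution and trusts the annotation table;
  mis-annotations must be supplied as an exclusion list.
* Distance annotation is geometric only; it says nothing about energetics
  or dynamics.
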