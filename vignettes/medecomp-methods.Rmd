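---
title: "Minimum entropy decomposition: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum entropy decomposition: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medecomp)
```

## The model

`medecomp` treats an amplicon dataset as a matrix of residues — reads as
rows, alignment positions as columns over `{A,C,G,T,N,-}` — and asks of
each column: how much information does it carry? The answer is the
base-2 Shannon entropy of the column's residue frequencies,

$$H_j = -\sum_k p_{kj} \log_2 p_{kj}.$$

A column fixed at one residue contributes nothing; a column that splits
the reads into distinct groups contributes up to $\log_2 6$ bits. The
decomposition repeatedly carves the dataset along its highest-entropy
columns until every resulting unit is homogeneous up to sequencing
noise. Because a split fixes the discriminant columns within each
child, the size-weighted total entropy
$\sum_v (n_v/N)\sum_j H_{jv}$ can only decrease (the grouping property
of Shannon entropy), which is what gives the algorithm its name, its
termination guarantee, and the monotone trace recorded in the
iteration log.

The procedure assumes the input is quality-filtered and
length-consistent. Length variation that is *biological* is encoded by
`pad_reads()` as trailing gaps, which count as an ordinary sixth
character state and can therefore legitimately direct splits; length
variation caused by error processes (e.g. homopolymer indels) must be
resolved upstream by alignment or discarding, since the method performs
no alignment of its own.

## The loop and its parameters

The dataset enters a decomposition pool as the root node. Each
iteration pops one node (FIFO, so the iteration log reads level by
level through the emerging tree) and applies three rules in order:

* **Noise filter `M` (minimum substantive abundance).** If the node's
  most abundant *unique* sequence occurs fewer than `M` times, the node
  is discarded — the criterion deliberately ignores node size, because
  a cloud of rare singletons is noise no matter how large. The default
  resolves to `recommend_M(N) = ceiling(N / 10000)` for `N` input
  reads; the package's own validation runs use `M = 100` at the
  10 000-read scale, the stricter choice appropriate when per-template
  abundances are in the thousands. Discarding the root is reported to
  the user as an error by `med_run()`: it means the whole dataset fails
  the filter.

* **Convergence at threshold `m'`.** Sequencing error keeps column
  entropy slightly above zero even in pure nodes, so entropy below a
  threshold is treated as absent. The base value `m0 = 0.0965` bits is
  the entropy of a column with a 99% consensus and the remaining 1%
  spread evenly across the three other bases
  ($-0.99\log_2 0.99 - 3\cdot\tfrac{0.01}{3}\log_2\tfrac{0.01}{3}
  \approx 0.0966$) — the noise floor of a 1%-error instrument. Base 2
  is not a free choice: it is the only base under which that
  1%-error model reproduces the 0.0965 constant. Per node the
  threshold is scaled as $m' = \min(m_0,\; m_0\, n/N)$, with `n` the
  node size and `N` the frequency of the dataset's most abundant
  unique read, fixed once at the start. The linear-with-clamp form is
  the simplest function consistent with "decreases from `m0`
  proportionally to `n/N`"; it is isolated in `normalized_m()` so an
  alternative heuristic can be swapped in without touching the loop.
  Comparisons are strict: a column exactly at `m'` does not trigger a
  split, so `is_converged()` and `select_discriminant_positions()` can
  never disagree.

* **Decomposition under the cap `c`.** Up to `c` positions above `m'`
  — ranked by entropy, ties to the left-most position — direct one
  split, *simultaneously*: reads are grouped by their exact character
  tuple at those positions. The default `c = 4` balances two failure
  modes: a small `c` needs more iterations, while a large `c`
  fragments a node into many small tuple groups, more of which then
  fall under `M` and are discarded. Children are ranked by size
  (descending, ties by tuple) and named by appending their rank to the
  parent id with a dot (`0.1.2`), so node ids are stable, deterministic
  records of lineage.

Representative sequences are the most abundant unique sequence of each
final node, written with trailing padding stripped (padding encodes
absence of sequence, not sequence).

## What the simulator emulates — and what it does not

`make_templates()` + `simulate_reads()` generate the regime the method
is designed for: a handful of template sequences at small pairwise
Hamming distance (down to the single-nucleotide scale that fixed-radius
clustering cannot resolve), per-sample abundance tables, and
independent per-base substitution error, 1% by default, with an
optional per-position error vector and optional truncated-length
templates for biological length variation. Substitution-only is a
deliberate restriction: indel-type error is assumed handled upstream,
matching the method's own preconditions.

What the simulator does *not* model: chimeras, correlated errors,
quality-score structure, platform-specific artifacts (homopolymer
indels), compositional PCR bias, and the long-tailed richness of real
communities. Tests passing on simulated data therefore demonstrate the
algorithm's behavior under its stated assumptions — noise removal,
template recovery, determinism — not robustness to everything a real
sequencing run can produce.

On study-condition simulations (5 templates × 2 000 reads of 250 nt at
1% error, `M = 100`) a substantial fraction of reads ends in discarded
nodes. This is expected, honest behavior, not a defect: at 1% error
over 250 nt, ~92% of reads carry at least one substitution, each
large node's per-column entropy hovers at the `m0` noise floor, and
the loop strips error variants position by position into sub-`M`
children until the surviving core is homogeneous. The final units and
their representatives are exact; abundance *ratios* between nodes are
preserved far better than absolute counts, which is the quantity
downstream diversity analyses consume (the percent matrix).

## Numerical and design notes

* **Tie-breaks** are total everywhere: unique sequences order by count
  descending then sequence ascending (byte order, locale-independent);
  equal-entropy positions prefer the smaller index; equal-size children
  order by tuple. Two runs on the same finalized input are
  bit-identical.
* **Fully gapped or constant columns** have entropy exactly 0 by the
  standard formula; no special-casing.
* **`N` in the threshold** is a whole-dataset constant, not per-node,
  so `m'` of a node never depends on the order nodes are processed.
* **Profiles are computed once per node, at creation**, which makes the
  per-iteration entropy trace well defined (the sum over all live
  nodes) at linear cost; the per-column residue tally is the hot loop
  and is implemented in C++.
* **Discarded reads are retained in the topology** for accounting —
  conservation (final + discarded = input) is asserted by the test
  suite on every run — but excluded from matrices and representatives.
  No post-hoc relocation of discarded reads into surviving nodes is
  attempted.
* **`--quick`** in the CLI runs the raw decomposition and core outputs,
  skipping the RUNINFO summary log; it exists for interface fidelity
  with the published tool shape.
* **Problem sizes in the test suite** were chosen as the smallest that
  exercise each claim: the brute-force oracle equivalence runs 200
  random datasets of up to 100 reads × 30 nt; template recovery runs
  20 seeds of the full 10 000-read study condition; property suites
  use mixed-template datasets of up to 100 reads.

## Known limitations

* Reads must share a coordinate system. Datasets where length variation
  is artifactual require external alignment first; `pad_reads()` alone
  is only correct for biological length variation.
* The `m'` heuristic is calibrated for ~1% substitution error;
  platforms with substantially different error profiles warrant a
  different `m0` (exposed as a parameter throughout).
* Very low-abundance organisms (below `M`) are removed by design; the
  filter cannot distinguish a rare organism from noise.
* Representative sequences of different runs are comparable only up to
  the padding/trimming convention; cross-study unit matching is out of
  scope.
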