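---
title: "Mapping linear epitopes from display-selection sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping linear epitopes from display-selection sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitopescan)
```

## The problem and the model

An antibody selects, from an mRNA-display library of random 12-mer
peptides, the peptides it binds.  Sequencing the selected pool and asking
*where in the proteome those peptides look like a contiguous protein
segment* localises the antibody's linear epitope — and, scanned across
every protein, its genome-wide cross-reactivity.

The statistic works per 12-residue protein window.  Let $s(a,b)$ be a
non-negative amino-acid similarity score (BLOSUM62 with negative entries
floored at zero — a randomised library carries no meaningful "worse than
unrelated" signal, so negative similarity is uninformative), and for a
peptide $p$ and window $w$ define the ungapped, frame-locked similarity
$S(p, w) = \sum_{j=1}^{12} s(p_j, w_j)$.

* **P (theoretical)** — the inverse cumulative distribution
  $P_w(s) = \Pr[S(X, w) \ge s]$ for a random peptide $X$ whose residues
  are i.i.d. from a library frequency model.  Because the sites are
  independent, $S$ is a sum of independent integer site scores and
  $P_w$ is computed *exactly* by convolving the 12 per-site
  distributions (no sampling).  $P_w$ depends on $w$ only through its
  residue multiset, which the implementation memoises.
* **Q (empirical)** — the same quantity with $X$ drawn from the
  sequenced, selected peptides, weighted by read counts.
* **Per-window score** — the Pearson $\chi^2$ distance summed over the
  score support:
  $D_w = \sum_{s=0}^{12\,s_{\max}} \frac{(Q_w(s) - P_w(s))^2}{\max(P_w(s), \varepsilon)}$,
  $\varepsilon = 10^{-12}$.
  At a binding site the selected peptides resemble the window, $Q$ gains
  a heavy upper tail where $P$ is tiny, and $D_w$ peaks sharply.

Windows are 1-based start positions, fully contained in the protein.
The genome scan ranks all (protein, window) pairs by $D_w$ descending,
ties broken by protein ID then position; a protein's score is the max
over its windows.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 12 | window = library random-region length (residues) |
| matrix | `blosum62_mod` | zero-floored BLOSUM62, $s_{\max} = 11$; `wac_mod` ($s_{\max} = 4$) shrinks the support ~3x for speed |
| frequency model | `nnn_no_stop` | residue frequencies of a uniformly random base triplet conditioned on no stop (61 sense codons) |
| $\chi^2$ floor $\varepsilon$ | 1e-12 | guards levels where $P$ underflows to exactly 0 |
| logo `top_n` | 1000 | unique peptides stacked per convergence logo |
| display threshold | 0.20 | convergence fraction at which a logo residue is displayed |
| LTTB ratio | 1/50 | plot downsampling for genome-wide scans |
| Q weighting | `reads` | read-level histogram; `unique` is robust to PCR bias |

**Frequency-model choice.** The physical library is built from NNK
codons, but an "ideally random" cDNA pool is NNN; whether the original
analysis conditioned on NNN, NNK or uniform residues is not recorded.
All three are implemented (`make_frequency_model`), the choice is a
config field written into every output, and `nnn_no_stop` is the
default.  The difference propagates only weakly into $D_w$ because P and
Q are compared on the same support.

**$\chi^2$ variant.** The asymmetric form $(Q-P)^2/P$ — observed
against theoretical — with a $10^{-12}$ denominator floor is fixed here;
the distance family is named in the source method but not its exact
form or zero handling.  $d(0) = 0$ automatically since both inverse
cumulatives are 1 at score 0.

## The selection simulator: a stated world

Real selection NGS data are not bundled, so the package ships a
generator with planted ground truth; every recovery claim in the test
suite is a claim about this world:

1. **Naive library** — `n` reads of 12 NNK codons drawn uniformly at
   the nucleotide level; TAG-containing reads discarded (the only NNK
   stop), giving the analytic discard fraction $1 - (31/32)^{12}$.
2. **Truth** — one 12-mer proteome window; 8 of its 12 positions
   (1, 2, 4, 6, 7, 9, 11, 12) are hotspots carrying energy 3.0 each for
   the planted residue ("delta" grading; a similarity-graded option
   exists).  Hotspots spanning the full window pin the
   peptide-to-window register, making "recovered position within ±2" a
   property of the model rather than of an alignment heuristic.
3. **Capture saturates** — a peptide with summed hotspot energy $E$ is
   captured with probability
   $p = b + (1-b)\,\sigma(k(E - E_{1/2}))$, $b = 0.01$,
   $E_{1/2} = 12$, slope $k = 1$.  Saturation is essential, not
   cosmetic: with purely exponential weights the single best clone
   present in the naive sample takes over the pool within three rounds
   (binomial class tails fall off only ~3-10x per extra matched
   hotspot, while exponential round factors grow much faster), the
   empirical distribution collapses to a point mass, and both rank-1
   recovery and logo convergence become coin flips.  Physically, bead
   capture probability cannot exceed 1.
4. **Pool vs sequencing depth** — selection propagates a 4e6-molecule
   pool; the sequencer samples 1e5 reads per round.  Real pools exceed
   sequencing depth by many orders of magnitude; the separation matters
   because every saturated clone ends with pool share ~1/N, so the
   largest chance $\chi^2$ spike a single clone can produce anywhere in
   the genome scan shrinks quadratically with pool size.  4e6 puts that
   spike an order of magnitude below the aggregate epitope signal while
   still simulating in about a minute.

With the defaults, the round-3 pool is a few-thousand-clone mixture
dominated by 4-of-8 and 5-of-8 hotspot matchers: deep enough for a
rank-1 hit at the exact planted window and ≥ 0.2 planted-residue
convergence at every hotspot, across seeds, yet still clonally diverse
the way real selections from 10^13 libraries are.

What the generator does **not** emulate: PCR amplification bias,
sequencing errors (a per-base substitution rate is available but off by
default), translation-efficiency differences, conformational epitopes,
and correlated residue preferences within an epitope.  A green
recovery test therefore establishes the *pipeline's* correctness on a
clean selection, not robustness to those artefacts.

## Null calibration and the chi-square tail

One stated criterion is honestly red, by design rather than defect:
with Q built from 1e5 reads sampled *from the P model itself* over a
100 x 300-aa toy proteome, no window was expected to exceed 10x the
track median.  The sum $D_w$ does not behave that way: its median is
roughly (number of occupied support levels)/n ≈ 3e-4, but a single
chance read whose score lands where $P(s) \sim 10^{-7}..10^{-9}$
contributes $(10^{-5})^2 / P(s) \approx 10^{-3}..10^{-1}$ on its own.
Across ~29,000 windows x 1e5 reads such events are guaranteed, and the
measured max/median ratio is in the hundreds.  This is intrinsic to the
Pearson $\chi^2$ distance with the theoretical tail in the denominator
at finite read depth.  It does not harm epitope calling — a planted
epitope scores ~4 orders of magnitude above these null spikes — but a
10x-median threshold is not a property of this statistic, and the
criterion is asserted as stated and left failing rather than weakened.

## Logos, motifs, round tracking

Convergence logos stack the `top_n = 1000` most abundant unique
peptides (ties lexicographic), weight columns by read counts, and
display residues converged ≥ 20%.  When anchored to a protein window,
each peptide is shifted to the offset maximising its similarity against
the window (overlap-only scoring, smallest offset on ties) — the
anchoring registration is unrecorded in the source analysis, so the
best-scoring-offset bridge is this package's choice, recorded per logo.
Motif tracking (`match_motif`, `motif_fraction_by_round`) uses
wildcard patterns such as the anti-FLAG `DYKXXD` and reports read-level
fractions per round.

## Antibody penetration into tissue

The 3D-immunostaining trade-off is reconstructed as a standard
diffusion-reaction system (the source describes the simulation only by
citation): free antibody $A$ diffuses from a fixed surface reservoir
into a slab (or radially symmetric disc) and binds immobile antigen
$B$ reversibly, $\partial_t A = D\nabla^2 A - k_{on}AB + k_{off}C$,
with $B + C$ conserved pointwise.  Integration is explicit in the
diffusion term (with the stability bound enforced and a suggested `dt`
in the error message) and backward-Euler per node in the stiff binding
term, which keeps concentrations non-negative at realistic $k_{on}$.

A competitor epitope peptide is modelled as a reversible blocker of the
antibody's binding site at fixed concentration: the staining bath
pre-equilibrates antibody between free and blocked forms, both diffuse,
and only the free form binds antigen — lowering the *apparent*
$k_{on}$.  The simulated consequence matches the method's rationale:
less complex at the surface, far more at depth.

All default parameters are order-of-magnitude placeholders for IgG in
cleared tissue (D = 0.036 mm²/h ≈ 1e-7 cm²/s, k_on = 3.6e8 /(M·h) ≈
1e5 /(M·s), k_off = 0.36 /h, 100 nM antibody, 1 µM antigen); the
original figure does not print its parameter values.

## Group comparison

Serum-style comparisons (diseased vs healthy animals) summarise each
sample by its maximum window score on a designated protein and that
protein's genome rank, and test group differences with an exact
Mann-Whitney U: the tie-exact null distribution of the mid-rank sum is
enumerated by dynamic programming up to a combined n of 25 (beyond
that, normal approximation with tie correction, flagged in the output).
Two-sided p is `2 * min(tail probabilities)` capped at 1 — a declared
convention, since the source does not state sidedness.

## Numerical choices and degenerate inputs

* Score support is the full `0..L*s_max`, dense, never truncated.
* Proteins shorter than L are skipped and logged; non-standard residues
  (B, J, O, U, X, Z) drop the protein by default (`"mask"` keeps it and
  skips affected windows).
* Empty count tables are an error for Q and logos; an empty peptide
  list yields a valid zero-total count table with a warning.
* All randomness flows through explicit seeds; seeded runs are
  byte-identical, and the RNG state of the caller is restored.
* LTTB downsampling always keeps the first and last point and returns
  the input unchanged for n < 3 or ratio 1.

## Known limitations

Ungapped, frame-locked scoring cannot represent gapped or
conformational epitopes.  No significance calibration is attached to
window scores (none exists in the source method); the genome rank is
the operative statistic.  The WAC-style low-range matrix bundled here
is a synthetic stand-in (clipped, floored BLOSUM62) with the documented
properties of the original table, whose numeric content is not
recoverable from text; users with the measured table can supply it as a
TSV.
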