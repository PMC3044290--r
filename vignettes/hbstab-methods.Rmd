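---
title: "Modelling hydrogen-bond stability with regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydrogen-bond stability with regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbstab)
```

## The model

A hydrogen bond is identified across a trajectory by its (donor, hydrogen,
acceptor) atom triple; its *occurrence* at tick $t_i = i\delta$ is the event
that the triple satisfies the geometric detection criteria in the
conformation at $t_i$. The quantity modelled is the probability that a bond
present now is present at an arbitrary instant within a horizon
$\Delta = l\,\delta$; its empirical counterpart, the **measured stability**,
is $y = m/l$ with $m$ the number of the next $l$ ticks at which the bond is
detected. $y$ is a count ratio: it lives on the grid $\{0, 1/l, \dots, 1\}$,
and rows whose future window is truncated by the end of the trajectory are
dropped rather than labelled on a shorter window (truncation would bias $y$
near the trajectory end; dropping loses $l$ ticks of data per bond).

The regressor $\sigma$ is a binary tree. At each node the split
$s = (p, r)$ tests $p < r$ for a numerical predictor or $p \in r$ for a
categorical one, and is chosen to maximise the variance reduction
$$w(s) \;=\; \operatorname{Var}(y) - \tfrac{n_L}{n}\operatorname{Var}(y_L)
  - \tfrac{n_R}{n}\operatorname{Var}(y_R),$$
with population variances. This per-sample convention (rather than raw SSE
reduction) was chosen deliberately: the importance measure
$\sum_{s \in N_p} w(s)\,n(s)$ then equals the SSE reduction contributed by
the nodes split on $p$, so the two definitions are mutually consistent.
Numerical candidate thresholds are midpoints between consecutive distinct
sorted values; categorical candidates are prefix subsets of the categories
sorted by mean response, which is provably optimal for least-squares binary
splits and avoids enumerating $2^{k-1}$ bipartitions (the exhaustive
enumeration survives as the test oracle). Ties are broken deterministically:
registry order, then smaller threshold or smaller subset.

Growth stops at depth 5 (root at depth 0), below 10 rows per node, or when
no split has positive score. Pruning sets aside a validation subset,
repeatedly collapses the intermediate node whose *growth-time* split score
is minimal (deepest first on ties), and returns the member of the resulting
tree sequence with the smallest validation mean square error, preferring
fewer nodes on ties. Whether the original procedure re-evaluated scores
after each collapse is not decidable from its description; freezing scores
at growth time makes the collapse order fully determined and reproducible,
and is flagged here as an interpretive choice.

## Predictors

Thirteen predictors are implemented: six geometric distances/angles
(`Dist_H_A`, `Dist_D_A`, `Dist_H_D`, `Dist_D_AA`, `Angle_D_H_A`,
`Angle_H_A_AA`; the acceptor antecedent AA is the acceptor's covalent heavy
neighbour, the one nearest the hydrogen if several); the Mayo-form energy
`FIRST_energy`; two environment counts (`Num_hb_spaceNbr`, other bonds
whose H&ndash;A midpoint lies within 5 &Aring; of this bond's midpoint, and
`Num_hb_spaceRgdNbr`, the same count restricted to bonds with energy
&le; &minus;1 kcal/mol); and four sequence-context predictors (`Ch_type`
&isin; {MM, MS, SM, SS}, `Range` = |&Delta;residue number| with a +1000
offset across chains, and the two residue names). The registry is
configurable and models work with any subset. The full attribute list of
the original study is longer but mostly unnamed; the implemented set covers
every named attribute.

Units are &Aring;ngstr&ouml;m, degrees, picoseconds and kcal/mol
throughout. The energy is
$E = V_0\,(5(R_0/R)^{12} - 6(R_0/R)^{10})\,F(\theta,\phi)$ with $R$ the
donor&ndash;acceptor distance, $V_0 = 8$ kcal/mol, $R_0 = 2.8$ &Aring;,
$\theta$ = Angle_D_H_A, $\phi$ = Angle_H_A_AA, and $F$ given by the four
donor/acceptor hybridization cases (sp3&ndash;sp3:
$\cos^2\theta\,e^{-(\pi-\theta)^6}\cos^2(\phi-109.5^\circ)$; sp3&ndash;sp2:
$\cos^2\theta\,e^{-(\pi-\theta)^6}\cos^2\phi$; sp2&ndash;sp3:
$\cos^4\theta\,e^{-2(\pi-\theta)^6}$; sp2&ndash;sp2:
$\cos^2\theta\,e^{-(\pi-\theta)^6}\cos^2(\max(\phi, 90^\circ))$). Two
simplifications are deliberate: the true sp2&ndash;sp2 term involves a
plane-normal angle that cannot be recovered from atom triples alone, so the
in-plane convention with a 90&deg; floor is used; and
`Num_hb_spaceRgdNbr`'s energy filter approximates rigid-cluster membership,
whose exact computation requires pebble-game rigidity analysis (out of
scope). $F$ is zero for $\theta < 90^\circ$ and $E$ is clamped to be
non-positive. Hybridization is a name-keyed lookup over common protein
donors/acceptors; unknown atoms default to sp3 with a warning.

Time-varying predictors are averaged over a **trailing** window of
$l' = 50$ ticks (truncated at the trajectory start). Trailing rather than
centred or leading: a centred window would leak future geometry into the
predictors of a row whose label is defined entirely by the future, which
would corrupt the train/test contract. Predictors are computed at every
tick, present or not, so windows are complete; only present ticks become
rows. Missing numerical values (e.g. angles of a degenerate geometry)
travel as sentinels that every split routes to the left child; missing
categorical values form the category `"NA"`; categories unseen at training
time route right.

## Evaluation

RMSE is normalised across tables by the **relative base error decrease**
$\mathrm{RBED} = 100\,(\mathrm{RMSE}(\sigma_0) -
\mathrm{RMSE}(\sigma))/\mathrm{RMSE}(\sigma_0)$, where $\sigma_0$ is either
the global mean stability of the training data or a tree grown from the
same data with `FIRST_energy` as the only predictor. (The defining formula
is typographically lost in the source text; this reconstruction matches its
verbal definition and reported magnitudes.) The **identification curve**
$w(u)$ takes $S$ = the $\lceil 0.10\,n\rceil$ occurrences of smallest
measured stability (ties broken by row order), ranks occurrences by
ascending predicted stability, and reports the fraction of $S$ among the
first $\lfloor u\,n\rfloor$; the ideal curve ranks by true $y$, and the
energy baseline ranks by decreasing energy value (weakest bonds first). The
leave-one-protein-out protocol mixes a fraction of each remaining table
(sampling per table, without replacement, $\lceil f n_j \rceil$ rows),
splits off a validation subset *by bond identity* (all rows of a bond land
on one side, preventing near-duplicate leakage between highly autocorrelated
rows of the same bond), trains, prunes, and evaluates on the held-out
table, repeating with derived sub-seeds to report mean and variance of
RBED.

## The synthetic world

`generate_trajectory()` emulates what the method needs from an MD
trajectory without simulating physics: isolated D&ndash;H&hellip;A&ndash;AA
clusters (> 20 &Aring; apart, so environment counts are exactly zero; a
crowded mode stacks clusters 4 &Aring; apart along z for known non-zero
counts) whose H&hellip;A distance follows a stationary AR(1) process around
a bond-specific equilibrium $\mu_k$ (default grid 2.0&ndash;3.0 &Aring;,
spanning the 2.5 &Aring; cutoff), with per-tick autocorrelation
$\rho = 0.9$ and stationary spread $s_k = 0.25$ &Aring; &mdash; the
simplest stationary process with tunable memory, mimicking the thermal
noise that $l'$-averaging targets.

Each bond draws its own equilibrium angles once:
$\theta_k \sim U(110^\circ, 168^\circ)$ for the donor&ndash;hydrogen&ndash;
acceptor angle and $\phi_k \sim U(100^\circ, 160^\circ)$ for the
antecedent angle, with 8&deg; per-tick jitter. This matters: if all bonds
shared one geometry, every distance predictor would be an equally clean
monotone proxy of $\mu_k$ and the root split would be a coin toss among
them (indeed, the trailing mean of the slightly convex transform
dist(D,A) then carries a spurious volatility signal that beats the direct
distance by a hair). Giving bonds independent angle regimes &mdash; as real
bonds have &mdash; makes the angle-contaminated predictors honestly noisy,
and the hydrogen&ndash;acceptor distance emerges as the most
differentiating predictor, as it should.

Per-tick $\theta$ is clipped to $[95^\circ, 174^\circ]$. With the
D&ndash;H distance fixed at 1.0 &Aring;, dist(D,A) =
$\sqrt{1 + d^2 - 2d\cos\theta} \le 3.495$ &Aring; whenever
$d = \mathrm{dist(H,A)} \le 2.5$ &Aring;, and the angle criterion holds
with margin, so ground-truth presence is *exactly* $d \le 2.5$ &mdash;
robust even to PDB coordinate rounding, because coordinates are pre-rounded
to the format's $10^{-3}$ &Aring; precision and the truth is computed from
the rounded values. This exactness is what lets the labelling tests demand
bit-identical $y$ end to end. The optional secondary driver assigns
alternating bonds a low antecedent-angle regime ($\phi \approx 95^\circ$)
whose distance fluctuation is inflated 2.5&times;, so true stability
depends on a second predictor beyond distance (larger antecedent angles
associate with more stable bonds, the direction reported for real
proteins).

What the generator does *not* emulate: force-field physics, solvent,
cooperative bond networks, correlated motions between bonds, and any
correlation between a bond's equilibrium distance and its equilibrium
angles. The last point is a known mirror limitation: in real MD data the
energy alone ranks stability moderately well, whereas in this decorrelated
world the energy-only baseline tree achieves near-zero RBED. A green
protocol test therefore establishes that the pipeline generalises across
synthetic "proteins" and that the full model beats the energy-only model
where stability has two drivers &mdash; not that the synthetic RBED values
match any particular real-data figure (the source trajectories are not
publicly deposited, so those figures are out of reach by construction).

`generate_table()` skips the structural layer entirely: i.i.d. predictor
vectors, an explicit threshold rule for the mean response, optional
Gaussian noise, clipping to $[0,1]$ and quantisation to multiples of $1/l$
(a measured stability is always a count ratio). It exists for rule-recovery
and pruning tests where the ground truth must be a tree.

## Numerical choices

* Population (biased) variance in scores; irrelevant to the argmax, fixed
  for reproducibility.
* A split must improve on zero score by more than $10^{-12}$; constant-$y$
  nodes therefore become leaves.
* Tree JSON uses 17 significant digits so predictions round-trip
  bit-for-bit (`digits = NA` in the installed jsonlite loses one digit).
* All randomness flows through explicit integer seeds; sub-seeds are drawn
  once from a master seed and stay below $2^{31}$. Reruns are byte-identical
  (the CLI test asserts this on the serialized model).
* Covalent topology is inferred on the first conformation only (sum of
  covalent radii + 0.4 &Aring;) and held fixed; bond topology does not
  change along a classical MD trajectory.
* The validation split requires &ge; 2 distinct bonds; a single-bond table
  is a hard error rather than a silent degenerate split.

## Known limitations

* Only the ~13 named attributes of the original 32 are implemented; the
  registry is extensible but models trained here are not exchangeable with
  models using the unnamed attributes.
* The Mayo sp2&ndash;sp2 case is simplified (see above); FIRST's exact
  "modified" Mayo potential is not public, so constants and cases follow
  the published Mayo form and are configurable.
* No hydrogen placement: trajectories must contain explicit hydrogens.
* Detection criteria are purely geometric; no energy cutoff is applied at
  detection time (the reference criteria may have used one &mdash; they are
  exposed as configuration rather than guessed).
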