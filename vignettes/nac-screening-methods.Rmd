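---
title: "Geometric NAC screening for enantioselective epoxide hydrolase design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric NAC screening for enantioselective epoxide hydrolase design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacscreen)
```

## The scientific problem

Limonene epoxide hydrolase (LEH) hydrolyses *meso*-epoxides by activating a
single water molecule for direct nucleophilic attack on one of the two
oxirane carbons.  Because the substrate is *meso*, the two attack
regiochemistries give enantiomeric diols: attack on one carbon yields the
(*R*,*R*)-diol (*proRR*), attack on the other the (*S*,*S*)-diol
(*proSS*).  The water is held by hydrogen bonds to Asn55 and Tyr53 while
Asp132 abstracts a proton and Asp101 protonates the epoxide oxygen.
Engineering enantioselectivity therefore reduces to engineering which
carbon sits in front of the activated water.

`nacscreen` implements the computational screening side of such a design
campaign.  Given conformational ensembles of the enzyme–substrate–water
active site (in practice from many short, independently initialised MD
trajectories per design — high-throughput multiple independent MD), every
frame is classified geometrically as *proRR*-reactive, *proSS*-reactive, or
non-reactive, and the replica-averaged frequencies of the two reactive
states predict the product enantiomeric excess.

## The near-attack-conformation model

A frame is a near-attack conformation (NAC) for attack mode $m$ with
attacked carbon $C_m$ when **all** of the following closed windows hold
(bounds inclusive; defaults in parentheses):

* attack distance $d_1 = |W_O - C_m|$ (0–3.22 Å),
* attack angle $\theta_{1A} = \angle(W_O, C_m, O_{epox})$ (128–163°),
* second attack angle $\theta_{1B} = \angle(W_O, C_m, C_{other})$
  (128–163°),
* five catalytic hydrogen bonds at donor–acceptor distance 0–3.50 Å
  (and, in explicit-hydrogen mode, donor–H–acceptor angle 120–180°).

The two mode flags are evaluated independently; no mutual exclusion is
imposed, because the two frequencies enter the predictor independently.

Design decisions where the convention was genuinely open:

* **$\theta_{1B}$** is taken as the angle at the attacked carbon between
  the water and the *other* oxirane carbon — the second substituent
  direction at the reacting centre, approximating backside-attack geometry.
  It is configurable in `nac_definition()`.
* **The five H-bond pairs** are not individually enumerated in the
  published criteria; the packaged default is the catalytic contact set
  (epoxide O to both Asp101 carboxylate oxygens; water O to Asp132, Tyr53
  and Asn55).  The set is config-driven.
* **Heavy-atom H-bond mode is the default**: it checks only the
  donor–acceptor distance window, so unprotonated models can be scored.
  An explicit-hydrogen mode measures the donor–H–acceptor angle window as
  well.  Which convention the original screening used is not recorded;
  both are supported.

Note a geometric coupling worth knowing when configuring windows: the two
attack angles share the ~59° epoxide ring angle at the attacked carbon, so
$\theta_{1A} + \theta_{1B} \lesssim 301°$.  Window combinations violating
this are detected by the generator and rejected as infeasible.

## The enantioselectivity predictor

With $[NAC]_{proRR}$ and $[NAC]_{proSS}$ the replica-averaged percentages
of frames in each reactive state,

$$ee^{pred} = 100 \cdot
  \frac{[NAC]_{proRR} - [NAC]_{proSS}}{[NAC]_{proRR} + [NAC]_{proSS}}$$

Positive values predict (*R*,*R*)-diol preference, negative (*S*,*S*).
Replica aggregation is the unweighted mean of per-replica frequencies
(identical to pooled counting for equal-length replicas; both are
reported).  Table output rounds to the nearest integer percent, half away
from zero; the unrounded value is retained internally.  When both
frequencies are zero the selectivity is *undefined* and `predict_ee()`
raises an error rather than silently returning 0; the cascade treats such
designs as failing the round.

```{r}
st <- list(freq_RR = 3.86, freq_SS = 0.040)
predict_ee(st)
```

## The elimination cascade

Screening thousands of primary designs with a full MD budget each is
wasteful; instead designs are eliminated as soon as they fail a criterion
under a growing budget.  `default_cascade_config()` encodes the published
scheme: 5, 10, 20, 40 and 80 cumulative 10-ps replicas with ee thresholds
97/97/97/98/98 %, a `[NAC]pref` threshold at the 80-replica round (5 % for
the small epoxides, 10 % for *cis*-stilbene oxide), and a final standalone
round of five 100-ps replicas at ee > 98 % (`[NAC]pref` > 5 % for
stilbene oxide).  Thresholds are strict inequalities, read literally from
the published criteria, and the surviving design's predicted sign must
match its target enantiomer.

Two semantics were open and are fixed as follows: 10-ps rounds are
**cumulative** (later rounds extend and re-use the earlier replicas — the
provider contract requires earlier replicas to be returned unchanged as a
prefix), while the 100-ps round is evaluated on its own replicas.  This
makes survivor sets nested by construction for fixed trajectories.

Ranking for experimental characterisation (`select_top_designs()`) keeps
candidates with the correct sign and sufficient $|ee^{pred}|$ and orders
them by `[NAC]pref` descending, ties broken by $|ee^{pred}|$, then design
id.

## Cavity-volume triage

Designs that carve out too much active-site volume tend to be too spacious
and catalytically poor.  `delta_cavity_volume()` sums
$V_{wt} - V_{new}$ over a design's mutations and flags designs exceeding
a 100 Å³ enlargement.  The packaged table is the Chothia (1975) mean
residue volume set; since every mutation delta subtracts two residue
volumes, the backbone contribution cancels and the deltas equal side-chain
volume differences.  The volume table behind the originally published
per-design values is not recorded, so different tables shift deltas by
tens of Å³ (with this table the 46C design set gives +40 Å³ and the 60A
set +92 Å³); the table is therefore an explicit, overridable argument.

## The synthetic-ensemble generator

Real MD trajectories for this system are not distributable, so the package
ships a generator that emulates exactly the features the screening
statistics depend on — and nothing else:

* **Replica structure.**  Each design gets `n_replicas` independently
  seeded replicas (default 5 × 10 ps, matching the first screening round).
  Replica `r` draws from substream `(seed * 48271 + r * 9973) mod
  (2^31 - 2) + 1` of the master seed, so a replica never changes when more
  replicas are requested — the property the cumulative cascade relies on.
* **Hidden-state process.**  Frame states follow a 3-state Markov chain
  with stationary distribution $(p_{RR}, p_{SS}, 1 - p_{RR} - p_{SS})$ and
  a single self-transition (persistence) parameter; persistence 0 (the
  default) gives i.i.d. frames.  This emulates the short-window temporal
  correlation of 10-ps MD without any physics.
* **Inverse geometry.**  Only the nine catalytic role atoms are placed, in
  an abstract active-site frame (epoxide triangle with C–C 1.47 Å and
  C–O 1.43 Å).  For a reactive state the water position is sampled
  uniformly in $(d_1, \theta_{1A}, \theta_{1B})$ inside the windows,
  rejecting draws that fall inside the other mode's distance window;
  H-bond acceptors are sampled in the upper 30 % of the distance window
  around their donors (the lower part would mean steric overlap).
  Non-reactive frames displace the water 1.5–5 Å beyond the attack-distance
  window.  At zero geometric noise, classification recovers the intended
  state label with probability 1 — the round-trip property the tests
  verify on 1000 frames.
* **Frame interval.**  Default 0.005 ps.  NACs in the original protocol
  are counted "on the fly", i.e. at essentially every integration step;
  5 fs sampling reproduces that counting density at tractable cost.  The
  binomial error of a NAC frequency estimated from $n$ frames is
  $\sqrt{p(1-p)/n}$, so the choice of interval trades runtime against
  threshold sharpness near the cascade's 97–98 % ee cuts.

What the generator does **not** emulate: force-field physics, barrier
crossing kinetics, solvent, correlated geometric distortions, or Rosetta
energies.  Passing tests on synthetic ensembles therefore demonstrate the
correctness of the counting, averaging, prediction and elimination
machinery under known ground truth — not the accuracy of MD itself.

## Numerical and degenerate-input choices

* All interval bounds are inclusive; ties at a threshold ("ee > 97")
  eliminate, since the inequality is strict.
* `angle3d()` clamps cosines to $[-1, 1]$ before `acos`; zero-length arms
  and non-finite coordinates are domain errors.
* The static pose validator checks the designed (pre-MD) geometry: water
  1.8 Å from the attacked carbon (tolerance ±0.4 Å, this package's
  choice), attack angle within ±15° of 180° (the published restraint says
  only "close to 180°"), water > 3.8 Å from the non-attacked carbon, and
  the four catalytic H-bonds formed.  Note the first and third restraints
  cannot hold simultaneously on a rigid epoxide (1.8 + 1.47 < 3.8): the
  validator deliberately scores each restraint independently as pure
  geometry.
* Michaelis–Menten fits use Levenberg–Marquardt with $V_{max,0} = \max v$
  and $K_{M,0} = S$ at half-maximal velocity; a fitted $K_M$ with relative
  standard error above 50 % or below half the smallest measured
  concentration is flagged as poorly identified (the classic
  $S \gg K_M$ symptom).  $K_M$ is stored in mM and the specificity
  constant reported in M⁻¹ s⁻¹.

## Problem sizes used in the tests

The statistical tests run at deliberately chosen sizes: frequency-estimator
checks at 5–80 replicas × 100 frames against 3σ binomial bounds; the
Markov-chain stationarity check at one replica of 10⁴ frames against the
$\pi(1-\pi)(1+\rho)/(1-\rho)/L$ CLT variance; the planted-library cascade
at 100 designs (20 separable at $p_{RR} = 15\,\%, p_{SS} = 0.1\,\%$ among
80 unselective at 5 %/5 %) under the full six-round scheme with a uniform
97 % ee threshold, where the separable designs' true ee of 98.7 % gives a
comfortable margin at the default 5 fs frame interval; and
Michaelis–Menten recovery over 100 seeds at 5 % multiplicative noise.

## Known limitations

* The geometric criteria are a binary window product; no energetic
  weighting of near-misses, no H-bond energy model, no automated
  protonation.
* The predictor is frequency-ratio based and carries no information about
  absolute rates; experimentally, designs with fine NAC statistics can
  still have poor $k_{cat}$, particularly for bulky aromatic substrates
  where π–π interactions (not modelled here or in the underlying MD) help
  determine positioning.
* The PDB reader supports the fixed-column `ATOM`/`HETATM` +
  `MODEL`/`ENDMDL` subset needed for active-site trajectories; it is not a
  general PDB chemistry perceiver, and binary trajectory formats are out
  of scope.
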