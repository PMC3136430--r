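---
title: "Double-well Gō models of open/closed transitions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-well Go models of open/closed transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dwgo` studies proteins with two functional conformations — an open (O) and
a closed (C) state, typically two lobes that close over a hinge when a
ligand binds. Each reference conformation defines a single-well C-alpha Gō
potential: the attractive interactions are exactly the native contacts of
that conformation, so that conformation is the potential's minimum. The two
wells are then combined by exponential averaging,

$$E(x) = -\frac{1}{\beta_{mix}}
  \ln\!\left[e^{-\beta_{mix}(E_O(x)+\varepsilon_O)} +
             e^{-\beta_{mix} E_C(x)}\right],$$

which produces a smooth two-state landscape with two independent dials:
$\varepsilon_O$ (kcal/mol) shifts the relative stability of the open state,
and $\beta_{mix}$ (mol/kcal) sets how sharply the wells join — large values
approach $\min(E_O+\varepsilon_O, E_C)$ and a high, cuspy barrier; small
values blend the wells and smooth the barrier. Because both wells are
evaluated at every configuration, the mixed force is the weight-averaged
single-well force with softmax weights, and the per-frame pair
$(E_O, E_C)$ is stored so the mixed energy at any other $\varepsilon_O$ can
be recomputed exactly afterwards (the basis of the calibration below).

### Terms of each single-well potential

* **Bonds**: harmonic about the native consecutive C-alpha distances
  ($k_b$ = 100 kcal/mol/Å²).
* **Angles**: a generic double-basin pseudo-bond-angle potential,
  $-\varepsilon_a\ln(g_{92^\circ}+g_{130^\circ})$ with Gaussian basins of
  width 15° and $\varepsilon_a$ = 2 kcal/mol, permitting both helix-like
  and extended local geometry. This term is deliberately *not* native-biased,
  which is what allows local unfolding.
* **Dihedrals**: per-quadruple cosine series
  $k_d[1-\cos\Delta\phi] + \tfrac{1}{2}k_d[1-\cos 3\Delta\phi]$ with the
  minimum at that conformation's native torsion ($k_d$ = 0.5 kcal/mol).
  Per-residue stiffness multipliers emulate backbone-flexibility mutations
  at C-alpha resolution (glycine-like 0.2, proline-like 5); a dihedral's
  depth is the base depth times the product over its four residues, so a
  single edit softens or stiffens the four torsions that involve it.
* **Native contacts**: the 12-10-6 well
  $\varepsilon[13 x^{12} - 18 x^{10} + 4 x^6]$, $x = r_0/r$, with minimum
  $-\varepsilon$ at the native distance $r_0$ and a small desolvation-like
  barrier on the way out.
* **Excluded volume**: $\varepsilon_{rep}(\sigma/r)^{12}$ for non-native
  pairs with $\sigma$ = 4 Å, shifted to zero at $3\sigma$.

Contacts are all residue pairs with $|i-j|\ge 3$ and C-alpha distance
$\le 8$ Å, each carrying the same base depth (0.45 kcal/mol) times a global
contact scale of 2.5. This is a documented simplification of all-atom
contact-energy assignment: the analyses downstream depend on contact
topology and relative energies, and a per-contact energy table can be
injected through the `contacts` argument to restore heterogeneity. The
uniform scale is applied identically to both wells so that equivalent
residue pairs interact identically in either conformation; setting it to 1
gives the unscaled "weak" control. Ligand binding is modelled by adding a
few *ligand-mediated contacts* — pairs bridging the closed interdomain
interface — to the closed-state contact list only.

Shared contacts whose native distances differ between the references use
their own per-well distance inside each single-well potential, so each well
keeps its minimum at its own reference.

## Dynamics

Sampling uses BAOAB-split Langevin dynamics in the compiled core. Any
quantitatively correct Langevin scheme would do; BAOAB was chosen for its
configurational accuracy at large time steps. Defaults: 15-fs time step,
friction 0.2 ps⁻¹ (low, to speed barrier crossing), bead mass 110 g/mol.
The mass is the mean amino-acid residue mass rather than a unit reduced
mass: with the 15-fs step and the bond stiffness above, a unit mass would
put the bond period near two time steps and the integrator would be
unstable, while 110 g/mol yields a ~320-fs bond period and a ~2%
configurational error on the stiffest mode. Trajectories are
bit-reproducible for a fixed seed; an energy-divergence guard (|E| > 10⁶)
aborts with the failing step. Internally the code works in
kcal/mol–Å–g/mol units (time unit ≈ 48.9 fs).

## Reaction coordinates and ensembles

Frames are projected onto $Q_O$ and $Q_C$ — the fraction of contacts
*unique* to the open/closed reference formed in the frame, a contact
counting as formed within 1.1× its native distance — plus $Q_{O,all}$,
$Q_{C,all}$ (shared contacts included), superposed RMSDs to either
reference, and interdomain center-of-mass distances. Residue ranges listed
in a structure's exclusion list (e.g. helices that connect two domains and
would blur their separation) are omitted from that domain's center of mass.
For shared contacts in $Q_{*,all}$ the formation criterion uses the native
distance of the well being scored by default (config flag `shared_native`
switches to the other well's distance; the choice is not dictated by the
method and matters only for the few interface contacts whose distances
differ).

The closed basin is the high-$Q_C$ mode of the $Q_C$ histogram; the open
basin is the *first* (lowest-$Q_C$) local maximum — identification through
$Q_C$ is robust when the wells overlap along $Q_O$. Core radii extend to
the nearest intervening histogram minimum (floor: two bin widths), and the
bin count never exceeds the number of distinct values the coordinate can
take ($k$ contacts give a lattice of $k+1$ levels). A reactive transition
path runs from the last frame inside one core to the first frame inside the
other with no intermediate return; excursions that re-enter their origin
core are discarded.

The separatrix is the line $Q_C = m\,Q_O + b$ (slope grid $[-3,3]$ in 61
steps, intercepts spanning the data, both configurable) that maximises
$p_{TP}$: the fraction of frames within a band of the line that lie on
reactive paths. Candidate lines must put the two basin centers on opposite
sides. The band half-width defaults to 0.02 in Q units for continuous
coordinates; when the coordinates live on a coarse contact lattice the band
adapts to a little over half the lattice spacing, so a band can actually
capture a lattice column. For diffusive dynamics $p_{TP}\le 0.5$; the toy
system typically yields 0.2–0.3.

TS frames are those inside the band *and* on a reactive path, keeping the
crossing direction; all remaining frames are labelled O or C by their side
of the line, and $K_{eq} = N_C/N_O$ over those frames (a config switch
restricts counting to basin cores). TS statistics are reported as the
unweighted mean of the closing- and opening-direction values, and an empty
ensemble propagates as missing — never as zero, which would fabricate
difference signals.

### Calibrating $\varepsilon_O$

`calibrate()` alternates simulation and exponential reweighting: the stored
per-frame $(E_O, E_C)$ let it predict $K_{eq}$ at any trial
$\varepsilon_O'$ by reweighting each frame with
$\exp[-\beta(E'(x)-E(x))]$, and a root-find on the pooled prediction across
all calibration runs (each reweighted from the $\varepsilon_O$ it was
generated at) proposes the next offset. Pooling matters: single-run
$K_{eq}$ estimates at desk scale carry 20–35% noise, and a secant update on
individual runs oscillates. The loop stops when a fresh simulation measures
$K_{eq}$ within a stated relative tolerance of the target (default ±25%,
reflecting the stochastic spread of repeat runs).

## The synthetic two-state system

`make_toy_two_state()` builds a chain of two ideal α-helix-like C-alpha
spirals (1.5 Å rise, 100°/residue, radius chosen for exact 3.8 Å virtual
bonds) joined by a three-residue hinge. The closed conformation differs
from the open one only by a rigid rotation of the second lobe about the
hinge, so lobe-internal contacts are shared by construction. The hinge axis
*precesses* with the bend (azimuth 120° + 2.5° per degree of bend): closure
engages a different face of the first lobe than partial opening, a
closing-with-twist motion that gives *both* end states their own unique
interface contacts (defaults 100°/55° yield 7 O-unique and 8 C-unique
contacts and no steric clash). A conformation depends only on its hinge
angle, so equal angles produce bitwise-identical structures. Seeded
Gaussian jitter (0.05 Å, with bond lengths re-regularised) decorates the
shared base spiral; the geometry is otherwise deterministic. Ligand
pseudo-contacts are the three shortest closed-state inter-lobe pairs that
are not already native contacts — a deterministic stand-in for substrate
bridging of the closed interface.

The toy's default operating point — contact depth 0.45 kcal/mol × 2.5,
$\beta_{mix}$ = 0.1 mol/kcal, 300 K, $\varepsilon_O \approx 3.8$ kcal/mol —
was calibrated once, like any study system: it gives genuine bimodality in
$Q_C$, a few hundred well-to-well crossings per 10⁶ steps, $p_{TP}$ within
the diffusive bound, and a closed/open ratio near the standard calibration
target of 4. Two honest costs of that choice: the closed basin holds
$Q_{C,all}\approx 0.75$ (a strongly folded real protein sits nearer 0.9 —
the toy trades some foldedness for transition statistics), and the measured
equilibrium ratio still fluctuates by ~20–35% between multi-million-step
runs because the lobes exchange through long-lived interface substates.
Tests and the reproduction script therefore average over several seeds.
Raising the temperature much beyond 300 K is not a usable shortcut: near
330 K the toy begins to melt, and entire runs can wander as a disordered
coil. What passing tests on the toy do *not* show: that the simplified
uniform contact energies reproduce any particular real protein's
flexibility pattern; they validate the machinery, not a parameterisation.

The 1-D overdamped double well ($V = h[(x/a)^2-1]^2$, Euler–Maruyama,
kT = 1) provides an exactly controlled reference for basin finding,
transition-path extraction and the $p_{TP}\le 0.5$ bound, independent of
the molecular machinery.

## Per-residue and per-contact statistics

For each interior residue the pseudodihedral $\alpha$ (torsion over
C-alphas $i-2,i-1,i,i+1$, assigned to residue $i$, wrapped to
$(-180°,180°]$) is compared against a native reference: if the open and
closed native values differ by less than 20° the reference is their
circular midpoint; otherwise three candidates are used (O value, C value,
midpoint) and the best within-window fraction is taken. `p_folded` uses a
60° window; `p_rigid` uses 20°. Contact probabilities are per-ensemble
formation fractions under the same 1.1× criterion. Contacts are
O-characteristic when $p_O - p_C \ge 0.2$ (C-characteristic symmetrically);
display conventions follow the standard figures: only contacts with
$\max(p_O,p_C)\ge 0.5$ are drawn, binned by $p_{TS}$ at 0.5 and 0.7, and
difference maps show $|\Delta p| \ge 0.1$ (inclusive, with a 10⁻⁹ float
guard) for contacts characteristic in either simulation. Variants —
heated, stiffness-edited, contact-edited — are plain configuration diffs;
`compare_runs(perturbed, reference)` subtracts in that order.

## Potentials of mean force

PMFs are raw histograms of the equilibrium trajectory,
$F = -k_BT\ln(n/n_{max})$, min-shifted to zero, with no reweighting (the
simulation samples the mixed potential directly). Defaults: 40 bins per
axis over the observed range padded 2%; empty bins are `NA`, never
interpolated. The construction identity
$F_i - F_j = -k_BT\ln(n_i/n_j)$ holds bin-by-bin by definition and is
tested as such.

## Numerical choices and degenerate inputs

* Angle wrapping is $(-180°, 180°]$ everywhere, with minimal-image angular
  distances; collinear torsion quadruples yield `NA` for that frame.
* Superposition is Kabsch/SVD with a collinearity guard; RMSD is reported
  over the fitted selection.
* Mixing is evaluated with the log-sum-exp shift, so extreme
  $\beta_{mix}|E_O - E_C|$ cannot overflow.
* Separatrix ties resolve to the first grid line found; a degenerate or
  unimodal $Q_C$ distribution is an explicit error advising recalibration
  rather than a silent partition.
* `K_eq` with an empty open ensemble is `NA` with a warning, not infinity.

## Problem sizes used in the tests

The test-suite fixture is a 44-residue toy sampled for 4 × 10⁵ steps; the
end-to-end check uses a 10⁶-step run and the calibration-recovery check
2 × 10⁶-step runs; the reproduction script calibrates on 3 × 10⁶-step runs
and averages three 7 × 10⁶-step productions. These sizes give a few hundred
transitions per production run, which is what the ±25% calibration
tolerance assumes.

## Known limitations

C-alpha resolution blurs side-chain packing: individual contact
probabilities are indicative at the level of contact clusters, not single
pairs. The uniform contact-depth simplification ignores the energetic
heterogeneity a full contact-energy assignment would provide. Mutations
enter only as stiffness/contact edits, not as re-minimised structures, so
mean-structure shifts caused by real mutations are out of scope. No
replica exchange or umbrella sampling is provided; systems whose two states
exchange much slower than the toy will need externally longer runs.
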