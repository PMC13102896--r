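---
title: "Virtual patient databases from a 0D-1D cardiovascular digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual patient databases from a 0D-1D cardiovascular digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiovpd)
```

## What the package computes

`cardiovpd` synthesises *virtual patient databases* (VPDs): cohorts of
simulated cardiovascular systems ("digital twins"), each defined by a
sampled parameter set, each evaluated by a coupled 0D-1D hemodynamic
simulation, and each summarised by eleven physiological quantities of
interest (QOIs): radial, aortic and carotid systolic/diastolic
pressures, cardiac output, and four diagnostic pulse wave velocities
(aortic, carotid-femoral, brachial-radial, femoral-ankle). Cohorts are
then *resampled* against literature target distributions to remove
physiologically implausible members, and stratified into sex and age
classes by a moment-matching assignment.

The intended use is methodological: in-silico trial populations,
training data for waveform-based machine learning, and boundary-condition
ensembles for 3D simulations.

## The hemodynamic model

### 1D pulse-wave model

Each artery is a tapered elastic tube governed by the 1D continuity and
momentum equations

$$\partial_t A + \partial_x q = 0, \qquad
  \partial_t q + \partial_x\!\left(\frac{q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x p = -K_R\,\frac{q}{A},$$

with lumen area $A$, volumetric flow $q$, blood density $\rho$
(1055 kg/m³) and a Poiseuille-type friction coefficient
$K_R = 2(\gamma + 2)\pi\nu$. The velocity-profile constant defaults to
$\gamma = 9$ (a flat profile, the common choice for large arteries);
it is configurable in the reference file.

The system is closed by the Olufsen elastic wall law

$$p(A) = p_0 + \tfrac{4}{3}\,\frac{Eh}{r_0}
         \left(1 - \sqrt{A_0/A}\right), \qquad
  \frac{Eh}{r_0} = k_1 e^{k_2 r_0} + k_3,$$

which makes the local pulse wave speed
$c = \sqrt{(2/3\rho)\,(Eh/r_0)\,(A_0/A)^{1/2}}$ depend on the stiffness
but *not* on the absolute lumen area: central arteries can be given a
generous cross-section (adding volume compliance where the reduced tree
omits whole vascular territories) without altering wave speeds.

Interior grid nodes advance with the explicit MacCormack
predictor-corrector (forward-difference predictor, backward-difference
corrector, averaged), which is second-order for smooth pulse waves.
The time step obeys the CFL bound
$\Delta t = s\,\min_i \Delta x_i/(|u_i| + c_i)$ with safety $s = 0.5$
evaluated at the warm-start state plus a fixed 2 m/s convective
allowance; for this wall law $c$ *decreases* with distension, so the
bound evaluated near the diastolic state holds throughout the beat.

### Boundary closure by characteristics

At every segment end the outgoing characteristic of the hyperbolic
system is linearised at its foot (located one time step back along
$dx/dt = u \pm c$ and interpolated quadratically from the three nodes
nearest the boundary), producing one linear relation
$p_b = W \pm Z_c q_b$ between boundary pressure and flow. That relation
is solved simultaneously with the attached 0D element:

* **Junctions** - mass is conserved exactly and each branch sees the
  junction pressure through half the nodal resistance, so a two-branch
  junction drops $R_{node} q$ end to end. With all characteristic
  relations linearised the junction reduces to a closed-form nodal
  pressure; conservation holds to machine precision by construction.
* **Peripheral beds** - four RLC compartments (arteriolar, capillary,
  venular, venous). Each compartment is a capacitor node followed by a
  series R-L branch; the arteriolar capacitor sits directly at the 1D
  interface (the classic Windkessel placement) and the venous branch
  drains to a fixed venous pressure. The exact wiring inside
  lumped peripheral models is rarely published; this one is documented
  here and encoded in one place (`bed_step`). Compartment resistance
  ratios are fixed (0.40/0.30/0.20/0.10) and the RC and L/R time
  constants are held invariant when a patient's resistance factors are
  scaled, so resistance scaling never changes the bed's time response.
  The first-compartment RC time is a per-terminal property of the
  topology: visceral and proximal-limb beds carry large values (they
  lump the compliance of vasculature the reduced tree omits), distal
  limb beds small ones (so wrist and ankle sites keep their
  physiological pulse amplification).
* **Coronary bed** - same structure, with the arteriolar and capillary
  elements modulated by normalised left-ventricular pressure
  $n(t) = \mathrm{clip}(p_{lv}/p_{norm}, 0, 1)$:
  $R_i(t) = R_i\,(1 + \alpha\,n)$ and $C_i(t) = C_i\,(1 + \beta\,n)$.
  The capacitor update conserves charge,
  $(C^{new}\pi^{new} - C^{old}\pi^{old})/\Delta t = q_{in} - q_{out}$;
  the $\pi\,dC/dt$ part of that update *is* the intramyocardial pumping
  term, and discretising $C\,d\pi/dt$ instead silently injects volume
  (we measured a 6.7% per-cycle imbalance before adopting the
  charge-conserving form).
* **Heart** - both ventricles share a normalised double-cosine
  elastance waveform (rise fraction 0.35 of the period, relaxation
  0.19) scaled between their minimal and maximal elastances; the left
  atrium is a constant-elastance reservoir; the right atrium holds a
  constant pressure; the pulmonary circulation is one RC stage whose
  R·C product is invariant under patient scaling. The four valves are
  ideal diodes with series resistance and inertance, handled by flag
  switching inside the implicit step (open valves closing on reverse
  flow, closed valves opening on positive pressure drop, iterated to a
  consistent state). All 0D states advance by backward Euler inside a
  small dense linear solve per step - with the characteristic relation
  frozen at its foot, the per-step system is linear and the Newton
  iteration reduces to the valve-state fixed point.

The atrioventricular valves are given a much smaller resistance
(5×10⁵ Pa s/m³) than the arterial valves (2.5×10⁶). Besides being
physiological, this matters dynamically: with slow diastolic filling
the end-diastolic volume becomes history-dependent and the beat-to-beat
map can settle into a period-2 alternation (the model analogue of
pulsus alternans) that never meets the periodicity criterion. Fast
filling plus a damping arterial valve keeps the beat-to-beat map
contractive.

### Periodicity

A run repeats cardiac cycles until the relative L2 difference of the
aortic-root pressure between consecutive cycles falls below `1e-3`
(default), up to 40 cycles. The shipped reference patient needs about
29 cycles from the warm start (tree initialised at 90 mmHg, beds at
their steady operating point); pathological parameter draws either
diverge quickly (flagged, with a reason, never an R error) or fail the
periodicity criterion. All QOIs are extracted from the final converged
cycle only.

## The reference patient and the 17 factors

Every digital twin is defined by 17 dimensionless factors multiplying a
tuned reference configuration: vessel diameter `D`, length `l`, nodal
resistance `R_node`, wall coefficients `k1 k2 k3`, peripheral
resistance `R_perif`, right-atrial pressure `V_ra`, ventricular
elastances `E_min E_max`, atrial elastance `E_la`, valve factor `R_h`
(resistance and inertance together), heart rate `HR`, pulmonary
resistance `R_p` (capacitance reciprocal), coronary resistance `R_c`
(capacitance reciprocal) and the coronary modulation amplitudes
`alpha_c beta_c`. The vessel-related factors (`D l R_perif R_node`)
compose with an additive per-body-location offset:

$$D_{DT} = (D + D_{bl})\,D_{ref},$$

where $D_{bl} \sim N(0, 0.15\,\sigma_D)$ is drawn once per patient per
body location (arms, legs, spine, coronaries, brain, face, trunk), so
e.g. all arm vessels of one patient share a proportion while arms and
legs vary independently. The composition is literal - factor plus
offset, then multiplication - so a +x and a -x offset average back to
the reference exactly.

Factor distributions default to: normal for most factors, lognormal
(moment-matched on the factor scale, since the table lists plain
mean/sd pairs) for the resistance factors `R_perif`, `R_node`, `R_c`
whose spreads are widest and must stay positive. The defaults are the
study conditions of the package's acceptance runs; see
`distribution_spec()`.

The reference configuration itself (`default_reference()`) was tuned
with the package's own `sensitivity_matrix()` helper, iterating the
published calibration loop: simulate, compare against the population
targets, adjust, including small test cohorts to check where the
*population* lands. The mean-factor patient on the reduced tree reads
aortic 111/65 mmHg, radial 114/61, cardiac output 4.47 l/min, aortic
PWV 7.8 m/s. The pressures sit deliberately below the population
averages because both the stochastic sampling and the closest-match
resampling shift the cohort upwards (the hypotensive tail of the
cohort is unmatchable, so matching consumes upper-half patients); what
is calibrated to the literature is the resampled database, whose
aortic moments land near 118/71 mmHg with aortic PWV centred on
7.6 m/s. Users fitting a different topology should re-run the
sensitivity helper and adjust the reference file; the matrix
quantifies the percent change of each QOI per percent change of each
factor (central differences at 1%).

## The reduced arterial tree

The shipped topology (`fixture_tree()`) is a deliberately reduced
21-segment tree: aortic trunk, one carotid with internal/external
branches, a right-arm brachial-radial-ulnar path, left subclavian,
one coronary branch, celiac and renal branches, and both iliacs with a
right-leg femoral-tibial path. It exists so that all seven measurement
sites (aortic root, carotid, brachial, radial, femoral, ankle, distal
aorta) and every body-location tag are present; it is *not* an
anatomical atlas. Two deliberate distortions compensate for the missing
vasculature: central vessels are wider than anatomical (volume
compliance; wave speeds unaffected, see above) and terminal flow
fractions route only ~2% of cardiac output through the single radial,
ulnar and tibial vessels (a real limb drains through several parallel
arteries). Substitute a full anatomical tree through the same topology
file format (`read_topology()`) for anatomical studies.

## Quantities of interest

Pressure extrema are the minimum and maximum of the final-cycle series
at a site, in mmHg. Cardiac output is the cycle-mean aortic root flow
in ml/min. Pulse wave velocity divides the centerline path length
between two sites by the foot-to-foot transit time; feet are located by
the intersecting-tangent method (intersection of the diastolic
horizontal with the tangent at maximal upstroke slope), with a
minimum-point variant available (`wave_foot(method = "minimum")`).
Transit times are computed cyclically, so the extraction is invariant
to the phase origin of the stored cycle. The aortic PWV path runs from
the aortic root to the distal-aorta site; the carotid-femoral path is
the centerline distance through the arch, which (as in clinical
practice) makes cf-PWV read higher than the true aortic wave speed.

## Cohort, resampling, demographics

`build_cohort()` draws N parameter sets, rejects draws whose composed
physical parameters are non-positive *before* simulation, runs the
rest, and returns a QOI table plus a manifest whose counts always
reconcile (requested = rejected + failed + completed). All randomness
derives from one seed and the simulations are deterministic, so results
are identical for any worker count.

`resample_vpd()` implements the literature-guided reduction: for each
QOI an independent synthetic "literature dataset" of size
$N_l \le N_0$ is drawn from the target normal; each literature value is
matched to the nearest not-yet-matched cohort value (ascending order,
ties to the lower index - matching *without replacement*, otherwise one
cohort member could absorb arbitrarily many literature values and the
match-count bookkeeping $\sum_j K_j = 11 N_l$ would fail); a patient
survives if it was matched in at least $K_{th}$ of the 11 QOIs. The
defaults $N_l = 0.75\,N_0$, $K_{th} = 8$ are the published working
point. The scalar score
$F^{rs} = \sum_i |\Delta\sigma_i/\sigma_{l,i}| + |\Delta\mu_i/\mu_{l,i}|$
quantifies the moment agreement before and after.

`classify_vpd()` assigns sex (two groups) and age (six bins: -30,
30-40, 40-50, 50-60, 60-70, 70+) labels in two steps: nearest-group
initialisation by the scaled distance
$F^{DT}_j = \sum_i |\mu'_{ji} - m_i|/\sigma'_{ji}$, then greedy
first-improvement descent of the population objective

$$F^{vpd} = S + \sum_{j}\sum_i
  \left(\frac{\mu_{ji}-\mu'_{ji}}{\mu'_{ji}}\right)^2 +
  \left(\frac{\sigma_{ji}-\sigma'_{ji}}{\sigma'_{ji}}\right)^2,$$

sweeping patients in a seeded random order and also offering a
*no-data* class penalised by $S = s_{coef} N_{nd}$ (defaults:
1/50,000 per member for sex, 0 for age). Sweep order,
first-improvement acceptance and the seed are fixed because
best-improvement or a different order changes the local optimum.
Moves that would leave a group with a single member are disallowed;
this is also the guard that keeps the $s_{coef} = 0$ age setting from
degenerating (with a zero penalty, emptying whole groups into no-data
can only be blocked structurally). Group moment updates are incremental
(count/sum/sum-of-squares per group and QOI) and agree with full
recomputation to 1e-9.

Three properties of this refinement are worth knowing. First, the
objective strictly decreases over accepted moves and terminates.
Second, the refinement optimises *group moment agreement*, not
individual label correctness: on synthetic mixtures with known labels
the nearest-group initialisation is already close to the optimal
decision rule, and descending $F^{vpd}$ further tends to shuffle
overlap members symmetrically - it reliably improves the objective but
not, in our experiments, the fraction of correctly recovered labels.
Treat the labels as population-level strata, not per-patient truth.
Third, the objective contains no order constraint between groups: when
the cohort cannot populate the outermost group targets (e.g. a
moderate-sized cohort whose PWV spread is narrower than the span of
the age-bin targets), the greedy optimum can swap the means of
adjacent upper bins even though the nearest-target initialisation was
perfectly ordered. On large cohorts whose spread covers the targets
the published increasing age trends are reproduced; on small ones,
check `group_moments()` before relying on the ordering.

### Demographic target tables

The shipped `group_targets()` tables are **synthetic fixtures**, not
transcriptions of any study appendix: they encode the qualitative
population trends reported for aging and sex (all four PWVs rising
roughly linearly with age - aortic PWV about 6.3 m/s below 30 to
8.8 m/s above 70 - systolic pressure rising, diastolic falling,
cardiac output drifting down; males with slightly higher diastolic
pressure and higher brachial-radial/femoral-ankle PWV, females with
larger pressure spreads). Supply your own table via
`read_group_targets()` for any application where the absolute group
values matter.

## What the synthetic data generator does and does not emulate

The sampled cohorts emulate: physiological between-subject variability
through the 17-factor scaling of one tuned reference; body-proportion
variability through the per-location offsets; measurement-site
diversity of pressure and PWV; the long right tail of resistance
parameters. They do not emulate: correlations between factors (all 17
are sampled independently, while real height correlates diameter,
length and PWV paths), pathology (no stenoses, no valve disease),
vessel-level heterogeneity beyond the body-location grouping,
viscoelastic wall behaviour, or measurement error in the QOIs. Passing
the population-level acceptance checks therefore shows that the
machinery reproduces target *marginal distributions* and *trends*;
it does not validate any individual waveform clinically.

## Problem sizes and numerical choices

The package's own verification runs use: a 301-node uniform tube for
the wave-speed oracle (foot-to-foot within 2% of the closed form);
one reference-patient run at periodicity 3e-4 for conservation checks
(junction residual ~1e-15; cardiac output vs summed venous outflow
within 1%); a 500-patient cohort on the reduced tree for the
population reproduction (resampled at the default working point, then
age/sex classified); 10,000 draws for the sampling-moment checks. A
500-patient cohort takes a few minutes on one core; the published
full-scale experiment (50,000 patients) is the same code at a larger N
and was not rerun here. Grid spacing defaults to 15 mm (halving it
moves systolic aortic pressure by <1%); the inverse tube law guards
against the pressure asymptote; degenerate draws (non-positive
diameters, lengths, resistances, stiffness) are rejected before
simulation, and any in-run divergence marks the patient failed rather
than aborting the cohort.

## Known limitations

* The reduced tree is a methodological stand-in; absolute peripheral
  waveform shapes (especially at the ankle) inherit its coarseness.
* Carotid-femoral PWV uses the centerline path; clinical cf-PWV
  conventions (subtracted distances) would scale it down.
* The demographic targets are fixtures (see above).
* Independent factor sampling understates joint physiological
  correlations; the resampling step corrects marginals, not the joint
  distribution.
* The refinement labels are population strata; per-patient label
  recovery is not a property of the moment objective (see above).
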