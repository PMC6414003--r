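---
title: "Superparamagnetic clustering of serum Raman spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superparamagnetic clustering of serum Raman spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ramanspc` implements an unsupervised pipeline for discriminating blood-serum
Raman spectra of different cancer types — breast cancer, cervical cancer and
leukemia in the reference design — using superparamagnetic clustering (SPC),
a clustering method built on the physics of disordered Potts ferromagnets.
This vignette is the package's own account of the models, the parameters
that matter, the design decisions taken where the method left choices open,
and what the bundled synthetic data can and cannot establish.

## The data and its conditioning

A serum Raman spectrum is a vector of scattering intensities on a wavenumber
grid; the reference design uses 2330 points covering 400–1800 cm⁻¹ (about
0.6 cm⁻¹ resolution). Vibrational bands of serum constituents appear at
characteristic positions: phenylalanine at 622, 1002, 1028, 1063 and
1103 cm⁻¹, tyrosine at 642, 828, 853 and 1603 cm⁻¹, the amide III envelope
at 1230–1282 cm⁻¹, phospholipid at 1447 cm⁻¹, β-carotene at 1160 and
1523 cm⁻¹, tryptophan at 509, 760, 1208, 1556 and 1620 cm⁻¹,
polysaccharides at 714 cm⁻¹, the skeletal α mode at 938 cm⁻¹ and amide I at
1654 cm⁻¹ — 21 catalog assignments in all (`band_catalog()`).

Raw spectra ride on a fluorescence background that dwarfs the Raman signal.
Preprocessing runs in the order **baseline → smooth → normalize**:

* `correct_baseline()` subtracts an iteratively re-fitted 5th-order
  polynomial. Plain least squares would cut through the peaks; the iteration
  clips the working signal to `min(signal, fit + dev)` and refits, where
  `dev` is the residual standard deviation. The `dev` allowance (the
  I-ModPoly idea) stops the fit from chasing the noise floor, which is what
  makes a second pipeline pass a near-no-op; without it the baseline of an
  already-corrected spectrum converges to the lower noise envelope and
  shifts everything by a few percent. Negative residuals are kept so that
  distances stay unbiased.
* `sg_smooth()` applies a Savitzky–Golay filter, polynomial order 2. The
  window length is not dictated by the measurement protocol; the default of
  11 points (~6.6 cm⁻¹) attenuates a one-point artifact by ~79% (central
  impulse coefficient 89/429) while reproducing any locally quadratic
  signal exactly. For bands whose FWHM is close to the window (~13 grid
  points for an 8 cm⁻¹ Lorentzian) each pass still bites ~1–2% off the peak
  top: smoothing is not idempotent, and the pipeline's double-run
  invariance is therefore bounded by this effect rather than exactly zero.
* `normalize_spectrum()` divides by the maximum within ±5 cm⁻¹ of
  1002 cm⁻¹, the phenylalanine band that is the tallest feature of serum
  spectra. A windowed rather than global maximum keeps the reference
  immune to residual artifacts elsewhere.

## The coupling graph

Preprocessed spectra become columns of the data matrix (2330 × 352 for the
reference cohort); all pairwise Euclidean distances form the distance
matrix. Points interact only with neighbors: the edge set is the mutual
K-nearest-neighbor relation (default K = 10), augmented with the edges of
the minimum spanning tree so the graph is connected — without the MST
augmentation an outlying spectrum has no path into the ferromagnetic
cluster at any temperature. Ties in neighbor ranking break toward the lower
index, so graphs are reproducible. Each edge carries the ferromagnetic
coupling

$$J_{ij} = \frac{1}{\hat K}\exp\left\{-\frac{1}{2}\frac{d_{ij}^2}{\bar d^2}\right\},$$

where $\bar d$ is the mean edge distance and $\hat K = 2|E|/n$ the mean
number of interacting neighbors, both computed from the final edge set.
Couplings decrease monotonically with distance and are zero off-edges.

## The Potts model and its sampling

Each spectrum carries a spin $s_i \in \{1, \dots, q\}$ (default q = 20; SPC
results are insensitive to q once it is ~10 or more, and q = 20 keeps the
paramagnetic correlation baseline $1/q$ well below the 0.5 threshold). The
energy of a configuration is

$$H = \sum_{(i,j)} J_{ij}\,(1 - \delta_{s_i, s_j}),$$

summed over edges. The chain samples $\exp(-H/T)$ by Swendsen–Wang cluster
updates: every satisfied edge ($s_i = s_j$) freezes independently with
probability $p_{ij} = 1 - \exp(-J_{ij}/T)$, the connected components of
frozen edges (SW clusters) each draw a fresh uniform label. This move
satisfies detailed balance and decorrelates quickly even near transitions;
its correctness is checked against exact Boltzmann enumeration on 4-node
systems in the test suite.

Per temperature the engine estimates:

* the spin–spin correlation $g_{ij} = \langle\delta_{s_i,s_j}\rangle$ per
  edge, by default through the variance-reduced SW estimator
  $g_{ij} = ((q-1)\,c_{ij} + 1)/q$ with $c_{ij}$ the SW-cluster
  co-membership frequency (plain equal-spin counting is available as
  `estimator = "delta"`);
* the susceptibility $\chi = (N/T)(\langle m^2\rangle - \langle m\rangle^2)$
  with per-sweep magnetization $m = (q N_{\max} - N)/((q-1)N)$, $N_{\max}$
  being the largest spin-value class;
* the data partition: connected components of the edges with
  $g_{ij} > 0.5$.

`temperature_sweep()` anneals from `t_min = t_step` upward in steps of
0.001, carrying the spin state between temperatures and starting from all
spins aligned. By default the grid extends until the largest cluster has
stayed below 5% of the points for 20 consecutive steps. Defaults are 1000
sweeps per temperature with 200 discarded as burn-in; at the problem sizes
used here the correlation standard errors are ~0.02, small enough that
partitions flip only for genuinely borderline points.

The three phases appear in order: ferromagnetic (one cluster holding every
point) at low T, superparamagnetic (clusters of aligned spins = data
classes) in between, paramagnetic (singletons) at high T. χ rises steeply
at the ferro→superparamagnetic transition, which is also where the main
cluster first fragments.

## The cluster tree and natural clusters

Partitions along the sweep are turned into a temperature hierarchy by
*restricted split tracking*: each tracked cluster keeps the member set it
was born with — matching the convention of printed cluster tables, where a
cluster has one definitive member list — and at each higher temperature the
full partition cuts that set into pieces. A cluster

* **survives** while one piece covering ≥ `match_jaccard` (default 0.8) of
  its members holds together; members that evaporate as singletons do not
  end it. Tracking identity through a strict Jaccard match between
  *adjacent-temperature* clusters was tried first and discarded: Monte
  Carlo flicker of one or two borderline points (e.g. 7 of 9 members
  persisting, Jaccard 0.78) would kill a lineage and restart its clocks,
  corrupting every lifetime;
* **splits** when ≥ 2 pieces of at least `min_cluster_size` (default 2)
  members persist for `persistence` (default 3) consecutive grid steps;
  the pieces become children. The persistence window guards against a
  transient fragmentation at a single temperature creating spurious
  long-lived children;
* **dissolves** when coverage falls below the floor.

Each node records `t_ferro` (birth to first split — its ferromagnetic
range), `t_cl` (largest child lifetime — the T-range of its most stable
cluster), `t_max` (where its members become majority singletons — its
paramagnetic transition) and the relative stability `s_t`. The stability
reference is the root's *ordered-regime span*, from its birth at the lowest
temperature to its paramagnetic transition. Using instead the root's own
lifetime (birth to first split), as a literal lifetime-ratio reading would
suggest, makes the denominator a few grid steps — the whole-set cluster
often splits almost immediately — and every transient fragment then counts
as maximally stable.

Natural clusters are the deepest stable nodes: `s_t` at or above
`s_theta = 0.5`, size at least `min_cluster_size`, and no stable
substructure. The whole-set root is never natural. The direction of the
threshold comparison is configurable (`direction = "lt"`) because the
method's verbal description ("less stable than a threshold") reads inverted
relative to its stated goal of keeping the *most* stable clusters; the
default keeps stable nodes. Extracted natural clusters form the right
branches of the rendered tree and residual structure continues on the left,
reproducing the sequential-extraction layout.

The package also ships, as data, the published cluster table of the
352-spectrum serum study (four leaf clusters of sizes 135, 132, 33 and 52
with full member lists, three internal nodes) together with the cohort
design (indices 1–160 breast, 161–310 cervical, 311–352 leukemia).
`table2_tree()` rebuilds that hierarchy so `membership_report()` can be
exercised against exact printed counts: 120 of the 135 members of cluster
"1 1 1" are cervical, cluster "1 1 2" holds 41 of the 42 leukemia spectra,
and the leaf sizes sum to 135 + 132 + 33 + 52 = 352.

## The PCA cross-check

`run_pca()` treats spectra as observations (mean-centered, unscaled — all
spectra already share the peak-normalized intensity scale). Component signs
are fixed by making the largest-magnitude loading positive, so results are
deterministic. `loading_curve()` pairs loadings with wavenumbers; the
positions of large |loading| indicate which spectral regions drive
between-spectrum variance — on cohorts built from the default templates
these are the amide I / high-wavenumber region and the other
class-discriminating bands, mirroring what the mean spectra show. The
agreement check clusters the first two PC scores with k-means and compares
against the SPC natural-leaf partition by adjusted Rand index.

## The synthetic cohort generator

No raw spectra are deposited with the reference study, so the generator is
a first-class module that emulates the *published account* of the data:

* grid and design: 2330 points on 400–1800 cm⁻¹; 160/150/42 spectra from
  16/21/7 patients, in cohort order;
* a shared catalog of Lorentzian bands (width 8 cm⁻¹; 25 cm⁻¹ for the two
  amide III shoulders; a broad 40 cm⁻¹ envelope at 1070 cm⁻¹ for the bulged
  1040–1100 region), with the 1002 cm⁻¹ band globally maximal;
* class identity as band suppression: leukemia lacks amide I entirely and
  its 1620/1603/1556/1523/1447 neighbors; breast and cervical lack the left
  amide III shoulder and the 938 region; cervical additionally lacks
  714 cm⁻¹; breast flattens 1040–1100;
* per (patient, band) log-normal amplitude factors (`patient_effect_sd`,
  default 0.05), one draw per patient, so all spectra of a patient share a
  band-intensity fingerprint — mild within-class substructure;
* a random positive 5th-degree polynomial baseline about twice the peak
  scale; Gaussian shot-like noise (`noise_sd`, default 0.04); and
  Poisson-placed cosmic-ray spikes (rate 0.2 per spectrum, width 1–3
  points, amplitude 5–10 × `spike_scale`).

Band amplitudes are free parameters — the study reports no intensities —
and two of them were set deliberately. The 1070 cm⁻¹ envelope (0.50) and
the 714 cm⁻¹ band (0.35) carry the breast- and cervical-discriminating
contrasts; with smaller values those two classes nearly coincide relative
to within-class spread and no clustering method could separate them, which
would contradict the account the generator is built to emulate. `noise_sd`
was set so that the cohort exhibits the reported *phase phenomenology*: the
mean neighbor distance $\bar d$ scales with within-class spread, and with
much weaker noise the between-class distances are so many multiples of
$\bar d$ that cross-class couplings cannot bind the classes into one
cluster even at the lowest grid temperature — there would be no
ferromagnetic phase and no transition peak in χ. At the default, a
30-spectrum cohort shows the full sequence: one all-spectra cluster at low
T, a χ peak at the first split, three class clusters across a wide
superparamagnetic plateau, then singletons.

Cosmic-ray spikes deserve a note. Raw cosmic events are far taller than
the Raman signal, but the modeled measurement narrative states that
Savitzky–Golay smoothing removes them; an 11-point quadratic filter only
attenuates a narrow spike to ~20–55% of its height, so spikes several times
the signal scale would survive preprocessing as extreme outliers. Emulated
faithfully, such outliers detach from every cluster at all temperatures
(their couplings are exponentially small), dominate the first principal
components, and generally contradict the published phenomenology the
generator exists to reproduce. The default therefore scales spikes to the
shot-noise level (`spike_scale = 0.02`, i.e. spikes of 0.1–0.2 relative
intensity) — sharp artifacts that smoothing genuinely removes. Users who
want raw-scale cosmic rays can set `spike_scale` accordingly and should
then expect outlier rejection rather than complete clustering.

What passing tests on this generator do **not** establish: performance on
real serum spectra with instrument drift, wavenumber miscalibration,
between-batch baseline families, correlated (non-white) noise, or class
differences that are concentration gradients rather than band
presence/absence. The full-scale 352-spectrum default cohort also shows a
caution worth knowing: with ten replicate spectra per patient, patient-level
clusters are genuinely tight, long-lived structures, and at `s_theta = 0.5`
the extracted natural clusters can sit below the class level. The
class-level organization is still visible in the internal nodes of the
tree; the threshold, like the study's own, is a control parameter to be
read against the tree, not an oracle.

## Numerical choices and degenerate inputs

* Temperatures are in the package's own units — couplings set the scale
  through the $J_{ij}$ formula. Published temperature values for this kind
  of analysis are not unit-reproducible (the reference figures use an
  unstated normalization), so only *structural* quantities (cluster
  compositions, peak-to-split colocation, stability ratios) are compared.
* The SW freeze probability $1 - \exp(-J_{ij}/T)$ is the standard form
  consistent with the Hamiltonian above divided by T.
* All randomness flows through R's RNG: a seed makes cohorts, sweeps and
  the full pipeline bit-reproducible. The SW core is compiled (Rcpp) and
  draws from the same RNG stream.
* Degenerate inputs error early and loudly: all-coincident points (zero
  $\bar d$), flat spectra at normalization, empty sweeps, a root lineage
  with zero lifetime, out-of-range neighborhood sizes.
* Problem sizes in the test-suite: unit identities run on 2–7-node toys;
  Monte Carlo oracle checks on a 4-node path with $q \le 3$ (≤ 81 states,
  exact enumeration); recovery studies on 30-spectrum cohorts (10 spectra ×
  3 classes, 3 patients each) over ten seeds. The full 352-spectrum
  pipeline runs in well under a minute on one core and is exercised for
  shape contracts.

## Known limitations

* The stability statistic `s_t` has no published closed form; the
  lifetime-over-ordered-span definition used here matches the magnitude
  and intent of the published values but not necessarily their exact
  formula (the single printed value 0.666667 is consistent with several
  definitions).
* Restricted split tracking fixes each node's member set at birth, so
  late-joining points (cluster drift toward *larger* sets) are credited to
  no node; in MC practice drift is dominated by evaporation, which is
  handled.
* The sequential extraction here peels within one sweep; it does not re-run
  the Monte Carlo on residual sets, which the original sequential procedure
  does at additional cost. On data where removing a dominant cluster
  changes $\bar d$ and $\hat K$ substantially, a re-run could refine the
  residual structure.
* LDA is deliberately absent: the modeled study mentions it generically but
  applies only PCA, and classification-accuracy claims are out of scope.
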