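---
title: "CCS determination methods in imsccs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CCS determination methods in imsccs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsccs)
```

## The physical model

An ion of charge $q = ze$ drifting through a buffer gas at low field
strength has a mobility determined by its momentum-transfer collision
cross section $\Omega$ through the Mason–Schamp relation

$$\Omega \;=\; \frac{3ze}{16 N_0}\,
  \sqrt{\frac{2\pi}{\mu k T}}\;\frac{1}{K_0},$$

where $N_0$ is the buffer-gas number density at 273.15 K and 760 Torr,
$\mu = m_I m_B/(m_I + m_B)$ the ion/gas reduced mass, $k$ the Boltzmann
constant, $T$ the drift-gas temperature and $K_0$ the reduced mobility
(normalized to standard temperature and pressure). The package pins the
CODATA values $k = 1.380649\times10^{-23}$ J/K,
$e = 1.602176634\times10^{-19}$ C, $N_0 = 2.6867801\times10^{25}$
m$^{-3}$, and buffer-gas masses N$_2$ = 28.0134 Da, He = 4.002602 Da
(user-overridable). Ion masses are derived from m/z as
$m_I = mz\cdot z \mp z\,m_e$ (electrons removed in positive mode, added
in negative mode, $m_e = 5.48579909\times10^{-4}$ Da); the correction is
far below reported precision but is fixed so that all outputs are
deterministic.

Units are contractual throughout: arrival times in ms, drift length in
cm, pressure in Torr, temperature in °C at the I/O boundary (converted
to K internally), $K_0$ in cm²/(V·s), CCS in Å². These match the
conventions of exported instrument metadata.

## Stepped-field regression

At each drift voltage $V_n$ the arrival time obeys

$$t_A \;=\; \frac{L^2}{K_0}\,\frac{273.15}{760}\,
  \frac{P_n}{T_n V_n} \;+\; t_0 ,$$

so regressing $t_A$ on the per-field term
$x_n = 1000\,L^2(273.15/760)\,P_n/(T_n V_n)$ (the factor 1000 keeps
$t_A$ in ms) yields $K_0 = 1/\mathrm{slope}$ and the out-of-cell time
$t_0$ as intercept. Two design choices were genuinely open:

* **Temperature placement.** The per-field temperature is kept *inside*
  the regressor rather than treating $P/V$ alone as the field term.
  Under the drift-time relation this is exact, and it removes bias when
  temperature drifts between fields. The representative temperature for
  the final Mason–Schamp evaluation is the mean of the per-field
  temperatures of the fields entering the chosen combination.
* **Field subsets.** By default a combination must span *all* fields
  (`min_fields = number of fields`): a conformer detected in only a few
  fields is weak evidence. Configurations may lower `min_fields`, in
  which case combinations may skip fields and surviving fits carry the
  `low_fields` flag.

The combination search takes at most one candidate feature per field
(candidates are the features matching the target ion's m/z within the
ppm tolerance, truncated to the top `max_rank = 3` by intensity, ties
broken by earlier arrival time then lower m/z). With rank limit $r$ and
$f$ fields at most $(r+1)^f$ ordinary least-squares fits are evaluated —
at the defaults ($r = 3$, $f = 7$) this is bounded by $4^7 = 16384$
closed-form fits, which run in milliseconds. Fits with
$R^2 \ge 0.99$ (default threshold) and a positive slope are kept; each
is a candidate conformer. Near-duplicates — CCS within 0.5% relative
*and* sharing at least half their features — are merged keeping the
higher-$R^2$ fit, since the combination search otherwise reports the
same conformer many times with one field swapped. Both the merge
tolerance and the threshold are configuration-exposed.

Replicate statistics use the arithmetic mean and the percent relative
standard deviation with the sample ($n-1$) denominator; single
replicates report RSD 0 and carry a `single_replicate` flag rather than
an undefined value.

## Single-field calibration

At a single drift voltage all instrument factors collapse into a linear
relation between arrival time and the *reduced* CCS

$$\Omega' \;=\; \frac{1}{z}\sqrt{\frac{m_I}{m_I+m_B}}\;\Omega ,$$

so two or more reference ions define the calibration
$t_A = s\,\Omega' + t_0$. Unknown features are converted untargeted:
$\Omega = (t_A - t_0)/s \cdot z / \sqrt{m_I/(m_I+m_B)}$, with charge
defaulting to 1 unless the feature table carries a `charge_z` column.

The **enhanced** mode regresses on the *adjusted* reduced CCS
$\Omega'' = (P/T)\,\Omega'$ instead, using the calibrant run's own mean
pressure and temperature; at application time the sample run's own
$P/T$ inverts the factor. When $P/T$ is identical in both runs the two
modes are algebraically equivalent (the package verifies agreement to
$10^{-9}$ relative); when pressure or temperature drifts between runs
only the enhanced mode corrects it. Per-run $P$ and $T$ are the means
over the run's frame-metadata records — the deterministic reduction of
"well-recorded readings".

Calibrant runs are assigned to sample runs automatically: among
calibrations of the same polarity, the one whose timestamp is at or
after the sample run's and closest to it wins; if none follows, the
closest preceding one is used and results carry a
`fallback_calibration` flag. Ties break on run id. Naive timestamps are
interpreted as UTC so assignment is reproducible across machines. The
alternative of interpolating between the preceding and following
calibrant runs was considered and rejected: choosing one run keeps every
CCS traceable to a single auditable calibration.

The `tims_scan` mode is the standard linear fit with IMS scan numbers
standing in for arrival times and no pressure/temperature terms, the
substitution used for trapped-IMS exports.

## Traveling-wave calibration

TWIMS fields are non-uniform and dynamic, so $t_A$–CCS is non-linear.
Arrival times are first corrected,

$$t' = t_A - \frac{C\sqrt{m/z}}{1000} - t_\mathrm{acc},$$

where $C$ is the EDC delay coefficient (an instrument constant on
Synapt systems, 0 for SLIM) and $t_\mathrm{acc}$ the ion accumulation
time (1000 ms for the SLIM-style fixtures, where ions are accumulated
in the path before separation). Two calibration families are offered:

* **Polynomial** (default degree 2): least squares of $\Omega'$ on
  $t'$, requiring at least $D+2$ points so the fit is always
  overdetermined — an exactly interpolating calibration has no residual
  information and is refused. Prediction uses Horner evaluation.
* **Linearized power law**: $\ln\Omega' = X\ln t' + \ln Y$ by log-log
  least squares, then $t'' = (t')^X z/\sqrt{\mu}$, then the final
  linear map $\Omega = a\,t'' + b$. Both stage $R^2$ values are kept.

Two typographically ambiguous details of the published protocol are
resolved the way the standard TWIMS literature does, and deliberately
so: the doubly corrected time uses $z/\sqrt{\mu}$ (not $z\cdot 1/\mu$),
which makes the final fit dimensionally consistent with
$\Omega' \propto \Omega\sqrt{\mu}/z$, and the EDC term is
$C\sqrt{m/z}/1000$ ms. On data generated from an exact power law the
final fit is exactly linear with $a = Y\sqrt{m_B}$ and $b = 0$, which
the tests exploit as a round-trip oracle. The reduced-CCS normalization
uses the same $\sqrt{m_I/(m_I+m_B)}/z$ scaling as the drift-tube modes,
applied uniformly.

Features whose $t'$ falls outside the calibrant range are flagged
`extrapolated` (never dropped): a calibration is an interpolation
device, and values outside the anchored range carry a larger,
unquantified uncertainty. The flag is monotone by construction — any
$t'$ farther from the range on the same side is also flagged.

## What the synthetic generators emulate

The generators are pure functions of their parameters and a seed (the
caller's RNG state is saved and restored), and they write the exact
CSV/CEF/metadata dialects the readers parse.

* `synth_stepped_campaign()` plants ions with known CCS on the
  drift-time relation across a 7-field 850–1450 V layout (100 V
  increments) at 3.95 Torr, 28 °C and a 78.24 cm drift length —
  representative commercial drift-tube geometry and the field layout of
  typical stepped-field acquisitions. True $K_0$ is derived from the
  planted CCS by the inverse Mason–Schamp relation at the campaign
  temperature, so truth is self-consistent by construction. Optional
  decoy features at a controlled ppm offset exercise the matching
  tolerance, and multiplicative Gaussian arrival-time noise (default 0)
  exercises robustness.
* `synth_single_field_campaign()` interleaves calibrant and sample runs
  on a timeline (one calibrant run before every `cal_every` sample
  runs, 30 min spacing) and draws per-run pressure/temperature from
  constant, linear, three-level step, or seeded random-walk drift
  models (default amplitude 2%, matching the scale of drift a
  malfunctioning flow controller produces). Arrival times follow the
  single-field forward model $t_A = s\,(P_r/T_r)\,\Omega' + t_0$ with
  the run's own conditions; the defaults $s = 12$ ms per
  adjusted-reduced-CCS unit and $t_0 = 0.3$ ms give realistic 15–45 ms
  arrival times for tune-mix-sized ions. Because the drift enters
  through exactly the factor the enhanced mode models, the enhanced
  correction is exact up to noise here — the generator demonstrates the
  mechanism, not the messy residual physics of a real instrument.
* `synth_twims_campaign()` inverts an exact power law
  $t' = (\Omega'/Y)^{1/X}$ and adds the EDC/accumulation corrections.
  The default scale $Y$ places the median calibrant at $t' = 200$ ms.

What passing these tests shows — and does not. The generators produce
exactly the functional forms the calibrations assume, with clean peaks,
no isotope structure, no chromatographic dimension and noise only as a
multiplicative Gaussian on arrival time. Recovery to $10^{-6}$–$10^{-9}$
on such data validates the estimators' correctness, the combination
search's equivalence to brute-force enumeration, and the flag/assignment
logic; it does not validate peak picking (out of scope), nor how far
real TWIMS devices deviate from a single power law, nor the enhanced
mode's benefit when drift is *not* of the $P/T$ form.

## Numerical choices and degenerate inputs

* All straight-line fits are unweighted ordinary least squares
  (`stats::lm`, or the closed form inside the combination search where
  thousands of tiny fits may run). $R^2$ is computed directly from
  residuals; a two-point fit reports $R^2 = 1$, and a zero-variance
  response reports `NA` rather than a misleading 1.
* A passing stepped-field fit with non-positive slope (unphysical
  mobility) is discarded; a single-field or power calibration with
  non-positive slope/exponent is an error, since every downstream value
  would be meaningless.
* Features that cannot be calibrated ($t_A \le t_0$, or non-positive
  corrected time) yield records flagged `invalid` with `NA` CCS —
  output row count always equals input row count.
* Result tables are written with fixed column order, fixed formatting
  (CCS and $K_0$ at 4 decimals), radix-sorted rows and `\n` line
  endings, so identical inputs give byte-identical files on any
  platform. Reports contain no timestamps for the same reason.
* Numeric parsing is locale-independent (period decimal separator);
  naive timestamps are taken as UTC.

The test suite runs entirely on generated data at the sizes above
(7-field campaigns, 12–16 run batches, 100-seed noise studies, 5-ion
calibrant ladders), which a desk machine completes in seconds; the
tune-mix reference CCS values are library values, while the TAA-style
helium calibrant ladder used in the TWIMS tests is a synthetic
stand-in with plausible masses and cross sections.

## Known limitations

* Peak finding, raw-file parsing (mzML, UIMF, vendor formats) and
  arrival-time re-centroiding are out of scope; the package starts from
  feature tables.
* CCS is computed from the peak apex/centroid arrival time only;
  arrival-time-distribution widths and conformational ensembles are not
  characterized.
* The enhanced mode corrects drift of the $P/T$ form only; high-field
  mobility corrections and temperature-dependent collision-integral
  models are not modelled.
* Confidence reporting on TWIMS calibrations is limited to the stored
  $R^2$ values and the extrapolation flag; prediction bands beyond
  pointwise OLS are not computed.
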