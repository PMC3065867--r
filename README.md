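# BayesSPECT

Iterative SPECT reconstruction with collimator response modelling and
one-step-late (OSL) Bayesian priors, built to study — and suppress — the
Gibbs-like ringing artefacts that collimator correction introduces.

Modelling the distance-dependent collimator blur inside OSEM ("resolution
recovery", RR) sharpens SPECT images, but the implicit deconvolution
overshoots at sharp activity edges: hot spheres develop a central hole and
their profiles become two-peaked. This package provides everything needed
to reproduce and quantify that behaviour without scanner data, for people
developing or validating emission-tomography reconstruction: a
rotation-based projector, OSEM/OSL reconstruction with three Bayesian
priors, digital phantoms with a Poisson simulator, and artefact metrics.

## The model

The OSEM update over angular subset $S_n$ is

$$f_j^{new} = \frac{f_j^{old}}{\sum_{i\in S_n} a_{ij}}\sum_{i\in S_n}
a_{ij}\,\frac{p_i}{\sum_k a_{ik} f_k^{old}},$$

with measured projections $p$ and system matrix $a_{ij}$ realised per
angle as sparse bilinear rotation → attenuation factors (from a CT-derived
µ-map) → a detector-bound plane sweep with incremental Gaussian blurs
("Gaussian diffusion") realising the distance-dependent PSF
$\sigma(d) = \sigma_0 + slope\cdot d$. The back-projector is the exact
matrix adjoint. The OSL update multiplies in a penalty factor

$$c^P_j = \frac{1}{\sum_{i\in S_n} a_{ij} + \beta\,(f_j - A_j)/A_j},$$

where $A_j$ is the inverse-distance-weighted neighbourhood mean
(quadratic smoothing prior), the neighbourhood median (median root prior,
MRP), or the weighted mean over the $B$ most CT-similar neighbours
(Bowsher anatomical prior, AMAP). $\beta = 0$ reduces to OSEM bitwise.

## Worked example

Simulate the hot-sphere phantom (23.6 cm water body; 10–37 mm spheres),
reconstruct with the five standard methods at the usual protocol
(128 angles, 24 cm orbit, 16 subsets × 5 iterations, β = 0.3,
Bowsher 18/9), and evaluate:

```r
library(BayesSPECT)
study <- runStudy(studyConfig(spherePhantomSpec(),
                              totalCounts = 2e6, seed = 1))
subset(study$metrics, sphereId == 1,
       select = c(method, contrast, ringingLargest))
```

```
   method  contrast ringingLargest
1    NORR 0.7958850      0.0000000
5      RR 0.9649416      0.1742855
9     MRP 0.9349655      0.0000000
13 SMOOTH 0.9153143      0.0000000
17   AMAP 0.9950542      0.0000000
```

The ringing index is the fractional depth of the central dip in the
profile through the largest (37 mm) sphere: OSEM with collimator
correction (RR) digs a ~17% hole, while every Bayesian prior — median
root (MRP), quadratic smoothing (SMOOTH), Bowsher anatomical (AMAP) —
and the uncorrected reconstruction (NORR) score 0. Contrast is the
concentric-ROI measure $(A_{sph}-A_{bg})/(A_{sph}+A_{bg})$ on the largest
sphere: collimator correction raises it well above NORR, the smoothing
and median-root priors give a little of it back in exchange for artefact
suppression, and the anatomical prior suppresses the artefact while
scoring the highest contrast of all. On a uniform cylinder at the same
protocol the interior coefficient of variation orders
SMOOTH < MRP < RR (0.060 / 0.067 / 0.141), the expected noise hierarchy.

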