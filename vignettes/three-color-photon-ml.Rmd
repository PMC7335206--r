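---
title: "Photon-by-photon likelihood analysis of three-color FRET: models, corrections, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-by-photon likelihood analysis of three-color FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fret3cw)
```

This vignette is the package's own account of the statistics it implements:
the kinetic/emission models, the likelihood and its numerics, the
fraction-to-efficiency algebra, the Gaussian-chain averaging, and — because
every claim in this package is validated on synthetic data — exactly what
the simulator emulates and what passing tests do and do not establish about
real measurements.

## The likelihood and its state space

A photon trajectory is a sequence of arrival times $t_i$ (seconds,
strictly increasing) and detection channels $c_i \in \{D, A1, A2\}$. For a
continuous-time Markov model with generator $K$ (column convention:
$K_{ij}$ is the rate $j \to i$, columns sum to zero) and initial population
vector $p$, the trajectory likelihood is

$$ L = \mathbf{1}^T \prod_{i=N}^{2} \left[ F(c_i)\, e^{K (t_i - t_{i-1})}
\right] F(c_1)\, p , $$

with diagonal photon-color matrices $F(A1) = E_1$, $F(A2) = E_2$,
$F(D) = I - E_1 - E_2$ holding per-state acceptor photon fractions
$\varepsilon$. Because $\sum_c F(c) = I$, the likelihood is a normalized
distribution over color sequences at fixed arrival times — the package's
tests exploit this by enumerating all $2^6$ and $3^6$ sequences and
checking the sum is 1 to $10^{-10}$.

The model families mirror the experimental segment structure:

* **Folding**: two conformational states (F/U) with relaxation rate
  $k = k_F + k_U$ and folded population $p_F = k_F/k$. Three-color and
  two-color (DA1, DA2) segments are independent, so the global likelihood
  is the product over classes with shared kinetics.
* **Binding**: bound/unbound states, where incomplete A2 labeling and slow
  A2 photobleaching force the three-color and DA1 photons into one
  three-state generator (bound-bright, unbound, bound-dark/unlabeled) with
  labeling fraction $\varphi$ and primed bleaching rates. The product-form
  initial vector $(\varphi p_B, 1 - p_B, (1-\varphi) p_B)$ is used as-is;
  because photobleaching is irreversible it is *not* the stationary vector
  of $K$, and the package deliberately does not replace it with one.
* **Blinking**: each acceptor's bright/dark photophysics multiplies the
  state space (8 states for folding with both acceptors blinking, 8 for
  binding, 4 for DA2 segments). Dark-entry rates scale with each
  trajectory's mean count rate, $k_d = k_d^0 (n / n_0)$ with
  $n_0 = 100$ photons/ms, since dark-state entry is excitation-driven;
  recovery rates are intensity-independent.
* An $N$-state linear chain generalizes the two-state folding model; its
  equilibrium vector is solved from the null space of $K$.

### Parameter tying

Dark-state emission fractions are not free parameters. The package ties
them in one place (`apply_tying()`): a molecule with A2 dark emits like a
DA1 molecule, so its three-color fractions are the DA1 fraction split
between the A1 and A2 channels by the A1-into-A2 leak $l_{12}$ (zero when
no correction factors are supplied); a molecule with A1 dark emits like a
DA2 molecule (all acceptor signal in the A2 channel); with both dark only
donor photons remain. For binding, the unbound-state ratio relation
$\varepsilon_{2Bd}/\varepsilon_{1Bd} = \varepsilon_{2U}/\varepsilon_{1U}$
removes one more fraction. No complete canonical table of such relations
exists to pin every entry, so the mapping above is the package's
documented choice; the verifiable consequences — 14 free
parameters for global folding with blinking, 16 for binding with blinking,
12 for binding without, 5 independent binding fractions — are pinned by
unit tests. A practical corollary of the zero dark-state entries: with
distorted (leaky) data a dark-state dwell containing a stray acceptor
photon would zero that path's contribution; fits with blinking families
are therefore meant for leak-corrected or undistorted input.

## Numerics

* **Renormalized recursion.** The product above underflows beyond roughly
  $10^3$ photons, so the state vector is renormalized after every photon
  and the log of the divisor accumulated. A test confirms equality with the
  naive product on short trajectories.
* **Propagators by diagonalization.** One eigendecomposition of $K$ per
  (model, count-rate) pair, then $e^{\Lambda \Delta t}$ per gap. Real
  spectra (all reversible generators here) take a preallocated real-arithmetic
  path; complex spectra (possible for the irreversible binding generators)
  are handled in complex arithmetic with the imaginary residue checked
  against $10^{-8}$. If the eigenbasis condition number exceeds $10^8$ the
  code falls back to scaling-and-squaring matrix exponentials per gap. The
  independent oracle in the tests is `Matrix::expm`, never the same code
  path.
* **Chunked products.** `partial_products()` implements the associative
  contract used for parallel evaluation: contiguous chunks of the factor
  sequence are multiplied independently (with their own rescaling) and
  combined in order. Split invariance to $10^{-9}$ is tested for splits
  from 1 chunk to one photon per chunk; scheduling across hardware is out
  of scope.
* **Optimization.** Nelder–Mead on transformed coordinates — log for
  rates, logit for lone fractions, and an additive-logistic map for
  $(\varepsilon_1, \varepsilon_2)$ pairs so $\varepsilon_1 +
  \varepsilon_2 < 1$ throughout. Three restarts (the initial point and
  ±20% shifts in transformed space), convergence at relative tolerance
  $10^{-8}$ with at most $5 \times 10^4$ evaluations; one-dimensional
  problems use bracketed Brent instead. These settings are conventional
  defaults, documented here because no canonical values exist.
* **Uncertainties.** Central-difference Hessian of $-\ln L$ in transformed
  coordinates (step $10^{-4}$, Richardson-refined diagonal at
  $5 \times 10^{-5}$), inverted and mapped to natural units by the delta
  method. Non-positive-definite curvature or boundary estimates yield `NA`
  standard deviations, never NaN propagation. The binomial closed form
  $\sqrt{\varepsilon(1-\varepsilon)/N}$ is reproduced to 5% in the
  no-dynamics limit, and doubling the data shrinks errors by
  $\approx 1/\sqrt{2}$.
* **BIC.** $-2 \ln L + P \ln N$ with $N$ the total photon count — photons
  are the likelihood's observation units; no other sample size is defined.
  State-count selection by BIC alone deserves caution (heterogeneity or
  impurities mimic extra states), so the ranking report is advisory.

## Corrections and conversions

The correction order is fixed: background subtraction, then donor/A1 leak
inversion, then direct-acceptor-excitation removal — each formula takes
the previous step's output. The three-color direct-excitation correction
needs the true efficiencies, which depend on the corrected fractions, so
`iterate_3c_conversion()` alternates correction and anchored conversion
from the uncorrected values until the change drops below $10^{-8}$
(at most 100 iterations; the direct-excitation fractions are small, so a
handful suffice in practice). Corrected fractions that fall slightly
negative from finite-count noise are clipped to zero with a warning —
never silently.

Anchor choice is a scientific decision, not a numerical detail: the
conversion's error amplification grows without bound along the pathway of
a weak efficiency, so a low $E_2$ must be anchored from DA2 segments
rather than inferred. A test verifies this sensitivity growth
numerically, and the `EfficiencyTriplet` output records which anchor was
used.

## Gaussian-chain averaging

For disordered states the inter-dye vectors $r_1$ (D–A1) and $r_{12}$
(A1–A2) are modeled as independent isotropic Gaussians, so
$\langle r_2^2 \rangle = \langle r_1^2 \rangle + \langle r_{12}^2
\rangle$. Two-color efficiencies are radial averages of
$E(r) = 1/(1 + (r/R)^6)$; three-color efficiencies come from
distance-averaged count rates pushed through the same anchored conversion.
Quadrature is Gauss–Legendre with radial supports truncated at
$6\sqrt{\langle r^2 \rangle}$ (the Gaussian weight is below $e^{-54}$
there) and grids doubled until the relative change is under $10^{-8}$ —
the scheme and truncation are this package's choices. The donor average
uses the one-dimensional difference kernel in $(r_1, r_2)$, with the
angular triple integral implemented as its cross-check; both agree to
$10^{-6}$ in tests, and all averages match $10^6$-sample Monte Carlo
within 3 standard errors at the default Förster radii (5.4, 4.3, 7.0 nm).

## What the simulator emulates — and what it does not

`simulate_photons()` draws homogeneous Poisson arrivals at a single rate
and colors them from an exact Gillespie state path; `recolor()` does the
same over fixed (e.g. experimental) arrival times. The forward distortion
block is the exact inverse, in expectation, of the correction chain:
direct-excitation acceptor photons enter as added Poisson streams, leak as
per-photon channel misassignment with probabilities $(l_1, l_2, l_{12})$,
background as per-channel Poisson streams — applied in that order so the
corrections unwind them in theirs. All randomness flows through R's RNG,
so a seed fixes every dataset byte-for-byte. One wrinkle worth knowing:
R's `runif` has 32-bit resolution, so sorted arrival draws can tie at
realistic photon counts; ties are nudged apart by femtoseconds, far below
any physical timescale.

Deliberately not emulated: state-dependent brightness (arrivals are
state-independent by default), detector dead time and afterpulsing,
triplet/radical photophysics beyond the two-state bright/dark scheme, and
diffusion through a confocal spot. Consequently, passing the recovery
tests demonstrates the estimator's correctness and dynamic range under the
stated generative model — it does not certify robustness to instrument
artifacts absent from that model.

## Validation design and problem sizes

The acceptance-style checks simulate at the benchmark conditions of the
recoloring designs: folding at 80 photons/ms with folded populations
$\{0.3, 0.47, 0.63\}$ and relaxation rates swept over $k/n \in \{0.01,
0.1, 0.5, 1\}$, five replicate seeds per grid point — the regime where the
relaxation rate approaches the photon count rate and binned analyses fail.
The package runs this grid at $6 \times 10^4$ photons per dataset and the
intermediate-state detection (a linear three-state chain with a 10%
intermediate) at $2 \times 10^5$ photons; these sizes are the package's
validation choices, large enough that the bias checks are meaningful while
keeping the full suite quick to run routinely. Unbiasedness is asserted as
mean-versus-truth within three empirical standard deviations over
replicates, per grid point.

Segment boundaries (photobleaching steps) are taken as given in the input
metadata; automated bleach-step detection is not implemented, since no
canonical procedure exists to pin it to. The Photon-HDF5 dialect is part
of the reader interface but requires an HDF5 binding this build does not
link against; the TSV dialect is complete and lossless (round trip below
$10^{-12}$ s). Viterbi ties break toward the lower state index; histogram
bins need 20 photons by default (suppressing edge artifacts at 1 ms bins
and typical count rates); correlation curves are computed on binned counts
(10 µs default) because that is the form the estimator is defined in.

## Known limitations

* Dark-state emission tying is a documented reconstruction (see above),
  exact in parameter count but not guaranteed to match the original
  relations entry-for-entry.
* The binding families use the product-form non-stationary initial vector; if
  the experimental convention were the stationary vector of $K$, bound
  fractions near the bleaching timescale would shift slightly.
* Leak/background distortions are incompatible with the hard-zero
  dark-state emissions of the blinking families; correct before fitting
  with blinking.
* The Gaussian chain is the only fluctuating-distance model implemented;
  worm-like-chain or self-avoiding statistics are out of scope.
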