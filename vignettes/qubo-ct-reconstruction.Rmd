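---
title: "CT reconstruction as a binary quadratic ground-state problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT reconstruction as a binary quadratic ground-state problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quboCT)
```

## The reconstruction model

Parallel-beam CT measures a sinogram: for each projection angle $\theta$
and detector bin $s$, a value $P(\theta, s)$ proportional to the integral
of the X-ray mass attenuation along the corresponding strip through the
sample (one axial slice at a time; a 3D volume is a loop over slices).
Classical reconstruction inverts this linear map approximately; `quboCT`
instead poses exact inversion as a combinatorial energy minimization that
annealing-style samplers can attack.

Each unknown pixel is assumed integer-valued and expanded in bits,
$I_{ij} = \sum_{k=0}^{m} 2^k q_k^{ij}$ with $q_k^{ij} \in \{0,1\}$, so an
$n \times n$ image at $m{+}1$ bits per pixel uses $n^2(m{+}1)$ binary
variables. The forward model is
$IP(\theta,s) = \sum_{ij} c_{ij} I_{ij}$ with $c_{ij}$ the exact
pixel/strip overlap area, and the objective is the squared residual summed
over the whole sinogram,
$$F \;=\; \sum_{\theta}\sum_{s}\bigl(IP(\theta,s) - P(\theta,s)\bigr)^2 .$$
Expanding the square and using $q^2 = q$ yields a quadratic form over the
bits. The constant $\sum P^2$ is excluded from the model, as binary
quadratic solvers conventionally require, and is tracked as the model
`offset`. Three consequences the package leans on throughout:

* **Lower bound.** $F \ge 0$ implies every model energy is $\ge -\sum P^2$
  (`expectedMinEnergy()`).
* **Certificate.** An assignment attaining the bound reproduces the
  sinogram exactly; `reconstruct()` reports the gap for this reason.
* **Exactness.** When the sinogram is itself the projection of an integer
  image within the bit budget, the bound is attained and the global
  minimizer decodes to a consistent image — identical to the original
  whenever the minimizer is unique.

The Ising form substitutes $q = (\sigma+1)/2$: couplings $J = Q/4$, fields
$h_i = \ell_i/2 + \sum_j Q_{ij}/4$, plus a second tracked constant. Both
offsets are reported, never silently added, so QUBO and Ising energies can
always be reconciled assignment by assignment.

## Conventions that had to be fixed

The mathematics above leaves several representational choices open; the
package fixes them once and documents them here because every file format
and test depends on them.

**Variable order.** Bits are ordered row-major by pixel, ascending bit:
variable $((i{-}1)n + (j{-}1))(m{+}1) + k + 1$. For $n = 2$, $m = 1$ this
is $(q_0^{11}, q_1^{11}, q_0^{12}, q_1^{12}, q_0^{21}, q_1^{21}, q_0^{22},
q_1^{22})$.

**Geometry.** Pixel $(i, j)$ is row $i$ from the top, column $j$, a unit
square on an image centered at the origin. The detector coordinate at
angle $\theta$ (degrees, counterclockwise) is $t = x\cos\theta +
y\sin\theta$; bin $s$ collects $t \in [s - 1 - n/2,\; s - n/2]$. At
$\theta = 0$ bin $s$ is exactly column $s$; at $\theta = 90$ bin $s$ is row
$n{+}1{-}s$ (bin 1 is the bottom row). Angle sweeps are end-exclusive on
$[0, 180)$: `makeGeometry(n, k)` uses $0, 180/k, \ldots, 180 - 180/k$.
The QUBO is invariant to relabeling bins within an angle, since the
objective sums squared residuals over all bins.

**Overlap areas.** Coefficients are *exact* pixel/strip intersection
areas, computed in closed form: the projection of a uniform point in the
unit square onto $t$ is the sum of two independent uniforms of widths
$|\cos\theta|$ and $|\sin\theta|$, so the cumulative overlap is a
trapezoidal CDF. This equals polygon clipping exactly (the test suite
keeps an independent Sutherland–Hodgman clipping oracle) but vectorizes.
Coefficients below $10^{-12}$ are pruned to keep the matrix sparse.

**Detector coverage.** With $n$ unit bins per angle, image corners extend
past the detector ends at oblique angles. The two end bins are therefore
extended to half-infinite strips, so the detector spans the image at every
angle. This keeps the per-pixel area-conservation identity
$\sum_s c_{ij} = 1$ exact for every angle — which in turn makes per-angle
mass conservation of sinograms exact — and leaves axis-aligned angles
untouched.

**Phantom.** `sheppLogan()` rasterizes the canonical ten-ellipse head
phantom by evaluating the ellipse-sum at pixel centers on $[-1,1]^2$ and
clamping to $[0,1]$. Both the classic intensity table and the
high-contrast ("modified") variant are available; the modified table is
the default, as is usual in imaging toolboxes. Pixel-center sampling was
chosen as the simplest deterministic rule; published renderings of the
phantom differ in sampling and variant, so absolute sinogram energies are
rendering-dependent and the tests assert only rendering-independent
content (zero reconstruction error and the energy $\equiv -\sum P^2$
identity). `quantize()` rounds half-up (`0.5` at one bit becomes 1), so
value 1.0 at 10 bits is 1023; `binarize()` maps strictly positive pixels
to 1.

## Solvers

`solveExhaustive()` enumerates all $2^{\text{numVars}}$ assignments in
chunks (refusing above 24 variables) and is the ground-truth oracle; ties
break to the lexicographically smallest assignment so results are
deterministic.

`solveSA()` is best-of-`numReads` single-flip Metropolis annealing over a
geometric inverse-temperature ladder, implemented in C++ with $O(\deg)$
incremental field updates. Defaults: $\beta_0 = 0.1/\langle|c|\rangle$,
$\beta_1 = 10/\min |c|$ over the nonzero coefficients, `sweeps = 10 *
numVars`, `numReads = 32`. These are deliberately generic magnitudes — hot
enough that initial acceptance is near-free, cold enough that the final
sweeps are a quench; on the 900-variable phantom models below, far smaller
read counts already reach the analytic minimum.

`solveTabu()` is multistart steepest-descent tabu search with aspiration
(a tabu variable may still flip if it improves the best energy seen);
tenure defaults to $\max(10, \text{numVars}/10)$.

Both heuristics use R's RNG, so runs are bit-reproducible under a seed.
Every solver's reported energy is re-verified by direct evaluation before
a result is returned — external samplers plugged in through the file
contract (`solveExternal()`) get the same treatment, which catches
bookkeeping drift in either party.

## What the phantom experiments show — and what they do not

The test suite and the worked examples operate under these conditions:

* the 2×2 two-bit sample with its 0°/90° sinogram (8 variables,
  enumerable), for which the printed coefficient matrix, minimum energy
  −46, Ising minimum −20 and offset −26 are reproduced exactly;
* binary 30×30 Shepp–Logan phantoms with 30 and with 18 equally spaced
  projections (900 variables). Simulated annealing (8 reads) and tabu
  search reach the analytic minimum and reconstruct the phantom with zero
  mismatched pixels — including at 18 projections, where 540 equations
  constrain 900 unknowns, illustrating recovery with fewer projections
  than the image side;
* randomized small instances ($n \le 4$, $m \le 2$) where the QUBO energy
  plus offset is checked against a directly evaluated
  $\|A\,\mathrm{decode}(q) - P\|^2$ at $10^{-9}$, and heuristic solvers
  are checked against exhaustive enumeration.

These sizes keep the default suite to about a minute of CPU. The
generator emulates noise-free, geometrically exact projections of
integer-valued samples — the regime in which the exactness argument is a
theorem. Passing tests therefore demonstrate correctness of the model
construction and solver plumbing, *not* robustness to measured data:
real sinograms carry noise, Beer–Lambert deviations, scatter and
discretization mismatch, under which the residual minimum is positive and
the minimizer need not equal the true image. For measured inputs the
package implements only the stated first calibration step
(`calibrateXray()`: subtract the empty-space mean, clamp at zero);
further physics corrections are accepted as preprocessed input. Larger
instances (50×50 and beyond) grow the coupling count roughly with
$n^2 \times$ angles $\times$ strip length, and heuristic solve quality at
fixed budget degrades — consistent with reports that tabu-style solvers
miss the ground state at $100\times100$ while stronger samplers do not;
no claim about that scale is tested here.

## Numerical choices and degenerate inputs

* Accumulation is double precision throughout; model coefficients and
  overlap areas below $10^{-12}$ are pruned.
* Real-valued (non-integer) sinograms are accepted: the bound
  $E \ge -\sum P^2$ still holds, but attainability is approximate and the
  report's energy gap quantifies it.
* A zero sinogram yields a purely positive-diagonal QUBO whose minimum, 0,
  is the all-zeros image.
* `solveSA()` tie handling: the best state is tracked across all proposals
  within a read, so a late uphill wander cannot lose a visited optimum.
* Exhaustive enumeration reports `occurrencesBest`, the number of global
  minimizers — the reconstruction tests use it to detect non-unique
  instances rather than asserting recovery blindly.

## File formats

Images and sinograms travel as headerless CSV grids with a JSON sidecar
(side length, bit depth or angle list, format version); models as
coordinate-list text (`i j value`, diagonal = linear terms) with a sidecar
carrying the variable count, offset and indexing convention; results as
JSON with the assignment as a compact 0/1 string. Integer data round-trip
losslessly; duplicate model coordinates are rejected on read with a line
diagnostic. PNG/TIFF export is for visualization only and scales by the
declared bit depth.
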