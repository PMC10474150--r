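# quboCT

CT image reconstruction as a binary quadratic ground-state problem.

`quboCT` reconstructs parallel-beam computed-tomography images by recasting
the sinogram least-squares problem as a **quadratic unconstrained binary
optimization (QUBO)** — or, equivalently, an **Ising** — model whose global
minimum encodes the attenuation image consistent with the measured
projections. It is aimed at people studying annealing-style optimization for
tomography: the package builds the models, solves them with classical
samplers (exhaustive enumeration, simulated annealing, tabu search), and
exports them in a plain-text coordinate format that external annealing
services can consume through a small file contract.

## The model

Let `I_ij` be the unknown integer attenuation at pixel `(i, j)` of an
`n × n` image, expanded in bits as

```
I_ij = Σ_{k=0..m} 2^k q_k^ij ,   q_k^ij ∈ {0, 1}.
```

A parallel-beam projection at angle `θ` and detector bin `s` is the
overlap-area-weighted sum `IP(θ, s) = Σ_ij c_ij I_ij`, where `c_ij` is the
exact area of intersection between the unit pixel square and the unit-width
detector strip. Against a measured sinogram `P(θ, s)` the reconstruction
objective is

```
F = Σ_θ Σ_s ( IP(θ, s) − P(θ, s) )² .
```

Expanding the square over the bits and using `q² = q` makes `F` a quadratic
form over binary variables. Dropping its constant term `Σ P²` (tracked as
the model *offset*) gives the QUBO; since `F ≥ 0`, every energy is bounded
below by `−Σ P²`, and an assignment attaining that bound is a *certificate*
that the decoded image reproduces the sinogram exactly. The substitution
`q = (σ + 1)/2` produces the equivalent Ising model with fields `h`,
couplings `J = Q/4`, and a tracked constant offset.

## Worked example

The bundled 2×2 sample `[[0, 1], [2, 3]]`, projected at 0° and 90°,
reproduces the model's standard worked example end to end:

```r
library(quboCT)
geom <- makeGeometry(2, 2)            # angles 0 and 90 degrees
sm   <- systemMatrix(geom)
sino <- project(toySample2x2(), sm)
sinogramValues(sino)
#>      [,1] [,2]
#> [1,]    2    4        # column sums at 0 deg
#> [2,]    5    1        # row sums at 90 deg

qm <- buildQubo(sm, sino, m = 1)      # two bits per pixel
qm
#> QuboModel: 8 variables, 20 couplings, offset 46 (min energy >= -46)
qm@linear
#> [1]  -4  -4  -8 -12 -12 -20 -16 -28

res <- solveExhaustive(qm)
res
#> SolveResult [exhaustive]: energy -46 (1/256 reads at best)
imageValues(decodeImage(assignment(res), n = 2, m = 1))
#>      [,1] [,2]
#> [1,]    0    1
#> [2,]    2    3        # the sample, recovered exactly

quboToIsing(qm)
#> IsingModel: 8 spins, 20 couplings, offset -26
solveExhaustive(quboToIsing(qm))
#> SolveResult [exhaustive]: energy -20 (1/256 reads at best)
```

The minimum energy `−46` equals `−(2² + 4² + 5² + 1²)`, the negated sum of
squared sinogram values — the analytic bound attained because an exactly
consistent image exists. At phantom scale, simulated annealing recovers a
binary 30×30 Shepp–Logan phantom from 30 (and even 18) projections:

```r
ph   <- binarize(sheppLogan(30))
sino <- project(ph, systemMatrix(makeGeometry(30, 30)))
reconstruct(sino, m = 0, solver = "sa", numReads = 8, seed = 1,
            reference = ph)
#> ReconstructionReport: achieved -189837, analytic minimum -189837, gap 2.91038e-11
#>   vs reference: 0 mismatched pixel(s), relative error 0
```

A command-line pipeline (`phantom`, `project`, `build`, `solve`,
`reconstruct`, `compare`) is available via
`inst/scripts/quboct`; see `?quboctCLI`.

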