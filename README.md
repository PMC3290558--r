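# mimnet

Stochastic simulation of collective departures on weighted social
networks, for behavioural ecologists studying how a group's affiliation
structure shapes its consensus decisions. The package asks a minimal
question: if every individual has the *same* intrinsic motivation to
leave, and joining is amplified only by affiliation toward those
already moving, how does the identity of the initiator and the shape of
the network decide whether the whole group follows?

## The model

A group of `N` individuals carries a directed affiliation matrix
`r(i,k)` (row gives, column receives); each individual distributes a
fixed unit budget, `Σₖ r(i,k) = 1`. Networks span a continuum from the
**star** (every non-central individual gives its whole budget to the
central individual `C`) to the **equal** network (all dyads share
`1/(N−1)`), plus chain and connected Erdős–Rényi generators.

Time advances in 1-s steps. Before anyone moves, each agent departs
with intrinsic probability `λ = 0.00007` per second, so the collective
initiation probability is `ψ₀₁ = Nλ = 0.0007` at `N = 10`. Once `j`
agents are moving, a resting agent `i` joins with probability

```
ψᵢ = λ + M · A(j, N) · Σₖ∈moving r(i,k),      M = 0.002
```

where the amplification `A(j, N)` is the mimetic kernel — `1` (K1),
`N−j` (K2, the calibrated default) or `j(N−j)` (K3). A replicate ends
when all have left or when 300 s pass without a departure. Group-level
behaviour is read off Monte-Carlo batches (canonically 10,000
replicates): number of departed individuals, first-joiner latency
`ΔT₁,₂`, joining duration `ΔT₁,₁₀`, split by whether `C` or a
non-central `c` initiated.

Centrality is the dominant eigenvector of the *received* affiliation
matrix (power iteration, unit norm); the **centrality index** — `C`'s
score minus the mean of the others — quantifies centralization, from 0
(equal) to 0.85 (star, reported-score convention).

## Worked example

```r
library(mimnet)

star <- build_continuum_network(10, 1, name = "star")
eigenvector_centrality(star)
#> Eigenvector centrality (received affiliation), eigenvalue 1
#>      C     c1     c2     c3     c4     c5     c6     c7     c8     c9
#> 0.9487 0.1054 0.1054 0.1054 0.1054 0.1054 0.1054 0.1054 0.1054 0.1054
#> Central individual: C
#> Centrality index: 0.8433 exact, 0.85 on reported scores

batch <- run_batch(star, sim_config(replicates = 2000, seed = 7))
summary(batch)
#> Movement summary for 'star' (N = 10, 0 void replicates excluded)
#>           class    n mean_joiners mean_first_latency mean_duration ...
#>             all 2000       5.7670           108.8746      486.7167
#>          C_init  211       9.3270             6.9336      370.4333
#>          c_init 1789       5.3471           130.7117      513.5513
#>  C_first_joiner  787       9.3164           129.9212      490.6261
#>  c_first_joiner  409       8.3081            68.3765      478.1987
#> Absolute C-vs-c differences (initiator classes):
#>       mean_joiners mean_first_latency      mean_duration
#>             3.9799           123.7780           143.1179
```

The asymmetry is the star network's signature: when the central
individual initiates, nearly everyone follows within seconds
(mean ≈ 9.3 departed, first joiner after ≈ 7 s); when a non-central
individual initiates, the movement usually dies unless `C` joins
(mean ≈ 5.3 departed, first joiner after ≈ 131 s). On the equal
network the same contrasts vanish — consensus becomes shared. The
`reproduce()` driver runs this comparison across the whole continuum
and fits the centrality-response curves; `vignettes/` explains the
model, the kernel calibration and the numerical conventions in detail.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/mimnet.R centrality --generator star
Rscript inst/cli/mimnet.R summarize --generator star --replicates 2000 --seed 7
Rscript inst/cli/mimnet.R reproduce --replicates 10000 --seed 1 --out report/
```

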