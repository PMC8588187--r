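# casenmr

Computer-assisted structure elucidation (CASE) of small organic molecules
from routine NMR data, as an R package. Given a molecular formula and the
1D/2D correlation tables a spectroscopist would extract (13C peak list with
DEPT/edited-HSQC multiplicities, HSQC, COSY, HMBC), `casenmr`:

1. translates the correlations into heavy-atom connectivity constraints
   (COSY assumed 2–3 bonds when strong, 3–4 when weak; HMBC 2–3 bonds) and
   lays out a **molecular connectivity diagram** (MCD) with per-carbon
   hybridization/hetero-neighbor properties inferred from shift ranges;
2. **exhaustively generates** every constitutional isomer consistent with
   the MCD — sound, complete up to isomorphism, duplicate-free;
3. detects **contradictions** caused by non-standard correlations (true
   coupling paths of 4+ bonds) and handles them by **fuzzy structure
   generation**: subsets of up to *m* suspect connectivities are elongated
   by *a* bonds (or deleted, by the `a = 16` convention), generation is
   re-run per subset, and the outputs are unified — for *N* connectivities
   and subset size *m* there are C(*N*, *m*) combinations
   (C(60, 5) = 5,461,512, which is why *m* stays small);
4. **ranks** candidates by empirical 13C shift prediction: a fast additive
   increment scheme (deviation d_I) for every candidate, then
   environment-code (HOSE-style) re-scoring (d_A, plus d_H for protons) of
   the top 50, with optimal predicted-to-observed assignment solved as a
   min-cost bipartite matching restricted within multiplicity classes — a
   best candidate with d_A > 5.5 ppm is flagged as indirect evidence of an
   undetected non-standard correlation;
5. optionally accelerates generation with **user fragment databases**
   (fragments matched to the spectrum within a tolerance E, default
   1.5 ppm, and embedded into the MCD as fixed bonds), and
6. selects **relative stereochemistry** from NOE distance classes (strong
   1.8–2.5 Å, medium 2.5–4.0 Å, weak 4.0–5.0 Å) by enumerating
   stereoisomers, embedding conformers with a built-in distance-geometry
   provider, and ranking configurations by a penalty with r⁻⁶ conformer
   averaging.

A forward **simulator** generates correlation tables from known structures
(with controlled long-range injections, drops and noise), so the entire
loop is testable from first principles without spectrometer data; a
12-molecule fixture corpus ships with the package.

Who it is for: spectroscopists and cheminformaticians who want a
transparent, scriptable, fully tested desk-scale CASE engine — not a
replacement for commercial systems with million-fragment knowledge bases.

## Worked example

Simulate vanillin's correlation data from its structure, then elucidate
from the data alone:

```r
library(casenmr)
mols <- fixture_molecules()            # the packaged corpus, shifts assigned
g <- mols$vanillin
set <- simulate_correlations(g, sim_options(seed = 7))
print(set)
#> <correlation_set> C8H8O3: 8 13C peaks, 5 1H peaks, 24 correlations

db <- build_shift_db(unname(mols))     # environment-code shift database
res <- elucidate(set, db = db)
print(res)
#> <elucidation> common mode: 12 ranked candidates
#>   #1  d_I=1.22  d_A=0.00  C8H8O3
#>   #2  d_I=7.30  d_A=9.68  C8H8O3
#>   #3  d_I=7.30  d_A=9.68  C8H8O3
#>   #4  d_I=1.22  d_A=12.87  C8H8O3
#>   #5  d_I=10.17  d_A=13.25  C8H8O3
```

Twelve constitutions satisfy the constraints; the true one is ranked
first. `d_I` is the fast incremental 13C deviation in ppm, `d_A` the
accurate environment-code deviation — 0.00 here because the database
contains vanillin's own environments, and nearly 10 ppm for the runner-up.
The run log records every stage decision:

```r
res$log[, c("stage", "detail")]
#>         stage                               detail
#> 1        read         8 13C peaks, 24 correlations
#> 2         mcd             11 atoms, 14 constraints
#> 3 consistency feasible=TRUE suspicious=0 (stage 3)
#> 4    generate           common mode: 12 structures
#> 5      verify                  12 of 12 pass audit
#> 6        rank             12 ranked; best d_I=1.22
```

Contradictory data take the fuzzy route automatically: with a 4-bond HMBC
injected, `elucidate()` reports `fuzzy` mode, the consistency stage flags
the suspicious connectivities, and the truth reappears in the union. A
command-line wrapper is installed as `exec/casenmr`
(`elucidate`, `simulate`, `predict`, `fragments`, `stereo` subcommands).

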