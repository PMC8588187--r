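---
title: "Structure elucidation from NMR correlation data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure elucidation from NMR correlation data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Computer-assisted structure elucidation (CASE) asks: given a molecular
formula and the correlations observed in routine 2D NMR experiments, which
constitutions (heavy-atom skeletons with bond orders and attached-hydrogen
counts) are consistent with the data, and which of them best explains the
observed chemical shifts? `casenmr` implements the full loop at desk scale:
constraint extraction, exhaustive isomer generation, contradiction handling,
empirical shift-based ranking, and NOE-based relative stereochemistry.

## Data model

The unit of input is a *correlation set*: a formula, 1D peak tables
(13C with DEPT/edited-HSQC multiplicities and degeneracy counts for
symmetry-equivalent carbons; 1H), and 2D records for HSQC, COSY, HMBC
(optionally 1H-15N HMBC and NOESY), each a pair of chemical-shift
coordinates with an intensity class. 2D coordinates are positions in ppm,
not atom labels, so `match_shifts()` snaps each coordinate to the nearest
1D peak within a tolerance (defaults 0.1 ppm for 13C, 0.01 ppm for 1H —
the data themselves do not fix these, so they are configurable). A
coordinate with two or more peaks in tolerance is *marked ambiguous* and
later handled disjunctively; it is never resolved silently, because in
practice such overlap is resolved by the spectroscopist, not the software.

### Coupling-length policy

A COSY response is assumed to span 2–3 bonds when strong and 3–4 bonds when
weak; an HMBC response 2–3 bonds. These are the package defaults and can be
overridden per file (`policy` records) or per call. The arithmetic that
turns them into skeletal constraints removes the terminal C–H bonds: a COSY
between protons whose coupling path is $n$ bonds long constrains their
carrier carbons to $n-2$ skeletal bonds; an HMBC proton-to-carbon response
of $n$ bonds constrains the carrier-to-target distance to $n-1$. Duplicate
constraints on one atom pair intersect their intervals; an empty
intersection is reported as a contradiction naming the records.

## The molecular connectivity diagram (MCD)

`build_mcd()` lays out one skeleton atom per heavy atom: carbons come from
the 13C peak table (a peak with degeneracy $d$ contributes $d$
interchangeable atoms), heteroatoms are added unplaced, and the hydrogen
balance becomes the free-H count (OH/NH protons). Each carbon carries
properties from the *atom property correlation table* (APCT): a set of
shift-range rules assigning the allowed hybridizations (sp3/sp2/sp) and a
hetero-neighbor flag (forbidden, obligatory, undefined). The packaged table
(`inst/apct.yaml`, ~10 rules) is deliberately conservative: for example
90–100 ppm allows both sp3 and sp2, because a signal there can belong to
either; 60–90 ppm allows sp3 and sp, covering both oxygenated sp3 carbons
and alkynes. The table is configuration, not code, and was constructed so
the package's own predicted shifts map back to the correct hybridizations
on the fixture corpus. Nitriles and alkynes above 90 ppm are the known
blind spot of the default table.

Constraints over degenerate peak groups are *existential*: the constraint
holds if some pair of carrier atoms lies in range. This is the faithful
reading of symmetric data — the observable cannot distinguish which member
of an equivalent set responds — and it is also what makes symmetric
molecules harder: a long-range response between degenerate peaks may alias
onto an admissible short-range pair.

## Contradiction detection

Real data contain *non-standard correlations* (NSCs): responses whose true
coupling path is 4–6 bonds, which make the default-range constraint set
unsatisfiable — or worse, satisfiable only by wrong structures. Detection
is a three-stage heuristic:

1. **Pigeonhole** — an atom's forced distance-1 partners cannot exceed its
   free valence.
2. **Interval propagation** — triangle-inequality closure of pairwise
   distance upper bounds against lower bounds, plus a ball-size bound (the
   number of atoms forced within radius $r$ of an atom cannot exceed what
   its free valence can branch to).
3. **Bounded trial generation** — a node-budgeted exhaustive run; an empty
   complete result proves infeasibility.

When infeasibility localizes to an atom, every constraint incident to it is
marked suspicious; a stage-3 proof without localization marks all
constraints. Detection is heuristic by design: a constraint set that is
wrong but satisfiable (an "implicit" NSC) is undetectable by logic alone,
and in the closed-loop experiments below two of the nine injected-NSC cases
are of exactly this kind. The indirect symptom — a best-ranked candidate
whose accurate-method deviation exceeds 5.5 ppm — is flagged by the ranking
stage instead.

## Structure generation

`generate()` enumerates every molecular graph satisfying the MCD: element
valences (C 4, N 3, O 2 by default; pentavalent nitrogen behind an option),
fixed attached-H counts for carbons with edited multiplicities, a free-H
budget over flexible atoms, per-atom pi-bond budgets implied by the allowed
hybridizations (sp3 0, sp2 1, sp 2), hetero-neighbor flags, user-fixed
bonds, connectivity, and every distance constraint. The search assigns
bond orders to atom pairs in row-major order (compiled code), pruning with:

- exact-degree and H-budget bookkeeping at each completed row;
- an optimistic-distance bound per constraint — breadth-first search over
  current bonds plus every still-assignable pair with spare capacity
  (committed hydrogens excluded; a midpath atom crossed by two potential
  bonds needs two spare valences) — since adding bonds only shortens
  distances, a pair that cannot come within `dhi` even optimistically, or
  that is already closer than `dlo`, kills the branch;
- symmetry breaking over interchangeable atoms (identical element,
  attached H, properties, peak identity and constraint membership): the
  bond matrix must be lexicographically no smaller than its image under the
  transposition of adjacent group members, so each isomorphism orbit keeps
  its lexicographically greatest labeled representative.

Survivors are deduplicated by a canonical key (BLISS canonicalization of a
vertex-colored transform in which each bond becomes an auxiliary vertex
colored by its order), giving one representative per isomorphism class.
The output contract — sound, complete up to isomorphism, duplicate-free —
is audited in the tests against an independent brute-force enumerator and
an independent backtracking isomorphism matcher.

`verify_candidate()` re-derives every requirement from scratch (BFS path
lengths, pi counts, H bookkeeping) and is used both as a post-hoc audit and
as the spectral filter for fuzzy-generation unions.

## Fuzzy structure generation (FSG)

When the constraint set is contradictory, subsets of up to `m`
connectivities are declared suspicious and *elongated* by `a` bonds — or
*deleted*, encoded by the convention `a = 16` — and generation is re-run
per renewed constraint set, with the union of outputs deduplicated. The
eligible set is the suspicious set when detection localized one, else all
$N$ connectivities; the theoretical combination count is
$\sum_{i \le m} \binom{N}{i}$ (the single-size count $\binom{N}{m}$ is also
available: $\binom{60}{5} = 5{,}461{,}512$, about 5.5 million, is the scale
that motivates keeping $m$ small). Each combination is pre-tested with
stages 1–2 of the consistency check and skipped when already infeasible;
the result records theoretical versus processed combination counts,
generated/filtered/unique structure counts and wall time. The pipeline
driver escalates $m = 1, 2, \dots$ (default cap 3) until a non-empty result
appears, in both the detected-contradiction and the empty-common-result
cases.

Elongation only relaxes constraints, so common-mode output is always a
subset of fuzzy output — a property test in the suite.

## Shift prediction and ranking

Two predictors with complementary cost/accuracy:

- **Incremental (fast, deviation $d_I$)** — base value per carbon class
  (sp3, sp2, carbonyl split by O/N substitution, sp) plus additive
  alpha/beta/gamma increments per substituent element, from an editable
  YAML table with rounded textbook-flavored values. O(atoms), used to score
  every candidate.
- **Environment codes (accurate, deviation $d_A$)** — the canonical
  serialization of the induced subgraph within $k$ bonds of a carbon, root
  marked, $k \le 4$. A shift database stores count/mean/sd per code;
  prediction looks up depth 4 and falls back 3, 2, 1; unmatched carbons get
  a flagged element-class default. Proton means ride along for a $d_H$
  deviation when 1H data are present.

A deviation compares predicted against observed by a minimum-cost bipartite
assignment (Hungarian algorithm), by default restricted within multiplicity
classes — CH3 predictions may only map to CH3 peaks — since edited peak
tables carry that information and it shrinks the assignment polytope
(configurable off; the tests check optimality against the exhaustive
permutation minimum).

Ranking follows a four-step protocol: $d_I$ for all candidates; duplicate
families collapse to their best-assigned member; sort by $d_I$;
environment-code re-scoring of the top `k_accurate` (default 50)
candidates, which are re-ordered by $d_A$ (ties by $d_I$, then canonical
key, making the ranking order-deterministic). A best candidate with
$d_A > 5.5$ ppm (configurable) is flagged suspicious — the indirect NSC
symptom.

## Fragment mode

A user fragment database is cut from assigned structures: atom-centered
spheres of radius 1–3 and small rings with their first shell, up to a size
cap, deduplicated by canonical key with per-atom shift averaging (the
per-atom spread across merged occurrences is kept and widens the search
tolerance, since a merged mean averages distinct parent contexts).
`search_fragments()` declares a fragment *found* when an injective
carbon-to-peak map exists with per-carbon deviation within the tolerance
`E` (default 1.5 ppm), compatible multiplicities, and no peak-level
constraint demanding a shorter distance than the fragment's internal
topology allows (an internal distance *above* the range is not a
contradiction — supergraph paths can only shorten). Found fragments are
embedded as fixed bonds into MCD variants (non-overlapping combinations of
at least `min_fragments_per_mcd` fragments, ranked by skeletal coverage and
capped — the cap-and-rank policy is this package's own choice), which can
shrink the generation search by orders of magnitude while preserving the
output (a closed-loop property test).

## Relative stereochemistry from NOE

NOE/ROE responses are modeled as three distance classes between protons —
strong 1.8–2.5 Å, medium 2.5–4.0 Å, weak 4.0–5.0 Å, with no response
expected beyond 5.0 Å. The printed source for these ranges lists
"2.5–4.0" twice; we read the weak class as 4.0–5.0 Å, the only assignment
consistent with the 5.0 Å absence cutoff (configurable). Quantitative
volume-to-distance calibration is deliberately not attempted: crosspeak
intensities depend on mixing time and relaxation, so only the class model
is used.

`enumerate_stereoisomers()` detects tetrahedral stereocenters (sp3 carbons
whose branches — components after deleting the center, rooted at each
neighbor — are pairwise distinct) and stereogenic acyclic C=C double bonds,
then quotients the $2^k$ parity/EZ assignments by the constitution's
automorphism group (an automorphism permutes centers and multiplies each
parity by the sign of the induced substituent permutation) and by the
global mirror: only relative configurations remain. Exhaustive enumeration
with a cap (default $2^{14}$) replaces any stochastic search over
configurations. Configuration-dependent ("para") stereocenters and ring
double-bond geometry are not modeled.

Each configuration is embedded by a small distance-geometry provider:
exact bonded and geminal distances, 1-4 windows (syn to anti) around
single bonds, exact cis/trans 1-4 distances across stereogenic double
bonds, chiral-volume targets for parities, planarity terms for sp2
centers; random metric embeddings refined by BFGS. Any provider honoring
the `embed_conformers()` contract (configuration in, conformers with
coordinates and an energy proxy out) can be substituted. The penalty per
constraint is zero inside the class range and the squared distance to the
nearest bound outside, with the effective distance
$r_\mathrm{eff} = (\overline{r^{-6}})^{-1/6}$ averaged over conformers —
the inverse-sixth-power weighting that governs NOE intensity. The exact
penalty functional is this package's own choice (the class model pins down
only the ranges); it is validated by correct discrimination on rigid
fixtures, e.g. the vinyl-proton pair of 2-butene at ~2.5 Å (cis) versus
~3.1 Å (trans) under one strong constraint.

## The simulator and what passing tests mean

`simulate_correlations()` inverts the data model: HSQC per protonated
carbon class, COSY for 3J proton pairs, HMBC for 2–3-bond (H, C) pairs,
optional 1H-15N HMBC, with records collapsed over symmetry classes and
degeneracy counts kept. Controlled corruptions: *injected NSCs* (a
correlation whose true path is 4 bonds, which the elucidator reads as
2–3), record drops, and Gaussian coordinate noise, all under one seed.

Reference shifts for the 12-molecule fixture corpus are the package's own
incremental predictions plus fixed per-symmetry-class offsets, spread so
that distinct classes stay at least 0.8 ppm apart — *internally consistent
ground truth with no claim of matching literature spectra*. Proton shifts
derive from carbon shifts by a fixed affine map. Consequently the closed
loop demonstrates constraint logic, generation, contradiction handling and
ranking behavior; it does not demonstrate prediction accuracy on real
spectra, which would require an external assigned-shift corpus.

The corpus (8–16 heavy atoms: indole, quinoline, naphthalene, para-xylene,
4-methoxybenzaldehyde, a menthone-like and an acyclic terpenoid-like
aliphatic, 1,3-dimethyluracil, para-benzoquinone, coumarin, vanillin,
2-acetylpyridine) spans fused aromatics and N-heteroaromatics, symmetric
para-disubstituted benzenes, terpenoid-like aliphatics and proton-deficient
structures with hydrogen-free ("silent") carbonyl substructures. Sizes were
chosen once so the whole closed loop — including fuzzy generation over
every injected-NSC case — runs in minutes on one CPU; molecules whose
1H-13C data leave thousands of consistent constitutions (heavily
proton-deficient alkaloids such as caffeine) are genuinely underdetermined
without fragment knowledge or 15N data and are outside the corpus; fragment
mode is the intended route for them. An aromatic ring is represented by a
fixed Kekulé pattern, so simulated symmetry classes are those of the
bond-order-labeled graph (naphthalene shows five aromatic CH classes, not
two); aromatic perception is out of scope throughout.

A per-molecule injected-NSC case exists only when some single 4-bond
response actually *excludes* the true constitution from the common-mode
solution set (verified by an exact assignment search); in symmetric
molecules every long-range response may alias onto an admissible
short-range pair, and such molecules contribute no NSC case — which is the
chemically correct statement.

## Numerical and engineering choices

- Determinism: atom order is input order; dedup keeps the first-found
  representative until ranking replaces it with the best-assigned one;
  all stochastic steps (simulation, embedding) take explicit seeds; search
  budgets are node counts, not wall-clock, so results are
  machine-independent.
- Degenerate inputs: geminal COSY (both protons on one carbon) collapses
  to no constraint, since the generator works on heavy-atom distances;
  shift ties in matching are marked, not broken; a half-integer degree of
  unsaturation warns rather than fails.
- The generation cap (`max_structures`, default 50,000 labeled structures)
  and node budget flag the output incomplete rather than erroring.
- Problem sizes in the shipped tests: fixtures of 8–16 heavy atoms,
  brute-force oracle limited to 7; these are the package's choices for a
  desk-scale suite.

## Known limitations

- No aromatic perception, tautomers, charges, isotopes or radicals.
- The APCT default table trades precision for safety; user editing is
  expected for exotic chemistry.
- Incremental predictions are rough (several ppm); they only need to rank
  within the head that the environment-code method re-scores.
- Proton-deficient molecules with large silent substructures defeat
  1H-13C-only elucidation at desk scale; supply fragments or more data.
- The distance-geometry embedder targets rigid and semi-rigid molecules;
  conformational ensembles of floppy systems are averaged only through the
  r^-6 rule over a handful of conformers.
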