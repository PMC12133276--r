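---
title: "Classifying enzyme active sites by residue signature clustering"
author: "siteclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying enzyme active sites by residue signature clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteclust)
```

## The problem and the model

Within a large enzyme family, the residues lining the substrate-binding
pocket carry most of the signal about reaction and substrate specificity:
two members whose pocket residues are chemically equivalent are likely to
catalyse the same reaction, while a full-length sequence tree mixes that
signal with scaffold divergence. `siteclust` classifies a family into
putative isofunctional groups from those pocket residues alone.

The method has four stages:

1. **Pocket definition.** An ordered list of reference residue positions
   `(chain, residue number, insertion code)`, obtained from a P2RANK
   predictions file (highest ligandability score by default), from ligand
   proximity in a holo structure (heavy atoms within a cutoff of a bound
   ligand), or from a user-supplied residue list.
2. **Site extraction.** Each family member is aligned to the reference —
   either by a structural aligner whose aligned-FASTA output is consumed
   (3D mode), or through the column correspondence of an MSA (2D mode).
   The pocket positions are located in the reference row and the target
   row's characters at those columns form the member's *active-site
   string*: one character per pocket position over the 20 residues, `X`
   (unknown) and `-` (gap). A member aligned to a reference below the
   identity gate (default 30%) is discarded, as is any site string with
   more than a threshold fraction of gaps (default 0.5); both discards
   are logged with the member id and reason.
3. **Scoring.** All site pairs are compared with an amino-acid distance
   matrix; the site distance is the positional mean, so the n x n score
   matrix is symmetric, has a zero diagonal and lies in [0, 1] by
   construction without a rescaling pass.
4. **Clustering.** DBSCAN on the precomputed score matrix, with
   parameters chosen automatically unless supplied. Clusters are numbered
   1..K by decreasing size; noise points carry label 0 and are reported
   in an `unclustered` section. Each cluster is summarised by a position
   frequency matrix, information-content profile and consensus site, and
   any cluster can be re-clustered on its own submatrix.

## The amino-acid distance matrix

The default matrix groups the 20 residues into six physicochemical
classes — aliphatic `{A,V,L,I,M}`, aromatic `{F,W,Y}`, polar
`{S,T,N,Q,C}`, basic `{K,R,H}`, acidic `{D,E}` and conformationally
special `{G,P}` — and sets

* `d(a, a) = 0`,
* `d(a, b) = 0.3` for distinct residues of the same class,
* `d(a, b) = 1.0` across classes,
* `d(residue, '-') = 1.0`, `d('-','-') = 0`,
* `d(X, anything) = 0.5`, `d(X, X) = 0`.

The within-class value 0.3 makes conservative substitutions cheap
relative to class changes while keeping them distinguishable from
identity; gaps are as far from residues as a class change; unknown
residues are mildly penalised rather than treated as matches or gaps.
The matrix is symmetric, bounded by [0, 1] and satisfies the triangle
inequality (verified exhaustively over all symbol triples in the test
suite), so the score matrix is a genuine semi-metric. Any matrix in the
same labelled-TSV layout can be dropped in via `load_distance_matrix()`,
which validates every invariant and names the violated one.

No position weighting is applied: all pocket positions count equally in
the site distance.

## Automatic DBSCAN parameters

`min_samples` is `max(5, round(ln n))` — a floor of five points keeps
tiny accidental aggregates from becoming clusters, and the logarithmic
growth tracks family size weakly.

`eps` is read off the k-distance curve (each member's distance to its
`min_samples`-th nearest neighbour, sorted ascending). Site score
matrices are nearly discrete — many members share identical sites, so
the curve is a staircase with a large flat bottom — which defeats
curvature-based elbow detection: the strongest bend is usually at the
bottom plateau, far below any useful radius. Instead the distinct curve
values between the 80th and 95th percentile ranks (the upper bend, where
the dense regime hands over to density outliers) are treated as
candidate radii; DBSCAN is run at each and the candidate maximising a
silhouette sum over clustered members (noise contributing zero) is kept.
The direct scoring step matters because site distances concentrate on a
few levels: a fixed quantile can land exactly on the level of a rare
"bridge" pair — two core points of different groups whose sites happen
to coincide, e.g. through a shared gap at a discriminating position —
and a single such edge merges two clusters. The silhouette score
collapses for such merges and the selection avoids them. The procedure
is deterministic, and both parameters remain user-overridable
(`--eps`/`--min-samples`); the values actually used, and whether they
were chosen automatically, are echoed to `run_metadata.yaml`.

With fewer than five members automatic selection refuses to guess and
asks for explicit parameters.

## The synthetic family generator

`generate_family()` emulates the one structure this method relies on: a
homologous family whose pocket residues fall into a few chemically
distinct patterns.

* Group signatures share a base signature and differ at `n_distinct`
  positions (default 3), where every group draws its residue from a
  *different* physicochemical class, so between-group site distances are
  at least `n_distinct / L` under the default matrix.
* Within-group noise substitutes residues *within* their class at rate
  `p_noise` (default 0.05) — modelling the premise that chemically
  equivalent residues belong to the same functional group — and gaps
  appear at rate `p_gap` (default 0.02).
* Non-site positions start from one family base scaffold (uniform over
  the 20 residues) and diverge per member at rate `p_scaffold` (default
  0.2), giving members roughly 80% full-length identity to the
  reference — a realistic homologous family, comfortably above the 30%
  identity gate. (Fully independent random scaffolds would put every
  member near 25% identity and the pipeline's own gate would discard
  the whole family.)
* The MSA contains one column per scaffold position and the per-member
  pairwise alignments are exactly the MSA-induced pairs, so 2D and 3D
  extraction agree character for character by construction — this is
  the fixture on which the 2D/3D consistency property is tested.
* A noise-free reference member (`REF`, planted in group 1) provides the
  reference row, sequence and pocket. Seeds are mandatory; identical
  seeds give identical families.

What these fixtures deliberately do **not** model: insertion columns in
the MSA relative to the reference (real aligners produce them; the
mapping code handles them and is tested on hand-built cases, but the
generator keeps alignments column-consistent so that 2D/3D agreement is
exact), realistic folds (toy structures are ideal helices with a
single-atom ligand at the site centroid), and phylogenetic correlation
between members. Passing the planted-recovery test therefore shows that
the distance matrix + DBSCAN machinery recovers chemically coherent
groups under positional noise and gaps; it does not certify performance
on families whose subfamily structure is driven by insertions or by
correlated evolution.

Planted-group recovery is measured as the adjusted Rand index between
the clustering and the planted labels, with each noise point counted as
its own singleton cluster — lumping all noise into one pseudo-cluster
would count unrelated outliers as agreeing with each other.

## Numerical and procedural choices

* Identity is counted over columns where both rows are non-gap, so
  terminal-gap padding differences between aligners do not change it;
  the 30% gate is inclusive (exactly 30% passes).
* The gap-discard threshold is a fraction of site positions (default
  0.5, i.e. a site more than half gaps is discarded).
* DBSCAN uses closed balls (distance <= eps); border points are claimed
  by the first cluster reaching them under index-order expansion, making
  results reproducible for a fixed input order. Cluster numbering is by
  decreasing size with ties to the cluster containing the earliest
  member.
* The fallback global aligner (used only when no alignment file is
  supplied for a target) is Needleman-Wunsch with BLOSUM62 and affine
  gaps: a run of g gaps costs `10 + 0.5 (g - 1)`. Trace-back ties prefer
  an aligned pair over a gap in the target row over a gap in the
  reference row. Its scores are verified against exhaustive alignment
  enumeration on short pairs.
* PDB parsing keeps altloc blank or `A` only (one deterministic
  conformer); water is excluded from HET groups; modified residues map
  to their parent one-letter code where known, otherwise to `X`.
  Ligand-proximity detection uses heavy atoms only with a default 4.5 A
  first-shell cutoff.
* Consensus ties prefer residues over gap, then the lexicographically
  smallest symbol. Information content is `(1 - f_gap) (log2 20 - H)`
  bits with `H` the Shannon entropy of the non-gap composition; no
  small-sample correction or pseudocounts.
* Internally all column indices are 0/1-based R conventions; every
  user-facing report uses 1-based positions and author numbering.

## Problem sizes used by the checks

The test suite and the acceptance script regenerate everything they
measure: planted families of 5 groups x 40 members (site length 12,
sequence length 60) over 20 seeds for recovery; 100 random distance
matrices (n <= 50) against a brute-force DBSCAN; 100 random toy
structures against all-pair atom distances; 200 random short sequence
pairs against exhaustive alignment enumeration. These sizes keep each
oracle exact (enumeration spaces stay small) while exercising every
branch of the implementation.

## Known limitations

* DBSCAN inherits single-linkage behaviour between core points: two
  genuinely distinct groups connected by a chain of intermediate sites
  can merge at any eps that accommodates within-group spread. The
  silhouette-guided selection avoids the discrete-level version of this
  on site data, but families with a true density continuum between
  subfamilies will cluster coarsely — that is what the re-clustering
  option is for.
* The default distance matrix is a documented class-based construction,
  not a fitted object; families whose specificity turns on finer
  distinctions (e.g. within the polar class) may need a custom matrix
  via `load_distance_matrix()`.
* 2D mode is only as good as the MSA: misaligned reference columns
  translate directly into wrong site strings. Comparing 2D and 3D
  extractions with `compare_2d_3d()` is the recommended sanity check
  whenever structures are available.
* Automatic parameters assume the family contains at least one dense
  group; a family of singletons will come back mostly unclustered.
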