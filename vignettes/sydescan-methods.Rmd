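---
title: "Methods: SLiM-based interactor prediction for the SYDE C2-RhoGAP family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SLiM-based interactor prediction for the SYDE C2-RhoGAP family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sydescan)
```

# The problem

SYDE1 and SYDE2 are RhoGAP proteins with central C2 and RhoGAP domains
flanked by long intrinsically disordered regions (IDRs). Short linear
motifs (SLiMs) -- 3- to 11-residue patterns hosted in IDRs -- mediate many
of their transient interactions, modifications and degradation signals.
Because SLiMs are short, they occur constantly by chance; a credible
in-silico interactor prediction therefore needs three orthogonal filters:

1. **pattern probability** -- a match must be rarer than a stated
   background threshold;
2. **disorder localization** -- a functional SLiM should sit in an IDR;
3. **ortholog conservation** -- the match should persist at the aligned
   position across orthologs.

`sydescan` implements this selection procedure end to end, together with
the surrounding analyses (domain percent identity, a distance-based
ortholog phylogeny, and assembly of a tiered interaction network), and a
synthetic ortholog-family generator so that the whole pipeline can be
exercised and scored against a known truth without any downloads.

All coordinates, everywhere in the package, are 1-based and inclusive.

# The motif catalog

The packaged catalog (`load_catalog()`) carries 15 motif classes with 19
instance peptides on SYDE1/SYDE2, transcribed from the published
interactor table, plus site annotations (the C-terminal Cys734
palmitoylation site and two nuclear-export-signal candidates). Each class
stores the published consensus *text*, its printed probability score
(metadata only -- never recomputed), and a *machine pattern* in a bounded
dialect: literals, `.`, residue classes `[KR]`, negated classes `[^P]`,
and bounded quantifiers (`?`, `{m}`, `{m,n}`). Unbounded repetition is
rejected at load time, which guarantees every pattern expands into a
finite set of fixed-length residue-class strings -- the form needed for
exact scanning and closed-form probabilities.

The published table names the classes and consensus prose but not machine
regexes, so the shipped patterns are a design choice under one hard
constraint (the *catalog invariant*, enforced by `validate_catalog()` and
the test suite): every pattern must match inside each of its printed
instance peptides. Where the canonical class regex satisfies the
invariant we use its shape; two classes need a documented decision:

* **MAPK D-motif**: packaged as `[KR][KR].{2,4}[ILVM].[ILVF]`, requiring
  the basic *pair* present in the printed instance. The looser one-basic
  reading has a background probability above the `1e-2` threshold under
  the packaged composition, which would contradict the published
  retention of the motif; the two-basic reading is an equally standard
  statement of the D-motif consensus.
* **Cyclin docking (RxL)**: packaged with the cyclin-recruitment shape
  `[RK].L.{0,1}[FYLIVMP]`, treating RxL as the operative core as the
  published description does.
* **14-3-3**: the printed instance does not fit the classical mode-I
  consensus, so the packaged pattern (`R..[ST][^P][^P]`) simply honors
  the catalog invariant without guessing which binding mode was meant.

Two coordinate inconsistencies in the source table are kept visible
rather than silently fixed: the 11-residue cyclin-docking peptide is
stored with a length-consistent end (176) and the printed end recorded as
metadata, and the two overlapping C-terminal SYDE1 instances (positions
641-647 vs 645-651) are transcribed verbatim even though both cannot be
simultaneously correct.

# Scanning and the probability score

`scan_motifs()` reports **all** matches, overlapping included, ordered by
start then length. `X` is tolerated in sequences but never matches any
residue class, including negated classes.

`site_probability()` is the package's internal analogue of a motif
probability score: the probability that a random position begins a match,
computed as the sum over length variants of the product over positions of
the background mass of the allowed set. The packaged background is a
SwissProt-like composition (`background_frequencies()`); it is explicitly
*not* a replica of any external resource's background model, so printed
scores are stored but never compared numerically. The Monte-Carlo
property test checks the closed form against match counts on 10^6 random
residues (within three standard errors); note the quantity is an expected
match *count* per position (variants can overlap), which only matters for
variable-length patterns.

# Candidate selection

`select_candidates()` retains a match iff

1. `site_probability < 1e-2` **or** the class is whitelisted,
2. the match overlaps a disorder region (when disorder is required), and
3. the conserved fraction is at least 0.8 (when conservation was
   assessed).

Matches with *unknown* disorder or conservation are retained but flagged
(`"unknown"` verdicts); every row carries all three verdicts for audit.
The default whitelist holds the modification-site classes (CK1, CK2,
GSK3) and the SH3 class: their published scores sit above the threshold
and the published procedure selects them on disorder propensity plus
annotated phosphosites, a different criterion from the
probability cut-off. The whitelist reproduces the published retained set
without moving the threshold itself.

# Disorder

Two first-class routes provide disorder intervals:

* **Import** (`import_regions()`): annotation TSVs in the same schema as
  all other interval tables, for output of external consensus predictors.
  Imported intervals take precedence and are unioned with the surrogate
  in the pipeline's `"both"` mode.
* **Surrogate** (`foldindex_profile()`): the published fold-index form
  `2.785 <H> - |<R>| - 1.151` over a window (default 51, truncated at the
  termini, not padded), with `<H>` the Kyte-Doolittle hydropathy rescaled
  by `(KD + 4.5)/9` and `<R>` the mean net charge (K, R: +1; D, E: -1;
  H: +0.5). Negative scores mark disorder. `call_regions()` keeps
  negative runs of at least 5 residues and merges runs separated by
  fewer than 3.

The surrogate is a stand-in for the consensus servers used in the
original analysis, which are not algorithmically described; the import
path is the faithful route for real data. Published disorder boundaries
are not reproduced anywhere, and no check depends on exact boundaries.

# Conservation and domain identity

`global_align()` wraps an optimal Needleman-Wunsch global alignment with
affine gaps (BLOSUM62, open 10, extend 0.5; a gap of length *k* costs
`open + k * extend`). Unknown residues score 0 with a warning. The test
suite checks the score against an independent exhaustive/state-machine
oracle for sequences up to length 8.

`percent_identity()` -- identical columns over all alignment columns,
reported to 0.1 -- operationalizes the published domain "homology"
percentages. Whether those were identity or similarity, and over exactly
which boundaries, is not stated in the source; that is why every
comparison against them carries a +/-1.5 percentage-point tolerance and
why domain boundaries are an *input* (an InterProScan-derived table),
never computed.

`motif_conservation()` maps a reference match through a multiple
alignment: the match's columns are widened by +/-5 columns (slack), each
ortholog's ungapped residues in that window are extracted, and the
ortholog counts as conserved iff the class pattern matches inside the
window. The conserved fraction is the mean over orthologs assessed.
Alignments come from aligned FASTA (e.g. MAFFT output) or, for the
synthetic path, from the built-in star-progressive aligner
(`star_align()`, center = reference) -- adequate for close orthologs, not
a general MSA tool.

# Phylogeny

The published ortholog tree was a maximum-likelihood analysis; that is
out of scope here and `sydescan` deliberately ships a distance surrogate
instead: `protein_distance()` uses the Kimura-style correction
`d = -ln(1 - p - 0.2 p^2)` on the mismatch fraction over shared ungapped
columns (saturated pairs capped at 10 with a warning), and
`neighbor_joining()` implements standard NJ with a deterministic
tie-break (lexicographically smallest cluster pair; clusters labelled by
their smallest member leaf) and negative branch estimates clamped to
zero. NJ is exact on additive matrices, which is the tested and accepted
surface -- recovery of synthetic clades, not the published topology.
`bootstrap_supports()` resamples alignment columns with replacement
(resampling depends only on the seed and column count, so supports are
invariant to taxa order), rebuilds the tree per replicate, and reports
the percentage of replicates containing each internal bipartition of the
full-data tree. Newick output quotes labels containing metacharacters.

# Network assembly

`assemble_network()` combines three edge sources into one graph with
SYDE1/SYDE2 hub nodes (plus DmSyd1 when its curated rows are included):

* curated experimentally supported interactions (packaged TSV; rows
  backed by any low-throughput method -- coIP, pull-down, Y2H, ITC, FLAP
  -- get tier `curated-low-throughput`, AP-MS-only rows
  `high-throughput-or-predicted`);
* retained SLiM candidates (tier `high-throughput-or-predicted`, each
  edge carrying its motif id);
* docking-derived RhoA/RhoB edges (tier `structural-prediction`; these
  are not motif classes and are excluded from SLiM audit joins).

One node is created per interactor *entity*: names listed together in a
single catalog row ("Cyclin B/CDK1", "p38 alpha/beta") are one entity,
and the same protein appearing in multiple rows merges into one node. The
noncanonical SH3 row "Crk, Src" is carried by its primary partner Crk, so
the SH3- and SH2-derived predictions share a single Crk node. Under this
rule the packaged motif table yields 11 distinct predicted SYDE1 entities
and 8 SYDE2 entities. Exports are a lossless node/edge TSV pair and GML
(attribute keys camel-cased to satisfy GML syntax and restored on
import; the igraph Creator stamp is pinned so identical networks export
byte-identically).

# The synthetic generator

`simulate_family()` emulates exactly what the pipeline needs to be tested
against: ortholog families with known disordered segments, implanted
motif instances, and controlled conservation.

* **Root sequence**: segment-specific composition. Disordered spans are
  enriched in E, S, P, K, Q, R and depleted in W, F, I, L, V -- the
  canonical IDR bias; its expected fold-index score is about -0.5, so
  spans are called disordered essentially everywhere. Ordered spans draw
  from a hydrophobic, core-like composition whose expected score
  (about +0.6, more than five standard deviations of a 51-residue window
  mean above zero) keeps them unambiguously ordered: their role in the
  testbed is to host decoy implants that the disorder criterion must
  reject, so the segment model must not itself produce spurious
  disorder calls. Neither composition pretends to be a realistic
  evolutionary model of any particular protein.
* **Implants** overwrite the root with a peptide sampled from the class
  pattern (variant chosen uniformly, then residues uniformly within each
  position's allowed set); overlapping or out-of-bounds implants are
  errors.
* **Orthologs** are derived from the root by per-site substitution:
  probability `q_bg` outside implants, `q_motif` inside (conserved
  implants require `q_motif <= q_bg`), with replacements drawn from the
  segment's own composition excluding the current residue, so the
  compositional bias is stationary under mutation. Ortholog 1 is the
  unmutated root and serves as the reference. Non-conserved implants are
  disrupted in every non-reference ortholog by forcing the most
  constrained motif position outside its allowed set. Indels are off,
  which keeps the trivial alignment exact; column mapping is tested
  separately on gapped fixtures.
* **Truth is recomputed, never assumed**: an implant "survives" in an
  ortholog iff its pattern still matches inside the implant interval in
  the emitted sequence, and background matches of an implanted class
  outside the implants are recorded as *incidental* -- they count as
  neither true nor false positives in `evaluate_recovery()`.

The reference study conditions -- the `family_params()` defaults -- are 8
orthologs of length 800, two disordered spans (residues 1-260 and
521-660), `q_bg = 0.2`, `q_motif = 0`, six conserved implants in the
disordered spans and four decoys in the ordered spans. The acceptance
suite runs this operating point over 20 seeds and requires mean recall of
at least 0.9 for the conserved disordered implants with zero retained
ordered decoys.

What passing these tests shows -- and what it does not: the generator
validates the *mechanics* (scanning, interval algebra, column mapping,
selection logic, conservation accounting) under controlled conditions.
Real IDRs have milder composition bias, real motifs sit in fuzzier
disorder, real ortholog sets have indels and rate heterogeneity, and real
conservation is confounded by alignment error; performance on synthetic
families is therefore an upper bound, not a claim about real proteomes.

# Reproducing the sequence-dependent numbers

The checks that re-find the published instance coordinates on the actual
UniProt entries (Q6ZW31, Q5VT97, Q9V7SV) and reproduce the published
domain homology percentages require those sequences and an
InterProScan-derived boundary table. They are not redistributed with the
package; place them under `inst/extdata/reference/` (see the README for
the exact file contract) before installing, and the corresponding
acceptance tests and `scripts/acceptance.R` entries will run. Without
them those two acceptance tests fail with an explanatory message -- they
are deliberately not skipped, because the package cannot verify claims
about data it does not have.

# Numerical choices, sizes and limitations

* Deterministic tie-breaks: scanner output ordered by start then length;
  NJ joins the lexicographically smallest tying pair; node/edge tables
  sorted lexicographically.
* Degenerate inputs: two-taxon "trees" split the distance evenly;
  saturated distances cap at 10; empty catalogs load with a warning;
  empty networks keep their two hub nodes.
* Problem sizes in the default test run were chosen to keep the suite
  fast while leaving the statistics meaningful: scanner/aligner oracles
  on random sequences up to length 2000 and 8 respectively, Monte-Carlo
  probability checks on 10^6 residues, bootstrap determinism at 50-100
  replicates, and the 20-seed end-to-end recovery described above.
* Known limitations: the probability score is an analogue, not a
  calibration, of any external scoring; the fold-index surrogate misses
  context-dependent disorder; the star aligner is not a general MSA
  method; the NJ surrogate does not attempt the published ML topology;
  and the entity-counting rules, while they reproduce both published hub
  counts, are one reasonable reading of an ambiguous table.
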