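---
title: "Detecting horizontal DNA transfer between MAG groups with k-mer TF-IDF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal DNA transfer between MAG groups with k-mer TF-IDF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Horizontal genetic transfer (HGT) moves DNA between organisms outside
parent-to-offspring inheritance. Phylogeny-based detection only sees
transfers that are protein-coding and old enough to align well, so recent,
non-coding or degraded transfers — most of the background gene flow in a
microbial community — are invisible to it. `hgtweave` implements an
alignment-free alternative for communities of metagenome-assembled genomes
(MAGs): the term frequency–inverse document frequency (TF-IDF) statistic
applied to nucleotide k-mers.

The analogy is textual. Group the MAGs by taxonomic class; each group is a
*document*, and every canonical k-mer (the lexicographic minimum of a k-mer
and its reverse complement, so counting is strand-independent) is a *word*.
For k-mer $t$ and group $G$:

$$\mathrm{tf}(t,G) = \frac{n_{t,G}}{N_G}, \qquad
  \mathrm{idf}(t) = \ln\frac{|\mathcal{G}|}{\mathrm{df}(t)}, \qquad
  \mathrm{tfidf}(t,G) = \mathrm{tf}(t,G)\,\mathrm{idf}(t),$$

where $n_{t,G}$ counts occurrences of $t$ in $G$, $N_G$ is the total k-mer
tokens of $G$, $|\mathcal{G}|$ is the number of groups and
$\mathrm{df}(t)$ the number of groups containing $t$. A k-mer frequent in
one group but confined to few groups scores high; a k-mer present
everywhere has $\mathrm{idf} = 0$.

An occurrence of k-mer $t$ at a position of recipient MAG $R$ (group $A$)
is **flagged** as foreign with respect to donor group $B \ne A$ iff

1. *common in the donor group*: $t$ is present in at least
   $\lceil \theta_{don} |B| \rceil$ MAGs of $B$ (default
   $\theta_{don} = 0.5$; a singleton group requires its single MAG, which
   keeps singleton groups such as individual algal species usable);
2. *rare in the recipient's group*: $t$ occurs in at most $\theta_{rec}$
   MAGs of $A$ other than $R$ itself (default $\theta_{rec} = 0$,
   the most conservative reading — the k-mer must be recipient-exclusive
   within its own group);
3. *group-specific*: $\mathrm{df}(t) \le d_{max}$ (default 2, allowing the
   donor group plus, through the transfer itself, the recipient's group).

Flagged k-mer start positions on one scaffold are merged into maximal runs:
consecutive starts at most $g$ apart join one region, and a run of starts
$s_1..s_m$ becomes the interval $[s_1, s_m + k)$. Each region's
significance is bounded by a run-length argument: if flags arose
independently at the recipient-wide rate $q$ (the flagged fraction for this
(recipient, donor) pair), the chance of seeing at least one run of $m$
flagged starts anywhere among the recipient's $n$ k-mer positions is at
most

$$p = \min(1,\; n\,q^m),$$

a Bonferroni-style bound over run start positions. It is an upper bound,
not an exact p-value; only the $p \le \alpha$ decision is consumed
downstream, and the bound is conservative there. Regions with
$p \le \alpha$ become candidates. When several donor groups call the same
interval (≥ 50% reciprocal overlap), the donor with the highest region
score (summed $\mathrm{tfidf}(t, B)$ over flagged occurrences) wins, ties
broken by lexicographic donor name.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 25 bp | k-mer size; the published optimum for class-grouped MAG data. Below ~11 bp k-mers stop being taxonomically specific, so small `k` requires an explicit override. Packed 2-bit encoding bounds `k` at 26. |
| `alpha` | 0.05 | significance cut on the run-length bound |
| `donor_prevalence` | 0.5 | fraction of donor-group MAGs that must carry a k-mer |
| `recipient_rarity` | 0 | other recipient-group MAGs allowed to carry it |
| `max_group_df` | 2 | maximum groups a flagged k-mer may occupy |
| `merge_gap` | 4k (100 bp) | maximum gap between flagged starts in one region |

The `merge_gap` default deserves its derivation. After a transfer, every
substitution that accumulates in the donor lineage (or in the transferred
copy) suppresses all `k` windows that cross it: a cluster of substitutions
spanning `s` bp opens a flagged-start gap of exactly `s + k + 1`. With
`g = k` a *single* substitution already splits a genuine transferred
fragment into two regions. At percent-level within-group divergence,
substitutions land every ~50 bp, so fragments would shatter. `g = 4k`
bridges every gap caused by a substitution cluster spanning less than
`3k` bp — i.e. anything short of four or more substitutions each within
`k` bp of the next — while staying at the scale of the smallest reportable
event (100 bp), so unrelated regions are not merged. Raising
`donor_prevalence` shrinks the flag set monotonically, but the *candidate
count* is not monotone in it: removing background flags lowers `q` and can
promote borderline regions past `alpha`. This is a property of the
run-length bound, not a defect; `alpha` itself acts monotonically.

## The validation funnel

Raw candidates pass through six steps in a fixed order, each recording a
pass / flag / discard decision per candidate so the whole trace is
auditable, and each boundary read strictly as published:

1. **virus_overlap** — drop virus→virus calls (taxonomy inside viral bins
   cannot exclude shared homology) and scaffolds present in both a viral
   and a cellular catalogue;
2. **min_length** — drop events < 100 bp (100 passes);
3. **scaffold_saturation** — drop events covering > 95% of their scaffold
   (95.0% passes): a saturated scaffold has no flanking sequence left to
   anchor it to its MAG;
4. **repeat_n_content** — drop events on scaffolds > 50% simple repeat or
   > 50% `N` (50.0% passes), measured on the whole scaffold, since the
   published filter removes *scaffolds* with that composition;
5. **taxonomic_consistency** — the top homology hit of the scaffold's
   non-transferred flank must not match the donor class; matching the
   recipient class confirms the scaffold, no hit passes with a flag
   (provenance unassessable), and ambiguous classes pass flagged in
   `lenient` mode (default) or are discarded in `strict` mode;
6. **coverage_congruence** — a correctly binned scaffold tracks its MAG's
   depth: samples where the scaffold's mean depth is more than one
   standard deviation from the MAG mean are aberrant; > 2 aberrant samples
   discard, 1–2 flag, 0 pass. MAG mean and SD are computed per sample over
   the MAG's per-scaffold mean depths, unweighted by scaffold length —
   the congruence assumption treats scaffolds, not bases, as the sampling
   unit. For eukaryote recipients only samples from the MAG's own
   environment are comparable (eukaryote references are built and mapped
   per environment), so only those are counted.

Missing evidence never silently discards: absent depth or homology tables
skip their steps with a logged warning and a funnel row marked `skipped`,
and a candidate without depth rows passes flagged `no-coverage-data`.
GC content is annotated (`gc_region`, `gc_mag`, `delta_gc`, N excluded
from denominators) but never filters. Candidates whose transferred region
itself has homology hits are labelled putatively `coding`, the rest
`non_coding`.

## The synthetic community generator

`simulate_community()` provides the positive and negative controls that
make every stage testable without downloads. Per group it draws an
ancestor i.i.d. uniform over ACGT; each member MAG is the ancestor with
i.i.d. substitutions at the within-group divergence rate, cut into
scaffolds. Planted events copy a verbatim segment from a donor MAG over an
equal-length block of a recipient scaffold in another group — replacement
rather than insertion keeps scaffold lengths and depth bookkeeping simple
and does not affect detection. Defaults mirror the study design at desk
scale: 6 groups × 4 MAGs × 5 scaffolds × 20 kb (100 kb per MAG, 2.4 Mb
community), 2% divergence, 20 events of 150–1000 bp, and a 12-sample depth
design (4 creek biofilm, 4 endolithic, 4 soil). `plant_decoys()` adds
scaffolds > 50% tandem repeat or > 50% N; `simulate_depths()` gives
resident scaffolds depth `Normal(base, sd)` around a per-(MAG, sample)
base and shifts designated contaminants in more than two samples;
`simulate_homology()` emits consistent / donor-like / absent top hits per
scenario.

What the generator deliberately does not emulate: compositional (GC/codon)
structure — ancestors are uniform i.i.d., which maximises inter-group k-mer
distinctness and gives a clean positive control; amelioration of planted
fragments after transfer; within-group transfers; read-level artefacts
(chimeras, uneven coverage along scaffolds). Passing recovery tests
therefore demonstrates correctness of the machinery under the model's own
assumptions, not performance on real communities, where shared mobile
elements and compositional convergence make both rules (a) and (b) softer.
Uniform ancestors also mean two random groups share essentially no 25-mers
(< 0.1% of distinct k-mers), which the property suite asserts, since that
premise is what makes TF-IDF detection possible at all.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; conversion to 1-based
  inclusive happens only when writing the human-readable report. BED output
  stays 0-based half-open.
* k-mers are packed 2 bits per base into doubles; all codes are exact
  integers below $2^{53}$ for $k \le 26$, and numeric order equals
  lexicographic order, so canonicalisation is a `min`.
* Ambiguous IUPAC bases are normalised to `N` on input (MAG assemblies
  routinely contain them); any window containing `N` is skipped entirely.
* `q = 0` with observed flags means the flags exist only inside the region;
  the bound degenerates to `p = 0` and a note is logged.
* A MAG with a single depth-covered scaffold has SD 0; its scaffold
  coincides with the MAG mean, so it is never aberrant.
* Bitscore ties in homology tables keep input order (stable ranking).
* Donor ties during cross-donor overlap resolution break lexicographically
  and deterministically; candidate ids are zero-padded ranks by
  (recipient, scaffold, start), so identical inputs give byte-identical
  outputs.
* Splice junctions of planted fragments can extend the verbatim donor match
  by chance (probability 1/4 per boundary base), so a flagged k-mer one
  base outside a planted interval is correct behaviour, not leakage.

## Problem sizes used by the test-suite and acceptance script

Desk-scale conditions are used throughout: toy communities of a few kb for
exact brute-force (oracle) comparison; the default 2.4 Mb community for
planted-event recovery (20 events, seed-fixed); ten event-free 2.4 Mb
communities for the null control; designed fixtures for funnel and
boundary behaviour. The acceptance script reruns recovery, the null
control, and a full decoys-depths-homology-funnel-network pass and reports
recall, precision, donor accuracy, null candidate rate, funnel survivor
counts and network totals. Full-scale runs on the deposited MAG catalogues
are possible in principle (the detector is linear in community size) but
are not part of the desk-scale surface, and exact agreement with the
original counts is not expected because the scoring internals are a
reconstruction.

## Known limitations

* The run-length p-value is an upper bound under an independence
  assumption that flagged positions clearly violate (overlapping windows);
  it is used only as a conservative `alpha` gate.
* Whether term frequency should be computed at MAG or group level is
  ambiguous in the method's lineage; group level is implemented, and
  MAG-level presence is retained in the profiles so the alternative can be
  added without recounting.
* Within-group (same-class) transfers are invisible by construction —
  rules (b) and (c) exclude them.
* Detection degrades with donor-recipient divergence (amelioration): a
  fragment acquires gaps at every substitution, and once clusters of four
  or more substitutions per `3k` bp are common, regions fragment below the
  length filter. This mirrors the method's intrinsic bias toward recent
  transfers.
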