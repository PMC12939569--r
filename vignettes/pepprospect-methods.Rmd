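---
title: "In silico prospecting of ACE-inhibitory peptides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico prospecting of ACE-inhibitory peptides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepprospect)
```

## The problem

Angiotensin-converting enzyme (ACE) converts angiotensin I into the
vasoconstrictor angiotensin II; inhibiting it lowers blood pressure.
Food-derived peptides that inhibit ACE are a long-standing alternative to
synthetic inhibitors, and collagen is an attractive precursor: it is
abundant, cheap, and its hydrolysates are rich in short proline-containing
peptides of the kind that bind the ACE active site. `pepprospect`
implements the standard computer-aided workflow for mining such peptides
from collagen alpha-chains:

1. **Preprocess** the chains (signal-peptide removal, stoichiometry).
2. **Profile** the precursor: how densely do known bioactive fragments tile
   the sequence?
3. **Digest in silico** with one or more proteases and score the
   hydrolysate.
4. **Screen** the released peptides: novelty, then safety (toxicity and
   allergenicity), then classifier activity votes, then docking energy
   against a reference inhibitor.
5. **Characterise** the survivors (molecular weight, charge, pI,
   hydropathy) and run a **network-pharmacology** stage over their
   predicted targets.

The package computes everything that is a deterministic function of
sequences and tables. It deliberately does *not* re-implement external
predictors (signal-peptide neural networks, toxicity/allergenicity
servers, protein-language-model classifiers, docking engines, target
predictors): their exports are ingested as TSV tables at well-defined
stage boundaries, which is also where the synthetic-data generator plugs
in.

## Core statistics

**Occurrence frequency.** For a chain of $N$ residues and a reference
database of peptides with a given activity, the occurrence frequency is

$$A = \frac{a}{N},$$

where $a$ counts bioactive fragments in the chain. For precursor profiling
(`occurrence_profile()`), $a$ counts substring occurrences; every
positional occurrence counts and overlaps are allowed by default. Reference
databases do not state how they handle overlaps, so the choice is exposed
as a switch (`overlapping`), with the overlapping variant as the
documented default because it is the most literal reading of "number of
fragments with specific activity" and is deterministic. For hydrolysates
(`release_frequency()`), $a$ counts *released* fragments whose whole
sequence is a reference peptide, with positional multiplicity (a dipeptide
released twice counts twice). $A$ is a per-residue frequency, not a
probability, and is not clamped at 1.

**Theoretical degree of hydrolysis.** For a chain with $D$ peptide bonds
of which a digestion cleaves $d$,

$$DH_T = \frac{d}{D} \times 100\%.$$

Type I collagen assembles from two alpha-1 chains and one alpha-2 chain,
so pooled $A$ and $DH_T$ values are copy-number-weighted means with
weights 2:1 (`copy_number` on each chain; `weighted_profile()`,
`degree_of_hydrolysis()`).

## Cleavage-rule grammar

An enzyme rule is a set of *cleavage specs* over the four residues around
a bond (P2, P1, P1′, P2′ in Schechter–Berger notation): a spec lists the
allowed residues at each constrained position, a bond is cut when some
spec matches and no exception spec matches. Internally bonds are indexed
0-based between residues $i$ and $i+1$, while all user-facing fragment
coordinates are 1-based inclusive. A context position that falls off the
chain fails any constraint placed on it; bonds adjacent to an `'X'`
(unknown) residue are never cut. Multi-enzyme digestion is
*simultaneous*: the site set is the union of the per-enzyme site sets, as
in the standard "enzyme(s) action" semantics of peptide databases — not
sequential digestion.

The shipped rule table (`default_enzymes()`) covers trypsin,
chymotrypsin A, pancreatic elastase, papain, ficin, stem bromelain and
calpain 2. The serine-protease rules are canonical; the papain-family
encodings are approximations built from the specificity literature
(dominant hydrophobic-P2 determinant), because databases do not publish
their exact encodings. Fragment-level counts are sensitive to these
encodings, which is why the table is plain, commented YAML that users are
expected to edit, and why fragment-count reproduction of any published
digest should always start with a rule-table audit.

`rank_enzyme_combinations()` enumerates binary and ternary enzyme subsets
and ranks them by weighted release frequency, breaking ties by higher
$DH_T$ and then lexicographic enzyme names, mirroring how an optimal
cocktail is chosen in practice.

## The screening cascade

`run_cascade()` runs fixed stages — novelty → safety → activity → docking —
over a `candidate_set`, rejecting records in place so that every input
sequence ends in exactly one terminal state with a complete per-stage
audit log. Free amino acids are excluded from screening (minimum length
2); there is no maximum length.

* **Novelty**: exact full-sequence match against the reference database
  removes already-known peptides.
* **Safety**: keep iff non-toxic AND non-allergenic. Unannotated records
  are rejected under the default *strict* policy; a permissive switch
  exists for partially annotated data.
* **Activity**: three classifier votes per peptide (logistic regression,
  SVM, MLP); keep if *any* vote is "high". The mapping from raw server
  labels (e.g. `"low & non-activity"`) to the controlled vocabulary lives
  in a user-supplied mapping (`default_vocab()`), not in code.
* **Docking**: keep iff both negated CDOCKER energies (-CE and -CIE,
  kcal/mol; larger = stronger predicted binding) are *strictly above* the
  reference ligand's. Published screens say "higher than the control"
  without specifying which energy; on the bundled 27-peptide panel the
  -CIE-only and both-energies readings give the same four survivors, and
  the both-energies rule is the conservative one, so it is the
  implementation. Survivors are ranked by -CIE descending.

## Property panel

* **Molecular weight**: sum of *average* residue masses plus one water
  (18.0153 Da), since average masses are what peptide-property servers
  print; monoisotopic masses are available behind a flag. Reported to two
  decimals.
* **Net charge**: side chains only, $(\#K + \#R) - (\#D + \#E)$, histidine
  neutral — the convention that reproduces published panel values at
  neutral pH.
* **Isoelectric point**: bisection on pH ∈ [0, 14] (tolerance $10^{-4}$)
  of the Henderson–Hasselbalch net charge over both termini and the D, E,
  C, Y, H, K, R side chains. The default pKa set is the Lehninger-style
  textbook set; published pI values depend on the (unstated) pKa sets of
  the servers that produced them, so agreement is expected only to a few
  tenths of a pH unit. Peptides whose charge cannot cross zero return
  `NA`.
* **Hydropathy**: Kyte–Doolittle shipped (mean or sum); output always
  labels the scale. Published "hydrophobicity (kcal/mol)" panels use
  unstated proprietary scales, and this package does not pretend to
  reproduce them.

## Network-pharmacology stage

Edges are loaded from a STRING-style TSV and gated at
`combined_score > 0.9` ("highest confidence"); scores are then discarded
and all path-based methods treat the graph as unweighted. Eight hub
rankings are computed (`centrality()`): Degree, MNC (largest connected
component of the neighbour-induced subgraph), MCC (sum of
$(|C|-1)!$ over maximal cliques containing the node), harmonic Closeness
($\sum 1/d$, robust to disconnection), Betweenness, Stress (number of
shortest paths through the node), Radiality (per connected component,
$\mathrm{mean}(\Delta + 1 - d)$ with $\Delta$ the component diameter;
singletons score 0 — the component-wise convention is documented here
because published tools do not state theirs), and EPC (Monte-Carlo mean
size of the node's component under independent edge retention).

EPC defaults: 1000 repetitions, keep probability 0.5, and a mandatory
seed — the stochastic estimator is otherwise irreproducible. The
Monte-Carlo draws are isolated from the caller's RNG stream.

Top-$k$ lists (default $k = 10$) break score ties lexicographically by
gene symbol, and `consensus_hubs()` is the *strict intersection* of all
lists — membership in every ranking, the standard "overlap in all
algorithms" rule. `enrichment()` reports plain fold enrichment
$(k/n)/(K/N)$ with an upper-tail hypergeometric p-value; it is labelled
as such and makes no attempt to reproduce tool-specific modified
statistics.

## Synthetic data and what passing tests mean

`synth_spec()` fixes every generator knob under a mandatory master seed;
each artifact derives its own sub-stream from the seed and a stable
label, so adding a generator never perturbs another. The defaults are the
study conditions the pipeline is built around: two chains of 1450
residues (a realistic type I collagen length) with a 22-residue signal
peptide, 2:1 stoichiometry, a 95% Gly-X-Y body with proline-rich X/Y
positions; a candidate pool of 107 novel peptides with 1 toxic and 1
allergenic plant, 27 high-activity votes and 4 docking passes; a
112-node, 4-hub interaction network; and 4×100 predicted target sets
whose union overlaps a disease list in exactly 201 genes.

The graph generator uses a sparse preferential-attachment background
(attachment 1, matching the low mean degree of real highest-confidence
interaction networks of this size) and wires each hub to half the
background plus a clique among the hubs. The sparseness matters for the
percolation-based method: on a dense background a half-retained graph
stays essentially one component, every node's expected component size
ties, and planted hubs are indistinguishable from the background — so
hub planting is only well-posed on a sparse background.

Plants can optionally be re-drawn until no cleavage site of a chosen
rule set falls inside a planted peptide, so digestion releases them
intact.

What the generator does *not* emulate: real collagen telopeptides and
hydroxylation, realistic docking-energy distributions, degree-correlated
confidence scores, or biological gene-set structure. Passing the
planted-recovery tests therefore demonstrates that the *bookkeeping and
algorithms* are correct — coordinates, counts, rankings, set algebra —
not that the pipeline's biological predictions are accurate; those
depend entirely on the quality of the ingested annotations.

## Numerical and testing choices

* All randomized components take explicit seeds; reports are
  byte-identical across re-runs with the same inputs.
* The digestion engine is property-tested against a naive per-bond oracle
  on 1000 random chain/rule pairs; the reference matcher against a naive
  substring scan; each centrality against exhaustive brute-force oracles
  (path enumeration, subset clique enumeration, Floyd–Warshall, exact
  percolation expectation by subset summation) on *all* connected labeled
  graphs with up to 5 vertices plus random connected 6–7-vertex graphs —
  full enumeration at 7 vertices (millions of graphs) buys no additional
  structural coverage worth its cost.
* Cascade-count recovery is checked across 20 master seeds; planted-hub
  recovery across multiple seeds requires every method's top-$(h+2)$ list
  to contain all $h$ hubs.
* Degenerate inputs have defined behaviour: single-residue chains make
  $DH_T$ an error (no bonds), empty digests yield one fragment, empty
  graphs refuse centrality, saturated enrichment gives fold 1, empty
  candidate lists flow through the cascade as all-zero counts.

## Known limitations

* Published fragment-level digest counts are reproducible only with the
  exact cleavage encodings of the database that produced them; the
  shipped YAML is an editable approximation and says so.
* $A$ values depend on the reference-database snapshot; the bundled
  snapshot is the small published collagen-hydrolysate list, not a full
  database export.
* The pI and hydrophobicity panels are convention-labelled rather than
  server-identical (unstated pKa sets and scales upstream).
* The enrichment statistic is the plain hypergeometric, not any
  tool-specific variant.
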