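# pepprospect

In silico prospecting of ACE-inhibitory peptides from collagen chains.

Angiotensin-converting enzyme (ACE) turns angiotensin I into the
vasoconstrictor angiotensin II; peptides that inhibit ACE lower blood
pressure, and collagen hydrolysates are a rich natural source of them.
`pepprospect` is an R package for the computer-aided version of this
search, written for researchers mining protein sequences for bioactive
peptides:

* **Simulated proteolysis** under an editable cleavage-specificity rule
  grammar (P2/P1/P1′/P2′ residue sets with exceptions), single enzymes or
  simultaneous cocktails, with the theoretical degree of hydrolysis
  *DH*<sub>T</sub> = *d*/*D* × 100 % and fragment length distributions.
* **Bioactive-fragment profiling** against a reference peptide database:
  the occurrence frequency *A* = *a*/*N* for precursors (substring
  occurrences per residue) and for hydrolysates (released matching
  fragments per residue), with copy-number weighting for multi-chain
  proteins such as type I collagen (2 × α1 : 1 × α2).
* **A screening cascade** — novelty → toxicity/allergenicity → classifier
  activity votes → docking energies versus a reference ligand — over
  ingested tool exports, with a complete per-peptide audit trail.
* **A physicochemical panel**: average molecular weight, side-chain net
  charge, Henderson–Hasselbalch isoelectric point (bisection), hydropathy.
* **Network pharmacology**: confidence-gated interaction graphs, eight
  topological hub rankings (MCC, MNC, Degree, EPC, Closeness, Betweenness,
  Radiality, Stress), strict top-*k* consensus, and hypergeometric fold
  enrichment.
* **A synthetic-data generator** that plants reference peptides, cascade
  outcomes and network hubs with exact ground truth, so the whole pipeline
  is testable offline.

See `vignettes/pepprospect-methods.Rmd` for the model, conventions and
design decisions.

## Worked example

Screen the bundled panel of 27 collagen-derived candidate peptides
(classifier votes and CDOCKER energies against ACE) against the
lisinopril positive control, then characterise the survivors:

```r
library(pepprospect)

panel <- default_candidate_panel()
cs <- candidate_set(panel$sequence)
cs <- ingest_annotations(cs, panel, "activity")
cs <- ingest_annotations(cs, panel, "docking")
cs <- activity_select(cs)
cs <- docking_select(cs, default_reference_ligand())
docking_ranking(cs)
#>   sequence cdocker_energy cdocker_interaction
#> 1  QICVCDS        125.954             118.496
#> 2     DVWK        117.488             106.022
#> 3     IIEY        105.960             105.308
#> 4   APMDVG        100.198             104.216
```

Exactly four peptides beat lisinopril (-CE 93.7579, -CIE 103.348
kcal/mol) on **both** energies; larger negated CDOCKER energies mean
stronger predicted binding. Their property panel:

```r
property_panel(docking_ranking(cs)$sequence)
#>   sequence length molecular_weight net_charge isoelectric_point hydrophobicity
#> 1  QICVCDS      7           766.88         -1              2.99      0.8428571
#> 2     DVWK      4           546.62          0              6.65     -1.0250000
#> 3     IIEY      4           536.63         -1              3.30      1.0500000
#> 4   APMDVG      6           588.68         -1              3.00      0.4000000
```

Molecular weights are average-mass (residues + one water, Da); net charge
is the side-chain count (#K + #R) − (#D + #E); the pI comes from bisecting
the Henderson–Hasselbalch charge under a textbook pKa set, so the three
acidic peptides sit near pH 3 while DVWK is near neutral; hydropathy is
labelled with its scale (Kyte–Doolittle mean here).

Digestion and profiling on a toy collagen-like chain:

```r
ch <- protein_chain("demo", "GPAGAKGFRGPAGPK")
d  <- digest(ch, default_enzymes()[c("papain", "ficin")])
d$fragments
#>   sequence start end
#> 1     GPAG     1   4
#> 2       AK     5   6
#> 3      GFR     7   9
#> 4   GPAGPK    10  15

release_frequency(d, default_refdb(), "ACE inhibitor")[c("a", "N", "A")]
#> a = 1, N = 15, A = 0.0667   (one released fragment, AK, is a known ACE inhibitor)
```

And the hub-gene consensus over eight published top-10 centrality
columns, shipped as a fixture:

```r
consensus_hubs(load_rank_columns())
#> [1] "BCL2"     "HSP90AA1" "SRC"      "STAT3"
```

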