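# Enzyme cleavage-specificity table.
#
# Grammar: each spec constrains up to four positions around a peptide bond
# (p2, p1, p1prime, p2prime = P2, P1, P1', P2' in Schechter-Berger notation);
# the bond between P1 and P1' is cleaved when some spec matches and no
# exception matches. Residue sets are one-letter codes.
#
# The encodings below are working approximations assembled from the protease
# specificity literature (MEROPS summaries, classic PeptideCutter-style
# rules). Published databases differ in how they encode the cysteine
# proteases in particular, and fragment-level results are sensitive to the
# encoding - edit this file to match the rule set you need to reproduce.
enzymes:
  - name: trypsin
    ec: "3.4.21.4"
    source: "canonical rule: after K/R, not before P"
    specs:
      - p1: ["K", "R"]
    exceptions:
      - p1prime: ["P"]
  - name: chymotrypsin A
    ec: "3.4.21.1"
    source: "high-specificity rule: after F/Y/W, not before P"
    specs:
      - p1: ["F", "Y", "W"]
    exceptions:
      - p1prime: ["P"]
  - name: pancreatic elastase
    ec: "3.4.21.36"
    source: "after small uncharged residues A/G/S/V, not before P"
    specs:
      - p1: ["A", "G", "S", "V"]
    exceptions:
      - p1prime: ["P"]
  - name: papain
    ec: "3.4.22.2"
    source: >-
      cysteine protease; dominant determinant is a bulky hydrophobic residue
      at P2 (Schechter & Berger), encoded as P2 in {A,V,L,I,F,W,Y}, not
      before P
    specs:
      - p2: ["A", "V", "L", "I", "F", "W", "Y"]
    exceptions:
      - p1prime: ["P"]
  - name: ficin
    ec: "3.4.22.3"
    source: >-
      papain-family cysteine protease with a narrower P2 preference,
      encoded as P2 in {F, L, V, I}, not before P
    specs:
      - p2: ["F", "L", "V", "I"]
    exceptions:
      - p1prime: ["P"]
  - name: stem bromelain
    ec: "3.4.22.32"
    source: >-
      papain-family; marked preference for basic P1 (Z-R-R-type substrates),
      encoded as P1 in {K, R}, P2 unconstrained, not before P
    specs:
      - p1: ["K", "R"]
    exceptions:
      - p1prime: ["P"]
  - name: calpain 2
    ec: "3.4.22.53"
    source: >-
      calcium-dependent cysteine protease; P2 preference for L/V,
      encoded as P2 in {L, V}, not before P
    specs:
      - p2: ["L", "V"]
    exceptions:
      - p1prime: ["P"]
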