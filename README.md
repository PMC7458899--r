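# MolCurate

Structure curation for small-molecule registration: a penalty-scoring
**Checker**, a rule-based **Standardizer**, and a salt/solvent/isotope-stripping
**GetParent**, operating on V2000 molfiles and SD files.

## The problem

Bioactivity databases receive the "same" compound drawn many ways: as a free
base or a hydrochloride, charged or neutral, isotopically labelled, with
sloppy wedge bonds, or in a broken connection table. To aggregate data by
compound, structures must be validated, rewritten under one set of
conventions, and reduced to a common parent. MolCurate implements that
three-stage pipeline:

* **Checker** — validates a molblock *without modifying it* and emits
  penalty-scored flags, score ∈ {2, 5, 6, 7} with 7 fatal. Flags cover format
  errors (unreadable input, V3000 records, polymer S-groups, illegal bond
  type/stereo codes, unkekulizable aromatic systems), coordinate pathologies
  (all-zero, coincident atoms, 3D coordinates), unknown radicals, stereo
  drawing problems, and the InChI engine's own warnings. A record's reported
  score is the maximum over its flags. A distinctive check cross-validates
  three stereocentre counts — the number of wedge-origin atoms in the molfile
  (*Mol*), tetrahedral centres in the Standard InChI /t layer (*InChI*), and
  algorithmically assigned centres (*perception*) — and classifies any
  disagreement; molfile-vs-InChI disagreements score 5 because the database
  identifier is derived from the molfile.
* **Standardizer** — first sets an *exclude flag* for organometallics (66
  listed metals) and molecules with more than 7 borons, which pass through
  untouched; then applies, in order: reset of unknown ("either") stereo,
  S-group clearing, kekulization, explicit-H removal (keeping isotopic H,
  wedge-held H, H on stereocentres, and H on atoms in non-default valence
  states such as the P–H of phosphinic acid), an ordered normalization rule
  set (hypervalent nitro N(=O)=O → [N+](=O)[O−], covalent alkali-metal–O/N →
  ion pair, amide tautomer N=C–OH → N–C(=O), sulfoxide → [S+]–[O−], diazonium
  → [N+]≡N, charging of quaternary N / trivalent O / trivalent S / lone
  halogens), canonical neutralization by hydrogen bookkeeping, and
  straightening of triple bonds and allenes. The pipeline is idempotent and
  conserves the heavy-atom multiset.
* **GetParent** — erases isotopes and strips components matching a
  salt/solvent dictionary, with matching insensitive to charge state
  (acetate ≡ acetic acid), depicted stereochemistry (the tartrates) and
  cis/trans isomerism (maleate ≡ fumarate); the match key is the skeleton
  block of the Standard InChIKey after isotope erasure, neutralization and
  stereo stripping. All-salt records (sodium chloride) and true mixtures
  pass through whole; excluded records lose solvents but never salts (so a
  transplatin-style complex is not reduced to a bare metal ion); 2:1
  complexes collapse their identical leftovers to one parent; the remainder
  is re-neutralized and re-standardized.

Standard InChI/InChIKey generation is delegated to OpenBabel's bundled InChI
library (`obabel` on PATH plus the ChemmineOB package).

## Worked example

```r
library(MolCurate)

## a cyclohexane drawn with a wedge on a ring bond
mb <- makeIssueFixture("Molecule has a stereo bond in a ring")$molblock
checkMolblock(mb)
#> CheckReport: max penalty score 5
#>   [5] InChI_RDKit/Mol stereo mismatch
#>   [2] Molecule has a stereo bond in a ring
```

The ring wedge itself is only cosmetic (score 2), but it makes the molfile
claim a stereocentre neither the InChI engine nor perception finds, so the
record is prioritised at score 5.

```r
## a deposited acetate anion is neutralized to acetic acid
res <- standardizeMolblock(writeMolblock(smilesToMolecule("CC(=O)[O-]")))
res
#> StandardizationResult: changed=TRUE; applied: neutralize
res@inchikeyBefore; res@inchikeyAfter
#> "QTBSBXVTEAMEQO-UHFFFAOYSA-M"
#> "QTBSBXVTEAMEQO-UHFFFAOYSA-N"   # protonation layer changed

## an amphetamine-like hydrochloride hydrate reduces to its parent
dict <- loadSaltDictionary()
getParent(makeSaltFixture("CC(N)Cc1ccccc1", c("hydrochloride", "water"),
                          dict), dict)
#> ParentResult: branch=salts_stripped; removed: hydrochloride(salt), water(solvent)
```

## Command line

```
Rscript inst/scripts/curate.R check       in.sdf --report report.tsv [--fail-on 6]
Rscript inst/scripts/curate.R standardize in.sdf -o out.sdf --report report.tsv
Rscript inst/scripts/curate.R getparent   in.sdf -o parents.sdf --salts FILE
```

Records stream one at a time; depositor SD fields pass through untouched and
pipeline annotations use namespaced tags (`CURATION_*`, `EXCLUDE`,
`PARENT_BRANCH`).

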