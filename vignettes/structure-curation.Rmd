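---
title: "Structure curation with MolCurate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure curation with MolCurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

MolCurate curates small-molecule structure records the way a registration
system must: first judge the record as deposited, then rewrite it under one
set of conventions, then reduce it to the parent under which assay data are
aggregated. This vignette documents the model behind each stage, the
parameters that matter, and the design decisions taken where more than one
reasonable reading existed.

## The Checker model

The checker treats a molblock as evidence, never as something to repair.
Parsing is deliberately non-correcting — illegal bond type codes, bond
stereo codes, odd element symbols and broken valences are preserved exactly
so the scoring sees the record as deposited. Each detected problem maps to
a penalty score in {2, 5, 6, 7}; the record's reported score is the maximum
over its flags. The intended reading of the grades: 7 — unusable input
(unreadable connection tables, unknown elements, aromatic systems that
admit no kekulé assignment); 6 — a usable graph whose structure is not
trustworthy (all-zero or 3D coordinates, six-fold coincident atoms, empty
structures, V3000 records, polymer S-groups, unknown radicals, unusual
valences); 5 — content that is likely wrong but fixable (illegal bond
codes, coincident atom pairs, crossed ring double bonds, most stereo-count
mismatches); 2 — cosmetic drawing conventions and routine InChI warnings.

### Stereocentre cross-validation

Three counts are compared per record:

* **mol** — distinct atoms from which a wedged/hashed bond (stereo code 1
  or 6) originates: what the depositor drew;
* **inchi** — tetrahedral centres in the main `/t` layer of the Standard
  InChI computed from the molfile (isotopic sublayers excluded);
* **perception** — tetrahedral centres assigned by algorithmic stereo
  perception, counted from the engine's canonical SMILES.

When the two derived counts agree with each other but not with the drawing,
or all three disagree, the record scores 5; when only the perception count
is the odd one out it scores 2, because the registered identifier (the
InChI) is still faithful to the molfile. The classification is total over
non-negative triples and is tested against an independently written
enumeration over {0..3}³.

The three routes genuinely disagree on real chemistry, which is what the
fixtures exploit: the InChI engine perceives pyramidal phosphorus (and
allene axial) stereo that canonical-SMILES perception drops, and both
ignore isotope-only stereocentres. A wedge on a non-stereogenic carbon
gives (1,0,0); a wedged phosphine (1,1,0); a 3D phosphine with no wedges
(0,1,0); a phosphine plus a spurious wedge (2,1,0) — covering all four
mismatch classes.

### Numerical and policy choices

* Coordinate identity uses a tolerance of 1e-4 molfile units — below the
  format's four-decimal precision — so trailing-zero formatting can never
  create or mask a coincidence. The all-zero flag requires at least two
  atoms (a lone atom legitimately sits at the origin). The six-or-more and
  two-or-more coincident flags are mutually exclusive by construction.
* Legal bond stereo codes are {0,1,6} on single bonds and {0,3} on double
  bonds. The historic "either" code 4 is treated as illegal, following
  curation practice for this flag rather than the letter of the CTfile
  specification; this divergence is intentional and confined to the
  checker.
* Bond order 4 (aromatic) is legal at parse time but must kekulize; the
  kekulizer demands exactly one in-system double bond per atom with spare
  valence capacity, letting N/P/As/O/S/Se and charged or radical atoms
  contribute lone pairs instead, and searches assignments by backtracking.
  Failure raises the fatal aromatic-bond flag.
* "Stereo bond to a stereocenter" is read as a wedge whose *end* atom is a
  perceived stereocentre (wedges should originate at the stereocentre).
  The END-atom reading is a documented choice, not asserted as the only
  one. Stereocentre perception for this flag is a conservative in-package
  test: an sp3 C/Si with four substituents, at most one hydrogen and
  pairwise-distinct Morgan-rank branches; rare rank collisions of distinct
  branches under-report, which is acceptable for a drawing-quality flag.
* The known-radical list ships as a SMILES file (nitric oxide, nitrogen
  dioxide, TEMPO) compared by engine-canonical SMILES; aminoxyl-type N–O
  monoradicals are additionally recognised structurally so substituted
  nitroxides need not be enumerated.
* InChI warnings map to issues through a data-driven table
  (`inchi_warning_map.tsv`), because warning strings vary with the engine
  version; anything unmapped is reported verbatim at score 2. The engine
  version string is recorded in every report. One synthesis: the engine is
  not invoked for 0-atom connection tables, so the wrapper itself reports
  the engine's "Empty structure" warning text for them.

## The Standardizer model

Exclusion comes first: records containing any of 66 listed metals, or more
than 7 boron atoms, are returned byte-identical with the exclude flag set —
a V2000 table cannot faithfully represent their coordination bonds, so no
automated edit is safe. The boron threshold (default 7) and metal list are
configuration.

The pipeline order is fixed: reset unknown stereo → clear S-groups →
kekulize → remove explicit hydrogens → normalize → neutralize → straighten.
Decisions worth recording:

* *Unknown stereo* is read as single bonds carrying the "either" wedge
  code 4: these are reset to plain bonds and any atom parity carried only
  by them is cleared. Crossed double bonds (code 3) are kept — they express
  unknown geometry deliberately. The narrower reading (not also resetting
  crossed double bonds) is a documented choice.
* *Explicit-H removal* folds hydrogens into implicit counts except:
  isotopic H; H held by a wedge; H on atoms with tetrahedral stereo set;
  and H on atoms in a non-default valence state that is not simply
  protonated — default valences are charge-adjusted, so a protonated amine
  folds normally while the P–H of phosphinic acid is retained. Hydrogens
  whose neighbour cannot carry implicit H (metals), charged/radical H,
  bridging H and lone H atoms are also kept, since folding them would
  change the formula.
* *Normalization* is an ordered rule set (nitro, covalent alkali metal–O/N,
  amide tautomer, sulfoxide, diazonium, quaternary N, trivalent O,
  trivalent S, lone halogen) iterated to a fixpoint with a 200-pass cap.
  "Alkaline metals" is implemented as the alkali metals Li–Cs; extending to
  alkaline-earth metals would be a one-line configuration change but is not
  the default, since the motivating pattern (covalent Na–O alkoxides) and
  the exclusion list's composition both point at group 1. The amide rule is
  restricted to acyclic C=N bonds so ring tautomers (2-pyridinone) are
  never rewritten — tautomer canonicalization is explicitly out of scope.
  The rule registry ships as a TSV of named SMARTS patterns that selects
  and documents the rules; the graph edits are implemented in the package.
* *Neutralization* is the closing sub-rule of the normalization block and
  iterates jointly with it, because fixing the charge bookkeeping can
  expose new rule matches (a protonation-balanced N=C–OH, for instance).
  It moves hydrogens from protonated to deprotonated centres (including
  across components), then adds or removes hydrogens for any remaining
  imbalance. Atoms in an adjacent (+,−) pair — nitro, sulfoxide, ylides —
  stay charge-separated unless nothing else can absorb the imbalance.
  Permanent cations (quaternary N) have no removable hydrogen and keep
  their charge; balanced ion pairs (Na⁺ / carboxylate) are left ionic
  because no proton exists to move. When several atoms qualify, the one
  with the smallest Morgan-style canonical rank is chosen, making the
  result independent of input atom order. A disconnected neutral halogen
  is charged only while a cationic surplus exists for it to balance;
  charging it unconditionally would be undone by neutralization on the
  next pass (a rule cycle).
* *Straightening* moves the outer substituents of triple bonds and allene
  centres onto the extended axis, preserving distances, and only when the
  angle deviates by more than 1e-3 radians. That tolerance is above the
  angular error that four-decimal coordinate rounding can introduce, which
  is what makes the written output a true fixpoint: re-standardizing a
  rounded file never drifts.

The invariants the test suite enforces: byte-identical idempotence,
heavy-atom-multiset conservation, neutrality except for permanent ions,
exclusion passthrough, and InChIKey invariance under atom-order
permutation.

## The GetParent model

Single-component, isotope-free records are their own parent. Otherwise
isotopes are erased first (the ordering against component matching is
unobservable in the output, but fixed for determinism), then components are
matched against the dictionary:

* The match key is the skeleton (first) block of the Standard InChIKey of
  the component after isotope erasure, neutralization and removal of all
  tetrahedral and double-bond stereo. This single canonical identity
  delivers all three required insensitivities — charge state, depicted
  stereochemistry, cis/trans isomerism — which also means a dictionary may
  list only one representative per skeleton (maleate covers fumarate;
  listing both is rejected as a duplicate).
* Excluded records match solvents only: stripping apparent counter-ions
  from a coordination complex drawn as disconnected components would
  fabricate a bare metal ion parent.
* If every component matches, nothing is removed (sodium chloride stays
  sodium chloride); if the record is multi-component and nothing matches,
  it is a true mixture and passes through as the identical mixture, and —
  a documented choice — without re-neutralization, since no edit was made.
* Otherwise matched components are dropped, exactly key-identical leftovers
  are collapsed to one copy (the 2:1 acid–calcium complex), and the
  remainder is neutralized and re-standardized, so every parent is a
  standardizer fixpoint. Deduplication only ever runs after at least one
  dictionary removal, so genuine mixtures are never collapsed.
* A component matching both roles is treated as a salt; the removal table
  records which role actually matched.

The shipped dictionary is a starter set (44 salts from the common
pharmacological salt classes, 9 solvents); production deployments load
their own lists via `loadSaltDictionary()`.

## What the fixture generator emulates — and what it does not

`randomMolecules()` produces small heavy-atom trees over C/N/O/S with
valence-respecting degrees, occasional protonated amines, carboxylate-style
anions and either-wedge codes; `randomSaltFixtures()` (test helper)
combines cached parent structures with dictionary salts, solvents and
isotope labels into multi-component records. `makeIssueFixture()` covers
every checker label with a minimal pathological molblock, and
`makeRulePair()` gives a before/after pair per normalization rule.

These generators emulate the *feature mix* the pipeline must handle, not
real depositor data: they contain no macrocycles or fused ring systems, no
large aromatic systems, no genuinely 3D conformers and no drawing styles of
specific sketching tools. Passing the property suites therefore
demonstrates the algebraic contracts (idempotence, conservation,
invariance) and per-rule correctness, not distributional performance on any
particular database's deposition stream; the dataset-level helpers
(`benchmarkChecker()`, `benchmarkStandardizer()`) exist for running the
pipeline over real compound sets.

Problem sizes used by the shipped suite: the full checker-label fixture
sweep (25 labels), 1000 random molecules for standardizer idempotence and
conservation, 1000 randomized salt-form records for parent idempotence, 100
molecules for permutation invariance, and exhaustive enumeration for the
mismatch classifier.

## Known limitations

* Stereo perception for the perception count is delegated to the engine's
  canonical SMILES; its behaviour (e.g. dropping phosphine stereo) is part
  of the recorded engine version, and reports should always be compared
  under the same engine.
* Morgan-rank canonicalization can, on adversarial graphs, rank
  constitutionally distinct branches equally; this can under-report the
  stereo-bond-to-stereocentre flag and, in principle, make a neutralization
  tie-break between genuinely different atoms — the result is still
  deterministic, just not guaranteed CIP-canonical.
* The molfile legacy mass-difference column is ignored; isotopes are read
  from `M  ISO` (and the legacy charge column is honoured only when no
  `M  CHG`/`M  RAD` block is present, per the format's precedence rule).
* V3000 records are detected and scored, never parsed.
* The InChI warning strings, and hence the low-score checker output, vary
  with the InChI engine version; the mapping table is data so it can track
  engine upgrades.
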