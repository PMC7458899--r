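# Standard InChI generation contract.

test_that("ethanol gets the reference Standard InChI and a shaped key", {
    res <- computeInchi(exampleMolblock("ethanol"))
    expect_false(res$failed)
    # frozen from a direct run of the reference engine on this fixture
    expect_identical(res$inchi, "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
    expect_match(res$inchikey, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("engine warnings are captured verbatim and failures encoded", {
    res <- computeInchi(makeIssueFixture("InChI: Empty structure")$molblock)
    expect_true(res$failed)
    expect_true("Empty structure" %in% res$warnings)

    res <- computeInchi(makeIssueFixture("InChI: Unknown element(s)")$molblock)
    expect_true(res$failed)
    expect_true(any(grepl("Unknown element", res$warnings)))
    expect_identical(res$inchi, "")

    res <- computeInchi(exampleMolblock("flat_2_butanol"))
    expect_false(res$failed)
    expect_true(any(grepl("Omitted undefined stereo", res$warnings)))
})

test_that("identical graphs give identical InChI regardless of atom order", {
    mbs <- randomMolecules(15, seed = 3)
    for (mb in mbs) {
        mol <- parseMolblock(mb)
        perm <- sample(natoms(mol))
        permuted <- MolCurate:::.permuteAtoms(mol, perm)
        expect_identical(computeInchi(writeMolblock(permuted))$inchi,
                         computeInchi(mb)$inchi)
    }
})

test_that("SMILES conversion yields a parseable 2D molecule", {
    mol <- smilesToMolecule("CC(=O)[O-].[Na+]", "sodium acetate")
    expect_true(parseOk(mol))
    expect_identical(natoms(mol), 5L)
    expect_true(all(abs(atoms(mol)$z) < 1e-9))
    expect_null(smilesToMolecule("not-a-smiles(((("))
})
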