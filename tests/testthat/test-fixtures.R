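# Fixture/checker and fixture/standardizer agreement: the generated
# pathological molblocks must actually trigger what they claim to.

test_that("every issue fixture triggers its declared label and score", {
    reg <- issueRegistry()
    for (lab in issueFixtureLabels()) {
        fx <- makeIssueFixture(lab)
        iss <- issues(checkMolblock(fx$molblock))
        hit <- iss$label == lab & iss$score == fx$expectedScore
        expect_true(any(hit), info = lab)
    }
})

test_that("the fixture registry covers every closed-registry label", {
    reg <- issueRegistry()
    fixed <- setdiff(reg$label, "Other InChI Warnings")
    expect_true(all(fixed %in% issueFixtureLabels()))
    # and the dynamic family has a representative
    expect_true("InChI: Omitted undefined stereo" %in% issueFixtureLabels())
})

test_that("every shipped normalization rule has a working before/after pair", {
    enabled <- MolCurate:::.enabledRuleNames(defaultRulesFile())
    expect_setequal(enabled, rulePairNames())
})

test_that("salt fixtures are well-formed multi-component records", {
    dict <- loadSaltDictionary()
    mb <- makeSaltFixture("CC(N)Cc1ccccc1", c("hydrochloride", "water"),
                          dict)
    mol <- parseMolblock(mb)
    expect_true(parseOk(mol))
    expect_length(splitComponents(mol), 3L)
    # no coincident atoms across components
    a <- atoms(mol)
    expect_false(any(duplicated(paste(round(a$x, 4), round(a$y, 4)))))
    expect_error(makeSaltFixture("CC", "no-such-salt", dict), "no entry")
})

test_that("random molecules are parseable, non-excluded and standardizable", {
    mbs <- randomMolecules(30, seed = 23)
    rules <- exclusionRules()
    for (mb in mbs) {
        mol <- parseMolblock(mb)
        expect_true(parseOk(mol))
        expect_false(computeExcludeFlag(mol, rules))
    }
    expect_identical(randomMolecules(5, seed = 1), randomMolecules(5, seed = 1))
})
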