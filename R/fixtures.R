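# Programmatic fixture generation.
#
# Every checker label, every normalization rule and every parent branch has
# a constructor here, so the test surface needs no stored structure files:
# coordinate and format pathologies are exact by construction.

.zigzag <- function(n, x0 = 0, y0 = 0) {
    data.frame(x = x0 + (seq_len(n) - 1) * 0.866,
               y = y0 + (seq_len(n) - 1) %% 2 * 0.5)
}

.hexagon <- function(r = 1) {
    th <- pi / 6 + (0:5) * pi / 3
    data.frame(x = r * cos(th), y = r * sin(th))
}

.chainMol <- function(elements, name = "", orders = NULL, stereo = NULL) {
    n <- length(elements)
    a <- cbind(element = data.frame(element = elements,
                                    stringsAsFactors = FALSE),
               .zigzag(n))
    if (n > 1) {
        b <- data.frame(begin = 1:(n - 1), end = 2:n,
                        order = if (is.null(orders)) 1L else orders,
                        stereo = if (is.null(stereo)) 0L else stereo)
    } else b <- NULL
    newMolecule(a, b, name = name)
}

# patch helpers operating on molblock text
.setCountsVersion <- function(mb, version) {
    lines <- strsplit(mb, "\n", fixed = TRUE)[[1]]
    lines[4] <- sub("V2000", version, lines[4], fixed = TRUE)
    paste(lines, collapse = "\n")
}

.setDimFlag <- function(mb, flag) {
    lines <- strsplit(mb, "\n", fixed = TRUE)[[1]]
    l2 <- lines[2]
    if (nchar(l2) < 22) l2 <- formatC(l2, width = -22)
    substr(l2, 21, 22) <- flag
    lines[2] <- l2
    paste(lines, collapse = "\n")
}

.injectBeforeEnd <- function(mb, extra) {
    sub("M  END", paste(c(extra, "M  END"), collapse = "\n"), mb,
        fixed = TRUE)
}

# canonical small structures used across examples, tests and vignette
.EXAMPLES <- list(
    ethanol = function() .chainMol(c("C", "C", "O"), "ethanol"),
    propane = function() .chainMol(c("C", "C", "C"), "propane"),
    benzene = function() {
        a <- cbind(data.frame(element = rep("C", 6)), .hexagon())
        b <- data.frame(begin = 1:6, end = c(2:6, 1),
                        order = c(2L, 1L, 2L, 1L, 2L, 1L), stereo = 0L)
        newMolecule(a, b, name = "benzene")
    },
    sodium_acetate = function() {
        a <- data.frame(element = c("C", "C", "O", "O", "Na"),
                        x = c(0, 0.866, 0.866, 1.732, 3.2),
                        y = c(0, 0.5, 1.5, 0, 1.5),
                        charge = c(0L, 0L, 0L, -1L, 1L))
        b <- data.frame(begin = c(1, 2, 2), end = c(2, 3, 4),
                        order = c(1L, 2L, 1L), stereo = 0L)
        newMolecule(a, b, name = "sodium acetate")
    },
    flat_2_butanol = function() {
        a <- cbind(data.frame(element = c("C", "C", "C", "C", "O")),
                   rbind(.zigzag(4), data.frame(x = 0.866, y = 1.5)))
        b <- data.frame(begin = c(1, 2, 3, 2), end = c(2, 3, 4, 5),
                        order = 1L, stereo = 0L)
        newMolecule(a, b, name = "2-butanol")
    }
)

#' Canonical example molblocks
#'
#' Small structures used throughout the documentation and tests, built in
#' code (no stored files).
#'
#' @param name one of \code{"ethanol"}, \code{"propane"}, \code{"benzene"},
#'   \code{"sodium_acetate"}, \code{"flat_2_butanol"}.
#' @return a molblock string.
#' @export
exampleMolblock <- function(name) {
    fn <- .EXAMPLES[[name]]
    if (is.null(fn))
        stop("unknown example '", name, "'; available: ",
             paste(names(.EXAMPLES), collapse = ", "))
    writeMolblock(fn())
}

# 2D wedged phosphine: a stereocentre the InChI engine perceives but
# algorithmic SMILES perception drops -- counts (mol=1, inchi=1, perc=0).
.phosphineWedged <- function(x0 = 0) {
    a <- data.frame(element = c("P", "C", "O", "S"),
                    x = x0 + c(0, 0.866, -0.866, 0),
                    y = c(0, 0.5, 0.5, -1))
    b <- data.frame(begin = c(1, 1, 1), end = c(2, 3, 4), order = 1L,
                    stereo = c(1L, 0L, 0L))
    list(a = a, b = b)
}

# spurious wedge on the (non-stereogenic) central carbon of 2-propanol:
# counts (mol=1, inchi=0, perc=0).
.spuriousWedge <- function(x0 = 0) {
    a <- data.frame(element = c("C", "C", "C", "O"),
                    x = x0 + c(0, 0.866, 1.732, 0.866),
                    y = c(0, 0.5, 0, 1.5))
    b <- data.frame(begin = c(2, 2, 2), end = c(1, 3, 4), order = 1L,
                    stereo = c(1L, 0L, 0L))
    list(a = a, b = b)
}

.ISSUE_FIXTURES <- list(
    "Error-9986 (Cannot process aromatic bonds)" = function() {
        th <- pi / 2 + (0:4) * 2 * pi / 5
        a <- data.frame(element = rep("C", 5), x = cos(th), y = sin(th))
        b <- data.frame(begin = 1:5, end = c(2:5, 1), order = 4L, stereo = 0L)
        writeMolblock(newMolecule(a, b, name = "odd aromatic ring"))
    },
    "Illegal input" = function() {
        paste(c("truncated", "", "",
                "  3  2  0  0  0  0  0  0  0  0999 V2000",
                "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                "M  END"), collapse = "\n")
    },
    "InChI: Unknown element(s)" = function() {
        writeMolblock(newMolecule(
            data.frame(element = "Xx", x = 0, y = 0), name = "unknown element"))
    },
    "All atoms have zero coordinates" = function() {
        a <- data.frame(element = c("C", "C", "O"), x = 0, y = 0)
        b <- data.frame(begin = 1:2, end = 2:3, order = 1L, stereo = 0L)
        writeMolblock(newMolecule(a, b, name = "zeroed ethanol"))
    },
    "InChI: Accepted unusual valence(s)" = function() {
        a <- cbind(data.frame(element = rep("C", 6)),
                   data.frame(x = c(0, 1, -1, 0, 0, 0.7),
                              y = c(0, 0, 0, 1, -1, 0.7)))
        b <- data.frame(begin = 1L, end = 2:6, order = 1L, stereo = 0L)
        writeMolblock(newMolecule(a, b, name = "pentavalent carbon"))
    },
    "InChI: Empty structure" = function() {
        paste(c("empty", "", "",
                "  0  0  0  0  0  0  0  0  0  0999 V2000",
                "M  END"), collapse = "\n")
    },
    "Molecule has 3D coordinates" = function() {
        m <- .EXAMPLES$ethanol()
        a <- atoms(m); a$z[3] <- 0.7
        writeMolblock(.withGraph(m, a))
    },
    "Molecule has a radical that is not found in the known list" = function() {
        a <- data.frame(element = "C", x = 0, y = 0, radical = 2L)
        writeMolblock(newMolecule(a, name = "methyl radical"))
    },
    "Molecule has six (or more) atoms with exactly the same coordinates" = function() {
        a <- data.frame(element = rep("C", 6), x = 1.2, y = 0.8)
        b <- data.frame(begin = 1:5, end = 2:6, order = 1L, stereo = 0L)
        writeMolblock(newMolecule(a, b, name = "stacked hexane"))
    },
    "Number of atoms less than 1" = function() {
        .ISSUE_FIXTURES[["InChI: Empty structure"]]()
    },
    "Polymer information in mol file" = function() {
        .injectBeforeEnd(exampleMolblock("ethanol"), "M  STY  1   1 SRU")
    },
    "V3000 mol file" = function() {
        .setCountsVersion(exampleMolblock("ethanol"), "V3000")
    },
    "InChI_RDKit/Mol stereo mismatch" = function() {
        g <- .spuriousWedge()
        writeMolblock(newMolecule(g$a, g$b, name = "spurious wedge"))
    },
    "RDKit_Mol/InChI stereo mismatch" = function() {
        a <- data.frame(element = c("P", "C", "O", "S"),
                        x = c(0, 1.3, -1.3, 0),
                        y = c(0, 0.75, 0.75, -1.4),
                        z = c(0, 0.3, 0.3, 0.6))
        b <- data.frame(begin = c(1, 1, 1), end = c(2, 3, 4), order = 1L,
                        stereo = 0L)
        writeMolblock(newMolecule(a, b, name = "3D phosphine"))
    },
    "InChI_Mol/RDKit stereo mismatch" = function() {
        g <- .phosphineWedged()
        writeMolblock(newMolecule(g$a, g$b, name = "wedged phosphine"))
    },
    "Mol/Inchi/RDKit stereo mismatch" = function() {
        p <- .phosphineWedged()
        s <- .spuriousWedge(x0 = 5)
        a <- rbind(p$a, s$a)
        s$b$begin <- s$b$begin + nrow(p$a)
        s$b$end <- s$b$end + nrow(p$a)
        writeMolblock(newMolecule(a, rbind(p$b, s$b),
                                  name = "phosphine plus spurious wedge"))
    },
    "Molecule has a bond with an illegal stereo flag" = function() {
        writeMolblock(.chainMol(c("C", "C", "C"), "either-wedge propane",
                                stereo = c(4L, 0L)))
    },
    "Molecule has a bond with an illegal type" = function() {
        writeMolblock(.chainMol(c("C", "C", "C"), "query bond propane",
                                orders = c(5L, 1L)))
    },
    "Molecule has a crossed bond in a ring" = function() {
        a <- cbind(data.frame(element = rep("C", 6)), .hexagon())
        b <- data.frame(begin = 1:6, end = c(2:6, 1),
                        order = c(2L, 1L, 1L, 1L, 1L, 1L),
                        stereo = c(3L, 0L, 0L, 0L, 0L, 0L))
        writeMolblock(newMolecule(a, b, name = "crossed ring bond"))
    },
    "Molecule has two (or more) atoms with exactly the same coordinates" = function() {
        a <- cbind(data.frame(element = rep("C", 4)), .zigzag(4))
        a$x[4] <- a$x[2]; a$y[4] <- a$y[2]
        b <- data.frame(begin = 1:3, end = 2:4, order = 1L, stereo = 0L)
        writeMolblock(newMolecule(a, b, name = "two stacked atoms"))
    },
    "Molecule has a stereo bond in a ring" = function() {
        a <- cbind(data.frame(element = rep("C", 6)), .hexagon())
        b <- data.frame(begin = 1:6, end = c(2:6, 1), order = 1L,
                        stereo = c(1L, 0L, 0L, 0L, 0L, 0L))
        writeMolblock(newMolecule(a, b, name = "ring wedge"))
    },
    "Molecule has an atom with multiple stereo bonds" = function() {
        a <- data.frame(element = rep("C", 5),
                        x = c(0, 1, -1, 0, 0), y = c(0, 0.5, 0.5, 1.2, -1.2))
        b <- data.frame(begin = 1L, end = 2:5, order = 1L,
                        stereo = c(1L, 1L, 0L, 0L))
        writeMolblock(newMolecule(a, b, name = "double wedge"))
    },
    "Molecule has a stereo bond to a stereocenter" = function() {
        # wedge drawn from the methyl INTO the stereocentre C2 (F/Cl/CH3/CC)
        a <- data.frame(element = c("C", "C", "F", "Cl", "C", "C"),
                        x = c(0, 0.866, 0.866, 1.732, 1.732, 2.598),
                        y = c(0, 0.5, 1.5, 0, 1.0, 1.5))
        b <- data.frame(begin = c(1, 2, 2, 2, 5),
                        end = c(2, 3, 4, 5, 6), order = 1L,
                        stereo = c(1L, 0L, 0L, 0L, 0L))
        writeMolblock(newMolecule(a, b, name = "wedge into stereocentre"))
    },
    "Molecule has the 3D flag set for a 2D conformer" = function() {
        .setDimFlag(exampleMolblock("ethanol"), "3D")
    },
    "InChI: Omitted undefined stereo" = function() {
        exampleMolblock("flat_2_butanol")
    }
)

#' Labels covered by the issue fixture generator
#' @return character vector of labels accepted by [makeIssueFixture()].
#' @export
issueFixtureLabels <- function() names(.ISSUE_FIXTURES)

#' Generate a molblock that triggers a specific checker issue
#'
#' Each of the closed-registry labels (and the representative
#' "InChI: Omitted undefined stereo" member of the Other-warnings family)
#' has a constructor producing a minimal pathological molblock. The fixture
#' may unavoidably raise additional flags (e.g. a 3D record also carries
#' the 3D-coordinates flag); [checkMolblock()] is guaranteed to emit at
#' least the requested label.
#'
#' @param label a label from [issueFixtureLabels()].
#' @return list with elements \code{id} (the label), \code{molblock}, and
#'   \code{expectedScore} (the registry score of the label).
#' @export
makeIssueFixture <- function(label) {
    fn <- .ISSUE_FIXTURES[[label]]
    if (is.null(fn)) stop("no fixture constructor for label: ", label)
    reg <- issueRegistry()
    score <- reg$score[match(label, reg$label)]
    if (is.na(score)) score <- 2L  # Other InChI Warnings family
    list(id = label, molblock = fn(), expectedScore = as.integer(score))
}

# --- standardizer rule pairs ----------------------------------------------

.RULE_PAIRS <- list(
    nitro = function() {
        bad <- .chainMol(c("C", "N", "O"), "nitroethane-like",
                         orders = c(1L, 2L))
        a <- atoms(bad); b <- bonds(bad)
        a <- rbind(a, data.frame(element = "O", x = 1.732, y = -0.5, z = 0,
                                 charge = 0L, isotope = 0L, radical = 0L,
                                 parity = 0L))
        b <- rbind(b, data.frame(begin = 2L, end = 4L, order = 2L,
                                 stereo = 0L))
        before <- .withGraph(bad, a, b)
        a2 <- a; b2 <- b
        a2$charge <- c(0L, 1L, 0L, -1L)
        b2$order[3] <- 1L
        after <- .withGraph(bad, a2, b2)
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    alkali_metal = function() {
        before <- .chainMol(c("C", "O", "Na"), "sodium methoxide covalent")
        a <- atoms(before); b <- bonds(before)
        a$charge <- c(0L, -1L, 1L)
        after <- .withGraph(before, a, b[-2, , drop = FALSE])
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    amide_tautomer = function() {
        # CH3-C(OH)=NH  ->  CH3-C(=O)-NH2
        a <- data.frame(element = c("C", "C", "N", "O"),
                        x = c(0, 0.866, 1.732, 0.866), y = c(0, 0.5, 0, 1.5))
        b <- data.frame(begin = c(1, 2, 2), end = c(2, 3, 4),
                        order = c(1L, 2L, 1L), stereo = 0L)
        before <- newMolecule(a, b, name = "acetamide iminol")
        b2 <- b; b2$order <- c(1L, 1L, 2L)
        after <- newMolecule(a, b2, name = "acetamide")
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    sulfoxide = function() {
        a <- data.frame(element = c("C", "S", "C", "O"),
                        x = c(0, 0.866, 1.732, 0.866), y = c(0, 0.5, 0, 1.5))
        b <- data.frame(begin = c(1, 2, 2), end = c(2, 3, 4),
                        order = c(1L, 1L, 2L), stereo = 0L)
        before <- newMolecule(a, b, name = "DMSO double-bond form")
        a2 <- a; a2$charge <- c(0L, 1L, 0L, -1L)
        b2 <- b; b2$order[3] <- 1L
        after <- newMolecule(a2, b2, name = "DMSO charge-separated")
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    diazonium = function() {
        before <- .chainMol(c("C", "N", "N"), "methyl diazo",
                            orders = c(1L, 2L))
        a <- atoms(before); b <- bonds(before)
        a$charge <- c(0L, 1L, 0L)
        b$order[2] <- 3L
        after <- .withGraph(before, a, b)
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    quaternary_N = function() {
        a <- data.frame(element = c("N", "C", "C", "C", "C"),
                        x = c(0, 1, -1, 0, 0), y = c(0, 0.5, 0.5, 1.2, -1.2))
        b <- data.frame(begin = 1L, end = 2:5, order = 1L, stereo = 0L)
        before <- newMolecule(a, b, name = "uncharged quaternary N")
        a2 <- a; a2$charge <- c(1L, 0L, 0L, 0L, 0L)
        after <- newMolecule(a2, b, name = "tetramethylammonium")
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    trivalent_O = function() {
        a <- data.frame(element = c("O", "C", "C", "C"),
                        x = c(0, 1, -1, 0), y = c(0, 0.5, 0.5, -1.2))
        b <- data.frame(begin = 1L, end = 2:4, order = 1L, stereo = 0L)
        before <- newMolecule(a, b, name = "uncharged trimethyloxonium")
        a2 <- a; a2$charge <- c(1L, 0L, 0L, 0L)
        after <- newMolecule(a2, b, name = "trimethyloxonium")
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    trivalent_S = function() {
        a <- data.frame(element = c("S", "C", "C", "C"),
                        x = c(0, 1, -1, 0), y = c(0, 0.5, 0.5, -1.2))
        b <- data.frame(begin = 1L, end = 2:4, order = 1L, stereo = 0L)
        before <- newMolecule(a, b, name = "uncharged trimethylsulfonium")
        a2 <- a; a2$charge <- c(1L, 0L, 0L, 0L)
        after <- newMolecule(a2, b, name = "trimethylsulfonium")
        list(before = writeMolblock(before), after = writeMolblock(after))
    },
    lone_halogen = function() {
        # quaternary ammonium + neutral disconnected Cl atom vs the ion pair
        a <- data.frame(element = c("N", "C", "C", "C", "C", "Cl"),
                        x = c(0, 1, -1, 0, 0, 3.5),
                        y = c(0, 0.5, 0.5, 1.2, -1.2, 0),
                        charge = c(1L, 0L, 0L, 0L, 0L, 0L))
        b <- data.frame(begin = 1L, end = 2:5, order = 1L, stereo = 0L)
        before <- newMolecule(a, b, name = "ammonium + lone chlorine")
        a2 <- a; a2$charge[6] <- -1L
        after <- newMolecule(a2, b, name = "ammonium chloride salt")
        list(before = writeMolblock(before), after = writeMolblock(after))
    }
)

#' Before/after fixture pair for a normalization rule
#'
#' Standardizing \code{before} must reach the same InChIKey as
#' standardizing \code{after}, and \code{after} must already be a
#' standardization fixpoint.
#'
#' @param rule a rule name from the shipped rule table.
#' @return list with molblock strings \code{before} and \code{after}.
#' @export
makeRulePair <- function(rule) {
    fn <- .RULE_PAIRS[[rule]]
    if (is.null(fn)) stop("no rule pair for: ", rule)
    fn()
}

#' Names of rules with shipped before/after pairs
#' @return character vector.
#' @export
rulePairNames <- function() names(.RULE_PAIRS)

# --- salt fixtures ---------------------------------------------------------

.offsetMol <- function(mol, dx) {
    a <- atoms(mol)
    a$x <- a$x + dx
    .withGraph(mol, a)
}

#' Build a multi-component salt-form fixture
#'
#' Combines a parent structure with named dictionary entries (and optional
#' isotope labelling) into one molblock, the way salt forms are deposited.
#'
#' @param parentSmiles SMILES of the parent component, or NULL for
#'   salt-only records; may be given more than once via \code{copies}.
#' @param saltNames character vector of dictionary entry names (from either
#'   role); each contributes one component.
#' @param dict the dictionary to draw structures from.
#' @param copies number of copies of the parent component (2 for the 2:1
#'   complex case).
#' @param isotopeFirstAtom mass number to stamp on the parent's first atom
#'   (0 for none).
#' @return a molblock string.
#' @export
makeSaltFixture <- function(parentSmiles = NULL, saltNames = character(),
                            dict = loadSaltDictionary(), copies = 1L,
                            isotopeFirstAtom = 0L) {
    ent <- dictEntries(dict)
    comps <- list()
    if (!is.null(parentSmiles)) {
        p <- smilesToMolecule(parentSmiles, name = "parent")
        if (is.null(p)) stop("cannot parse parent SMILES: ", parentSmiles)
        if (isotopeFirstAtom > 0L) {
            a <- atoms(p)
            a$isotope[1] <- as.integer(isotopeFirstAtom)
            p <- .withGraph(p, a)
        }
        comps <- rep(list(p), copies)
    }
    for (nm in saltNames) {
        row <- match(nm, ent$name)
        if (is.na(row)) stop("dictionary has no entry named: ", nm)
        s <- smilesToMolecule(ent$smiles[row], name = nm)
        if (is.null(s)) stop("cannot parse dictionary SMILES for: ", nm)
        comps <- c(comps, list(s))
    }
    if (!length(comps)) stop("fixture needs at least one component")
    # spread components so no two atoms coincide
    dx <- 0
    for (i in seq_along(comps)) {
        comps[[i]] <- .offsetMol(comps[[i]], dx)
        dx <- dx + diff(range(atoms(comps[[i]])$x)) + 2.5
    }
    writeMolblock(.combineComponents(comps, name = "salt fixture"))
}

# --- randomized molecules for property suites ------------------------------

#' Random small organic molecules for property testing
#'
#' Generates parseable, non-excluded molblocks: random heavy-atom trees
#' over C/N/O/S with valence-respecting degrees, occasional protonated
#' amines, carboxylate-style anions, either-wedge codes and explicit
#' hydrogens -- the feature mix the standardizer has to normalize. The
#' generator is deterministic for a given seed.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return character vector of molblock strings.
#' @export
randomMolecules <- function(n, seed = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
    maxDeg <- c(C = 4L, N = 3L, O = 2L, S = 2L)
    vapply(seq_len(n), function(i) {
        nat <- sample(3:10, 1)
        el <- sample(c("C", "C", "C", "C", "N", "O", "S"), nat,
                     replace = TRUE)
        deg <- integer(nat)
        b <- data.frame(begin = integer(), end = integer(),
                        order = integer(), stereo = integer())
        for (v in 2:nat) {
            cand <- which(seq_len(nat) < v & deg < maxDeg[el[seq_len(nat)]] &
                          seq_len(nat) %in% 1:(v - 1))
            cand <- cand[deg[cand] < maxDeg[el[cand]]]
            if (!length(cand)) cand <- v - 1L
            u <- if (length(cand) == 1L) cand else sample(cand, 1)
            b <- rbind(b, data.frame(begin = u, end = v, order = 1L,
                                     stereo = 0L))
            deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
        }
        # occasional double bond where both ends have spare valence
        for (e in seq_len(nrow(b))) {
            u <- b$begin[e]; w <- b$end[e]
            if (runif(1) < 0.2 &&
                deg[u] < maxDeg[el[u]] && deg[w] < maxDeg[el[w]]) {
                b$order[e] <- 2L
                deg[u] <- deg[u] + 1L; deg[w] <- deg[w] + 1L
            }
        }
        a <- cbind(data.frame(element = el, stringsAsFactors = FALSE),
                   .zigzag(nat))
        a$charge <- 0L
        # a protonated amine or a deprotonated terminal oxygen now and then
        if (runif(1) < 0.3) {
            ns <- which(el == "N" & deg <= 3L)
            if (length(ns)) a$charge[ns[1]] <- 1L
        }
        if (runif(1) < 0.3) {
            os <- which(el == "O" & deg == 1L &
                        !seq_len(nat) %in% c(b$begin[b$order == 2L],
                                             b$end[b$order == 2L]))
            if (length(os)) a$charge[os[1]] <- -1L
        }
        if (runif(1) < 0.2 && nrow(b)) {
            e <- sample(nrow(b), 1)
            if (b$order[e] == 1L) b$stereo[e] <- 4L
        }
        writeMolblock(newMolecule(a, b, name = sprintf("random-%03d", i)))
    }, character(1))
}
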