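# The GetParent stage: isotope erasure and dictionary-based salt/solvent
# stripping, with the full branch logic for all-salt records, true
# mixtures, excluded (organometallic) records and 2:1 complexes.

#' Default salt and solvent dictionary files
#'
#' \code{SMILES<TAB>name} lines, \code{#} comments. The shipped salt list is
#' a curated starter set built from the USAN pharmacological salt classes;
#' a site-specific list can be loaded instead via [loadSaltDictionary()].
#' @return file path.
#' @rdname dictionaryFiles
#' @export
defaultSaltsFile <- function() {
    system.file("extdata", "salts.smi", package = "MolCurate",
                mustWork = TRUE)
}

#' @rdname dictionaryFiles
#' @export
defaultSolventsFile <- function() {
    system.file("extdata", "solvents.smi", package = "MolCurate",
                mustWork = TRUE)
}

#' Identity key for salt/solvent matching
#'
#' The key under which dictionary components are matched, engineered to be
#' insensitive to (i) charge state (acetic acid vs acetate, HCl vs
#' chloride), (ii) depicted stereochemistry (the tartrates) and (iii)
#' cis/trans isomerism (maleate vs fumarate). It is the skeleton (first)
#' block of the Standard InChIKey computed after erasing isotopes,
#' neutralizing by hydrogen bookkeeping and stripping all tetrahedral and
#' double-bond stereo annotations. Pure and independent of atom order.
#'
#' @param component a connected \linkS4class{Molecule}.
#' @return a 14-character key, or "" when the engine cannot process the
#'   component.
#' @examples
#' k1 <- buildMatchKey(smilesToMolecule("CC(=O)O"))
#' k2 <- buildMatchKey(smilesToMolecule("CC(=O)[O-]"))
#' identical(k1, k2)
#' @export
buildMatchKey <- function(component) {
    stopifnot(is(component, "Molecule"), parseOk(component))
    mol <- removeIsotopes(component)
    mol <- .stepNeutralize(mol)$mol
    a <- atoms(mol); b <- bonds(mol)
    a$parity <- 0L
    if (nrow(b)) b$stereo <- 0L
    mol <- .withGraph(mol, a, b)
    key <- .inchikeyOf(writeMolblock(mol))
    if (!nzchar(key)) return("")
    substr(key, 1, 14)
}

#' Erase all isotope information
#'
#' Sets every atom's isotope field to 0; explicit isotopic hydrogens become
#' ordinary hydrogens (and are then subject to the usual explicit-H removal
#' on re-standardization).
#'
#' @param mol a parsed \linkS4class{Molecule}.
#' @return the isotope-free \linkS4class{Molecule}.
#' @export
removeIsotopes <- function(mol) {
    stopifnot(is(mol, "Molecule"), parseOk(mol))
    a <- atoms(mol)
    if (!nrow(a) || all(a$isotope == 0L)) return(mol)
    a$isotope <- 0L
    .withGraph(mol, a)
}

.readSmilesFile <- function(path, role) {
    if (!file.exists(path))
        stop("dictionary file not found: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(data.frame(name = character(), role = character(),
                          smiles = character(), matchKey = character(),
                          stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[[`, "", 1L)
    nm <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else p[[1]],
                 "")
    keys <- vapply(seq_along(smi), function(i) {
        mol <- smilesToMolecule(smi[i], name = nm[i])
        if (is.null(mol)) stop("cannot parse dictionary SMILES for '",
                               nm[i], "': ", smi[i])
        buildMatchKey(mol)
    }, character(1))
    bad <- !nzchar(keys)
    if (any(bad))
        stop("cannot key dictionary entries: ",
             paste(nm[bad], collapse = ", "))
    data.frame(name = nm, role = role, smiles = smi, matchKey = keys,
               stringsAsFactors = FALSE)
}

#' Load the salt/solvent dictionary
#'
#' Entries are keyed with [buildMatchKey()]; two entries of the same role
#' that collapse to the same key (e.g. listing both acetic acid and
#' acetate) are rejected with a clear message, since they would be
#' indistinguishable at matching time.
#'
#' @param saltsFile,solventsFile paths to \code{SMILES<TAB>name} files.
#' @return a \linkS4class{SaltSolventDictionary}.
#' @export
loadSaltDictionary <- function(saltsFile = defaultSaltsFile(),
                               solventsFile = defaultSolventsFile()) {
    entries <- rbind(.readSmilesFile(saltsFile, "salt"),
                     .readSmilesFile(solventsFile, "solvent"))
    for (r in unique(entries$role)) {
        sub <- entries[entries$role == r, ]
        dup <- duplicated(sub$matchKey)
        if (any(dup)) {
            clash <- sub$matchKey[dup][1]
            stop("duplicate ", r, " match key ", clash, ": ",
                 paste(sub$name[sub$matchKey == clash], collapse = " / "),
                 " are the same skeleton under charge/stereo-insensitive ",
                 "matching; keep one")
        }
    }
    rownames(entries) <- NULL
    new("SaltSolventDictionary", entries = entries)
}

.cachedDefaultDictionary <- function() {
    d <- .molcurateEnv$defaultDict
    if (is.null(d)) {
        d <- loadSaltDictionary()
        .molcurateEnv$defaultDict <- d
    }
    d
}

#' Derive the parent structure of a record
#'
#' Implements the parent-generation branch logic:
#' \enumerate{
#'   \item a single-component, isotope-free record is its own parent
#'     (\code{identity});
#'   \item isotope information is erased;
#'   \item components matching the dictionary are identified -- for
#'     excluded (organometallic/polyborane) records only solvents are
#'     eligible, since stripping apparent counter-ions from a coordination
#'     complex would fabricate a bare metal ion parent;
#'   \item if every component matched, nothing is removed and the parent is
#'     the input mixture (\code{all_salt_unchanged}, the sodium chloride
#'     case);
#'   \item if the record is multi-component and nothing matched, it is a
#'     true mixture and passes through (\code{true_mixture_unchanged});
#'   \item otherwise matched components are dropped, key-identical
#'     leftovers are collapsed to one copy (the 2:1 complex case), and the
#'     remainder is neutralized and re-standardized.
#' }
#' A component matching both roles is treated as a salt (flagged in the
#' removal table by its role).
#'
#' @param text a parseable molblock string, ordinarily already
#'   standardized.
#' @param dict a \linkS4class{SaltSolventDictionary}.
#' @param metalsFile,boronThreshold exclusion configuration (must match the
#'   standardizer's).
#' @return a \linkS4class{ParentResult}.
#' @examples
#' dict <- loadSaltDictionary()
#' res <- getParent(exampleMolblock("sodium_acetate"), dict)
#' branch(res)
#' @export
getParent <- function(text, dict = loadSaltDictionary(),
                      metalsFile = defaultMetalsFile(),
                      boronThreshold = 7L) {
    mol <- parseMolblock(text)
    if (!parseOk(mol))
        stop("cannot derive a parent: ", mol@parseError)
    if (natoms(mol) < 1L)
        stop("cannot derive a parent of an empty structure")
    rules <- exclusionRules(metalsFile, boronThreshold)
    excluded <- computeExcludeFlag(mol, rules)
    comps <- splitComponents(mol)
    hasIso <- any(atoms(mol)$isotope != 0L)

    if (length(comps) == 1L && !hasIso && !excluded) {
        return(new("ParentResult", parentMolblock = text,
                   isotopesRemoved = FALSE, deduplicated = FALSE,
                   branch = "identity"))
    }

    comps <- lapply(comps, removeIsotopes)
    keys <- vapply(comps, buildMatchKey, character(1))
    ent <- dictEntries(dict)
    roles <- if (excluded) "solvent" else c("salt", "solvent")
    matchRow <- vapply(keys, function(k) {
        hits <- which(ent$matchKey == k & ent$role %in% roles)
        if (!length(hits)) return(NA_integer_)
        # salt takes precedence when a key matches both roles
        hits[order(match(ent$role[hits], c("salt", "solvent")))][1]
    }, integer(1))
    matched <- !is.na(matchRow)

    removedTab <- data.frame(component = which(matched),
                             name = ent$name[matchRow[matched]],
                             role = ent$role[matchRow[matched]],
                             stringsAsFactors = FALSE)

    emit <- function(molOut, branchName, removed, dedup) {
        new("ParentResult", parentMolblock = writeMolblock(molOut),
            removed = removed, isotopesRemoved = hasIso,
            deduplicated = dedup, branch = branchName)
    }
    noRemoval <- data.frame(component = integer(), name = character(),
                            role = character(), stringsAsFactors = FALSE)
    wholeIsoFree <- removeIsotopes(mol)

    if (excluded) {
        if (!any(matched))
            return(emit(wholeIsoFree, "excluded_solvent_only", noRemoval,
                        FALSE))
        if (all(matched))   # solvent-only record: keep it intact
            return(emit(wholeIsoFree, "all_salt_unchanged", noRemoval, FALSE))
        keep <- comps[!matched]
        out <- .combineComponents(keep, mol@name)
        return(emit(out, "excluded_solvent_only", removedTab, FALSE))
    }

    if (any(matched) && all(matched))
        return(emit(wholeIsoFree, "all_salt_unchanged", noRemoval, FALSE))
    if (length(comps) > 1L && !any(matched))
        return(emit(wholeIsoFree, "true_mixture_unchanged", noRemoval, FALSE))

    keep <- which(!matched)
    dedup <- FALSE
    if (any(matched) && length(keep) > 1L) {
        first <- !duplicated(keys[keep])
        dedup <- any(!first)
        keep <- keep[first]
    }
    out <- .combineComponents(comps[keep], mol@name)
    res <- .standardizeMolecule(out, .enabledRuleNames(defaultRulesFile()))
    emit(res$mol, "salts_stripped", removedTab, dedup)
}

# Reassemble components into one Molecule (atom blocks concatenated).
.combineComponents <- function(comps, name = "") {
    stopifnot(length(comps) >= 1L)
    a <- do.call(rbind, lapply(comps, atoms))
    offs <- cumsum(c(0L, vapply(comps, natoms, integer(1))))
    b <- do.call(rbind, lapply(seq_along(comps), function(i) {
        bi <- bonds(comps[[i]])
        if (nrow(bi)) {
            bi$begin <- bi$begin + offs[i]
            bi$end <- bi$end + offs[i]
        }
        bi
    }))
    newMolecule(a, b, name = name)
}
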