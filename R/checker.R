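# The Checker: penalty-scored validation of molblocks.
#
# Scores grade severity (7 fatal .. 2 cosmetic); a record's reported score
# is the maximum over its flags. Errors are never corrected here -- the
# structure is scored exactly as deposited and the input text is never
# modified.

#' The closed registry of checker issue labels and their penalty scores
#'
#' Labels are opaque identifiers; every label emitted by the checker maps to
#' exactly one score. Warnings of the InChI engine that have no dedicated
#' row are reported verbatim as \code{"InChI: <warning>"} under the
#' score-2 "Other InChI Warnings" class.
#'
#' @return data.frame with columns \code{score}, \code{label}.
#' @export
issueRegistry <- function() {
    data.frame(
        score = c(rep(7L, 3), rep(6L, 9), rep(5L, 7), rep(2L, 6)),
        label = c(
            "Error-9986 (Cannot process aromatic bonds)",
            "Illegal input",
            "InChI: Unknown element(s)",
            "All atoms have zero coordinates",
            "InChI: Accepted unusual valence(s)",
            "InChI: Empty structure",
            "Molecule has 3D coordinates",
            "Molecule has a radical that is not found in the known list",
            "Molecule has six (or more) atoms with exactly the same coordinates",
            "Number of atoms less than 1",
            "Polymer information in mol file",
            "V3000 mol file",
            "InChI_RDKit/Mol stereo mismatch",
            "Mol/Inchi/RDKit stereo mismatch",
            "RDKit_Mol/InChI stereo mismatch",
            "Molecule has a bond with an illegal stereo flag",
            "Molecule has a bond with an illegal type",
            "Molecule has a crossed bond in a ring",
            "Molecule has two (or more) atoms with exactly the same coordinates",
            "InChI_Mol/RDKit stereo mismatch",
            "Molecule has a stereo bond in a ring",
            "Molecule has an atom with multiple stereo bonds",
            "Molecule has a stereo bond to a stereocenter",
            "Molecule has the 3D flag set for a 2D conformer",
            "Other InChI Warnings"
        ),
        stringsAsFactors = FALSE)
}

.issue <- function(score, label) {
    data.frame(score = as.integer(score), label = label,
               stringsAsFactors = FALSE)
}

.COORD_TOL <- 1e-4  # below the 4-decimal precision of the molfile format

#' Format-level checks
#'
#' Scores connection-table level problems: unreadable input, V3000 records
#' (detected but never parsed), polymer S-groups, empty atom blocks, illegal
#' bond type codes (legal: 1-4) and illegal bond stereo codes. Legal stereo
#' codes are {0,1,6} on single bonds and {0,3} on double bonds; in
#' particular the historic "either" code 4 is treated as illegal, matching
#' curation practice rather than the letter of the CTfile specification.
#' Aromatic bond codes are legal at parse time but must admit a kekule
#' assignment; failure is the fatal aromatic-bonds error.
#'
#' @param record a \linkS4class{Molecule}.
#' @return issue data.frame (columns \code{score}, \code{label}).
#' @export
checkFormat <- function(record) {
    iss <- .issue(integer(), character())
    if (!parseOk(record)) {
        if (identical(record@version, "V3000"))
            return(.issue(6L, "V3000 mol file"))
        return(.issue(7L, "Illegal input"))
    }
    if (record@hasPolymerSgroup)
        iss <- rbind(iss, .issue(6L, "Polymer information in mol file"))
    if (natoms(record) < 1L)
        iss <- rbind(iss, .issue(6L, "Number of atoms less than 1"))
    b <- bonds(record)
    if (nrow(b)) {
        if (any(!b$order %in% 1:4))
            iss <- rbind(iss, .issue(5L, "Molecule has a bond with an illegal type"))
        legal <- b$order == 1L & b$stereo %in% c(0L, 1L, 6L) |
                 b$order == 2L & b$stereo %in% c(0L, 3L) |
                 b$order %in% c(3L, 4L) & b$stereo == 0L
        if (any(b$order %in% 1:4 & !legal))
            iss <- rbind(iss, .issue(5L, "Molecule has a bond with an illegal stereo flag"))
        if (any(b$order == 4L)) {
            kek <- tryCatch({ .kekulizeMolecule(record); TRUE },
                            error = function(e) FALSE)
            if (!kek)
                iss <- rbind(iss, .issue(7L, "Error-9986 (Cannot process aromatic bonds)"))
        }
    }
    iss
}

#' Coordinate checks
#'
#' Coordinate identity is evaluated after parsing with tolerance 1e-4
#' molfile units (below the format's 4-decimal precision), so trailing-zero
#' formatting differences never matter. The all-zero flag requires at least
#' two atoms: a single atom legitimately sits at the origin. The score-6
#' (six or more coincident atoms) and score-5 (two or more) flags are
#' mutually exclusive; the more serious one wins.
#'
#' @param record a parsed \linkS4class{Molecule} with at least one atom.
#' @return issue data.frame.
#' @export
checkCoordinates <- function(record) {
    a <- atoms(record)
    iss <- .issue(integer(), character())
    if (!nrow(a)) return(iss)
    if (nrow(a) > 1L &&
        all(abs(a$x) <= .COORD_TOL & abs(a$y) <= .COORD_TOL &
            abs(a$z) <= .COORD_TOL))
        iss <- rbind(iss, .issue(6L, "All atoms have zero coordinates"))
    key <- paste(round(a$x / .COORD_TOL), round(a$y / .COORD_TOL),
                 round(a$z / .COORD_TOL))
    sizes <- table(key)
    if (any(sizes >= 6L)) {
        iss <- rbind(iss, .issue(6L,
            "Molecule has six (or more) atoms with exactly the same coordinates"))
    } else if (any(sizes >= 2L)) {
        iss <- rbind(iss, .issue(5L,
            "Molecule has two (or more) atoms with exactly the same coordinates"))
    }
    if (any(abs(a$z) > .COORD_TOL))
        iss <- rbind(iss, .issue(6L, "Molecule has 3D coordinates"))
    else if (identical(record@dimFlag, "3D"))
        iss <- rbind(iss, .issue(2L, "Molecule has the 3D flag set for a 2D conformer"))
    iss
}

# Canonical-SMILES keys of the known-radical list (loaded once per file).
.knownRadicalKeys <- function(path) {
    cache <- .molcurateEnv$radicalCache
    if (is.null(cache)) { cache <- list(); }
    if (!is.null(cache[[path]])) return(cache[[path]])
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    smi <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    keys <- vapply(smi, function(s) {
        out <- .convertQuiet("SMI", "CAN", paste0(s, "\n"))
        strsplit(trimws(out), "[\t\n]")[[1]][1]
    }, character(1))
    keys <- unname(keys[nzchar(keys) & !is.na(keys)])
    cache[[path]] <- keys
    .molcurateEnv$radicalCache <- cache
    keys
}

#' Default known-radical list file
#'
#' Stable radicals that are legitimate database entries (nitric oxide,
#' nitrogen dioxide, a TEMPO-type aminoxyl). Aminoxyl-type N-O monoradicals
#' are additionally recognised structurally, so substituted nitroxides need
#' not be enumerated. The file holds one \code{SMILES<TAB>name} per line and
#' can be replaced to tailor the list.
#' @return path to the shipped file.
#' @export
defaultRadicalFile <- function() {
    system.file("extdata", "known_radicals.smi", package = "MolCurate",
                mustWork = TRUE)
}

#' Radical check
#'
#' Flags any radical-carrying record whose radical component is not on the
#' known list (compared by engine-canonical SMILES) and is not an
#' aminoxyl-type N-O monoradical.
#'
#' @param record a parsed \linkS4class{Molecule}.
#' @param radicalFile path to the known-radical list.
#' @return issue data.frame.
#' @export
checkRadicals <- function(record, radicalFile = defaultRadicalFile()) {
    a <- atoms(record)
    iss <- .issue(integer(), character())
    if (!nrow(a) || all(a$radical == 0L)) return(iss)
    known <- .knownRadicalKeys(radicalFile)
    adj <- .adjacency(record)
    comp <- .componentLabels(record)
    for (k in unique(comp[a$radical > 0L])) {
        idx <- which(comp == k)
        sub <- .subsetAtoms(record, idx)
        sa <- atoms(sub)
        radAtoms <- which(sa$radical > 0L)
        aminoxyl <- length(radAtoms) == 1L && {
            v <- radAtoms[1]
            nb <- .adjacency(sub)[[v]]
            sa$element[v] == "O" && length(nb) == 1L &&
                sa$element[nb] == "N"
        }
        if (aminoxyl) next
        key <- .canonicalSmilesOf(sub)
        if (!nzchar(key) || !key %in% known) {
            iss <- .issue(6L,
                "Molecule has a radical that is not found in the known list")
            break
        }
    }
    iss
}

#' Stereo-drawing checks
#'
#' Flags drawing conventions that make wedge interpretation unreliable:
#' wedged bonds lying in rings, atoms from which several wedges originate,
#' wedges pointing at (ending on) a perceived stereocentre -- the wedge
#' should originate from the stereocentre -- and crossed ("either") double
#' bonds inside rings.
#'
#' @param record a parsed \linkS4class{Molecule}.
#' @return issue data.frame.
#' @export
checkStereoDrawing <- function(record) {
    b <- bonds(record)
    iss <- .issue(integer(), character())
    if (!nrow(b)) return(iss)
    ring <- .ringBonds(record)
    wedge <- b$stereo %in% .WEDGE_CODES
    if (any(wedge & ring))
        iss <- rbind(iss, .issue(2L, "Molecule has a stereo bond in a ring"))
    if (any(table(b$begin[wedge]) >= 2L))
        iss <- rbind(iss, .issue(2L, "Molecule has an atom with multiple stereo bonds"))
    if (any(wedge)) {
        centres <- .potentialStereocentres(record)
        if (any(b$end[wedge] %in% centres))
            iss <- rbind(iss, .issue(2L, "Molecule has a stereo bond to a stereocenter"))
    }
    if (any(b$order == 2L & b$stereo == 3L & ring))
        iss <- rbind(iss, .issue(5L, "Molecule has a crossed bond in a ring"))
    iss
}

#' Default InChI warning mapping file
#'
#' Tab-separated columns \code{pattern}, \code{score}, \code{label}: engine
#' warnings containing \code{pattern} map to the given issue; anything
#' unmapped is reported verbatim at score 2 under the "Other InChI
#' Warnings" class. Data-driven because warning strings vary between engine
#' versions.
#' @return path to the shipped file.
#' @export
defaultWarningMapFile <- function() {
    system.file("extdata", "inchi_warning_map.tsv", package = "MolCurate",
                mustWork = TRUE)
}

.warningMap <- function(path) {
    cache <- .molcurateEnv$warnMapCache
    if (is.null(cache)) cache <- list()
    if (!is.null(cache[[path]])) return(cache[[path]])
    map <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             comment.char = "#")
    stopifnot(all(c("pattern", "score", "label") %in% names(map)))
    cache[[path]] <- map
    .molcurateEnv$warnMapCache <- cache
    map
}

#' InChI-layer checks
#'
#' Runs the InChI engine on the record and maps its warnings to issues via
#' the warning map; unmapped warnings are reported verbatim with the low
#' score 2 (they mostly reflect atom reorganisation or racemic drawings,
#' not structural defects).
#'
#' @param record a \linkS4class{Molecule} or molblock string.
#' @param inchi optional precomputed [computeInchi()] result.
#' @param warningMapFile path to the mapping table.
#' @return issue data.frame.
#' @export
checkInchiLayer <- function(record, inchi = NULL,
                            warningMapFile = defaultWarningMapFile()) {
    if (is.null(inchi)) inchi <- computeInchi(record)
    iss <- .issue(integer(), character())
    if (!length(inchi$warnings)) return(iss)
    map <- .warningMap(warningMapFile)
    for (w in inchi$warnings) {
        hit <- which(vapply(map$pattern, grepl, logical(1), x = w,
                            fixed = TRUE))
        if (length(hit)) {
            iss <- rbind(iss, .issue(map$score[hit[1]], map$label[hit[1]]))
        } else {
            iss <- rbind(iss, .issue(2L, paste0("InChI: ", w)))
        }
    }
    iss
}

#' Run the full checker on a molblock
#'
#' Aggregates every check into a \linkS4class{CheckReport}. Graph-level
#' checks are short-circuited when parsing fails; the stereocentre
#' cross-validation is skipped when the InChI engine fails (its count would
#' be meaningless). The input text is never modified and the result is
#' deterministic for a fixed input and configuration.
#'
#' @param text molblock string.
#' @param radicalFile,warningMapFile configuration file paths.
#' @return a \linkS4class{CheckReport}.
#' @examples
#' rep <- checkMolblock(exampleMolblock("ethanol"))
#' maxScore(rep)
#' @export
checkMolblock <- function(text, radicalFile = defaultRadicalFile(),
                          warningMapFile = defaultWarningMapFile()) {
    record <- parseMolblock(text)
    iss <- checkFormat(record)
    if (parseOk(record)) {
        inchi <- computeInchi(record)
        iss <- rbind(iss, checkInchiLayer(record, inchi, warningMapFile))
        if (natoms(record) >= 1L) {
            iss <- rbind(iss, checkCoordinates(record))
            iss <- rbind(iss, checkRadicals(record, radicalFile))
            iss <- rbind(iss, checkStereoDrawing(record))
            if (!inchi$failed) {
                mm <- classifyStereoMismatch(countStereo(record, inchi))
                if (!is.null(mm)) iss <- rbind(iss, mm)
            }
        }
    }
    iss <- unique(iss)
    iss <- iss[order(-iss$score, iss$label), , drop = FALSE]
    rownames(iss) <- NULL
    new("CheckReport", issues = iss,
        maxScore = if (nrow(iss)) max(iss$score) else 0L,
        engineVersion = engineVersion())
}
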