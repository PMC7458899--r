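#' @import methods
NULL

.emptyAtoms <- function() {
    data.frame(element = character(), x = numeric(), y = numeric(),
               z = numeric(), charge = integer(), isotope = integer(),
               radical = integer(), parity = integer(),
               stringsAsFactors = FALSE)
}

.emptyBonds <- function() {
    data.frame(begin = integer(), end = integer(), order = integer(),
               stereo = integer(), stringsAsFactors = FALSE)
}

.emptyIssues <- function() {
    data.frame(score = integer(), label = character(),
               stringsAsFactors = FALSE)
}

#' Molecule: a parsed V2000 molblock
#'
#' Container for one connection-table record as deposited. Parsing is
#' deliberately non-correcting: illegal bond type/stereo codes, unusual
#' element symbols and bad valences are preserved verbatim so that the
#' checker can score the input exactly as received. Failed parses keep the
#' raw text and carry a diagnostic in \code{parseError}.
#'
#' @slot name character, molfile header line 1.
#' @slot dimFlag character, the \code{"2D"}/\code{"3D"} flag of header line 2
#'   (may be empty or other text; never trusted, only reported).
#' @slot atoms data.frame with columns \code{element, x, y, z, charge,
#'   isotope, radical, parity}. \code{isotope} is an absolute mass number or
#'   0 (natural); \code{radical} is the molfile \code{M  RAD} code (0 none).
#' @slot bonds data.frame with columns \code{begin, end, order, stereo};
#'   codes are kept exactly as read.
#' @slot hasPolymerSgroup logical, TRUE if an S-group of a polymer type
#'   (SRU, MON, COP, CRO, MOD, GRA, ANY) is declared.
#' @slot hasAnySgroup logical, TRUE if any \code{M  STY} line is present.
#' @slot version character, \code{"V2000"}, \code{"V3000"} or other text
#'   found in the counts line.
#' @slot parseOk logical; FALSE means \code{atoms}/\code{bonds} may be empty
#'   and \code{parseError} is non-empty.
#' @slot parseError character diagnostic ("" when \code{parseOk}).
#' @slot rawText character, the original molblock, byte-identical.
#' @slot sdfFields named character vector of SD data fields attached to the
#'   record (empty for bare molblocks); passed through untouched by the
#'   pipeline commands.
#'
#' @seealso [parseMolblock()], [writeMolblock()], [splitComponents()]
#' @export
setClass("Molecule",
    representation(
        name = "character",
        dimFlag = "character",
        atoms = "data.frame",
        bonds = "data.frame",
        hasPolymerSgroup = "logical",
        hasAnySgroup = "logical",
        version = "character",
        parseOk = "logical",
        parseError = "character",
        rawText = "character",
        sdfFields = "character"
    ),
    prototype(
        name = "", dimFlag = "2D",
        atoms = .emptyAtoms(), bonds = .emptyBonds(),
        hasPolymerSgroup = FALSE, hasAnySgroup = FALSE,
        version = "V2000", parseOk = TRUE, parseError = "",
        rawText = "", sdfFields = character()
    )
)

setValidity("Molecule", function(object) {
    msg <- character()
    a <- object@atoms
    b <- object@bonds
    need_a <- c("element", "x", "y", "z", "charge", "isotope", "radical",
                "parity")
    need_b <- c("begin", "end", "order", "stereo")
    if (!all(need_a %in% names(a)))
        msg <- c(msg, "atoms must have columns element,x,y,z,charge,isotope,radical,parity")
    if (!all(need_b %in% names(b)))
        msg <- c(msg, "bonds must have columns begin,end,order,stereo")
    if (object@parseOk) {
        if (nrow(a) && any(is.na(a$element) | !nzchar(a$element)))
            msg <- c(msg, "atom element symbols must be non-empty")
        if (nrow(a) && any(a$isotope < 0))
            msg <- c(msg, "isotope mass numbers must be >= 0")
        if (nrow(b)) {
            if (any(b$begin == b$end))
                msg <- c(msg, "bond begin and end atoms must differ")
            if (any(b$begin < 1 | b$begin > nrow(a) |
                    b$end < 1 | b$end > nrow(a)))
                msg <- c(msg, "bond atom indices out of range")
        }
    } else if (!nzchar(object@parseError)) {
        msg <- c(msg, "parseOk=FALSE requires a non-empty parseError")
    }
    if (length(msg)) msg else TRUE
})

#' CheckReport: penalty-scored validation result
#'
#' Result of running the full checker over one molblock. Each issue is a
#' (score, label) pair; labels are opaque identifiers from the closed
#' registry (see [issueRegistry()]) plus the dynamic \code{"InChI: <warning>"}
#' family. Issues are deduplicated and ordered by descending score then
#' label; \code{maxScore} is the record's reported (most serious) score, or
#' 0 when the record is clean.
#'
#' @slot issues data.frame with columns \code{score} (integer, one of
#'   2/5/6/7) and \code{label} (character).
#' @slot maxScore integer.
#' @slot engineVersion character, identifies the InChI/perception engine so
#'   that warning-string provenance is recorded with every report.
#' @seealso [checkMolblock()]
#' @export
setClass("CheckReport",
    representation(issues = "data.frame", maxScore = "integer",
                   engineVersion = "character"),
    prototype(issues = .emptyIssues(), maxScore = 0L, engineVersion = "")
)

setValidity("CheckReport", function(object) {
    iss <- object@issues
    msg <- character()
    if (!all(c("score", "label") %in% names(iss)))
        msg <- c(msg, "issues must have columns score,label")
    else {
        if (nrow(iss) && !all(iss$score %in% c(2L, 5L, 6L, 7L)))
            msg <- c(msg, "scores must be in {2,5,6,7}")
        want <- if (nrow(iss)) max(iss$score) else 0L
        if (object@maxScore != want)
            msg <- c(msg, "maxScore must equal max issue score (or 0)")
        if (anyDuplicated(paste(iss$score, iss$label)))
            msg <- c(msg, "issues must be deduplicated")
    }
    if (length(msg)) msg else TRUE
})

#' StandardizationResult
#'
#' @slot molblock character, the standardized molblock (the input unchanged
#'   when \code{excludeFlag} is TRUE).
#' @slot excludeFlag logical; TRUE for organometallic/polyborane records on
#'   which no standardization is attempted.
#' @slot appliedRules character, names of pipeline steps that changed the
#'   structure, in application order (empty when excluded).
#' @slot changed logical, TRUE when the Standard InChIKey differs before vs
#'   after standardization; NA when key computation was not requested.
#' @slot inchikeyBefore,inchikeyAfter character ("" when not computed).
#' @seealso [standardizeMolblock()]
#' @export
setClass("StandardizationResult",
    representation(molblock = "character", excludeFlag = "logical",
                   appliedRules = "character", changed = "logical",
                   inchikeyBefore = "character", inchikeyAfter = "character"),
    prototype(molblock = "", excludeFlag = FALSE, appliedRules = character(),
              changed = NA, inchikeyBefore = "", inchikeyAfter = "")
)

setValidity("StandardizationResult", function(object) {
    if (object@excludeFlag && length(object@appliedRules))
        "excluded records must carry an empty applied-rule trace"
    else TRUE
})

#' SaltSolventDictionary
#'
#' Dictionary of removable counter-ions and crystallization solvents, keyed
#' by a match key that is insensitive to charge state, depicted
#' stereochemistry and cis/trans isomerism (see [buildMatchKey()]).
#'
#' @slot entries data.frame with columns \code{name, role, smiles, matchKey};
#'   \code{role} is \code{"salt"} or \code{"solvent"}. No two entries share
#'   \code{(matchKey, role)}.
#' @seealso [loadSaltDictionary()], [getParent()]
#' @export
setClass("SaltSolventDictionary",
    representation(entries = "data.frame"),
    prototype(entries = data.frame(name = character(), role = character(),
                                   smiles = character(),
                                   matchKey = character(),
                                   stringsAsFactors = FALSE))
)

setValidity("SaltSolventDictionary", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("name", "role", "smiles", "matchKey") %in% names(e)))
        msg <- c(msg, "entries must have columns name,role,smiles,matchKey")
    else {
        if (nrow(e) && !all(e$role %in% c("salt", "solvent")))
            msg <- c(msg, "role must be 'salt' or 'solvent'")
        if (anyDuplicated(paste(e$matchKey, e$role)))
            msg <- c(msg, "duplicate (matchKey, role) entries")
    }
    if (length(msg)) msg else TRUE
})

.parentBranches <- c("identity", "salts_stripped", "all_salt_unchanged",
                     "true_mixture_unchanged", "excluded_solvent_only")

#' ParentResult
#'
#' @slot parentMolblock character, the parent structure.
#' @slot removed data.frame with columns \code{component} (1-based index in
#'   the input's component list), \code{name}, \code{role}: the dictionary
#'   entries that were stripped.
#' @slot isotopesRemoved logical.
#' @slot deduplicated logical, TRUE when key-identical leftover components
#'   were collapsed to one copy (the 2:1 acid/calcium case).
#' @slot branch character, one of \code{identity}, \code{salts_stripped},
#'   \code{all_salt_unchanged}, \code{true_mixture_unchanged},
#'   \code{excluded_solvent_only}.
#' @seealso [getParent()]
#' @export
setClass("ParentResult",
    representation(parentMolblock = "character", removed = "data.frame",
                   isotopesRemoved = "logical", deduplicated = "logical",
                   branch = "character"),
    prototype(parentMolblock = "",
              removed = data.frame(component = integer(), name = character(),
                                   role = character(), stringsAsFactors = FALSE),
              isotopesRemoved = FALSE, deduplicated = FALSE,
              branch = "identity")
)

setValidity("ParentResult", function(object) {
    msg <- character()
    if (!object@branch %in% .parentBranches)
        msg <- c(msg, paste("branch must be one of:",
                            paste(.parentBranches, collapse = ", ")))
    if (object@branch == "identity" && nrow(object@removed))
        msg <- c(msg, "identity branch must not remove components")
    if (length(msg)) msg else TRUE
})
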