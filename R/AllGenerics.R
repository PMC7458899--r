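#' @rdname Molecule-class
#' @param x,object a \linkS4class{Molecule} (or other pipeline object).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname Molecule-class
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname Molecule-class
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))
#' @rdname Molecule-class
#' @export
setGeneric("parseOk", function(x) standardGeneric("parseOk"))
#' @rdname Molecule-class
#' @export
setGeneric("rawText", function(x) standardGeneric("rawText"))
#' @rdname Molecule-class
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))

#' @rdname CheckReport-class
#' @param x a \linkS4class{CheckReport}.
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))
#' @rdname CheckReport-class
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))

#' @rdname SaltSolventDictionary-class
#' @param x a \linkS4class{SaltSolventDictionary}.
#' @export
setGeneric("dictEntries", function(x) standardGeneric("dictEntries"))

#' @rdname ParentResult-class
#' @param x a \linkS4class{ParentResult}.
#' @export
setGeneric("branch", function(x) standardGeneric("branch"))

setMethod("atoms", "Molecule", function(x) x@atoms)
setMethod("bonds", "Molecule", function(x) x@bonds)
setMethod("molName", "Molecule", function(x) x@name)
setMethod("parseOk", "Molecule", function(x) x@parseOk)
setMethod("rawText", "Molecule", function(x) x@rawText)
setMethod("natoms", "Molecule", function(x) nrow(x@atoms))

setMethod("issues", "CheckReport", function(x) x@issues)
setMethod("maxScore", "CheckReport", function(x) x@maxScore)
setMethod("dictEntries", "SaltSolventDictionary", function(x) x@entries)
setMethod("branch", "ParentResult", function(x) x@branch)

setMethod("show", "Molecule", function(object) {
    if (!object@parseOk) {
        cat("Molecule (parse failed, version=", object@version, "): ",
            object@parseError, "\n", sep = "")
        return(invisible(NULL))
    }
    cat("Molecule '", object@name, "': ", nrow(object@atoms), " atoms, ",
        nrow(object@bonds), " bonds", sep = "")
    extras <- c(
        if (any(object@atoms$charge != 0)) "charges",
        if (any(object@atoms$isotope != 0)) "isotopes",
        if (any(object@atoms$radical != 0)) "radicals",
        if (object@hasAnySgroup) "S-groups"
    )
    if (length(extras)) cat(" [", paste(extras, collapse = ", "), "]", sep = "")
    cat("\n")
})

setMethod("show", "CheckReport", function(object) {
    cat("CheckReport: max penalty score ", object@maxScore, "\n", sep = "")
    if (nrow(object@issues))
        cat(sprintf("  [%d] %s\n", object@issues$score, object@issues$label),
            sep = "")
    else cat("  no issues\n")
})

setMethod("show", "StandardizationResult", function(object) {
    if (object@excludeFlag) {
        cat("StandardizationResult: EXCLUDED (passed through unchanged)\n")
    } else {
        cat("StandardizationResult: changed=", object@changed, sep = "")
        if (length(object@appliedRules))
            cat("; applied: ", paste(object@appliedRules, collapse = ", "),
                sep = "")
        cat("\n")
    }
})

setMethod("show", "ParentResult", function(object) {
    cat("ParentResult: branch=", object@branch, sep = "")
    if (nrow(object@removed))
        cat("; removed: ",
            paste(sprintf("%s(%s)", object@removed$name, object@removed$role),
                  collapse = ", "), sep = "")
    if (object@isotopesRemoved) cat("; isotopes removed")
    if (object@deduplicated) cat("; duplicates collapsed")
    cat("\n")
})

setMethod("show", "SaltSolventDictionary", function(object) {
    e <- object@entries
    cat("SaltSolventDictionary: ", sum(e$role == "salt"), " salts, ",
        sum(e$role == "solvent"), " solvents\n", sep = "")
})
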