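# Dataset-level summaries, for reproducing published per-set statistics on
# benchmark SD files (or any local compound set).

#' Summarise checker results over an SD file
#'
#' Runs [checkMolblock()] on every record and tabulates the per-record
#' maximum penalty score, distinguishing score-2 records whose only issues
#' are InChI warnings from other score-2 records, the way curation
#' statistics are usually reported.
#'
#' @param path SD file path.
#' @param limit optional cap on the number of records (NULL = all).
#' @return list with \code{n} (records), \code{counts} (named integer:
#'   "7","6","5","2 (non InChI)","2 (InChI)","No errors") and
#'   \code{pctNoErrors} (percentage of clean records).
#' @export
benchmarkChecker <- function(path, limit = NULL) {
    con <- file(path, "r")
    on.exit(close(con), add = TRUE)
    counts <- c("7" = 0L, "6" = 0L, "5" = 0L, "2 (non InChI)" = 0L,
                "2 (InChI)" = 0L, "No errors" = 0L)
    n <- 0L
    repeat {
        rec <- .nextSdfRecord(con)
        if (is.null(rec)) break
        n <- n + 1L
        sp <- .splitSdfRecord(rec)
        rep <- tryCatch(checkMolblock(sp$molblock),
                        error = function(e)
                            new("CheckReport",
                                issues = .issue(7L, "Illegal input"),
                                maxScore = 7L,
                                engineVersion = engineVersion()))
        ms <- maxScore(rep)
        bucket <- if (ms == 0L) "No errors"
            else if (ms > 2L) as.character(ms)
            else if (all(startsWith(issues(rep)$label, "InChI:")))
                "2 (InChI)"
            else "2 (non InChI)"
        counts[bucket] <- counts[bucket] + 1L
        if (!is.null(limit) && n >= limit) break
    }
    list(n = n, counts = counts,
         pctNoErrors = if (n) 100 * counts[["No errors"]] / n else NA_real_)
}

#' Summarise standardization-induced identifier changes over an SD file
#'
#' Standardizes every record and reports how many end with a different
#' Standard InChIKey than they started with (excluded and unparseable
#' records count as unchanged, since no edit is made).
#'
#' @param path SD file path.
#' @param limit optional record cap.
#' @return list with \code{n}, \code{nChanged} and \code{pctChanged}.
#' @export
benchmarkStandardizer <- function(path, limit = NULL) {
    con <- file(path, "r")
    on.exit(close(con), add = TRUE)
    n <- 0L; nChanged <- 0L
    repeat {
        rec <- .nextSdfRecord(con)
        if (is.null(rec)) break
        n <- n + 1L
        sp <- .splitSdfRecord(rec)
        res <- tryCatch(standardizeMolblock(sp$molblock),
                        error = function(e) NULL)
        if (!is.null(res) && !res@excludeFlag && isTRUE(res@changed))
            nChanged <- nChanged + 1L
        if (!is.null(limit) && n >= limit) break
    }
    list(n = n, nChanged = nChanged,
         pctChanged = if (n) 100 * nChanged / n else NA_real_)
}
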