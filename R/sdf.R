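# SD file reading/writing with data-field passthrough.

# Pull one raw SDF record (character vector of lines) off a connection;
# NULL at end of input. Records are delimited by "$$$$".
.nextSdfRecord <- function(con) {
    lines <- character()
    repeat {
        l <- readLines(con, n = 1L, warn = FALSE)
        if (!length(l)) {
            if (!length(lines) || !any(nzchar(trimws(lines)))) return(NULL)
            return(lines)
        }
        l <- .stripCR(l)
        if (identical(trimws(l), "$$$$")) return(lines)
        lines <- c(lines, l)
    }
}

.splitSdfRecord <- function(lines) {
    endIdx <- which(startsWith(lines, "M  END"))
    if (length(endIdx)) {
        mb <- paste(lines[seq_len(endIdx[1])], collapse = "\n")
        rest <- lines[-seq_len(endIdx[1])]
    } else {
        mb <- paste(lines, collapse = "\n")
        rest <- character()
    }
    fields <- character()
    i <- 1L
    while (i <= length(rest)) {
        m <- regmatches(rest[i], regexec("^>.*<(.+)>", rest[i]))[[1]]
        if (length(m) == 2) {
            tag <- m[2]
            vals <- character()
            i <- i + 1L
            while (i <= length(rest) && nzchar(trimws(rest[i]))) {
                vals <- c(vals, rest[i])
                i <- i + 1L
            }
            fields[tag] <- paste(vals, collapse = "\n")
        }
        i <- i + 1L
    }
    list(molblock = mb, fields = fields)
}

#' Read an SD file
#'
#' Each record is parsed with [parseMolblock()]; SD data fields are
#' attached to the \code{sdfFields} slot and passed through untouched by
#' the pipeline commands. Malformed records are returned as failed-parse
#' molecules rather than aborting the read.
#'
#' @param path file path (or a connection).
#' @return list of \linkS4class{Molecule} objects.
#' @export
readSDF <- function(path) {
    con <- if (inherits(path, "connection")) path else file(path, "r")
    if (!inherits(path, "connection")) on.exit(close(con), add = TRUE)
    out <- list()
    repeat {
        rec <- .nextSdfRecord(con)
        if (is.null(rec)) break
        sp <- .splitSdfRecord(rec)
        mol <- tryCatch(parseMolblock(sp$molblock),
                        error = function(e)
                            .failedMolecule(sp$molblock,
                                            conditionMessage(e)))
        mol@sdfFields <- sp$fields
        out[[length(out) + 1L]] <- mol
    }
    out
}

.formatSdfRecord <- function(molblock, fields = character()) {
    out <- molblock
    if (length(fields))
        out <- paste0(out, "\n",
                      paste(sprintf(">  <%s>\n%s\n", names(fields), fields),
                            collapse = "\n"))
    paste0(out, "\n$$$$")
}

#' Write records to an SD file
#'
#' @param molblocks character vector of molblock strings.
#' @param path output file path.
#' @param fields optional list (same length) of named character vectors of
#'   SD data fields.
#' @return invisibly, the number of records written.
#' @export
writeSDF <- function(molblocks, path, fields = NULL) {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_along(molblocks)) {
        f <- if (is.null(fields)) character() else fields[[i]]
        writeLines(.formatSdfRecord(molblocks[i], f), con)
    }
    invisible(length(molblocks))
}
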