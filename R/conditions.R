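# Typed conditions used across the package. Each user-facing failure mode has
# its own class so the CLI can map it to a stable exit code and tests can
# assert on the category rather than on message wording.

.abort <- function(class, msg, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "dicombidsError", "error", "condition"),
    list(message = msg, call = call, ...)
  )
  stop(cond)
}

.warnClass <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "dicombidsWarning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  warning(cond)
}

inputError     <- function(msg, ...) .abort("inputError", msg, ...)
archiveError   <- function(msg, ...) .abort("archiveError", msg, ...)
contractError  <- function(msg, ...) .abort("heuristicContractError", msg, ...)
planError      <- function(msg, ...) .abort("planError", msg, ...)
assemblyError  <- function(msg, ...) .abort("assemblyError", msg, ...)
collisionError <- function(msg, ...) .abort("collisionError", msg, ...)
templateError  <- function(msg, ...) .abort("templateError", msg, ...)
parseError     <- function(msg, ...) .abort("parseError", msg, ...)
validationError <- function(msg, ...) .abort("validationError", msg, ...)
idInferenceError <- function(msg, ...) .abort("idInferenceError", msg, ...)
usageError     <- function(msg, ...) .abort("usageError", msg, ...)
mergeConflictError <- function(msg, ...) .abort("mergeConflictError", msg, ...)

#' Rejection values
#'
#' Non-fatal per-file or per-series refusals (a non-DICOM file, a series name
#' that does not follow the naming grammar) are returned as rejection values
#' rather than raised, so that one bad input never aborts a whole run.
#'
#' @param what short machine-readable category.
#' @param reason human-readable explanation.
#' @param ... extra context fields stored on the object.
#' @return an object of class `"rejection"`.
#' @export
rejection <- function(what, reason, ...) {
  structure(list(what = what, reason = reason, ...), class = "rejection")
}

#' @rdname rejection
#' @param x object to test.
#' @export
isRejection <- function(x) inherits(x, "rejection")

#' @export
print.rejection <- function(x, ...) {
  cat(sprintf("<rejection:%s> %s\n", x$what, x$reason))
  invisible(x)
}
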