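# Plain-text named-vector format for survival experiments:
#   '#'-prefixed lines are comments; data lines are "name:v1,v2,..."
# where names C<i>, Ct<i>, y<i>, yt<i> come in complete quadruples per
# experiment index i (concentrations, their times, survivor counts, their
# times).

.parseNamedVectors <- function(lines) {
  entries <- list()
  lineno <- integer()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z]+[0-9]*)\\s*:(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("line %d: expected 'name: v1,v2,...', got '%s'", k, ln))
    nm <- m[2]
    if (nm %in% names(entries))
      stop(sprintf("line %d: duplicate name '%s'", k, nm))
    raw <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(raw))
    if (!length(vals) || anyNA(vals))
      stop(sprintf("line %d: unparseable number in vector '%s'", k, nm))
    entries[[nm]] <- vals
    lineno[nm] <- k
  }
  entries
}

#' Read survival experiments from the named-vector text format
#'
#' Parses a plain-text file (or a character vector of lines / a single
#' string with newlines) where each data line is a named, comma-separated
#' numeric vector (\code{C1:102.65,97.59,...}) and lines starting with
#' \code{#} are comments.  Vectors \code{C<i>}, \code{Ct<i>}, \code{y<i>},
#' \code{yt<i>} are assembled -- by numeric suffix, not file order -- into
#' one validated experiment per index.
#'
#' @param pathOrText path to a file, or the text itself.
#' @return list of \code{\linkS4class{GutsExperiment}} objects, ordered by
#'   index.
#' @export
readExperimentList <- function(pathOrText) {
  lines <- if (length(pathOrText) == 1L && !grepl("\n", pathOrText) &&
               file.exists(pathOrText)) readLines(pathOrText)
  else unlist(strsplit(pathOrText, "\n", fixed = TRUE))
  entries <- .parseNamedVectors(lines)
  sufs <- regmatches(names(entries),
                     regexec("^(C|Ct|y|yt)([0-9]+)$", names(entries)))
  idx <- sort(unique(as.integer(
    vapply(sufs[lengths(sufs) == 3], `[`, "", 3))))
  if (!length(idx)) stop("no experiments found")
  lapply(idx, function(i) {
    need <- paste0(c("C", "Ct", "y", "yt"), i)
    miss <- setdiff(need, names(entries))
    if (length(miss))
      stop(sprintf("experiment %d is incomplete: missing %s", i,
                   paste(miss, collapse = ", ")))
    gutsExperiment(entries[[need[1]]], entries[[need[2]]],
                   entries[[need[3]]], entries[[need[4]]],
                   label = paste0("experiment ", i))
  })
}

# shortest decimal representation that round-trips exactly
.fmtNum <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    s
  }, "")
}

#' Write survival experiments in the named-vector text format
#'
#' Writes the inverse of \code{\link{readExperimentList}}: all \code{C}
#' vectors, then all \code{Ct}, \code{y}, \code{yt} vectors.  Numbers are
#' rendered with enough digits for an exact round-trip.
#'
#' @param experiments non-empty list of
#'   \code{\linkS4class{GutsExperiment}} objects.
#' @param path output file path.
#' @param comment optional comment placed on the first line.
#' @return \code{path}, invisibly.
#' @export
writeExperimentList <- function(experiments, path, comment = NULL) {
  if (!length(experiments)) stop("cannot write an empty experiment list")
  slots <- list(C = "conc", Ct = "concTime", y = "y", yt = "yTime")
  lines <- unlist(lapply(names(slots), function(pre)
    vapply(seq_along(experiments), function(i)
      paste0(pre, i, ":", paste(.fmtNum(slot(experiments[[i]],
                                             slots[[pre]])),
                                collapse = ",")), "")))
  if (!is.null(comment)) lines <- c(paste("#", comment), lines)
  writeLines(lines, path)
  invisible(path)
}

#' The diazinon pulsed-exposure dataset
#'
#' Three pulsed toxicity experiments exposing the freshwater amphipod
#' \emph{Gammarus pulex} to the organophosphate insecticide diazinon, each
#' starting with 70 individuals: concentrations (nmol/l) were measured
#' around each pulse and survivors counted daily for 22 days.  The three
#' experiments differ in pulse timing and recovery intervals.
#'
#' @return list of 3 \code{\linkS4class{GutsExperiment}} objects.
#' @examples
#' exps <- loadDiazinon()
#' survivors(exps[[1]])[1]  # 70
#' @export
loadDiazinon <- function() {
  readExperimentList(system.file("extdata", "diazinon.txt",
                                 package = "gutsBayes", mustWork = TRUE))
}
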