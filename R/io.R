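# Readers and writers for the two plain-text spike-pattern dialects:
#   TSV:   pattern_id <TAB> neuron_id <TAB> time_ms [<TAB> label]
#   JSONL: {"id": "...", "events": [[neuron, time_ms], ...], "label": "..."}
# Neuron indices are 1-based in both; times in ms with up to 3 decimals.

.ioFormat <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "tsv"
}

#' Write spike patterns to a file
#'
#' Events are written in canonical order (by neuron, then time). Note that
#' the TSV dialect cannot represent a pattern with zero events; use the JSONL
#' dialect for datasets that may contain empty patterns.
#'
#' @param ds a [SpikeDataset-class].
#' @param path output file path.
#' @param format `"tsv"`, `"jsonl"`, or `"auto"` (by file extension,
#'   defaulting to TSV).
#' @return `path`, invisibly.
#' @seealso [readPatterns()]
#' @export
writePatterns <- function(ds, path, format = c("auto", "tsv", "jsonl")) {
  format <- .ioFormat(path, match.arg(format))
  hasLabels <- length(ds@labels) > 0L
  if (format == "tsv") {
    rows <- lapply(seq_along(ds@patterns), function(k) {
      ev <- patternEvents(ds@patterns[[k]])
      if (nrow(ev) == 0L) return(character())
      base <- paste(ds@ids[k], ev$neuron,
                    formatC(ev$time, format = "f", digits = 3), sep = "\t")
      if (hasLabels) paste(base, ds@labels[k], sep = "\t") else base
    })
    header <- paste(c("pattern_id", "neuron_id", "time_ms",
                      if (hasLabels) "label"), collapse = "\t")
    writeLines(c(header, unlist(rows)), path)
  } else {
    lines <- vapply(seq_along(ds@patterns), function(k) {
      ev <- patternEvents(ds@patterns[[k]])
      obj <- list(id = jsonlite::unbox(ds@ids[k]),
                  events = if (nrow(ev)) unname(cbind(ev$neuron, round(ev$time, 3)))
                           else matrix(numeric(), 0, 2))
      if (hasLabels) obj$label <- jsonlite::unbox(ds@labels[k])
      as.character(jsonlite::toJSON(obj, digits = NA))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

.validateTimes <- function(time, grid, lineNo) {
  snapped <- round(time / grid@delta) * grid@delta
  off <- abs(time - snapped) > 5e-4 + 1e-9
  if (any(off))
    stop("time(s) off the ", grid@delta, " ms grid at line(s) ",
         paste(lineNo[off], collapse = ", "))
  bad <- snapped < 0 | snapped >= grid@period
  if (any(bad))
    stop("time(s) outside [0, ", grid@period, ") ms at line(s) ",
         paste(lineNo[bad], collapse = ", "))
  snapped
}

#' Read spike patterns from a file
#'
#' Accepts the TSV dialect (header line required) or the JSONL dialect.
#' Times must lie on the grid (within the 3-decimal rounding tolerance of
#' the file format) and inside `[0, period)`; violations are reported with
#' their line numbers. A file with only a header yields an empty dataset.
#'
#' @param path input file path.
#' @param grid the [TimeGrid-class] the patterns live on.
#' @param nNeurons number of neurons; inferred as the largest neuron index
#'   present when `NULL`.
#' @param format `"tsv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @return A [SpikeDataset-class].
#' @export
readPatterns <- function(path, grid = timeGrid(), nNeurons = NULL,
                         format = c("auto", "tsv", "jsonl")) {
  format <- .ioFormat(path, match.arg(format))
  if (format == "tsv") .readTSV(path, grid, nNeurons)
  else .readJSONL(path, grid, nNeurons)
}

.readTSV <- function(path, grid, nNeurons) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file (header line required): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("pattern_id", "neuron_id", "time_ms")
  if (!all(need %in% header))
    stop("TSV header must contain: ", paste(need, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(spikeDataset(list(), ids = character()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    stop("malformed line(s) ", paste(which(nf != length(header)) + 1L, collapse = ", "),
         ": expected ", length(header), " fields")
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- header
  lineNo <- seq_along(body) + 1L
  neuron <- suppressWarnings(as.integer(tab$neuron_id))
  time <- suppressWarnings(as.numeric(tab$time_ms))
  if (anyNA(neuron) || any(neuron < 1L, na.rm = TRUE))
    stop("invalid neuron_id at line(s) ",
         paste(lineNo[is.na(neuron) | neuron < 1L], collapse = ", "))
  if (anyNA(time))
    stop("invalid time_ms at line(s) ", paste(lineNo[is.na(time)], collapse = ", "))
  time <- .validateTimes(time, grid, lineNo)
  if (is.null(nNeurons)) nNeurons <- max(neuron)
  ids <- unique(tab$pattern_id)
  byPat <- split(seq_len(nrow(tab)), factor(tab$pattern_id, levels = ids))
  pats <- lapply(byPat, function(r)
    spikePattern(neuron[r], time[r], nNeurons, grid, snap = TRUE))
  labels <- character()
  if ("label" %in% header) {
    lab <- vapply(byPat, function(r) unique(tab$label[r])[1], character(1))
    labels <- unname(lab)
  }
  spikeDataset(unname(pats), labels = labels, ids = ids)
}

.readJSONL <- function(path, grid, nNeurons) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(spikeDataset(list(), ids = character()))
  parsed <- lapply(seq_along(lines), function(k) {
    obj <- tryCatch(jsonlite::fromJSON(lines[k]),
                    error = function(e) stop("malformed JSON at line ", k, ": ",
                                             conditionMessage(e)))
    ev <- obj$events
    if (is.null(ev) || length(ev) == 0L) {
      neuron <- integer()
      time <- numeric()
    } else {
      ev <- matrix(as.numeric(ev), ncol = 2)
      neuron <- as.integer(ev[, 1])
      time <- .validateTimes(ev[, 2], grid, rep(k, nrow(ev)))
    }
    list(id = if (is.null(obj$id)) paste0("p", k) else as.character(obj$id),
         label = if (is.null(obj$label)) NA_character_ else as.character(obj$label),
         neuron = neuron, time = time)
  })
  allNeurons <- unlist(lapply(parsed, `[[`, "neuron"))
  if (is.null(nNeurons))
    nNeurons <- if (length(allNeurons)) max(allNeurons) else 1L
  pats <- lapply(parsed, function(x)
    spikePattern(x$neuron, x$time, nNeurons, grid, snap = TRUE))
  labs <- vapply(parsed, `[[`, character(1), "label")
  spikeDataset(pats, labels = if (all(is.na(labs))) character() else labs,
               ids = vapply(parsed, `[[`, character(1), "id"))
}

#' Write a model to JSON
#'
#' Serializes the learnable parameters together with the kernel, grid and
#' readout kind (and optionally the seed it was trained from), so a trained
#' model can be reloaded with [readModel()].
#'
#' @param model a [DelaySNN-class].
#' @param path output file path.
#' @param seed optional seed to record alongside the parameters.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path, seed = NULL) {
  obj <- list(kind = model@kind, weights = model@weights,
              delays = model@delays, tauBounds = model@tauBounds,
              vBias = model@vBias, bTilde = model@bTilde,
              bPlus = model@bPlus, bMinus = model@bMinus,
              kernel = list(mu = model@kernel@mu, sigma = model@kernel@sigma,
                            clampRule = model@kernel@clampRule),
              grid = list(delta = model@grid@delta, period = model@grid@period))
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path a file written by [writeModel()].
#' @return A [DelaySNN-class].
#' @export
readModel <- function(path) {
  o <- jsonlite::fromJSON(path)
  delaySNN(length(o$weights), kind = o$kind, weights = o$weights,
           delays = o$delays, tauBounds = o$tauBounds, vBias = o$vBias,
           bTilde = o$bTilde, bPlus = o$bPlus, bMinus = o$bMinus,
           kernel = kernelConfig(o$kernel$mu, o$kernel$sigma, o$kernel$clampRule),
           grid = timeGrid(o$grid$delta, o$grid$period))
}
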