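## The .tsc interchange format: per-reflection, per-atom complex scattering
## factors keyed by atom label, plus builder and merger.

#' Per-reflection scattering factor table (.tsc)
#'
#' Holds one complex scattering factor per (reflection, atom label) pair,
#' the interchange object written to and read from .tsc files.
#'
#' @slot title Free-text title.
#' @slot symm Symmetry declaration (the builder writes "expanded": factors
#'   are given for every reflection explicitly).
#' @slot labels Ordered scatterer labels.
#' @slot hkl n x 3 integer matrix of Miller indices, no duplicates.
#' @slot values n x length(labels) complex matrix.
#' @export
setClass("TscTable",
  representation(title = "character", symm = "character",
                 labels = "character", hkl = "matrix", values = "matrix"))

setValidity("TscTable", function(object) {
  msgs <- character()
  if (ncol(object@hkl) != 3) msgs <- c(msgs, "hkl must have 3 columns")
  if (nrow(object@values) != nrow(object@hkl))
    msgs <- c(msgs, "values must have one row per hkl")
  if (ncol(object@values) != length(object@labels))
    msgs <- c(msgs, "values must have one column per scatterer label")
  if (nrow(object@hkl) && anyDuplicated(apply(object@hkl, 1, paste, collapse = ",")))
    msgs <- c(msgs, "duplicate hkl rows")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TscTable-class
#' @param title,symm,labels,hkl,values Table fields.
#' @return A `TscTable`.
#' @export
tscTable <- function(labels, hkl, values, title = "SlaterSF scattering factors",
                     symm = "expanded") {
  hkl <- matrix(as.integer(hkl), ncol = 3, dimnames = list(NULL, c("h", "k", "l")))
  values <- if (is.matrix(values))
    matrix(as.complex(values), nrow(values), ncol(values))
  else matrix(as.complex(values), nrow = nrow(hkl),
              ncol = if (nrow(hkl)) length(values) / nrow(hkl) else length(labels))
  new("TscTable", title = title, symm = symm, labels = labels,
      hkl = hkl, values = values)
}

setMethod("show", "TscTable", function(object) {
  cat(sprintf("TscTable '%s': %d reflection(s) x %d scatterer(s) [%s]\n",
              object@title, nrow(object@hkl), length(object@labels),
              paste(object@labels, collapse = " ")))
  invisible(NULL)
})

#' Build a .tsc table from a crystal model
#'
#' Enumerates all reflections to the resolution limit and evaluates the
#' analytic scattering factor of each atom's species at each reflection's
#' exact s = sin(theta)/lambda (no grid interpolation). In electron mode the
#' Mott-Bethe transformed factors are used; s = 0 never occurs because the
#' 000 reflection is excluded from the sphere, so ionic species are safe.
#' Ion overrides map atom labels to net charges; a missing ionic
#' wavefunction falls back to the neutral species with a warning.
#'
#' @param model A [CrystalModel-class].
#' @param table A [WavefunctionTable-class].
#' @param dMin Resolution limit in angstroms.
#' @param radiation `"xray"` or `"electron"`.
#' @param ionOverrides Named integer vector, atom label -> charge.
#' @return A [TscTable-class].
#' @export
buildTsc <- function(model, table, dMin, radiation = c("xray", "electron"),
                     ionOverrides = integer()) {
  radiation <- match.arg(radiation)
  H <- hklSphere(model@cell, dMin)
  s <- attr(H, "s")
  labels <- vapply(model@sites, function(st) st@label, character(1))
  values <- matrix(complex(real = 0), nrow(H), length(labels))
  cache <- new.env(parent = emptyenv())
  for (j in seq_along(model@sites)) {
    st <- model@sites[[j]]
    q <- if (st@label %in% names(ionOverrides))
      as.integer(ionOverrides[[st@label]]) else st@charge
    key <- .speciesKey(st@element, q)
    f <- cache[[key]]
    if (is.null(f)) {
      wf <- lookupWavefunction(table, st@element, q)
      f <- if (radiation == "xray") xrayFormFactor(wf, s) else edFormFactor(wf, s)
      assign(key, f, envir = cache)
    }
    values[, j] <- complex(real = f, imaginary = 0)
  }
  tscTable(labels, H, values,
           title = sprintf("SlaterSF %s scattering factors, d_min = %g",
                           radiation, dMin))
}

#' Write and read the .tsc text format
#'
#' Dialect: header lines `TITLE:`, `SYMM:`, `SCATTERERS:` (space-separated
#' labels) and `DATA:`, followed by one line per reflection:
#' `h k l re,im re,im ...` with one complex pair per scatterer, printed with
#' 8 significant digits. The reader skips unknown header keys (the official
#' field set is larger), so files from other writers parse as long as the
#' scatterer list and data block are present. `readTsc(writeTsc(t))`
#' reproduces `t` bit-for-bit on the formatted values.
#'
#' @param table A [TscTable-class].
#' @param path Optional output file.
#' @return `writeTsc`: the text (invisibly when written to a file).
#' @export
writeTsc <- function(table, path = NULL) {
  fmt <- function(z) sprintf("%.8g,%.8g", Re(z), Im(z))
  header <- c(paste0("TITLE: ", table@title),
              paste0("SYMM: ", table@symm),
              paste0("SCATTERERS: ", paste(table@labels, collapse = " ")),
              "DATA:")
  body <- vapply(seq_len(nrow(table@hkl)), function(i) {
    paste(c(table@hkl[i, 1], table@hkl[i, 2], table@hkl[i, 3],
            fmt(table@values[i, ])), collapse = " ")
  }, character(1))
  txt <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' @rdname writeTsc
#' @param text .tsc content (scalar/lines) or a path ending in `.tsc`.
#' @return `readTsc`: a [TscTable-class].
#' @export
readTsc <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && grepl("\\.tsc$", text, ignore.case = TRUE))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  title <- ""; symm <- ""; labels <- character(); dataAt <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^TITLE:", ln)) title <- trimws(sub("^TITLE:", "", ln))
    else if (grepl("^SYMM:", ln)) symm <- trimws(sub("^SYMM:", "", ln))
    else if (grepl("^SCATTERERS:", ln))
      labels <- strsplit(trimws(sub("^SCATTERERS:", "", ln)), "[[:space:]]+")[[1]]
    else if (grepl("^DATA:", ln)) { dataAt <- i; break }
    else if (grepl("^[A-Z0-9_]+:", ln)) next    # unknown header key: skip
    else stop(".tsc parse error at line ", i, ": unexpected '", ln, "'")
  }
  if (is.na(dataAt)) stop(".tsc parse error: no DATA: section")
  if (!length(labels)) stop(".tsc parse error: no SCATTERERS: header")
  body <- lines[-seq_len(dataAt)]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  hkl <- matrix(0L, n, 3)
  values <- matrix(complex(real = 0), n, length(labels))
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(tok) != 3 + length(labels))
      stop(".tsc parse error at data line ", i, ": expected ",
           3 + length(labels), " fields, found ", length(tok))
    hkl[i, ] <- as.integer(tok[1:3])
    for (j in seq_along(labels)) {
      ri <- as.numeric(strsplit(tok[3 + j], ",", fixed = TRUE)[[1]])
      if (length(ri) != 2 || any(is.na(ri)))
        stop(".tsc parse error at data line ", i, ": bad complex pair '",
             tok[3 + j], "'")
      values[i, j] <- complex(real = ri[1], imaginary = ri[2])
    }
  }
  tscTable(labels, hkl, values, title = title, symm = symm)
}

#' Merge .tsc tables
#'
#' All tables must cover exactly the same reflection set (otherwise the
#' error lists the symmetric difference). Scatterer columns are
#' concatenated; when a label occurs in more than one table the later table
#' wins and a warning is emitted.
#'
#' @param tables List of [TscTable-class] objects.
#' @return The merged [TscTable-class].
#' @export
mergeTsc <- function(tables) {
  if (!length(tables)) stop("no tables to merge")
  base <- tables[[1]]
  keyOf <- function(t) apply(t@hkl, 1, paste, collapse = ",")
  baseKey <- keyOf(base)
  labels <- base@labels
  values <- base@values
  for (t in tables[-1]) {
    if (!length(t@labels)) next
    k <- keyOf(t)
    if (length(k) != length(baseKey) || !setequal(k, baseKey)) {
      diffs <- c(setdiff(baseKey, k), setdiff(k, baseKey))
      stop("hkl sets differ; symmetric difference: ",
           paste(utils::head(diffs, 10), collapse = " "),
           if (length(diffs) > 10) " ..." else "")
    }
    perm <- match(baseKey, k)
    for (j in seq_along(t@labels)) {
      lab <- t@labels[j]
      colv <- t@values[perm, j]
      at <- match(lab, labels)
      if (!is.na(at)) {
        warning("duplicate scatterer label '", lab, "': later table wins")
        values[, at] <- colv
      } else {
        labels <- c(labels, lab)
        values <- cbind(values, colv)
      }
    }
  }
  tscTable(labels, base@hkl, values, title = base@title, symm = base@symm)
}
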