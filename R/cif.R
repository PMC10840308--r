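## Minimal CIF subset reader/writer: cell, explicit symmetry operation
## strings, atom sites, optional anisotropic displacement loop. This is not
## a general CIF parser; it covers the subset needed to drive kinematic
## structure-factor calculations from deposited small-molecule files.

.cifNum <- function(x) as.numeric(sub("\\(.*\\)$", "", x))  # strip s.u. "1.234(5)"

.cifTokens <- function(line) {
  ## split on whitespace, honouring single/double quoted fields
  out <- character(); i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1)); i <- j + 1
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", substr(line, j, j))) j <- j + 1
      out <- c(out, substr(line, i, j - 1)); i <- j
    }
  }
  out
}

#' Read a minimal CIF into a crystal model
#'
#' Parses cell parameters, the symmetry loop
#' (`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`),
#' the `_atom_site_*` loop (label, type symbol, fractional coordinates,
#' occupancy, `_atom_site_U_iso_or_equiv`) and an optional
#' `_atom_site_aniso_*` loop whose U matrices override U_iso. Files lacking
#' a symmetry loop default to P1.
#'
#' @param text CIF content (scalar with newlines, or vector of lines), or a
#'   file path ending in `.cif`.
#' @return A [CrystalModel-class].
#' @export
readCifMinimal <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && grepl("\\.cif$", text, ignore.case = TRUE))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)

  scal <- list()
  loops <- list()   # each: list(tags = character, rows = list of token vectors)
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "data_")) { i <- i + 1; next }
    if (tolower(ln) == "loop_") {
      tags <- character(); i <- i + 1
      while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, tolower(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]][1]))
        i <- i + 1
      }
      rows <- list()
      while (i <= length(lines)) {
        ln2 <- trimws(lines[i])
        if (!nzchar(ln2) || startsWith(ln2, "_") || tolower(ln2) == "loop_" ||
            startsWith(ln2, "#") || startsWith(ln2, "data_")) break
        toks <- .cifTokens(ln2)
        if (length(toks) != length(tags))
          stop("CIF loop row has ", length(toks), " fields, expected ",
               length(tags), ": ", ln2)
        rows[[length(rows) + 1L]] <- toks
        i <- i + 1
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
    } else if (startsWith(ln, "_")) {
      toks <- .cifTokens(ln)
      scal[[tolower(toks[1])]] <- paste(toks[-1], collapse = " ")
      i <- i + 1
    } else i <- i + 1
  }

  need <- paste0("_cell_length_", c("a", "b", "c"))
  if (!all(need %in% names(scal))) stop("CIF is missing cell parameters")
  cell <- unitCell(.cifNum(scal[["_cell_length_a"]]),
                   .cifNum(scal[["_cell_length_b"]]),
                   .cifNum(scal[["_cell_length_c"]]),
                   if (!is.null(scal[["_cell_angle_alpha"]])) .cifNum(scal[["_cell_angle_alpha"]]) else 90,
                   if (!is.null(scal[["_cell_angle_beta"]])) .cifNum(scal[["_cell_angle_beta"]]) else 90,
                   if (!is.null(scal[["_cell_angle_gamma"]])) .cifNum(scal[["_cell_angle_gamma"]]) else 90)

  findLoop <- function(tag) {
    for (lp in loops) if (tag %in% lp$tags) return(lp)
    NULL
  }
  col <- function(lp, tag) {
    j <- match(tag, lp$tags)
    if (is.na(j)) return(NULL)
    vapply(lp$rows, `[[`, character(1), j)
  }

  symops <- list(list(R = diag(3), t = c(0, 0, 0)))
  symLoop <- findLoop("_symmetry_equiv_pos_as_xyz")
  if (is.null(symLoop)) symLoop <- findLoop("_space_group_symop_operation_xyz")
  if (!is.null(symLoop)) {
    tag <- intersect(c("_symmetry_equiv_pos_as_xyz",
                       "_space_group_symop_operation_xyz"), symLoop$tags)[1]
    symops <- lapply(col(symLoop, tag), parseSymop)
  }

  siteLoop <- findLoop("_atom_site_fract_x")
  if (is.null(siteLoop)) stop("CIF is missing the atom_site loop")
  labels <- col(siteLoop, "_atom_site_label")
  elems <- col(siteLoop, "_atom_site_type_symbol")
  if (is.null(elems)) elems <- gsub("[0-9'\"]+.*$", "", labels)
  xs <- .cifNum(col(siteLoop, "_atom_site_fract_x"))
  ys <- .cifNum(col(siteLoop, "_atom_site_fract_y"))
  zs <- .cifNum(col(siteLoop, "_atom_site_fract_z"))
  occ <- col(siteLoop, "_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, length(xs)) else .cifNum(occ)
  uiso <- col(siteLoop, "_atom_site_u_iso_or_equiv")
  uiso <- if (is.null(uiso)) rep(0, length(xs)) else .cifNum(uiso)

  aniso <- findLoop("_atom_site_aniso_label")
  uMats <- list()
  if (!is.null(aniso)) {
    alab <- col(aniso, "_atom_site_aniso_label")
    u11 <- .cifNum(col(aniso, "_atom_site_aniso_u_11"))
    u22 <- .cifNum(col(aniso, "_atom_site_aniso_u_22"))
    u33 <- .cifNum(col(aniso, "_atom_site_aniso_u_33"))
    u23 <- .cifNum(col(aniso, "_atom_site_aniso_u_23"))
    u13 <- .cifNum(col(aniso, "_atom_site_aniso_u_13"))
    u12 <- .cifNum(col(aniso, "_atom_site_aniso_u_12"))
    for (j in seq_along(alab))
      uMats[[alab[j]]] <- matrix(c(u11[j], u12[j], u13[j],
                                   u12[j], u22[j], u23[j],
                                   u13[j], u23[j], u33[j]), 3, 3)
  }

  ## charge hints from type symbols like "O1-" / "Ca2+"
  sites <- lapply(seq_along(labels), function(j) {
    el <- elems[j]; q <- 0L
    mm <- regmatches(el, regexec("^([A-Za-z]+)([0-9]*)([+-])$", el))[[1]]
    if (length(mm)) {
      el <- mm[2]
      mag <- if (nzchar(mm[3])) as.integer(mm[3]) else 1L
      q <- if (mm[4] == "-") -mag else mag
    }
    ua <- uMats[[labels[j]]]
    atomSite(labels[j], el, c(xs[j], ys[j], zs[j]), occupancy = occ[j],
             uIso = if (is.null(ua)) uiso[j] else 0, uAniso = ua, charge = q)
  })
  crystalModel(cell, sites, symops)
}

#' Write the minimal CIF subset
#'
#' Inverse of [readCifMinimal()] for round-trip testing and fixture
#' generation; coordinates are written with 6 decimals.
#'
#' @param model A [CrystalModel-class].
#' @param path Optional output file; when NULL the text is returned.
#' @return CIF text (invisibly when written to a file).
#' @export
writeCifMinimal <- function(model, path = NULL) {
  c0 <- model@cell
  out <- c("data_model",
           sprintf("_cell_length_a %.6f", c0@a),
           sprintf("_cell_length_b %.6f", c0@b),
           sprintf("_cell_length_c %.6f", c0@c),
           sprintf("_cell_angle_alpha %.6f", c0@alpha),
           sprintf("_cell_angle_beta %.6f", c0@beta),
           sprintf("_cell_angle_gamma %.6f", c0@gamma),
           "loop_", "_symmetry_equiv_pos_as_xyz",
           vapply(model@symops, function(op) sprintf("'%s'", formatSymop(op)),
                  character(1)),
           "loop_", "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "_atom_site_occupancy", "_atom_site_U_iso_or_equiv")
  for (st in model@sites) {
    el <- st@element
    if (st@charge != 0)
      el <- sprintf("%s%d%s", el, abs(st@charge), if (st@charge < 0) "-" else "+")
    out <- c(out, sprintf("%s %s %.6f %.6f %.6f %.6f %.6f", st@label, el,
                          st@xyz[1], st@xyz[2], st@xyz[3], st@occupancy,
                          if (isAnisotropic(st)) 0 else st@uIso))
  }
  anis <- Filter(isAnisotropic, model@sites)
  if (length(anis)) {
    out <- c(out, "loop_", "_atom_site_aniso_label",
             "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
             "_atom_site_aniso_U_33", "_atom_site_aniso_U_23",
             "_atom_site_aniso_U_13", "_atom_site_aniso_U_12")
    for (st in anis) {
      U <- st@uAniso
      out <- c(out, sprintf("%s %.6f %.6f %.6f %.6f %.6f %.6f", st@label,
                            U[1, 1], U[2, 2], U[3, 3], U[2, 3], U[1, 3], U[1, 2]))
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' Read a SHELX HKLF 4 reflection file
#'
#' Fixed-format lines `(3I4, 2F8.2)` holding h, k, l, Fo^2, sigma(Fo^2),
#' terminated by the all-zero record (which is dropped). Negative Fo^2 are
#' preserved; clamping happens only inside the weighting statistic.
#'
#' @param text File content (scalar/lines) or a path ending in `.hkl`.
#' @return data.frame with columns `h, k, l, Fo2, sigFo2`.
#' @export
readShelxHkl <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && grepl("\\.hkl$", text, ignore.case = TRUE))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  h <- k <- l <- integer(); Fo2 <- sig <- numeric()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (nchar(ln) < 28) ln <- formatC(ln, width = -28)
    fields <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
                substr(ln, 13, 20), substr(ln, 21, 28))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("HKLF4 parse error at line ", i, ": '", lines[i], "'")
    if (all(vals[1:3] == 0)) break   # terminator
    h <- c(h, as.integer(vals[1])); k <- c(k, as.integer(vals[2]))
    l <- c(l, as.integer(vals[3])); Fo2 <- c(Fo2, vals[4]); sig <- c(sig, vals[5])
  }
  data.frame(h = h, k = k, l = l, Fo2 = Fo2, sigFo2 = sig)
}

#' Write a SHELX HKLF 4 reflection file
#'
#' @param records data.frame with columns `h, k, l, Fo2, sigFo2`.
#' @param path Optional output file.
#' @return The text (invisibly when written).
#' @export
writeShelxHkl <- function(records, path = NULL) {
  body <- sprintf("%4d%4d%4d%8.2f%8.2f", records$h, records$k, records$l,
                  records$Fo2, records$sigFo2)
  txt <- paste0(paste(c(body, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)),
                      collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' Read a minimal XYZ file
#'
#' Standard XYZ: atom count, comment line, then `El x y z` rows (Cartesian
#' angstroms). Used by the command-line interface to supply element symbols
#' and labels when the CIF lacks them.
#'
#' @param text XYZ content or a path ending in `.xyz`.
#' @return data.frame with columns `element, x, y, z`.
#' @export
readXyz <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && grepl("\\.xyz$", text, ignore.case = TRUE))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error: first line must be the atom count")
  rows <- lines[3:(2 + n)]
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  data.frame(element = vapply(toks, `[[`, character(1), 1),
             x = as.numeric(vapply(toks, `[[`, character(1), 2)),
             y = as.numeric(vapply(toks, `[[`, character(1), 3)),
             z = as.numeric(vapply(toks, `[[`, character(1), 4)))
}
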