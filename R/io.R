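# PDB fixed-column parsing. Only ATOM records are honoured by default;
# HETATM (waters, crystallisation ions such as sulphate) are skipped unless
# whitelisted, matching common trajectory-analysis practice.

.parse_pdb_atom_lines <- function(lines, lineno, het_whitelist = character()) {
  keep <- logical(length(lines))
  is_atom <- startsWith(lines, "ATOM  ")
  is_het <- startsWith(lines, "HETATM")
  keep <- is_atom
  if (length(het_whitelist) && any(is_het)) {
    resn <- trimws(substr(lines, 18, 20))
    keep <- keep | (is_het & resn %in% het_whitelist)
  }
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) stop("no ATOM records found", call. = FALSE)

  # altloc: blank or 'A' preferred
  altloc <- substr(lines, 17, 17)
  sel <- altloc %in% c(" ", "A")
  lines <- lines[sel]; lineno <- lineno[sel]

  chain <- substr(lines, 22, 22)
  first_chain <- chain[1]
  sel <- chain == first_chain
  lines <- lines[sel]; lineno <- lineno[sel]

  xs <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad)) {
    stop("malformed coordinate field at line ", lineno[bad[1]], call. = FALSE)
  }
  resseq <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  if (anyNA(resseq)) {
    stop("malformed residue number at line ", lineno[which(is.na(resseq))[1]],
         call. = FALSE)
  }
  bcol <- suppressWarnings(as.numeric(substr(lines, 61, 66)))
  atom_name <- trimws(substr(lines, 13, 16))
  residue_name <- trimws(substr(lines, 18, 20))
  element <- trimws(substr(lines, 77, 78))
  # fall back to deriving the element from the atom name
  noel <- element == ""
  if (any(noel)) {
    guess <- sub("^[0-9]*", "", atom_name[noel])
    two <- toupper(substr(guess, 1, 2))
    one <- toupper(substr(guess, 1, 1))
    element[noel] <- ifelse(two %in% names(.bondi_radii) &
                              !(one %in% c("C", "N", "O", "H", "S", "P")),
                            two, one)
  }
  # renumber residues 1-based, preserving file order
  uid <- match(resseq, unique(resseq))

  list(atom_name = atom_name, residue_index = uid,
       residue_name = residue_name, element = element,
       coords = cbind(xs, ys, zs),
       b_column = if (all(is.na(bcol))) NULL else bcol)
}

.split_pdb_models <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    return(list(list(lines = lines, lineno = seq_along(lines))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }
  lapply(seq_along(model_starts), function(i) {
    idx <- (model_starts[i] + 1L):(model_ends[i] - 1L)
    list(lines = lines[idx], lineno = idx)
  })
}

#' Read a single-conformation structure file
#'
#' Supports PDB (ATOM records, first chain, altloc A) and plain XYZ
#' (count line, comment line, then `element x y z` rows). Van der Waals
#' radii are assigned from the Bondi element table; unknown elements are
#' an error.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @param het_whitelist HETATM residue names to keep (PDB only).
#' @return a [new_structure()] `Structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           het_whitelist = character()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (format == "pdb") {
    models <- .split_pdb_models(lines)
    if (length(models) > 1L) {
      stop("multi-model file; use read_ensemble()", call. = FALSE)
    }
    p <- .parse_pdb_atom_lines(models[[1]]$lines, models[[1]]$lineno,
                               het_whitelist)
    do.call(new_structure, p)
  } else {
    fr <- .parse_xyz_frames(lines)
    if (length(fr) > 1L) stop("multi-frame file; use read_ensemble()",
                              call. = FALSE)
    f <- fr[[1]]
    new_structure(f$coords, element = f$element,
                  atom_name = f$element,
                  residue_index = seq_len(nrow(f$coords)))
  }
}

.parse_xyz_frames <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ count at line ", i, call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed XYZ coordinates near line ", i,
                         call. = FALSE)
    frames[[length(frames) + 1L]] <- list(element = el, coords = xyz)
    i <- i + 2L + n
  }
  frames
}

#' Read a multi-conformation file as an Ensemble
#'
#' Multi-model PDB (`MODEL`/`ENDMDL`) or multi-frame XYZ. Topology is
#' taken from the first frame; all frames must have the same atom count.
#'
#' @inheritParams read_structure
#' @param align_mask optional atom-index subset passed to [new_ensemble()].
#' @return an `Ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"),
                          het_whitelist = character(), align_mask = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (format == "pdb") {
    models <- .split_pdb_models(lines)
    parsed <- lapply(models, function(m)
      .parse_pdb_atom_lines(m$lines, m$lineno, het_whitelist))
    topo <- do.call(new_structure, parsed[[1]])
    n <- n_atoms(topo)
    frames <- lapply(seq_along(parsed), function(i) {
      if (nrow(parsed[[i]]$coords) != n) {
        stop("frame ", i, " has ", nrow(parsed[[i]]$coords),
             " atoms; expected ", n, call. = FALSE)
      }
      parsed[[i]]$coords
    })
  } else {
    fr <- .parse_xyz_frames(lines)
    topo <- new_structure(fr[[1]]$coords, element = fr[[1]]$element,
                          atom_name = fr[[1]]$element)
    n <- n_atoms(topo)
    frames <- lapply(seq_along(fr), function(i) {
      if (nrow(fr[[i]]$coords) != n) {
        stop("frame ", i, " has ", nrow(fr[[i]]$coords),
             " atoms; expected ", n, call. = FALSE)
      }
      fr[[i]]$coords
    })
  }
  new_ensemble(topo, frames, align_mask = align_mask)
}

.format_pdb_atom <- function(i, s, coords, bfac) {
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, ifelse(nchar(s$atom_name[i]) < 4,
                    paste0(" ", s$atom_name[i]), s$atom_name[i]),
          s$residue_name[i], s$residue_index[i],
          coords[i, 1], coords[i, 2], coords[i, 3],
          1.0, bfac[i], s$element[i])
}

#' Write a Structure to a PDB file
#' @param s a `Structure`.
#' @param path output path.
#' @export
write_structure <- function(s, path) {
  bfac <- if (is.null(s$b_column)) rep(0, n_atoms(s)) else s$b_column
  lines <- vapply(seq_len(n_atoms(s)), .format_pdb_atom, "",
                  s = s, coords = s$coords, bfac = bfac)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an Ensemble as a multi-model PDB file
#' @param ens an `Ensemble`.
#' @param path output path.
#' @export
write_ensemble <- function(ens, path) {
  s <- ens$topology
  bfac <- rep(0, n_atoms(s))
  out <- character(0)
  for (m in seq_len(n_frames(ens))) {
    lines <- vapply(seq_len(n_atoms(s)), .format_pdb_atom, "",
                    s = s, coords = ens$frames[[m]], bfac = bfac)
    out <- c(out, sprintf("MODEL %8d", m), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a SAXS curve from 2-3 column whitespace-delimited text
#'
#' The de facto `.dat` layout: momentum transfer s (1/Angstrom),
#' intensity, and optionally a per-point error.
#'
#' @param path file path.
#' @return a [new_saxs_curve()] `SAXSCurve`.
#' @export
read_saxs_curve <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#")
  new_saxs_curve(d[[1]], d[[2]], if (ncol(d) >= 3) d[[3]] else NULL)
}

#' Write a SAXS curve as whitespace-delimited text
#' @param curve a `SAXSCurve`.
#' @param path output path.
#' @export
write_saxs_curve <- function(curve, path) {
  m <- cbind(curve$s, curve$intensity)
  if (!is.null(curve$sigma)) m <- cbind(m, curve$sigma)
  utils::write.table(format(m, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an experimental phi-value profile from TSV
#'
#' Expected columns: `residue_index`, `phi`, optional `stderr`.
#' @param path file path.
#' @return a `PhiProfile` (see [phi_calc()]).
#' @export
read_phi_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_phi_profile(residue_index = d$residue_index, phi = d$phi,
                  source = "experimental")
}

#' Write a phi-value profile as TSV
#' @param profile a `PhiProfile`.
#' @param path output path.
#' @export
write_phi_profile <- function(profile, path) {
  d <- data.frame(residue_index = profile$residue_index, phi = profile$phi)
  utils::write.table(d, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write a per-residue profile (B-factors, SASA) as TSV
#' @param residue_index residue numbers.
#' @param value per-residue values.
#' @param path output path.
#' @param value_name column header for the value.
#' @export
write_residue_profile <- function(residue_index, value, path,
                                  value_name = "value") {
  d <- data.frame(residue_index = residue_index, value = value)
  names(d)[2] <- value_name
  utils::write.table(d, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a spectra series matrix from CSV
#'
#' Layout: first column wavelengths (nm), remaining columns one per
#' temperature with the temperature (K) as header.
#' @param path file path.
#' @return a `SpectraSeries` (see [new_spectra_series()]).
#' @export
read_spectra_series <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  wl <- d[[1]]
  Y <- as.matrix(d[, -1, drop = FALSE])
  temps <- as.numeric(colnames(Y))
  new_spectra_series(wavelengths = wl, temperatures = temps, Y = unname(Y))
}

#' Write a spectra series matrix as CSV
#' @param series a `SpectraSeries`.
#' @param path output path.
#' @export
write_spectra_series <- function(series, path) {
  d <- data.frame(wavelength = series$wavelengths)
  m <- as.data.frame(series$Y)
  names(m) <- as.character(series$temperatures)
  utils::write.csv(cbind(d, m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
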