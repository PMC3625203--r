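# Structure I/O: XYZ (single and multi-frame, annotated comment lines) and a
# pragmatic PDB subset (ATOM/HETATM/CONECT).

#' Read an XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then `element x y z`
#' rows with coordinates in angstrom.  Multi-frame files are supported; by
#' default the first frame is returned.
#'
#' @param path Path to the file.
#' @param frame Frame index (1-based) for multi-frame files.
#' @return An `efmo_system` (no bonds or fragments).  The frame's comment
#'   line is attached as attribute `"comment"`.
#' @export
read_xyz <- function(path, frame = 1L) {
  frames <- read_frames(path)
  if (length(frames) == 0) stop("XYZ parse error in ", path, ": empty file (line 1)")
  if (frame < 1L || frame > length(frames)) {
    stop("frame ", frame, " requested but ", path, " has ", length(frames), " frame(s)")
  }
  frames[[frame]]
}

#' Read all frames of a (multi-frame) XYZ file
#'
#' @inheritParams read_xyz
#' @return List of `efmo_system` objects, each with attribute `"comment"`;
#'   comment lines of the form produced by [write_frames()] are also parsed
#'   into `"R"` and `"energy"` attributes.
#' @export
read_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0) stop("XYZ parse error in ", path, ": bad atom count (line ", i, ")")
    if (i + 1L + n > length(lines)) {
      stop("XYZ parse error in ", path, ": truncated frame (line ", i, ")")
    }
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + n)]
    atoms <- .parse_xyz_rows(rows, path, i + 2L)
    sys <- molecular_system(atoms)
    attr(sys, "comment") <- comment
    ann <- .parse_annotation(comment)
    attr(sys, "R") <- ann$R
    attr(sys, "energy") <- ann$energy
    frames[[length(frames) + 1L]] <- sys
    i <- i + 2L + n
  }
  frames
}

.parse_xyz_rows <- function(rows, path, first_line) {
  parts <- strsplit(trimws(rows), "[[:space:]]+")
  bad <- which(vapply(parts, length, 0L) < 4L)
  if (length(bad)) {
    stop("XYZ parse error in ", path, ": expected 'element x y z' (line ",
         first_line + bad[1] - 1L, ")")
  }
  elem <- vapply(parts, `[`, "", 1L)
  xyz <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])), numeric(3))
  bad <- which(apply(xyz, 2, anyNA))
  if (length(bad)) {
    stop("XYZ parse error in ", path, ": non-numeric coordinate (line ",
         first_line + bad[1] - 1L, ")")
  }
  data.frame(element = elem, x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
}

# Parse "R= -1.95 E= -10.0" style annotations from a comment line.
.parse_annotation <- function(comment) {
  grab <- function(key) {
    m <- regmatches(comment, regexec(paste0(key, "=\\s*([-+0-9.eE]+)"), comment))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else NA_real_
  }
  list(R = grab("R"), energy = grab("E"))
}

#' Write systems as a multi-frame annotated XYZ file
#'
#' Each frame's comment line carries its reaction coordinate and energy as
#' `R= <value> E= <value>`, which [read_frames()] parses back.
#'
#' @param frames List of `efmo_system` objects sharing one atom roster.
#' @param path Output path.
#' @param R Optional numeric vector of reaction coordinates (angstrom), one
#'   per frame.
#' @param energy Optional numeric vector of energies (hartree), one per frame.
#' @return Invisibly, `path`.
#' @export
write_frames <- function(frames, path, R = NULL, energy = NULL) {
  if (inherits(frames, "efmo_system")) frames <- list(frames)
  if (length(frames) == 0) { writeLines(character(0), path); return(invisible(path)) }
  ref <- frames[[1]]$atoms$element
  out <- character(0)
  for (k in seq_along(frames)) {
    sys <- frames[[k]]
    if (!identical(sys$atoms$element, ref)) {
      stop("frame ", k, " has a different atom roster than frame 1")
    }
    ann <- c(
      if (!is.null(R)) sprintf("R= %.10g", R[k]),
      if (!is.null(energy)) sprintf("E= %.15g", energy[k])
    )
    out <- c(out, as.character(n_atoms(sys)),
             if (length(ann)) paste(ann, collapse = " ") else sprintf("frame %d", k),
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     sys$atoms$element, sys$atoms$x, sys$atoms$y, sys$atoms$z))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (and CONECT records into bonds).  Residue
#' identity is (chain, resSeq, iCode); water residues HOH/WAT/TIP/SOL are
#' recognized like any other residue.  For altloc collisions the highest
#' occupancy wins, with a warning.  The element is taken from columns 77-78
#' when present, otherwise deduced from the atom name.
#'
#' @param path Path to the file.
#' @return An `efmo_system` with `residue_id`/`residue_name`/`chain`/`name`
#'   populated; coordinates in angstrom.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  at <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(at) == 0) stop("PDB parse error in ", path, ": no ATOM/HETATM records")
  f <- function(l, a, b) substr(l, a, b)
  lns <- lines[at]
  serial <- suppressWarnings(as.integer(f(lns, 7, 11)))
  name <- trimws(f(lns, 13, 16))
  altloc <- f(lns, 17, 17)
  resname <- trimws(f(lns, 18, 20))
  chain <- f(lns, 22, 22)
  resseq <- suppressWarnings(as.integer(f(lns, 23, 26)))
  icode <- f(lns, 27, 27)
  x <- suppressWarnings(as.numeric(f(lns, 31, 38)))
  y <- suppressWarnings(as.numeric(f(lns, 39, 46)))
  z <- suppressWarnings(as.numeric(f(lns, 47, 54)))
  occ <- suppressWarnings(as.numeric(f(lns, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- trimws(f(lns, 77, 78))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("PDB parse error in ", path, ": missing coordinates (line ", at[bad[1]], ")")
  }
  # element fallback: leading alphabetic characters of the atom name, with
  # two-letter symbols honored only when they are known elements
  miss <- !nzchar(elem)
  if (any(miss)) elem[miss] <- .element_from_name(name[miss])
  elem <- .normalize_element(elem)

  reskey <- paste(chain, resseq, icode, sep = "|")
  # altloc resolution: keep highest occupancy per (residue, atom name)
  atomkey <- paste(reskey, name, sep = "|")
  keep <- rep(TRUE, length(at))
  if (any(altloc != " ")) {
    for (k in unique(atomkey[altloc != " "])) {
      idx <- which(atomkey == k)
      if (length(idx) > 1) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
        warning("altloc collision for ", k, ": keeping highest occupancy")
      }
    }
  }
  ord <- which(keep)
  rid <- match(reskey[ord], unique(reskey[ord]))
  atoms <- data.frame(
    element = elem[ord], x = x[ord], y = y[ord], z = z[ord],
    name = name[ord], residue_id = rid, residue_name = resname[ord],
    chain = chain[ord]
  )
  sys <- molecular_system(atoms)
  # CONECT records become bonds (indices mapped through serial numbers)
  con <- lines[rec == "CONECT"]
  if (length(con)) {
    serial_kept <- serial[ord]
    pairs <- list()
    for (l in con) {
      ids <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))),
                                                  "[[:space:]]+")[[1]]))
      ids <- ids[!is.na(ids)]
      if (length(ids) >= 2) {
        a <- match(ids[1], serial_kept)
        for (b in match(ids[-1], serial_kept)) {
          if (!is.na(a) && !is.na(b)) pairs[[length(pairs) + 1L]] <- c(a, b)
        }
      }
    }
    if (length(pairs)) sys$bonds <- .normalize_bonds(do.call(rbind, pairs), n_atoms(sys))
  }
  sys
}

# PDB atom names put the element in the leading characters; digits and
# greek-position letters follow.  "CA" in a standard residue is carbon.
.element_from_name <- function(name) {
  lead <- sub("^([A-Za-z]+).*$", "\\1", sub("^[0-9]*", "", name))
  two <- .normalize_element(substr(lead, 1, 2))
  one <- .normalize_element(substr(lead, 1, 1))
  ifelse(nchar(lead) >= 2 & two %in% c("Cl", "Na", "Br") , two, one)
}

#' Write a fragment map file
#'
#' Plain-text format, one fragment per line:
#' `fragment_id atom_indices... charge=<q>` with 1-based atom indices.
#'
#' @param system A fragmented `efmo_system`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragment_map <- function(system, path) {
  if (is.null(system$fragments)) stop("system has no fragments")
  out <- vapply(system$fragments, function(f) {
    paste(f$id, paste(f$atoms, collapse = " "),
          sprintf("charge=%g", f$net_charge))
  }, "")
  writeLines(out, path)
  invisible(path)
}
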