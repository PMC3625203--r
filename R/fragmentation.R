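# Bond detection, residue-granular fragmentation with shared covalent
# boundary atoms, and the unitless interfragment distance.

#' Detect covalent bonds from interatomic distances
#'
#' A bond is added for every atom pair with
#' `r_ij <= scale * (r_cov,i + r_cov,j)` using the package's covalent radius
#' table.  Isolated atoms are allowed.
#'
#' @param system An `efmo_system`.
#' @param scale Dimensionless scale factor on the covalent-radius sum.
#' @return The system with its `bonds` matrix replaced.
#' @export
detect_bonds <- function(system, scale = 1.2) {
  n <- n_atoms(system)
  xyz <- coords(system)
  rc <- covalent_radius(system$atoms$element)
  pairs <- list()
  if (n >= 2 && scale > 0) {
    d <- as.matrix(stats::dist(xyz))
    cutoff <- outer(rc, rc, `+`) * scale
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) pairs <- list(hit)
  }
  system$bonds <- .normalize_bonds(if (length(pairs)) pairs[[1]] else NULL, n)
  system
}

# Three-letter codes of the standard amino acids (for the peptide cut rule).
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Assign residues from covalent connectivity
#'
#' For structures without residue information (plain XYZ input), each
#' connected component of the bond graph becomes one residue, numbered in
#' order of its lowest atom index.  Components with an H2O composition are
#' named `HOH`, everything else `MOL`.
#'
#' @param system An `efmo_system` with bonds detected.
#' @return The system with `residue_id`/`residue_name` replaced.
#' @export
assign_residues_by_connectivity <- function(system) {
  n <- n_atoms(system)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(system$bonds)) {
    for (k in seq_len(nrow(system$bonds))) {
      a <- find(system$bonds[k, 1]); b <- find(system$bonds[k, 2])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  rid <- match(root, unique(root))
  system$atoms$residue_id <- rid
  name <- vapply(seq_len(max(rid)), function(r) {
    els <- sort(system$atoms$element[rid == r])
    if (identical(els, c("H", "H", "O"))) "HOH" else "MOL"
  }, "")
  system$atoms$residue_name <- name[rid]
  system
}

#' Fragment a system at one residue / one water per fragment
#'
#' Produces one fragment per residue.  Covalent bonds between fragments are
#' not cut: for each inter-fragment bond the boundary atom belonging to the
#' lower-numbered fragment is shared into the partner fragment, so bonded
#' neighbors overlap in exactly one atom per junction.
#'
#' For standard amino-acid residues with PDB atom names, the fragment
#' boundary is moved to the C-alpha--C(carbonyl) bond (the usual automated
#' peptide-fragmentation convention): the backbone carbonyl C and O of
#' residue *i* join the
#' fragment of residue *i+1*, and C-alpha of residue *i* becomes the shared
#' atom.  For systems without atom names the residue boundary itself is used,
#' with the bond atom in the lower-numbered fragment shared.
#'
#' @param system An `efmo_system` with residues assigned and bonds detected.
#' @return The system with `fragments` populated (validated).
#' @export
fragment_by_residue <- function(system) {
  atoms <- system$atoms
  rid <- atoms$residue_id
  res_ids <- unique(rid)
  frag_of_res <- stats::setNames(seq_along(res_ids), res_ids)
  # atom -> fragment assignment, before boundary sharing
  assign <- unname(frag_of_res[as.character(rid)])

  # Peptide shift: carbonyl C and O of residue i move into the fragment that
  # holds the bonded amide N of the next residue.
  bonds <- system$bonds
  if (nrow(bonds) && !all(is.na(atoms$name))) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]
      if (rid[a] == rid[b]) next
      nm <- atoms$name[c(a, b)]
      rn <- atoms$residue_name[c(a, b)]
      if (!all(rn %in% .aa3)) next
      cidx <- c(a, b)[match("C", nm)]
      nidx <- c(a, b)[match("N", nm)]
      if (is.na(cidx) || is.na(nidx)) next
      target <- assign[nidx]
      assign[cidx] <- target
      # carbonyl O rides with its C
      o <- which(rid == rid[cidx] & atoms$name == "O")
      if (length(o)) assign[o] <- target
    }
  }

  # shared atoms: one per inter-fragment bond, taken from the lower fragment
  rosters <- split(seq_len(nrow(atoms)), assign)
  shared_rows <- list()
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]
      fa <- assign[a]; fb <- assign[b]
      if (fa == fb) next
      lo <- min(fa, fb); hi <- max(fa, fb)
      s <- if (assign[a] == lo) a else b
      shared_rows[[length(shared_rows) + 1L]] <-
        data.frame(atom = s, lo = lo, hi = hi)
    }
  }
  shared <- if (length(shared_rows)) unique(do.call(rbind, shared_rows)) else NULL
  if (!is.null(shared)) {
    dup <- duplicated(shared$atom) | duplicated(shared$atom, fromLast = TRUE)
    if (any(dup)) {
      multi <- shared[dup, ]
      if (any(table(multi$atom) > 1)) {
        stop("atom ", paste(unique(multi$atom[table(multi$atom)[as.character(multi$atom)] > 1]),
                            collapse = ", "),
             " would be shared into more than two fragments")
      }
    }
  }

  fragments <- vector("list", length(rosters))
  for (i in seq_along(rosters)) {
    fid <- as.integer(names(rosters)[i])
    roster <- rosters[[i]]
    sh <- NULL
    if (!is.null(shared)) {
      out_rows <- shared[shared$lo == fid, , drop = FALSE]   # owned, shared out
      in_rows <- shared[shared$hi == fid, , drop = FALSE]    # shared in
      roster <- sort(unique(c(roster, in_rows$atom)))
      sh <- data.frame(
        atom = c(out_rows$atom, in_rows$atom),
        partner = c(out_rows$hi, in_rows$lo),
        owner = c(out_rows$lo, in_rows$lo)
      )
    }
    res_of_frag <- as.integer(names(frag_of_res))[match(fid, frag_of_res)]
    fragments[[fid]] <- new_fragment(
      id = fid, atoms = roster, shared = sh,
      net_charge = .residue_charge(system, res_of_frag)
    )
  }
  system$fragments <- fragments
  validate_fragments(system)
  system
}

#' Unitless interfragment distance
#'
#' The minimum over atom pairs (one atom in each fragment, atoms shared
#' between the two fragments excluded) of the interatomic distance divided by
#' the sum of the two atoms' van der Waals radii.  Symmetric, translation-
#' and rotation-invariant, and dimensionless; a value of 1 means the closest
#' contact sits exactly at the van der Waals touching distance.
#'
#' @param system A fragmented `efmo_system`.
#' @param i,j Fragment ids.
#' @return A non-negative number.
#' @export
interfragment_distance <- function(system, i, j) {
  if (i == j) stop("interfragment distance requires two distinct fragments")
  fi <- system$fragments[[i]]; fj <- system$fragments[[j]]
  common <- intersect(fi$atoms, fj$atoms)
  ai <- setdiff(fi$atoms, common)
  aj <- setdiff(fj$atoms, common)
  if (length(ai) == 0 || length(aj) == 0) {
    stop("fragment pair (", i, ", ", j, ") has a side consisting only of shared atoms")
  }
  xyz <- coords(system)
  rv <- vdw_radius(system$atoms$element)
  di <- xyz[ai, , drop = FALSE]
  dj <- xyz[aj, , drop = FALSE]
  d2 <- outer(rowSums(di^2), rowSums(dj^2), `+`) - 2 * di %*% t(dj)
  d2[d2 < 0] <- 0
  ratio <- sqrt(d2) / outer(rv[ai], rv[aj], `+`)
  min(ratio)
}
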