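# Molecular data model: atoms, bonds, fragments.
#
# A molecular system is a plain list with class "efmo_system":
#   atoms     data.frame: element, x, y, z (angstrom), name (atom name, may be
#             NA), residue_id (integer), residue_name, chain, frozen (logical)
#   bonds     two-column integer matrix of atom indices (i < j), unordered
#   fragments list of "efmo_fragment" or NULL until fragmentation
#   residue_charges  named numeric: net charge (e) per residue_id, default 0
#
# Atom indices are 1-based throughout, matching both R and the chemistry
# convention for user-facing reports.
#
# A fragment is a list with class "efmo_fragment":
#   id           integer
#   atoms        integer vector: full roster (owned atoms plus atoms shared
#                in from covalently bonded neighbor fragments)
#   shared       data.frame(atom, partner, owner): boundary atoms that appear
#                in this fragment and in fragment `partner`; `owner` is the
#                fragment id that owns the atom for charge bookkeeping
#   net_charge   numeric (e)
#   layer        character level tag for multilayer runs ("high"/"low"/NA)

#' Construct a molecular system
#'
#' @param atoms Data frame with at least columns `element`, `x`, `y`, `z`
#'   (coordinates in angstrom).  Optional columns: `name` (atom name),
#'   `residue_id`, `residue_name`, `chain`, `frozen`.
#' @param bonds Two-column integer matrix of bonded atom pairs, or `NULL`.
#' @param residue_charges Named numeric vector of per-residue net charges (e),
#'   names are residue ids.  Residues not listed carry charge 0.
#' @return An object of class `efmo_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, residue_charges = NULL) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  atoms$element <- .normalize_element(as.character(atoms$element))
  unknown <- setdiff(unique(atoms$element), .known_elements)
  if (length(unknown) || anyNA(atoms$element)) {
    stop("unknown element symbol(s): ",
         paste(unique(c(unknown, if (anyNA(atoms$element)) "<blank>")), collapse = ", "))
  }
  for (col in c("x", "y", "z")) {
    atoms[[col]] <- as.numeric(atoms[[col]])
    if (any(!is.finite(atoms[[col]]))) stop("non-finite coordinate in column ", col)
  }
  if (is.null(atoms$name)) atoms$name <- NA_character_
  if (is.null(atoms$residue_id)) atoms$residue_id <- 1L
  if (is.null(atoms$residue_name)) atoms$residue_name <- "UNK"
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$frozen)) atoms$frozen <- FALSE
  rownames(atoms) <- NULL
  sys <- structure(
    list(atoms = atoms, bonds = .normalize_bonds(bonds, n), fragments = NULL,
         residue_charges = .normalize_residue_charges(residue_charges)),
    class = "efmo_system"
  )
  sys
}

.normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || length(bonds) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1L) || any(bonds > n_atoms)) stop("bond references atom outside the system")
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("i", "j"))
  bonds
}

.normalize_residue_charges <- function(rc) {
  if (is.null(rc)) return(numeric(0))
  stopifnot(is.numeric(rc), !is.null(names(rc)))
  rc
}

#' Number of atoms in a system
#' @param system An `efmo_system`.
#' @return Integer.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Get or set coordinates of a system
#'
#' @param system An `efmo_system`.
#' @return `coords()`: an `n x 3` numeric matrix (angstrom).
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value An `n x 3` matrix of new coordinates (angstrom).
#' @export
`coords<-` <- function(system, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == n_atoms(system), ncol(value) == 3)
  system$atoms$x <- value[, 1]
  system$atoms$y <- value[, 2]
  system$atoms$z <- value[, 3]
  system
}

# Net charge of a residue (0 unless set).
.residue_charge <- function(system, residue_id) {
  rc <- system$residue_charges
  key <- as.character(residue_id)
  out <- rc[key]
  out[is.na(out)] <- 0
  unname(out)
}

#' Per-atom partial charges of the mock electrostatic model
#'
#' Element charges (O -0.8, H +0.4, N -0.4, C 0.0 e, others 0) shifted
#' uniformly within each residue so that every residue carries its assigned
#' net charge.  These charges are a property of atoms and residues only, so
#' monomer, dimer and supermolecule calculations see identical values.
#'
#' @param system An `efmo_system`.
#' @return Numeric vector of charges (e), one per atom.
#' @export
atom_charges <- function(system) {
  elem_q <- c(O = -0.8, H = 0.4, N = -0.4, C = 0.0)
  q <- elem_q[system$atoms$element]
  q[is.na(q)] <- 0
  rid <- system$atoms$residue_id
  for (r in unique(rid)) {
    sel <- rid == r
    q[sel] <- q[sel] + (.residue_charge(system, r) - sum(q[sel])) / sum(sel)
  }
  unname(q)
}

# --- fragments -------------------------------------------------------------

new_fragment <- function(id, atoms, shared = NULL, net_charge = 0, layer = NA_character_) {
  if (length(atoms) == 0) stop("fragment ", id, " has no atoms")
  if (is.null(shared)) {
    shared <- data.frame(atom = integer(0), partner = integer(0), owner = integer(0))
  }
  structure(
    list(id = as.integer(id), atoms = as.integer(atoms), shared = shared,
         net_charge = net_charge, layer = layer),
    class = "efmo_fragment"
  )
}

# Atoms owned by a fragment: roster minus shared atoms owned by a partner.
owned_atoms <- function(fragment) {
  foreign <- fragment$shared$atom[fragment$shared$owner != fragment$id]
  setdiff(fragment$atoms, foreign)
}

#' @export
print.efmo_fragment <- function(x, ...) {
  cat(sprintf("<fragment %d: %d atoms (%d shared), charge %+g e%s>\n",
              x$id, length(x$atoms), nrow(x$shared), x$net_charge,
              if (!is.na(x$layer)) paste0(", layer ", x$layer) else ""))
  invisible(x)
}

#' @export
print.efmo_system <- function(x, ...) {
  cat(sprintf("Molecular system: %d atoms, %d bonds", n_atoms(x), nrow(x$bonds)))
  if (!is.null(x$fragments)) {
    ns <- sum(vapply(x$fragments, function(f) sum(f$shared$owner == f$id), 0L))
    cat(sprintf(", %d fragments (%d shared atoms)", length(x$fragments), ns))
  }
  cat("\n")
  counts <- table(x$atoms$element)
  cat("  composition:", paste(names(counts), counts, sep = "", collapse = " "), "\n")
  invisible(x)
}

# Check fragment bookkeeping: partition up to shared atoms, no atom in more
# than two fragments, charges consistent.  Called by fragmentation routines.
validate_fragments <- function(system) {
  frs <- system$fragments
  if (is.null(frs)) return(invisible(system))
  membership <- integer(n_atoms(system))
  total_roster <- 0L
  n_shared_pairs <- 0L
  for (f in frs) {
    membership[f$atoms] <- membership[f$atoms] + 1L
    total_roster <- total_roster + length(f$atoms)
    n_shared_pairs <- n_shared_pairs + sum(f$shared$owner == f$id)
  }
  if (any(membership == 0L)) stop("atom(s) not assigned to any fragment")
  if (any(membership > 2L)) stop("atom(s) assigned to more than two fragments")
  if (total_roster - n_shared_pairs != n_atoms(system)) {
    stop("fragment rosters do not partition the system up to shared atoms")
  }
  invisible(system)
}
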