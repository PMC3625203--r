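# Partition of a fragmented system into active (A), buffer (b) and frozen
# (F) regions for frozen-domain calculations.  Only A-region atoms move; a
# boundary atom shared between two fragments is mobile only when both owners
# are active.

#' Assign active, buffer and frozen regions around target fragments
#'
#' The active region A holds every fragment whose minimum atom--atom
#' distance to any target-fragment atom is at most `R_active` (targets
#' included); the buffer b holds the remaining fragments within `R_buffer`
#' of any active atom; everything else is frozen (F).  All atoms enter the
#' distance predicate (no heavy-atom filtering).  Buffer and frozen atoms
#' are flagged frozen; active atoms are mobile except shared boundary atoms
#' co-owned with a buffer or frozen fragment.
#'
#' @param system A fragmented `efmo_system`.
#' @param target Fragment id(s) the radii are measured from.
#' @param R_active Active-region radius, angstrom.
#' @param R_buffer Buffer radius around the active region, angstrom.
#' @return An object of class `efmo_regions`: `active`, `buffer`, `frozen`
#'   (fragment id vectors), `target`, `frozen_atoms` (logical per atom) and
#'   `mobile_atoms` (integer vector).
#' @export
assign_regions <- function(system, target, R_active = 2.0, R_buffer = 2.5) {
  stopifnot(R_active > 0, R_buffer > 0)
  frs <- system$fragments
  if (is.null(frs)) stop("system has no fragments")
  ids <- vapply(frs, `[[`, 0L, "id")
  if (!all(target %in% ids)) {
    stop("target fragment(s) not found: ", paste(setdiff(target, ids), collapse = ", "))
  }
  xyz <- coords(system)
  min_dist_to <- function(set_atoms, frag_atoms) {
    a <- xyz[set_atoms, , drop = FALSE]
    b <- xyz[frag_atoms, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    sqrt(max(0, min(d2)))
  }
  target_atoms <- unique(unlist(lapply(frs[match(target, ids)], `[[`, "atoms")))
  active <- ids[vapply(frs, function(f) {
    f$id %in% target || min_dist_to(target_atoms, f$atoms) <= R_active
  }, TRUE)]
  active_atoms <- unique(unlist(lapply(frs[match(active, ids)], `[[`, "atoms")))
  rest <- setdiff(ids, active)
  buffer <- rest[vapply(frs[match(rest, ids)], function(f) {
    min_dist_to(active_atoms, f$atoms) <= R_buffer
  }, TRUE)]
  frozen <- setdiff(rest, buffer)
  region_assignment(system, active, buffer, frozen, target)
}

#' Construct a region assignment explicitly
#'
#' Lower-level constructor used by [assign_regions()] and for pinning
#' regions across a scan; `active`, `buffer` and `frozen` must partition the
#' fragment ids.
#'
#' @inheritParams assign_regions
#' @param active,buffer,frozen Fragment id vectors.
#' @export
region_assignment <- function(system, active, buffer, frozen, target = integer(0)) {
  frs <- system$fragments
  ids <- vapply(frs, `[[`, 0L, "id")
  all3 <- c(active, buffer, frozen)
  if (length(all3) != length(ids) || !setequal(all3, ids) || anyDuplicated(all3)) {
    stop("active, buffer and frozen must partition the fragment set")
  }
  frozen_atoms <- rep(TRUE, n_atoms(system))
  for (id in active) frozen_atoms[frs[[match(id, ids)]]$atoms] <- FALSE
  # shared boundary atoms: mobile only when both owners are active
  for (f in frs) {
    non_active_owner <- !(f$id %in% active)
    if (non_active_owner) {
      frozen_atoms[f$atoms] <- TRUE
    }
  }
  # the loop above freezes atoms shared into A from b/F owners as a side
  # effect of freezing every atom in a non-active fragment's roster; active
  # fragments' unshared atoms stay mobile because no non-active roster
  # contains them
  structure(list(active = sort(active), buffer = sort(buffer),
                 frozen = sort(frozen), target = target,
                 frozen_atoms = frozen_atoms,
                 mobile_atoms = which(!frozen_atoms)),
            class = "efmo_regions")
}

#' @export
print.efmo_regions <- function(x, ...) {
  cat("Region assignment (A / b / F):\n")
  cat(sprintf("  active: %d fragment(s)  buffer: %d  frozen: %d\n",
              length(x$active), length(x$buffer), length(x$frozen)))
  cat(sprintf("  mobile atoms: %d of %d\n",
              length(x$mobile_atoms), length(x$frozen_atoms)))
  invisible(x)
}

#' Per-region atom counts of an assignment
#'
#' Counts owned atoms per region, which are disjoint and exhaustive.
#'
#' @param system A fragmented `efmo_system`.
#' @param regions An `efmo_regions`.
#' @return Named integer vector with entries `active`, `buffer`, `frozen`.
#' @export
region_atom_counts <- function(system, regions) {
  frs <- system$fragments
  ids <- vapply(frs, `[[`, 0L, "id")
  cnt <- function(set) {
    sum(vapply(frs[match(set, ids)], function(f) length(owned_atoms(f)), 0L))
  }
  c(active = cnt(regions$active), buffer = cnt(regions$buffer),
    frozen = cnt(regions$frozen))
}

#' Region report as a plain list (for JSON serialization)
#'
#' @inheritParams region_atom_counts
#' @return List with per-fragment region tags, per-region atom counts and
#'   the frozen-flag map; accepted back by [region_assignment()] to pin
#'   regions across a scan.
#' @export
region_report <- function(system, regions) {
  ids <- vapply(system$fragments, `[[`, 0L, "id")
  tag <- ifelse(ids %in% regions$active, "A",
                ifelse(ids %in% regions$buffer, "b", "F"))
  list(fragment_region = stats::setNames(tag, ids),
       atom_counts = as.list(region_atom_counts(system, regions)),
       frozen_atoms = which(regions$frozen_atoms),
       target = regions$target)
}
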