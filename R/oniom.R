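# Subtractive two-layer ONIOM refinement of reaction-path energies:
# E = E_low(total) + E_high(model) - E_low(model), with the model region a
# capped fragment set computed in the gas phase (no environment multipoles).

#' Subtractive two-layer ONIOM combination
#'
#' @param E_low_total Low-level energy of the full system (hartree).
#' @param E_high_model High-level energy of the model region (hartree).
#' @param E_low_model Low-level energy of the model region (hartree).
#' @return `E_low_total + E_high_model - E_low_model`.
#' @export
oniom_combine <- function(E_low_total, E_high_model, E_low_model) {
  E_low_total + E_high_model - E_low_model
}

#' Specify an ONIOM model region and its two levels
#'
#' @param model_fragments Fragment id(s) forming the high-level model
#'   region (the reacting substrate, typically).
#' @param high,low [level_spec()] objects for the two layers.
#' @return An object of class `efmo_oniom_spec`.
#' @export
oniom_spec <- function(model_fragments, high, low = level_spec()) {
  stopifnot(inherits(high, "efmo_level"), inherits(low, "efmo_level"))
  structure(list(model_fragments = as.integer(model_fragments),
                 high = high, low = low),
            class = "efmo_oniom_spec")
}

# gas-phase model energy: capped union roster of the model fragments,
# evaluated directly by the backend (no environment moments are passed)
.model_energy <- function(system, model_fragments, level, session) {
  frs <- system$fragments
  ids <- vapply(frs, `[[`, 0L, "id")
  if (!all(model_fragments %in% ids)) stop("model fragment(s) not in system")
  roster <- sort(unique(unlist(lapply(frs[match(model_fragments, ids)],
                                      `[[`, "atoms"))))
  .eval_roster(system, roster, level, session, "monomer",
               model_fragments, gradient = FALSE)$energy
}

#' Refine reaction-path energies with subtractive ONIOM
#'
#' For each frame, the path energy is replaced by
#' `E_frame + E_high(model) - E_low(model)` where the model region is the
#' capped union of `spec$model_fragments` in the gas phase.  Frame
#' geometries, order and count are untouched; the original energies are
#' kept in `E_unrefined`.
#'
#' @param path An `efmo_reaction_path` (frames should be converged).
#' @param spec An [oniom_spec()].
#' @param session Calculation session.
#' @return The refined `efmo_reaction_path` with extra fields
#'   `E_unrefined`, `E_high_model`, `E_low_model`.
#' @export
refine_path <- function(path, spec, session = new_session()) {
  n <- length(path$frames)
  Eh <- numeric(n); El <- numeric(n)
  for (k in seq_len(n)) {
    sys <- path$frames[[k]]$system
    Eh[k] <- .model_energy(sys, spec$model_fragments, spec$high, session)
    El[k] <- .model_energy(sys, spec$model_fragments, spec$low, session)
  }
  refined <- path
  refined$E_unrefined <- path$E
  refined$E_high_model <- Eh
  refined$E_low_model <- El
  refined$E <- oniom_combine(path$E, Eh, El)
  for (k in seq_len(n)) refined$frames[[k]]$E <- refined$E[k]
  refined
}
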