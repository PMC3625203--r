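# The fragment-energy backend contract.
#
# A backend supplies, for any (capped) atom roster: energy, gradient,
# atom-centered multipoles and distributed polarizabilities.  The package
# ships the deterministic analytic "mock" backend (see R/mock.R); an adapter
# for a real electronic-structure engine only needs to register the same
# four callbacks.  Units at the contract boundary are hartree and
# hartree/bohr, non-negotiable.

.backend_registry <- new.env(parent = emptyenv())

#' Register a fragment-energy backend
#'
#' A backend is a list of four callbacks:
#' \describe{
#'   \item{`eval(elements, xyz_bohr, bonds, charges, level, gradient)`}{
#'     returns `list(energy, gradient)` for a capped roster (gradient over
#'     the roster including caps, hartree/bohr).}
#'   \item{`multipole_values(elements, charges, level)`}{per-site charge,
#'     dipole and traceless quadrupole values (positions are supplied by the
#'     caller at evaluation time).}
#'   \item{`polarizability_values(elements, level)`}{per-site 3x3
#'     polarizability tensors (bohr^3).}
#'   \item{`describe()`}{one-line description.}
#' }
#'
#' @param name Registry name (the `method` field of [level_spec()]).
#' @param backend The callback list.
#' @return Invisibly, `name`.
#' @export
register_backend <- function(name, backend) {
  stopifnot(is.character(name), is.list(backend), is.function(backend$eval))
  assign(name, backend, envir = .backend_registry)
  invisible(name)
}

get_backend <- function(method) {
  if (!exists(method, envir = .backend_registry, inherits = FALSE)) {
    stop("no backend registered under method '", method, "'")
  }
  get(method, envir = .backend_registry, inherits = FALSE)
}

#' Specify a calculation level
#'
#' @param method Backend registry name (`"mock"` or `"mock-pol"` are built
#'   in; `"mock-pol"` is the mock potential with nonzero site
#'   polarizabilities).
#' @param basis Free-form basis label, passed through to reports.
#' @param role Layer tag (`"high"`, `"low"` or `NA`) for multilayer runs.
#' @param params Named list of backend-specific parameter overrides (for the
#'   mock backend: any constant of [mock_model_definition()], plus `shift`, a
#'   constant added to every energy).
#' @return An object of class `efmo_level`.
#' @export
level_spec <- function(method = "mock", basis = "mock", role = NA_character_,
                       params = list()) {
  get_backend(method)  # fail early on unregistered methods
  structure(list(method = method, basis = basis, role = role, params = params),
            class = "efmo_level")
}

#' @export
print.efmo_level <- function(x, ...) {
  cat(sprintf("<level %s/%s%s>\n", x$method, x$basis,
              if (!is.na(x$role)) paste0(" (", x$role, ")") else ""))
  invisible(x)
}

# key fragment of a level for caching
.level_key <- function(level) {
  paste(level$method, level$basis,
        paste(names(level$params), vapply(level$params, function(p)
          paste(format(p, digits = 17), collapse = ","), ""), collapse = ";"))
}

# --- session: caching and call accounting ----------------------------------

#' Create a calculation session
#'
#' A session caches monomer/dimer results (keyed by roster, coordinates and
#' level, so moving any involved atom invalidates the entry) and fragment
#' multipole/polarizability *values* (keyed by fragment id and level,
#' invalidated only by [reset_session()] -- site positions always track the
#' current geometry).  It also counts backend calls, which is how the
#' frozen-domain code proves that frozen-region fragments never trigger new
#' QM work.
#'
#' @return An environment of class `efmo_session`.
#' @export
new_session <- function() {
  s <- new.env(parent = emptyenv())
  s$cache <- new.env(parent = emptyenv())
  s$moment_cache <- new.env(parent = emptyenv())
  s$counts <- c(monomer = 0L, dimer = 0L, moments = 0L)
  s$log <- list()
  class(s) <- "efmo_session"
  s
}

#' @rdname new_session
#' @param session An `efmo_session`.
#' @export
reset_session <- function(session) {
  session$cache <- new.env(parent = emptyenv())
  session$moment_cache <- new.env(parent = emptyenv())
  session$counts <- c(monomer = 0L, dimer = 0L, moments = 0L)
  session$log <- list()
  invisible(session)
}

#' @rdname new_session
#' @return `session_counts()`: named integer vector of backend call counts
#'   (cache hits are not counted).
#' @export
session_counts <- function(session) session$counts

#' @rdname new_session
#' @return `session_log()`: data frame with one row per backend call
#'   (`kind`, `fragments`).
#' @export
session_log <- function(session) {
  if (length(session$log) == 0) {
    return(data.frame(kind = character(0), fragments = character(0)))
  }
  do.call(rbind, lapply(session$log, function(e)
    data.frame(kind = e$kind, fragments = paste(e$ids, collapse = "+"))))
}

.log_call <- function(session, kind, ids) {
  session$counts[kind] <- session$counts[kind] + 1L
  session$log[[length(session$log) + 1L]] <- list(kind = kind, ids = ids)
}

# --- capping ---------------------------------------------------------------

#' Cap the severed bonds of an atom roster with link hydrogens
#'
#' For every covalent bond with one end inside the roster and one end
#' outside, a hydrogen cap is placed on the bond axis at distance `d_cap`
#' from the inside atom.  This link-atom construction stands in for detached
#' bonds so a fragment can be evaluated in isolation; cap positions are
#' functions of the two bond-end positions, and gradients on caps are
#' chain-ruled back onto those atoms.
#'
#' @param system An `efmo_system` with bonds.
#' @param atoms Integer vector: the roster (e.g. a fragment's atom list).
#' @param d_cap Cap bond length, angstrom.
#' @return List with `atoms` (the roster), `caps` (data frame: `anchor`
#'   inside atom, `partner` outside atom, `x`,`y`,`z` cap position in
#'   angstrom) and `d_cap`.
#' @export
cap_fragment <- function(system, atoms, d_cap = 1.09) {
  atoms <- as.integer(atoms)
  bonds <- system$bonds
  caps <- data.frame(anchor = integer(0), partner = integer(0),
                     x = numeric(0), y = numeric(0), z = numeric(0))
  if (nrow(bonds)) {
    inside <- matrix(bonds %in% atoms, ncol = 2)
    sev <- which(xor(inside[, 1], inside[, 2]))
    xyz <- coords(system)
    for (k in sev) {
      a <- if (inside[k, 1]) bonds[k, 1] else bonds[k, 2]
      b <- if (inside[k, 1]) bonds[k, 2] else bonds[k, 1]
      u <- xyz[b, ] - xyz[a, ]
      r <- sqrt(sum(u^2))
      if (r == 0) stop("cannot cap zero-length bond ", a, "-", b)
      p <- xyz[a, ] + d_cap * u / r
      caps <- rbind(caps, data.frame(anchor = a, partner = b,
                                     x = p[1], y = p[2], z = p[3]))
    }
  }
  list(atoms = atoms, caps = caps, d_cap = d_cap)
}

# --- roster evaluation (shared by monomer and dimer) -----------------------

# Evaluate the backend on a capped roster; returns energy plus a gradient
# over `atoms` = c(roster, cap partners), in system indices, with cap
# gradients chain-ruled onto anchor and partner atoms.
.eval_roster <- function(system, roster, level, session, kind, ids,
                         gradient = TRUE) {
  capped <- cap_fragment(system, roster)
  xyz <- coords(system)
  key <- paste(kind, paste(ids, collapse = "+"), .level_key(level),
               paste(sprintf("%.17g", t(xyz[roster, , drop = FALSE])), collapse = ","),
               paste(sprintf("%.17g", t(as.matrix(capped$caps[, c("x", "y", "z")]))),
                     collapse = ","),
               gradient, sep = "|")
  hit <- session$cache[[key]]
  if (!is.null(hit)) return(hit)

  nc <- nrow(capped$caps)
  ros_xyz <- rbind(xyz[roster, , drop = FALSE],
                   as.matrix(capped$caps[, c("x", "y", "z")]))
  elements <- c(system$atoms$element[roster], rep("H", nc))
  q <- c(atom_charges(system)[roster], rep(0, nc))
  # local bonds: system bonds inside the roster, plus anchor-cap bonds
  loc <- match(system$bonds, roster)
  loc <- matrix(loc, ncol = 2)
  keep <- !is.na(loc[, 1]) & !is.na(loc[, 2])
  local_bonds <- loc[keep, , drop = FALSE]
  if (nc) {
    local_bonds <- rbind(local_bonds,
                         cbind(match(capped$caps$anchor, roster),
                               length(roster) + seq_len(nc)))
  }
  backend <- get_backend(level$method)
  res <- backend$eval(elements, ros_xyz * efmo_units$angstrom_to_bohr,
                      local_bonds, q, level, gradient)
  .log_call(session, kind, ids)

  out_atoms <- roster
  grad <- NULL
  if (gradient) {
    grad <- res$gradient[seq_along(roster), , drop = FALSE]
    if (nc) {
      partners <- unique(capped$caps$partner)
      out_atoms <- c(roster, partners)
      grad <- rbind(grad, matrix(0, length(partners), 3))
      for (k in seq_len(nc)) {
        gc <- res$gradient[length(roster) + k, ]
        a <- capped$caps$anchor[k]; b <- capped$caps$partner[k]
        u <- (xyz[b, ] - xyz[a, ])
        r <- sqrt(sum(u^2))
        u <- u / r
        d <- capped$d_cap * efmo_units$angstrom_to_bohr  # not used: ratio below
        # cap = a + d_cap * (b - a)/|b - a|; the Jacobian only involves the
        # dimensionless ratio d_cap/|b - a|, so angstrom lengths are fine
        ratio <- capped$d_cap / r
        perp <- gc - u * sum(u * gc)
        ia <- match(a, out_atoms); ib <- match(b, out_atoms)
        grad[ia, ] <- grad[ia, ] + gc - ratio * perp
        grad[ib, ] <- grad[ib, ] + ratio * perp
      }
    }
  }
  out <- list(energy = res$energy, atoms = out_atoms, gradient = grad,
              roster = roster, n_caps = nc)
  session$cache[[key]] <- out
  out
}

#' Monomer energy and gradient of a fragment
#'
#' The gas-phase backend energy of one (capped) fragment, with the gradient
#' mapped back onto system atoms: cap-atom gradients are chain-ruled onto
#' the cap's anchor and its outside bond partner.
#'
#' @param system A fragmented `efmo_system`.
#' @param i Fragment id.
#' @param level An [level_spec()].
#' @param session An [new_session()] (one is created if omitted).
#' @param gradient Compute the gradient?
#' @return List with `energy` (hartree), `atoms` (system indices carrying
#'   gradient contributions), `gradient` (hartree/bohr rows matching
#'   `atoms`), `roster`, `n_caps`.
#' @export
compute_monomer <- function(system, i, level = level_spec(),
                            session = new_session(), gradient = TRUE) {
  fr <- system$fragments[[i]]
  if (is.null(fr)) stop("no fragment with id ", i)
  .eval_roster(system, fr$atoms, level, session, "monomer", i, gradient)
}

#' Dimer energy and gradient of a fragment pair
#'
#' The backend energy of the deduplicated union roster of two fragments
#' (shared boundary atoms enter once); caps are placed only on bonds severed
#' at the union's outside boundary.
#'
#' @inheritParams compute_monomer
#' @param j Second fragment id (`i != j`).
#' @export
compute_dimer <- function(system, i, j, level = level_spec(),
                          session = new_session(), gradient = TRUE) {
  if (i == j) stop("dimer requires two distinct fragments")
  fi <- system$fragments[[i]]; fj <- system$fragments[[j]]
  roster <- sort(unique(c(fi$atoms, fj$atoms)))
  .eval_roster(system, roster, level, session, "dimer", sort(c(i, j)), gradient)
}

# --- fragment moments ------------------------------------------------------

#' Distributed multipoles and polarizabilities of a fragment
#'
#' Sites sit on the fragment's *owned* atoms (a shared boundary atom
#' contributes its charge through its owning fragment only, so no charge is
#' double counted in classical sums).  Multipole and polarizability *values*
#' are cached per fragment and level in the session; site positions always
#' follow the current geometry.
#'
#' @inheritParams compute_monomer
#' @return `fragment_multipoles()`: an `efmo_multipoles` set;
#'   `fragment_polarizabilities()`: an `efmo_polarizabilities` set.
#' @export
fragment_multipoles <- function(system, i, level = level_spec(),
                                session = new_session()) {
  fr <- system$fragments[[i]]
  own <- owned_atoms(fr)
  key <- paste("M", i, .level_key(level), sep = "|")
  vals <- session$moment_cache[[key]]
  if (is.null(vals)) {
    backend <- get_backend(level$method)
    vals <- backend$multipole_values(system$atoms$element[own],
                                     atom_charges(system)[own], level)
    .log_call(session, "moments", i)
    session$moment_cache[[key]] <- vals
  }
  multipole_set(coords(system)[own, , drop = FALSE] * efmo_units$angstrom_to_bohr,
                q = vals$q, mu = vals$mu, theta = vals$theta, atoms = own)
}

#' @rdname fragment_multipoles
#' @export
fragment_polarizabilities <- function(system, i, level = level_spec(),
                                      session = new_session()) {
  fr <- system$fragments[[i]]
  own <- owned_atoms(fr)
  key <- paste("P", i, .level_key(level), sep = "|")
  vals <- session$moment_cache[[key]]
  if (is.null(vals)) {
    backend <- get_backend(level$method)
    vals <- backend$polarizability_values(system$atoms$element[own], level)
    session$moment_cache[[key]] <- vals
  }
  polarizability_set(coords(system)[own, , drop = FALSE] * efmo_units$angstrom_to_bohr,
                     alpha = vals$alpha, atoms = own)
}

# --- built-in backends -----------------------------------------------------

.mock_backend <- function(polarizable) {
  force(polarizable)
  list(
    eval = function(elements, xyz, bonds, charges, level, gradient) {
      mock_eval(elements, xyz, bonds, charges, level$params, gradient)
    },
    multipole_values = function(elements, charges, level) {
      n <- length(elements)
      list(q = charges, mu = matrix(0, n, 3),
           theta = replicate(n, matrix(0, 3, 3), simplify = FALSE))
    },
    polarizability_values = function(elements, level) {
      mm <- utils::modifyList(mock_model_definition(), level$params)
      pol <- polarizable || isTRUE(level$params$polarizable)
      alpha <- lapply(elements, function(el) {
        a <- if (pol) mm$polarizability[[el]] else 0
        if (is.null(a) || is.na(a)) a <- 0
        diag(3) * a
      })
      list(alpha = alpha)
    },
    describe = function() "deterministic analytic mock potential"
  )
}

# registered at definition time so level_spec("mock") works immediately
register_backend("mock", .mock_backend(polarizable = FALSE))
register_backend("mock-pol", .mock_backend(polarizable = TRUE))
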