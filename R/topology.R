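# Structure-based (Go-like) coarse-grained topology.  The internal energy
# U_MD is a surrogate built from a reference conformation: bonds, angles and
# dihedrals restrained at their reference values, native contacts between
# non-neighbour pairs within a cutoff, and a soft excluded-volume repulsion
# for all remaining pairs.  The reference conformation is therefore a
# stationary point (gradient zero) of its own topology.

#' Default force-field parameters for the coarse-grained topology
#'
#' @return Named list: \code{bond_k} (kcal/mol/A^2), \code{angle_k}
#'   (kcal/mol/rad^2), \code{dihedral_k} (kcal/mol), \code{contact_cutoff}
#'   (A), \code{contact_eps} (kcal/mol), \code{ev_sigma}, \code{ev_cutoff}
#'   (A), \code{ev_eps} (kcal/mol).
#' @export
topology_params <- function() {
  # Stiffnesses are chosen so that internal forces dominate the per-bead
  # curvature of the map potential (zeta * w / s^2, ~60 kcal/mol/A^2 at
  # full coupling): thermal bead fluctuations are then governed by the
  # force field rather than by the current map, as they are for an
  # all-atom model, which keeps the energies of neighbouring blur rungs
  # comparable during resolution exchange.
  list(bond_k = 100, angle_k = 40, dihedral_k = 2,
       contact_cutoff = 8, contact_eps = 5,
       ev_sigma = 4, ev_eps = 1, ev_cutoff = 6)
}

#' Build a structure-based topology from a reference conformation
#'
#' Bonds connect consecutive beads within each chain at their reference
#' lengths; angles and dihedrals take their reference values (dihedrals use
#' the smooth Go-model cosine form).  Native contacts are added between
#' pairs separated by at least 3 positions along the chain (or in different
#' chains) whose reference distance is below \code{contact_cutoff}; all
#' remaining non-bonded pairs are given a soft excluded-volume repulsion.
#' The construction is deterministic.
#'
#' @param reference a \code{\link{cg_structure}}; each chain needs at least
#'   3 beads.
#' @param params parameter list as from \code{\link{topology_params}}.
#' @return An object of class \code{cg_topology}.
#' @export
build_topology <- function(reference, params = topology_params()) {
  stopifnot(inherits(reference, "cg_structure"))
  p <- utils::modifyList(topology_params(), params)
  b <- reference$beads
  xyz <- bead_coords(reference)
  n <- nrow(b)
  chains <- split(seq_len(n), b$chain)
  if (any(lengths(chains) < 3))
    stop("every chain needs at least 3 beads to build a topology")

  bonds <- angles <- dihedrals <- NULL
  for (idx in chains) {
    idx <- idx[order(b$resid[idx])]
    m <- length(idx)
    i1 <- idx[-m]; i2 <- idx[-1]
    r0 <- sqrt(rowSums((xyz[i1, , drop = FALSE] - xyz[i2, , drop = FALSE])^2))
    bonds <- rbind(bonds, cbind(i1, i2, r0, p$bond_k))
    if (m >= 3) {
      ia <- idx[1:(m - 2)]; ib <- idx[2:(m - 1)]; ic <- idx[3:m]
      th0 <- vapply(seq_along(ia), function(t) {
        angle_value(xyz[ia[t], ], xyz[ib[t], ], xyz[ic[t], ])
      }, numeric(1))
      angles <- rbind(angles, cbind(ia, ib, ic, th0, p$angle_k))
    }
    if (m >= 4) {
      ia <- idx[1:(m - 3)]; ib <- idx[2:(m - 2)]
      ic <- idx[3:(m - 1)]; id <- idx[4:m]
      ph0 <- vapply(seq_along(ia), function(t) {
        dihedral_value(xyz[ia[t], ], xyz[ib[t], ], xyz[ic[t], ], xyz[id[t], ])
      }, numeric(1))
      dihedrals <- rbind(dihedrals, cbind(ia, ib, ic, id, ph0, p$dihedral_k))
    }
  }
  if (any(bonds[, 3] <= 0)) stop("coincident consecutive beads: zero bond length")
  if (is.null(angles)) angles <- matrix(numeric(0), ncol = 5)
  if (is.null(dihedrals)) dihedrals <- matrix(numeric(0), ncol = 6)

  # chain separation matrix: Inf across chains
  pos_in_chain <- integer(n)
  chain_of <- integer(n)
  for (ci in seq_along(chains)) {
    idx <- chains[[ci]][order(b$resid[chains[[ci]]])]
    pos_in_chain[idx] <- seq_along(idx)
    chain_of[idx] <- ci
  }
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  sep <- ifelse(chain_of[pairs[, 1]] == chain_of[pairs[, 2]],
                abs(pos_in_chain[pairs[, 1]] - pos_in_chain[pairs[, 2]]), Inf)
  d <- dm[pairs]
  is_contact <- sep >= 3 & d < p$contact_cutoff
  contacts <- if (any(is_contact)) {
    cbind(pairs[is_contact, 1], pairs[is_contact, 2], d[is_contact],
          p$contact_eps)
  } else matrix(numeric(0), ncol = 4)
  is_excl <- sep >= 3 & !is_contact
  ev_pairs <- if (any(is_excl)) {
    cbind(pairs[is_excl, 1], pairs[is_excl, 2])
  } else matrix(integer(0), ncol = 2)

  topo <- structure(list(
    bonds = unname(bonds), angles = unname(angles),
    dihedrals = unname(dihedrals),
    contacts = matrix(contacts, ncol = 4),
    ev_pairs = matrix(as.integer(ev_pairs), ncol = 2),
    ev_sigma = p$ev_sigma, ev_eps = p$ev_eps, ev_cutoff = p$ev_cutoff,
    n_beads = n), class = "cg_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  n <- topo$n_beads
  refs <- c(topo$bonds[, 1:2], topo$angles[, 1:3], topo$dihedrals[, 1:4],
            topo$contacts[, 1:2], topo$ev_pairs)
  if (length(refs) && (min(refs) < 1 || max(refs) > n))
    stop("topology references a bead outside the structure")
  key <- paste(pmin(topo$bonds[, 1], topo$bonds[, 2]),
               pmax(topo$bonds[, 1], topo$bonds[, 2]))
  if (anyDuplicated(key)) stop("duplicated bond in topology")
  if (nrow(topo$contacts) && any(topo$contacts[, 3] <= 0))
    stop("non-positive contact equilibrium distance")
  invisible(topo)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(paste0("<cg_topology> %d beads: %d bonds, %d angles, ",
                     "%d dihedrals, %d contacts, %d excluded pairs\n"),
              x$n_beads, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$contacts), nrow(x$ev_pairs)))
  invisible(x)
}

angle_value <- function(a, b, c) {
  u <- a - b; w <- c - b
  cosv <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  acos(pmin(pmax(cosv, -1), 1))
}

dihedral_value <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m <- cross3(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Empty restraint set
#' @return A \code{restraint_set} with no terms.
#' @export
empty_restraints <- function() {
  structure(list(dihedrals = matrix(numeric(0), ncol = 6),
                 distances = matrix(numeric(0), ncol = 4)),
            class = "restraint_set")
}

#' Secondary-structure segments of a structure
#'
#' Contiguous runs of identically labelled helix or strand beads within a
#' chain, as a data frame of (chain, from, to) residue ranges.  Convenience
#' input for \code{\link{assign_ss_restraints}}.
#'
#' @param structure a \code{\link{cg_structure}}.
#' @return Data frame with columns \code{chain}, \code{from}, \code{to}.
#' @export
ss_segments <- function(structure) {
  b <- structure$beads
  out <- NULL
  for (ch in unique(b$chain)) {
    sub <- b[b$chain == ch, ]
    sub <- sub[order(sub$resid), ]
    r <- rle(sub$ss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (r$values[i] %in% c("helix", "strand") && r$lengths[i] >= 4) {
        out <- rbind(out, data.frame(chain = ch,
                                     from = sub$resid[starts[i]],
                                     to = sub$resid[ends[i]]))
      }
    }
  }
  if (is.null(out)) data.frame(chain = character(0), from = integer(0),
                               to = integer(0)) else out
}

#' Harmonic secondary-structure restraints
#'
#' For every contiguous helix/strand segment, harmonic restraints are placed
#' on all in-segment pseudo-dihedrals (consecutive bead quadruples) and 1-4
#' bead distances at their current values, preventing the map forces from
#' warping the secondary structure.  A segment of m beads contributes m - 3
#' dihedral and m - 3 distance restraints.
#'
#' @param structure a \code{\link{cg_structure}}.
#' @param segments data frame (chain, from, to) of disjoint residue ranges;
#'   defaults to \code{\link{ss_segments}(structure)}.
#' @param k force constant (kcal/mol/rad^2 for dihedrals, kcal/mol/A^2 for
#'   distances).
#' @return A \code{restraint_set}.
#' @export
assign_ss_restraints <- function(structure, segments = ss_segments(structure),
                                 k = 2) {
  stopifnot(inherits(structure, "cg_structure"))
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0) return(empty_restraints())
  # overlap check within chains
  for (ch in unique(segments$chain)) {
    s <- segments[segments$chain == ch, ]
    s <- s[order(s$from), ]
    if (nrow(s) > 1 && any(s$from[-1] <= s$to[-nrow(s)]))
      stop("overlapping secondary-structure segments")
  }
  b <- structure$beads
  xyz <- bead_coords(structure)
  rd <- NULL; rb <- NULL
  for (si in seq_len(nrow(segments))) {
    idx <- which(b$chain == segments$chain[si] &
                 b$resid >= segments$from[si] & b$resid <= segments$to[si])
    idx <- idx[order(b$resid[idx])]
    m <- length(idx)
    if (m < 4) next
    for (t in 1:(m - 3)) {
      q <- idx[t:(t + 3)]
      ph0 <- dihedral_value(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
      rd <- rbind(rd, c(q, ph0, k))
      r0 <- sqrt(sum((xyz[q[1], ] - xyz[q[4], ])^2))
      rb <- rbind(rb, c(q[1], q[4], r0, k))
    }
  }
  if (is.null(rd)) return(empty_restraints())
  out <- list(dihedrals = unname(rd), distances = unname(rb))
  class(out) <- "restraint_set"
  out
}
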