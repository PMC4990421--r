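#' Coarse-grained structure
#'
#' One bead per residue, carrying position, mass, map-coupling weight and a
#' secondary-structure label.  Constructed from a bead table with columns
#' \code{id}, \code{resid}, \code{chain}, \code{x}, \code{y}, \code{z},
#' \code{mass}, \code{weight}, \code{ss}.
#'
#' @param beads data frame of beads as described above.  \code{weight}
#'   defaults to \code{mass} (the usual atom-mass coupling weight) and
#'   \code{ss} to \code{"coil"}.
#' @return An object of class \code{cg_structure}.
#' @export
cg_structure <- function(beads) {
  beads <- as.data.frame(beads)
  req <- c("id", "resid", "chain", "x", "y", "z")
  if (!all(req %in% names(beads)))
    stop("bead table must have columns: ", paste(req, collapse = ", "))
  if (!"mass" %in% names(beads)) beads$mass <- 110
  if (!"weight" %in% names(beads)) beads$weight <- beads$mass
  if (!"ss" %in% names(beads)) beads$ss <- "coil"
  if (anyDuplicated(beads$id)) stop("bead ids must be unique")
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("bead positions must be finite")
  if (any(beads$mass <= 0) || any(beads$weight <= 0))
    stop("bead masses and weights must be > 0")
  if (!all(beads$ss %in% c("helix", "strand", "coil")))
    stop("ss labels must be 'helix', 'strand' or 'coil'")
  rownames(beads) <- NULL
  structure(list(beads = beads), class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  b <- x$beads
  cat(sprintf("<cg_structure> %d beads, %d chain(s), extent %.1f A\n",
              nrow(b), length(unique(b$chain)),
              max(dist_range(bead_coords(x)))))
  invisible(x)
}

dist_range <- function(xyz) apply(xyz, 2, function(v) diff(range(v)))

#' Bead coordinates as an N x 3 matrix
#' @param structure a \code{\link{cg_structure}}.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
bead_coords <- function(structure) {
  as.matrix(structure$beads[, c("x", "y", "z")])
}

#' Replace bead coordinates
#' @param structure a \code{\link{cg_structure}}.
#' @param xyz N x 3 numeric matrix.
#' @return The updated structure.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$beads), ncol(xyz) == 3,
            all(is.finite(xyz)))
  structure$beads[, c("x", "y", "z")] <- xyz
  structure
}

#' Read a structure from PDB
#'
#' All-atom files are reduced to one bead per residue at the C-alpha
#' position.  Residue numbering, chain ids and the B-factor column are
#' preserved.
#'
#' @param path path to a PDB file.
#' @param mass bead mass in amu (default 110, an average residue mass).
#' @return A \code{\link{cg_structure}}; per-bead B-factors, when present,
#'   are attached as attribute \code{"bfactor"}.
#' @export
read_structure <- function(path, mass = 110) {
  if (!file.exists(path)) stop("structure file does not exist: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("not a readable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no recognized atom records (no C-alpha atoms) in ", path)
  key <- paste(ca$chain, ca$resno)
  if (anyDuplicated(key))
    stop("duplicate residue index within a chain in ", path)
  if (any(!is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)))
    stop("missing coordinates in ", path)
  out <- cg_structure(data.frame(
    id = seq_len(nrow(ca)), resid = ca$resno,
    chain = ifelse(is.na(ca$chain), "A", ca$chain),
    x = ca$x, y = ca$y, z = ca$z, mass = mass, weight = mass,
    ss = "coil", stringsAsFactors = FALSE))
  attr(out, "bfactor") <- ca$b
  out
}

#' Write a structure to PDB
#'
#' Beads are written as C-alpha ATOM records; the \code{bfactor} argument
#' fills the B-factor column (clipped to the 999.99 column maximum with a
#' warning).
#'
#' @param structure a \code{\link{cg_structure}}.
#' @param path output path.
#' @param bfactor optional per-bead numeric vector for the B column.
#' @export
write_structure <- function(structure, path, bfactor = NULL) {
  stopifnot(inherits(structure, "cg_structure"))
  b <- structure$beads
  if (is.null(bfactor)) bfactor <- rep(0, nrow(b))
  stopifnot(length(bfactor) == nrow(b))
  if (any(bfactor > 999.99)) {
    warning("B-factors above 999.99 clipped to the PDB column limit")
    bfactor <- pmin(bfactor, 999.99)
  }
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    b$id %% 100000, substr(b$chain, 1, 1), b$resid %% 10000,
    b$x, b$y, b$z, 1.0, pmax(bfactor, 0))
  writeLines(c(lines, "END"), path)
  invisible(NULL)
}

# append one model of a multi-model trajectory PDB
write_model <- function(structure, path, model, append = TRUE) {
  b <- structure$beads
  lines <- c(sprintf("MODEL     %4d", model),
             sprintf("ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     b$id %% 100000, substr(b$chain, 1, 1), b$resid %% 10000,
                     b$x, b$y, b$z, 1.0, 0),
             "ENDMDL")
  cat(paste0(lines, "\n"), file = path, sep = "", append = append)
}

#' Root-mean-square deviation between two structures
#'
#' By default no superposition is applied: fitted and target structures
#' share the fixed frame of the map, so the raw coordinate deviation is the
#' relevant measure.  With \code{superpose = TRUE} the deviation is
#' minimised over rigid transforms first (Kabsch algorithm).
#'
#' @param a,b \code{\link{cg_structure}} objects (or N x 3 matrices) with
#'   matching bead counts and ordering.
#' @param superpose logical; superpose before measuring (default
#'   \code{FALSE}).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  A <- if (inherits(a, "cg_structure")) bead_coords(a) else as.matrix(a)
  B <- if (inherits(b, "cg_structure")) bead_coords(b) else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("bead counts differ between the two structures")
  if (superpose) A <- kabsch_superpose(A, B)
  sqrt(mean(rowSums((A - B)^2)))
}

# rigid-body superposition of A onto B (returns transformed A)
kabsch_superpose <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(t(A0) %*% B0)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A0 %*% t(R), 2, cb, "+")
}
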