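# United-residue representation: one residue = its alpha carbon plus a single
# side-chain characteristic point, the unweighted centroid of all side-chain
# heavy atoms. The five-parameter geometry of an aligned residue pair (two
# distances, two planar angles, one dihedral) lives here.

#' Convert a residue to its united-residue representation
#'
#' The side-chain characteristic point `sc` is the unweighted mean of all
#' heavy atoms outside the backbone set `{N, CA, C, O, OXT}`. Glycine, or any
#' residue without such atoms, gets `sc == ca` and `has_distinct_sc = FALSE`.
#'
#' @param res a `pdb_residue` (see [structure_residues()]).
#' @return an object of class `ur_residue`: list with `ca`, `sc` (numeric
#'   length-3, Angstrom), `has_distinct_sc`, and `res_name`.
#' @export
to_united_residue <- function(res) {
  stopifnot(inherits(res, "pdb_residue"))
  ca <- .atom_coord(res, "CA")
  if (is.null(ca)) {
    stop("residue ", res$chain_id, res$seq_num, res$icode, " (", res$res_name,
         ") has no CA atom; cannot build united-residue representation",
         call. = FALSE)
  }
  has_sc <- .residue_has_sc(res)
  if (has_sc) {
    side <- res$atoms[!(res$atoms$atom %in% .BACKBONE_ATOMS), c("x", "y", "z"), drop = FALSE]
    sc <- colMeans(side)
    names(sc) <- NULL
  } else {
    sc <- ca
  }
  structure(list(ca = ca, sc = sc, has_distinct_sc = has_sc,
                 res_name = res$res_name),
            class = "ur_residue")
}

#' Five-parameter geometry of an aligned united-residue pair
#'
#' Maps the model residue into the native frame with `transform`, then
#' computes: the alpha-carbon distance `d`; the side-chain displacement
#' vector `rvec = native$sc - model$sc` (model-to-native convention), its
#' magnitude `r`; the planar angles `theta1` (model virtual bond vs `rvec`)
#' and `theta2` (native virtual bond vs `rvec`), both as arccos of the
#' clamped normalized dot product; and `phi`, the counterclockwise dihedral
#' of the native bond about the displacement direction relative to the model
#' bond, mapped to `[0, 2*pi)`.
#'
#' Degenerate geometry -- coincident side-chain points (`r < eps`), a missing
#' distinct side chain on either residue, or a vanishing virtual bond --
#' yields `angles_defined = FALSE` and zero angles: coincident side chains
#' are perfect agreement, so the zeros award full credit downstream. When the
#' bonds are collinear with the displacement (both sines vanish) the torsion
#' degenerates to the inter-bond angle and `phi` is 0 for parallel bonds,
#' `pi` for antiparallel.
#'
#' @param model,native `ur_residue` objects.
#' @param transform a [rigid_transform()] mapping model coordinates into the
#'   native frame.
#' @param eps degeneracy threshold in Angstrom.
#' @return an object of class `ur_pair_geometry`: list with `d`, `r`
#'   (Angstrom), `theta1`, `theta2` (radians in `[0, pi]`), `phi` (radians in
#'   `[0, 2*pi)`), and `angles_defined`.
#' @export
pair_geometry <- function(model, native, transform, eps = 1e-6) {
  stopifnot(inherits(model, "ur_residue"), inherits(native, "ur_residue"))
  .check_rigid_transform(transform)

  m_ca <- drop(apply_transform(transform, matrix(model$ca, 1L)))
  m_sc <- drop(apply_transform(transform, matrix(model$sc, 1L)))

  d <- vnorm(m_ca - native$ca)
  rvec <- native$sc - m_sc
  r <- vnorm(rvec)
  u1 <- m_sc - m_ca
  u2 <- native$sc - native$ca

  degenerate <- !model$has_distinct_sc || !native$has_distinct_sc ||
    r < eps || vnorm(u1) < eps || vnorm(u2) < eps
  if (degenerate) {
    return(structure(list(d = d, r = r, theta1 = 0, theta2 = 0, phi = 0,
                          angles_defined = FALSE),
                     class = "ur_pair_geometry"))
  }

  rhat <- rvec / r
  u1 <- unit(u1)
  u2 <- unit(u2)
  theta1 <- acos(clamp_cos(sum(u1 * rhat)))
  theta2 <- acos(clamp_cos(sum(u2 * rhat)))

  if (sin(theta1) * sin(theta2) < 1e-9) {
    # bonds collinear with the displacement: torsion plane undefined
    phi <- if (sum(u1 * u2) >= 0) 0 else pi
  } else {
    a <- u1 - sum(u1 * rhat) * rhat
    b <- u2 - sum(u2 * rhat) * rhat
    y <- sum(cross3(a, b) * rhat)
    x <- sum(a * b)
    if (abs(y) < 1e-9) {
      # coplanar geometry: snap to 0/pi so floating noise of sign -eps does
      # not wrap a perfect-agreement pair to ~2*pi (the worst bin)
      phi <- if (x >= 0) 0 else pi
    } else {
      phi <- atan2(y, x) %% (2 * pi)
    }
  }

  structure(list(d = d, r = r, theta1 = theta1, theta2 = theta2, phi = phi,
                 angles_defined = TRUE),
            class = "ur_pair_geometry")
}

#' @export
print.ur_pair_geometry <- function(x, ...) {
  cat(sprintf("<ur_pair_geometry> d = %.3f A, r = %.3f A", x$d, x$r))
  if (x$angles_defined) {
    cat(sprintf(", theta1 = %.1f, theta2 = %.1f, phi = %.1f (deg)\n",
                rad2deg(x$theta1), rad2deg(x$theta2), rad2deg(x$phi)))
  } else {
    cat(" (angles undefined: degenerate side-chain geometry)\n")
  }
  invisible(x)
}
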