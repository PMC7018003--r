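# Deterministic synthetic model/native pairs. Backbones are idealized, not
# stereochemically refined: the scoring pipeline consumes only heavy-atom
# coordinates, so consecutive alpha carbons at 3.8 A on a smooth trace plus
# plausible local geometry are enough to exercise every code path. Side
# chains are built from small per-type templates with a randomized chi1
# rotamer, giving 1-4 side-chain heavy atoms per residue.

.SC_PALETTE <- c("ALA", "SER", "CYS", "VAL", "THR", "LEU", "ILE", "ASP", "ASN")

#' Specification of a synthetic structure pair
#'
#' @param n_residues chain length, >= 3.
#' @param fold `"helix"` (idealized alpha-helical spiral) or `"extended"`
#'   (zigzag strand); both have consecutive alpha-carbon spacing 3.8 A.
#' @param ca_noise_sigma per-residue Gaussian displacement (A) applied
#'   rigidly to the whole residue in [make_decoy()]; 0 keeps alpha-carbon
#'   traces exactly coincident.
#' @param sc_rotation_deg rotation (degrees) of each residue's side-chain
#'   atoms about its CA-CB axis, i.e. a chi1-rotamer perturbation; glycine
#'   and alanine centroids are unaffected (no atoms beyond CB).
#' @param sc_displacement rigid displacement (A) of each side chain along a
#'   random direction.
#' @param domain_split optional `list(index =, displacement =)`: residues at
#'   or after `index` are rigidly displaced by `displacement` A, producing a
#'   two-domain decoy.
#' @param glycine_fraction fraction of residues built as glycine
#'   (`round(fraction * n)` of them, at seeded random positions).
#' @param seed integer seed; identical specs produce byte-identical output.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues, fold = c("helix", "extended"),
                         ca_noise_sigma = 0, sc_rotation_deg = 0,
                         sc_displacement = 0, domain_split = NULL,
                         glycine_fraction = 0.1, seed = 1L) {
  fold <- match.arg(fold)
  stopifnot(n_residues >= 3, ca_noise_sigma >= 0, sc_displacement >= 0,
            glycine_fraction >= 0, glycine_fraction < 1)
  if (!is.null(domain_split))
    stopifnot(is.list(domain_split), domain_split$index >= 1,
              domain_split$displacement >= 0)
  structure(list(n_residues = as.integer(n_residues), fold = fold,
                 ca_noise_sigma = ca_noise_sigma,
                 sc_rotation_deg = sc_rotation_deg,
                 sc_displacement = sc_displacement,
                 domain_split = domain_split,
                 glycine_fraction = glycine_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# alpha-carbon trace with consecutive spacing 3.8 A
.ca_trace <- function(n, fold) {
  if (fold == "helix") {
    rise <- 1.5
    step <- deg2rad(100)
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(step / 2))
    i <- seq_len(n) - 1L
    cbind(radius * cos(i * step), radius * sin(i * step), rise * i)
  } else {
    i <- seq_len(n) - 1L
    dy <- sqrt(3.8^2 - 3.6^2) / 2
    cbind(3.6 * i, dy * (-1)^i, 0)
  }
}

# side-chain template in the local frame (x toward CB, gamma direction in
# the xy plane at chi1 = 0), rotated about x by the chi1 rotamer
.sidechain_template <- function(resname, chi1_rad) {
  cb <- c(1.53, 0, 0)
  g0 <- c(cos(deg2rad(70.5)), sin(deg2rad(70.5)), 0)
  rx <- function(a) rotation_about_axis(c(1, 0, 0), a)
  branch <- function(g, v, len, psi_deg) {
    w <- cross3(v, c(1, 0, 0))
    if (vnorm(w) < 1e-6) w <- c(0, 0, 1) else w <- unit(w)
    vw <- cross3(v, w)
    lapply(deg2rad(psi_deg), function(psi) {
      g + len * unit(0.45 * v + 0.89 * (cos(psi) * w + sin(psi) * vw))
    })
  }
  at <- function(names, coords) stats::setNames(coords, names)
  tpl <- switch(resname,
    ALA = at("CB", list(cb)),
    SER = at(c("CB", "OG"), list(cb, cb + 1.42 * g0)),
    CYS = at(c("CB", "SG"), list(cb, cb + 1.81 * g0)),
    VAL = at(c("CB", "CG1", "CG2"),
             list(cb, cb + 1.52 * g0, cb + 1.52 * drop(rx(deg2rad(120)) %*% g0))),
    THR = at(c("CB", "OG1", "CG2"),
             list(cb, cb + 1.42 * g0, cb + 1.52 * drop(rx(deg2rad(-120)) %*% g0))),
    LEU = {
      cg <- cb + 1.52 * g0
      at(c("CB", "CG", "CD1", "CD2"), c(list(cb, cg), branch(cg, g0, 1.52, c(60, 180))))
    },
    ILE = {
      cg1 <- cb + 1.52 * g0
      at(c("CB", "CG1", "CG2", "CD1"),
         c(list(cb, cg1, cb + 1.52 * drop(rx(deg2rad(120)) %*% g0)),
           branch(cg1, g0, 1.52, 120)))
    },
    ASP = {
      cg <- cb + 1.52 * g0
      at(c("CB", "CG", "OD1", "OD2"), c(list(cb, cg), branch(cg, g0, 1.25, c(90, 270))))
    },
    ASN = {
      cg <- cb + 1.52 * g0
      at(c("CB", "CG", "OD1", "ND2"), c(list(cb, cg), branch(cg, g0, 1.25, c(90, 270))))
    },
    stop("no side-chain template for ", resname))
  R <- rx(chi1_rad)
  lapply(tpl, function(p) drop(R %*% p))
}

#' Generate a deterministic synthetic native structure
#'
#' Residues sit on an idealized trace (consecutive CA-CA distance 3.8 A) with
#' backbone atoms N/CA/C/O placed in a per-residue local frame and side
#' chains drawn from a small template palette with randomized chi1 rotamers.
#' Fully seeded: the same spec always yields byte-identical output, and the
#' seed is recorded in a REMARK line by [write_pdb()].
#'
#' @param spec a [fixture_spec()].
#' @return a `pdb_structure`.
#' @export
make_native <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  with_seed(spec$seed, {
    ca <- .ca_trace(n, spec$fold)
    n_gly <- round(spec$glycine_fraction * n)
    gly_pos <- if (n_gly > 0) sample(n, n_gly) else integer(0)
    resnames <- sample(.SC_PALETTE, n, replace = TRUE)
    resnames[gly_pos] <- "GLY"

    # backbone template in the local frame (CA at origin, x toward CB)
    n_local <- 1.46 * c(cos(deg2rad(110.5)), 0, sin(deg2rad(110.5)))
    c_local <- 1.52 * unit(c(-0.35, -0.82, -0.45))
    o_local <- c_local + 1.23 * unit(c(-0.2, -0.9, 0.4))

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      tang <- unit(ca[min(i + 1L, n), ] - ca[max(i - 1L, 1L), ])
      perp <- cross3(tang, c(0, 0, 1))
      if (vnorm(perp) < 1e-6) perp <- cross3(tang, c(1, 0, 0))
      perp <- unit(perp)
      bin <- cross3(tang, perp)
      # side-chain direction: mostly away from the trace, with seeded tilt
      e1 <- unit(bin + 0.2 * stats::rnorm(3))
      aux <- tang - sum(tang * e1) * e1
      e2 <- unit(aux)
      e3 <- cross3(e1, e2)
      M <- cbind(e1, e2, e3)
      place <- function(p) ca[i, ] + drop(M %*% p)

      chi1 <- deg2rad(sample(c(-60, 60, 180), 1L) + stats::rnorm(1L, 0, 10))
      coords <- list(N = place(n_local), CA = ca[i, ], C = place(c_local),
                     O = place(o_local))
      if (resnames[i] != "GLY") {
        side <- .sidechain_template(resnames[i], chi1)
        coords <- c(coords, lapply(side, place))
      }
      nm <- names(coords)
      xyz <- do.call(rbind, coords)
      rows[[i]] <- data.frame(chain = "A", resno = i, icode = "",
                              resname = resnames[i], atom = nm,
                              x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                              occ = 1, element = substr(nm, 1L, 1L),
                              stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    rownames(atoms) <- NULL
    out <- structure(list(atoms = atoms,
                          source_label = sprintf("synthetic-native-%s-n%d-seed%d",
                                                 spec$fold, n, spec$seed)),
                     class = "pdb_structure")
    attr(out, "fixture_seed") <- spec$seed
    out
  })
}

#' Perturb a native structure into a decoy
#'
#' Applies, in order: an optional rigid displacement of the second domain;
#' per-residue Gaussian noise (propagated rigidly, so the whole residue moves
#' together); a chi1-style rotation of the side chain about the CA-CB axis
#' (alpha carbons stay exactly in place); and a rigid side-chain displacement
#' along a seeded random direction. With all magnitudes zero the decoy is
#' identical to the native.
#'
#' @param native a `pdb_structure`, typically from [make_native()].
#' @param spec a [fixture_spec()] carrying the perturbation magnitudes and
#'   seed (an offset of the seed drives the decoy's own random stream).
#' @return a `pdb_structure`.
#' @export
make_decoy <- function(native, spec) {
  stopifnot(inherits(native, "pdb_structure"), inherits(spec, "fixture_spec"))
  atoms <- native$atoms
  key <- .residue_key(atoms$chain, atoms$resno, atoms$icode)
  res_keys <- unique(key)

  with_seed(spec$seed + 1000003L, {
    for (ri in seq_along(res_keys)) {
      rows <- which(key == res_keys[ri])
      xyz <- as.matrix(atoms[rows, c("x", "y", "z")])
      anames <- atoms$atom[rows]

      if (!is.null(spec$domain_split) && ri >= spec$domain_split$index) {
        xyz <- sweep(xyz, 2L, c(spec$domain_split$displacement, 0, 0), `+`)
      }
      if (spec$ca_noise_sigma > 0) {
        xyz <- sweep(xyz, 2L, stats::rnorm(3L, 0, spec$ca_noise_sigma), `+`)
      }
      side <- which(!(anames %in% .BACKBONE_ATOMS))
      if (spec$sc_rotation_deg != 0 && "CB" %in% anames && length(side) > 1L) {
        ca_xyz <- xyz[anames == "CA", ]
        cb_xyz <- xyz[anames == "CB", ]
        R <- rotation_about_axis(cb_xyz - ca_xyz, deg2rad(spec$sc_rotation_deg))
        rot <- setdiff(side, which(anames == "CB"))
        xyz[rot, ] <- sweep(sweep(xyz[rot, , drop = FALSE], 2L, ca_xyz) %*% t(R),
                            2L, ca_xyz, `+`)
      }
      if (spec$sc_displacement > 0 && length(side)) {
        u <- unit(stats::rnorm(3L))
        xyz[side, ] <- sweep(xyz[side, , drop = FALSE], 2L,
                             spec$sc_displacement * u, `+`)
      }
      atoms[rows, c("x", "y", "z")] <- xyz
    }
  })

  out <- structure(list(atoms = atoms,
                        source_label = paste0(native$source_label, "-decoy")),
                   class = "pdb_structure")
  attr(out, "fixture_seed") <- spec$seed
  out
}
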