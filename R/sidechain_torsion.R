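# chi1 torsion angles and their angular RMSD. chi1 is the dihedral
# N-CA-CB-X, where X is the residue-type-specific gamma-position atom.

# standard gamma atom per residue type; GLY/ALA have no chi1
.CHI1_GAMMA <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                 GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                 MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                 TRP = "CG", TYR = "CG", VAL = "CG1")

#' chi1 torsion angle of a residue
#'
#' Signed dihedral N-CA-CB-X in `(-pi, pi]`, where X is `CG` for most residue
#' types, `CG1` for valine/isoleucine, `OG` for serine, `OG1` for threonine
#' and `SG` for cysteine. Returns `NA` for glycine and alanine (no chi1) or
#' when any required atom is missing -- a valid result, not an error.
#'
#' @param res a `pdb_residue`.
#' @return chi1 in radians, or `NA_real_` when undefined.
#' @export
compute_chi1 <- function(res) {
  stopifnot(inherits(res, "pdb_residue"))
  gamma <- .CHI1_GAMMA[res$res_name]
  if (is.na(gamma)) return(NA_real_)
  pts <- lapply(c("N", "CA", "CB", unname(gamma)), .atom_coord, res = res)
  if (any(vapply(pts, is.null, NA))) return(NA_real_)
  dihedral4(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
}

#' Angular RMSD between two torsion-angle vectors
#'
#' Root mean square of the wrapped differences
#' `min(|x2 - x1|, 2*pi - |x2 - x1|)`, so the result lies in `[0, pi]` and is
#' invariant to adding multiples of `2*pi` to any entry.
#'
#' @param x1,x2 equal-length vectors of angles in radians.
#' @return angular RMSD in radians.
#' @export
angular_rmsd <- function(x1, x2) {
  if (!length(x1) || length(x1) != length(x2))
    stop("x1 and x2 must be non-empty vectors of equal length")
  d <- abs(x1 - x2) %% (2 * pi)
  w <- pmin(d, 2 * pi - d)
  sqrt(mean(w^2))
}

#' Normalize an angular RMSD to a similarity in (0, 1]
#'
#' `1 / (1 + (armsd / (pi/4))^2)`: 0 maps to 1, `pi/4` to 0.5, `pi/2` to 0.2.
#' Strictly decreasing, so rankings by angular RMSD and by the normalized
#' score are reversals of each other.
#'
#' @param armsd angular RMSD in radians, >= 0.
#' @return normalized score.
#' @export
normalized_angular_rmsd <- function(armsd) {
  if (any(!is.finite(armsd)) || any(armsd < 0)) stop("armsd must be finite and >= 0")
  1 / (1 + (armsd / (pi / 4))^2)
}

#' chi1 comparison between a model and a native structure
#'
#' Pairs residues by identifier (see [pair_residues()]), computes chi1 on both
#' sides, and keeps only residues where both angles are defined. Reports the
#' per-residue table plus the target-level angular RMSD and its normalized
#' form.
#'
#' @param model,native `pdb_structure` objects.
#' @return an object of class `chi1_result`: list with `records` (data frame
#'   of `chain`, `seq_num`, `icode`, `res_name`, `chi1_model`, `chi1_native`,
#'   radians), `armsd` (radians), `armsd_deg`, `normalized`, and `n`.
#' @export
chi1_compare <- function(model, native) {
  corr <- pair_residues(model, native)
  mres <- structure_residues(model)
  nres <- structure_residues(native)

  cm <- vapply(mres[corr$pairs$model_idx], compute_chi1, 0)
  cn <- vapply(nres[corr$pairs$native_idx], compute_chi1, 0)
  ok <- !is.na(cm) & !is.na(cn)
  if (!any(ok))
    stop("no residues with chi1 defined in both structures", call. = FALSE)

  ids <- corr$pairs$native_idx[ok]
  records <- data.frame(
    chain = vapply(nres[ids], `[[`, "", "chain_id"),
    seq_num = vapply(nres[ids], `[[`, 0L, "seq_num"),
    icode = vapply(nres[ids], `[[`, "", "icode"),
    res_name = vapply(nres[ids], `[[`, "", "res_name"),
    chi1_model = cm[ok],
    chi1_native = cn[ok],
    stringsAsFactors = FALSE)

  armsd <- angular_rmsd(records$chi1_model, records$chi1_native)
  structure(list(records = records, armsd = armsd,
                 armsd_deg = rad2deg(armsd),
                 normalized = normalized_angular_rmsd(armsd),
                 n = nrow(records)),
            class = "chi1_result")
}

#' @export
print.chi1_result <- function(x, ...) {
  cat("<chi1_result> ", x$n, " residue(s)\n",
      sprintf("  angular RMSD: %.4f rad (%.2f deg); normalized: %.4f\n",
              x$armsd, x$armsd_deg, x$normalized), sep = "")
  invisible(x)
}
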