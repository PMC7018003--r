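# The five-component similarity score. Half the weight goes to the GDT-style
# alpha-carbon term, half to the four side-chain terms (distance, two planar
# angles, one dihedral), each of which is a cumulative-bin score: values are
# assigned to every bin at or above their own, and lower bins earn more
# credit via linearly decreasing weights
#
#   score = 2 * sum_{i=1..k} (k - i + 1) * p_i / (k * (k + 1))
#
# where p_i is the proportion of the normalization count falling at or below
# bin bound i. All values <= bound 1 therefore score 1; all values beyond the
# last bound score 0.

#' Scoring configuration
#'
#' Defaults follow the published scheme: alpha-carbon thresholds 0.5/1/2/4 A
#' (the high-accuracy GDT set), ten cumulative side-chain distance bins of
#' 0.5 A width up to 5 A, planar-angle bins at 30/60/90/120 degrees, and ten
#' dihedral bins of 30 degrees up to 300. The seventh dihedral bound is 210
#' degrees by default, treating the published "201" as a typographical break
#' in the otherwise uniform 30-degree progression; set `dihedral_bin7 = 201`
#' to reproduce the printed value.
#'
#' @param ca_thresholds alpha-carbon distance thresholds, Angstrom, ascending.
#' @param sc_bin_width side-chain distance bin width, Angstrom.
#' @param n_sc_bins number of side-chain distance bins.
#' @param planar_bins_deg cumulative planar-angle bin bounds, degrees.
#' @param dihedral_bin7 seventh dihedral bound in degrees (210 or 201).
#' @param ca_weight weight of the alpha-carbon component.
#' @param total_weight divisor of the weighted sum.
#' @return an object of class `specs_config`.
#' @export
specs_config <- function(ca_thresholds = c(0.5, 1, 2, 4),
                         sc_bin_width = 0.5,
                         n_sc_bins = 10L,
                         planar_bins_deg = c(30, 60, 90, 120),
                         dihedral_bin7 = 210,
                         ca_weight = 4,
                         total_weight = 8) {
  dihedral_bins_deg <- c(30, 60, 90, 120, 150, 180, dihedral_bin7, 240, 270, 300)
  stopifnot(!is.unsorted(ca_thresholds, strictly = TRUE),
            !is.unsorted(planar_bins_deg, strictly = TRUE),
            !is.unsorted(dihedral_bins_deg, strictly = TRUE),
            sc_bin_width > 0, n_sc_bins >= 1, ca_weight > 0, total_weight > 0)
  structure(list(ca_thresholds = ca_thresholds,
                 sc_bins = sc_bin_width * seq_len(n_sc_bins),
                 planar_bins = deg2rad(planar_bins_deg),
                 dihedral_bins = deg2rad(dihedral_bins_deg),
                 ca_weight = ca_weight,
                 total_weight = total_weight),
            class = "specs_config")
}

# Shared cumulative-bin kernel: proportions of `n` at or below each bound,
# then the linearly weighted average.
.cumulative_bin_score <- function(values, bounds, n) {
  k <- length(bounds)
  counts <- vapply(bounds, function(b) sum(values <= b), 0L)
  p <- counts / n
  score <- 2 * sum((k - seq_len(k) + 1) * p) / (k * (k + 1))
  list(score = score, profile = p)
}

#' Alpha-carbon distance component
#'
#' The mean, over the distance thresholds, of the proportion of native
#' residues whose paired alpha carbon lies within the threshold. `max_counts`
#' normally comes from [gdt_search()], where each threshold's count is the
#' best over multiple superpositions; computed from a single superposition's
#' distances the component coincides with the high-accuracy GDT formula.
#'
#' @param max_counts integer vector of per-threshold counts.
#' @param n_native normalization count (full native length).
#' @return list with `score` and `profile` (per-threshold proportions).
#' @export
score_dca <- function(max_counts, n_native) {
  if (!is.numeric(n_native) || n_native < 1) stop("n_native must be >= 1")
  p <- as.numeric(max_counts) / n_native
  list(score = mean(p), profile = p)
}

#' Side-chain distance component
#'
#' Cumulative bins of `sc_bin_width` Angstrom (defaults: 0.5 to 5.0 A).
#'
#' @param r_values side-chain centroid distances, Angstrom, one per scorable
#'   pair.
#' @param n_sc normalization count: native residues bearing a side chain.
#' @param config a [specs_config()].
#' @return list with `score` and `profile`; both `NA` when `n_sc == 0`
#'   (component undefined, e.g. polyglycine).
#' @export
score_rsc <- function(r_values, n_sc, config = specs_config()) {
  if (n_sc == 0) return(list(score = NA_real_, profile = rep(NA_real_, length(config$sc_bins))))
  .cumulative_bin_score(r_values, config$sc_bins, n_sc)
}

#' Planar-angle component
#'
#' Cumulative bins at 30/60/90/120 degrees, applied to either set of virtual
#' planar angles. Degenerate pairs enter with angle 0 (full credit).
#'
#' @param angles planar angles in radians.
#' @inheritParams score_rsc
#' @return list with `score` and `profile`; `NA` when `n_sc == 0`.
#' @export
score_planar <- function(angles, n_sc, config = specs_config()) {
  if (n_sc == 0) return(list(score = NA_real_, profile = rep(NA_real_, length(config$planar_bins))))
  .cumulative_bin_score(angles, config$planar_bins, n_sc)
}

#' Dihedral-angle component
#'
#' Cumulative bins of 30 degrees up to 300 (see [specs_config()] for the
#' seventh bound). Angles are expected in `[0, 2*pi)`; degenerate pairs enter
#' with angle 0.
#'
#' @param angles dihedral angles in radians.
#' @inheritParams score_rsc
#' @return list with `score` and `profile`; `NA` when `n_sc == 0`.
#' @export
score_dihedral <- function(angles, n_sc, config = specs_config()) {
  if (n_sc == 0) return(list(score = NA_real_, profile = rep(NA_real_, length(config$dihedral_bins))))
  .cumulative_bin_score(angles, config$dihedral_bins, n_sc)
}

#' Weighted total from the five components
#'
#' `total = (ca_weight * dca + rsc + theta1 + theta2 + phi) / total_weight`,
#' with the default weights giving the alpha-carbon term half of the score.
#'
#' @param dca,rsc,theta1,theta2,phi component scores in `[0, 1]`.
#' @param ca_weight,total_weight weights (defaults 4 and 8).
#' @return the weighted total in `[0, 1]`.
#' @export
specs_total <- function(dca, rsc, theta1, theta2, phi,
                        ca_weight = 4, total_weight = 8) {
  comps <- c(dca = dca, rsc = rsc, theta1 = theta1, theta2 = theta2, phi = phi)
  if (any(!is.finite(comps)) || any(comps < 0) || any(comps > 1))
    stop("all components must be finite and within [0, 1]")
  (ca_weight * dca + rsc + theta1 + theta2 + phi) / total_weight
}

#' Score a model against a native structure
#'
#' Full evaluation pipeline: residues are paired by identifier, paired alpha
#' carbons drive the GDT-style multi-superposition search, and the search's
#' per-threshold maximal counts give the alpha-carbon component. The single
#' reference superposition from that search (best count at the largest
#' threshold) is then applied to the model's side-chain centroids, and the
#' four side-chain components are scored from the per-pair united-residue
#' geometry.
#'
#' Normalization follows the GDT convention: the alpha-carbon component
#' divides by the full native length, the side-chain components by the number
#' of native residues bearing at least one side-chain heavy atom (glycine
#' excluded). A paired native residue whose model counterpart lacks
#' side-chain atoms counts in the denominator but contributes to no bin. If
#' the native has no side-chain-bearing residues at all, the side-chain
#' components are undefined and the total equals the alpha-carbon component
#' (flagged via `sc_defined`).
#'
#' @param model,native `pdb_structure` objects sharing >= 3 residue
#'   identifiers.
#' @param config a [specs_config()].
#' @return an object of class `specs_result`: list with `components` (named
#'   list `dca`, `rsc`, `theta1`, `theta2`, `phi`), `total`, `profiles`,
#'   counts (`n_pairs`, `n_native`, `n_native_sc`), `sc_defined`,
#'   `reference` (the chosen superposition), and `per_residue` (data frame of
#'   per-pair geometry).
#' @export
#' @examples
#' nat <- make_native(fixture_spec(n_residues = 12, seed = 7))
#' res <- specs_score(nat, nat)
#' res$total  # exact self-identity: 1
specs_score <- function(model, native, config = specs_config()) {
  corr <- pair_residues(model, native)
  np <- nrow(corr$pairs)
  if (np < 3L) stop("need at least 3 paired residues to evaluate a model")

  mres <- structure_residues(model)
  nres <- structure_residues(native)
  m_ur <- lapply(mres[corr$pairs$model_idx], to_united_residue)
  n_ur <- lapply(nres[corr$pairs$native_idx], to_united_residue)

  m_ca <- do.call(rbind, lapply(m_ur, `[[`, "ca"))
  n_ca <- do.call(rbind, lapply(n_ur, `[[`, "ca"))
  gdt <- gdt_search(m_ca, n_ca, thresholds = config$ca_thresholds)
  dca <- score_dca(gdt$max_counts, corr$n_native)

  ref <- gdt$reference$transform
  geoms <- Map(function(mu, nu) pair_geometry(mu, nu, ref), m_ur, n_ur)
  nat_has_sc <- vapply(n_ur, `[[`, NA, "has_distinct_sc")
  mod_has_sc <- vapply(m_ur, `[[`, NA, "has_distinct_sc")
  scorable <- nat_has_sc & mod_has_sc

  r_values <- vapply(geoms[scorable], `[[`, 0, "r")
  th1 <- vapply(geoms[scorable], `[[`, 0, "theta1")
  th2 <- vapply(geoms[scorable], `[[`, 0, "theta2")
  phi <- vapply(geoms[scorable], `[[`, 0, "phi")

  n_sc <- corr$n_native_sc
  rsc <- score_rsc(r_values, n_sc, config)
  theta1 <- score_planar(th1, n_sc, config)
  theta2 <- score_planar(th2, n_sc, config)
  phic <- score_dihedral(phi, n_sc, config)

  sc_defined <- n_sc > 0
  if (sc_defined) {
    total <- specs_total(dca$score, rsc$score, theta1$score, theta2$score,
                         phic$score, config$ca_weight, config$total_weight)
  } else {
    total <- dca$score
  }

  ids <- corr$pairs$native_idx
  per_residue <- data.frame(
    chain = vapply(nres[ids], `[[`, "", "chain_id"),
    seq_num = vapply(nres[ids], `[[`, 0L, "seq_num"),
    icode = vapply(nres[ids], `[[`, "", "icode"),
    res_name = vapply(nres[ids], `[[`, "", "res_name"),
    d = gdt$reference$ca_distances,
    r = vapply(geoms, `[[`, 0, "r"),
    theta1_deg = rad2deg(vapply(geoms, `[[`, 0, "theta1")),
    theta2_deg = rad2deg(vapply(geoms, `[[`, 0, "theta2")),
    phi_deg = rad2deg(vapply(geoms, `[[`, 0, "phi")),
    angles_defined = vapply(geoms, `[[`, NA, "angles_defined"),
    sc_scored = scorable,
    stringsAsFactors = FALSE)

  structure(list(
    components = list(dca = dca$score, rsc = rsc$score,
                      theta1 = theta1$score, theta2 = theta2$score,
                      phi = phic$score),
    total = total,
    profiles = list(dca = dca$profile, rsc = rsc$profile,
                    theta1 = theta1$profile, theta2 = theta2$profile,
                    phi = phic$profile),
    n_pairs = np,
    n_native = corr$n_native,
    n_native_sc = n_sc,
    sc_defined = sc_defined,
    reference = gdt$reference,
    max_counts = gdt$max_counts,
    config = config,
    per_residue = per_residue),
    class = "specs_result")
}

#' @export
print.specs_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "   NA " else sprintf("%.4f", v)
  cat("<specs_result>\n",
      "  pairs: ", x$n_pairs, "  n_native: ", x$n_native,
      "  n_native_sc: ", x$n_native_sc, "\n",
      "  dCA    ", fmt(x$components$dca), "\n",
      "  rSC    ", fmt(x$components$rsc), "\n",
      "  theta1 ", fmt(x$components$theta1), "\n",
      "  theta2 ", fmt(x$components$theta2), "\n",
      "  phi    ", fmt(x$components$phi), "\n",
      "  total  ", fmt(x$total),
      if (!x$sc_defined) "  (side-chain components undefined; total = dCA)" else "",
      "\n", sep = "")
  invisible(x)
}
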