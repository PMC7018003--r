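# PDB reading/writing and residue correspondence.
#
# The structure container is deliberately light: a data frame of heavy-atom
# records plus a label, in file order. Only fixed-column ATOM records of the
# first MODEL are honored; hydrogens, HETATM records (waters included) and
# losing alternate locations are dropped at parse time so every downstream
# computation sees exactly one conformer of heavy atoms.

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.residue_key <- function(chain, resno, icode) paste(chain, resno, icode, sep = "|")

#' Parse a PDB file or text into a structure object
#'
#' Reads fixed-column `ATOM` records of the first model. Hydrogen and
#' deuterium atoms, `HETATM` records, and waters are excluded. When a residue
#' carries alternate locations for an atom, the highest-occupancy conformer is
#' retained (first record on ties). Residues whose name is not one of the 20
#' standard amino acids are dropped with a warning; selenomethionine can
#' instead be remapped to methionine via `map_mse`.
#'
#' @param source path to a PDB file, or a character scalar/vector of PDB text.
#' @param map_mse if `TRUE`, `MSE` residues are renamed to `MET` (their `SE`
#'   atom to `SD`) instead of being dropped.
#' @param source_label label stored on the returned object; defaults to the
#'   file path or `"<text>"`.
#' @return an object of class `pdb_structure`: a list with `atoms` (data frame
#'   with columns `chain`, `resno`, `icode`, `resname`, `atom`, `x`, `y`, `z`,
#'   `occ`, `element`) and `source_label`.
#' @export
#' @examples
#' txt <- c(
#'   "ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C")
#' s <- parse_pdb(txt)
#' nrow(s$atoms)
parse_pdb <- function(source, map_mse = FALSE, source_label = NULL) {
  if (length(source) == 1L && !grepl("\n", source)) {
    # a single newline-free string is a file path
    if (!file.exists(source))
      stop("cannot read PDB source '", source, "': no such file", call. = FALSE)
    lines <- tryCatch(readLines(source, warn = FALSE),
                      error = function(e) stop("cannot read PDB source '", source,
                                               "': ", conditionMessage(e), call. = FALSE))
    if (is.null(source_label)) source_label <- source
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(source_label)) source_label <- "<text>"
  }

  # first MODEL only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom)) stop("no ATOM records found in '", source_label, "'", call. = FALSE)
  idx <- which(is_atom)
  rec <- lines[idx]

  fld <- function(a, b) trimws(substr(rec, a, b))
  atom <- fld(13L, 16L)
  altloc <- substr(rec, 17L, 17L)
  resname <- fld(18L, 20L)
  chain <- substr(rec, 22L, 22L)
  resno_s <- fld(23L, 26L)
  icode <- trimws(substr(rec, 27L, 27L))
  xs <- fld(31L, 38L); ys <- fld(39L, 46L); zs <- fld(47L, 54L)
  occ_s <- fld(55L, 60L)
  element <- toupper(fld(77L, 78L))

  suppressWarnings({
    x <- as.numeric(xs); y <- as.numeric(ys); z <- as.numeric(zs)
    resno <- as.integer(resno_s)
    occ <- as.numeric(occ_s)
  })
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad)) {
    stop("malformed coordinate fields in ATOM record at line ", idx[bad[1L]],
         ": '", rec[bad[1L]], "'", call. = FALSE)
  }
  bad <- which(is.na(resno))
  if (length(bad)) {
    stop("malformed residue number in ATOM record at line ", idx[bad[1L]], call. = FALSE)
  }
  occ[!is.finite(occ)] <- 1

  # element fallback from the atom name when columns 77-78 are absent
  guess <- sub("^[0-9']+", "", atom)
  guess <- toupper(substr(guess, 1L, 1L))
  element <- ifelse(element == "", guess, element)

  atoms <- data.frame(chain = chain, resno = resno, icode = icode,
                      resname = resname, atom = atom, altloc = trimws(altloc),
                      x = x, y = y, z = z, occ = occ, element = element,
                      stringsAsFactors = FALSE)

  # filters: hydrogens/deuterium and waters (belt and braces; waters are
  # normally HETATM anyway)
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  if (map_mse && any(atoms$resname == "MSE")) {
    sel <- atoms$resname == "MSE"
    atoms$atom[sel & atoms$atom == "SE"] <- "SD"
    atoms$element[sel & atoms$element == "SE"] <- "S"
    atoms$resname[sel] <- "MET"
  }
  nonstd <- setdiff(unique(atoms$resname), .STANDARD_AA)
  if (length(nonstd)) {
    warning("dropping nonstandard residue(s): ", paste(nonstd, collapse = ", "),
            call. = FALSE)
    atoms <- atoms[atoms$resname %in% .STANDARD_AA, , drop = FALSE]
  }
  if (!nrow(atoms)) stop("no usable ATOM records remain after filtering in '",
                         source_label, "'", call. = FALSE)

  # alt-loc resolution: per residue+atom keep the highest occupancy, first on
  # ties (stable order preserved by using a max-occupancy scan in file order)
  key <- paste(.residue_key(atoms$chain, atoms$resno, atoms$icode), atoms$atom, sep = "@")
  keep <- rep(TRUE, nrow(atoms))
  dup_groups <- unique(key[duplicated(key)])
  for (g in dup_groups) {
    rows <- which(key == g)
    best <- rows[which.max(atoms$occ[rows])]
    keep[setdiff(rows, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL

  structure(list(atoms = atoms, source_label = source_label),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat("<pdb_structure> ", x$source_label, "\n",
      "  ", length(res), " residue(s), ", nrow(x$atoms), " heavy atom(s)\n", sep = "")
  invisible(x)
}

#' Split a structure into residue objects
#'
#' @param x a `pdb_structure`.
#' @return a list of `pdb_residue` objects in file order, each a list with
#'   `chain_id`, `seq_num`, `icode`, `res_name` and an `atoms` data frame.
#' @export
structure_residues <- function(x) {
  stopifnot(inherits(x, "pdb_structure"))
  a <- x$atoms
  key <- .residue_key(a$chain, a$resno, a$icode)
  ord <- unique(key)
  lapply(ord, function(k) {
    rows <- a[key == k, , drop = FALSE]
    structure(list(chain_id = rows$chain[1L], seq_num = rows$resno[1L],
                   icode = rows$icode[1L], res_name = rows$resname[1L],
                   atoms = rows),
              class = "pdb_residue")
  })
}

# TRUE when a residue carries at least one side-chain heavy atom usable for
# the united-residue centroid. Glycine never qualifies: its virtual bond is
# undefined in the coarse-grained scheme.
.residue_has_sc <- function(res) {
  if (res$res_name == "GLY") return(FALSE)
  any(!(res$atoms$atom %in% .BACKBONE_ATOMS))
}

.atom_coord <- function(res, name) {
  i <- match(name, res$atoms$atom)
  if (is.na(i)) return(NULL)
  as.numeric(res$atoms[i, c("x", "y", "z")])
}

#' Establish the model-to-native residue correspondence
#'
#' Residues are paired by identical `(chain, residue number, insertion code)`
#' identifiers, the convention for model/native pairs that share the target
#' numbering. Pairs whose residue names disagree are dropped with a warning.
#' The native denominators (`n_native`, `n_native_sc`) always reflect the full
#' native structure, so missing model residues are penalized downstream.
#'
#' @param model,native `pdb_structure` objects.
#' @return an object of class `residue_correspondence`: list with `pairs`
#'   (data frame of `model_idx`, `native_idx` into the respective residue
#'   lists), `n_native`, and `n_native_sc` (native residues bearing at least
#'   one side-chain heavy atom, glycine excluded).
#' @export
pair_residues <- function(model, native) {
  mres <- structure_residues(model)
  nres <- structure_residues(native)
  if (!length(mres) || !length(nres)) stop("both structures must be non-empty")

  mkey <- vapply(mres, function(r) .residue_key(r$chain_id, r$seq_num, r$icode), "")
  nkey <- vapply(nres, function(r) .residue_key(r$chain_id, r$seq_num, r$icode), "")
  if (anyDuplicated(mkey) || anyDuplicated(nkey))
    stop("duplicate residue identifiers within a structure")

  native_idx <- match(mkey, nkey)
  model_idx <- which(!is.na(native_idx))
  native_idx <- native_idx[model_idx]
  if (!length(model_idx))
    stop("structures share no residue identifiers; cannot establish correspondence")

  mnames <- vapply(mres[model_idx], `[[`, "", "res_name")
  nnames <- vapply(nres[native_idx], `[[`, "", "res_name")
  mismatch <- mnames != nnames
  if (any(mismatch)) {
    warning("dropping ", sum(mismatch), " residue pair(s) with mismatched names: ",
            paste(utils::head(mkey[model_idx][mismatch], 5L), collapse = ", "),
            call. = FALSE)
    model_idx <- model_idx[!mismatch]
    native_idx <- native_idx[!mismatch]
  }
  if (!length(model_idx))
    stop("structures share no residue identifiers; cannot establish correspondence")

  n_native_sc <- sum(vapply(nres, .residue_has_sc, NA))

  structure(list(pairs = data.frame(model_idx = model_idx, native_idx = native_idx),
                 n_native = length(nres),
                 n_native_sc = n_native_sc),
            class = "residue_correspondence")
}

#' @export
print.residue_correspondence <- function(x, ...) {
  cat("<residue_correspondence> ", nrow(x$pairs), " pair(s); n_native = ",
      x$n_native, ", n_native_sc = ", x$n_native_sc, "\n", sep = "")
  invisible(x)
}

#' Write a structure as fixed-column PDB ATOM records
#'
#' Coordinates are printed with the standard three decimals, so a write/parse
#' round trip preserves them to 1e-3 Angstrom. A generator seed stored on the
#' structure (see [make_native()]) is recorded in a REMARK line.
#'
#' @param x a `pdb_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "pdb_structure"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path, "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  seed <- attr(x, "fixture_seed")
  if (!is.null(seed)) writeLines(sprintf("REMARK 250 FIXTURE SEED %d", as.integer(seed)), con)
  a <- x$atoms
  # atom names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
  lines <- sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(a)), nm, a$resname, a$chain, a$resno,
                   ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}
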