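# GPCR activation descriptors: ionic-lock distance d_IL, toggle-switch
# dihedral chi_TS, and TM6 outward displacement d_TM6 / delta d_TM6, resolved
# through a Ballesteros-Weinstein residue map.

#' Ballesteros-Weinstein residue map
#'
#' Maps generic helix.position labels ("3.50", "6.48", ...) to concrete
#' (chain, residue id, residue name) triples of a structure.
#'
#' @param df data.frame with columns `bw_label`, `chain`, `resid`, `resname`.
#' @return object of class `"residue_map"` (a validated data.frame).
#' @export
residue_map <- function(df) {
  need <- c("bw_label", "chain", "resid", "resname")
  if (!all(need %in% names(df)))
    abort_ap(sprintf("residue map needs columns %s", paste(need, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$bw_label <- as.character(df$bw_label)
  df$chain <- as.character(df$chain)
  df$resid <- as.integer(df$resid)
  df$resname <- as.character(df$resname)
  if (anyDuplicated(df$bw_label))
    abort_ap("duplicate Ballesteros-Weinstein labels in residue map")
  class(df) <- c("residue_map", "data.frame")
  df
}

#' Read a residue map from a 4-column TSV
#'
#' Expected columns: `bw_label`, `chain`, `resid`, `resname` (header required).
#'
#' @param path file path.
#' @return a [residue_map()].
#' @export
read_residue_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = c("character", "character",
                                         "integer", "character"))
  residue_map(df)
}

#' Write a residue map as TSV
#' @param map a [residue_map()].
#' @param path file path.
#' @export
write_residue_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Atom indices of one mapped residue; `atoms` optionally restricts by name.
resolve_bw_atoms <- function(conf, map, label, atoms = NULL) {
  row <- map[map$bw_label == label, , drop = FALSE]
  if (nrow(row) != 1L)
    abort_ap(sprintf("label %s not present in residue map", label),
             "actipath_selection_error")
  idx <- which(conf$chain_ids == row$chain & conf$residue_ids == row$resid)
  if (!is.null(atoms)) idx <- idx[conf$atom_names[idx] %in% atoms]
  if (length(idx) == 0L || (!is.null(atoms) &&
      !all(atoms %in% conf$atom_names[idx])))
    abort_ap(sprintf("residue %s (chain %s, resid %d): atoms {%s} not found",
                     label, row$chain, row$resid,
                     paste(atoms %||% "any", collapse = ",")),
             "actipath_selection_error")
  idx
}

#' Ionic-lock distance d_IL
#'
#' Distance between the center of mass of the guanidinium eta-nitrogens
#' (NH1/NH2) of R3.50 and of the carboxylate oxygens (OE1/OE2) of E6.30.
#' (Glutamate carboxylate oxygens carry PDB names OE1/OE2 -- formally
#' epsilon; the conventional "delta-oxygen" wording maps to these two
#' terminal oxygens.)
#'
#' @param conf a [conformation()].
#' @param map a [residue_map()] resolving labels 3.50 and 6.30.
#' @return distance in Angstrom.
#' @export
ionic_lock_distance <- function(conf, map) {
  iR <- resolve_bw_atoms(conf, map, "3.50", c("NH1", "NH2"))
  iE <- resolve_bw_atoms(conf, map, "6.30", c("OE1", "OE2"))
  pR <- centroid(conf, iR); pE <- centroid(conf, iE)
  sqrt(sum((pR - pE)^2))
}

#' Toggle-switch dihedral chi_TS
#'
#' First side-chain dihedral (chi1: N-CA-CB-CG) of the W6.48 tryptophan.
#'
#' @inheritParams ionic_lock_distance
#' @return angle in degrees, in (-180, 180].
#' @export
toggle_switch_angle <- function(conf, map) {
  idx <- resolve_bw_atoms(conf, map, "6.48", c("N", "CA", "CB", "CG"))
  get1 <- function(nm) conf$coords[idx[conf$atom_names[idx] == nm][1], ]
  dihedral(get1("N"), get1("CA"), get1("CB"), get1("CG"))
}

# Default alignment mask for tm6_displacement: all CA atoms, minus residues
# in `exclude_residues` (the flexible-loop set).
default_align_mask <- function(conf, exclude_residues = NULL) {
  idx <- which(conf$atom_names == "CA")
  if (!is.null(exclude_residues))
    idx <- idx[!(conf$residue_ids[idx] %in% exclude_residues)]
  idx
}

#' TM6 outward displacement d_TM6 and its change from the inactive reference
#'
#' The anchor point M is the midpoint of the all-atom centroids of residues
#' 2.41 and 6.35 computed once from the inactive reference.  The query
#' conformation is rigid-fit to the inactive reference over `align_mask`,
#' then `d_TM6 = ||M - <R_6.35>||` and `delta = d_TM6 - d_TM6(inactive)`.
#'
#' @param conf query [conformation()].
#' @param inactive_ref inactive reference [conformation()] with identical
#'   atom ordering.
#' @param map a [residue_map()] resolving labels 2.41 and 6.35.
#' @param align_mask atom indices used for the rigid fit; default all CA
#'   atoms minus `exclude_residues`.
#' @param exclude_residues residue ids dropped from the default mask
#'   (flexible loops).
#' @return list with elements `d_tm6` and `delta`, both in Angstrom.
#' @export
tm6_displacement <- function(conf, inactive_ref, map, align_mask = NULL,
                             exclude_residues = NULL) {
  if (is.null(align_mask))
    align_mask <- default_align_mask(inactive_ref, exclude_residues)
  i241 <- resolve_bw_atoms(inactive_ref, map, "2.41")
  i635 <- resolve_bw_atoms(inactive_ref, map, "6.35")
  M <- 0.5 * (centroid(inactive_ref, i241) + centroid(inactive_ref, i635))
  d_ref <- sqrt(sum((M - centroid(inactive_ref, i635))^2))
  fit <- superpose(conf, inactive_ref, align_mask)
  aligned <- apply_transform(conf, fit)
  d <- sqrt(sum((M - centroid(aligned, resolve_bw_atoms(conf, map, "6.35")))^2))
  list(d_tm6 = d, delta = d - d_ref)
}

#' All three activation descriptors of a conformation
#'
#' @inheritParams tm6_displacement
#' @return named numeric vector `c(d_il, chi_ts, d_tm6, delta_d_tm6)`.
#' @export
activation_descriptors <- function(conf, inactive_ref, map, align_mask = NULL,
                                   exclude_residues = NULL) {
  tm6 <- tm6_displacement(conf, inactive_ref, map, align_mask, exclude_residues)
  c(d_il = ionic_lock_distance(conf, map),
    chi_ts = toggle_switch_angle(conf, map),
    d_tm6 = tm6$d_tm6, delta_d_tm6 = tm6$delta)
}
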