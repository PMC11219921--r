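# Van der Waals radii (angstrom) for heavy elements seen in protein/DNA
# structures.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75, CA = 2.31)

# Theoretical maximum accessible surface areas per residue (angstrom^2),
# Tien et al. (2013) theoretical values, used to turn absolute SASA into
# a percentage.
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
             CYS = 167.0, GLU = 223.0, GLN = 225.0, GLY = 104.0,
             HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
             MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
             THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Subdomain region of each construct position
#'
#' Partition of the 1-150 construct: N-terminal subdomain (NTS) 4-63,
#' linker 64-79, C-terminal subdomain (CTS) 80-136, and `other` for 1-3
#' and 137-150 (positions outside the crystallised domain).
#'
#' @param position integer positions (1-150; values outside map to
#'   `other`).
#' @return character vector in `{NTS, Linker, CTS, other}`.
#' @export
region_of <- function(position) {
  out <- rep("other", length(position))
  out[position >= 4 & position <= 63] <- "NTS"
  out[position >= 64 & position <= 79] <- "Linker"
  out[position >= 80 & position <= 136] <- "CTS"
  out
}

#' Parse a protein-DNA complex from PDB text
#'
#' Reads ATOM/HETATM records (fixed columns, PDB v3.3), drops hydrogens
#' and deuteriums, resolves alternate locations to the highest-occupancy
#' copy, and labels each atom's role from the requested chains.
#'
#' @param pdb path to a PDB file or a character vector of PDB lines.
#' @param protein_chain single chain identifier of the protein.
#' @param dna_chains chain identifiers of the DNA duplex.
#' @return data frame: `chain`, `resid`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`, `occupancy`, `role` (`protein`/`dna`).
#' @export
parse_complex <- function(pdb, protein_chain = "A",
                          dna_chains = c("B", "C")) {
  lines <- if (length(pdb) == 1 && file.exists(pdb)) readLines(pdb) else pdb
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  assert_that(length(lines) > 0, "no ATOM/HETATM records found")

  fx <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b) suppressWarnings(as.numeric(fx(a, b)))
  atoms <- data.frame(
    atom = fx(13, 16), altloc = fx(17, 17), resname = fx(18, 20),
    chain = fx(22, 22), resid = suppressWarnings(as.integer(fx(23, 26))),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60), element = toupper(fx(77, 78)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
      anyNA(atoms$resid)) {
    stop_y1h(sprintf("unparseable PDB record: %s",
                     lines[which(is.na(atoms$x) | is.na(atoms$resid))[1]]))
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1

  # Element fallback from the atom-name column when columns 77-78 are blank.
  blank <- atoms$element == ""
  atoms$element[blank] <- toupper(substr(gsub("[0-9']", "",
                                              atoms$atom[blank]), 1, 1))

  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]

  # Alternate locations: keep the highest-occupancy copy per atom site.
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  has_alt <- atoms$altloc != ""
  if (any(has_alt)) {
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resid,
                                     atoms$atom)), , drop = FALSE]
  }

  wanted <- c(protein_chain, dna_chains)
  missing <- setdiff(wanted, unique(atoms$chain))
  assert_that(length(missing) == 0,
              sprintf("chains not present in structure: %s",
                      paste(missing, collapse = ", ")))
  atoms <- atoms[atoms$chain %in% wanted, , drop = FALSE]
  atoms$role <- ifelse(atoms$chain == protein_chain, "protein", "dna")
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

#' Minimum residue-DNA distances
#'
#' Euclidean minimum over all pairs of residue heavy atoms and DNA
#' non-hydrogen atoms, per protein residue, discretised into 1-angstrom
#' half-open bins `[k, k + 1)`.
#'
#' @param atoms parsed complex from [parse_complex()].
#' @return data frame: `resid`, `dna_distance`, `distance_bin`.
#' @export
min_dna_distance <- function(atoms) {
  prot <- atoms[atoms$role == "protein", , drop = FALSE]
  dna <- atoms[atoms$role == "dna", , drop = FALSE]
  assert_that(nrow(dna) >= 1, "no DNA atoms")
  assert_that(nrow(prot) >= 1, "no protein atoms")

  pm <- as.matrix(prot[, c("x", "y", "z")])
  dm <- as.matrix(dna[, c("x", "y", "z")])
  # Squared cross-distances via the Gram expansion.
  d2 <- outer(rowSums(pm^2), rowSums(dm^2), "+") - 2 * pm %*% t(dm)
  d2[d2 < 0] <- 0
  atom_min <- sqrt(apply(d2, 1, min))
  res_min <- tapply(atom_min, prot$resid, min)
  data.frame(resid = as.integer(names(res_min)),
             dna_distance = as.numeric(res_min),
             distance_bin = floor(as.numeric(res_min)),
             row.names = NULL)
}

#' Per-residue relative solvent accessibility (Shrake-Rupley)
#'
#' Samples `n_points` near-uniform points on each heavy atom's solvent-
#' extended sphere (radius + probe), counts points not buried inside any
#' neighbouring atom's extended sphere, sums atom areas per protein
#' residue, and normalises by the residue's theoretical maximum ASA.
#' Occlusion considers every atom passed in (so DNA and dummy atoms
#' shield the interface). Residues whose name has no reference maximum
#' (e.g. dummy cage residues) occlude others but are omitted from the
#' output.
#'
#' @param atoms parsed complex from [parse_complex()].
#' @param probe solvent probe radius (angstrom; water = 1.4).
#' @param n_points sphere sample points per atom.
#' @param threshold percent relative SASA above which a residue counts as
#'   solvent accessible.
#' @return data frame: `resid`, `resname`, `sasa` (absolute, angstrom^2),
#'   `rel_sasa` (percent), `accessible`.
#' @export
relative_sasa <- function(atoms, probe = 1.4, n_points = 200L,
                          threshold = 25) {
  unknown <- setdiff(unique(atoms$element), names(VDW_RADII))
  assert_that(length(unknown) == 0,
              sprintf("unknown element(s): %s",
                      paste(unknown, collapse = ", ")))
  r <- VDW_RADII[atoms$element] + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)

  area <- numeric(n)
  # Neighbour prefilter: only atoms within r_i + max(r) can occlude atom i.
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + rmax)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    sp <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- rowSums(sweep(sp[free, , drop = FALSE], 2, xyz[j, ])^2)
        free[free] <- dj2 > r[j]^2
      }
      acc <- sum(free)
    } else {
      acc <- n_points
    }
    area[i] <- 4 * pi * r[i]^2 * acc / n_points
  }

  prot <- atoms$role == "protein"
  res_area <- tapply(area[prot], atoms$resid[prot], sum)
  resname <- atoms$resname[prot][match(names(res_area),
                                       as.character(atoms$resid[prot]))]
  known <- resname %in% names(MAX_ASA)
  rel <- rep(NA_real_, length(res_area))
  rel[known] <- 100 * as.numeric(res_area)[known] / MAX_ASA[resname[known]]
  out <- data.frame(resid = as.integer(names(res_area)),
                    resname = resname,
                    sasa = as.numeric(res_area),
                    rel_sasa = rel,
                    accessible = rel > threshold,
                    row.names = NULL)
  out[!is.na(out$rel_sasa), , drop = FALSE]
}

#' Median fitness score per residue position
#'
#' @param scores score data frame with `variant` (ids like `K12E`) and
#'   `score`; variants without a parsable position are skipped.
#' @return data frame: `position`, `median_score`, `n_variants`.
#' @export
per_residue_median <- function(scores) {
  pos <- variant_position(scores$variant)
  keep <- !is.na(pos) & !is.na(scores$score)
  med <- tapply(scores$score[keep], pos[keep], stats::median)
  nv <- tapply(scores$score[keep], pos[keep], length)
  data.frame(position = as.integer(names(med)),
             median_score = as.numeric(med),
             n_variants = as.integer(nv),
             row.names = NULL)
}

#' Write a PDB with per-position medians in the B-factor column
#'
#' Produces a structure colourable by mutational sensitivity in any
#' molecular viewer. Positions without a median get B-factor 0.
#'
#' @param pdb path or lines of the source PDB.
#' @param medians output of [per_residue_median()].
#' @param path output file.
#' @param protein_chain chain whose B-factors are replaced.
#' @export
write_bfactor_pdb <- function(pdb, medians, path, protein_chain = "A") {
  lines <- if (length(pdb) == 1 && file.exists(pdb)) readLines(pdb) else pdb
  is_atom <- trimws(substr(lines, 1, 6)) %in% c("ATOM", "HETATM")
  chain <- substr(lines, 22, 22)
  resid <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  b <- medians$median_score[match(resid, medians$position)]
  b[is.na(b)] <- 0
  sel <- is_atom & chain == protein_chain
  substr(lines[sel], 61, 66) <- sprintf("%6.2f", b[sel])
  writeLines(lines, path)
  invisible(path)
}

#' Associate fitness scores with structural context
#'
#' Joins variant scores (by construct position) to per-residue covariates
#' and runs rank-sum comparisons of scores grouped by solvent
#' accessibility, 1-angstrom DNA-distance bin, and subdomain region.
#' Strata with a single populated group report medians only.
#'
#' @param scores score data frame (`variant`, `score`).
#' @param contexts per-residue data frame with `resid` and any of
#'   `accessible`, `distance_bin`, plus the derived `region`.
#' @return list of per-covariate results: each has `medians` (per group)
#'   and, when >= 2 groups, `comparisons` from [group_compare()].
#' @export
context_association <- function(scores, contexts) {
  pos <- variant_position(scores$variant)
  keep <- !is.na(pos) & pos %in% contexts$resid & !is.na(scores$score)
  assert_that(any(keep), "no variants join onto the structural context")
  df <- data.frame(score = scores$score[keep],
                   resid = pos[keep], stringsAsFactors = FALSE)
  ctx <- contexts[match(df$resid, contexts$resid), , drop = FALSE]
  ctx$region <- region_of(ctx$resid)

  one <- function(fac, name) {
    fac <- as.factor(fac)
    med <- tapply(df$score, fac, stats::median)
    res <- list(covariate = name,
                medians = data.frame(group = names(med),
                                     median = as.numeric(med),
                                     n = as.integer(base::table(fac)),
                                     row.names = NULL))
    sizes <- base::table(droplevels(fac))
    if (length(sizes) >= 2 && all(sizes >= 2)) {
      res$comparisons <- group_compare(df$score, fac)
    }
    res
  }
  out <- list()
  if (!is.null(ctx$accessible)) {
    out$accessibility <- one(ifelse(ctx$accessible, "accessible", "buried"),
                             "accessibility")
  }
  if (!is.null(ctx$distance_bin)) {
    out$dna_distance <- one(ctx$distance_bin, "dna_distance_bin")
  }
  out$region <- one(ctx$region, "region")
  out
}
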