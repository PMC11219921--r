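#' Generate a toy protein-DNA complex structure
#'
#' Builds PDB-format text for a synthetic complex whose geometry is known
#' by construction, for exercising the structural-context operations.
#' Protein residues are single glycine CA atoms on a line (chain A,
#' `spacing` angstroms apart); DNA phosphorus atoms sit in two chains (B
#' and C, alternating) with residue `i`'s nearest DNA atom placed exactly
#' `dna_offset + (i - 1)` angstroms away. Optionally, chosen residues are
#' caged inside a dense shell of dummy occluding atoms so their solvent
#' accessibility is ~0 by construction.
#'
#' @param n_residues number of protein residues (>= 1).
#' @param dna_atoms optional data frame (`x`, `y`, `z`, optional `chain`)
#'   of DNA atom coordinates; default lattice described above.
#' @param spacing inter-residue spacing along x (angstroms).
#' @param dna_offset distance of residue 1 to its DNA atom (angstroms).
#' @param cage_residues indices of residues to bury under a dummy shell.
#' @param cage_radius radius of the occluding shell (angstroms).
#' @param cage_points number of shell atoms per caged residue.
#' @return list: `text` (PDB lines), `truth` (data frame `resid`,
#'   `dna_distance`, `caged`).
#' @export
gen_toy_structure <- function(n_residues, dna_atoms = NULL, spacing = 10,
                              dna_offset = 3, cage_residues = integer(0),
                              cage_radius = 3.2, cage_points = 80L) {
  assert_that(n_residues >= 1, "n_residues must be >= 1")
  px <- spacing * (seq_len(n_residues) - 1)

  if (is.null(dna_atoms)) {
    dna_atoms <- data.frame(x = px,
                            y = dna_offset + (seq_len(n_residues) - 1),
                            z = 0,
                            chain = rep_len(c("B", "C"), n_residues))
  }
  if (is.null(dna_atoms$chain)) dna_atoms$chain <- "B"

  # Ground-truth minimum residue-DNA distance, straight from the lattice.
  truth_d <- vapply(seq_len(n_residues), function(i) {
    min(sqrt((px[i] - dna_atoms$x)^2 + (0 - dna_atoms$y)^2 +
               (0 - dna_atoms$z)^2))
  }, numeric(1))

  lines <- character(0)
  serial <- 0L
  emit <- function(name, resname, chain, resid, x, y, z, element,
                   record = "ATOM") {
    serial <<- serial + 1L
    lines[length(lines) + 1L] <<- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, serial, name, resname, chain, resid, x, y, z, 1.00, 0.00,
      element)
  }
  for (i in seq_len(n_residues)) {
    emit(" CA ", "GLY", "A", i, px[i], 0, 0, "C")
  }
  for (i in seq_len(n_residues)) {
    if (i %in% cage_residues) {
      pts <- sphere_points(cage_points)
      for (k in seq_len(nrow(pts))) {
        emit(" X  ", "DUM", "A", 900L + i,
             px[i] + cage_radius * pts[k, 1],
             cage_radius * pts[k, 2],
             cage_radius * pts[k, 3], "C", record = "HETATM")
      }
    }
  }
  for (k in seq_len(nrow(dna_atoms))) {
    emit(" P  ", "DA", dna_atoms$chain[k], k,
         dna_atoms$x[k], dna_atoms$y[k], dna_atoms$z[k], "P")
  }
  lines <- c(lines, "END")

  list(text = lines,
       truth = data.frame(resid = seq_len(n_residues),
                          dna_distance = truth_d,
                          caged = seq_len(n_residues) %in% cage_residues))
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
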