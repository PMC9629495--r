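# Unit-cell arithmetic: metric tensors, orthogonalization, d-spacings.

deg2rad <- function(x) x * pi / 180

# direct-space metric tensor from 6 cell parameters
cell_metric <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  matrix(c(
    a * a, a * b * cos(ga), a * c * cos(be),
    a * b * cos(ga), b * b, b * c * cos(al),
    a * c * cos(be), b * c * cos(al), c * c
  ), 3, 3)
}

# orthogonalization matrix (fractional -> cartesian), PDB convention
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), c * cos(be),
    0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, c * v / sin(ga)
  ), 3, 3, byrow = TRUE)
}

frac_matrix <- function(cell) solve(orth_matrix(cell))

#' Convert cartesian coordinates to fractional
#' @param xyz numeric matrix (n x 3), Angstrom
#' @param cell numeric(6)
#' @return fractional coordinate matrix (n x 3)
#' @export
cart_to_frac <- function(xyz, cell) xyz %*% t(frac_matrix(cell))

#' Convert fractional coordinates to cartesian
#' @param frac numeric matrix (n x 3)
#' @param cell numeric(6)
#' @return cartesian coordinate matrix (n x 3), Angstrom
#' @export
frac_to_cart <- function(frac, cell) frac %*% t(orth_matrix(cell))

#' Resolution of reflections in a given cell
#' @param hkl integer matrix (n x 3) of Miller indices
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees)
#' @return d-spacings in Angstrom
#' @export
d_spacing <- function(hkl, cell) {
  gstar <- solve(cell_metric(cell))
  inv_d2 <- rowSums((hkl %*% gstar) * hkl)
  1 / sqrt(inv_d2)
}

cell_volume <- function(cell) det(orth_matrix(cell))
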