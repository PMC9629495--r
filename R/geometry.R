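
# --- small vector helpers (3-vectors as numeric(3)) ---

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors, degrees
vangle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Natural extension reference frame: place atom D given positions A, B, C,
# bond length |CD|, angle B-C-D (deg) and torsion A-B-C-D (deg).
place_atom <- function(a, b, c_, length, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- unitv(c_ - b)
  ab <- unitv(b - a)
  n <- unitv(vcross(ab, bc))
  m <- vcross(n, bc)
  d2 <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c_ + bc * d2[1] + m * d2[2] + n * d2[3]
}

# Standard Engh-Huber-like backbone geometry used by the ideal-chain builder.
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, omega = 180
)

#' Build an ideal-geometry polypeptide backbone from dihedral angles
#'
#' Constructs N, CA, C, O (and optionally CB) coordinates for a chain with
#' the given backbone dihedrals, using idealized bond lengths and angles.
#' An ideal alpha-helix corresponds to phi = -57, psi = -47; an extended
#' beta-strand to phi = -119, psi = 113.
#'
#' @param phi numeric vector of phi dihedrals, degrees (first value unused)
#' @param psi numeric vector of psi dihedrals, degrees, same length
#' @param with_cb logical; add a CB atom per residue (alanine-like)
#' @return data.frame with columns resseq, name, element, x, y, z
#' @export
build_chain <- function(phi, psi, with_cb = TRUE) {
  n <- length(phi)
  stopifnot(n >= 1, length(psi) == n)
  g <- .bb
  pos <- list()
  # residue 1 seeded in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C <- CA + g$ca_c * c(-cos(th), sin(th), 0)
  pos[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)[-1]) {
    p <- pos[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i - 1])
    CAi <- place_atom(p$CA, p$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
    Ci <- place_atom(p$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
    pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pos[[i]]
    psi_i <- if (i < n) psi[i] else -40
    O <- place_atom(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o, psi_i + 180)
    at <- rbind(
      data.frame(name = "N", element = "N", x = p$N[1], y = p$N[2], z = p$N[3]),
      data.frame(name = "CA", element = "C", x = p$CA[1], y = p$CA[2], z = p$CA[3]),
      data.frame(name = "C", element = "C", x = p$C[1], y = p$C[2], z = p$C[3]),
      data.frame(name = "O", element = "O", x = O[1], y = O[2], z = O[3])
    )
    if (with_cb) {
      CB <- place_atom(p$N, p$C, p$CA, g$ca_cb, g$ang_n_ca_cb, 122.55)
      at <- rbind(at, data.frame(name = "CB", element = "C",
                                 x = CB[1], y = CB[2], z = CB[3]))
    }
    at$resseq <- i
    rows[[i]] <- at
  }
  out <- do.call(rbind, rows)
  out[, c("resseq", "name", "element", "x", "y", "z")]
}

#' Build an ideal alpha-helix backbone
#' @param n_res number of residues
#' @param with_cb logical; include CB atoms
#' @return data.frame as in [build_chain()]
#' @export
build_helix <- function(n_res, with_cb = TRUE) {
  build_chain(rep(-57, n_res), rep(-47, n_res), with_cb = with_cb)
}

#' Build an ideal extended beta-strand backbone
#' @inheritParams build_helix
#' @export
build_strand <- function(n_res, with_cb = TRUE) {
  build_chain(rep(-119, n_res), rep(113, n_res), with_cb = with_cb)
}

#' Random proper rotation matrix (uniform over SO(3))
#' @return 3x3 rotation matrix with determinant 1
#' @export
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Rotation matrix about an axis
#' @param axis 3-vector (need not be normalized)
#' @param angle degrees
#' @return 3x3 rotation matrix
#' @export
axis_rotation <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
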