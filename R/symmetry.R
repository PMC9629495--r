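# Space-group machinery for the toy-crystal setting.
#
# Operators are stored as coordinate triplets in the standard setting and
# parsed once into (R, v) pairs: 3x3 integer rotation part and fractional
# translation. The supported set covers the groups exercised by the
# fragment-phasing workflow; anything else raises an explicit error.

.sg_table <- list(
  "P1"       = "x,y,z",
  "P21"      = "x,y,z; -x,y+1/2,-z",
  "C2"       = "x,y,z; -x,y,-z; x+1/2,y+1/2,z; -x+1/2,y+1/2,-z",
  "P222 1"   = NULL, # placeholder guard, never matched
  "P2221"    = "x,y,z; -x,-y,z+1/2; x,-y,-z; -x,y,-z+1/2",
  "P21212"   = "x,y,z; -x,-y,z; x+1/2,-y+1/2,-z; -x+1/2,y+1/2,-z",
  "P212121"  = "x,y,z; -x+1/2,-y,z+1/2; x+1/2,-y+1/2,-z; -x,y+1/2,-z+1/2",
  "P41"      = "x,y,z; -y,x,z+1/4; -x,-y,z+1/2; y,-x,z+3/4",
  "P41212"   = paste("x,y,z; -y+1/2,x+1/2,z+1/4; -x,-y,z+1/2;",
                     "y+1/2,-x+1/2,z+3/4; x+1/2,-y+1/2,-z+3/4;",
                     "-y,-x,-z+1/2; -x+1/2,y+1/2,-z+1/4; y,x,-z"),
  "P63"      = "x,y,z; x-y,x,z+1/2; -y,x-y,z; -x,-y,z+1/2; -x+y,-x,z; y,-x+y,z+1/2",
  "P6122"    = paste("x,y,z; x-y,x,z+1/6; -y,x-y,z+1/3; -x,-y,z+1/2;",
                     "-x+y,-x,z+2/3; y,-x+y,z+5/6; -y,-x,-z+5/6;",
                     "-x,-x+y,-z+2/3; -x+y,y,-z+1/2; y,x,-z+1/3;",
                     "x,x-y,-z+1/6; x-y,-y,-z"),
  "P6522"    = paste("x,y,z; x-y,x,z+5/6; -y,x-y,z+2/3; -x,-y,z+1/2;",
                     "-x+y,-x,z+1/3; y,-x+y,z+1/6; -y,-x,-z+1/6;",
                     "-x,-x+y,-z+1/3; -x+y,y,-z+1/2; y,x,-z+2/3;",
                     "x,x-y,-z+5/6; x-y,-y,-z")
)

# normalize a Hermann-Mauguin symbol: strip spaces/underscores, map
# subscripted digits, case-insensitive on the lattice letter
normalize_sg_symbol <- function(symbol) {
  s <- gsub("[ _()]", "", symbol)
  s <- gsub("₁", "1", s); s <- gsub("₂", "2", s)
  s <- gsub("₃", "3", s); s <- gsub("₅", "5", s)
  s <- gsub("₆", "6", s)
  toupper(s)
}

parse_triplet_term <- function(term) {
  # one coordinate expression like "-x+y+1/2" -> c(rx, ry, rz, t)
  out <- c(0, 0, 0, 0)
  term <- gsub(" ", "", tolower(term))
  # tokenize into signed pieces
  pieces <- regmatches(term, gregexpr("[+-]?[^+-]+", term))[[1]]
  for (p in pieces) {
    sign <- if (startsWith(p, "-")) -1 else 1
    body <- sub("^[+-]", "", p)
    if (body == "x") out[1] <- out[1] + sign
    else if (body == "y") out[2] <- out[2] + sign
    else if (body == "z") out[3] <- out[3] + sign
    else if (grepl("^\\d+/\\d+$", body)) {
      fr <- as.numeric(strsplit(body, "/")[[1]])
      out[4] <- out[4] + sign * fr[1] / fr[2]
    } else if (grepl("^\\d*\\.?\\d+$", body)) {
      out[4] <- out[4] + sign * as.numeric(body)
    } else stop("cannot parse symmetry term: ", p)
  }
  out
}

parse_symop <- function(triplet) {
  parts <- strsplit(triplet, ",")[[1]]
  stopifnot(length(parts) == 3)
  m <- t(vapply(parts, parse_triplet_term, numeric(4)))
  list(R = unname(m[, 1:3, drop = FALSE]), v = unname(m[, 4]) %% 1)
}

#' Symmetry operators of a supported space group
#'
#' @param spacegroup Hermann-Mauguin symbol (spaces/underscores ignored),
#'   e.g. "P21 21 21", "C2", "P63".
#' @return list with `symbol` (normalized), `ops` (list of `(R, v)` pairs,
#'   rotation part and fractional translation) and `n_ops`.
#' @export
sg_ops <- function(spacegroup) {
  key <- normalize_sg_symbol(spacegroup)
  trip <- .sg_table[[key]]
  if (is.null(trip)) {
    stop("unsupported space group '", spacegroup, "'; supported: ",
         paste(setdiff(names(.sg_table), "P222 1"), collapse = ", "))
  }
  ops <- lapply(strsplit(trip, ";")[[1]], function(t) parse_symop(trimws(t)))
  list(symbol = key, ops = ops, n_ops = length(ops))
}

#' Test whether two space-group symbols denote the same group
#' @param a,b Hermann-Mauguin symbols
#' @return logical
#' @export
same_spacegroup <- function(a, b) {
  identical(normalize_sg_symbol(a), normalize_sg_symbol(b))
}

#' Allowed origin shifts of a space group
#'
#' Enumerates the translations `t` that map the symmetry framework onto
#' itself: for every operator `(R, v)`, `(R - I) t` must be a lattice
#' vector. Along polar directions (invariant under every rotation part)
#' any shift is allowed and the component is reported as polar rather
#' than enumerated.
#'
#' @param spacegroup Hermann-Mauguin symbol
#' @param denom grid denominator for the discrete enumeration (default 24)
#' @return list with `polar_axes` (logical 3-vector along a, b, c) and
#'   `shifts` (matrix, one fractional shift per row; polar components 0)
#' @export
allowed_origin_shifts <- function(spacegroup, denom = 24) {
  sg <- sg_ops(spacegroup)
  Rs <- lapply(sg$ops, `[[`, "R")
  # polar axis j: e_j fixed by every rotation part
  polar <- vapply(1:3, function(j) {
    ej <- as.numeric(seq_len(3) == j)
    all(vapply(Rs, function(R) all(R[, j] == ej), logical(1)))
  }, logical(1))
  grid <- (0:(denom - 1)) / denom
  axes <- lapply(1:3, function(j) if (polar[j]) 0 else grid)
  cand <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  ok <- apply(cand, 1, function(t) {
    all(vapply(Rs, function(R) {
      d <- (R - diag(3)) %*% t
      all(abs(d - round(d)) < 1e-9)
    }, logical(1)))
  })
  shifts <- cand[ok, , drop = FALSE]
  dimnames(shifts) <- NULL
  o <- order(shifts[, 1], shifts[, 2], shifts[, 3])
  list(polar_axes = polar, shifts = shifts[o, , drop = FALSE])
}

# indices h (n x 3) -> logical: is the reflection systematically absent?
systematic_absent <- function(hkl, sg) {
  apply(hkl, 1, function(h) {
    for (op in sg$ops) {
      hR <- as.numeric(h %*% op$R)
      if (all(hR == h)) {
        ph <- sum(h * op$v)
        if (abs(ph - round(ph)) > 1e-9) return(TRUE)
      }
    }
    FALSE
  })
}

# canonical symmetry-unique representative of each index under the group
# plus Friedel inversion; returns matrix of same size
canonical_hkl <- function(hkl, sg) {
  t(apply(hkl, 1, function(h) {
    best <- NULL
    for (op in sg$ops) {
      for (s in c(1, -1)) {
        cand <- s * as.numeric(h %*% op$R)
        if (is.null(best) || cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] > best[2]) ||
            (cand[1] == best[1] && cand[2] == best[2] && cand[3] > best[3])) {
          best <- cand
        }
      }
    }
    best
  }))
}

# centric test + allowed phase (degrees) for each reflection
centric_info <- function(hkl, sg) {
  n <- nrow(hkl)
  centric <- logical(n)
  phase0 <- numeric(n)
  for (i in seq_len(n)) {
    h <- hkl[i, ]
    for (op in sg$ops) {
      hR <- as.numeric(h %*% op$R)
      if (all(hR == -h)) {
        centric[i] <- TRUE
        phase0[i] <- (180 * sum(h * op$v)) %% 180
        break
      }
    }
  }
  list(centric = centric, phase0 = phase0)
}
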