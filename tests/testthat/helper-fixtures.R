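# Shared fixture builders: all fixtures are generated in code at test time.

# a bundle of ideal helices packed side by side (antiparallel), each on its
# own chain; returns the atom data.frame
fix_bundle <- function(n_hel = 3, helix_len = 12, offset = c(0, 0, 0),
                       chains = LETTERS[seq_len(n_hel)], spacing = 9.5) {
  parts <- lapply(seq_len(n_hel) - 1, function(k) {
    h <- build_helix(helix_len)
    xyz <- as.matrix(h[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    if (k %% 2 == 1) xyz <- xyz %*% t(axis_rotation(c(0, 0, 1), 180))
    xyz <- sweep(xyz, 2, c(spacing * k, 0, 0) + offset, "+")
    h[, c("x", "y", "z")] <- xyz
    h$chain <- chains[k + 1]
    h
  })
  out <- do.call(rbind, parts)
  out$resname <- "ALA"
  out
}

fix_bundle_model <- function(...) structure_model(fix_bundle(...))

# helix with an appended disordered tail grafted at a random orientation
fix_helix_with_tail <- function(helix_len = 20, tail_len = 10, seed = 1) {
  set.seed(seed)
  h <- build_helix(helix_len)
  phi <- stats::runif(tail_len, -160, -60)
  psi <- c(stats::runif(ceiling(tail_len / 2), -70, -20),
           stats::runif(floor(tail_len / 2), 100, 175))[seq_len(tail_len)]
  tl <- build_chain(phi, psi)
  tl$resseq <- tl$resseq + helix_len
  txyz <- as.matrix(tl[, c("x", "y", "z")]) %*% t(random_rotation())
  hca <- as.matrix(h[h$name == "CA", c("x", "y", "z")])
  off <- hca[helix_len, ] + c(6, 0, 0) - txyz[1, ]
  tl[, c("x", "y", "z")] <- sweep(txyz, 2, off, "+")
  out <- rbind(h, tl)
  out$resname <- "ALA"
  structure_model(out)
}

# random-coil chain drawn from broadly allowed backbone torsions
fix_coil_model <- function(n_res = 30, seed = 1) {
  set.seed(seed)
  phi <- stats::runif(n_res, -160, -60)
  psi <- sample(c(stats::runif(ceiling(n_res / 2), -70, -20),
                  stats::runif(floor(n_res / 2), 100, 175)))[seq_len(n_res)]
  df <- build_chain(phi, psi)
  df$resname <- "ALA"
  structure_model(df)
}

# small shared toy crystal (memoized: building costs ~1 s)
fix_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_crystal(toy_crystal_spec(
        spacegroup = "P21", cell = c(34, 30, 38, 90, 105, 90),
        n_helices = 2, helix_len = 14, d_min = 2.5, seed = 3))
    }
    cache
  }
})

# three-helix toy crystal for verification fixtures
fix_toy3 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_crystal(toy_crystal_spec(
        spacegroup = "P21", cell = c(40, 34, 42, 90, 105, 90),
        n_helices = 3, helix_len = 14, d_min = 2.5, seed = 3))
    }
    cache
  }
})

# minimum cartesian distance between two fractional translations, modulo
# lattice, allowed origin shifts and polar axes
shift_distance <- function(t1, t2, refl) {
  osh <- allowed_origin_shifts(refl$spacegroup)
  d <- t1 - t2
  best <- Inf
  for (r in seq_len(nrow(osh$shifts))) {
    dd <- d - osh$shifts[r, ]
    dd[osh$polar_axes] <- 0
    dd <- dd - round(dd)
    best <- min(best, sqrt(sum(frac_to_cart(matrix(dd, 1), refl$cell)^2)))
  }
  best
}

# brute-force independent oracle for structure factors: expand to P1 and
# sum atom by atom (no vectorization shared with the implementation)
sf_oracle <- function(model, refl) {
  sg <- refl$sg
  frac <- cart_to_frac(as.matrix(model$atoms[, c("x", "y", "z")]), refl$cell)
  stol2 <- 1 / (4 * refl$d^2)
  fc <- rep(0 + 0i, nrow(refl$hkl))
  for (op in sg$ops) {
    for (j in seq_len(nrow(frac))) {
      x <- as.numeric(op$R %*% frac[j, ]) + op$v
      f <- fragphase:::form_factor(model$atoms$element[j], stol2) *
        model$atoms$occ[j] * exp(-model$atoms$b_iso[j] * stol2)
      fc <- fc + f * exp(2i * pi * as.numeric(refl$hkl %*% x))
    }
  }
  fc
}

# minimal mmCIF writer used only to exercise the mmCIF reading path
write_min_cif <- function(m, path) {
  at <- m$atoms
  lines <- c("data_fixture",
    sprintf("_cell.length_a %.3f", m$cell[1]),
    sprintf("_cell.length_b %.3f", m$cell[2]),
    sprintf("_cell.length_c %.3f", m$cell[3]),
    sprintf("_cell.angle_alpha %.2f", m$cell[4]),
    sprintf("_cell.angle_beta %.2f", m$cell[5]),
    sprintf("_cell.angle_gamma %.2f", m$cell[6]),
    sprintf("_symmetry.space_group_name_H-M '%s'", m$spacegroup),
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            seq_len(nrow(at)), at$element, at$name, at$resname, at$chain,
            at$resseq, at$x, at$y, at$z, at$occ, at$b_iso, at$resseq,
            at$resname, at$chain, at$name))
  writeLines(lines, path)
}
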