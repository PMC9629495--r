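# Synthetic toy crystals: known cell, symmetry and coordinates, with
# "observed" amplitudes computed from the truth structure and the true
# phases kept for scoring. Perturbation mimics predicted-model inputs:
# locally correlated coordinate error, disordered tails, confidence
# values in the B column and no cell card.

#' Specification of a toy crystal
#'
#' @param spacegroup supported Hermann-Mauguin symbol
#' @param cell numeric(6); chosen large enough to pack the contents
#' @param n_helices number of ideal helices in the asymmetric unit
#' @param helix_len residues per helix
#' @param d_min resolution limit for the synthetic data, Angstrom
#' @param seed integer seed; all placement noise derives from it
#' @return list of class `toy_spec`
#' @export
toy_crystal_spec <- function(spacegroup = "P21",
                             cell = c(34, 30, 38, 90, 105, 90),
                             n_helices = 2, helix_len = 14,
                             d_min = default_config()$d_min_general,
                             seed = 1) {
  structure(list(spacegroup = spacegroup, cell = cell,
                 n_helices = n_helices, helix_len = helix_len,
                 d_min = d_min, seed = seed), class = "toy_spec")
}

#' Build a toy crystal: truth structure plus synthetic observed data
#'
#' Ideal-geometry helices are placed at random orientations inside the
#' cell, rejecting placements that clash with their own symmetry images
#' (CA-CA below 3 Angstrom). Observed amplitudes are the exact moduli of
#' the truth structure factors; the true phases are stored for scoring.
#' Deterministic per seed.
#'
#' @param spec a [toy_crystal_spec()]
#' @return list: `truth` (an `xmodel` with cell card), `refl` (a
#'   `reflset` with `f_obs` and `phi_true`), `spec`
#' @export
make_toy_crystal <- function(spec = toy_crystal_spec()) {
  set.seed(spec$seed)
  sg <- sg_ops(spec$spacegroup)
  placed <- list()
  for (hx in seq_len(spec$n_helices)) {
    ok <- FALSE
    for (try in 1:200) {
      df <- build_helix(spec$helix_len)
      xyz <- as.matrix(df[, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, colMeans(xyz))
      xyz <- xyz %*% t(random_rotation())
      tfrac <- stats::runif(3, 0.15, 0.85)
      xyz <- sweep(xyz, 2, as.numeric(frac_to_cart(matrix(tfrac, 1), spec$cell)), "+")
      cand <- df
      cand$x <- xyz[, 1]; cand$y <- xyz[, 2]; cand$z <- xyz[, 3]
      cand$chain <- LETTERS[hx]
      if (!clashes_with_symmetry(rbind_placed(placed, cand), spec$cell, sg)) {
        placed[[hx]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not pack helix ", hx,
                  " without symmetry clashes; use a larger cell")
  }
  atoms <- rbind_placed(placed, NULL)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$b_iso <- 20
  truth <- structure_model(atoms, cell = spec$cell,
                           spacegroup = spec$spacegroup)
  refl <- generate_hkl(spec$cell, spec$spacegroup, spec$d_min)
  sf <- calc_structure_factors(truth, refl)
  refl$f_obs <- sf$f
  refl$i_obs <- sf$f^2
  refl$phi_true <- sf$phi
  list(truth = truth, refl = refl, spec = spec)
}

rbind_placed <- function(placed, extra) {
  parts <- c(placed, if (!is.null(extra)) list(extra))
  if (length(parts) == 0) return(NULL)
  do.call(rbind, parts)
}

# CA-CA clash check against own symmetry images (and lattice neighbours)
clashes_with_symmetry <- function(atoms, cell, sg, cutoff = 3) {
  ca <- as.matrix(atoms[atoms$name == "CA", c("x", "y", "z")])
  frac <- cart_to_frac(ca, cell)
  for (k in seq_along(sg$ops)) {
    op <- sg$ops[[k]]
    img <- sweep(frac %*% t(op$R), 2, op$v, "+")
    # minimum-image distances between the original and this image
    for (i in seq_len(nrow(frac))) {
      d <- sweep(img, 2, frac[i, ])
      d <- d - round(d)
      dc <- frac_to_cart(d, cell)
      dist <- sqrt(rowSums(dc^2))
      if (k == 1) dist[i] <- Inf  # identity: same atom
      excl <- if (k == 1) abs(seq_len(nrow(frac)) - i) <= 4 else FALSE
      if (any(dist < cutoff & !excl)) return(TRUE)
    }
  }
  FALSE
}

#' Perturbation specification for predicted-like models
#'
#' @param rmsd_target CA rmsd of the perturbed model, Angstrom
#' @param coil_tail_len residues of disordered tail appended (0 = none)
#' @param displaced_chain optional chain id displaced rigidly
#' @param displace_shift rigid shift of the displaced chain, Angstrom
#' @param seed integer seed
#' @return list of class `perturb_spec`
#' @export
perturb_spec <- function(rmsd_target = 0.8, coil_tail_len = 0,
                         displaced_chain = NULL, displace_shift = 8,
                         seed = 1) {
  stopifnot(rmsd_target >= 0)
  structure(list(rmsd_target = rmsd_target, coil_tail_len = coil_tail_len,
                 displaced_chain = displaced_chain,
                 displace_shift = displace_shift, seed = seed),
            class = "perturb_spec")
}

#' Perturb a truth structure into a predicted-like model
#'
#' Applies locally correlated coordinate noise (per-residue displacements
#' smoothed over a 5-residue window, scaled to the target CA rmsd), an
#' optional disordered coil tail, an optional rigid displacement of one
#' chain, fills the B column with pLDDT-like confidence values inversely
#' related to the local displacement, and removes the cell card.
#'
#' @param truth an `xmodel`
#' @param spec a [perturb_spec()]
#' @return an `xmodel` without cell card, confidence in the B column
#' @export
perturb_to_predicted <- function(truth, spec = perturb_spec()) {
  set.seed(spec$seed)
  at <- truth$atoms
  rt <- residue_table(truth)
  key <- residue_keys(truth)
  ridx <- match(key, rt$key)
  nres <- nrow(rt)
  disp <- matrix(stats::rnorm(nres * 3), nres, 3)
  # smooth per chain with a 5-residue moving average for local coherence
  for (ch in unique(rt$chain)) {
    i <- which(rt$chain == ch)
    if (length(i) >= 2) {
      for (j in 1:3) {
        disp[i, j] <- stats::filter(disp[i, j], rep(1 / 5, 5), sides = 2) |>
          (\(v) { v[is.na(v)] <- disp[i, j][is.na(v)]; v })()
      }
    }
  }
  if (spec$rmsd_target > 0 && nres > 0) {
    scale <- spec$rmsd_target / sqrt(mean(rowSums(disp^2)))
    disp <- disp * scale
  } else {
    disp <- disp * 0
  }
  xyz <- as.matrix(at[, c("x", "y", "z")]) + disp[ridx, , drop = FALSE]
  local_err <- sqrt(rowSums(disp^2))
  if (!is.null(spec$displaced_chain)) {
    shift <- unitv(stats::rnorm(3)) * spec$displace_shift
    sel <- at$chain == spec$displaced_chain
    xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, shift, "+")
    local_err[rt$chain == spec$displaced_chain] <-
      local_err[rt$chain == spec$displaced_chain] + spec$displace_shift
  }
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  conf <- pmin(99, pmax(20, 100 - 40 * local_err))
  at$b_iso <- conf[ridx]
  at$confidence <- conf[ridx]
  if (spec$coil_tail_len > 0) {
    at <- rbind(at, coil_tail(at, spec$coil_tail_len))
  }
  at$serial <- seq_len(nrow(at))
  structure_model(at, cell = NULL, spacegroup = NULL)
}

# append a random-coil tail to the C-terminus of the last chain
coil_tail <- function(at, len) {
  n <- len + 1
  phi <- stats::runif(n, -160, -60)
  psi <- ifelse(stats::runif(n) < 0.5, stats::runif(n, -80, -20),
                stats::runif(n, 90, 175))
  tail <- build_chain(phi, psi)
  last_chain <- at$chain[nrow(at)]
  last_res <- max(at$resseq[at$chain == last_chain])
  last_ca <- as.numeric(at[at$chain == last_chain & at$resseq == last_res &
                             at$name == "CA", c("x", "y", "z")][1, ])
  # drop the anchor residue and graft beyond the last CA
  tail <- tail[tail$resseq > 1, , drop = FALSE]
  txyz <- as.matrix(tail[, c("x", "y", "z")])
  txyz <- txyz %*% t(random_rotation())
  off <- last_ca + unitv(stats::rnorm(3)) * 4 - txyz[1, ]
  txyz <- sweep(txyz, 2, off, "+")
  data.frame(serial = 0, name = tail$name, element = tail$element,
             resname = "GLY", chain = last_chain,
             resseq = last_res + tail$resseq - 1, ins = "",
             x = txyz[, 1], y = txyz[, 2], z = txyz[, 3],
             occ = 1, b_iso = 25, confidence = 25,
             stringsAsFactors = FALSE)
}

#' CA rmsd between two models with identical residue sets (no fitting)
#' @param a,b `xmodel` objects
#' @return rmsd in Angstrom over shared CA atoms
#' @export
ca_rmsd <- function(a, b) {
  ka <- paste(residue_keys(a), a$atoms$name)
  kb <- paste(residue_keys(b), b$atoms$name)
  sel <- a$atoms$name == "CA" & ka %in% kb
  xa <- as.matrix(a$atoms[sel, c("x", "y", "z")])
  xb <- as.matrix(b$atoms[match(ka[sel], kb), c("x", "y", "z")])
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Random phase set respecting centric restrictions
#'
#' Acentric reflections get phases uniform on [0, 360); centric ones draw
#' from their two allowed values. Weights are the observed amplitudes.
#'
#' @param refl a `reflset` with `f_obs`
#' @param seed integer seed
#' @return a `phaseset`
#' @export
make_random_phase_set <- function(refl, seed = 1) {
  set.seed(seed)
  n <- n_refl(refl)
  phi <- stats::runif(n, 0, 360)
  cen <- refl$centric
  phi[cen] <- (refl$phase0[cen] +
                 180 * (stats::runif(sum(cen)) < 0.5)) %% 360
  phase_set(phi, weights = refl$f_obs %||% rep(1, n), label = paste0("random", seed))
}

#' True-phase reference as a phase set
#' @param refl a `reflset` carrying `phi_true`
#' @export
true_phase_set <- function(refl) {
  if (is.null(refl$phi_true)) stop("reflection set has no reference phases")
  phase_set(refl$phi_true, weights = refl$f_obs %||% rep(1, n_refl(refl)),
            label = "truth")
}

#' Synthetic expansion backend
#'
#' Stands in for the external density-modification/autotracing program in
#' tests and demos. Its contract mirrors the real behaviour: a starting
#' phase set close enough to the truth (weighted mean phase error below
#' `expand_threshold`, default 75 degrees) "expands" into a trace built
#' from truth atoms strictly outside the supplied mask, with coverage
#' increasing as the starting phases improve; an incorrect starting
#' hypothesis impedes expansion and yields an empty trace.
#'
#' @param truth the truth `xmodel` (test harness only)
#' @param expand_threshold degrees; starting sets worse than this fail
#' @return a backend function `(start, mask, refl) -> list(trace, phases,
#'   cc, expanded)` usable with [run_verification()]
#' @export
synthetic_backend <- function(truth,
                              expand_threshold = default_config()$expand_threshold) {
  force(truth)
  function(start, mask, refl) {
    truth_phases <- true_phase_set(refl)
    wmpe <- wmpd(start, truth_phases, refl)
    if (wmpe >= expand_threshold) {
      return(list(trace = NULL, phases = NULL, cc = 0, expanded = FALSE,
                  start_wmpe = wmpe))
    }
    frac_keep <- 0.3 + 0.7 * (1 - wmpe / expand_threshold)
    outside <- filter_trace_outside_mask(truth, mask)
    rt <- residue_table(outside)
    if (nrow(rt) == 0) {
      return(list(trace = NULL, phases = NULL, cc = 0, expanded = FALSE,
                  start_wmpe = wmpe))
    }
    keep_n <- max(1, round(nrow(rt) * frac_keep))
    # deterministic but label-dependent subsample, so different seeds
    # trace different (overlapping) parts and combination gains coverage
    off <- sum(utf8ToInt(paste0("x", start$label))) %% nrow(rt)
    idx <- sort(unique((round(seq(0, nrow(rt) - 1,
                                  length.out = keep_n)) + off) %% nrow(rt)) + 1)
    trace <- subset_residues(outside, rt$key[idx])
    sf <- calc_structure_factors(trace, refl)
    refl_n <- normalize_E(refl)
    cc <- cc_normalized(refl_n$e_obs, e_from_f(sf$f, refl))
    list(trace = trace,
         phases = phase_set(sf$phi, weights = rep(1, n_refl(refl)),
                            label = "trace"),
         cc = cc, expanded = TRUE, start_wmpe = wmpe)
  }
}
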