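# Model-free verification of molecular-replacement solutions, and the
# multicopy prioritization search.
#
# The verification driver shreds a placed solution into spheres, masks
# the region of the whole original model, asks the expansion backend to
# trace outside that region, keeps only out-of-mask traces, clusters the
# trace phase sets in reciprocal space and combines the consistent ones.
# Everything that contributes to the final phases comes from the traces:
# the starting model is eliminated from the pipeline state.

#' Verification configuration
#'
#' @param n_res residues per shredding sphere (NULL: sized by eLLG target)
#' @param max_spheres cap on the representative sphere selection
#' @param mask_radius Angstrom; dilation radius of the model-region mask
#' @param mask_spacing Angstrom; mask voxel size (default d_min / 4 at
#'   run time when NULL)
#' @param max_cycles backend iteration cycles on combined phases
#' @param cc_verified percentage CC threshold for blind-mode verdicts
#' @param scan_grid Angstrom; translation-scan step
#' @param top_n probes flagged for expansion in the multicopy search
#' @param n_copies expected copies in the asymmetric unit
#' @return list of class `verify_config`
#' @export
verify_config <- function(n_res = NULL, max_spheres = 24,
                          mask_radius = default_config()$mask_radius,
                          mask_spacing = NULL,
                          max_cycles = default_config()$max_cycles,
                          cc_verified = default_config()$cc_verified,
                          scan_grid = 1.5, top_n = 3, n_copies = 2) {
  structure(list(n_res = n_res, max_spheres = max_spheres,
                 mask_radius = mask_radius, mask_spacing = mask_spacing,
                 max_cycles = max_cycles, cc_verified = cc_verified,
                 scan_grid = scan_grid, top_n = top_n, n_copies = n_copies),
            class = "verify_config")
}

#' Shred a placed solution into covering spheres
#'
#' Candidate spheres of `n_res` residues are centred on every CA; a
#' greedy set cover selects at most `max_spheres` of them such that every
#' residue of the model lies in at least one selected sphere. A model
#' smaller than `n_res` yields a single whole-model fragment.
#'
#' @param model placed `xmodel` (cell card present)
#' @param n_res residues per sphere
#' @param max_spheres selection cap
#' @return list of fragments as in [generate_sphere_library()]
#' @export
shred_placed_solution <- function(model, n_res, max_spheres = 24) {
  rt <- residue_table(model)
  ca <- atom_per_residue(model, "CA")
  nres <- nrow(rt)
  if (nres <= n_res) {
    return(list(list(center = colMeans(ca, na.rm = TRUE),
                     center_res = rt$key[1], residues = rt$key,
                     n_res = nres, scattering = scattering_sum(model),
                     domain_id = 1L, connected = TRUE)))
  }
  centers <- which(stats::complete.cases(ca))
  members <- lapply(centers, function(ci) {
    d2 <- rowSums(sweep(ca, 2, ca[ci, ])^2)
    sort(order(d2)[seq_len(n_res)])
  })
  covered <- rep(FALSE, nres)
  chosen <- integer()
  while (!all(covered) && length(chosen) < max_spheres) {
    gain <- vapply(seq_along(members), function(i) {
      if (i %in% chosen) return(-1L)
      sum(!covered[members[[i]]])
    }, integer(1))
    best <- which.max(gain)
    if (gain[best] <= 0) break
    chosen <- c(chosen, best)
    covered[members[[best]]] <- TRUE
  }
  lapply(chosen, function(i) {
    sel <- members[[i]]
    keys <- rt$key[sel]
    list(center = ca[centers[i], ], center_res = rt$key[centers[i]],
         residues = keys, n_res = length(sel),
         scattering = scattering_sum(model, keys), domain_id = 1L,
         connected = TRUE)
  })
}

#' Build the symmetry-expanded mask of the model region
#'
#' A voxel over the unit cell is masked iff any symmetry image of any
#' model atom lies within `radius` of it, with periodic wrapping.
#'
#' @param model placed `xmodel`
#' @param refl a `reflset` supplying cell and symmetry
#' @param radius Angstrom (default 2.5)
#' @param spacing Angstrom voxel size
#' @return list of class `mask_volume`: `flags` (logical 3d array),
#'   `dims`, `radius`, `spacing`, `cell`
#' @export
build_model_mask <- function(model, refl,
                             radius = default_config()$mask_radius,
                             spacing = 1) {
  if (spacing <= 0) stop("mask spacing must be positive")
  cell <- refl$cell
  dims <- pmax(2L, as.integer(ceiling(cell[1:3] / spacing)))
  flags <- array(FALSE, dims)
  if (radius > 0) {
    frac <- cart_to_frac(as.matrix(model$atoms[, c("x", "y", "z")]), cell)
    imgs <- list()
    for (op in refl$sg$ops) {
      imgs[[length(imgs) + 1]] <- (sweep(frac %*% t(op$R), 2, op$v, "+")) %% 1
    }
    allfrac <- do.call(rbind, imgs)
    finv <- frac_matrix(cell)
    # conservative fractional half-widths of the dilation box per axis
    halfw <- radius * sqrt(rowSums(finv^2))
    orth <- orth_matrix(cell)
    for (a in seq_len(nrow(allfrac))) {
      fa <- allfrac[a, ]
      rng <- lapply(1:3, function(j) {
        lo <- floor((fa[j] - halfw[j]) * dims[j])
        hi <- ceiling((fa[j] + halfw[j]) * dims[j])
        lo:hi
      })
      vox <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
      fc <- sweep(vox + 0.5, 2, dims, "/")
      d <- sweep(fc, 2, fa)
      d <- d - round(d)
      dc <- d %*% t(orth)
      hit <- rowSums(dc^2) <= radius^2
      if (any(hit)) {
        idx <- vox[hit, , drop = FALSE] %% rep(dims, each = sum(hit)) + 1
        flags[idx] <- TRUE
      }
    }
  }
  structure(list(flags = flags, dims = dims, radius = radius,
                 spacing = spacing, cell = cell),
            class = "mask_volume")
}

#' Fraction of the unit cell covered by a mask
#' @param mask a `mask_volume`
#' @export
mask_fraction <- function(mask) mean(mask$flags)

# logical: is each cartesian point inside the mask?
points_in_mask <- function(xyz, mask) {
  frac <- cart_to_frac(xyz, mask$cell) %% 1
  idx <- floor(frac * rep(mask$dims, each = nrow(frac))) + 1
  idx <- pmin(idx, rep(mask$dims, each = nrow(frac)))
  mask$flags[idx]
}

#' Remove trace atoms that fall inside the masked model region
#'
#' @param trace an `xmodel` (CA-level traces acceptable)
#' @param mask a `mask_volume`
#' @return the filtered trace; attribute `inside_fraction` records the
#'   fraction of input atoms that were masked
#' @export
filter_trace_outside_mask <- function(trace, mask) {
  if (nrow(trace$atoms) == 0) return(trace)
  inside <- points_in_mask(as.matrix(trace$atoms[, c("x", "y", "z")]), mask)
  out <- trace
  out$atoms <- trace$atoms[!inside, , drop = FALSE]
  rownames(out$atoms) <- NULL
  attr(out, "inside_fraction") <- mean(inside)
  out
}

#' Translation scan of a rotated fragment against the data
#'
#' Scores every fractional translation on a cartesian grid of step
#' `grid` by the correlation coefficient between observed and calculated
#' normalized intensities (already-placed fixed copies contribute to the
#' calculated set). The translation z-score is standardized over the
#' scan.
#'
#' @param fragment an `xmodel` (coordinates at the rotated origin pose)
#' @param rotation 3x3 proper rotation applied to the fragment
#' @param refl a `reflset` with observed data
#' @param grid Angstrom step of the translation grid
#' @param fixed list of already-placed `xmodel` objects
#' @param refine_top number of top peaks refined off-grid by local
#'   pattern search (0 disables refinement)
#' @return data.frame sorted by score: tx, ty, tz (fractional), score
#'   (CC %), tfz (z-score over the scan)
#' @export
translation_scan <- function(fragment, rotation = diag(3), refl,
                             grid = 1.5, fixed = list(), refine_top = 40) {
  stopifnot(grid > 0, abs(det(rotation) - 1) < 1e-6)
  nt <- pmax(2L, as.integer(round(refl$cell[1:3] / grid)))
  if (any(nt < 8)) {
    warning("translation grid coarser than 8 points on at least one axis")
  }
  frag <- transform_model(fragment, rotation = rotation)
  at <- frag$atoms
  stol2 <- 1 / (4 * refl$d^2)
  elements <- toupper(at$element)
  uel <- unique(elements)
  fmat <- vapply(uel, function(e) form_factor(e, stol2),
                 numeric(length(stol2)))
  w <- fmat[, match(elements, uel), drop = FALSE] *
    exp(-outer(stol2, at$b_iso)) * rep(at$occ, each = length(stol2))
  frac <- cart_to_frac(as.matrix(at[, c("x", "y", "z")]), refl$cell)
  # per-op partial sums at t = 0, and the symmetry-rotated index sets
  aops <- list(); hrops <- list()
  for (op in refl$sg$ops) {
    xs <- sweep(frac %*% t(op$R), 2, op$v, "+")
    ph <- 2 * pi * (refl$hkl %*% t(xs))
    aops[[length(aops) + 1]] <- rowSums(w * exp(1i * ph))
    hrops[[length(hrops) + 1]] <- refl$hkl %*% op$R
  }
  f_fixed <- 0 + 0i
  for (fx in fixed) f_fixed <- f_fixed + calc_structure_factors(fx, refl)$fc
  tg <- as.matrix(expand.grid(tx = (0:(nt[1] - 1)) / nt[1],
                              ty = (0:(nt[2] - 1)) / nt[2],
                              tz = (0:(nt[3] - 1)) / nt[3]))
  refl_n <- normalize_E(refl)
  bins <- refl_n$bin
  bin_n <- as.vector(table(bins))
  nr <- n_refl(refl)
  e2_obs <- refl_n$e_obs^2
  score_grid <- function(tmat) {
    # chunked: the n_refl x n_trans complex matrix is built in slabs
    chunk <- max(16L, floor(4e6 / nr))
    cc <- numeric(nrow(tmat))
    for (c0 in seq(1, nrow(tmat), by = chunk)) {
      ix <- c0:min(nrow(tmat), c0 + chunk - 1)
      fc <- matrix(f_fixed, nr, length(ix))
      for (k in seq_along(aops)) {
        fc <- fc + aops[[k]] *
          exp(2i * pi * (hrops[[k]] %*% t(tmat[ix, , drop = FALSE])))
      }
      # binned E^2 of each candidate, correlated against observed E^2
      i_calc <- Mod(fc)^2
      binmeans <- rowsum(i_calc, bins) / bin_n
      e2 <- i_calc / binmeans[bins, , drop = FALSE]
      cc[ix] <- as.vector(stats::cor(e2_obs, e2)) * 100
    }
    cc
  }
  cc <- score_grid(tg)
  tfz <- (cc - mean(cc)) / stats::sd(cc)
  out <- data.frame(tx = tg[, 1], ty = tg[, 2], tz = tg[, 3],
                    score = cc, tfz = tfz)
  out <- out[order(-out$score), ]
  if (refine_top > 0) {
    # local pattern search around the best peaks recovers the score lost
    # to grid discretization before the final ranking; peaks are
    # deduplicated first (one candidate per distinct region, so a broad
    # or polar-degenerate top peak cannot exhaust the refinement budget)
    sel <- integer()
    min_sep <- 2.5 / nt
    # with no fixed copies the score is exactly invariant along polar
    # axes, so those components are ignored when spotting duplicates
    polar <- if (length(fixed) == 0) {
      allowed_origin_shifts(refl$spacegroup)$polar_axes
    } else rep(FALSE, 3)
    for (r in seq_len(nrow(out))) {
      if (length(sel) >= refine_top) break
      t_ <- as.numeric(out[r, c("tx", "ty", "tz")])
      dup <- FALSE
      for (s in sel) {
        d <- t_ - as.numeric(out[s, c("tx", "ty", "tz")])
        d <- abs(d - round(d))
        d[polar] <- 0
        if (all(d <= min_sep)) { dup <- TRUE; break }
      }
      if (!dup) sel <- c(sel, r)
    }
    out <- rbind(out[sel, , drop = FALSE],
                 out[-sel, , drop = FALSE])
    ntop <- length(sel)
    step0 <- 0.5 / nt
    for (r in seq_len(ntop)) {
      t_ <- as.numeric(out[r, c("tx", "ty", "tz")])
      best <- out$score[r]
      step <- step0
      for (it in 1:7) {
        nb <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1)))
        cand <- sweep(nb %*% diag(step), 2, t_, "+") %% 1
        sc <- score_grid(cand)
        if (max(sc) > best + 1e-9) {
          best <- max(sc)
          t_ <- cand[which.max(sc), ]
        } else {
          step <- step / 2
        }
      }
      out[r, c("tx", "ty", "tz")] <- t_
      out$score[r] <- best
    }
    out <- out[order(-out$score), ]
    out$tfz <- (out$score - mean(cc)) / stats::sd(cc)
  }
  out
}

#' Packing filter against fixed copies and their symmetry images
#'
#' Rejects a candidate placement when any of its CA atoms lies within
#' `clash_cutoff` of a CA of any fixed copy or of a symmetry image of a
#' fixed copy (minimum-image convention).
#'
#' @param candidate placed `xmodel`
#' @param fixed list of placed `xmodel` objects
#' @param refl a `reflset` (symmetry source)
#' @param clash_cutoff Angstrom (default 3.0)
#' @return TRUE (accepted) or FALSE (rejected)
#' @export
packing_filter <- function(candidate, fixed, refl,
                           clash_cutoff = default_config()$clash_cutoff) {
  ca_c <- candidate$atoms[candidate$atoms$name == "CA", c("x", "y", "z")]
  if (nrow(ca_c) == 0 || length(fixed) == 0) return(TRUE)
  fc <- cart_to_frac(as.matrix(ca_c), refl$cell)
  for (fx in fixed) {
    ca_f <- fx$atoms[fx$atoms$name == "CA", c("x", "y", "z")]
    if (nrow(ca_f) == 0) next
    ff <- cart_to_frac(as.matrix(ca_f), refl$cell)
    for (op in refl$sg$ops) {
      img <- sweep(ff %*% t(op$R), 2, op$v, "+")
      for (i in seq_len(nrow(fc))) {
        d <- sweep(img, 2, fc[i, ])
        d <- d - round(d)
        dc <- frac_to_cart(d, refl$cell)
        if (min(rowSums(dc^2)) < clash_cutoff^2) return(FALSE)
      }
    }
  }
  TRUE
}

# place a fragment: rotate about its centroid pose then shift so that its
# fractional translation becomes t
place_fragment <- function(fragment, rotation, t, cell) {
  m <- transform_model(fragment, rotation = rotation)
  shift <- as.numeric(frac_to_cart(matrix(t, 1), cell))
  transform_model(m, translation = shift)
}

#' Multicopy prioritization by a second-copy translation search
#'
#' For each first-copy probe, scans translations of a second copy with
#' the first fixed, applies the packing filter to the top of the scan and
#' records the best packing-valid second-copy score; probes are then
#' re-ranked by that score and the top `cfg$top_n` flagged for expansion.
#' With `cfg$n_copies` greater than 2 the scan-and-fix loop repeats until
#' all expected copies are placed per probe.
#'
#' @param first_copies list of probes, each `list(model, rotation, score,
#'   label)` with `model` a placed `xmodel`
#' @param fragment the search fragment (`xmodel`, origin pose)
#' @param refl a `reflset`
#' @param cfg a [verify_config()]
#' @return data.frame ranked by the last-copy score: label, first_score,
#'   second_score, rank, flagged; attribute `placements` holds per-probe
#'   lists of placed models
#' @export
prioritize_multicopy <- function(first_copies, fragment, refl,
                                 cfg = verify_config()) {
  stopifnot(length(first_copies) >= 1)
  n_probes <- length(first_copies)
  second <- rep(NA_real_, n_probes)
  placements <- vector("list", n_probes)
  any_valid <- FALSE
  for (p in seq_len(n_probes)) {
    probe <- first_copies[[p]]
    fixed <- list(probe$model)
    best_last <- NA_real_
    for (copy in 2:max(2, cfg$n_copies)) {
      scan <- translation_scan(fragment, rotation = probe$rotation %||% diag(3),
                               refl = refl, grid = cfg$scan_grid,
                               fixed = fixed)
      found <- FALSE
      for (r in seq_len(min(nrow(scan), 50))) {
        cand <- place_fragment(fragment, probe$rotation %||% diag(3),
                               as.numeric(scan[r, c("tx", "ty", "tz")]),
                               refl$cell)
        if (packing_filter(cand, fixed, refl)) {
          fixed <- c(fixed, list(cand))
          best_last <- scan$score[r]
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
    second[p] <- best_last
    placements[[p]] <- fixed
    if (!is.na(best_last)) any_valid <- TRUE
  }
  first_scores <- vapply(first_copies, function(x) x$score %||% NA_real_, 1)
  labels <- vapply(seq_len(n_probes), function(p) {
    first_copies[[p]]$label %||% paste0("probe", p)
  }, "")
  if (!any_valid) {
    warning("no packing-valid additional placement for any probe; ",
            "ranking by first-copy score")
    key <- first_scores
  } else {
    key <- second
  }
  o <- order(-ifelse(is.na(key), -Inf, key))
  out <- data.frame(label = labels[o], first_score = first_scores[o],
                    second_score = second[o], rank = seq_len(n_probes),
                    flagged = seq_len(n_probes) <= cfg$top_n,
                    stringsAsFactors = FALSE)
  attr(out, "placements") <- placements[o]
  out
}

#' Model-free verification of a placed solution
#'
#' Shreds the placed model into covering spheres; for each sphere,
#' computes its phases, masks the region of the FULL original model,
#' calls the expansion backend, filters the returned trace against the
#' mask and derives trace-only phases. Trace phase sets are clustered in
#' reciprocal space (priority by backend CC), the best cluster is
#' combined, and the backend is iterated on the combined phases for up to
#' `cfg$max_cycles` cycles. Fragments whose phases are at random level
#' yield empty traces, realizing the principle that an incorrect starting
#' hypothesis impedes expansion.
#'
#' @param solution placed `xmodel` (input recognized as a solution)
#' @param refl a `reflset` with observed data (and, in synthetic mode,
#'   `phi_true` for scoring)
#' @param backend an expansion backend function `(start, mask, refl) ->
#'   list(trace, phases, cc, expanded)`, e.g. [synthetic_backend()]
#' @param cfg a [verify_config()]
#' @return list of class `verification_report`: `fragments` (per-fragment
#'   table), `verdict`, `combined` (final `phaseset` or NULL),
#'   `combined_wmpe`, `n_clustered`, `mask_fraction`
#' @export
run_verification <- function(solution, refl, backend,
                             cfg = verify_config()) {
  n_res <- cfg$n_res
  if (is.null(n_res)) {
    n_res <- sphere_size_for_target(solution, refl)$n_res
  }
  frags <- shred_placed_solution(solution, n_res, cfg$max_spheres)
  spacing <- cfg$mask_spacing %||% (min(refl$d) / 4)
  mask <- build_model_mask(solution, refl, radius = cfg$mask_radius,
                           spacing = spacing)
  have_truth <- !is.null(refl$phi_true)
  truth_phases <- if (have_truth) true_phase_set(refl) else NULL
  rows <- list(); traces <- list(); trace_phases <- list()
  for (i in seq_along(frags)) {
    fm <- fragment_model(solution, frags[[i]])
    res <- tryCatch({
      sf <- calc_structure_factors(fm, refl)
      start <- phase_set(sf$phi, weights = rep(1, n_refl(refl)),
                         label = paste0("frag", i))
      bk <- backend(start, mask, refl)
      trace <- bk$trace
      n_in <- 0
      if (!is.null(trace) && nrow(trace$atoms) > 0) {
        trace <- filter_trace_outside_mask(trace, mask)
        n_in <- sum(points_in_mask(
          as.matrix(trace$atoms[, c("x", "y", "z")]), mask))
        stopifnot(n_in == 0)  # model-freedom guarantee
      }
      tp <- NULL; t_wmpe <- NA_real_
      if (!is.null(trace) && nrow(trace$atoms) > 0) {
        tsf <- calc_structure_factors(trace, refl)
        tp <- phase_set(tsf$phi, weights = rep(1, n_refl(refl)),
                        label = paste0("trace", i))
        if (have_truth) t_wmpe <- wmpd(tp, truth_phases, refl)
      }
      s_wmpe <- if (have_truth) wmpd(start, truth_phases, refl) else NA_real_
      ok_trace <- !is.null(tp)
      verdict <- ok_trace && ((have_truth && is_nonrandom(t_wmpe)) ||
                                (!have_truth && bk$cc > cfg$cc_verified))
      list(row = data.frame(fragment = i, n_res = frags[[i]]$n_res,
                            start_wmpe = s_wmpe, trace_wmpe = t_wmpe,
                            cc = bk$cc, n_trace_atoms = if (ok_trace)
                              nrow(trace$atoms) else 0L,
                            verified = verdict),
           trace = if (ok_trace) trace else NULL,
           phases = tp)
    }, error = function(e) {
      list(row = data.frame(fragment = i, n_res = frags[[i]]$n_res,
                            start_wmpe = NA_real_, trace_wmpe = NA_real_,
                            cc = NA_real_, n_trace_atoms = 0L,
                            verified = FALSE),
           trace = NULL, phases = NULL)
    })
    rows[[i]] <- res$row
    traces[[i]] <- res$trace
    trace_phases[[i]] <- res$phases
  }
  ftab <- do.call(rbind, rows)
  good <- which(!vapply(trace_phases, is.null, logical(1)))
  combined <- NULL; combined_wmpe <- NA_real_; n_clustered <- 0L
  if (length(good) > 0) {
    # cluster in backend-CC priority order
    pri <- good[order(-ftab$cc[good])]
    clusters <- cluster_phase_sets(trace_phases[pri], refl)
    sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
    best <- clusters[[which.max(sizes)]]
    combined <- best$combined
    n_clustered <- max(sizes)
    # iterate the backend on the combined phases
    for (cyc in seq_len(cfg$max_cycles)) {
      bk <- backend(combined, mask, refl)
      if (is.null(bk$phases)) break
      trace <- filter_trace_outside_mask(bk$trace, mask)
      if (nrow(trace$atoms) == 0) break
      tsf <- calc_structure_factors(trace, refl)
      combined <- phase_set(tsf$phi, weights = rep(1, n_refl(refl)),
                            label = sprintf("cycle%d", cyc))
    }
    if (have_truth) combined_wmpe <- wmpd(combined, truth_phases, refl)
  }
  overall <- if (have_truth) {
    !is.null(combined) && is_nonrandom(combined_wmpe)
  } else {
    any(ftab$verified)
  }
  structure(list(fragments = ftab,
                 verdict = if (overall) "verified" else "not-verified",
                 combined = combined, combined_wmpe = combined_wmpe,
                 n_clustered = n_clustered,
                 mask_fraction = mask_fraction(mask)),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("verification:", x$verdict, "|", nrow(x$fragments), "fragments,",
      sum(x$fragments$verified), "verified,", x$n_clustered,
      "traces clustered")
  if (!is.na(x$combined_wmpe)) {
    cat(sprintf(", combined wMPE %.1f deg", x$combined_wmpe))
  }
  cat("\n")
  invisible(x)
}
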