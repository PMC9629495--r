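# Expected-LLG fragment sizing and the spherical fragment library.
#
# The expected log-likelihood gain of a partial model is predicted from
# its scattering fraction f_m and the assumed coordinate error, through a
# Luzzati-type sigmaA curve:
#   sigmaA(s) = sqrt(f_m) * exp(-(8 pi^2 / 3) * rmsd^2 * s^2)   s = 1/(2d)
#   eLLG      = sum over reflections of sigmaA^4 / 2
# The default target of 60 defines the sphere size; when the template
# cannot support it the achieved value is reported as lowered.

#' Expected LLG of a partial model
#'
#' @param f_m scattering fraction of the fragment, in [0, 1]
#' @param params an [ellg_params()]
#' @param refl a `reflset` supplying the resolution distribution
#' @return dimensionless expected LLG (0 when `f_m` is 0); strictly
#'   increasing in `f_m`, decreasing in the rmsd estimate
#' @export
estimate_ellg <- function(f_m, params, refl) {
  if (f_m < 0 || f_m > 1) stop("scattering fraction must lie in [0, 1]")
  if (n_refl(refl) == 0) stop("empty reflection set")
  stol2 <- 1 / (4 * refl$d^2)
  sigma_a2 <- f_m * exp(-2 * (8 * pi^2 / 3) * params$rmsd_est^2 * stol2)
  sum(sigma_a2^2) / 2
}

#' Sphere size (residue count) reaching the eLLG target
#'
#' Scans fragment sizes assuming scattering proportional to residue
#' count and returns the smallest count whose expected LLG reaches the
#' target. When even the whole model falls short, the model size is
#' returned and the achieved (lowered) target recorded.
#'
#' @param model prepared `xmodel`
#' @param refl a `reflset`
#' @param params an [ellg_params()]
#' @return list: `n_res`, `achieved_ellg`, `lowered` (logical)
#' @export
sphere_size_for_target <- function(model, refl, params = ellg_params()) {
  n_total <- n_residues(model)
  full <- estimate_ellg(1, params, refl)
  per <- function(n) estimate_ellg(n / n_total, params, refl)
  if (per(n_total) < params$ellg_target) {
    return(list(n_res = n_total, achieved_ellg = per(n_total),
                lowered = TRUE))
  }
  # eLLG is monotone in n: binary search for the smallest sufficient n
  lo <- 1L; hi <- n_total
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (per(mid) >= params$ellg_target) hi <- mid else lo <- mid + 1L
  }
  list(n_res = lo, achieved_ellg = per(lo), lowered = FALSE)
}

#' Generate the spherical fragment library
#'
#' One candidate sphere per (sub-sampled) CA position: the `n_res`
#' residues nearest the centre, drawn only from the centre's domain so
#' that domains stay segregated. Candidates with disjoint regions (not a
#' single component in the 5-Angstrom CA graph, sequence-adjacent
#' residues always connected) or with large voids (occupied-volume
#' fraction inside the bounding sphere below the shipped threshold) are
#' removed.
#'
#' @param model prepared `xmodel`
#' @param partition a `domain_partition` of the same model
#' @param n_res residues per fragment
#' @param max_fragments cap on library size (centres sub-sampled evenly)
#' @return list of fragments; each has `center`, `center_res`, `residues`
#'   (keys), `n_res`, `scattering`, `domain_id`, `connected`, `ellg`
#' @export
generate_sphere_library <- function(model, partition, n_res,
                                    max_fragments = default_config()$max_fragments,
                                    params = ellg_params(), refl = NULL) {
  cfg <- default_config()
  rt <- residue_table(model)
  ca <- atom_per_residue(model, "CA")
  nres_tot <- nrow(rt)
  dom <- partition$residue_domain
  if (n_res > nres_tot) stop("n_res exceeds model size")
  centers <- which(!is.na(dom) & stats::complete.cases(ca))
  stride <- max(1L, ceiling(length(centers) / max_fragments))
  centers <- centers[seq(1, length(centers), by = stride)]
  total_scatt <- scattering_sum(model)
  frags <- list()
  for (ci in centers) {
    same_dom <- which(dom == dom[ci] & stats::complete.cases(ca))
    d2 <- rowSums(sweep(ca[same_dom, , drop = FALSE], 2, ca[ci, ])^2)
    k <- min(n_res, length(same_dom))
    sel <- same_dom[order(d2)[seq_len(k)]]
    sel <- sort(sel)
    if (!fragment_connected(sel, rt, ca, cfg$connect_dist)) next
    if (fragment_void_fraction(model, rt$key[sel], ca[ci, ]) <
        cfg$void_fraction_min) next
    keys <- rt$key[sel]
    scatt <- scattering_sum(model, keys)
    frag <- list(center = ca[ci, ], center_res = rt$key[ci],
                 residues = keys, n_res = length(sel),
                 scattering = scatt, domain_id = dom[ci], connected = TRUE,
                 ellg = if (!is.null(refl)) {
                   estimate_ellg(scatt / total_scatt, params, refl)
                 } else NA_real_)
    frags[[length(frags) + 1]] <- frag
  }
  # deduplicate identical residue sets (neighbouring centres often agree)
  sig <- vapply(frags, function(f) paste(f$residues, collapse = ","), "")
  frags[!duplicated(sig)]
}

# single connected component in the CA graph (edges: sequence neighbours
# within the selection, or CA-CA distance <= cutoff)
fragment_connected <- function(sel, rt, ca, cutoff) {
  n <- length(sel)
  if (n <= 1) return(TRUE)
  a <- ca[sel, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(a^2), "+") - 2 * a %*% t(a)
  adj <- d2 <= cutoff^2
  # BFS
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# occupied-volume fraction of a fragment inside its bounding sphere:
# grid at 1 A spacing, atoms dilated by 2.5 A
fragment_void_fraction <- function(model, keys, center, dilate = 2.5,
                                   spacing = 1) {
  at <- model$atoms[residue_keys(model) %in% keys, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rmax <- sqrt(max(rowSums(sweep(xyz, 2, center)^2))) + dilate
  ax <- seq(center[1] - rmax, center[1] + rmax, by = spacing)
  ay <- seq(center[2] - rmax, center[2] + rmax, by = spacing)
  az <- seq(center[3] - rmax, center[3] + rmax, by = spacing)
  grid <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  inside <- rowSums(sweep(grid, 2, center)^2) <= rmax^2
  grid <- grid[inside, , drop = FALSE]
  occupied <- rep(FALSE, nrow(grid))
  d2lim <- dilate^2
  for (j in seq_len(nrow(xyz))) {
    occupied <- occupied | (rowSums(sweep(grid, 2, xyz[j, ])^2) <= d2lim)
  }
  mean(occupied)
}

#' Extract a fragment as a stand-alone structure model
#' @param model the parent `xmodel`
#' @param fragment one element of [generate_sphere_library()]'s output
#' @return an `xmodel` restricted to the fragment's residues
#' @export
fragment_model <- function(model, fragment) {
  subset_residues(model, fragment$residues)
}
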