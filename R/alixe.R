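# Reciprocal-space phase combination: origin-shift alignment, greedy
# clustering by aligned weighted mean phase difference, and coherent
# phasor averaging of cluster members.

#' Shift the origin of a phase set
#'
#' An allowed origin shift `t` changes each phase by -360 (h . t) degrees
#' and leaves amplitudes untouched.
#'
#' @param p a `phaseset`
#' @param refl the matching `reflset`
#' @param t fractional 3-vector
#' @return the shifted `phaseset` (shift recorded in `origin_shift`)
#' @export
apply_origin_shift <- function(p, refl, t) {
  stopifnot(length(p$phi) == n_refl(refl))
  out <- p
  out$phi <- (p$phi - 360 * as.numeric(refl$hkl %*% t)) %% 360
  out$origin_shift <- (p$origin_shift + t) %% 1
  out
}

#' Align one phase set onto another over the allowed origin shifts
#'
#' Minimizes the weighted mean phase difference of `q` against `p` over
#' the discrete allowed shifts of the space group, combined with a grid
#' search (1/`polar_grid` steps) plus golden-section refinement along any
#' polar axes. Ties break to the lexicographically smallest shift.
#'
#' @param p,q `phaseset` objects on the same `reflset`
#' @param refl the common `reflset`
#' @return list: `shift` (fractional 3-vector), `wmpd` (aligned, degrees),
#'   `aligned` (the shifted copy of `q`)
#' @export
align_phase_sets <- function(p, q, refl) {
  cfg <- default_config()
  osh <- allowed_origin_shifts(refl$spacegroup)
  polar <- osh$polar_axes
  score <- function(t) wmpd(p, apply_origin_shift(q, refl, t), refl)
  best <- NULL
  for (r in seq_len(nrow(osh$shifts))) {
    base <- osh$shifts[r, ]
    t <- base
    if (any(polar)) {
      # coarse grid on the polar axes, then golden-section refinement;
      # with several polar axes the grid is coarsened to keep the search
      # tractable and the refinement recovers the precision
      steps <- if (sum(polar) == 1) cfg$polar_grid else 12
      g <- (0:(steps - 1)) / steps
      ax <- lapply(1:3, function(j) if (polar[j]) g else base[j])
      cand <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
      sc <- apply(cand, 1, score)
      t <- cand[which.min(sc), ]
      for (pass in 1:2) {
        for (j in which(polar)) {
          t[j] <- golden_refine(function(v) {
            tt <- t; tt[j] <- v %% 1; score(tt)
          }, t[j] - 1 / steps, t[j] + 1 / steps)
        }
      }
      t <- t %% 1
    }
    s <- score(t)
    if (is.null(best) || s < best$wmpd - 1e-12 ||
        (abs(s - best$wmpd) <= 1e-12 && lex_less(t, best$shift))) {
      best <- list(shift = t, wmpd = s)
    }
  }
  best$aligned <- apply_origin_shift(q, refl, best$shift)
  best
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

golden_refine <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc < fd) { b <- d; d <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
  }
  (a + b) / 2
}

#' Greedy clustering of phase sets by aligned phase difference
#'
#' The first (caller-priority) unassigned set seeds a cluster; every
#' remaining set whose aligned weighted mean phase difference against the
#' seed is at most `tol` joins, carrying its aligning origin shift.
#' Remaining sets seed further clusters; unmatched sets end up as
#' singletons.
#'
#' @param sets list of `phaseset` objects, in decreasing prior quality
#' @param refl the common `reflset`
#' @param tol join threshold in degrees (default 60)
#' @return list of clusters; each has `members` (indices), `labels`,
#'   `shifts` (matrix), `wmpd_to_seed`, `combined` (a `phaseset`),
#'   `internal_wmpd` (matrix over members after alignment)
#' @export
cluster_phase_sets <- function(sets, refl, tol = default_config()$cluster_tol) {
  stopifnot(length(sets) >= 1)
  unassigned <- seq_along(sets)
  clusters <- list()
  while (length(unassigned) > 0) {
    seed <- unassigned[1]
    members <- seed
    shifts <- matrix(0, 1, 3)
    aligned <- list(sets[[seed]])
    wm <- 0
    for (i in setdiff(unassigned, seed)) {
      al <- align_phase_sets(sets[[seed]], sets[[i]], refl)
      if (al$wmpd <= tol) {
        members <- c(members, i)
        shifts <- rbind(shifts, al$shift)
        aligned <- c(aligned, list(al$aligned))
        wm <- c(wm, al$wmpd)
      }
    }
    nm <- length(members)
    internal <- matrix(0, nm, nm)
    if (nm > 1) {
      for (a in 1:(nm - 1)) for (b in (a + 1):nm) {
        internal[a, b] <- internal[b, a] <- wmpd(aligned[[a]], aligned[[b]], refl)
      }
    }
    combined <- if (nm > 1) combine_cluster(aligned, refl) else aligned[[1]]
    clusters[[length(clusters) + 1]] <- list(
      members = members,
      labels = vapply(sets[members], function(s) s$label, ""),
      shifts = shifts, wmpd_to_seed = wm, combined = combined,
      internal_wmpd = internal)
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

#' Combine aligned phase sets by weighted phasor averaging
#'
#' Per reflection, the combined phase is the argument of the weighted
#' phasor sum and the combined weight its coherence
#' |sum w e^(i phi)| / sum w, in [0, 1] (0 where members cancel, flagged
#' as undefined).
#'
#' @param members list of `phaseset` objects already on a common origin
#' @param refl the common `reflset`
#' @return a `phaseset` with coherence weights; attribute `undefined`
#'   marks reflections with zero combined weight
#' @export
combine_cluster <- function(members, refl) {
  stopifnot(length(members) >= 1)
  n <- length(members[[1]]$phi)
  z <- complex(real = rep(0, n), imaginary = rep(0, n))
  wtot <- rep(0, n)
  for (m in members) {
    z <- z + m$w * exp(1i * m$phi * pi / 180)
    wtot <- wtot + m$w
  }
  coher <- ifelse(wtot > 0, Mod(z) / wtot, 0)
  undef <- coher < 1e-9
  phi <- (Arg(z) * 180 / pi) %% 360
  phi[undef] <- 0
  out <- phase_set(phi, coher, label = paste0("combined(",
                                              length(members), ")"))
  attr(out, "undefined") <- undef
  out
}
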