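# Reciprocal-space core: reflection generation, direct-summation structure
# factors with tabulated atomic form factors, E-value normalization and the
# figures of merit used for decision making (CC on normalized intensities,
# weighted mean phase difference, map correlation in reciprocal space).

# Cromer-Mann 4-Gaussian + constant form-factor coefficients
.ff_table <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

# atomic numbers for scattering-mass bookkeeping (sum of Z^2)
.z_table <- c(H = 1, C = 6, N = 7, O = 8, S = 16)

# scattering factor of an element at sin(theta)/lambda^2 values
form_factor <- function(element, stol2) {
  ff <- .ff_table[[toupper(element)]]
  if (is.null(ff)) {
    stop("no form factor tabulated for element '", element,
         "'; available: ", paste(names(.ff_table), collapse = ", "))
  }
  out <- rep(ff$c, length(stol2))
  for (i in 1:4) out <- out + ff$a[i] * exp(-ff$b[i] * stol2)
  out
}

#' Construct a reflection set
#'
#' Low-level constructor; most users will call [generate_hkl()].
#'
#' @param hkl integer matrix (n x 3)
#' @param cell numeric(6)
#' @param spacegroup Hermann-Mauguin symbol
#' @param f_obs,sigma,phi_true optional per-reflection columns
#' @return object of class `reflset`
#' @export
reflection_set <- function(hkl, cell, spacegroup, f_obs = NULL,
                           sigma = NULL, phi_true = NULL) {
  hkl <- as.matrix(hkl)
  dimnames(hkl) <- NULL
  storage.mode(hkl) <- "double"
  sg <- sg_ops(spacegroup)
  ci <- centric_info(hkl, sg)
  r <- list(
    hkl = hkl, cell = cell, spacegroup = sg$symbol, sg = sg,
    d = d_spacing(hkl, cell),
    f_obs = f_obs, i_obs = if (!is.null(f_obs)) f_obs^2 else NULL,
    sigma = sigma, e_obs = NULL, phi_true = phi_true,
    centric = ci$centric, phase0 = ci$phase0
  )
  class(r) <- "reflset"
  r
}

#' @export
print.reflset <- function(x, ...) {
  cat("reflset:", nrow(x$hkl), "unique reflections,", x$spacegroup,
      sprintf("cell %.2f %.2f %.2f %.1f %.1f %.1f", x$cell[1], x$cell[2],
              x$cell[3], x$cell[4], x$cell[5], x$cell[6]),
      sprintf("d %.2f-%.2f A\n", max(x$d), min(x$d)))
  invisible(x)
}

#' Number of reflections in a reflection set
#' @param refl a `reflset`
#' @export
n_refl <- function(refl) nrow(refl$hkl)

#' Generate all symmetry-unique reflections to a resolution limit
#'
#' Enumerates Miller indices inside the resolution sphere, removes (0,0,0),
#' systematic absences and symmetry/Friedel duplicates.
#'
#' @param cell numeric(6)
#' @param spacegroup Hermann-Mauguin symbol (supported set, see [sg_ops()])
#' @param d_min high-resolution limit, Angstrom
#' @return a `reflset` (without observed data)
#' @export
generate_hkl <- function(cell, spacegroup, d_min) {
  stopifnot(d_min > 0)
  sg <- sg_ops(spacegroup)
  gstar <- solve(cell_metric(cell))
  lim <- vapply(1:3, function(j) floor(1 / (d_min * sqrt(gstar[j, j]))), 0)
  grid <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  hkl <- as.matrix(grid)
  dimnames(hkl) <- NULL
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  d <- d_spacing(hkl, cell)
  hkl <- hkl[d >= d_min - 1e-9, , drop = FALSE]
  hkl <- canonical_hkl(hkl, sg)
  hkl <- unique(hkl)
  hkl <- hkl[!systematic_absent(hkl, sg), , drop = FALSE]
  d <- d_spacing(hkl, cell)
  o <- order(-d, hkl[, 1], hkl[, 2], hkl[, 3])
  reflection_set(hkl[o, , drop = FALSE], cell, spacegroup)
}

#' Structure factors by direct summation
#'
#' F(h) = sum over symmetry copies and atoms of
#' f_el(s) occ exp(-B s^2/4) exp(2 pi i h.(Rx + v)), with tabulated
#' form factors and isotropic B.
#'
#' @param model a structure model (see [read_structure()])
#' @param refl a `reflset`; its cell/symmetry define the summation
#' @return list with `f` (amplitudes), `phi` (phases, degrees in [0, 360)),
#'   and `fc` (complex structure factors)
#' @export
calc_structure_factors <- function(model, refl) {
  at <- model$atoms
  if (nrow(at) == 0) stop("empty model")
  stol2 <- 1 / (4 * refl$d^2)          # (sin theta / lambda)^2
  elements <- toupper(at$element)
  uel <- unique(elements)
  fmat <- vapply(uel, function(e) form_factor(e, stol2),
                 numeric(length(stol2)))    # n_refl x n_el
  fidx <- match(elements, uel)
  # per-atom resolution-dependent weight: f_el(s) * occ * exp(-B stol2)
  damp <- exp(-outer(stol2, at$b_iso))      # n_refl x n_atoms
  w <- fmat[, fidx, drop = FALSE] * damp * rep(at$occ, each = length(stol2))
  frac <- cart_to_frac(as.matrix(at[, c("x", "y", "z")]), refl$cell)
  fc <- complex(real = numeric(n_refl(refl)), imaginary = 0)
  for (op in refl$sg$ops) {
    xs <- frac %*% t(op$R)
    xs <- sweep(xs, 2, op$v, "+")
    ph <- 2 * pi * (refl$hkl %*% t(xs))     # n_refl x n_atoms
    fc <- fc + rowSums(w * exp(1i * ph))
  }
  list(f = Mod(fc), phi = (Arg(fc) * 180 / pi) %% 360, fc = fc)
}

#' Normalize intensities to E-values in equal-count resolution bins
#'
#' E^2(h) = I(h) / <I> within its resolution bin, so that <E^2> = 1 per bin.
#'
#' @param refl `reflset` with `i_obs` (or `f_obs`) present
#' @param n_bins number of resolution bins (equal reflection count)
#' @return the `reflset` with `e_obs` filled in
#' @export
normalize_E <- function(refl, n_bins = 10) {
  i_obs <- refl$i_obs
  if (is.null(i_obs)) {
    if (is.null(refl$f_obs)) stop("no intensities or amplitudes to normalize")
    i_obs <- refl$f_obs^2
  }
  n <- length(i_obs)
  n_bins <- max(1, min(n_bins, floor(n / 2)))
  o <- order(refl$d, decreasing = TRUE)
  bin <- integer(n)
  bin[o] <- ceiling(seq_along(o) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  mean_i <- tapply(i_obs, bin, mean)
  # guard: a degenerate (all-zero) bin is merged into the global mean
  mean_i[mean_i <= 0] <- mean(i_obs[i_obs > 0])
  e2 <- i_obs / mean_i[bin]
  refl$e_obs <- as.numeric(sqrt(e2))
  refl$bin <- bin
  refl
}

# E-values for an arbitrary amplitude vector using the same binning
e_from_f <- function(f, refl, n_bins = 10) {
  tmp <- refl
  tmp$f_obs <- f
  tmp$i_obs <- f^2
  normalize_E(tmp, n_bins)$e_obs
}

#' Correlation coefficient between observed and calculated normalized
#' intensities
#'
#' 100 x Pearson correlation of E_obs^2 against E_calc^2; the statistic is
#' invariant under positive affine transformations of either argument and
#' symmetric in the two.
#'
#' @param e_obs,e_calc normalized amplitudes (E-values)
#' @return CC on the percentage scale
#' @export
cc_normalized <- function(e_obs, e_calc) {
  stopifnot(length(e_obs) == length(e_calc), length(e_obs) >= 3)
  x <- e_obs^2; y <- e_calc^2
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined CC: zero variance in normalized intensities")
  }
  100 * stats::cor(x, y)
}

#' Construct a phase set
#' @param phi phases in degrees (wrapped into [0, 360))
#' @param weights non-negative per-reflection weights (figure of merit or
#'   amplitude); default 1
#' @param label provenance string
#' @return object of class `phaseset`
#' @export
phase_set <- function(phi, weights = rep(1, length(phi)), label = "") {
  stopifnot(length(weights) == length(phi), all(weights >= 0))
  p <- list(phi = phi %% 360, w = weights, label = label,
            origin_shift = c(0, 0, 0))
  class(p) <- "phaseset"
  p
}

#' @export
print.phaseset <- function(x, ...) {
  cat("phaseset '", x$label, "': ", length(x$phi), " phases, mean fom ",
      sprintf("%.3f", mean(x$w / max(x$w, 1e-12))), "\n", sep = "")
  invisible(x)
}

# circular difference folded into [0, 180]
fold_phase_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Weighted mean phase difference between two phase sets
#'
#' Mean absolute circular phase difference, folded into [0, 180] degrees,
#' weighted by amplitude times the smaller of the two per-reflection
#' weights. Random uncorrelated phase sets score close to 90 degrees.
#'
#' @param p,q `phaseset` objects aligned to the same reflection set
#' @param refl the common `reflset` (supplies amplitude weights); optional
#' @return degrees in [0, 180]
#' @export
wmpd <- function(p, q, refl = NULL) {
  stopifnot(length(p$phi) == length(q$phi))
  w <- pmin(p$w, q$w)
  if (!is.null(refl) && !is.null(refl$f_obs)) w <- w * refl$f_obs
  if (sum(w) <= 0) stop("all-zero combined weights in wmpd")
  sum(w * fold_phase_diff(p$phi, q$phi)) / sum(w)
}

#' Map correlation coefficient in reciprocal space
#'
#' For two maps with Fourier amplitudes f1, f2 and phases p, q:
#' sum(f1 f2 cos(dphi)) / sqrt(sum(f1^2) sum(f2^2)).
#'
#' @param f1 amplitudes of the first map
#' @param p,q `phaseset` objects
#' @param f2 amplitudes of the second map (default `f1`: both maps share
#'   the observed amplitudes)
#' @return value in [-1, 1]
#' @export
mapcc <- function(f1, p, q, f2 = f1) {
  stopifnot(length(f1) == length(p$phi), length(p$phi) == length(q$phi))
  if (length(f1) == 0) stop("empty input to mapcc")
  dphi <- (p$phi - q$phi) * pi / 180
  sum(f1 * f2 * cos(dphi)) / sqrt(sum(f1^2) * sum(f2^2))
}

#' Nonrandom-solution rule on the weighted mean phase error
#'
#' A phase set is regarded as a nonrandom solution when its weighted mean
#' phase error against the true phases is strictly below 80 degrees
#' (random phases score about 90 degrees).
#'
#' @param wmpe weighted mean phase error, degrees in [0, 180]
#' @return logical
#' @export
is_nonrandom <- function(wmpe) {
  stopifnot(wmpe >= 0, wmpe <= 180)
  wmpe < default_config()$wmpe_nonrandom
}

#' Classify an input model as a placed solution or an unplaced model
#'
#' A model is regarded as a previously placed molecular-replacement
#' solution when (i) it carries a cell card coincident with the
#' experimental data and (ii) the correlation coefficient between the
#' intensities calculated from the model and the observed intensities
#' exceeds the classification threshold (default 25%). Otherwise it is
#' treated as an unplaced search model.
#'
#' @param model a structure model
#' @param refl a `reflset` carrying observed amplitudes
#' @param cc_threshold CC boundary on the percentage scale (default 25)
#' @param n_bins resolution bins for normalization (default 20: wide
#'   equal-count bins leave a residual falloff trend inside the lowest
#'   bin that inflates the correlation for arbitrary compact models on
#'   small cells)
#' @return list with `class` ("placed_solution" or "unplaced_model"),
#'   `cc` (percentage, NA when no comparable cell) and `cryst1_match`
#' @export
classify_input <- function(model, refl,
                           cc_threshold = default_config()$cc_threshold,
                           n_bins = 20) {
  match_cell <- cryst1_matches(model, refl)
  cc <- NA_real_
  if (match_cell) {
    sf <- calc_structure_factors(model, refl)
    refl_n <- normalize_E(refl, n_bins)
    e_calc <- e_from_f(sf$f, refl, n_bins)
    cc <- cc_normalized(refl_n$e_obs, e_calc)
  }
  cls <- if (match_cell && !is.na(cc) && cc > cc_threshold) {
    "placed_solution"
  } else "unplaced_model"
  list(class = cls, cc = cc, cryst1_match = match_cell)
}

#' Write a reflection file
#'
#' Tab-separated columns H K L FOBS SIGF and optionally PHITRUE, preceded
#' by header lines carrying CELL and SPACEGROUP. Round-trips exactly with
#' [read_reflections()].
#'
#' @param refl a `reflset` with `f_obs`
#' @param path output file
#' @export
write_reflections <- function(refl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# CELL %.6g %.6g %.6g %.6g %.6g %.6g", refl$cell[1], refl$cell[2],
            refl$cell[3], refl$cell[4], refl$cell[5], refl$cell[6]),
    paste("# SPACEGROUP", refl$spacegroup)
  ), con)
  df <- data.frame(H = refl$hkl[, 1], K = refl$hkl[, 2], L = refl$hkl[, 3],
                   FOBS = refl$f_obs,
                   SIGF = if (is.null(refl$sigma)) 0 else refl$sigma)
  if (!is.null(refl$phi_true)) df$PHITRUE <- refl$phi_true
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a reflection file written by [write_reflections()]
#' @param path file path
#' @return a `reflset`
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cell_line <- grep("^# CELL", hdr, value = TRUE)
  sg_line <- grep("^# SPACEGROUP", hdr, value = TRUE)
  if (length(cell_line) == 0 || length(sg_line) == 0) {
    stop("reflection file lacks CELL/SPACEGROUP headers: ", path)
  }
  cell <- as.numeric(strsplit(trimws(sub("^# CELL", "", cell_line)),
                              "\\s+")[[1]])
  sg <- trimws(sub("^# SPACEGROUP", "", sg_line))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  reflection_set(as.matrix(df[, c("H", "K", "L")]), cell, sg,
                 f_obs = df$FOBS, sigma = df$SIGF,
                 phi_true = if ("PHITRUE" %in% names(df)) df$PHITRUE else NULL)
}

#' Write a phase set alongside its reflection data
#'
#' The reflection format of [write_reflections()] extended with PHI and
#' FOM columns; round-trips with [read_phase_file()].
#'
#' @param p a `phaseset` aligned to `refl`
#' @param refl the matching `reflset` (with `f_obs`)
#' @param path output file
#' @export
write_phase_file <- function(p, refl, path) {
  stopifnot(length(p$phi) == n_refl(refl))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# CELL %.6g %.6g %.6g %.6g %.6g %.6g", refl$cell[1],
            refl$cell[2], refl$cell[3], refl$cell[4], refl$cell[5],
            refl$cell[6]),
    paste("# SPACEGROUP", refl$spacegroup),
    paste("# LABEL", p$label)
  ), con)
  df <- data.frame(H = refl$hkl[, 1], K = refl$hkl[, 2], L = refl$hkl[, 3],
                   FOBS = refl$f_obs %||% rep(1, n_refl(refl)),
                   PHI = p$phi, FOM = p$w)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phase file written by [write_phase_file()]
#' @param path file path
#' @return list with `refl` (a `reflset`) and `phases` (a `phaseset`)
#' @export
read_phase_file <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cell <- as.numeric(strsplit(trimws(sub("^# CELL", "",
                                         grep("^# CELL", hdr, value = TRUE)[1])),
                              "\\s+")[[1]])
  sgl <- trimws(sub("^# SPACEGROUP", "",
                    grep("^# SPACEGROUP", hdr, value = TRUE)[1]))
  lab <- grep("^# LABEL", hdr, value = TRUE)
  lab <- if (length(lab)) trimws(sub("^# LABEL", "", lab[1])) else ""
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  refl <- reflection_set(as.matrix(df[, c("H", "K", "L")]), cell, sgl,
                         f_obs = df$FOBS)
  list(refl = refl,
       phases = phase_set(df$PHI, weights = df$FOM, label = lab))
}
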