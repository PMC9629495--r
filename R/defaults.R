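#' Shipped default configuration
#'
#' Central registry of the constants that govern the workflow. The values
#' are the adopted defaults of the predicted-model pipeline: B-factor
#' policy 25/50 Angstrom^2 (main chain / side chain, 25 for polyalanine),
#' input-recognition CC boundary at 25%, nonrandom phase-error boundary at
#' 80 degrees, eLLG target of 60 for sphere sizing, fragment rmsd estimate
#' 0.8 Angstrom (0.6 after internal refinement) and a general resolution
#' limit of 2.5 Angstrom.
#'
#' @return named list of configuration values
#' @export
default_config <- function() {
  list(
    # model preparation
    b_main = 25,            # Angstrom^2, main-chain B
    b_side = 50,            # Angstrom^2, side-chain B
    b_polyala = 25,         # Angstrom^2, polyalanine mode, all atoms
    keep_side_chains = TRUE,
    min_segment_len = 7,    # residues; removable internal coil length
    coil_contact_dist = 8,  # Angstrom; CB contact to structured elements
    # cell comparison
    cell_rel_tol = 0.005,   # relative, axis lengths
    cell_ang_tol = 0.5,     # degrees, absolute
    # decision thresholds
    cc_threshold = 25,      # %, placed-solution recognition
    wmpe_nonrandom = 80,    # degrees, nonrandom-solution boundary
    d_min_general = 2.5,    # Angstrom, general resolution limit
    # fragment sizing
    ellg_target = 60,
    rmsd_est = 0.8,         # Angstrom, search-fragment rmsd estimate
    rmsd_refined = 0.6,     # Angstrom, after internal refinement
    # secondary-structure annotation (frozen calibration, see vignette)
    helix_angle_max = 25,   # deg between consecutive characteristic vectors
    helix_mod_range = c(2.0, 2.6),  # Angstrom, CV modulus band
    strand_mod_range = c(1.2, 2.0),
    strand_straight_min = 9.0,  # Angstrom, CA(i)-CA(i+3) straightness
    strand_ang2_max = 30,   # deg between next-nearest CVs (pleat period 2)
    min_element_len = 3,    # residues
    # domain decomposition
    edge_dist_scale = 8,    # Angstrom, exp(-d/scale) edge weights
    domain_merge_dist = 12, # Angstrom; folds closer than this share a domain
    # sphere library
    max_fragments = 256,
    # occupied fraction of the bounding sphere (atoms dilated 2.5 A on a
    # 1 A grid); calibrated on generated fragments: compact helical
    # fragments score ~0.05-0.06, fragments with >14 A voids <=0.035
    void_fraction_min = 0.045,
    connect_dist = 5,       # Angstrom, CA-CA connectivity graph
    # phase clustering
    cluster_tol = 60,       # degrees, aligned wMPD join threshold
    polar_grid = 48,        # polar-axis search: 1/48 steps + refinement
    # verification
    mask_radius = 2.5,      # Angstrom
    clash_cutoff = 3.0,     # Angstrom, CA-CA packing filter
    max_cycles = 3,         # expansion cycles
    expand_threshold = 75,  # degrees; synthetic backend expansion limit
    cc_verified = 30        # %, blind-mode verification CC threshold
  )
}

#' Model-preparation configuration
#'
#' @param b_main,b_side,b_polyala B values in Angstrom^2
#' @param keep_side_chains keep side chains (predicted mode) or trim to
#'   polyalanine
#' @param min_segment_len minimum length of a removable internal coil
#'   segment, residues
#' @return list of class `prep_config`
#' @export
prep_config <- function(b_main = 25, b_side = 50, b_polyala = 25,
                        keep_side_chains = TRUE, min_segment_len = 7) {
  stopifnot(b_main > 0, b_side > 0, b_polyala > 0)
  structure(list(b_main = b_main, b_side = b_side, b_polyala = b_polyala,
                 keep_side_chains = keep_side_chains,
                 min_segment_len = min_segment_len),
            class = "prep_config")
}

#' eLLG parameterization
#'
#' @param rmsd_est expected coordinate error of search fragments, Angstrom
#' @param ellg_target expected log-likelihood-gain target for sphere sizing
#' @return list of class `ellg_params`
#' @export
ellg_params <- function(rmsd_est = default_config()$rmsd_est,
                        ellg_target = default_config()$ellg_target) {
  stopifnot(rmsd_est >= 0, ellg_target > 0)
  structure(list(rmsd_est = rmsd_est, ellg_target = ellg_target),
            class = "ellg_params")
}
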