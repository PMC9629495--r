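# Coordinate-file handling and predicted-model preparation.
#
# A structure model is a flat ordered atom table plus an optional cell
# card. PDB parsing is delegated to bio3d; the cell card and the confidence
# column (pLDDT or error estimate, stored in the B field by predictors)
# need handling that bio3d does not expose, so they are captured here.

.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "UNK"
)

.main_chain_names <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns name, element, x, y, z and
#'   optionally serial, resname, chain, resseq, ins, occ, b_iso, confidence
#' @param cell numeric(6) or NULL
#' @param spacegroup Hermann-Mauguin symbol or NULL
#' @return object of class `xmodel`
#' @export
structure_model <- function(atoms, cell = NULL, spacegroup = NULL) {
  n <- nrow(atoms)
  defaults <- list(serial = seq_len(n), resname = "ALA", chain = "A",
                   resseq = seq_len(n), ins = "", occ = 1, b_iso = 20,
                   confidence = NA_real_)
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  }
  stopifnot(all(nzchar(atoms$element)),
            all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))),
            all(atoms$b_iso >= 0))
  if (!is.null(cell)) stopifnot(length(cell) == 6, all(cell > 0))
  m <- list(atoms = atoms[, c("serial", "name", "element", "resname",
                              "chain", "resseq", "ins", "x", "y", "z",
                              "occ", "b_iso", "confidence")],
            cell = cell, spacegroup = spacegroup,
            has_cryst1 = !is.null(cell),
            conf_convention = detect_confidence_convention(atoms$confidence))
  class(m) <- "xmodel"
  m
}

#' @export
print.xmodel <- function(x, ...) {
  cat("xmodel:", nrow(x$atoms), "atoms,", n_residues(x), "residues",
      if (x$has_cryst1) {
        sprintf("| cell %.2f %.2f %.2f %s", x$cell[1], x$cell[2], x$cell[3],
                x$spacegroup %||% "?")
      } else "| no cell card", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residue key (chain|resseq|ins) per atom, in file order
residue_keys <- function(model) {
  paste(model$atoms$chain, model$atoms$resseq, model$atoms$ins, sep = "|")
}

#' Number of residues in a model
#' @param model an `xmodel`
#' @export
n_residues <- function(model) length(unique(residue_keys(model)))

#' Residue table of a model
#'
#' One row per residue in file order, with the residue key used
#' throughout the package (`chain|resseq|insertion`).
#'
#' @param model an `xmodel`
#' @return data.frame with key, chain, resseq, ins, resname, is_protein
#' @export
residue_table <- function(model) {
  key <- residue_keys(model)
  idx <- !duplicated(key)
  at <- model$atoms
  data.frame(key = key[idx], chain = at$chain[idx], resseq = at$resseq[idx],
             ins = at$ins[idx],
             resname = at$resname[idx],
             is_protein = at$resname[idx] %in% .protein_resnames,
             stringsAsFactors = FALSE)
}

#' Subset a model to a set of residues
#'
#' @param model an `xmodel`
#' @param keys residue keys as in [residue_table()]
#' @return the `xmodel` restricted to those residues (atom order kept)
#' @export
subset_residues <- function(model, keys) {
  keep <- residue_keys(model) %in% keys
  out <- model
  out$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

# coordinates of one named atom per residue (NA row when missing)
atom_per_residue <- function(model, name, fallback = NULL) {
  rt <- residue_table(model)
  key <- residue_keys(model)
  at <- model$atoms
  out <- matrix(NA_real_, nrow(rt), 3)
  for (i in seq_len(nrow(rt))) {
    j <- which(key == rt$key[i] & at$name == name)
    if (length(j) == 0 && !is.null(fallback)) {
      j <- which(key == rt$key[i] & at$name == fallback)
    }
    if (length(j) > 0) out[i, ] <- as.numeric(at[j[1], c("x", "y", "z")])
  }
  out
}

detect_confidence_convention <- function(conf) {
  conf <- conf[!is.na(conf)]
  if (length(conf) == 0) return("unknown")
  if (all(conf >= 0 & conf <= 100) && stats::median(conf) > 40) return("plddt")
  if (all(conf < 30) && stats::sd(conf) < 1) return("error_estimate")
  "unknown"
}

#' Read a coordinate file (PDB or mmCIF)
#'
#' All ATOM/HETATM records are loaded; the B column is captured verbatim
#' into the `confidence` field (predictors store pLDDT or error estimates
#' there) before any preparation overwrites B. Alternate locations keep
#' the highest-occupancy conformer (ties: first in file order).
#'
#' @param path file path; dialect chosen by extension (.cif/.mmcif vs PDB)
#' @return an `xmodel`
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else
      bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("unparsable coordinate file: ", path, " (",
                             conditionMessage(e), ")")
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty model: no atoms in ", path)
  # alternate locations: keep highest occupancy, tie -> first in file
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    j <- which(key == k)
    best <- j[which.max(at$o[j])]
    keep[setdiff(j, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) elem <- guess_element(at$elety)
  elem[is.na(elem) | !nzchar(elem)] <- guess_element(at$elety[
    is.na(elem) | !nzchar(elem)])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety,
    element = toupper(trimws(elem)),
    resname = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
    resseq = at$resno, ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b_iso = ifelse(is.na(at$b), 0, at$b),
    confidence = at$b, stringsAsFactors = FALSE
  )
  cc <- read_cell_card(path, is_cif)
  structure_model(atoms, cell = cc$cell, spacegroup = cc$spacegroup)
}

guess_element <- function(name) {
  n <- gsub("[0-9'\"]", "", trimws(name))
  two <- toupper(substr(n, 1, 2))
  one <- toupper(substr(n, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "HG", "NA", "CL"), two, one)
}

read_cell_card <- function(path, is_cif) {
  lines <- readLines(path, warn = FALSE)
  if (is_cif) {
    getval <- function(tag) {
      l <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (length(l) == 0) return(NA)
      gsub("['\"]", "", trimws(sub(paste0("^", tag), "", l[1])))
    }
    vals <- suppressWarnings(as.numeric(c(
      getval("_cell.length_a"), getval("_cell.length_b"),
      getval("_cell.length_c"), getval("_cell.angle_alpha"),
      getval("_cell.angle_beta"), getval("_cell.angle_gamma"))))
    sg <- getval("_symmetry.space_group_name_H-M")
    if (any(is.na(vals))) return(list(cell = NULL, spacegroup = NULL))
    return(list(cell = vals, spacegroup = if (is.na(sg)) NULL else sg))
  }
  l <- grep("^CRYST1", lines, value = TRUE)
  if (length(l) == 0) return(list(cell = NULL, spacegroup = NULL))
  l <- l[1]
  cell <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33),
                       substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)))
  sg <- trimws(substr(l, 56, 66))
  list(cell = cell, spacegroup = if (nzchar(sg)) sg else NULL)
}

#' Write a structure model as a PDB file
#'
#' Emits a CRYST1 card when the model carries a cell, then fixed-column
#' ATOM/HETATM records. Round-trips with [read_structure()] for names,
#' coordinates (1e-3 Angstrom) and B (1e-2 Angstrom^2).
#'
#' @param model an `xmodel`, non-empty
#' @param path output path
#' @export
write_structure <- function(model, path) {
  if (nrow(model$atoms) == 0) stop("refusing to write an empty model")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write: ", path))
  on.exit(close(con))
  if (model$has_cryst1) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       model$cell[1], model$cell[2], model$cell[3],
                       model$cell[4], model$cell[5], model$cell[6],
                       model$spacegroup %||% "P 1"), con)
  }
  at <- model$atoms
  rec <- ifelse(at$resname %in% .protein_resnames, "ATOM  ", "HETATM")
  name4 <- vapply(at$name, function(n) {
    if (nchar(n) >= 4) substr(n, 1, 4) else sprintf(" %-3s", n)
  }, character(1))
  lines <- sprintf(
    "%s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, at$serial %% 100000, name4, substr(at$resname, 1, 3),
    substr(at$chain, 1, 1), at$resseq %% 10000, ifelse(nzchar(at$ins),
                                                       at$ins, " "),
    at$x, at$y, at$z, at$occ, at$b_iso, at$element)
  writeLines(c(lines, "END"), con)
  invisible(NULL)
}

#' Remove hydrogen and deuterium atoms
#'
#' Predicted models place H atoms at distances inappropriate for X-ray
#' scattering; they are removed by element field (never by atom name, so
#' mercury "HG" survives while hydrogen "HG1" does not). Idempotent.
#'
#' @param model an `xmodel`
#' @return the model without H/D atoms
#' @export
strip_hydrogens <- function(model) {
  keep <- !(toupper(model$atoms$element) %in% c("H", "D"))
  out <- model
  out$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Apply the predicted-model B-factor policy
#'
#' Sets every main-chain protein atom (N, CA, C, O, OXT) to `b_main` and
#' every other protein atom (CB included) to `b_side`. In polyalanine mode
#' (`keep_side_chains = FALSE`) side chains are trimmed past CB and all
#' remaining atoms get `b_polyala`, producing fragments of equivalent
#' scattering. The original confidence column is preserved. Idempotent.
#'
#' @param model an `xmodel` (hydrogens already stripped)
#' @param cfg a [prep_config()]
#' @return the model with the policy applied
#' @export
apply_b_policy <- function(model, cfg = prep_config()) {
  at <- model$atoms
  prot <- at$resname %in% .protein_resnames
  if (!cfg$keep_side_chains) {
    keep <- !prot | at$name %in% c(.main_chain_names, "CB")
    at <- at[keep, , drop = FALSE]
    prot <- at$resname %in% .protein_resnames
    at$b_iso[prot] <- cfg$b_polyala
  } else {
    main <- prot & at$name %in% .main_chain_names
    at$b_iso[main] <- cfg$b_main
    at$b_iso[prot & !main] <- cfg$b_side
  }
  out <- model
  out$atoms <- at
  rownames(out$atoms) <- NULL
  out
}

#' Prepare a predicted model for fragment-based phasing
#'
#' Removes unstructured regions based on the geometric secondary-structure
#' annotation (never on the confidence scores: genuinely correct regions
#' can carry low prediction scores, and the measured data are left to
#' judge model correctness), strips hydrogens and applies the B policy.
#' Coil segments at chain termini, and internal coil segments of at least
#' `cfg$min_segment_len` residues with no contact to any annotated
#' element, are removed; short connecting coils are kept.
#'
#' @param model an `xmodel`
#' @param annotation an [annotate_ss()] result computed on the same model
#' @param cfg a [prep_config()]
#' @return the prepared `xmodel`
#' @export
prepare_predicted_model <- function(model, annotation, cfg = prep_config()) {
  model <- strip_hydrogens(model)
  rt <- residue_table(model)
  lab <- annotation$labels[match(rt$key, annotation$keys)]
  lab[is.na(lab)] <- "coil"
  drop <- removable_coil(rt, lab, model, cfg)
  keep_keys <- rt$key[!drop]
  if (length(keep_keys) == 0) {
    stop("empty after preparation: no structured residues retained")
  }
  out <- subset_residues(model, keep_keys)
  apply_b_policy(out, cfg)
}

# which residues belong to removable coil segments
removable_coil <- function(rt, lab, model, cfg) {
  cfgd <- default_config()
  drop <- rep(FALSE, nrow(rt))
  cb <- atom_per_residue(model, "CB", fallback = "CA")
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch)
    l <- lab[idx]
    r <- rle(l)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    el_res <- idx[l != "coil"]
    for (s in seq_along(r$values)) {
      if (r$values[s] != "coil") next
      seg <- idx[starts[s]:ends[s]]
      terminal <- starts[s] == 1 || ends[s] == length(idx)
      if (terminal) {
        if (length(seg) >= 3) drop[seg] <- TRUE
        next
      }
      if (length(seg) < cfg$min_segment_len) next
      # contact check: any CB of the segment near any element CB
      if (length(el_res) == 0) { drop[seg] <- TRUE; next }
      a <- cb[seg, , drop = FALSE]
      b <- cb[el_res, , drop = FALSE]
      ok <- stats::complete.cases(a)
      mind <- Inf
      if (any(ok) && any(stats::complete.cases(b))) {
        b <- b[stats::complete.cases(b), , drop = FALSE]
        d2 <- outer(rowSums(a[ok, , drop = FALSE]^2), rowSums(b^2), "+") -
          2 * a[ok, , drop = FALSE] %*% t(b)
        mind <- sqrt(max(0, min(d2)))
      }
      if (mind >= cfgd$coil_contact_dist) drop[seg] <- TRUE
    }
  }
  drop
}

#' Does the model's cell card match the experimental data?
#'
#' True iff the model carries a cell whose six parameters agree with the
#' reflection set's within tolerance (0.5% relative on lengths, 0.5
#' degrees on angles) and the space-group symbols denote the same group.
#'
#' @param model an `xmodel`
#' @param refl a `reflset`
#' @param rel_tol relative tolerance on axis lengths
#' @param ang_tol absolute tolerance on angles, degrees
#' @return logical
#' @export
cryst1_matches <- function(model, refl,
                           rel_tol = default_config()$cell_rel_tol,
                           ang_tol = default_config()$cell_ang_tol) {
  if (!model$has_cryst1 || is.null(model$cell)) return(FALSE)
  len_ok <- all(abs(model$cell[1:3] - refl$cell[1:3]) / refl$cell[1:3] <=
                  rel_tol)
  ang_ok <- all(abs(model$cell[4:6] - refl$cell[4:6]) <= ang_tol)
  sg_ok <- !is.null(model$spacegroup) &&
    same_spacegroup(model$spacegroup, refl$spacegroup)
  len_ok && ang_ok && sg_ok
}

#' Apply a rigid motion to a model
#'
#' @param model an `xmodel`
#' @param rotation 3x3 cartesian rotation matrix
#' @param translation cartesian 3-vector, Angstrom
#' @return the transformed `xmodel`
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  out <- model
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

# total scattering mass sum(Z^2) of a model (or subset of residue keys)
scattering_sum <- function(model, keys = NULL) {
  at <- model$atoms
  if (!is.null(keys)) at <- at[residue_keys(model) %in% keys, , drop = FALSE]
  z <- .z_table[toupper(at$element)]
  z[is.na(z)] <- 7  # unknown elements counted as nitrogen-like
  sum(z^2 * at$occ)
}
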