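# Geometric secondary/tertiary-structure annotation from characteristic
# vectors, and community-clustering domain decomposition.
#
# A characteristic vector (CV) describes one overlapping tripeptide: it
# runs from the centroid of its three CA atoms to the centroid of its
# three carbonyl O atoms. Regular secondary structure shows up as narrow
# bands in CV modulus and in the angles between consecutive CVs; the
# numeric bands were calibrated once on ideal generated geometries and are
# frozen in default_config().

#' Characteristic vectors of all overlapping tripeptides
#'
#' One vector per overlapping tripeptide within each contiguous chain
#' segment (n - 2 vectors per segment of n residues). Tripeptides with a
#' residue missing CA or O are skipped with a warning.
#'
#' @param model an `xmodel`
#' @return data.frame with columns `first_res` (index into the residue
#'   table of the first residue), `chain`, start/end centroids (`sx..ez`),
#'   unit `direction` components (`dx,dy,dz`) and `modulus` (Angstrom)
#' @export
characteristic_vectors <- function(model) {
  rt <- residue_table(model)
  ca <- atom_per_residue(model, "CA")
  o <- atom_per_residue(model, "O")
  segs <- chain_segments(rt, ca)
  rows <- list()
  skipped <- 0L
  for (seg in segs) {
    if (length(seg) < 3) next
    for (k in seq_len(length(seg) - 2)) {
      i <- seg[k:(k + 2)]
      if (anyNA(ca[i, ]) || anyNA(o[i, ])) { skipped <- skipped + 1L; next }
      st <- colMeans(ca[i, , drop = FALSE])
      en <- colMeans(o[i, , drop = FALSE])
      v <- en - st
      mod <- vnorm(v)
      rows[[length(rows) + 1]] <- data.frame(
        first_res = i[1], chain = rt$chain[i[1]],
        sx = st[1], sy = st[2], sz = st[3],
        ex = en[1], ey = en[2], ez = en[3],
        dx = v[1] / mod, dy = v[2] / mod, dz = v[3] / mod,
        modulus = mod)
    }
  }
  if (skipped > 0) {
    warning(skipped, " tripeptide(s) skipped: residue missing CA or O")
  }
  if (length(rows) == 0) {
    return(data.frame(first_res = integer(), chain = character(),
                      sx = numeric(), sy = numeric(), sz = numeric(),
                      ex = numeric(), ey = numeric(), ez = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      modulus = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# contiguous protein segments: runs of residues in one chain with
# consecutive numbering and peptide-plausible CA-CA steps (numbering gaps
# and broken geometry both split segments)
chain_segments <- function(rt, ca) {
  segs <- list()
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch & rt$is_protein)
    if (length(idx) == 0) next
    step_ok <- c(FALSE, diff(rt$resseq[idx]) == 1)
    if (length(idx) > 1) {
      d <- sqrt(rowSums((ca[idx[-1], , drop = FALSE] -
                           ca[idx[-length(idx)], , drop = FALSE])^2))
      step_ok[-1] <- step_ok[-1] & (is.na(d) | d <= 4.5)
    }
    grp <- cumsum(!step_ok)
    for (g in unique(grp)) segs[[length(segs) + 1]] <- idx[grp == g]
  }
  segs
}

#' Annotate secondary structure from characteristic vectors
#'
#' Each CV is classified from its modulus, the angle to the following CV
#' and the local CA straightness; residues take the majority label of the
#' CVs covering them, and runs shorter than the minimum element length
#' are demoted to coil. Deterministic, and invariant under rigid motions
#' of the model.
#'
#' @param cvs output of [characteristic_vectors()]
#' @param model the same `xmodel`
#' @return list of class `ss_annotation`: `keys` (residue keys), `labels`
#'   (helix/strand/coil per residue) and `elements` (data.frame label,
#'   start, end as residue-table indices)
#' @export
annotate_ss <- function(cvs, model) {
  cfg <- default_config()
  rt <- residue_table(model)
  ca <- atom_per_residue(model, "CA")
  nres <- nrow(rt)
  labels <- rep("coil", nres)
  if (nrow(cvs) >= 1) {
    v <- as.matrix(cvs[, c("dx", "dy", "dz")])
    n <- nrow(cvs)
    # angle to the neighbouring CV along the same chain (next; previous
    # for the last CV of a run)
    ang <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      j <- if (i < n && cvs$first_res[i + 1] == cvs$first_res[i] + 1 &&
               cvs$chain[i + 1] == cvs$chain[i]) i + 1 else
        if (i > 1 && cvs$first_res[i - 1] == cvs$first_res[i] - 1 &&
            cvs$chain[i - 1] == cvs$chain[i]) i - 1 else NA
      if (!is.na(j)) ang[i] <- vangle(v[i, ], v[j, ])
    }
    # local straightness: CA(first) to CA(first+3) distance
    straight <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      a <- cvs$first_res[i]; b <- a + 3
      if (b <= nres && rt$chain[b] == cvs$chain[i] &&
          rt$resseq[b] - rt$resseq[a] == 3 && !anyNA(ca[c(a, b), ])) {
        straight[i] <- vnorm(ca[b, ] - ca[a, ])
      } else if (a - 1 >= 1 && rt$chain[a - 1] == cvs$chain[i] &&
                 !anyNA(ca[c(a - 1, a + 2), ])) {
        straight[i] <- vnorm(ca[a + 2, ] - ca[a - 1, ])
      }
    }
    # period-2 direction consistency (strand pleat): CV i vs CV i+2
    ang2 <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      j <- if (i + 2 <= n && cvs$first_res[i + 2] == cvs$first_res[i] + 2 &&
               cvs$chain[i + 2] == cvs$chain[i]) i + 2 else
        if (i - 2 >= 1 && cvs$first_res[i - 2] == cvs$first_res[i] - 2 &&
            cvs$chain[i - 2] == cvs$chain[i]) i - 2 else NA
      if (!is.na(j)) ang2[i] <- vangle(v[i, ], v[j, ])
    }
    cls <- rep("coil", n)
    helix <- !is.na(ang) & ang <= cfg$helix_angle_max &
      cvs$modulus >= cfg$helix_mod_range[1] &
      cvs$modulus <= cfg$helix_mod_range[2]
    strand <- !helix & cvs$modulus >= cfg$strand_mod_range[1] &
      cvs$modulus <= cfg$strand_mod_range[2] &
      !is.na(straight) & straight >= cfg$strand_straight_min &
      !is.na(ang2) & ang2 <= cfg$strand_ang2_max
    cls[helix] <- "helix"
    cls[strand] <- "strand"
    # residue vote over covering CVs (CV i covers residues i, i+1, i+2)
    votes <- matrix(0L, nres, 3, dimnames = list(NULL, c("helix", "strand", "coil")))
    for (i in seq_len(n)) {
      r <- cvs$first_res[i] + 0:2
      votes[r, cls[i]] <- votes[r, cls[i]] + 1L
    }
    for (r in seq_len(nres)) {
      if (sum(votes[r, ]) == 0) next
      w <- votes[r, c("helix", "strand")]
      if (max(w) > 0 && max(w) >= votes[r, "coil"]) {
        labels[r] <- c("helix", "strand")[which.max(w)]
      }
    }
    # demote runs shorter than the minimum element length
    r <- rle(paste(rt$chain, labels))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (s in seq_along(r$values)) {
      if (!grepl("coil$", r$values[s]) && r$lengths[s] < cfg$min_element_len) {
        labels[starts[s]:ends[s]] <- "coil"
      }
    }
  }
  elements <- ss_elements(rt, labels)
  structure(list(keys = rt$key, labels = labels, elements = elements),
            class = "ss_annotation")
}

ss_elements <- function(rt, labels) {
  r <- rle(paste(rt$chain, labels, sep = "|"))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  lab <- sub("^.*\\|", "", r$values)
  keep <- lab != "coil"
  data.frame(label = lab[keep], start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.ss_annotation <- function(x, ...) {
  cat("ss_annotation:", length(x$labels), "residues;",
      sum(x$labels == "helix"), "helix,", sum(x$labels == "strand"),
      "strand,", sum(x$labels == "coil"), "coil;",
      nrow(x$elements), "elements\n")
  invisible(x)
}

#' Domain decomposition by community clustering of the element graph
#'
#' Builds a weighted graph over secondary-structure elements (edge weight
#' exp(-d_min / 8 Angstrom) from the minimum inter-element CA distance)
#' and partitions it by greedy modularity optimization. A second,
#' coarser level is obtained by re-running the community detection on the
#' quotient graph of the first-level communities; this is the domain
#' level used to segregate fragments.
#'
#' @param annotation an `ss_annotation`
#' @param model the same `xmodel`
#' @return list of class `domain_partition`: `elements`, `fold_id` and
#'   `domain_id` (per element), `residue_domain` (per residue, coil
#'   residues attached to the nearest element), `graph` (igraph object)
#' @export
community_partition <- function(annotation, model) {
  cfg <- default_config()
  el <- annotation$elements
  rt <- residue_table(model)
  ca <- atom_per_residue(model, "CA")
  ne <- nrow(el)
  if (ne == 0) stop("no annotated elements to partition")
  if (ne == 1) {
    fold <- domain <- 1L
    g <- igraph::make_empty_graph(1, directed = FALSE)
  } else {
    dmin <- matrix(0, ne, ne)
    for (i in seq_len(ne - 1)) {
      a <- ca[el$start[i]:el$end[i], , drop = FALSE]
      for (j in (i + 1):ne) {
        b <- ca[el$start[j]:el$end[j], , drop = FALSE]
        d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
        dmin[i, j] <- dmin[j, i] <- sqrt(max(0, min(d2)))
      }
    }
    w <- exp(-dmin / cfg$edge_dist_scale)
    diag(w) <- 0
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    fold <- as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
    # coarser domain level: folds whose elements come within the merge
    # distance of one another belong to the same domain (connected
    # components of the thresholded fold-quotient graph); modularity
    # alone always splits even compact bundles
    nf <- max(fold)
    merge_adj <- matrix(FALSE, nf, nf)
    for (i in seq_len(nf)) for (j in seq_len(nf)) {
      merge_adj[i, j] <- min(dmin[fold == i, fold == j]) <=
        cfg$domain_merge_dist
    }
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      merge_adj, mode = "undirected"))$membership
    domain <- as.integer(comp[fold])
  }
  # canonical community ids: renumber by lowest element index
  fold <- canonical_ids(fold)
  domain <- canonical_ids(domain)
  residue_domain <- rep(NA_integer_, nrow(rt))
  for (e in seq_len(ne)) {
    residue_domain[el$start[e]:el$end[e]] <- domain[e]
  }
  # coil residues: domain of the nearest annotated element CA
  el_res <- which(!is.na(residue_domain))
  for (r in which(is.na(residue_domain))) {
    if (anyNA(ca[r, ]) || length(el_res) == 0) next
    d2 <- rowSums(sweep(ca[el_res, , drop = FALSE], 2, ca[r, ])^2)
    residue_domain[r] <- residue_domain[el_res[which.min(d2)]]
  }
  structure(list(elements = el, fold_id = fold, domain_id = domain,
                 residue_domain = residue_domain, graph = g),
            class = "domain_partition")
}

canonical_ids <- function(ids) {
  match(ids, unique(ids))
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("domain_partition:", nrow(x$elements), "elements,",
      length(unique(x$fold_id)), "folds,",
      length(unique(x$domain_id)), "domains\n")
  invisible(x)
}
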