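# Characteristic vectors, secondary-structure annotation, domain
# decomposition and the spherical fragment library.

test_that("characteristic-vector count follows the n-2 law per segment", {
  h <- build_helix(10); h$resname <- "ALA"
  m <- structure_model(h)
  expect_equal(nrow(characteristic_vectors(m)), 8)
  # two chain segments of 5 and 6 residues: 3 + 4 vectors, none across gap
  a <- build_helix(5); a$resname <- "ALA"
  b <- build_helix(6); b$resname <- "ALA"
  b$resseq <- b$resseq + 7  # numbering gap
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + 30
  m2 <- structure_model(rbind(a, b))
  expect_equal(nrow(characteristic_vectors(m2)), 7)
  # unit directions, start/end are exact centroids
  cvs <- characteristic_vectors(m)
  expect_equal(sqrt(cvs$dx^2 + cvs$dy^2 + cvs$dz^2), rep(1, nrow(cvs)),
               tolerance = 1e-9)
  ca <- as.matrix(h[h$name == "CA", c("x", "y", "z")])
  expect_equal(as.numeric(cvs[1, c("sx", "sy", "sz")]), colMeans(ca[1:3, ]),
               ignore_attr = TRUE)
})

test_that("tripeptides missing CA or O are skipped with a warning", {
  h <- build_helix(8); h$resname <- "ALA"
  h <- h[!(h$resseq == 4 & h$name == "O"), ]
  m <- structure_model(h)
  expect_warning(cvs <- characteristic_vectors(m), "skipped")
  expect_equal(nrow(cvs), 6 - 3)  # three tripeptides touch residue 4
})

test_that("ideal helix CVs are nearly parallel and annotate as helix", {
  h <- build_helix(20); h$resname <- "ALA"
  m <- structure_model(h)
  cvs <- characteristic_vectors(m)
  v <- as.matrix(cvs[, c("dx", "dy", "dz")])
  angles <- vapply(seq_len(nrow(v) - 1), function(i) {
    acos(min(1, sum(v[i, ] * v[i + 1, ]))) * 180 / pi
  }, 1)
  expect_true(all(angles < 25))
  ann <- annotate_ss(cvs, m)
  expect_true(all(ann$labels == "helix"))
})

test_that("ideal strand annotates as strand, random coil mostly as coil", {
  s <- build_strand(12); s$resname <- "ALA"
  ms <- structure_model(s)
  anns <- annotate_ss(characteristic_vectors(ms), ms)
  expect_true(all(anns$labels == "strand"))
  for (seed in 1:5) {
    mc <- fix_coil_model(30, seed = seed)
    annc <- annotate_ss(characteristic_vectors(mc), mc)
    expect_gte(mean(annc$labels == "coil"), 0.8)
  }
})

test_that("annotation is invariant under rigid motions", {
  m <- fix_helix_with_tail(16, 8, seed = 4)
  ann <- annotate_ss(characteristic_vectors(m), m)
  set.seed(11)
  m2 <- transform_model(m, rotation = random_rotation(),
                        translation = c(13.2, -8.1, 40))
  ann2 <- annotate_ss(characteristic_vectors(m2), m2)
  expect_identical(ann$labels, ann2$labels)
})

test_that("community partition separates distant bundles and keeps one compact bundle together", {
  b <- rbind(fix_bundle(3, chains = c("A", "B", "C")),
             fix_bundle(3, offset = c(0, 40, 0), chains = c("D", "E", "F")))
  m <- structure_model(b)
  ann <- annotate_ss(characteristic_vectors(m), m)
  part <- community_partition(ann, m)
  expect_equal(length(unique(part$domain_id)), 2)
  # elements of the same bundle share a community
  el_chain <- fragphase:::residue_table(m)$chain[part$elements$start]
  expect_equal(length(unique(part$domain_id[el_chain %in% c("A", "B", "C")])), 1)
  expect_equal(length(unique(part$domain_id[el_chain %in% c("D", "E", "F")])), 1)
  # single compact bundle: one domain
  m1 <- fix_bundle_model(4, chains = c("A", "B", "C", "D"))
  ann1 <- annotate_ss(characteristic_vectors(m1), m1)
  expect_equal(length(unique(community_partition(ann1, m1)$domain_id)), 1)
})

test_that("duplicated bundle at zero separation merges into one community", {
  b <- rbind(fix_bundle(3, chains = c("A", "B", "C")),
             fix_bundle(3, chains = c("D", "E", "F")))  # same coordinates
  m <- structure_model(b)
  ann <- annotate_ss(characteristic_vectors(m), m)
  part <- community_partition(ann, m)
  expect_equal(length(unique(part$domain_id)), 1)
})

test_that("community partition is invariant to atom-order permutation", {
  b <- rbind(fix_bundle(3, chains = c("A", "B", "C")),
             fix_bundle(3, offset = c(0, 40, 0), chains = c("D", "E", "F")))
  m <- structure_model(b)
  ann <- annotate_ss(characteristic_vectors(m), m)
  p1 <- community_partition(ann, m)
  # permute residue blocks (keep residues contiguous, reverse chain order)
  b2 <- b[order(match(b$chain, rev(LETTERS[1:6])), b$resseq), ]
  m2 <- structure_model(b2)
  ann2 <- annotate_ss(characteristic_vectors(m2), m2)
  p2 <- community_partition(ann2, m2)
  ch1 <- fragphase:::residue_table(m)$chain
  ch2 <- fragphase:::residue_table(m2)$chain
  d1 <- split(p1$residue_domain, ch1)
  d2 <- split(p2$residue_domain, ch2)
  # same grouping of chains into domains (ids may be renumbered)
  grp <- function(d) {
    key <- vapply(d, function(x) x[1], 1)
    split(names(key), key) |> lapply(sort) |> (\(l) l[order(vapply(l, `[`, "", 1))])()
  }
  expect_equal(unname(grp(d1)), unname(grp(d2)))
})

test_that("eLLG matches an independent per-reflection summation oracle", {
  toy <- fix_toy()
  params <- ellg_params(rmsd_est = 0.8)
  for (fm in c(0.1, 0.25, 0.7, 1)) {
    # independent oracle: explicit loop over reflections
    acc <- 0
    for (i in seq_len(nrow(toy$refl$hkl))) {
      s2 <- 1 / (4 * toy$refl$d[i]^2)
      sa <- sqrt(fm) * exp(-(8 * pi^2 / 3) * 0.8^2 * s2)
      acc <- acc + sa^4 / 2
    }
    expect_equal(estimate_ellg(fm, params, toy$refl), acc,
                 tolerance = 1e-10)
  }
  expect_equal(estimate_ellg(0, params, toy$refl), 0)
  expect_error(estimate_ellg(1.2, params, toy$refl), "\\[0, 1\\]")
  # monotone in f_m, decreasing in rmsd
  expect_gt(estimate_ellg(0.4, params, toy$refl),
            estimate_ellg(0.2, params, toy$refl))
  expect_gt(estimate_ellg(0.4, ellg_params(rmsd_est = 0.6), toy$refl),
            estimate_ellg(0.4, ellg_params(rmsd_est = 0.8), toy$refl))
})

test_that("sphere sizing inverts the eLLG and lowers the target when unsupported", {
  toy <- fix_toy()
  m <- toy$truth
  # scan oracle: smallest n with eLLG(n/N) >= target
  params <- ellg_params(ellg_target = 20)
  n_tot <- n_residues(m)
  per <- vapply(seq_len(n_tot), function(n) {
    estimate_ellg(n / n_tot, params, toy$refl)
  }, 1)
  res <- sphere_size_for_target(m, toy$refl, params)
  if (any(per >= 20)) {
    expect_equal(res$n_res, min(which(per >= 20)))
    expect_false(res$lowered)
  }
  # tiny model cannot reach a big target
  big <- ellg_params(ellg_target = 1e6)
  res2 <- sphere_size_for_target(m, toy$refl, big)
  expect_true(res2$lowered)
  expect_equal(res2$n_res, n_tot)
  expect_lt(res2$achieved_ellg, 1e6)
  # boundary: target reachable with a single residue
  tiny <- ellg_params(ellg_target = per[1] / 2)
  expect_equal(sphere_size_for_target(m, toy$refl, tiny)$n_res, 1)
})

test_that("fragment library: domain purity, connectivity, coverage", {
  b <- rbind(fix_bundle(3, chains = c("A", "B", "C")),
             fix_bundle(3, offset = c(0, 40, 0), chains = c("D", "E", "F")))
  m <- structure_model(b)
  ann <- annotate_ss(characteristic_vectors(m), m)
  part <- community_partition(ann, m)
  lib <- generate_sphere_library(m, part, n_res = 20)
  expect_gt(length(lib), 0)
  rt <- fragphase:::residue_table(m)
  for (f in lib) {
    doms <- unique(part$residue_domain[match(f$residues, rt$key)])
    expect_length(doms, 1)                       # never mixes domains
    sel <- match(f$residues, rt$key)
    ca <- fragphase:::atom_per_residue(m, "CA")
    expect_true(fragphase:::fragment_connected(sort(sel), rt, ca, 5))
    expect_gt(f$scattering, 0)
  }
  covered <- unique(unlist(lapply(lib, `[[`, "residues")))
  noncoil <- rt$key[ann$labels != "coil"]
  expect_gte(mean(noncoil %in% covered), 0.95)
})

test_that("a fragment centred on a protruding loop is rejected as disjoint", {
  h <- build_helix(24); h$resname <- "ALA"
  # 2-residue "loop" far from the helix body, numbered adjacent to the end
  loop <- h[h$resseq %in% 1:2, ]
  loop$resseq <- loop$resseq + 24
  loop[, c("x", "y", "z")] <- loop[, c("x", "y", "z")] + 25
  m <- structure_model(rbind(h, loop))
  ann <- annotate_ss(characteristic_vectors(m), m)
  part <- community_partition(ann, m)
  lib <- generate_sphere_library(m, part, n_res = 6)
  centers <- vapply(lib, `[[`, "", "center_res")
  loop_keys <- fragphase:::residue_table(m)$key[25:26]
  expect_false(any(centers %in% loop_keys))
})
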