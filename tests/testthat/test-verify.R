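# Shredding, masking, trace filtering, verification driver, translation
# scan, packing filter and multicopy prioritization.

test_that("shredding covers every residue within the sphere budget", {
  toy <- fix_toy3()
  sol <- toy$truth   # 42 residues
  frags <- shred_placed_solution(sol, n_res = 12, max_spheres = 10)
  expect_lte(length(frags), 10)
  rt <- fragphase:::residue_table(sol)
  covered <- unique(unlist(lapply(frags, `[[`, "residues")))
  expect_setequal(covered, rt$key)   # 100% residue coverage
  expect_true(all(vapply(frags, `[[`, 1, "n_res") == 12))
  # degenerate: model smaller than the sphere -> one whole-model fragment
  small <- subset_residues(sol, rt$key[1:8])
  f1 <- shred_placed_solution(small, n_res = 40)
  expect_length(f1, 1)
  expect_equal(f1[[1]]$n_res, 8)
  # per-atom budget: coverage trivially complete
  fa <- shred_placed_solution(sol, n_res = 12,
                              max_spheres = nrow(sol$atoms))
  expect_setequal(unique(unlist(lapply(fa, `[[`, "residues"))), rt$key)
})

test_that("model mask volume matches the analytic sphere and wraps periodically", {
  cell <- c(20, 20, 20, 90, 90, 90)
  refl <- generate_hkl(cell, "P1", 4)
  at <- data.frame(name = "C", element = "C", x = 10, y = 10, z = 10,
                   occ = 1, b_iso = 15)
  m <- structure_model(at)
  mask <- build_model_mask(m, refl, radius = 3, spacing = 0.5)
  vol_frac <- mask_fraction(mask) * prod(cell[1:3])
  expect_lt(abs(vol_frac - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.05)
  # radius zero: nothing masked
  expect_equal(mask_fraction(build_model_mask(m, refl, radius = 0,
                                              spacing = 1)), 0)
  expect_error(build_model_mask(m, refl, spacing = 0), "spacing")
  # atom at the cell corner: the mask wraps into all eight octants
  corner <- structure_model(transform(at, x = 0, y = 0, z = 0))
  wrap <- build_model_mask(corner, refl, radius = 3, spacing = 1)
  f <- wrap$flags
  d <- dim(f)
  expect_true(f[1, 1, 1] && f[d[1], 1, 1] && f[1, d[2], 1] &&
                f[1, 1, d[3]] && f[d[1], d[2], d[3]])
  centered <- build_model_mask(m, refl, radius = 3, spacing = 1)
  expect_lt(abs(mask_fraction(wrap) - mask_fraction(centered)) /
              mask_fraction(centered), 0.15)
})

test_that("symmetry images are masked too", {
  toy <- fix_toy()
  one_atom <- subset_residues(toy$truth,
                              fragphase:::residue_table(toy$truth)$key[1])
  mask <- build_model_mask(one_atom, toy$refl, radius = 2.5, spacing = 1)
  # oracle: fraction of random points within radius of any expanded image
  set.seed(12)
  pts <- matrix(stats::runif(3000), ncol = 3)
  cart <- frac_to_cart(pts, toy$refl$cell)
  inside <- fragphase:::points_in_mask(cart, mask)
  frac <- cart_to_frac(as.matrix(one_atom$atoms[, c("x", "y", "z")]),
                       toy$refl$cell)
  ops <- toy$refl$sg$ops
  truth_inside <- vapply(seq_len(nrow(pts)), function(i) {
    for (op in ops) {
      img <- (sweep(frac %*% t(op$R), 2, op$v, "+")) %% 1
      dd <- sweep(img, 2, pts[i, ])
      dd <- dd - round(dd)
      if (min(rowSums(frac_to_cart(dd, toy$refl$cell)^2)) <= 2.5^2) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  # voxelization blurs the boundary; demand 97% agreement
  expect_gt(mean(inside == truth_inside), 0.97)
})

test_that("trace filtering removes exactly the in-mask part", {
  toy <- fix_toy()
  mask <- build_model_mask(toy$truth, toy$refl, radius = 2.5, spacing = 0.8)
  # trace fully inside: every atom of the model itself
  full <- filter_trace_outside_mask(toy$truth, mask)
  expect_equal(nrow(full$atoms), 0)
  expect_equal(attr(full, "inside_fraction"), 1)
  # constructed half-in / half-out trace
  far <- toy$truth$atoms[1:10, ]
  frac <- cart_to_frac(as.matrix(far[, c("x", "y", "z")]), toy$refl$cell)
  keep_away <- !fragphase:::points_in_mask(
    frac_to_cart((frac + 0.5) %% 1, toy$refl$cell), mask)
  far[, c("x", "y", "z")] <- frac_to_cart((frac + 0.5) %% 1, toy$refl$cell)
  mixed <- structure_model(rbind(toy$truth$atoms[11:20, ], far))
  out <- filter_trace_outside_mask(mixed, mask)
  expect_equal(nrow(out$atoms), sum(keep_away))
  expect_equal(sum(fragphase:::points_in_mask(
    as.matrix(out$atoms[, c("x", "y", "z")]), mask)), 0)
})

test_that("verification verdicts: positive, negative and displaced-domain controls", {
  toy <- fix_toy3()
  rt <- fragphase:::residue_table(toy$truth)
  sol <- subset_residues(toy$truth, rt$key[rt$chain %in% c("A", "B")])
  bk <- synthetic_backend(toy$truth)
  cfg <- verify_config(n_res = 10, max_spheres = 8)
  rep_pos <- run_verification(sol, toy$refl, bk, cfg)
  expect_equal(rep_pos$verdict, "verified")
  expect_true(all(rep_pos$fragments$verified))
  expect_true(is_nonrandom(rep_pos$combined_wmpe))
  # negative control: randomly rotated model fails everywhere
  set.seed(19)
  bad <- transform_model(sol, rotation = random_rotation())
  rep_neg <- run_verification(bad, toy$refl, bk, cfg)
  expect_equal(rep_neg$verdict, "not-verified")
  expect_false(any(rep_neg$fragments$verified))
  # displaced chain: fragments in the intact chain verify, the rest fail
  disp <- sol
  sel <- disp$atoms$chain == "B"
  disp$atoms[sel, c("x", "y", "z")] <- disp$atoms[sel, c("x", "y", "z")] +
    8 / sqrt(3)
  rep_mix <- run_verification(disp, toy$refl, bk, cfg)
  frags <- shred_placed_solution(disp, 10, 8)
  frac_b <- vapply(frags, function(f) {
    mean(startsWith(f$residues, "B"))
  }, 1)
  expected <- frac_b < 0.5
  accuracy <- mean(rep_mix$fragments$verified == expected)
  expect_gte(accuracy, 0.75)
  expect_true(any(rep_mix$fragments$verified))
  expect_false(all(rep_mix$fragments$verified))
})

test_that("no retained trace atom ever lies in the masked region", {
  toy <- fix_toy3()
  rt <- fragphase:::residue_table(toy$truth)
  sol <- subset_residues(toy$truth, rt$key[rt$chain == "A"])
  mask <- build_model_mask(sol, toy$refl, radius = 2.5, spacing = 0.7)
  bk <- synthetic_backend(toy$truth)
  sf <- calc_structure_factors(sol, toy$refl)
  res <- bk(phase_set(sf$phi, label = "a"), mask, toy$refl)
  expect_true(res$expanded)
  expect_equal(sum(fragphase:::points_in_mask(
    as.matrix(res$trace$atoms[, c("x", "y", "z")]), mask)), 0)
  # and none of the solution's own atoms survive in the trace
  sol_xyz <- as.matrix(sol$atoms[, c("x", "y", "z")])
  tr_xyz <- as.matrix(res$trace$atoms[, c("x", "y", "z")])
  d2min <- min(outer(rowSums(tr_xyz^2), rowSums(sol_xyz^2), "+") -
                 2 * tr_xyz %*% t(sol_xyz))
  expect_gt(sqrt(max(0, d2min)), 1)
})

test_that("translation scan recovers a planted fragment and standardizes scores", {
  toy <- fix_toy()
  rt <- fragphase:::residue_table(toy$truth)
  helA <- subset_residues(toy$truth, rt$key[rt$chain == "A"])
  cen <- colMeans(as.matrix(helA$atoms[, c("x", "y", "z")]))
  frag0 <- transform_model(helA, translation = -cen)
  true_t <- as.numeric(cart_to_frac(matrix(cen, 1), toy$refl$cell)) %% 1
  # standardization is exact by construction on the raw (unrefined) scan
  raw <- translation_scan(frag0, diag(3), toy$refl, grid = 1.5,
                          refine_top = 0)
  expect_equal(mean(raw$tfz), 0, tolerance = 1e-9)
  expect_equal(stats::sd(raw$tfz), 1, tolerance = 1e-9)
  scan <- translation_scan(frag0, diag(3), toy$refl, grid = 1.0)
  expect_lt(shift_distance(as.numeric(scan[1, c("tx", "ty", "tz")]),
                           true_t, toy$refl), 1.0 * sqrt(3))
  # wrong rotation scores below the correct one
  scan_bad <- translation_scan(frag0, axis_rotation(c(0, 0, 1), 90),
                               toy$refl, grid = 1.5)
  expect_gt(max(scan$tfz), max(scan_bad$tfz))
})

test_that("packing filter rejects clashes, including pure symmetry clashes", {
  toy <- fix_toy()
  rt <- fragphase:::residue_table(toy$truth)
  helA <- subset_residues(toy$truth, rt$key[rt$chain == "A"])
  expect_false(packing_filter(helA, list(helA), toy$refl))   # identical
  far <- transform_model(helA, translation = c(300, 0, 0))
  big_refl <- generate_hkl(c(600, 600, 600, 90, 90, 90), "P1", 50)
  expect_true(packing_filter(far, list(helA), big_refl))
  # symmetry-only clash: candidate near the 2-fold screw image of fixed
  frac <- cart_to_frac(as.matrix(helA$atoms[, c("x", "y", "z")]),
                       toy$refl$cell)
  op <- toy$refl$sg$ops[[2]]
  img <- sweep(frac %*% t(op$R), 2, op$v, "+")
  cand <- helA
  cand$atoms[, c("x", "y", "z")] <- frac_to_cart(img, toy$refl$cell)
  # far from the fixed copy directly, clashing only through symmetry
  direct_min <- min(dist(rbind(
    colMeans(as.matrix(cand$atoms[, c("x", "y", "z")])),
    colMeans(as.matrix(helA$atoms[, c("x", "y", "z")])))))
  expect_false(packing_filter(cand, list(helA), toy$refl))
})

test_that("multicopy prioritization promotes the true probe; single-copy control stays flat", {
  wins <- 0
  for (seed in 1:5) {
    toy2 <- make_toy_crystal(toy_crystal_spec(
      spacegroup = "P21", cell = c(30, 26, 34, 90, 100, 90),
      n_helices = 2, helix_len = 12, d_min = 3.0, seed = seed))
    rt <- fragphase:::residue_table(toy2$truth)
    helA <- subset_residues(toy2$truth, rt$key[rt$chain == "A"])
    cen <- colMeans(as.matrix(helA$atoms[, c("x", "y", "z")]))
    frag0 <- transform_model(helA, translation = -cen)
    correct <- helA
    set.seed(seed * 100)
    decoys <- lapply(1:3, function(i) {
      t_ <- stats::runif(3)
      fragphase:::place_fragment(frag0, diag(3), t_, toy2$refl$cell)
    })
    # constructed landscape: decoys carry higher first-copy scores
    probes <- c(list(list(model = correct, rotation = diag(3), score = 10,
                          label = "correct")),
                lapply(seq_along(decoys), function(i) {
                  list(model = decoys[[i]], rotation = diag(3),
                       score = 20 + i, label = paste0("decoy", i))
                }))
    rk <- prioritize_multicopy(probes, frag0, toy2$refl,
                               verify_config(scan_grid = 2, top_n = 1,
                                             n_copies = 2))
    if (rk$label[1] == "correct") wins <- wins + 1
    expect_equal(sum(rk$flagged), 1)
  }
  expect_gte(wins, 4)
})

test_that("second-copy promotion signal vanishes on a single-copy crystal", {
  seed <- 2
  # two-copy crystal: correct probe gains a strong second-copy score
  toy2 <- make_toy_crystal(toy_crystal_spec(
    "P21", c(30, 26, 34, 90, 100, 90), 2, 12, 3.0, seed))
  rt2 <- fragphase:::residue_table(toy2$truth)
  helA2 <- subset_residues(toy2$truth, rt2$key[rt2$chain == "A"])
  cen2 <- colMeans(as.matrix(helA2$atoms[, c("x", "y", "z")]))
  frag2 <- transform_model(helA2, translation = -cen2)
  probes2 <- list(list(model = helA2, rotation = diag(3), score = 10,
                       label = "correct"))
  rk2 <- prioritize_multicopy(probes2, frag2, toy2$refl,
                              verify_config(scan_grid = 2, top_n = 1,
                                            n_copies = 2))
  # single-copy crystal, same search asked for two copies
  toy1 <- make_toy_crystal(toy_crystal_spec(
    "P21", c(30, 26, 34, 90, 100, 90), 1, 12, 3.0, seed))
  rt1 <- fragphase:::residue_table(toy1$truth)
  helA1 <- subset_residues(toy1$truth, rt1$key[rt1$chain == "A"])
  cen1 <- colMeans(as.matrix(helA1$atoms[, c("x", "y", "z")]))
  frag1 <- transform_model(helA1, translation = -cen1)
  probes1 <- list(list(model = helA1, rotation = diag(3), score = 10,
                       label = "correct"))
  # in the crowded single-copy cell a packing-valid second placement may
  # not exist at all; either way the promotion signal must be weaker
  rk1 <- suppressWarnings(
    prioritize_multicopy(probes1, frag1, toy1$refl,
                         verify_config(scan_grid = 2, top_n = 1,
                                       n_copies = 2)))
  expect_true(is.na(rk1$second_score[1]) ||
                rk1$second_score[1] < rk2$second_score[1])
})
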