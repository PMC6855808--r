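# tiny frame builder: single-bead lipids at given xy per leaflet
tiny_frame <- function(lip_xy, species, leaflet_z, protein_xy = NULL,
                       box = c(100, 100)) {
  if (is.null(protein_xy)) {
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    protein_xy <- cbind(50 + 10 * cos(ang), 50 + 10 * sin(ang))
  }
  protein <- data.frame(x = rep(protein_xy[, 1], 2),
                        y = rep(protein_xy[, 2], 2),
                        z = rep(c(17, -17), each = nrow(protein_xy)),
                        tmd = TRUE)
  lipids <- data.frame(lipid_id = sprintf("L%03d", seq_len(nrow(lip_xy))),
                       species = species, bead = "PO4",
                       x = lip_xy[, 1], y = lip_xy[, 2], z = leaflet_z,
                       phosphate = TRUE)
  membrane_frame(protein, lipids, box = box)
}

test_that("leaflet assignment splits lipids by phosphate z about the median", {
  fr <- tiny_frame(rbind(c(10, 10), c(20, 20)), "POPC", c(20, -20))
  lab <- assign_leaflets(fr)
  expect_equal(unname(lab), c("outer", "inner"))
  # mirroring the frame in z swaps the labels
  fr2 <- fr; fr2$lipids$z <- -fr2$lipids$z
  expect_equal(unname(assign_leaflets(fr2)), c("inner", "outer"))
  # generator round-trip: construction leaflets recovered exactly
  frames <- gen_membrane_frames(c(POPG = 0.5, POPC = 0.5), n_lipids = 200,
                                n_frames = 1, seed = 7)
  fr3 <- frames[[1]]
  lab3 <- assign_leaflets(fr3)
  truth <- ifelse(fr3$lipids$z[fr3$lipids$phosphate] > 0, "outer", "inner")
  expect_equal(unname(lab3[as.character(fr3$lipids$lipid_id[fr3$lipids$phosphate])]),
               truth)
  flat <- fr
  flat$lipids$z <- 5
  expect_error(assign_leaflets(flat), "coplanar")
})

test_that("boundary classification applies the 6 A cutoff inclusively", {
  # protein ring radius 10 about (50,50); nearest bead at angle 0 is (60,50)
  fr_in <- tiny_frame(rbind(c(65.9, 50)), "POPG", 17)
  expect_equal(find_boundary(fr_in)$b_tot, 1L)
  fr_out <- tiny_frame(rbind(c(66.1, 50)), "POPG", 17)
  expect_equal(find_boundary(fr_out)$b_tot, 0L)
  # periodic image: lipid near the far box edge is close to a lipid-free
  # protein only through wrap-around of distances
  fr_pbc <- tiny_frame(rbind(c(0.5, 50)), "POPG", 17,
                       protein_xy = cbind(99, 50), box = c(100, 100))
  expect_equal(find_boundary(fr_pbc, cutoff = 2)$b_tot, 1L)
})

test_that("vectorized boundary search equals brute-force all-pairs", {
  frames <- gen_membrane_frames(c(POPG = 0.3, POPC = 0.7), n_lipids = 300,
                                n_frames = 2, seed = 42,
                                box = c(120, 120))
  for (fr in frames) {
    bc <- find_boundary(fr)
    expect_setequal(bc$boundary_ids, brute_force_boundary_ids(fr))
  }
})

test_that("enrichment follows the boundary-over-bulk definition", {
  # single-species membrane: B = 0 exactly
  fr <- gen_membrane_frames(c(POPC = 1 - 1e-9, POPG = 1e-9), n_lipids = 400,
                            n_frames = 1, seed = 3)[[1]]
  fr$lipids$species <- "POPC"
  expect_equal(enrichment(fr, "POPC")$B, 0)
  # boundary fraction 0.2 against bulk 0.1 gives B = 1 (hand-built frames)
  ang_in <- seq(0, 2 * pi, length.out = 11)[-11]
  ang_out <- seq(0.1, 2 * pi + 0.1, length.out = 41)[-41]
  xy <- rbind(cbind(50 + 13 * cos(ang_in), 50 + 13 * sin(ang_in)),   # 10 boundary
              cbind(50 + 45 * cos(ang_out), 50 + 45 * sin(ang_out))) # 40 bulk
  sp <- c(rep(c("POPG", "POPC"), times = c(2, 8)),   # boundary: 0.2 POPG
          rep(c("POPG", "POPC"), times = c(3, 37))) # census: 5/50 = 0.1
  fr2 <- tiny_frame(xy, sp, 17, box = c(200, 200))
  res <- enrichment(fr2, "POPG")
  expect_equal(res$B, 1.0)
  expect_error(enrichment(fr2, "POPS"), "x_i = 0")
})

test_that("mixing conservation: species enrichments weighted by bulk sum to zero", {
  frames <- gen_membrane_frames(c(POPG = 0.2, POPE = 0.3, POPC = 0.5),
                                n_lipids = 600, n_frames = 3, seed = 9,
                                bias = c(POPG = 2, POPE = 1, POPC = 0.7))
  for (fr in frames) {
    bc <- find_boundary(fr)
    census <- table(tapply(as.character(fr$lipids$species),
                           fr$lipids$lipid_id, `[`, 1L))
    x <- as.numeric(census[bc$species]) / sum(census)
    B <- (bc$per_species / bc$b_tot) / x - 1
    expect_equal(sum(x * B), 0, tolerance = 1e-12)
  }
})

test_that("biased placement reproduces the closed-form enrichment", {
  comp <- c(POPG = 0.1, POPC = 0.9)
  bias <- c(POPG = 2.25, POPC = 1)
  frames <- gen_membrane_frames(comp, n_lipids = 1000, n_frames = 100,
                                bias = bias, seed = 21, box = c(200, 200),
                                protein_radius = 20)
  gt <- attr(frames, "ground_truth")
  expect_equal(unname(gt$expected_B["POPG"]), 1.0)  # 2.25/1.125 - 1
  res <- enrichment(frames, "POPG")
  se <- res$sd / sqrt(res$n_frames)
  expect_lt(abs(res$B - gt$expected_B[["POPG"]]), 3 * se)
})

test_that("boundary census reports mean and SD of totals", {
  fr <- gen_membrane_frames(c(POPG = 0.5, POPC = 0.5), n_lipids = 500,
                            n_frames = 2, seed = 5)[[1]]
  expect_equal(boundary_census(list(fr, fr))$sd, 0)
  # frames constructed with exactly 30 boundary lipids
  ang_b <- seq(0, 2 * pi, length.out = 31)[-31]
  ang_f <- seq(0.05, 2 * pi + 0.05, length.out = 21)[-21]
  xy <- rbind(cbind(50 + 13 * cos(ang_b), 50 + 13 * sin(ang_b)),
              cbind(50 + 45 * cos(ang_f), 50 + 45 * sin(ang_f)))
  fr30 <- tiny_frame(xy, "POPC", 17, box = c(200, 200))
  cen <- boundary_census(list(fr30, fr30))
  expect_equal(cen$mean, 30)
  # total equals the sum of per-species boundary counts
  bc <- find_boundary(fr)
  expect_equal(sum(bc$per_species), bc$b_tot)
})

test_that("polar density maps bin phosphates and conserve counts", {
  # single phosphate at r = 10, theta = 0.1 rad from the protein center
  ctr <- c(50, 50)
  xy <- rbind(ctr + 10 * c(cos(0.1), sin(0.1)), c(5, 5))
  fr <- tiny_frame(xy, "POPG", c(17, -17), box = c(100, 100))
  pd <- polar_density(list(fr), "POPG", leaflet = "outer",
                      frame_window = "all")
  expect_equal(dim(pd$counts), c(10L, 30L))
  expect_equal(pd$counts[3, 1], 1)  # radial bin [8,12), angular [0, pi/15)
  expect_equal(sum(pd$counts), 1)
  # absent species: all-zero map
  pd0 <- polar_density(list(fr), "POPE", leaflet = "outer",
                       frame_window = "all")
  expect_true(all(pd0$counts == 0))
  expect_error(polar_density(list(fr), "POPG", r_max = 41), "binning")
  # count conservation on generated frames
  frames <- gen_membrane_frames(c(POPG = 1 - 1e-9, POPC = 1e-9),
                                n_lipids = 1200, n_frames = 4, seed = 11,
                                box = c(150, 150), protein_radius = 15)
  pdw <- polar_density(frames, "POPG", leaflet = "outer",
                       frame_window = "all")
  counts_direct <- vapply(frames, function(fr) {
    leaf <- assign_leaflets(fr)
    ph <- fr$lipids[fr$lipids$phosphate & fr$lipids$species == "POPG", ]
    tmd <- fr$protein[fr$protein$tmd, ]
    r <- sqrt((ph$x - mean(tmd$x))^2 + (ph$y - mean(tmd$y))^2)
    sum(r < 40 & leaf[as.character(ph$lipid_id)] == "outer")
  }, numeric(1))
  expect_equal(sum(pdw$counts), mean(counts_direct))
})

test_that("isotropic placement yields Poisson-consistent angular counts", {
  frames <- gen_membrane_frames(c(POPG = 1 - 1e-9, POPC = 1e-9),
                                n_lipids = 3000, n_frames = 10, seed = 13,
                                box = c(300, 300))
  pd <- polar_density(frames, "POPG", leaflet = "outer",
                      frame_window = "all")
  ang_counts <- colSums(pd$counts) * pd$n_frames  # total counts per angular bin
  p <- stats::chisq.test(ang_counts)$p.value
  expect_gt(p, 0.01)
})
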