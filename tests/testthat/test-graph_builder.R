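test_that("local frames are right-handed orthonormal bases at the CA", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0.5, 0.2), c(7.4, -0.3, 0.5),
              c(11, 0.2, 1))
  chain <- chain_from_ca(ca)
  frames <- build_local_frames(chain)
  for (i in seq_along(frames)) {
    R <- frames[[i]]$rotation
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
    expect_equal(frames[[i]]$origin, ca[i, ])
  }
  # hand Gram-Schmidt on the stated N/CA/C example
  r <- graphdock:::new_residue("ALA", 0L, "1",
                               rbind(N = c(-1, 0, 0), CA = c(0, 0, 0),
                                     C = c(1, 0.1, 0)),
                               matrix(numeric(0), 0, 3))
  f <- build_local_frames(
    graphdock:::chain_structure("Z", list(r, local({
      r2 <- r; r2$seq_index <- 1L
      r2$bb <- r2$bb + 4; r2
    }))))[[1L]]
  b3 <- c(0, 0, 1) * sign(graphdock:::cross3(c(1, 0, 0), c(1, 0.1, 0))[3L])
  expect_equal(abs(sum(f$rotation[3L, ] * b3)), 1, tolerance = 1e-8)
  expect_equal(f$rotation[1L, ],
               graphdock:::unit(c(2, 0.1, 0) -
                 sum(c(2, 0.1, 0) * f$rotation[3L, ]) * f$rotation[3L, ]),
               tolerance = 1e-8)
})

test_that("collinear backbone atoms raise a degenerate-geometry error", {
  r <- graphdock:::new_residue("ALA", 0L, "1",
                               rbind(N = c(-1, 0, 0), CA = c(0, 0, 0),
                                     C = c(1, 0, 0)),
                               matrix(numeric(0), 0, 3))
  r2 <- r; r2$seq_index <- 1L; r2$bb <- r2$bb + 5
  chain <- graphdock:::chain_structure("A", list(r, r2))
  expect_error(build_local_frames(chain), "collinear")
})

test_that("RBF encoding matches the Gaussian formula", {
  centers <- seq(0, 20, length.out = 16L)
  width <- centers[2L]
  enc <- rbf_encode(centers[5L], centers, width)
  expect_equal(enc[5L], 1.0)
  enc0 <- rbf_encode(0, centers, width)
  expect_equal(enc0[1L], 1.0)
  expect_true(all(enc0[-1L] < 1))
  # direct formula evaluation at d = 10
  d <- 10.0
  expect_equal(rbf_encode(d, centers, width),
               exp(-(d - centers)^2 / (2 * width^2)), tolerance = 1e-12)
})

test_that("relative rotation quaternions behave as expected", {
  f <- list(origin = c(0, 0, 0), rotation = diag(3))
  expect_equal(relative_rotation_quaternion(f, f), c(1, 0, 0, 0))
  # 180 degrees about the local z axis
  Rz <- diag(c(-1, -1, 1))
  g <- list(origin = c(0, 0, 0), rotation = Rz %*% f$rotation)
  q <- relative_rotation_quaternion(f, g)
  expect_equal(abs(q), c(0, 0, 0, 1), tolerance = 1e-9)
  expect_true(q[1L] >= -1e-6)  # scalar part at numerical zero for 180 deg
  # invariance under one global rotation applied to both frames
  set.seed(11)
  for (rep in 1:5) {
    Ra <- rand_rotation(); Rb <- rand_rotation(); G <- rand_rotation()
    fa <- list(origin = c(0, 0, 0), rotation = Ra)
    fb <- list(origin = c(0, 0, 0), rotation = Rb)
    ga <- list(origin = c(0, 0, 0), rotation = Ra %*% t(G))
    gb <- list(origin = c(0, 0, 0), rotation = Rb %*% t(G))
    expect_equal(relative_rotation_quaternion(fa, fb),
                 relative_rotation_quaternion(ga, gb), tolerance = 1e-9)
  }
})

test_that("node features: glycine zero side-chain block, one-hot sums to 1", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0.5, 0.2), c(7.4, -0.3, 0.5))
  chain <- chain_from_ca(ca, aa = c("ALA", "GLY", "TRP"))
  frames <- build_local_frames(chain)
  nf <- build_node_features(chain, frames)
  expect_equal(rowSums(nf[, 1:20]), rep(1, 3))
  layout <- attr(nf, "layout")
  sc_cols <- 20L + seq_len(layout$sidechain_slots * layout$slot_width)
  expect_true(all(nf[2L, sc_cols] == 0))   # glycine
  expect_true(any(nf[1L, sc_cols] != 0))
})

test_that("torsion block matches an independent dihedral computation", {
  chain <- make_toy_chain(6L, "helix", seed = 9L)
  frames <- build_local_frames(chain)
  nf <- build_node_features(chain, frames)
  tor_off <- ncol(nf) - 6L
  res <- chain$residues
  for (i in 2:5) {
    phi_ref <- bio3d::torsion.xyz(c(res[[i - 1L]]$bb["C", ],
                                    res[[i]]$bb["N", ],
                                    res[[i]]$bb["CA", ],
                                    res[[i]]$bb["C", ])) * pi / 180
    psi_ref <- bio3d::torsion.xyz(c(res[[i]]$bb["N", ],
                                    res[[i]]$bb["CA", ],
                                    res[[i]]$bb["C", ],
                                    res[[i + 1L]]$bb["N", ])) * pi / 180
    expect_equal(nf[i, tor_off + 1:2], c(sin(phi_ref), cos(phi_ref)),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(nf[i, tor_off + 3:4], c(sin(psi_ref), cos(psi_ref)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(unname(nf[1L, tor_off + 1:2]), c(0, 0))  # terminal phi sentinel
  expect_equal(unname(nf[6L, tor_off + 3:4]), c(0, 0))  # terminal psi sentinel
})

test_that("intra edges: k-NN matches brute force, short chains are masked", {
  chain <- make_toy_chain(5L, "helix", seed = 4L)
  frames <- build_local_frames(chain)
  e <- build_intra_edges(chain, frames, k = 30L)
  expect_equal(rowSums(e$mask), rep(4, 5))
  expect_true(all(is.na(e$neighbor_index[, 5:30])))
  ca <- graphdock:::ca_coords(chain)
  for (i in 1:5) {
    expect_equal(e$neighbor_index[i, 1:4], brute_knn(ca, i, 30L))
  }
  chain2 <- make_toy_chain(20L, "coil", seed = 8L)
  frames2 <- build_local_frames(chain2)
  e2 <- build_intra_edges(chain2, frames2, k = 7L)
  ca2 <- graphdock:::ca_coords(chain2)
  for (i in seq_len(20L)) {
    expect_equal(e2$neighbor_index[i, ], brute_knn(ca2, i, 7L))
  }
  # distances recoverable from sorted neighbour order are non-decreasing
  for (i in seq_len(20L)) {
    d <- sqrt(colSums((t(ca2[e2$neighbor_index[i, ], ]) - ca2[i, ])^2))
    expect_true(all(diff(d) >= -1e-9))
  }
})

test_that("interface residues match a brute-force all-pairs scan", {
  nat <- small_native()
  a <- nat$chains$A; b <- nat$chains$B
  iface <- find_interface_residues(a, b, cutoff = 10)
  D <- graphdock:::cross_dist(graphdock:::ca_coords(a),
                              graphdock:::ca_coords(b))
  expect_equal(iface$a, which(apply(D <= 10, 1L, any)))
  expect_equal(iface$b, which(apply(D <= 10, 2L, any)))
  expect_false(is.unsorted(iface$a))
  # far-apart chains have an empty interface
  far <- graphdock:::transform_chain(b, shift = c(500, 0, 0))
  iface2 <- find_interface_residues(a, far, cutoff = 10)
  expect_length(iface2$a, 0L)
  expect_length(iface2$b, 0L)
  # boundary: a single CA pair just inside the cutoff
  ca1 <- rbind(c(0, 0, 0), c(100, 0, 0))
  ca2 <- rbind(c(9.9, 0, 0), c(200, 0, 0))
  i3 <- find_interface_residues(chain_from_ca(ca1), chain_from_ca(ca2, "B"),
                                cutoff = 10)
  expect_equal(i3$a, 1L)
  expect_equal(i3$b, 1L)
})

test_that("inter edges: partners match brute force; short partner chains mask", {
  nat <- small_native()
  feats <- small_features()
  ie <- feats$inter
  ca_b <- graphdock:::ca_coords(nat$chains$B)
  ca_a <- graphdock:::ca_coords(nat$chains$A)
  for (r in seq_along(ie$interface_a)) {
    i <- ie$interface_a[r]
    d <- sqrt(colSums((t(ca_b) - ca_a[i, ])^2))
    expect_equal(ie$partner_a_to_b[r, 1:10],
                 order(round(d, 6L), seq_along(d))[1:10])
  }
  # |B| = 3 < m = 10 leaves trailing masked slots
  short_b <- chain_from_ca(rbind(c(8, 0, 0), c(11, 0, 0), c(14, 0, 0)), "B")
  a <- chain_from_ca(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  iface <- find_interface_residues(a, short_b)
  ie2 <- build_inter_edges(a, short_b, build_local_frames(a),
                           build_local_frames(short_b), iface)
  expect_equal(rowSums(ie2$mask_a_to_b), rep(3, length(iface$a)))
  expect_true(all(is.na(ie2$partner_a_to_b[, 4:10])))
})

test_that("swapping receptor/ligand permutes the A and B blocks exactly", {
  nat <- small_native()
  fa <- build_local_frames(nat$chains$A)
  fb <- build_local_frames(nat$chains$B)
  iface <- find_interface_residues(nat$chains$A, nat$chains$B)
  e_ab <- build_inter_edges(nat$chains$A, nat$chains$B, fa, fb, iface)
  e_ba <- build_inter_edges(nat$chains$B, nat$chains$A, fb, fa,
                            list(a = iface$b, b = iface$a))
  expect_equal(e_ab$edges_a_to_b, e_ba$edges_b_to_a)
  expect_equal(e_ab$partner_a_to_b, e_ba$partner_b_to_a)
  expect_equal(e_ab$edges_b_to_a, e_ba$edges_a_to_b)
  expect_equal(e_ab$interface_a, e_ba$interface_b)
})

test_that("all feature tensors are invariant under rigid transforms", {
  nat <- small_native()
  feats <- small_features()
  set.seed(21)
  for (rep in 1:20) {
    R <- rand_rotation()
    shift <- stats::rnorm(3L, sd = 30)
    moved <- graphdock:::transform_complex(nat, R = R, shift = shift)
    f2 <- featurize_complex(moved$chains$A, moved$chains$B)
    expect_lt(max(abs(f2$graph_a$nodes - feats$graph_a$nodes)), 1e-5)
    expect_lt(max(abs(f2$graph_b$nodes - feats$graph_b$nodes)), 1e-5)
    expect_lt(max(abs(f2$graph_a$edges$values - feats$graph_a$edges$values)),
              1e-5)
    expect_lt(max(abs(f2$inter$edges_a_to_b - feats$inter$edges_a_to_b)),
              1e-5)
    expect_lt(max(abs(f2$inter$edges_b_to_a - feats$inter$edges_b_to_a)),
              1e-5)
    expect_equal(f2$inter$interface_a, feats$inter$interface_a)
  }
})

test_that("quaternion blocks are unit norm with non-negative scalar part", {
  feats <- small_features()
  n_rbf <- length(feature_config()$rbf_centers)
  q_cols <- (n_rbf + 3L + 1L):(n_rbf + 3L + 4L)
  vals <- feats$graph_a$edges$values
  mask <- feats$graph_a$edges$mask
  for (i in seq_len(dim(vals)[1L])) {
    for (s in which(mask[i, ])) {
      q <- vals[i, s, q_cols]
      expect_equal(sum(q^2), 1, tolerance = 1e-6)
      expect_gte(q[1L], -1e-6)
    }
  }
})

test_that("feature archives round trip and refuse a layout mismatch", {
  feats <- small_features()
  tf <- withr::local_tempfile(fileext = ".rds")
  save_features(feats, tf)
  back <- load_features(tf)
  expect_equal(back$graph_a$nodes, feats$graph_a$nodes)
  bad <- readRDS(tf)
  bad$layout_version <- "other-layout"
  saveRDS(bad, tf)
  expect_error(load_features(tf), "layout")
})
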