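# Rotation/translation-invariant graph featurization of a docked chain pair.
# Every geometric quantity is expressed in per-residue local coordinate
# frames anchored at the alpha-carbons, so the resulting tensors are exactly
# invariant under rigid motions of the complex.

FEATURE_LAYOUT_VERSION <- "graphdock-features-1"

#' Featurization configuration
#'
#' Defaults: 16 radial-basis centers evenly spaced on 0-20 Angstrom with
#' width equal to the center spacing (covers contact through mid-range
#' distances), 30 intra-chain neighbours, 10 inter-chain partners, a
#' 10 Angstrom Calpha interface cutoff for exchange-layer membership, and
#' relative sequence offsets clipped to +/-32 (one-hot over 65 bins).
#'
#' @param n_rbf number of Gaussian centers.
#' @param rbf_max largest center, Angstrom.
#' @param k_intra intra-chain neighbour count.
#' @param m_inter inter-chain partner count.
#' @param interface_cutoff Calpha-Calpha interface membership cutoff, Angstrom.
#' @param relpos_clip sequence-offset clip; the one-hot has `2*clip+1` bins.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(n_rbf = 16L, rbf_max = 20, k_intra = 30L,
                           m_inter = 10L, interface_cutoff = 10,
                           relpos_clip = 32L) {
  centers <- seq(0, rbf_max, length.out = n_rbf)
  structure(list(
    rbf_centers = centers,
    rbf_width = centers[2L] - centers[1L],
    k_intra = as.integer(k_intra),
    m_inter = as.integer(m_inter),
    interface_cutoff = interface_cutoff,
    relpos_clip = as.integer(relpos_clip),
    layout_version = FEATURE_LAYOUT_VERSION
  ), class = "feature_config")
}

# Feature widths implied by a config.
feature_dims <- function(cfg) {
  n_rbf <- length(cfg$rbf_centers)
  relpos <- 2L * cfg$relpos_clip + 1L
  list(
    d_node = 20L + MAX_SIDECHAIN_ATOMS * (n_rbf + 3L) + 6L,
    d_edge_intra = n_rbf + 3L + 4L + relpos,
    d_edge_inter = n_rbf + 3L + 4L,
    n_rbf = n_rbf, relpos = relpos
  )
}

#' Gaussian radial-basis encoding of a distance
#'
#' Component j is `exp(-(d - center_j)^2 / (2 width^2))`; distances beyond the
#' center range decay smoothly rather than erroring.
#'
#' @param d non-negative distance(s), Angstrom.
#' @param centers vector of Gaussian centers.
#' @param width common Gaussian width.
#' @return For scalar `d` a vector; for vector `d` a `length(d) x n_centers`
#'   matrix.
#' @export
rbf_encode <- function(d, centers, width) {
  stopifnot(all(d >= 0), width > 0)
  out <- exp(-outer(d, centers, "-")^2 / (2 * width^2))
  if (length(d) == 1L) out[1L, ] else out
}

#' Build per-residue local coordinate frames
#'
#' Frame i is anchored at residue i's alpha-carbon: `b3` is the unit normal of
#' the N-CA-C plane (from the N->CA and CA->C cross product), `b1` the
#' backbone direction C-N orthogonalized against `b3`, and `b2 = b3 x b1`
#' completes a right-handed basis. The rotation matrix rows are (b1, b2, b3),
#' so left-multiplying a global vector yields its local coordinates.
#'
#' @param chain a `chain_structure`.
#' @return list of frames, each `list(origin, rotation)`.
#' @export
build_local_frames <- function(chain) {
  lapply(chain$residues, function(r) {
    N <- r$bb["N", ]; CA <- r$bb["CA", ]; C <- r$bb["C", ]
    nvec <- cross3(CA - N, C - CA)
    if (vec_norm(nvec) < 1e-8) {
      stop("degenerate backbone geometry (collinear N/CA/C) at residue ",
           r$seq_index, " (", r$aa, " ", r$author, ")")
    }
    b3 <- nvec / vec_norm(nvec)
    u <- C - N
    u <- u - sum(u * b3) * b3
    b1 <- u / vec_norm(u)
    b2 <- cross3(b3, b1)
    rot <- rbind(b1, b2, b3)
    dimnames(rot) <- NULL
    list(origin = CA, rotation = rot)
  })
}

#' Relative orientation quaternion of two local frames
#'
#' Returns the unit quaternion of the rotation carrying frame j's basis onto
#' frame i's (the orientation of j expressed in i), `R_i %*% t(R_j)` in the
#' rows-as-basis convention. This product is unchanged when one global
#' rotation is applied to both frames, which is what makes the edge features
#' invariant. Sign is canonicalized so the scalar part is non-negative.
#'
#' @param frame_i,frame_j frames from [build_local_frames()].
#' @return unit quaternion `(w, x, y, z)`.
#' @export
relative_rotation_quaternion <- function(frame_i, frame_j) {
  rotmat_to_quat(frame_i$rotation %*% t(frame_j$rotation))
}

# (sin, cos) embedding of backbone phi/psi/omega on the 3-torus; angles that
# are undefined at chain termini get the (0, 0) sentinel.
build_torsions <- function(chain) {
  n <- n_residues(chain)
  res <- chain$residues
  out <- matrix(0, n, 6L)
  colnames(out) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi",
                     "sin_omega", "cos_omega")
  for (i in seq_len(n)) {
    r <- res[[i]]
    if (i > 1L) {
      prev <- res[[i - 1L]]
      phi <- dihedral4(prev$bb["C", ], r$bb["N", ], r$bb["CA", ], r$bb["C", ])
      omega <- dihedral4(prev$bb["CA", ], prev$bb["C", ], r$bb["N", ],
                         r$bb["CA", ])
      out[i, 1:2] <- c(sin(phi), cos(phi))
      out[i, 5:6] <- c(sin(omega), cos(omega))
    }
    if (i < n) {
      nxt <- res[[i + 1L]]
      psi <- dihedral4(r$bb["N", ], r$bb["CA", ], r$bb["C", ], nxt$bb["N", ])
      out[i, 3:4] <- c(sin(psi), cos(psi))
    }
  }
  out
}

#' Build the node feature matrix for one chain
#'
#' Per residue: 20-dim one-hot amino-acid identity; for each of the
#' `MAX_SIDECHAIN_ATOMS` (10) topology-ordered heavy side-chain atom slots,
#' the RBF-encoded Calpha-to-atom distance and the unit direction vector in
#' the residue's local frame (empty slots zero-padded; glycine has none);
#' and the (sin, cos) torus embedding of phi, psi, omega.
#'
#' @param chain a `chain_structure`.
#' @param frames frames from [build_local_frames()].
#' @param config a [feature_config()].
#' @return `n x d_node` numeric matrix with a `layout` attribute describing
#'   the column blocks.
#' @export
build_node_features <- function(chain, frames, config = feature_config()) {
  n <- n_residues(chain)
  if (length(frames) != n) stop("frames do not match chain length")
  dims <- feature_dims(config)
  n_rbf <- dims$n_rbf
  slot_w <- n_rbf + 3L
  out <- matrix(0, n, dims$d_node)
  tors <- build_torsions(chain)
  for (i in seq_len(n)) {
    r <- chain$residues[[i]]
    aa_i <- match(r$aa, AA_ORDER)
    out[i, aa_i] <- 1
    sc <- r$sidechain
    if (nrow(sc) > 0) {
      Ri <- frames[[i]]$rotation
      ca <- frames[[i]]$origin
      for (s in seq_len(min(nrow(sc), MAX_SIDECHAIN_ATOMS))) {
        v <- sc[s, ] - ca
        d <- vec_norm(v)
        off <- 20L + (s - 1L) * slot_w
        out[i, (off + 1L):(off + n_rbf)] <-
          rbf_encode(d, config$rbf_centers, config$rbf_width)
        if (d > 1e-9) {
          out[i, (off + n_rbf + 1L):(off + slot_w)] <- as.numeric(Ri %*% (v / d))
        }
      }
    }
  }
  tor_off <- 20L + MAX_SIDECHAIN_ATOMS * slot_w
  out[, (tor_off + 1L):(tor_off + 6L)] <- tors
  attr(out, "layout") <- list(
    aa_onehot = 20L,
    sidechain_slots = MAX_SIDECHAIN_ATOMS,
    slot_width = slot_w,
    torsion = 6L,
    version = config$layout_version
  )
  out
}

# Edge feature vector for source residue i -> target j given frames and
# Calpha coordinates; relpos one-hot appended only for intra-chain edges.
edge_feature <- function(frame_i, frame_j, ca_i, ca_j, config,
                         relpos_offset = NULL) {
  v <- ca_j - ca_i
  d <- vec_norm(v)
  rbf <- rbf_encode(d, config$rbf_centers, config$rbf_width)
  dir_local <- if (d > 1e-9) as.numeric(frame_i$rotation %*% (v / d)) else
    c(0, 0, 0)
  quat <- relative_rotation_quaternion(frame_i, frame_j)
  feat <- c(rbf, dir_local, quat)
  if (!is.null(relpos_offset)) {
    clip <- config$relpos_clip
    bin <- max(-clip, min(clip, relpos_offset)) + clip + 1L
    rel <- numeric(2L * clip + 1L)
    rel[bin] <- 1
    feat <- c(feat, rel)
  }
  feat
}

#' Build intra-chain k-nearest-neighbour edge features
#'
#' For each residue, its `k` nearest residues by Calpha-Calpha distance
#' (ties broken by lower residue index; all residues if `n - 1 < k`, with a
#' validity mask). Per edge: RBF-encoded distance, unit direction in the
#' source residue's local frame, relative-orientation quaternion, and the
#' clipped one-hot relative sequence position. Neighbour slots are sorted by
#' increasing distance so masked slots always trail.
#'
#' @inheritParams build_node_features
#' @param k neighbour count.
#' @return list with `values` (`n x k x d_edge` array), `neighbor_index`
#'   (`n x k`, NA for masked slots), `mask` (`n x k` logical) and `k`.
#' @export
build_intra_edges <- function(chain, frames, k = NULL,
                              config = feature_config()) {
  n <- n_residues(chain)
  if (n < 2L) stop("chain must have at least 2 residues")
  k <- as.integer(k %||% config$k_intra)
  dims <- feature_dims(config)
  ca <- ca_coords(chain)
  D <- cross_dist(ca, ca)
  k_eff <- min(k, n - 1L)
  values <- array(0, dim = c(n, k, dims$d_edge_intra))
  nbr <- matrix(NA_integer_, n, k)
  mask <- matrix(FALSE, n, k)
  for (i in seq_len(n)) {
    # distances compared at 1e-6 A so exact ties (and their floating-point
    # perturbations under rigid motion) always break by lower residue index
    ord <- order(round(D[i, ], 6L), seq_len(n))
    ord <- ord[ord != i][seq_len(k_eff)]
    nbr[i, seq_len(k_eff)] <- ord
    mask[i, seq_len(k_eff)] <- TRUE
    for (s in seq_len(k_eff)) {
      j <- ord[s]
      values[i, s, ] <- edge_feature(frames[[i]], frames[[j]],
                                     ca[i, ], ca[j, ], config,
                                     relpos_offset = j - i)
    }
  }
  list(values = values, neighbor_index = nbr, mask = mask, k = k)
}

#' Find interface residues of a docked chain pair
#'
#' Residues of each chain with any Calpha within `cutoff` of any Calpha of
#' the partner chain. Both lists are sorted ascending and may be empty.
#'
#' @param a,b `chain_structure` objects.
#' @param cutoff Calpha-Calpha distance cutoff, Angstrom.
#' @return list with integer vectors `a` and `b` (1-based residue indices).
#' @export
find_interface_residues <- function(a, b, cutoff = 10.0) {
  D <- cross_dist(ca_coords(a), ca_coords(b))
  list(a = which(apply(D <= cutoff, 1L, any)),
       b = which(apply(D <= cutoff, 2L, any)))
}

#' Build inter-chain interface edges
#'
#' For each interface residue of A, edges to the `m` nearest residues of B by
#' Calpha distance (masked if B is shorter than `m`), carrying RBF distance,
#' local-frame direction and relative-orientation quaternion blocks only —
#' no relative sequence position, which is meaningless across chains. The
#' construction is symmetric for B to A.
#'
#' @param a,b chains; `frames_a`, `frames_b` their local frames.
#' @param interface result of [find_interface_residues()].
#' @param m partner count.
#' @param config a [feature_config()].
#' @return list of class `inter_chain_edges` with per-direction `values`
#'   (`n_interface x m x d_edge_inter`), `partner_index`, `mask`, the
#'   interface index vectors, and `m`.
#' @export
build_inter_edges <- function(a, b, frames_a, frames_b, interface,
                              m = NULL, config = feature_config()) {
  m <- as.integer(m %||% config$m_inter)
  dims <- feature_dims(config)
  ca_a <- ca_coords(a); ca_b <- ca_coords(b)
  one_direction <- function(idx_src, ca_src, frames_src, ca_dst, frames_dst) {
    n_src <- length(idx_src)
    n_dst <- nrow(ca_dst)
    m_eff <- min(m, n_dst)
    values <- array(0, dim = c(n_src, m, dims$d_edge_inter))
    partner <- matrix(NA_integer_, n_src, m)
    mask <- matrix(FALSE, n_src, m)
    if (n_src == 0L) {
      return(list(values = values, partner_index = partner, mask = mask))
    }
    D <- cross_dist(ca_src[idx_src, , drop = FALSE], ca_dst)
    for (r in seq_len(n_src)) {
      i <- idx_src[r]
      ord <- order(round(D[r, ], 6L), seq_len(n_dst))[seq_len(m_eff)]
      partner[r, seq_len(m_eff)] <- ord
      mask[r, seq_len(m_eff)] <- TRUE
      for (s in seq_len(m_eff)) {
        j <- ord[s]
        values[r, s, ] <- edge_feature(frames_src[[i]], frames_dst[[j]],
                                       ca_src[i, ], ca_dst[j, ], config)
      }
    }
    list(values = values, partner_index = partner, mask = mask)
  }
  ab <- one_direction(interface$a, ca_a, frames_a, ca_b, frames_b)
  ba <- one_direction(interface$b, ca_b, frames_b, ca_a, frames_a)
  structure(list(
    interface_a = interface$a, interface_b = interface$b,
    edges_a_to_b = ab$values, partner_a_to_b = ab$partner_index,
    mask_a_to_b = ab$mask,
    edges_b_to_a = ba$values, partner_b_to_a = ba$partner_index,
    mask_b_to_a = ba$mask,
    m = m
  ), class = "inter_chain_edges")
}

#' Build the full graph for one chain
#'
#' @inheritParams build_node_features
#' @param k intra-chain neighbour count (default from `config`).
#' @return list of class `protein_graph` with `nodes`, `edges`, `frames`.
#' @export
build_protein_graph <- function(chain, config = feature_config(), k = NULL) {
  frames <- build_local_frames(chain)
  structure(list(
    nodes = build_node_features(chain, frames, config),
    edges = build_intra_edges(chain, frames, k = k, config = config),
    frames = frames,
    n = n_residues(chain)
  ), class = "protein_graph")
}

#' Featurize a receptor/ligand pair for scoring
#'
#' Convenience wrapper producing both chain graphs and the interface edge
#' set in one call.
#'
#' @param receptor,ligand `chain_structure` objects.
#' @param config a [feature_config()].
#' @return list with `graph_a`, `graph_b`, `inter`, and the `config` used.
#' @export
featurize_complex <- function(receptor, ligand, config = feature_config()) {
  frames_a <- build_local_frames(receptor)
  frames_b <- build_local_frames(ligand)
  graph_a <- structure(list(
    nodes = build_node_features(receptor, frames_a, config),
    edges = build_intra_edges(receptor, frames_a, config = config),
    frames = frames_a, n = n_residues(receptor)
  ), class = "protein_graph")
  graph_b <- structure(list(
    nodes = build_node_features(ligand, frames_b, config),
    edges = build_intra_edges(ligand, frames_b, config = config),
    frames = frames_b, n = n_residues(ligand)
  ), class = "protein_graph")
  interface <- find_interface_residues(receptor, ligand,
                                       cutoff = config$interface_cutoff)
  inter <- build_inter_edges(receptor, ligand, frames_a, frames_b,
                             interface, config = config)
  list(graph_a = graph_a, graph_b = graph_b, inter = inter, config = config)
}

#' Save/load featurized complexes
#'
#' Feature archives embed the layout version; loading refuses archives
#' written under a different layout.
#'
#' @param features result of [featurize_complex()].
#' @param path file path (RDS archive).
#' @export
save_features <- function(features, path) {
  features$layout_version <- features$config$layout_version
  saveRDS(features, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  x <- readRDS(path)
  if (!identical(x$layout_version, FEATURE_LAYOUT_VERSION)) {
    stop("feature archive layout '", x$layout_version %||% "<missing>",
         "' does not match '", FEATURE_LAYOUT_VERSION, "'")
  }
  x
}
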