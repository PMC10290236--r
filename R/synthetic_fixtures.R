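# Deterministic generator of toy protein complexes and docking decoys.
# Chains are built on idealized fold geometry (helix: 1.5 Angstrom rise,
# 100 degree twist) with a single pseudo side-chain heavy atom per
# non-glycine residue (a "bulky" variant places three, exercising the
# multi-slot node layout). Near-native decoys come from small rigid
# perturbations of the ligand; incorrect decoys from re-placing the ligand
# on a shell around the receptor with the native interface destroyed.

#' Specification of a synthetic two-chain fixture
#'
#' @param n_residues_a,n_residues_b chain lengths (>= 4).
#' @param fold backbone geometry: `helix`, `strand`, or `coil` (helix with
#'   small seeded coordinate noise).
#' @param contact_target desired number of interface Calpha contacts at
#'   6 Angstrom.
#' @param seed integer; fixes every random choice downstream.
#' @param bulky place 3 pseudo side-chain atoms per residue instead of 1.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues_a = 24L, n_residues_b = 18L,
                         fold = c("helix", "strand", "coil"),
                         contact_target = 6L, seed = 1L, bulky = FALSE) {
  fold <- match.arg(fold)
  stopifnot(n_residues_a >= 4L, n_residues_b >= 4L)
  structure(list(n_residues_a = as.integer(n_residues_a),
                 n_residues_b = as.integer(n_residues_b),
                 fold = fold, contact_target = as.integer(contact_target),
                 seed = as.integer(seed), bulky = isTRUE(bulky)),
            class = "fixture_spec")
}

helix_point <- function(t, radius, rise = 1.5, twist = 100 * pi / 180) {
  cbind(radius * cos(twist * t), radius * sin(twist * t), rise * t)
}

#' Generate a toy chain on idealized fold geometry
#'
#' @param n number of residues (>= 4).
#' @param fold `helix`, `strand`, or `coil`.
#' @param seed RNG seed (sequence, coil noise).
#' @param chain_id chain identifier.
#' @param bulky use 3 pseudo side-chain atoms (topology-named) per residue.
#' @return a `chain_structure`.
#' @export
make_toy_chain <- function(n, fold = "helix", seed = 1L, chain_id = "A",
                           bulky = FALSE) {
  stopifnot(n >= 4L)
  with_seed(seed, {
    pool <- if (bulky) {
      names(SIDECHAIN_TOPOLOGY)[lengths(SIDECHAIN_TOPOLOGY) >= 3L]
    } else AA_ORDER
    seq_aa <- sample(pool, n, replace = TRUE)
    ts <- seq_len(n)
    if (fold %in% c("helix", "coil")) {
      ca <- helix_point(ts, 2.3)
      nn <- helix_point(ts - 0.35, 1.6)
      cc <- helix_point(ts + 0.35, 1.6)
    } else {  # extended strand zigzag
      ca <- cbind(3.3 * ts, 0.5 * (-1)^ts, 0)
      nn <- ca + cbind(rep(-1.2, n), 0, 0.5)
      cc <- ca + cbind(rep(1.2, n), 0, 0.5)
    }
    if (fold == "coil") {
      jit <- function(m) m + matrix(stats::rnorm(length(m), sd = 0.15),
                                    nrow = nrow(m))
      ca <- jit(ca); nn <- jit(nn); cc <- jit(cc)
    }
    axis_xy <- if (fold == "strand") {
      cbind(ca[, 1L], 0, 0)
    } else cbind(0, 0, ca[, 3L])
    residues <- vector("list", n)
    for (i in seq_len(n)) {
      out_dir <- unit(ca[i, ] - axis_xy[i, ])
      o_atom <- cc[i, ] + 1.23 * out_dir
      bb <- rbind(N = nn[i, ], CA = ca[i, ], C = cc[i, ], O = o_atom)
      aa <- seq_aa[i]
      topo <- SIDECHAIN_TOPOLOGY[[aa]]
      n_sc <- if (aa == "GLY") 0L else if (bulky) 3L else 1L
      n_sc <- min(n_sc, length(topo))
      sc <- matrix(numeric(0), 0L, 3L)
      if (n_sc > 0L) {
        sc <- t(vapply(seq_len(n_sc), function(s) {
          ca[i, ] + (0.5 + s) * out_dir
        }, numeric(3)))
        rownames(sc) <- topo[seq_len(n_sc)]
      }
      residues[[i]] <- new_residue(aa = aa, seq_index = i - 1L,
                                   author = as.character(i),
                                   bb = bb, sidechain = sc)
    }
    chain_structure(chain_id, residues)
  })
}

chain_centroid <- function(chain) colMeans(heavy_atoms(chain)$xyz)

chain_radius <- function(chain) {
  h <- heavy_atoms(chain)$xyz
  max(sqrt(rowSums((h - rep(colMeans(h), each = nrow(h)))^2)))
}

center_chain <- function(chain) {
  transform_chain(chain, shift = -chain_centroid(chain))
}

min_interchain_dist <- function(a, b) {
  min(cross_dist(heavy_atoms(a)$xyz, heavy_atoms(b)$xyz))
}

ca_contact_count <- function(a, b, cutoff = 6.0) {
  sum(cross_dist(ca_coords(a), ca_coords(b)) <= cutoff)
}

#' Build a native synthetic complex
#'
#' Two toy chains are rigidly placed (seeded orientation search, receptor at
#' the origin, ligand approached along +x) so that the Calpha contact count
#' at 6 Angstrom reaches `max(3, contact_target)` without steric clash
#' (minimum inter-chain heavy-atom distance >= 2.5 Angstrom). The result is
#' guaranteed to pass [find_interacting_pairs()] with defaults.
#'
#' @param spec a [fixture_spec()].
#' @return a `complex_structure` with chains `A` (receptor) and `B` (ligand).
#' @export
make_native_complex <- function(spec) {
  a <- center_chain(make_toy_chain(spec$n_residues_a, spec$fold, spec$seed,
                                   "A", spec$bulky))
  b0 <- center_chain(make_toy_chain(spec$n_residues_b, spec$fold,
                                    spec$seed + 1L, "B", spec$bulky))
  target <- max(3L, spec$contact_target)
  placed <- with_seed(spec$seed + 7L, {
    found <- NULL
    for (attempt in seq_len(200L)) {
      R <- random_rotation()
      dir <- random_unit_vector()
      b_rot <- transform_chain(b0, R = R)
      d <- chain_radius(a) + chain_radius(b_rot) + 5
      while (d > 2) {
        b_try <- transform_chain(b_rot, shift = d * dir)
        if (min_interchain_dist(a, b_try) < 2.5) break
        if (ca_contact_count(a, b_try) >= target) {
          found <- b_try
          break
        }
        # approach in coarse steps while far, finer near contact range
        d <- d - if (min_interchain_dist(a, b_try) > 8) 0.5 else 0.1
      }
      if (!is.null(found)) break
    }
    found
  })
  if (is.null(placed)) {
    stop("could not place chains with >= ", target,
         " contacts and no clash; re-seed the fixture spec")
  }
  structure(list(chains = list(A = a, B = placed),
                 source = sprintf("synthetic-%d", spec$seed)),
            class = "complex_structure")
}

ligand_id <- function(complex) names(complex$chains)[2L]

apply_to_ligand <- function(complex, R = diag(3), shift = c(0, 0, 0),
                            about_centroid = TRUE) {
  lid <- ligand_id(complex)
  lig <- complex$chains[[lid]]
  if (about_centroid) {
    ctr <- chain_centroid(lig)
    lig <- transform_chain(lig, shift = -ctr)
    lig <- transform_chain(lig, R = R)
    lig <- transform_chain(lig, shift = ctr + shift)
  } else {
    lig <- transform_chain(lig, R = R, shift = shift)
  }
  complex$chains[[lid]] <- lig
  complex
}

random_unit_vector <- function() unit(stats::rnorm(3L))

#' Perturb a complex into a near-native decoy
#'
#' The ligand chain is rigidly moved by a seeded random translation of
#' magnitude up to `max_translation` and rotated about its centroid by up to
#' `max_rotation` degrees. The defaults (1.5 Angstrom, 8 degrees) keep the
#' decoys CAPRI acceptable or better on the toy fixtures.
#'
#' @param complex a two-chain `complex_structure`.
#' @param max_translation Angstrom.
#' @param max_rotation degrees.
#' @param seed RNG seed.
#' @return the perturbed `complex_structure`.
#' @export
perturb_near_native <- function(complex, max_translation = 1.5,
                                max_rotation = 8, seed = 1L) {
  stopifnot(length(complex$chains) == 2L)
  with_seed(seed, {
    shift <- if (max_translation > 0) {
      stats::runif(1L, 0, max_translation) * random_unit_vector()
    } else c(0, 0, 0)
    R <- diag(3)
    if (max_rotation > 0) {
      ang <- stats::runif(1L, 0, max_rotation) * pi / 180
      ax <- random_unit_vector()
      R <- quat_to_rotmat(c(cos(ang / 2), sin(ang / 2) * ax))
    }
    apply_to_ligand(complex, R = R, shift = shift)
  })
}

#' Randomize the ligand placement into an incorrect decoy
#'
#' The ligand is re-oriented randomly and its centroid placed on a shell
#' around the receptor (radius = sum of chain radii + margin), rejecting
#' placements that clash (minimum heavy-atom distance < 2.5 Angstrom) or
#' retain any native contact, so fnat against the native is exactly 0.
#'
#' @param complex the native two-chain `complex_structure`.
#' @param seed RNG seed.
#' @param margin shell margin, Angstrom.
#' @return the randomized `complex_structure`.
#' @export
randomize_placement <- function(complex, seed = 1L, margin = 6) {
  stopifnot(length(complex$chains) == 2L)
  rec <- complex$chains[[1L]]
  lig <- complex$chains[[ligand_id(complex)]]
  nat_contacts <- nrow(native_contacts(rec, lig))
  shell <- chain_radius(rec) + chain_radius(lig) + margin
  rec_ctr <- chain_centroid(rec)
  out <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(100L)) {
      R <- random_rotation()
      pos <- rec_ctr + shell * random_unit_vector()
      cand <- complex
      lid <- ligand_id(complex)
      l2 <- transform_chain(lig, shift = -chain_centroid(lig))
      l2 <- transform_chain(l2, R = R)
      l2 <- transform_chain(l2, shift = pos)
      cand$chains[[lid]] <- l2
      if (min_interchain_dist(rec, l2) < 2.5) next
      if (nat_contacts > 0 &&
          fraction_native_contacts(rec, l2, rec, lig) > 0) next
      found <- cand
      break
    }
    found
  })
  if (is.null(out)) {
    stop("rejection budget exhausted while randomizing ligand placement")
  }
  out
}

#' Generate a labeled synthetic decoy dataset
#'
#' One native per target spec; positives via [perturb_near_native()],
#' negatives via [randomize_placement()]. Every record carries quality
#' metrics computed against its native with the standard metric routines,
#' the CAPRI class, and a binary label (positives are acceptable or better
#' by construction).
#'
#' @param n_positive,n_negative decoy counts, split evenly across targets.
#' @param spec a [fixture_spec()] or a list of them (one target each).
#' @param seed master RNG seed.
#' @return list with `records` (manifest data.frame), `decoys` (list of
#'   `complex_structure`), and `natives` (one per target).
#' @export
make_dataset <- function(n_positive, n_negative, spec = fixture_spec(),
                         seed = 1L) {
  specs <- if (inherits(spec, "fixture_spec")) list(spec) else spec
  n_t <- length(specs)
  natives <- lapply(specs, make_native_complex)
  names(natives) <- sprintf("target%02d", seq_len(n_t))
  decoys <- list(); rows <- list()
  counts <- list(pos = n_positive, neg = n_negative)
  for (kind in names(counts)) {
    n_k <- counts[[kind]]
    for (i in seq_len(n_k)) {
      t_i <- ((i - 1L) %% n_t) + 1L
      nat <- natives[[t_i]]
      s_i <- seed + 1000L * (kind == "neg") + 10L * i + t_i
      dec <- if (kind == "pos") {
        perturb_near_native(nat, seed = s_i)
      } else {
        randomize_placement(nat, seed = s_i)
      }
      qm <- quality_metrics(dec, nat, "A", "B")
      id <- sprintf("%s_%s%03d", names(natives)[t_i], kind, i)
      decoys[[id]] <- dec
      rows[[id]] <- data.frame(
        decoy_id = id, target_id = names(natives)[t_i],
        chain_a = "A", chain_b = "B",
        irmsd = qm$irmsd, fnat = qm$fnat, lrmsd = qm$lrmsd,
        capri_class = qm$capri_class,
        label = as.integer(qm$capri_class != "incorrect"))
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, decoys = decoys, natives = natives)
}

#' Write a dataset to disk as PDB files plus a manifest TSV
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- dataset$records
  rec$decoy_path <- file.path(dir, paste0(rec$decoy_id, ".pdb"))
  rec$native_path <- file.path(dir, paste0(rec$target_id, "_native.pdb"))
  for (tid in names(dataset$natives)) {
    write_structure(dataset$natives[[tid]],
                    file.path(dir, paste0(tid, "_native.pdb")))
  }
  for (i in seq_len(nrow(rec))) {
    write_structure(dataset$decoys[[rec$decoy_id[i]]], rec$decoy_path[i])
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(rec, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
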