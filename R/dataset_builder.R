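# Decoy quality metrics (fnat, interface RMSD, ligand RMSD), CAPRI class
# assignment, binary labeling conventions, class balancing, and application
# of precomputed redundancy-filter tables.

as_xyz <- function(m) as.numeric(t(m))

#' Find interacting chain pairs in a complex
#'
#' A chain pair interacts when it has at least `min_pairs` alpha-carbon
#' pairs within `cutoff` Angstrom — the rule used to select biounit
#' complexes worth re-docking.
#'
#' @param complex a `complex_structure` with at least two chains.
#' @param min_pairs minimum number of Calpha contacts.
#' @param cutoff Calpha-Calpha contact distance, Angstrom.
#' @return data.frame with columns `chain_a`, `chain_b`, `n_contacts`
#'   (each unordered pair listed once).
#' @export
find_interacting_pairs <- function(complex, min_pairs = 3L, cutoff = 6.0) {
  ids <- names(complex$chains)
  if (length(ids) < 2L) stop("complex must have at least 2 chains")
  out <- data.frame(chain_a = character(0), chain_b = character(0),
                    n_contacts = integer(0))
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq((i + 1L), length(ids))) {
      D <- cross_dist(ca_coords(complex$chains[[ids[i]]]),
                      ca_coords(complex$chains[[ids[j]]]))
      nc <- sum(D <= cutoff)
      if (nc >= min_pairs) {
        out <- rbind(out, data.frame(chain_a = ids[i], chain_b = ids[j],
                                     n_contacts = nc))
      }
    }
  }
  out
}

#' Native inter-chain residue contacts
#'
#' Residue pairs (i in A, j in B) with any heavy-atom distance at or below
#' `contact_cutoff` Angstrom.
#'
#' @param native_a,native_b the two native chains.
#' @param contact_cutoff heavy-atom contact distance, Angstrom.
#' @return two-column integer matrix of 1-based residue index pairs.
#' @export
native_contacts <- function(native_a, native_b, contact_cutoff = 5.0) {
  ha <- heavy_atoms(native_a); hb <- heavy_atoms(native_b)
  D <- cross_dist(ha$xyz, hb$xyz)
  hit <- which(D <= contact_cutoff, arr.ind = TRUE)
  pairs <- unique(cbind(ha$residue[hit[, 1L]], hb$residue[hit[, 2L]]))
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  colnames(pairs) <- c("res_a", "res_b")
  pairs
}

#' Fraction of native contacts recapitulated by a decoy
#'
#' Residue correspondence is positional (`seq_index`), which assumes decoy
#' and native were parsed from structures with identical residue content.
#'
#' @param decoy_a,decoy_b decoy chains.
#' @param native_a,native_b native chains of the same lengths.
#' @param contact_cutoff heavy-atom contact distance, Angstrom.
#' @return fnat in `[0, 1]`; 0 with a warning if the native has no contacts.
#' @export
fraction_native_contacts <- function(decoy_a, decoy_b, native_a, native_b,
                                     contact_cutoff = 5.0) {
  if (n_residues(decoy_a) != n_residues(native_a) ||
      n_residues(decoy_b) != n_residues(native_b)) {
    stop("decoy and native chains differ in length; cannot correspond residues")
  }
  nat <- native_contacts(native_a, native_b, contact_cutoff)
  if (nrow(nat) == 0L) {
    warning("native interface has no contacts; fnat undefined, returning 0")
    return(0)
  }
  dec <- native_contacts(decoy_a, decoy_b, contact_cutoff)
  key <- function(p) paste(p[, 1L], p[, 2L])
  sum(key(nat) %in% key(dec)) / nrow(nat)
}

# Residues of each native chain with any heavy atom within `cutoff` of the
# partner chain (heavy-atom interface definition used by iRMSD).
interface_residues_heavy <- function(a, b, cutoff = 10.0) {
  ha <- heavy_atoms(a); hb <- heavy_atoms(b)
  D <- cross_dist(ha$xyz, hb$xyz)
  close_ab <- D <= cutoff
  list(a = sort(unique(ha$residue[apply(close_ab, 1L, any)])),
       b = sort(unique(hb$residue[apply(close_ab, 2L, any)])))
}

# Stack backbone atoms (N, CA, C, and O when present) of selected residues.
stack_backbone <- function(chain, residues) {
  out <- list()
  for (i in residues) {
    bb <- chain$residues[[i]]$bb
    out[[length(out) + 1L]] <- bb
  }
  do.call(rbind, out)
}

#' Interface RMSD between a decoy and its native complex
#'
#' Native interface residues are those with any heavy atom within
#' `interface_cutoff` of the partner chain. The decoy is superposed onto the
#' native by least squares over the backbone atoms (N, CA, C, plus O when
#' present) of those residues across both chains jointly, and the RMSD of
#' the same atoms is returned.
#'
#' @inheritParams fraction_native_contacts
#' @param interface_cutoff heavy-atom interface cutoff, Angstrom.
#' @return iRMSD in Angstrom.
#' @export
interface_rmsd <- function(decoy_a, decoy_b, native_a, native_b,
                           interface_cutoff = 10.0) {
  if (n_residues(decoy_a) != n_residues(native_a) ||
      n_residues(decoy_b) != n_residues(native_b)) {
    stop("decoy and native chains differ in length; cannot correspond residues")
  }
  iface <- interface_residues_heavy(native_a, native_b, interface_cutoff)
  if (length(iface$a) == 0L && length(iface$b) == 0L) {
    stop("native interface is empty; iRMSD undefined")
  }
  nat <- rbind(stack_backbone(native_a, iface$a),
               stack_backbone(native_b, iface$b))
  dec <- rbind(stack_backbone(decoy_a, iface$a),
               stack_backbone(decoy_b, iface$b))
  inds <- bio3d::atom2xyz(seq_len(nrow(nat)))
  fitted <- bio3d::fit.xyz(as_xyz(nat), as_xyz(dec),
                           fixed.inds = inds, mobile.inds = inds)
  diff <- matrix(fitted - as_xyz(nat), ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums(diff^2)))
}

#' Ligand RMSD between a decoy and its native complex
#'
#' Superposes the decoy receptor backbone onto the native receptor backbone
#' and reports the RMSD over the ligand backbone without refitting.
#'
#' @inheritParams fraction_native_contacts
#' @return LRMSD in Angstrom.
#' @export
ligand_rmsd <- function(decoy_a, decoy_b, native_a, native_b) {
  if (n_residues(decoy_a) != n_residues(native_a) ||
      n_residues(decoy_b) != n_residues(native_b)) {
    stop("decoy and native chains differ in length; cannot correspond residues")
  }
  nat_rec <- stack_backbone(native_a, seq_len(n_residues(native_a)))
  dec_rec <- stack_backbone(decoy_a, seq_len(n_residues(decoy_a)))
  nat_lig <- stack_backbone(native_b, seq_len(n_residues(native_b)))
  dec_lig <- stack_backbone(decoy_b, seq_len(n_residues(decoy_b)))
  n_rec <- nrow(nat_rec)
  fixed <- as_xyz(rbind(nat_rec, nat_lig))
  mobile <- as_xyz(rbind(dec_rec, dec_lig))
  rec_inds <- bio3d::atom2xyz(seq_len(n_rec))
  fitted <- bio3d::fit.xyz(fixed, mobile,
                           fixed.inds = rec_inds, mobile.inds = rec_inds)
  lig_inds <- bio3d::atom2xyz(n_rec + seq_len(nrow(nat_lig)))
  diff <- matrix(fitted[lig_inds] - fixed[lig_inds], ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums(diff^2)))
}

capri_env <- new.env(parent = emptyenv())

capri_table <- function() {
  if (is.null(capri_env$table)) {
    path <- system.file("extdata", "capri_criteria.csv", package = "graphdock")
    if (path == "") path <- file.path("inst", "extdata", "capri_criteria.csv")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    capri_env$table <- tab[order(-tab$rank), ]
  }
  capri_env$table
}

#' CAPRI quality class of a decoy
#'
#' Applies the standard four-level decision table (shipped as a reviewable
#' CSV in `extdata`): a decoy is `high` if fnat >= 0.5 and (LRMSD <= 1 or
#' iRMSD <= 1), `medium` if fnat >= 0.3 and (LRMSD <= 5 or iRMSD <= 2),
#' `acceptable` if fnat >= 0.1 and (LRMSD <= 10 or iRMSD <= 4), else
#' `incorrect`. The mapping is monotone: improving any metric never lowers
#' the class.
#'
#' @param irmsd,fnat,lrmsd quality metrics (vectorized).
#' @return character vector of classes.
#' @export
capri_quality <- function(irmsd, fnat, lrmsd) {
  stopifnot(all(irmsd >= 0), all(lrmsd >= 0),
            all(fnat >= 0 & fnat <= 1))
  tab <- capri_table()
  out <- rep("incorrect", length(irmsd))
  for (r in rev(seq_len(nrow(tab)))) {  # worst class first, best overwrites
    ok <- fnat >= tab$fnat_min[r] &
      (lrmsd <= tab$lrmsd_max[r] | irmsd <= tab$irmsd_max[r])
    out[ok] <- tab$class[r]
  }
  out
}

#' Compute all quality metrics for one decoy against its native
#'
#' @param decoy,native `complex_structure` objects with matching chains.
#' @param chain_a,chain_b receptor and ligand chain ids.
#' @param contact_cutoff heavy-atom contact cutoff for fnat, Angstrom.
#' @param interface_cutoff heavy-atom interface cutoff for iRMSD, Angstrom.
#' @return one-row data.frame: `irmsd`, `fnat`, `lrmsd`, `capri_class`.
#' @export
quality_metrics <- function(decoy, native, chain_a, chain_b,
                            contact_cutoff = 5.0, interface_cutoff = 10.0) {
  da <- decoy$chains[[chain_a]]; db <- decoy$chains[[chain_b]]
  na_ <- native$chains[[chain_a]]; nb <- native$chains[[chain_b]]
  if (is.null(da) || is.null(db) || is.null(na_) || is.null(nb)) {
    stop("chain '", chain_a, "'/'", chain_b, "' missing from decoy or native")
  }
  irmsd <- interface_rmsd(da, db, na_, nb, interface_cutoff)
  fnat <- suppressWarnings(
    fraction_native_contacts(da, db, na_, nb, contact_cutoff))
  lrmsd <- ligand_rmsd(da, db, na_, nb)
  data.frame(irmsd = irmsd, fnat = fnat, lrmsd = lrmsd,
             capri_class = capri_quality(irmsd, fnat, lrmsd))
}

#' Label and balance decoys for pre-training
#'
#' Positives are CAPRI acceptable or better; negatives (incorrect) are
#' subsampled uniformly (seeded) down to the positive count. Positives are
#' never upsampled and their internal quality composition is left as
#' generated. Rows gain `label` and `convention = "pretraining"`.
#'
#' @param records data.frame with a `capri_class` column.
#' @param seed RNG seed for the negative subsample.
#' @return balanced data.frame.
#' @export
label_pretraining <- function(records, seed = 1L) {
  pos <- records[records$capri_class != "incorrect", , drop = FALSE]
  neg <- records[records$capri_class == "incorrect", , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no positive (acceptable-or-better) decoys; returning empty set")
    out <- records[0L, , drop = FALSE]
    out$label <- integer(0); out$convention <- character(0)
    return(out)
  }
  if (nrow(neg) > nrow(pos)) {
    keep <- with_seed(seed, sample.int(nrow(neg), nrow(pos)))
    neg <- neg[sort(keep), , drop = FALSE]
  }
  pos$label <- 1L; neg$label <- 0L
  out <- rbind(pos, neg)
  out$convention <- "pretraining"
  rownames(out) <- NULL
  out
}

#' Label decoys for fine-tuning
#'
#' Positive iff iRMSD <= 4 Angstrom (boundary inclusive); no balancing.
#'
#' @param records data.frame with an `irmsd` column.
#' @return records with `label` and `convention = "finetuning"` added.
#' @export
label_finetuning <- function(records) {
  if (!"irmsd" %in% names(records)) stop("records must carry an 'irmsd' column")
  records$label <- as.integer(records$irmsd <= 4.0)
  records$convention <- "finetuning"
  records
}

#' Apply sequence-cluster and structure-similarity redundancy filters
#'
#' Removes (1) any example one of whose chains shares a sequence cluster
#' with a holdout member, then (2) any surviving example whose maximum
#' TM-score against any holdout reference is at or above `tm_threshold`
#' (0.40 is removed, 0.39 kept). The clustering and alignment tools run
#' upstream; their output tables are consumed here.
#'
#' @param examples data.frame in long form: `example_id`, `sequence_id`
#'   (one row per chain of each example).
#' @param cluster_table data.frame `sequence_id`, `cluster_id`.
#' @param tm_table data.frame `example_id`, `reference_id`, `tm_score`.
#' @param holdout_members character vector of holdout sequence ids.
#' @param tm_threshold removal threshold on the TM-score (inclusive).
#' @param strict error (TRUE) or warn (FALSE) on examples missing from the
#'   tables.
#' @return list: `kept` (example ids), `removed_cluster`, `removed_tm`,
#'   and `counts` per rule.
#' @export
apply_redundancy_filter <- function(examples, cluster_table, tm_table,
                                    holdout_members, tm_threshold = 0.4,
                                    strict = TRUE) {
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      stop("malformed ", what, " table: need columns ",
           paste(cols, collapse = ", "))
    }
  }
  need(examples, c("example_id", "sequence_id"), "examples")
  need(cluster_table, c("sequence_id", "cluster_id"), "cluster")
  need(tm_table, c("example_id", "reference_id", "tm_score"), "TM-score")

  miss_seq <- setdiff(examples$sequence_id, cluster_table$sequence_id)
  if (length(miss_seq)) {
    msg <- paste("sequence ids missing from cluster table:",
                 paste(utils::head(miss_seq, 5L), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  holdout_clusters <- cluster_table$cluster_id[
    cluster_table$sequence_id %in% holdout_members]
  ex_cluster <- merge(examples, cluster_table, by = "sequence_id",
                      all.x = TRUE)
  bad_cluster <- unique(ex_cluster$example_id[
    !is.na(ex_cluster$cluster_id) &
      ex_cluster$cluster_id %in% holdout_clusters])

  ids <- unique(examples$example_id)
  survivors <- setdiff(ids, bad_cluster)
  miss_tm <- setdiff(survivors, tm_table$example_id)
  if (length(miss_tm)) {
    msg <- paste("example ids missing from TM-score table:",
                 paste(utils::head(miss_tm, 5L), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  tm_max <- tapply(tm_table$tm_score, tm_table$example_id, max)
  bad_tm <- survivors[survivors %in% names(tm_max) &
                        tm_max[survivors] >= tm_threshold]
  kept <- setdiff(survivors, bad_tm)
  list(kept = kept,
       removed_cluster = sort(bad_cluster),
       removed_tm = sort(bad_tm),
       counts = c(cluster = length(bad_cluster), tm = length(bad_tm)))
}
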