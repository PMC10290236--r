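# Parsing of PDB-format coordinate files into validated chain/residue/atom
# records. Parsing itself is delegated to bio3d; this module owns the cleanup
# policy: altloc resolution, hydrogen/water/hetero exclusion, nonstandard
# residue mapping, and the complete-backbone requirement.

# The 20 standard residues, fixed order used by the one-hot node encoding.
AA_ORDER <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")

# Heavy side-chain atoms in standard topology order (CB first, then outward).
# TRP is the largest with 10 atoms, which fixes the node-feature slot count.
SIDECHAIN_TOPOLOGY <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

MAX_SIDECHAIN_ATOMS <- max(lengths(SIDECHAIN_TOPOLOGY))

# Nonstandard residues mapped to a standard parent; anything else is dropped.
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS")

new_residue <- function(aa, seq_index, author, bb, sidechain) {
  structure(list(aa = aa, seq_index = seq_index, author = author,
                 bb = bb, sidechain = sidechain),
            class = "residue_record")
}

#' Construct a chain structure
#'
#' @param chain_id single chain identifier string.
#' @param residues list of residue records as produced by [parse_structure()].
#' @return An object of class `chain_structure`.
#' @keywords internal
chain_structure <- function(chain_id, residues) {
  if (length(residues) < 2L) {
    stop("chain '", chain_id, "' has fewer than 2 usable residues")
  }
  idx <- vapply(residues, function(r) r$seq_index, integer(1))
  if (!identical(idx, seq_along(residues) - 1L)) {
    stop("seq_index must be consecutive from 0")
  }
  structure(list(chain_id = chain_id, residues = residues),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat("<chain_structure> chain", x$chain_id, "with",
      length(x$residues), "residues\n")
  invisible(x)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure>", x$source %||% "", "\n")
  for (ch in x$chains) {
    cat("  chain", ch$chain_id, ":", length(ch$residues), "residues\n")
  }
  invisible(x)
}

n_residues <- function(chain) length(chain$residues)

# n x 3 matrix of alpha-carbon coordinates.
ca_coords <- function(chain) {
  t(vapply(chain$residues, function(r) r$bb["CA", ], numeric(3)))
}

# All heavy atoms of a chain: matrix plus the residue index (1-based) of each.
heavy_atoms <- function(chain, backbone = TRUE, sidechain = TRUE) {
  coords <- list(); res_of <- integer(0)
  for (i in seq_along(chain$residues)) {
    r <- chain$residues[[i]]
    m <- NULL
    if (backbone) m <- r$bb
    if (sidechain && nrow(r$sidechain) > 0) m <- rbind(m, r$sidechain)
    if (!is.null(m)) {
      coords[[length(coords) + 1L]] <- m
      res_of <- c(res_of, rep.int(i, nrow(m)))
    }
  }
  list(xyz = do.call(rbind, coords), residue = res_of)
}

# Backbone atoms shared with a reference residue set; used by RMSD metrics.
backbone_coords <- function(chain, atoms = c("N", "CA", "C", "O")) {
  out <- list(); res_of <- integer(0)
  for (i in seq_along(chain$residues)) {
    bb <- chain$residues[[i]]$bb
    keep <- intersect(atoms, rownames(bb))
    out[[i]] <- bb[keep, , drop = FALSE]
    res_of <- c(res_of, rep.int(i, length(keep)))
  }
  list(xyz = do.call(rbind, out), residue = res_of)
}

#' Parse PDB-format text into a complex structure
#'
#' Reads ATOM/HETATM records (first MODEL only) and returns per-chain,
#' per-residue records with complete N/CA/C backbones. Alternate locations are
#' resolved to the highest occupancy (ties keep the first listed); hydrogens,
#' waters and hetero residues are excluded; selenomethionine and
#' selenocysteine are mapped to their standard parents (MSE to MET, SEC to
#' CYS); other nonstandard residues are dropped with a warning, as are
#' residues missing any of N, CA, C. Remaining residues are renumbered with a
#' gap-free 0-based `seq_index`; the author numbering (residue number plus
#' insertion code) is retained for reporting.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB-format text.
#' @param source optional identifier stored on the result.
#' @return A `complex_structure`: named list of chains plus `source`.
#' @export
parse_structure <- function(pdb_text, source = "text") {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(paste(pdb_text, collapse = "\n"), tf)
  read_structure(tf, source = source)
}

#' Read a PDB file from disk
#'
#' @inherit parse_structure return
#' @param path path to a PDB-format file.
#' @param source identifier stored on the result; defaults to the file name.
#' @export
read_structure <- function(path, source = basename(path)) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("no parseable ATOM records: ", conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no parseable ATOM records")

  # exclude hydrogens/deuterium and water
  elesy <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  guess_h <- grepl("^[0-9]*[HD]", trimws(at$elety))
  is_h <- elesy %in% c("H", "D") | (elesy == "" & guess_h)
  is_water <- at$resid %in% c("HOH", "WAT", "DOD")
  at <- at[!is_h & !is_water, , drop = FALSE]
  if (nrow(at) == 0L) stop("no parseable ATOM records")

  # residue identity: map or drop nonstandard residues
  resid <- toupper(at$resid)
  mapped <- resid %in% names(NONSTANDARD_MAP)
  hetero_keep <- at$type == "ATOM" | mapped
  standard <- resid %in% AA_ORDER
  dropped_res <- unique(resid[!(standard | mapped) & at$type == "ATOM"])
  if (length(dropped_res)) {
    warning("dropping nonstandard residue(s): ",
            paste(dropped_res, collapse = ", "))
  }
  keep <- hetero_keep & (standard | mapped)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable standard-residue ATOM records")
  resid <- toupper(at$resid)
  at$resid <- ifelse(resid %in% names(NONSTANDARD_MAP),
                     NONSTANDARD_MAP[resid], resid)
  # MSE selenium takes methionine's SD slot
  at$elety[resid == "MSE" & trimws(at$elety) == "SE"] <- "SD"

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- " "

  chains <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    res_key <- paste(ca$resno, ca$insert, sep = "|")
    residues <- list()
    warn_missing <- 0L
    for (rk in unique(res_key)) {
      ra <- ca[res_key == rk, , drop = FALSE]
      # altloc: per atom name keep highest occupancy, ties first listed
      nm <- trimws(ra$elety)
      pick <- unlist(lapply(split(seq_len(nrow(ra)), nm), function(ii) {
        ii[which.max(ra$o[ii])]
      }), use.names = FALSE)
      ra <- ra[sort(pick), , drop = FALSE]
      nm <- trimws(ra$elety)
      aa <- ra$resid[1L]
      if (!all(c("N", "CA", "C") %in% nm)) {
        warn_missing <- warn_missing + 1L
        next
      }
      bb_names <- intersect(c("N", "CA", "C", "O"), nm)
      bb <- unname(as.matrix(ra[match(bb_names, nm), c("x", "y", "z")]))
      dimnames(bb) <- list(bb_names, NULL)
      topo <- SIDECHAIN_TOPOLOGY[[aa]]
      sc_names <- topo[topo %in% nm]
      sc <- if (length(sc_names)) {
        m <- unname(as.matrix(ra[match(sc_names, nm), c("x", "y", "z"),
                                 drop = FALSE]))
        dimnames(m) <- list(sc_names, NULL)
        m
      } else matrix(numeric(0), 0L, 3L)
      residues[[length(residues) + 1L]] <- new_residue(
        aa = aa, seq_index = length(residues),
        author = paste0(ra$resno[1L], trimws(ra$insert[1L])),
        bb = bb, sidechain = sc)
    }
    if (warn_missing > 0L) {
      warning("chain '", ch, "': dropped ", warn_missing,
              " residue(s) with incomplete N/CA/C backbone")
    }
    if (length(residues) < 2L) {
      warning("chain '", ch, "' has <2 usable residues; dropped")
      next
    }
    chains[[ch]] <- chain_structure(ch, residues)
  }
  if (length(chains) == 0L) stop("no chain with >=2 usable residues")
  structure(list(chains = chains, source = source),
            class = "complex_structure")
}

#' Select a receptor/ligand chain pair from a complex
#'
#' Roles are positional only: the scoring model treats the pair symmetrically
#' apart from the order of the interface update.
#'
#' @param complex a `complex_structure`.
#' @param receptor_id,ligand_id chain identifiers, distinct.
#' @return list with elements `receptor` and `ligand` (chain structures).
#' @export
select_chain_pair <- function(complex, receptor_id, ligand_id) {
  if (identical(receptor_id, ligand_id)) {
    stop("receptor and ligand chain ids must be distinct")
  }
  for (id in c(receptor_id, ligand_id)) {
    if (!id %in% names(complex$chains)) {
      stop("chain '", id, "' not present in complex (has: ",
           paste(names(complex$chains), collapse = ", "), ")")
    }
  }
  list(receptor = complex$chains[[receptor_id]],
       ligand = complex$chains[[ligand_id]])
}

#' Write a complex structure as sanitized PDB
#'
#' @param complex a `complex_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(complex, path) {
  xyz <- c(); resno <- c(); chain <- c(); resid <- c(); elety <- c()
  for (ch in complex$chains) {
    for (r in ch$residues) {
      atoms <- rbind(r$bb, r$sidechain)
      for (j in seq_len(nrow(atoms))) {
        xyz <- c(xyz, atoms[j, ])
        resno <- c(resno, r$seq_index + 1L)
        chain <- c(chain, ch$chain_id)
        resid <- c(resid, r$aa)
        elety <- c(elety, rownames(atoms)[j])
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(xyz), resno = resno,
                   chain = chain, resid = resid, elety = elety)
  invisible(path)
}

# Apply one rigid transform (rotation R then translation shift) to every atom
# of a chain; used by fixtures and invariance tests.
transform_chain <- function(chain, R = diag(3), shift = c(0, 0, 0)) {
  move <- function(m) {
    out <- t(R %*% t(m)) + rep(shift, each = nrow(m))
    rownames(out) <- rownames(m)
    out
  }
  chain$residues <- lapply(chain$residues, function(r) {
    r$bb <- move(r$bb)
    if (nrow(r$sidechain) > 0) r$sidechain <- move(r$sidechain)
    r
  })
  chain
}

transform_complex <- function(complex, R = diag(3), shift = c(0, 0, 0)) {
  complex$chains <- lapply(complex$chains, transform_chain,
                           R = R, shift = shift)
  complex
}
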