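# Independent reference implementations used as oracles: per-residue loop
# attention, brute-force geometry scans, pairwise AUC, step-sum AP, Kabsch
# superposition via SVD, and an independently transcribed CAPRI gate table.
# These deliberately share no code with the package internals they check.

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Per-head, per-node loop attention. Hq: queries (n_g x d); edge_emb and
# partner node rows are concatenated per slot before the key/value maps.
naive_attention <- function(Hq, Eemb, partner_rows, mask, p, n_heads, dk, dv) {
  n_g <- nrow(Hq)
  slots <- length(mask) / n_g
  mask_mat <- matrix(mask, n_g, slots, byrow = TRUE)
  out <- matrix(0, n_g, n_heads * dv)
  for (i in seq_len(n_g)) {
    for (h in seq_len(n_heads)) {
      qc <- ((h - 1L) * dk + 1L):(h * dk)
      vc <- ((h - 1L) * dv + 1L):(h * dv)
      q <- as.numeric(Hq[i, ] %*% p$Wq[, qc])
      valid <- which(mask_mat[i, ])
      scores <- numeric(length(valid))
      vals <- matrix(0, length(valid), dv)
      for (s_i in seq_along(valid)) {
        s <- valid[s_i]
        row <- (i - 1L) * slots + s
        x <- c(Eemb[row, ], partner_rows[row, ])
        k <- as.numeric(x %*% p$Wk[, qc])
        vals[s_i, ] <- as.numeric(x %*% p$Wv[, vc])
        scores[s_i] <- sum(q * k) / sqrt(dk)
      }
      a <- softmax_vec(scores)
      out[i, vc] <- as.numeric(t(vals) %*% a)
    }
  }
  out %*% p$Wo + matrix(p$bo, n_g, length(p$bo), byrow = TRUE)
}

naive_layernorm <- function(X, g, b, eps = 1e-5) {
  t(apply(X, 1L, function(x) {
    g * (x - mean(x)) / sqrt(mean((x - mean(x))^2) + eps) + b
  }))
}

# Full intra-chain block mirror: attention + residual + LN + FFN + LN.
naive_intra_block <- function(H, Eemb, nbr_flat, mask_flat, p, cfg) {
  n <- nrow(H)
  partner_rows <- H[nbr_flat, , drop = FALSE]
  att <- naive_attention(H, Eemb, partner_rows, mask_flat, p,
                         cfg$n_heads, cfg$d_k, cfg$d_v)
  h1 <- naive_layernorm(H + att, p$ln1_g, p$ln1_b)
  f <- pmax(h1 %*% p$ffn_W1 + matrix(p$ffn_b1, n, cfg$d_inner, byrow = TRUE),
            0) %*% p$ffn_W2 + matrix(p$ffn_b2, n, cfg$d_model, byrow = TRUE)
  naive_layernorm(h1 + f, p$ln2_g, p$ln2_b)
}

# Interface update mirror: rows `idx` of H_src replaced via attention over
# edges to H_dst partner residues.
naive_exchange <- function(H_src, H_dst, Eemb, partner_flat, mask_flat,
                           idx, p, cfg) {
  if (length(idx) == 0L) return(H_src)
  Hq <- H_src[idx, , drop = FALSE]
  partner_rows <- H_dst[partner_flat, , drop = FALSE]
  att <- naive_attention(Hq, Eemb, partner_rows, mask_flat, p,
                         cfg$n_heads, cfg$d_k, cfg$d_v)
  upd <- naive_layernorm(Hq + att, p$ln_g, p$ln_b)
  H_src[idx, ] <- upd
  H_src
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Step-sum AP computed from an explicit ranked table (independent path).
stepsum_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1L)
  ap <- 0; r_prev <- 0
  for (t in thr) {
    pred <- scores >= t
    prec <- sum(labels[pred]) / sum(pred)
    rec <- sum(labels[pred]) / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# Full-sort top-N membership with the documented tie rule.
sorted_top_n <- function(set, n) {
  o <- order(-set$score, set$decoy_id, method = "radix")
  set$decoy_id[o][seq_len(n)]
}

# Kabsch superposition via SVD; returns RMSD of b onto a.
kabsch_rmsd <- function(a, b) {
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  s <- svd(t(bc) %*% ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- bc %*% t(R)
  sqrt(mean(rowSums((fit - ac)^2)))
}

# Independent transcription of the CAPRI gates as explicit branches.
capri_oracle <- function(irmsd, fnat, lrmsd) {
  if (fnat >= 0.5 && (lrmsd <= 1 || irmsd <= 1)) return("high")
  if (fnat >= 0.3 && (lrmsd <= 5 || irmsd <= 2)) return("medium")
  if (fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

class_rank <- function(x) {
  match(x, c("incorrect", "acceptable", "medium", "high"))
}

# Brute-force k nearest neighbours by CA distance; ties (compared at the
# documented 1e-6 A resolution) go to the lower index.
brute_knn <- function(ca, i, k) {
  d <- sqrt(colSums((t(ca) - ca[i, ])^2))
  ord <- order(round(d, 6L), seq_len(nrow(ca)))
  ord <- ord[ord != i]
  ord[seq_len(min(k, nrow(ca) - 1L))]
}
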