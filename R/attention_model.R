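# The scoring network: linear input embeddings, stacked neighbour-attention
# blocks (Transformer-style residual + layer normalization + position-wise
# feed-forward), a bi-directional interface exchange layer per block, masked
# mean pooling and a sigmoid head. Forward pass, analytic backpropagation and
# the Adam optimizer are implemented directly on base-R matrices; all
# randomness (initialization, dropout, shuffling) flows from the config seed.

#' Model configuration
#'
#' Defaults are the tuned hyperparameters of the scoring network:
#' `d_model = 16`, 3 heads, 3 layers, `d_k = 16`, `d_v = 32`,
#' `d_inner = 16`, 30 intra-chain neighbours and 10 inter-chain partners.
#'
#' @param d_model embedding width.
#' @param n_heads attention heads per block.
#' @param n_layers stacked blocks.
#' @param d_k,d_v per-head key and value widths.
#' @param d_inner feed-forward hidden width.
#' @param dropout dropout fraction in `[0, 1)` (training only).
#' @param seed master seed for initialization, dropout and shuffling.
#' @param exchange_mode `"sequential"` (the B-direction update reads A's
#'   already-updated embeddings) or `"simultaneous"` (both directions read
#'   pre-update snapshots).
#' @param feature a [feature_config()]; fixes the input widths.
#' @return list of class `model_config`.
#' @export
model_config <- function(d_model = 16L, n_heads = 3L, n_layers = 3L,
                         d_k = 16L, d_v = 32L, d_inner = 16L,
                         dropout = 0.1, seed = 1L,
                         exchange_mode = c("sequential", "simultaneous"),
                         feature = feature_config()) {
  exchange_mode <- match.arg(exchange_mode)
  stopifnot(d_model > 0, n_heads > 0, n_layers > 0, d_k > 0, d_v > 0,
            d_inner > 0, dropout >= 0, dropout < 1)
  dims <- feature_dims(feature)
  structure(list(
    d_model = as.integer(d_model), n_heads = as.integer(n_heads),
    n_layers = as.integer(n_layers), d_k = as.integer(d_k),
    d_v = as.integer(d_v), d_inner = as.integer(d_inner),
    dropout = dropout, seed = as.integer(seed),
    exchange_mode = exchange_mode,
    k_intra = feature$k_intra, m_inter = feature$m_inter,
    d_node = dims$d_node, d_edge_intra = dims$d_edge_intra,
    d_edge_inter = dims$d_edge_inter,
    feature = feature
  ), class = "model_config")
}

mat_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = 1 / sqrt(nrow)), nrow, ncol)
}

attn_param_init <- function(d, dk, dv, nh, ln = TRUE) {
  p <- list(Wq = mat_init(d, nh * dk),
            Wk = mat_init(2L * d, nh * dk),
            Wv = mat_init(2L * d, nh * dv),
            Wo = mat_init(nh * dv, d),
            bo = numeric(d))
  if (ln) { p$ln_g <- rep(1, d); p$ln_b <- numeric(d) }
  p
}

#' Initialize model parameters
#'
#' Fan-in-scaled Gaussian initialization (`sd = 1/sqrt(fan_in)`), zero
#' biases, unit layer-norm gains; deterministic given `config$seed`.
#'
#' @param config a [model_config()].
#' @return nested list of class `model_params` (weights plus the config).
#' @export
init_model <- function(config) {
  d <- config$d_model; nh <- config$n_heads
  dk <- config$d_k; dv <- config$d_v; di <- config$d_inner
  params <- with_seed(config$seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      intra <- attn_param_init(d, dk, dv, nh, ln = FALSE)
      intra$bo <- numeric(d)
      intra <- c(intra, list(
        ln1_g = rep(1, d), ln1_b = numeric(d),
        ffn_W1 = mat_init(d, di), ffn_b1 = numeric(di),
        ffn_W2 = mat_init(di, d), ffn_b2 = numeric(d),
        ln2_g = rep(1, d), ln2_b = numeric(d)))
      list(intra = intra,
           ex_ab = attn_param_init(d, dk, dv, nh),
           ex_ba = attn_param_init(d, dk, dv, nh))
    })
    list(
      embed = list(
        node_W = mat_init(config$d_node, d), node_b = numeric(d),
        edge_intra_W = mat_init(config$d_edge_intra, d),
        edge_intra_b = numeric(d),
        edge_inter_W = mat_init(config$d_edge_inter, d),
        edge_inter_b = numeric(d)),
      layers = layers,
      head = list(W1 = mat_init(2L * d, di), b1 = numeric(di),
                  W2 = mat_init(di, 1L), b2 = numeric(1L)))
  })
  params$config <- config
  class(params) <- "model_params"
  params
}

#' Total trainable parameter count
#'
#' @param params a `model_params` object.
#' @return integer count over all weight and bias tensors.
#' @export
count_params <- function(params) {
  p <- unclass(params); p$config <- NULL
  length(unlist(p, use.names = FALSE))
}

# ---- forward/backward primitives -------------------------------------------

add_bias <- function(X, b) X + rep(b, each = nrow(X))

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd_
  list(Y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, sd = sd_)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dX = (dxhat - m1 - xhat * m2) / cache$sd,
       dg = colSums(dY * xhat), db = colSums(dY))
}

drop_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL, rate = rate))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X))
  list(Y = X * mask / (1 - rate), mask = mask, rate = rate)
}

drop_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) return(dY)
  dY * cache$mask / (1 - cache$rate)
}

# Multi-head neighbour attention: queries from Hq (n_g x d), keys/values
# from X ((n_g*slots) x 2d) = [edge embedding ; neighbour node embedding].
attn_fwd <- function(Hq, X, p, n_g, slots, mask_flat, cfg) {
  nh <- cfg$n_heads; dk <- cfg$d_k; dv <- cfg$d_v
  Q <- Hq %*% p$Wq
  K <- X %*% p$Wk
  V <- X %*% p$Wv
  gidx <- rep(seq_len(n_g), each = slots)
  O <- matrix(0, n_g, nh * dv)
  Aflat <- vector("list", nh)
  for (h in seq_len(nh)) {
    qc <- ((h - 1L) * dk + 1L):(h * dk)
    vc <- ((h - 1L) * dv + 1L):(h * dv)
    S <- rowSums(Q[gidx, qc, drop = FALSE] * K[, qc, drop = FALSE]) / sqrt(dk)
    S[!mask_flat] <- -Inf
    M <- matrix(S, n_g, slots, byrow = TRUE)
    M <- M - apply(M, 1L, max)
    W <- exp(M)
    W <- W / rowSums(W)
    af <- as.vector(t(W))
    Aflat[[h]] <- af
    O[, vc] <- rowsum(V[, vc, drop = FALSE] * af, gidx)
  }
  out <- add_bias(O %*% p$Wo, p$bo)
  list(out = out, Q = Q, K = K, V = V, X = X, Hq = Hq, O = O,
       Aflat = Aflat, gidx = gidx, n_g = n_g, slots = slots,
       mask_flat = mask_flat)
}

attn_bwd <- function(dOut, cache, p, cfg) {
  nh <- cfg$n_heads; dk <- cfg$d_k; dv <- cfg$d_v
  n_g <- cache$n_g; slots <- cache$slots; gidx <- cache$gidx
  dWo <- t(cache$O) %*% dOut
  dbo <- colSums(dOut)
  dO <- dOut %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(nh)) {
    qc <- ((h - 1L) * dk + 1L):(h * dk)
    vc <- ((h - 1L) * dv + 1L):(h * dv)
    af <- cache$Aflat[[h]]
    dOh_exp <- dO[gidx, vc, drop = FALSE]
    dA_flat <- rowSums(dOh_exp * cache$V[, vc, drop = FALSE])
    dV[, vc] <- af * dOh_exp
    W <- matrix(af, n_g, slots, byrow = TRUE)
    dA <- matrix(dA_flat, n_g, slots, byrow = TRUE)
    dS <- W * (dA - rowSums(W * dA))
    dS_flat <- as.vector(t(dS)) / sqrt(dk)
    dQ[, qc] <- rowsum(dS_flat * cache$K[, qc, drop = FALSE], gidx)
    dK[, qc] <- dS_flat * cache$Q[gidx, qc, drop = FALSE]
  }
  list(dHq = dQ %*% t(p$Wq),
       dX = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = t(cache$Hq) %*% dQ,
                    Wk = t(cache$X) %*% dK,
                    Wv = t(cache$X) %*% dV,
                    Wo = dWo, bo = dbo))
}

# Intra-chain attention block: attention sub-layer + FFN, each with residual,
# dropout and layer normalization.
intra_fwd <- function(H, Eemb, nbr_flat, mask_flat, p, cfg, training) {
  n <- nrow(H); k <- length(nbr_flat) / n
  Hn <- H[nbr_flat, , drop = FALSE]
  X <- cbind(Eemb, Hn)
  at <- attn_fwd(H, X, p, n, k, mask_flat, cfg)
  d1 <- drop_fwd(at$out, cfg$dropout, training)
  l1 <- ln_fwd(H + d1$Y, p$ln1_g, p$ln1_b)
  F1 <- add_bias(l1$Y %*% p$ffn_W1, p$ffn_b1)
  Fr <- pmax(F1, 0)
  F2 <- add_bias(Fr %*% p$ffn_W2, p$ffn_b2)
  d2 <- drop_fwd(F2, cfg$dropout, training)
  l2 <- ln_fwd(l1$Y + d2$Y, p$ln2_g, p$ln2_b)
  list(out = l2$Y, at = at, d1 = d1, l1 = l1, F1 = F1, Fr = Fr,
       d2 = d2, l2 = l2, nbr_flat = nbr_flat, H = H)
}

intra_bwd <- function(dOut, cache, p, cfg) {
  d <- cfg$d_model
  b2 <- ln_bwd(dOut, cache$l2, p$ln2_g)
  dZ2 <- b2$dX
  dL1Y <- dZ2
  dF2 <- drop_bwd(dZ2, cache$d2)
  dFr <- dF2 %*% t(p$ffn_W2)
  g_ffn_W2 <- t(cache$Fr) %*% dF2
  g_ffn_b2 <- colSums(dF2)
  dF1 <- dFr * (cache$F1 > 0)
  dL1Y <- dL1Y + dF1 %*% t(p$ffn_W1)
  g_ffn_W1 <- t(cache$l1$Y) %*% dF1
  g_ffn_b1 <- colSums(dF1)
  b1 <- ln_bwd(dL1Y, cache$l1, p$ln1_g)
  dZ1 <- b1$dX
  dH <- dZ1
  datt <- drop_bwd(dZ1, cache$d1)
  ab <- attn_bwd(datt, cache$at, p, cfg)
  dH <- dH + ab$dHq
  dX <- ab$dX
  dE <- dX[, seq_len(d), drop = FALSE]
  dHn <- dX[, d + seq_len(d), drop = FALSE]
  sc <- rowsum(dHn, cache$nbr_flat)
  ridx <- as.integer(rownames(sc))
  dH[ridx, ] <- dH[ridx, , drop = FALSE] + sc
  grads <- ab$grads
  grads$ln1_g <- b1$dg; grads$ln1_b <- b1$db
  grads$ffn_W1 <- g_ffn_W1; grads$ffn_b1 <- g_ffn_b1
  grads$ffn_W2 <- g_ffn_W2; grads$ffn_b2 <- g_ffn_b2
  grads$ln2_g <- b2$dg; grads$ln2_b <- b2$db
  list(dH = dH, dE = dE, grads = grads)
}

zero_attn_grads <- function(p) lapply(p, function(x) x * 0)

# Interface exchange in one direction: rows `idx` of H_src are replaced by
# attention over their edges to partner residues of H_dst.
ex_fwd <- function(H_src, H_dst, Eemb, partner_flat, mask_flat, idx,
                   p, cfg, training) {
  if (length(idx) == 0L) {
    return(list(out = H_src, empty = TRUE))
  }
  m <- length(partner_flat) / length(idx)
  Hq <- H_src[idx, , drop = FALSE]
  Hp <- H_dst[partner_flat, , drop = FALSE]
  X <- cbind(Eemb, Hp)
  at <- attn_fwd(Hq, X, p, length(idx), m, mask_flat, cfg)
  dd <- drop_fwd(at$out, cfg$dropout, training)
  l <- ln_fwd(Hq + dd$Y, p$ln_g, p$ln_b)
  out <- H_src
  out[idx, ] <- l$Y
  list(out = out, empty = FALSE, at = at, dd = dd, l = l, idx = idx,
       partner_flat = partner_flat, n_dst = nrow(H_dst))
}

ex_bwd <- function(dOut, cache, p, cfg) {
  if (isTRUE(cache$empty)) {
    return(list(dH_src = dOut, dH_dst = NULL, dE = NULL,
                grads = zero_attn_grads(p)))
  }
  d <- cfg$d_model
  idx <- cache$idx
  dH_src <- dOut
  dRows <- dOut[idx, , drop = FALSE]
  lb <- ln_bwd(dRows, cache$l, p$ln_g)
  dZ <- lb$dX
  dHq <- dZ
  datt <- drop_bwd(dZ, cache$dd)
  ab <- attn_bwd(datt, cache$at, p, cfg)
  dHq <- dHq + ab$dHq
  dH_src[idx, ] <- dHq
  dX <- ab$dX
  dE <- dX[, seq_len(d), drop = FALSE]
  dHp <- dX[, d + seq_len(d), drop = FALSE]
  dH_dst <- matrix(0, cache$n_dst, d)
  sc <- rowsum(dHp, cache$partner_flat)
  ridx <- as.integer(rownames(sc))
  dH_dst[ridx, ] <- dH_dst[ridx, , drop = FALSE] + sc
  grads <- ab$grads
  grads$ln_g <- lb$dg; grads$ln_b <- lb$db
  list(dH_src = dH_src, dH_dst = dH_dst, dE = dE, grads = grads)
}

# ---- example preparation ---------------------------------------------------

flatten_edges <- function(values) {
  dm <- dim(values)
  matrix(aperm(values, c(2L, 1L, 3L)), dm[1L] * dm[2L], dm[3L])
}

flat_index <- function(idx_mat) {
  v <- as.vector(t(idx_mat))
  v[is.na(v)] <- 1L
  v
}

#' Prepare a featurized complex for the network
#'
#' Flattens the edge tensors and neighbour indices into the layout the
#' forward/backward passes consume. Called automatically by
#' [score_complex()] and the training loop.
#'
#' @param features result of [featurize_complex()].
#' @return list of class `prepared_example`.
#' @export
prepare_example <- function(features) {
  ga <- features$graph_a; gb <- features$graph_b; ie <- features$inter
  structure(list(
    n_a = ga$n, n_b = gb$n, k = ga$edges$k, m = ie$m,
    nodes_a = ga$nodes, nodes_b = gb$nodes,
    Ea = flatten_edges(ga$edges$values),
    nbrA = flat_index(ga$edges$neighbor_index),
    maskA = as.vector(t(ga$edges$mask)),
    Eb = flatten_edges(gb$edges$values),
    nbrB = flat_index(gb$edges$neighbor_index),
    maskB = as.vector(t(gb$edges$mask)),
    ia = ie$interface_a, ib = ie$interface_b,
    Eab = flatten_edges(ie$edges_a_to_b),
    pab = flat_index(ie$partner_a_to_b),
    mab = as.vector(t(ie$mask_a_to_b)),
    Eba = flatten_edges(ie$edges_b_to_a),
    pba = flat_index(ie$partner_b_to_a),
    mba = as.vector(t(ie$mask_b_to_a))
  ), class = "prepared_example")
}

# ---- full forward and backward ---------------------------------------------

score_fwd <- function(prep, params, training = FALSE) {
  cfg <- params$config
  em <- params$embed
  HA <- add_bias(prep$nodes_a %*% em$node_W, em$node_b)
  HB <- add_bias(prep$nodes_b %*% em$node_W, em$node_b)
  EA <- add_bias(prep$Ea %*% em$edge_intra_W, em$edge_intra_b)
  EB <- add_bias(prep$Eb %*% em$edge_intra_W, em$edge_intra_b)
  has_ab <- length(prep$ia) > 0L
  has_ba <- length(prep$ib) > 0L
  Eab <- if (has_ab) add_bias(prep$Eab %*% em$edge_inter_W, em$edge_inter_b)
  Eba <- if (has_ba) add_bias(prep$Eba %*% em$edge_inter_W, em$edge_inter_b)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    cA <- intra_fwd(HA, EA, prep$nbrA, prep$maskA, lp$intra, cfg, training)
    HA <- cA$out
    cB <- intra_fwd(HB, EB, prep$nbrB, prep$maskB, lp$intra, cfg, training)
    HB <- cB$out
    HB_for_ab <- HB
    e1 <- ex_fwd(HA, HB_for_ab, Eab, prep$pab, prep$mab, prep$ia,
                 lp$ex_ab, cfg, training)
    HA_snapshot <- HA
    HA <- e1$out
    HA_for_ba <- if (cfg$exchange_mode == "sequential") HA else HA_snapshot
    e2 <- ex_fwd(HB, HA_for_ba, Eba, prep$pba, prep$mba, prep$ib,
                 lp$ex_ba, cfg, training)
    HB <- e2$out
    caches[[l]] <- list(cA = cA, cB = cB, e1 = e1, e2 = e2)
  }
  va <- colMeans(HA); vb <- colMeans(HB)
  z <- matrix(c(va, vb), 1L)
  h1 <- add_bias(z %*% params$head$W1, params$head$b1)
  hr <- pmax(h1, 0)
  logit <- as.numeric(hr %*% params$head$W2 + params$head$b2)
  list(logit = logit, probability = 1 / (1 + exp(-logit)),
       caches = caches, z = z, h1 = h1, hr = hr,
       HA = HA, HB = HB, EA = EA, EB = EB, Eab = Eab, Eba = Eba,
       has_ab = has_ab, has_ba = has_ba)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

score_bwd <- function(prep, params, fwd, dlogit) {
  cfg <- params$config
  d <- cfg$d_model
  hd <- params$head
  g_head <- list(W1 = NULL, b1 = NULL, W2 = t(fwd$hr) * dlogit,
                 b2 = dlogit)
  dhr <- dlogit * t(hd$W2)
  dh1 <- dhr * (fwd$h1 > 0)
  g_head$W1 <- t(fwd$z) %*% dh1
  g_head$b1 <- as.numeric(dh1)
  dz <- dh1 %*% t(hd$W1)
  dHA <- matrix(dz[1L, seq_len(d)], prep$n_a, d, byrow = TRUE) / prep$n_a
  dHB <- matrix(dz[1L, d + seq_len(d)], prep$n_b, d, byrow = TRUE) / prep$n_b
  dEA <- 0; dEB <- 0; dEab <- 0; dEba <- 0
  g_layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    sequential <- cfg$exchange_mode == "sequential"
    b2x <- ex_bwd(dHB, cc$e2, lp$ex_ba, cfg)
    dHB <- b2x$dH_src
    # the B-direction read A's post-update matrix in sequential mode (its
    # gradient passes back through the A update) but the pre-update snapshot
    # in simultaneous mode (added after the A-direction backward)
    if (sequential && !is.null(b2x$dH_dst)) dHA <- dHA + b2x$dH_dst
    if (!is.null(b2x$dE)) dEba <- dEba + b2x$dE
    b1x <- ex_bwd(dHA, cc$e1, lp$ex_ab, cfg)
    dHA <- b1x$dH_src
    if (!sequential && !is.null(b2x$dH_dst)) dHA <- dHA + b2x$dH_dst
    if (!is.null(b1x$dH_dst)) dHB <- dHB + b1x$dH_dst
    if (!is.null(b1x$dE)) dEab <- dEab + b1x$dE
    bB <- intra_bwd(dHB, cc$cB, lp$intra, cfg)
    dHB <- bB$dH
    dEB <- dEB + bB$dE
    bA <- intra_bwd(dHA, cc$cA, lp$intra, cfg)
    dHA <- bA$dH
    dEA <- dEA + bA$dE
    g_layers[[l]] <- list(intra = add_grads(bA$grads, bB$grads),
                          ex_ab = b1x$grads, ex_ba = b2x$grads)
  }
  em_g <- list(
    node_W = t(prep$nodes_a) %*% dHA + t(prep$nodes_b) %*% dHB,
    node_b = colSums(dHA) + colSums(dHB),
    edge_intra_W = t(prep$Ea) %*% dEA + t(prep$Eb) %*% dEB,
    edge_intra_b = colSums(dEA) + colSums(dEB),
    edge_inter_W = matrix(0, cfg$d_edge_inter, d),
    edge_inter_b = numeric(d))
  if (fwd$has_ab && !identical(dEab, 0)) {
    em_g$edge_inter_W <- em_g$edge_inter_W + t(prep$Eab) %*% dEab
    em_g$edge_inter_b <- em_g$edge_inter_b + colSums(dEab)
  }
  if (fwd$has_ba && !identical(dEba, 0)) {
    em_g$edge_inter_W <- em_g$edge_inter_W + t(prep$Eba) %*% dEba
    em_g$edge_inter_b <- em_g$edge_inter_b + colSums(dEba)
  }
  list(embed = em_g, layers = g_layers, head = g_head)
}

# Binary cross-entropy loss and its gradient for one example.
bce_loss_grads <- function(prep, params, label, training = FALSE,
                           want_grads = TRUE) {
  fwd <- score_fwd(prep, params, training = training)
  p <- min(max(fwd$probability, 1e-12), 1 - 1e-12)
  loss <- -(label * log(p) + (1 - label) * log(1 - p))
  out <- list(loss = loss, probability = fwd$probability)
  if (want_grads) {
    out$grads <- score_bwd(prep, params, fwd, dlogit = fwd$probability - label)
  }
  out
}

#' Score a docked chain pair
#'
#' Runs the network in inference mode (dropout off; deterministic) and
#' returns the near-native probability. Higher is more near-native.
#'
#' @param graph_a,graph_b `protein_graph`s of receptor and ligand.
#' @param inter the `inter_chain_edges` between them.
#' @param params trained or initialized `model_params`.
#' @param metadata optional decoy identifier carried on the result.
#' @return list of class `score_prediction`: `probability`, `logit`,
#'   `metadata`.
#' @export
score_complex <- function(graph_a, graph_b, inter, params, metadata = NULL) {
  if (!inherits(params, "model_params")) stop("params must be model_params")
  cfg <- params$config
  if (ncol(graph_a$nodes) != cfg$d_node) {
    stop("graph featurization does not match the model config ",
         "(node width ", ncol(graph_a$nodes), " vs ", cfg$d_node, ")")
  }
  prep <- prepare_example(list(graph_a = graph_a, graph_b = graph_b,
                               inter = inter))
  fwd <- score_fwd(prep, params, training = FALSE)
  structure(list(probability = fwd$probability, logit = fwd$logit,
                 metadata = metadata), class = "score_prediction")
}

#' @export
print.score_prediction <- function(x, ...) {
  cat(sprintf("<score_prediction> p(near-native) = %.4f (logit %.4f)%s\n",
              x$probability, x$logit,
              if (is.null(x$metadata)) "" else paste0(" [", x$metadata, "]")))
  invisible(x)
}

# ---- optimization ----------------------------------------------------------

strip_params <- function(params) {
  p <- unclass(params); p$config <- NULL
  p
}

mean_val_loss <- function(preps, labels, params) {
  mean(vapply(seq_along(preps), function(i) {
    bce_loss_grads(preps[[i]], params, labels[i], training = FALSE,
                   want_grads = FALSE)$loss
  }, numeric(1)))
}

as_preps <- function(dataset) {
  lapply(dataset, function(ex) {
    if (inherits(ex$features, "prepared_example")) ex$features
    else prepare_example(ex$features)
  })
}

#' Train the scoring network
#'
#' Minimizes binary cross-entropy with Adam (default learning rate 1e-4),
#' one complex per step. The validation loss is checked several times per
#' epoch; training stops early when it has failed to improve for `patience`
#' consecutive checks, and the best-validation parameters are returned.
#' Fully deterministic given `config$seed`.
#'
#' @param train_set,val_set disjoint lists of examples, each a list with
#'   `features` (from [featurize_complex()] or [prepare_example()]) and
#'   `label` (0/1).
#' @param config a [model_config()].
#' @param params optional warm-start `model_params` (defaults to a fresh
#'   [init_model()]).
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience, in validation checks.
#' @param checks_per_epoch validation checks per epoch (default 4).
#' @param shuffle reshuffle the training order every epoch.
#' @param verbose print per-check losses.
#' @return list: `params` (best), `history` (data.frame with `step`,
#'   `epoch`, `split`, `loss`, `lr`).
#' @export
train_model <- function(train_set, val_set, config, params = NULL,
                        lr = 1e-4, epochs = 10L, patience = 3L,
                        checks_per_epoch = 4L, shuffle = TRUE,
                        verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L) {
    stop("train and validation sets must be non-empty")
  }
  labels_tr <- vapply(train_set, function(e) e$label, numeric(1))
  labels_va <- vapply(val_set, function(e) e$label, numeric(1))
  stopifnot(all(labels_tr %in% c(0, 1)), all(labels_va %in% c(0, 1)))
  preps_tr <- as_preps(train_set)
  preps_va <- as_preps(val_set)
  if (is.null(params)) params <- init_model(config)

  pv <- unlist(strip_params(params), use.names = FALSE)
  skeleton <- strip_params(params)
  m <- numeric(length(pv)); v <- numeric(length(pv))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n_tr <- length(preps_tr)
  check_every <- max(1L, floor(n_tr / checks_per_epoch))
  hist_rows <- list()
  best_val <- Inf; best_pv <- pv; bad_checks <- 0L
  step <- 0L; stopped <- FALSE

  rebuild <- function(pv) {
    p <- utils::relist(pv, skeleton)
    p$config <- config
    class(p) <- "model_params"
    p
  }

  with_seed(config$seed, {
    for (epoch in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(n_tr) else seq_len(n_tr)
      for (i in ord) {
        step <- step + 1L
        cur <- rebuild(pv)
        res <- bce_loss_grads(preps_tr[[i]], cur, labels_tr[i],
                              training = TRUE)
        gv <- unlist(res$grads, use.names = FALSE)
        m <- beta1 * m + (1 - beta1) * gv
        v <- beta2 * v + (1 - beta2) * gv^2
        mh <- m / (1 - beta1^step)
        vh <- v / (1 - beta2^step)
        pv <- pv - lr * mh / (sqrt(vh) + eps)
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          step = step, epoch = epoch, split = "train",
          loss = res$loss, lr = lr)
        if (step %% check_every == 0L) {
          vl <- mean_val_loss(preps_va, labels_va, rebuild(pv))
          hist_rows[[length(hist_rows) + 1L]] <- data.frame(
            step = step, epoch = epoch, split = "validation",
            loss = vl, lr = lr)
          if (verbose) {
            message(sprintf("step %d (epoch %d): val loss %.4f",
                            step, epoch, vl))
          }
          if (vl < best_val - 1e-9) {
            best_val <- vl; best_pv <- pv; bad_checks <- 0L
          } else {
            bad_checks <- bad_checks + 1L
            if (bad_checks >= patience) { stopped <- TRUE; break }
          }
        }
      }
      if (stopped) break
    }
  })
  history <- if (length(hist_rows)) do.call(rbind, hist_rows) else {
    data.frame(step = integer(0), epoch = integer(0),
               split = character(0), loss = numeric(0), lr = numeric(0))
  }
  list(params = rebuild(if (best_val < Inf) best_pv else pv),
       history = history)
}

#' Fine-tune a pre-trained model
#'
#' Identical loop to [train_model()] with a learning rate of 1e-5 and
#' warm-started weights.
#'
#' @inheritParams train_model
#' @param params pre-trained `model_params` (required).
#' @param lr learning rate (default 1e-5).
#' @param ... passed to [train_model()].
#' @return as [train_model()].
#' @export
fine_tune <- function(params, train_set, val_set, config = params$config,
                      lr = 1e-5, ...) {
  if (!inherits(params, "model_params")) {
    stop("fine_tune requires pre-trained model_params")
  }
  train_model(train_set, val_set, config, params = params, lr = lr, ...)
}

#' Save or load a model checkpoint
#'
#' Single-file archive of all named tensors with the embedded config and
#' feature-layout version; loading refuses a layout mismatch.
#'
#' @param params `model_params`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(params, path) {
  obj <- list(params = unclass(params),
              layout_version = params$config$feature$layout_version)
  saveRDS(obj, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$layout_version, FEATURE_LAYOUT_VERSION)) {
    stop("checkpoint feature layout '", obj$layout_version %||% "<missing>",
         "' does not match '", FEATURE_LAYOUT_VERSION, "'")
  }
  params <- obj$params
  class(params) <- "model_params"
  params
}
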