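test_that("initialization is seed-deterministic with the declared size", {
  cfg <- model_config(seed = 5L)
  p1 <- init_model(cfg)
  p2 <- init_model(cfg)
  expect_identical(p1, p2)
  p3 <- init_model(model_config(seed = 6L))
  expect_false(identical(p1$embed$node_W, p3$embed$node_W))

  # closed-form parameter count from the declared shapes
  d <- cfg$d_model; nh <- cfg$n_heads; dk <- cfg$d_k; dv <- cfg$d_v
  di <- cfg$d_inner
  attn <- d * nh * dk + 2 * d * nh * dk + 2 * d * nh * dv + nh * dv * d + d
  intra <- attn + 2 * d + (d * di + di) + (di * d + d) + 2 * d
  exch <- attn + 2 * d
  embed <- (cfg$d_node * d + d) + (cfg$d_edge_intra * d + d) +
    (cfg$d_edge_inter * d + d)
  head_ <- (2 * d * di + di) + (di * 1 + 1)
  expect_equal(count_params(p1),
               embed + cfg$n_layers * (intra + 2 * exch) + head_)
})

test_that("attention weights normalize over valid slots only", {
  cfg <- tiny_config()
  feats <- small_features()
  prep <- prepare_example(feats)
  params <- init_model(cfg)
  H <- graphdock:::add_bias(prep$nodes_a %*% params$embed$node_W,
                            params$embed$node_b)
  E <- graphdock:::add_bias(prep$Ea %*% params$embed$edge_intra_W,
                            params$embed$edge_intra_b)
  X <- cbind(E, H[prep$nbrA, , drop = FALSE])
  at <- graphdock:::attn_fwd(H, X, params$layers[[1L]]$intra, prep$n_a,
                             prep$k, prep$maskA, cfg)
  for (h in seq_len(cfg$n_heads)) {
    A <- matrix(at$Aflat[[h]], prep$n_a, prep$k, byrow = TRUE)
    expect_equal(rowSums(A), rep(1, prep$n_a), tolerance = 1e-6)
    expect_true(all(A[!feats$graph_a$edges$mask] == 0))
  }
  # a single valid neighbour receives weight exactly 1
  two <- chain_from_ca(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  f2 <- featurize_complex(two, small_native()$chains$B, cfg$feature)
  p2 <- prepare_example(f2)
  H2 <- graphdock:::add_bias(p2$nodes_a %*% params$embed$node_W,
                             params$embed$node_b)
  E2 <- graphdock:::add_bias(p2$Ea %*% params$embed$edge_intra_W,
                             params$embed$edge_intra_b)
  X2 <- cbind(E2, H2[p2$nbrA, , drop = FALSE])
  at2 <- graphdock:::attn_fwd(H2, X2, params$layers[[1L]]$intra, 2L,
                              p2$k, p2$maskA, cfg)
  expect_equal(at2$Aflat[[1L]][1L], 1)
})

test_that("batched blocks match unbatched per-residue loop oracles", {
  set.seed(31)
  for (rep in 1:6) {
    cfg <- tiny_config(seed = rep)
    nat <- make_native_complex(fixture_spec(
      n_residues_a = sample(6:12, 1L), n_residues_b = sample(5:10, 1L),
      seed = 50L + rep))
    prep <- prepare_example(
      featurize_complex(nat$chains$A, nat$chains$B, cfg$feature))
    params <- init_model(cfg)
    em <- params$embed
    H_A <- graphdock:::add_bias(prep$nodes_a %*% em$node_W, em$node_b)
    H_B <- graphdock:::add_bias(prep$nodes_b %*% em$node_W, em$node_b)
    E_A <- graphdock:::add_bias(prep$Ea %*% em$edge_intra_W, em$edge_intra_b)
    lp <- params$layers[[1L]]

    got <- graphdock:::intra_fwd(H_A, E_A, prep$nbrA, prep$maskA, lp$intra,
                                 cfg, training = FALSE)$out
    want <- naive_intra_block(H_A, E_A, prep$nbrA, prep$maskA, lp$intra, cfg)
    expect_lt(max(abs(got - want)), 1e-5)

    E_ab <- graphdock:::add_bias(prep$Eab %*% em$edge_inter_W,
                                 em$edge_inter_b)
    got_ex <- graphdock:::ex_fwd(H_A, H_B, E_ab, prep$pab, prep$mab,
                                 prep$ia, lp$ex_ab, cfg,
                                 training = FALSE)$out
    want_ex <- naive_exchange(H_A, H_B, E_ab, prep$pab, prep$mab,
                              prep$ia, lp$ex_ab, cfg)
    expect_lt(max(abs(got_ex - want_ex)), 1e-5)
    # non-interface rows are untouched
    untouched <- setdiff(seq_len(prep$n_a), prep$ia)
    expect_identical(got_ex[untouched, ], H_A[untouched, ])
  }
})

test_that("an empty interface makes the exchange an identity", {
  cfg <- tiny_config()
  nat <- small_native()
  far <- graphdock:::transform_complex(nat, shift = c(0, 0, 0))
  far$chains$B <- graphdock:::transform_chain(far$chains$B,
                                              shift = c(500, 0, 0))
  feats <- featurize_complex(far$chains$A, far$chains$B, cfg$feature)
  expect_length(feats$inter$interface_a, 0L)
  params <- init_model(cfg)
  prep <- prepare_example(feats)
  H <- matrix(stats::rnorm(prep$n_a * cfg$d_model), prep$n_a)
  out <- graphdock:::ex_fwd(H, H, NULL, prep$pab, prep$mab, integer(0),
                            params$layers[[1L]]$ex_ab, cfg, FALSE)
  expect_identical(out$out, H)
  # scoring is still legal with no interface
  pred <- score_complex(feats$graph_a, feats$graph_b, feats$inter, params)
  expect_true(pred$probability > 0 && pred$probability < 1)
})

test_that("scores are valid probabilities, deterministic, SE(3) invariant", {
  cfg <- model_config(seed = 9L)
  params <- init_model(cfg)
  nat <- small_native()
  feats <- small_features()
  p1 <- score_complex(feats$graph_a, feats$graph_b, feats$inter, params)
  p2 <- score_complex(feats$graph_a, feats$graph_b, feats$inter, params)
  expect_identical(p1$logit, p2$logit)
  expect_true(p1$probability > 0 && p1$probability < 1)
  expect_equal(p1$probability, 1 / (1 + exp(-p1$logit)))
  set.seed(41)
  for (rep in 1:10) {
    moved <- graphdock:::transform_complex(nat, R = rand_rotation(),
                                           shift = stats::rnorm(3, sd = 20))
    f2 <- featurize_complex(moved$chains$A, moved$chains$B, cfg$feature)
    pm <- score_complex(f2$graph_a, f2$graph_b, f2$inter, params)
    expect_lt(abs(pm$probability - p1$probability), 1e-5)
  }
})

test_that("analytic gradients match central finite differences", {
  for (mode in c("sequential", "simultaneous")) {
    cfg <- tiny_config(seed = 2L, mode = mode)
    nat <- make_native_complex(fixture_spec(n_residues_a = 8L,
                                            n_residues_b = 6L, seed = 4L))
    prep <- prepare_example(
      featurize_complex(nat$chains$A, nat$chains$B, cfg$feature))
    params <- init_model(cfg)
    res <- graphdock:::bce_loss_grads(prep, params, 1)
    gv <- unlist(graphdock:::strip_params(res$grads), use.names = FALSE)
    pv <- unlist(graphdock:::strip_params(params), use.names = FALSE)
    skel <- graphdock:::strip_params(params)
    loss_at <- function(vec) {
      p2 <- utils::relist(vec, skel)
      p2$config <- cfg
      class(p2) <- "model_params"
      graphdock:::bce_loss_grads(prep, p2, 1, want_grads = FALSE)$loss
    }
    idx <- graphdock:::with_seed(77, sort(sample(length(pv), 25L)))
    h <- 1e-5
    for (i in idx) {
      e <- numeric(length(pv)); e[i] <- h
      num <- (loss_at(pv + e) - loss_at(pv - e)) / (2 * h)
      denom <- max(1e-6, abs(num) + abs(gv[i]))
      expect_lt(abs(num - gv[i]) / denom, 1e-4)
    }
  }
})

test_that("training reduces the loss deterministically and can overfit", {
  cfg <- tiny_config(seed = 12L)
  ds <- make_dataset(4L, 4L, fixture_spec(n_residues_a = 10L,
                                          n_residues_b = 8L, seed = 60L),
                     seed = 60L)
  examples <- lapply(seq_len(nrow(ds$records)), function(i) {
    cx <- ds$decoys[[ds$records$decoy_id[i]]]
    list(features = featurize_complex(cx$chains$A, cx$chains$B, cfg$feature),
         label = ds$records$label[i])
  })
  tr <- examples[1:6]; va <- examples[7:8]
  fit1 <- train_model(tr, va, cfg, lr = 1e-2, epochs = 25L, patience = 100L)
  fit2 <- train_model(tr, va, cfg, lr = 1e-2, epochs = 25L, patience = 100L)
  expect_identical(fit1$history, fit2$history)   # determinism contract
  tl <- subset(fit1$history, split == "train")$loss
  expect_lt(mean(tail(tl, 6L)), mean(head(tl, 6L)))
  # overfit capacity: training examples classified correctly at 0.5
  for (ex in tr) {
    prep <- prepare_example(ex$features)
    p <- graphdock:::bce_loss_grads(prep, fit1$params, ex$label,
                                    want_grads = FALSE)$probability
    expect_equal(as.numeric(p > 0.5), ex$label)
  }
})

test_that("fine-tuning warm-starts at lr 1e-5 and zero epochs is a no-op", {
  cfg <- tiny_config(seed = 13L)
  nat <- make_native_complex(fixture_spec(n_residues_a = 8L,
                                          n_residues_b = 6L, seed = 61L))
  pos <- perturb_near_native(nat, seed = 62L)
  ex <- function(cx, label) list(
    features = featurize_complex(cx$chains$A, cx$chains$B, cfg$feature),
    label = label)
  tr <- list(ex(pos, 1), ex(randomize_placement(nat, seed = 63L), 0))
  params <- init_model(cfg)
  ft <- fine_tune(params, tr, tr, epochs = 1L)
  expect_true(all(ft$history$lr == 1e-5))
  # fine-tuning on the training data itself does not increase its loss
  loss_of <- function(p) mean(vapply(tr, function(e) {
    graphdock:::bce_loss_grads(prepare_example(e$features), p, e$label,
                               want_grads = FALSE)$loss
  }, numeric(1)))
  expect_lte(loss_of(ft$params), loss_of(params) + 1e-6)
  ft0 <- fine_tune(params, tr, tr, epochs = 0L)
  expect_equal(ft0$params$embed, params$embed)
  expect_equal(nrow(ft0$history), 0L)
})

test_that("checkpoints round trip and refuse a feature-layout mismatch", {
  cfg <- tiny_config(seed = 14L)
  params <- init_model(cfg)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, tf)
  back <- load_checkpoint(tf)
  expect_equal(back$embed, params$embed)
  expect_equal(back$config$d_model, cfg$d_model)
  bad <- readRDS(tf); bad$layout_version <- "other"
  saveRDS(bad, tf)
  expect_error(load_checkpoint(tf), "layout")
})
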