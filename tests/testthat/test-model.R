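# Model components: positional encoding closed forms, attention algebra,
# encoder behavior, CNN feature extraction, embedding contracts.

test_that("positional encoding matches its closed forms", {
  pe <- positional_encoding(8, 16)
  # position 0: sin columns are 0, cos columns are 1
  expect_equal(pe[1, seq(1, 16, by = 2)], rep(0, 8))
  expect_equal(pe[1, seq(2, 16, by = 2)], rep(1, 8))
  # first column (i = 0): divisor 10000^0 = 1, so PE(pos, 0) = sin(pos)
  expect_equal(pe[, 1], sin(0:7))
  expect_equal(pe[, 2], cos(0:7))
  # duplicated-sine variant: odd columns repeat the sine of the pair
  pe_s <- positional_encoding(8, 16, odd_sin = TRUE)
  expect_equal(pe_s[, 2], sin(0:7))
  expect_equal(pe_s[, seq(1, 16, by = 2)], pe_s[, seq(2, 16, by = 2)])
})

test_that("scaled dot-product attention is a row-stochastic convex mix", {
  set.seed(6)
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rnorm(20), 5, 4)
  V <- matrix(rnorm(10), 5, 2)
  at <- scaled_dot_attention(Q, K, V)
  expect_equal(rowSums(at$weights), rep(1, 3), tolerance = 1e-12)
  expect_true(all(at$weights >= 0))

  # identical value rows collapse to that row regardless of Q, K
  v <- c(2.5, -1)
  Vsame <- matrix(rep(v, each = 5), 5, 2)
  at2 <- scaled_dot_attention(Q, K, Vsame)
  expect_equal(at2$context, matrix(rep(v, each = 3), 3, 2), tolerance = 1e-12)

  # zero scores average the value rows: softmax([0,0]) = (1/2, 1/2)
  at3 <- scaled_dot_attention(matrix(0, 1, 2), matrix(0, 2, 2),
                              matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(at3$context, matrix(c(2, 3), 1, 2), tolerance = 1e-12)
})

test_that("multi-head attention preserves shape and reduces to single-head", {
  cfg <- tiny_model_config()
  m <- model_init(cfg, seed = 2)
  set.seed(7)
  x <- matrix(rnorm(3 * 8), 3, 8)
  out <- ecglink:::mha_forward(x, m$params, "enc1_", cfg$n_heads)
  expect_equal(dim(out$out), c(3, 8))

  # n_heads = 1 with identity projections and zero biases = plain attention
  p <- m$params
  for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0("enc1_", nm)]] <- diag(8)
  for (nm in c("bq", "bk", "bv", "bo")) p[[paste0("enc1_", nm)]] <- numeric(8)
  out1 <- ecglink:::mha_forward(x, p, "enc1_", 1L)
  ref <- scaled_dot_attention(x, x, x)
  expect_equal(out1$out, ref$context, tolerance = 1e-12)
})

test_that("self-attention and encoder layers are permutation-equivariant", {
  cfg <- tiny_model_config()
  m <- model_init(cfg, seed = 4)
  set.seed(8)
  x <- matrix(rnorm(3 * 8), 3, 8)
  perm <- c(3, 1, 2)
  out <- ecglink:::encoder_layer_forward(x, m$params, "enc1_", cfg)$out
  out_p <- ecglink:::encoder_layer_forward(x[perm, ], m$params, "enc1_",
                                           cfg)$out
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
})

test_that("with zero sublayer weights the encoder layer is LayerNorm(LayerNorm(x))", {
  cfg <- tiny_model_config()
  m <- model_init(cfg, seed = 5)
  p <- m$params
  for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0("enc1_", nm)]] <- matrix(0, 8, 8)
  p$enc1_ffn_W1 <- matrix(0, 8, cfg$ffn_hidden)
  p$enc1_ffn_W2 <- matrix(0, cfg$ffn_hidden, 8)
  set.seed(9)
  x <- matrix(rnorm(4 * 8), 4, 8)
  out <- ecglink:::encoder_layer_forward(x, p, "enc1_", cfg)$out
  ln <- function(z) ecglink:::layernorm_forward(z, rep(1, 8), numeric(8))$out
  expect_equal(out, ln(ln(x)), tolerance = 1e-12)
})

test_that("cnn_extract maps windows independently to fixed-width features", {
  cfg <- tiny_model_config()
  m <- model_init(cfg, seed = 10)
  one <- fake_stack("one", 1, 0L, seed = 20)
  f1 <- cnn_extract(one, m)
  expect_equal(dim(f1), c(1, cfg$cnn_feature_dim))

  # identical windows give identical rows; feature width ignores n_windows
  seg <- one$segments[1, , ]
  three <- one
  three$segments <- array(0, dim = c(3, 12, 20))
  for (w in 1:3) three$segments[w, , ] <- seg
  f3 <- cnn_extract(three, m)
  expect_equal(dim(f3), c(3, cfg$cnn_feature_dim))
  for (w in 2:3) expect_equal(f3[w, ], f3[1, ], tolerance = 1e-12)
  expect_equal(f3[1, ], f1[1, ], tolerance = 1e-12)

  bad <- fake_stack("bad", 1, 0L, window = 24)
  expect_error(cnn_extract(bad, m), "20")
})

test_that("record embeddings are d_model wide for any window count", {
  cfg <- tiny_model_config()
  m <- model_init(cfg, seed = 11)
  stacks <- list(fake_stack("a", 1, 0L, seed = 30),
                 fake_stack("b", 4, 1L, seed = 31),
                 fake_stack("c", 7, 2L, seed = 32))
  fw <- model_forward(m, stacks, training = FALSE)
  expect_equal(dim(fw$embeddings), c(3, cfg$d_model))
  expect_equal(dim(fw$probs), c(3, cfg$n_classes))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-12)

  # evaluation mode is deterministic
  fw2 <- model_forward(m, stacks, training = FALSE)
  expect_identical(fw$embeddings, fw2$embeddings)
  expect_identical(fw$probs, fw2$probs)

  # identical records get identical embeddings
  fw3 <- model_forward(m, list(stacks[[2]], stacks[[2]]), training = FALSE)
  expect_equal(fw3$embeddings[1, ], fw3$embeddings[2, ], tolerance = 1e-12)
})

test_that("window order is immaterial without positional encoding, material with it", {
  cfg <- tiny_model_config()
  m <- model_init(cfg, seed = 12)
  st <- fake_stack("a", 3, 0L, seed = 40)
  st_perm <- st
  st_perm$segments <- st$segments[c(2, 3, 1), , ]

  emb <- model_forward(m, list(st), training = FALSE)$embeddings
  emb_perm <- model_forward(m, list(st_perm), training = FALSE)$embeddings
  # positional encoding breaks permutation invariance
  expect_gt(max(abs(emb - emb_perm)), 1e-6)

  # disable the encoding: mean-pooled embeddings become order-invariant
  mock_pe <- function(n, d, odd_sin = FALSE) matrix(0, n, d)
  with_mocked_bindings(positional_encoding = mock_pe, .package = "ecglink", {
    e1 <- model_forward(m, list(st), training = FALSE)$embeddings
    e2 <- model_forward(m, list(st_perm), training = FALSE)$embeddings
    expect_equal(e1, e2, tolerance = 1e-10)
  })
})

test_that("model configuration contracts are enforced", {
  expect_error(model_config(d_model = 30, n_heads = 4), "divisible")
  expect_error(model_config(window_size = 3001), "3001")
  expect_error(tiny_model_config(window_size = 21), "21")
  # default architecture: seven conv blocks, 150-dim features, 256-wide encoder
  cfg <- model_config()
  expect_length(cfg$conv_layers, 7)
  expect_equal(cfg$cnn_feature_dim, 150L)
  expect_equal(cfg$d_model, 256L)
  expect_equal(cfg$n_encoder_layers, 8L)
  expect_equal(cfg$ffn_hidden, 1024L)
})

test_that("describe_model reports one row per stage with positive parameter counts", {
  m <- model_init(tiny_model_config(), seed = 1)
  tab <- describe_model(m)
  expect_s3_class(tab, "data.frame")
  expect_gte(nrow(tab), 6)
  expect_equal(sum(tab$params), sum(vapply(m$params, length, numeric(1))))
})
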