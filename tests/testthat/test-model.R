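tiny_cfg <- function(...) dti_config(d = 8L, hidden = c(16L, 8L, 4L),
                                     seed = 3L, ...)

test_that("classifier outputs calibrated probabilities in (0,1)", {
  cfg <- tiny_cfg()
  m <- dti_model(cfg)
  p <- model_params(m, "classifier")

  p0 <- p
  for (nm in c("W1", "W2", "W3", "W4", "b1", "b2", "b3", "b4")) p0[[nm]][] <- 0
  z <- list(Z_smiles = rnorm(8), Z_graph = rnorm(8), Z_seq = rnorm(8),
            Z_mer = rnorm(8))
  expect_equal(classifier_forward(z, p0), 0.5)   # sigmoid(0)

  # inference is deterministic (dropout off) and stays inside (0,1)
  set.seed(20)
  for (i in 1:100) {
    z <- list(Z_smiles = rnorm(8, sd = 3), Z_graph = rnorm(8, sd = 3),
              Z_seq = rnorm(8, sd = 3), Z_mer = rnorm(8, sd = 3))
    pr <- classifier_forward(z, p)
    expect_identical(pr, classifier_forward(z, p))
    expect_gt(pr, 0); expect_lt(pr, 1)
  }
  expect_error(classifier_forward(list(Z_smiles = 1, Z_graph = 1, Z_seq = 1,
                                       Z_mer = 1), p),
               class = "dtifuse_shape_error")
})

test_that("binary cross-entropy matches its closed forms and is monotone", {
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(1, 0.25), -log(0.25))
  expect_lt(bce_loss(c(1, 0), c(1 - 1e-7, 1e-7)), 1e-5)
  expect_equal(bce_loss(c(1, 1), c(0.5, 0.5), reduction = "mean"), log(2))
  expect_error(bce_loss(2, 0.5), class = "dtifuse_invalid_input")

  p_grid <- seq(0.01, 0.99, by = 0.01)
  losses <- vapply(p_grid, function(p) bce_loss(1, p), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("tape gradients agree with central finite differences", {
  cfg <- tiny_cfg(dropout = 0)
  m <- dti_model(cfg)
  feats <- featurize_record("c1ccncc1CC(O)C", "MKVLAWYKFGHACDEFGHIKLMNPQRST", cfg)

  loss_of <- function(model) {
    tp <- dtifuse:::new_tape()
    pid <- dtifuse:::.tp_params(tp, model)
    pr <- dtifuse:::.forward_sample(tp, pid, model, feats, training = FALSE)
    as.numeric(dtifuse:::tp_val(tp, dtifuse:::tp_bce(tp, pr, 1)))
  }
  tp <- dtifuse:::new_tape()
  pid <- dtifuse:::.tp_params(tp, m)
  pr <- dtifuse:::.forward_sample(tp, pid, m, feats, training = FALSE)
  l <- dtifuse:::tp_bce(tp, pr, 1)
  dtifuse:::tp_backward(tp, l)

  set.seed(21)
  h <- 1e-5
  checked <- 0L
  for (nm in sample(names(m$params), 14)) {
    g <- dtifuse:::tp_grad(tp, pid[[nm]])
    if (is.null(g)) next
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
    fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    expect_lt(abs(fd - as.numeric(g)[i]), 1e-4 * max(1, abs(fd)))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("the training forward path equals the composed public operations", {
  cfg <- tiny_cfg()
  m <- dti_model(cfg)
  rec <- data.frame(smiles = "c1ccncc1CCO", sequence = "MKVLAWYKFGHACDEFGH")
  x_s <- cnn_block(embed_tokens(featurize_record(rec$smiles, rec$sequence, cfg)$tok_smiles,
                                model_params(m, "embedding_smiles")),
                   model_params(m, "cnn_smiles"))
  feats <- featurize_record(rec$smiles, rec$sequence, cfg)
  x_q <- cnn_block(embed_tokens(feats$tok_seq, model_params(m, "embedding_seq")),
                   model_params(m, "cnn_seq"))
  x_m <- cnn_block(embed_tokens(feats$tok_mer, model_params(m, "embedding_mer")),
                   model_params(m, "cnn_mer"))
  x_g <- dmpnn_encode(feats$graph, model_params(m, "dmpnn"))
  fz <- hmsa_fuse(x_s, x_g, x_q, x_m,
                  model_params(m, "attn_level1_drug"),
                  model_params(m, "attn_level1_protein"),
                  model_params(m, "attn_level2"))
  p_pub <- classifier_forward(fz$pooled, model_params(m, "classifier"))
  p_tape <- predict_pairs(m, rec)$probability
  expect_equal(p_pub, p_tape, tolerance = 1e-12)
})

test_that("prediction preserves order, is deterministic, and quarantines bad records", {
  cfg <- tiny_cfg()
  m <- dti_model(cfg)
  rec <- gen_dti_dataset(synth_config(n_pairs = 6, n_drugs = 10, n_proteins = 10,
                                      protein_length = c(50L, 80L)))$records
  rec <- rbind(rec, rec[1, ])                       # duplicate record
  rec$smiles[3] <- "C1CC"                            # unparseable
  pb <- predict_pairs(m, rec)
  expect_identical(nrow(pb), nrow(rec))
  expect_equal(pb$probability[nrow(rec)], pb$probability[1])
  rej <- attr(pb, "rejects")
  expect_identical(rej$row, 3L)
  expect_true(is.na(pb$probability[3]))
  expect_true(all(!is.na(pb$probability[-3])))
})

test_that("a small model overfits a tiny planted dataset", {
  rec <- gen_dti_dataset(synth_config(n_pairs = 32, n_drugs = 20, n_proteins = 20,
                                      protein_length = c(50L, 100L)))$records
  cfg <- dti_config(d = 16L, hidden = c(32L, 16L, 8L), epochs = 40L,
                    batch_size = 8L, lr = 1e-3, seed = 5L)
  ck <- dti_train(cfg, rec, split = list(train = 1:32, validation = 1:8))
  expect_lt(min(ck$history$train_loss), 0.05)
})
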