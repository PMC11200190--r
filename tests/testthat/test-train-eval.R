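test_that("the split protocol holds a fixed 10% test set and 10 rotating folds", {
  plan <- make_splits(100, seed = 4)
  expect_length(plan$test, 10L)
  expect_length(plan$folds, 10L)
  for (f in plan$folds) {
    expect_length(f$validation, 9L)
    expect_length(f$train, 81L)
    expect_length(intersect(plan$test, c(f$train, f$validation)), 0L)
    expect_length(intersect(f$train, f$validation), 0L)
  }
  vals <- sort(unlist(lapply(plan$folds, `[[`, "validation")))
  expect_identical(vals, sort(setdiff(1:100, plan$test)))

  expect_identical(make_splits(100, seed = 4), plan)       # deterministic
  expect_false(identical(make_splits(100, seed = 5)$test, plan$test))
  expect_error(make_splits(19), class = "dtifuse_invalid_input")
})

test_that("metrics match hand values and flag one-class batches", {
  b <- data.frame(label = c(1, 0, 1, 0), probability = c(0.9, 0.8, 0.7, 0.1))
  mt <- evaluate(b)
  expect_equal(mt$auc, 0.75)                 # 3 of 4 concordant pairs
  expect_equal(mt$auc, oracle_auc(b$label, b$probability))

  sep <- data.frame(label = c(1, 1, 0, 0), probability = c(0.9, 0.8, 0.2, 0.1))
  mt <- evaluate(sep)
  expect_equal(mt$auc, 1); expect_equal(mt$aupr, 1)
  expect_equal(mt$acc, 1); expect_equal(mt$precision, 1); expect_equal(mt$recall, 1)

  one <- data.frame(label = c(1, 1), probability = c(0.9, 0.2))
  mt <- evaluate(one)
  expect_true(mt$undefined_rank_metrics)
  expect_true(is.na(mt$auc))
  expect_equal(mt$recall, 0.5)
})

test_that("AUC and AUPR agree with sweep oracles on random tied score sets", {
  set.seed(30)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    lab <- sample(0:1, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- sample(seq(0.1, 0.9, by = 0.2), n, replace = TRUE)  # forces ties
    mt <- evaluate(data.frame(label = lab, probability = sc))
    expect_equal(mt$auc, oracle_auc(lab, sc), tolerance = 1e-10)
    expect_equal(mt$aupr, oracle_aupr(lab, sc), tolerance = 1e-10)
  }
})

test_that("the training loop logs per epoch, keeps the best-validation model, and is seed-stable", {
  rec <- gen_dti_dataset(synth_config(n_pairs = 24, n_drugs = 15, n_proteins = 15,
                                      protein_length = c(50L, 80L)))$records
  cfg <- dti_config(d = 8L, hidden = c(16L, 8L, 4L), epochs = 2L,
                    batch_size = 8L, lr = 1e-3, seed = 9L)
  sp <- list(train = 1:18, validation = 19:24)
  ck <- dti_train(cfg, rec, split = sp)
  expect_identical(nrow(ck$history), 2L)
  expect_identical(ck$best_epoch, which.max(ck$history$val_auc))

  ck2 <- dti_train(cfg, rec, split = sp)
  expect_identical(ck$history$val_auc, ck2$history$val_auc)
  expect_equal(ck$model$params, ck2$model$params)
})

test_that("checkpoints round-trip through the text format", {
  cfg <- dti_config(d = 8L, hidden = c(16L, 8L, 4L), seed = 2L)
  m <- dti_model(cfg)
  dir <- tempfile("ckpt")
  save_checkpoint(m, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  m2 <- load_checkpoint(dir)
  expect_equal(m2$params, m$params)
  rec <- data.frame(smiles = "c1ccncc1CC", sequence = "MKVLAWYKFGHACDEF")
  expect_equal(predict_pairs(m2, rec)$probability,
               predict_pairs(m, rec)$probability)
})

test_that("candidate ranking sorts by score with stable ties and honors top_n", {
  cfg <- dti_config(d = 8L, hidden = c(16L, 8L, 4L), seed = 6L)
  m <- dti_model(cfg)
  prots <- gen_proteins(6, length_range = c(50L, 70L), seed = 3)
  cands <- c(prots, prots[1])                     # duplicate candidate
  rk <- rank_candidates(m, anchor = list(smiles = "c1ccncc1CCO"),
                        candidates = cands, top_n = 4L)
  expect_identical(nrow(rk), 4L)
  expect_true(all(diff(rk$score) <= 0))
  full <- rank_candidates(m, anchor = list(smiles = "c1ccncc1CCO"),
                          candidates = cands, top_n = 10L)
  dup <- full[full$candidate == prots[1], ]
  expect_equal(dup$score[1], dup$score[2])        # identical inputs, same score
  expect_lt(which(full$candidate_id == "cand1"),
            which(full$candidate_id == "cand7")) # stable: earlier input first
})

test_that("interaction TSVs round-trip without loss", {
  rec <- gen_dti_dataset(synth_config(n_pairs = 20, n_drugs = 12, n_proteins = 12,
                                      protein_length = c(50L, 70L)))$records
  path <- tempfile(fileext = ".tsv")
  write_interactions(rec, path, manifest = list(note = "round-trip"))
  back <- read_interactions(path)
  expect_equal(back, rec)
  expect_true(file.exists(paste0(path, ".manifest.json")))
})
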