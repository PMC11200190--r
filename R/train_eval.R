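# Dataset splitting (fixed test set + 10-fold rotation), Adam training loop
# with best-on-validation checkpointing, ROC/PR metrics, and the case-study
# candidate ranking protocol.

#' Split records into a fixed test set and 10 cross-validation folds
#'
#' 10% of the indices (rounded) are held out as the test set, fixed across
#' folds; the remaining pool rotates through 10 folds, each using one part as
#' validation and the other nine as training. Deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param n Number of records (>= 20).
#' @param seed Integer seed.
#' @return A `split_plan`: list with `test` (indices) and `folds`, a list of
#'   10 lists each holding `train` and `validation` indices.
#' @export
make_splits <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 20L)
    stop_invalid("`n` must be a single count >= 20")
  n <- as.integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  test <- sort(sample.int(n, round(0.1 * n)))
  pool <- sample(setdiff(seq_len(n), test))
  fold_id <- rep_len(1:10, length(pool))
  folds <- lapply(1:10, function(f) {
    list(train = sort(pool[fold_id != f]), validation = sort(pool[fold_id == f]))
  })
  structure(list(test = test, folds = folds, n = n, seed = as.integer(seed)),
            class = "split_plan")
}

# ---- metrics ---------------------------------------------------------------

.aupr <- function(labels, scores) {
  ord <- order(-scores)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab)
  n_pos <- sum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / n_pos
  # keep the last point of each distinct-score block (ties share a threshold)
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate predictions
#'
#' AUC is the rank-based area under the ROC curve (via pROC); AUPR the area
#' under the step-function precision-recall curve. Accuracy, precision and
#' recall are computed at the declared threshold. If only one class is
#' present, AUC/AUPR are returned as NA with `undefined_rank_metrics = TRUE`
#' while the thresholded metrics are still reported.
#'
#' @param batch A `prediction_batch` (or data frame with `label` and
#'   `probability` columns); rows with NA probability are dropped.
#' @param threshold Decision threshold (default 0.5).
#' @return A `dti_metrics` list: `auc`, `aupr`, `acc`, `precision`, `recall`,
#'   `threshold`, `n`, `undefined_rank_metrics`.
#' @export
evaluate <- function(batch, threshold = 0.5) {
  df <- as.data.frame(batch)
  if (is.null(df$label)) stop_invalid("`batch` must carry labels")
  ok <- !is.na(df$probability)
  lab <- as.numeric(df$label[ok]); p <- df$probability[ok]
  if (!all(lab %in% c(0, 1))) stop_invalid("labels must be 0 or 1")
  pred <- as.numeric(p >= threshold)
  tp <- sum(pred == 1 & lab == 1); fp <- sum(pred == 1 & lab == 0)
  fn <- sum(pred == 0 & lab == 1)
  one_class <- length(unique(lab)) < 2L
  auc <- aupr <- NA_real_
  if (!one_class) {
    auc <- as.numeric(pROC::auc(pROC::roc(lab, p, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    aupr <- .aupr(lab, p)
  }
  structure(list(auc = auc, aupr = aupr,
                 acc = mean(pred == lab),
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 threshold = threshold, n = length(lab),
                 undefined_rank_metrics = one_class),
            class = "dti_metrics")
}

#' @export
print.dti_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f | AUPR %.4f | ACC %.4f | P %.4f | R %.4f (n=%d, thr=%.2f)\n",
              x$auc, x$aupr, x$acc, x$precision, x$recall, x$n, x$threshold))
  invisible(x)
}

# ---- training --------------------------------------------------------------

.featurize_all <- function(records, config) {
  df <- .as_records(records)
  # parse unique molecules in one OpenBabel call to amortize parser startup
  smi <- unique(df$smiles)
  if (is.null(.dtifuse_env$graph_cache))
    .dtifuse_env$graph_cache <- new.env(parent = emptyenv())
  todo <- smi[!vapply(smi, function(s) !is.null(.dtifuse_env$graph_cache[[s]]),
                      logical(1))]
  if (length(todo)) {
    sdfs <- tryCatch(suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(todo, seq_along(todo)))),
      error = function(e) NULL)
    if (!is.null(sdfs) && length(sdfs) == length(todo)) {
      for (i in seq_along(todo))
        .dtifuse_env$graph_cache[[todo[i]]] <-
          tryCatch(.parse_sdf_one(sdfs[[i]], todo[i]), error = function(e) NULL)
    }
  }
  lapply(seq_len(nrow(df)), function(i)
    featurize_record(df$smiles[i], df$sequence[i], config))
}

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.batch_pass <- function(model, feats_list, labels, training = TRUE) {
  B <- length(feats_list)
  acc <- NULL
  loss_sum <- 0
  for (b in seq_len(B)) {
    tp <- new_tape()
    pid <- .tp_params(tp, model)
    prob <- .forward_sample(tp, pid, model, feats_list[[b]], training = training)
    loss <- tp_bce(tp, prob, labels[b], eps = model$config$label_smooth_eps)
    loss_sum <- loss_sum + tp_val(tp, loss)
    if (training) {
      tp_backward(tp, loss, seed_grad = 1 / B)
      if (is.null(acc)) {
        acc <- lapply(pid, function(id) tp_grad(tp, id))
      } else {
        for (nm in names(pid)) {
          g <- tp_grad(tp, pid[[nm]])
          if (!is.null(g))
            acc[[nm]] <- if (is.null(acc[[nm]])) g else acc[[nm]] + g
        }
      }
    }
  }
  # padding embedding rows are pinned at zero
  for (nm in c("emb.seq", "emb.mer", "emb.smiles"))
    if (!is.null(acc[[nm]])) acc[[nm]][1L, ] <- 0
  list(loss = loss_sum / B, grads = acc)
}

.predict_feats <- function(model, feats_list) {
  vapply(feats_list, function(f) {
    tp <- new_tape()
    pid <- .tp_params(tp, model)
    as.numeric(tp_val(tp, .forward_sample(tp, pid, model, f, training = FALSE)))
  }, numeric(1))
}

.rank_auc <- function(labels, scores) {
  # Wilcoxon form; internal quick AUC for validation monitoring
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the predictor on one fold
#'
#' Runs `epochs` passes of minibatch Adam over the training indices, evaluates
#' the validation AUC after every epoch, and retains the parameters of the
#' best-validation epoch (best-on-validation checkpointing). Fully
#' deterministic given the configuration seed.
#'
#' @param config A [dti_config()]; `epochs`, `batch_size`, `lr`, `seed` and
#'   `fusion_mode` all matter here.
#' @param records Data frame with `smiles`, `sequence`, `label`.
#' @param split List with `train` and `validation` index vectors (one fold of
#'   [make_splits()]); NULL uses a 90/10 tail split.
#' @param verbose Print per-epoch loss and validation AUC.
#' @return A `dti_checkpoint`: list with `model` (best-epoch parameters),
#'   `history` (epoch, train_loss, val_auc), `best_epoch`, `config`.
#' @export
dti_train <- function(config, records, split = NULL, verbose = FALSE) {
  df <- .as_records(records)
  if (is.null(df$label)) stop_invalid("training records need a `label` column")
  if (is.null(split)) {
    n <- nrow(df)
    cut <- floor(0.9 * n)
    split <- list(train = seq_len(cut), validation = seq.int(cut + 1L, n))
  }
  stopifnot(all(split$train <= nrow(df)), all(split$validation <= nrow(df)))
  model <- dti_model(config)
  feats <- .featurize_all(df, config)
  labels <- as.numeric(df$label)
  adam <- .adam_new(model$params)
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (epoch in seq_len(config$epochs)) {
    set.seed(config$seed + 131L * epoch)
    idx <- sample(split$train)
    nb <- ceiling(length(idx) / config$batch_size)
    ep_loss <- 0
    for (j in seq_len(nb)) {
      ids <- idx[((j - 1L) * config$batch_size + 1L):min(j * config$batch_size,
                                                         length(idx))]
      pass <- .batch_pass(model, feats[ids], labels[ids], training = TRUE)
      if (!is.finite(pass$loss))
        stop(errorCondition(
          sprintf("non-finite training loss at epoch %d (batch record ids: %s)",
                  epoch, paste(ids, collapse = ", ")),
          class = c("dtifuse_train_error", "dtifuse_error")))
      upd <- .adam_step(model$params, pass$grads, adam, config$lr)
      model$params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + pass$loss
    }
    val_p <- .predict_feats(model, feats[split$validation])
    val_auc <- .rank_auc(labels[split$validation], val_p)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                         val_auc = val_auc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AUC %s", epoch, ep_loss / nb,
                      formatC(val_auc, digits = 4, format = "f")))
    if (!is.na(val_auc) && val_auc > best$auc)
      best <- list(auc = val_auc, params = model$params, epoch = epoch)
  }
  model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 config = config), class = "dti_checkpoint")
}

#' Rank candidate partners for one anchor entity
#'
#' Scores every (anchor, candidate) pair with the model in evaluation mode and
#' returns the candidates sorted by descending predicted interaction
#' probability; ties keep input order (stable sort). Invalid candidates go to
#' the rejects report.
#'
#' @param model A `dti_model` (or `dti_checkpoint`).
#' @param anchor Named list with either `smiles` (drug anchor, candidates are
#'   protein sequences) or `sequence` (protein anchor, candidates are SMILES).
#' @param candidates Character vector of the complementary entity.
#' @param top_n Number of rows to return (default 20).
#' @param candidate_ids Optional identifiers (default positional).
#' @return data.table with `rank`, `candidate_id`, `candidate`, `score`;
#'   rejected candidates in `attr(, "rejects")`.
#' @export
rank_candidates <- function(model, anchor, candidates, top_n = 20L,
                            candidate_ids = NULL) {
  if (inherits(model, "dti_checkpoint")) model <- model$model
  if (length(candidates) < 1L) stop_invalid("`candidates` must be non-empty")
  if (is.null(candidate_ids)) candidate_ids <- paste0("cand", seq_along(candidates))
  if (!is.null(anchor$smiles)) {
    smiles_to_graph(anchor$smiles)  # anchor must parse
    rec <- data.frame(smiles = anchor$smiles, sequence = candidates,
                      stringsAsFactors = FALSE)
  } else if (!is.null(anchor$sequence)) {
    rec <- data.frame(smiles = candidates, sequence = anchor$sequence,
                      stringsAsFactors = FALSE)
  } else stop_invalid("`anchor` needs a `smiles` or `sequence` entry")
  pb <- predict_pairs(model, rec)
  ok <- which(!is.na(pb$probability))
  ord <- ok[order(-pb$probability[ok])]   # radix order: stable for ties
  ord <- head(ord, top_n)
  out <- data.table::data.table(rank = seq_along(ord),
                                candidate_id = candidate_ids[ord],
                                candidate = candidates[ord],
                                score = pb$probability[ord])
  data.table::setattr(out, "rejects", attr(pb, "rejects"))
  out
}

#' Run the full cross-validation protocol
#'
#' Applies [make_splits()], trains one model per requested fold, and reports
#' per-fold and mean test metrics.
#'
#' @param config A [dti_config()].
#' @param records Labelled records.
#' @param seed Split seed (default `config$seed`).
#' @param folds Which folds to run (default all 10).
#' @return List with `per_fold` metrics, `mean` metrics and the `plan`.
#' @export
cross_validate <- function(config, records, seed = config$seed, folds = 1:10) {
  df <- .as_records(records)
  plan <- make_splits(nrow(df), seed = seed)
  per_fold <- lapply(folds, function(f) {
    ck <- dti_train(config, df, split = plan$folds[[f]])
    pb <- predict_pairs(ck$model, df[plan$test, ])
    evaluate(pb, threshold = config$threshold)
  })
  keys <- c("auc", "aupr", "acc", "precision", "recall")
  means <- sapply(keys, function(k)
    mean(vapply(per_fold, function(m) m[[k]], numeric(1)), na.rm = TRUE))
  list(per_fold = per_fold, mean = as.list(means), plan = plan)
}

# ---- checkpoint I/O --------------------------------------------------------

#' Save a checkpoint as text
#'
#' Writes the flat parameter list (full double precision) and a JSON config
#' sidecar so a model reloads bit-exactly.
#'
#' @param checkpoint A `dti_checkpoint` or `dti_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, dir) {
  model <- if (inherits(checkpoint, "dti_checkpoint")) checkpoint$model else checkpoint
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shapes <- lapply(model$params, function(p)
    if (is.matrix(p)) dim(p) else length(p))
  jsonlite::write_json(
    list(config = unclass(model$config), shapes = shapes),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  con <- gzfile(file.path(dir, "params.tsv.gz"), "wt")
  on.exit(close(con))
  for (nm in names(model$params))
    writeLines(paste(nm, paste(
      formatC(as.numeric(model$params[[nm]]), format = "g", digits = 17),
      collapse = "\t"), sep = "\t"), con)
  invisible(dir)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param dir Checkpoint directory.
#' @return A `dti_model`.
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  cfg_args <- meta$config
  cfg_args$kernel_sizes <- unlist(cfg_args$kernel_sizes)
  cfg_args$hidden <- unlist(cfg_args$hidden)
  cfg <- do.call(dti_config, cfg_args)
  lines <- readLines(gzfile(file.path(dir, "params.tsv.gz")))
  params <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    nm <- parts[1]
    vals <- as.numeric(parts[-1])
    sh <- unlist(meta$shapes[[nm]])
    params[[nm]] <- if (length(sh) == 2L) matrix(vals, sh[1], sh[2]) else vals
  }
  structure(list(params = params, config = cfg), class = "dti_model")
}
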