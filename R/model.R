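## The radical-augmented Bi-LSTM-CRF tagger: training (Adam, gradient
## accumulation in batches, global-norm clipping) and whole-document
## prediction with fragment reassembly.

#' Training configuration
#'
#' Defaults follow the reference experimental settings for this architecture:
#' batch size 16, Bi-LSTM hidden width 128 per direction, radical embedding
#' width 20, Adam learning rate 5e-5, maximum sequence length 512. The 5e-5
#' rate is appropriate when the token features come from a pretrained
#' contextual backend that only needs fine-tuning; for from-scratch training
#' of the lookup provider pass `learning_rate = 1e-3` (see the package
#' vignette).
#'
#' @param batch_size Sequences per Adam update (default 16).
#' @param lstm_hidden Hidden units per LSTM direction (default 128).
#' @param token_dim Width of the trainable character-lookup vectors (default 64).
#' @param radical_dim Radical embedding width (default 20).
#' @param learning_rate Adam step size (default 5e-5).
#' @param max_len Maximum model sequence length including control tokens
#'   (default 512); longer documents are split.
#' @param epochs Training epochs (default 20).
#' @param dropout Dropout rate on the Bi-LSTM output (default 0.1).
#' @param clip Global gradient-norm clipping threshold (default 5).
#' @param mask_illegal If `TRUE`, transitions that violate the BIO grammar
#'   (e.g. `O -> I-Drug`) are hard-masked to `-Inf` instead of being learned.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, lstm_hidden = 128L, token_dim = 64L,
                         radical_dim = 20L, learning_rate = 5e-5,
                         max_len = 512L, epochs = 20L, dropout = 0.1,
                         clip = 5, mask_illegal = FALSE, seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size),
              lstm_hidden = as.integer(lstm_hidden),
              token_dim = as.integer(token_dim),
              radical_dim = as.integer(radical_dim),
              learning_rate = learning_rate,
              max_len = as.integer(max_len),
              epochs = as.integer(epochs),
              dropout = dropout, clip = clip,
              mask_illegal = isTRUE(mask_illegal),
              seed = as.integer(seed))
  stopifnot(cfg$batch_size >= 1, cfg$lstm_hidden >= 1, cfg$token_dim >= 1,
            cfg$radical_dim >= 1, cfg$learning_rate > 0, cfg$max_len >= 4,
            cfg$epochs >= 1, cfg$dropout >= 0, cfg$dropout < 1, cfg$clip > 0)
  structure(cfg, class = "train_config")
}

## BIO grammar mask: -Inf where tag j cannot follow tag i (I-T requires a
## preceding B-T or I-T of the same type); start cannot be I-T.
bio_transition_mask <- function(labels) {
  K <- length(labels)
  trans <- matrix(0, K, K)
  start <- numeric(K)
  for (j in seq_len(K)) {
    if (startsWith(labels[j], "I-")) {
      ty <- substring(labels[j], 3)
      ok <- labels %in% paste0(c("B-", "I-"), ty)
      trans[!ok, j] <- -Inf
      start[j] <- -Inf
    }
  }
  list(transitions = trans, start = start)
}

## Fragment-level training instance: character rows, radical ids, gold tags.
prepare_instances <- function(docs, cfg, provider, index) {
  insts <- list()
  for (doc in docs) {
    for (frag in split_long(doc, cfg$max_len - 2L)) {
      ms <- to_model_sequence(frag, cfg$max_len)
      chars <- ms$tokens[ms$mask]
      insts[[length(insts) + 1L]] <- list(
        rows = token_rows(chars, provider),
        rads = radicals_of(chars, index) + 1L,
        gold = match(spans_to_tags(frag), bio_tags()))
    }
  }
  insts
}

new_zero_like <- function(theta) {
  lapply(theta, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
}

#' Train the radical-augmented Bi-LSTM-CRF tagger
#'
#' Character vectors from the token provider are concatenated with radical
#' vectors, encoded by a bidirectional LSTM, projected to per-tag emission
#' scores, and trained by maximizing the linear-chain CRF log-likelihood of
#' the gold BIO paths (Adam, gradient accumulation over `batch_size`
#' sequences, global-norm clipping). Fully reproducible given `cfg$seed`.
#'
#' @param docs Non-empty list of [ann_doc()] training documents.
#' @param cfg A [train_config()].
#' @param provider An [embedding_provider()]; defaults to a trainable
#'   character lookup over the corpus vocabulary.
#' @param index A [build_radical_index()]; defaults to the shipped table.
#' @param eval_docs Optional held-out documents; if given, held-out micro-F1
#'   is logged per epoch in the history.
#' @param init Optional `radner_model` checkpoint to resume from: its
#'   parameters, provider and history are carried over and the epoch counter
#'   continues (optimizer moments restart).
#' @param quiet Suppress per-epoch messages.
#' @return A `radner_model` with trained parameters and a `history`
#'   data.frame (`epoch`, `loss`, optionally `eval_f1`).
#' @export
train_tagger <- function(docs, cfg = train_config(), provider = NULL,
                         index = NULL, eval_docs = NULL, init = NULL,
                         quiet = FALSE) {
  stopifnot(length(docs) > 0)
  if (is.null(index)) index <- build_radical_index()
  with_local_seed(cfg$seed, {
    if (!is.null(init)) {
      stopifnot(inherits(init, "radner_model"))
      provider <- init$provider
    }
    if (is.null(provider)) {
      provider <- embedding_provider("trainable_lookup", dim = cfg$token_dim,
                                     vocabulary = corpus_vocabulary(docs),
                                     seed = cfg$seed)
    }
    if (provider$kind != "trainable_lookup") {
      stop("training currently requires a trainable_lookup provider; ",
           "contextual adapters are a prediction-time feature contract")
    }
    labels <- bio_tags()
    K <- length(labels)
    D <- provider$dim + cfg$radical_dim
    H <- cfg$lstm_hidden
    mask <- if (cfg$mask_illegal) bio_transition_mask(labels) else NULL

    if (is.null(init)) {
      theta <- list(
        emb = provider$vectors,
        rad = radical_embedding_table(cfg$radical_dim, seed = cfg$seed),
        Wf = NULL, Uf = NULL, bf = NULL, Wb = NULL, Ub = NULL, bb = NULL,
        Wp = matrix(stats::runif(K * 2 * H, -1 / sqrt(2 * H), 1 / sqrt(2 * H)), K, 2 * H),
        bp = numeric(K),
        trans = matrix(0, K, K), start = numeric(K), end = numeric(K))
      lf <- lstm_init(D, H); lb <- lstm_init(D, H)
      theta$Wf <- lf$W; theta$Uf <- lf$U; theta$bf <- lf$b
      theta$Wb <- lb$W; theta$Ub <- lb$U; theta$bb <- lb$b
      history <- data.frame()
    } else {
      stopifnot(identical(init$cfg$lstm_hidden, cfg$lstm_hidden),
                identical(init$cfg$radical_dim, cfg$radical_dim))
      theta <- init$theta
      history <- init$history
    }
    epoch0 <- if (nrow(history)) max(history$epoch) else 0L

    insts <- prepare_instances(docs, cfg, provider, index)
    n <- length(insts)
    adam_m <- new_zero_like(theta); adam_v <- new_zero_like(theta)
    step <- 0L

    for (epoch in epoch0 + seq_len(cfg$epochs)) {
      order_ <- sample.int(n)
      epoch_loss <- 0
      done <- 0L
      while (done < n) {
        batch <- order_[(done + 1L):min(done + cfg$batch_size, n)]
        done <- done + length(batch)
        grad <- new_zero_like(theta)
        batch_loss <- 0
        for (bi in batch) {
          r <- tagger_seq_grad(theta, insts[[bi]], cfg, H, K, mask,
                               dropout = cfg$dropout)
          batch_loss <- batch_loss + r$loss
          for (nm in names(r$grad)) grad[[nm]] <- grad[[nm]] + r$grad[[nm]]
        }
        if (!is.finite(batch_loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch)
        }
        grad <- lapply(grad, function(g) g / length(batch))
        gn <- sqrt(sum(vapply(grad, function(g) sum(g * g), numeric(1))))
        if (gn > cfg$clip) grad <- lapply(grad, function(g) g * (cfg$clip / gn))
        step <- step + 1L
        theta <- adam_update(theta, grad, adam_m, adam_v, step,
                             lr = cfg$learning_rate)
        adam_m <- attr(theta, "m"); adam_v <- attr(theta, "v")
        attr(theta, "m") <- NULL; attr(theta, "v") <- NULL
        epoch_loss <- epoch_loss + batch_loss
      }
      row <- data.frame(epoch = epoch, loss = epoch_loss / n)
      model_now <- build_model(theta, cfg, provider, index, labels, mask, history)
      if (!is.null(eval_docs)) {
        pred <- predict_tagger(model_now, vapply(eval_docs, `[[`, "", "text"),
                               doc_ids = vapply(eval_docs, `[[`, "", "doc_id"))
        row$eval_f1 <- strict_match_score(eval_docs, pred)$micro$f1
      }
      history <- rbind(history, row)
      if (!quiet) {
        message(sprintf("epoch %d/%d  loss %.4f%s", epoch, epoch0 + cfg$epochs, row$loss,
                        if (!is.null(row$eval_f1))
                          sprintf("  heldout F1 %.3f", row$eval_f1) else ""))
      }
    }
    build_model(theta, cfg, provider, index, labels, mask, history)
  })
}

## Forward + backward for one training sequence; returns loss and gradients
## for every parameter tensor touched (embedding gradients are sparse and
## returned dense for simplicity -- vocabularies here are small).
tagger_seq_grad <- function(theta, inst, cfg, H, K, mask, dropout = 0) {
  T_ <- length(inst$rows)
  d_tok <- ncol(theta$emb)
  X <- t(cbind(theta$emb[inst$rows, , drop = FALSE],
               theta$rad[inst$rads, , drop = FALSE]))
  pf <- list(W = theta$Wf, U = theta$Uf, b = theta$bf, hidden = H)
  pb <- list(W = theta$Wb, U = theta$Ub, b = theta$bb, hidden = H)
  enc <- bilstm_forward(pf, pb, X)
  Hc <- enc$H
  drop_mask <- NULL
  if (dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(Hc), 1, 1 - dropout), nrow(Hc)) /
      (1 - dropout)
    Hc <- Hc * drop_mask
  }
  E <- t(theta$Wp %*% Hc + theta$bp)
  params <- crf_params(bio_tags(), transitions = theta$trans + (if (is.null(mask)) 0 else mask$transitions),
                       start = theta$start + (if (is.null(mask)) 0 else mask$start),
                       end = theta$end)
  g <- crf_grad(E, params, inst$gold)
  dEt <- t(g$emissions)                       # K x T
  dWp <- dEt %*% t(Hc)
  dbp <- rowSums(dEt)
  dHc <- crossprod(theta$Wp, dEt)             # 2H x T
  if (!is.null(drop_mask)) dHc <- dHc * drop_mask
  gb <- bilstm_backward(pf, pb, enc, dHc)
  # scatter input gradients back into the embedding tables
  dX <- gb$X
  d_emb <- matrix(0, nrow(theta$emb), d_tok)
  acc <- rowsum(t(dX[1:d_tok, , drop = FALSE]), group = inst$rows)
  d_emb[as.integer(rownames(acc)), ] <- acc
  d_rad <- matrix(0, nrow(theta$rad), ncol(theta$rad))
  accr <- rowsum(t(dX[(d_tok + 1L):nrow(dX), , drop = FALSE]), group = inst$rads)
  d_rad[as.integer(rownames(accr)), ] <- accr
  d_trans <- g$transitions
  if (!is.null(mask)) d_trans[mask$transitions == -Inf] <- 0
  d_start <- g$start
  if (!is.null(mask)) d_start[mask$start == -Inf] <- 0
  list(loss = g$nll,
       grad = list(emb = d_emb, rad = d_rad,
                   Wf = gb$fwd$W, Uf = gb$fwd$U, bf = gb$fwd$b,
                   Wb = gb$bwd$W, Ub = gb$bwd$U, bb = gb$bwd$b,
                   Wp = dWp, bp = dbp,
                   trans = d_trans, start = d_start, end = g$end))
}

## One Adam step over the whole parameter list; moment states ride along as
## attributes to keep the call site compact.
adam_update <- function(theta, grad, m, v, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grad)) {
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grad[[nm]]
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- m[[nm]] / (1 - beta1^step)
    vhat <- v[[nm]] / (1 - beta2^step)
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  attr(theta, "m") <- m
  attr(theta, "v") <- v
  theta
}

build_model <- function(theta, cfg, provider, index, labels, mask, history) {
  provider$vectors <- theta$emb
  structure(list(format = "radner-checkpoint-1",
                 cfg = cfg, provider = provider,
                 radical_table = index$table,
                 theta = theta, labels = labels, mask = mask,
                 history = history),
            class = "radner_model")
}

#' @export
print.radner_model <- function(x, ...) {
  cat(sprintf("<radner_model> BiLSTM(%d)+CRF, token dim %d, radical dim %d, vocab %d\n",
              x$cfg$lstm_hidden, x$provider$dim, x$cfg$radical_dim,
              length(x$provider$vocab)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs, final loss %.4f\n", last$epoch, last$loss))
  }
  invisible(x)
}

## Emission scores for a character sequence under a trained model (no dropout).
model_emissions <- function(model, chars, index) {
  th <- model$theta
  X <- t(cbind(th$emb[token_rows(chars, model$provider), , drop = FALSE],
               th$rad[radicals_of(chars, index) + 1L, , drop = FALSE]))
  pf <- list(W = th$Wf, U = th$Uf, b = th$bf, hidden = model$cfg$lstm_hidden)
  pb <- list(W = th$Wb, U = th$Ub, b = th$bb, hidden = model$cfg$lstm_hidden)
  enc <- bilstm_forward(pf, pb, X)
  t(th$Wp %*% enc$H + th$bp)
}

model_crf <- function(model) {
  th <- model$theta
  if (is.null(model$mask)) {
    crf_params(model$labels, transitions = th$trans, start = th$start, end = th$end)
  } else {
    crf_params(model$labels, transitions = th$trans + model$mask$transitions,
               start = th$start + model$mask$start, end = th$end)
  }
}

#' Predict entity spans in plain texts
#'
#' Each text is split below the model's length limit, encoded, Viterbi
#' decoded, and the fragment tag sequences are mapped back to whole-document
#' character offsets.
#'
#' @param model A trained [train_tagger()] model.
#' @param texts Character vector of narratives.
#' @param doc_ids Optional ids (default `"text1"`, `"text2"`, ...).
#' @return List of [ann_doc()] with predicted entities.
#' @export
predict_tagger <- function(model, texts, doc_ids = NULL) {
  stopifnot(inherits(model, "radner_model"))
  if (length(texts) == 0) return(list())
  if (is.null(doc_ids)) doc_ids <- paste0("text", seq_along(texts))
  stopifnot(length(doc_ids) == length(texts))
  index <- index_from_table(model$radical_table)
  params <- model_crf(model)
  out <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    doc <- ann_doc(doc_ids[i], texts[i])
    etype <- character(0); start <- integer(0); end <- integer(0)
    if (nchar(texts[i]) > 0) {
      for (frag in split_long(doc, model$cfg$max_len - 2L)) {
        chars <- chars_of(frag$text)
        e <- model_emissions(model, chars, index)
        spans <- tags_to_spans(crf_viterbi(e, params))
        off <- attr(frag, "origin_offset")
        etype <- c(etype, spans$etype)
        start <- c(start, spans$start + off)
        end <- c(end, spans$end + off)
      }
    }
    out[[i]] <- ann_doc(doc_ids[i], texts[i], entity_spans(etype, start, end))
  }
  out
}

index_from_table <- function(tab) {
  env <- new.env(parent = emptyenv())
  env$table <- tab
  env$warned <- TRUE  # silent at prediction time
  structure(env, class = "radical_index")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding every parameter tensor,
#' the training configuration, the provider vocabulary and the radical
#' table, with a format version identifier.
#'
#' @param model A `radner_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "radner_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "radner-checkpoint-1")) {
    stop("unrecognized checkpoint format: ", obj$format)
  }
  structure(obj, class = "radner_model")
}
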