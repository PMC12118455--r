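# The 6mA caller: a small dense neural network over per-adenine feature
# windows, trained with mini-batch Adam and early stopping, plus evaluation
# metrics and a logistic-regression reference model.

relu <- function(x) pmax(x, 0)

init_layer <- function(n_in, n_out, mirrored = FALSE) {
  # He-uniform initialisation; `mirrored` seeds the layer with +/- column
  # pairs so rectifier pairs start as magnitude detectors — the 6mA level
  # shift has a context-dependent random sign, so |z|-like functions are
  # what the first layer must represent
  r <- sqrt(6 / n_in)
  W <- matrix(runif(n_in * n_out, -r, r), n_in, n_out)
  if (mirrored && n_out >= 2L) {
    half <- n_out %/% 2L
    W[, (half + 1L):(2L * half)] <- -W[, 1:half]
  }
  list(W = W, b = numeric(n_out))
}

nn_forward <- function(params, X) {
  h1 <- relu(sweep(X %*% params[[1L]]$W, 2L, params[[1L]]$b, "+"))
  h2 <- relu(sweep(h1 %*% params[[2L]]$W, 2L, params[[2L]]$b, "+"))
  o <- sweep(h2 %*% params[[3L]]$W, 2L, params[[3L]]$b, "+")
  p <- 1 / (1 + exp(-o))
  list(h1 = h1, h2 = h2, p = as.numeric(p))
}

nn_gradients <- function(params, X, y, fwd) {
  n <- nrow(X)
  d_o <- matrix((fwd$p - y) / n, n, 1L)
  g3 <- list(W = t(fwd$h2) %*% d_o, b = colSums(d_o))
  d_h2 <- (d_o %*% t(params[[3L]]$W)) * (fwd$h2 > 0)
  g2 <- list(W = t(fwd$h1) %*% d_h2, b = colSums(d_h2))
  d_h1 <- (d_h2 %*% t(params[[2L]]$W)) * (fwd$h1 > 0)
  g1 <- list(W = t(X) %*% d_h1, b = colSums(d_h1))
  list(g1, g2, g3)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train the 6mA caller
#'
#' A dense network (flattened `W x 7` features -> 64 -> 32 -> sigmoid) with
#' cross-entropy loss, mini-batch Adam, and early stopping on validation
#' loss. The validation split is positional: all windows centred on a
#' held-out 20% of genomic positions form the validation set, preventing
#' label leakage through shared genomic context between reads.
#'
#' @param windows a `feature_windows` object with labels, or a list with
#'   `features` (matrix) and `meta` (with `contig`, `pos`, `strand`, `label`).
#' @param seed training seed (initialisation, shuffling, split).
#' @param hidden hidden layer sizes (default `c(64, 32)`).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs (default 12: the
#'   sign-symmetric shift pattern takes tens of epochs to emerge, well after
#'   the first validation-loss plateau).
#' @param val_fraction fraction of genomic positions held out.
#' @param tau decision threshold for binary calls (default 0.5).
#' @param weight_decay decoupled L2 penalty applied to weight matrices
#'   (default 1e-3).
#' @param context_decay much stronger decoupled L2 applied to first-layer
#'   weights fed by binary (one-hot sequence) inputs (default 0.3).
#'   Regularisation is load-bearing here: a window's 17-base context
#'   identifies its genomic position almost uniquely, so an unregularised
#'   network memorises position labels through the one-hot block instead of
#'   learning the signal-level 6mA shift; penalising context weights makes
#'   sequence unable to substitute for signal evidence.
#' @param dropout input dropout probability during training (default 0.1).
#' @return list `(model, report)`: `model` is a `caller_model` (parameters,
#'   feature normalisation constants, `tau`, seed); `report` is a
#'   `train_report` (epochs, losses, validation AUROC, class balance).
#' @export
train_caller <- function(windows, seed = 1L, hidden = c(64L, 32L), lr = 1e-3,
                         batch_size = 128L, max_epochs = 120L, patience = 12L,
                         val_fraction = 0.2, tau = 0.5, weight_decay = 1e-3,
                         context_decay = 0.3, dropout = 0.1) {
  X <- windows$features
  y <- windows$meta$label
  if (anyNA(y)) stop("training windows must all carry labels", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; need both methylated and ",
         "unmethylated examples", call. = FALSE)
  }
  if (nrow(X) < 200L) stop("need at least 200 labelled windows", call. = FALSE)
  pos_key <- paste(windows$meta$contig, windows$meta$pos, windows$meta$strand)
  upos <- unique(pos_key)
  with_seed(seed, {
    val_pos <- sample(upos, max(1L, round(val_fraction * length(upos))))
    is_val <- pos_key %in% val_pos
    if (all(is_val) || !any(is_val)) stop("degenerate positional split", call. = FALSE)
    mu <- colMeans(X[!is_val, , drop = FALSE])
    sg <- pmax(apply(X[!is_val, , drop = FALSE], 2L, sd), 1e-6)
    # binary (one-hot) columns stay on their natural 0/1 scale: standardising
    # a rare indicator inflates it into a high-magnitude input that drowns
    # the signal features
    is_binary <- apply(X[!is_val, , drop = FALSE], 2L,
                       function(col) all(col %in% c(0, 1)))
    mu[is_binary] <- 0
    sg[is_binary] <- 1
    Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
    Xtr <- Xs[!is_val, , drop = FALSE]; ytr <- y[!is_val]
    Xva <- Xs[is_val, , drop = FALSE]; yva <- y[is_val]
    if (length(unique(ytr)) < 2L) stop("training split has a single class", call. = FALSE)
    sizes <- c(ncol(X), hidden, 1L)
    params <- lapply(seq_len(length(sizes) - 1L),
                     function(i) init_layer(sizes[i], sizes[i + 1L],
                                            mirrored = (i == 1L)))
    wd_layer1 <- rep(weight_decay, ncol(X))
    wd_layer1[is_binary] <- context_decay
    mstate <- rapply(params, function(x) x * 0, how = "replace")
    vstate <- mstate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
    best_val <- Inf; best_auc <- -Inf
    best_params <- params; best_epoch <- 0L; stall <- 0L
    tr_loss <- NA_real_
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(nrow(Xtr))
      losses <- c()
      for (bs in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[bs:min(bs + batch_size - 1L, length(ord))]
        Xb <- Xtr[idx, , drop = FALSE]
        if (dropout > 0) {
          mask <- matrix(runif(length(Xb)) >= dropout, nrow(Xb), ncol(Xb))
          Xb <- Xb * mask / (1 - dropout)
        }
        fwd <- nn_forward(params, Xb)
        losses <- c(losses, bce_loss(fwd$p, ytr[idx]))
        grads <- nn_gradients(params, Xb, ytr[idx], fwd)
        step <- step + 1L
        for (l in seq_along(params)) {
          for (nm in c("W", "b")) {
            g <- grads[[l]][[nm]]
            mstate[[l]][[nm]] <- b1 * mstate[[l]][[nm]] + (1 - b1) * g
            vstate[[l]][[nm]] <- b2 * vstate[[l]][[nm]] + (1 - b2) * g^2
            mhat <- mstate[[l]][[nm]] / (1 - b1^step)
            vhat <- vstate[[l]][[nm]] / (1 - b2^step)
            upd <- lr * mhat / (sqrt(vhat) + eps)
            if (nm == "W") {
              wd <- if (l == 1L) wd_layer1 else weight_decay
              upd <- upd + lr * wd * params[[l]][[nm]]
            }
            params[[l]][[nm]] <- params[[l]][[nm]] - upd
          }
        }
      }
      tr_loss <- mean(losses)
      if (!is.finite(tr_loss)) {
        stop("training diverged (non-finite loss) with lr=", lr,
             " batch_size=", batch_size, " hidden=", paste(hidden, collapse = ","),
             call. = FALSE)
      }
      # model selection tracks validation AUROC (the deployment metric);
      # validation loss can degrade through a calibration drift while
      # ranking quality is still improving
      val_fwd <- nn_forward(params, Xva)$p
      val_loss <- bce_loss(val_fwd, yva)
      val_auc <- auroc(val_fwd, yva)
      if (val_auc > best_auc + 1e-5) {
        best_auc <- val_auc; best_val <- val_loss; best_params <- params
        best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    val_p <- nn_forward(best_params, Xva)$p
    model <- structure(list(hidden = hidden, params = best_params,
                            feature_mean = mu, feature_sd = sg,
                            tau = tau, seed = as.integer(seed),
                            n_features = ncol(X)),
                       class = "caller_model")
    report <- structure(list(epochs = epoch, best_epoch = best_epoch,
                             train_loss = tr_loss, val_loss = best_val,
                             val_auroc = auroc(val_p, yva),
                             class_balance = mean(y),
                             n_train = nrow(Xtr), n_val = nrow(Xva),
                             seed = as.integer(seed)),
                        class = "train_report")
    list(model = model, report = report)
  })
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(paste0("train_report: %d epoch(s) (best %d), train loss %.4f, ",
                     "val loss %.4f, val AUROC %.4f, positive fraction %.3f\n"),
              x$epochs, x$best_epoch, x$train_loss, x$val_loss, x$val_auroc,
              x$class_balance))
  invisible(x)
}

#' Predict per-read site probabilities
#'
#' Applies the stored feature normalisation and forward pass; processing is
#' chunked and order-independent.
#'
#' @param model a trained `caller_model`.
#' @param windows a `feature_windows` object.
#' @param chunk rows per forward-pass chunk.
#' @return data.table of per-read calls: `read_id`, `contig`, `pos`,
#'   `strand`, `prob`, `call` (`prob >= tau`).
#' @export
predict_read_sites <- function(model, windows, chunk = 50000L) {
  stopifnot(inherits(model, "caller_model"))
  X <- windows$features
  if (ncol(X) != model$n_features) {
    stop("feature width mismatch: model expects ", model$n_features,
         ", windows have ", ncol(X), call. = FALSE)
  }
  n <- nrow(X)
  p <- numeric(n)
  if (n > 0L) {
    Xs <- sweep(sweep(X, 2L, model$feature_mean, "-"), 2L, model$feature_sd, "/")
    for (bs in seq(1L, n, by = chunk)) {
      idx <- bs:min(bs + chunk - 1L, n)
      p[idx] <- nn_forward(model$params, Xs[idx, , drop = FALSE])$p
    }
  }
  out <- data.table(read_id = windows$meta$read_id, contig = windows$meta$contig,
                    pos = windows$meta$pos, strand = windows$meta$strand,
                    prob = p, call = as.integer(p >= model$tau))
  out[]
}

#' Rank-statistic AUROC with midrank tie handling
#' @param scores numeric prediction scores.
#' @param labels 0/1 truth labels (both classes present).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate per-read calls against truth labels
#'
#' @param calls data.table from [predict_read_sites()].
#' @param truth_labels 0/1 vector aligned with `calls` rows, or a
#'   `feature_windows` object whose `meta$label` supplies the labels.
#' @param tau decision threshold (defaults to the calls' binary column).
#' @return list of class `caller_metrics`: `auroc`, `precision`, `recall`,
#'   `f1`, `n`, `tau`.
#' @export
evaluate_caller <- function(calls, truth_labels, tau = NULL) {
  if (inherits(truth_labels, "feature_windows")) {
    truth_labels <- truth_labels$meta$label
  }
  if (length(truth_labels) != nrow(calls) || anyNA(truth_labels)) {
    stop("need one non-missing truth label per call", call. = FALSE)
  }
  y <- as.integer(truth_labels)
  pred <- if (is.null(tau)) calls$call else as.integer(calls$prob >= tau)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(auroc = auroc(calls$prob, y), precision = precision,
                 recall = recall, f1 = f1, n = nrow(calls),
                 tau = if (is.null(tau)) NA_real_ else tau),
            class = "caller_metrics")
}

#' @export
print.caller_metrics <- function(x, ...) {
  cat(sprintf("caller_metrics: AUROC %.4f, precision %.4f, recall %.4f, F1 %.4f (n=%d)\n",
              x$auroc, x$precision, x$recall, x$f1, x$n))
  invisible(x)
}

#' Save / load a trained caller model
#' @param model a `caller_model`.
#' @param path file path.
#' @return `path` (save) or the restored `caller_model` (load).
#' @export
save_caller <- function(model, path) {
  stopifnot(inherits(model, "caller_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_caller
#' @export
load_caller <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "caller_model")) stop("not a caller model: ", path,
                                             call. = FALSE)
  model
}

#' Logistic-regression reference caller
#'
#' An L2-free logistic regression on the same flattened features, fitted
#' with IRLS via `glm.fit`. Serves as an internal reference the network is
#' expected to match or beat on the default simulation.
#'
#' @param windows labelled `feature_windows`.
#' @param seed split seed (same positional split rule as [train_caller()]).
#' @param val_fraction held-out fraction of genomic positions.
#' @return list: `val_auroc`, `coefficients`, `is_val`.
#' @export
logistic_baseline <- function(windows, seed = 1L, val_fraction = 0.2) {
  X <- windows$features
  y <- windows$meta$label
  pos_key <- paste(windows$meta$contig, windows$meta$pos, windows$meta$strand)
  upos <- unique(pos_key)
  with_seed(seed, {
    val_pos <- sample(upos, max(1L, round(val_fraction * length(upos))))
    is_val <- pos_key %in% val_pos
    mu <- colMeans(X[!is_val, , drop = FALSE])
    sg <- pmax(apply(X[!is_val, , drop = FALSE], 2L, sd), 1e-6)
    Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, Xs[!is_val, , drop = FALSE]), y[!is_val],
                     family = stats::binomial())
    )
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0 # collinear/constant columns drop out
    eta <- cbind(1, Xs[is_val, , drop = FALSE]) %*% beta
    list(val_auroc = auroc(as.numeric(eta), y[is_val]),
         coefficients = fit$coefficients, is_val = is_val)
  })
}
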