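# Recurrent Pmus estimator: a small Elman recurrent network mapping the
# (paw, flow, volume) sample stream to Pmus, trained by backpropagation
# through time with Adam on simulator-generated records. A desk-scale
# demonstration of learning Pmus from airway signals; the transparent
# model-based inversion remains the package's reference method.

rnn_init <- function(n_in, hidden, seed) {
  set.seed(as.integer(seed))
  list(
    Wx = matrix(stats::rnorm(hidden * n_in, 0, 0.3), hidden, n_in),
    Wh = matrix(stats::rnorm(hidden * hidden, 0, 1 / sqrt(hidden)), hidden, hidden),
    b = numeric(hidden),
    wo = stats::rnorm(hidden, 0, 0.3),
    bo = 0
  )
}

rnn_forward <- function(par, X) {
  Tn <- nrow(X); H <- length(par$b)
  Hs <- matrix(0, H, Tn)
  h <- numeric(H)
  XT <- t(X)
  for (t in seq_len(Tn)) {
    h <- tanh(par$Wx %*% XT[, t] + par$Wh %*% h + par$b)
    Hs[, t] <- h
  }
  yhat <- as.vector(crossprod(Hs, par$wo)) + par$bo
  list(Hs = Hs, yhat = yhat)
}

rnn_backward <- function(par, X, y, fw) {
  Tn <- nrow(X); H <- length(par$b)
  Hs <- fw$Hs
  dy <- 2 * (fw$yhat - y) / Tn
  g <- list(Wx = matrix(0, H, ncol(X)), Wh = matrix(0, H, H),
            b = numeric(H), wo = as.vector(Hs %*% dy), bo = sum(dy))
  dpre_next <- numeric(H)
  XT <- t(X)
  for (t in Tn:1) {
    h <- Hs[, t]
    dh <- par$wo * dy[t] + crossprod(par$Wh, dpre_next)
    dpre <- as.vector(dh) * (1 - h^2)
    g$Wx <- g$Wx + tcrossprod(dpre, XT[, t])
    hprev <- if (t > 1L) Hs[, t - 1L] else numeric(H)
    g$Wh <- g$Wh + tcrossprod(dpre, hprev)
    g$b <- g$b + dpre
    dpre_next <- dpre
  }
  g
}

downsample_record <- function(signals, factor) {
  idx <- seq(1L, nrow(signals), by = factor)
  list(X = cbind(paw = signals$paw[idx], flow = signals$flow[idx],
                 volume = signals$volume[idx]),
       y = signals$pmus_true[idx], idx = idx)
}

#' Train the recurrent Pmus estimator
#'
#' Trains a single-layer Elman recurrent network (inputs per time step: paw,
#' flow, volume; output: Pmus) on simulator-rendered records by full
#' backpropagation through time with Adam. Deterministic given the seed.
#' Training and evaluation records must come from disjoint scenario ids
#' (no leakage across 30-s records of the same scenario).
#'
#' @param records list of rendered scenarios ([render_scenario()] outputs).
#' @param train_ids,eval_ids disjoint scenario-id sets selecting the split.
#' @param seed integer seed (weight init and record ordering).
#' @param hidden hidden units (default 16).
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate (default 0.02).
#' @param downsample keep every k-th sample for training/prediction
#'   (default 5, i.e. 20 Hz from a 100-Hz record).
#' @param pmus_scale output normalization (cmH2O per unit), default 10.
#' @return object of class `pmus_rnn` with the weights, normalization
#'   constants, hyperparameters, split manifest, per-epoch training loss and
#'   held-out evaluation table (`rms_error` per eval record).
#' @export
train_recurrent_estimator <- function(records, train_ids, eval_ids,
                                      seed = 1L, hidden = 16L, epochs = 30L,
                                      lr = 0.02, downsample = 5L,
                                      pmus_scale = 10) {
  if (length(intersect(train_ids, eval_ids))) {
    stop("training/evaluation scenario ids overlap")
  }
  ids <- vapply(records, function(r) r$key$scenario_id, integer(1))
  tr <- records[ids %in% train_ids]
  ev <- records[ids %in% eval_ids]
  if (!length(tr)) stop("no training records match train_ids")
  if (anyNA(unlist(lapply(tr, function(r) r$signals$pmus_true)))) {
    stop("training records need a gold Pmus channel")
  }

  dtr <- lapply(tr, function(r) downsample_record(r$signals, downsample))
  Xall <- do.call(rbind, lapply(dtr, `[[`, "X"))
  mu <- colMeans(Xall); sdv <- apply(Xall, 2, stats::sd)
  sdv[sdv < 1e-9] <- 1
  norm_X <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  dtr <- lapply(dtr, function(d) { d$X <- norm_X(d$X); d$y <- d$y / pmus_scale; d })

  par <- rnn_init(3L, hidden, seed)
  mstate <- vstate <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  loss_trace <- numeric(epochs)
  set.seed(as.integer(seed) + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(dtr))
    tot <- 0
    for (i in ord) {
      d <- dtr[[i]]
      fw <- rnn_forward(par, d$X)
      tot <- tot + mean((fw$yhat - d$y)^2)
      g <- rnn_backward(par, d$X, d$y, fw)
      gn <- sqrt(sum(unlist(lapply(g, function(x) sum(x^2)))))
      if (gn > 5) g <- lapply(g, function(x) x * 5 / gn)
      step <- step + 1
      for (nm in names(par)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_trace[ep] <- tot / length(dtr)
  }

  model <- structure(list(par = par, mu = mu, sd = sdv,
                          pmus_scale = pmus_scale, downsample = downsample,
                          hidden = hidden, epochs = epochs, lr = lr,
                          seed = as.integer(seed),
                          split = list(train_ids = sort(train_ids),
                                       eval_ids = sort(eval_ids)),
                          loss_trace = loss_trace),
                     class = "pmus_rnn")
  if (length(ev)) {
    evtab <- do.call(rbind, lapply(ev, function(r) {
      est <- predict_recurrent(model, r$signals)
      data.frame(scenario_id = r$key$scenario_id,
                 rms_error = sqrt(mean((est - r$signals$pmus_true)^2)),
                 mean_abs = mean(abs(est)))
    }))
    model$eval <- evtab
    model$eval_rms_pooled <- sqrt(mean(evtab$rms_error^2))
  }
  model
}

#' Predict Pmus with a trained recurrent estimator
#'
#' @param model a `pmus_rnn` from [train_recurrent_estimator()].
#' @param signals a `breath_signals` record.
#' @return estimated Pmus series (cmH2O) aligned to the record's time grid
#'   (nonnegative, linearly interpolated back from the training rate).
#' @export
predict_recurrent <- function(model, signals) {
  stopifnot(inherits(model, "pmus_rnn"), inherits(signals, "breath_signals"))
  d <- downsample_record(signals, model$downsample)
  X <- sweep(sweep(d$X, 2, model$mu), 2, model$sd, "/")
  yhat <- rnn_forward(model$par, X)$yhat * model$pmus_scale
  yhat <- pmax(yhat, 0)
  stats::approx(d$idx, yhat, xout = seq_len(nrow(signals)), rule = 2)$y
}

#' @export
print.pmus_rnn <- function(x, ...) {
  cat(sprintf(
    "<pmus_rnn> %d hidden units, %d epochs, seed %d; train n=%d, eval n=%d%s\n",
    x$hidden, x$epochs, x$seed, length(x$split$train_ids),
    length(x$split$eval_ids),
    if (!is.null(x$eval_rms_pooled))
      sprintf(", held-out rms %.2f cmH2O", x$eval_rms_pooled) else ""))
  invisible(x)
}

#' Save / load a trained recurrent estimator
#'
#' The artifact is a single JSON file carrying the weights together with the
#' sidecar metadata (normalization constants, seed, split manifest,
#' hyperparameters).
#'
#' @param model a `pmus_rnn`.
#' @param path output file (JSON).
#' @return `path` (save) or the restored `pmus_rnn` (load).
#' @export
save_estimator <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("saving the estimator artifact requires the jsonlite package")
  }
  obj <- unclass(model)
  obj$par <- lapply(model$par, function(p)
    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else p)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("loading the estimator artifact requires the jsonlite package")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$par <- lapply(obj$par, function(p)
    if (is.list(p) && !is.null(p$dim)) matrix(p$data, p$dim[1L], p$dim[2L])
    else unlist(p))
  obj$mu <- unlist(obj$mu); obj$sd <- unlist(obj$sd)
  structure(obj, class = "pmus_rnn")
}
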