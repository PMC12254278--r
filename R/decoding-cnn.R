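#' Extract trial-aligned calcium feature tensors
#'
#' Cuts each unit's dF/F trace into windows of `n_pre` frames before and
#' `n_post` frames after each trial's touch time (12 + 12 frames = 400 ms
#' each side at 30 Hz).
#'
#' @param calcium A `wt_calcium` tibble (`unit_id`, `t`, `dff`).
#' @param trials Tibble with `t_touch` and `label`.
#' @param n_pre,n_post Frames before / after touch.
#' @return A list with `tensor` (array trials x units x frames) and
#'   `labels`.
#' @export
calcium_trial_features <- function(calcium, trials, n_pre = 12,
                                   n_post = 12) {
  fps <- attr(calcium, "fps") %||% (1 / median(diff(unique(calcium$t))))
  units <- sort(unique(calcium$unit_id))
  tgrid <- sort(unique(calcium$t))
  n_fr <- n_pre + n_post
  keep <- vapply(trials$t_touch, function(x) {
    i0 <- which.min(abs(tgrid - x))
    i0 - n_pre >= 1 && i0 + n_post - 1 <= length(tgrid)
  }, logical(1))
  trials <- trials[keep, ]
  tensor <- array(NA_real_, dim = c(nrow(trials), length(units), n_fr))
  for (ui in seq_along(units)) {
    dff <- calcium$dff[calcium$unit_id == units[ui]]
    for (k in seq_len(nrow(trials))) {
      i0 <- which.min(abs(tgrid - trials$t_touch[k]))
      tensor[k, ui, ] <- dff[(i0 - n_pre):(i0 + n_post - 1)]
    }
  }
  list(tensor = tensor, labels = trials$label, units = units, fps = fps)
}

# ---- minimal CNN primitives (layout: H x W x N x C arrays) --------------

conv_forward <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  Xp <- array(0, c(H + 2, Wd + 2, N, Cin))
  Xp[2:(H + 1), 2:(Wd + 1), , ] <- X
  P <- matrix(0, H * Wd * N, 9 * Cin)
  q <- 0L
  for (cc in seq_len(Cin)) for (dx in 1:3) for (dy in 1:3) {
    q <- q + 1L
    P[, q] <- as.vector(Xp[dy:(dy + H - 1), dx:(dx + Wd - 1), , cc])
  }
  Wmat <- matrix(W, nrow = 9 * Cin, ncol = Cout)
  out_mat <- P %*% Wmat
  out_mat <- sweep(out_mat, 2, b, "+")
  list(out = array(out_mat, c(H, Wd, N, Cout)), P = P,
       dims = c(H, Wd, N, Cin))
}

conv_backward <- function(dOut, cache, W) {
  H <- cache$dims[1]; Wd <- cache$dims[2]; N <- cache$dims[3]
  Cin <- cache$dims[4]; Cout <- dim(W)[4]
  dOm <- matrix(dOut, ncol = Cout)
  Wmat <- matrix(W, nrow = 9 * Cin, ncol = Cout)
  dW <- array(crossprod(cache$P, dOm), dim = dim(W))
  db <- colSums(dOm)
  dP <- dOm %*% t(Wmat)
  dXp <- array(0, c(H + 2, Wd + 2, N, Cin))
  q <- 0L
  for (cc in seq_len(Cin)) for (dx in 1:3) for (dy in 1:3) {
    q <- q + 1L
    dXp[dy:(dy + H - 1), dx:(dx + Wd - 1), , cc] <-
      dXp[dy:(dy + H - 1), dx:(dx + Wd - 1), , cc] +
      array(dP[, q], c(H, Wd, N))
  }
  list(dX = dXp[2:(H + 1), 2:(Wd + 1), , , drop = FALSE], dW = dW, db = db)
}

bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  C <- dim(X)[4]
  Xm <- matrix(X, ncol = C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(sweep(Xm, 2, mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  std <- sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, std, "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(out, dim(X)), xhat = xhat, std = std,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dOut, cache, gamma) {
  C <- length(gamma)
  dOm <- matrix(dOut, ncol = C)
  m <- nrow(dOm)
  dgamma <- colSums(dOm * cache$xhat)
  dbeta <- colSums(dOm)
  t1 <- sweep(dOm, 2, colMeans(dOm))
  t2 <- sweep(cache$xhat, 2, colMeans(dOm * cache$xhat), "*")
  dXm <- sweep(t1 - t2, 2, gamma / cache$std, "*")
  list(dX = array(dXm, dim(dOut)), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(X) {
  d <- dim(X); H2 <- d[1] %/% 2; W2 <- d[2] %/% 2
  ri <- seq_len(2 * H2); ci <- seq_len(2 * W2)
  Xc <- X[ri, ci, , , drop = FALSE]
  s <- list(
    Xc[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
    Xc[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
    Xc[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE],
    Xc[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE]
  )
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # deterministic tie-break: first slice in fixed order wins
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4)
  for (k in 1:4) {
    masks[[k]] <- (s[[k]] == out) & !taken
    taken <- taken | masks[[k]]
  }
  list(out = out, masks = masks, in_dim = d, H2 = H2, W2 = W2)
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$in_dim; H2 <- cache$H2; W2 <- cache$W2
  dX <- array(0, d)
  rows <- list(seq(1, 2 * H2, 2), seq(2, 2 * H2, 2))
  cols <- list(seq(1, 2 * W2, 2), seq(2, 2 * W2, 2))
  combo <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    r <- rows[[combo[[k]][1]]]; cl <- cols[[combo[[k]][2]]]
    dX[r, cl, , ] <- dX[r, cl, , ] + dOut * cache$masks[[k]]
  }
  dX
}

# Flatten (H,W,N,C) -> (D x N) feature matrix per sample.
flatten_fw <- function(X) {
  d <- dim(X)
  Xp <- aperm(X, c(1, 2, 4, 3))      # H, W, C, N
  list(out = matrix(Xp, nrow = d[1] * d[2] * d[4], ncol = d[3]), dims = d)
}
flatten_bw <- function(dF, dims) {
  aperm(array(dF, c(dims[1], dims[2], dims[4], dims[3])), c(1, 2, 4, 3))
}

cnn_init <- function(H, W, filters, n_class, seed) {
  with_seed(seed, {
    mk_conv <- function(cin, cout) list(
      W = array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                c(3, 3, cin, cout)),
      b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
      run_mean = numeric(cout), run_var = rep(1, cout)
    )
    H2 <- H %/% 2; W2 <- W %/% 2
    D <- (H2 %/% 2) * (W2 %/% 2) * filters[2]
    list(c1 = mk_conv(1, filters[1]), c2 = mk_conv(filters[1], filters[2]),
         fc = list(W = matrix(rnorm(n_class * D, 0, sqrt(2 / D)),
                              n_class, D),
                   b = numeric(n_class)))
  })
}

cnn_forward <- function(net, X, training) {
  cv1 <- conv_forward(X, net$c1$W, net$c1$b)
  bn1 <- bn_forward(cv1$out, net$c1$gamma, net$c1$beta, net$c1$run_mean,
                    net$c1$run_var, training)
  r1 <- pmax(bn1$out, 0)
  p1 <- maxpool_forward(r1)
  cv2 <- conv_forward(p1$out, net$c2$W, net$c2$b)
  bn2 <- bn_forward(cv2$out, net$c2$gamma, net$c2$beta, net$c2$run_mean,
                    net$c2$run_var, training)
  r2 <- pmax(bn2$out, 0)
  p2 <- maxpool_forward(r2)
  fl <- flatten_fw(p2$out)
  logits <- sweep(net$fc$W %*% fl$out, 1, net$fc$b, "+")
  em <- exp(sweep(logits, 2, apply(logits, 2, max)))
  probs <- sweep(em, 2, colSums(em), "/")
  list(cv1 = cv1, bn1 = bn1, r1 = r1, p1 = p1, cv2 = cv2, bn2 = bn2,
       r2 = r2, p2 = p2, fl = fl, logits = logits, probs = probs)
}

cnn_backward <- function(net, fw, X, Y) {
  N <- ncol(fw$probs)
  dlog <- (fw$probs - Y) / N
  g <- list()
  g$fc_W <- dlog %*% t(fw$fl$out)
  g$fc_b <- rowSums(dlog)
  dF <- t(net$fc$W) %*% dlog
  dP2 <- flatten_bw(dF, fw$fl$dims)
  dR2 <- maxpool_backward(dP2, fw$p2)
  dB2 <- dR2 * (fw$r2 > 0)
  bb2 <- bn_backward(dB2, fw$bn2, net$c2$gamma)
  cb2 <- conv_backward(bb2$dX, fw$cv2, net$c2$W)
  dR1 <- maxpool_backward(cb2$dX, fw$p1)
  dB1 <- dR1 * (fw$r1 > 0)
  bb1 <- bn_backward(dB1, fw$bn1, net$c1$gamma)
  cb1 <- conv_backward(bb1$dX, fw$cv1, net$c1$W)
  g$c2_W <- cb2$dW; g$c2_b <- cb2$db
  g$c2_gamma <- bb2$dgamma; g$c2_beta <- bb2$dbeta
  g$c1_W <- cb1$dW; g$c1_b <- cb1$db
  g$c1_gamma <- bb1$dgamma; g$c1_beta <- bb1$dbeta
  g
}

#' Aperture decoding from calcium transients with a small CNN
#'
#' Binary classification of trial-aligned dF/F tensors (units x 24
#' frames: 12 before and 12 after touch) with a compact ReLU-activated
#' convolutional network: two convolutional blocks (3x3 convolution with
#' padding that preserves the input dimensions, batch normalization, ReLU,
#' then 2x2 max pooling that halves the feature maps), followed by a fully
#' connected layer with two outputs and a softmax. Training uses
#' stochastic gradient descent with momentum over `epochs` epochs at the
#' given initial learning rate; all randomness (initialization, the
#' stratified train/validation split, minibatch order) is seeded, so a
#' rerun reproduces the accuracy exactly.
#'
#' @param tensor Array trials x units x frames.
#' @param labels Trial labels (two classes).
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param batch_size Minibatch size.
#' @param filters Filters in the two conv blocks.
#' @param split Training fraction (stratified).
#' @param seed Integer seed.
#' @return A `wt_cnn_decoding` list: `val_accuracy`, `train_accuracy`,
#'   `loss_history`, `n_train`, `n_val`, `seed`.
#' @export
decode_calcium_cnn <- function(tensor, labels, epochs = 100, lr = 0.01,
                               momentum = 0.9, batch_size = 32,
                               filters = c(8, 16), split = 0.8, seed = 1) {
  d <- dim(tensor)
  if (d[2] < 8 || d[1] < 40) {
    abort("need at least 8 neurons and 40 trials (architecture underdetermined)")
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("need exactly two label classes")
  H <- d[2]; W <- d[3]; n <- d[1]
  idx_tr <- with_seed(substream_seed(seed, "split"), {
    sort(unlist(lapply(levels(labels), function(lv) {
      i <- which(labels == lv)
      sample(i, round(split * length(i)))
    })))
  })
  idx_va <- setdiff(seq_len(n), idx_tr)
  # standardize with training statistics only
  mu <- mean(tensor[idx_tr, , ]); sdv <- sd(tensor[idx_tr, , ])
  if (sdv == 0) sdv <- 1
  Xall <- aperm(array((tensor - mu) / sdv, c(n, H, W, 1)), c(2, 3, 1, 4))
  Yall <- t(stats::model.matrix(~ labels - 1))   # 2 x n one-hot
  net <- cnn_init(H, W, filters, 2, substream_seed(seed, "init"))
  vel <- list(c1_W = net$c1$W * 0, c1_b = net$c1$b * 0,
              c1_gamma = net$c1$gamma * 0, c1_beta = net$c1$beta * 0,
              c2_W = net$c2$W * 0, c2_b = net$c2$b * 0,
              c2_gamma = net$c2$gamma * 0, c2_beta = net$c2$beta * 0,
              fc_W = net$fc$W * 0, fc_b = net$fc$b * 0)
  apply_grads <- function(net, vel, g, lr, mom) {
    upd <- function(p, v, gr) {
      v2 <- mom * v - lr * gr
      list(p = p + v2, v = v2)
    }
    map <- list(c("c1", "W", "c1_W"), c("c1", "b", "c1_b"),
                c("c1", "gamma", "c1_gamma"), c("c1", "beta", "c1_beta"),
                c("c2", "W", "c2_W"), c("c2", "b", "c2_b"),
                c("c2", "gamma", "c2_gamma"), c("c2", "beta", "c2_beta"),
                c("fc", "W", "fc_W"), c("fc", "b", "fc_b"))
    for (m in map) {
      r <- upd(net[[m[1]]][[m[2]]], vel[[m[3]]], g[[m[3]]])
      net[[m[1]]][[m[2]]] <- r$p
      vel[[m[3]]] <- r$v
    }
    list(net = net, vel = vel)
  }
  loss_hist <- numeric(epochs)
  order_seed <- substream_seed(seed, "batches")
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seed + ep, sample(idx_tr))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, length(ord))]
      if (length(bi) < 2) next
      Xb <- Xall[, , bi, , drop = FALSE]
      Yb <- Yall[, bi, drop = FALSE]
      fw <- cnn_forward(net, Xb, training = TRUE)
      net$c1$run_mean <- fw$bn1$run_mean; net$c1$run_var <- fw$bn1$run_var
      net$c2$run_mean <- fw$bn2$run_mean; net$c2$run_var <- fw$bn2$run_var
      ep_loss <- ep_loss - mean(log(pmax(colSums(fw$probs * Yb), 1e-12)))
      nb <- nb + 1
      g <- cnn_backward(net, fw, Xb, Yb)
      res <- apply_grads(net, vel, g, lr, momentum)
      net <- res$net; vel <- res$vel
    }
    loss_hist[ep] <- ep_loss / max(nb, 1)
  }
  predict_acc <- function(idx) {
    fw <- cnn_forward(net, Xall[, , idx, , drop = FALSE], training = FALSE)
    mean((apply(fw$probs, 2, which.max) == 2) ==
           (labels[idx] == levels(labels)[2]))
  }
  structure(list(val_accuracy = predict_acc(idx_va),
                 train_accuracy = predict_acc(idx_tr),
                 loss_history = loss_hist,
                 n_train = length(idx_tr), n_val = length(idx_va),
                 seed = seed),
            class = "wt_cnn_decoding")
}
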