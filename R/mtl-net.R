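# Internal engine of the multi-task 1-D CNN.
#
# Activations for a minibatch of B windows of length T are stored as a
# (B*T) x C matrix (time fastest). Convolutions use "same" zero padding and
# are computed as im2col gathers followed by a single GEMM per layer, which
# keeps the whole forward/backward pass inside BLAS. The network is a stack
# of conv(kernel k, stride 1) + ReLU layers, global average pooling over
# time, and two task heads (optionally with ReLU hidden layers): a 3-way
# classification head trained with cross-entropy and a scalar regression
# head trained with MSE on the standardized degree scale, combined as
# CE + lambda * MSE.

net_init <- function(c_in, conv_channels, kernel, n_class,
                     cls_hidden = integer(), reg_hidden = integer()) {
  he <- function(nin, nout) {
    matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  conv <- list()
  cin <- c_in
  for (cout in conv_channels) {
    conv[[length(conv) + 1L]] <- list(W = he(cin * kernel, cout),
                                      b = numeric(cout))
    cin <- cout
  }
  mk_head <- function(widths, n_out) {
    dims <- c(cin, widths, n_out)
    lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = he(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
    })
  }
  list(conv = conv, cls = mk_head(cls_hidden, n_class),
       reg = mk_head(reg_hidden, 1L), kernel = kernel, c_in = c_in)
}

# im2col gather indices for B samples of padded length tpad
conv_indices <- function(b_sz, t_len, kernel) {
  pad <- (kernel - 1L) %/% 2L
  tpad <- t_len + 2L * pad
  base <- rep((seq_len(b_sz) - 1L) * tpad, each = t_len) + seq_len(t_len)
  list(
    core = base + pad,                       # rows holding real samples
    taps = lapply(seq_len(kernel) - 1L, function(j) base + j),
    n_pad = b_sz * tpad
  )
}

conv_forward <- function(x, layer, idx) {
  cin <- ncol(x)
  apad <- matrix(0, idx$n_pad, cin)
  apad[idx$core, ] <- x
  m <- do.call(cbind, lapply(idx$taps, function(rows) apad[rows, ,
                                                           drop = FALSE]))
  z <- m %*% layer$W
  z <- z + rep(layer$b, rep.int(nrow(z), length(layer$b)))
  list(a = pmax(z, 0), z = z, m = m)
}

conv_backward <- function(da, cache, layer, idx, cin) {
  dz <- da * (cache$z > 0)
  dW <- crossprod(cache$m, dz)
  db <- colSums(dz)
  dm <- tcrossprod(dz, layer$W)
  dapad <- matrix(0, idx$n_pad, cin)
  for (j in seq_along(idx$taps)) {
    cols <- ((j - 1L) * cin + 1L):(j * cin)
    rows <- idx$taps[[j]]
    dapad[rows, ] <- dapad[rows, ] + dm[, cols, drop = FALSE]
  }
  list(dx = dapad[idx$core, , drop = FALSE], dW = dW, db = db)
}

dense_forward <- function(x, head) {
  caches <- vector("list", length(head))
  a <- x
  for (i in seq_along(head)) {
    z <- a %*% head[[i]]$W
    z <- z + rep(head[[i]]$b, rep.int(nrow(z), length(head[[i]]$b)))
    caches[[i]] <- list(input = a, z = z)
    a <- if (i < length(head)) pmax(z, 0) else z
  }
  list(out = a, caches = caches)
}

dense_backward <- function(dout, head, caches) {
  grads <- vector("list", length(head))
  da <- dout
  for (i in rev(seq_along(head))) {
    dz <- if (i < length(head)) da * (caches[[i]]$z > 0) else da
    grads[[i]] <- list(dW = crossprod(caches[[i]]$input, dz),
                       db = colSums(dz))
    da <- tcrossprod(dz, head[[i]]$W)
  }
  list(grads = grads, dx = da)
}

# full forward pass; returns logits, regression output, pooled features
net_forward <- function(net, x, b_sz, t_len, keep_cache = FALSE) {
  idx <- conv_indices(b_sz, t_len, net$kernel)
  caches <- vector("list", length(net$conv))
  a <- x
  for (i in seq_along(net$conv)) {
    fw <- conv_forward(a, net$conv[[i]], idx)
    if (keep_cache) caches[[i]] <- list(z = fw$z, m = fw$m, input_cols = ncol(a))
    a <- fw$a
  }
  gap <- rowsum(a, rep(seq_len(b_sz), each = t_len), reorder = FALSE) / t_len
  rownames(gap) <- NULL
  cls <- dense_forward(gap, net$cls)
  reg <- dense_forward(gap, net$reg)
  list(logits = cls$out, reg = drop(reg$out), gap = gap,
       caches = if (keep_cache) list(conv = caches, idx = idx,
                                     cls = cls$caches, reg = reg$caches,
                                     a_last_rows = nrow(a)))
}

net_loss_grads <- function(net, x, y_class, y_deg, lambda, b_sz, t_len,
                           label_smoothing = 0) {
  fw <- net_forward(net, x, b_sz, t_len, keep_cache = TRUE)
  # softmax cross-entropy with optional label smoothing
  lg <- fw$logits - apply(fw$logits, 1, max)
  p <- exp(lg) / rowSums(exp(lg))
  n_class <- ncol(p)
  onehot <- matrix(0, b_sz, n_class)
  onehot[cbind(seq_len(b_sz), y_class)] <- 1
  if (label_smoothing > 0) {
    onehot <- onehot * (1 - label_smoothing) + label_smoothing / n_class
  }
  ce <- -mean(rowSums(onehot * log(pmax(p, 1e-12))))
  mse <- mean((fw$reg - y_deg)^2)
  if (!is.finite(ce) || !is.finite(mse)) {
    stop("non-finite loss (ce = ", ce, ", mse = ", mse, ")", call. = FALSE)
  }
  dlogits <- (p - onehot) / b_sz
  dreg <- matrix(2 * lambda * (fw$reg - y_deg) / b_sz, ncol = 1)

  bc <- dense_backward(dlogits, net$cls, fw$caches$cls)
  br <- dense_backward(dreg, net$reg, fw$caches$reg)
  dgap <- bc$dx + br$dx
  da <- dgap[rep(seq_len(b_sz), each = t_len), , drop = FALSE] / t_len

  idx <- fw$caches$idx
  conv_grads <- vector("list", length(net$conv))
  for (i in rev(seq_along(net$conv))) {
    cb <- conv_backward(da, fw$caches$conv[[i]], net$conv[[i]], idx,
                        cin = fw$caches$conv[[i]]$input_cols)
    conv_grads[[i]] <- list(dW = cb$dW, db = cb$db)
    da <- cb$dx
  }
  list(ce = ce, mse = mse,
       grads = list(conv = conv_grads, cls = bc$grads, reg = br$grads))
}

# flatten / apply utilities so Adam can treat the net as one parameter list
net_params <- function(net) {
  c(lapply(net$conv, `[`, c("W", "b")),
    lapply(net$cls, `[`, c("W", "b")),
    lapply(net$reg, `[`, c("W", "b")))
}

adam_init <- function(net) {
  lapply(net_params(net), function(p) {
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(net, grads, state, lr, t_step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  gl <- c(grads$conv, grads$cls, grads$reg)
  n_conv <- length(net$conv); n_cls <- length(net$cls)
  upd <- function(p, g, s) {
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mW_h <- s$mW / (1 - beta1^t_step); vW_h <- s$vW / (1 - beta2^t_step)
    mb_h <- s$mb / (1 - beta1^t_step); vb_h <- s$vb / (1 - beta2^t_step)
    p$W <- p$W - lr * (mW_h / (sqrt(vW_h) + eps) + weight_decay * p$W)
    p$b <- p$b - lr * mb_h / (sqrt(vb_h) + eps)
    list(p = p, s = s)
  }
  k <- 0L
  for (i in seq_along(net$conv)) {
    k <- k + 1L
    r <- upd(net$conv[[i]], gl[[k]], state[[k]])
    net$conv[[i]] <- r$p; state[[k]] <- r$s
  }
  for (i in seq_along(net$cls)) {
    k <- k + 1L
    r <- upd(net$cls[[i]], gl[[k]], state[[k]])
    net$cls[[i]] <- r$p; state[[k]] <- r$s
  }
  for (i in seq_along(net$reg)) {
    k <- k + 1L
    r <- upd(net$reg[[i]], gl[[k]], state[[k]])
    net$reg[[i]] <- r$p; state[[k]] <- r$s
  }
  list(net = net, state = state)
}

# stack a list of 6 x T matrices into the (N*T) x 6 activation layout
stack_windows <- function(windows_x) {
  n <- length(windows_x)
  t_len <- ncol(windows_x[[1]])
  out <- matrix(0, n * t_len, nrow(windows_x[[1]]))
  for (i in seq_len(n)) {
    out[((i - 1L) * t_len + 1L):(i * t_len), ] <- t(windows_x[[i]])
  }
  out
}

# forward a (possibly large) stacked matrix in chunks; returns logits, reg
# and pooled features
net_predict_mat <- function(net, xmat, n, t_len, chunk = 256L) {
  logits <- NULL; reg <- NULL; gap <- NULL
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    rows <- ((i - 1L) * t_len + 1L):(j * t_len)
    fw <- net_forward(net, xmat[rows, , drop = FALSE], j - i + 1L, t_len)
    logits <- rbind(logits, fw$logits)
    reg <- c(reg, unname(fw$reg))
    gap <- rbind(gap, fw$gap)
    i <- j + 1L
  }
  list(logits = logits, reg = reg, gap = gap)
}
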