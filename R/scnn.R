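#' Configuration of the stacked multi-branch 1-D CNN
#'
#' Each configured input channel (by default the three filtered acceleration
#' axes and the three orientation angles) enters its own convolutional
#' sub-model: conv(32 filters, kernel 16) - batch norm - ReLU - maxpool(2),
#' then conv(16 filters, kernel 16) - batch norm - ReLU - maxpool(2). The
#' flattened sub-model outputs are concatenated, passed through dropout
#' (p = 0.25) and a softmax layer. Training uses Adam (learning rate 0.001),
#' batch size 32, categorical cross-entropy, at most 500 epochs, and stops
#' early when validation accuracy has not improved for 100 epochs (best
#' weights are restored).
#'
#' @param channels Channel names drawn from the intermediate feature columns.
#' @param branch_mode `"single"` (one branch per channel, the strict reading
#'   of "channels taken separately"), `"grouped"` (one acceleration branch and
#'   one angle branch) or `"stacked"` (all channels in one branch — the
#'   traditional-CNN baseline).
#' @param conv1_filters,conv2_filters,kernel,pool Convolution stack shape.
#' @param dropout Dropout probability on the concatenated features.
#' @param lr,batch_size,epochs,patience Optimiser settings.
#' @param val_frac Fraction of training segments carved off (stratified,
#'   seeded) as the validation split monitored for early stopping.
#' @param input_len Model input length in samples; segments are
#'   edge-padded/truncated to this length (default 60, the evaluation window).
#' @param seed Seed for initialisation, the validation split, shuffling and
#'   dropout.
#' @return An object of class `scnn_config`.
#' @export
scnn_config <- function(channels = c("ax", "ay", "az", "angle_x", "angle_y", "angle_z"),
                        branch_mode = c("single", "grouped", "stacked"),
                        conv1_filters = 32, conv2_filters = 16, kernel = 16,
                        pool = 2, dropout = 0.25, lr = 0.001, batch_size = 32,
                        epochs = 500, patience = 100, val_frac = 0.2,
                        input_len = 60, seed = 1) {
  branch_mode <- match.arg(branch_mode)
  check(dropout >= 0 && dropout < 1, "scnn_config: dropout must be in [0, 1)")
  check(pool == 2, "scnn_config: only pool size 2 is supported")
  branches <- switch(branch_mode,
    single = as.list(channels),
    grouped = {
      ang <- grepl("^angle", channels)
      Filter(length, list(channels[!ang], channels[ang]))
    },
    stacked = list(channels))
  structure(list(channels = channels, branch_mode = branch_mode, branches = branches,
                 conv1_filters = conv1_filters, conv2_filters = conv2_filters,
                 kernel = kernel, pool = pool, dropout = dropout, lr = lr,
                 batch_size = batch_size, epochs = epochs, patience = patience,
                 val_frac = val_frac, input_len = input_len, seed = as.integer(seed)),
            class = "scnn_config")
}

# minimum input length for two valid conv(kernel)+pool(2) stages
scnn_min_len <- function(kernel) 3 * kernel + 1

scnn_shapes <- function(L, kernel) {
  check(L >= scnn_min_len(kernel),
        "stacked CNN: input length %d too short for two kernel-%d stages; minimum is %d",
        L, kernel, scnn_min_len(kernel))
  P1 <- L - kernel + 1
  L1 <- P1 %/% 2
  P2 <- L1 - kernel + 1
  L2 <- P2 %/% 2
  list(P1 = P1, L1 = L1, P2 = P2, L2 = L2)
}

#' Channel tensors of a segment set for the stacked CNN
#'
#' Filters each segment, computes the intermediate feature matrix, selects the
#' configured channels, and edge-pads or truncates to the model input length.
#'
#' @param set A `har_segmentset`.
#' @param config An [scnn_config()].
#' @param filter Apply median + Butterworth filtering first.
#' @return List with `x` (array segments x input_len x channels), `activity`,
#'   `user`, `uids`.
#' @export
scnn_tensors <- function(set, config = scnn_config(), filter = TRUE) {
  n <- length(set)
  L <- config$input_len
  x <- array(0, c(n, L, length(config$channels)),
             dimnames = list(NULL, NULL, config$channels))
  for (i in seq_len(n)) {
    s <- set$segments[[i]]
    if (filter) s <- filter_segment(s)
    ifs <- compute_ifs(s)
    m <- nrow(ifs)
    idx <- if (m >= L) seq_len(L) else c(seq_len(m), rep(m, L - m))  # edge pad
    x[i, , ] <- ifs[idx, config$channels]
  }
  list(x = x, activity = activities(set), user = users(set), uids = segment_uids(set))
}

# ---- layer primitives -------------------------------------------------------
#
# Internal layout: per-sample feature maps are flat matrices, n x (P * C),
# where column (c - 1) * P + p holds position p of channel c; im2col matrices
# are (n * P) x (k * C) with row (p - 1) * n + i. Both reshapes are plain
# column-major `matrix()` casts, which keeps every step a BLAS call or a
# single vectorized op.

# flat feature-map matrix (n x (L*C)) -> (n*P) x (k*C) sliding windows
im2col_m <- function(Xm, n, L, C, k) {
  P <- L - k + 1
  M <- matrix(0, n * P, k * C)
  coff <- (seq_len(C) - 1) * L
  for (kk in seq_len(k)) {
    cols <- rep(coff, each = P) + kk + 0:(P - 1)
    M[, (seq_len(C) - 1) * k + kk] <- matrix(Xm[, cols], n * P, C)
  }
  M
}

# scatter-add adjoint of im2col_m
col2im_add_m <- function(dM, n, L, C, k) {
  P <- L - k + 1
  dX <- matrix(0, n, L * C)
  coff <- (seq_len(C) - 1) * L
  for (kk in seq_len(k)) {
    cols <- rep(coff, each = P) + kk + 0:(P - 1)
    dX[, cols] <- dX[, cols] + matrix(dM[, (seq_len(C) - 1) * k + kk], n, P * C)
  }
  dX
}

# max-pool of width 2 over positions, on the flat layout (odd position count
# drops the trailing position)
pool_fwd <- function(X, P, C) {
  Pp <- P %/% 2
  oddc <- rep((seq_len(C) - 1) * P, each = Pp) + seq_len(Pp) * 2 - 1
  o1 <- X[, oddc, drop = FALSE]
  o2 <- X[, oddc + 1, drop = FALSE]
  list(out = pmax(o1, o2), mask = o1 >= o2, oddc = oddc, P = P, C = C)
}

pool_bwd <- function(d, cache, n) {
  dX <- matrix(0, n, cache$P * cache$C)
  d1 <- d; d1[!cache$mask] <- 0
  d2 <- d; d2[cache$mask] <- 0
  dX[, cache$oddc] <- d1
  dX[, cache$oddc + 1] <- d2
  dX
}

bn_fwd <- function(Z, g, b, training, run_m, run_v, eps = 1e-5) {
  N <- nrow(Z)
  if (training) {
    mu <- colMeans(Z)
    va <- pmax(colMeans(Z^2) - mu^2, 0)
  } else {
    mu <- run_m; va <- run_v
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- (Z - rep(mu, each = N)) * rep(ivar, each = N)
  list(out = xhat * rep(g, each = N) + rep(b, each = N),
       xhat = xhat, ivar = ivar, mu = mu, va = va)
}

bn_bwd <- function(dY, cache, g) {
  N <- nrow(dY)
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dZ <- (dY - rep(db / N, each = N) - cache$xhat * rep(dg / N, each = N)) *
    rep(g * cache$ivar, each = N)
  list(dZ = dZ, dg = dg, db = db)
}

# precompute the first-layer im2col of every branch once per data set
scnn_prepare <- function(x, config) {
  n <- dim(x)[1]; L <- dim(x)[2]; k <- config$kernel
  M1 <- lapply(config$branches, function(ch) {
    C <- length(ch)
    Xm <- matrix(0, n, L * C)
    for (c in seq_along(ch)) Xm[, (c - 1) * L + seq_len(L)] <- x[, , ch[c]]
    im2col_m(Xm, n, L, C, k)
  })
  list(M1 = M1, n = n, P1 = L - k + 1)
}

# rows of the prepared im2col matrices belonging to a sample subset
scnn_subset <- function(prep, idx) {
  rowsel <- as.vector(outer(idx, (seq_len(prep$P1) - 1) * prep$n, "+"))
  list(M1 = lapply(prep$M1, function(M) M[rowsel, , drop = FALSE]),
       n = length(idx), P1 = prep$P1)
}

# ---- parameter trees --------------------------------------------------------

scnn_init <- function(config, n_classes) {
  k <- config$kernel
  F1 <- config$conv1_filters; F2 <- config$conv2_filters
  sh <- scnn_shapes(config$input_len, k)
  branches <- lapply(config$branches, function(ch) {
    C <- length(ch)
    list(W1 = matrix(stats::rnorm(k * C * F1, 0, sqrt(2 / (k * C))), k * C, F1),
         b1 = numeric(F1), g1 = rep(1, F1), be1 = numeric(F1),
         W2 = matrix(stats::rnorm(k * F1 * F2, 0, sqrt(2 / (k * F1))), k * F1, F2),
         b2 = numeric(F2), g2 = rep(1, F2), be2 = numeric(F2))
  })
  D <- length(config$branches) * sh$L2 * F2
  list(branches = branches,
       Wd = matrix(stats::rnorm(D * n_classes, 0, sqrt(1 / D)), D, n_classes),
       bd = numeric(n_classes))
}

scnn_run_init <- function(config) {
  lapply(config$branches, function(ch) {
    list(m1 = numeric(config$conv1_filters), v1 = rep(1, config$conv1_filters),
         m2 = numeric(config$conv2_filters), v2 = rep(1, config$conv2_filters))
  })
}

tmap <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- lapply(seq_along(xs[[1]]), function(i) {
      do.call(tmap, c(list(f), lapply(xs, `[[`, i)))
    })
    names(out) <- names(xs[[1]])
    out
  } else {
    do.call(f, xs)
  }
}

# ---- forward / backward -----------------------------------------------------

scnn_forward <- function(params, run, prep, config, training = FALSE,
                         drop_mask = NULL, momentum = 0.9) {
  n <- prep$n
  k <- config$kernel
  sh <- scnn_shapes(config$input_len, k)
  F1 <- config$conv1_filters; F2 <- config$conv2_filters
  caches <- vector("list", length(config$branches))
  flats <- vector("list", length(config$branches))
  for (b in seq_along(config$branches)) {
    pb <- params$branches[[b]]
    rb <- run[[b]]
    M1 <- prep$M1[[b]]
    Z1 <- M1 %*% pb$W1
    Z1 <- Z1 + rep(pb$b1, each = nrow(Z1))
    bn1 <- bn_fwd(Z1, pb$g1, pb$be1, training, rb$m1, rb$v1)
    A1 <- pmax(bn1$out, 0)
    pl1 <- pool_fwd(matrix(A1, n, sh$P1 * F1), sh$P1, F1)
    M2 <- im2col_m(pl1$out, n, sh$L1, F1, k)
    Z2 <- M2 %*% pb$W2
    Z2 <- Z2 + rep(pb$b2, each = nrow(Z2))
    bn2 <- bn_fwd(Z2, pb$g2, pb$be2, training, rb$m2, rb$v2)
    A2 <- pmax(bn2$out, 0)
    pl2 <- pool_fwd(matrix(A2, n, sh$P2 * F2), sh$P2, F2)
    flats[[b]] <- pl2$out
    if (training) {
      run[[b]]$m1 <- momentum * rb$m1 + (1 - momentum) * bn1$mu
      run[[b]]$v1 <- momentum * rb$v1 + (1 - momentum) * bn1$va
      run[[b]]$m2 <- momentum * rb$m2 + (1 - momentum) * bn2$mu
      run[[b]]$v2 <- momentum * rb$v2 + (1 - momentum) * bn2$va
    }
    caches[[b]] <- list(M1 = M1, bn1 = bn1, pl1 = pl1, M2 = M2, bn2 = bn2,
                        pl2 = pl2)
  }
  H <- do.call(cbind, flats)
  if (training && config$dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(stats::runif(length(H)) >= config$dropout, nrow(H), ncol(H))
    }
    Hd <- H * drop_mask / (1 - config$dropout)
  } else {
    drop_mask <- NULL
    Hd <- H
  }
  S <- Hd %*% params$Wd
  S <- S + rep(params$bd, each = n)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  probs <- E / rowSums(E)
  list(probs = probs, run = run,
       cache = list(branch = caches, H = H, Hd = Hd, drop_mask = drop_mask, n = n))
}

scnn_backward <- function(params, fw, Y, config) {
  n <- fw$cache$n
  k <- config$kernel
  sh <- scnn_shapes(config$input_len, k)
  F1 <- config$conv1_filters; F2 <- config$conv2_filters
  dS <- (fw$probs - Y) / n
  grads <- list(branches = vector("list", length(config$branches)),
                Wd = crossprod(fw$cache$Hd, dS), bd = colSums(dS))
  dH <- tcrossprod(dS, params$Wd)
  if (!is.null(fw$cache$drop_mask)) {
    dH <- dH * fw$cache$drop_mask / (1 - config$dropout)
  }
  off <- 0L
  for (b in seq_along(config$branches)) {
    ca <- fw$cache$branch[[b]]
    pb <- params$branches[[b]]
    w <- sh$L2 * F2
    dflat <- dH[, (off + 1):(off + w), drop = FALSE]
    off <- off + w
    dA2 <- matrix(pool_bwd(dflat, ca$pl2, n), n * sh$P2, F2)
    dBn2 <- dA2 * (ca$bn2$out > 0)
    bb2 <- bn_bwd(dBn2, ca$bn2, pb$g2)
    dM2 <- tcrossprod(bb2$dZ, pb$W2)
    dpl1 <- col2im_add_m(dM2, n, sh$L1, F1, k)
    dA1 <- matrix(pool_bwd(dpl1, ca$pl1, n), n * sh$P1, F1)
    dBn1 <- dA1 * (ca$bn1$out > 0)
    bb1 <- bn_bwd(dBn1, ca$bn1, pb$g1)
    grads$branches[[b]] <- list(
      W1 = crossprod(ca$M1, bb1$dZ), b1 = colSums(bb1$dZ),
      g1 = bb1$dg, be1 = bb1$db,
      W2 = crossprod(ca$M2, bb2$dZ), b2 = colSums(bb2$dZ),
      g2 = bb2$dg, be2 = bb2$db)
  }
  grads
}

# ---- training ---------------------------------------------------------------

#' Fit the stacked CNN
#'
#' @param x A `har_segmentset`, or a channel tensor list from [scnn_tensors()].
#' @param y Class labels; for a segment set, `NULL` selects labels via
#'   `target`.
#' @param config An [scnn_config()].
#' @param target `"activity"` or `"user"` (used when `x` is a segment set and
#'   `y` is `NULL`).
#' @param filter Filter segments before channel extraction.
#' @return An object of class `scnn` with `predict` support and a per-epoch
#'   training `history`.
#' @export
scnn_fit <- function(x, y = NULL, config = scnn_config(),
                     target = c("activity", "user"), filter = TRUE) {
  target <- match.arg(target)
  if (inherits(x, "har_segmentset")) {
    tens <- scnn_tensors(x, config, filter = filter)
    if (is.null(y)) y <- if (target == "activity") tens$activity else tens$user
    x <- tens$x
  } else if (is.list(x) && !is.null(x$x)) {
    x <- x$x
  }
  y <- factor(y)
  n <- dim(x)[1]
  check(n == length(y), "scnn_fit: inputs and labels disagree in length")
  check(nlevels(y) >= 2, "scnn_fit: need at least 2 classes")
  classes <- levels(y)
  scnn_shapes(config$input_len, config$kernel)  # validates the input length
  prep <- scnn_prepare(x, config)

  with_seed(config$seed, {
    params <- scnn_init(config, length(classes))
    run <- scnn_run_init(config)
    # stratified validation carve-out for early stopping
    val_idx <- integer(0)
    if (config$val_frac > 0 && n >= 5) {
      for (cl in classes) {
        members <- which(y == cl)
        nv <- floor(length(members) * config$val_frac)
        if (nv >= 1) val_idx <- c(val_idx, sample(members, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    has_val <- length(val_idx) > 0
    Y <- diag(length(classes))[as.integer(y), , drop = FALSE]

    adam_m <- tmap(function(p) p * 0, params)
    adam_v <- tmap(function(p) p * 0, params)
    tstep <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

    best <- list(acc = -Inf, params = params, run = run, epoch = 0)
    hist <- list()
    stale <- 0
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bidx in batches) {
        fw <- scnn_forward(params, run, scnn_subset(prep, bidx), config,
                           training = TRUE)
        run <- fw$run
        Yb <- Y[bidx, , drop = FALSE]
        ep_loss <- ep_loss - sum(Yb * log(pmax(fw$probs, 1e-12))) / length(bidx)
        if (!all(is.finite(fw$probs))) stop("scnn_fit: non-finite loss", call. = FALSE)
        g <- scnn_backward(params, fw, Yb, config)
        tstep <- tstep + 1
        adam_m <- tmap(function(m, gr) b1 * m + (1 - b1) * gr, adam_m, g)
        adam_v <- tmap(function(v, gr) b2 * v + (1 - b2) * gr^2, adam_v, g)
        corr <- config$lr * sqrt(1 - b2^tstep) / (1 - b1^tstep)
        params <- tmap(function(p, m, v) p - corr * m / (sqrt(v) + eps),
                       params, adam_m, adam_v)
      }
      mon_idx <- if (has_val) val_idx else tr_idx
      fw_mon <- scnn_forward(params, run, scnn_subset(prep, mon_idx), config,
                             training = FALSE)
      acc <- mean(max.col(fw_mon$probs, ties.method = "first") ==
                  as.integer(y[mon_idx]))
      hist[[epoch]] <- c(epoch = epoch, loss = ep_loss / length(batches), val_acc = acc)
      if (acc > best$acc) {
        best <- list(acc = acc, params = params, run = run, epoch = epoch)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= config$patience) break
      }
    }
    structure(list(params = best$params, run = best$run, classes = classes,
                   config = config, filter = filter,
                   best_val_acc = best$acc, best_epoch = best$epoch,
                   history = as.data.frame(do.call(rbind, hist))),
              class = "scnn")
  })
}

#' @export
print.scnn <- function(x, ...) {
  cat(sprintf("<scnn> %d branch(es) [%s], classes: %s\n",
              length(x$config$branches), x$config$branch_mode,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epoch(s); best monitored accuracy %.3f at epoch %d\n",
              nrow(x$history), x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' @param object A fitted `scnn`.
#' @param newdata A `har_segmentset`, [scnn_tensors()] list, or channel array.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @rdname scnn_fit
#' @export
predict.scnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "har_segmentset")) {
    newdata <- scnn_tensors(newdata, object$config, filter = object$filter)$x
  } else if (is.list(newdata) && !is.null(newdata$x)) {
    newdata <- newdata$x
  }
  fw <- scnn_forward(object$params, object$run,
                     scnn_prepare(newdata, object$config), object$config,
                     training = FALSE)
  pr <- fw$probs
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  factor(object$classes[max.col(pr, ties.method = "first")], levels = object$classes)
}
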