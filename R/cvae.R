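#' Distance-matrix dataset for latent-space state discrimination
#'
#' Builds, for every frame of two trajectories, the pairwise distance
#' matrix over a fixed set of site atoms (for the default synthetic
#' hexamer: the 36 pseudo-histidine beads coordinating the metal sites),
#' attaches the state labels, and draws a seeded train/validation split.
#'
#' @param traj_a,traj_b trajectories of the two states.
#' @param selection atom indices of the site atoms in `traj_a`.
#' @param selection_b atom indices in `traj_b` (default: same as
#'   `selection`); must resolve to the same number of atoms.
#' @param labels length-2 character vector of state names.
#' @param split train fraction (default 0.8).
#' @param seed split seed.
#' @return object of class `hxd_distance_dataset`: `matrices`
#'   (frames x d x d array, symmetric, zero diagonal), `labels` (factor),
#'   `split` (list of `train` and `val` frame indices), `seed`.
#' @export
build_dataset <- function(traj_a, traj_b, selection, selection_b = selection,
                          labels = c("a", "b"), split = 0.8, seed = 1L) {
  if (length(selection) != length(selection_b))
    stop("site selections resolve to different atom counts")
  d <- length(selection)
  one <- function(traj, sel) {
    nf <- n_frames(traj)
    out <- array(NA_real_, dim = c(nf, d, d))
    for (t in seq_len(nf))
      out[t, , ] <- as.matrix(stats::dist(
        frame_coords(traj, t)[sel, , drop = FALSE]))
    out
  }
  ma <- one(traj_a, selection); mb <- one(traj_b, selection_b)
  mats <- array(NA_real_, dim = c(dim(ma)[1] + dim(mb)[1], d, d))
  mats[seq_len(dim(ma)[1]), , ] <- ma
  mats[dim(ma)[1] + seq_len(dim(mb)[1]), , ] <- mb
  lab <- factor(rep(labels, c(dim(ma)[1], dim(mb)[1])), levels = labels)
  n <- dim(mats)[1]
  tr <- with_seed(seed, sort(sample.int(n, round(split * n))))
  structure(list(matrices = mats, labels = lab,
                 split = list(train = tr, val = setdiff(seq_len(n), tr)),
                 seed = seed),
            class = "hxd_distance_dataset")
}

#' @export
print.hxd_distance_dataset <- function(x, ...) {
  cat(sprintf("<hxd_distance_dataset> %d frames of %d x %d matrices (%s)\n",
              dim(x$matrices)[1], dim(x$matrices)[2], dim(x$matrices)[3],
              paste(sprintf("%s: %d", levels(x$labels),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

## ---- network internals ---------------------------------------------------
## The network is implemented directly in vectorised base R: an im2col
## convolutional encoder (3 stride-2 layers), a dense bottleneck with
## Gaussian latent (reparameterisation trick), a dense decoder, and Adam.

.conv_plan <- function(H, W, C, k = 3L, stride = 2L, pad = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  oh <- (Hp - k) %/% stride + 1L
  ow <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  topl_h <- (oi - 1L) * stride
  topl_w <- (oj - 1L) * stride
  kh <- rep(rep(seq_len(k), times = k), times = C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  I <- outer(seq_len(k * k * C), seq_len(oh * ow), function(a, p) {
    (topl_h[p] + kh[a]) + (topl_w[p] + kw[a] - 1L) * Hp +
      (kc[a] - 1L) * Hp * Wp
  })
  ph <- rep(seq_len(H) + pad, times = W)
  pw <- rep(seq_len(W) + pad, each = H)
  base <- ph + (pw - 1L) * Hp
  pad_idx <- as.vector(outer(base, (seq_len(C) - 1L) * Hp * Wp, `+`))
  list(I = I, pad_idx = pad_idx, Hp = Hp, Wp = Wp, oh = oh, ow = ow,
       Cin = C, k2c = k * k * C)
}

.conv_fwd <- function(X, Wm, b, plan) {
  B <- ncol(X)
  Xp <- matrix(0, plan$Hp * plan$Wp * plan$Cin, B)
  Xp[plan$pad_idx, ] <- X
  M <- matrix(Xp[as.vector(plan$I), , drop = FALSE], nrow = plan$k2c)
  Y <- Wm %*% M + b
  o2 <- plan$oh * plan$ow
  out <- aperm(array(Y, c(nrow(Wm), o2, B)), c(2, 1, 3))
  dim(out) <- c(o2 * nrow(Wm), B)
  list(out = out, M = M)
}

.conv_bwd <- function(dOut, M, Wm, plan) {
  B <- ncol(dOut)
  o2 <- plan$oh * plan$ow; Cout <- nrow(Wm)
  dY <- aperm(array(dOut, c(o2, Cout, B)), c(2, 1, 3))
  dim(dY) <- c(Cout, o2 * B)
  dW <- tcrossprod(dY, M)
  db <- rowSums(dY)
  dM <- crossprod(Wm, dY)
  dPm <- matrix(dM, nrow = plan$k2c * o2)
  rs <- rowsum(dPm, group = as.vector(plan$I))
  dXp <- matrix(0, plan$Hp * plan$Wp * plan$Cin, B)
  dXp[as.integer(rownames(rs)), ] <- rs
  list(dX = dXp[plan$pad_idx, , drop = FALSE], dW = dW, db = db)
}

.init_cvae_params <- function(d_in, latent_dim, filters, dense_units) {
  plans <- list()
  H <- d_in; C <- 1L
  for (i in seq_along(filters)) {
    plans[[i]] <- .conv_plan(H, H, C)
    H <- plans[[i]]$oh; C <- filters[i]
  }
  flat <- H * H * C
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)),
                                nr, nc)
  p <- list()
  Cin <- 1L
  for (i in seq_along(filters)) {
    p[[paste0("cW", i)]] <- he(filters[i], 9L * Cin)
    p[[paste0("cb", i)]] <- numeric(filters[i])
    Cin <- filters[i]
  }
  p$dW <- he(dense_units, flat);       p$db <- numeric(dense_units)
  p$muW <- he(latent_dim, dense_units); p$mub <- numeric(latent_dim)
  p$lvW <- matrix(0, latent_dim, dense_units); p$lvb <- numeric(latent_dim)
  p$g1W <- he(dense_units, latent_dim); p$g1b <- numeric(dense_units)
  p$g2W <- he(4L * dense_units, dense_units); p$g2b <- numeric(4L * dense_units)
  p$g3W <- he(d_in^2, 4L * dense_units);      p$g3b <- numeric(d_in^2)
  list(params = p, plans = plans, flat = flat)
}

.cvae_fwd <- function(p, plans, X, eps = NULL) {
  ca <- list(); h <- X
  for (i in seq_along(plans)) {
    cf <- .conv_fwd(h, p[[paste0("cW", i)]], p[[paste0("cb", i)]], plans[[i]])
    a <- pmax(cf$out, 0)
    ca[[i]] <- list(M = cf$M, pre = cf$out, act = a)
    h <- a
  }
  d_pre <- p$dW %*% h + p$db
  d_act <- pmax(d_pre, 0)
  mu <- p$muW %*% d_act + p$mub
  lv <- p$lvW %*% d_act + p$lvb
  lv <- pmin(pmax(lv, -10), 10)  # numerical guard
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  g1_pre <- p$g1W %*% z + p$g1b;  g1 <- pmax(g1_pre, 0)
  g2_pre <- p$g2W %*% g1 + p$g2b; g2 <- pmax(g2_pre, 0)
  xhat <- p$g3W %*% g2 + p$g3b
  list(conv = ca, conv_out = h, d_pre = d_pre, d_act = d_act,
       mu = mu, lv = lv, z = z, eps = eps,
       g1_pre = g1_pre, g1 = g1, g2_pre = g2_pre, g2 = g2, xhat = xhat)
}

.cvae_loss <- function(fw, X, beta) {
  recon <- 0.5 * colSums((fw$xhat - X)^2)
  kl <- -0.5 * colSums(1 + fw$lv - fw$mu^2 - exp(fw$lv))
  mean(recon + beta * kl)
}

.cvae_bwd <- function(p, plans, fw, X, beta) {
  B <- ncol(X)
  g <- list()
  dxhat <- (fw$xhat - X) / B
  g$g3W <- tcrossprod(dxhat, fw$g2); g$g3b <- rowSums(dxhat)
  dg2 <- crossprod(p$g3W, dxhat) * (fw$g2_pre > 0)
  g$g2W <- tcrossprod(dg2, fw$g1); g$g2b <- rowSums(dg2)
  dg1 <- crossprod(p$g2W, dg2) * (fw$g1_pre > 0)
  g$g1W <- tcrossprod(dg1, fw$z); g$g1b <- rowSums(dg1)
  dz <- crossprod(p$g1W, dg1)
  dmu <- dz + beta * fw$mu / B
  dlv <- beta * 0.5 * (exp(fw$lv) - 1) / B
  if (!is.null(fw$eps)) dlv <- dlv + dz * fw$eps * 0.5 * exp(0.5 * fw$lv)
  g$muW <- tcrossprod(dmu, fw$d_act); g$mub <- rowSums(dmu)
  g$lvW <- tcrossprod(dlv, fw$d_act); g$lvb <- rowSums(dlv)
  dd <- (crossprod(p$muW, dmu) + crossprod(p$lvW, dlv)) * (fw$d_pre > 0)
  g$dW <- tcrossprod(dd, fw$conv_out); g$db <- rowSums(dd)
  dh <- crossprod(p$dW, dd)
  for (i in rev(seq_along(plans))) {
    dh <- dh * (fw$conv[[i]]$pre > 0)
    cb <- .conv_bwd(dh, fw$conv[[i]]$M, p[[paste0("cW", i)]], plans[[i]])
    g[[paste0("cW", i)]] <- cb$dW
    g[[paste0("cb", i)]] <- cb$db
    dh <- cb$dX
  }
  g
}

.dataset_X <- function(d) {
  n <- dim(d$matrices)[1]; dd <- dim(d$matrices)[2]
  X <- matrix(NA_real_, dd * dd, n)
  for (t in seq_len(n)) X[, t] <- as.vector(d$matrices[t, , ])
  X
}

#' Train the convolutional variational autoencoder
#'
#' An hourglass network: three stride-2 convolutional layers compress the
#' (min-max normalized) distance matrix, a dense layer feeds the Gaussian
#' latent mean/log-variance, and a mirrored dense decoder reconstructs the
#' input. The objective is the reconstruction error plus the
#' Kullback-Leibler divergence of the latent distribution from the unit
#' Gaussian prior, which keeps the latent space normally populated.
#' Optimized by Adam on minibatches; deterministic under a fixed seed.
#'
#' @param d an `hxd_distance_dataset`.
#' @param latent_dim latent dimensionality (default 7).
#' @param epochs training epochs (default 100); `epochs = 0` returns the
#'   untrained (randomly initialized) model.
#' @param batch_size minibatch size (default 32, kept low on purpose).
#' @param lr Adam learning rate.
#' @param beta weight of the divergence term.
#' @param filters convolutional filter counts.
#' @param dense_units width of the dense bottleneck layer.
#' @param seed RNG seed for initialization, shuffling and sampling.
#' @param verbose print the loss every 10 epochs.
#' @return object of class `hxd_cvae`: parameters, architecture plans,
#'   normalization constants, `loss` (per-epoch `data.frame` with `epoch`,
#'   `train`, `val`), `latent_dim`, `seed`.
#' @export
train_cvae <- function(d, latent_dim = 7L, epochs = 100L, batch_size = 32L,
                       lr = 1e-3, beta = 1.0, filters = c(8L, 16L, 32L),
                       dense_units = 64L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(d, "hxd_distance_dataset"))
  d_in <- dim(d$matrices)[2]
  X <- .dataset_X(d)
  mn <- min(X); mx <- max(X)
  Xn <- (X - mn) / max(mx - mn, 1e-12)
  tr <- d$split$train; va <- d$split$val
  if (epochs > 0L && length(tr) < 2L * batch_size)
    stop("need at least 2*batch_size training frames")
  model <- with_seed(seed, {
    ini <- .init_cvae_params(d_in, latent_dim, filters, dense_units)
    p <- ini$params
    mstate <- lapply(p, function(w) w * 0)
    vstate <- lapply(p, function(w) w * 0)
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       val = numeric(0))
    step <- 0L
    for (ep in seq_len(epochs)) {
      idx <- sample(tr)
      nb <- floor(length(idx) / batch_size)
      tl <- 0
      for (b in seq_len(nb)) {
        cols <- idx[(b - 1L) * batch_size + seq_len(batch_size)]
        Xb <- Xn[, cols, drop = FALSE]
        eps <- matrix(stats::rnorm(latent_dim * batch_size),
                      latent_dim, batch_size)
        fw <- .cvae_fwd(p, ini$plans, Xb, eps)
        loss <- .cvae_loss(fw, Xb, beta)
        if (!is.finite(loss))
          stop("training diverged to a non-finite loss at epoch ", ep)
        tl <- tl + loss
        gr <- .cvae_bwd(p, ini$plans, fw, Xb, beta)
        step <- step + 1L
        for (nm in names(p)) {
          mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * gr[[nm]]
          vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * gr[[nm]]^2
          mhat <- mstate[[nm]] / (1 - 0.9^step)
          vhat <- vstate[[nm]] / (1 - 0.999^step)
          p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      fwv <- .cvae_fwd(p, ini$plans, Xn[, va, drop = FALSE])
      vl <- .cvae_loss(fwv, Xn[, va, drop = FALSE], beta)
      hist <- rbind(hist, data.frame(epoch = ep, train = tl / max(nb, 1L),
                                     val = vl))
      if (verbose && ep %% 10L == 0L)
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        tl / max(nb, 1L), vl))
    }
    list(params = p, plans = ini$plans, hist = hist)
  })
  structure(list(params = model$params, plans = model$plans,
                 latent_dim = as.integer(latent_dim),
                 filters = filters, dense_units = dense_units,
                 norm = list(min = mn, max = mx), beta = beta,
                 loss = model$hist, d_in = d_in, seed = as.integer(seed),
                 epochs = as.integer(epochs)),
            class = "hxd_cvae")
}

#' @export
print.hxd_cvae <- function(x, ...) {
  cat(sprintf("<hxd_cvae> latent dim %d, %d epoch(s)", x$latent_dim, x$epochs))
  if (!is.null(x$loss) && nrow(x$loss))
    cat(sprintf("; final val loss %.4f", x$loss$val[nrow(x$loss)]))
  cat("\n")
  invisible(x)
}

.cvae_encode <- function(m, d) {
  X <- .dataset_X(d)
  Xn <- (X - m$norm$min) / max(m$norm$max - m$norm$min, 1e-12)
  fw <- .cvae_fwd(m$params, m$plans, Xn)
  list(mu = fw$mu, xhat = fw$xhat, Xn = Xn)
}

#' Scan latent dimensionalities
#'
#' Trains one model per latent dimension under identical seeds and epochs
#' and tabulates the final validation losses; the best dimension is the
#' argmin.
#'
#' @param d an `hxd_distance_dataset`.
#' @param dims integer vector of latent dimensions (duplicates are dropped
#'   with a warning).
#' @param epochs,seed,... passed to [train_cvae()].
#' @return `data.frame` with `latent_dim` and `val_loss`; attribute
#'   `"best"` holds the argmin dimension.
#' @export
scan_latent_dims <- function(d, dims = 3:10, epochs = 100L, seed = 1L, ...) {
  if (anyDuplicated(dims)) {
    warning("duplicate latent dimensions dropped")
    dims <- unique(dims)
  }
  losses <- vapply(dims, function(k) {
    m <- train_cvae(d, latent_dim = k, epochs = epochs, seed = seed, ...)
    m$loss$val[nrow(m$loss)]
  }, numeric(1))
  out <- data.frame(latent_dim = as.integer(dims), val_loss = losses)
  attr(out, "best") <- out$latent_dim[which.min(out$val_loss)]
  out
}

#' Embed frames into the learnt latent space
#'
#' Encodes every frame to its latent mean and attaches a low-dimensional
#' projection for visualization: t-SNE (default, with fixed seed and
#' stated perplexity) or a deterministic linear (principal component)
#' projection.
#'
#' @param m a trained `hxd_cvae`.
#' @param d an `hxd_distance_dataset` (same matrix size as training).
#' @param projection `"tsne"` or `"linear"`.
#' @param dims projection dimensionality, 2 or 3.
#' @param perplexity,iter t-SNE controls.
#' @param seed t-SNE seed.
#' @return object of class `hxd_embedding`: `data` (`data.frame` with
#'   `frame`, `label`, `z1..zk` latent means and `p1..pd` projection),
#'   `projection`, `latent` (frames x latent matrix).
#' @export
embed_frames <- function(m, d, projection = c("tsne", "linear"), dims = 2L,
                         perplexity = 30, iter = 300L, seed = 1L) {
  projection <- match.arg(projection)
  if (dim(d$matrices)[2] != m$d_in) stop("matrix size does not match model")
  enc <- .cvae_encode(m, d)
  Z <- t(enc$mu)
  n <- nrow(Z)
  if (n == 1L) {
    warning("single frame: projection skipped")
    proj <- matrix(0, 1L, dims)
  } else if (projection == "linear") {
    pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
    proj <- pc$x[, seq_len(min(dims, ncol(pc$x))), drop = FALSE]
  } else {
    proj <- tsne_embed(Z, dims = dims,
                       perplexity = min(perplexity, (n - 1) / 3),
                       iter = iter, seed = seed)
  }
  df <- data.frame(frame = seq_len(n), label = d$labels)
  for (k in seq_len(ncol(Z))) df[[paste0("z", k)]] <- Z[, k]
  for (k in seq_len(ncol(proj))) df[[paste0("p", k)]] <- proj[, k]
  structure(list(data = df, projection = projection, latent = Z,
                 labels = d$labels),
            class = "hxd_embedding")
}

#' @export
print.hxd_embedding <- function(x, ...) {
  cat(sprintf("<hxd_embedding> %d frames, latent dim %d, %s projection\n",
              nrow(x$latent), ncol(x$latent), x$projection))
  invisible(x)
}

#' Silhouette of the state labels in latent space
#'
#' Mean silhouette width of the (true or shuffled) labels over the latent
#' coordinates; near 1 for cleanly separated states, near 0 for none.
#'
#' @param emb an `hxd_embedding` (or a plain matrix of coordinates).
#' @param labels factor of state labels (taken from `emb` if missing).
#' @return numeric mean silhouette width.
#' @export
latent_silhouette <- function(emb, labels = NULL) {
  Z <- if (inherits(emb, "hxd_embedding")) emb$latent else emb
  if (is.null(labels)) labels <- emb$labels
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(Z))
  mean(sil[, "sil_width"])
}

#' Reconstruction quality report
#'
#' Per-frame mean absolute error between the original and reconstructed
#' (de-normalized) distance matrices, plus the paired matrices for the
#' requested frames.
#'
#' @param m a trained `hxd_cvae`.
#' @param d an `hxd_distance_dataset`.
#' @param keep_frames frames whose original/reconstructed matrix pair is
#'   returned (default: first frame of each label).
#' @return object of class `hxd_recon_report`: `per_frame`
#'   (`data.frame` with `frame`, `label`, `mae` in Angstrom), `pairs`
#'   (named list of `original`/`reconstructed` matrices), `mean_mae`.
#' @export
reconstruction_report <- function(m, d, keep_frames = NULL) {
  enc <- .cvae_encode(m, d)
  scale <- max(m$norm$max - m$norm$min, 1e-12)
  err <- colMeans(abs(enc$xhat - enc$Xn)) * scale
  n <- length(err)
  if (is.null(keep_frames))
    keep_frames <- vapply(levels(d$labels), function(l)
      which(d$labels == l)[1], integer(1))
  dd <- dim(d$matrices)[2]
  pairs <- lapply(keep_frames, function(f) {
    rec <- matrix(enc$xhat[, f] * scale + m$norm$min, dd, dd)
    list(original = d$matrices[f, , ], reconstructed = rec)
  })
  names(pairs) <- paste0("frame_", keep_frames)
  structure(list(per_frame = data.frame(frame = seq_len(n),
                                        label = d$labels, mae = err),
                 pairs = pairs, mean_mae = mean(err)),
            class = "hxd_recon_report")
}

#' @export
print.hxd_recon_report <- function(x, ...) {
  cat(sprintf("<hxd_recon_report> mean reconstruction MAE %.3f A over %d frames\n",
              x$mean_mae, nrow(x$per_frame)))
  invisible(x)
}
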