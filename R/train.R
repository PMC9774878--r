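#' Training configuration
#'
#' Hyperparameters shared by CAE pretraining and joint end-to-end training.
#' The defaults follow the study conditions of the phantom experiments:
#' Adam with learning rate 0.001 and batch size 58; joint training runs
#' until fewer than 0.1% of hard assignments change after an epoch, or
#' until `max_joint_epochs` (50; 20 for the 3D architecture, which is also
#' pretrained for a fixed 40 epochs instead of early stopping).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param gamma weight of the clustering loss in the joint objective
#'   `L = L_rec + gamma * L_clu`.
#' @param pretrain_patience early-stopping patience (epochs without
#'   validation improvement) for pretraining.
#' @param pretrain_min_delta relative validation-loss improvement below
#'   which an epoch counts as stalled (0.01 = 1%); on the near-noiseless
#'   phantoms the loss decays over many orders of magnitude, so an absolute
#'   threshold would never trigger.
#' @param max_pretrain_epochs cap on pretraining epochs (`NULL`: 50 for the
#'   2D architectures; fixed 40, no early stopping, for `generic3d`).
#' @param max_joint_epochs cap on joint epochs (`NULL`: 50, or 20 for
#'   `generic3d`).
#' @param label_change_tol joint training stops when the fraction of
#'   changed hard assignments after an epoch drops below this (default
#'   0.001, i.e. 0.1%).
#' @param target_update_interval epochs between refreshes of the target
#'   distribution.
#' @param validation_fraction fraction of patches held out for the
#'   early-stopping criterion.
#' @param seed master seed for batching and validation split.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 58L,
                         gamma = 0.1, pretrain_patience = 10L,
                         pretrain_min_delta = 0.001,
                         max_pretrain_epochs = NULL, max_joint_epochs = NULL,
                         label_change_tol = 0.001,
                         target_update_interval = 1L,
                         validation_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, gamma >= 0,
            pretrain_patience >= 1, pretrain_min_delta >= 0,
            label_change_tol > 0, label_change_tol < 1,
            target_update_interval >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), gamma = gamma,
                 pretrain_patience = as.integer(pretrain_patience),
                 pretrain_min_delta = pretrain_min_delta,
                 max_pretrain_epochs = max_pretrain_epochs,
                 max_joint_epochs = max_joint_epochs,
                 label_change_tol = label_change_tol,
                 target_update_interval = as.integer(target_update_interval),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

.batches <- function(idx, size) {
  if (length(idx) == 0L) return(list())
  split(idx, ceiling(seq_along(idx) / size))
}

#' Pretrain a CAE on reconstruction alone
#'
#' Minimises the mean squared reconstruction error with Adam.  A fraction
#' of the patches is held out; for the 2D architectures training stops when
#' the held-out loss has not improved for `pretrain_patience` epochs (the
#' best-scoring parameters are kept), while the 3D architecture trains for
#' a fixed 40 epochs.  If the loss diverges (non-finite), training restarts
#' from a fresh initialisation, up to 3 times.
#'
#' Training can fail to leave its initial saddle region, in which case the
#' validation loss never shows the expected exponential decay; such runs
#' (best validation loss not at least an order of magnitude below the
#' first epoch's) are reinitialised from a fresh seed like divergent ones,
#' and the best attempt is kept.
#'
#' @param cae an [build_cae()] model.
#' @param ps a normalised [extract_patches()] patch set (or patch matrix).
#' @param tc a [train_config()].
#' @param verbose print per-epoch losses.
#' @param decay_factor a finished attempt counts as healthy when its best
#'   validation loss is below `decay_factor` times the first epoch's;
#'   set to `Inf` to disable decay-failure restarts.
#' @return list with `cae` (trained model, `pretrained = TRUE`) and
#'   `history` (data frame of train/validation loss per epoch plus the
#'   recorded hyperparameters).
#' @export
pretrain_cae <- function(cae, ps, tc = train_config(), verbose = FALSE,
                         decay_factor = 0.1) {
  stopifnot(inherits(cae, "hsi_cae"), inherits(tc, "train_config"))
  X <- .as_patch_matrix(ps, cae$cfg)
  n <- ncol(X)
  fixed_epochs <- cae$cfg$arch == "generic3d"
  max_ep <- tc$max_pretrain_epochs %||% (if (fixed_epochs) 40L else 50L)
  .local_seed(substream_seed(tc$seed, "pretrain"))
  n_val <- max(1L, round(tc$validation_fraction * n))
  val_ix <- sample.int(n, n_val)
  train_ix <- setdiff(seq_len(n), val_ix)
  if (length(train_ix) == 0L) { train_ix <- val_ix }  # tiny-data fallback
  Xval <- X[, val_ix, drop = FALSE]

  best_attempt <- NULL
  for (restart in 0:3) {
    if (restart > 0) {
      cfg <- cae$cfg
      cfg$seed <- substream_seed(cfg$seed, paste0("restart", restart))
      cae <- build_cae(cfg)
      cae$pretrained <- FALSE
    }
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    best_val <- Inf; best_layers <- NULL; stall <- 0L
    diverged <- FALSE
    for (ep in seq_len(max_ep)) {
      bt <- .batches(sample(train_ix), tc$batch_size)
      tl <- 0
      for (b in bt) {
        Xb <- X[, b, drop = FALSE]
        fw <- .cae_forward(cae, Xb)
        diff <- fw$xhat - Xb
        tl <- tl + sum(diff * diff) / nrow(X)
        grads <- .cae_backward(cae, fw, (2 / length(diff)) * diff)
        cae <- .cae_adam_step(cae, grads, tc$learning_rate)
      }
      tl <- tl / length(train_ix)
      vl <- reconstruction_loss(Xval, decode(cae, encode(cae, Xval)))
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("pretrain epoch %3d  train %.3e  val %.3e", ep, tl, vl))
      if (!is.finite(tl) || !is.finite(vl)) { diverged <- TRUE; break }
      if (!fixed_epochs) {
        if (vl < best_val * (1 - (tc$pretrain_min_delta %||% 0))) {
          best_val <- vl; best_layers <- cae$layers; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= tc$pretrain_patience) break
        }
      }
    }
    if (!diverged) {
      if (!fixed_epochs && !is.null(best_layers)) cae$layers <- best_layers
      cae$pretrained <- TRUE
      attr(hist, "config") <- list(optimizer = tc$optimizer,
                                   batch_size = tc$batch_size,
                                   learning_rate = tc$learning_rate,
                                   restarts = restart)
      attempt_val <- if (fixed_epochs) hist$val_loss[nrow(hist)] else best_val
      if (is.null(best_attempt) || attempt_val < best_attempt$val)
        best_attempt <- list(cae = cae, history = hist, val = attempt_val)
      # runs too short to have shown the decay are not judged by it
      healthy <- attempt_val <= decay_factor * hist$val_loss[1L] ||
        nrow(hist) < 10L
      if (healthy || restart == 3L) {
        if (!healthy)
          warning("validation loss never showed the expected decay; ",
                  "returning the best of 4 initialisations")
        return(best_attempt[c("cae", "history")])
      }
      warning("validation loss failed to decay (stuck initialisation); ",
              "reinitialising (", restart + 1L, "/3)")
    } else if (restart < 3L) {
      warning("non-finite pretraining loss; restarting (", restart + 1L, "/3)")
    }
  }
  if (!is.null(best_attempt)) return(best_attempt[c("cae", "history")])
  stop("pretraining diverged after 3 restarts", call. = FALSE)
}

#' Joint end-to-end training of autoencoder and clustering head
#'
#' Starting from a pretrained CAE, cluster centres are initialised with
#' k-means on the current latents, then the autoencoder and the centres
#' are optimised together under
#' `L = L_rec + gamma * KL(p || q)`, where `q` are the Student's-t soft
#' assignments and `p` the sharpened target distribution (refreshed every
#' `target_update_interval` epochs).  Training stops when fewer than
#' `label_change_tol` of the hard assignments change after an epoch, or at
#' the epoch cap.
#'
#' @param cae a pretrained [build_cae()] model.
#' @param ps a normalised [extract_patches()] patch set (or patch matrix).
#' @param k number of clusters.
#' @param tc a [train_config()].
#' @param verbose print per-epoch diagnostics.
#' @return an object of class `dec_fit`: list with `labels` (per-patch hard
#'   assignments, 1-based), `q` (final soft assignments), `cae`, `centers`
#'   ([init_centers()] state after training), and `history` (per-epoch
#'   losses, label-change fraction, stop reason).
#' @export
train_end_to_end <- function(cae, ps, k, tc = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(cae, "hsi_cae"), inherits(tc, "train_config"))
  if (!isTRUE(cae$pretrained))
    warning("CAE does not look pretrained; joint training from scratch")
  X <- .as_patch_matrix(ps, cae$cfg)
  n <- ncol(X)
  max_ep <- tc$max_joint_epochs %||%
    (if (cae$cfg$arch == "generic3d") 20L else 50L)
  .local_seed(substream_seed(tc$seed, "joint"))

  cs <- init_centers(encode(cae, X), k,
                     seed = substream_seed(tc$seed, "init_centers"))
  alpha <- cs$alpha
  mu_opt <- list(m = cs$centers * 0, v = cs$centers * 0)
  q <- soft_assign(encode(cae, X), cs)
  p <- target_distribution(q)
  labels <- max.col(q, ties.method = "first")
  hist <- data.frame(epoch = integer(), rec_loss = numeric(),
                     clu_loss = numeric(), total_loss = numeric(),
                     label_change = numeric(), q_row_dev = numeric())
  stop_reason <- "max_epochs"
  tstep <- 0L

  Zfull <- matrix(0, cae$cfg$latent_total, n)
  for (ep in seq_len(max_ep)) {
    bt <- .batches(sample.int(n), tc$batch_size)
    rl <- 0; cl <- 0
    for (b in bt) {
      Xb <- X[, b, drop = FALSE]
      fw <- .cae_forward(cae, Xb)
      Zfull[, b] <- fw$zcat
      qb <- soft_assign(fw$zcat, cs)
      pb <- p[b, , drop = FALSE]
      diff <- fw$xhat - Xb
      rl <- rl + sum(diff * diff) / nrow(X)
      cl <- cl + clustering_loss(qb, pb) * length(b)
      cg <- .cluster_grads(fw$zcat, cs$centers, qb, pb, alpha,
                           scale = tc$gamma / length(b))
      grads <- .cae_backward(cae, fw, (2 / length(diff)) * diff,
                             dz_extra = if (tc$gamma > 0) cg$dz else NULL)
      cae <- .cae_adam_step(cae, grads, tc$learning_rate)
      if (tc$gamma > 0) {
        tstep <- tstep + 1L
        mu_opt$m <- 0.9 * mu_opt$m + 0.1 * cg$dmu
        mu_opt$v <- 0.999 * mu_opt$v + 0.001 * cg$dmu^2
        cs$centers <- cs$centers - tc$learning_rate *
          (mu_opt$m / (1 - 0.9^tstep)) /
          (sqrt(mu_opt$v / (1 - 0.999^tstep)) + 1e-8)
      }
    }
    # latents accumulated over the epoch's batches stand in for a fresh
    # full pass; they lag the final parameters by less than one epoch
    q <- soft_assign(Zfull, cs)
    new_labels <- max.col(q, ties.method = "first")
    changed <- mean(new_labels != labels)
    if (min(colSums(q)) < .Machine$double.eps * n)
      warning("empty cluster at epoch ", ep, "; training continues")
    hist <- rbind(hist, data.frame(
      epoch = ep, rec_loss = rl / n, clu_loss = cl / n,
      total_loss = rl / n + tc$gamma * cl / n, label_change = changed,
      q_row_dev = max(abs(rowSums(q) - 1), abs(rowSums(p) - 1))))
    if (verbose)
      message(sprintf(
        "joint epoch %3d  rec %.3e  clu %.3e  changed %.4f",
        ep, rl / n, cl / n, changed))
    labels <- new_labels
    if (changed < tc$label_change_tol) { stop_reason <- "label_change"; break }
    if (ep %% tc$target_update_interval == 0L) p <- target_distribution(q)
  }
  attr(hist, "stop_reason") <- stop_reason
  structure(list(labels = labels, q = q, cae = cae, centers = cs,
                 history = hist, k = as.integer(k)),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf(
    "<dec_fit> %d patches into %d clusters after %d epoch(s) (stop: %s)\n",
    length(x$labels), x$k, nrow(x$history), attr(x$history, "stop_reason")))
  invisible(x)
}

#' CAE + k-means segmentation (not end-to-end)
#'
#' The two-stage baseline: encode all patches with a reconstruction-only
#' pretrained CAE, concatenate the branch latents, and cluster them with
#' k-means.  No further training takes place, so the compression is
#' optimised purely for reconstruction, not for clustering.
#'
#' @param cae a pretrained [build_cae()] model.
#' @param ps a normalised [extract_patches()] patch set (or patch matrix).
#' @param k number of clusters.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return integer vector of per-patch labels (1-based).
#' @export
cae_kmeans <- function(cae, ps, k, seed = 1L, nstart = 30L) {
  stopifnot(inherits(cae, "hsi_cae"))
  Z <- concat_latents(encode(cae, ps))
  k <- as.integer(k)
  if (k == 1L) return(rep(1L, ncol(Z)))
  .local_seed(seed)
  fit <- .robust_kmeans(t(Z), k, nstart = nstart)
  as.integer(fit$cluster)
}
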