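#' Configure a convolutional autoencoder architecture
#'
#' Three feature-mining architectures are available, all mapping a
#' `p x p x B` patch to a `latent_total`-element vector and back:
#'
#' * `"uwu2d"` — a branched 2D CAE: a front stack (a 1x1 spectral-mixing
#'   convolution over the `B` bands followed by 3x3 spatial convolutions)
#'   reduces the input to `branches` activation maps (fewer maps than
#'   bands), each map is compressed by its own small branch encoder into a
#'   latent of length `latent_total / branches`, and the branch decoders'
#'   outputs are re-concatenated and mapped back to `B` channels through a
#'   mirrored stack ending in a 1x1 spectral-synthesis convolution.  The
#'   branch isolation specialises each branch to the spectral features its
#'   activation map encodes.
#' * `"generic2d"` — a plain unbranched 2D CAE with the same spectral
#'   front/back layers and a dense bottleneck of length `latent_total`;
#'   its filter budget is chosen so its parameter count matches `"uwu2d"`
#'   within 20%, isolating the effect of branching.
#' * `"generic3d"` — a single-channel 3D CAE convolving jointly over space
#'   and the band axis (kernels spanning 7 bands), with a reduced filter
#'   budget.
#'
#' @param arch one of `"uwu2d"`, `"generic2d"`, `"generic3d"`.
#' @param patch_size patch side `p` in pixels.
#' @param bands number of spectral points `B`.
#' @param latent_total total latent length `D` (default 100).
#' @param branches number of branches `M` (`"uwu2d"` only; must divide
#'   `latent_total` and be smaller than `bands`).
#' @param filters optional per-architecture filter budget; defaults:
#'   `uwu2d` `list(spectral = 16, front = 16, branch = c(8, 16))`,
#'   `generic2d` `list(spectral = 16, enc = c(16, 16))`,
#'   `generic3d` `list(enc = c(8, 16, 16))`.
#' @param activation hidden nonlinearity; only `"relu"` is implemented
#'   (output layers are linear).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `cae_config`.
#' @export
#' @examples
#' cfg <- cae_config("uwu2d", patch_size = 20, bands = 100)
#' cfg$latent_total / cfg$branches  # latent length per branch
cae_config <- function(arch = c("uwu2d", "generic2d", "generic3d"),
                       patch_size, bands, latent_total = 100L,
                       branches = if (arch == "uwu2d") 4L else 1L,
                       filters = NULL, activation = "relu", seed = 1L) {
  arch <- match.arg(arch)
  patch_size <- as.integer(patch_size); bands <- as.integer(bands)
  latent_total <- as.integer(latent_total); branches <- as.integer(branches)
  if (latent_total < 1L) stop("latent_total must be positive", call. = FALSE)
  if (activation != "relu") stop("only 'relu' is implemented", call. = FALSE)
  if (arch == "uwu2d") {
    if (latent_total %% branches != 0L)
      stop("latent_total (", latent_total, ") must be divisible by branches (",
           branches, ")", call. = FALSE)
    if (branches >= bands)
      stop("uwu2d needs fewer branches than spectral bands", call. = FALSE)
  } else branches <- 1L
  if (is.null(filters))
    filters <- switch(arch,
                      uwu2d = list(spectral = 16L, front = 16L,
                                   branch = c(8L, 16L)),
                      generic2d = list(spectral = 16L, enc = c(16L, 16L)),
                      generic3d = list(enc = c(8L, 16L, 16L)))
  structure(list(arch = arch, patch_size = patch_size, bands = bands,
                 latent_total = latent_total, branches = branches,
                 filters = filters, activation = activation,
                 seed = as.integer(seed)),
            class = "cae_config")
}

#' Build a convolutional autoencoder from a configuration
#'
#' Instantiates the encoder/decoder pair with seeded He-initialised
#' weights.  The returned model is a plain list, so training functions can
#' return updated copies without hidden state.
#'
#' @param cfg a [cae_config()].
#' @return an object of class `hsi_cae` with fields `cfg`, `layers` (flat
#'   named list), `prog` (layer ids per stage), `opt` (Adam state), and
#'   `pretrained` flag.
#' @export
#' @examples
#' cae <- build_cae(cae_config("generic2d", 8, 16, latent_total = 10))
#' n_parameters(cae)
build_cae <- function(cfg) {
  stopifnot(inherits(cfg, "cae_config"))
  p <- cfg$patch_size; B <- cfg$bands; D <- cfg$latent_total; M <- cfg$branches
  Dm <- D %/% M
  sp <- function(d) c(d, d)
  layers <- list(); prog <- list()
  add <- function(stage, id, l) {
    layers[[id]] <<- l
    prog[[stage]] <<- c(prog[[stage]], id)
  }
  if (cfg$arch == "uwu2d") {
    F0 <- cfg$filters$spectral; F1 <- cfg$filters$front
    bf <- cfg$filters$branch
    ph <- as.integer(ceiling(p / 2)); ph2 <- as.integer(ceiling(ph / 2))
    add("front", "s0", .smix_layer(B, p^2, F0))
    add("front", "s0a", .relu_layer())
    add("front", "f1", .conv_layer(sp(p), F0, F1, c(3L, 3L), c(2L, 2L)))
    add("front", "f1a", .relu_layer())
    add("front", "f2", .conv_layer(sp(ph), F1, M, c(3L, 3L)))
    add("front", "f2a", .relu_layer())
    ph3 <- as.integer(ceiling(ph2 / 2))
    ph4 <- as.integer(ceiling(ph3 / 2))
    # Branch encoders/decoders: a deep stride-2 stack (inner U-Net style)
    # before the dense map makes the branch latents approximately
    # translation invariant, so patches are grouped by texture rather than
    # by the sub-patch phase of a repeating pattern.  The M branches are
    # realised as grouped layers (block-diagonal weight masks), which is
    # mathematically identical to M independent stacks.
    g <- function(l) .with_groups(l, M)
    add("enc", "e1", g(.conv_layer(sp(ph), M, M * bf[1L], c(3L, 3L), c(2L, 2L))))
    add("enc", "e1a", .relu_layer())
    add("enc", "e2", g(.conv_layer(sp(ph2), M * bf[1L], M * bf[2L], c(3L, 3L), c(2L, 2L))))
    add("enc", "e2a", .relu_layer())
    add("enc", "e3", g(.conv_layer(sp(ph3), M * bf[2L], M * bf[2L], c(3L, 3L), c(2L, 2L))))
    add("enc", "e3a", .relu_layer())
    add("enc", "e4", g(.dense_layer(M * bf[2L] * ph4^2, D)))
    add("dec", "d1", g(.dense_layer(D, M * bf[2L] * ph4^2)))
    add("dec", "d1a", .relu_layer())
    add("dec", "d2", g(.conv_layer(sp(ph4), M * bf[2L], M * bf[2L], c(3L, 3L))))
    add("dec", "d2a", .relu_layer())
    add("dec", "d2u", .upsample_layer(sp(ph4), M * bf[2L], sp(ph3)))
    add("dec", "d3", g(.conv_layer(sp(ph3), M * bf[2L], M * bf[1L], c(3L, 3L))))
    add("dec", "d3a", .relu_layer())
    add("dec", "d3u", .upsample_layer(sp(ph3), M * bf[1L], sp(ph2)))
    add("dec", "d4", g(.conv_layer(sp(ph2), M * bf[1L], M * bf[1L], c(3L, 3L))))
    add("dec", "d4a", .relu_layer())
    add("dec", "d4u", .upsample_layer(sp(ph2), M * bf[1L], sp(ph)))
    add("dec", "d5", g(.conv_layer(sp(ph), M * bf[1L], M, c(3L, 3L))))
    add("dec", "d5a", .relu_layer())
    add("back", "g1", .conv_layer(sp(ph), M, F1, c(3L, 3L)))
    add("back", "g1a", .relu_layer())
    add("back", "g2", .conv_layer(sp(ph), F1, F1, c(3L, 3L)))
    add("back", "g2a", .relu_layer())
    add("back", "g2u", .upsample_layer(sp(ph), F1, sp(p)))
    add("back", "g3", .ssynth_layer(F1, p^2, B))
    split_spatial <- ph^2
  } else if (cfg$arch == "generic2d") {
    F0 <- cfg$filters$spectral; Fe <- cfg$filters$enc
    ph <- as.integer(ceiling(p / 2)); ph2 <- as.integer(ceiling(ph / 2))
    add("front", "s0", .smix_layer(B, p^2, F0))
    add("front", "s0a", .relu_layer())
    add("front", "f1", .conv_layer(sp(p), F0, Fe[1L], c(3L, 3L), c(2L, 2L)))
    add("front", "f1a", .relu_layer())
    ph3 <- as.integer(ceiling(ph2 / 2))
    add("front", "f2", .conv_layer(sp(ph), Fe[1L], Fe[2L], c(3L, 3L), c(2L, 2L)))
    add("front", "f2a", .relu_layer())
    add("front", "f3", .conv_layer(sp(ph2), Fe[2L], Fe[2L], c(3L, 3L), c(2L, 2L)))
    add("front", "f3a", .relu_layer())
    add("enc", "e1", .dense_layer(Fe[2L] * ph3^2, D))
    add("dec", "d1", .dense_layer(D, Fe[2L] * ph3^2))
    add("dec", "d1a", .relu_layer())
    add("back", "g1", .conv_layer(sp(ph3), Fe[2L], Fe[2L], c(3L, 3L)))
    add("back", "g1a", .relu_layer())
    add("back", "g1u", .upsample_layer(sp(ph3), Fe[2L], sp(ph2)))
    add("back", "g2", .conv_layer(sp(ph2), Fe[2L], Fe[2L], c(3L, 3L)))
    add("back", "g2a", .relu_layer())
    add("back", "g2u", .upsample_layer(sp(ph2), Fe[2L], sp(ph)))
    add("back", "g3", .conv_layer(sp(ph), Fe[2L], Fe[2L], c(3L, 3L)))
    add("back", "g3a", .relu_layer())
    add("back", "g3u", .upsample_layer(sp(ph), Fe[2L], sp(p)))
    add("back", "g4", .ssynth_layer(Fe[2L], p^2, B))
    split_spatial <- Fe[2L] * ph3^2
  } else { # generic3d: band-fastest layout, so the band axis comes first
    Fe <- cfg$filters$enc
    d0 <- c(B, p, p)
    d1 <- as.integer(ceiling(d0 / c(4L, 2L, 2L)))
    d2 <- as.integer(ceiling(d1 / c(4L, 1L, 1L)))
    d3 <- as.integer(ceiling(d2 / c(2L, 2L, 2L)))
    add("front", "f1", .conv_layer(d0, 1L, Fe[1L], c(7L, 3L, 3L), c(4L, 2L, 2L)))
    add("front", "f1a", .relu_layer())
    add("front", "f2", .conv_layer(d1, Fe[1L], Fe[2L], c(7L, 3L, 3L), c(4L, 1L, 1L)))
    add("front", "f2a", .relu_layer())
    add("front", "f3", .conv_layer(d2, Fe[2L], Fe[3L], c(3L, 3L, 3L), c(2L, 2L, 2L)))
    add("front", "f3a", .relu_layer())
    add("enc", "e1", .dense_layer(Fe[3L] * prod(d3), D))
    add("dec", "d1", .dense_layer(D, Fe[3L] * prod(d3)))
    add("dec", "d1a", .relu_layer())
    add("back", "g1", .conv_layer(d3, Fe[3L], Fe[3L], c(3L, 3L, 3L)))
    add("back", "g1a", .relu_layer())
    add("back", "g1u", .upsample_layer(d3, Fe[3L], d2))
    add("back", "g2", .conv_layer(d2, Fe[3L], Fe[1L], c(7L, 3L, 3L)))
    add("back", "g2a", .relu_layer())
    add("back", "g2u", .upsample_layer(d2, Fe[1L], d0))
    add("back", "g3", .conv_layer(d0, Fe[1L], 1L, c(7L, 3L, 3L)))
    split_spatial <- Fe[3L] * prod(d3)
  }
  .local_seed(cfg$seed)
  layers <- lapply(layers, .init_layer)
  cae <- list(cfg = cfg, layers = layers, prog = prog,
              split_spatial = as.integer(split_spatial),
              opt = NULL, t = 0L, pretrained = FALSE)
  class(cae) <- "hsi_cae"
  cae
}

#' @export
print.hsi_cae <- function(x, ...) {
  cat(sprintf(
    "<hsi_cae> %s: %d x %d x %d patch -> latent %d (%d branch%s), %d parameters%s\n",
    x$cfg$arch, x$cfg$patch_size, x$cfg$patch_size, x$cfg$bands,
    x$cfg$latent_total, x$cfg$branches, if (x$cfg$branches > 1L) "es" else "",
    n_parameters(x), if (x$pretrained) ", pretrained" else ""))
  invisible(x)
}

#' Number of trainable parameters of a CAE
#'
#' @param cae an [build_cae()] model.
#' @return integer parameter count (weights + biases).
#' @export
n_parameters <- function(cae) {
  stopifnot(inherits(cae, "hsi_cae"))
  .count_params(cae$layers)
}

.stage_layers <- function(cae, stage) cae$layers[cae$prog[[stage]]]

# Full forward pass with caches; X is (p*p*B) x n.  All architectures are
# four sequential stages: front (patch -> activation maps), enc (maps ->
# latent; branch isolation via grouped layers), dec (latent -> maps), back
# (maps -> reconstruction).
.cae_forward <- function(cae, X) {
  fr <- .seq_forward(.stage_layers(cae, "front"), X)
  en <- .seq_forward(.stage_layers(cae, "enc"), fr$out)
  de <- .seq_forward(.stage_layers(cae, "dec"), en$out)
  bk <- .seq_forward(.stage_layers(cae, "back"), de$out)
  list(zcat = en$out, xhat = bk$out, front = fr, enc = en, dec = de,
       back = bk)
}

# Backward pass given dxhat (and optionally an extra gradient on the
# concatenated latent, e.g. from the clustering loss); returns a flat named
# gradient list aligned with cae$layers.
.cae_backward <- function(cae, fw, dxhat, dz_extra = NULL) {
  grads <- vector("list", length(cae$layers))
  names(grads) <- names(cae$layers)
  put <- function(stage, g) {
    ids <- cae$prog[[stage]]
    for (i in seq_along(ids))
      if (!is.null(g[[i]])) grads[[ids[i]]] <<- g[[i]]
  }
  bk <- .seq_backward(.stage_layers(cae, "back"), fw$back$caches, dxhat)
  put("back", bk$grads)
  dd <- .seq_backward(.stage_layers(cae, "dec"), fw$dec$caches, bk$din)
  put("dec", dd$grads)
  dz <- dd$din
  if (!is.null(dz_extra)) dz <- dz + dz_extra
  de <- .seq_backward(.stage_layers(cae, "enc"), fw$enc$caches, dz)
  put("enc", de$grads)
  fr <- .seq_backward(.stage_layers(cae, "front"), fw$front$caches, de$din,
                      need_din = FALSE)
  put("front", fr$grads)
  grads
}

.cae_adam_step <- function(cae, grads, lr) {
  if (is.null(cae$opt)) cae$opt <- .adam_init(cae$layers)
  cae$t <- cae$t + 1L
  upd <- .adam_step(cae$layers, grads, cae$opt, lr, cae$t)
  cae$layers <- upd$layers
  cae$opt <- upd$state
  cae
}

.as_patch_matrix <- function(x, cfg) {
  if (inherits(x, "patch_set")) x <- x$patches
  if (is.array(x) && length(dim(x)) == 3L) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  S <- cfg$patch_size^2 * cfg$bands
  if (nrow(x) != S)
    stop("patch data has ", nrow(x), " values per patch; the model expects ",
         S, " (", cfg$patch_size, " x ", cfg$patch_size, " x ", cfg$bands, ")",
         call. = FALSE)
  x
}

#' Encode patches into latent vectors
#'
#' Runs the encoder on one patch or a whole patch set, producing the
#' per-branch latent vectors and their concatenation (the representation
#' used for clustering).  Deterministic given the model parameters.
#'
#' @param cae an [build_cae()] model.
#' @param x a [extract_patches()] patch set, a `p x p x B` array, or a
#'   matrix with one column per patch.
#' @param chunk number of patches encoded per internal block (memory
#'   control).
#' @return an object of class `latent_set`: list with `per_branch` (list of
#'   `D/M x n` matrices), `concat` (`D x n` matrix), `branches`, `latent_total`.
#' @export
encode <- function(cae, x, chunk = 512L) {
  stopifnot(inherits(cae, "hsi_cae"))
  X <- .as_patch_matrix(x, cae$cfg)
  M <- cae$cfg$branches
  D <- cae$cfg$latent_total
  Dm <- D %/% M
  n <- ncol(X)
  front_l <- .stage_layers(cae, "front")
  enc_l <- .stage_layers(cae, "enc")
  Z <- matrix(0, D, n)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fo <- .seq_forward(front_l, X[, ix, drop = FALSE])$out
    Z[, ix] <- .seq_forward(enc_l, fo)$out
  }
  per_branch <- lapply(seq_len(M), function(m)
    Z[((m - 1L) * Dm + 1L):(m * Dm), , drop = FALSE])
  structure(list(per_branch = per_branch, concat = Z,
                 branches = M, latent_total = D),
            class = "latent_set")
}

#' @export
print.latent_set <- function(x, ...) {
  cat(sprintf("<latent_set> %d patches, latent %d (%d branch%s)\n",
              ncol(x$concat), x$latent_total, x$branches,
              if (x$branches > 1L) "es" else ""))
  invisible(x)
}

#' Concatenate per-branch latent vectors
#'
#' Stacks the branch latents in branch order into the single vector (or
#' `D x n` matrix) consumed by the clustering stage.
#'
#' @param ls a [encode()] latent set.
#' @return a `D x n` numeric matrix.
#' @export
concat_latents <- function(ls) {
  stopifnot(inherits(ls, "latent_set"))
  if (length(ls$per_branch) != ls$branches)
    stop("latent set is missing branches", call. = FALSE)
  out <- do.call(rbind, ls$per_branch)
  if (nrow(out) != ls$latent_total)
    stop("concatenated latent has wrong length", call. = FALSE)
  out
}

#' Decode latent vectors back to patches
#'
#' @param cae an [build_cae()] model.
#' @param ls a [encode()] latent set, or a `D x n` matrix of concatenated
#'   latents.
#' @param chunk patches decoded per internal block.
#' @return a `(p * p * B) x n` matrix of reconstructions; use
#'   `array(out[, i], c(p, p, B))` for a single patch volume.
#' @export
decode <- function(cae, ls, chunk = 512L) {
  stopifnot(inherits(cae, "hsi_cae"))
  Z <- if (inherits(ls, "latent_set")) ls$concat else as.matrix(ls)
  if (nrow(Z) != cae$cfg$latent_total)
    stop("latent length ", nrow(Z), " does not match the model's ",
         cae$cfg$latent_total, call. = FALSE)
  dec_l <- .stage_layers(cae, "dec")
  back_l <- .stage_layers(cae, "back")
  n <- ncol(Z)
  out <- matrix(0, cae$cfg$patch_size^2 * cae$cfg$bands, n)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    maps <- .seq_forward(dec_l, Z[, ix, drop = FALSE])$out
    out[, ix] <- .seq_forward(back_l, maps)$out
  }
  out
}

#' Mean squared reconstruction error
#'
#' @param x,xhat patch data of identical shape (arrays or matrices).
#' @return non-negative scalar; zero iff `x == xhat`.
#' @export
reconstruction_loss <- function(x, xhat) {
  if (inherits(x, "patch_set")) x <- x$patches
  if (!all(length(x) == length(xhat)) ||
      !isTRUE(all.equal(dim(x) %||% length(x), dim(xhat) %||% length(xhat))))
    stop("shape mismatch between x and xhat", call. = FALSE)
  mean((as.numeric(x) - as.numeric(xhat))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
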