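# Pre/post-processing, the ResUnet generator and patch discriminator at
# configurable scale, the two-phase learning-rate schedule, the paired
# cycleGAN training loop and slice-wise inference.

#' PreprocessSpec: slice resampling and intensity normalization
#'
#' @slot targetSize in-plane output size in pixels (default 256).
#' @slot targetPixelMM in-plane output pixel size in mm (default 1.6).
#' @slot huLow,huHigh HU window mapped affinely to `[-1, 1]`; values outside
#'   are clipped first (defaults -1000 and 2000).
#' @export
setClass("PreprocessSpec",
  representation(targetSize = "integer", targetPixelMM = "numeric",
                 huLow = "numeric", huHigh = "numeric"))

setValidity("PreprocessSpec", function(object) {
  msg <- character()
  if (object@targetSize < 1L) msg <- c(msg, "'targetSize' must be positive")
  if (object@targetPixelMM <= 0) msg <- c(msg, "'targetPixelMM' must be positive")
  if (object@huLow >= object@huHigh) msg <- c(msg, "'huLow' must be < 'huHigh'")
  if (length(msg)) msg else TRUE
})

#' @rdname PreprocessSpec-class
#' @param targetSize,targetPixelMM,huLow,huHigh see slots.
#' @export
preprocessSpec <- function(targetSize = 256L, targetPixelMM = 1.6,
                           huLow = -1000, huHigh = 2000) {
  new("PreprocessSpec", targetSize = as.integer(targetSize),
      targetPixelMM = targetPixelMM, huLow = huLow, huHigh = huHigh)
}

#' GeneratorSpec: ResUnet generator architecture
#'
#' Encoder levels halve resolution with stride-2 convolutions and double the
#' channel width; each level carries short residual blocks; the decoder
#' mirrors with nearest-neighbour upsampling, and the first `longSkipLevels`
#' levels are bridged by Unet-style long skip concatenations. A final
#' saturating tanh bounds outputs to `[-1, 1]`.
#'
#' @slot levels encoder/decoder depth (default 5).
#' @slot longSkipLevels number of shallowest levels with long skips
#'   (default 3).
#' @slot baseChannels channel width of the first level.
#' @slot resBlocks residual blocks per level.
#' @export
setClass("GeneratorSpec",
  representation(levels = "integer", longSkipLevels = "integer",
                 baseChannels = "integer", resBlocks = "integer"))

setValidity("GeneratorSpec", function(object) {
  msg <- character()
  if (object@levels < 1L) msg <- c(msg, "'levels' must be >= 1")
  if (object@longSkipLevels > object@levels)
    msg <- c(msg, "'longSkipLevels' must be <= 'levels'")
  if (object@baseChannels < 1L) msg <- c(msg, "'baseChannels' must be > 0")
  if (object@resBlocks < 0L) msg <- c(msg, "'resBlocks' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneratorSpec-class
#' @param levels,longSkipLevels,baseChannels,resBlocks see slots.
#' @export
generatorSpec <- function(levels = 5L, longSkipLevels = 3L, baseChannels = 32L,
                          resBlocks = 1L) {
  new("GeneratorSpec", levels = as.integer(levels),
      longSkipLevels = as.integer(longSkipLevels),
      baseChannels = as.integer(baseChannels), resBlocks = as.integer(resBlocks))
}

#' Toy generator specification used throughout the tests
#'
#' Two levels, eight base channels: desk-scale while exercising every
#' architectural element (stride-2 encoder, residual blocks, long skip,
#' upsampling decoder, tanh output).
#' @export
toyGeneratorSpec <- function() generatorSpec(levels = 2L, longSkipLevels = 1L,
                                             baseChannels = 8L, resBlocks = 1L)

#' DiscriminatorSpec: patch discriminator architecture
#'
#' The reference cycleGAN patch discriminator: `nStride2` stride-2 4x4
#' convolutions with doubling channels (no normalization on the first), a
#' stride-1 4x4 layer, and a final 1-channel 4x4 stride-1 scoring layer.
#'
#' @slot nStride2 number of stride-2 layers (default 3).
#' @slot baseChannels channel width of the first layer (default 64).
#' @export
setClass("DiscriminatorSpec",
  representation(nStride2 = "integer", baseChannels = "integer"))

setValidity("DiscriminatorSpec", function(object) {
  if (object@nStride2 < 1L || object@baseChannels < 1L)
    "'nStride2' and 'baseChannels' must be positive" else TRUE
})

#' @rdname DiscriminatorSpec-class
#' @param nStride2,baseChannels see slots.
#' @export
discriminatorSpec <- function(nStride2 = 3L, baseChannels = 64L) {
  new("DiscriminatorSpec", nStride2 = as.integer(nStride2),
      baseChannels = as.integer(baseChannels))
}

#' TrainConfig: optimizer and schedule
#'
#' @slot epochs total epochs (default 40).
#' @slot constantLREpochs epochs at the base learning rate before the linear
#'   decay to zero (default 20).
#' @slot baseLR Adam base learning rate (default 0.0002).
#' @slot batchSize slices per batch (default 4).
#' @slot valFraction held-out fraction of slice pairs (default 0.1).
#' @slot seed RNG seed governing initialization and shuffling.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", constantLREpochs = "integer",
                 baseLR = "numeric", batchSize = "integer",
                 valFraction = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "'epochs' must be >= 1")
  if (object@constantLREpochs > object@epochs)
    msg <- c(msg, "'constantLREpochs' must be <= 'epochs'")
  if (object@baseLR < 0) msg <- c(msg, "'baseLR' must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be >= 1")
  if (object@valFraction < 0 || object@valFraction >= 1)
    msg <- c(msg, "'valFraction' must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param epochs,constantLREpochs,baseLR,batchSize,valFraction,seed see slots.
#' @export
trainConfig <- function(epochs = 40L, constantLREpochs = 20L, baseLR = 2e-4,
                        batchSize = 4L, valFraction = 0.1, seed = 0L) {
  new("TrainConfig", epochs = as.integer(epochs),
      constantLREpochs = as.integer(constantLREpochs), baseLR = baseLR,
      batchSize = as.integer(batchSize), valFraction = valFraction,
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# pre / post processing
# ---------------------------------------------------------------------------

.resampleSlices <- function(vox, spacing, origin, outSize, outPix, fill) {
  nz <- dim(vox)[3]
  cx <- origin[1] + (dim(vox)[1] - 1) / 2 * spacing[1]
  cy <- origin[2] + (dim(vox)[2] - 1) / 2 * spacing[2]
  u <- (seq_len(outSize) - (outSize + 1) / 2) * outPix
  P <- cbind(rep(cx + u, times = outSize), rep(cy + u, each = outSize), 0)
  out <- array(0, c(outSize, outSize, nz))
  for (k in seq_len(nz)) {
    sl <- array(vox[, , k], c(dim(vox)[1], dim(vox)[2], 1L))
    P[, 3] <- 0
    out[, , k] <- .interp3(sl, c(spacing[1:2], 1), c(origin[1:2], 0), P,
                           fill = fill)
  }
  out
}

.gridsMatch <- function(geom, spec) {
  d <- geom$dim
  d[1] == spec@targetSize && d[2] == spec@targetSize &&
    abs(geom$spacing[1] - spec@targetPixelMM) < 1e-9 &&
    abs(geom$spacing[2] - spec@targetPixelMM) < 1e-9
}

#' Preprocess a volume into a normalized slice stack
#'
#' Axial slices are resampled (bilinear, centre-aligned) to the target
#' in-plane grid, clipped to the HU window and mapped affinely to `[-1, 1]`
#' (so -1000 HU maps to -1, 2000 HU to +1 under the defaults). When the input
#' grid already equals the target grid the resampling is skipped exactly.
#' The returned geometry record suffices for [postprocessSlices()] to invert
#' the transformation.
#'
#' @param vol an [ImageVolume-class].
#' @param spec a [PreprocessSpec-class].
#' @return `list(slices = 3D array [target, target, nSlices] in [-1, 1],
#'   geom = geometry record)`.
#' @export
preprocessVolume <- function(vol, spec = preprocessSpec()) {
  stopifnot(is(vol, "ImageVolume"), is(spec, "PreprocessSpec"))
  geom <- list(dim = dim(vol@voxels), spacing = vol@spacing,
               origin = vol@origin, spec = spec)
  v <- vol@voxels
  if (!.gridsMatch(geom, spec))
    v <- .resampleSlices(v, vol@spacing, vol@origin, spec@targetSize,
                         spec@targetPixelMM, fill = spec@huLow)
  v <- pmin(pmax(v, spec@huLow), spec@huHigh)
  norm <- (v - spec@huLow) / (spec@huHigh - spec@huLow) * 2 - 1
  list(slices = norm, geom = geom)
}

#' Invert preprocessing: normalized slices back to an HU volume
#'
#' Applies the inverse affine intensity map, then resamples back to the
#' original grid (positions outside the slice stack's extent become
#' `huLow`). On a matching grid the resampling is skipped, so
#' `postprocessSlices(preprocessVolume(v))` reproduces
#' `clip(v, huLow, huHigh)` exactly.
#'
#' @param slices normalized slice stack in `[-1, 1]`.
#' @param geom geometry record from the matching [preprocessVolume()] call.
#' @return An [ImageVolume-class] on the original grid.
#' @export
postprocessSlices <- function(slices, geom) {
  spec <- geom$spec
  if (dim(slices)[3] != geom$dim[3])
    stop("slice stack does not match the geometry record")
  hu <- (slices + 1) / 2 * (spec@huHigh - spec@huLow) + spec@huLow
  if (!.gridsMatch(geom, spec)) {
    t <- spec@targetSize; q <- spec@targetPixelMM
    cx <- geom$origin[1] + (geom$dim[1] - 1) / 2 * geom$spacing[1]
    cy <- geom$origin[2] + (geom$dim[2] - 1) / 2 * geom$spacing[2]
    tOrigin <- c(cx - (t - 1) / 2 * q, cy - (t - 1) / 2 * q)
    x <- geom$origin[1] + (seq_len(geom$dim[1]) - 1) * geom$spacing[1]
    y <- geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2]
    P <- cbind(rep(x, times = geom$dim[2]), rep(y, each = geom$dim[1]), 0)
    out <- array(0, geom$dim)
    for (k in seq_len(geom$dim[3])) {
      sl <- array(hu[, , k], c(t, t, 1L))
      out[, , k] <- .interp3(sl, c(q, q, 1), c(tOrigin, 0), P, fill = spec@huLow)
    }
    hu <- out
  }
  imageVolume(array(hu, geom$dim), geom$spacing, geom$origin)
}

# ---------------------------------------------------------------------------
# network builders
# ---------------------------------------------------------------------------

.resBlockOps <- function(name, ch) {
  list(list(kind = "rsave"),
       list(kind = "conv", name = paste0(name, ".c1"), k = 3L, stride = 1L,
            pad = 1L, cin = ch, cout = ch),
       list(kind = "inorm", name = paste0(name, ".n1"), ch = ch),
       list(kind = "relu"),
       list(kind = "conv", name = paste0(name, ".c2"), k = 3L, stride = 1L,
            pad = 1L, cin = ch, cout = ch),
       list(kind = "inorm", name = paste0(name, ".n2"), ch = ch),
       list(kind = "radd"))
}

.generatorOps <- function(spec, inCh = 1L, outCh = 1L) {
  L <- spec@levels; C <- spec@baseChannels
  S <- min(spec@longSkipLevels, L - 1L); R <- spec@resBlocks
  ch <- C * 2L^(seq_len(L) - 1L)
  ops <- list(
    list(kind = "conv", name = "e1", k = 3L, stride = 1L, pad = 1L,
         cin = inCh, cout = ch[1]),
    list(kind = "inorm", name = "e1n", ch = ch[1]),
    list(kind = "relu"))
  for (r in seq_len(R)) ops <- c(ops, .resBlockOps(paste0("e1r", r), ch[1]))
  if (S >= 1L) ops <- c(ops, list(list(kind = "tap", name = "skip1")))
  for (l in seq_len(L)[-1]) {
    ops <- c(ops, list(
      list(kind = "conv", name = paste0("e", l), k = 3L, stride = 2L, pad = 1L,
           cin = ch[l - 1], cout = ch[l]),
      list(kind = "inorm", name = paste0("e", l, "n"), ch = ch[l]),
      list(kind = "relu")))
    for (r in seq_len(R)) ops <- c(ops, .resBlockOps(paste0("e", l, "r", r), ch[l]))
    if (l < L && l <= S) ops <- c(ops, list(list(kind = "tap",
                                                 name = paste0("skip", l))))
  }
  for (l in rev(seq_len(L - 1L))) {
    ops <- c(ops, list(
      list(kind = "up2"),
      list(kind = "conv", name = paste0("u", l), k = 3L, stride = 1L, pad = 1L,
           cin = ch[l + 1], cout = ch[l]),
      list(kind = "inorm", name = paste0("u", l, "n"), ch = ch[l]),
      list(kind = "relu")))
    if (l <= S) {
      ops <- c(ops, list(
        list(kind = "concat", name = paste0("skip", l)),
        list(kind = "conv", name = paste0("f", l), k = 3L, stride = 1L,
             pad = 1L, cin = 2L * ch[l], cout = ch[l]),
        list(kind = "inorm", name = paste0("f", l, "n"), ch = ch[l]),
        list(kind = "relu")))
    }
    for (r in seq_len(R)) ops <- c(ops, .resBlockOps(paste0("d", l, "r", r), ch[l]))
  }
  c(ops, list(
    list(kind = "conv", name = "out", k = 3L, stride = 1L, pad = 1L,
         cin = ch[1], cout = outCh),
    list(kind = "tanh")))
}

.discriminatorOps <- function(spec, inCh = 1L) {
  n <- spec@nStride2; C <- spec@baseChannels
  ch <- C * 2L^(seq_len(n) - 1L)
  ops <- list(
    list(kind = "conv", name = "c1", k = 4L, stride = 2L, pad = 1L,
         cin = inCh, cout = ch[1]),
    list(kind = "lrelu"))
  for (l in seq_len(n)[-1]) {
    ops <- c(ops, list(
      list(kind = "conv", name = paste0("c", l), k = 4L, stride = 2L, pad = 1L,
           cin = ch[l - 1], cout = ch[l]),
      list(kind = "inorm", name = paste0("c", l, "n"), ch = ch[l]),
      list(kind = "lrelu")))
  }
  c(ops, list(
    list(kind = "conv", name = "pf", k = 4L, stride = 1L, pad = 1L,
         cin = ch[n], cout = 2L * ch[n]),
    list(kind = "inorm", name = "pfn", ch = 2L * ch[n]),
    list(kind = "lrelu"),
    list(kind = "conv", name = "fin", k = 4L, stride = 1L, pad = 1L,
         cin = 2L * ch[n], cout = 1L)))
}

#' Build a ResUnet generator
#'
#' Maps an `H x W` slice (values in `[-1, 1]`) to a slice of the same shape,
#' bounded by the final tanh. `H` and `W` must be divisible by
#' `2^(levels - 1)`. Initialization (Gaussian, sd 0.02) is seeded, so two
#' builds with the same seed are identical.
#'
#' @param spec a [GeneratorSpec-class].
#' @param seed integer RNG seed for initialization.
#' @param inChannels,outChannels slice channel counts.
#' @return An object of class `"sctganNet"`; apply with [applyNetwork()].
#' @export
buildGenerator <- function(spec = generatorSpec(), seed = 0L, inChannels = 1L,
                           outChannels = 1L) {
  validObject(spec)
  set.seed(seed)
  ops <- .generatorOps(spec, inChannels, outChannels)
  net <- list(kind = "generator", spec = spec, ops = ops,
              params = .opsParams(ops, inChannels),
              divisor = 2L^(spec@levels - 1L))
  class(net) <- "sctganNet"
  net
}

#' Build a patch discriminator
#'
#' Maps a slice to a spatial map of patch realism scores; the map extent
#' follows the stride arithmetic of the layer stack (a 256x256 input through
#' the reference 3 stride-2 + 2 stride-1 stack yields 30x30). Errors if the
#' input is smaller than the receptive field.
#'
#' @param spec a [DiscriminatorSpec-class].
#' @param seed integer RNG seed for initialization.
#' @param inChannels slice channel count.
#' @return An object of class `"sctganNet"`.
#' @export
buildDiscriminator <- function(spec = discriminatorSpec(), seed = 0L,
                               inChannels = 1L) {
  validObject(spec)
  set.seed(seed)
  ops <- .discriminatorOps(spec, inChannels)
  net <- list(kind = "discriminator", spec = spec, ops = ops,
              params = .opsParams(ops, inChannels), divisor = 1L)
  class(net) <- "sctganNet"
  net
}

#' @export
print.sctganNet <- function(x, ...) {
  cat(sprintf("sctganNet (%s): %d ops, %d parameters\n", x$kind, length(x$ops),
              .paramCount(x$params)))
  invisible(x)
}

#' Apply a network to a slice stack
#'
#' @param net an `"sctganNet"` from [buildGenerator()] or
#'   [buildDiscriminator()].
#' @param x matrix (single slice) or array `[H, W, nSlices]` /
#'   `[H, W, C, N]`.
#' @return Output with the batch layout of the input.
#' @export
applyNetwork <- function(net, x) {
  asMatrix <- is.matrix(x)
  if (asMatrix) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
  d <- dim(x)
  if (net$kind == "generator" && (d[1] %% net$divisor || d[2] %% net$divisor))
    stop("slice size ", d[1], "x", d[2], " not divisible by 2^(levels-1) = ",
         net$divisor)
  y <- .netForward(x, net$ops, net$params, keepCache = FALSE)$y
  if (asMatrix) y <- y[, , 1L, 1L]
  y
}

#' Learning rate at a given epoch
#'
#' The base rate for the first `constantLREpochs` epochs, then a linear
#' decrease reaching exactly zero at the final epoch (rate sampled at epoch
#' start: `baseLR * (epochs - e) / (epochs - constantLREpochs)` for
#' `e > constantLREpochs`).
#'
#' @param e epoch index in `1..epochs`.
#' @param cfg a [TrainConfig-class].
#' @return The learning rate.
#' @examples
#' lrAtEpoch(10, trainConfig())  # 2e-4
#' lrAtEpoch(30, trainConfig())  # 1e-4
#' lrAtEpoch(40, trainConfig())  # 0
#' @export
lrAtEpoch <- function(e, cfg = trainConfig()) {
  if (e < 1 || e > cfg@epochs) stop("epoch index out of range 1..", cfg@epochs)
  if (e <= cfg@constantLREpochs) return(cfg@baseLR)
  cfg@baseLR * (cfg@epochs - e) / (cfg@epochs - cfg@constantLREpochs)
}

# ---------------------------------------------------------------------------
# training
# ---------------------------------------------------------------------------

.checkFinite <- function(value, term) {
  if (any(!is.finite(value)))
    stop("non-finite loss in term '", term, "' - aborting training")
  value
}

#' Train the SSIM-weighted cycleGAN on paired phantom samples
#'
#' The paired training scheme: for each CBCT slice `x` and its registered-CT
#' slice `y`, generators `G` (CBCT to CT) and `F` (CT to CBCT) are optimized
#' with least-squares adversarial terms, cycle-consistency
#' `|F(G(x)) - x| + |G(F(y)) - y|`, and the thresholded SSIM-weighted L1
#' terms `w * |G(x) - y|` and `w * |F(y) - x|`, where `w` is the thresholded
#' local SSIM of `(x, y)` (a fixed constant of the pair, receiving no
#' gradient). Discriminators are updated before the generators on every
#' batch. Fully seeded and deterministic.
#'
#' @param samples list of [PairedSample-class] objects.
#' @param genSpec a [GeneratorSpec-class] (both generators).
#' @param discSpec a [DiscriminatorSpec-class] (both discriminators).
#' @param lossCfg a [LossConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param preSpec a [PreprocessSpec-class].
#' @param maxPairs optional cap on the number of slice pairs used (pairs
#'   beyond the cap, in sample order, are dropped).
#' @param verbose print per-epoch losses.
#' @return A model-state list (class `"sctganModel"`) with generators `G`
#'   (CBCT to sCT) and `F`, discriminators, configs, the per-epoch
#'   `history` data frame, the held-out slice indices `valIdx`, and the
#'   pair-to-(sample, slice) map `pairMap`.
#' @export
trainCycleGAN <- function(samples, genSpec = toyGeneratorSpec(),
                          discSpec = discriminatorSpec(nStride2 = 2L,
                                                       baseChannels = 16L),
                          lossCfg = lossConfig(), trainCfg = trainConfig(),
                          preSpec = preprocessSpec(targetSize = 64L,
                                                   targetPixelMM = 3),
                          maxPairs = NULL, verbose = FALSE) {
  stopifnot(length(samples) >= 1L)
  set.seed(trainCfg@seed)
  # assemble slice pairs and their fixed SSIM weight maps
  xs <- list(); ys <- list(); ws <- list()
  pairMap <- data.frame(sample = integer(), slice = integer())
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    px <- preprocessVolume(s@cbct, preSpec)$slices
    py <- preprocessVolume(s@registeredCT, preSpec)$slices
    for (k in seq_len(dim(px)[3])) {
      if (!is.null(maxPairs) && length(xs) >= maxPairs) break
      xs[[length(xs) + 1L]] <- px[, , k]
      ys[[length(ys) + 1L]] <- py[, , k]
      ws[[length(ws) + 1L]] <- ssimWeightMap(
        localSSIMMap(px[, , k], py[, , k], lossCfg), lossCfg@alpha)
      pairMap <- rbind(pairMap, data.frame(sample = si, slice = k))
    }
  }
  nPairs <- length(xs)
  perm <- sample.int(nPairs)
  nVal <- floor(trainCfg@valFraction * nPairs)
  valIdx <- if (nVal > 0L) sort(perm[seq_len(nVal)]) else integer()
  trainIdx <- sort(setdiff(perm, valIdx))

  G <- buildGenerator(genSpec, seed = trainCfg@seed + 1L)
  Fb <- buildGenerator(genSpec, seed = trainCfg@seed + 2L)
  DY <- buildDiscriminator(discSpec, seed = trainCfg@seed + 3L)
  DX <- buildDiscriminator(discSpec, seed = trainCfg@seed + 4L)
  optG <- .adamInit(G$params); optF <- .adamInit(Fb$params)
  optDY <- .adamInit(DY$params); optDX <- .adamInit(DX$params)

  hist <- data.frame(epoch = integer(), lr = numeric(), ssimL1 = numeric(),
                     cycle = numeric(), adversarial = numeric(),
                     total = numeric(), discX = numeric(), discY = numeric())
  stack4 <- function(lst, idx)
    array(unlist(lst[idx], use.names = FALSE),
          c(dim(lst[[1]]), 1L, length(idx)))

  for (epoch in seq_len(trainCfg@epochs)) {
    lr <- lrAtEpoch(epoch, trainCfg)
    ord <- sample(trainIdx)
    nb <- ceiling(length(ord) / trainCfg@batchSize)
    acc <- c(ssimL1 = 0, cycle = 0, adversarial = 0, total = 0,
             discX = 0, discY = 0)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * trainCfg@batchSize + 1L):
                   min(bi * trainCfg@batchSize, length(ord))]
      x <- stack4(xs, idx); y <- stack4(ys, idx); w <- stack4(ws, idx)
      nEl <- length(x)

      fG <- .netForward(x, G$ops, G$params)   # fakeY = G(x)
      fF <- .netForward(y, Fb$ops, Fb$params) # fakeX = F(y)
      fakeY <- fG$y; fakeX <- fF$y

      # --- discriminators first ---
      for (du in list(list(net = "DY", real = y, fake = fakeY),
                      list(net = "DX", real = x, fake = fakeX))) {
        net <- if (du$net == "DY") DY else DX
        fr <- .netForward(du$real, net$ops, net$params)
        ff <- .netForward(du$fake, net$ops, net$params)
        nS <- length(fr$y)
        dl <- .checkFinite(mean((fr$y - 1)^2) + mean(ff$y^2),
                           paste0("adversarial/", du$net))
        gr <- .addGrads(
          .netBackward(2 * (fr$y - 1) / nS, net$ops, fr$caches, net$params)$grads,
          .netBackward(2 * ff$y / nS, net$ops, ff$caches, net$params)$grads)
        if (du$net == "DY") {
          st <- .adamStep(DY$params, gr, optDY, lr)
          DY$params <- st$params; optDY <- st$state
          acc["discY"] <- acc["discY"] + dl
        } else {
          st <- .adamStep(DX$params, gr, optDX, lr)
          DX$params <- st$params; optDX <- st$state
          acc["discX"] <- acc["discX"] + dl
        }
      }

      # --- generators ---
      fCyc <- .netForward(fakeY, Fb$ops, Fb$params)  # recX = F(G(x))
      gCyc <- .netForward(fakeX, G$ops, G$params)    # recY = G(F(y))
      recX <- fCyc$y; recY <- gCyc$y
      sY <- .netForward(fakeY, DY$ops, DY$params)
      sX <- .netForward(fakeX, DX$ops, DX$params)

      ssimL1 <- .checkFinite(mean(w * abs(fakeY - y)) + mean(w * abs(fakeX - x)),
                             "ssimWeightedL1")
      cyc <- .checkFinite(mean(abs(recX - x)) + mean(abs(recY - y)), "cycle")
      adv <- .checkFinite(mean((sY$y - 1)^2) + mean((sX$y - 1)^2), "adversarial")
      total <- lossCfg@lambdaSSIM * ssimL1 + lossCfg@lambdaCycle * cyc +
        lossCfg@lambdaAdv * adv

      bG2 <- .netBackward(lossCfg@lambdaCycle * sign(recY - y) / nEl,
                          G$ops, gCyc$caches, G$params)
      bF2 <- .netBackward(lossCfg@lambdaCycle * sign(recX - x) / nEl,
                          Fb$ops, fCyc$caches, Fb$params)
      dFakeY <- lossCfg@lambdaSSIM * w * sign(fakeY - y) / nEl +
        lossCfg@lambdaAdv *
          .netBackward(2 * (sY$y - 1) / length(sY$y), DY$ops, sY$caches,
                       DY$params)$dx +
        bF2$dx
      dFakeX <- lossCfg@lambdaSSIM * w * sign(fakeX - x) / nEl +
        lossCfg@lambdaAdv *
          .netBackward(2 * (sX$y - 1) / length(sX$y), DX$ops, sX$caches,
                       DX$params)$dx +
        bG2$dx
      gradsG <- .addGrads(bG2$grads,
                          .netBackward(dFakeY, G$ops, fG$caches, G$params)$grads)
      gradsF <- .addGrads(bF2$grads,
                          .netBackward(dFakeX, Fb$ops, fF$caches, Fb$params)$grads)
      st <- .adamStep(G$params, gradsG, optG, lr)
      G$params <- st$params; optG <- st$state
      st <- .adamStep(Fb$params, gradsF, optF, lr)
      Fb$params <- st$params; optF <- st$state

      acc[c("ssimL1", "cycle", "adversarial", "total")] <-
        acc[c("ssimL1", "cycle", "adversarial", "total")] +
        c(ssimL1, cyc, adv, total)
    }
    acc <- acc / nb
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   ssimL1 = acc["ssimL1"], cycle = acc["cycle"],
                                   adversarial = acc["adversarial"],
                                   total = acc["total"], discX = acc["discX"],
                                   discY = acc["discY"], row.names = NULL))
    if (verbose)
      message(sprintf("epoch %d/%d lr %.2e total %.4f (ssim %.4f cycle %.4f adv %.4f)",
                      epoch, trainCfg@epochs, lr, acc["total"], acc["ssimL1"],
                      acc["cycle"], acc["adversarial"]))
  }
  model <- list(G = G, F = Fb, DX = DX, DY = DY, genSpec = genSpec,
                discSpec = discSpec, lossCfg = lossCfg, trainCfg = trainCfg,
                preSpec = preSpec, history = hist, valIdx = valIdx,
                pairMap = pairMap, nPairs = nPairs)
  class(model) <- "sctganModel"
  model
}

#' @export
print.sctganModel <- function(x, ...) {
  cat(sprintf("sctganModel: %d epochs on %d slice pairs (%d held out), final total loss %.4f\n",
              nrow(x$history), x$nPairs, length(x$valIdx),
              x$history$total[nrow(x$history)]))
  invisible(x)
}

#' Generate a synthetic CT from a CBCT volume
#'
#' Preprocesses, applies the CBCT-to-CT generator slice by slice, and inverts
#' the preprocessing, so output geometry equals input geometry and output HU
#' lie within the preprocessing window. Deterministic.
#'
#' @param cbct an [ImageVolume-class].
#' @param model an `"sctganModel"` from [trainCycleGAN()].
#' @return The synthetic CT as an [ImageVolume-class].
#' @export
inferSCT <- function(cbct, model) {
  stopifnot(inherits(model, "sctganModel"), is(cbct, "ImageVolume"))
  pre <- preprocessVolume(cbct, model$preSpec)
  d <- dim(pre$slices)
  x <- array(pre$slices, c(d[1], d[2], 1L, d[3]))
  y <- .netForward(x, model$G$ops, model$G$params, keepCache = FALSE)$y
  postprocessSlices(array(y, d), pre$geom)
}

#' Held-out translation quality of a trained model
#'
#' For every held-out slice pair, the body-masked mean absolute HU error of
#' the synthetic CT against the clean CT, next to the same error of the raw
#' CBCT — the improvement the translation is supposed to deliver.
#'
#' @param model an `"sctganModel"`.
#' @param samples the [PairedSample-class] list the model was trained on.
#' @return `data.frame` per held-out slice: `sample`, `slice`, `mae_cbct`,
#'   `mae_sct` (HU).
#' @export
heldOutMAE <- function(model, samples) {
  stopifnot(inherits(model, "sctganModel"), length(model$valIdx) >= 1L)
  sctCache <- list()
  rows <- lapply(model$valIdx, function(i) {
    si <- model$pairMap$sample[i]; k <- model$pairMap$slice[i]
    key <- as.character(si)
    if (is.null(sctCache[[key]]))
      sctCache[[key]] <<- inferSCT(samples[[si]]@cbct, model)
    s <- samples[[si]]
    body <- s@structures[["body"]][, , k]
    clip <- function(v) pmin(pmax(v, model$preSpec@huLow), model$preSpec@huHigh)
    ct <- clip(s@ct@voxels[, , k])
    data.frame(sample = si, slice = k,
               mae_cbct = mean(abs(clip(s@cbct@voxels[, , k]) - ct)[body]),
               mae_sct = mean(abs(sctCache[[key]]@voxels[, , k] - ct)[body]))
  })
  do.call(rbind, rows)
}

#' Structure preservation inside the mismatch region
#'
#' Over all slices containing mismatch voxels, compares the synthetic CT
#' against the CBCT and against the registered CT inside the mismatch mask.
#' A structure-preserving model stays close to the CBCT (which contains the
#' structure) rather than to the registered CT (which lacks it).
#'
#' @param model an `"sctganModel"`.
#' @param samples [PairedSample-class] list.
#' @return `list(maeToCBCT, maeToRegisteredCT)` mean absolute HU differences
#'   inside the mismatch region.
#' @export
mismatchPreservation <- function(model, samples) {
  stopifnot(inherits(model, "sctganModel"))
  dToCB <- c(); dToReg <- c()
  clip <- function(v) pmin(pmax(v, model$preSpec@huLow), model$preSpec@huHigh)
  for (s in samples) {
    if (!any(s@mismatchMask)) next
    sct <- inferSCT(s@cbct, model)
    m <- s@mismatchMask
    dToCB <- c(dToCB, abs(sct@voxels - clip(s@cbct@voxels))[m])
    dToReg <- c(dToReg, abs(sct@voxels - clip(s@registeredCT@voxels))[m])
  }
  if (!length(dToCB)) stop("no mismatch voxels in the supplied samples")
  list(maeToCBCT = mean(dToCB), maeToRegisteredCT = mean(dToReg))
}
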