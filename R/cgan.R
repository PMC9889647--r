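# Conditional adversarial image-to-image network: U-Net generator mapping a
# [S,S,1] normalized BEV dose map to an [S,S,6] MU-weighted aperture stack,
# and a 70x70-receptive-field patch discriminator with spectral
# normalization. Layers are mutable environments; backpropagation is
# hand-derived and exercised against finite differences in the test suite.

EPS_NORM <- 1e-5

# --- layers ----------------------------------------------------------------

new_conv_layer <- function(c_in, c_out, k = 4, s = 2, p = 1,
                           transpose = FALSE, norm = TRUE,
                           act = c("lrelu", "relu", "linear", "tanh"),
                           dropout = 0, sn = FALSE, init_sd = 0.02) {
  act <- match.arg(act)
  e <- new.env(parent = emptyenv())
  e$type <- if (transpose) "convT" else "conv"
  e$k <- k; e$s <- s; e$p <- p
  e$c_in <- c_in; e$c_out <- c_out
  if (transpose) {
    e$W <- matrix(rnorm(c_in * c_out * k * k, 0, init_sd), c_in, c_out * k * k)
  } else {
    e$W <- matrix(rnorm(c_out * c_in * k * k, 0, init_sd), c_out, c_in * k * k)
  }
  e$b <- rep(0, c_out)
  e$norm <- norm
  if (norm) { e$g <- rep(1, c_out); e$beta <- rep(0, c_out) }
  e$act <- act
  e$dropout <- dropout
  e$sn <- sn
  if (sn) e$u <- rnorm(nrow(e$W))
  e
}

sn_weight <- function(ly, update = TRUE) {
  W <- ly$W
  u <- ly$u
  v <- as.numeric(crossprod(W, u)); v <- v / sqrt(sum(v^2) + 1e-12)
  u <- as.numeric(W %*% v); u <- u / sqrt(sum(u^2) + 1e-12)
  sigma <- as.numeric(t(u) %*% W %*% v)
  if (update) ly$u <- u
  list(W_sn = W / sigma, sigma = sigma, u = u, v = v)
}

inorm_fwd <- function(z, g, beta) {
  d <- dim(z); N <- d[1] * d[2]
  zm <- matrix(z, N, d[3])
  mu <- colMeans(zm)
  zc <- sweep(zm, 2, mu)
  v <- colMeans(zc^2)
  invstd <- 1 / sqrt(v + EPS_NORM)
  zhat <- sweep(zc, 2, invstd, "*")
  out <- sweep(sweep(zhat, 2, g, "*"), 2, beta, "+")
  list(out = array(out, d), zhat = zhat, invstd = invstd, d = d)
}

inorm_bwd <- function(gy, cache, g) {
  d <- cache$d; N <- d[1] * d[2]
  gym <- matrix(gy, N, d[3])
  dzhat <- sweep(gym, 2, g, "*")
  s1 <- colMeans(dzhat)
  s2 <- colMeans(dzhat * cache$zhat)
  dz <- sweep(sweep(sweep(dzhat, 2, s1), 1, 1, "*") -
                sweep(cache$zhat, 2, s2, "*"), 2, cache$invstd, "*")
  list(gz = array(dz, d),
       gg = colSums(gym * cache$zhat),
       gbeta = colSums(gym))
}

layer_fwd <- function(ly, x, train = TRUE) {
  W <- ly$W
  snc <- NULL
  if (ly$sn) {
    snc <- sn_weight(ly, update = train)
    W <- snc$W_sn
  }
  if (ly$type == "conv") {
    z <- cpp_conv_fwd(x, W, ly$b, ly$k, ly$s, ly$p)
  } else {
    z <- cpp_convT_fwd(x, W, ly$b, ly$k, ly$s, ly$p,
                       dim(x)[1] * ly$s, dim(x)[2] * ly$s)
  }
  cache <- list(x = x, snc = snc)
  if (ly$norm) {
    nf <- inorm_fwd(z, ly$g, ly$beta)
    cache$norm <- nf[c("zhat", "invstd", "d")]
    z <- nf$out
  }
  cache$pre_act <- z
  h <- switch(ly$act,
              lrelu = { pos <- z > 0; z * (0.2 + 0.8 * pos) },
              relu = z * (z > 0),
              tanh = tanh(z),
              linear = z)
  if (ly$act == "tanh") cache$act_out <- h
  if (train && ly$dropout > 0) {
    keep <- 1 - ly$dropout
    mask <- array(runif(length(h)) < keep, dim(h)) / keep
    cache$mask <- mask
    h <- h * mask
  }
  ly$cache <- cache
  h
}

# returns gradient w.r.t. the layer input; accumulates parameter gradients
# into ly$gW / ly$gb / ly$gg / ly$gbeta
layer_bwd <- function(ly, gy) {
  cache <- ly$cache
  if (!is.null(cache$mask)) gy <- gy * cache$mask
  z <- cache$pre_act
  gz <- switch(ly$act,
               lrelu = gy * (0.2 + 0.8 * (z > 0)),
               relu = gy * (z > 0),
               tanh = gy * (1 - cache$act_out^2),
               linear = gy)
  if (ly$norm) {
    nb <- inorm_bwd(gz, cache$norm, ly$g)
    gz <- nb$gz
    ly$gg <- ly$gg + nb$gg
    ly$gbeta <- ly$gbeta + nb$gbeta
  }
  W <- if (ly$sn) cache$snc$W_sn else ly$W
  if (ly$type == "conv") {
    r <- cpp_conv_bwd(cache$x, W, gz, ly$k, ly$s, ly$p)
  } else {
    r <- cpp_convT_bwd(cache$x, W, gz, ly$k, ly$s, ly$p)
  }
  gW <- r$gW
  if (ly$sn) {
    snc <- cache$snc
    gW <- (gW - sum(gW * snc$W_sn) * (snc$u %o% snc$v)) / snc$sigma
  }
  ly$gW <- ly$gW + gW
  ly$gb <- ly$gb + as.numeric(r$gb)
  r$gx
}

zero_grads <- function(layers) {
  for (ly in layers) {
    ly$gW <- ly$W * 0
    ly$gb <- ly$b * 0
    if (ly$norm) { ly$gg <- ly$g * 0; ly$gbeta <- ly$beta * 0 }
  }
  invisible(NULL)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  for (ly in layers) {
    ly$adam <- list()
    for (p in c("W", "b", if (isTRUE(ly$norm)) c("g", "beta"))) {
      ly$adam[[p]] <- list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    }
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, beta1, beta2, t, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (ly in layers) {
    for (p in c("W", "b", if (isTRUE(ly$norm)) c("g", "beta"))) {
      gname <- paste0("g", if (p == "g") "g" else p)
      st <- ly$adam[[p]]
      cpp_adam_step(ly[[p]], ly[[gname]], st$m, st$v, lr, beta1, beta2,
                    b1t, b2t, eps)
    }
  }
  invisible(NULL)
}

# --- generator -------------------------------------------------------------

build_generator <- function(size, n_down, base_filters, out_channels = 6,
                            dropout = 0.5) {
  stopifnot(size %% (2^n_down) == 0 || size == 2^n_down)
  nf <- pmin(base_filters * 2^(0:(n_down - 1)), base_filters * 8)
  downs <- vector("list", n_down)
  c_prev <- 1
  for (i in seq_len(n_down)) {
    sp_out <- size / 2^i
    downs[[i]] <- new_conv_layer(c_prev, nf[i],
                                 norm = (i > 1 && sp_out > 1),
                                 act = "lrelu")
    c_prev <- nf[i]
  }
  ups <- vector("list", n_down)
  for (j in seq_len(n_down)) {
    # up j consumes the previous up's output concatenated with the mirrored
    # down block's output (both nf[n_down - j + 1] channels)
    c_in <- if (j == 1) nf[n_down] else 2 * nf[n_down - j + 1]
    c_out <- if (j == n_down) out_channels else nf[n_down - j]
    ups[[j]] <- new_conv_layer(c_in, c_out, transpose = TRUE,
                               norm = (j < n_down),
                               act = if (j < n_down) "relu" else "tanh",
                               dropout = if (j <= 3 && j < n_down) dropout else 0)
  }
  list(downs = downs, ups = ups, n_down = n_down, size = size,
       out_channels = out_channels)
}

cat_cubes <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

gen_forward <- function(G, x, train = TRUE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  n <- G$n_down
  d_out <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    h <- layer_fwd(G$downs[[i]], h, train)
    d_out[[i]] <- h
  }
  for (j in seq_len(n)) {
    inp <- if (j == 1) d_out[[n]] else cat_cubes(h, d_out[[n - j + 1]])
    h <- layer_fwd(G$ups[[j]], inp, train)
  }
  h
}

gen_backward <- function(G, gy) {
  n <- G$n_down
  gskip <- vector("list", n)
  g <- gy
  for (j in n:1) {
    gin <- layer_bwd(G$ups[[j]], g)
    if (j == 1) {
      gskip[[n]] <- if (is.null(gskip[[n]])) gin else gskip[[n]] + gin
    } else {
      c_prev <- G$ups[[j - 1]]$c_out
      g <- gin[, , seq_len(c_prev), drop = FALSE]
      sk <- gin[, , (c_prev + 1):dim(gin)[3], drop = FALSE]
      i <- n - j + 1
      gskip[[i]] <- if (is.null(gskip[[i]])) sk else gskip[[i]] + sk
    }
  }
  g <- gskip[[n]]
  for (i in n:1) {
    gin <- layer_bwd(G$downs[[i]], g)
    if (i > 1) {
      g <- gin
      if (!is.null(gskip[[i - 1]])) g <- g + gskip[[i - 1]]
    }
  }
  invisible(NULL)
}

# --- discriminator ---------------------------------------------------------

build_discriminator <- function(in_channels = 7, base_filters = 64,
                                size = 128) {
  db <- base_filters
  # three stride-2 blocks give the 70x70 receptive field; shrink for tiny
  # inputs so the patch grid never collapses below 2x2
  n_s2 <- min(3, max(1, floor(log2(size)) - 3))
  layers <- list(new_conv_layer(in_channels, db, s = 2, norm = FALSE,
                                act = "lrelu", sn = TRUE))
  c_prev <- db
  for (i in seq_len(n_s2 - 1)) {
    layers <- c(layers, list(new_conv_layer(c_prev, c_prev * 2, s = 2,
                                            norm = TRUE, act = "lrelu",
                                            sn = TRUE)))
    c_prev <- c_prev * 2
  }
  layers <- c(layers,
              list(new_conv_layer(c_prev, c_prev * 2, s = 1, norm = TRUE,
                                  act = "lrelu", sn = TRUE),
                   new_conv_layer(c_prev * 2, 1, s = 1, norm = FALSE,
                                  act = "linear", sn = TRUE)))
  list(layers = layers)
}

disc_forward <- function(D, x, y, train = TRUE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  h <- cat_cubes(x, y)
  for (ly in D$layers) h <- layer_fwd(ly, h, train)
  h  # logits, patch grid
}

disc_backward <- function(D, gz) {
  g <- gz
  for (ly in rev(D$layers)) g <- layer_bwd(ly, g)
  g  # gradient w.r.t. the concatenated input
}

# --- losses and labels -----------------------------------------------------

#' Adversarial (conditional GAN) loss from discriminator scores
#'
#' Binary cross-entropy of patch probability scores against (possibly soft,
#' possibly flipped) labels, summed over the real and fake terms:
#' the discriminator maximizes `log D(x, y) + log(1 - D(x, G(x)))`.
#'
#' @param d_real,d_fake Discriminator probability grids for real and
#'   generated pairs.
#' @param labels_real,labels_fake Label grids (or scalars), broadcast to the
#'   score shape.
#' @return Scalar loss (mean per grid, summed over the two terms).
#' @export
cgan_loss <- function(d_real, d_fake, labels_real = 1, labels_fake = 0) {
  bce <- function(p, t) {
    if (length(t) == 1) t <- array(t, dim(p) %||% length(p))
    if (!is.null(dim(p)) && !identical(dim(p), dim(t))) {
      stop("score and label grids have different shapes")
    }
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    -mean(t * log(p) + (1 - t) * log(1 - p))
  }
  bce(d_real, labels_real) + bce(d_fake, labels_fake)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full generator objective
#'
#' Adversarial term plus `lambda_l1` times the mean absolute error between
#' predicted and ground-truth aperture stacks.
#' @param l1 Mean absolute error term.
#' @param adv Adversarial loss term.
#' @param lambda_l1 Weight on the L1 term.
#' @return Scalar objective.
#' @export
generator_objective <- function(l1, adv, lambda_l1 = 100) {
  stopifnot(lambda_l1 >= 0)
  adv + lambda_l1 * l1
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate. The default is the standard value
#'   for this architecture family; see the methods vignette for alternatives.
#' @param beta1,beta2 Adam moment decay rates.
#' @param lambda_l1 Weight of the L1 term in the generator objective.
#' @param label_real,label_fake Soft-label ranges for real/fake patches; all
#'   labels stay within `[0, 1.2]`.
#' @param flip_prob Probability that a sample's real/fake labels are swapped
#'   (noisy labels).
#' @param base_filters,base_filters_d First-layer channel counts of generator
#'   and discriminator.
#' @param n_down Number of generator down-sampling blocks.
#' @param dropout Generator dropout rate, the stochasticity source.
#' @param seed Training seed.
#' @export
train_config <- function(epochs = 200, learning_rate = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, lambda_l1 = 100,
                         label_real = c(0.8, 1.2), label_fake = c(0, 0.2),
                         flip_prob = 0.05, base_filters = 64,
                         base_filters_d = 64, n_down = 6, dropout = 0.5,
                         seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, beta1 > 0, beta2 > 0,
            lambda_l1 >= 0, flip_prob >= 0, flip_prob < 0.5, dropout > 0)
  as.list(environment())
}

#' Generate (soft, noisy) discriminator labels
#'
#' Real labels are drawn uniformly from `label_real`, fake labels from
#' `label_fake`; with probability `flip_prob` the sample is mislabeled (its
#' labels are drawn from the other class's range). The flip decision is made
#' once per call and recorded in the `"flipped"` attribute.
#'
#' @param shape Dimensions of the label grid.
#' @param kind `"real"` or `"fake"`.
#' @param config A [train_config()].
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A label array with attribute `flipped`.
#' @export
make_labels <- function(shape, kind = c("real", "fake"),
                        config = train_config(), seed = NULL) {
  kind <- match.arg(kind)
  gen <- function() {
    flipped <- runif(1) < config$flip_prob
    eff <- if (flipped) setdiff(c("real", "fake"), kind) else kind
    rng <- if (eff == "real") config$label_real else config$label_fake
    lab <- array(runif(prod(shape), rng[1], rng[2]), shape)
    attr(lab, "flipped") <- flipped
    lab
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# --- model -----------------------------------------------------------------

#' Build an untrained conditional adversarial model
#'
#' @param size Input/output raster size (pixels per side).
#' @param config A [train_config()].
#' @return A `cgan_model` (untrained).
#' @export
cgan_model <- function(size = 128, config = train_config()) {
  n_down <- min(config$n_down, as.integer(log2(size)))
  model <- with_seed(derive_seed(config$seed, "init"), {
    G <- build_generator(size, n_down, config$base_filters,
                         dropout = config$dropout)
    D <- build_discriminator(7, config$base_filters_d, size)
    list(G = G, D = D)
  })
  structure(list(G = model$G, D = model$D, size = size, config = config,
                 history = NULL, trained = FALSE),
            class = "cgan_model")
}

#' @export
print.cgan_model <- function(x, ...) {
  cat(sprintf("<cgan_model> %dx%d, %d down blocks, %s\n", x$size, x$size,
              x$G$n_down,
              if (x$trained) sprintf("trained %d epochs", length(x$history$g_loss))
              else "untrained"))
  invisible(x)
}

#' Train the conditional adversarial network
#'
#' Alternating discriminator/generator updates with Adam, soft noisy labels
#' and spectral normalization in the discriminator. The generator minimizes
#' the adversarial cross-entropy plus `lambda_l1` times the L1 error; the
#' discriminator minimizes binary cross-entropy of its patch scores.
#' Deterministic given `config$seed`.
#'
#' @param pairs A [build_training_pairs()] result, or a plain list of
#'   `list(x = matrix, y = array)` pairs.
#' @param config A [train_config()].
#' @param split Optional [make_loocv_splits()] element; trains on
#'   `split$train` indices only.
#' @param model Optional existing [cgan_model()] to continue training.
#' @param verbose Print per-epoch losses.
#' @return A trained `cgan_model` with `history` (per-epoch G and D losses).
#' @export
train_cgan <- function(pairs, config = train_config(), split = NULL,
                       model = NULL, verbose = FALSE) {
  plist <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  if (!is.null(split)) plist <- plist[split$train]
  n <- length(plist)
  if (n == 0) stop("empty training set")
  size <- nrow(plist[[1]]$x)
  if (is.null(model)) model <- cgan_model(size, config)
  G <- model$G; D <- model$D
  all_layers_g <- c(G$downs, G$ups)
  all_layers_d <- D$layers
  adam_init(all_layers_g)
  adam_init(all_layers_d)
  g_hist <- d_hist <- numeric(config$epochs)
  t_g <- t_d <- 0L
  sig <- function(z) 1 / (1 + exp(-z))
  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      gl_ep <- dl_ep <- 0
      for (i in ord) {
        # images live in [-1, 1] inside the network (tanh output range);
        # the background of an aperture stack maps to the lower rail
        x <- array(2 * plist[[i]]$x - 1, c(size, size, 1L))
        y <- array(2 * plist[[i]]$y - 1, c(size, size, 6L))
        yhat <- gen_forward(G, x, train = TRUE)
        # discriminator update (generator output detached)
        zero_grads(all_layers_d)
        z_r <- disc_forward(D, x, y, train = TRUE)
        lab_r <- make_labels(dim(z_r), "real", config)
        disc_backward(D, (sig(z_r) - lab_r) / length(z_r))
        loss_d <- mean(log1p(exp(-abs(z_r))) + pmax(z_r, 0) - lab_r * z_r)
        z_f <- disc_forward(D, x, yhat, train = TRUE)
        lab_f <- make_labels(dim(z_f), "fake", config)
        disc_backward(D, (sig(z_f) - lab_f) / length(z_f))
        loss_d <- loss_d +
          mean(log1p(exp(-abs(z_f))) + pmax(z_f, 0) - lab_f * z_f)
        t_d <- t_d + 1L
        adam_step(all_layers_d, config$learning_rate, config$beta1,
                  config$beta2, t_d)
        # generator update (through the refreshed discriminator)
        zero_grads(all_layers_g)
        zero_grads(all_layers_d)
        z_f2 <- disc_forward(D, x, yhat, train = TRUE)
        g_in <- disc_backward(D, (sig(z_f2) - 1) / length(z_f2))
        g_adv <- g_in[, , 2:7, drop = FALSE]
        l1 <- mean(abs(yhat - y))
        g_l1 <- config$lambda_l1 * sign(yhat - y) / length(yhat)
        gen_backward(G, g_adv + g_l1)
        t_g <- t_g + 1L
        adam_step(all_layers_g, config$learning_rate, config$beta1,
                  config$beta2, t_g)
        loss_g <- generator_objective(
          l1, mean(log1p(exp(-abs(z_f2))) + pmax(z_f2, 0) - z_f2),
          config$lambda_l1)
        gl_ep <- gl_ep + loss_g / n
        dl_ep <- dl_ep + loss_d / n
      }
      if (!is.finite(gl_ep) || !is.finite(dl_ep)) {
        stop(sprintf("non-finite loss at epoch %d (G %.3g, D %.3g)",
                     ep, gl_ep, dl_ep))
      }
      g_hist[ep] <- gl_ep
      d_hist[ep] <- dl_ep
      if (verbose) message(sprintf("epoch %3d  G %.4f  D %.4f", ep, gl_ep,
                                   dl_ep))
    }
  })
  model$G <- G; model$D <- D
  model$history <- list(g_loss = g_hist, d_loss = d_hist)
  model$trained <- TRUE
  model
}

#' Predict an aperture stack from a normalized BEV dose map
#'
#' Inference-mode forward pass (dropout disabled) with non-negativity
#' enforced by clipping at zero. Deterministic.
#'
#' @param model A [cgan_model()] (usually trained).
#' @param dose_map A [normalize_resample()] result or a matrix with values
#'   in `[0, 1]`.
#' @param mu_scale Optional MU normalization constant to carry along.
#' @return A continuous-valued `aperture_stack`.
#' @export
predict_apertures <- function(model, dose_map, mu_scale = NA_real_,
                              extent_x = NULL, extent_y = NULL) {
  px <- if (inherits(dose_map, "dose_map2d")) dose_map$pixels else dose_map
  if (max(px) > 1 + 1e-6) {
    stop("input dose map is not normalized (max > 1); run normalize_resample")
  }
  ch <- (gen_forward(model$G, 2 * px - 1, train = FALSE) + 1) / 2
  ch[ch < 0] <- 0
  structure(list(channels = ch, mu_scale = mu_scale,
                 n_real_segments = NA_integer_, gantry = NA_real_,
                 extent_x = extent_x, extent_y = extent_y),
            class = "aperture_stack")
}

#' Patient-based leave-one-out cross-validation splits
#'
#' One split per patient. The training set holds all beams of the other
#' patients plus exactly one fraction (the first) of the held-out patient, so
#' the model can learn to replan from a prior plan; the remaining fractions
#' of the held-out patient form the test set.
#'
#' @param meta A `pair_set` (or its `meta` data.frame with `patient_id` and
#'   `fraction` columns).
#' @param retain_fraction The held-out patient's fraction kept in training.
#' @return A list of splits: `held_out_patient`, `train`, `test` (indices).
#' @export
make_loocv_splits <- function(meta, retain_fraction = 1L) {
  if (inherits(meta, "pair_set")) meta <- meta$meta
  patients <- unique(meta$patient_id)
  if (length(patients) < 2) stop("need at least 2 patients for LOOCV")
  for (p in patients) {
    if (length(unique(meta$fraction[meta$patient_id == p])) < 2) {
      stop(sprintf("patient %s has fewer than 2 fractions", p))
    }
  }
  lapply(patients, function(p) {
    held <- meta$patient_id == p
    test <- which(held & meta$fraction != retain_fraction)
    train <- which(!held | meta$fraction == retain_fraction)
    list(held_out_patient = p, train = train, test = test)
  })
}
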