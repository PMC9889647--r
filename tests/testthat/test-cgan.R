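ns <- asNamespace("leafseq")

test_that("adversarial loss matches hand-computed values on toy grids", {
  # perfect discriminator with hard labels: loss 0
  r <- matrix(1 - 1e-7, 2, 2)
  f <- matrix(1e-7, 2, 2)
  expect_lt(cgan_loss(r, f, 1, 0), 1e-5)
  # maximally uncertain discriminator: log 2 per term
  h <- matrix(0.5, 2, 2)
  expect_equal(cgan_loss(h, h, 1, 0), 2 * log(2), tolerance = 1e-12)
  # hand-computed 2x2 case with soft labels
  p_r <- matrix(c(0.9, 0.8, 0.6, 0.7), 2)
  p_f <- matrix(c(0.2, 0.1, 0.3, 0.4), 2)
  t_r <- matrix(1.1, 2, 2)
  t_f <- matrix(0.1, 2, 2)
  by_hand <- -mean(t_r * log(p_r) + (1 - t_r) * log(1 - p_r)) -
    mean(t_f * log(p_f) + (1 - t_f) * log(1 - p_f))
  expect_equal(cgan_loss(p_r, p_f, t_r, t_f), by_hand, tolerance = 1e-12)
  expect_error(cgan_loss(matrix(0.5, 2, 2), h, matrix(1, 3, 3), 0),
               "shapes")
})

test_that("loss gradient matches finite differences", {
  set.seed(1)
  p <- matrix(runif(9, 0.1, 0.9), 3)
  t <- matrix(runif(9, 0, 1.2), 3)
  f <- matrix(0.5, 3, 3)
  analytic <- (-t / p + (1 - t) / (1 - p)) / length(p)
  eps <- 1e-6
  for (i in c(1, 5, 9)) {
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    fd <- (cgan_loss(pp, f, t, 0) - cgan_loss(pm, f, t, 0)) / (2 * eps)
    expect_equal(fd, analytic[i], tolerance = 1e-4)
  }
})

test_that("generator objective weights the L1 term linearly", {
  expect_equal(generator_objective(0.3, 1.2, 0), 1.2)
  expect_equal(generator_objective(0, 1.2, 100), 1.2)
  l0 <- generator_objective(0.3, 1.2, 50)
  l1 <- generator_objective(0.3, 1.2, 100)
  expect_equal(l1 - 1.2, 2 * (l0 - 1.2), tolerance = 1e-12)
})

test_that("soft labels stay in range and flip at the configured rate", {
  cfg <- train_config(epochs = 1, flip_prob = 0)
  lr <- make_labels(c(4, 4, 1), "real", cfg, seed = 1)
  expect_true(all(lr >= 0.8 & lr <= 1.2))
  lf <- make_labels(c(4, 4, 1), "fake", cfg, seed = 2)
  expect_true(all(lf >= 0 & lf <= 0.2))
  # all labels stay within [0, 1.2] even with flipping on
  cfg2 <- train_config(epochs = 1, flip_prob = 0.3)
  set.seed(3)
  n <- 2500
  labs <- replicate(n, make_labels(c(2, 2, 1), "real", cfg2),
                    simplify = FALSE)
  expect_true(all(vapply(labs, function(l) all(l >= 0 & l <= 1.2), TRUE)))
  n_flip <- sum(vapply(labs, function(l) attr(l, "flipped"), TRUE))
  sd3 <- 3 * sqrt(n * 0.3 * 0.7)
  expect_lt(abs(n_flip - n * 0.3), sd3)
})

test_that("network gradients agree with finite differences", {
  set.seed(3)
  size <- 16
  model <- cgan_model(size, tiny_train_config())
  G <- model$G
  x <- matrix(runif(size * size), size)
  y <- array(runif(size * size * 6), c(size, size, 6))
  loss_fn <- function() mean(abs(ns$gen_forward(G, x, train = FALSE) - y))
  ns$zero_grads(c(G$downs, G$ups))
  yhat <- ns$gen_forward(G, x, train = FALSE)
  ns$gen_backward(G, sign(yhat - y) / length(yhat))
  fd_check <- function(ly, pname, idx) {
    eps <- 1e-5
    orig <- ly[[pname]][idx]
    ly[[pname]][idx] <- orig + eps; lp <- loss_fn()
    ly[[pname]][idx] <- orig - eps; lm <- loss_fn()
    ly[[pname]][idx] <- orig
    fd <- (lp - lm) / (2 * eps)
    an <- ly[[paste0("g", if (pname == "g") "g" else pname)]][idx]
    expect_equal(an, fd, tolerance = 1e-4)
  }
  fd_check(G$downs[[1]], "W", 5)
  fd_check(G$downs[[2]], "W", 17)
  fd_check(G$downs[[2]], "g", 2)
  fd_check(G$ups[[2]], "W", 11)
  fd_check(G$ups[[3]], "b", 3)
  # discriminator, including the spectral-norm chain and the input gradient
  D <- model$D
  sig <- function(z) 1 / (1 + exp(-z))
  d_loss <- function() {
    z <- ns$disc_forward(D, x, y, train = FALSE)
    mean(log1p(exp(-abs(z))) + pmax(z, 0) - z)
  }
  ns$zero_grads(D$layers)
  z <- ns$disc_forward(D, x, y, train = FALSE)
  gin <- ns$disc_backward(D, (sig(z) - 1) / length(z))
  fd_check_d <- function(ly, pname, idx) {
    eps <- 1e-5
    orig <- ly[[pname]][idx]
    ly[[pname]][idx] <- orig + eps; lp <- d_loss()
    ly[[pname]][idx] <- orig - eps; lm <- d_loss()
    ly[[pname]][idx] <- orig
    expect_equal(ly[[paste0("g", if (pname == "g") "g" else pname)]][idx],
                 (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
  fd_check_d(D$layers[[1]], "W", 7)
  fd_check_d(D$layers[[2]], "W", 30)
  fd_check_d(D$layers[[3]], "W", 3)
  eps <- 1e-5
  yy <- y; yy[100] <- y[100] + eps
  lp <- { ytmp <- yy; zz <- ns$disc_forward(D, x, ytmp, train = FALSE)
          mean(log1p(exp(-abs(zz))) + pmax(zz, 0) - zz) }
  yy[100] <- y[100] - eps
  lm <- { ytmp <- yy; zz <- ns$disc_forward(D, x, ytmp, train = FALSE)
          mean(log1p(exp(-abs(zz))) + pmax(zz, 0) - zz) }
  expect_equal(gin[, , 2:7][100], (lp - lm) / (2 * eps), tolerance = 1e-4)
})

test_that("one training epoch runs end to end with finite losses", {
  set.seed(5)
  mk_pair <- function(i) {
    list(x = matrix(runif(16 * 16), 16),
         y = array(runif(16 * 16 * 6, 0, 0.5), c(16, 16, 6)))
  }
  pairs <- lapply(1:4, mk_pair)
  model <- train_cgan(pairs, tiny_train_config(seed = 9))
  expect_true(all(is.finite(model$history$g_loss)))
  expect_true(all(is.finite(model$history$d_loss)))
  expect_length(model$history$g_loss, 1)
  expect_error(train_cgan(list(), tiny_train_config()), "empty")
})

test_that("training is reproducible under a fixed seed", {
  set.seed(6)
  pairs <- lapply(1:3, function(i)
    list(x = matrix(runif(16 * 16), 16),
         y = array(runif(16 * 16 * 6, 0, 0.5), c(16, 16, 6))))
  m1 <- train_cgan(pairs, tiny_train_config(epochs = 2, seed = 4))
  m2 <- train_cgan(pairs, tiny_train_config(epochs = 2, seed = 4))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$G$downs[[1]]$W, m2$G$downs[[1]]$W)
})

test_that("the generator can memorize a small training set", {
  # overfit sanity oracle: with the L1-dominated objective the network must
  # reproduce a handful of targets almost exactly
  set.seed(7)
  size <- 32
  mkblob <- function(cx, cy, r, val) {
    xs <- seq_len(size)
    m <- outer((xs - cx)^2, (xs - cy)^2, "+") <= r^2
    m * val
  }
  pairs <- lapply(1:6, function(i) {
    x <- mkblob(8 + 2 * i, 16, 6, 1)
    y <- array(0, c(size, size, 6))
    y[, , 1] <- mkblob(8 + 2 * i, 16, 5, 0.8)
    if (i %% 2 == 0) y[, , 2] <- mkblob(8 + 2 * i, 20, 3, 0.4)
    list(x = x, y = y)
  })
  cfg <- train_config(epochs = 150, base_filters = 8, base_filters_d = 4,
                      n_down = 5, seed = 11)
  model <- train_cgan(pairs, cfg)
  maes <- vapply(pairs, function(p) {
    pred <- predict_apertures(model, p$x)
    mean(abs(pred$channels - p$y))
  }, 1)
  expect_lt(mean(maes), 0.05)
})

test_that("prediction is deterministic, clipped, and validates input", {
  set.seed(8)
  model <- cgan_model(16, tiny_train_config())
  x <- matrix(runif(256), 16)
  p1 <- predict_apertures(model, x)
  p2 <- predict_apertures(model, x)
  expect_identical(p1$channels, p2$channels)
  expect_equal(dim(p1$channels), c(16, 16, 6))
  expect_true(all(p1$channels >= 0))
  expect_error(predict_apertures(model, x * 3), "not normalized")
})

test_that("LOOCV splits partition the cohort with one retained fraction", {
  meta <- expand.grid(beam = 1:11, fraction = 1:5,
                      patient_id = sprintf("p%02d", 1:10),
                      stringsAsFactors = FALSE)
  fake <- structure(list(meta = meta, pairs = vector("list", nrow(meta))),
                    class = "pair_set")
  splits <- make_loocv_splits(fake)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(sp$test, 44)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(nrow(meta)))
    held <- unique(meta$patient_id[sp$test])
    expect_equal(as.character(held), sp$held_out_patient)
    retained <- meta$fraction[sp$train[meta$patient_id[sp$train] ==
                                         sp$held_out_patient]]
    expect_true(all(retained == 1))
  }
  one <- fake; one$meta <- meta[meta$patient_id == "p01", ]
  expect_error(make_loocv_splits(one), "at least 2 patients")
})
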