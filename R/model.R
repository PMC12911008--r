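#' Configuration of the fusion classifier
#'
#' Architecture and training schedule of the four-channel network:
#' connectivity channel Conv1D (`conv_filters` filters, kernel
#' `conv_kernel`, stride `conv_stride`) over the ordered upper-triangle
#' vector, max-pooling of size `pool_size`, dense `conv_to_dense`; graph
#' channel dense `graph_widths` over the 12 graph metrics; motor and
#' cognitive channels dense `behavior_dense` each; concatenated channel
#' outputs pass through a fusion MLP of widths `fusion_widths` with dropout,
#' ending in a single logit. Training uses binary cross-entropy, the Adam
#' optimizer at `learning_rate`, batches of `batch_size`, at most
#' `max_epochs` epochs with early stopping after `early_stop_patience`
#' epochs without validation-loss improvement (best weights restored).
#'
#' @param variant `"multimodal"` (all four channels),
#'   `"connectivity_only"` (connectivity + graph) or `"behavioral_only"`
#'   (motor + cognitive).
#' @param conv_filters,conv_kernel,conv_stride,pool_size,conv_to_dense
#'   Connectivity-channel sizes (defaults 128 / 7 / 1 / 4 / 64).
#' @param graph_widths Graph-channel dense widths (default `c(32, 16)`).
#' @param behavior_dense Motor/cognitive channel width (default 32).
#' @param fusion_widths Fusion MLP widths (default `c(128, 64, 32)`).
#' @param dropout_rate Dropout on the first two fusion layers (default 0.3).
#' @param learning_rate,batch_size,max_epochs,early_stop_patience Training
#'   schedule (defaults 0.001 / 32 / 100 / 10).
#' @param seed Integer seed; training is fully deterministic given data,
#'   config and seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("multimodal", "connectivity_only",
                                     "behavioral_only"),
                         conv_filters = 128L, conv_kernel = 7L,
                         conv_stride = 1L, pool_size = 4L,
                         conv_to_dense = 64L, graph_widths = c(32L, 16L),
                         behavior_dense = 32L, fusion_widths = c(128L, 64L, 32L),
                         dropout_rate = 0.3, learning_rate = 0.001,
                         batch_size = 32L, max_epochs = 100L,
                         early_stop_patience = 10L, seed = 1L) {
  variant <- match.arg(variant)
  cfg <- list(variant = variant, conv_filters = conv_filters,
              conv_kernel = conv_kernel, conv_stride = conv_stride,
              pool_size = pool_size, conv_to_dense = conv_to_dense,
              graph_widths = graph_widths, behavior_dense = behavior_dense,
              fusion_widths = fusion_widths, dropout_rate = dropout_rate,
              learning_rate = learning_rate, batch_size = batch_size,
              max_epochs = max_epochs, early_stop_patience = early_stop_patience,
              seed = as.integer(seed))
  if (any(unlist(cfg[c("conv_filters", "conv_kernel", "conv_stride",
                       "pool_size", "conv_to_dense", "graph_widths",
                       "behavior_dense", "fusion_widths")]) <= 0))
    stop("all widths must be positive")
  if (early_stop_patience >= max_epochs) stop("patience must be below max_epochs")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  class(cfg) <- "model_config"
  cfg
}

#' Per-participant feature bundle
#'
#' The concatenable feature channels the classifier consumes: the ordered
#' upper-triangle connectivity vector, the 12 graph metrics, 16 motor scores
#' and 12 cognitive scores, with a feature-group index map for importance
#' bookkeeping.
#'
#' @param conn n x P(P-1)/2 matrix of connectivity features.
#' @param graph n x 12 matrix of graph metrics.
#' @param motor n x 16 matrix of motor scores.
#' @param cog n x 12 matrix of cognitive scores.
#' @param participant Participant ids (length n).
#' @return Object of class `feature_bundle`: list of the four channel
#'   matrices plus `participant`.
#' @export
feature_bundle <- function(conn, graph, motor, cog, participant) {
  ns <- c(nrow(conn), nrow(graph), nrow(motor), nrow(cog), length(participant))
  if (length(unique(ns)) != 1L) stop("channel row counts must agree")
  if (ncol(graph) != 12L) stop("graph channel must have exactly 12 features")
  out <- list(conn = as.matrix(conn), graph = as.matrix(graph),
              motor = as.matrix(motor), cog = as.matrix(cog),
              participant = participant)
  class(out) <- "feature_bundle"
  out
}

#' Channels consumed by each model variant
#' @param variant Model variant string.
#' @return Character vector of channel names.
#' @export
variant_channels <- function(variant) {
  switch(variant,
         multimodal = c("conn", "graph", "motor", "cog"),
         connectivity_only = c("conn", "graph"),
         behavioral_only = c("motor", "cog"),
         stop("unknown variant"))
}

#' Subset a feature bundle by row
#' @param bundle A [feature_bundle()].
#' @param idx Row indices.
#' @return The sub-bundle.
#' @export
bundle_rows <- function(bundle, idx) {
  feature_bundle(bundle$conn[idx, , drop = FALSE],
                 bundle$graph[idx, , drop = FALSE],
                 bundle$motor[idx, , drop = FALSE],
                 bundle$cog[idx, , drop = FALSE],
                 bundle$participant[idx])
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

conv_geometry <- function(L, cfg) {
  Lc <- (L - cfg$conv_kernel) %/% cfg$conv_stride + 1L
  if (Lc < cfg$pool_size) stop("connectivity vector too short for conv/pool sizes")
  Lp <- Lc %/% cfg$pool_size
  list(Lc = Lc, Lp = Lp, flat = Lp * cfg$conv_filters)
}

init_params <- function(cfg, dims) {
  p <- list()
  fusion_in <- 0L
  ch <- variant_channels(cfg$variant)
  if ("conn" %in% ch) {
    geo <- conv_geometry(dims$conn, cfg)
    p$convK <- he_init(cfg$conv_kernel, cfg$conv_filters)
    p$convb <- numeric(cfg$conv_filters)
    p$connW <- he_init(geo$flat, cfg$conv_to_dense)
    p$connb <- numeric(cfg$conv_to_dense)
    fusion_in <- fusion_in + cfg$conv_to_dense
  }
  if ("graph" %in% ch) {
    p$graphW1 <- he_init(dims$graph, cfg$graph_widths[1])
    p$graphb1 <- numeric(cfg$graph_widths[1])
    p$graphW2 <- he_init(cfg$graph_widths[1], cfg$graph_widths[2])
    p$graphb2 <- numeric(cfg$graph_widths[2])
    fusion_in <- fusion_in + cfg$graph_widths[2]
  }
  if ("motor" %in% ch) {
    p$motorW <- he_init(dims$motor, cfg$behavior_dense)
    p$motorb <- numeric(cfg$behavior_dense)
    fusion_in <- fusion_in + cfg$behavior_dense
  }
  if ("cog" %in% ch) {
    p$cogW <- he_init(dims$cog, cfg$behavior_dense)
    p$cogb <- numeric(cfg$behavior_dense)
    fusion_in <- fusion_in + cfg$behavior_dense
  }
  widths <- c(fusion_in, cfg$fusion_widths)
  for (l in seq_along(cfg$fusion_widths)) {
    p[[paste0("fusW", l)]] <- he_init(widths[l], widths[l + 1])
    p[[paste0("fusb", l)]] <- numeric(widths[l + 1])
  }
  p$outW <- he_init(widths[length(widths)], 1L)
  p$outb <- 0
  p
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))

dense_fwd <- function(x, W, b, relu = TRUE) {
  z <- add_bias(x %*% W, b)
  list(a = if (relu) pmax(z, 0) else z, z = z)
}

conv_fwd <- function(X, cfg, p) {
  # compiled Conv1D + ReLU + non-overlapping max pool, then a dense layer
  cp <- .conv_pool_fwd_cpp(X, p$convK, p$convb,
                           as.integer(cfg$conv_stride),
                           as.integer(cfg$pool_size))
  d <- dense_fwd(cp$flat, p$connW, p$connb)
  list(out = d$a, cache = list(X = X, flat = cp$flat, amax = cp$amax,
                               dz_dense = d$z))
}

conv_bwd <- function(dout, cfg, p, cache) {
  gr <- list()
  dflatz <- dout * (cache$dz_dense > 0)
  gr$connW <- crossprod(cache$flat, dflatz)
  gr$connb <- colSums(dflatz)
  dflat <- dflatz %*% t(p$connW)
  cb <- .conv_pool_bwd_cpp(cache$X, dflat, cache$amax,
                           as.integer(cfg$conv_kernel),
                           as.integer(cfg$conv_filters),
                           as.integer(cfg$conv_stride))
  gr$convK <- cb$dK
  gr$convb <- as.numeric(cb$db)
  gr
}

model_forward <- function(p, cfg, bundle, training = FALSE) {
  ch <- variant_channels(cfg$variant)
  outs <- list(); caches <- list()
  if ("conn" %in% ch) {
    cv <- conv_fwd(bundle$conn, cfg, p)
    outs$conn <- cv$out; caches$conn <- cv$cache
  }
  if ("graph" %in% ch) {
    g1 <- dense_fwd(bundle$graph, p$graphW1, p$graphb1)
    g2 <- dense_fwd(g1$a, p$graphW2, p$graphb2)
    outs$graph <- g2$a; caches$graph <- list(g1 = g1, g2 = g2)
  }
  if ("motor" %in% ch) {
    mo <- dense_fwd(bundle$motor, p$motorW, p$motorb)
    outs$motor <- mo$a; caches$motor <- mo
  }
  if ("cog" %in% ch) {
    cg <- dense_fwd(bundle$cog, p$cogW, p$cogb)
    outs$cog <- cg$a; caches$cog <- cg
  }
  H <- do.call(cbind, outs[ch])
  widths <- sapply(outs[ch], ncol)
  n_fus <- length(cfg$fusion_widths)
  fus <- vector("list", n_fus); x <- H
  masks <- vector("list", n_fus)
  for (l in seq_len(n_fus)) {
    d <- dense_fwd(x, p[[paste0("fusW", l)]], p[[paste0("fusb", l)]])
    a <- d$a
    if (training && cfg$dropout_rate > 0 && l <= 2L) {
      keep <- 1 - cfg$dropout_rate
      mask <- matrix(stats::runif(length(a)) < keep, nrow(a), ncol(a)) / keep
      a <- a * mask
      masks[[l]] <- mask
    }
    fus[[l]] <- list(z = d$z, a = a, x = x)
    x <- a
  }
  logit <- add_bias(x %*% p$outW, p$outb)
  list(prob = stats::plogis(as.numeric(logit)), logit = as.numeric(logit),
       cache = list(channel = caches, H = H, widths = widths, fus = fus,
                    masks = masks, x_out = x, ch = ch))
}

model_backward <- function(p, cfg, bundle, fwd, y) {
  B <- length(y)
  gr <- list()
  dlogit <- matrix((fwd$prob - y) / B, B, 1)
  gr$outW <- crossprod(fwd$cache$x_out, dlogit)
  gr$outb <- sum(dlogit)
  dx <- dlogit %*% t(p$outW)
  n_fus <- length(cfg$fusion_widths)
  for (l in rev(seq_len(n_fus))) {
    if (!is.null(fwd$cache$masks[[l]])) dx <- dx * fwd$cache$masks[[l]]
    dz <- dx * (fwd$cache$fus[[l]]$z > 0)
    gr[[paste0("fusW", l)]] <- crossprod(fwd$cache$fus[[l]]$x, dz)
    gr[[paste0("fusb", l)]] <- colSums(dz)
    dx <- dz %*% t(p[[paste0("fusW", l)]])
  }
  # split fusion input gradient back into channels
  ch <- fwd$cache$ch
  offs <- cumsum(c(0, fwd$cache$widths))
  for (i in seq_along(ch)) {
    dch <- dx[, (offs[i] + 1):offs[i + 1], drop = FALSE]
    nm <- ch[i]
    if (nm == "conn") {
      gr <- c(gr, conv_bwd(dch, cfg, p, fwd$cache$channel$conn))
    } else if (nm == "graph") {
      cgc <- fwd$cache$channel$graph
      dz2 <- dch * (cgc$g2$z > 0)
      gr$graphW2 <- crossprod(cgc$g1$a, dz2)
      gr$graphb2 <- colSums(dz2)
      dz1 <- (dz2 %*% t(p$graphW2)) * (cgc$g1$z > 0)
      gr$graphW1 <- crossprod(bundle$graph, dz1)
      gr$graphb1 <- colSums(dz1)
    } else if (nm == "motor") {
      dz <- dch * (fwd$cache$channel$motor$z > 0)
      gr$motorW <- crossprod(bundle$motor, dz)
      gr$motorb <- colSums(dz)
    } else if (nm == "cog") {
      dz <- dch * (fwd$cache$channel$cog$z > 0)
      gr$cogW <- crossprod(bundle$cog, dz)
      gr$cogb <- colSums(dz)
    }
  }
  gr
}

bce_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Train the fusion classifier
#'
#' Mini-batch training with binary cross-entropy loss and the Adam
#' adaptive-moment optimizer; early stopping monitors the validation loss
#' and restores the best-validation weights. Fully deterministic for fixed
#' data, config and seed.
#'
#' @param train_bundle,train_y Training [feature_bundle()] and 0/1 labels.
#' @param val_bundle,val_y Validation set for early stopping (disjoint from
#'   training by participant).
#' @param cfg A [model_config()].
#' @return Object of class `fusion_model`: `params`, `cfg`, `history`
#'   (per-epoch train/validation loss), `best_epoch`.
#' @export
train_model <- function(train_bundle, train_y, val_bundle, val_y, cfg) {
  if (length(unique(train_y)) < 2L) stop("training labels are class-degenerate")
  if (length(intersect(train_bundle$participant, val_bundle$participant)) > 0L)
    stop("train and validation sets must be disjoint by participant")
  set.seed(cfg$seed)
  dims <- list(conn = ncol(train_bundle$conn), graph = ncol(train_bundle$graph),
               motor = ncol(train_bundle$motor), cog = ncol(train_bundle$cog))
  p <- init_params(cfg, dims)
  mom <- lapply(p, function(x) x * 0)
  vel <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n <- length(train_y)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_loss <- Inf; best_params <- p; best_epoch <- 0L; stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- bundle_rows(train_bundle, idx)
      fwd <- model_forward(p, cfg, xb, training = TRUE)
      loss <- bce_loss(fwd$prob, train_y[idx])
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d (lr=%.4g); aborting",
                     epoch, cfg$learning_rate))
      batch_losses <- c(batch_losses, loss)
      gr <- model_backward(p, cfg, xb, fwd, train_y[idx])
      t_step <- t_step + 1L
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (nm in names(gr)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr[[nm]]^2
        p[[nm]] <- p[[nm]] - cfg$learning_rate *
          (mom[[nm]] / corr1) / (sqrt(vel[[nm]] / corr2) + eps)
      }
    }
    val_prob <- model_forward(p, cfg, val_bundle, training = FALSE)$prob
    val_loss <- bce_loss(val_prob, val_y)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss; best_params <- p; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  # recalibrate the output bias on the training fold so the mean predicted
  # probability equals the training base rate (early stopping can leave the
  # logit offset off-center); uses training data only
  logits <- model_forward(best_params, cfg, train_bundle, training = FALSE)$logit
  target <- mean(train_y)
  delta <- tryCatch(
    stats::uniroot(function(d) mean(stats::plogis(logits + d)) - target,
                   c(-10, 10))$root,
    error = function(e) 0)
  best_params$outb <- best_params$outb + delta
  out <- list(params = best_params, cfg = cfg, history = history,
              best_epoch = best_epoch)
  class(out) <- "fusion_model"
  out
}

#' Predicted class-1 probabilities
#'
#' Deterministic forward pass (no dropout) of a trained model. Inputs must
#' be preprocessed with the same fold parameters as the training data.
#'
#' @param model A `fusion_model` from [train_model()].
#' @param bundle A [feature_bundle()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, bundle) {
  ch <- variant_channels(model$cfg$variant)
  # shape check on each consumed channel
  if ("graph" %in% ch && ncol(bundle$graph) != nrow(model$params$graphW1))
    stop("graph feature length mismatch")
  if ("motor" %in% ch && ncol(bundle$motor) != nrow(model$params$motorW))
    stop("motor feature length mismatch")
  if ("cog" %in% ch && ncol(bundle$cog) != nrow(model$params$cogW))
    stop("cognitive feature length mismatch")
  if ("conn" %in% ch) {
    geo <- conv_geometry(ncol(bundle$conn), model$cfg)
    if (geo$flat != nrow(model$params$connW))
      stop("connectivity feature length mismatch")
  }
  pr <- model_forward(model$params, model$cfg, bundle, training = FALSE)$prob
  pmin(1 - 1e-12, pmax(1e-12, pr))
}
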