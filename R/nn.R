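# Compact deterministic CPU training engine for the three routes.
#
# Feature layout: a sample is an array (spatial dims..., channels) flattened
# column-major (first spatial dim fastest, channels last); a batch is the
# n x n_features matrix of such rows. Convolution and pooling are expressed
# through index matrices precomputed per layer (im2col), so forward and
# backward passes reduce to dense GEMMs plus one sparse scatter, which keeps
# single-CPU training of the scaled-profile networks in seconds to minutes.

# linear offsets (0-based) of a column-major grid walk over `dims` with the
# given per-dimension strides
grid_offsets <- function(dims, strides) {
  off <- 0
  for (i in seq_along(dims)) {
    off <- outer(off, (0:(dims[i] - 1L)) * strides[i], "+")
  }
  as.vector(off)
}

# im2col index matrix for valid stride-1 nd convolution:
# rows = output positions (column-major), cols = kernel offsets x in-channels
conv_index <- function(spatial, cin, kernel) {
  out <- spatial - kernel + 1L
  strides <- cumprod(c(1L, spatial))[seq_along(spatial)]
  stride_ch <- prod(spatial)
  base <- grid_offsets(out, strides)
  off_k <- grid_offsets(kernel, strides)
  off <- as.vector(outer(off_k, (0:(cin - 1L)) * stride_ch, "+"))
  list(idx = outer(base + 1L, off, "+"), out = out,
       K = prod(kernel) * cin, P = prod(out))
}

# pooling index matrix: rows = output features (position-major, channel
# last), cols = elements of each disjoint window
pool_index <- function(spatial, ch, kernel) {
  out <- spatial %/% kernel
  strides <- cumprod(c(1L, spatial))[seq_along(spatial)]
  stride_ch <- prod(spatial)
  base_pos <- grid_offsets(out, strides * kernel)
  base <- as.vector(outer(base_pos, (0:(ch - 1L)) * stride_ch, "+"))
  off <- grid_offsets(kernel, strides)
  list(idx = outer(base + 1L, off, "+"), out = out, Kp = prod(kernel))
}

# instantiate runtime layers (weights + cached index structures) for a spec
build_network <- function(spec) {
  shapes <- c(list(spec$input_shape), shape_trace(spec))
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    ins <- shapes[[i]]
    rt <- list(kind = ly$kind, activation = ly$activation,
               in_shape = ins, out_shape = shapes[[i + 1]])
    if (ly$kind %in% c("conv1d", "conv2d", "conv3d")) {
      sp <- ins[-length(ins)]
      cin <- ins[length(ins)]
      ci <- conv_index(sp, cin, ly$kernel)
      rt$idx <- ci$idx
      rt$P <- ci$P
      rt$K <- ci$K
      rt$cout <- ly$filters
      rt$scatter <- Matrix::sparseMatrix(
        i = seq_len(length(ci$idx)), j = as.vector(ci$idx), x = 1,
        dims = c(length(ci$idx), prod(ins))
      )
      lim <- sqrt(6 / (ci$K + ly$filters))   # Glorot uniform
      rt$W <- matrix(stats::runif(ci$K * ly$filters, -lim, lim),
                     ci$K, ly$filters)
      rt$b <- numeric(ly$filters)
    } else if (ly$kind %in% c("maxpool1d", "maxpool2d", "maxpool3d")) {
      sp <- ins[-length(ins)]
      ch <- ins[length(ins)]
      pi <- pool_index(sp, ch, ly$kernel)
      rt$idx <- pi$idx
      rt$F <- nrow(pi$idx)
      rt$Kp <- pi$Kp
    } else if (ly$kind == "batchnorm") {
      ch <- ins[length(ins)]
      rt$gamma <- rep(1, ch)
      rt$beta <- numeric(ch)
      rt$run_mean <- numeric(ch)
      rt$run_var <- rep(1, ch)
      rt$momentum <- 0.9
      rt$eps <- 1e-5
    } else if (ly$kind == "dense") {
      fin <- ins
      lim <- sqrt(6 / (fin + ly$units))       # Glorot uniform
      rt$W <- matrix(stats::runif(fin * ly$units, -lim, lim), fin, ly$units)
      rt$b <- numeric(ly$units)
    } else if (ly$kind == "dropout") {
      rt$rate <- ly$rate
    }
    layers[[i]] <- rt
  }
  structure(list(spec = spec, layers = layers), class = "mvmdm_network")
}

add_bias <- function(Z, b) {
  Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
}

# forward pass; returns logits and per-layer caches when training = TRUE
network_forward <- function(net, X, training = FALSE) {
  n <- nrow(X)
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$kind %in% c("conv1d", "conv2d", "conv3d")) {
      A <- X[, as.vector(ly$idx), drop = FALSE]
      dim(A) <- c(n * ly$P, ly$K)
      Z <- add_bias(A %*% ly$W, ly$b)
      mask <- NULL
      if (ly$activation == "relu") {
        mask <- Z > 0
        Z[!mask] <- 0
      }
      if (training) caches[[i]] <- list(A = A, mask = mask)
      dim(Z) <- c(n, ly$P * ly$cout)
      X <- Z
    } else if (ly$kind %in% c("maxpool1d", "maxpool2d", "maxpool3d")) {
      fin <- ncol(X)
      A <- X[, as.vector(ly$idx), drop = FALSE]
      dim(A) <- c(n * ly$F, ly$Kp)
      amax <- max.col(A, ties.method = "first")
      Y <- A[cbind(seq_len(n * ly$F), amax)]
      dim(Y) <- c(n, ly$F)
      if (training) caches[[i]] <- list(amax = amax, fin = fin)
      X <- Y
    } else if (ly$kind == "batchnorm") {
      ch <- length(ly$gamma)
      m <- n * (ncol(X) %/% ch)
      Xa <- X
      dim(Xa) <- c(m, ch)
      if (training) {
        mu <- colMeans(Xa)
        xc <- sweep(Xa, 2, mu)
        v <- colMeans(xc^2)
        inv <- 1 / sqrt(v + ly$eps)
        xhat <- sweep(xc, 2, inv, "*")
        net$layers[[i]]$run_mean <-
          ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
        net$layers[[i]]$run_var <-
          ly$momentum * ly$run_var + (1 - ly$momentum) * v
        caches[[i]] <- list(xhat = xhat, inv = inv)
      } else {
        inv <- 1 / sqrt(ly$run_var + ly$eps)
        xhat <- sweep(sweep(Xa, 2, ly$run_mean), 2, inv, "*")
      }
      Y <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      dim(Y) <- dim(X)
      X <- Y
    } else if (ly$kind == "dense") {
      Z <- add_bias(X %*% ly$W, ly$b)
      mask <- NULL
      if (ly$activation == "relu") {
        mask <- Z > 0
        Z[!mask] <- 0
      }
      if (training) caches[[i]] <- list(A = X, mask = mask)
      X <- Z
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (stats::runif(length(X)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(X)
        X <- X * mask
        caches[[i]] <- list(mask = mask)
      }
    }
    # flatten: identity (layout is already flat)
  }
  list(logits = X, caches = caches, net = net)
}

# backward pass from d(loss)/d(logits); returns gradients per layer
network_backward <- function(net, caches, dY, n) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$kind %in% c("conv1d", "conv2d", "conv3d")) {
      cache <- caches[[i]]
      dim(dY) <- c(n * ly$P, ly$cout)
      if (!is.null(cache$mask)) dY[!cache$mask] <- 0
      grads[[i]] <- list(W = crossprod(cache$A, dY), b = colSums(dY))
      dA <- dY %*% t(ly$W)
      dim(dA) <- c(n, ly$P * ly$K)
      dY <- as.matrix(dA %*% ly$scatter)
    } else if (ly$kind %in% c("maxpool1d", "maxpool2d", "maxpool3d")) {
      cache <- caches[[i]]
      dX <- matrix(0, n, cache$fin)
      iv <- rep(seq_len(n), times = ly$F)
      jf <- rep(seq_len(ly$F), each = n)
      cols <- ly$idx[cbind(jf, cache$amax)]
      dX[cbind(iv, cols)] <- as.vector(dY)
      dY <- dX
    } else if (ly$kind == "batchnorm") {
      cache <- caches[[i]]
      ch <- length(ly$gamma)
      dmat <- dY
      dim(dmat) <- c(length(dmat) %/% ch, ch)
      mrows <- nrow(dmat)
      dgamma <- colSums(dmat * cache$xhat)
      dbeta <- colSums(dmat)
      dxhat <- sweep(dmat, 2, ly$gamma, "*")
      dX <- sweep(
        dxhat * mrows - matrix(colSums(dxhat), mrows, ch, byrow = TRUE) -
          cache$xhat * matrix(dgamma, mrows, ch, byrow = TRUE),
        2, cache$inv / mrows, "*"
      )
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dim(dX) <- c(n, length(dX) %/% n)
      dY <- dX
    } else if (ly$kind == "dense") {
      cache <- caches[[i]]
      if (!is.null(cache$mask)) dY[!cache$mask] <- 0
      grads[[i]] <- list(W = crossprod(cache$A, dY), b = colSums(dY))
      dY <- dY %*% t(ly$W)
    } else if (ly$kind == "dropout") {
      if (!is.null(caches[[i]])) dY <- dY * caches[[i]]$mask
    }
  }
  grads
}

# Adam state and update
adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    nm <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    if (!length(nm)) return(NULL)
    stats::setNames(lapply(nm, function(p) {
      list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    }), nm)
  })
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

bce_loss <- function(logits, y) {
  p <- stats::plogis(logits)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}
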