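# Independent reference implementations used as oracles. All are written as
# plain explicit loops, deliberately sharing no code with the package.

# fuzzy c-means objective by double loop
ref_fcm_objective <- function(X, U, Z, omega) {
  J <- 0
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(nrow(Z))) {
      J <- J + U[i, k]^omega * sum((X[i, ] - Z[k, ])^2)
    }
  }
  J
}

# one full alternating fuzzy c-means run from a given initial membership matrix
ref_fcm_run <- function(X, U, omega, alpha, max_iter) {
  c <- ncol(U)
  Z <- matrix(0, c, ncol(X))
  for (it in seq_len(max_iter)) {
    for (j in seq_len(c)) {
      w <- U[, j]^omega
      Z[j, ] <- colSums(X * w) / sum(w)
    }
    U_new <- matrix(0, nrow(X), c)
    for (i in seq_len(nrow(X))) {
      d2 <- vapply(seq_len(c), function(k) sum((X[i, ] - Z[k, ])^2), numeric(1))
      if (any(d2 == 0)) {
        U_new[i, which(d2 == 0)[1]] <- 1
      } else {
        for (k in seq_len(c)) {
          U_new[i, k] <- 1 / sum((d2[k] / d2)^(1 / (omega - 1)))
        }
      }
    }
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta <= alpha) break
  }
  list(U = U, Z = Z, J = ref_fcm_objective(X, U, Z, omega))
}

# max-min composition by triple loop
ref_maxmin <- function(U) {
  N <- nrow(U)
  M <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      best <- 0
      for (k in seq_len(ncol(U))) {
        v <- min(U[i, k], U[j, k])
        if (v > best) best <- v
      }
      M[i, j] <- best
    }
  }
  diag(M) <- 1
  M
}

# symbolic shape calculator for stream specs, independent of the package's
ref_stream_shape <- function(specs, shape) {
  for (sp in specs) {
    if (sp$kind %in% c("conv1d", "conv2d")) {
      shape[length(shape)] <- sp$filters
    } else if (sp$kind == "avgpool") {
      for (d in seq_len(length(shape) - 1)) {
        shape[d] <- floor(shape[d] / sp$pool)
      }
    } else if (sp$kind == "flatten") {
      shape <- prod(shape)
    } else if (sp$kind == "dense") {
      shape <- sp$units
    }
  }
  shape
}

# small labelled segment fixture from the generator
make_segments <- function(n_records = 2, duration = 40, window = 256,
                          seed = 5, ...) {
  recs <- lapply(seq_len(n_records), function(i) {
    generate_record(generator_config(duration = duration, seed = seed + i, ...))
  })
  lapply(recs, segment_record, window = window, stride = window)
}

# tiny ready-to-train dataset (1-D only unless side given)
make_tiny_dataset <- function(n_records = 2, duration = 40, window = 128,
                              side = NULL, seed = 5, target = "sbp") {
  segs <- unlist(make_segments(n_records, duration, window, seed), recursive = FALSE)
  build_dataset(segs, target = target, side = side, seed = seed)
}
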