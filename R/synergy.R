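#' Linear-envelope extraction for synergy estimation
#'
#' Muscle-synergy factorization needs a non-negative activation signal, so
#' signed raw sEMG is full-wave rectified and low-pass filtered (4th-order
#' Butterworth, zero-phase) to its linear envelope before NMF. This is a
#' standard preparation step; the autoencoder itself always consumes raw
#' windows.
#'
#' @param semg channels x samples matrix of raw sEMG.
#' @param rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz.
#' @return Non-negative matrix of the same shape.
#' @export
semg_envelope <- function(semg, rate, cutoff = 4) {
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  out <- t(apply(abs(semg), 1L, function(x) signal::filtfilt(bf, x)))
  out[out < 0] <- 0
  dimnames(out) <- dimnames(semg)
  out
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (samples x muscles) into synergy
#' activations `W` (n x r) and synergy weights `H` (r x m), minimizing the
#' Frobenius reconstruction error with Lee-Seung multiplicative updates. The
#' objective is non-increasing at every update; iteration stops at a relative
#' objective change below `tol` or after `max_iter` iterations. The best of
#' `n_restarts` random non-negative initializations is returned.
#'
#' @param V non-negative n x m matrix (e.g. stacked sEMG envelopes).
#' @param r number of synergies, at most `min(n, m)`.
#' @param tol relative-change stopping tolerance.
#' @param max_iter maximum multiplicative updates per restart.
#' @param n_restarts random restarts.
#' @param seed optional seed for the restarts.
#' @return An object of class `synergy_model` with `W`, `H`, `r`,
#'   `recon_error` (Frobenius residual), `rel_error` and the per-iteration
#'   `objective` trace of the winning restart.
#' @export
fit_nmf <- function(V, r = 5L, tol = 1e-6, max_iter = 500L, n_restarts = 5L,
                    seed = NULL) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  n <- nrow(V); m <- ncol(V)
  if (r > min(n, m)) stop("r must not exceed min(dim(V))")
  eps <- 1e-12
  run_once <- function() {
    W <- matrix(stats::runif(n * r, 0, 1), n, r) * sqrt(mean(V) / r)
    H <- matrix(stats::runif(r * m, 0, 1), r, m) * sqrt(mean(V) / r)
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      e <- sqrt(sum((V - W %*% H)^2))
      obj <- c(obj, e)
      if (is.finite(prev) && abs(prev - e) <= tol * max(prev, eps)) break
      prev <- e
    }
    list(W = W, H = H, obj = obj, err = obj[length(obj)])
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(n_restarts), function(i) run_once())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "err"))]]
  })
  structure(list(W = best$W, H = best$H, r = as.integer(r),
                 recon_error = best$err,
                 rel_error = best$err / sqrt(sum(V^2)),
                 objective = best$obj),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("synergy_model: r = %d, W %d x %d, H %d x %d\n",
              x$r, nrow(x$W), ncol(x$W), nrow(x$H), ncol(x$H)))
  if (!is.null(x$rel_error)) {
    cat(sprintf("  relative Frobenius reconstruction error: %.3g\n", x$rel_error))
  }
  invisible(x)
}

#' Channel permutations derived from synergy weights
#'
#' One permutation of the sEMG channel indices per feature-map group: the
#' channels sorted by descending weight in the corresponding synergy, ties
#' broken by original index. Sorting by synergy weight places each synergy's
#' cooperating channels adjacently, so the following small 2-D kernels can
#' cover them inside one receptive field.
#'
#' @param H r x m non-negative synergy-weight matrix.
#' @return An object of class `channel_orders`: a list of r integer
#'   permutations of `1:m`.
#' @export
derive_channel_orders <- function(H) {
  perms <- lapply(seq_len(nrow(H)), function(g) {
    order(-H[g, ], seq_len(ncol(H)))
  })
  structure(perms, class = "channel_orders")
}

inverse_orders <- function(orders) {
  structure(lapply(orders, order), class = "channel_orders")
}

#' Rearrange feature-map channel axes by synergy group
#'
#' Splits the feature maps into `length(orders)` equal groups and permutes
#' the channel (muscle) axis of every map in group g by `orders[[g]]`; values
#' are otherwise untouched, so per-map sums and norms are conserved.
#'
#' @param maps array with dim (channels, time, n_maps, batch).
#' @param orders a `channel_orders` object.
#' @return Array of the same shape with permuted channel axes.
#' @export
rearrange <- function(maps, orders) {
  n_maps <- dim(maps)[3L]
  n_groups <- length(orders)
  if (n_maps %% n_groups != 0L) {
    stop("number of feature maps not divisible by number of groups")
  }
  per <- n_maps %/% n_groups
  out <- maps
  for (g in seq_len(n_groups)) {
    sel <- ((g - 1L) * per + 1L):(g * per)
    out[, , sel, ] <- maps[orders[[g]], , sel, , drop = FALSE]
  }
  out
}

#' Cosine similarity between two synergy-weight matrices
#'
#' Computes the r x r cosine-similarity matrix between rows of `H_a` and
#' `H_b` and the optimal one-to-one row matching (exact assignment by
#' exhaustive search over permutations, feasible for r <= 8). Zero rows have
#' similarity 0 by convention.
#'
#' @param H_a,H_b r x m non-negative matrices.
#' @return List with `cosine` (r x r matrix), `matching` (for each row of
#'   `H_a` the matched row of `H_b`), `matched` (the matched similarities)
#'   and their `mean`.
#' @export
synergy_similarity <- function(H_a, H_b) {
  stopifnot(all(dim(H_a) == dim(H_b)))
  r <- nrow(H_a)
  if (r > 8L) stop("exact matching supported for r <= 8")
  nrm <- function(H) sqrt(rowSums(H^2))
  na <- nrm(H_a); nb <- nrm(H_b)
  cosm <- (H_a %*% t(H_b)) / (na %o% nb)
  cosm[!is.finite(cosm)] <- 0
  perms <- all_permutations(r)
  scores <- vapply(perms, function(p) sum(cosm[cbind(seq_len(r), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  matched <- cosm[cbind(seq_len(r), best)]
  list(cosine = cosm, matching = best, matched = matched,
       mean = mean(matched))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      q <- integer(n)
      q[i] <- n
      q[-i] <- p
      out[[k]] <- q
    }
  }
  out
}

#' Serialize a synergy model as delimited text
#'
#' @param model a `synergy_model`.
#' @param path directory for `W.tsv`, `H.tsv` and `meta.dcf`.
#' @export
write_synergy_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$W, file.path(path, "W.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$H, file.path(path, "H.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  write.dcf(data.frame(r = model$r, recon_error = model$recon_error),
            file.path(path, "meta.dcf"))
  invisible(path)
}

#' @rdname write_synergy_model
#' @export
read_synergy_model <- function(path) {
  meta <- read.dcf(file.path(path, "meta.dcf"))
  structure(list(W = as.matrix(utils::read.table(file.path(path, "W.tsv"))),
                 H = as.matrix(utils::read.table(file.path(path, "H.tsv"))),
                 r = as.integer(meta[1, "r"]),
                 recon_error = as.numeric(meta[1, "recon_error"])),
            class = "synergy_model")
}
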