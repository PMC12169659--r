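# Self-consistent configuration recovery (S-CORE): restore particle-number
# and spin-z symmetry of noise-corrupted samples using the current average
# occupancies, draw frequency-weighted batches, and close them under spin
# inversion.
#
# Flip rule (one realization of "flip using the distance between the bit and
# n_p"): while a spin sector has too many (few) electrons, one occupied
# (virtual) bit is flipped, chosen with probability proportional to
# |x_p - n_p| over the eligible bits; each flip moves the count one step
# toward the target, so the procedure always terminates.  Spin sectors are
# repaired independently.

#' Occupancy distribution
#'
#' @param alpha,beta per-orbital average occupations in [0, 1].
#' @param normalize rescale each spin channel to sum to `target` counts.
#' @param targets optional c(n_alpha, n_beta) for normalization.
#' @return An `occupancy` object.
#' @export
occupancy <- function(alpha, beta, normalize = FALSE, targets = NULL) {
  if (normalize) {
    alpha <- alpha * targets[1] / sum(alpha)
    beta <- beta * targets[2] / sum(beta)
  }
  if (any(alpha < -1e-9 | alpha > 1 + 1e-9 | beta < -1e-9 | beta > 1 + 1e-9))
    stop("occupancies must lie in [0, 1]")
  structure(list(alpha = pmin(pmax(alpha, 0), 1), beta = pmin(pmax(beta, 0), 1)),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  cat("occupancy: alpha =", paste(sprintf("%.3f", x$alpha), collapse = " "), "\n")
  cat("           beta  =", paste(sprintf("%.3f", x$beta), collapse = " "), "\n")
  invisible(x)
}

#' Initial occupancy from symmetry-correct shots
#'
#' Counts-weighted mean occupation over only those shots that already carry
#' the target particle numbers per spin.
#'
#' @param samples a `sample_set` (possibly noisy).
#' @param n_alpha,n_beta target electron counts per spin.
#' @return An `occupancy`.
#' @export
initial_occupancy <- function(samples, n_alpha, n_beta) {
  r <- samples$records
  norb <- samples$norb
  ok <- .popcount(r$alpha, norb) == n_alpha & .popcount(r$beta, norb) == n_beta
  if (!any(ok))
    stop(paste("no symmetry-correct shots to seed the occupancy;",
               "lower the noise or draw more shots"))
  w <- r$count[ok]
  oa <- .occ_matrix(r$alpha[ok], norb)
  ob <- .occ_matrix(r$beta[ok], norb)
  occupancy(as.vector(crossprod(oa, w)) / sum(w),
            as.vector(crossprod(ob, w)) / sum(w))
}

# repair one spin channel of expanded shots; returns integer masks
.recover_channel <- function(masks, n_target, nprob, norb) {
  cnt <- .popcount(masks, norb)
  it <- 0L
  while (any(cnt != n_target)) {
    it <- it + 1L
    if (it > 10L * norb) stop("internal: recovery failed to terminate")
    for (dir in c(1L, -1L)) {
      sel <- if (dir > 0) cnt > n_target else cnt < n_target
      if (!any(sel)) next
      m <- masks[sel]
      occm <- .occ_matrix(m, norb)
      eligible <- if (dir > 0) occm else 1 - occm
      # weight = |x_p - n_p|: occupied -> 1 - n_p, virtual -> n_p
      w <- eligible * if (dir > 0) rep(1 - nprob, each = length(m))
                      else rep(nprob, each = length(m))
      w <- matrix(w, length(m), norb) + eligible * 1e-12
      cs <- w %*% upper.tri(diag(norb), diag = TRUE)
      r <- runif(length(m)) * cs[, norb]
      pick <- rowSums(cs < r)               # 0-based orbital index
      masks[sel] <- bitwXor(m, bitwShiftL(1L, pick))
      cnt[sel] <- cnt[sel] - dir
    }
  }
  masks
}

#' S-CORE configuration recovery
#'
#' Flips bits of symmetry-broken shots toward the target particle numbers,
#' weighting each eligible bit by its distance from the current occupancy.
#' Symmetry-correct shots pass through unchanged; output shot count equals
#' the input shot count.
#'
#' @param samples a `sample_set`.
#' @param occ an `occupancy` (current estimate).
#' @param n_alpha,n_beta target electron counts per spin.
#' @param seed RNG seed.
#' @return A recovered `sample_set` in which every record has exactly
#'   `(n_alpha, n_beta)` electrons.
#' @export
recover_configurations <- function(samples, occ, n_alpha, n_beta, seed = 1L) {
  norb <- samples$norb
  r <- samples$records
  a <- rep(r$alpha, r$count)
  b <- rep(r$beta, r$count)
  .with_seed(seed, {
    a <- .recover_channel(a, n_alpha, occ$alpha, norb)
    b <- .recover_channel(b, n_beta, occ$beta, norb)
  })
  sample_set(a, b, rep(1, length(a)), norb,
             provenance = paste0(samples$provenance, "+recovered"),
             seed = as.integer(seed))
}

#' Draw configuration batches
#'
#' Pulls `K` subsets of `batch_size` distinct configurations each,
#' frequency-weighted without replacement within a batch and independently
#' across batches.
#'
#' @param recovered a symmetry-correct `sample_set`.
#' @param K number of batches.
#' @param batch_size distinct configurations per batch; truncated with a
#'   warning if fewer distinct strings exist.
#' @param seed RNG seed.
#' @return List of `K` data.frames with columns `alpha`, `beta`, `count`.
#' @export
partition_batches <- function(recovered, K, batch_size, seed = 1L) {
  r <- recovered$records
  nd <- nrow(r)
  if (nd == 0) stop("empty sample set")
  if (batch_size > nd) {
    warning(sprintf("batch_size %d exceeds the %d distinct configurations; truncating",
                    batch_size, nd))
    batch_size <- nd
  }
  .with_seed(seed, lapply(seq_len(K), function(b) {
    idx <- sample.int(nd, batch_size, replace = FALSE, prob = r$count)
    r[sort(idx), , drop = FALSE]
  }))
}

#' Close a batch under spin inversion
#'
#' The half-string set `U` is the union of the alpha and beta halves of the
#' batch; the implied determinant set is `U x U`, which contains `(b, a)`
#' whenever it contains `(a, b)`.
#'
#' @param batch data.frame with `alpha`/`beta` bitmask columns.
#' @param norb active orbitals.
#' @param n_alpha electrons per spin.
#' @return A `config_subspace` of dimension `d = |U|^2 >= nrow(batch)`.
#' @export
close_under_spin_inversion <- function(batch, norb, n_alpha) {
  configuration_subspace(union(batch$alpha, batch$beta), norb, n_alpha)
}

#' Average occupancies over batch ground states
#'
#' The occupation-number distribution used by the next S-CORE iteration:
#' the K batch wavefunctions' diagonal densities, averaged with equal
#' weights; each spin channel sums to its electron count by construction.
#'
#' @param results list of `solvated_result` (one per batch).
#' @return An `occupancy`.
#' @export
update_occupancy <- function(results) {
  K <- length(results)
  if (K == 0) stop("no batch results")
  a <- Reduce(`+`, lapply(results, function(r) r$occupancies$alpha)) / K
  b <- Reduce(`+`, lapply(results, function(r) r$occupancies$beta)) / K
  occupancy(a, b)
}
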