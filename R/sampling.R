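# Bitstring samples: multinomial draws from a simulated LUCJ state, an
# independent bit-flip noise emulator standing in for hardware noise, and a
# plain-text sample file format.
#
# Bitstring text convention (shared by every module): characters left to
# right are alpha orbitals 0..n-1 then beta orbitals 0..n-1, '1' = occupied,
# orbital 0 lowest.  Internally a record is a pair of integer bitmasks.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a sample set
#'
#' @param alpha,beta integer occupation bitmasks per record.
#' @param count positive counts per record.
#' @param norb orbitals per spin.
#' @param provenance `"noiseless"`, `"noisy(p)"` or `"file"`.
#' @param seed RNG seed used to generate the set (or NA).
#' @return A `sample_set` (records aggregated over identical strings).
#' @export
sample_set <- function(alpha, beta, count, norb, provenance = "noiseless",
                       seed = NA_integer_) {
  if (any(count <= 0)) stop("counts must be positive")
  key <- alpha * 2^norb + beta
  agg <- rowsum(as.numeric(count), key)
  k <- as.numeric(rownames(agg))
  out <- data.frame(alpha = as.integer(k %/% 2^norb),
                    beta = as.integer(k %% 2^norb),
                    count = as.numeric(agg[, 1]))
  out <- out[order(-out$count, out$alpha, out$beta), ]
  rownames(out) <- NULL
  structure(list(records = out, norb = as.integer(norb),
                 shots = sum(out$count), provenance = provenance,
                 seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d shots, %d distinct strings, %d orbitals/spin, %s\n",
              x$shots, nrow(x$records), x$norb, x$provenance))
  invisible(x)
}

.mask_to_bits <- function(mask, norb) {
  vapply(mask, function(m)
    paste(bitwAnd(bitwShiftR(m, seq_len(norb) - 1L), 1L), collapse = ""), "")
}

.bits_to_mask <- function(bits) {
  vapply(strsplit(bits, ""), function(b)
    sum(bitwShiftL(1L, which(b == "1") - 1L)), 0L) |> as.integer()
}

#' Bitstring text representation of a sample set
#'
#' @param samples a `sample_set`.
#' @return Character vector, one `2*norb`-character string per record.
#' @export
sample_bitstring_text <- function(samples) {
  paste0(.mask_to_bits(samples$records$alpha, samples$norb),
         .mask_to_bits(samples$records$beta, samples$norb))
}

#' Draw bitstring samples from a LUCJ state
#'
#' Multinomial sampling from `p(x) = |<x|Phi>|^2`.
#'
#' @param state a `lucj_state`.
#' @param shots number of shots (> 0).
#' @param seed RNG seed (draws are reproducible under a fixed seed).
#' @return A `sample_set` with provenance `"noiseless"`.
#' @export
sample_bitstrings <- function(state, shots, seed = 1L) {
  if (shots <= 0) stop("shots must be positive")
  p <- as.vector(Mod(state$amp)^2)
  p <- p / sum(p)
  counts <- .with_seed(seed, as.vector(rmultinom(1, shots, p)))
  nz <- which(counts > 0)
  N <- length(state$strings)
  ib <- (nz - 1L) %% N + 1L          # row = beta
  ia <- (nz - 1L) %/% N + 1L         # column = alpha
  sample_set(state$strings[ia], state$strings[ib], counts[nz], state$norb,
             provenance = "noiseless", seed = as.integer(seed))
}

#' Corrupt samples with independent bit flips
#'
#' Emulates symmetry-breaking hardware noise: every bit of every shot is
#' flipped independently with probability `p_flip`, which breaks particle
#' number and spin-z on a fraction `1 - (1 - p_flip)^(2 norb)` of the shots.
#'
#' @param samples a `sample_set`.
#' @param p_flip per-bit flip probability in [0, 1].
#' @param seed RNG seed.
#' @return A `sample_set` with provenance `"noisy(p_flip)"`; shot count is
#'   conserved.
#' @export
inject_noise <- function(samples, p_flip, seed = 1L) {
  stopifnot(p_flip >= 0, p_flip <= 1)
  if (p_flip == 0) return(samples)
  norb <- samples$norb
  a <- rep(samples$records$alpha, samples$records$count)
  b <- rep(samples$records$beta, samples$records$count)
  n <- length(a)
  .with_seed(seed, {
    for (p in seq_len(norb) - 1L) {
      a <- bitwXor(a, bitwShiftL(as.integer(runif(n) < p_flip), p))
      b <- bitwXor(b, bitwShiftL(as.integer(runif(n) < p_flip), p))
    }
  })
  sample_set(a, b, rep(1, n), norb,
             provenance = sprintf("noisy(%g)", p_flip), seed = as.integer(seed))
}

#' Write a sample set to a plain-text file
#'
#' Format: `#`-prefixed header lines carrying shots, seed, provenance and
#' orbital count, then one `<bitstring> <count>` record per line.
#'
#' @param samples a `sample_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_file <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# shots=%d", samples$shots),
    sprintf("# seed=%s", samples$seed),
    sprintf("# provenance=%s", samples$provenance),
    sprintf("# norb=%d", samples$norb)), con)
  writeLines(sprintf("%s %d", sample_bitstring_text(samples),
                     as.integer(samples$records$count)), con)
  invisible(path)
}

#' Read a sample file
#'
#' Records with a missing count field get count 1.
#'
#' @param path sample file written by [write_sample_file()] or hand-made in
#'   the same format.
#' @param norb orbitals per spin; taken from the header when present.
#' @return A `sample_set` with provenance `"file"`.
#' @export
read_sample_file <- function(path, norb = NULL) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- trimws(ln[!startsWith(ln, "#")])
  body <- body[nzchar(body)]
  gethdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^#\\s*", key, "="), "", m[1]) else NA
  }
  if (is.null(norb)) {
    norb <- suppressWarnings(as.integer(gethdr("norb")))
    if (is.na(norb)) {
      norb <- nchar(strsplit(body[1], "\\s+")[[1]][1]) %/% 2L
    }
  }
  parts <- strsplit(body, "\\s+")
  bits <- vapply(parts, `[[`, "", 1)
  cnt <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1, 0)
  if (any(nchar(bits) != 2L * norb)) stop("bitstring length inconsistent with norb")
  am <- .bits_to_mask(substr(bits, 1L, norb))
  bm <- .bits_to_mask(substr(bits, norb + 1L, 2L * norb))
  seed <- suppressWarnings(as.integer(gethdr("seed")))
  sample_set(am, bm, cnt, norb, provenance = "file", seed = seed)
}
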