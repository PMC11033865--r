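# Internal helpers: error conditions, seeded RNG scopes, reflect-padded
# convolution, 8-connected labeling.

stop_rasp <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rasp_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_validation <- function(msg) stop_rasp(msg, "rasp_validation_error")
stop_io <- function(msg) stop_rasp(msg, "rasp_io_error")

check_image <- function(image, arg = "image", min_dim = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_validation(sprintf("`%s` must be a numeric matrix", arg))
  if (any(dim(image) < min_dim))
    stop_validation(sprintf("`%s` must be at least %dx%d", arg, min_dim, min_dim))
  invisible(image)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards. With `seed = NULL` the code runs against the current
#' RNG stream. Used by every stochastic operation so that results are
#' reproducible without clobbering the caller's stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("`rng_seed` must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds, kept inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 999983 * as.numeric(k)) %% 2147483647)
}

# Reflect (mirror-with-edge) index mapping: ... 2 1 | 1 2 ... n | n n-1 ...
idx_reflect <- function(i, n) {
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j)
}

pad_reflect <- function(image, w) {
  nr <- nrow(image); nc <- ncol(image)
  image[idx_reflect(seq_len(nr + 2L * w) - w, nr),
        idx_reflect(seq_len(nc + 2L * w) - w, nc), drop = FALSE]
}

# 2D linear filtering with reflect boundary handling; `kernel` must be odd
# square with its origin at the central element. FFT backend via EBImage.
convolve2 <- function(image, kernel) {
  w <- (nrow(kernel) - 1L) %/% 2L
  if (w == 0L) return(image * kernel[1L, 1L])
  padded <- pad_reflect(image, w)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out <- as.matrix(out)
  out[w + seq_len(nrow(image)), w + seq_len(ncol(image)), drop = FALSE]
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Sampled Laplacian-of-Gaussian, adjusted to zero sum so constants map to 0.
log_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  r2 <- outer(x^2, x^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

# 8-connected component labeling. EBImage::bwlabel() is 4-connected, so
# labels touching diagonally are merged afterwards with a union-find pass.
label_components <- function(mask) {
  if (!is.matrix(mask)) stop_validation("`mask` must be a matrix")
  lab <- EBImage::bwlabel(mask > 0)
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal
  d1 <- a > 0L & b > 0L & a != b
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]  # down-left diagonal
  d2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a[d1], b[d1]), cbind(a2[d2], b2[d2]))
  if (nrow(pairs) > 0L) {
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (p in seq_len(nrow(pairs))) {
      ra <- find(pairs[p, 1L]); rb <- find(pairs[p, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(k), find, integer(1))
    compact <- match(root, sort(unique(root)))
    lut <- c(0L, compact)
    lab <- matrix(lut[lab + 1L], nr, nc)
  }
  lab
}

# Quantile convention used throughout: linear interpolation between order
# statistics (type 7), stated for reproducibility.
rasp_quantile <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)
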