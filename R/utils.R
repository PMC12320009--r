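#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn
#' @importFrom stats fft mad median quantile rnorm runif sd shapiro.test
#' @importFrom stats cor.test t.test wilcox.test rpois prcomp
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic sub-seed derivation: one master seed, one stream per component.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(tag)) h <- (h * 69069 + k) %% 2147483647
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# centred moving-average of width w samples (w >= 1), edges padded by reflection
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  pad <- w  # enough for any alignment
  xe <- c(x[pmin(pad:1, n)], x, x[pmax(n - (1:pad) + 1L, 1L)])
  cs <- cumsum(c(0, xe))
  lo <- floor((w - 1) / 2); hi <- w - 1L - lo
  i <- (pad + 1):(pad + n)
  (cs[i + hi + 1L] - cs[i - lo]) / w
}

# merge overlapping / touching [start, end) windows; input 2-col matrix or tibble
merge_windows <- function(win) {
  win <- as.matrix(win)
  if (length(win) == 0 || nrow(win) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  win <- win[order(win[, 1]), , drop = FALSE]
  out <- win[1, , drop = FALSE]
  if (nrow(win) > 1) for (i in 2:nrow(win)) {
    j <- nrow(out)
    if (win[i, 1] <= out[j, 2]) out[j, 2] <- max(out[j, 2], win[i, 2])
    else out <- rbind(out, win[i, ])
  }
  colnames(out) <- c("start", "end")
  out
}

windows_tbl <- function(win) {
  win <- merge_windows(win)
  tibble(start = win[, 1], end = win[, 2])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Hungarian algorithm (O(n^3), square cost matrix); returns col index per row.
# Used for bijective template-layout channel matching: no LSAP solver is
# available in the dependency set, so the standard potentials-based algorithm
# is implemented here and checked against brute-force enumeration in tests.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j+1] = row assigned to column j (1-based cols shifted)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0 + 0L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) match[p[j + 1L]] <- j
  match
}
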