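# Test helpers: small image builders and independent oracles.

# noise-free frame with Gaussian spots (0-based centers, x = column)
gaussian_frame <- function(ny, nx, centers, amp = 1, sigma = 1.5, bg = 0) {
  img <- matrix(bg, ny, nx)
  if (length(centers) == 0) return(img)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    a <- if (length(amp) > 1) amp[k] else amp
    gy <- exp(-((0:(ny - 1)) - cy)^2 / (2 * sigma^2))
    gx <- exp(-((0:(nx - 1)) - cx)^2 / (2 * sigma^2))
    img <- img + a * outer(gy, gx)
  }
  img
}

# exhaustive minimum-total-distance assignment between two detection sets,
# forbidding links beyond max_disp; returns list of c(i, j) pairs.
# Independent oracle for the greedy linker on small scenes.
optimal_assignment <- function(p1, p2, max_disp) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 == 0 || n2 == 0) return(list())
  dmat <- outer(seq_len(n1), seq_len(n2), Vectorize(function(i, j)
    sqrt((p1$x[i] - p2$x[j])^2 + (p1$y[i] - p2$y[j])^2)))
  best <- NULL; best_cost <- Inf; best_n <- -1L
  subsets2 <- function(n, k) if (k == 0) list(integer(0)) else
    combn(n, k, simplify = FALSE)
  for (k in seq(min(n1, n2), 0)) {
    for (s1 in subsets2(n1, k)) for (s2 in subsets2(n2, k)) {
      perms <- if (k == 0) list(integer(0)) else
        lapply(asplit(.permutations(k), 1), as.integer)
      for (pm in perms) {
        d <- if (k == 0) numeric(0) else dmat[cbind(s1, s2[pm])]
        if (any(d > max_disp)) next
        cost <- sum(d)
        # maximize number of links, then minimize cost
        if (k > best_n || (k == best_n && cost < best_cost)) {
          best_n <- k; best_cost <- cost
          best <- if (k == 0) list() else
            lapply(seq_len(k), function(t) c(s1[t], s2[pm[t]]))
        }
      }
    }
    if (best_n == k) break  # no larger matching possible below
  }
  best %||% list()
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# links of a trajectory list as a set of "frame:x,y->frame:x,y" strings
link_set <- function(trajs) {
  out <- character(0)
  for (tr in trajs) {
    d <- tr$detections
    if (nrow(d) < 2) next
    for (i in seq_len(nrow(d) - 1))
      out <- c(out, sprintf("%d:%.4f,%.4f->%d:%.4f,%.4f",
                            d$frame[i], d$x[i], d$y[i],
                            d$frame[i + 1], d$x[i + 1], d$y[i + 1]))
  }
  sort(out)
}
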