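# Independent oracles and small builders shared across tests. These stay
# deliberately naive (queue-based flood fill, direct formula evaluation) so
# they check the implementation rather than mirror it.

# flood-fill connected-component labeling, pure R, breadth-first
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    moves <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(moves))) {
        r2 <- p[1] + moves[k, 1]; c2 <- p[2] + moves[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# two labelings agree up to label permutation
same_partition <- function(a, b) {
  if (max(a) != max(b)) return(FALSE)
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == max(a)
}

# direct evaluation of the Feltz-Miller statistic, written independently
cv_stat_oracle <- function(groups) {
  n <- lengths(groups)
  cv <- vapply(groups, function(g) stats::sd(g) / mean(g), numeric(1))
  m <- n - 1
  cbar <- sum(m * cv) / sum(m)
  sum(m * (cv - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
}

# a stack with a single deposit-like channel built from an explicit matrix
stack_from_plane <- function(plane, role = "deposit", pixel_size_um = 0.3) {
  image_stack(array(plane, c(dim(plane), 1, 1)), pixel_size_um, role)
}

# default config used by imaging tests; overrides win over the defaults
test_config <- function(...) {
  args <- utils::modifyList(list(deposit_threshold = 150, yfp_threshold = 100,
                                 pixel_size_um = 0.3), list(...))
  do.call(pipeline_config, args)
}

# planted, well-separated event times over 60 s (30 events)
planted_times <- function(n = 30, spacing = 1.9, jitter = 0.8) {
  (seq_len(n) - 1) * spacing + 0.5 + runif(n, 0, jitter)
}

# match detected onsets to true onsets within a tolerance (seconds);
# returns c(tp, n_detected, n_true)
match_events <- function(detected_s, true_s, tol_s) {
  tp <- sum(vapply(detected_s, function(d) any(abs(true_s - d) <= tol_s),
                   logical(1)))
  c(tp = tp, det = length(detected_s), true = length(true_s))
}
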