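# Shared fixtures. Slides are generated once per R session and memoised, so
# several test files can reuse the same pseudo-slides without regenerating.

.fixture_env <- new.env(parent = emptyenv())

fixture_slide <- function(seed, ...) {
  key <- paste0("slide_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_slide(synthetic_slide_spec(seed = seed, ...))
  }
  .fixture_env[[key]]
}

# a 256 px @40x window of a slide centred on tumor (maximal tumor coverage)
fixture_tumor_tile <- function(slide, size = 256L) {
  tm <- slide$tumor_mask40
  n <- nrow(tm)
  best <- c(0L, 0L); bf <- -1
  for (x0 in seq(0L, n - size, by = 128L)) {
    for (y0 in seq(0L, n - size, by = 128L)) {
      f <- mean(tm[y0 + seq_len(size), x0 + seq_len(size)])
      if (f > bf) { bf <- f; best <- c(x0, y0) }
    }
  }
  pdl1tps:::crop_det_tile(slide, best[1], best[2], size)
}

# Independent greedy-NMS oracle: O(n^2) suppression over all candidate
# pixels sorted by score (desc) then row-major.
nms_oracle <- function(score, min_distance, threshold) {
  cand <- which(score >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = integer(0), y = integer(0), confidence = numeric(0)))
  df <- data.frame(x = cand[, 2] - 1L, y = cand[, 1] - 1L,
                   confidence = score[cand])
  df <- df[order(-df$confidence, df$y, df$x), ]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    p <- df[i, ]
    if (nrow(kept) == 0 ||
        all((kept$x - p$x)^2 + (kept$y - p$y)^2 >= min_distance^2)) {
      kept <- rbind(kept, p)
    }
  }
  rownames(kept) <- NULL
  kept
}

# Independent maximum-matching oracle (Kuhn's augmenting paths) on the
# thresholded distance matrix; returns the maximum number of matches.
matching_oracle <- function(pred, truth, max_dist) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  d <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
  adj <- d < max_dist
  match_t <- rep(0L, nt)
  try_kuhn <- function(p, visited) {
    for (t in seq_len(nt)) {
      if (adj[p, t] && !visited[t]) {
        visited[t] <- TRUE
        if (match_t[t] == 0L) {
          match_t[t] <<- p
          return(list(ok = TRUE, visited = visited))
        }
        res <- try_kuhn(match_t[t], visited)
        visited <- res$visited
        if (res$ok) {
          match_t[t] <<- p
          return(list(ok = TRUE, visited = visited))
        }
      }
    }
    list(ok = FALSE, visited = visited)
  }
  n_match <- 0L
  for (p in seq_len(np)) {
    if (try_kuhn(p, rep(FALSE, nt))$ok) n_match <- n_match + 1L
  }
  n_match
}

# Exhaustive maximum-matching count by recursion (small n only).
matching_exhaustive <- function(pred, truth, max_dist) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  d <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
  adj <- d < max_dist
  rec <- function(p, used) {
    if (p > np) return(0L)
    best <- rec(p + 1L, used)  # leave p unmatched
    for (t in seq_len(nt)) {
      if (adj[p, t] && !(t %in% used)) {
        best <- max(best, 1L + rec(p + 1L, c(used, t)))
      }
    }
    best
  }
  rec(1L, integer(0))
}

random_points <- function(n, lim = 64) {
  tibble::tibble(x = runif(n, 0, lim), y = runif(n, 0, lim))
}
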