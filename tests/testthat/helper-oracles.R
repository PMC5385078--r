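# Independent brute-force oracles and shared fixtures for the test suite.

# Flood-fill connected-component labeling, written independently of the
# package's labeler: plain R, explicit stack, raster-scan seeding.
flood_fill_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    nbr <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nbr <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  lab <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc] || labels[rr, cc] != 0L) next
      lab <- lab + 1L
      stack <- list(c(rr, cc))
      labels[rr, cc] <- lab
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nbr))) {
          r2 <- p[1] + nbr[k, 1]; c2 <- p[2] + nbr[k, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] && labels[r2, c2] == 0L) {
            labels[r2, c2] <- lab
            stack[[length(stack) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  labels
}

# Are two labelings identical up to a relabeling of component ids?
same_partition <- function(a, b) {
  if (!all(dim(a) == dim(b)) || !all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Confusion-matrix metric oracles: literal double loops over Table-style
# definitions, no vectorized shortcuts.
oracle_confusion <- function(actual, predicted, classes) {
  m <- matrix(0L, length(classes), length(classes))
  for (i in seq_along(actual)) {
    r <- which(classes == actual[i])
    c <- which(classes == predicted[i])
    m[r, c] <- m[r, c] + 1L
  }
  m
}

oracle_accuracy <- function(cm) {
  correct <- 0
  for (i in seq_len(nrow(cm))) correct <- correct + cm[i, i]
  100 * correct / sum(cm)
}

oracle_mpca <- function(cm) {
  pcas <- c()
  for (i in seq_len(nrow(cm))) {
    rs <- sum(cm[i, ])
    if (rs > 0) pcas <- c(pcas, cm[i, i] / rs)
  }
  100 * mean(pcas)
}

oracle_cost <- function(cm, w) {
  total <- 0
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(ncol(cm))) {
      total <- total + cm[i, j] * w[i, j]
    }
  }
  total / sum(cm)
}

# Tight, well-separated 5-cluster table: every classifier should nail it.
separable_table <- function(n_per_class = 40, seed = 42) {
  centers <- rbind(c(5, 1), c(30, 2), c(55, 4), c(75, 10), c(50, 35))
  set.seed(seed)
  rows <- lapply(1:5, function(r) {
    data.frame(yellow_pct = pmax(0, centers[r, 1] + stats::rnorm(n_per_class, 0, 0.8)),
               brown_pct = pmax(0, centers[r, 2] + stats::rnorm(n_per_class, 0, 0.4)),
               rating = r)
  })
  do.call(rbind, rows)
}

# Uniform probe points over the feasible simplex for determinism checks.
probe_grid <- function(step = 5) {
  g <- expand.grid(yellow_pct = seq(0, 100, step), brown_pct = seq(0, 100, step))
  g[g$yellow_pct + g$brown_pct <= 100, ]
}

# A soil-only image: low-saturation noise, no canopy blob.
soil_image <- function(size = 128, seed = 99) {
  set.seed(seed)
  n <- size * size
  h <- matrix(runif(n, 20, 60), size, size)
  s <- matrix(runif(n, 0, 0.1), size, size)
  v <- matrix(runif(n, 0.35, 0.65), size, size)
  idcscore:::hsv_to_rgb(structure(list(h = h, s = s, v = v),
                                  class = "idc_hsv"))
}
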