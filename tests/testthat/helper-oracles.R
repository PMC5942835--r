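# Independent brute-force oracles, deliberately written with different
# algorithms from the package implementations.

# Connected-component labelling by explicit flood fill with a queue.
oracle_flood_fill <- function(cells) {
  key <- paste(cells$col, cells$row)
  label <- rep(NA_integer_, nrow(cells))
  next_id <- 0L
  for (start in seq_len(nrow(cells))) {
    if (!is.na(label[start])) next
    next_id <- next_id + 1L
    queue <- start
    label[start] <- next_id
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      nb <- c(paste(cells$col[i] + 1, cells$row[i]),
              paste(cells$col[i] - 1, cells$row[i]),
              paste(cells$col[i], cells$row[i] + 1),
              paste(cells$col[i], cells$row[i] - 1))
      j <- match(nb, key)
      j <- j[!is.na(j)]
      j <- j[is.na(label[j])]
      label[j] <- next_id
      queue <- c(queue, j)
    }
  }
  label
}

# Do two labelings induce the same partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

oracle_dmax <- function(m) {
  best <- 0
  n <- nrow(m)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt((m[i, 1] - m[j, 1])^2 + (m[i, 2] - m[j, 2])^2)
      if (d > best) best <- d
    }
  }
  unname(best)
}

# Perimeter by enumerating each cell's four sides.
oracle_perimeter <- function(m) {
  key <- paste(m[, 1], m[, 2])
  total <- 0L
  for (i in seq_len(nrow(m))) {
    nb <- c(paste(m[i, 1] + 1, m[i, 2]), paste(m[i, 1] - 1, m[i, 2]),
            paste(m[i, 1], m[i, 2] + 1), paste(m[i, 1], m[i, 2] - 1))
    total <- total + sum(!(nb %in% key))
  }
  total
}

# Characteristic length by explicit double loop over cell pairs.
oracle_cl <- function(m, pops) {
  n <- sum(pops)
  if (n < 2) return(NA_real_)
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (j <= i) next
      d <- sqrt((m[i, 1] - m[j, 1])^2 + (m[i, 2] - m[j, 2])^2)
      acc <- acc + pops[i] * pops[j] * d
    }
  }
  unname(acc / choose(n, 2) / sqrt(nrow(m)))
}

# Kendall tau-b by explicit concordant/discordant counting.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Random connected polyomino grown by a process unlike the package's
# frontier-based Eden growth: pick a random member cell, step to a random
# neighbour, add it if new.
random_polyomino <- function(n_cells) {
  cells <- matrix(c(0L, 0L), ncol = 2)
  key <- "0 0"
  while (nrow(cells) < n_cells) {
    i <- sample.int(nrow(cells), 1)
    step <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1)[[1]]
    cand <- cells[i, ] + step
    ck <- paste(cand[1], cand[2])
    if (!(ck %in% key)) {
      cells <- rbind(cells, cand)
      key <- c(key, ck)
    }
  }
  dimnames(cells) <- list(NULL, c("col", "row"))
  cells
}
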