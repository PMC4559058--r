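# Independent closed-form oracles, kept deliberately separate from the
# package's gamma/alpha code path.

oracle_sorensen <- function(x, y) {
  a <- sum(x > 0 & y > 0)
  2 * a / (sum(x > 0) + sum(y > 0))
}

oracle_horn <- function(x, y) {
  p <- x / sum(x)
  q <- y / sum(y)
  H <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  m <- (p + q) / 2
  # overlap = 1 - (H(mix) - mean entropies)/log 2
  1 - (H(m) - (H(p) + H(q)) / 2) / log(2)
}

oracle_morisita_horn <- function(x, y) {
  p <- x / sum(x)
  q <- y / sum(y)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

oracle_pairwise <- function(x, y, q) {
  switch(as.character(q),
         "0" = oracle_sorensen(x, y),
         "1" = oracle_horn(x, y),
         "2" = oracle_morisita_horn(x, y),
         stop("no classic oracle for q = ", q))
}

# BH step-up applied literally from its definition
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k_ok <- which(p[ord] <= seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(k_ok)) reject[ord[seq_len(max(k_ok))]] <- TRUE
  reject
}

# random community pair over a shared species axis
random_pair <- function(S = 30, shared_frac = 0.5) {
  x <- rgamma(S, 0.5)
  y <- rgamma(S, 0.5)
  drop_x <- sample.int(S, round(S * (1 - shared_frac) / 2))
  drop_y <- sample(setdiff(seq_len(S), drop_x), round(S * (1 - shared_frac) / 2))
  x[drop_x] <- 0
  y[drop_y] <- 0
  list(x = x, y = y)
}

# small abundance matrix fixture
toy_matrix <- function() {
  abundance_matrix(rbind(s1 = c(spA = 3, spB = 0, spC = 2),
                         s2 = c(spA = 0, spB = 1, spC = 4),
                         s3 = c(spA = 5, spB = 5, spC = 0)))
}

toy_metadata <- function(ids, habitat, lat = NULL, lon = NULL) {
  n <- length(ids)
  data.frame(sample_id = ids, habitat = habitat,
             block = rep("blk", n),
             latitude = if (is.null(lat)) rep(5, n) else lat,
             longitude = if (is.null(lon)) rep(117, n) else lon,
             year = rep(2011L, n), stringsAsFactors = FALSE)
}
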