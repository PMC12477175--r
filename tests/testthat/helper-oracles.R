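# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths (EBImage labeling, wilcox.test, ...):
# flood fill by explicit queue, rank formulas written from the
# textbook definitions, exhaustive enumeration for exact p-values.

# Connected-component labeling by breadth-first flood fill.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nbr))) {
        r <- pr + nbr[k, 1]; c <- pc + nbr[k, 2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        q <- (c - 1L) * nr + r
        if (mask[q] != 0 && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Component pixel sets (sorted lists of linear indices), label-order
# independent representation for comparisons.
component_sets <- function(lab) {
  if (max(lab) == 0) return(list())
  unname(lapply(split(which(lab > 0), lab[lab > 0]), sort))
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (no ties assumed).
mw_enum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Kruskal-Wallis H with tie correction, straight from the rank-sum
# formula.
kw_formula_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  t <- table(x)
  h / (1 - sum(t^3 - t) / (n^3 - n))
}

# All-pairs minimum chessboard distance between two lists of pixel
# index sets; returns the pair table at a gap tolerance.
contact_pairs_oracle <- function(sets_a, sets_b, nrow_img, max_gap) {
  out <- NULL
  for (i in seq_along(sets_a)) {
    ra <- (sets_a[[i]] - 1L) %% nrow_img; ca <- (sets_a[[i]] - 1L) %/% nrow_img
    for (j in seq_along(sets_b)) {
      rb <- (sets_b[[j]] - 1L) %% nrow_img; cb <- (sets_b[[j]] - 1L) %/% nrow_img
      d <- min(outer(ra, rb, function(u, v) abs(u - v)) |>
                 pmax(outer(ca, cb, function(u, v) abs(u - v))))
      if (max(0, d - 1) <= max_gap) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Minimal ZIP archiver (stored entries, no compression) so ROI-archive
# fixtures can be built in code without an external zip binary.
crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320 as signed
      else bitwShiftR(c, 1)
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(bitwShiftR(c, 8) , crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  bitwXor(c, -1L)
}

le <- function(v, n) {  # little-endian n-byte encoding of a (possibly signed) int
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(bitwAnd(v, 255L))
    v <- bitwShiftR(v, 8)
  }
  out
}

make_zip <- function(files, zipfile) {
  locals <- raw(0); centrals <- raw(0); offset <- 0L
  for (f in files) {
    data <- readBin(f, "raw", file.size(f))
    name <- charToRaw(basename(f))
    crc <- crc32(data)
    sz <- length(data)
    lh <- c(charToRaw("PK"), as.raw(c(3, 4)), le(20L, 2), le(0L, 2), le(0L, 2),
            le(0L, 2), le(33L, 2), le(crc, 4), le(sz, 4), le(sz, 4),
            le(length(name), 2), le(0L, 2), name, data)
    ch <- c(charToRaw("PK"), as.raw(c(1, 2)), le(20L, 2), le(20L, 2), le(0L, 2),
            le(0L, 2), le(0L, 2), le(33L, 2), le(crc, 4), le(sz, 4), le(sz, 4),
            le(length(name), 2), le(0L, 2), le(0L, 2), le(0L, 2), le(0L, 2),
            le(0L, 4), le(offset, 4), name)
    locals <- c(locals, lh)
    centrals <- c(centrals, ch)
    offset <- offset + length(lh)
  }
  eocd <- c(charToRaw("PK"), as.raw(c(5, 6)), le(0L, 2), le(0L, 2),
            le(length(files), 2), le(length(files), 2),
            le(length(centrals), 4), le(length(locals), 4), le(0L, 2))
  writeBin(c(locals, centrals, eocd), zipfile)
  zipfile
}

# small, fast generator configuration used by module tests; user
# arguments override the downsized defaults
small_config <- function(...) {
  args <- list(image_shape = c(360L, 360L), n_follicles = 1L,
               follicle_radius_px = c(mean = 95, sd = 5),
               cell_counts = c("B" = 25, "GC-B" = 15, "T_FH" = 10,
                               "T_FK" = 5, "Treg" = 10, "other" = 5))
  user <- list(...)
  args[names(user)] <- user
  do.call(synth_config, args)
}
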