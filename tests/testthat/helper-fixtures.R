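# Shared fixture builders: everything is generated in code at test time.

# Synthetic catalog + HDF5 embedding store in a fresh temp dir.
make_fixture <- function(n, dim = 8L, seed = 7L, length_range = c(20L, 60L),
                         prefix = "p") {
  dir <- tempfile("fixture")
  dir.create(dir)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  fx <- generate_synthetic_store(ids, file.path(dir, "embeddings.h5"),
                                 length_range = length_range, dim = dim,
                                 seed = seed)
  list(catalog = fx$catalog, store = fx$store, dir = dir, ids = ids)
}

# Canonical multiset key for a prediction record set: id pair + score at the
# written precision. Set comparisons go through sort() so row order (which
# is completion order under multiple workers) never matters.
pred_key <- function(df) sort(sprintf("%s|%s|%.6f", df$id1, df$id2, df$score))

# Independent brute-force oracle for the unordered-pair universe: explicit
# double loop, no closed forms shared with the implementation.
brute_pairs <- function(n) {
  out <- list()
  k <- 0L
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n) {
      k <- k + 1L
      out[[k]] <- c(i, j)
      j <- j + 1L
    }
  }
  if (k == 0L) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
}

# All unordered distinct-protein pairs of a catalog as "u|v" keys in
# catalog order.
all_pair_keys <- function(catalog) {
  pos <- brute_pairs(length(catalog))
  sprintf("%s|%s", catalog$ids[pos[, 1L]], catalog$ids[pos[, 2L]])
}
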