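#' Open a keyed per-protein embedding store
#'
#' The store is a single HDF5 file holding one 2-D float dataset per protein
#' id at the container root; each dataset has shape `length x dim` (one row
#' per residue). Opening reads only the key listing and shapes, never the
#' arrays, so arbitrarily large stores can be opened cheaply and read
#' block-by-block.
#'
#' @param path Path to an HDF5 file.
#' @return An object of class `embedding_store` with fields `path`, `ids`,
#'   `lengths`, `dims` (per-key embedding dimensionality).
#' @export
open_embedding_store <- function(path) {
  if (!file.exists(path)) {
    stop("embedding store not found: ", path, call. = FALSE)
  }
  ls <- tryCatch(
    rhdf5::h5ls(path, recursive = FALSE),
    error = function(e) stop("malformed embedding store at ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ls <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
  if (anyDuplicated(ls$name)) {
    stop("duplicate keys in embedding store: ",
         paste(unique(ls$name[duplicated(ls$name)]), collapse = ", "),
         call. = FALSE)
  }
  shapes <- strsplit(ls$dim, " x ", fixed = TRUE)
  structure(
    list(path = path,
         ids = ls$name,
         lengths = vapply(shapes, function(d)
           if (length(d) >= 1L) as.integer(d[[1L]]) else NA_integer_,
           integer(1)),
         dims = vapply(shapes, function(d)
           if (length(d) >= 2L) as.integer(d[[2L]]) else NA_integer_,
           integer(1))),
    class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d proteins at %s\n", length(x$ids), x$path))
  invisible(x)
}

#' Protein ids available in a store
#' @param store An [open_embedding_store()] handle.
#' @return Character vector of keys.
#' @export
store_ids <- function(store) {
  stopifnot(inherits(store, "embedding_store"))
  store$ids
}

#' Fetch one protein's embedding
#'
#' @param store An [open_embedding_store()] handle.
#' @param id Protein identifier (store key).
#' @return The embedding matrix, `length x dim`.
#' @export
fetch_embedding <- function(store, id) {
  stopifnot(inherits(store, "embedding_store"))
  if (!id %in% store$ids) {
    stop("protein missing from embedding store: ", id, call. = FALSE)
  }
  emb <- rhdf5::h5read(store$path, id)
  if (!is.matrix(emb)) emb <- as.matrix(emb)
  storage.mode(emb) <- "double"
  emb
}

#' Write a named list of embedding matrices as a store
#'
#' @param embeddings Named list; each element a numeric `length x dim`
#'   matrix, names are protein ids. Values are stored as 32-bit floats, the
#'   precision the engine's byte accounting assumes.
#' @param path Destination HDF5 file.
#' @param overwrite Replace an existing file.
#' @return An [open_embedding_store()] handle on the new file.
#' @export
write_embedding_store <- function(embeddings, path, overwrite = FALSE) {
  if (is.null(names(embeddings)) || anyDuplicated(names(embeddings))) {
    stop("`embeddings` must be a uniquely named list", call. = FALSE)
  }
  if (file.exists(path)) {
    if (!overwrite) stop("refusing to overwrite existing store: ", path,
                         call. = FALSE)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  for (id in names(embeddings)) {
    emb <- embeddings[[id]]
    if (!is.matrix(emb) || !is.numeric(emb)) {
      stop("embedding for ", id, " is not a numeric matrix", call. = FALSE)
    }
    rhdf5::h5createDataset(path, id, dims = dim(emb),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(emb, path, id)
  }
  rhdf5::h5closeAll()
  open_embedding_store(path)
}

#' Generate a seeded synthetic embedding store
#'
#' Writes one pseudo-random embedding per id: lengths drawn uniformly from
#' `length_range`, values standard normal, stored as 32-bit floats. The same
#' seed reproduces the store exactly; fixture suites and benchmarks are built
#' on this. (Real upstream embeddings come from a protein language model; the
#' engine treats both identically as opaque keyed arrays.)
#'
#' @param ids Unique protein identifiers.
#' @param path Destination HDF5 file.
#' @param length_range Integer two-vector, inclusive residue-count range.
#' @param dim Embedding dimensionality (default 32).
#' @param seed Integer seed.
#' @param overwrite Replace an existing file.
#' @return A list with the store handle (`store`) and the matching
#'   [protein_catalog()] (`catalog`) recording the drawn lengths.
#' @export
generate_synthetic_store <- function(ids, path, length_range = c(50L, 200L),
                                     dim = 32L, seed = 1L,
                                     overwrite = FALSE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("`ids` must be unique", call. = FALSE)
  dim <- as.integer(assert_count(dim, "dim"))
  if (dim < 1L) stop("`dim` must be at least 1", call. = FALSE)
  if (length(length_range) != 2L || any(length_range < 1L) ||
      length_range[1L] > length_range[2L]) {
    stop("`length_range` must be an increasing pair of positive integers",
         call. = FALSE)
  }
  embeddings <- with_seed(seed, {
    lens <- sample.int(length_range[2L] - length_range[1L] + 1L,
                       length(ids), replace = TRUE) + length_range[1L] - 1L
    out <- lapply(lens, function(L) matrix(stats::rnorm(L * dim), L, dim))
    names(out) <- ids
    out
  })
  store <- write_embedding_store(embeddings, path, overwrite = overwrite)
  list(store = store,
       catalog = protein_catalog(ids, vapply(embeddings, nrow, integer(1))))
}

#' Memory accountant for resident embedding blocks
#'
#' Tracks which blocks are resident, their byte sizes (4 bytes per float
#' value), and the running peak. The accountant enforces a residency
#' capacity: a load that would exceed it aborts with a diagnostic. For
#' full-block serpentine traversal the capacity is `min(B, 3)` — the
#' engine's memory guarantee is enforced at run time, not merely asserted.
#'
#' @param capacity Maximum number of simultaneously resident blocks.
#' @return An object of class `memory_accountant`.
#' @export
memory_accountant <- function(capacity = 3L) {
  capacity <- as.integer(assert_count(capacity, "capacity"))
  if (capacity < 1L) stop("`capacity` must be at least 1", call. = FALSE)
  acct <- new.env(parent = emptyenv())
  acct$capacity <- capacity
  acct$resident <- list()   # block label -> list(bytes, n_proteins)
  acct$peak_blocks <- 0L
  acct$total_loads <- 0L
  acct$loaded_proteins <- 0
  acct$loaded_bytes <- 0
  class(acct) <- "memory_accountant"
  acct
}

#' @export
print.memory_accountant <- function(x, ...) {
  cat(sprintf(
    "<memory_accountant> %d/%d blocks resident (%.1f MB); peak %d; %d loads\n",
    length(x$resident), x$capacity, resident_bytes(x) / 2^20,
    x$peak_blocks, x$total_loads))
  invisible(x)
}

#' Total bytes currently resident according to the accountant
#' @param accountant A [memory_accountant()].
#' @return Byte count (double).
#' @export
resident_bytes <- function(accountant) {
  sum(vapply(accountant$resident, `[[`, numeric(1), "bytes"))
}

#' Resident block labels
#' @param accountant A [memory_accountant()].
#' @return Character vector of block labels currently resident.
#' @export
resident_blocks <- function(accountant) {
  names(accountant$resident)
}

register_load <- function(accountant, label, bytes, n_proteins) {
  if (label %in% names(accountant$resident)) {
    stop("block already resident: ", label, call. = FALSE)
  }
  if (length(accountant$resident) + 1L > accountant$capacity) {
    stop(sprintf(
      "memory bound exceeded: loading block %s would make %d resident (capacity %d)",
      label, length(accountant$resident) + 1L, accountant$capacity),
      call. = FALSE)
  }
  accountant$resident[[label]] <- list(bytes = bytes, n_proteins = n_proteins)
  accountant$peak_blocks <- max(accountant$peak_blocks,
                                length(accountant$resident))
  accountant$total_loads <- accountant$total_loads + 1L
  accountant$loaded_proteins <- accountant$loaded_proteins + n_proteins
  accountant$loaded_bytes <- accountant$loaded_bytes + bytes
  invisible(accountant)
}

#' Load one block of embeddings into memory
#'
#' Reads the embeddings of a block's proteins (all of them, or a requested
#' subset in sparse-loading mode) from the store and registers the block with
#' the memory accountant. Byte size is accounted as
#' `length x dim x 4` per protein (32-bit floats).
#'
#' @param store An [open_embedding_store()] handle.
#' @param partition A catalog-backed [block_partition()].
#' @param block_index 1-based block index.
#' @param selection Optional character vector of protein ids to load; must be
#'   a subset of the block's membership (sparse-loading mode).
#' @param accountant Optional [memory_accountant()]; when given, the load is
#'   registered (and capacity enforced) under `label`.
#' @param label Block label used in accounting (defaults to the index).
#' @return A `resident_block`: list with `block_index`, `label`, `records`
#'   (named list of embedding matrices) and `byte_size`.
#' @export
load_block <- function(store, partition, block_index, selection = NULL,
                       accountant = NULL, label = as.character(block_index)) {
  members <- block_members(partition, block_index)
  wanted <- members
  if (!is.null(selection)) {
    bad <- setdiff(selection, members)
    if (length(bad) > 0L) {
      stop("selection contains proteins outside block ", block_index, ": ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    wanted <- members[members %in% selection]
  }
  absent <- setdiff(wanted, store$ids)
  if (length(absent) > 0L) {
    stop("proteins missing from embedding store: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  records <- lapply(wanted, function(id) fetch_embedding(store, id))
  names(records) <- wanted
  bytes <- sum(vapply(records, function(m) nrow(m) * ncol(m) * 4, numeric(1)))
  if (!is.null(accountant)) {
    register_load(accountant, label, bytes, length(records))
  }
  structure(
    list(block_index = as.integer(block_index), label = label,
         records = records, byte_size = bytes),
    class = "resident_block")
}

#' Evict a resident block
#'
#' Releases a block from the accountant's resident set and reports the bytes
#' freed. Evicting a block that is not resident is a state error.
#'
#' @param accountant A [memory_accountant()].
#' @param label Block label previously registered by [load_block()].
#' @return Bytes released, invisibly.
#' @export
evict_block <- function(accountant, label) {
  label <- as.character(label)
  if (!label %in% names(accountant$resident)) {
    stop("cannot evict block ", label, ": not resident", call. = FALSE)
  }
  bytes <- accountant$resident[[label]]$bytes
  accountant$resident[[label]] <- NULL
  invisible(bytes)
}
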