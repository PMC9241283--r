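#' @title File-backed hash-chained stream store
#'
#' @description
#' A single-node emulation of a private blockchain with named data streams:
#' append-only publication of key:value items, key-indexed retrieval, batching
#' of transactions into hash-linked blocks, on-chain permissions, and whole
#' chain integrity verification. Persistence is an append-only item log plus a
#' block log under one directory; the in-memory key index is derived data,
#' rebuilt on open, and never part of integrity checks.
#'
#' "Nodes" of a real network are modelled as publisher identities with
#' permissions recorded on-chain, not as processes.
#'
#' @name chainstore
NULL

RESERVED_STREAMS <- c("_streams", "_permissions")
GENESIS_HASH <- strrep("0", 64)

# Stream keys: 1-256 printable ASCII characters, no whitespace, no single or
# double quotes (the stream-item contract of the emulated platform).
KEY_REGEX <- "^[!#-&(-~]{1,256}$"

is_valid_key <- function(k) {
  is.character(k) & !is.na(k) & grepl(KEY_REGEX, k, perl = TRUE)
}

is_valid_identity <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) && grepl("^[!#-&(-~]{1,64}$", x, perl = TRUE)
}

chain_paths <- function(dir) {
  list(
    header = file.path(dir, "chain.json"),
    items  = file.path(dir, "items.log"),
    blocks = file.path(dir, "blocks.log")
  )
}

#' Create a new chain
#'
#' Initializes an empty chain directory: a self-describing header (chain name,
#' hash algorithm, block size), an empty append-only item log and block log.
#' The reserved streams `_streams` (stream registry) and `_permissions`
#' (grant/revoke records) exist from the start, and the owner identity is
#' granted read, write and admin on-chain.
#'
#' @param dir Directory to create the chain in (must not already hold a chain).
#' @param name Chain name (printable ASCII identifier).
#' @param owner Identity string of the chain owner.
#' @param block_size Seal a block automatically every `block_size` pending
#'   transactions (logical sealing; deterministic). An explicit
#'   [mine_pending()] seals earlier.
#' @return A chain handle (environment of class `genochain_store`).
#' @export
chain_create <- function(dir, name = "genochain", owner = "owner",
                         block_size = 1000L) {
  if (!is_valid_identity(owner)) stop("invalid owner identity: ", owner)
  if (!is_valid_identity(name)) stop("invalid chain name: ", name)
  p <- chain_paths(dir)
  if (file.exists(p$header)) stop("chain already exists in ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    name = name, owner = owner, hash_algo = "sha256",
    block_size = as.integer(block_size), format = 1L
  )
  writeLines(canonical_json(header), p$header)
  file.create(p$items, p$blocks)
  ch <- chain_state(dir, header)
  # bootstrap: owner holds every role, recorded on-chain like any other grant
  for (role in c("read", "write", "admin")) {
    publish_permission(ch, owner, owner, role, TRUE)
  }
  ch
}

#' Open an existing chain
#'
#' Replays the item and block logs to rebuild the in-memory state: stream
#' registry, per-key index, effective permissions, transaction counter and the
#' pending (unsealed) pool.
#'
#' @param dir Chain directory created by [chain_create()].
#' @return A chain handle.
#' @export
chain_open <- function(dir) {
  p <- chain_paths(dir)
  if (!file.exists(p$header)) stop("no chain found in ", dir)
  header <- jsonlite::fromJSON(readLines(p$header, warn = FALSE))
  ch <- chain_state(dir, header)
  replay_logs(ch)
  ch
}

# fresh in-memory state bound to an on-disk chain directory
chain_state <- function(dir, header) {
  ch <- new.env(parent = emptyenv())
  ch$dir <- dir
  ch$name <- header$name
  ch$owner <- header$owner
  ch$hash_algo <- header$hash_algo
  ch$block_size <- as.integer(header$block_size)
  ch$counter <- 0L
  ch$n_items <- 0L
  ch$items <- new.env(parent = emptyenv())       # "<id>" -> item record
  ch$streams <- new.env(parent = emptyenv())     # stream -> integer item ids
  ch$key_index <- new.env(parent = emptyenv())   # "stream\x1fkey" -> item ids
  ch$perms <- new.env(parent = emptyenv())       # "who\x1frole" -> logical
  ch$blocks <- list()
  ch$pending <- character(0)                     # txids awaiting sealing
  ch$txid_height <- new.env(parent = emptyenv()) # txid -> block height
  ch$read_log <- NULL
  ch$log_con <- NULL
  for (s in RESERVED_STREAMS) ch$streams[[s]] <- integer(0)
  class(ch) <- "genochain_store"
  reg.finalizer(ch, function(e) {
    if (!is.null(e$log_con)) try(close(e$log_con), silent = TRUE)
  }, onexit = TRUE)
  ch
}

# During bulk insertion a persistent append connection avoids per-item
# open/close cost; it is flushed after every write so other handles (and
# verify_chain) always see a complete file, and closed when the batch ends.
begin_batch <- function(chain) {
  chain$batch_mode <- TRUE
  invisible(chain)
}

end_batch <- function(chain) {
  chain$batch_mode <- FALSE
  if (!is.null(chain$log_con)) {
    try(close(chain$log_con), silent = TRUE)
    chain$log_con <- NULL
  }
  invisible(chain)
}

append_log_line <- function(chain, line) {
  if (isTRUE(chain$batch_mode)) {
    if (is.null(chain$log_con)) {
      chain$log_con <- file(chain_paths(chain$dir)$items, open = "at")
    }
    writeLines(line, chain$log_con)
    flush(chain$log_con)
  } else {
    con <- file(chain_paths(chain$dir)$items, open = "at")
    writeLines(line, con)
    close(con)
  }
}

#' @export
print.genochain_store <- function(x, ...) {
  cat(sprintf(
    "<genochain store '%s'>\n  dir: %s\n  streams: %d (+%d reserved)  items: %d  blocks: %d  pending: %d\n",
    x$name, x$dir,
    length(chain_streams(x)), length(RESERVED_STREAMS),
    x$n_items, length(x$blocks), length(x$pending)
  ))
  invisible(x)
}

#' List stream names on a chain
#' @param chain Chain handle.
#' @param include_reserved Include the reserved `_streams` / `_permissions`
#'   streams.
#' @return Character vector of stream names in creation order.
#' @export
chain_streams <- function(chain, include_reserved = FALSE) {
  ids <- chain$streams[["_streams"]]
  nm <- vapply(ids, function(i) get_item(chain, i)$data, "")
  if (include_reserved) c(RESERVED_STREAMS, nm) else nm
}

get_item <- function(chain, i) chain$items[[as.character(i)]]

has_permission <- function(chain, who, role) {
  isTRUE(chain$perms[[paste(who, role, sep = "\x1f")]])
}

require_permission <- function(chain, who, role) {
  if (!has_permission(chain, who, role)) {
    stop(sprintf("permission denied: '%s' lacks %s permission", who, role),
         call. = FALSE)
  }
}

# digest of (stream, publisher, sorted keys, counter) || data bytes;
# the chain-wide counter makes txids unique even for duplicate payloads
make_txid <- function(stream, publisher, keys, data_raw, counter) {
  head <- paste(stream, publisher,
                paste(sort(keys), collapse = " "), counter, sep = "\x1f")
  digest::digest(c(charToRaw(head), as.raw(0x1f), data_raw),
                 algo = "sha256", serialize = FALSE)
}

block_hash <- function(height, timestamp, txids, prev_hash) {
  sha256_hex(paste(height, timestamp, paste(txids, collapse = " "),
                   prev_hash, sep = "\x1f"))
}

#' Create a data stream
#'
#' Registers a new named stream. The creation is itself a transaction: an item
#' in the reserved `_streams` registry, so stream creation is timestamped and
#' sealed into a block like any data publication.
#'
#' @param chain Chain handle.
#' @param name Stream name (printable ASCII identifier, unique on the chain).
#' @param creator Identity creating the stream; needs write or admin
#'   permission.
#' @return The stream name, invisibly.
#' @export
create_stream <- function(chain, name, creator = chain$owner) {
  if (!is_valid_identity(name)) stop("invalid stream name: ", name)
  if (name %in% RESERVED_STREAMS || !is.null(chain$streams[[name]])) {
    stop("duplicate stream name: ", name, call. = FALSE)
  }
  if (!(has_permission(chain, creator, "write") ||
        has_permission(chain, creator, "admin"))) {
    stop(sprintf("permission denied: '%s' lacks write permission", creator),
         call. = FALSE)
  }
  publish_item(chain, "_streams", creator, keys = name, data = name,
               system = TRUE)
  chain$streams[[name]] <- integer(0)
  invisible(name)
}

#' Publish an item to a stream
#'
#' Appends one key:value item; the publication is a pending transaction until
#' a block seals it. The per-key retrieval index is updated immediately
#' (subscribe-time indexing).
#'
#' @param chain Chain handle.
#' @param stream Stream name.
#' @param publisher Publishing identity; needs write permission.
#' @param keys Character vector of retrieval keys (each 1-256 printable ASCII
#'   characters, no whitespace or quotes). May be empty.
#' @param data Item payload: a character scalar.
#' @return The transaction id (SHA-256 hex digest).
#' @export
publish <- function(chain, stream, publisher, keys = character(0), data = "") {
  if (stream %in% RESERVED_STREAMS) {
    stop("cannot publish directly to reserved stream ", stream, call. = FALSE)
  }
  if (is.null(chain$streams[[stream]])) {
    stop("unknown stream: ", stream, call. = FALSE)
  }
  require_permission(chain, publisher, "write")
  publish_item(chain, stream, publisher, keys, data, system = FALSE)
}

publish_item <- function(chain, stream, publisher, keys, data, system) {
  keys <- as.character(keys)
  bad <- keys[!is_valid_key(keys)]
  if (length(bad)) {
    stop("invalid stream key: '", bad[[1]],
         "' (1-256 printable ASCII characters, no whitespace or quotes)",
         call. = FALSE)
  }
  if (!is.character(data) || length(data) != 1L || is.na(data)) {
    stop("data must be a character scalar", call. = FALSE)
  }
  chain$counter <- chain$counter + 1L
  data_raw <- charToRaw(data)
  txid <- make_txid(stream, publisher, keys, data_raw, chain$counter)
  blocktime <- as.integer(Sys.time())
  line <- paste(chain$counter, txid, stream, publisher, blocktime,
                paste(keys, collapse = " "), hex_encode(data_raw), sep = "\t")
  append_log_line(chain, line)
  index_item(chain, chain$counter, txid, stream, publisher, blocktime,
             keys, data, pending = TRUE)
  if (length(chain$pending) >= chain$block_size) mine_pending(chain)
  txid
}

# register one item in the in-memory state (shared by publish and replay)
index_item <- function(chain, counter, txid, stream, publisher, blocktime,
                       keys, data, pending) {
  i <- chain$n_items + 1L
  chain$n_items <- i
  chain$items[[as.character(i)]] <-
    list(txid = txid, stream = stream, publisher = publisher,
         blocktime = blocktime, keys = keys, data = data)
  chain$streams[[stream]] <- c(chain$streams[[stream]], i)
  for (k in keys) {
    kk <- paste(stream, k, sep = "\x1f")
    chain$key_index[[kk]] <- c(chain$key_index[[kk]], i)
  }
  if (stream == "_permissions") apply_permission_item(chain, data)
  if (stream == "_streams" && is.null(chain$streams[[data]])) {
    chain$streams[[data]] <- integer(0)   # registry entry: stream may be empty
  }
  if (pending) chain$pending <- c(chain$pending, txid)
  i
}

#' Seal pending transactions into a block
#'
#' Batches every pending transaction into a new block linked to its
#' predecessor by hash. With no pending transactions this is a no-op. Blocks
#' are also sealed automatically every `block_size` publications; an optional
#' wall-clock mode (see [insert_alignments()]'s `flush_seconds`) can seal on a
#' timer instead, mirroring a 15-second target block time.
#'
#' @param chain Chain handle.
#' @param timestamp Unix-seconds block timestamp (defaults to now).
#' @return The sealed block as a list (`height`, `timestamp`, `txids`,
#'   `prev_hash`, `hash`), or `NULL` when nothing was pending.
#' @export
mine_pending <- function(chain, timestamp = as.integer(Sys.time())) {
  if (length(chain$pending) == 0L) return(invisible(NULL))
  height <- length(chain$blocks)
  prev <- if (height == 0L) GENESIS_HASH else chain$blocks[[height]]$hash
  txids <- chain$pending
  blk <- list(
    height = height, timestamp = as.integer(timestamp), txids = txids,
    prev_hash = prev, hash = block_hash(height, timestamp, txids, prev)
  )
  line <- paste(blk$height, blk$timestamp, blk$prev_hash, blk$hash,
                paste(txids, collapse = " "), sep = "\t")
  con <- file(chain_paths(chain$dir)$blocks, open = "at")
  writeLines(line, con)
  close(con)
  chain$blocks[[height + 1L]] <- blk
  for (tx in txids) chain$txid_height[[tx]] <- height
  chain$pending <- character(0)
  invisible(blk)
}

items_frame <- function(chain, ids) {
  recs <- lapply(ids, get_item, chain = chain)
  n_blocks <- length(chain$blocks)
  data.frame(
    publisher = vapply(recs, `[[`, "", "publisher"),
    keys = I(lapply(recs, `[[`, "keys")),
    data = vapply(recs, `[[`, "", "data"),
    txid = vapply(recs, `[[`, "", "txid"),
    blocktime = vapply(recs, `[[`, 0L, "blocktime"),
    confirmations = vapply(recs, function(r) {
      h <- chain$txid_height[[r$txid]]
      if (is.null(h)) 0L else n_blocks - h
    }, 0L),
    stringsAsFactors = FALSE
  )
}

note_read <- function(chain, stream) {
  if (!is.null(chain$read_log)) chain$read_log <- c(chain$read_log, stream)
}

#' Retrieve all items of a stream
#'
#' @param chain Chain handle.
#' @param stream Stream name.
#' @param reader Identity reading; needs read permission.
#' @return A data.frame with one row per item in publication order: columns
#'   `publisher`, `keys` (list column), `data`, `txid`, `blocktime`,
#'   `confirmations` (blocks sealed at or after the item's block; 0 while
#'   pending).
#' @export
list_stream_items <- function(chain, stream, reader = chain$owner) {
  if (is.null(chain$streams[[stream]])) {
    stop("unknown stream: ", stream, call. = FALSE)
  }
  require_permission(chain, reader, "read")
  note_read(chain, stream)
  items_frame(chain, chain$streams[[stream]])
}

#' Retrieve the items of a stream carrying a given key
#'
#' Uses the per-key index; an unknown key yields an empty result, not an
#' error.
#'
#' @inheritParams list_stream_items
#' @param key Key string to look up.
#' @return As [list_stream_items()], restricted to items whose key list
#'   contains `key`, in publication order.
#' @export
list_stream_key_items <- function(chain, stream, key, reader = chain$owner) {
  if (is.null(chain$streams[[stream]])) {
    stop("unknown stream: ", stream, call. = FALSE)
  }
  require_permission(chain, reader, "read")
  note_read(chain, stream)
  ids <- chain$key_index[[paste(stream, key, sep = "\x1f")]] %||% integer(0)
  items_frame(chain, ids)
}

#' Record read activity per stream
#'
#' Turns on (or off) an instrumentation log of every stream touched by
#' [list_stream_items()] / [list_stream_key_items()], used to demonstrate that
#' region queries only read the streams their bins dictate.
#'
#' @param chain Chain handle.
#' @param enable Start a fresh log (`TRUE`) or disable logging (`FALSE`).
#' @return The previous log contents, invisibly.
#' @export
chain_read_log <- function(chain, enable = TRUE) {
  old <- chain$read_log
  chain$read_log <- if (enable) character(0) else NULL
  invisible(old)
}

# ---- permissions ---------------------------------------------------------

perm_payload <- function(grantee, role, granted) {
  paste(grantee, role, if (granted) "1" else "0")
}

apply_permission_item <- function(chain, data) {
  f <- strsplit(data, " ", fixed = TRUE)[[1]]
  chain$perms[[paste(f[[1]], f[[2]], sep = "\x1f")]] <- identical(f[[3]], "1")
}

publish_permission <- function(chain, admin, grantee, role, granted) {
  publish_item(
    chain, "_permissions", admin,
    keys = c(paste0("who=", grantee), paste0("role=", role)),
    data = perm_payload(grantee, role, granted), system = TRUE
  )
}

#' Grant or revoke a permission
#'
#' Publishes a grant/revoke record to the reserved `_permissions` stream, so
#' every permission change is an on-chain, timestamped transaction. Effective
#' permissions are the latest record per (grantee, role).
#'
#' @param chain Chain handle.
#' @param grantee Identity receiving (or losing) the role.
#' @param role One of `"read"`, `"write"`, `"admin"`.
#' @param granted `TRUE` to grant, `FALSE` to revoke.
#' @param admin Acting identity; must hold the admin role.
#' @return The transaction id of the permission record.
#' @export
set_permission <- function(chain, grantee, role, granted,
                           admin = chain$owner) {
  role <- match.arg(role, c("read", "write", "admin"))
  if (!is_valid_identity(grantee)) stop("invalid grantee identity: ", grantee)
  require_permission(chain, admin, "admin")
  publish_permission(chain, admin, grantee, role, isTRUE(granted))
}

# ---- replay and verification --------------------------------------------

parse_item_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 7L) return(NULL)
  list(counter = suppressWarnings(as.integer(f[[1]])), txid = f[[2]],
       stream = f[[3]], publisher = f[[4]],
       blocktime = suppressWarnings(as.integer(f[[5]])),
       keys = if (nzchar(f[[6]])) strsplit(f[[6]], " ", fixed = TRUE)[[1]]
              else character(0),
       data_hex = f[[7]])
}

parse_block_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 5L) return(NULL)
  list(height = suppressWarnings(as.integer(f[[1]])),
       timestamp = suppressWarnings(as.integer(f[[2]])),
       prev_hash = f[[3]], hash = f[[4]],
       txids = if (nzchar(f[[5]])) strsplit(f[[5]], " ", fixed = TRUE)[[1]]
               else character(0))
}

replay_logs <- function(chain) {
  p <- chain_paths(chain$dir)
  for (line in readLines(p$items, warn = FALSE)) {
    it <- parse_item_line(line)
    if (is.null(it)) stop("corrupt item log line in ", p$items)
    if (!(it$stream %in% RESERVED_STREAMS) &&
        is.null(chain$streams[[it$stream]])) {
      chain$streams[[it$stream]] <- integer(0)
    }
    raw <- hex_decode(it$data_hex)
    if (is.null(raw)) stop("corrupt item payload in ", p$items)
    index_item(chain, it$counter, it$txid, it$stream, it$publisher,
               it$blocktime, it$keys, rawToChar(raw), pending = TRUE)
    chain$counter <- max(chain$counter, it$counter)
  }
  sealed <- character(0)
  for (line in readLines(p$blocks, warn = FALSE)) {
    blk <- parse_block_line(line)
    if (is.null(blk)) stop("corrupt block log line in ", p$blocks)
    chain$blocks[[blk$height + 1L]] <- blk
    for (tx in blk$txids) chain$txid_height[[tx]] <- blk$height
    sealed <- c(sealed, blk$txids)
  }
  chain$pending <- setdiff(chain$pending, sealed)
  invisible(chain)
}

#' Verify chain integrity
#'
#' Re-reads the persisted logs and recomputes, from stored bytes alone, every
#' item's transaction id, every block digest and every previous-hash link, and
#' checks that every sealed transaction resolves to a logged item. Any
#' single-byte modification of persisted item data or block metadata is
#' detected. Corruption is reported, never raised.
#'
#' @param chain Chain handle (only its directory is used; verification never
#'   trusts in-memory state).
#' @return A list of class `genochain_integrity`: `valid` (logical),
#'   `first_bad_height` (height of the earliest corrupted block, `NA` if valid
#'   or if only a pending item is corrupt), `n_items`, `n_blocks`.
#' @export
verify_chain <- function(chain) {
  p <- chain_paths(chain$dir)
  bad_heights <- integer(0)
  pending_bad <- FALSE

  txid_ok <- new.env(parent = emptyenv())   # logged txid -> recomputation ok?
  for (line in readLines(p$items, warn = FALSE)) {
    it <- parse_item_line(line)
    if (is.null(it) || is.na(it$counter)) { pending_bad <- TRUE; next }
    raw <- hex_decode(it$data_hex)
    ok <- !is.null(raw) &&
      identical(make_txid(it$stream, it$publisher, it$keys, raw, it$counter),
                it$txid)
    # keep the worst verdict if a txid somehow appears twice
    txid_ok[[it$txid]] <- isTRUE(txid_ok[[it$txid]] %||% TRUE) && ok
  }

  blocks <- list()
  for (line in readLines(p$blocks, warn = FALSE)) {
    blk <- parse_block_line(line)
    if (is.null(blk) || is.na(blk$height)) { pending_bad <- TRUE; next }
    blocks[[length(blocks) + 1L]] <- blk
  }
  prev <- GENESIS_HASH
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    ok <- blk$height == i - 1L &&
      identical(blk$prev_hash, prev) &&
      identical(block_hash(blk$height, blk$timestamp, blk$txids,
                           blk$prev_hash), blk$hash)
    for (tx in blk$txids) {
      v <- txid_ok[[tx]]
      if (is.null(v) || !isTRUE(v)) ok <- FALSE
    }
    if (!ok) bad_heights <- c(bad_heights, i - 1L)
    prev <- blk$hash
  }
  # a corrupt item never sealed into any block still invalidates the chain
  sealed <- unlist(lapply(blocks, `[[`, "txids"))
  for (tx in ls(txid_ok)) {
    if (!isTRUE(txid_ok[[tx]]) && !(tx %in% sealed)) pending_bad <- TRUE
  }

  valid <- length(bad_heights) == 0L && !pending_bad
  out <- list(
    valid = valid,
    first_bad_height = if (length(bad_heights)) min(bad_heights) else NA_integer_,
    n_items = length(ls(txid_ok)),
    n_blocks = length(blocks)
  )
  class(out) <- "genochain_integrity"
  out
}

#' @export
print.genochain_integrity <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("chain OK: %d items in %d blocks, all digests verified\n",
                x$n_items, x$n_blocks))
  } else {
    cat(sprintf("chain CORRUPT: first bad block height %s (%d items, %d blocks)\n",
                format(x$first_bad_height), x$n_items, x$n_blocks))
  }
  invisible(x)
}
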