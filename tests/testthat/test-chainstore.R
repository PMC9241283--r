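test_that("streams are created empty with unique names", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "metaData")
  expect_identical(chain_streams(ch), "metaData")
  expect_identical(nrow(list_stream_items(ch, "metaData")), 0L)
  expect_error(create_stream(ch, "metaData"), "duplicate stream name")
  expect_error(list_stream_items(ch, "nope"), "unknown stream")
})

test_that("published items round-trip in publication order", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "s")
  for (d in c("A", "B", "C")) publish(ch, "s", "owner", keys = d, data = d)
  it <- list_stream_items(ch, "s")
  expect_identical(it$data, c("A", "B", "C"))
  expect_identical(anyDuplicated(it$txid), 0L)
  # identical payloads still get distinct txids (counter-salted digest)
  t1 <- publish(ch, "s", "owner", keys = "A", data = "A")
  expect_false(t1 %in% it$txid)
})

test_that("keys must be 1-256 printable ASCII chars without whitespace or quotes", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "s")
  expect_error(publish(ch, "s", "owner", keys = "FLANK 1", data = "x"),
               "invalid stream key")
  expect_error(publish(ch, "s", "owner", keys = "it's", data = "x"),
               "invalid stream key")
  expect_error(publish(ch, "s", "owner", keys = 'say"no"', data = "x"),
               "invalid stream key")
  expect_error(publish(ch, "s", "owner", keys = "", data = "x"),
               "invalid stream key")
  expect_error(publish(ch, "s", "owner", keys = strrep("k", 257L),
                       data = "x"), "invalid stream key")
  expect_silent(publish(ch, "s", "owner", keys = strrep("k", 256L),
                        data = "x"))
})

test_that("key-indexed retrieval filters exactly and unknown keys give empty results", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "s")
  publish(ch, "s", "owner", keys = "FLANK=0", data = "in-bin")
  publish(ch, "s", "owner", keys = "FLANK=1", data = "spans")
  publish(ch, "s", "owner", keys = "FLANK=0", data = "in-bin-2")
  expect_identical(list_stream_key_items(ch, "s", "FLANK=1")$data, "spans")
  expect_identical(list_stream_key_items(ch, "s", "FLANK=0")$data,
                   c("in-bin", "in-bin-2"))
  expect_identical(nrow(list_stream_key_items(ch, "s", "never-used")), 0L)
})

test_that("key index agrees with a brute-force filter over random items", {
  ch <- chain_create(new_chain_dir(), "c1", "owner", block_size = 100L)
  create_stream(ch, "s")
  set.seed(42)
  keyspace <- paste0("k", 1:20)
  for (i in 1:400) {
    publish(ch, "s", "owner",
            keys = sample(keyspace, sample(0:3, 1)),
            data = paste0("payload", i))
  }
  all_items <- list_stream_items(ch, "s")
  seen <- character(0)
  for (k in keyspace) {
    got <- list_stream_key_items(ch, "s", k)
    want <- all_items[vapply(all_items$keys, function(ks) k %in% ks, TRUE), ]
    expect_identical(got$txid, want$txid)
    seen <- union(seen, got$txid)
  }
  # retrieval completeness: union over keys = all keyed items
  keyed <- all_items$txid[lengths(all_items$keys) > 0L]
  expect_setequal(seen, keyed)
})

test_that("confirmations count blocks sealed at or after an item's block", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "s")
  publish(ch, "s", "owner", data = "early")
  expect_identical(list_stream_items(ch, "s")$confirmations, 0L)
  mine_pending(ch, 100L)
  expect_identical(list_stream_items(ch, "s")$confirmations, 1L)
  publish(ch, "s", "owner", data = "late")
  mine_pending(ch, 200L)
  expect_identical(list_stream_items(ch, "s")$confirmations, c(2L, 1L))
})

test_that("blocks link consecutively by hash from the genesis digest", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "s")
  b0 <- mine_pending(ch, 10L)
  expect_identical(b0$height, 0L)
  expect_identical(b0$prev_hash, strrep("0", 64))
  t1 <- publish(ch, "s", "owner", data = "x")
  t2 <- publish(ch, "s", "owner", data = "y")
  b1 <- mine_pending(ch, 20L)
  expect_identical(b1$height, 1L)
  expect_identical(b1$txids, c(t1, t2))
  expect_identical(b1$prev_hash, b0$hash)
  expect_null(mine_pending(ch, 30L))   # nothing pending, no block
  v <- verify_chain(ch)
  expect_true(v$valid)
  expect_identical(v$n_blocks, 2L)
})

test_that("automatic sealing keeps the chain valid through a long insertion", {
  ch <- chain_create(new_chain_dir(), "c1", "owner", block_size = 50L)
  create_stream(ch, "s")
  for (i in 1:220) {
    publish(ch, "s", "owner", data = paste0("item", i))
    if (i %% 50L == 0L) expect_true(verify_chain(ch)$valid)
  }
  mine_pending(ch)
  v <- verify_chain(ch)
  expect_true(v$valid)
  expect_identical(nrow(list_stream_items(ch, "s")), 220L)
})

test_that("a reopened chain replays to the same state", {
  d <- new_chain_dir()
  ch <- chain_create(d, "c1", "owner", block_size = 10L)
  create_stream(ch, "s")
  for (i in 1:25) publish(ch, "s", "owner", keys = "k", data = paste0("p", i))
  mine_pending(ch)
  ch2 <- chain_open(d)
  expect_identical(list_stream_items(ch2, "s"), list_stream_items(ch, "s"))
  expect_identical(list_stream_key_items(ch2, "s", "k")$txid,
                   list_stream_key_items(ch, "s", "k")$txid)
  expect_identical(ch2$counter, ch$counter)
  expect_identical(length(ch2$blocks), length(ch$blocks))
})

test_that("any single-byte tamper of persisted data is detected with its block height", {
  d <- new_chain_dir()
  ch <- chain_create(d, "c1", "owner", block_size = 5L)
  create_stream(ch, "s")
  for (i in 1:30) publish(ch, "s", "owner", keys = "k", data = paste0("pay", i))
  mine_pending(ch)
  expect_true(verify_chain(ch)$valid)

  flip <- function(path, line_no, col) {
    lines <- readLines(path, warn = FALSE)
    ch0 <- substr(lines[[line_no]], col, col)
    repl <- if (ch0 == "0") "1" else "0"
    substr(lines[[line_no]], col, col) <- repl
    writeLines(lines, path)
  }

  items_path <- file.path(d, "items.log")
  orig_items <- readLines(items_path, warn = FALSE)
  # fuzz bytes of the persisted item *data* (the hex payload after the sixth
  # tab); publisher/keys/stream/counter are equally covered by the txid
  # digest, while blocktime is item metadata outside it by design
  data_span <- function(line) {
    tabs <- gregexpr("\t", line, fixed = TRUE)[[1]]
    c(tabs[[6]] + 1L, nchar(line))
  }
  set.seed(7)
  for (trial in 1:15) {
    ln <- sample(length(orig_items), 1)
    sp <- data_span(orig_items[[ln]])
    col <- sample(sp[[1]]:sp[[2]], 1)
    flip(items_path, ln, col)
    v <- verify_chain(ch)
    expect_false(v$valid)
    expect_false(is.na(v$first_bad_height))
    writeLines(orig_items, items_path)   # restore
  }
  expect_true(verify_chain(ch)$valid)

  blocks_path <- file.path(d, "blocks.log")
  orig_blocks <- readLines(blocks_path, warn = FALSE)
  for (trial in 1:10) {
    ln <- sample(length(orig_blocks), 1)
    col <- sample(nchar(orig_blocks[[ln]]), 1)
    flip(blocks_path, ln, col)
    expect_false(verify_chain(ch)$valid)
    writeLines(orig_blocks, blocks_path)
  }
  expect_true(verify_chain(ch)$valid)
})

test_that("permissions are on-chain, last-writer-wins, and enforced", {
  ch <- chain_create(new_chain_dir(), "c1", "owner")
  create_stream(ch, "s")
  expect_error(publish(ch, "s", "sequencer", data = "x"),
               "permission denied")
  expect_error(set_permission(ch, "mallory", "write", TRUE,
                              admin = "sequencer"), "permission denied")
  set_permission(ch, "sequencer", "write", TRUE)
  expect_silent(publish(ch, "s", "sequencer", data = "x"))
  set_permission(ch, "sequencer", "write", FALSE)
  expect_error(publish(ch, "s", "sequencer", data = "y"),
               "permission denied")
  set_permission(ch, "sequencer", "write", TRUE)
  expect_silent(publish(ch, "s", "sequencer", data = "z"))
  # every grant/revoke is an on-chain item in the reserved permissions stream
  grants <- list_stream_key_items(ch, "_permissions", "who=sequencer")
  expect_identical(nrow(grants), 3L)
  # read permission gates retrieval
  expect_error(list_stream_items(ch, "s", reader = "stranger"),
               "permission denied")
  set_permission(ch, "stranger", "read", TRUE)
  expect_silent(list_stream_items(ch, "s", reader = "stranger"))
})
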